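#' Construct a gene count table
#'
#' Bundles a gene x sample matrix of raw read counts with per-gene lengths
#' (bases). This is the entry point of the profiling stage.
#'
#' @param counts integer-like matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids).
#' @param gene_lengths named numeric vector of gene lengths (> 0), covering
#'   every row of `counts`.
#' @return object of class `gene_counts`: list with `counts`, `gene_lengths`.
#' @export
gene_count_table <- function(counts, gene_lengths) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  gl <- gene_lengths[rownames(counts)]
  if (anyNA(gl)) stop("gene_lengths missing for some genes in counts")
  if (any(gl <= 0)) stop("all gene lengths must be > 0")
  structure(list(counts = counts, gene_lengths = gl), class = "gene_counts")
}

#' @export
print.gene_counts <- function(x, ...) {
  cat("Gene count table:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples; median depth", stats::median(colSums(x$counts)), "\n")
  invisible(x)
}

#' Rarefy a gene count table to a common depth
#'
#' Per-sample subsampling without replacement (multivariate hypergeometric)
#' to exactly `target_depth` reads, removing sequencing-depth differences
#' between samples before normalisation. Samples whose total count is below
#' the target cannot be rarefied and are dropped with a warning.
#'
#' @param table a [gene_count_table()].
#' @param target_depth reads to keep per sample (> 0).
#' @param seed integer RNG seed.
#' @return a `gene_counts` object whose columns each sum to `target_depth`.
#' @export
downsize_counts <- function(table, target_depth, seed = 1L) {
  stopifnot(inherits(table, "gene_counts"))
  if (target_depth <= 0) stop("target_depth must be > 0")
  totals <- colSums(table$counts)
  keep <- totals >= target_depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below target depth dropped: ",
            paste(colnames(table$counts)[!keep], collapse = ", "))
  }
  cnt <- table$counts[, keep, drop = FALSE]
  out <- cnt
  withr_seed(seed)
  for (j in seq_len(ncol(cnt))) {
    tot <- totals[keep][j]
    if (tot == target_depth) next           # already at depth: keep as is
    out[, j] <- rhyper_multi(cnt[, j], target_depth)
  }
  gene_count_table(out, table$gene_lengths)
}

# internal: multivariate hypergeometric draw of m items from counts vector
# via sequential univariate hypergeometric (exact, O(#genes))
rhyper_multi <- function(counts, m) {
  out <- integer(length(counts))
  remaining <- sum(counts)
  todraw <- m
  for (i in seq_along(counts)) {
    if (todraw == 0L) break
    ci <- counts[i]
    if (ci == 0L) next
    k <- stats::rhyper(1L, ci, remaining - ci, todraw)
    out[i] <- k
    todraw <- todraw - k
    remaining <- remaining - ci
  }
  out
}

# internal: local set.seed that does not clobber an unset RNG state oddly
withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
}

#' Length-normalised gene frequency table
#'
#' Divides each gene's count by its length and renormalises within sample so
#' columns sum to one: the within-sample relative frequency of
#' length-corrected coverage (the FPKM-style scaling constant cancels).
#' All-zero samples stay all-zero.
#'
#' @param table a [gene_count_table()].
#' @return numeric matrix genes x samples, columns summing to 1 (or 0).
#' @export
normalize_frequencies <- function(table) {
  stopifnot(inherits(table, "gene_counts"))
  rate <- table$counts / table$gene_lengths
  tot <- colSums(rate)
  tot[tot == 0] <- 1  # keep all-zero columns all-zero
  sweep(rate, 2L, tot, "/")
}

#' MSP abundance from marker-gene frequencies
#'
#' The abundance of an MSP in a sample is the arithmetic mean of the
#' frequencies of its 100 marker genes, zeros included. If fewer than 10% of
#' the markers are detected (frequency > 0) in a sample, the MSP is
#' considered absent and its abundance set to 0.
#'
#' @param gene_freqs gene x sample frequency matrix
#'   (from [normalize_frequencies()]).
#' @param catalog an [msp_catalog()].
#' @param min_detected_frac detection rule threshold; an MSP is nulled when
#'   the detected-marker fraction is strictly below this (default 0.10).
#' @param include_zero_markers if `TRUE` (default) undetected markers enter
#'   the mean as zeros; `FALSE` averages detected markers only.
#' @return MSP x sample abundance matrix.
#' @export
msp_abundance <- function(gene_freqs, catalog, min_detected_frac = 0.10,
                          include_zero_markers = TRUE) {
  stopifnot(inherits(catalog, "msp_catalog"))
  mk <- catalog$genes[catalog$genes$is_marker, c("msp_id", "gene_id")]
  missing <- setdiff(mk$gene_id, rownames(gene_freqs))
  if (length(missing))
    stop("marker genes missing from frequency table, e.g. ", missing[1])
  f <- gene_freqs[mk$gene_id, , drop = FALSE]
  grp <- factor(mk$msp_id, levels = unique(mk$msp_id))
  n_mark <- as.vector(table(grp))
  sums <- rowsum(f, grp)                       # per-MSP marker sums
  ndet <- rowsum((f > 0) + 0, grp)             # per-MSP detected markers
  ab <- if (include_zero_markers) sums / n_mark else {
    d <- ndet; d[d == 0] <- 1; sums / d
  }
  ab[ndet < min_detected_frac * n_mark] <- 0   # strict <10% detection rule
  ab <- as.matrix(ab)
  rownames(ab) <- levels(grp)
  colnames(ab) <- colnames(gene_freqs)
  ab
}

#' Aggregate MSP abundances to a higher taxonomic rank
#'
#' Each taxon's abundance is the sum over its member MSP; per-sample totals
#' are conserved exactly. MSP unclassified at the requested rank are grouped
#' under a per-lineage placeholder (`"unclassified <last classified rank>"`)
#' so that no abundance is discarded.
#'
#' @param msp_abund MSP x sample matrix.
#' @param catalog an [msp_catalog()].
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`.
#' @return taxon x sample matrix.
#' @export
aggregate_taxa <- function(msp_abund, catalog, rank = "genus") {
  ranks <- c(domain = 1L, phylum = 2L, class = 3L, order = 4L,
             family = 5L, genus = 6L, species = 7L)
  if (!rank %in% names(ranks)[-1]) stop("unknown rank: ", rank)
  check_abundance(msp_abund)
  tax <- taxonomy_at_rank(catalog, rank)[rownames(msp_abund)]
  if (anyNA(tax)) stop("MSP missing from catalog: ",
                       rownames(msp_abund)[which(is.na(tax))[1]])
  grp <- factor(tax)
  out <- rowsum(msp_abund, grp)
  rownames(out) <- levels(grp)
  out
}

# internal: label of every MSP at a rank, with unclassified placeholder
taxonomy_at_rank <- function(catalog, rank) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus",
             "species")
  idx <- match(rank, ranks)
  meta <- catalog$msp
  labels <- vapply(strsplit(meta$taxonomy, ";", fixed = TRUE), function(tt) {
    tt <- sub("^[a-z]__", "", trimws(tt))
    if (length(tt) < idx || tt[idx] == "" || is.na(tt[idx])) {
      last <- if (any(tt != "")) tt[max(which(tt != ""))] else "root"
      paste("unclassified", last)
    } else tt[idx]
  }, character(1))
  stats::setNames(labels, meta$msp_id)
}

#' Per-sample species richness
#'
#' Number of features with non-null abundance in each sample.
#'
#' @param msp_abund feature x sample matrix.
#' @return named integer vector per sample.
#' @export
richness <- function(msp_abund) {
  check_abundance(msp_abund)
  colSums(msp_abund > 0)
}

#' Gram-positive to Gram-negative abundance ratio
#'
#' Per-sample ratio of summed abundances of Gram-positive species to
#' Gram-negative species, a proxy for the LPS-bearing fraction of the
#' community. MSP without a species-level Gram annotation inherit the
#' majority Gram status of the annotated species of their phylum; an
#' unresolvable MSP (no annotated phylum peer, or a tie) is an error, which
#' forces explicit catalog annotation.
#'
#' @param msp_abund MSP x sample matrix.
#' @param catalog an [msp_catalog()]; `gram` in `{"positive","negative",NA}`.
#' @return named numeric vector; `NA` with a warning where the
#'   Gram-negative total is 0.
#' @export
gram_ratio <- function(msp_abund, catalog) {
  check_abundance(msp_abund)
  gram <- resolve_gram(catalog)[rownames(msp_abund)]
  if (anyNA(gram)) stop("unresolved Gram status for ",
                        rownames(msp_abund)[which(is.na(gram))[1]])
  pos <- colSums(msp_abund[gram == "positive", , drop = FALSE])
  neg <- colSums(msp_abund[gram == "negative", , drop = FALSE])
  out <- pos / neg
  if (any(neg == 0)) {
    warning("Gram-negative total is 0 in ", sum(neg == 0),
            " sample(s); ratio undefined there")
    out[neg == 0] <- NA_real_
  }
  out
}

# internal: per-MSP Gram status with phylum-majority fallback
resolve_gram <- function(catalog) {
  meta <- catalog$msp
  gram <- meta$gram
  phyla <- taxonomy_at_rank(catalog, "phylum")[meta$msp_id]
  need <- which(is.na(gram) | !gram %in% c("positive", "negative"))
  for (i in need) {
    peers <- gram[phyla == phyla[i] & !is.na(gram) &
                    !startsWith(phyla, "unclassified")]
    peers <- peers[peers %in% c("positive", "negative")]
    if (length(peers) == 0L)
      stop("MSP ", meta$msp_id[i],
           ": no Gram annotation and no annotated phylum peer")
    tab <- table(peers)
    if (length(tab) == 2L && tab[1] == tab[2])
      stop("MSP ", meta$msp_id[i], ": Gram fallback tie within phylum ",
           phyla[i], "; annotate the catalog explicitly")
    gram[i] <- names(which.max(tab))
  }
  stats::setNames(gram, meta$msp_id)
}

#' Oral-to-total detected species ratio
#'
#' Fraction of detected species that originate from the oral catalog:
#' `n_oral / (n_oral + n_gut)` per sample, where a species present in both
#' catalogs is counted once, as oral. Returns 0 where nothing is detected.
#'
#' @param gut_abund,oral_abund species x sample matrices on matched samples
#'   (identical colnames, same order).
#' @return named numeric vector in `[0, 1]`.
#' @export
oral_gut_ratio <- function(gut_abund, oral_abund) {
  check_abundance(gut_abund, "gut abundance")
  check_abundance(oral_abund, "oral abundance")
  if (!identical(colnames(gut_abund), colnames(oral_abund)))
    stop("sample ids of the gut and oral tables do not match")
  shared <- intersect(rownames(gut_abund), rownames(oral_abund))
  gut_only <- gut_abund[!rownames(gut_abund) %in% shared, , drop = FALSE]
  n_oral <- colSums(oral_abund > 0)
  n_gut <- colSums(gut_only > 0)
  total <- n_oral + n_gut
  out <- ifelse(total == 0, 0, n_oral / total)
  stats::setNames(out, colnames(gut_abund))
}
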