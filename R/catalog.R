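#' Construct an MSP catalog
#'
#' An MSP (MetaGenomic Species) is a cluster of co-abundant genes
#' representing one microbial species' pangenome. The catalog records gene
#' membership (with marker and core flags) and per-MSP metadata: a
#' GTDB-style taxonomy string (`d__...;p__...;...;s__...`), Gram wall status
#' and habitat origin (gut or oral catalog).
#'
#' @param genes data.frame with columns `msp_id`, `gene_id`, `is_marker`
#'   (logical), `is_core` (logical). Marker genes must be core; each gene
#'   belongs to at most one MSP.
#' @param msp data.frame with columns `msp_id`, `taxonomy`, `gram`
#'   (`"positive"`, `"negative"` or `NA`), `origin` (`"gut"` or `"oral"`).
#' @param n_markers expected marker count per MSP (default 100); set to
#'   `NULL` to skip the check (small test fixtures).
#' @return object of class `msp_catalog`.
#' @export
msp_catalog <- function(genes, msp, n_markers = 100L) {
  need <- c("msp_id", "gene_id", "is_marker", "is_core")
  if (!all(need %in% names(genes))) stop("genes must have columns ",
                                         paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("a gene may belong to only one MSP")
  if (any(genes$is_marker & !genes$is_core))
    stop("marker genes must be core genes")
  if (!all(genes$msp_id %in% msp$msp_id)) stop("gene rows reference MSP absent from metadata")
  if (anyDuplicated(msp$msp_id)) stop("duplicated msp_id in metadata")
  if (!is.null(n_markers)) {
    nm <- tapply(genes$is_marker, genes$msp_id, sum)
    if (any(nm != n_markers))
      stop("every MSP must have exactly ", n_markers, " marker genes")
  }
  bad <- !is.na(msp$gram) & !msp$gram %in% c("positive", "negative")
  if (any(bad)) stop("gram must be 'positive', 'negative' or NA")
  if (!all(msp$origin %in% c("gut", "oral"))) stop("origin must be 'gut' or 'oral'")
  genes <- genes[, need]
  msp <- msp[, c("msp_id", "taxonomy", "gram", "origin")]
  rownames(genes) <- NULL
  rownames(msp) <- NULL
  structure(list(genes = genes, msp = msp), class = "msp_catalog")
}

#' @export
print.msp_catalog <- function(x, ...) {
  cat("MSP catalog:", nrow(x$msp), "MSP,", nrow(x$genes), "genes (",
      sum(x$genes$is_marker), "markers,", sum(x$genes$is_core), "core )\n")
  cat("  origin:", paste(names(table(x$msp$origin)),
                         table(x$msp$origin), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write an MSP catalog as TSV
#'
#' One row per gene with columns `msp_id`, `gene_id`, `is_marker`,
#' `is_core`, `taxonomy`, `gram`, `origin` (per-MSP metadata repeated on
#' each gene row; empty `gram` means unannotated).
#'
#' @param path file path.
#' @param catalog an [msp_catalog()].
#' @param n_markers passed to [msp_catalog()] on read.
#' @return `read_msp_catalog` returns an `msp_catalog`;
#'   `write_msp_catalog` returns `path` invisibly.
#' @export
read_msp_catalog <- function(path, n_markers = 100L) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  df$is_marker <- as.logical(df$is_marker)
  df$is_core <- as.logical(df$is_core)
  meta <- unique(df[, c("msp_id", "taxonomy", "gram", "origin")])
  msp_catalog(df[, c("msp_id", "gene_id", "is_marker", "is_core")],
              meta, n_markers = n_markers)
}

#' @rdname read_msp_catalog
#' @export
write_msp_catalog <- function(catalog, path) {
  df <- catalog$genes
  idx <- match(df$msp_id, catalog$msp$msp_id)
  df$taxonomy <- catalog$msp$taxonomy[idx]
  df$gram <- catalog$msp$gram[idx]
  df$origin <- catalog$msp$origin[idx]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a feature x sample matrix as TSV
#'
#' Features as rows (first column `feature_id`), samples as columns,
#' tab-separated with '.' decimal marks.
#'
#' @param path file path.
#' @param x numeric matrix with rownames and colnames.
#' @return `read_matrix_tsv` returns a numeric matrix; `write_matrix_tsv`
#'   returns `path` invisibly.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the cohort metadata table
#'
#' CSV with one row per sample: `sample_id`, `group` (one of `0`, `1`, `2`,
#' `D`; ordered, ordinal codes 0-3), covariates (`sex`, `age`, `bmi`,
#' `activity`, `smoking`) and any number of dietary variable columns.
#'
#' @param path file path.
#' @param cohort data.frame as above.
#' @return `read_cohort` returns the data.frame with `group` as an ordered
#'   factor; `write_cohort` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort(df)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: validate/coerce a cohort data.frame
as_cohort <- function(df) {
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("cohort table needs 'sample_id' and 'group' columns")
  if (anyNA(df$group)) stop("group labels must be non-missing")
  df$group <- factor(as.character(df$group), levels = c("0", "1", "2", "D"),
                     ordered = TRUE)
  if (anyNA(df$group)) stop("group labels must be in {0, 1, 2, D}")
  df
}

#' Ordinal codes of the risk groups
#'
#' Fixed encoding 0, 1, 2, D -> 0, 1, 2, 3 used by all rank statistics
#' (equal spacing; the rank-based tests are insensitive to the spacing).
#'
#' @param group factor/character of group labels.
#' @return integer vector of ordinal codes.
#' @export
group_ordinal <- function(group) {
  code <- c("0" = 0L, "1" = 1L, "2" = 2L, "D" = 3L)
  out <- code[as.character(group)]
  if (anyNA(out)) stop("unknown group label")
  unname(out)
}
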