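#' Module definitions and the gene-to-ortholog map
#'
#' A functional module (KEGG-module-like, gut metabolic module, gut-brain
#' module) is a set of ortholog identifiers; alternative component sets
#' (OR-paths) are supported, with module completeness taken as the maximum
#' over alternatives. A CAZyme family is the degenerate single-component
#' case: any member gene makes an MSP a carrier.
#'
#' `module_defs()` validates a list `module_id -> list(of character
#' vectors)`; the TSV dialect is one row per alternative:
#' `module_id <tab> alternative <tab> comma-separated orthologs`.
#'
#' @param x named list; each element a list of non-empty character vectors.
#' @param path file path.
#' @param modules validated module definition list.
#' @return `module_defs`/`read_module_defs` return the validated list;
#'   `write_module_defs` returns `path` invisibly.
#' @export
module_defs <- function(x) {
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("modules must be a uniquely named list")
  for (m in names(x)) {
    if (!is.list(x[[m]])) x[[m]] <- list(x[[m]])
    if (any(lengths(x[[m]]) == 0L))
      stop("module ", m, " has an empty component set")
  }
  x
}

#' @rdname module_defs
#' @export
read_module_defs <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  out <- lapply(split(df, df$module_id), function(d)
    lapply(d$orthologs[order(d$alternative)],
           function(s) strsplit(s, ",", fixed = TRUE)[[1]]))
  module_defs(out[unique(df$module_id)])
}

#' @rdname module_defs
#' @export
write_module_defs <- function(modules, path) {
  rows <- do.call(rbind, lapply(names(modules), function(m) {
    alts <- modules[[m]]
    data.frame(module_id = m, alternative = seq_along(alts),
               orthologs = vapply(alts, paste, character(1), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# internal: ortholog set of selected genes of one MSP
orthologs_of <- function(gene_ids, funcmap) {
  unique(funcmap$ortholog[funcmap$gene_id %in% gene_ids])
}

#' Baseline (core-gene) module presence per MSP
#'
#' A module is present in an MSP when at least 90% of its components are
#' covered by orthologs of the MSP's core genes; with alternative component
#' sets, the best-covered alternative counts. This baseline is
#' sample-independent; [refine_presence_per_sample()] adds detected
#' accessory genes.
#'
#' @param catalog an [msp_catalog()].
#' @param funcmap data.frame `gene_id`, `ortholog` (best hit; at most one
#'   ortholog per gene).
#' @param modules a [module_defs()] list.
#' @param min_completeness presence threshold (default 0.9, inclusive).
#' @return object of class `module_presence`: list with `completeness` and
#'   `present` (MSP x module matrices), `min_completeness`.
#' @export
core_module_presence <- function(catalog, funcmap, modules,
                                 min_completeness = 0.9) {
  modules <- module_defs(modules)
  if (anyDuplicated(funcmap$gene_id))
    stop("funcmap must map each gene to at most one ortholog")
  msp_ids <- catalog$msp$msp_id
  comp <- matrix(0, length(msp_ids), length(modules),
                 dimnames = list(msp_ids, names(modules)))
  core_by_msp <- split(catalog$genes$gene_id[catalog$genes$is_core],
                       catalog$genes$msp_id[catalog$genes$is_core])
  for (i in msp_ids) {
    orth <- orthologs_of(core_by_msp[[i]], funcmap)
    comp[i, ] <- vapply(modules, function(alts)
      max(vapply(alts, function(a) mean(a %in% orth), numeric(1))),
      numeric(1))
  }
  structure(list(completeness = comp, present = comp >= min_completeness,
                 min_completeness = min_completeness),
            class = "module_presence")
}

#' Per-sample refinement of module presence with accessory genes
#'
#' Recomputes completeness with core genes plus the accessory genes
#' detected (frequency > 0) in each sample; the 90% presence rule is
#' unchanged. Refinement only applies where the MSP itself is detected in
#' the sample (non-null abundance after the 10%-marker rule); an undetected
#' MSP carries nothing there.
#'
#' @param baseline result of [core_module_presence()].
#' @param catalog,funcmap,modules as in [core_module_presence()].
#' @param gene_freqs gene x sample frequency matrix
#'   ([normalize_frequencies()]); genes absent from it count as undetected.
#' @param msp_abund MSP x sample abundance matrix gating MSP detection.
#' @return object of class `module_presence_refined`: list with `present`
#'   (MSP x module x sample logical array) and `completeness` (same shape).
#' @export
refine_presence_per_sample <- function(baseline, catalog, funcmap, modules,
                                       gene_freqs, msp_abund) {
  stopifnot(inherits(baseline, "module_presence"))
  modules <- module_defs(modules)
  check_abundance(msp_abund)
  msp_ids <- rownames(baseline$completeness)
  mod_ids <- colnames(baseline$completeness)
  samples <- colnames(msp_abund)
  if (!identical(sort(msp_ids), sort(rownames(msp_abund))))
    stop("baseline and abundance matrix must cover the same MSP")
  msp_abund <- msp_abund[msp_ids, , drop = FALSE]

  pres <- array(FALSE, c(length(msp_ids), length(mod_ids), length(samples)),
                dimnames = list(msp_ids, mod_ids, samples))
  compl <- array(0, dim(pres), dimnames = dimnames(pres))

  genes <- catalog$genes
  acc <- genes[!genes$is_core, c("msp_id", "gene_id")]
  acc <- acc[acc$gene_id %in% funcmap$gene_id, ]
  acc$ortholog <- funcmap$ortholog[match(acc$gene_id, funcmap$gene_id)]

  core_orth <- lapply(split(genes$gene_id[genes$is_core],
                            genes$msp_id[genes$is_core]),
                      orthologs_of, funcmap = funcmap)
  acc_by_msp <- split(acc, acc$msp_id)

  # only (msp, module, alternative) triples that accessory genes could flip
  # need per-sample work; everything else is decided at baseline
  for (i in msp_ids) {
    det_i <- msp_abund[i, ] > 0
    compl[i, , ] <- baseline$completeness[i, ]
    pres[i, , ] <- outer(baseline$present[i, ], det_i, "&")
    compl[i, , !det_i] <- 0
    ai <- acc_by_msp[[i]]
    if (is.null(ai) || !any(det_i)) next
    corth <- core_orth[[i]]
    # detection matrix of this MSP's accessory genes across samples
    have <- ai$gene_id %in% rownames(gene_freqs)
    detg <- matrix(FALSE, nrow(ai), length(samples))
    detg[have, ] <- gene_freqs[ai$gene_id[have], samples, drop = FALSE] > 0
    for (m in mod_ids) {
      if (baseline$present[i, m]) next       # already present wherever detected
      for (alt in modules[[m]]) {
        miss <- setdiff(alt, corth)
        if (length(miss) == 0L) next
        gain_rows <- which(ai$ortholog %in% miss)
        if (length(gain_rows) == 0L) next
        # per-sample count of distinct missing components recovered
        rec <- vapply(seq_along(samples), function(s) {
          if (!det_i[s]) return(0L)
          length(unique(ai$ortholog[gain_rows][detg[gain_rows, s]]))
        }, integer(1))
        cc <- (length(alt) - length(miss) + rec) / length(alt)
        upd <- cc > compl[i, m, ] & det_i
        compl[i, m, upd] <- cc[upd]
        pres[i, m, ] <- pres[i, m, ] |
          (det_i & cc >= baseline$min_completeness)
      }
    }
  }
  structure(list(present = pres, completeness = compl,
                 min_completeness = baseline$min_completeness),
            class = "module_presence_refined")
}

#' Module potential per sample
#'
#' The potential of a module in a sample is the summed abundance of all MSP
#' carrying that module in that sample (per-sample refined presence).
#'
#' @param presence result of [refine_presence_per_sample()].
#' @param msp_abund MSP x sample abundance matrix.
#' @return module x sample abundance matrix.
#' @export
module_abundance <- function(presence, msp_abund) {
  stopifnot(inherits(presence, "module_presence_refined"))
  check_abundance(msp_abund)
  msp_ids <- dimnames(presence$present)[[1]]
  samples <- dimnames(presence$present)[[3]]
  msp_abund <- msp_abund[msp_ids, samples, drop = FALSE]
  mod_ids <- dimnames(presence$present)[[2]]
  out <- matrix(0, length(mod_ids), length(samples),
                dimnames = list(mod_ids, samples))
  for (s in seq_along(samples)) {
    out[, s] <- crossprod(presence$present[, , s] + 0, msp_abund[, s])
  }
  out
}

#' CAZyme families as single-component modules
#'
#' Builds degenerate module definitions (one family = one "component" per
#' family id) from a gene-to-family map so CAZyme abundance runs through
#' the same presence/potential machinery as KEGG-style modules.
#'
#' @param family_map data.frame `gene_id`, `family`.
#' @return a [module_defs()] list keyed by family id.
#' @export
cazyme_defs <- function(family_map) {
  fams <- sort(unique(family_map$family))
  module_defs(stats::setNames(lapply(fams, function(f) list(f)), fams))
}
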