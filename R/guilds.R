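#' Centered log-ratio transform
#'
#' Per-sample CLR with a pseudocount of half the smallest non-zero value in
#' that sample (standard practice for compositional microbiome data).
#'
#' @param abund feature x sample non-negative matrix.
#' @return feature x sample CLR matrix.
#' @export
clr_transform <- function(abund) {
  check_abundance(abund)
  out <- abund
  for (j in seq_len(ncol(abund))) {
    v <- abund[, j]
    nz <- v[v > 0]
    if (length(nz) == 0L) stop("all-zero sample in CLR transform: ",
                               colnames(abund)[j])
    v <- v + min(nz) / 2
    lv <- log(v)
    out[, j] <- lv - mean(lv)
  }
  out
}

#' Stability-selected co-abundance network for one group
#'
#' Simplified single-method stand-in for consensus stability selection:
#' species passing a within-group prevalence filter (50%) are
#' CLR-transformed; on each of `n_resamples` subsamples (63% of the group's
#' samples, without replacement) a sparse association graph is built by
#' keeping the strongest absolute Pearson correlations of the CLR profiles,
#' at a graph density tuned (StARS-style) so the mean edge-selection
#' stability is approximately `stability_target` (0.9). Edge frequency is
#' the fraction of resamples containing the edge; edges at frequency >=
#' `edge_threshold` (70%) are retained.
#'
#' @param abund MSP x sample matrix (all samples).
#' @param group_samples sample ids (or logical/integer index) of the group.
#' @param min_prevalence within-group prevalence filter (default 0.5).
#' @param n_resamples subsamples (default 100).
#' @param edge_threshold retention frequency (default 0.7).
#' @param stability_target mean edge-selection stability to tune the
#'   density to (default 0.9).
#' @param seed RNG seed.
#' @return object of class `stability_network`: `nodes`, `edges`
#'   (data.frame node_i, node_j, frequency, retained), `density`,
#'   `stability`.
#' @export
infer_network <- function(abund, group_samples, min_prevalence = 0.5,
                          n_resamples = 100L, edge_threshold = 0.7,
                          stability_target = 0.9, seed = 1L) {
  check_abundance(abund)
  sub <- abund[, group_samples, drop = FALSE]
  n <- ncol(sub)
  if (n < 20L) stop("group too small for network inference (need >= 20)")
  keep <- rowMeans(sub > 0) >= min_prevalence
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) < 3L) stop("fewer than 3 nodes pass the prevalence filter")
  if (any(rowSums(sub) == 0)) stop("all-zero node after filter")
  x <- clr_transform(sub)
  p <- nrow(x)
  n_pairs <- p * (p - 1L) / 2L
  m_sub <- max(20L, floor(0.63 * n))

  set.seed(as.integer(seed))
  # |correlation| rank matrix per resample, flattened lower triangles
  lower <- which(lower.tri(matrix(0, p, p)))
  absr <- matrix(0, n_pairs, n_resamples)
  for (b in seq_len(n_resamples)) {
    cols <- sample.int(n, m_sub)
    cr <- suppressWarnings(stats::cor(t(x[, cols, drop = FALSE])))
    cr[is.na(cr)] <- 0
    absr[, b] <- abs(cr[lower])
  }

  # tune graph density: keep the top-m pairs per resample, choose the
  # largest m whose mean edge stability (1 - 2 mean f(1-f)) still meets
  # the target
  grid <- unique(pmax(1L, floor(n_pairs * c(0.005, 0.01, 0.02, 0.03, 0.05,
                                            0.08, 0.12, 0.2))))
  sel_freq_at <- function(m) {
    sel <- apply(absr, 2L, function(v)
      v >= sort(v, decreasing = TRUE)[m])
    rowMeans(sel)
  }
  best_m <- grid[1]; best_freq <- sel_freq_at(grid[1])
  best_stab <- 1 - 2 * mean(best_freq * (1 - best_freq))
  for (m in grid[-1]) {
    fr <- sel_freq_at(m)
    st <- 1 - 2 * mean(fr * (1 - fr))
    if (st >= stability_target) { best_m <- m; best_freq <- fr
      best_stab <- st }
  }

  ij <- which(lower.tri(matrix(0, p, p)), arr.ind = TRUE)
  edges <- data.frame(node_i = rownames(x)[ij[, 2]],
                      node_j = rownames(x)[ij[, 1]],
                      frequency = best_freq,
                      retained = best_freq >= edge_threshold,
                      stringsAsFactors = FALSE)
  structure(list(nodes = rownames(x), edges = edges,
                 density = best_m / n_pairs, stability = best_stab,
                 n_resamples = n_resamples,
                 edge_threshold = edge_threshold),
            class = "stability_network")
}

#' @export
print.stability_network <- function(x, ...) {
  cat("Stability network:", length(x$nodes), "nodes,",
      sum(x$edges$retained), "retained edges (freq >=", x$edge_threshold,
      "), tuned density", signif(x$density, 3), ", stability",
      signif(x$stability, 3), "\n")
  invisible(x)
}

#' Cluster a stability network into guilds
#'
#' Communities of the retained-edge graph by greedy modularity
#' optimisation; vertices are ordered by sorted node id so ties break
#' deterministically. Nodes without retained edges become singletons.
#'
#' @param net a `stability_network`.
#' @return object of class `guild_partition`: `membership` (named integer
#'   vector over all nodes), `guilds` (list of node-id vectors).
#' @export
cluster_guilds <- function(net) {
  stopifnot(inherits(net, "stability_network"))
  ed <- net$edges[net$edges$retained, c("node_i", "node_j")]
  nodes <- sort(net$nodes)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(ed)) {
    g <- igraph::add_edges(g, rbind(match(ed$node_i, nodes),
                                    match(ed$node_j, nodes)))
  }
  memb <- if (igraph::ecount(g) == 0L) seq_along(nodes)
    else {
      cl <- igraph::cluster_fast_greedy(g)
      comp <- igraph::components(g)$membership
      # modularity tie-break: when splitting connected components buys no
      # modularity, keep whole components as guilds (deterministic)
      if (igraph::modularity(g, comp) >= igraph::modularity(cl))
        comp else igraph::membership(cl)
    }
  memb <- stats::setNames(as.integer(memb), nodes)
  guilds <- split(names(memb), memb)
  names(guilds) <- paste0("guild_", seq_along(guilds))
  structure(list(membership = memb, guilds = unname(guilds)),
            class = "guild_partition")
}

#' @export
print.guild_partition <- function(x, ...) {
  sizes <- lengths(x$guilds)
  cat("Guild partition:", length(x$guilds), "guilds; sizes:",
      paste(sort(sizes, decreasing = TRUE), collapse = " "), "\n")
  invisible(x)
}

#' Track focal taxa across per-group guild partitions
#'
#' For each group, reports how many of the focal taxa share a single guild
#' (the maximum over guilds), the focal co-membership matrix, and which
#' focal taxa are absent from that group's network (below the prevalence
#' filter).
#'
#' @param partitions named list of `guild_partition` per group (in group
#'   order).
#' @param focal_taxa character vector of focal taxon ids.
#' @return data.frame with one row per group: `group`,
#'   `n_focal_present`, `n_focal_in_largest_shared_guild`; co-membership
#'   matrices in `attr(, "co_membership")`.
#' @export
track_taxa_across_groups <- function(partitions, focal_taxa) {
  present_any <- any(vapply(partitions, function(p)
    any(focal_taxa %in% names(p$membership)), logical(1)))
  if (!present_any) stop("no focal taxon present in any partition")
  co <- list()
  rows <- lapply(names(partitions), function(gname) {
    p <- partitions[[gname]]
    present <- intersect(focal_taxa, names(p$membership))
    best <- if (length(present)) max(table(p$membership[present])) else 0L
    cm <- matrix(FALSE, length(focal_taxa), length(focal_taxa),
                 dimnames = list(focal_taxa, focal_taxa))
    for (a in present) for (b in present)
      cm[a, b] <- p$membership[a] == p$membership[b]
    co[[gname]] <<- cm
    data.frame(group = gname, n_focal_present = length(present),
               n_focal_in_largest_shared_guild = as.integer(best),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "co_membership") <- co
  out
}
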