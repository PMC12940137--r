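#' Genus-level integer counts for enterotyping
#'
#' The Dirichlet multinomial mixture operates on integer counts; relative
#' genus abundances are rescaled to a common depth and rounded.
#'
#' @param genus_abund genus x sample relative abundance matrix
#'   (from [aggregate_taxa()]).
#' @param scale common depth (default 1e4).
#' @return genus x sample integer matrix.
#' @export
genus_count_table <- function(genus_abund, scale = 1e4) {
  check_abundance(genus_abund)
  tot <- colSums(genus_abund)
  tot[tot == 0] <- 1
  round(sweep(genus_abund, 2L, tot, "/") * scale)
}

# internal: per-sample Dirichlet-multinomial log-likelihood (multinomial
# coefficient dropped; constant across components). x: n x J, alpha: J
dm_loglik_rows <- function(x, alpha) {
  A <- sum(alpha)
  n_i <- rowSums(x)
  lgamma(A) - lgamma(A + n_i) +
    rowSums(lgamma(sweep(x, 2L, alpha, "+"))) - sum(lgamma(alpha))
}

# internal: Minka fixed-point update of alpha for weighted samples
dm_alpha_update <- function(x, alpha, w, n_inner = 5L) {
  n_i <- rowSums(x)
  for (it in seq_len(n_inner)) {
    A <- sum(alpha)
    denom <- sum(w * (digamma(n_i + A) - digamma(A)))
    if (denom <= 0) break
    num <- colSums(w * (digamma(sweep(x, 2L, alpha, "+")) -
                          matrix(digamma(alpha), nrow(x), length(alpha),
                                 byrow = TRUE)))
    alpha <- pmax(alpha * num / denom, 1e-8)
  }
  alpha
}

#' Fit a Dirichlet multinomial mixture by EM
#'
#' Mixture of K Dirichlet-multinomial components over genus counts:
#' responsibilities from component DM likelihoods (E-step), mixture weights
#' and per-component Dirichlet parameters by Minka's fixed-point iteration
#' on the weighted DM log-likelihood (M-step). Convergence when the
#' log-likelihood improves by less than `tol` (default 1e-6) or after
#' `max_iter` iterations; the log-likelihood is asserted non-decreasing at
#' every iteration. The reported `fit_score` is the Laplace-approximated
#' negative log model evidence (BIC in `fit_score_bic` as an alternative).
#'
#' @param genus_counts genus x sample integer count matrix.
#' @param K number of mixture components (>= 1).
#' @param seed RNG seed (initialisation is a random hard partition).
#' @param max_iter,tol EM stopping rule.
#' @return object of class `dmm_model`: `K`, `alphas` (J x K), `weights`,
#'   `posteriors` (sample x K), `loglik`, `fit_score`, `fit_score_bic`,
#'   `genera`, `samples`.
#' @export
fit_dmm <- function(genus_counts, K, seed = 1L, max_iter = 1000L,
                    tol = 1e-6) {
  if (K < 1) stop("K must be >= 1")
  x <- t(genus_counts)                       # samples x genera
  if (any(x < 0) || max(abs(x - round(x))) > 1e-8)
    stop("genus_counts must be non-negative integers")
  x <- round(x)
  if (any(rowSums(x) == 0)) stop("empty samples are not allowed")
  n <- nrow(x); J <- ncol(x)
  set.seed(as.integer(seed))

  # init: random hard partition, moment-matched alphas
  grp <- sample(rep_len(seq_len(K), n))
  alphas <- sapply(seq_len(K), function(k) {
    p <- colSums(x[grp == k, , drop = FALSE]) + 0.5
    10 * p / sum(p)
  })
  alphas <- matrix(alphas, J, K)
  weights <- rep(1 / K, K)

  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    logp <- sapply(seq_len(K), function(k)
      log(weights[k]) + dm_loglik_rows(x, alphas[, k]))
    logp <- matrix(logp, n, K)
    mx <- apply(logp, 1L, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    ll <- sum(lse)
    stopifnot(ll >= ll_old - 1e-6)           # EM monotonicity guard
    r <- exp(logp - lse)
    if (ll - ll_old < tol && iter > 1L) break
    ll_old <- ll
    weights <- pmax(colMeans(r), 1e-12)
    weights <- weights / sum(weights)
    for (k in seq_len(K))
      alphas[, k] <- dm_alpha_update(x, alphas[, k], r[, k])
  }

  p_free <- K * J + (K - 1)
  laplace <- ll + 0.5 * p_free * log(2 * pi) - 0.5 * neg_hessian_logdet(
    x, alphas, r, fallback = p_free * log(n))
  structure(list(K = K, alphas = alphas, weights = weights, posteriors = r,
                 loglik = ll, fit_score = -laplace,
                 fit_score_bic = -ll + 0.5 * p_free * log(n),
                 genera = colnames(x), samples = rownames(x)),
            class = "dmm_model")
}

# internal: sum over components of log det(-H_k) for the DM alphas
# (diagonal + rank-one structure; matrix determinant lemma). Falls back to
# a BIC-style penalty if the curvature is not negative definite.
neg_hessian_logdet <- function(x, alphas, r, fallback) {
  n_i <- rowSums(x)
  total <- 0
  for (k in seq_len(ncol(alphas))) {
    a <- alphas[, k]; A <- sum(a); w <- r[, k]
    d <- -colSums(w * (trigamma(sweep(x, 2L, a, "+")) -
                         matrix(trigamma(a), nrow(x), length(a),
                                byrow = TRUE)))
    b <- sum(w * (trigamma(A) - trigamma(n_i + A)))
    d <- pmax(d, 1e-8)
    lemma <- 1 - b * sum(1 / d)
    if (lemma <= 0) return(fallback)
    total <- total + sum(log(d)) + log(lemma)
  }
  total
}

#' @export
print.dmm_model <- function(x, ...) {
  cat("Dirichlet multinomial mixture: K =", x$K, "| logLik",
      format(x$loglik, digits = 8), "| fit score",
      format(x$fit_score, digits = 8), "\n")
  invisible(x)
}

#' Select the number of enterotype components
#'
#' Fits each K in `K_range` with multiple random restarts and returns the
#' model minimising the Laplace fit score; exact ties resolve toward the
#' smaller K (parsimony).
#'
#' @param genus_counts genus x sample integer counts.
#' @param K_range candidate component counts (default 1:6).
#' @param seed base seed; restart seeds are derived from it.
#' @param n_restarts random restarts per K (default 5).
#' @param criterion `"bic"` (default; well calibrated for small genus
#'   panels) or `"laplace"`.
#' @return the winning `dmm_model` (with `selection` attribute: a
#'   data.frame of K, loglik, score).
#' @export
select_k <- function(genus_counts, K_range = 1:6, seed = 1L,
                     n_restarts = 5L, criterion = c("bic", "laplace")) {
  criterion <- match.arg(criterion)
  if (length(K_range) == 0L) stop("K_range must be non-empty")
  best <- NULL
  trace <- NULL
  for (K in sort(K_range)) {
    bk <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- fit_dmm(genus_counts, K,
                     seed = as.integer(seed) + 1000L * K + r)
      if (is.null(bk) || fit$loglik > bk$loglik) bk <- fit
    }
    sc <- if (criterion == "bic") bk$fit_score_bic else bk$fit_score
    trace <- rbind(trace, data.frame(K = K, loglik = bk$loglik, score = sc))
    if (is.null(best) || sc < best_score) { best <- bk; best_score <- sc }
  }
  attr(best, "selection") <- trace
  best
}

#' Name enterotype components and assign samples
#'
#' Components are named from their expected genus composition
#' (`alpha / sum(alpha)`): a Prevotella-dominated component is `EtP`;
#' Bacteroides-dominated components are `EtB1`, `EtB2`, ... ordered by
#' decreasing Bacteroides mean share; any other component is named from its
#' dominant phylum (`EtF` for Bacillota/Firmicutes). Samples take the name
#' of their maximum-posterior component.
#'
#' @param model a fitted `dmm_model`.
#' @param genus_phylum named character vector mapping genus to phylum (or
#'   an [msp_catalog()], from which the map is derived).
#' @return object of class `enterotype_assignment`: data.frame `sample`,
#'   `label`, `component`, `posterior`; component names in
#'   `attr(, "component_names")`.
#' @export
name_enterotypes <- function(model, genus_phylum) {
  stopifnot(inherits(model, "dmm_model"))
  if (inherits(genus_phylum, "msp_catalog")) {
    g <- taxonomy_at_rank(genus_phylum, "genus")
    p <- taxonomy_at_rank(genus_phylum, "phylum")
    genus_phylum <- tapply(p, g, function(v) v[1])
  }
  means <- sweep(model$alphas, 2L, colSums(model$alphas), "/")
  rownames(means) <- model$genera
  top <- model$genera[apply(means, 2L, which.max)]
  nm <- character(model$K)
  bact <- which(top == "Bacteroides")
  if (length(bact)) {
    ordb <- bact[order(means["Bacteroides", bact], decreasing = TRUE)]
    nm[ordb] <- paste0("EtB", seq_along(ordb))
  }
  for (k in seq_len(model$K)) {
    if (nm[k] != "") next
    if (top[k] == "Prevotella") { nm[k] <- "EtP"; next }
    ph <- genus_phylum[model$genera]
    ph[is.na(ph)] <- "unknown"
    ph_share <- tapply(means[, k], ph, sum)
    dom <- names(which.max(ph_share))
    nm[k] <- if (dom %in% c("Bacillota", "Firmicutes")) "EtF"
      else paste0("Et", substr(dom, 1, 2))
  }
  dup <- duplicated(nm) | duplicated(nm, fromLast = TRUE)
  if (any(dup)) nm[dup] <- paste0(nm[dup], seq_len(sum(dup)))
  comp <- apply(model$posteriors, 1L, which.max)
  out <- data.frame(sample = model$samples, label = nm[comp],
                    component = comp,
                    posterior = model$posteriors[cbind(seq_along(comp),
                                                       comp)],
                    stringsAsFactors = FALSE)
  structure(out, class = c("enterotype_assignment", "data.frame"),
            component_names = nm)
}

#' Test the enterotype-by-group distribution
#'
#' Fisher exact test on the enterotype x group contingency table; for
#' tables larger than 2x2 the p-value is estimated by Monte-Carlo
#' simulation with at least 1e5 draws (seeded). Per-enterotype pairwise
#' 2x2 tests (this enterotype vs the rest, group a vs group b) are reported
#' with Benjamini-Hochberg correction.
#'
#' @param assignment an `enterotype_assignment` (or factor of labels).
#' @param groups group labels aligned with the assignment rows.
#' @param seed RNG seed for the Monte-Carlo p-value.
#' @param B Monte-Carlo draws (default 1e5).
#' @return list with `p`, `table`, `pairwise` (data.frame label, group_a,
#'   group_b, p, q).
#' @export
enterotype_group_test <- function(assignment, groups, seed = 1L, B = 1e5) {
  labels <- if (inherits(assignment, "enterotype_assignment"))
    assignment$label else as.character(assignment)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  tab <- table(label = labels, group = groups)
  if (nrow(tab) < 2L || ncol(tab) < 2L || any(rowSums(tab) == 0) ||
        any(colSums(tab) == 0))
    stop("degenerate contingency table (a margin of zeros)")
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    p <- stats::fisher.test(tab)$p.value
  } else {
    set.seed(as.integer(seed))
    p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value
  }
  pw <- list(); i <- 0L
  glev <- levels(groups)
  for (lab in rownames(tab)) for (a in seq_along(glev)) {
    for (b in seq_along(glev)) {
      if (a >= b) next
      t2 <- rbind(c(tab[lab, a], sum(tab[, a]) - tab[lab, a]),
                  c(tab[lab, b], sum(tab[, b]) - tab[lab, b]))
      i <- i + 1L
      pw[[i]] <- data.frame(label = lab, group_a = glev[a],
                            group_b = glev[b],
                            p = stats::fisher.test(t2)$p.value,
                            stringsAsFactors = FALSE)
    }
  }
  pw <- do.call(rbind, pw)
  pw$q <- bh_adjust(pw$p)
  list(p = p, table = tab, pairwise = pw)
}
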