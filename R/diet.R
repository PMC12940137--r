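#' Dietary patterns by varimax-rotated principal components
#'
#' Principal-component factor analysis of the food-group intake matrix:
#' columns are z-standardised, loadings are taken as eigenvectors scaled by
#' the square root of their eigenvalues, the retained factors are rotated
#' with normalised orthogonal varimax, and participant scores are computed
#' by the regression method. Loadings with `|loading| >= 0.30` are flagged
#' significant; each pattern is named after its top-loading food groups.
#'
#' @param food_intakes sample x food-group numeric matrix or data.frame
#'   (g/day; any units, columns are standardised).
#' @param n_factors factors to retain (default 3).
#' @param loading_threshold significance flag threshold (default 0.30).
#' @param score_method `"regression"` (default) or `"bartlett"`.
#' @param n_name_groups food groups joined into each pattern name.
#' @return object of class `dietary_patterns`: `loadings` (food x factor),
#'   `scores` (sample x factor), `significant_loadings` (logical mask),
#'   `pattern_names`, `eigenvalues`, `communalities`.
#' @export
dietary_patterns <- function(food_intakes, n_factors = 3L,
                             loading_threshold = 0.30,
                             score_method = c("regression", "bartlett"),
                             n_name_groups = 3L) {
  score_method <- match.arg(score_method)
  x <- as.matrix(food_intakes)
  if (!is.numeric(x)) stop("food_intakes must be numeric")
  if (anyNA(x)) stop("food_intakes must be complete")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) stop("constant food-group column(s): ",
                          paste(colnames(x)[sds == 0], collapse = ", "))
  if (n_factors > min(dim(x)) - 1L || n_factors < 1L)
    stop("n_factors out of range")
  z <- scale(x)
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  L <- eig$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(n_factors)]), n_factors)
  rownames(L) <- colnames(x)
  rot <- if (n_factors > 1L) stats::varimax(L, normalize = TRUE)$loadings
    else L
  L <- matrix(rot, nrow(L), n_factors,
              dimnames = list(colnames(x), paste0("pattern", 1:n_factors)))
  # fix signs so each pattern's largest loading is positive
  flip <- apply(L, 2L, function(v) sign(v[which.max(abs(v))]))
  L <- sweep(L, 2L, flip, "*")
  scores <- switch(score_method,
    regression = z %*% solve(R, L),
    bartlett = {
      u2 <- pmax(1 - rowSums(L^2), 1e-6)       # uniquenesses
      Li <- L / u2
      z %*% Li %*% solve(crossprod(L, Li))
    })
  colnames(scores) <- colnames(L)
  rownames(scores) <- rownames(x)
  sig <- abs(L) >= loading_threshold
  nms <- apply(L, 2L, function(v)
    paste(names(sort(abs(v), decreasing = TRUE))[seq_len(n_name_groups)],
          collapse = "+"))
  structure(list(loadings = L, scores = scores, significant_loadings = sig,
                 pattern_names = nms, eigenvalues = eig$values,
                 communalities = rowSums(L^2)),
            class = "dietary_patterns")
}

#' @export
print.dietary_patterns <- function(x, ...) {
  cat("Dietary patterns:", ncol(x$loadings), "varimax-rotated factors\n")
  for (k in seq_len(ncol(x$loadings)))
    cat("  ", colnames(x$loadings)[k], ": ", x$pattern_names[k], "\n",
        sep = "")
  invisible(x)
}

#' Gradient screen over dietary variables
#'
#' Applies the dual-window gradient criterion of
#' [detect_gradient_markers()] to dietary variables (food groups,
#' nutrients, pattern scores). Constant variables are reported with `NA`
#' statistics and never selected.
#'
#' @param diet_vars sample x variable matrix/data.frame, rows aligned with
#'   `cohort`.
#' @param cohort cohort table.
#' @param ... passed to [detect_gradient_markers()].
#' @return a `gradient_screen` data.frame (one row per dietary variable).
#' @export
diet_group_tests <- function(diet_vars, cohort, ...) {
  x <- t(as.matrix(diet_vars))
  colnames(x) <- cohort$sample_id
  # the screen's rank statistics are location-free; shift to >= 0 to
  # satisfy the abundance-matrix contract
  x <- sweep(x, 1L, pmin(0, apply(x, 1L, min)), "-")
  detect_gradient_markers(x, cohort, ...)
}

#' LMG relative importance decomposition
#'
#' Decomposes a linear model's R-squared over predictors (or predictor
#' groups, e.g. the dummy block of a categorical factor) by averaging each
#' predictor's incremental R-squared over all orderings of model entry.
#' Exact computation enumerates all `2^p` predictor subsets with Shapley
#' weights for `p <= max_exact` groups; beyond that, a seeded Monte-Carlo
#' average over random orderings is used. Importances are non-negative for
#' orthogonal designs and always sum to the full-model R-squared.
#'
#' @param design numeric predictor matrix (n x columns), or data.frame.
#' @param outcome numeric response.
#' @param groups optional named list of column index/name vectors defining
#'   predictor groups (default: each column its own group).
#' @param max_exact largest group count for exact enumeration (default 12).
#' @param n_orderings Monte-Carlo orderings when `p > max_exact`.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return named numeric vector of importances (sums to the model
#'   R-squared); full R-squared in `attr(, "r_squared")`.
#' @export
lmg_importance <- function(design, outcome, groups = NULL, max_exact = 12L,
                           n_orderings = 2000L, seed = 1L) {
  X <- as.matrix(design)
  if (!is.numeric(X)) stop("design must be numeric (dummy-code factors)")
  y <- as.numeric(outcome)
  stopifnot(nrow(X) == length(y))
  if (is.null(groups)) {
    groups <- as.list(seq_len(ncol(X)))
    names(groups) <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  }
  groups <- lapply(groups, function(g)
    if (is.character(g)) match(g, colnames(X)) else as.integer(g))
  p <- length(groups)
  yc <- y - mean(y)
  tss <- sum(yc^2)
  if (tss == 0) stop("outcome is constant")

  r2_of <- function(cols) {
    if (length(cols) == 0L) return(0)
    Xs <- cbind(1, X[, cols, drop = FALSE])
    fit <- tryCatch(stats::lm.fit(Xs, y), error = function(e) NULL)
    if (is.null(fit)) {                     # singular: pseudo-inverse path
      warning("singular submodel; using pseudo-inverse")
      b <- MASS_ginv(crossprod(Xs)) %*% crossprod(Xs, y)
      res <- y - Xs %*% b
      return(1 - sum(res^2) / tss)
    }
    1 - sum(fit$residuals^2) / tss
  }

  imp <- stats::setNames(numeric(p), names(groups))
  if (p <= max_exact) {
    # subset-sum formulation: importance_k = sum over subsets S (k not in
    # S) of |S|!(p-|S|-1)!/p! * [R2(S + k) - R2(S)]
    r2_cache <- numeric(2^p)
    for (code in 0:(2^p - 1)) {
      members <- which(bitwAnd(code, bitwShiftL(1L, 0:(p - 1))) > 0)
      r2_cache[code + 1] <- r2_of(unlist(groups[members]))
    }
    lfact <- lfactorial(0:p)
    for (k in seq_len(p)) {
      bit <- bitwShiftL(1L, k - 1L)
      for (code in 0:(2^p - 1)) {
        if (bitwAnd(code, bit) > 0) next
        s <- sum(bitwAnd(code, bitwShiftL(1L, 0:(p - 1))) > 0)
        w <- exp(lfact[s + 1] + lfact[p - s] - lfact[p + 1])
        imp[k] <- imp[k] + w * (r2_cache[bitwOr(code, bit) + 1] -
                                  r2_cache[code + 1])
      }
    }
  } else {
    set.seed(as.integer(seed))
    for (b in seq_len(n_orderings)) {
      ordn <- sample.int(p)
      prev <- integer(0); r2_prev <- 0
      for (k in ordn) {
        cur <- c(prev, groups[[k]])
        r2_cur <- r2_of(cur)
        imp[k] <- imp[k] + (r2_cur - r2_prev) / n_orderings
        prev <- cur; r2_prev <- r2_cur
      }
    }
  }
  attr(imp, "r_squared") <- r2_of(unlist(groups))
  imp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: Moore-Penrose pseudo-inverse via SVD (singular submodels)
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Diet vs group attribution for a microbiota feature
#'
#' Linear model `feature ~ group + diet variable + covariates`; F-tests for
#' the group block and the dietary term (each against the model without
#' it), and an LMG decomposition of the model R-squared with the group
#' dummies as one block. The pair is classified diet-dominant or
#' group-dominant by comparing the two importances.
#'
#' @param feature numeric microbiota feature values aligned with `cohort`.
#' @param cohort cohort table containing the dietary variable column.
#' @param diet_var name of the dietary variable column in `cohort`.
#' @param covariates covariate columns (default sex, age, bmi, activity,
#'   smoking).
#' @return list `p_group`, `p_diet`, `importance` (named: group, diet,
#'   covariates), `r_squared`, `dominant` (`"diet"` or `"group"`),
#'   `jarque_bera_p`.
#' @export
diet_microbiota_attribution <- function(feature, cohort, diet_var,
                                        covariates = c("sex", "age", "bmi",
                                                       "activity",
                                                       "smoking")) {
  if (!diet_var %in% names(cohort)) stop("unknown dietary variable: ",
                                         diet_var)
  dat <- cohort[, c("group", diet_var, covariates)]
  dat$group <- factor(as.character(dat$group))
  dat$.y <- feature
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]

  rhs_all <- paste(c("group", diet_var, covariates), collapse = " + ")
  m_full <- stats::lm(stats::as.formula(paste(".y ~", rhs_all)), data = dat)
  m_nog <- stats::update(m_full, paste(". ~ . - group"))
  m_nod <- stats::update(m_full, paste(". ~ . -", diet_var))
  p_group <- stats::anova(m_nog, m_full)[2, "Pr(>F)"]
  p_diet <- stats::anova(m_nod, m_full)[2, "Pr(>F)"]

  mm <- stats::model.matrix(m_full)[, -1, drop = FALSE]
  asg <- attr(stats::model.matrix(m_full), "assign")[-1]
  terms_lab <- attr(stats::terms(m_full), "term.labels")
  grp_list <- lapply(seq_along(terms_lab), function(t) which(asg == t))
  names(grp_list) <- terms_lab
  imp <- lmg_importance(mm, dat$.y, groups = grp_list)
  names(imp)[names(imp) == diet_var] <- "diet"
  list(p_group = p_group, p_diet = p_diet, importance = imp,
       r_squared = attr(imp, "r_squared"),
       dominant = if (imp["diet"] > imp["group"]) "diet" else "group",
       jarque_bera_p = jarque_bera(stats::residuals(m_full))$p.value)
}
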