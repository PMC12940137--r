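#' Prevalence filter
#'
#' Removes rare features detected (abundance > 0) in strictly less than
#' `min_prevalence` of the samples.
#'
#' @param abund feature x sample matrix.
#' @param min_prevalence detection fraction required to keep a feature
#'   (default 0.10).
#' @return filtered matrix (possibly zero rows).
#' @export
prevalence_filter <- function(abund, min_prevalence = 0.10) {
  check_abundance(abund)
  stopifnot(min_prevalence > 0, min_prevalence < 1)
  prev <- rowMeans(abund > 0)
  abund[prev >= min_prevalence, , drop = FALSE]
}

#' Rank tests of a feature across groups
#'
#' Kruskal-Wallis across all groups plus, for every group pair, a
#' Wilcoxon-Mann-Whitney test and Cliff's delta (delta of `a` over `b`,
#' where `a` precedes `b` in the group ordering).
#'
#' @param values numeric feature values per sample.
#' @param groups group labels (factor).
#' @return list `kruskal_p`, `kruskal_stat`, `pairwise` (data.frame
#'   group_a, group_b, wilcoxon_p, cliffs_delta).
#' @export
group_tests <- function(values, groups) {
  groups <- factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need >= 2 groups with >= 2 observations each")
  kw <- stats::kruskal.test(values, groups)
  glev <- levels(groups)
  rows <- list(); i <- 0L
  for (a in seq_along(glev)) for (b in seq_along(glev)) {
    if (a >= b) next
    va <- values[groups == glev[a]]; vb <- values[groups == glev[b]]
    i <- i + 1L
    rows[[i]] <- data.frame(
      group_a = glev[a], group_b = glev[b],
      wilcoxon_p = stats::wilcox.test(va, vb, exact = FALSE)$p.value,
      cliffs_delta = cliffs_delta(va, vb), stringsAsFactors = FALSE)
  }
  list(kruskal_p = kw$p.value, kruskal_stat = unname(kw$statistic),
       pairwise = do.call(rbind, rows))
}

#' Spearman correlation of a feature with the ordinal group code
#'
#' Spearman rho with mid-rank tie handling and the t-approximation
#' p-value. A constant feature has no defined rank correlation and returns
#' `NA` for both rho and p.
#'
#' @param values numeric feature values.
#' @param ordinal_groups ordinal codes (see [group_ordinal()]).
#' @return list `rho`, `p`.
#' @export
spearman_gradient <- function(values, ordinal_groups) {
  ok <- !is.na(values)
  v <- values[ok]; g <- ordinal_groups[ok]
  if (length(unique(v)) < 2L || length(unique(g)) < 2L)
    return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(v, g, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Dual-window gradient marker screen
#'
#' The core selection procedure: a feature is a gradient marker only if its
#' Spearman association with the ordered risk groups is significant with
#' adequate effect size in BOTH analysis windows — the non-diseased window
#' (groups 0-1-2) and the full window (groups 0-1-2-D) — with a consistent
#' sign. Default thresholds `p < alpha` and `|rho| > min_effect` (strict,
#' per the published wording; set `inclusive = TRUE` for the `<=`/`>=`
#' variant). Benjamini-Hochberg q-values are computed within the feature
#' family (species, modules, CAZymes and dietary variables are corrected
#' separately by calling the screen per family), annotated at tiers
#' q <= 0.3, 0.1, 0.05. Kruskal-Wallis and pairwise Wilcoxon/Cliff's delta
#' are reported alongside but do not drive selection.
#'
#' @param abund feature x sample matrix, already prevalence-filtered.
#' @param cohort cohort table ([read_cohort()] dialect) matching the
#'   samples.
#' @param alpha significance threshold (default 0.05).
#' @param min_effect minimum `|rho|` (default 0.2).
#' @param inclusive use `<=`/`>=` thresholds instead of strict.
#' @param require_sign_consistency require equal rho signs in both windows
#'   (default TRUE).
#' @param pairwise also compute per-pair Wilcoxon/Cliff's delta (default
#'   FALSE; costs one pass per group pair).
#' @return object of class `gradient_screen`: data.frame with one row per
#'   feature: `feature`, `rho_012`, `p_012`, `q_012`, `rho_012D`,
#'   `p_012D`, `q_012D`, `q_tier`, `kruskal_p`, `selected`; pairwise stats
#'   in `attr(, "pairwise")` when requested.
#' @export
detect_gradient_markers <- function(abund, cohort, alpha = 0.05,
                                    min_effect = 0.2, inclusive = FALSE,
                                    require_sign_consistency = TRUE,
                                    pairwise = FALSE) {
  check_abundance(abund)
  cohort <- as_cohort(cohort)
  if (!identical(colnames(abund), cohort$sample_id))
    stop("abundance columns must match cohort sample_id (same order)")
  ord <- group_ordinal(cohort$group)
  w1 <- ord <= 2                      # window 0-1-2
  if (length(unique(ord[w1])) < 3L || length(unique(ord)) < 4L)
    stop("both analysis windows need all their groups represented")

  nfeat <- nrow(abund)
  res <- data.frame(feature = rownames(abund), rho_012 = NA_real_,
                    p_012 = NA_real_, q_012 = NA_real_,
                    rho_012D = NA_real_, p_012D = NA_real_,
                    q_012D = NA_real_, q_tier = "", kruskal_p = NA_real_,
                    selected = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nfeat)) {
    s1 <- spearman_gradient(abund[i, w1], ord[w1])
    s2 <- spearman_gradient(abund[i, ], ord)
    res$rho_012[i] <- s1$rho; res$p_012[i] <- s1$p
    res$rho_012D[i] <- s2$rho; res$p_012D[i] <- s2$p
    res$kruskal_p[i] <- tryCatch(
      stats::kruskal.test(abund[i, ], cohort$group)$p.value,
      error = function(e) NA_real_)
  }
  res$q_012 <- bh_adjust(res$p_012)
  res$q_012D <- bh_adjust(res$p_012D)
  qmax <- pmax(res$q_012, res$q_012D)
  deg <- "\u00b0" # q-value tier marks: one to three degree signs
  res$q_tier <- ifelse(is.na(qmax), "",
                ifelse(qmax <= 0.05, strrep(deg, 3),
                ifelse(qmax <= 0.1, strrep(deg, 2),
                ifelse(qmax <= 0.3, deg, ""))))
  lt <- if (inclusive) `<=` else `<`
  gt <- if (inclusive) `>=` else `>`
  pass <- lt(res$p_012, alpha) & gt(abs(res$rho_012), min_effect) &
    lt(res$p_012D, alpha) & gt(abs(res$rho_012D), min_effect)
  if (require_sign_consistency)
    pass <- pass & (sign(res$rho_012) == sign(res$rho_012D))
  res$selected <- !is.na(pass) & pass

  if (pairwise) {
    pw <- lapply(seq_len(nfeat), function(i) {
      out <- group_tests(abund[i, ], cohort$group)$pairwise
      out$feature <- rownames(abund)[i]
      out
    })
    attr(res, "pairwise") <- do.call(rbind, pw)
  }
  class(res) <- c("gradient_screen", "data.frame")
  res
}

#' @export
print.gradient_screen <- function(x, ...) {
  cat("Gradient screen:", nrow(x), "features,", sum(x$selected),
      "selected (dual-window criterion)\n")
  if (sum(x$selected)) {
    df <- as.data.frame(x)[x$selected, c("feature", "rho_012", "q_012",
                                         "rho_012D", "q_012D")]
    print(utils::head(df, 10), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Covariate-adjusted nested-model validation
#'
#' Compares nested models with and without the risk-group term, adjusting
#' for sex, age, BMI, physical activity and smoking status. Numeric
#' outcomes use a Gaussian linear model and an F-test between the nested
#' fits; categorical outcomes (e.g. enterotype labels) use a multinomial
#' logit and a likelihood-ratio chi-square test. Complete cases only
#' (listwise deletion, counted in the output). Diagnostics: Jarque-Bera
#' residual-normality p and the model R-squared (numeric outcomes).
#'
#' @param outcome numeric vector, or factor/character for categorical
#'   outcomes, aligned with `cohort` rows.
#' @param cohort cohort table with `group`, `sex`, `age`, `bmi`,
#'   `activity`, `smoking`.
#' @param covariates covariate column names (default the five above).
#' @return list `adjusted_p`, `model` (`"glm"` or `"multinom"`),
#'   `r_squared`, `jarque_bera_p` (numeric outcomes), `n_used`,
#'   `n_dropped`.
#' @export
covariate_validation <- function(outcome, cohort,
                                 covariates = c("sex", "age", "bmi",
                                                "activity", "smoking")) {
  missing_cov <- setdiff(c("group", covariates), names(cohort))
  if (length(missing_cov))
    stop("cohort lacks columns: ", paste(missing_cov, collapse = ", "))
  dat <- cohort[, c("group", covariates)]
  dat$group <- factor(as.character(dat$group))   # plain factor in models
  dat$.y <- outcome
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  rhs0 <- paste(covariates, collapse = " + ")
  f1 <- stats::as.formula(paste(".y ~ group +", rhs0))
  f0 <- stats::as.formula(paste(".y ~", rhs0))

  qr_check <- stats::model.matrix(f1, dat)
  qq <- qr(qr_check)
  if (qq$rank < ncol(qr_check)) {
    bad <- colnames(qr_check)[qq$pivot[(qq$rank + 1):ncol(qr_check)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  if (is.numeric(outcome)) {
    m1 <- stats::glm(f1, data = dat, family = stats::gaussian())
    m0 <- stats::glm(f0, data = dat, family = stats::gaussian())
    an <- stats::anova(m0, m1, test = "F")
    pval <- an[2, "Pr(>F)"]
    r2 <- 1 - m1$deviance / m1$null.deviance
    jb <- jarque_bera(stats::residuals(m1))$p.value
    list(adjusted_p = pval, model = "glm", r_squared = r2,
         jarque_bera_p = jb, n_used = nrow(dat),
         n_dropped = sum(!cc))
  } else {
    dat$.y <- factor(dat$.y)
    m1 <- nnet::multinom(f1, data = dat, trace = FALSE, maxit = 200)
    m0 <- nnet::multinom(f0, data = dat, trace = FALSE, maxit = 200)
    lr <- m0$deviance - m1$deviance
    df <- length(stats::coef(m1)) - length(stats::coef(m0))
    pval <- stats::pchisq(lr, df = df, lower.tail = FALSE)
    list(adjusted_p = pval, model = "multinom", r_squared = NA_real_,
         jarque_bera_p = NA_real_, n_used = nrow(dat), n_dropped = sum(!cc))
  }
}

#' Append covariate-adjusted validation to a gradient screen
#'
#' Runs [covariate_validation()] on every selected feature (or all
#' features with `selected_only = FALSE`) and adds `adjusted_p` /
#' `adjusted_pass` columns.
#'
#' @param screen a `gradient_screen` result.
#' @param abund the feature x sample matrix the screen was run on.
#' @param cohort the cohort table.
#' @param alpha significance threshold for `adjusted_pass` (default 0.05).
#' @param selected_only validate selected features only (default TRUE).
#' @return the screen with `adjusted_p`, `adjusted_pass` filled in.
#' @export
validate_screen <- function(screen, abund, cohort, alpha = 0.05,
                            selected_only = TRUE) {
  stopifnot(inherits(screen, "gradient_screen"))
  screen$adjusted_p <- NA_real_
  screen$adjusted_pass <- NA
  idx <- if (selected_only) which(screen$selected) else seq_len(nrow(screen))
  for (i in idx) {
    v <- covariate_validation(abund[screen$feature[i], ], cohort)
    screen$adjusted_p[i] <- v$adjusted_p
    screen$adjusted_pass[i] <- v$adjusted_p < alpha
  }
  screen
}
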