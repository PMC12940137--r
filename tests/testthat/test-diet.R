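# align recovered loadings to truth up to column permutation and sign
align_loadings <- function(L, truth) {
  perm <- apply(abs(stats::cor(truth, L)), 1L, which.max)
  L <- L[, perm, drop = FALSE]
  sgn <- sign(colSums(L * truth))
  sweep(L, 2L, ifelse(sgn == 0, 1, sgn), "*")
}

test_that("PCA + varimax recovers a planted 3-factor loading matrix", {
  fm <- factor_model_data(loading = 0.95)
  dp <- dietary_patterns(fm$x, n_factors = 3)
  aligned <- align_loadings(dp$loadings, fm$lambda)
  expect_lt(max(abs(aligned - fm$lambda)), 0.1)
  # significant-loading mask picks exactly the planted blocks
  sig <- align_loadings(dp$loadings, fm$lambda)
  expect_identical(unname(abs(sig) >= 0.30), unname(fm$lambda > 0))
})

test_that("varimax rotation preserves communalities and the fitted subspace", {
  fm <- factor_model_data(seed = 2)
  x <- fm$x
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  L_raw <- eig$vectors[, 1:3] %*% diag(sqrt(eig$values[1:3]))
  dp <- dietary_patterns(x, n_factors = 3)
  expect_equal(unname(rowSums(dp$loadings^2)), unname(rowSums(L_raw^2)),
               tolerance = 1e-10)
  # projection onto the loading span is rotation-invariant
  P_raw <- L_raw %*% solve(crossprod(L_raw)) %*% t(L_raw)
  L <- unclass(dp$loadings)
  P_rot <- L %*% solve(crossprod(L)) %*% t(L)
  expect_lt(max(abs(P_raw - P_rot)), 1e-10)
})

test_that("a single dominant factor yields scores tracking the truth", {
  fm <- factor_model_data(seed = 3)
  x1 <- fm$x[, 1:6]
  dp <- dietary_patterns(x1, n_factors = 1)
  expect_gte(abs(stats::cor(dp$scores[, 1], fm$f[, 1])), 0.95)
})

test_that("pattern scores ignore the units of the intake columns", {
  fm <- factor_model_data(seed = 4)
  dp1 <- dietary_patterns(fm$x, n_factors = 3)
  x2 <- sweep(fm$x, 2L, c(rep(1000, 9), rep(0.01, 9)), "*")
  dp2 <- dietary_patterns(x2, n_factors = 3)
  expect_equal(dp1$scores, dp2$scores, tolerance = 1e-8)
  expect_error(dietary_patterns(cbind(fm$x, const = 1)), "constant")
})

test_that("LMG importances match enumeration and analytic cases", {
  set.seed(5)
  n <- 100
  # orthogonal predictors: importance = squared simple correlation
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  y <- 0.8 * x1 + 0.3 * x2 + rnorm(n)
  imp <- lmg_importance(cbind(a = x1, b = x2), y)
  expect_equal(unname(imp["a"]), stats::cor(x1, y)^2, tolerance = 1e-10)
  expect_equal(unname(imp["b"]), stats::cor(x2, y)^2, tolerance = 1e-10)
  expect_equal(sum(imp), attr(imp, "r_squared"), tolerance = 1e-10)

  # p = 4 vs brute-force over all 24 orderings
  X <- matrix(rnorm(4 * n), n, 4, dimnames = list(NULL, paste0("x", 1:4)))
  X[, 2] <- X[, 1] * 0.6 + X[, 2] * 0.8
  yy <- X %*% c(1, 0.5, -0.3, 0) + rnorm(n)
  imp4 <- lmg_importance(X, yy)
  r2_of <- function(cols) {
    if (!length(cols)) return(0)
    summary(stats::lm(yy ~ X[, cols, drop = FALSE]))$r.squared
  }
  brute <- numeric(4)
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1L, function(r) length(unique(r)) == 4), ]
  for (r in seq_len(nrow(perms))) {
    ordn <- perms[r, ]
    for (k in seq_len(4)) {
      prev <- ordn[seq_len(k - 1)]
      brute[ordn[k]] <- brute[ordn[k]] +
        (r2_of(c(prev, ordn[k])) - r2_of(prev)) / nrow(perms)
    }
  }
  expect_equal(as.numeric(imp4), brute, tolerance = 1e-10)

  # duplicated predictor shares its importance equally
  Xd <- cbind(a = x1, b = x1, c = x2)
  suppressWarnings(impd <- lmg_importance(Xd, y))
  expect_equal(unname(impd["a"]), unname(impd["b"]), tolerance = 1e-10)
})

test_that("Monte-Carlo LMG approximates the exact decomposition", {
  set.seed(6)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- X %*% c(1, -0.5, 0.3, 0, 0.2) + rnorm(60)
  exact <- lmg_importance(X, y)
  mc <- lmg_importance(X, y, max_exact = 2L, n_orderings = 4000L, seed = 9)
  expect_lt(max(abs(exact - mc)), 0.02)
  expect_equal(sum(mc), attr(mc, "r_squared"), tolerance = 1e-10)
})

test_that("planted dietary gradients pass the dual-window diet screen", {
  sim <- sim_default()
  diet_cols <- setdiff(names(sim$cohort),
                       c("sample_id", "group", "sex", "age", "bmi",
                         "activity", "smoking"))
  scr <- diet_group_tests(sim$cohort[, diet_cols], sim$cohort)
  truth <- sim$truth$diet_gradient_ids
  sel <- scr$feature[scr$selected]
  expect_gte(mean(names(truth) %in% sel), 0.6)
  # recovered signs agree where selected
  hit <- intersect(names(truth), sel)
  expect_equal(sign(scr$rho_012D[match(hit, scr$feature)]),
               unname(truth[hit]))
  # a constant variable is flagged undefined, never selected
  co2 <- sim$cohort
  co2$constvar <- 5
  scr2 <- diet_group_tests(co2[, c(diet_cols, "constvar")], co2)
  expect_true(is.na(scr2$rho_012D[scr2$feature == "constvar"]))
  expect_false(scr2$selected[scr2$feature == "constvar"])
})

test_that("attribution separates diet-driven from group-driven features", {
  sim <- sim_default()
  co <- sim$cohort
  # purely diet-driven planted species
  dv <- names(sim$truth$diet_effects)[1]
  target <- names(sim$truth$diet_effects[[dv]])[1]
  att <- diet_microbiota_attribution(log1p(sim$abundance[target, ] * 1e4),
                                     co, dv)
  expect_identical(att$dominant, "diet")
  expect_lt(att$p_diet, 0.01)
  # purely group-driven construction
  set.seed(7)
  yg <- 0.8 * group_ordinal(co$group) + rnorm(nrow(co))
  attg <- diet_microbiota_attribution(yg, co, dv)
  expect_identical(attg$dominant, "group")
  expect_lt(attg$p_group, 1e-6)
  expect_equal(sum(attg$importance), attg$r_squared, tolerance = 1e-8)
  expect_true(all(c("group", "diet") %in% names(attg$importance)))
})
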