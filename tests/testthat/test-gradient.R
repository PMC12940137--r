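test_that("Cliff's delta matches the stated examples and the bounds", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(cliffs_delta(1:5, 1:5), 0)
  expect_equal(cliffs_delta(c(1, 2, 3, 4), c(2, 3, 4, 5)), -7 / 16)
  expect_error(cliffs_delta(numeric(0), 1), "non-empty")
})

test_that("Cliff's delta equals brute-force pair counting on random data", {
  set.seed(1)
  for (r in 1:50) {
    nx <- sample(2:60, 1); ny <- sample(2:60, 1)
    x <- sample(round(rnorm(nx), 1))   # rounded: plenty of ties
    y <- sample(round(rnorm(ny), 1))
    expect_equal(cliffs_delta(x, y), cliffs_delta_brute(x, y),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  for (r in 1:100) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_reference(p), tolerance = 1e-12)
  }
})

test_that("the prevalence filter removes strictly-below-threshold features", {
  n <- 192
  ab <- rbind(rare = c(rep(1, 19), rep(0, n - 19)),
              kept = c(rep(1, 20), rep(0, n - 20)),
              ubiquitous = rep(1, n))
  colnames(ab) <- paste0("s", 1:n)
  out <- prevalence_filter(ab, 0.10)
  expect_identical(rownames(out), c("kept", "ubiquitous"))
})

test_that("rank tests behave at their extremes", {
  g <- rep(c("a", "b"), each = 10)
  v <- c(rnorm(10), rnorm(10) + 100)
  r <- group_tests(v, g)
  expect_lt(r$pairwise$wilcoxon_p, 1e-3)
  expect_equal(abs(r$pairwise$cliffs_delta), 1)
  # three identical groups -> zero Kruskal-Wallis statistic
  r3 <- group_tests(rep(c(5, 7, 9), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(r3$kruskal_stat, 0)
  expect_error(group_tests(1:3, c("a", "a", "b")), ">= 2")
})

test_that("Spearman gradient is antisymmetric and handles constants", {
  set.seed(3)
  v <- rnorm(40)
  g <- rep(0:3, each = 10)
  s <- spearman_gradient(v, g)
  s_rev <- spearman_gradient(v, 3 - g)
  expect_equal(s$rho, -s_rev$rho, tolerance = 1e-12)
  expect_equal(s$p, s_rev$p, tolerance = 1e-12)
  expect_true(is.na(spearman_gradient(rep(1, 40), g)$rho))
  # strictly increasing in the group code with no within-group variance:
  # rho from the mid-rank formula (all within-group values tied)
  v2 <- rep(c(1, 2, 3, 4), each = 10)
  expect_equal(spearman_gradient(v2, g)$rho, 1)
})

test_that("rank statistics are invariant under monotone transforms", {
  sim <- sim_default()
  ab <- prevalence_filter(sim$abundance)[1:20, , drop = FALSE]
  scr1 <- detect_gradient_markers(ab, sim$cohort)
  scr2 <- detect_gradient_markers(sqrt(ab), sim$cohort)
  expect_equal(scr1$rho_012D, scr2$rho_012D, tolerance = 1e-12)
  expect_identical(scr1$selected, scr2$selected)
})

test_that("the dual-window criterion requires both windows", {
  set.seed(4)
  n <- 48
  groups <- factor(rep(c("0", "1", "2", "D"), each = n),
                   levels = c("0", "1", "2", "D"), ordered = TRUE)
  cohort <- data.frame(sample_id = sprintf("S%03d", 1:(4 * n)),
                       group = groups)
  ordc <- group_ordinal(groups)
  d_only <- exp(rnorm(4 * n, ifelse(ordc == 3, 2, 0), 0.5))
  monotone <- exp(rnorm(4 * n, 0.7 * ordc, 0.5))
  ab <- rbind(d_only = d_only, monotone = monotone)
  colnames(ab) <- cohort$sample_id
  scr <- detect_gradient_markers(ab, cohort)
  expect_false(scr$selected[scr$feature == "d_only"])  # flat across 0-1-2
  expect_true(scr$selected[scr$feature == "monotone"])
})

test_that("planted gradient species are selected on the synthetic cohort", {
  sim <- sim_default()
  ab <- prevalence_filter(sim$abundance)
  scr <- detect_gradient_markers(ab, sim$cohort)
  planted <- names(sim$truth$gradient_species_ids)
  sens <- mean(planted %in% scr$feature[scr$selected])
  expect_gte(sens, 0.8)
  # recovered signs match the planted signs
  hit <- intersect(planted, scr$feature[scr$selected])
  got <- sign(scr$rho_012D[match(hit, scr$feature)])
  expect_equal(got, as.numeric(sim$truth$gradient_species_ids[hit]))
})

test_that("covariate validation detects group effects and flags collinearity", {
  sim <- sim_default()
  co <- sim$cohort
  ordc <- group_ordinal(co$group)
  set.seed(5)
  y <- 0.5 * ordc + 0.05 * co$age + rnorm(nrow(co))
  v <- covariate_validation(y, co)
  expect_lt(v$adjusted_p, 0.001)
  expect_equal(v$model, "glm")
  expect_gt(v$jarque_bera_p, 0.001)   # Gaussian residuals
  expect_equal(v$n_used, nrow(co))

  # pure covariate effect: group term stays null far more often than not
  y0 <- 0.2 * co$age + rnorm(nrow(co))
  expect_gt(covariate_validation(y0, co)$adjusted_p, 1e-4)

  co_bad <- co
  co_bad$age2 <- co_bad$age * 2
  expect_error(covariate_validation(y, co_bad,
                                    covariates = c("age", "age2")),
               "collinear")
})

test_that("categorical outcomes go through the multinomial path", {
  sim <- sim_default()
  lab <- sim$truth$enterotype_labels[sim$cohort$sample_id]
  v <- covariate_validation(lab, sim$cohort)
  expect_equal(v$model, "multinom")
  expect_true(v$adjusted_p >= 0 && v$adjusted_p <= 1)
  # planted enterotype mixing differs by group: the term should register
  expect_lt(v$adjusted_p, 0.05)
})

test_that("screen validation appends adjusted p-values for selected features", {
  sim <- sim_default()
  ab <- prevalence_filter(sim$abundance)
  scr <- detect_gradient_markers(ab, sim$cohort)
  idx <- which(scr$selected)[1:3]
  sub <- scr[c(idx, which(!scr$selected)[1]), ]
  class(sub) <- class(scr)
  val <- validate_screen(sub, ab, sim$cohort)
  expect_true(all(!is.na(val$adjusted_p[val$selected])))
  expect_true(all(is.na(val$adjusted_p[!val$selected])))
})
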