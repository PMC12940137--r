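make_counts <- function(counts, lengths = NULL) {
  if (is.null(lengths))
    lengths <- stats::setNames(rep(100, nrow(counts)), rownames(counts))
  gene_count_table(counts, lengths)
}

test_that("downsizing subsamples to exact depth and drops shallow samples", {
  cnt <- matrix(c(600L, 400L, 50L, 30L), 2,
                dimnames = list(c("g1", "g2"), c("deep", "shallow")))
  expect_warning(out <- downsize_counts(make_counts(cnt), 100, seed = 1),
                 "below target depth")
  expect_equal(colnames(out$counts), "deep")
  expect_equal(sum(out$counts[, "deep"]), 100)

  # target equal to the sample total leaves the sample untouched
  same <- downsize_counts(make_counts(cnt[, 1, drop = FALSE]), 1000,
                          seed = 1)
  expect_identical(same$counts[, 1], cnt[, 1])

  # degenerate support: one gene holds everything
  one <- matrix(c(500L, 0L), 2, 1,
                dimnames = list(c("g1", "g2"), "s"))
  expect_equal(downsize_counts(make_counts(one), 77, 1)$counts[, 1],
               c(g1 = 77, g2 = 0))
  expect_error(downsize_counts(make_counts(one), 0), "> 0")
})

test_that("downsize-then-normalize is unbiased for the full-table frequencies", {
  set.seed(11)
  cnt <- matrix(rpois(8 * 3, 500), 8, 3,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:3)))
  storage.mode(cnt) <- "integer"
  tab <- make_counts(cnt, stats::setNames(sample(100:500, 8),
                                          rownames(cnt)))
  full <- normalize_frequencies(tab)
  acc <- 0
  for (s in 1:200)
    acc <- acc + normalize_frequencies(downsize_counts(tab, 800, seed = s))
  expect_lt(max(abs(acc / 200 - full)), 0.01)
})

test_that("length normalisation gives within-sample relative frequencies", {
  cnt <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tab <- gene_count_table(cnt, c(a = 100, b = 200))
  f <- normalize_frequencies(tab)
  expect_equal(f[, 1], c(a = 2 / 3, b = 1 / 3))

  # all-zero sample stays all-zero, no division error
  z <- make_counts(matrix(0L, 2, 1, dimnames = list(c("a", "b"), "s")))
  expect_equal(unname(normalize_frequencies(z)[, 1]), c(0, 0))

  # equal lengths reduce to relative counts
  eq <- make_counts(matrix(c(3L, 1L), 2, 1,
                           dimnames = list(c("a", "b"), "s")))
  expect_equal(unname(normalize_frequencies(eq)[, 1]), c(0.75, 0.25))
})

test_that("MSP abundance is the marker mean with the detection-null rule", {
  cat3 <- tiny_catalog()
  markers <- cat3$genes$gene_id[cat3$genes$is_marker]
  f <- matrix(0, length(markers), 3,
              dimnames = list(markers, c("s1", "s2", "s3")))
  # msp1: 1 of 10 markers detected (10% < 20%) -> nulled at threshold 0.2
  f["m1_g01", "s1"] <- 0.5
  # msp2: all 10 markers at 0.02 -> mean 0.02
  f[paste0("m2_g", sprintf("%02d", 1:10)), "s1"] <- 0.02
  # msp3: exactly 2 of 10 (= 20%, not strictly below) -> retained
  f["m3_g01", "s1"] <- 0.1
  f["m3_g02", "s1"] <- 0.1
  ab <- msp_abundance(f, cat3, min_detected_frac = 0.20)
  expect_equal(ab["msp1", "s1"], 0)          # below the detection fraction
  expect_equal(ab["msp2", "s1"], 0.02)
  expect_equal(ab["msp3", "s1"], 0.02)       # mean includes zeros

  # homogeneity of degree 1 above the detection threshold
  ab2 <- msp_abundance(f * 3, cat3, min_detected_frac = 0.20)
  expect_equal(ab2, ab * 3)

  expect_error(msp_abundance(f[-1, , drop = FALSE], cat3), "missing")
})

test_that("the 100-marker null rule nulls below 10 detected markers", {
  genes <- data.frame(msp_id = "msp1",
                      gene_id = sprintf("g%03d", 1:100),
                      is_marker = TRUE, is_core = TRUE,
                      stringsAsFactors = FALSE)
  msp <- data.frame(msp_id = "msp1",
                    taxonomy = "d__B;p__Bacillota;c__C;o__O;f__F;g__G;s__s",
                    gram = "positive", origin = "gut",
                    stringsAsFactors = FALSE)
  cat100 <- msp_catalog(genes, msp)
  f <- matrix(0, 100, 3, dimnames = list(genes$gene_id,
                                         c("nine", "ten", "all")))
  f[1:9, "nine"] <- 0.01            # 9 of 100 detected -> null
  f[1:10, "ten"] <- 0.01            # 10 of 100 detected -> mean 0.001
  f[, "all"] <- 0.004               # all markers at f -> abundance f
  ab <- msp_abundance(f, cat100)
  expect_equal(unname(ab["msp1", ]), c(0, 0.001, 0.004))
})

test_that("taxon aggregation sums member MSP and conserves totals", {
  cat3 <- tiny_catalog()
  ab <- matrix(c(0.2, 0.3, 0.5, 0.1, 0.6, 0.3), 3,
               dimnames = list(paste0("msp", 1:3), c("s1", "s2")))
  gen <- aggregate_taxa(ab, cat3, "genus")
  expect_equal(gen["Bacteroides", "s1"], 0.3)
  expect_equal(colSums(gen), colSums(ab))
  phy <- aggregate_taxa(ab, cat3, "phylum")
  expect_equal(phy["Bacteroidota", "s1"], 0.8)
  # species-unclassified msp3 gets a per-lineage placeholder
  sp <- aggregate_taxa(ab, cat3, "species")
  expect_true("unclassified Prevotella" %in% rownames(sp))
  expect_error(aggregate_taxa(ab, cat3, "kingdom"), "unknown rank")
})

test_that("richness counts detected features and ignores scaling", {
  ab <- matrix(c(0, 0, 1, 2, 0, 3), 3,
               dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  expect_equal(unname(richness(ab)), c(1, 2))
  expect_equal(richness(ab * 100), richness(ab))
  expect_equal(unname(richness(ab * 0)), c(0, 0))
})

test_that("Gram ratio uses the phylum-majority fallback for unclassified MSP", {
  cat3 <- tiny_catalog()   # msp3 unannotated; Bacteroidota peers negative
  ab <- matrix(c(0.6, 0.1, 0.1), 3, 1,
               dimnames = list(paste0("msp", 1:3), "s1"))
  expect_equal(unname(gram_ratio(ab, cat3)), 0.6 / 0.2)
  abeq <- matrix(c(0.3, 0.2, 0.1), 3, 1,
                 dimnames = list(paste0("msp", 1:3), "s1"))
  expect_equal(unname(gram_ratio(abeq, cat3)), 1.0)
  # zero Gram-negative total -> NA with warning
  abz <- matrix(c(0.5, 0, 0), 3, 1,
                dimnames = list(paste0("msp", 1:3), "s1"))
  expect_warning(r <- gram_ratio(abz, cat3), "undefined")
  expect_true(is.na(r))
})

test_that("Gram fallback ties are an explicit error", {
  genes <- data.frame(msp_id = rep(paste0("m", 1:3), each = 2),
                      gene_id = paste0("g", 1:6),
                      is_marker = rep(c(TRUE, FALSE), 3),
                      is_core = TRUE, stringsAsFactors = FALSE)
  msp <- data.frame(msp_id = paste0("m", 1:3),
                    taxonomy = rep("d__B;p__P;c__C;o__O;f__F;g__G;s__", 3),
                    gram = c("positive", "negative", NA),
                    origin = "gut", stringsAsFactors = FALSE)
  cat2 <- msp_catalog(genes, msp, n_markers = 1L)
  ab <- matrix(1, 3, 1, dimnames = list(paste0("m", 1:3), "s"))
  expect_error(gram_ratio(ab, cat2), "tie")
})

test_that("oral-to-gut species ratio counts detected species per catalog", {
  gut <- matrix(rep(1, 90), 90, 1,
                dimnames = list(paste0("g", 1:90), "s1"))
  oral <- matrix(rep(1, 10), 10, 1,
                 dimnames = list(paste0("o", 1:10), "s1"))
  expect_equal(unname(oral_gut_ratio(gut, oral)), 0.10)
  expect_equal(unname(oral_gut_ratio(gut, oral * 0)), 0)
  expect_equal(unname(oral_gut_ratio(gut * 0, oral * 0)), 0)
  # a species listed in both catalogs counts once, as oral
  both_oral <- rbind(oral, g1 = 1)
  r <- oral_gut_ratio(gut, both_oral)
  expect_equal(unname(r), 11 / 100)
  expect_error(oral_gut_ratio(gut, `colnames<-`(oral, "other")), "match")
})
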