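# Shared fixtures, built in code. The default synthetic cohort is cached so
# several test files can reuse one draw.

.fixture_env <- new.env(parent = emptyenv())

sim_default <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_cohort(simulation_config(seed = 20260928L))
  .fixture_env$sim
}

# tiny 3-MSP catalog with 10 markers each (n_markers relaxed)
tiny_catalog <- function() {
  genes <- do.call(rbind, lapply(1:3, function(i) {
    ids <- sprintf("m%d_g%02d", i, 1:14)
    data.frame(msp_id = paste0("msp", i), gene_id = ids,
               is_marker = rep(c(TRUE, FALSE), c(10, 4)),
               is_core = rep(c(TRUE, FALSE), c(12, 2)),
               stringsAsFactors = FALSE)
  }))
  msp <- data.frame(
    msp_id = paste0("msp", 1:3),
    taxonomy = c(
      "d__Bacteria;p__Bacillota;c__C;o__O;f__F;g__Faecalibacterium;s__f_sp1",
      "d__Bacteria;p__Bacteroidota;c__C;o__O;f__F;g__Bacteroides;s__b_sp1",
      "d__Bacteria;p__Bacteroidota;c__C;o__O;f__F;g__Prevotella;s__"),
    gram = c("positive", "negative", NA),
    origin = c("gut", "gut", "oral"), stringsAsFactors = FALSE)
  msp_catalog(genes, msp, n_markers = 10L)
}

# random Dirichlet draws (test oracle utility)
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  x / rowSums(x)
}

# simulate a genus count matrix from a K-component DM mixture; returns
# counts (genus x sample) and the true component labels
simulate_dmm_counts <- function(n, alphas, depth = 1000L, seed = 1L) {
  set.seed(seed)
  K <- ncol(alphas)
  lab <- sample.int(K, n, replace = TRUE)
  counts <- sapply(seq_len(n), function(i) {
    p <- rdirichlet(1, alphas[, lab[i]])[1, ]
    stats::rmultinom(1, depth, p)[, 1]
  })
  rownames(counts) <- rownames(alphas) %||%
    paste0("genus", seq_len(nrow(alphas)))
  colnames(counts) <- paste0("s", seq_len(n))
  list(counts = counts, labels = lab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Cliff's delta (all-pairs double loop): independent oracle
cliffs_delta_brute <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

# reference step-up BH via stats::p.adjust: independent oracle
bh_reference <- function(p) stats::p.adjust(p, method = "BH")

# brute-force module potential oracle: enumerate (msp, module, sample)
# triples directly from first principles
module_potential_brute <- function(catalog, funcmap, modules, gene_freqs,
                                   msp_abund) {
  msp_ids <- rownames(msp_abund)
  out <- matrix(0, length(modules), ncol(msp_abund),
                dimnames = list(names(modules), colnames(msp_abund)))
  orth_of <- function(gs) unique(funcmap$ortholog[funcmap$gene_id %in% gs])
  for (s in colnames(msp_abund)) for (m in names(modules)) {
    for (i in msp_ids) {
      if (msp_abund[i, s] == 0) next
      gi <- catalog$genes[catalog$genes$msp_id == i, ]
      core <- gi$gene_id[gi$is_core]
      acc <- gi$gene_id[!gi$is_core]
      det_acc <- acc[acc %in% rownames(gene_freqs) &
                       gene_freqs[acc, s] > 0]
      orth <- orth_of(c(core, det_acc))
      compl <- max(vapply(modules[[m]], function(a) mean(a %in% orth),
                          numeric(1)))
      if (compl >= 0.9) out[m, s] <- out[m, s] + msp_abund[i, s]
    }
  }
  out
}

# a 2-MSP hand fixture: module M1 has 10 components; msp1 carries 9 in
# core, msp2 carries 8 in core + 1 accessory
module_fixture <- function() {
  kos <- sprintf("K%02d", 1:10)
  genes <- rbind(
    data.frame(msp_id = "msp1",
               gene_id = sprintf("a%02d", 1:12),
               is_marker = rep(c(TRUE, FALSE), c(2, 10)),
               is_core = TRUE, stringsAsFactors = FALSE),
    data.frame(msp_id = "msp2",
               gene_id = sprintf("b%02d", 1:12),
               is_marker = rep(c(TRUE, FALSE), c(2, 10)),
               is_core = rep(c(TRUE, FALSE), c(10, 2)),
               stringsAsFactors = FALSE))
  msp <- data.frame(msp_id = c("msp1", "msp2"),
                    taxonomy = "d__B;p__Bacillota;c__C;o__O;f__F;g__G;s__s",
                    gram = "positive", origin = "gut",
                    stringsAsFactors = FALSE)
  catalog <- msp_catalog(genes, msp, n_markers = 2L)
  funcmap <- rbind(
    data.frame(gene_id = sprintf("a%02d", 3:11), ortholog = kos[1:9],
               stringsAsFactors = FALSE),          # msp1 core: K01..K09
    data.frame(gene_id = sprintf("b%02d", 3:10), ortholog = kos[1:8],
               stringsAsFactors = FALSE),          # msp2 core: K01..K08
    data.frame(gene_id = "b11", ortholog = kos[9],
               stringsAsFactors = FALSE))          # msp2 accessory: K09
  modules <- module_defs(list(M1 = list(kos)))
  list(catalog = catalog, funcmap = funcmap, modules = modules)
}

# clean 3-factor intake matrix from a known loading matrix (factor
# analysis recovery oracle)
factor_model_data <- function(n = 192, loading = 0.8, seed = 1) {
  set.seed(seed)
  vars <- sprintf("food%02d", 1:18)
  lambda <- matrix(0, 18, 3, dimnames = list(vars, NULL))
  lambda[1:6, 1] <- loading
  lambda[7:12, 2] <- loading
  lambda[13:18, 3] <- loading
  f <- matrix(stats::rnorm(3 * n), n, 3)
  x <- f %*% t(lambda) +
    matrix(stats::rnorm(18 * n, 0, sqrt(1 - loading^2)), n, 18)
  colnames(x) <- vars
  list(x = 50 + 10 * x, lambda = lambda, f = f)
}

# small random instance for the module oracle checks
random_module_instance <- function(seed, n_msp = 8, n_mod = 6,
                                   n_samples = 5) {
  set.seed(seed)
  kos <- sprintf("K%03d", 1:40)
  genes <- do.call(rbind, lapply(seq_len(n_msp), function(i) {
    ng <- sample(8:14, 1)
    data.frame(msp_id = sprintf("msp%02d", i),
               gene_id = sprintf("m%02d_g%02d", i, seq_len(ng)),
               is_marker = rep(c(TRUE, FALSE), c(3, ng - 3)),
               is_core = c(rep(TRUE, 3),
                           sample(c(TRUE, FALSE), ng - 3, replace = TRUE)),
               stringsAsFactors = FALSE)
  }))
  msp <- data.frame(msp_id = sprintf("msp%02d", seq_len(n_msp)),
                    taxonomy = sprintf(
                      "d__B;p__Bacillota;c__C;o__O;f__F;g__G%d;s__sp%d",
                      seq_len(n_msp), seq_len(n_msp)),
                    gram = "positive", origin = "gut",
                    stringsAsFactors = FALSE)
  catalog <- msp_catalog(genes, msp, n_markers = 3L)
  nonmark <- genes$gene_id[!genes$is_marker]
  funcmap <- data.frame(gene_id = nonmark,
                        ortholog = sample(kos, length(nonmark),
                                          replace = TRUE),
                        stringsAsFactors = FALSE)
  modules <- module_defs(stats::setNames(
    lapply(seq_len(n_mod), function(m) list(sample(kos, sample(2:5, 1)))),
    sprintf("M%02d", seq_len(n_mod))))
  samples <- sprintf("s%02d", seq_len(n_samples))
  gene_freqs <- matrix(stats::rbinom(nrow(genes) * n_samples, 1, 0.6) *
                         stats::runif(nrow(genes) * n_samples),
                       nrow(genes), n_samples,
                       dimnames = list(genes$gene_id, samples))
  msp_abund <- matrix(stats::rbinom(n_msp * n_samples, 1, 0.8) *
                        stats::runif(n_msp * n_samples),
                      n_msp, n_samples,
                      dimnames = list(msp$msp_id, samples))
  list(catalog = catalog, funcmap = funcmap, modules = modules,
       gene_freqs = gene_freqs, msp_abund = msp_abund)
}
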