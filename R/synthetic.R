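#' Configuration of the synthetic cohort generator
#'
#' Fixes the study conditions emulated by [simulate_cohort()]: four ordered
#' risk groups (0 < 1 < 2 < D), a log-normal compositional community with
#' enterotype-like mixture structure, a planted monotone abundance gradient
#' on a known subset of species (and the modules they carry), dietary
#' variables with a planted 3-factor structure, and covariate imbalance
#' concentrated in group D (older age, higher BMI).
#'
#' @param n_per_group samples per risk group (default 48).
#' @param n_msp number of MetaGenomic Species in the catalog (default 300,
#'   minimum 80).
#' @param n_marker_genes marker genes per MSP (fixed at 100 in the real
#'   catalogs; configurable for small fixtures).
#' @param n_gradient_species planted monotone species (default 20; 60%
#'   decreasing with risk, the rest increasing).
#' @param gradient_log2fc per-step log2 fold change of planted species
#'   across the ordered groups (default 1.0).
#' @param n_modules functional module count (default 50; the first 10 are
#'   carried by planted species and therefore inherit the gradient).
#' @param n_diet_vars dietary variable count (default 40 = 28 food groups +
#'   12 nutrients; minimum 28).
#' @param depth target reads per sample for [simulate_gene_counts()]
#'   (default 1e6; desk scale).
#' @param seed RNG seed; a fixed seed gives byte-identical outputs.
#' @param n_enterotypes latent mixture components (3 or 4; default 4).
#' @param noise_sd per-sample log-scale noise (default 1.0).
#' @param n_accessory accessory genes per MSP (default 10).
#' @param age_shift,bmi_shift additive covariate offsets per group
#'   (defaults follow the published cohort's median imbalance: age +5 y in
#'   D; BMI +0.1/+1.4/+6.3 across groups 1/2/D).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = 48L, n_msp = 300L,
                              n_marker_genes = 100L,
                              n_gradient_species = 20L,
                              gradient_log2fc = 1.0, n_modules = 50L,
                              n_diet_vars = 40L, depth = 1e6, seed = 1L,
                              n_enterotypes = 4L, noise_sd = 1.0,
                              n_accessory = 10L,
                              age_shift = c(0, 0, 0, 5),
                              bmi_shift = c(0, 0.1, 1.4, 6.3)) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_msp = as.integer(n_msp),
              n_marker_genes = as.integer(n_marker_genes),
              n_gradient_species = as.integer(n_gradient_species),
              gradient_log2fc = gradient_log2fc,
              n_modules = as.integer(n_modules),
              n_diet_vars = as.integer(n_diet_vars),
              depth = depth, seed = as.integer(seed),
              n_enterotypes = as.integer(n_enterotypes),
              noise_sd = noise_sd, n_accessory = as.integer(n_accessory),
              age_shift = age_shift, bmi_shift = bmi_shift)
  with(cfg, {
    stopifnot(n_per_group > 0, n_msp >= 80, n_marker_genes > 0,
              n_gradient_species > 0, n_gradient_species <= n_msp %/% 4,
              is.finite(gradient_log2fc), n_modules >= 12,
              n_diet_vars >= 28, depth > 0, n_enterotypes %in% 3:4,
              noise_sd > 0, n_accessory >= 0)
  })
  structure(cfg, class = "simulation_config")
}

# 28 food groups (g/day); four "sweet", seven "fiber", eight "animal
# protein" groups carry the planted factor structure, the rest are noise
food_group_names <- function() {
  c("sweets", "pastries", "sweet_biscuits", "sweet_beverages",
    "vegetables", "oilseeds", "whole_grains", "legumes", "fruits",
    "unsweetened_beverages", "soup",
    "processed_meat", "red_meat", "added_fat", "tubers", "refined_cereals",
    "eggs", "alcoholic_beverages", "cheese",
    "milk", "yogurt", "fish", "poultry", "bread", "coffee", "water",
    "rice", "butter")
}

nutrient_names <- function() {
  c("fiber", "simple_carbohydrates", "total_protein", "protein_fiber_ratio",
    "vitamin_C", "vitamin_A", "vitamin_B9", "vitamin_B5", "copper", "zinc",
    "copper_zinc_ratio", "energy")
}

# internal: deterministic catalog layout with genus quotas.
# Returns catalog + funcmap + module definitions + gene lengths + the
# planted/focal species bookkeeping the abundance model needs.
# The layout is drawn under a fixed internal seed so that the ground-truth
# identifiers (planted species, modules, focal taxa) depend only on the
# configuration, not on the simulation seed; the caller re-seeds afterwards.
build_catalog <- function(config) {
  set.seed(193841L)
  nm <- config$n_msp
  msp_ids <- sprintf("msp_%04d", seq_len(nm))

  phyla <- list(
    Bacillota = list(gram = "positive",
                     genera = c("Faecalibacterium", "Blautia", "Anaerostipes",
                                "Roseburia", "Ruminococcus", "Clostridium",
                                "Lactobacillus", "Gemmiger")),
    Bacteroidota = list(gram = "negative",
                        genera = c("Parabacteroides", "Alistipes",
                                   "Odoribacter")),
    Pseudomonadota = list(gram = "negative",
                          genera = c("Escherichia", "Klebsiella",
                                     "Sutterella")),
    Actinomycetota = list(gram = "positive",
                          genera = c("Bifidobacterium", "Collinsella")),
    Fusobacteriota = list(gram = "negative", genera = c("Fusobacterium")))

  n_prev <- max(8L, round(0.05 * nm))
  n_bact <- max(15L, round(0.08 * nm))
  n_focal <- 4L
  phylum <- character(nm); genus <- character(nm)
  i_prev <- seq_len(n_prev)
  i_bact <- n_prev + seq_len(n_bact)
  i_focal <- n_prev + n_bact + seq_len(n_focal)
  phylum[i_prev] <- "Bacteroidota"; genus[i_prev] <- "Prevotella"
  phylum[i_bact] <- "Bacteroidota"; genus[i_bact] <- "Bacteroides"
  phylum[i_focal] <- "Bacillota";   genus[i_focal] <- "Enterocloster"
  rest <- setdiff(seq_len(nm), c(i_prev, i_bact, i_focal))
  ph_draw <- sample(names(phyla), length(rest), replace = TRUE,
                    prob = c(0.52, 0.18, 0.12, 0.13, 0.05))
  phylum[rest] <- ph_draw
  genus[rest] <- vapply(ph_draw, function(p)
    sample(phyla[[p]]$genera, 1L), character(1))

  # planted gradient species: decreasing = Gram+ Bacillota (gut),
  # increasing = Gram- Bacteroidota/Pseudomonadota, 3 of them oral
  n_neg <- round(0.6 * config$n_gradient_species)
  n_pos <- config$n_gradient_species - n_neg
  pool_neg <- rest[phylum[rest] == "Bacillota"]
  pool_pos <- rest[phylum[rest] %in% c("Bacteroidota", "Pseudomonadota")]
  planted_neg <- sort(sample(pool_neg, n_neg))
  planted_pos <- sort(sample(pool_pos, n_pos))

  # habitat origin: ~10% oral, Fusobacteriota always oral, plus up to 3 of
  # the increasing planted species so the oral fraction rises with risk
  oral <- which(phylum == "Fusobacteriota")
  oral <- union(oral, planted_pos[seq_len(min(3L, n_pos))])
  extra <- setdiff(rest, union(oral, c(planted_neg, planted_pos)))
  want <- max(0L, round(0.10 * nm) - length(oral))
  oral <- sort(union(oral, sample(extra, min(want, length(extra)))))
  origin <- ifelse(seq_len(nm) %in% oral, "oral", "gut")

  species <- paste0(tolower(genus), "_sp", seq_len(nm))
  unclassified <- sort(sample(rest, round(0.05 * nm)))
  species[unclassified] <- ""
  taxonomy <- sprintf(
    "d__Bacteria;p__%s;c__%s_c;o__%s_o;f__%s_f;g__%s;s__%s",
    phylum, phylum, phylum, genus, genus, species)
  gram <- vapply(phylum, function(p) phyla[[p]]$gram, character(1))
  gram[unclassified] <- NA_character_   # exercises the phylum fallback

  meta <- data.frame(msp_id = msp_ids, taxonomy = taxonomy, gram = gram,
                     origin = origin, stringsAsFactors = FALSE)

  ## ---- functional catalog ----
  ko_pool <- sprintf("K%05d", seq_len(600))
  n_mod <- config$n_modules
  module_ids <- sprintf("M%03d", seq_len(n_mod))
  mod_sizes <- sample(5:10, n_mod, replace = TRUE)
  mod_sizes[11:min(20, n_mod)] <- sample(5:8, length(11:min(20, n_mod)),
                                         replace = TRUE)
  modules <- lapply(mod_sizes, function(s) list(sample(ko_pool, s)))
  names(modules) <- module_ids

  # carriers: modules 1-5 ride the decreasing planted species, 6-10 the
  # increasing ones; 11-20 are "partial" (one component accessory, so
  # present only per-sample); the rest have random carrier sets
  carriers <- vector("list", n_mod)
  for (m in seq_len(n_mod)) {
    carriers[[m]] <-
      if (m <= 5) sample(planted_neg, min(6L, n_neg))
      else if (m <= 10) sample(planted_pos, min(5L, n_pos))
      else sample(seq_len(nm), sample(5:30, 1L))
  }
  partial <- 11:min(20, n_mod)

  ## ---- genes ----
  gene_rows <- vector("list", nm)
  func_rows <- vector("list", nm)
  gid <- 0L
  mk <- config$n_marker_genes
  for (i in seq_len(nm)) {
    mods_i <- which(vapply(carriers, function(cc) i %in% cc, logical(1)))
    core_orth <- character(0); acc_orth <- character(0)
    for (m in mods_i) {
      comp <- modules[[m]][[1]]
      if (m %in% partial) {
        acc_orth <- c(acc_orth, comp[1])      # one component accessory
        core_orth <- c(core_orth, comp[-1])
      } else core_orth <- c(core_orth, comp)
    }
    core_orth <- unique(core_orth)
    acc_orth <- unique(c(acc_orth,
                         sample(ko_pool, config$n_accessory, replace = TRUE)))
    acc_orth <- setdiff(acc_orth, core_orth)
    n_genes <- mk + length(core_orth) + length(acc_orth)
    ids <- sprintf("gene_%07d", gid + seq_len(n_genes))
    gid <- gid + n_genes
    gene_rows[[i]] <- data.frame(
      msp_id = msp_ids[i], gene_id = ids,
      is_marker = rep(c(TRUE, FALSE), c(mk, n_genes - mk)),
      is_core = rep(c(TRUE, FALSE),
                    c(mk + length(core_orth), length(acc_orth))),
      stringsAsFactors = FALSE)
    orth <- c(core_orth, acc_orth)
    if (length(orth))
      func_rows[[i]] <- data.frame(gene_id = ids[mk + seq_along(orth)],
                                   ortholog = orth, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  funcmap <- do.call(rbind, func_rows)
  gene_lengths <- stats::setNames(sample(500:2000, nrow(genes),
                                         replace = TRUE), genes$gene_id)

  list(catalog = msp_catalog(genes, meta, n_markers = mk),
       funcmap = funcmap, modules = modules, gene_lengths = gene_lengths,
       phylum = phylum, genus = genus,
       planted_neg = planted_neg, planted_pos = planted_pos,
       focal = i_focal,
       gradient_modules = module_ids[1:10],
       module_signs = c(rep(-1L, 5), rep(1L, 5)))
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Draws MSP abundances from a zero-inflated log-normal compositional model
#' with (i) latent enterotype-like mixture components whose frequencies
#' shift across groups, (ii) a planted monotone log-scale gradient on a
#' known species subset (decreasing species are Gram-positive gut
#' commensals, increasing ones Gram-negative and partly oral), (iii) a
#' focal species block whose co-abundance strengthens with the group
#' ordinal (guild emergence), (iv) dietary variables with a planted
#' 3-factor structure and group-ordered shifts, coupled to designated
#' microbiota features, and (v) covariates with group imbalance.
#' Compositional closure means planted log-fold changes leak slightly onto
#' unplanted features; this is accepted and documented.
#'
#' @param config a [simulation_config()].
#' @return list with elements `catalog` ([msp_catalog()]), `abundance`
#'   (MSP x sample relative abundances), `cohort` (per-sample metadata +
#'   dietary variables), `truth` (planted ground truth), `funcmap`
#'   (gene -> ortholog), `modules` (module definitions), `gene_lengths`,
#'   and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  group_levels <- c("0", "1", "2", "D")
  groups <- factor(rep(group_levels, each = config$n_per_group),
                   levels = group_levels, ordered = TRUE)
  n <- length(groups)
  sample_ids <- sprintf("S%03d", seq_len(n))
  ord <- group_ordinal(groups)

  parts <- build_catalog(config)   # fixed-seed layout
  set.seed(config$seed)            # simulation draws under the user's seed
  nm <- config$n_msp
  msp_ids <- parts$catalog$msp$msp_id

  ## latent enterotype components (log-mean offsets per species)
  K <- config$n_enterotypes
  boost <- matrix(0, K, nm)
  boost[1, parts$phylum == "Bacillota"] <- 1.2                    # EtF
  boost[2, parts$genus == "Bacteroides"] <- 2.2                   # EtB1
  boost[2, parts$genus == "Faecalibacterium"] <- 0.8
  boost[3, parts$genus == "Prevotella"] <- 3.5                    # EtP
  if (K >= 4) {                                                   # EtB2
    boost[4, parts$genus == "Bacteroides"] <- 3.2
    boost[4, parts$phylum == "Bacillota"] <- -1.0
  }
  # component frequencies per group (EtF, EtB1, EtP, EtB2)
  pi_g <- rbind(c(0.36, 0.50, 0.04, 0.10),
                c(0.33, 0.48, 0.08, 0.11),
                c(0.22, 0.47, 0.21, 0.10),
                c(0.17, 0.22, 0.13, 0.48))[, seq_len(K), drop = FALSE]
  pi_g <- pi_g / rowSums(pi_g)
  comp <- vapply(seq_len(n), function(i)
    sample.int(K, 1L, prob = pi_g[ord[i] + 1L, ]), integer(1))

  ## planted gradient (natural-log shift per ordinal step)
  step <- log(2) * config$gradient_log2fc
  planted <- c(parts$planted_neg, parts$planted_pos)
  signs <- c(rep(-1L, length(parts$planted_neg)),
             rep(1L, length(parts$planted_pos)))
  grad <- matrix(0, nm, n)
  grad[planted, ] <- outer(signs * step, ord)

  ## focal guild block: shared latent factor with group-increasing loading
  u <- stats::rnorm(n)
  w <- c(0.3, 0.8, 1.3, 1.8)[ord + 1L]
  focal_eff <- matrix(0, nm, n)
  focal_eff[parts$focal, ] <- rep(w * u, each = length(parts$focal))

  ## dietary variables
  diet <- simulate_diet(config, ord)

  ## diet -> microbiota coupling (on the log scale, z-scored diet vars)
  pool_bg <- setdiff(seq_len(nm), c(planted, parts$focal))
  diet_targets <- sort(sample(pool_bg, 2L))     # purely diet-driven species
  diet_effects <- list(
    sweet_beverages = stats::setNames(0.8, msp_ids[diet_targets[1]]),
    vitamin_C = stats::setNames(0.8, msp_ids[diet_targets[2]]),
    fruits = stats::setNames(0.3, msp_ids[planted[1]]))
  diet_eff <- matrix(0, nm, n)
  for (dv in names(diet_effects)) {
    z <- as.numeric(scale(diet$vars[, dv]))
    for (tg in names(diet_effects[[dv]])) {
      diet_eff[match(tg, msp_ids), ] <-
        diet_eff[match(tg, msp_ids), ] + diet_effects[[dv]][tg] * z
    }
  }

  ## assemble log abundances, zero-inflate, close to relative abundance
  mu <- stats::rnorm(nm, 0, 1.6)
  # planted, focal, diet-coupled and enterotype-signature species are kept
  # fully prevalent so the planted effects are observable
  always_on <- unique(c(planted, parts$focal, diet_targets,
                        which(parts$genus %in%
                                c("Prevotella", "Bacteroides"))))
  p_detect <- stats::runif(nm, 0.05, 1)
  p_detect[always_on] <- 1
  log_a <- matrix(mu, nm, n) + t(boost[comp, , drop = FALSE]) + grad +
    focal_eff + diet_eff +
    matrix(stats::rnorm(nm * n, 0, config$noise_sd), nm, n)
  present <- matrix(stats::rbinom(nm * n, 1L, rep(p_detect, n)), nm, n)
  ab <- exp(log_a) * present
  ab <- sweep(ab, 2L, pmax(colSums(ab), .Machine$double.eps), "/")
  dimnames(ab) <- list(msp_ids, sample_ids)

  ## covariates with group imbalance
  p_women <- c(0.81, 0.79, 0.88, 0.61)[ord + 1L]
  sex <- ifelse(stats::rbinom(n, 1L, p_women) == 1L, "W", "M")
  age <- round(stats::rnorm(n, 53, 6) + config$age_shift[ord + 1L])
  bmi <- round(stats::rnorm(n, 23.5, 2.5) + config$bmi_shift[ord + 1L], 1)
  act_p <- rbind(c(0.36, 0.30, 0.34), c(0.19, 0.35, 0.46),
                 c(0.26, 0.41, 0.33), c(0.30, 0.28, 0.42))
  activity <- vapply(seq_len(n), function(i)
    sample(c("low", "medium", "high"), 1L, prob = act_p[ord[i] + 1L, ]),
    character(1))
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.88, 0.05, 0.07))
  cohort <- data.frame(sample_id = sample_ids, group = groups, sex = sex,
                       age = age, bmi = bmi, activity = activity,
                       smoking = smoking, stringsAsFactors = FALSE)
  cohort <- cbind(cohort, diet$vars)

  truth <- list(
    gradient_species_ids = stats::setNames(signs, msp_ids[planted]),
    gradient_module_ids = stats::setNames(parts$module_signs,
                                          parts$gradient_modules),
    enterotype_labels = stats::setNames(
      c("EtF", "EtB1", "EtP", "EtB2")[comp], sample_ids),
    diet_effects = diet_effects,
    diet_gradient_ids = diet$gradient_ids,
    diet_loadings = diet$loadings,
    focal_species_ids = msp_ids[parts$focal])

  list(catalog = parts$catalog, abundance = ab, cohort = as_cohort(cohort),
       truth = truth, funcmap = parts$funcmap, modules = parts$modules,
       gene_lengths = parts$gene_lengths, config = config)
}

# internal: dietary variables. 28 food groups follow a 3-factor model
# ("sweet", "fiber", "animal protein") whose factor means shift across
# groups; nutrients are derived from the factors with extra planted
# monotone gradients.
simulate_diet <- function(config, ord) {
  n <- length(ord)
  foods <- food_group_names()
  lambda <- matrix(0, 28, 3, dimnames = list(foods, paste0("F", 1:3)))
  lambda[1:4, 1] <- 0.75                        # sweet pattern
  lambda[5:11, 2] <- 0.75                       # fiber pattern
  lambda[12:19, 3] <- 0.75                      # animal protein pattern
  f_means <- rbind(c(0.25, 0.30, -0.10), c(0.25, 0.10, -0.10),
                   c(-0.25, -0.20, -0.10), c(-0.35, -0.30, 0.40))
  f <- f_means[ord + 1L, ] + matrix(stats::rnorm(3 * n), n, 3)
  uniq <- sqrt(1 - 0.75^2)
  z_food <- f %*% t(lambda) + matrix(stats::rnorm(28 * n, 0, uniq), n, 28)
  food_vals <- sweep(sweep(z_food, 2L, rep(40, 28), "*"), 2L,
                     rep(200, 28), "+")
  colnames(food_vals) <- foods

  grad_step <- c(fiber = -0.30, simple_carbohydrates = -0.25,
                 vitamin_C = -0.20, protein_fiber_ratio = 0.25,
                 copper_zinc_ratio = 0.15)
  nut <- matrix(stats::rnorm(12 * n, 0, 1), n, 12,
                dimnames = list(NULL, nutrient_names()))
  nut[, "fiber"] <- 0.8 * f[, 2] + stats::rnorm(n, 0, 0.5)
  nut[, "simple_carbohydrates"] <- 0.8 * f[, 1] + stats::rnorm(n, 0, 0.5)
  nut[, "total_protein"] <- 0.6 * f[, 3] + stats::rnorm(n, 0, 0.6)
  nut[, "vitamin_C"] <- 0.7 * f[, 2] + stats::rnorm(n, 0, 0.6)
  nut[, "vitamin_A"] <- 0.3 * f[, 2] + stats::rnorm(n, 0, 0.9)
  nut[, "vitamin_B9"] <- 0.3 * f[, 2] + stats::rnorm(n, 0, 0.9)
  nut[, "energy"] <- 0.4 * f[, 1] + 0.3 * f[, 3] + stats::rnorm(n, 0, 0.8)
  nut[, "protein_fiber_ratio"] <-
    0.5 * (nut[, "total_protein"] - nut[, "fiber"]) + stats::rnorm(n, 0, 0.4)
  nut[, "copper_zinc_ratio"] <-
    0.5 * (nut[, "copper"] - nut[, "zinc"]) + stats::rnorm(n, 0, 0.4)
  for (v in names(grad_step)) nut[, v] <- nut[, v] + grad_step[v] * ord
  nut_vals <- sweep(sweep(nut, 2L, rep(15, 12), "*"), 2L, rep(100, 12), "+")

  vars <- cbind(as.data.frame(food_vals), as.data.frame(nut_vals))
  extra <- config$n_diet_vars - 40L
  if (extra > 0) {
    more <- matrix(stats::rnorm(extra * n, 100, 15), n, extra,
                   dimnames = list(NULL, sprintf("nutrient_x%02d",
                                                 seq_len(extra))))
    vars <- cbind(vars, as.data.frame(more))
  } else if (extra < 0) {
    vars <- vars[, seq_len(config$n_diet_vars), drop = FALSE]
  }
  list(vars = vars, loadings = lambda,
       gradient_ids = sign(grad_step))
}

#' Simulate a raw gene count table from MSP abundances
#'
#' Inverse of the profiling stage: per-sample gene counts are multinomial
#' with rates proportional to (owning-MSP abundance x gene length), so that
#' length normalisation followed by marker averaging recovers the input
#' abundances. A configurable fraction of each MSP's marker genes can be
#' zeroed per sample to exercise the 10%-detection rule.
#'
#' @param msp_abund MSP x sample abundance matrix (non-negative).
#' @param catalog the matching [msp_catalog()].
#' @param gene_lengths named lengths for every catalog gene.
#' @param depth reads per sample (> 0).
#' @param seed RNG seed.
#' @param marker_dropout fraction of each MSP's markers zeroed per sample
#'   (default 0).
#' @return a [gene_count_table()] whose columns each sum to `depth` (or 0
#'   for all-zero samples).
#' @export
simulate_gene_counts <- function(msp_abund, catalog, gene_lengths, depth,
                                 seed = 1L, marker_dropout = 0) {
  check_abundance(msp_abund)
  if (depth <= 0) stop("depth must be > 0")
  stopifnot(marker_dropout >= 0, marker_dropout < 1)
  genes <- catalog$genes
  gl <- gene_lengths[genes$gene_id]
  if (anyNA(gl)) stop("gene_lengths missing for some catalog genes")
  idx <- match(genes$msp_id, rownames(msp_abund))
  if (anyNA(idx)) stop("catalog MSP missing from abundance matrix")
  set.seed(as.integer(seed))
  out <- matrix(0L, nrow(genes), ncol(msp_abund),
                dimnames = list(genes$gene_id, colnames(msp_abund)))
  for (j in seq_len(ncol(msp_abund))) {
    rate <- msp_abund[idx, j] * gl
    if (marker_dropout > 0) {
      drop <- genes$is_marker &
        stats::runif(nrow(genes)) < marker_dropout
      rate[drop] <- 0
    }
    if (sum(rate) == 0) next
    out[, j] <- stats::rmultinom(1L, size = depth, prob = rate)[, 1]
  }
  gene_count_table(out, gene_lengths[rownames(out)])
}

#' Write the simulated inputs to a directory
#'
#' Emits the package's documented file dialects: `catalog.tsv`,
#' `msp_abundance.tsv`, `cohort.csv`, `funcmap.tsv`, `modules.tsv`,
#' `gene_lengths.tsv` and `ground_truth.json` (plus `gene_counts.tsv` when
#' a `counts` element is present).
#'
#' @param sim result of [simulate_cohort()] (optionally with an added
#'   `counts` element from [simulate_gene_counts()]).
#' @param outdir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_msp_catalog(sim$catalog, p("catalog.tsv"))
  write_matrix_tsv(sim$abundance, p("msp_abundance.tsv"))
  write_cohort(sim$cohort, p("cohort.csv"))
  utils::write.table(sim$funcmap, p("funcmap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_module_defs(sim$modules, p("modules.tsv"))
  utils::write.table(
    data.frame(gene_id = names(sim$gene_lengths),
               length = unname(sim$gene_lengths)),
    p("gene_lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c("catalog.tsv", "msp_abundance.tsv", "cohort.csv",
             "funcmap.tsv", "modules.tsv", "gene_lengths.tsv",
             "ground_truth.json")
  if (!is.null(sim$counts)) {
    write_matrix_tsv(sim$counts$counts, p("gene_counts.tsv"))
    files <- c(files, "gene_counts.tsv")
  }
  invisible(stats::setNames(file.path(outdir, files), files))
}
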