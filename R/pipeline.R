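#' Default pipeline configuration
#'
#' Assembles the parameters of every stage; any element can be overridden.
#' With `simulate = TRUE` the synthetic generator produces all inputs;
#' otherwise paths to the four input files must be supplied.
#'
#' @param simulate generate inputs with [simulate_cohort()] (default TRUE).
#' @param sim_config a [simulation_config()] for the generator.
#' @param paths named list of input paths (`catalog`, `abundance`,
#'   `cohort`, `funcmap`, `modules`) when `simulate = FALSE`.
#' @param seed master seed.
#' @param alpha,min_effect,prevalence gradient screen parameters.
#' @param k_range,dmm_scale enterotyping parameters.
#' @param n_resamples,edge_threshold,network_prevalence guild parameters.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = TRUE, sim_config = simulation_config(),
                       paths = list(), seed = 1L, alpha = 0.05,
                       min_effect = 0.2, prevalence = 0.10,
                       k_range = 2:5, dmm_scale = 1e4, n_resamples = 50L,
                       edge_threshold = 0.7, network_prevalence = 0.5) {
  structure(list(simulate = simulate, sim_config = sim_config,
                 paths = paths, seed = as.integer(seed), alpha = alpha,
                 min_effect = min_effect, prevalence = prevalence,
                 k_range = k_range, dmm_scale = dmm_scale,
                 n_resamples = as.integer(n_resamples),
                 edge_threshold = edge_threshold,
                 network_prevalence = network_prevalence),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> profiling metrics -> enterotyping ->
#' module potential -> gradient screen (species + modules) -> dietary
#' patterns and diet screen -> guild networks, writing each stage's tables
#' under `outdir` together with a manifest JSON (input hashes, parameters,
#' package version, seed). Re-running with an identical config and seed
#' reproduces every output byte for byte.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest` (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  stages <- character(0)
  log_stage <- function(s) {
    message(sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), s))
    stages <<- c(stages, s)
  }

  ## inputs
  if (config$simulate) {
    log_stage("simulate")
    sim <- simulate_cohort(config$sim_config)
    catalog <- sim$catalog; abund <- sim$abundance; cohort <- sim$cohort
    funcmap <- sim$funcmap; modules <- sim$modules
    write_simulation(sim, outdir)
  } else {
    log_stage("load")
    need <- c("catalog", "abundance", "cohort", "funcmap", "modules")
    for (nm in need) {
      if (is.null(config$paths[[nm]]))
        stop("config$paths$", nm, " is required when simulate = FALSE")
      if (!file.exists(config$paths[[nm]]))
        stop("input file not found: ", config$paths[[nm]])
    }
    catalog <- read_msp_catalog(config$paths$catalog)
    abund <- read_matrix_tsv(config$paths$abundance)
    cohort <- read_cohort(config$paths$cohort)
    funcmap <- utils::read.delim(config$paths$funcmap,
                                 stringsAsFactors = FALSE)
    modules <- read_module_defs(config$paths$modules)
    sim <- NULL
  }
  if (!identical(colnames(abund), cohort$sample_id))
    stop("abundance samples and cohort rows do not match")

  ## ecosystem metrics
  log_stage("profile")
  origin <- stats::setNames(catalog$msp$origin, catalog$msp$msp_id)
  gut <- abund[origin[rownames(abund)] == "gut", , drop = FALSE]
  oral <- abund[origin[rownames(abund)] == "oral", , drop = FALSE]
  metrics <- data.frame(
    sample_id = colnames(abund),
    richness = richness(abund),
    gram_ratio = suppressWarnings(gram_ratio(abund, catalog)),
    oral_gut_ratio = oral_gut_ratio(gut, oral))
  utils::write.csv(metrics, p("ecosystem_metrics.csv"), row.names = FALSE,
                   quote = FALSE)

  ## enterotypes
  log_stage("enterotype")
  genus <- aggregate_taxa(abund, catalog, "genus")
  counts <- genus_count_table(genus, scale = config$dmm_scale)
  model <- select_k(counts, K_range = config$k_range, seed = config$seed)
  assign <- name_enterotypes(model, catalog)
  et_test <- enterotype_group_test(assign, cohort$group,
                                   seed = config$seed)
  utils::write.csv(assign, p("enterotypes.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(K = model$K, weights = model$weights,
         component_names = attr(assign, "component_names"),
         alphas = as.data.frame(model$alphas), fisher_p = et_test$p),
    p("enterotype_model.json"), auto_unbox = TRUE, digits = NA)

  ## module potential
  log_stage("modules")
  gene_freqs <- NULL
  if (config$simulate) {
    counts_tab <- simulate_gene_counts(abund, catalog, sim$gene_lengths,
                                       depth = config$sim_config$depth,
                                       seed = config$seed)
    gene_freqs <- normalize_frequencies(counts_tab)
  }
  baseline <- core_module_presence(catalog, funcmap, modules)
  mod_abund <- if (!is.null(gene_freqs)) {
    refined <- refine_presence_per_sample(baseline, catalog, funcmap,
                                          modules, gene_freqs, abund)
    module_abundance(refined, abund)
  } else {
    # without gene-level data, fall back to baseline carriers everywhere
    carriers <- baseline$present + 0
    t(carriers) %*% abund
  }
  write_matrix_tsv(mod_abund, p("module_abundance.tsv"))

  ## gradient screens
  log_stage("gradient")
  sp_f <- prevalence_filter(abund, config$prevalence)
  sp_screen <- detect_gradient_markers(sp_f, cohort, alpha = config$alpha,
                                       min_effect = config$min_effect)
  sp_screen <- validate_screen(sp_screen, sp_f, cohort,
                               alpha = config$alpha)
  mod_f <- prevalence_filter(mod_abund, config$prevalence)
  mod_screen <- detect_gradient_markers(mod_f, cohort,
                                        alpha = config$alpha,
                                        min_effect = config$min_effect)
  utils::write.table(sp_screen, p("screen_species.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mod_screen, p("screen_modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## diet
  log_stage("diet")
  food_cols <- intersect(food_group_names(), names(cohort))
  diet_cols <- setdiff(names(cohort),
                       c("sample_id", "group", "sex", "age", "bmi",
                         "activity", "smoking"))
  patterns <- if (length(food_cols) >= 4)
    dietary_patterns(cohort[, food_cols]) else NULL
  diet_screen <- diet_group_tests(cohort[, diet_cols], cohort,
                                  alpha = config$alpha,
                                  min_effect = config$min_effect)
  utils::write.table(diet_screen, p("screen_diet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(patterns)) {
    write_matrix_tsv(patterns$loadings, p("diet_loadings.tsv"))
    utils::write.csv(data.frame(sample_id = cohort$sample_id,
                                patterns$scores),
                     p("diet_scores.csv"), row.names = FALSE, quote = FALSE)
  }

  ## guilds
  log_stage("guilds")
  parts <- list()
  for (g in levels(cohort$group)) {
    ids <- cohort$sample_id[cohort$group == g]
    net <- infer_network(abund, ids,
                         min_prevalence = config$network_prevalence,
                         n_resamples = config$n_resamples,
                         edge_threshold = config$edge_threshold,
                         seed = config$seed + match(g, levels(cohort$group)))
    parts[[g]] <- cluster_guilds(net)
    utils::write.table(net$edges[net$edges$retained, ],
                       p(sprintf("network_group%s_edges.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  memb <- do.call(rbind, lapply(names(parts), function(g)
    data.frame(group = g, node = names(parts[[g]]$membership),
               guild = unname(parts[[g]]$membership))))
  utils::write.csv(memb, p("guild_membership.csv"), row.names = FALSE,
                   quote = FALSE)

  ## manifest
  log_stage("manifest")
  outs <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    package = "microgradient",
    version = as.character(utils::packageVersion("microgradient")),
    seed = config$seed,
    parameters = config[c("alpha", "min_effect", "prevalence", "k_range",
                          "dmm_scale", "n_resamples", "edge_threshold",
                          "network_prevalence")],
    stages = stages,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, sort(outs)))), sort(outs))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  message(sprintf("pipeline finished in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(metrics = metrics, enterotypes = assign,
                 enterotype_test = et_test, module_abundance = mod_abund,
                 species_screen = sp_screen, module_screen = mod_screen,
                 diet_screen = diet_screen, patterns = patterns,
                 guilds = parts, manifest = manifest))
}
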