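# correlated block abundance data: `blocks` species groups share a latent
# factor; returns a features x samples relative-abundance matrix
block_abundance <- function(n_samples = 60, blocks = list(1:10, 11:20),
                            n_species = 30, rho = 0.9, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n_species * n_samples), n_species, n_samples)
  for (b in seq_along(blocks)) {
    u <- rnorm(n_samples)
    for (i in blocks[[b]])
      z[i, ] <- sqrt(rho) * u + sqrt(1 - rho) * z[i, ]
  }
  ab <- exp(z)
  ab <- sweep(ab, 2L, colSums(ab), "/")
  dimnames(ab) <- list(sprintf("sp%02d", 1:n_species),
                       sprintf("s%02d", 1:n_samples))
  ab
}

test_that("CLR transform centres each sample's log profile", {
  ab <- block_abundance(n_samples = 10)
  x <- clr_transform(ab)
  expect_lt(max(abs(colMeans(x))), 1e-12)
  ab0 <- ab; ab0[1, 1] <- 0          # zero handled by half-minimum pseudocount
  expect_silent(clr_transform(ab0))
})

test_that("planted correlation blocks are recovered as network modules", {
  ab <- block_abundance(seed = 2)
  net <- infer_network(ab, colnames(ab), n_resamples = 60, seed = 3)
  ed <- net$edges[net$edges$retained, ]
  blk <- function(id) (as.integer(sub("sp", "", id)) - 1) %/% 10 + 1
  same <- blk(ed$node_i) == blk(ed$node_j)
  within_bg <- blk(ed$node_i) <= 2 & blk(ed$node_j) <= 2
  n_within <- sum(same & within_bg)
  n_between <- sum(!same)
  expect_gt(n_within, 20)                      # blocks tightly connected
  expect_lte(n_between, 0.05 * max(n_within, 1))
  # symmetric by construction: each unordered pair appears once
  expect_false(any(paste(ed$node_i, ed$node_j) %in%
                     paste(ed$node_j, ed$node_i)))

  part <- cluster_guilds(net)
  memb <- part$membership[sprintf("sp%02d", 1:20)]
  expect_gte(adjusted_rand_index(memb, rep(1:2, each = 10)), 0.9)
})

test_that("independent species yield an almost empty network", {
  ab <- block_abundance(blocks = list(), seed = 4)
  net <- infer_network(ab, colnames(ab), n_resamples = 60, seed = 5)
  n_possible <- choose(length(net$nodes), 2)
  expect_lte(sum(net$edges$retained), 0.01 * n_possible)
})

test_that("a duplicated profile is linked at high frequency", {
  ab <- block_abundance(blocks = list(), seed = 6)
  ab <- rbind(ab, dup = ab["sp01", ] * exp(rnorm(ncol(ab), 0, 0.05)))
  ab <- sweep(ab, 2L, colSums(ab), "/")
  net <- infer_network(ab, colnames(ab), n_resamples = 60, seed = 7)
  e <- net$edges
  pair <- (e$node_i == "sp01" & e$node_j == "dup") |
    (e$node_i == "dup" & e$node_j == "sp01")
  expect_gte(e$frequency[pair], 0.9)
})

test_that("the prevalence filter and small groups are enforced", {
  ab <- block_abundance(seed = 8)
  ab["sp30", seq(1, 60, by = 2)] <- 0        # 50% prevalence: kept
  ab["sp29", 1:45] <- 0                      # 25% prevalence: dropped
  net <- infer_network(ab, colnames(ab), n_resamples = 20, seed = 9)
  expect_true("sp30" %in% net$nodes)
  expect_false("sp29" %in% net$nodes)
  expect_error(infer_network(ab, colnames(ab)[1:10], seed = 1),
               "too small")
})

test_that("guild partitions are true partitions with deterministic guilds", {
  ab <- block_abundance(seed = 10)
  net <- infer_network(ab, colnames(ab), n_resamples = 40, seed = 11)
  part <- cluster_guilds(net)
  expect_setequal(unlist(part$guilds), sort(net$nodes))
  expect_equal(sum(lengths(part$guilds)), length(net$nodes))
  # two disconnected cliques cluster into exactly two guilds
  toy <- structure(list(
    nodes = c("a", "b", "c", "d", "e", "f"),
    edges = data.frame(node_i = c("a", "a", "b", "d", "d", "e"),
                       node_j = c("b", "c", "c", "e", "f", "f"),
                       frequency = 1, retained = TRUE),
    edge_threshold = 0.7), class = "stability_network")
  p2 <- cluster_guilds(toy)
  expect_equal(length(p2$guilds), 2L)
  # a path of three nodes is one guild
  toy3 <- structure(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(node_i = c("a", "b"), node_j = c("b", "c"),
                       frequency = 1, retained = TRUE),
    edge_threshold = 0.7), class = "stability_network")
  expect_equal(length(cluster_guilds(toy3)$guilds), 1L)
})

test_that("edge sets are reproducible and stable under more resampling", {
  ab <- block_abundance(seed = 12)
  n1 <- infer_network(ab, colnames(ab), n_resamples = 40, seed = 13)
  n1b <- infer_network(ab, colnames(ab), n_resamples = 40, seed = 13)
  expect_identical(n1$edges, n1b$edges)
  n2 <- infer_network(ab, colnames(ab), n_resamples = 80, seed = 14)
  key <- function(net) with(net$edges[net$edges$retained, ],
                            paste(node_i, node_j))
  jac <- length(intersect(key(n1), key(n2))) /
    length(union(key(n1), key(n2)))
  expect_gte(jac, 0.9)
})

test_that("focal-taxon tracking counts shared-guild membership", {
  mk_part <- function(memb) structure(list(membership = memb,
                                           guilds = split(names(memb),
                                                          memb)),
                                      class = "guild_partition")
  p_all <- mk_part(c(a = 1, b = 1, c = 1, d = 1, x = 2))
  p_split <- mk_part(c(a = 1, b = 2, c = 3, d = 4, x = 4))
  p_missing <- mk_part(c(a = 1, b = 1, x = 2))
  tr <- track_taxa_across_groups(list(`0` = p_split, `1` = p_missing,
                                      `2` = p_all),
                                 c("a", "b", "c", "d"))
  expect_equal(tr$n_focal_in_largest_shared_guild, c(1L, 2L, 4L))
  expect_equal(tr$n_focal_present, c(4L, 2L, 4L))
  expect_error(track_taxa_across_groups(list(`0` = p_all), "zz"),
               "no focal taxon")
})

test_that("focal co-abundance rises with the group ordinal in the cohort", {
  sim <- sim_default()
  parts <- list()
  for (g in levels(sim$cohort$group)) {
    ids <- sim$cohort$sample_id[sim$cohort$group == g]
    net <- infer_network(sim$abundance, ids, n_resamples = 50,
                         seed = 100 + match(g, levels(sim$cohort$group)))
    parts[[g]] <- cluster_guilds(net)
  }
  tr <- track_taxa_across_groups(parts, sim$truth$focal_species_ids)
  expect_true(all(diff(tr$n_focal_in_largest_shared_guild) >= 0))
  expect_gt(tr$n_focal_in_largest_shared_guild[4], 1)
})
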