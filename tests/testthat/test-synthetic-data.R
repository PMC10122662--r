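# the synthetic study generator: determinism, missingness, planted
# correlations, community construction, phylogenetic eigenvectors

test_that("generators are deterministic under a fixed seed", {
  cfg <- synthetic_config(n_species = 40, n_watersheds = 12, seed = 5)
  a <- generate_traits(cfg)
  b <- generate_traits(cfg)
  expect_identical(a$traits, b$traits)
  ca <- generate_communities(cfg, a$traits, a$ground_truth)
  cb <- generate_communities(cfg, b$traits, b$ground_truth)
  expect_identical(ca$occurrences, cb$occurrences)
  expect_identical(ca$covariates, cb$covariates)
  h1 <- generate_human_use(30, seed = 3)
  expect_identical(h1, generate_human_use(30, seed = 3))
})

test_that("missingness is injected at the configured rate", {
  cfg <- synthetic_config(n_species = 859, n_watersheds = 10,
                          missing_rate = 0.181, seed = 2)
  tr <- generate_traits(cfg)
  cells <- as.matrix(tr$traits[, -1])
  expect_lt(abs(mean(is.na(cells)) - 0.181), 0.01)
  expect_false(anyNA(tr$ground_truth$complete_traits))
  cfg0 <- synthetic_config(n_species = 50, n_watersheds = 10,
                           missing_rate = 0, seed = 2)
  expect_false(anyNA(generate_traits(cfg0)$traits))
})

test_that("size trio and temperature trio carry the planted correlations", {
  cfg <- synthetic_config(n_species = 500, n_watersheds = 10,
                          missing_rate = 0, seed = 4)
  tr <- generate_traits(cfg)$traits
  expect_gte(cor(tr$MBl, tr$Lgv), 0.8)
  expect_gte(cor(tr$MBl, tr$MtA), 0.8)
  expect_gte(cor(tr$Lgv, tr$MtA), 0.8)
  expect_gte(cor(tr$TMn, tr$TMx), 0.6)
  expect_lte(cor(tr$TRg, tr$TMn), -0.6)
  expect_true(all(tr$DBt %in% as.character(1:9)))
  expect_true(all(tr$Euh %in% c(0, 1)))
})

test_that("a non-positive-semi-definite correlation target is rejected", {
  R <- default_trait_correlations()
  R["BEl", "REs"] <- R["REs", "BEl"] <- 0.99
  R["BEl", "OGp"] <- R["OGp", "BEl"] <- 0.99
  R["REs", "OGp"] <- R["OGp", "REs"] <- -0.99
  expect_error(synthetic_config(trait_correlations = R),
               "positive semi-definite")
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_species = 10), "n_species")
  expect_error(synthetic_config(n_watersheds = 5), "n_watersheds")
  expect_error(synthetic_config(missing_rate = 1.5), "missing_rate")
  expect_error(synthetic_config(planted_coefs = c(bogus = 1)),
               "planted_coefs")
})

test_that("every watershed holds at least six native species", {
  cfg <- synthetic_config(n_species = 60, n_watersheds = 40, seed = 9)
  tr <- generate_traits(cfg)
  com <- generate_communities(cfg, tr$traits, tr$ground_truth)
  natives <- dplyr::count(
    dplyr::filter(com$occurrences, status == "native"), watershed_id)
  expect_equal(nrow(natives), 40)
  expect_true(all(natives$n >= 6))
  expect_true(all(com$occurrences$status %in%
                    c("native", "translocated", "exotic")))
  # ground truth filled with positive rates
  expect_true(all(com$ground_truth$true_invasibility_rate$lambda > 0))
})

test_that("zero planted coefficients yield equidispersed Poisson counts", {
  cfg <- synthetic_config(n_species = 80, n_watersheds = 500,
                          planted_coefs = c(cd = 0, md = 0),
                          missing_rate = 0, seed = 10)
  tr <- generate_traits(cfg)
  com <- suppressWarnings(generate_communities(cfg, tr$traits,
                                               tr$ground_truth))
  y <- responses(com$occurrences)$invasibility$invasibility
  disp <- var(y) / mean(y)
  expect_gt(disp, 0.8)
  expect_lt(disp, 1.2)
  # constant rate everywhere
  expect_equal(sd(com$ground_truth$true_invasibility_rate$lambda), 0)
})

test_that("phylogenetic eigenvectors are orthogonal and reconstruct distances", {
  pe <- generate_phylo_eigenvectors(25, n_axes = 10, seed = 6)
  m <- as.matrix(pe[, -1])
  g <- crossprod(m)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_error(generate_phylo_eigenvectors(10, n_axes = 10), "n_axes")

  # full positive-axis embedding reproduces the patristic matrix
  set.seed(6)
  tree <- ape::rcoal(12, tip.label = sprintf("sp%04d", 1:12))
  pd <- ape::cophenetic.phylo(tree)[sprintf("sp%04d", 1:12),
                                    sprintf("sp%04d", 1:12)]
  fs <- pcoa(pd, n_axes = sum(eigen(-0.5 * invasispace:::double_center(pd^2),
                                    symmetric = TRUE,
                                    only.values = TRUE)$values > 1e-9),
             warn_low_variance = FALSE)
  rec <- as.matrix(dist(as.matrix(fs$coordinates[, -1])))
  expect_equal(unname(rec), unname(pd), tolerance = 1e-6)
})

test_that("a star tree yields equal patristic distances", {
  star <- ape::stree(4, type = "star")
  star$edge.length <- rep(1, 4)
  star$tip.label <- sprintf("sp%04d", 1:4)
  pd <- ape::cophenetic.phylo(star)
  off <- pd[upper.tri(pd)]
  expect_true(all(off == off[1]))
})

test_that("human-use flags are binary and drive the index downstream", {
  hu <- generate_human_use(200, seed = 12)
  expect_true(all(as.matrix(hu[, -1]) %in% c(0, 1)))
  idx <- human_use_index(hu)
  expect_true(all(idx$HUI >= 0 & idx$HUI <= 4))
  # an all-zero species has index 0
  zero <- hu[rowSums(hu[, -1]) == 0, ]
  if (nrow(zero)) {
    expect_true(all(idx$HUI[match(zero$species_id, idx$species_id)] == 0))
  }
})

test_that("overly aggressive non-native fractions are rejected", {
  cfg <- synthetic_config(n_species = 20, n_watersheds = 10,
                          frac_nonnative = 1, exotic_fraction = 0.9,
                          missing_rate = 0, seed = 1)
  tr <- generate_traits(cfg)
  expect_error(generate_communities(cfg, tr$traits, tr$ground_truth),
               "fewer than 6")
})

test_that("simulate_invasion_study bundles aligned components", {
  sim <- simulate_invasion_study(synthetic_config(n_species = 50,
                                                  n_watersheds = 15,
                                                  seed = 3))
  expect_s3_class(sim, "invasion_simulation")
  expect_setequal(sim$traits$species_id, sim$phylo$species_id)
  expect_true(all(sim$occurrences$species_id %in% sim$traits$species_id))
  expect_setequal(sim$covariates$watershed_id,
                  unique(sim$occurrences$watershed_id))
})
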