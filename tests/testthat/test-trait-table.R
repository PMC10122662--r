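# trait validation, imputation, composites, human use index and the
# native/translocated/exotic group comparisons

test_that("trait_spec and validate_traits enforce declared kinds", {
  spec <- trait_spec(c("x", "b"), c("continuous", "binary"))
  good <- tibble::tibble(species_id = c("a", "b"), x = c(1, 2), b = c(0, 1))
  expect_silent(validate_traits(good, spec))
  bad <- tibble::tibble(species_id = c("a", "b"), x = c(1, 2), b = c(0, 2))
  expect_error(validate_traits(bad, spec), "binary")
  expect_error(trait_spec("o", "ordinal"), "levels")
  expect_error(trait_spec("x", "numeric"), "Unknown trait kind")
})

test_that("imputation returns the input untouched when nothing is missing", {
  mk <- make_mixed_traits(n = 10)
  out <- impute_missing(mk$traits, mk$spec, seed = 1)
  expect_identical(out, mk$traits)
})

test_that("imputation fills every cell, keeps observed values and level sets", {
  mk <- make_mixed_traits(n = 40, seed = 2)
  set.seed(9)
  masked <- mk$traits
  for (tr in setdiff(names(masked), "species_id")) {
    masked[[tr]][sample(40, 8)] <- NA
  }
  out <- impute_missing(masked, mk$spec, seed = 5)
  expect_false(anyNA(out))
  for (tr in setdiff(names(masked), "species_id")) {
    obs <- !is.na(masked[[tr]])
    expect_equal(out[[tr]][obs], masked[[tr]][obs], ignore_attr = TRUE)
  }
  expect_true(all(out$sal %in% c(0, 1)))
  expect_true(all(out$care %in% c("none", "nest", "bearer")))
  expect_true(all(out$diet %in% as.character(1:5)))
})

test_that("imputation recovers a strongly correlated partner trait", {
  set.seed(4)
  n <- 350
  z <- MASS::mvrnorm(n, c(0, 0), rbind(c(1, 0.99), c(0.99, 1)))
  spec <- trait_spec(c("u", "v"), c("continuous", "continuous"))
  traits <- tibble::tibble(species_id = sprintf("s%03d", 1:n),
                           u = z[, 1], v = z[, 2])
  masked <- traits
  idx <- sample(n, round(0.2 * n))
  masked$v[idx] <- NA
  out <- impute_missing(masked, spec, seed = 6)
  expect_gte(cor(out$v[idx], traits$v[idx], method = "spearman"), 0.9)
})

test_that("imputation rejects an all-missing column by name", {
  spec <- trait_spec(c("x", "y"), c("continuous", "continuous"))
  tb <- tibble::tibble(species_id = c("a", "b"), x = c(1, 2),
                       y = c(NA_real_, NA_real_))
  expect_error(impute_missing(tb, spec), "y")
})

test_that("validate_imputation: forest beats mean-fill on correlated traits", {
  mk <- make_correlated_block(n = 120, k = 4, rho = 0.85, seed = 3)
  res <- validate_imputation(mk$traits, mk$spec, mask_rate = 0.2,
                             n_reps = 5, seed = 2, num_trees = 50)
  med <- tapply(res$spearman_continuous, res$method, median)
  expect_gt(med[["random_forest"]], med[["mean_fill"]])
  expect_equal(nrow(res), 10)
})

test_that("validate_imputation handles constant columns and bad rates", {
  spec <- trait_spec(c("k", "x"), c("continuous", "continuous"))
  tb <- tibble::tibble(species_id = sprintf("s%d", 1:30),
                       k = rep(1, 30), x = rnorm(30))
  expect_error(validate_imputation(tb, spec, mask_rate = 1.2), "mask_rate")
  # single rep reproducible under a fixed seed
  mk <- make_correlated_block(n = 60, k = 3, seed = 8)
  r1 <- validate_imputation(mk$traits, mk$spec, n_reps = 1, seed = 11,
                            num_trees = 30)
  r2 <- validate_imputation(mk$traits, mk$spec, n_reps = 1, seed = 11,
                            num_trees = 30)
  expect_equal(r1, r2)
})

test_that("composite axes: collinear trio, eigen oracle, orientation", {
  n <- 50
  set.seed(12)
  base <- rlnorm(n, 3, 0.4)
  traits <- tibble::tibble(
    species_id = sprintf("s%02d", 1:n),
    MBl = base, Lgv = base * 2, MtA = base / 3,   # perfectly collinear logs
    TRg = runif(n, 5, 20), TMn = rnorm(n, 10, 3), TMx = rnorm(n, 25, 3))
  ca <- composite_axes(traits)
  expect_equal(unname(ca$variance_explained["Size_PCA1"]), 1.0,
               tolerance = 1e-10)
  expect_gt(cor(ca$scores$Size_PCA1, traits$MBl), 0)
  expect_gt(cor(ca$scores$Temp_PCA1, traits$TMx), 0)
  expect_true(all(abs(colMeans(ca$scores[, -1])) < 1e-10))

  # first-axis variance equals largest eigenvalue / trace of the 3x3
  # correlation matrix (computed on the temperature trio, no log)
  tm <- scale(cbind(traits$TRg, traits$TMn, traits$TMx))
  ev <- eigen(cor(tm), symmetric = TRUE)$values
  expect_equal(unname(ca$variance_explained["Temp_PCA1"]), ev[1] / 3,
               tolerance = 1e-10)
})

test_that("composite scores are invariant (up to sign) to trio column order", {
  set.seed(14)
  n <- 30
  traits <- tibble::tibble(
    species_id = sprintf("s%02d", 1:n),
    MBl = rlnorm(n, 3, 0.3), Lgv = rlnorm(n, 2, 0.3),
    MtA = rlnorm(n, 1, 0.3),
    TRg = runif(n, 5, 20), TMn = rnorm(n, 10, 3), TMx = rnorm(n, 25, 3))
  a <- composite_axes(traits)
  b <- composite_axes(traits, size_traits = c("MtA", "MBl", "Lgv"))
  # identical axis up to sign; the sign itself follows the orientation anchor
  expect_equal(abs(cor(a$scores$Size_PCA1, b$scores$Size_PCA1)), 1,
               tolerance = 1e-10)
  expect_gt(cor(a$scores$Size_PCA1, traits$MBl), 0)
  expect_gt(cor(b$scores$Size_PCA1, traits$MtA), 0)
  expect_error(composite_axes(dplyr::select(traits, -MBl)), "MBl")
})

test_that("human use index sums flags and rejects non-binary input", {
  flags <- tibble::tibble(species_id = c("a", "b", "c"),
                          fisheries = c(0, 1, 1), aquaculture = c(0, 1, 0),
                          game = c(0, 1, 1), ornamental = c(0, 1, 0))
  h <- human_use_index(flags)
  expect_equal(h$HUI, c(0L, 4L, 2L))
  flags$game[1] <- 2
  expect_error(human_use_index(flags), "game")
})

test_that("group comparisons: identical samples give zero statistics", {
  set.seed(16)
  n <- 30
  spec <- trait_spec(c("x", "c"), c("continuous", "categorical"),
                     list(NULL, c("u", "v")))
  base <- tibble::tibble(species_id = sprintf("n%02d", 1:n),
                         x = rnorm(n), c = rep(c("u", "v"), n / 2))
  dup <- dplyr::mutate(base, species_id = sprintf("t%02d", 1:n))
  traits <- dplyr::bind_rows(base, dup)
  status <- setNames(rep(c("native", "translocated"), each = n),
                     traits$species_id)
  gc <- compare_groups(traits, status, spec)
  expect_equal(gc$statistic[gc$trait == "x"], 0)
  expect_equal(gc$statistic[gc$trait == "c"], 0, tolerance = 1e-12)
  expect_true(all(gc$p_value >= 0 & gc$p_value <= 1))
})

test_that("group comparisons run all three pairs and reject tiny groups", {
  mk <- make_mixed_traits(n = 30, seed = 17)
  status <- setNames(sample(c("native", "translocated", "exotic"), 30,
                            replace = TRUE, prob = c(0.6, 0.3, 0.1)),
                     mk$traits$species_id)
  while (min(table(status)) < 2) {
    status <- setNames(sample(c("native", "translocated", "exotic"), 30,
                              replace = TRUE), mk$traits$species_id)
  }
  gc <- compare_groups(mk$traits, status, mk$spec)
  expect_setequal(paste(gc$group1, gc$group2),
                  c("native translocated", "native exotic",
                    "translocated exotic"))
  expect_equal(nrow(gc), 5 * 3)
  status2 <- status
  status2[] <- "native"
  status2[1] <- "exotic"
  expect_error(compare_groups(mk$traits, status2, mk$spec), "fewer than 2")
})
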