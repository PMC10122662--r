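# the six functional-diversity indices against hand computations,
# invariances, and an independent brute-force oracle suite

test_that("FRic: unit square, degenerate cases, oracle agreement", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(fric(sq), 1.0)
  expect_error(fric(cbind(1:3, 1:3)), "degenerate")
  expect_error(fric(rbind(c(0, 0), c(1, 1))), "distinct points")
  set.seed(21)
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(fric(p), oracle_hull_volume(p), tolerance = 1e-9)
})

test_that("FRic standardized by the pool lies in [0, 1]", {
  set.seed(2)
  pool <- matrix(rnorm(60), 20, 3)
  mem <- pool[1:8, ]
  v <- fric(mem, pool = pool, standardize = TRUE)
  expect_gt(v, 0)
  expect_lte(v, 1)
  expect_error(fric(mem, standardize = TRUE), "pool")
})

test_that("FEve: equal spacing gives 1; hand example gives 0.5", {
  seg <- cbind(seq(0, 1, length.out = 6), 0)
  expect_equal(feve(seg), 1.0)
  # 3 points on a line with MST branches 1 and 3
  pts <- cbind(c(0, 1, 4), 0)
  expect_equal(feve(pts), 0.5)
})

test_that("FEve is invariant under rotation and translation", {
  set.seed(31)
  p <- matrix(rnorm(16), 8, 2)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(feve(p), feve(sweep(p %*% R, 2, c(3, -1), "+")),
               tolerance = 1e-12)
})

test_that("FEve handles duplicate points without crashing", {
  p <- rbind(c(0, 0), c(0, 0), c(1, 0), c(2, 0))
  expect_true(is.finite(feve(p)))
  expect_warning(v <- feve(rbind(c(1, 1), c(1, 1), c(1, 1))), "coincide")
  expect_true(is.na(v))
})

test_that("FDiv: equidistant members give 1; value bounded in (0, 1]", {
  # square corners are all equidistant from the vertex gravity center
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(fdiv(sq), 1.0)
  set.seed(41)
  p <- matrix(rnorm(30), 10, 3)
  v <- fdiv(p)
  expect_gt(v, 0)
  expect_lte(v, 1)
  expect_equal(v, oracle_fdiv(p), tolerance = 1e-9)
})

test_that("FDiv: square corners plus center matches scripted formula", {
  p <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  # vertices are the 4 corners, gravity center (0.5, 0.5)
  dg <- c(rep(sqrt(0.5), 4), 0)
  mdg <- mean(dg)
  expected <- mdg / (mean(abs(dg - mdg)) + mdg)
  expect_equal(fdiv(p), expected, tolerance = 1e-12)
})

test_that("FDis: hand cases and translation invariance", {
  expect_equal(fdis(rbind(c(0, 0), c(4, 0))), 2)  # two points: d/2
  p <- matrix(rnorm(20), 10, 2)
  expect_equal(fdis(p), fdis(sweep(p, 2, c(5, -3), "+")), tolerance = 1e-12)
  expect_equal(fdis(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
})

test_that("FSpe: hand mean over distances to the pool centroid", {
  pool <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))  # centroid (0,0)
  mem <- rbind(c(1, 0), c(3, 0))
  expect_equal(fspe(mem, pool), 2)  # distances 1 and 3
  expect_equal(fspe(rbind(c(0, 0)), pool), 0)
  expect_error(fspe(mem, pool, variant = "nope"))
})

test_that("FSpe mean_pairwise excludes self and is nonnegative", {
  pool <- matrix(rnorm(20), 10, 2,
                 dimnames = list(paste0("s", 1:10), NULL))
  mem <- pool[1:4, ]
  v1 <- fspe(mem, pool, variant = "mean_pairwise",
             member_ids = rownames(mem))
  # manual: mean over members of mean distance to the other 9
  manual <- mean(vapply(1:4, function(i) {
    mean(vapply(setdiff(1:10, i), function(j) {
      sqrt(sum((pool[i, ] - pool[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(v1, manual, tolerance = 1e-12)
  expect_gte(fspe(mem, pool, variant = "pool_centroid"), 0)
})

test_that("FOri: hand case, duplicates, pool-vs-within ordering", {
  pts <- cbind(c(0, 1, 3), 0)
  rownames(pts) <- paste0("s", 1:3)
  expect_equal(fori(pts, variant = "within"), mean(c(1, 1, 2)))
  # duplicated coordinates contribute 0
  dup <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 0))
  expect_equal(fori(dup, variant = "within"), mean(c(0, 0, 5)))
  # nearest neighbour in the pool can only be closer than within community
  set.seed(51)
  pool <- matrix(rnorm(40), 20, 2,
                 dimnames = list(paste0("s", 1:20), NULL))
  mem <- pool[1:6, ]
  expect_gte(fori(mem, variant = "within", member_ids = rownames(mem)),
             fori(mem, pool, variant = "pool", member_ids = rownames(mem)))
})

test_that("indices are invariant to rigid motions; FRic/FDis scale as volume/length", {
  set.seed(61)
  p <- matrix(rnorm(27), 9, 3)
  th <- 1.1
  R3 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  q <- sweep(p %*% R3, 2, c(1, 2, 3), "+")
  expect_equal(fric(p), fric(q), tolerance = 1e-8)
  expect_equal(fdis(p), fdis(q), tolerance = 1e-10)
  expect_equal(fdiv(p), fdiv(q), tolerance = 1e-8)
  s <- 2.5
  expect_equal(fric(s * p), s^3 * fric(p), tolerance = 1e-8)
  expect_equal(fdis(s * p), s * fdis(p), tolerance = 1e-10)
})

test_that("adding an interior species leaves FRic unchanged", {
  set.seed(71)
  p <- matrix(rnorm(24), 8, 3)
  inside <- colMeans(p)  # centroid is interior
  expect_equal(fric(rbind(p, inside)), fric(p), tolerance = 1e-9)
})

test_that("oracle suite: 50 random 8-species communities in 3-D", {
  set.seed(99)
  pool <- matrix(rnorm(40 * 3), 40, 3,
                 dimnames = list(sprintf("s%02d", 1:40), NULL))
  for (k in 1:50) {
    ids <- sample(rownames(pool), 8)
    p <- pool[ids, ]
    expect_equal(fric(p), oracle_hull_volume(p), tolerance = 1e-8)
    expect_equal(feve(p), oracle_feve(p), tolerance = 1e-8)
    expect_equal(fdiv(p), oracle_fdiv(p), tolerance = 1e-8)
    expect_equal(fdis(p), oracle_fdis(p), tolerance = 1e-8)
    expect_equal(fspe(p, pool), oracle_fspe(p, pool), tolerance = 1e-8)
    expect_equal(fori(p, pool, member_ids = ids),
                 oracle_fori(ids, pool), tolerance = 1e-8)
  }
})

test_that("fd_profile matches per-index calls and is composition-stable", {
  set.seed(81)
  n <- 25
  pool <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(sprintf("s%02d", 1:n), NULL))
  space <- structure(list(
    coordinates = tibble::tibble(species_id = rownames(pool),
                                 A1 = pool[, 1], A2 = pool[, 2],
                                 A3 = pool[, 3]),
    eigenvalues = rep(1, 3), variance_explained = rep(1 / 3, 3),
    correction = "none"), class = "functional_space")
  ids1 <- sample(rownames(pool), 8)
  occ <- dplyr::bind_rows(
    tibble::tibble(watershed_id = "w1", species_id = ids1, status = "native"),
    tibble::tibble(watershed_id = "w2", species_id = ids1, status = "native"),
    tibble::tibble(watershed_id = "w3", species_id = sample(rownames(pool), 3),
                   status = "native"))
  suppressMessages(prof <- fd_profile(space, occ))
  expect_equal(nrow(prof), 2)  # w3 below the 6-species floor
  # identical member sets give identical profiles
  expect_equal(unlist(prof[1, -1]), unlist(prof[2, -1]))
  p <- pool[ids1, ]
  expect_equal(prof$FRic[1], fric(p))
  expect_equal(prof$FEve[1], feve(p))
  expect_equal(prof$FDiv[1], fdiv(p))
  expect_equal(prof$FDis[1], fdis(p))
  expect_equal(prof$FSpe[1], fspe(p, pool))
  expect_equal(prof$FOri[1], fori(p, pool, member_ids = ids1))
})
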