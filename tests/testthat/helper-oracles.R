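# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with the package:
# plain loops, naive enumeration.

# Gower dissimilarity of two species by a per-trait loop
oracle_gower_pair <- function(traits, spec, i, j) {
  total <- 0; used <- 0
  for (tr in setdiff(names(traits), "species_id")) {
    kind <- spec$kind[match(tr, spec$trait)]
    x <- traits[[tr]]
    if (kind == "ordinal") {
      lv <- spec$levels[[match(tr, spec$trait)]]
      x <- rank(match(as.character(x), lv), ties.method = "average")
      kind <- "continuous"
    }
    if (kind == "continuous") {
      rng <- max(x) - min(x)
      if (rng == 0) next
      total <- total + abs(x[i] - x[j]) / rng
    } else {
      total <- total + as.numeric(as.character(x[i]) != as.character(x[j]))
    }
    used <- used + 1
  }
  total / used
}

# Exact hull volume of points in general position by facet enumeration
# (R loops; supports 2-D and 3-D which is all the oracle suite needs)
oracle_hull_volume <- function(P) {
  P <- as.matrix(P)
  d <- ncol(P); n <- nrow(P)
  ctr <- colMeans(P)
  vol <- 0
  for (comb in utils::combn(n, d, simplify = FALSE)) {
    pts <- P[comb, , drop = FALSE]
    E <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ])
    if (abs(det(tcrossprod(E))) < 1e-20) next
    nv <- if (d == 2) c(-E[1, 2], E[1, 1]) else
      c(E[1, 2] * E[2, 3] - E[1, 3] * E[2, 2],
        E[1, 3] * E[2, 1] - E[1, 1] * E[2, 3],
        E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1])
    nv <- nv / sqrt(sum(nv^2))
    s <- as.numeric(P %*% nv) - sum(nv * pts[1, ])
    if (all(s <= 1e-9) || all(s >= -1e-9)) {
      area <- if (d == 2) sqrt(sum(E^2)) else
        sqrt(abs(det(tcrossprod(E)))) / 2
      h <- abs(sum(nv * ctr) - sum(nv * pts[1, ]))
      vol <- vol + area * h / d
    }
  }
  vol
}

# hull vertices for the 3-D oracle: points appearing on some facet
oracle_hull_vertices <- function(P) {
  P <- as.matrix(P)
  d <- ncol(P); n <- nrow(P)
  verts <- logical(n)
  for (comb in utils::combn(n, d, simplify = FALSE)) {
    pts <- P[comb, , drop = FALSE]
    E <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ])
    if (abs(det(tcrossprod(E))) < 1e-20) next
    nv <- if (d == 2) c(-E[1, 2], E[1, 1]) else
      c(E[1, 2] * E[2, 3] - E[1, 3] * E[2, 2],
        E[1, 3] * E[2, 1] - E[1, 1] * E[2, 3],
        E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1])
    s <- as.numeric(P %*% nv) - sum(nv * pts[1, ])
    if (all(s <= 1e-9) || all(s >= -1e-9)) verts[comb] <- TRUE
  }
  which(verts)
}

# Prim's algorithm MST branch lengths (independent of vegan)
oracle_mst_lengths <- function(P) {
  D <- as.matrix(dist(P))
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  lens <- numeric(0)
  while (sum(in_tree) < n) {
    sub <- D[in_tree, !in_tree, drop = FALSE]
    lens <- c(lens, min(sub))
    j <- which(!in_tree)[which(sub == min(sub), arr.ind = TRUE)[1, 2]]
    in_tree[j] <- TRUE
  }
  lens
}

oracle_feve <- function(P) {
  lens <- oracle_mst_lengths(P)
  s <- nrow(P)
  pew <- lens / sum(lens)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

oracle_fdiv <- function(P) {
  v <- oracle_hull_vertices(P)
  gv <- colMeans(P[v, , drop = FALSE])
  dg <- apply(P, 1, function(r) sqrt(sum((r - gv)^2)))
  mdg <- mean(dg)
  (sum(dg - mdg) / length(dg) + mdg) /
    (sum(abs(dg - mdg)) / length(dg) + mdg)
}

oracle_fdis <- function(P) {
  ctr <- colMeans(P)
  mean(apply(P, 1, function(r) sqrt(sum((r - ctr)^2))))
}

oracle_fspe <- function(P, pool) {
  ctr <- colMeans(pool)
  mean(apply(P, 1, function(r) sqrt(sum((r - ctr)^2))))
}

oracle_fori <- function(ids, pool) {
  mean(vapply(ids, function(i) {
    min(vapply(setdiff(rownames(pool), i), function(j) {
      sqrt(sum((pool[i, ] - pool[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
}

# small complete trait table with every kind represented
make_mixed_traits <- function(n = 12, seed = 42) {
  set.seed(seed)
  spec <- trait_spec(
    trait = c("len", "ratio", "sal", "care", "diet"),
    kind = c("continuous", "continuous", "binary", "categorical", "ordinal"),
    levels = list(NULL, NULL, NULL, c("none", "nest", "bearer"),
                  as.character(1:5)))
  traits <- tibble::tibble(
    species_id = sprintf("s%02d", seq_len(n)),
    len = rlnorm(n, 3, 0.4),
    ratio = runif(n, 0.1, 0.9),
    sal = rbinom(n, 1, 0.3),
    care = sample(c("none", "nest", "bearer"), n, replace = TRUE),
    diet = as.character(sample(1:5, n, replace = TRUE)))
  list(traits = traits, spec = spec)
}

# correlated continuous block used in the imputation checks
make_correlated_block <- function(n = 350, k = 6, rho = 0.85, seed = 1) {
  set.seed(seed)
  R <- matrix(rho, k, k); diag(R) <- 1
  z <- MASS::mvrnorm(n, rep(0, k), R)
  traits <- tibble::as_tibble(as.data.frame(z))
  names(traits) <- paste0("t", seq_len(k))
  traits <- dplyr::mutate(traits, species_id = sprintf("s%03d", seq_len(n)),
                          .before = 1)
  spec <- trait_spec(paste0("t", seq_len(k)), rep("continuous", k))
  list(traits = traits, spec = spec)
}

small_brt_params <- function(...) {
  brt_params(learning_rate = 0.1, max_trees = 150, n_folds = 5,
             step_size = 15, patience = 4, ...)
}
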