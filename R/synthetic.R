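#' Configuration for the synthetic invasion study generator
#'
#' Bundles every knob of the synthetic world: community and species pool
#' sizes, the fraction of the pool that is non-native, the missing-data rate
#' of the raw trait table (default 0.181, the rate observed in compiled North
#' American fish trait databases), the latent correlation structure of the 17
#' continuous traits, and the planted log-linear Poisson coefficients that
#' make community invasibility causally depend on trait-space predictors.
#'
#' @param n_species Number of species in the pool (>= 20).
#' @param n_watersheds Number of watersheds (>= 10).
#' @param frac_nonnative Fraction of species capable of non-native
#'   establishment.
#' @param missing_rate Fraction of trait cells deleted completely at random.
#' @param trait_correlations Optional 17 x 17 named latent correlation matrix
#'   for the continuous block; defaults to [default_trait_correlations()].
#'   Rejected if not positive semi-definite.
#' @param planted_coefs Named numeric vector of log-scale Poisson
#'   coefficients on standardized predictors. Names must be drawn from the
#'   invasibility predictor set (`cd`, `md`, `FSpe`, `FDis`, `FOri`, `Area`,
#'   `NPP`, `GDP`, `HFI`, `DOF`).
#' @param mean_invasibility Expected non-native count per watershed when all
#'   planted coefficients are zero.
#' @param exotic_fraction Fraction of the non-native pool that is exotic
#'   (historically absent from the continent); the remainder is translocated.
#' @param richness_meanlog,richness_sdlog Log-normal parameters of native
#'   richness per watershed (floored at 6 species).
#' @param richness_cap Upper bound on native richness per watershed.
#' @param max_invasibility Upper bound on the planted Poisson rate: a
#'   watershed cannot accumulate implausibly many non-natives relative to
#'   the pool.
#' @param seed Integer seed; every generator derives its stream from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 300L,
                             n_watersheds = 200L,
                             frac_nonnative = 0.35,
                             missing_rate = 0.181,
                             trait_correlations = NULL,
                             planted_coefs = c(cd = -0.8, md = 0.8,
                                               FSpe = 0.6, GDP = 0.6),
                             mean_invasibility = 4,
                             exotic_fraction = 0.22,
                             richness_meanlog = log(25),
                             richness_sdlog = 0.30,
                             richness_cap = 45L,
                             max_invasibility = 25,
                             seed = 1L) {
  check_count(n_species, "n_species", min = 20L)
  check_count(n_watersheds, "n_watersheds", min = 10L)
  check_proportion(frac_nonnative, "frac_nonnative")
  check_proportion(missing_rate, "missing_rate")
  check_proportion(exotic_fraction, "exotic_fraction")
  allowed <- c("cd", "md", "FSpe", "FDis", "FOri", "Area", "NPP", "GDP",
               "HFI", "DOF")
  if (length(planted_coefs)) {
    if (is.null(names(planted_coefs)) ||
        !all(names(planted_coefs) %in% allowed)) {
      abort(sprintf("planted_coefs names must be drawn from: %s.",
                    paste(allowed, collapse = ", ")))
    }
  }
  R <- trait_correlations %||% default_trait_correlations()
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort("trait_correlations is not positive semi-definite.")
  }
  structure(list(
    n_species = as.integer(n_species),
    n_watersheds = as.integer(n_watersheds),
    frac_nonnative = frac_nonnative,
    missing_rate = missing_rate,
    trait_correlations = R,
    planted_coefs = planted_coefs,
    mean_invasibility = mean_invasibility,
    exotic_fraction = exotic_fraction,
    richness_meanlog = richness_meanlog,
    richness_sdlog = richness_sdlog,
    richness_cap = as.integer(richness_cap),
    max_invasibility = max_invasibility,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

continuous_roster <- function() {
  c("MBl", "BEl", "REs", "OGp", "RMl", "VEp", "BLs", "PFv", "PFs", "CPt",
    "Lgv", "FCt", "MtA", "TLl", "TRg", "TMn", "TMx")
}

#' Default latent correlation matrix for the continuous trait block
#'
#' The size trio (maximum body length, longevity, age at maturity) shares a
#' latent factor at pairwise r = 0.95 (its log-normal transforms retain
#' Pearson r around 0.93 on the trait scale). The temperature trio couples
#' minimum and maximum tolerated temperatures positively (0.7) and both
#' negatively to temperature range (-0.75, -0.6), so a single thermophily
#' axis dominates. Fecundity loads moderately on the size factor. All other
#' traits are uncorrelated.
#'
#' @return A 17 x 17 named correlation matrix.
#' @export
default_trait_correlations <- function() {
  traits <- continuous_roster()
  R <- diag(length(traits))
  dimnames(R) <- list(traits, traits)
  set_r <- function(R, a, b, r) {
    R[a, b] <- r; R[b, a] <- r; R
  }
  R <- set_r(R, "MBl", "Lgv", 0.95)
  R <- set_r(R, "MBl", "MtA", 0.95)
  R <- set_r(R, "Lgv", "MtA", 0.95)
  R <- set_r(R, "TMn", "TMx", 0.70)
  R <- set_r(R, "TRg", "TMn", -0.75)
  R <- set_r(R, "TRg", "TMx", -0.60)
  R <- set_r(R, "FCt", "MBl", 0.45)
  R <- set_r(R, "FCt", "Lgv", 0.40)
  R <- set_r(R, "FCt", "MtA", 0.40)
  R
}

#' Generate a synthetic species-by-trait table
#'
#' Draws the 17 continuous traits from a multivariate normal with the latent
#' correlations of `cfg`, then maps them to trait scales (log-normal body
#' length, longevity, maturity age and fecundity; linear temperature traits so
#' the planted correlations survive exactly). Diet breadth is an ordinal cut
#' of an independent latent normal, euryhalinity a Bernoulli flag and parental
#' care a five-level categorical draw. The complete table is stored in the
#' returned ground truth before cells are deleted completely at random at
#' `cfg$missing_rate`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `traits` (tibble with missing cells), `spec`
#'   ([fish_trait_spec()]) and `ground_truth` (list carrying
#'   `complete_traits` and the planted coefficients).
#' @export
generate_traits <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_species
  ids <- sprintf("sp%04d", seq_len(n))
  R <- cfg$trait_correlations
  z <- MASS::mvrnorm(n, mu = rep(0, ncol(R)), Sigma = R)
  colnames(z) <- colnames(R)

  traits <- tibble::tibble(
    species_id = ids,
    MBl = exp(3.4 + 0.30 * z[, "MBl"]),          # cm
    BEl = pmax(4.5 + 1.20 * z[, "BEl"], 0.8),    # body length / depth
    REs = pmax(0.10 + 0.03 * z[, "REs"], 0.01),
    OGp = pmin(pmax(0.60 + 0.15 * z[, "OGp"], 0), 1),
    RMl = pmax(0.25 + 0.08 * z[, "RMl"], 0.02),
    VEp = pmin(pmax(0.55 + 0.12 * z[, "VEp"], 0), 1),
    BLs = pmax(1.8 + 0.50 * z[, "BLs"], 0.3),
    PFv = pmin(pmax(0.45 + 0.15 * z[, "PFv"], 0), 1),
    PFs = pmax(0.20 + 0.05 * z[, "PFs"], 0.02),
    CPt = pmax(0.35 + 0.10 * z[, "CPt"], 0.02),
    Lgv = exp(2.1 + 0.30 * z[, "Lgv"]),          # years
    FCt = 10^(3.5 + 0.9 * z[, "FCt"]),           # eggs per female
    MtA = exp(0.8 + 0.30 * z[, "MtA"]),          # years
    TLl = pmin(pmax(3.0 + 0.45 * z[, "TLl"], 2), 4.6),
    TRg = 14 + 4 * z[, "TRg"],                   # degrees C
    TMn = 10 + 4 * z[, "TMn"],
    TMx = 26 + 4 * z[, "TMx"],
    Euh = rbinom(n, 1, 0.2),
    PCr = sample(c("open_substratum", "brood_hiders", "substratum_choosers",
                   "nest_spawners", "bearers"),
                 n, replace = TRUE,
                 prob = c(0.40, 0.15, 0.10, 0.25, 0.10)),
    DBt = as.character(findInterval(stats::pnorm(rnorm(n)),
                                    cumsum(c(.08, .12, .15, .15, .15, .12,
                                             .10, .08))) + 1L)
  )
  spec <- fish_trait_spec()
  validate_traits(traits, spec)

  complete <- traits
  if (cfg$missing_rate > 0) {
    cols <- trait_columns(traits, spec)
    n_cells <- n * length(cols)
    holes <- which(runif(n_cells) < cfg$missing_rate)
    for (h in holes) {
      i <- ((h - 1) %% n) + 1
      j <- ((h - 1) %/% n) + 1
      traits[[cols[j]]][i] <- NA
    }
  }
  gt <- list(complete_traits = complete,
             planted_coefs = cfg$planted_coefs,
             true_invasiveness_score = NULL,
             true_invasibility_rate = NULL)
  class(gt) <- "ground_truth"
  list(traits = traits, spec = spec, ground_truth = gt)
}

#' Phylogenetic eigenvectors from a simulated ultrametric tree
#'
#' Simulates a random bifurcating ultrametric tree (coalescent; exponential
#' inter-node times), computes the patristic distance matrix and returns the
#' leading principal-coordinate axes. These stand in for the phylogenetic
#' eigenvectors appended to a trait matrix during imputation.
#'
#' @param n_species Number of tips.
#' @param n_axes Number of eigenvector axes returned (default 10; must be
#'   smaller than `n_species`).
#' @param seed Integer seed.
#' @param species_ids Optional tip labels (default `sp0001`, ...).
#' @param tree Optional `phylo` tree to use instead of simulating one.
#' @return Tibble with `species_id` and columns `PE1..PEk`; the full positive
#'   eigenvalue vector is attached as attribute `eigenvalues`.
#' @export
generate_phylo_eigenvectors <- function(n_species, n_axes = 10L, seed = 1L,
                                        species_ids = NULL, tree = NULL) {
  check_count(n_species, "n_species", min = 3L)
  check_count(n_axes, "n_axes", min = 1L)
  if (n_axes >= n_species) abort("`n_axes` must be smaller than `n_species`.")
  ids <- species_ids %||% sprintf("sp%04d", seq_len(n_species))
  if (is.null(tree)) {
    set.seed(seed)
    tree <- ape::rcoal(n_species, tip.label = ids)
  }
  pd <- ape::cophenetic.phylo(tree)
  pd <- pd[ids, ids]
  fs <- pcoa(pd, n_axes = n_axes, correction = "none", warn_low_variance = FALSE)
  coords <- fs$coordinates
  names(coords) <- c("species_id", paste0("PE", seq_len(n_axes)))
  attr(coords, "eigenvalues") <- fs$eigenvalues[fs$eigenvalues > 0]
  coords
}

#' Per-species human-use flags
#'
#' Four independent Bernoulli columns recording whether a species matters to
#' fisheries, aquaculture, game fishing or the ornamental trade; their row sum
#' is the human use index (0-4), the propagule-pressure proxy.
#'
#' @param n_species Number of species.
#' @param seed Integer seed.
#' @param prob Named probabilities of each flag.
#' @param species_ids Optional ids.
#' @return Tibble with `species_id` and binary columns `fisheries`,
#'   `aquaculture`, `game`, `ornamental`.
#' @export
generate_human_use <- function(n_species, seed = 1L,
                               prob = c(fisheries = 0.30, aquaculture = 0.15,
                                        game = 0.25, ornamental = 0.20),
                               species_ids = NULL) {
  check_count(n_species, "n_species", min = 1L)
  set.seed(seed)
  ids <- species_ids %||% sprintf("sp%04d", seq_len(n_species))
  tibble::tibble(
    species_id = ids,
    fisheries = rbinom(n_species, 1, prob[["fisheries"]]),
    aquaculture = rbinom(n_species, 1, prob[["aquaculture"]]),
    game = rbinom(n_species, 1, prob[["game"]]),
    ornamental = rbinom(n_species, 1, prob[["ornamental"]])
  )
}

# latent species invasiveness: logistic in fecundity, the size composite and
# the human use index (all standardized over the pool)
invasiveness_score <- function(complete, human_use) {
  zfec <- as.numeric(scale(log10(complete$FCt + 1)))
  zsize <- as.numeric(scale(log(complete$MBl) + log(complete$Lgv) +
                              log(complete$MtA)))
  hui <- human_use$fisheries + human_use$aquaculture + human_use$game +
    human_use$ornamental
  zhui <- as.numeric(scale(hui))
  stats::plogis(-0.5 + 1.1 * zfec + 0.7 * zsize + 0.9 * zhui)
}

#' Generate watershed communities with a planted invasibility response
#'
#' Two-pass construction. Pass one draws native assemblages (log-normal
#' richness, floored at six species, members weighted by a species prevalence
#' factor) and a provisional set of non-native occupants per watershed. The
#' functional space of the complete trait table is then built, and the
#' provisional centroid distance (cd), nearest-native mean distance (md),
#' functional specialization (FSpe) and the covariates enter a log-linear
#' Poisson model with the planted coefficients. Pass two redraws each
#' watershed's established non-native count from that Poisson rate and fills
#' the slots with species sampled by their latent invasiveness score, so cd
#' and md are genuinely causal in the synthetic world.
#'
#' @param cfg A [synthetic_config()].
#' @param traits Output of [generate_traits()] (`$traits` may contain missing
#'   cells; the complete table in the ground truth is used for trait-space
#'   computations).
#' @param gt The ground truth returned by [generate_traits()].
#' @param human_use Optional output of [generate_human_use()]; generated from
#'   `cfg` when absent.
#' @return A list with `occurrences` (long tibble: watershed_id, species_id,
#'   status), `covariates` (tibble: watershed_id, Area, NPP, GDP, HFI, DOF),
#'   `human_use`, and the completed `ground_truth` (per-watershed Poisson
#'   rate `true_invasibility_rate`, per-species `true_invasiveness_score`).
#' @export
generate_communities <- function(cfg, traits, gt, human_use = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(gt, "ground_truth"))
  complete <- gt$complete_traits
  n <- cfg$n_species
  ids <- complete$species_id
  human_use <- human_use %||%
    generate_human_use(n, seed = derive_seed(cfg$seed, 211),
                       species_ids = ids)
  set.seed(derive_seed(cfg$seed, 101))

  # species pools ---------------------------------------------------------
  n_nn <- round(cfg$frac_nonnative * n)
  nn_pool <- sample(ids, n_nn)
  n_exotic <- round(cfg$exotic_fraction * n_nn)
  exotic <- if (n_exotic > 0) sample(nn_pool, n_exotic) else character()
  status_of <- setNames(rep("translocated", n_nn), nn_pool)
  status_of[exotic] <- "exotic"
  native_pool <- setdiff(ids, exotic)
  if (length(native_pool) < 6) {
    abort("frac_nonnative/exotic_fraction leave fewer than 6 possible natives per watershed.")
  }

  # native assemblages ----------------------------------------------------
  prevalence <- rlnorm(length(native_pool), 0, 1)
  wids <- sprintf("w%04d", seq_len(cfg$n_watersheds))
  richness <- pmin(pmax(6L, round(rlnorm(cfg$n_watersheds,
                                         cfg$richness_meanlog,
                                         cfg$richness_sdlog))),
                   cfg$richness_cap, length(native_pool))
  natives <- lapply(richness, function(k) {
    sample(native_pool, k, prob = prevalence)
  })

  # provisional non-natives -----------------------------------------------
  score <- invasiveness_score(complete, human_use)
  names(score) <- ids
  k0 <- pmin(rpois(cfg$n_watersheds, cfg$mean_invasibility), n_nn)
  provisional <- lapply(seq_along(wids), function(i) {
    pool <- setdiff(nn_pool, natives[[i]])
    if (k0[i] == 0 || !length(pool)) return(character())
    sample(pool, min(k0[i], length(pool)), prob = score[pool])
  })

  # covariates ------------------------------------------------------------
  covariates <- tibble::tibble(
    watershed_id = wids,
    Area = rlnorm(cfg$n_watersheds, log(3000), 0.8),     # km^2
    NPP = runif(cfg$n_watersheds, 200, 1500),            # g C m^-2 yr^-1
    GDP = rlnorm(cfg$n_watersheds, log(5e9), 1.0),       # US$
    HFI = runif(cfg$n_watersheds, 5, 45),
    DOF = runif(cfg$n_watersheds, 0, 100)
  )

  # metrics pass: build space once on the whole pool ----------------------
  model_traits <- complete
  model_traits$FCt <- log10(model_traits$FCt + 1)
  gow <- gower_matrix(model_traits, fish_trait_spec())
  # Gower spaces are near-Euclidean; the small negative eigenvalues are
  # expected here, so the embedding warning is silenced for this internal pass
  space <- suppressWarnings(pcoa(gow, n_axes = 5, warn_low_variance = FALSE))
  coords <- space_matrix(space)

  pool_centroid <- colMeans(coords)
  metrics <- vapply(seq_along(wids), function(i) {
    nat <- coords[natives[[i]], , drop = FALSE]
    nn <- coords[provisional[[i]], , drop = FALSE]
    # FSpe of the native assemblage: a pre-invasion watershed property, so
    # the establishment it causes cannot dilute it away
    fspe <- mean(sqrt(rowSums(sweep(nat, 2, pool_centroid)^2)))
    if (nrow(nn) == 0) {
      c(cd = NA_real_, md = NA_real_, FSpe = fspe)
    } else {
      c(cd = centroid_distance(nat, nn), md = mean_distance(nat, nn),
        FSpe = fspe)
    }
  }, numeric(3))
  metrics <- t(metrics)
  # watersheds with no provisional non-natives sit at the pool mean
  for (j in 1:2) {
    metrics[is.na(metrics[, j]), j] <- mean(metrics[, j], na.rm = TRUE)
  }

  predictors <- cbind(metrics,
                      Area = log(covariates$Area),
                      NPP = covariates$NPP,
                      GDP = log(covariates$GDP),
                      HFI = covariates$HFI,
                      DOF = covariates$DOF,
                      FDis = NA_real_, FOri = NA_real_)
  beta <- cfg$planted_coefs
  eta <- rep(log(cfg$mean_invasibility), cfg$n_watersheds)
  for (nm in names(beta)) {
    if (beta[[nm]] == 0) next
    x <- predictors[, nm]
    if (anyNA(x)) abort(sprintf("Planted predictor `%s` not computable.", nm))
    eta <- eta + beta[[nm]] * as.numeric(scale(x))
  }
  lambda <- exp(pmin(eta, log(cfg$max_invasibility)))

  # final establishment draw: counts are redrawn from the planted rate and
  # the provisional member set is resized (kept where possible) so the cd/md
  # that entered the rate stay causal for the realized assemblage
  y <- pmin(rpois(cfg$n_watersheds, lambda), n_nn)
  established <- lapply(seq_along(wids), function(i) {
    pool <- setdiff(nn_pool, natives[[i]])
    k <- min(y[i], length(pool))
    if (k == 0) return(character())
    base <- provisional[[i]]
    if (k <= length(base)) return(base[seq_len(k)])
    extra_pool <- setdiff(pool, base)
    c(base, sample(extra_pool, min(k - length(base), length(extra_pool)),
                   prob = score[extra_pool]))
  })

  occ <- dplyr::bind_rows(
    tibble::tibble(
      watershed_id = rep(wids, lengths(natives)),
      species_id = unlist(natives, use.names = FALSE),
      status = "native"
    ),
    tibble::tibble(
      watershed_id = rep(wids, lengths(established)),
      species_id = unlist(established, use.names = FALSE),
      status = unname(status_of[unlist(established, use.names = FALSE)])
    )
  )
  occ <- dplyr::arrange(occ, .data$watershed_id, .data$status, .data$species_id)

  gt$true_invasibility_rate <- tibble::tibble(watershed_id = wids,
                                              lambda = lambda)
  gt$true_invasiveness_score <- tibble::tibble(species_id = ids,
                                               score = unname(score),
                                               nonnative_pool = ids %in% nn_pool)
  list(occurrences = occ, covariates = covariates, human_use = human_use,
       ground_truth = gt)
}

#' Simulate a complete synthetic invasion study
#'
#' Convenience wrapper chaining [generate_traits()],
#' [generate_phylo_eigenvectors()], [generate_human_use()] and
#' [generate_communities()] under one configuration.
#'
#' @param cfg A [synthetic_config()].
#' @param phylo_axes Number of phylogenetic eigenvector axes (default 10).
#' @return A list of class `invasion_simulation` with elements `traits`,
#'   `spec`, `phylo`, `human_use`, `occurrences`, `covariates`,
#'   `ground_truth` and `config`.
#' @examples
#' sim <- simulate_invasion_study(synthetic_config(n_species = 60,
#'                                                 n_watersheds = 20))
#' head(sim$occurrences)
#' @export
simulate_invasion_study <- function(cfg = synthetic_config(),
                                    phylo_axes = 10L) {
  tr <- generate_traits(cfg)
  phylo <- generate_phylo_eigenvectors(cfg$n_species, n_axes = phylo_axes,
                                       seed = derive_seed(cfg$seed, 977),
                                       species_ids = tr$traits$species_id)
  com <- generate_communities(cfg, tr$traits, tr$ground_truth)
  structure(list(
    traits = tr$traits, spec = tr$spec, phylo = phylo,
    human_use = com$human_use, occurrences = com$occurrences,
    covariates = com$covariates, ground_truth = com$ground_truth,
    config = cfg
  ), class = "invasion_simulation")
}
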