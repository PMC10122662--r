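#' Greedy collinearity pruning of a predictor table
#'
#' While any pair of numeric predictors exceeds the absolute Pearson
#' correlation threshold, the member of the worst pair ranked later in
#' `keep_priority` (or, for unranked predictors, later in column order) is
#' dropped. Every drop is logged with its partner and correlation.
#'
#' @param X Data frame of predictors (non-numeric columns are kept,
#'   untouched).
#' @param threshold Absolute correlation above which a pair is collinear
#'   (default 0.7).
#' @param keep_priority Character vector; earlier names are preferred keeps.
#' @return List: `data` (pruned), `dropped` (tibble `dropped`, `partner`,
#'   `r`).
#' @export
prune_collinear <- function(X, threshold = 0.7, keep_priority = character()) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1.")
  }
  num_cols <- names(X)[vapply(X, is.numeric, TRUE)]
  dropped <- list()
  rank_of <- function(nm) {
    r <- match(nm, keep_priority)
    ifelse(is.na(r), length(keep_priority) + match(nm, names(X)), r)
  }
  repeat {
    if (length(num_cols) < 2) break
    cm <- abs(cor(X[num_cols]))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- num_cols[worst[1]]; b <- num_cols[worst[2]]
    drop <- if (rank_of(a) <= rank_of(b)) b else a
    keep <- setdiff(c(a, b), drop)
    dropped[[length(dropped) + 1]] <- tibble::tibble(
      dropped = drop, partner = keep, r = cor(X[[a]], X[[b]]))
    num_cols <- setdiff(num_cols, drop)
    X[[drop]] <- NULL
  }
  list(data = X,
       dropped = if (length(dropped)) dplyr::bind_rows(dropped) else
         tibble::tibble(dropped = character(), partner = character(),
                        r = numeric()))
}

#' Flag species with extreme trait values
#'
#' A species is flagged when any continuous trait puts it more than
#' `threshold` robust z-scores (median/MAD) from the pool. Traits with zero
#' MAD are skipped. The flag set is deterministic given the data.
#'
#' @param traits Complete trait tibble.
#' @param spec A [trait_spec()].
#' @param threshold Robust z threshold (default 6).
#' @return Tibble: `species_id`, `max_z`, `worst_trait`, `flagged`.
#' @export
flag_outlier_species <- function(traits, spec = attr(traits, "trait_spec"),
                                 threshold = 6) {
  if (is.null(spec)) abort("Supply a trait_spec.")
  cont <- spec$trait[spec$kind == "continuous"]
  cont <- intersect(cont, names(traits))
  z <- sapply(cont, function(tr) {
    x <- traits[[tr]]
    m <- mad(x)
    if (m == 0) return(rep(NA_real_, length(x)))  # MAD = 0: trait skipped
    abs(x - median(x)) / m
  })
  max_z <- apply(z, 1, function(r) if (all(is.na(r))) NA_real_ else
    max(r, na.rm = TRUE))
  worst <- apply(z, 1, function(r) if (all(is.na(r))) NA_character_ else
    cont[which.max(r)])
  tibble::tibble(species_id = traits$species_id, max_z = max_z,
                 worst_trait = worst,
                 flagged = !is.na(max_z) & max_z > threshold)
}

#' Pipeline configuration
#'
#' Collects every tunable of the two end-to-end analyses. Defaults mirror
#' the conventional choices: a five-axis functional space, the six-species
#' community floor, 0.7 collinearity pruning with NSR and FDis excluded from
#' the invasibility roster, robust-z 6 outlier screening with a
#' with/without-comparison policy, and multi-seed BRT aggregation.
#'
#' @param synthetic A [synthetic_config()] used when no data are supplied.
#' @param k_axes Retained PCoA axes.
#' @param correction PCoA correction ("none" or "cailliez").
#' @param min_species Community-size floor.
#' @param standardize_fric,fspe_variant,fori_variant Index options.
#' @param collinearity_threshold Pearson threshold for [prune_collinear()].
#' @param excluded_predictors Predictors removed from the invasibility
#'   roster even when the realized correlation stays below the threshold
#'   (the canonical 12-predictor roster excludes NSR and FDis, which are
#'   collinear with FRic and FSpe in the source fauna).
#' @param outlier_z,outlier_policy Outlier threshold and handling:
#'   `"compare"` fits with and without flagged species, `"keep"`/`"drop"`
#'   fit once.
#' @param brt A [brt_params()].
#' @param n_reruns BRT reruns aggregated per model.
#' @param compute_interactions Compute the pairwise interaction matrix of
#'   the invasibility model (single representative fit)?
#' @param imputation List: `num_trees`, `max_iter`.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            k_axes = 5L, correction = "none",
                            min_species = 6L, standardize_fric = FALSE,
                            fspe_variant = "pool_centroid",
                            fori_variant = "pool",
                            collinearity_threshold = 0.7,
                            excluded_predictors = c("NSR", "FDis"),
                            outlier_z = 6,
                            outlier_policy = c("compare", "keep", "drop"),
                            brt = brt_params(),
                            n_reruns = 100L,
                            compute_interactions = TRUE,
                            imputation = list(num_trees = 100L,
                                              max_iter = 10L),
                            seed = 1L) {
  outlier_policy <- match.arg(outlier_policy)
  if (collinearity_threshold <= 0 || collinearity_threshold >= 1) {
    abort("`collinearity_threshold` must lie strictly between 0 and 1.")
  }
  structure(list(
    synthetic = synthetic, k_axes = as.integer(k_axes),
    correction = correction, min_species = as.integer(min_species),
    standardize_fric = standardize_fric, fspe_variant = fspe_variant,
    fori_variant = fori_variant,
    collinearity_threshold = collinearity_threshold,
    excluded_predictors = excluded_predictors,
    outlier_z = outlier_z, outlier_policy = outlier_policy,
    brt = brt, n_reruns = as.integer(n_reruns),
    compute_interactions = compute_interactions,
    imputation = imputation, seed = as.integer(seed)
  ), class = "pipeline_config")
}

# shared preprocessing: impute, log10 fecundity, composites, responses
prepare_study <- function(data, config) {
  stopifnot(inherits(data, "invasion_simulation") || is.list(data))
  traits <- data$traits
  spec <- data$spec %||% fish_trait_spec()
  log <- list()
  if (anyNA(traits[trait_columns(traits, spec)])) {
    n_missing <- sum(is.na(traits[trait_columns(traits, spec)]))
    traits <- impute_missing(traits, spec, phylo = data$phylo,
                             max_iter = config$imputation$max_iter,
                             num_trees = config$imputation$num_trees,
                             seed = derive_seed(config$seed, 11))
    log$imputed_cells <- n_missing
  }
  if ("FCt" %in% names(traits)) {
    traits$FCt <- log10(traits$FCt + 1)  # fecundity spans orders of magnitude
  }
  occ <- filter_communities(data$occurrences,
                            min_species = config$min_species)
  log$watersheds_dropped_small <- attr(occ, "n_dropped")
  resp <- responses(occ)
  list(traits = traits, spec = spec, occ = occ, resp = resp, log = log)
}

#' Fit the species-invasiveness model
#'
#' Assembles the 18-predictor species table — the 14 traits left after the
#' size and temperature trios are collapsed into Size_PCA1 and Temp_PCA1
#' (fecundity log10-transformed), the two composites, the human use index
#' and the invasion type — for the established non-native species, takes
#' the number of watersheds where each is recorded non-native as the count
#' response, screens trait outliers per the configured policy, and fits the
#' cross-validated Poisson BRT under `n_reruns` seeds.
#'
#' @param data An `invasion_simulation` (or a list with elements `traits`,
#'   `spec`, `occurrences`, `human_use`, optional `phylo`).
#' @param config A [pipeline_config()].
#' @return Object of class `invasion_report` (model = "invasiveness").
#' @export
run_invasiveness <- function(data, config = pipeline_config()) {
  prep <- prepare_study(data, config)
  traits <- prep$traits
  spec <- prep$spec

  comp <- composite_axes(traits)
  hui <- human_use_index(data$human_use)
  inv <- prep$resp$invasiveness
  modeled <- dplyr::filter(inv, .data$invasiveness > 0)

  status <- setNames(ifelse(inv$invasiveness > 0, inv$invasion_type,
                            "native"), inv$species_id)
  grp <- tryCatch(
    compare_groups(traits[traits$species_id %in% names(status), ],
                   status, spec),
    error = function(e) NULL)

  trio <- c("MBl", "Lgv", "MtA", "TRg", "TMn", "TMx")
  trait_preds <- setdiff(trait_columns(traits, spec), trio)
  tab <- dplyr::left_join(modeled, traits[c("species_id", trait_preds)],
                          by = "species_id")
  tab <- dplyr::left_join(tab, comp$scores, by = "species_id")
  tab <- dplyr::left_join(tab, hui, by = "species_id")
  predictors <- c(trait_preds, "Size_PCA1", "Temp_PCA1", "HUI",
                  "invasion_type")
  expected <- 18L
  if (length(predictors) != expected) {
    abort(sprintf("Invasiveness roster mismatch: %d predictors instead of %d (%s).",
                  length(predictors), expected,
                  paste(predictors, collapse = ", ")))
  }
  model_data <- as.data.frame(tab[c("invasiveness", predictors)])
  model_data$invasion_type <- factor(model_data$invasion_type)
  for (tr in intersect(c("PCr", "DBt"), names(model_data))) {
    kind <- spec_kind(spec, tr)
    model_data[[tr]] <- if (kind == "ordinal") {
      match(as.character(model_data[[tr]]), spec_levels(spec, tr))
    } else factor(model_data[[tr]], levels = spec_levels(spec, tr))
  }

  out <- flag_outlier_species(traits[traits$species_id %in%
                                       modeled$species_id, ], spec,
                              threshold = config$outlier_z)
  flagged <- out$species_id[out$flagged]
  keep_rows <- !tab$species_id %in% flagged
  fit_rows <- switch(config$outlier_policy,
                     keep = rep(TRUE, nrow(model_data)),
                     drop = keep_rows,
                     compare = rep(TRUE, nrow(model_data)))
  agg <- rerun_aggregate(model_data[fit_rows, , drop = FALSE],
                         "invasiveness", params = config$brt,
                         n_runs = config$n_reruns,
                         base_seed = derive_seed(config$seed, 300),
                         pd_predictors = setdiff(predictors,
                                                 "invasion_type"))
  outlier_comparison <- NULL
  if (config$outlier_policy == "compare" && length(flagged)) {
    agg2 <- rerun_aggregate(model_data[keep_rows, , drop = FALSE],
                            "invasiveness", params = config$brt,
                            n_runs = config$n_reruns,
                            base_seed = derive_seed(config$seed, 301))
    both <- dplyr::inner_join(agg$mean_influence, agg2$mean_influence,
                              by = "predictor",
                              suffix = c("_all", "_no_outliers"))
    outlier_comparison <- list(
      mean_influence = both,
      rank_agreement = suppressWarnings(
        cor(both$mean_influence_all, both$mean_influence_no_outliers,
            method = "spearman")),
      n_removed = length(flagged))
  }

  structure(list(
    model = "invasiveness", predictors = predictors,
    n_species = nrow(model_data), aggregate = agg,
    outliers = out, outlier_comparison = outlier_comparison,
    group_comparison = grp,
    dropped = prep$log, config = config, seed = config$seed
  ), class = "invasion_report")
}

#' Fit the community-invasibility model
#'
#' Filters watersheds to the community-size floor, builds the shared
#' functional space (Gower + PCoA on `k_axes` axes), computes the six
#' functional-diversity indices of each recipient community and the cd/md
#' distances between its native and non-native assemblages, merges the
#' watershed covariates (Area, NPP, GDP, HFI, DOF) and native species
#' richness, prunes collinear predictors down to the canonical 12-predictor
#' roster, and fits the count of established non-native species with the
#' cross-validated Poisson BRT under `n_reruns` seeds. Optionally computes
#' the pairwise interaction matrix (representative fit) and Moran's I of its
#' residuals when a spatial weight matrix is supplied.
#'
#' @param data An `invasion_simulation` (or a list with `traits`, `spec`,
#'   `occurrences`, `covariates`, optional `phylo`).
#' @param config A [pipeline_config()].
#' @param weights Optional spatial weight matrix over the modeled
#'   watersheds (rownames = watershed ids).
#' @return Object of class `invasion_report` (model = "invasibility").
#' @export
run_invasibility <- function(data, config = pipeline_config(),
                             weights = NULL) {
  prep <- prepare_study(data, config)
  traits <- prep$traits
  occ <- prep$occ

  gow <- gower_matrix(traits, prep$spec)
  space <- pcoa(gow, n_axes = config$k_axes, correction = config$correction,
                warn_low_variance = FALSE)
  fd <- fd_profile(space, occ, min_species = config$min_species,
                   standardize_fric = config$standardize_fric,
                   fspe_variant = config$fspe_variant,
                   fori_variant = config$fori_variant)
  idist <- invasion_distances(space, occ)
  nsr <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(occ, .data$status == "native"),
                    .data$watershed_id),
    NSR = dplyr::n_distinct(.data$species_id), .groups = "drop")

  need_cov <- c("Area", "NPP", "GDP", "HFI", "DOF")
  missing_cov <- setdiff(need_cov, names(data$covariates))
  if (length(missing_cov)) {
    abort(sprintf("Covariate column(s) missing: %s.",
                  paste(missing_cov, collapse = ", ")))
  }
  tab <- dplyr::left_join(fd, idist, by = "watershed_id")
  tab <- dplyr::left_join(tab, nsr, by = "watershed_id")
  tab <- dplyr::left_join(tab, data$covariates[c("watershed_id", need_cov)],
                          by = "watershed_id")
  tab <- dplyr::left_join(tab, prep$resp$invasibility, by = "watershed_id")

  # cd/md are undefined without non-natives: those rows cannot enter a model
  # whose predictor set requires them
  no_nn <- is.na(tab$cd) | is.na(tab$md)
  dropped_no_nn <- tab$watershed_id[no_nn]
  tab <- tab[!no_nn, , drop = FALSE]

  candidates <- c("cd", "md", "NSR", "FRic", "FEve", "FDiv", "FDis", "FSpe",
                  "FOri", need_cov)
  # correlation screen over all candidates: collinear pairs are reported;
  # the model roster itself is declared via excluded_predictors (the
  # canonical screen outcome: NSR and FDis give way to FRic and FSpe)
  cand <- as.data.frame(tab[candidates])
  cm <- cor(cand)
  hi <- which(abs(cm) > config$collinearity_threshold & upper.tri(cm),
              arr.ind = TRUE)
  screen_log <- tibble::tibble(
    predictor_1 = rownames(cm)[hi[, 1]],
    predictor_2 = colnames(cm)[hi[, 2]],
    r = cm[hi])
  X <- cand[setdiff(candidates, config$excluded_predictors)]
  drop_log <- tibble::tibble(
    dropped = intersect(config$excluded_predictors, candidates),
    reason = "excluded from roster (collinear with retained functional indices)")
  predictors <- names(X)
  expected <- 12L
  if (length(predictors) != expected) {
    abort(sprintf("Invasibility roster mismatch: %d predictors instead of %d (%s).",
                  length(predictors), expected,
                  paste(predictors, collapse = ", ")))
  }
  model_data <- cbind(invasibility = tab$invasibility, X)

  agg <- rerun_aggregate(model_data, "invasibility", params = config$brt,
                         n_runs = config$n_reruns,
                         base_seed = derive_seed(config$seed, 500),
                         pd_predictors = predictors)

  interactions <- NULL
  if (isTRUE(config$compute_interactions)) {
    interactions <- interaction_matrix(agg$last_fit)
  }
  moran <- NULL
  if (!is.null(weights)) {
    fitv <- predict(agg$last_fit)
    resid <- tab$invasibility - fitv
    ids <- tab$watershed_id
    if (!all(ids %in% rownames(weights))) {
      abort("`weights` must cover every modeled watershed.")
    }
    moran <- morans_i(resid, weights[ids, ids], n_perm = 999L,
                      seed = derive_seed(config$seed, 77))
  }

  prep$log$watersheds_dropped_no_nonnative <- length(dropped_no_nn)
  structure(list(
    model = "invasibility", predictors = predictors,
    n_watersheds = nrow(model_data), aggregate = agg,
    predictor_table = tibble::as_tibble(cbind(
      watershed_id = tab$watershed_id, model_data)),
    space = space, fd_profile = fd, invasion_distances = idist,
    interactions = interactions, moran = moran,
    collinearity = list(screen = screen_log, dropped = drop_log),
    dropped = prep$log, config = config, seed = config$seed
  ), class = "invasion_report")
}

#' @export
print.invasion_report <- function(x, ...) {
  cat(sprintf("Invasion report: %s model, %d predictors, mean CV-D2 = %.3f over %d reruns\n",
              x$model, length(x$predictors), x$aggregate$mean_cv_D2,
              x$aggregate$n_runs))
  print(head(x$aggregate$mean_influence, 6))
  invisible(x)
}
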