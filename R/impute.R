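#' Iterative random-forest imputation of a mixed-type trait table
#'
#' missForest-style chained imputation: missing cells are first filled with
#' column means (continuous, ordinal) or modes (binary, categorical), then
#' columns are revisited in order of increasing missingness, each re-imputed
#' from a random forest trained on the currently observed part of all other
#' columns. After every sweep the change relative to the previous sweep is
#' measured separately for the continuous and the categorical parts; the
#' algorithm stops as soon as both criteria increase and returns the previous
#' iterate. Phylogenetic eigenvectors, when supplied, are appended as extra
#' predictors during fitting and stripped from the output. Observed cells are
#' never altered.
#'
#' @param traits Trait tibble (`species_id` + trait columns) with missing
#'   cells.
#' @param spec A [trait_spec()].
#' @param phylo Optional tibble of phylogenetic eigenvectors (`species_id` +
#'   numeric columns), row-aligned by id.
#' @param max_iter Maximum number of sweeps (default 10).
#' @param num_trees Trees per forest (default 100).
#' @param seed Integer seed.
#' @return The completed trait tibble (ordinal values rounded to declared
#'   levels), with attribute `imputation_iterations`.
#' @export
impute_missing <- function(traits, spec = attr(traits, "trait_spec"),
                           phylo = NULL, max_iter = 10L, num_trees = 100L,
                           seed = 1L) {
  if (is.null(spec)) abort("Supply a trait_spec.")
  validate_traits(traits, spec)
  set.seed(seed)  # the forest backend also reads the global RNG stream
  cols <- trait_columns(traits, spec)
  na_count <- vapply(traits[cols], function(x) sum(is.na(x)), integer(1))
  if (any(na_count == nrow(traits))) {
    abort(sprintf("Column(s) entirely missing: %s.",
                  paste(cols[na_count == nrow(traits)], collapse = ", ")))
  }
  if (all(na_count == 0)) return(traits)

  kinds <- setNames(spec_kind(spec, cols), cols)
  numeric_like <- names(kinds)[kinds %in% c("continuous", "ordinal")]
  factor_like <- names(kinds)[kinds %in% c("binary", "categorical")]

  # working frame: ordinals as numeric level positions, factors as factors
  work <- as.data.frame(traits[cols])
  for (tr in cols) {
    if (kinds[[tr]] == "ordinal") {
      work[[tr]] <- match(as.character(work[[tr]]), spec_levels(spec, tr))
    } else if (kinds[[tr]] == "binary") {
      work[[tr]] <- factor(work[[tr]], levels = c(0, 1))
    } else if (kinds[[tr]] == "categorical") {
      work[[tr]] <- factor(work[[tr]], levels = spec_levels(spec, tr))
    }
  }
  miss <- lapply(work, function(x) which(is.na(x)))

  # mean / mode starting fill
  for (tr in cols) {
    idx <- miss[[tr]]
    if (!length(idx)) next
    obs <- work[[tr]][-idx]
    work[[tr]][idx] <- if (is.factor(work[[tr]])) {
      factor(mode_value(obs), levels = levels(work[[tr]]))
    } else mean(obs)
  }

  extra <- NULL
  if (!is.null(phylo)) {
    m <- match(traits$species_id, phylo$species_id)
    if (anyNA(m)) abort("`phylo` must cover every species in the trait table.")
    extra <- as.data.frame(phylo[m, setdiff(names(phylo), "species_id")])
  }

  visit <- cols[na_count > 0][order(na_count[na_count > 0])]
  delta_prev <- c(cont = Inf, cat = Inf)
  rng_seed <- seed
  iterations <- 0L
  for (iter in seq_len(max_iter)) {
    before <- work
    for (tr in visit) {
      idx <- miss[[tr]]
      preds <- if (is.null(extra)) work[setdiff(cols, tr)] else
        cbind(work[setdiff(cols, tr)], extra)
      df <- cbind(preds, .target = work[[tr]])
      train <- df[-idx, , drop = FALSE]
      rng_seed <- rng_seed + 1L
      fit <- ranger::ranger(
        dependent.variable.name = ".target", data = train,
        num.trees = num_trees, seed = rng_seed, num.threads = 1,
        respect.unordered.factors = "partition"
      )
      pred <- predict(fit, df[idx, , drop = FALSE],
                      num.threads = 1)$predictions
      work[[tr]][idx] <- pred
    }
    iterations <- iter
    # stopping criterion, continuous and categorical parts separately
    d_cont <- NA_real_; d_cat <- NA_real_
    nl_miss <- numeric_like[lengths(miss[numeric_like]) > 0]
    if (length(nl_miss)) {
      num <- 0; den <- 0
      for (tr in nl_miss) {
        idx <- miss[[tr]]
        num <- num + sum((work[[tr]][idx] - before[[tr]][idx])^2)
        den <- den + sum(work[[tr]][idx]^2)
      }
      d_cont <- if (den > 0) num / den else 0
    }
    fl_miss <- factor_like[lengths(miss[factor_like]) > 0]
    if (length(fl_miss)) {
      changed <- 0; total <- 0
      for (tr in fl_miss) {
        idx <- miss[[tr]]
        changed <- changed + sum(work[[tr]][idx] != before[[tr]][idx])
        total <- total + length(idx)
      }
      d_cat <- changed / total
    }
    worse_cont <- is.na(d_cont) || d_cont >= delta_prev[["cont"]]
    worse_cat <- is.na(d_cat) || d_cat >= delta_prev[["cat"]]
    if (iter > 1 && worse_cont && worse_cat) {
      work <- before  # both criteria increased: keep the previous iterate
      iterations <- iter - 1L
      break
    }
    delta_prev <- c(cont = ifelse(is.na(d_cont), Inf, d_cont),
                    cat = ifelse(is.na(d_cat), Inf, d_cat))
  }

  out <- traits
  for (tr in cols) {
    idx <- miss[[tr]]
    if (!length(idx)) next
    val <- work[[tr]][idx]
    out[[tr]][idx] <- switch(kinds[[tr]],
      continuous = val,
      ordinal = spec_levels(spec, tr)[pmin(pmax(round(val), 1),
                                           length(spec_levels(spec, tr)))],
      binary = as.numeric(as.character(val)),
      categorical = as.character(val)
    )
  }
  attr(out, "imputation_iterations") <- iterations
  out
}

#' Cross-validate imputation accuracy against mean/mode filling
#'
#' Masks a fraction of the cells of a complete trait table completely at
#' random, re-imputes them with the random-forest scheme and with the
#' classical mean/mode fill, and scores each replicate by the Spearman
#' correlation between imputed and true values pooled over continuous traits
#' (plus the categorical accuracy, reported separately). A replicate whose
#' masked continuous values are constant has no defined rank correlation and
#' is reported as `NA` rather than a failure.
#'
#' @param traits Complete trait tibble.
#' @param spec A [trait_spec()].
#' @param mask_rate Fraction of cells masked per replicate (default 0.20).
#' @param n_reps Number of replicates (default 100).
#' @param seed Integer seed.
#' @param phylo,num_trees,max_iter Passed to [impute_missing()].
#' @return Tibble: `rep`, `method` (`"random_forest"` / `"mean_fill"`),
#'   `spearman_continuous`, `accuracy_categorical`.
#' @export
validate_imputation <- function(traits, spec = attr(traits, "trait_spec"),
                                mask_rate = 0.20, n_reps = 100L, seed = 1L,
                                phylo = NULL, num_trees = 100L,
                                max_iter = 10L) {
  if (is.null(spec)) abort("Supply a trait_spec.")
  if (!is.numeric(mask_rate) || mask_rate <= 0 || mask_rate >= 1) {
    abort("`mask_rate` must lie strictly between 0 and 1.")
  }
  check_count(n_reps, "n_reps", min = 1L)
  cols <- trait_columns(traits, spec)
  if (anyNA(traits[cols])) abort("`traits` must be complete for validation.")
  kinds <- setNames(spec_kind(spec, cols), cols)
  n <- nrow(traits)

  score_rep <- function(filled, masked_idx) {
    truth_cont <- c(); imp_cont <- c(); ok_cat <- c()
    for (tr in cols) {
      idx <- masked_idx[[tr]]
      if (!length(idx)) next
      if (kinds[[tr]] == "continuous") {
        truth_cont <- c(truth_cont, traits[[tr]][idx])
        imp_cont <- c(imp_cont, filled[[tr]][idx])
      } else {
        ok_cat <- c(ok_cat, as.character(filled[[tr]][idx]) ==
                      as.character(traits[[tr]][idx]))
      }
    }
    rho <- if (length(truth_cont) >= 3 && sd(truth_cont) > 0 &&
               sd(imp_cont) > 0) {
      cor(truth_cont, imp_cont, method = "spearman")
    } else NA_real_
    acc <- if (length(ok_cat)) mean(ok_cat) else NA_real_
    c(rho = rho, acc = acc)
  }

  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, 7919L * r)
    set.seed(rep_seed)
    masked <- traits
    masked_idx <- list()
    for (tr in cols) {
      idx <- which(runif(n) < mask_rate)
      masked_idx[[tr]] <- idx
      if (length(idx)) masked[[tr]][idx] <- NA
    }
    filled_rf <- impute_missing(masked, spec, phylo = phylo,
                                max_iter = max_iter, num_trees = num_trees,
                                seed = rep_seed)
    filled_base <- mean_mode_fill(masked, spec)
    s_rf <- score_rep(filled_rf, masked_idx)
    s_base <- score_rep(filled_base, masked_idx)
    out[[r]] <- tibble::tibble(
      rep = r,
      method = c("random_forest", "mean_fill"),
      spearman_continuous = c(s_rf[["rho"]], s_base[["rho"]]),
      accuracy_categorical = c(s_rf[["acc"]], s_base[["acc"]])
    )
  }
  dplyr::bind_rows(out)
}

#' Mean/mode baseline fill
#'
#' The classical imputation baseline: missing continuous and ordinal cells
#' get the column mean (ordinal rounded to a level), missing binary and
#' categorical cells the column mode.
#'
#' @inheritParams impute_missing
#' @return Completed trait tibble.
#' @export
mean_mode_fill <- function(traits, spec = attr(traits, "trait_spec")) {
  if (is.null(spec)) abort("Supply a trait_spec.")
  out <- traits
  for (tr in trait_columns(traits, spec)) {
    idx <- which(is.na(out[[tr]]))
    if (!length(idx)) next
    obs <- out[[tr]][-idx]
    if (!length(obs)) abort(sprintf("Column `%s` entirely missing.", tr))
    kind <- spec_kind(spec, tr)
    out[[tr]][idx] <- switch(kind,
      continuous = mean(obs),
      ordinal = {
        lv <- spec_levels(spec, tr)
        lv[pmin(pmax(round(mean(match(as.character(obs), lv))), 1), length(lv))]
      },
      binary = as.numeric(mode_value(obs)),
      categorical = mode_value(obs)
    )
  }
  out
}
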