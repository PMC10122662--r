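pd_grid_values <- function(fit, predictor, grid) {
  x <- fit$X[[predictor]]
  if (is.factor(x)) return(levels(x))
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  seq(r[1], r[2], length.out = grid)
}

pd_rows <- function(fit, sample_n) {
  n <- nrow(fit$X)
  if (n <= sample_n) return(seq_len(n))
  set.seed(derive_seed(fit$seed, 577))
  sample.int(n, sample_n)
}

# Friedman marginal: average prediction over training rows with `predictor`
# clamped at each grid value; one ensemble pass over the stacked frame
pd_compute <- function(fit, predictor, values, rows, type = "response") {
  base <- fit$X[rows, , drop = FALSE]
  stacked <- base[rep(seq_len(nrow(base)), times = length(values)), ,
                  drop = FALSE]
  stacked[[predictor]] <- rep(values, each = nrow(base))
  pred <- predict(fit, stacked, type = type)
  rowMeans(matrix(pred, nrow = length(values), byrow = TRUE))
}

#' Partial dependence of the response on one predictor
#'
#' For each grid value, the predictor is clamped at that value in every
#' (sub-sampled) training row and the ensemble predictions are averaged —
#' Friedman's marginal effect, reported on the count scale.
#'
#' @param fit A [fit_brt()] model.
#' @param predictor Predictor name.
#' @param grid Number of grid points (continuous predictors; factors use
#'   their levels).
#' @param sample_n Training rows averaged over (sub-sampled deterministically
#'   from the fit seed).
#' @return A tibble of class `pd_curve`: `predictor`, `value`, `yhat`.
#' @export
partial_dependence <- function(fit, predictor, grid = 20L, sample_n = 500L) {
  stopifnot(inherits(fit, "brt_fit"))
  if (!predictor %in% fit$predictors) {
    abort(sprintf("Predictor `%s` is not in the model.", predictor))
  }
  values <- pd_grid_values(fit, predictor, grid)
  rows <- pd_rows(fit, sample_n)
  yhat <- pd_compute(fit, predictor, values, rows)
  out <- tibble::tibble(predictor = predictor, value = values, yhat = yhat)
  class(out) <- c("pd_curve", class(out))
  out
}

#' Pairwise interaction strength between two predictors
#'
#' gbm.interactions semantics: the joint partial-dependence surface of the
#' pair (link scale) is regressed on the additive combination of the two
#' one-dimensional partial dependencies; the residual variance of that fit
#' is the interaction strength (zero for a purely additive model).
#'
#' @param fit A [fit_brt()] model.
#' @param i,j Predictor names.
#' @param grid Grid points per predictor.
#' @param sample_n Training rows averaged over.
#' @return Nonnegative scalar.
#' @export
interaction_strength <- function(fit, i, j, grid = 8L, sample_n = 100L) {
  stopifnot(inherits(fit, "brt_fit"))
  for (p in c(i, j)) {
    if (!p %in% fit$predictors) {
      abort(sprintf("Predictor `%s` is not in the model.", p))
    }
  }
  vi <- pd_grid_values(fit, i, grid)
  vj <- pd_grid_values(fit, j, grid)
  if (length(vi) < 2 || length(vj) < 2) return(0)  # degenerate grid
  rows <- pd_rows(fit, sample_n)
  base <- fit$X[rows, , drop = FALSE]
  cells <- expand.grid(ii = seq_along(vi), jj = seq_along(vj))
  stacked <- base[rep(seq_len(nrow(base)), times = nrow(cells)), ,
                  drop = FALSE]
  stacked[[i]] <- rep(vi[cells$ii], each = nrow(base))
  stacked[[j]] <- rep(vj[cells$jj], each = nrow(base))
  pred <- predict(fit, stacked, type = "link")
  joint <- rowMeans(matrix(pred, nrow = nrow(cells), byrow = TRUE))
  pdi <- pd_compute(fit, i, vi, rows, type = "link")
  pdj <- pd_compute(fit, j, vj, rows, type = "link")
  df <- data.frame(joint = joint, pdi = pdi[cells$ii], pdj = pdj[cells$jj])
  res <- residuals(lm(joint ~ pdi + pdj, data = df))
  mean(res^2)
}

#' All pairwise interaction strengths
#'
#' @param fit A [fit_brt()] model.
#' @param predictors Subset of predictors (default: all).
#' @param ... Passed to [interaction_strength()].
#' @return Symmetric matrix of class `interaction_matrix` with zero
#'   diagonal.
#' @export
interaction_matrix <- function(fit, predictors = fit$predictors, ...) {
  p <- length(predictors)
  m <- matrix(0, p, p, dimnames = list(predictors, predictors))
  if (p >= 2) {
    for (a in 1:(p - 1)) {
      for (b in (a + 1):p) {
        s <- interaction_strength(fit, predictors[a], predictors[b], ...)
        m[a, b] <- s
        m[b, a] <- s
      }
    }
  }
  class(m) <- c("interaction_matrix", class(m))
  m
}

#' Rerun a BRT under multiple seeds and aggregate
#'
#' Stochastic components (fold assignment, bagging) make single fits noisy;
#' the standard remedy is rerunning the model under independent seeds and
#' averaging the relative influences and the cross-validated deviance
#' explained. Optionally tracks per-run partial-dependence Spearman
#' correlations (monotone trend signs) for selected predictors.
#'
#' @param data,response,params As in [fit_brt()].
#' @param n_runs Number of reruns (default 100).
#' @param base_seed Seeds are `base_seed + 1 .. base_seed + n_runs`.
#' @param pd_predictors Optional predictor names whose partial-dependence
#'   trend (Spearman rho of yhat against the grid) is recorded per run.
#' @param pd_grid,pd_sample Partial-dependence resolution.
#' @return Object of class `brt_aggregate`: `mean_influence`, `mean_cv_D2`,
#'   `per_run`, `pd_trends`, `last_fit`.
#' @export
rerun_aggregate <- function(data, response, params = brt_params(),
                            n_runs = 100L, base_seed = 1L,
                            pd_predictors = NULL, pd_grid = 15L,
                            pd_sample = 200L) {
  check_count(n_runs, "n_runs", min = 1L)
  runs <- vector("list", n_runs)
  trends <- vector("list", n_runs)
  fit <- NULL
  for (r in seq_len(n_runs)) {
    fit <- fit_brt(data, response, params, seed = derive_seed(base_seed, r))
    infl <- fit$relative_influence
    runs[[r]] <- tibble::tibble(run = r, predictor = infl$predictor,
                                influence = infl$influence,
                                cv_D2 = fit$cv_D2, nt = fit$nt)
    if (length(pd_predictors)) {
      trends[[r]] <- dplyr::bind_rows(lapply(pd_predictors, function(p) {
        pd <- partial_dependence(fit, p, grid = pd_grid,
                                 sample_n = pd_sample)
        rho <- if (is.numeric(pd$value) && length(unique(pd$yhat)) > 1) {
          suppressWarnings(cor(as.numeric(pd$value), pd$yhat,
                               method = "spearman"))
        } else NA_real_
        tibble::tibble(run = r, predictor = p, pd_spearman = rho)
      }))
    }
  }
  per_run <- dplyr::bind_rows(runs)
  mean_influence <- dplyr::summarise(
    dplyr::group_by(per_run, .data$predictor),
    mean_influence = mean(.data$influence),
    sd_influence = sd(.data$influence), .groups = "drop")
  mean_influence <- dplyr::arrange(mean_influence,
                                   dplyr::desc(.data$mean_influence))
  pd_trends <- if (length(pd_predictors)) {
    dplyr::summarise(dplyr::group_by(dplyr::bind_rows(trends),
                                     .data$predictor),
                     mean_pd_spearman = mean(.data$pd_spearman, na.rm = TRUE),
                     .groups = "drop")
  } else NULL
  structure(list(
    mean_influence = mean_influence,
    mean_cv_D2 = mean(dplyr::distinct(per_run, .data$run,
                                      .data$cv_D2)$cv_D2),
    per_run = per_run, pd_trends = pd_trends,
    n_runs = n_runs, last_fit = fit
  ), class = "brt_aggregate")
}

#' @export
print.brt_aggregate <- function(x, ...) {
  cat(sprintf("BRT aggregate over %d runs: mean CV-D2 = %.3f\n", x$n_runs,
              x$mean_cv_D2))
  print(head(x$mean_influence, 6))
  invisible(x)
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (n / S0) * (sum_ij w_ij z_i z_j) / (sum_i z_i^2)` with `z` the
#' centered residuals and `S0` the total weight. The expectation under no
#' autocorrelation is `-1/(n-1)`. A permutation p-value (upper tail: positive
#' autocorrelation) is computed when `n_perm > 0`.
#'
#' @param residuals Numeric vector (e.g. model residuals per watershed).
#' @param W Nonnegative spatial weight matrix, zero diagonal.
#' @param n_perm Number of residual permutations (0 = skip).
#' @param seed Integer seed for the permutations.
#' @return Tibble: `statistic`, `expectation`, `p_value` (NA without
#'   permutations).
#' @export
morans_i <- function(residuals, W, n_perm = 0L, seed = 1L) {
  n <- length(residuals)
  W <- as.matrix(W)
  if (!all(dim(W) == n)) abort("`W` must be n x n.")
  if (any(W < 0)) abort("`W` must be nonnegative.")
  if (any(diag(W) != 0)) abort("`W` must have a zero diagonal.")
  s0 <- sum(W)
  if (s0 <= 0) abort("`W` has no positive weights.")
  z <- residuals - mean(residuals)
  denom <- sum(z^2)
  if (denom == 0) abort("Residuals are constant; Moran's I undefined.")
  stat <- (n / s0) * as.numeric(z %*% W %*% z) / denom
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(k) {
      zp <- z[sample.int(n)]
      (n / s0) * as.numeric(zp %*% W %*% zp) / sum(zp^2)
    }, numeric(1))
    p <- (1 + sum(perm >= stat)) / (n_perm + 1)
  }
  tibble::tibble(statistic = stat, expectation = -1 / (n - 1), p_value = p,
                 n_perm = as.integer(n_perm))
}

#' Read a spatial weight matrix from triplets
#'
#' @param triplets Data frame (or CSV path) with columns `i`, `j`, `w`
#'   naming watershed pairs and their weight.
#' @param ids Optional vector fixing the matrix order; defaults to the
#'   sorted union of `i` and `j`.
#' @return Dense weight matrix with dimnames.
#' @export
weight_matrix_from_triplets <- function(triplets, ids = NULL) {
  if (is.character(triplets)) triplets <- read.csv(triplets)
  if (!all(c("i", "j", "w") %in% names(triplets))) {
    abort("Triplets need columns i, j, w.")
  }
  ids <- ids %||% sort(unique(c(as.character(triplets$i),
                                as.character(triplets$j))))
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  W[cbind(as.character(triplets$i), as.character(triplets$j))] <- triplets$w
  W
}
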