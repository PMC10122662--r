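#' Hyperparameters for boosted regression trees
#'
#' @param learning_rate Shrinkage applied to every tree's contribution
#'   (`lr`, in (0, 1]).
#' @param tree_complexity Maximum depth of each regression tree (`tc`),
#'   controlling the interaction order that can be fitted.
#' @param bag_fraction Fraction of the training rows sampled (without
#'   replacement) for each tree (`bf`, in (0, 1]).
#' @param step_size Trees added per cross-validation stage.
#' @param n_folds Cross-validation folds (default 10).
#' @param max_trees Upper bound on the ensemble size.
#' @param patience Stages without CV improvement before growth stops.
#' @param min_node Minimum observations per terminal node.
#' @return A list of class `brt_params`.
#' @export
brt_params <- function(learning_rate = 0.05, tree_complexity = 3L,
                       bag_fraction = 0.75, step_size = 25L,
                       n_folds = 10L, max_trees = 1000L, patience = 8L,
                       min_node = 10L) {
  if (!is.numeric(learning_rate) || learning_rate <= 0 || learning_rate > 1) {
    abort("`learning_rate` must lie in (0, 1].")
  }
  if (!is.numeric(bag_fraction) || bag_fraction <= 0 || bag_fraction > 1) {
    abort("`bag_fraction` must lie in (0, 1].")
  }
  check_count(tree_complexity, "tree_complexity", min = 1L)
  check_count(step_size, "step_size", min = 1L)
  check_count(n_folds, "n_folds", min = 2L)
  check_count(max_trees, "max_trees", min = 1L)
  check_count(patience, "patience", min = 1L)
  check_count(min_node, "min_node", min = 1L)
  structure(list(
    learning_rate = learning_rate, tree_complexity = as.integer(tree_complexity),
    bag_fraction = bag_fraction, step_size = as.integer(step_size),
    n_folds = as.integer(n_folds), max_trees = as.integer(max_trees),
    patience = as.integer(patience), min_node = as.integer(min_node)
  ), class = "brt_params")
}

# ---- internal boosting machinery ---------------------------------------

# terminal-node ids (rpart node numbers) for newdata; exploits that
# predict.rpart returns frame$yval of the landing leaf
rpart_leaves <- function(fit, newdata) {
  fit$frame$yval <- as.numeric(rownames(fit$frame))
  as.character(predict(fit, newdata))
}

# Friedman importance of one tree: deviance (SS) reduction of every split,
# attributed to the split variable; node children of k are 2k and 2k+1
rpart_split_gains <- function(fit) {
  fr <- fit$frame
  if (nrow(fr) < 3) return(numeric(0))
  node <- as.integer(rownames(fr))
  internal <- which(fr$var != "<leaf>")
  gains <- vapply(internal, function(i) {
    kids <- match(c(2L * node[i], 2L * node[i] + 1L), node)
    fr$dev[i] - sum(fr$dev[kids])
  }, numeric(1))
  tapply(pmax(gains, 0), as.character(fr$var[internal]), sum)
}

# drop everything predict.rpart does not need and detach the formula env
strip_rpart <- function(fit) {
  fit$where <- NULL
  fit$call <- NULL
  fit$cptable <- NULL
  fit$variable.importance <- NULL
  fit$parms <- NULL
  fit$functions <- NULL
  environment(fit$terms) <- baseenv()
  fit
}

# per-row leaf updates; rows stranded at an internal node (factor level
# unseen in the bag: rpart sends them in no direction) get a zero update
gamma_update <- function(gamma, leaves) {
  upd <- unname(gamma[leaves])
  upd[is.na(upd)] <- 0
  upd
}

# mutable boosting state for one training set (optionally with a tracked
# held-out set); trees are stored only when `keep_trees`
new_booster <- function(X, y, params, keep_trees = FALSE,
                        X_test = NULL, y_test = NULL) {
  env <- new.env(parent = emptyenv())
  env$X <- X
  env$y <- y
  env$n <- nrow(X)
  env$init <- log(max(mean(y), 1e-8))
  env$f <- rep(env$init, env$n)
  env$mu <- exp(env$f)
  env$keep_trees <- keep_trees
  env$trees <- list()
  env$gains <- list()
  env$X_test <- X_test
  env$y_test <- y_test
  if (!is.null(X_test)) env$f_test <- rep(env$init, nrow(X_test))
  env$ctrl <- rpart::rpart.control(
    maxdepth = params$tree_complexity, cp = 0, xval = 0,
    maxcompete = 0, maxsurrogate = 0,
    minsplit = 2L * params$min_node, minbucket = params$min_node)
  env$lr <- params$learning_rate
  env$bf <- params$bag_fraction
  env
}

booster_add_trees <- function(env, k) {
  for (t in seq_len(k)) {
    bag <- sample.int(env$n, max(2L, floor(env$bf * env$n)))
    df <- env$X[bag, , drop = FALSE]
    df$.z <- env$y[bag] - env$mu[bag]
    fit <- rpart::rpart(.z ~ ., data = df, method = "anova",
                        control = env$ctrl)
    node_bag <- as.character(as.integer(rownames(fit$frame))[fit$where])
    bag_used <- bag
    dropped <- fit$na.action %||% attr(fit, "na.action")
    if (!is.null(dropped)) bag_used <- bag[-as.integer(dropped)]
    num <- tapply(env$y[bag_used], node_bag, sum)
    den <- tapply(env$mu[bag_used], node_bag, sum)
    gamma <- log(pmax(num, 1e-12) / pmax(den, 1e-12))
    gamma <- pmin(pmax(gamma, -4), 4)  # Newton leaf update, capped
    gamma <- setNames(as.numeric(gamma), names(gamma))  # drop tapply's dim
    leaves <- rpart_leaves(fit, env$X)
    env$f <- env$f + env$lr * gamma_update(gamma, leaves)
    env$f <- pmin(env$f, 30)
    env$mu <- exp(env$f)
    if (!is.null(env$X_test)) {
      lt <- rpart_leaves(fit, env$X_test)
      env$f_test <- pmin(env$f_test + env$lr * gamma_update(gamma, lt), 30)
    }
    if (env$keep_trees) {
      env$trees[[length(env$trees) + 1L]] <- list(tree = strip_rpart(fit),
                                                  gamma = gamma)
      env$gains[[length(env$gains) + 1L]] <- rpart_split_gains(fit)
    }
  }
  invisible(env)
}

# folds stratified by response quantile: order by y (ties shuffled), deal
# fold labels cyclically
stratified_folds <- function(y, k) {
  ord <- order(y, runif(length(y)))
  fold <- integer(length(y))
  fold[ord] <- rep_len(sample.int(k), length(y))
  fold
}

#' Fit a cross-validated Poisson boosted regression tree model
#'
#' Stagewise gradient boosting on the log link minimizing Poisson deviance:
#' each stage fits depth-limited regression trees to the gradient residuals
#' `y - mu` on a bagged subsample, applies a capped Newton update in every
#' terminal node and shrinks it by the learning rate. All cross-validation
#' folds are grown in lockstep in increments of `step_size` trees while the
#' mean held-out Poisson deviance is tracked; growth stops once the CV curve
#' has not improved for `patience` stages (or at `max_trees`, with a warning
#' if the curve is still falling). The selected tree count `nt` minimizes
#' the CV deviance; the final ensemble is refit on all rows. `cv_D2` is the
#' cross-validated proportion of Poisson deviance explained relative to the
#' intercept-only model.
#'
#' @param data Data frame holding the response and predictor columns.
#' @param response Name of the count response column.
#' @param params A [brt_params()].
#' @param seed Integer seed (folds and bagging).
#' @return An object of class `brt_fit`: ensemble, `nt`, `cv_trace`,
#'   `cv_D2`, `relative_influence`, training references.
#' @examples
#' d <- data.frame(x = rnorm(200))
#' d$y <- rpois(200, exp(0.5 + 0.7 * d$x))
#' fit <- fit_brt(d, "y", brt_params(n_folds = 3, max_trees = 50,
#'                                   learning_rate = 0.1))
#' glance(fit)
#' @export
fit_brt <- function(data, response, params = brt_params(), seed = 1L) {
  stopifnot(inherits(params, "brt_params"))
  if (!response %in% names(data)) {
    abort(sprintf("Response column `%s` not found.", response))
  }
  y <- data[[response]]
  if (anyNA(y) || any(y < 0) || any(y != round(y))) {
    abort("Response must be nonnegative integer counts without NAs.")
  }
  predictors <- setdiff(names(data), response)
  X <- as.data.frame(data[predictors])
  for (p in predictors) {
    if (is.character(X[[p]])) X[[p]] <- factor(X[[p]])
    if (anyNA(X[[p]])) abort(sprintf("Predictor `%s` has missing values.", p))
  }
  set.seed(seed)

  # lockstep CV growth -----------------------------------------------------
  fold <- stratified_folds(y, params$n_folds)
  boosters <- lapply(seq_len(params$n_folds), function(kk) {
    tr <- fold != kk
    new_booster(X[tr, , drop = FALSE], y[tr], params,
                X_test = X[!tr, , drop = FALSE], y_test = y[!tr])
  })
  cv_null <- mean(vapply(boosters, function(b) {
    poisson_deviance(b$y_test, rep(exp(b$init), length(b$y_test)))
  }, numeric(1)))

  trees_grid <- integer(0)
  mean_dev <- numeric(0)
  sd_dev <- numeric(0)
  n_cur <- 0L
  repeat {
    step <- min(params$step_size, params$max_trees - n_cur)
    for (b in boosters) booster_add_trees(b, step)
    n_cur <- n_cur + step
    devs <- vapply(boosters, function(b) {
      poisson_deviance(b$y_test, exp(b$f_test))
    }, numeric(1))
    trees_grid <- c(trees_grid, n_cur)
    mean_dev <- c(mean_dev, mean(devs))
    sd_dev <- c(sd_dev, sd(devs))
    best <- which.min(mean_dev)
    if (n_cur >= params$max_trees) {
      if (best == length(mean_dev)) {
        warn(sprintf("CV deviance still decreasing at max_trees = %d; using nt = max_trees.",
                     params$max_trees))
      }
      break
    }
    if (length(mean_dev) - best >= params$patience) break
  }
  best <- which.min(mean_dev)
  nt <- trees_grid[best]
  cv_dev <- mean_dev[best]
  cv_D2 <- 1 - cv_dev / cv_null

  # final refit on all rows -------------------------------------------------
  full <- new_booster(X, y, params, keep_trees = TRUE)
  booster_add_trees(full, nt)

  gains <- numeric(length(predictors))
  names(gains) <- predictors
  for (g in full$gains) {
    if (length(g)) gains[names(g)] <- gains[names(g)] + g
  }
  influence <- if (sum(gains) > 0) 100 * gains / sum(gains) else
    setNames(rep(100 / length(gains), length(gains)), predictors)
  ri <- tibble::tibble(predictor = predictors,
                       influence = unname(influence[predictors]))
  ri <- dplyr::arrange(ri, dplyr::desc(.data$influence))

  structure(list(
    init = full$init, learning_rate = params$learning_rate,
    trees = full$trees, nt = nt,
    cv_trace = tibble::tibble(trees = trees_grid, mean_deviance = mean_dev,
                              sd_deviance = sd_dev),
    cv_deviance = cv_dev, cv_null_deviance = cv_null, cv_D2 = cv_D2,
    train_deviance = poisson_deviance(y, full$mu),
    null_deviance = poisson_deviance(y, rep(mean(y), length(y))),
    relative_influence = ri,
    predictors = predictors, response = response,
    X = X, y = y, fitted = full$mu, params = params, seed = seed
  ), class = "brt_fit")
}

#' Predict from a boosted Poisson ensemble
#'
#' @param object A [fit_brt()] model.
#' @param newdata Data frame with the model's predictor columns; defaults to
#'   the training rows.
#' @param type `"response"` (expected count) or `"link"` (log scale).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.brt_fit <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else as.data.frame(newdata)
  missing <- setdiff(object$predictors, names(X))
  if (length(missing)) {
    abort(sprintf("newdata lacks predictor(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  X <- X[object$predictors]
  for (p in object$predictors) {
    if (is.character(X[[p]])) {
      X[[p]] <- factor(X[[p]], levels = levels(object$X[[p]]))
    }
  }
  f <- rep(object$init, nrow(X))
  for (tr in object$trees) {
    leaves <- rpart_leaves(tr$tree, X)
    f <- f + object$learning_rate * gamma_update(tr$gamma, leaves)
  }
  f <- pmin(f, 30)
  if (type == "link") f else exp(f)
}

#' Relative influence of each predictor
#'
#' Friedman importance: the squared-error (deviance) reduction of every
#' split, summed over all trees and attributed to the split variable, then
#' normalized to percentages summing to 100. A predictor never split on has
#' influence 0.
#'
#' @param fit A [fit_brt()] model.
#' @return Tibble `predictor`, `influence`, sorted decreasing.
#' @export
relative_influence <- function(fit) {
  stopifnot(inherits(fit, "brt_fit"))
  fit$relative_influence
}

#' @export
print.brt_fit <- function(x, ...) {
  cat(sprintf("Poisson BRT: %d trees (lr = %g, tc = %d, bf = %g), CV-D2 = %.3f\n",
              x$nt, x$learning_rate, x$params$tree_complexity,
              x$params$bag_fraction, x$cv_D2))
  cat("Top influences:\n")
  print(head(x$relative_influence, 5))
  invisible(x)
}

#' Grid search over BRT hyperparameters
#'
#' Fits [fit_brt()] for every combination of the supplied learning rates,
#' tree complexities and bag fractions and returns the fit with the highest
#' cross-validated deviance explained, together with the grid trace.
#'
#' @param data,response,seed As in [fit_brt()].
#' @param learning_rate,tree_complexity,bag_fraction Vectors of candidate
#'   values.
#' @param ... Further arguments passed to [brt_params()].
#' @return A list: `best_fit`, `grid` (tibble of combinations and CV-D2).
#' @export
tune_brt <- function(data, response,
                     learning_rate = c(0.01, 0.005, 0.001),
                     tree_complexity = c(2L, 3L, 5L),
                     bag_fraction = c(0.5, 0.75),
                     seed = 1L, ...) {
  grid <- expand.grid(lr = learning_rate, tc = tree_complexity,
                      bf = bag_fraction)
  best <- NULL
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    fit <- fit_brt(data, response,
                   brt_params(learning_rate = grid$lr[i],
                              tree_complexity = grid$tc[i],
                              bag_fraction = grid$bf[i], ...),
                   seed = seed)
    rows[[i]] <- tibble::tibble(lr = grid$lr[i], tc = grid$tc[i],
                                bf = grid$bf[i], nt = fit$nt,
                                cv_D2 = fit$cv_D2)
    if (is.null(best) || fit$cv_D2 > best$cv_D2) best <- fit
  }
  list(best_fit = best, grid = dplyr::bind_rows(rows))
}
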