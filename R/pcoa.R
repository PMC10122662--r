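#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric scaling: the squared dissimilarities are double-centered
#' (`-0.5 * C D^2 C`), eigendecomposed, and species coordinates on each
#' retained axis are the eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Variance explained is reported on the positive
#' eigenvalue mass. Gower matrices are typically near-Euclidean, so small
#' negative eigenvalues are tolerated; when the most negative eigenvalue
#' exceeds one thousandth of the largest positive one a warning is emitted
#' and the Cailliez additive correction can be requested instead.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param n_axes Number of axes to retain (default 5). Must not exceed the
#'   number of positive eigenvalues.
#' @param correction `"none"` or `"cailliez"` (adds the Cailliez constant to
#'   off-diagonal dissimilarities before embedding).
#' @param warn_low_variance Warn when the retained axes explain less than 80%
#'   of the positive-eigenvalue variance (the usual adequacy check for a
#'   functional space).
#' @return A list of class `functional_space`: `coordinates` (tibble
#'   `species_id`, `A1..Ak`), `eigenvalues` (all, including negatives),
#'   `variance_explained` (per retained axis), `correction`, `cailliez_constant`.
#' @examples
#' pts <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' fs <- pcoa(as.matrix(dist(pts)), n_axes = 2)
#' fs$variance_explained
#' @export
pcoa <- function(d, n_axes = 5L, correction = c("none", "cailliez"),
                 warn_low_variance = TRUE) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort("`d` must be square.")
  if (max(abs(d - t(d))) > 1e-12) abort("`d` must be symmetric.")
  ids <- rownames(d) %||% sprintf("s%d", seq_len(nrow(d)))
  n <- nrow(d)
  check_count(n_axes, "n_axes", min = 1L)

  cail <- NA_real_
  if (correction == "cailliez") {
    cail <- cailliez_constant(d)
    d <- d + cail
    diag(d) <- 0
  }

  B <- double_center(-0.5 * d^2)
  eig <- eigen(B, symmetric = TRUE)
  ev <- eig$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  if (n_axes > length(pos)) {
    abort(sprintf("Requested %d axes but only %d positive eigenvalues.",
                  n_axes, length(pos)))
  }
  most_neg <- min(ev)
  if (correction == "none" && most_neg < -1e-3 * max(ev)) {
    warn(sprintf(paste0("Dissimilarities are non-Euclidean (most negative ",
                        "eigenvalue %.3g vs largest %.3g); consider ",
                        "correction = \"cailliez\"."), most_neg, max(ev)))
  }
  keep <- pos[seq_len(n_axes)]
  coords <- eig$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]), n_axes)
  colnames(coords) <- paste0("A", seq_len(n_axes))
  ve <- ev[keep] / sum(ev[pos])
  if (warn_low_variance && sum(ve) < 0.80) {
    warn(sprintf("Retained %d axes explain only %.1f%% of the variance (< 80%%).",
                 n_axes, 100 * sum(ve)))
  }
  structure(list(
    coordinates = tibble::tibble(species_id = ids, !!!as.data.frame(coords)),
    eigenvalues = ev,
    variance_explained = ve,
    correction = correction,
    cailliez_constant = cail
  ), class = "functional_space")
}

double_center <- function(a) {
  r <- rowMeans(a); g <- mean(a)
  sweep(sweep(a, 1, r), 2, r) + g
}

# Cailliez (1983) additive constant: the largest real eigenvalue of the
# 2n x 2n special matrix built from the centered -0.5*D^2 and -0.5*D blocks.
cailliez_constant <- function(d) {
  n <- nrow(d)
  d1 <- double_center(-0.5 * d^2)
  d2 <- double_center(-0.5 * d)
  M <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  ev <- eigen(M, only.values = TRUE)$values
  max(Re(ev))
}

# coordinates of a functional_space as a plain matrix keyed by species id
space_matrix <- function(space) {
  stopifnot(inherits(space, "functional_space"))
  m <- as.matrix(space$coordinates[, -1, drop = FALSE])
  rownames(m) <- space$coordinates$species_id
  m
}

#' @export
print.functional_space <- function(x, ...) {
  k <- ncol(x$coordinates) - 1
  cat(sprintf("Functional space: %d species on %d axes (%.1f%% variance%s)\n",
              nrow(x$coordinates), k, 100 * sum(x$variance_explained),
              if (x$correction != "none") paste0(", ", x$correction,
                                                 " corrected") else ""))
  invisible(x)
}
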