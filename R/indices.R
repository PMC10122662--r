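#' Convex-hull volume of a point set
#'
#' Exact hull volume in k dimensions via supporting-hyperplane enumeration
#' (intended for community-sized point sets in a 3-5 dimensional functional
#' space). Returns the volume and the hull vertex rows.
#'
#' @param points Numeric matrix (rows = points).
#' @param tol Numerical tolerance.
#' @return List with `volume`, `vertices` (row indices) and `n_unique`.
#' @keywords internal
#' @export
hull_volume <- function(points, tol = 1e-9) {
  points <- as.matrix(points)
  d <- ncol(points)
  n <- nrow(points)
  if (choose(n, d) > 2e7) {
    abort("Too many hull facet candidates; reduce community size or dimensionality.")
  }
  res <- .convhull_cpp(points, tol)
  if (res$degenerate) {
    if (res$n_unique <= d) {
      abort(sprintf("Convex hull needs more than %d distinct points in %d-D (got %d).",
                    d, d, res$n_unique), class = "invasispace_too_few_points")
    }
    abort(sprintf("Points are degenerate in %d-D (lie in a lower-dimensional subspace).", d),
          class = "invasispace_degenerate_hull")
  }
  res
}

#' Functional richness (FRic)
#'
#' The size of the occupied functional space: the convex-hull volume of the
#' community's coordinates. Optionally standardized by the species-pool hull
#' volume, in which case it lies in `[0, 1]`.
#'
#' @param coords Matrix of community member coordinates (rows = species).
#' @param pool Pool coordinate matrix (required when `standardize = TRUE`).
#' @param standardize Divide by the pool hull volume?
#' @return Scalar volume.
#' @export
fric <- function(coords, pool = NULL, standardize = FALSE) {
  v <- hull_volume(coords)$volume
  if (standardize) {
    if (is.null(pool)) abort("`pool` coordinates required when standardize = TRUE.")
    v <- v / hull_volume(pool)$volume
  }
  v
}

#' Functional evenness (FEve)
#'
#' Regularity of species packing along the minimum spanning tree of the
#' community in functional space (presence/absence weighting): branch
#' proportions are truncated at `1/(S-1)` and rescaled so perfectly even
#' spacing gives 1.
#'
#' @param coords Matrix of member coordinates; needs at least 3 members.
#' @return Scalar in `[0, 1]` (`NA` when all members coincide).
#' @export
feve <- function(coords) {
  coords <- as.matrix(coords)
  s <- nrow(coords)
  if (s < 3) abort("FEve needs at least 3 members.")
  br <- vegan::spantree(dist(coords))$dist
  total <- sum(br)
  if (total == 0) {
    warn("All members coincide; FEve undefined.")
    return(NA_real_)
  }
  pew <- br / total
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional divergence (FDiv)
#'
#' Degree to which species sit toward the extremes of the occupied space:
#' distances `dG` to the gravity center of the hull vertices are compared to
#' their mean. With presence/absence weights the abundance-weighted deviation
#' term vanishes and FDiv reduces to `mean(dG) / (mean(|dG - mean(dG)|) +
#' mean(dG))`.
#'
#' @param coords Matrix of member coordinates (hull must exist).
#' @return Scalar in `(0, 1]`.
#' @export
fdiv <- function(coords) {
  coords <- as.matrix(coords)
  hv <- hull_volume(coords)
  gv <- colMeans(coords[hv$vertices, , drop = FALSE])
  dg <- sqrt(rowSums(sweep(coords, 2, gv)^2))
  mdg <- mean(dg)
  if (mdg == 0) abort("All members coincide; FDiv undefined.")
  s <- length(dg)
  delta_d <- sum(dg - mdg) / s          # zero by construction, kept explicit
  delta_abs <- sum(abs(dg - mdg)) / s
  (delta_d + mdg) / (delta_abs + mdg)
}

#' Functional dispersion (FDis)
#'
#' Mean Euclidean distance of community members to their own centroid.
#'
#' @param coords Matrix of member coordinates; needs at least 2 members.
#' @return Nonnegative scalar.
#' @export
fdis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) abort("FDis needs at least 2 members.")
  ctr <- colMeans(coords)
  mean(sqrt(rowSums(sweep(coords, 2, ctr)^2)))
}

#' Functional specialization (FSpe)
#'
#' How far, on average, community members sit from the species pool.
#' `pool_centroid` (default): mean member distance to the global pool
#' centroid. `mean_pairwise`: mean over members of their mean distance to all
#' other pool species.
#'
#' @param coords Member coordinates.
#' @param pool Pool coordinate matrix (rownames = species ids).
#' @param variant `"pool_centroid"` or `"mean_pairwise"`.
#' @param member_ids Ids of the members (needed by `mean_pairwise` to exclude
#'   self-distances); defaults to `rownames(coords)`.
#' @return Nonnegative scalar.
#' @export
fspe <- function(coords, pool, variant = c("pool_centroid", "mean_pairwise"),
                 member_ids = rownames(coords)) {
  variant <- match.arg(variant)
  coords <- as.matrix(coords); pool <- as.matrix(pool)
  if (variant == "pool_centroid") {
    ctr <- colMeans(pool)
    return(mean(sqrt(rowSums(sweep(coords, 2, ctr)^2))))
  }
  dd <- cross_dist(coords, pool)
  self <- if (!is.null(member_ids) && !is.null(rownames(pool))) {
    cbind(seq_along(member_ids), match(member_ids, rownames(pool)))
  } else NULL
  per_member <- vapply(seq_len(nrow(dd)), function(i) {
    row <- dd[i, ]
    if (!is.null(self) && !is.na(self[i, 2])) row <- row[-self[i, 2]]
    mean(row)
  }, numeric(1))
  mean(per_member)
}

#' Functional originality (FOri)
#'
#' Mean nearest-neighbour isolation of community members: distance from each
#' member to its nearest other species, in the global pool (default) or
#' within the community.
#'
#' @inheritParams fspe
#' @param variant `"pool"` or `"within"`.
#' @return Nonnegative scalar.
#' @export
fori <- function(coords, pool = coords, variant = c("pool", "within"),
                 member_ids = rownames(coords)) {
  variant <- match.arg(variant)
  coords <- as.matrix(coords)
  ref <- if (variant == "within") coords else as.matrix(pool)
  ref_ids <- rownames(ref)
  dd <- cross_dist(coords, ref)
  nn <- vapply(seq_len(nrow(dd)), function(i) {
    row <- dd[i, ]
    if (!is.null(member_ids) && !is.null(ref_ids)) {
      j <- match(member_ids[i], ref_ids)
      if (!is.na(j)) row <- row[-j]
    } else if (variant == "within") {
      row <- row[-i]
    }
    if (!length(row)) return(NA_real_)
    min(row)
  }, numeric(1))
  mean(nn)
}

#' Functional-diversity profile per watershed
#'
#' Computes the six presence/absence functional-diversity indices (FRic,
#' FEve, FDiv, FDis, FSpe, FOri) for every watershed of an occurrence table,
#' on the coordinates of a shared functional space. By default the recipient
#' community (natives plus established non-natives) is profiled.
#'
#' @param space A [pcoa()] functional space holding the full species pool.
#' @param occ Long occurrence tibble (`watershed_id`, `species_id`, `status`).
#' @param include_nonnative Include non-native members (default TRUE)?
#' @param min_species Minimum community size (watersheds below are dropped
#'   with a message; the conventional threshold is 6).
#' @param standardize_fric Standardize FRic by the pool hull volume?
#' @param fspe_variant,fori_variant Index variants, see [fspe()] and [fori()].
#' @return Tibble: `watershed_id`, `n_species`, `FRic`, `FEve`, `FDiv`,
#'   `FDis`, `FSpe`, `FOri`.
#' @export
fd_profile <- function(space, occ, include_nonnative = TRUE,
                       min_species = 6L, standardize_fric = FALSE,
                       fspe_variant = "pool_centroid",
                       fori_variant = "pool") {
  pool <- space_matrix(space)
  occ <- filter_communities(occ, min_species = min_species)
  if (!include_nonnative) occ <- dplyr::filter(occ, .data$status == "native")
  missing_sp <- setdiff(unique(occ$species_id), rownames(pool))
  if (length(missing_sp)) {
    abort(sprintf("Species absent from the functional space: %s.",
                  paste(head(missing_sp, 5), collapse = ", ")))
  }
  groups <- split(occ$species_id, occ$watershed_id)
  rows <- lapply(names(groups), function(w) {
    ids <- unique(groups[[w]])
    coords <- pool[ids, , drop = FALSE]
    tryCatch(
      tibble::tibble(
        watershed_id = w, n_species = length(ids),
        FRic = fric(coords, pool = pool, standardize = standardize_fric),
        FEve = feve(coords),
        FDiv = fdiv(coords),
        FDis = fdis(coords),
        FSpe = fspe(coords, pool, variant = fspe_variant, member_ids = ids),
        FOri = fori(coords, pool, variant = fori_variant, member_ids = ids)
      ),
      error = function(e) {
        abort(sprintf("Functional indices failed for watershed %s: %s",
                      w, conditionMessage(e)), parent = e)
      }
    )
  })
  dplyr::bind_rows(rows)
}
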