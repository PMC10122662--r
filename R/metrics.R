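#' Centroid distance (cd) between native and non-native assemblages
#'
#' Euclidean distance between the arithmetic centroids of the native and
#' non-native species of a community in functional space. Low cd means the
#' non-native assemblage sits where the native assemblage is densest.
#'
#' @param native_coords,nonnative_coords Coordinate matrices (rows =
#'   species) with equal dimensionality.
#' @return Nonnegative scalar.
#' @examples
#' centroid_distance(rbind(c(0, 0), c(2, 0)), rbind(c(1, 3), c(1, 5)))
#' @export
centroid_distance <- function(native_coords, nonnative_coords) {
  native_coords <- as.matrix(native_coords)
  nonnative_coords <- as.matrix(nonnative_coords)
  if (nrow(native_coords) == 0) abort("Native point set is empty.")
  if (nrow(nonnative_coords) == 0) abort("Non-native point set is empty.")
  if (ncol(native_coords) != ncol(nonnative_coords)) {
    abort("Point sets must share dimensionality.")
  }
  sqrt(sum((colMeans(native_coords) - colMeans(nonnative_coords))^2))
}

#' Mean nearest-native distance (md)
#'
#' For every non-native species, the distance to its nearest native
#' neighbour in functional space; md is the mean of those distances. High md
#' means non-natives occupy gaps between natives.
#'
#' @inheritParams centroid_distance
#' @return Nonnegative scalar.
#' @examples
#' mean_distance(rbind(c(0, 0), c(10, 0)), rbind(c(1, 0), c(4, 0)))
#' @export
mean_distance <- function(native_coords, nonnative_coords) {
  native_coords <- as.matrix(native_coords)
  nonnative_coords <- as.matrix(nonnative_coords)
  if (nrow(native_coords) == 0) abort("Native point set is empty.")
  if (nrow(nonnative_coords) == 0) abort("Non-native point set is empty.")
  dd <- cross_dist(nonnative_coords, native_coords)
  mean(apply(dd, 1, min))
}

#' Drop watersheds with too few species
#'
#' Functional-diversity indices in a k-dimensional space need more than k
#' species; communities below `min_species` (conventionally 6) are removed.
#'
#' @param occ Long occurrence tibble (`watershed_id`, `species_id`, `status`).
#' @param min_species Minimum distinct species per watershed.
#' @return The filtered occurrence tibble; the number of dropped watersheds
#'   is reported via a message and attribute `n_dropped`.
#' @export
filter_communities <- function(occ, min_species = 6L) {
  check_count(min_species, "min_species", min = 1L)
  sizes <- dplyr::summarise(dplyr::group_by(occ, .data$watershed_id),
                            n = dplyr::n_distinct(.data$species_id))
  keep <- sizes$watershed_id[sizes$n >= min_species]
  dropped <- nrow(sizes) - length(keep)
  if (dropped > 0) {
    message(sprintf("Dropped %d watershed(s) with fewer than %d species.",
                    dropped, min_species))
  }
  out <- dplyr::filter(occ, .data$watershed_id %in% keep)
  attr(out, "n_dropped") <- dropped
  out
}

valid_statuses <- c("native", "translocated", "exotic")

#' Invasiveness and invasibility response counts
#'
#' Species invasiveness is the number of watersheds where the species is
#' recorded as non-native (translocated or exotic); community invasibility is
#' the number of distinct established non-native species per watershed. Both
#' count the same (watershed, non-native species) pairs, so their totals
#' agree.
#'
#' @param occ Long occurrence tibble (`watershed_id`, `species_id`, `status`
#'   with levels native / translocated / exotic).
#' @return List with tibbles `invasiveness` (`species_id`, `invasiveness`,
#'   `invasion_type`) and `invasibility` (`watershed_id`, `invasibility`).
#'   Every species and watershed present in `occ` appears, zeros included.
#' @export
responses <- function(occ) {
  bad <- setdiff(unique(occ$status), valid_statuses)
  if (length(bad)) {
    abort(sprintf("Unknown status label(s): %s.", paste(bad, collapse = ", ")))
  }
  nn <- dplyr::filter(occ, .data$status != "native")
  nn <- dplyr::distinct(nn, .data$watershed_id, .data$species_id,
                        .keep_all = TRUE)
  inv_sp <- dplyr::summarise(
    dplyr::group_by(nn, .data$species_id),
    invasiveness = dplyr::n(),
    invasion_type = if (any(.data$status == "exotic")) "exotic" else "translocated",
    .groups = "drop"
  )
  all_sp <- tibble::tibble(species_id = sort(unique(occ$species_id)))
  inv_sp <- dplyr::left_join(all_sp, inv_sp, by = "species_id")
  inv_sp$invasiveness[is.na(inv_sp$invasiveness)] <- 0L

  inv_w <- dplyr::summarise(dplyr::group_by(nn, .data$watershed_id),
                            invasibility = dplyr::n(), .groups = "drop")
  all_w <- tibble::tibble(watershed_id = sort(unique(occ$watershed_id)))
  inv_w <- dplyr::left_join(all_w, inv_w, by = "watershed_id")
  inv_w$invasibility[is.na(inv_w$invasibility)] <- 0L

  list(invasiveness = inv_sp, invasibility = inv_w)
}

#' Native/non-native trait-space distances per watershed
#'
#' Computes cd ([centroid_distance()]) and md ([mean_distance()]) for every
#' watershed holding at least one non-native species, in the coordinates of
#' the shared functional space. Watersheds without non-natives (or without
#' natives) are returned with `NA` distances so downstream models can log
#' their exclusion.
#'
#' @param space A [pcoa()] functional space.
#' @param occ Long occurrence tibble.
#' @return Tibble: `watershed_id`, `cd`, `md`, `n_native`, `n_nonnative`.
#' @export
invasion_distances <- function(space, occ) {
  pool <- space_matrix(space)
  groups <- split(occ, occ$watershed_id)
  rows <- lapply(groups, function(g) {
    nat <- unique(g$species_id[g$status == "native"])
    nn <- unique(g$species_id[g$status != "native"])
    out <- tibble::tibble(watershed_id = g$watershed_id[[1]],
                          cd = NA_real_, md = NA_real_,
                          n_native = length(nat), n_nonnative = length(nn))
    if (length(nat) >= 1 && length(nn) >= 1) {
      out$cd <- centroid_distance(pool[nat, , drop = FALSE],
                                  pool[nn, , drop = FALSE])
      out$md <- mean_distance(pool[nat, , drop = FALSE],
                              pool[nn, , drop = FALSE])
    }
    out
  })
  dplyr::bind_rows(rows)
}
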