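#' Composite size and temperature axes
#'
#' Maximum body length, longevity and age at maturity are strongly
#' intercorrelated, as are the three temperature-tolerance traits. Each trio
#' is standardized and collapsed onto its first principal component
#' (Size_PCA1, Temp_PCA1). Axes are oriented so Size_PCA1 correlates
#' positively with body length (larger score = larger, longer-lived,
#' later-maturing fish) and Temp_PCA1 positively with maximum temperature
#' (larger score = more thermophilic).
#'
#' @param traits Trait tibble with the six trio columns complete.
#' @param size_traits,temp_traits Column names of the two trios (length,
#'   longevity, maturity age; temperature range, minimum, maximum).
#' @param log_size Log-transform the size trio before the PCA (these traits
#'   are log-normally distributed)? Default TRUE.
#' @return A list of class `composite_axes`: `scores` (tibble `species_id`,
#'   `Size_PCA1`, `Temp_PCA1`), `variance_explained` (named, per composite),
#'   `loadings`.
#' @export
composite_axes <- function(traits,
                           size_traits = c("MBl", "Lgv", "MtA"),
                           temp_traits = c("TRg", "TMn", "TMx"),
                           log_size = TRUE) {
  for (tr in c(size_traits, temp_traits)) {
    if (!tr %in% names(traits)) abort(sprintf("Trio column `%s` missing.", tr))
    if (anyNA(traits[[tr]])) abort(sprintf("Trio column `%s` has missing values.", tr))
  }
  first_axis <- function(block, orient_col) {
    p <- prcomp(block, center = TRUE, scale. = TRUE)
    score <- p$x[, 1]
    if (cor(score, block[[orient_col]]) < 0) {
      score <- -score
      p$rotation[, 1] <- -p$rotation[, 1]
    }
    list(score = score, ve = p$sdev[1]^2 / sum(p$sdev^2),
         loading = p$rotation[, 1])
  }
  size_block <- as.data.frame(traits[size_traits])
  if (log_size) size_block[] <- lapply(size_block, log)
  sz <- first_axis(size_block, size_traits[1])
  tp <- first_axis(as.data.frame(traits[temp_traits]), temp_traits[3])
  structure(list(
    scores = tibble::tibble(species_id = traits$species_id,
                            Size_PCA1 = unname(sz$score),
                            Temp_PCA1 = unname(tp$score)),
    variance_explained = c(Size_PCA1 = sz$ve, Temp_PCA1 = tp$ve),
    loadings = list(Size_PCA1 = sz$loading, Temp_PCA1 = tp$loading)
  ), class = "composite_axes")
}

#' Human use index
#'
#' Sum of the four binary human-use flags (fisheries, aquaculture, game,
#' ornamental): an integer between 0 (species not used by humans) and 4
#' (strongly used), the standard propagule-pressure proxy at the species
#' level.
#'
#' @param flags Tibble with `species_id` and four 0/1 columns.
#' @return Tibble `species_id`, `HUI`.
#' @export
human_use_index <- function(flags) {
  cols <- setdiff(names(flags), "species_id")
  if (length(cols) != 4) abort("Expected exactly four human-use flag columns.")
  for (cl in cols) {
    if (!is_binary01(flags[[cl]]) || anyNA(flags[[cl]])) {
      abort(sprintf("Flag column `%s` must contain only 0/1.", cl))
    }
  }
  tibble::tibble(species_id = flags$species_id,
                 HUI = as.integer(rowSums(flags[cols])))
}

#' Compare trait distributions across invasion-status groups
#'
#' For every trait and every pair of status groups (native vs translocated,
#' native vs exotic, translocated vs exotic), continuous and ordinal traits
#' are compared with the two-sample Kolmogorov-Smirnov test and binary /
#' categorical traits with a chi-square test on level counts. When any
#' expected cell count falls below 5 the chi-square p-value is replaced by a
#' Monte-Carlo estimate (10,000 table simulations). Ordinal traits carry
#' ties, which make the K-S p-value conservative.
#'
#' @param traits Complete trait tibble.
#' @param status Tibble (`species_id`, `status`) or named character vector
#'   giving each species a single label among native / translocated / exotic.
#' @param spec A [trait_spec()].
#' @return Tibble: `trait`, `kind`, `group1`, `group2`, `test`, `statistic`,
#'   `p_value`, `n1`, `n2`.
#' @export
compare_groups <- function(traits, status, spec = attr(traits, "trait_spec")) {
  if (is.null(spec)) abort("Supply a trait_spec.")
  if (is.data.frame(status)) {
    status <- setNames(status$status, status$species_id)
  }
  status <- status[traits$species_id]
  if (anyNA(status)) abort("Every species needs a status label.")
  bad <- setdiff(unique(status), valid_statuses)
  if (length(bad)) abort(sprintf("Unknown status label(s): %s.",
                                 paste(bad, collapse = ", ")))
  groups <- unique(status)
  counts <- table(status)
  if (any(counts < 2)) {
    abort(sprintf("Group(s) with fewer than 2 species: %s.",
                  paste(names(counts)[counts < 2], collapse = ", ")))
  }
  pairs <- utils::combn(intersect(valid_statuses, groups), 2, simplify = FALSE)
  cols <- trait_columns(traits, spec)
  rows <- list()
  for (tr in cols) {
    kind <- spec_kind(spec, tr)
    for (pr in pairs) {
      x <- traits[[tr]][status == pr[1]]
      y <- traits[[tr]][status == pr[2]]
      if (kind %in% c("continuous", "ordinal")) {
        if (kind == "ordinal") {
          lv <- spec_levels(spec, tr)
          x <- match(as.character(x), lv)
          y <- match(as.character(y), lv)
          kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
        } else {
          kt <- suppressWarnings(ks.test(x, y))
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          trait = tr, kind = kind, group1 = pr[1], group2 = pr[2],
          test = "ks", statistic = unname(kt$statistic),
          p_value = kt$p.value, n1 = length(x), n2 = length(y))
      } else {
        tab <- table(factor(as.character(c(x, y))),
                     rep(pr, c(length(x), length(y))))
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        if (any(ct$expected < 5)) {
          ct <- suppressWarnings(chisq.test(tab, simulate.p.value = TRUE,
                                            B = 10000))
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          trait = tr, kind = kind, group1 = pr[1], group2 = pr[2],
          test = "chisq", statistic = unname(ct$statistic),
          p_value = ct$p.value, n1 = length(x), n2 = length(y))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("group_comparison", class(out))
  out
}
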