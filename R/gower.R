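#' Gower dissimilarity over mixed trait types
#'
#' Pairwise species dissimilarity as the unweighted mean of per-trait
#' contributions: continuous traits contribute `|xi - xj| / range`, ordinal
#' traits are rank-transformed (ties averaged) and then treated as
#' continuous, binary and categorical traits contribute a 0/1 mismatch.
#' Requires a complete table (impute first); a continuous trait with zero
#' range is dropped with a warning since it cannot separate any pair.
#'
#' @param traits Complete trait tibble (`species_id` + trait columns).
#' @param spec A [trait_spec()].
#' @return A symmetric numeric matrix in `[0, 1]` with species ids as
#'   dimnames and attribute `traits_used`.
#' @examples
#' spec <- trait_spec(c("len", "mouth"), c("continuous", "categorical"),
#'                    list(NULL, c("sub", "sup")))
#' tb <- tibble::tibble(species_id = c("a", "b"), len = c(10, 30),
#'                      mouth = c("sub", "sup"))
#' gower_matrix(tb, spec)
#' @export
gower_matrix <- function(traits, spec = attr(traits, "trait_spec")) {
  if (is.null(spec)) abort("Supply a trait_spec.")
  validate_traits(traits, spec)
  cols <- trait_columns(traits, spec)
  if (anyNA(traits[cols])) {
    abort("Trait table has missing cells; run impute_missing() first.")
  }
  n <- nrow(traits)
  acc <- matrix(0, n, n)
  used <- character()
  for (tr in cols) {
    x <- traits[[tr]]
    kind <- spec_kind(spec, tr)
    if (kind == "ordinal") {
      x <- rank(match(as.character(x), spec_levels(spec, tr)),
                ties.method = "average")
      kind <- "continuous"
    }
    if (kind == "continuous") {
      rng <- diff(range(x))
      if (rng == 0) {
        warn(sprintf("Trait `%s` has zero range and was dropped from the Gower distance.", tr))
        next
      }
      contrib <- abs(outer(x, x, "-")) / rng
    } else { # binary / categorical mismatch
      contrib <- outer(as.character(x), as.character(x), "!=") * 1
    }
    acc <- acc + contrib
    used <- c(used, tr)
  }
  if (!length(used)) abort("No usable traits left for the Gower distance.")
  d <- acc / length(used)
  dimnames(d) <- list(traits$species_id, traits$species_id)
  attr(d, "traits_used") <- used
  d
}
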