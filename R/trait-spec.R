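#' Declare the measurement kind of each trait
#'
#' A trait specification maps every trait column of a trait table to one of
#' four kinds: `continuous`, `ordinal`, `binary` or `categorical`. The kind
#' drives Gower dissimilarity contributions, imputation engines (regression vs
#' classification forests) and the choice of two-sample test in group
#' comparisons. Ordinal traits carry their level order, categorical traits
#' their level set.
#'
#' @param trait Character vector of trait names.
#' @param kind Character vector, one of `"continuous"`, `"ordinal"`,
#'   `"binary"`, `"categorical"`.
#' @param levels List of level vectors (ordered for ordinal traits); `NULL`
#'   entries for continuous and binary traits.
#' @return A tibble of class `trait_spec` with columns `trait`, `kind`,
#'   `levels` (list column).
#' @examples
#' trait_spec(c("length", "care"), c("continuous", "categorical"),
#'            list(NULL, c("none", "nest", "bearer")))
#' @export
trait_spec <- function(trait, kind, levels = vector("list", length(trait))) {
  kinds <- c("continuous", "ordinal", "binary", "categorical")
  if (length(trait) != length(kind) || length(trait) != length(levels)) {
    abort("`trait`, `kind` and `levels` must have equal length.")
  }
  if (!all(kind %in% kinds)) {
    abort(sprintf("Unknown trait kind(s): %s.",
                  paste(setdiff(kind, kinds), collapse = ", ")))
  }
  bad <- kind %in% c("ordinal", "categorical") & vapply(levels, is.null, TRUE)
  if (any(bad)) {
    abort(sprintf("Ordinal/categorical traits need `levels`: %s.",
                  paste(trait[bad], collapse = ", ")))
  }
  out <- tibble::tibble(trait = as.character(trait), kind = kind,
                        levels = levels)
  class(out) <- c("trait_spec", class(out))
  out
}

#' The 20-trait fish functional roster
#'
#' Ten morphological traits (maximum body length plus nine unitless ratios
#' describing locomotion and food acquisition) and ten ecological /
#' life-history traits: longevity, fecundity, age at maturity, trophic level,
#' three temperature tolerances, euryhalinity (binary), parental care
#' (five-level categorical) and diet breadth (ordinal, 1-9). 17 traits are
#' continuous.
#'
#' @return A [trait_spec()] with 20 rows.
#' @export
fish_trait_spec <- function() {
  parental_levels <- c("open_substratum", "brood_hiders", "substratum_choosers",
                       "nest_spawners", "bearers")
  cont <- c("MBl", "BEl", "REs", "OGp", "RMl", "VEp", "BLs", "PFv", "PFs",
            "CPt", "Lgv", "FCt", "MtA", "TLl", "TRg", "TMn", "TMx")
  trait_spec(
    trait = c(cont, "Euh", "PCr", "DBt"),
    kind = c(rep("continuous", length(cont)), "binary", "categorical",
             "ordinal"),
    levels = c(rep(list(NULL), length(cont)), list(NULL),
               list(parental_levels), list(as.character(1:9)))
  )
}

spec_kind <- function(spec, trait) {
  k <- spec$kind[match(trait, spec$trait)]
  if (anyNA(k)) {
    abort(sprintf("Trait(s) absent from spec: %s.",
                  paste(trait[is.na(k)], collapse = ", ")))
  }
  k
}

spec_levels <- function(spec, trait) {
  spec$levels[[match(trait, spec$trait)]]
}

# columns of `traits` covered by the spec (everything except species_id)
trait_columns <- function(traits, spec) {
  cols <- setdiff(names(traits), "species_id")
  missing <- setdiff(cols, spec$trait)
  if (length(missing)) {
    abort(sprintf("Trait columns missing from spec: %s.",
                  paste(missing, collapse = ", ")))
  }
  cols
}

#' Validate a trait table against its specification
#'
#' Checks that every value conforms to its declared kind: binary traits hold
#' only 0/1, ordinal and categorical traits only their declared levels,
#' continuous traits are numeric. Missing values are allowed.
#'
#' @param traits Tibble with a `species_id` column and one column per trait.
#' @param spec A [trait_spec()].
#' @return `traits`, invisibly, after validation.
#' @export
validate_traits <- function(traits, spec) {
  if (!"species_id" %in% names(traits)) {
    abort("Trait table needs a `species_id` column.")
  }
  if (anyDuplicated(traits$species_id)) abort("Duplicated species_id values.")
  for (tr in trait_columns(traits, spec)) {
    x <- traits[[tr]]
    kind <- spec_kind(spec, tr)
    ok <- switch(kind,
      continuous = is.numeric(x),
      binary = is_binary01(x),
      ordinal = all(as.character(na.omit(x)) %in% spec_levels(spec, tr)),
      categorical = all(as.character(na.omit(x)) %in% spec_levels(spec, tr))
    )
    if (!ok) abort(sprintf("Trait `%s` violates its declared kind (%s).", tr, kind))
  }
  invisible(traits)
}
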