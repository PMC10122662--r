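# readers and writers for the plain-text interchange formats: trait CSV with
# a YAML schema, long-form occurrence CSV, covariates CSV, TSV reports and a
# JSON ground-truth sidecar

#' Write / read a trait table as CSV plus YAML schema
#'
#' The CSV holds `species_id` rows and one column per trait, empty cells for
#' missing values; the schema records each trait's kind and levels so the
#' table can be re-validated on read.
#'
#' @param traits Trait tibble.
#' @param spec A [trait_spec()].
#' @param path CSV path; the schema goes to `<path>.schema.yaml` (or
#'   `schema_path`).
#' @param schema_path Optional explicit schema path.
#' @return `path`, invisibly.
#' @export
write_trait_csv <- function(traits, spec, path,
                            schema_path = paste0(path, ".schema.yaml")) {
  validate_traits(traits, spec)
  write.csv(traits, path, row.names = FALSE, na = "")
  schema <- lapply(seq_len(nrow(spec)), function(i) {
    s <- list(kind = spec$kind[i])
    if (!is.null(spec$levels[[i]])) s$levels <- as.list(spec$levels[[i]])
    s
  })
  names(schema) <- spec$trait
  yaml::write_yaml(schema, schema_path)
  invisible(path)
}

#' @rdname write_trait_csv
#' @return For `read_trait_csv`: the validated trait tibble with the spec in
#'   attribute `trait_spec`.
#' @export
read_trait_csv <- function(path, schema_path = paste0(path, ".schema.yaml")) {
  schema <- yaml::read_yaml(schema_path)
  spec <- trait_spec(names(schema),
                     vapply(schema, function(s) s$kind, character(1)),
                     lapply(schema, function(s) {
                       if (is.null(s$levels)) NULL else
                         as.character(unlist(s$levels))
                     }))
  raw <- read.csv(path, colClasses = "character", na.strings = "")
  out <- tibble::tibble(species_id = raw$species_id)
  for (tr in spec$trait) {
    x <- raw[[tr]]
    kind <- spec_kind(spec, tr)
    out[[tr]] <- if (kind %in% c("continuous", "binary")) as.numeric(x) else x
  }
  validate_traits(out, spec)
  attr(out, "trait_spec") <- spec
  out
}

#' Write / read the long-form occurrence table
#'
#' Columns `watershed_id`, `species_id`, `status` (native / translocated /
#' exotic).
#'
#' @param occ Occurrence tibble.
#' @param path CSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_occurrence_csv <- function(occ, path) {
  bad <- setdiff(unique(occ$status), valid_statuses)
  if (length(bad)) abort(sprintf("Unknown status label(s): %s.",
                                 paste(bad, collapse = ", ")))
  write.csv(occ[c("watershed_id", "species_id", "status")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrence_csv
#' @export
read_occurrence_csv <- function(path) {
  occ <- tibble::as_tibble(read.csv(path, colClasses = "character"))
  bad <- setdiff(unique(occ$status), valid_statuses)
  if (length(bad)) abort(sprintf("Unknown status label(s): %s.",
                                 paste(bad, collapse = ", ")))
  occ
}

#' Write the ground truth of a synthetic study as a JSON sidecar
#'
#' @param gt The `ground_truth` element of an `invasion_simulation`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  jsonlite::write_json(list(
    planted_coefs = as.list(gt$planted_coefs),
    true_invasibility_rate = gt$true_invasibility_rate,
    true_invasiveness_score = gt$true_invasiveness_score
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an invasion report to a directory of TSV/JSON files
#'
#' Emits `summary.json` (model, predictors, mean CV-D2, seed, drop log),
#' `mean_influence.tsv`, `per_run.tsv`, and, when present,
#' `interactions.tsv`, `group_comparison.tsv`, `fd_profile.tsv`,
#' `invasion_distances.tsv`.
#'
#' @param report An `invasion_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "invasion_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(list(
    model = report$model,
    predictors = report$predictors,
    mean_cv_D2 = report$aggregate$mean_cv_D2,
    n_runs = report$aggregate$n_runs,
    seed = report$seed,
    dropped = report$dropped,
    moran = report$moran
  ), file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  tsv(report$aggregate$mean_influence, "mean_influence.tsv")
  tsv(report$aggregate$per_run, "per_run.tsv")
  if (!is.null(report$aggregate$pd_trends)) {
    tsv(report$aggregate$pd_trends, "pd_trends.tsv")
  }
  if (!is.null(report$interactions)) {
    m <- unclass(report$interactions)
    tsv(cbind(predictor = rownames(m), as.data.frame(m)), "interactions.tsv")
  }
  if (!is.null(report$group_comparison)) {
    tsv(report$group_comparison, "group_comparison.tsv")
  }
  if (!is.null(report$fd_profile)) tsv(report$fd_profile, "fd_profile.tsv")
  if (!is.null(report$invasion_distances)) {
    tsv(report$invasion_distances, "invasion_distances.tsv")
  }
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of [pipeline_config()];
#' `synthetic` and `brt` are nested maps passed to [synthetic_config()] and
#' [brt_params()]. `planted_coefs` under `synthetic` is a map
#' predictor-name to coefficient.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn_args <- raw$synthetic %||% list()
  if (!is.null(syn_args$planted_coefs)) {
    syn_args$planted_coefs <- unlist(syn_args$planted_coefs)
  }
  brt_args <- raw$brt %||% list()
  args <- raw[setdiff(names(raw), c("synthetic", "brt"))]
  args$synthetic <- do.call(synthetic_config, syn_args)
  args$brt <- do.call(brt_params, brt_args)
  do.call(pipeline_config, args)
}
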