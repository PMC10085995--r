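RESULTS_SCHEMA_VERSION <- "1.0"

#' Write results to disk
#'
#' Enrichment scans are written as TSV (one row per feature x biome test);
#' sphere models and classifier reports as JSON carrying a `schema_version`
#' field. All writers round-trip: reading the file back reproduces the
#' object exactly (doubles are serialized at full precision; `NaN` metrics
#' such as the AUC of a degenerate class are stored as JSON `null` and read
#' back as `NA`).
#'
#' @param object an `enrichment_result`, `sphere_model` or
#'   `classifier_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path) {
  UseMethod("write_results")
}

#' @export
write_results.enrichment_result <- function(object, path) {
  df <- as.data.frame(object)
  num <- vapply(df, is.double, TRUE)
  for (cn in names(df)[num]) df[[cn]] <- sprintf("%.17g", df[[cn]])
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8"),
    error = function(e) stop("cannot write results to '", path, "': ", conditionMessage(e))
  )
  invisible(path)
}

#' Read an enrichment-result TSV written by [write_results()]
#' @param path path to the TSV.
#' @return an `enrichment_result` data.frame.
#' @export
read_enrichment <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("feature_id", "biome", "k", "K", "n", "N", "p_value", "enriched",
            "fold", "skipped")
  if (!all(need %in% names(df))) stop("not an enrichment result TSV: ", path)
  coerce_enrichment_types(df)
}

coerce_enrichment_types <- function(df) {
  df$feature_id <- as.character(df$feature_id)
  df$biome <- as.character(df$biome)
  for (cn in intersect(c("k", "K", "n", "N", "p_value", "fold", "q_value"),
                       names(df))) {
    df[[cn]] <- as.numeric(df[[cn]])
  }
  df$enriched <- as.logical(df$enriched)
  df$skipped <- as.logical(df$skipped)
  class(df) <- c("enrichment_result", "data.frame")
  df
}

sphere_to_list <- function(s) {
  list(
    biome = s$biome,
    namespace = s$namespace,
    members = as.list(s$members),
    p_value = s$p_value,
    host_species = if (nrow(s$host_species) == 0) list() else
      lapply(seq_len(nrow(s$host_species)), function(i) {
        list(species_id = s$host_species$species_id[i],
             p_value = s$host_species$p_value[i])
      })
  )
}

list_to_sphere <- function(l) {
  hosts <- if (length(l$host_species) == 0) {
    data.frame(species_id = character(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      species_id = vapply(l$host_species, `[[`, "", "species_id"),
      p_value = vapply(l$host_species, `[[`, 0, "p_value"),
      stringsAsFactors = FALSE
    )
  }
  hosts$p_value <- as.numeric(hosts$p_value)
  function_sphere(biome = l$biome, members = as.character(unlist(l$members)),
                  p_value = as.numeric(l$p_value), namespace = l$namespace,
                  host_species = hosts)
}

#' @export
write_results.sphere_model <- function(object, path) {
  payload <- list(
    schema_version = RESULTS_SCHEMA_VERSION,
    object = "sphere_model",
    parameters = object$parameters,
    spheres = lapply(object$spheres, sphere_to_list),
    term_enrichment = enrichment_to_list(object$term_enrichment),
    species_enrichment = enrichment_to_list(object$species_enrichment)
  )
  write_json_file(payload, path)
}

enrichment_to_list <- function(enr) {
  if (is.null(enr)) return(NULL)
  df <- as.data.frame(enr)
  list(columns = as.list(names(df)),
       rows = lapply(seq_len(nrow(df)), function(i) unname(as.list(df[i, ]))),
       alpha = attr(enr, "alpha"))
}

list_to_enrichment <- function(l) {
  if (is.null(l) || length(l) == 0) return(NULL)
  cols <- unlist(l$columns)
  rows <- l$rows
  df <- as.data.frame(
    stats::setNames(lapply(seq_along(cols), function(j) {
      vals <- lapply(rows, `[[`, j)
      vals <- lapply(vals, function(v) if (is.null(v)) NA else v)
      unlist(vals)
    }), cols),
    stringsAsFactors = FALSE
  )
  df <- coerce_enrichment_types(df)
  attr(df, "alpha") <- l$alpha
  df
}

write_json_file <- function(payload, path) {
  tryCatch(
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null", pretty = TRUE),
    error = function(e) stop("cannot write JSON to '", path, "': ", conditionMessage(e))
  )
  invisible(path)
}

#' Read a sphere-model JSON written by [write_results()]
#' @param path path to the JSON file.
#' @return a `sphere_model`.
#' @export
read_sphere_model <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(l$object, "sphere_model")) stop("not a sphere_model JSON: ", path)
  structure(
    list(
      spheres = lapply(l$spheres, list_to_sphere),
      term_enrichment = list_to_enrichment(l$term_enrichment),
      species_enrichment = list_to_enrichment(l$species_enrichment),
      parameters = l$parameters
    ),
    class = "sphere_model"
  )
}

#' @export
write_results.classifier_report <- function(object, path) {
  payload <- list(
    schema_version = RESULTS_SCHEMA_VERSION,
    object = "classifier_report",
    report = unclass(object)
  )
  write_json_file(payload, path)
}

#' Read a classifier-report JSON written by [write_results()]
#' @param path path to the JSON file.
#' @return a `classifier_report`.
#' @export
read_classifier_report <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(l$object, "classifier_report")) {
    stop("not a classifier_report JSON: ", path)
  }
  structure(l$report, class = "classifier_report")
}
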