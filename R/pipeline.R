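#' Build a validated run configuration
#'
#' @param ontology path to the OBO ontology.
#' @param term_table path to the GO-term abundance TSV.
#' @param species_table path to the species abundance TSV (optional).
#' @param metadata path to the sample-metadata TSV.
#' @param gene_map path to the gene annotation map TSV (optional).
#' @param out_dir output directory (created if absent).
#' @param alpha enrichment threshold in (0, 1).
#' @param seed non-negative integer seed.
#' @param bh also report Benjamini-Hochberg q-values.
#' @param trace write the sphere expansion traces TSV.
#' @param features classifier feature set: `"both"`, `"go"` or `"species"`.
#' @param classify run the biome classifier after mining.
#' @param trees,folds classifier parameters.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(ontology, term_table, metadata, species_table = NULL,
                       gene_map = NULL, out_dir = ".", alpha = 0.01, seed = 1,
                       bh = FALSE, trace = FALSE,
                       features = c("both", "go", "species"),
                       classify = FALSE, trees = 100, folds = 10) {
  features <- match.arg(features)
  paths <- list(ontology = ontology, term_table = term_table, metadata = metadata)
  if (!is.null(species_table)) paths$species_table <- species_table
  if (!is.null(gene_map)) paths$gene_map <- gene_map
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) stop(nm, " path does not exist: ", paths[[nm]])
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!is_count_scalar(seed)) stop("seed must be a non-negative integer")
  cfg <- c(paths, list(out_dir = out_dir, alpha = alpha, seed = as.integer(seed),
                       bh = isTRUE(bh), trace = isTRUE(trace), features = features,
                       classify = isTRUE(classify), trees = trees, folds = folds))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full mining pipeline
#'
#' Executes prepare -> aggregate -> scan -> expand/merge -> link -> write
#' and, when requested, the biome classifier. Every JSON artifact embeds the
#' package version and a hash of the configuration, so reruns with the same
#' inputs and seed are byte-identical.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage log lines.
#' @return invisibly, a list with the `sphere_model`, optional
#'   `classifier_report` and the paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(...) if (!quiet) message("[enrichsphere] ", sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash covers the analysis-relevant configuration, not output locations
  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  cfg_string <- paste(names(cfg_for_hash),
                      vapply(cfg_for_hash, function(v) paste(format(v), collapse = ","), ""),
                      sep = "=", collapse = ";")
  hash <- config_hash(cfg_string)

  log_stage("parse_obo: %s", config$ontology)
  graph <- parse_obo(config$ontology)
  log_stage("ontology: %d terms, %d edges", nrow(graph$terms), nrow(graph$edges))

  terms_tab <- read_abundance_table(config$term_table, kind = "go_term",
                                    meta_path = config$metadata)
  log_stage("terms: %d features x %d samples (stage %s)",
            nrow(terms_tab$values), ncol(terms_tab$values), terms_tab$stage)
  term_counts <- aggregate_by_biome(prepare_counts(terms_tab))

  species_counts <- NULL
  species_tab <- NULL
  if (!is.null(config$species_table)) {
    species_tab <- read_abundance_table(config$species_table, kind = "species",
                                        meta_path = config$metadata)
    species_counts <- aggregate_by_biome(prepare_counts(species_tab))
    log_stage("species: %d features", nrow(species_tab$values))
  }
  gmap <- if (!is.null(config$gene_map)) read_gene_map(config$gene_map, graph = graph)

  log_stage("mining spheres at alpha = %g", config$alpha)
  model <- build_sphere_model(graph, term_counts, species_counts, gmap,
                              alpha = config$alpha)
  model$parameters$seed <- config$seed
  model$parameters$config_hash <- hash
  log_stage("spheres: %d", length(model$spheres))

  if (config$bh) {
    model$term_enrichment <- adjust_bh(model$term_enrichment, alpha = config$alpha)
    if (!is.null(model$species_enrichment)) {
      model$species_enrichment <- adjust_bh(model$species_enrichment,
                                            alpha = config$alpha)
    }
  }

  paths <- list(
    term_enrichment = file.path(config$out_dir, "term_enrichment.tsv"),
    sphere_model = file.path(config$out_dir, "sphere_model.json")
  )
  write_results(model$term_enrichment, paths$term_enrichment)
  if (!is.null(model$species_enrichment)) {
    paths$species_enrichment <- file.path(config$out_dir, "species_enrichment.tsv")
    write_results(model$species_enrichment, paths$species_enrichment)
  }
  write_results(model, paths$sphere_model)
  if (config$trace) {
    paths$trace <- file.path(config$out_dir, "expansion_trace.tsv")
    traces <- do.call(rbind, lapply(seq_along(model$spheres), function(i) {
      tr <- model$spheres[[i]]$trace
      if (is.null(tr)) return(NULL)
      cbind(sphere = i, biome = model$spheres[[i]]$biome, tr)
    }))
    if (is.null(traces)) {
      traces <- data.frame(sphere = integer(0), biome = character(0),
                           step = integer(0), candidate = character(0),
                           p = numeric(0))
    }
    utils::write.table(traces, paths$trace, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  report <- NULL
  if (config$classify) {
    if (length(model$spheres) == 0) {
      log_stage("classify skipped: no spheres, hence no enriched features")
    } else {
      log_stage("classifier: features = %s, %d trees, %d folds",
                config$features, config$trees, config$folds)
      tabs <- list(terms = to_proportions(terms_tab),
                   species = if (!is.null(species_tab)) to_proportions(species_tab))
      fm <- build_feature_matrix(tabs, model, features = config$features)
      report <- train_evaluate(fm, trees = config$trees, folds = config$folds,
                               seed = config$seed)
      report$parameters$config_hash <- hash
      report$parameters$package_version <-
        as.character(utils::packageVersion("enrichsphere"))
      paths$classifier_report <- file.path(config$out_dir, "classifier_report.json")
      write_results(report, paths$classifier_report)
      log_stage("classifier accuracy: %.3f", report$accuracy)
    }
  }
  invisible(list(model = model, classifier_report = report, paths = paths,
                 config_hash = hash))
}

#' Convert a count-stage table back to per-sample proportions
#'
#' @param table an [abundance_table()].
#' @return the table at stage `"proportion"` (each column divided by its
#'   observed total).
#' @export
to_proportions <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$stage == "proportion") return(table)
  totals <- pmax(colSums(table$values), 1)
  vals <- sweep(table$values, 2, totals, `/`)
  abundance_table(vals, table$meta, kind = table$kind, stage = "proportion")
}
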