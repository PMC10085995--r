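#' Null-calibration benchmark for the enrichment scan
#'
#' Simulates biome-labeled datasets with no planted signal (multinomial
#' sampling, biome-independent proportions) and reports the fraction of
#' (feature, biome) tests called at `p < alpha`. Discreteness makes the
#' exact test conservative, so the fraction should sit at or below the
#' nominal level.
#'
#' @param seeds integer vector; one simulated dataset per seed.
#' @param n_terms features per dataset (default 200).
#' @param samples_per_biome samples per biome (default 20).
#' @param depth reads per sample (default 1e4).
#' @param alpha nominal test level (default 0.01).
#' @param biomes biome labels (default the four-biome panel).
#' @return the pooled fraction of tests with `p < alpha`.
#' @export
typeI_fraction <- function(seeds, n_terms = 200, samples_per_biome = 20,
                           depth = 1e4, alpha = 0.01,
                           biomes = c("Engineered", "Gut", "Freshwater", "Soil")) {
  hits <- 0
  total <- 0
  for (s in seeds) {
    graph <- make_ontology(n_terms, 1, seed = s)
    truth <- plant_truth(graph, biomes, n_spheres = 0, n_species = 2, seed = s)
    sim <- simulate_dataset(truth, samples_per_biome = samples_per_biome,
                            depth = depth, concentration = Inf, seed = s)
    res <- scan_enrichment(aggregate_by_biome(sim$terms), alpha = alpha)
    res <- res[res$feature_id %in% graph$terms$id & !res$skipped, ]
    hits <- hits + sum(res$p_value < alpha)
    total <- total + nrow(res)
  }
  hits / total
}

#' One planted-sphere recovery replicate at the benchmark conditions
#'
#' Generates a planted dataset, mines it with [build_sphere_model()] and
#' scores the result with [score_recovery()]. Defaults are the benchmark
#' conditions used throughout the package: a 300-term three-namespace
#' ontology, four biomes, five planted spheres of 3-6 terms at effect 5,
#' 30 samples per biome at depth 5e4.
#'
#' @param seed integer seed driving ontology, truth and data.
#' @param n_terms,n_spheres,sphere_size_range,effect,n_species,samples_per_biome,depth,concentration
#'   generator settings, see [plant_truth()] and [simulate_dataset()].
#' @param alpha mining threshold.
#' @return list with `graph`, `truth`, `sim`, `model` and the recovery
#'   `report`.
#' @export
recovery_replicate <- function(seed, n_terms = 300, n_spheres = 5,
                               sphere_size_range = c(3, 6), effect = 5,
                               n_species = 40, samples_per_biome = 30,
                               depth = 5e4, concentration = 1e6, alpha = 0.01) {
  biomes <- c("Engineered", "Gut", "Freshwater", "Soil")
  graph <- make_ontology(n_terms, 3, seed = seed)
  truth <- plant_truth(graph, biomes, n_spheres = n_spheres,
                       sphere_size_range = sphere_size_range, effect = effect,
                       n_species = n_species, seed = seed)
  sim <- simulate_dataset(truth, samples_per_biome = samples_per_biome,
                          depth = depth, concentration = concentration,
                          seed = seed)
  model <- build_sphere_model(graph, aggregate_by_biome(sim$terms),
                              aggregate_by_biome(sim$species), sim$gene_map,
                              alpha = alpha)
  list(graph = graph, truth = truth, sim = sim, model = model,
       report = score_recovery(model, truth))
}
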