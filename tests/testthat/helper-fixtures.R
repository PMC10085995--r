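# Shared fixtures and independent oracles, built in code at test time.

FOUR_BIOMES <- c("Engineered", "Gut", "Freshwater", "Soil")

# Exact-integer enumeration oracle for the upper hypergeometric tail:
# sum of pmf terms C(K,x) C(N-K, n-x) / C(N,n) for x = k..min(K,n).
# For N <= 25 every binomial is an exact integer in double precision.
hyper_tail_enum <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Independent Monte-Carlo multivariate hypergeometric urn sampler: draws the
# per-color counts sequentially (color m conditional on colors 1..m-1), and
# estimates P(T >= t_obs) for T = total member-colored items in the draw.
mc_sphere_tail <- function(K_members, n, N, t_obs, draws = 1e5, seed = 1) {
  withr::with_seed(seed, {
    remaining_N <- rep(N, draws)
    remaining_n <- rep(n, draws)
    total <- rep(0, draws)
    for (Km in K_members) {
      x <- stats::rhyper(draws, m = Km, n = remaining_N - Km, k = remaining_n)
      total <- total + x
      remaining_N <- remaining_N - Km
      remaining_n <- remaining_n - x
    }
    mean(total >= t_obs)
  })
}

# A linear chain ontology A <- B <- C ... (each term is_a its predecessor).
chain_graph <- function(ids, namespace = "biological_process") {
  edges <- if (length(ids) > 1) {
    data.frame(child = ids[-1], parent = ids[-length(ids)])
  } else {
    NULL
  }
  ontology_graph(
    data.frame(id = ids, name = paste("term", ids), namespace = namespace),
    edges
  )
}

# Small biome_counts builder from a plain matrix.
toy_counts <- function(mat, features = NULL, biomes = NULL) {
  if (!is.null(features)) rownames(mat) <- features
  if (!is.null(biomes)) colnames(mat) <- biomes
  biome_counts(mat)
}

# Standard planted benchmark at the default study conditions.
planted_benchmark <- function(seed, n_terms = 300, n_spheres = 5,
                              samples_per_biome = 30, depth = 5e4,
                              effect = 5, concentration = 1e6) {
  graph <- make_ontology(n_terms, 3, seed = seed)
  truth <- plant_truth(graph, FOUR_BIOMES, n_spheres = n_spheres,
                       sphere_size_range = c(3, 6), effect = effect,
                       n_species = 40, seed = seed)
  sim <- simulate_dataset(truth, samples_per_biome = samples_per_biome,
                          depth = depth, concentration = concentration,
                          seed = seed)
  list(graph = graph, truth = truth, sim = sim)
}

# Separable toy classification problem: per-class one-hot features plus noise.
onehot_feature_tables <- function(per_class = 12, noise_features = 3, seed = 42) {
  withr::with_seed(seed, {
    n <- per_class * length(FOUR_BIOMES)
    biome <- rep(FOUR_BIOMES, each = per_class)
    ids <- sprintf("S%03d", seq_len(n))
    hot <- t(sapply(FOUR_BIOMES, function(b) ifelse(biome == b, 0.2, 0)))
    noise <- matrix(runif(noise_features * n, 0, 0.1), nrow = noise_features)
    vals <- rbind(hot, noise)
    rownames(vals) <- c(paste0("T:HOT_", FOUR_BIOMES),
                        sprintf("T:NOISE%d", seq_len(noise_features)))
    colnames(vals) <- ids
    meta <- data.frame(sample_id = ids, biome = biome, read_depth = 1e4)
    abundance_table(vals, meta, kind = "go_term", stage = "proportion")
  })
}
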