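test_that("make_ontology builds valid seeded DAGs of the requested shape", {
  g1 <- make_ontology(1, 1, seed = 1)
  expect_equal(nrow(g1$terms), 1)
  expect_equal(nrow(g1$edges), 0)

  g <- make_ontology(90, 3, mean_parents = 1.3, seed = 4)
  expect_equal(nrow(g$terms), 90)
  expect_equal(length(unique(g$terms$namespace)), 3)
  # acyclicity and namespace discipline are enforced by the constructor;
  # identical seeds give identical graphs
  expect_identical(make_ontology(90, 3, mean_parents = 1.3, seed = 4), g)
  expect_false(identical(make_ontology(90, 3, mean_parents = 1.3, seed = 5), g))
  expect_error(make_ontology(2, 5), "n_terms")
})

test_that("realized mean parent count tracks the mean_parents setting", {
  target <- 1.5
  means <- vapply(1:10, function(s) {
    g <- make_ontology(500, 1, mean_parents = target, seed = s)
    non_root <- setdiff(g$terms$id, g$terms$id[1])
    mean(vapply(g$parents[non_root], length, 0L))
  }, 0)
  expect_lt(abs(mean(means) - target), 0.2)
})

test_that("plant_truth places connected, disjoint, biome-cycled spheres", {
  g <- make_ontology(200, 3, seed = 8)
  tr <- plant_truth(g, FOUR_BIOMES, n_spheres = 5, sphere_size_range = c(3, 6),
                    effect = 5, n_species = 40, seed = 8)
  expect_equal(length(tr$planted_spheres), 5)
  expect_equal(vapply(tr$planted_spheres, `[[`, "", "biome"),
               FOUR_BIOMES[c(1, 2, 3, 4, 1)])
  sizes <- lengths(lapply(tr$planted_spheres, `[[`, "members"))
  expect_true(all(sizes >= 3 & sizes <= 6))
  # pairwise disjoint
  all_members <- unlist(lapply(tr$planted_spheres, `[[`, "members"))
  expect_equal(anyDuplicated(all_members), 0)
  # connected: every non-seed member adjacent to an earlier member
  for (sp in tr$planted_spheres) {
    for (j in seq_along(sp$members)[-1]) {
      nb <- unique(unlist(lapply(sp$members[1:(j - 1)], neighbors, graph = g)))
      expect_true(sp$members[j] %in% nb)
    }
  }
  # baselines are proper distributions; truth is a pure function of the seed
  expect_equal(sum(tr$baseline_terms), 1)
  expect_equal(sum(tr$baseline_species), 1)
  expect_identical(plant_truth(g, FOUR_BIOMES, 5, c(3, 6), 5, 40, seed = 8), tr)

  # n_spheres = 0: nothing planted
  tr0 <- plant_truth(g, FOUR_BIOMES, n_spheres = 0, seed = 1)
  expect_equal(length(tr0$planted_spheres), 0)
  expect_equal(length(tr0$planted_species), 0)
  expect_error(plant_truth(g, FOUR_BIOMES, effect = 1), "effect")
})

test_that("simulated samples hit the requested depth exactly and reproducibly", {
  bench <- planted_benchmark(21, n_terms = 60, n_spheres = 2,
                             samples_per_biome = 4, depth = 1234)
  sim <- bench$sim
  expect_true(all(colSums(sim$terms$values) == 1234))
  expect_true(all(colSums(sim$species$values) == 1234))
  expect_equal(sim$terms$stage, "count")
  expect_equal(unique(sim$meta$read_depth), 1234)
  # bit-identical rerun under the same seed
  sim2 <- simulate_dataset(bench$truth, samples_per_biome = 4, depth = 1234,
                           concentration = 1e6, seed = 21)
  expect_identical(sim2$terms$values, sim$terms$values)
  expect_identical(sim2$species$values, sim$species$values)
})

test_that("null simulation shows no systematic biome factor for any term", {
  # no planted spheres: per-feature mean counts should differ between the
  # first biome and the rest only by sampling noise (3-sigma check)
  g <- make_ontology(40, 1, seed = 31)
  reps <- 20
  depth <- 5000
  excess <- matrix(NA_real_, reps, 40)
  for (r in seq_len(reps)) {
    tr <- plant_truth(g, FOUR_BIOMES, n_spheres = 0, n_species = 10, seed = 300 + r)
    sim <- simulate_dataset(tr, samples_per_biome = 6, depth = depth,
                            concentration = Inf, seed = 300 + r)
    in_a <- sim$meta$biome == FOUR_BIOMES[1]
    feats <- g$terms$id
    excess[r, ] <- rowMeans(sim$terms$values[feats, in_a, drop = FALSE]) -
      rowMeans(sim$terms$values[feats, !in_a, drop = FALSE])
  }
  # standardize by the empirical replicate spread; mean over reps ~ N(0, sd/sqrt(reps))
  z <- colMeans(excess) / (apply(excess, 2, stats::sd) / sqrt(reps))
  expect_true(all(abs(z) < 4.5)) # 40 simultaneous checks; 4.5 sigma family bound
  expect_lt(mean(abs(z) > 3), 0.05)
})

test_that("planted terms realize close to the nominal fold in their biome", {
  folds <- c()
  for (s in 1:3) {
    bench <- planted_benchmark(400 + s, n_terms = 150, n_spheres = 4,
                               samples_per_biome = 30, depth = 5e4)
    sim <- bench$sim
    for (sp in bench$truth$planted_spheres) {
      in_b <- sim$meta$biome == sp$biome
      for (tm in sp$members) {
        folds <- c(folds, mean(sim$terms$values[tm, in_b]) /
                     mean(sim$terms$values[tm, !in_b]))
      }
    }
  }
  expect_true(all(folds > 3.5 & folds < 6.5))
})

test_that("recovery scoring counts matched members and hosts correctly", {
  g <- chain_graph(sprintf("T:%d", 1:6))
  tr <- list(
    ontology = g, biomes = c("A", "B"),
    planted_spheres = list(list(biome = "A", members = sprintf("T:%d", 1:4),
                                effect = 5)),
    planted_species = list(list(biome = "A", species_id = "SP:1", effect = 5)),
    gene_map = gene_annotation_map(data.frame(
      gene_id = "G1", term_id = "T:1", species_id = "SP:1"
    )),
    seed = 1
  )
  class(tr) <- "planted_truth"
  model_of <- function(members, hosts = character(0)) {
    structure(list(spheres = list(function_sphere(
      "A", members, 1e-9, "biological_process",
      host_species = data.frame(species_id = hosts,
                                p_value = rep(1e-6, length(hosts)))
    )), term_enrichment = NULL, species_enrichment = NULL,
    parameters = list(alpha = 0.01)), class = "sphere_model")
  }
  # perfect recovery
  rec <- score_recovery(model_of(sprintf("T:%d", 1:4), "SP:1"), tr)
  expect_equal(rec$mean_precision, 1)
  expect_equal(rec$mean_recall, 1)
  expect_equal(rec$mean_host_recall, 1)
  # one extra term: precision 0.8, recall 1
  rec <- score_recovery(model_of(sprintf("T:%d", 1:5)), tr)
  expect_equal(rec$mean_precision, 0.8)
  expect_equal(rec$mean_recall, 1)
  # empty model: 0/0 by convention
  empty <- structure(list(spheres = list(), term_enrichment = NULL,
                          species_enrichment = NULL,
                          parameters = list(alpha = 0.01)),
                     class = "sphere_model")
  rec <- score_recovery(empty, tr)
  expect_equal(rec$mean_precision, 0)
  expect_equal(rec$mean_recall, 0)
})
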