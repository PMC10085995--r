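test_that("sphere_pvalue is the pooled univariate tail (pooling identity)", {
  counts <- toy_counts(rbind(c(4, 1, 0, 0), c(4, 1, 0, 0),
                             c(4, 4, 4, 4), c(4, 10, 12, 4)),
                       c("T:A", "T:B", "T:C", "T:D"),
                       c("b1", "b2", "b3", "b4"))
  # |S| = 1 reduces to the univariate test
  expect_equal(sphere_pvalue("T:A", counts, "b1"),
               hypergeom_tail(4, 5, 16, 56))
  # two members, K = 5 each, k = 4 each, N = 40, n = 16
  c2 <- toy_counts(rbind(c(4, 1), c(4, 1), c(8, 22)),
                   c("T:A", "T:B", "T:OTHER"), c("b1", "b2"))
  expect_identical(sphere_pvalue(c("T:A", "T:B"), c2, "b1"),
                   hypergeom_tail(8, 10, 16, 40))
  expect_error(sphere_pvalue(c("T:A", "T:NOPE"), c2, "b1"), "T:NOPE")
  expect_error(sphere_pvalue(character(0), c2, "b1"), "nonempty")
})

test_that("pooling identity holds exactly on random member sets", {
  withr::with_seed(7, {
    for (rep in 1:100) {
      nf <- sample(5:15, 1); nb <- sample(2:4, 1)
      m <- matrix(rpois(nf * nb, 8), nf,
                  dimnames = list(sprintf("T:%03d", seq_len(nf)),
                                  sprintf("B%d", seq_len(nb))))
      counts <- biome_counts(m)
      members <- sample(rownames(m), sample(1:nf, 1))
      b <- sample(colnames(m), 1)
      expect_identical(
        sphere_pvalue(members, counts, b),
        hypergeom_tail(sum(m[members, b]), sum(m[members, ]),
                       sum(m[, b]), sum(m))
      )
    }
  })
})

test_that("closed-form sphere p agrees with a Monte-Carlo multivariate urn", {
  withr::with_seed(11, {
    for (i in 1:3) {
      nf <- 12
      m <- matrix(rpois(nf * 3, 30), nf,
                  dimnames = list(sprintf("T:%03d", 1:nf), c("A", "B", "C")))
      counts <- biome_counts(m)
      members <- sample(rownames(m), 3)
      t_obs <- sum(m[members, "A"])
      exact <- sphere_pvalue(members, counts, "A")
      mc <- mc_sphere_tail(unname(rowSums(m)[members]), sum(m[, "A"]), sum(m),
                           t_obs, draws = 1e5, seed = 100 + i)
      se <- sqrt(max(exact * (1 - exact), 1e-12) / 1e5)
      expect_lt(abs(mc - exact), 3 * se + 1e-12)
    }
  })
})

test_that("expansion absorbs a planted chain and stops at unsupported neighbors", {
  # chain T1 - T2 - T3 - T4 - T5; plant 5x signal on T2, T3, T4 in biome A
  ids <- sprintf("T:%d", 1:5)
  g <- chain_graph(ids)
  base <- c(20, 20, 20, 20, 20)
  planted <- c(FALSE, TRUE, TRUE, TRUE, FALSE)
  m <- cbind(A = ifelse(planted, base * 5, base), B = base, C = base, D = base)
  rownames(m) <- ids
  # background filler keeps biome totals equal
  m <- rbind(m, OTHER = c(sum(m[, "B"]) * 4 - sum(m[, "A"]) + 400, 400, 400, 400))
  counts <- biome_counts(m)

  sp <- expand_sphere("T:3", g, counts, "A", alpha = 0.01)
  expect_s3_class(sp, "function_sphere")
  expect_equal(sp$members[1], "T:3")
  expect_setequal(sp$members, c("T:2", "T:3", "T:4"))
  expect_lt(sp$p_value, 0.01)
  expect_equal(sp$namespace, "biological_process")

  # independent oracle: exhaustive best connected subset through T:3 of size <= 4
  connected_subsets <- function(seed, size) {
    subs <- list(seed)
    out <- list(seed)
    while (length(subs) > 0) {
      nxt <- list()
      for (s in subs) {
        if (length(s) >= size) next
        fr <- setdiff(unique(unlist(lapply(s, neighbors, graph = g))), s)
        for (f in fr) {
          cand <- sort(c(s, f))
          if (!any(vapply(out, identical, TRUE, y = cand))) {
            out[[length(out) + 1]] <- cand
            nxt[[length(nxt) + 1]] <- cand
          }
        }
      }
      subs <- nxt
    }
    out
  }
  subsets <- connected_subsets("T:3", 4)
  best <- subsets[[which.min(vapply(subsets, sphere_pvalue, 0,
                                    counts = counts, biome = "A"))]]
  expect_setequal(best, sp$members) # greedy finds the exhaustive optimum here

  # immediate stop: every neighbor unsupported in the biome
  m2 <- rbind(
    `T:1` = c(0, 30, 30, 30), `T:2` = c(40, 2, 2, 2), `T:3` = c(0, 30, 30, 30),
    OTHER = c(100, 78, 78, 78)
  )
  colnames(m2) <- c("A", "B", "C", "D")
  g3 <- chain_graph(sprintf("T:%d", 1:3))
  sp2 <- expand_sphere("T:2", g3, biome_counts(m2), "A")
  expect_equal(sp2$members, "T:2")
  expect_equal(sp2$p_value, hypergeom_tail(40, 46, 140, 560))

  # unenriched seed is refused
  expect_error(expand_sphere("T:1", g3, biome_counts(m2), "A"), "not enriched")
})

test_that("tied candidates resolve to the lexicographically smaller id", {
  # star seed T:M with children T:A and T:B having identical counts
  g <- ontology_graph(
    data.frame(id = c("T:M", "T:A", "T:B"), name = "x", namespace = "bp"),
    data.frame(child = c("T:A", "T:B"), parent = "T:M")
  )
  m <- rbind(`T:M` = c(50, 5, 5, 5), `T:A` = c(30, 3, 3, 3),
             `T:B` = c(30, 3, 3, 3), OTHER = c(100, 182, 182, 182))
  colnames(m) <- c("A", "B", "C", "D")
  sp <- expand_sphere("T:M", g, biome_counts(m), "A")
  expect_equal(sp$members[2], "T:A")
  expect_true(all(c("T:A", "T:B") %in% sp$members))
})

test_that("merge_spheres unions overlaps, keeps failing unions apart, dedups", {
  counts <- toy_counts(rbind(c(40, 4), c(40, 4), c(40, 4), c(30, 400)),
                       c("T:A", "T:B", "T:C", "T:D"), c("X", "Y"))
  mk <- function(members) {
    function_sphere("X", members, sphere_pvalue(members, counts, "X"), "bp")
  }
  # disjoint: unchanged
  out <- merge_spheres(list(mk("T:A"), mk("T:B")), counts)
  expect_equal(length(out), 2)
  # overlapping with passing union: merged
  out <- merge_spheres(list(mk(c("T:A", "T:B")), mk(c("T:B", "T:C"))), counts)
  expect_equal(length(out), 1)
  expect_setequal(out[[1]]$members, c("T:A", "T:B", "T:C"))
  expect_lt(out[[1]]$p_value, 0.01)
  # identical duplicates collapse
  out <- merge_spheres(list(mk("T:A"), mk("T:A")), counts)
  expect_equal(length(out), 1)
  # overlapping union that fails the gate: originals retained
  weak <- toy_counts(rbind(c(9, 2), c(5, 5), c(2, 9), c(100, 100)),
                     c("T:A", "T:B", "T:C", "T:D"), c("X", "Y"))
  s1 <- function_sphere("X", c("T:A", "T:B"),
                        sphere_pvalue(c("T:A", "T:B"), weak, "X"), "bp")
  s2 <- function_sphere("X", c("T:B", "T:C"),
                        sphere_pvalue(c("T:B", "T:C"), weak, "X"), "bp")
  out <- merge_spheres(list(s1, s2), weak, alpha = 1e-6)
  expect_equal(length(out), 2)
})

test_that("host linkage requires both gene ownership and biome enrichment", {
  sphere <- function_sphere("A", c("T:1", "T:2"), 1e-6, "bp")
  sc <- toy_counts(rbind(c(50, 2, 2, 2), c(10, 10, 10, 10), c(60, 3, 3, 3),
                         c(30, 130, 131, 130)),
                   c("SP:HOT", "SP:FLAT", "SP:NOGENE", "SP:REST"),
                   c("A", "B", "C", "D"))
  gm <- gene_annotation_map(data.frame(
    gene_id = c("G1", "G2"), term_id = c("T:1", "T:2"),
    species_id = c("SP:HOT", "SP:FLAT")
  ))
  out <- link_hosts(sphere, gm, sc)
  # enriched + linked kept; flat excluded; enriched-but-unlinked excluded
  expect_equal(out$host_species$species_id, "SP:HOT")
  expect_equal(out$host_species$p_value,
               hypergeom_tail(50, 56, 150, 586))
  # empty gene map: empty host list, not an error
  empty <- gene_annotation_map(data.frame(gene_id = character(0),
                                          term_id = character(0),
                                          species_id = character(0)))
  expect_equal(nrow(link_hosts(sphere, empty, sc)$host_species), 0)
})

test_that("the assembled model is empty on null data and finds planted spheres", {
  # null: perfectly flat counts
  g <- make_ontology(30, 1, seed = 2)
  flat <- matrix(10, 30, 4, dimnames = list(g$terms$id, FOUR_BIOMES))
  m0 <- build_sphere_model(g, biome_counts(flat))
  expect_equal(length(m0$spheres), 0)

  # planted benchmark: one sphere per planted truth, correct biome
  bench <- planted_benchmark(13, n_terms = 120, n_spheres = 2,
                             samples_per_biome = 15, depth = 2e4)
  model <- build_sphere_model(bench$graph, aggregate_by_biome(bench$sim$terms),
                              aggregate_by_biome(bench$sim$species),
                              bench$sim$gene_map)
  rec <- score_recovery(model, bench$truth)
  expect_true(all(rec$per_sphere$matched))
  expect_gte(rec$mean_recall, 0.8)

  # every sphere respects the gate and connectivity under the neighbor relation
  for (s in model$spheres) {
    expect_lt(s$p_value, 0.01)
    if (length(s$members) > 1) {
      for (j in 2:length(s$members)) {
        nb <- unique(unlist(lapply(s$members[1:(j - 1)], neighbors,
                                   graph = bench$graph)))
        expect_true(s$members[j] %in% nb)
      }
    }
  }
})

test_that("supplementation biome selection follows the strict-maximum rule", {
  counts <- c(Soil = 183, Freshwater = 125, Gut = 39, Engineered = 68)
  sel <- select_supplement_biome(counts, 182)
  expect_equal(sel$biome, "Soil")
  expect_equal(sel$count, 183)
  expect_equal(sel$supplemented_total, 365)
  expect_false(sel$tie)

  tie <- select_supplement_biome(c(A = 5, B = 5, C = 1), 10)
  expect_true(tie$tie)
  expect_true(is.na(tie$biome))

  single <- select_supplement_biome(c(A = 0, B = 7), 3)
  expect_equal(single$biome, "B")
  expect_equal(single$supplemented_total, 10)

  expect_error(select_supplement_biome(c(A = 0, B = 0), 3), "no homologs")
  expect_error(select_supplement_biome(c(5, 6), 3), "named")
})
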