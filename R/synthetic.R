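#' Generate a random ontology DAG
#'
#' Builds one rooted DAG per namespace: terms are added in order and each new
#' term draws its parent set uniformly from the terms already present in its
#' namespace, with parent count `1 + Poisson(mean_parents - 1)` capped at the
#' number of available terms — acyclic by construction and writable with
#' [write_obo()].
#'
#' @param n_terms total number of terms (>= `n_namespaces`).
#' @param n_namespaces number of namespaces (each gets one root). Up to
#'   three namespaces reuse the GO names (`biological_process`,
#'   `cellular_component`, `molecular_function`).
#' @param mean_parents target mean parent count of non-root terms (>= 1).
#' @param seed integer seed; the generator is a pure function of it.
#' @return an [ontology_graph()].
#' @export
make_ontology <- function(n_terms, n_namespaces = 1, mean_parents = 1.2, seed = 1) {
  if (!is_count_scalar(n_terms) || !is_count_scalar(n_namespaces) ||
      n_terms < n_namespaces || n_namespaces < 1) {
    stop("need n_terms >= n_namespaces >= 1")
  }
  if (mean_parents < 1) stop("mean_parents must be >= 1")
  go_ns <- c("biological_process", "cellular_component", "molecular_function")
  ns_names <- if (n_namespaces <= 3) go_ns[seq_len(n_namespaces)] else
    sprintf("namespace_%02d", seq_len(n_namespaces))
  withr::with_seed(as.integer(seed), {
    ids <- sprintf("T:%04d", seq_len(n_terms))
    namespace <- ns_names[1 + (seq_len(n_terms) - 1) %% n_namespaces]
    edges_child <- character(0)
    edges_parent <- character(0)
    for (i in seq_len(n_terms)) {
      prior <- ids[seq_len(i - 1)][namespace[seq_len(i - 1)] == namespace[i]]
      if (length(prior) == 0) next # namespace root
      np <- min(1 + stats::rpois(1, mean_parents - 1), length(prior))
      parents <- if (length(prior) == 1) prior else sample(prior, np)
      edges_child <- c(edges_child, rep(ids[i], length(parents)))
      edges_parent <- c(edges_parent, parents)
    }
    ontology_graph(
      terms = data.frame(id = ids, name = paste("synthetic term", seq_len(n_terms)),
                         namespace = namespace, stringsAsFactors = FALSE),
      edges = data.frame(child = edges_child, parent = edges_parent,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Plant ground-truth enrichment spheres and species
#'
#' Chooses `n_spheres` connected member sets on the ontology (sizes uniform
#' in `sphere_size_range`, grown by random frontier additions from a random
#' seed term), assigning biomes round-robin. Planted spheres are pairwise
#' disjoint and non-adjacent so recovery scoring is unambiguous. Baseline
#' term and species proportions are drawn Dirichlet(1); each sphere gets two
#' planted host species with the same effect in its biome and gene-map
#' records linking them to member terms. Non-planted species may carry decoy
#' annotations to non-planted terms.
#'
#' @param graph an [ontology_graph()].
#' @param biomes character vector of biome labels (>= 2).
#' @param n_spheres number of spheres to plant (0 allowed).
#' @param sphere_size_range integer `c(min, max)` member-set size.
#' @param effect abundance multiplier (> 1) applied to planted features in
#'   their biome before renormalization.
#' @param n_species total number of species features.
#' @param seed integer seed.
#' @return object of class `planted_truth`.
#' @export
plant_truth <- function(graph, biomes, n_spheres = 5, sphere_size_range = c(3, 6),
                        effect = 5, n_species = 40, seed = 1) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (length(biomes) < 2) stop("need >= 2 biome labels")
  if (!(effect > 1)) stop("`effect` must be > 1")
  lo <- sphere_size_range[1]; hi <- sphere_size_range[2]
  if (!(hi >= lo && lo >= 1)) stop("invalid sphere_size_range")
  withr::with_seed(as.integer(seed), {
    used <- character(0)      # members of planted spheres
    blocked <- character(0)   # members plus their 1-neighborhoods
    planted <- list()
    attempts <- 0
    while (length(planted) < n_spheres) {
      attempts <- attempts + 1
      if (attempts > 200 * max(n_spheres, 1)) {
        stop("cannot fit ", n_spheres, " disjoint non-adjacent spheres on this ontology")
      }
      size <- lo + sample.int(hi - lo + 1, 1) - 1L
      seed_term <- sample(setdiff(graph$terms$id, blocked), 1)
      members <- seed_term
      ok <- TRUE
      while (length(members) < size) {
        frontier <- setdiff(unique(unlist(lapply(members, neighbors, graph = graph))),
                            c(members, blocked))
        if (length(frontier) == 0) { ok <- FALSE; break }
        members <- c(members, sample(frontier, 1))
      }
      if (!ok) next
      planted[[length(planted) + 1L]] <- list(
        biome = biomes[1 + (length(planted) %% length(biomes))],
        members = members,
        effect = effect
      )
      used <- c(used, members)
      blocked <- unique(c(blocked, used,
                          unlist(lapply(members, neighbors, graph = graph))))
    }
    species_ids <- sprintf("SP:%03d", seq_len(n_species))
    planted_species <- list()
    gene_rows <- list()
    gene_i <- 0
    free_species <- species_ids
    for (si in seq_along(planted)) {
      sp <- planted[[si]]
      if (length(free_species) < 2) stop("n_species too small for 2 hosts per sphere")
      hosts <- sort(sample(free_species, 2))
      free_species <- setdiff(free_species, hosts)
      for (h in hosts) {
        planted_species[[length(planted_species) + 1L]] <-
          list(biome = sp$biome, species_id = h, effect = effect)
        n_genes <- sample(1:2, 1)
        terms <- sample(sp$members, min(n_genes, length(sp$members)))
        for (tm in terms) {
          gene_i <- gene_i + 1
          gene_rows[[length(gene_rows) + 1L]] <-
            data.frame(gene_id = sprintf("G:%04d", gene_i), term_id = tm,
                       species_id = h, stringsAsFactors = FALSE)
        }
      }
    }
    # decoy annotations: unplanted species on unplanted terms
    unplanted_terms <- setdiff(graph$terms$id, used)
    for (h in free_species) {
      if (length(unplanted_terms) > 0 && stats::runif(1) < 0.3) {
        gene_i <- gene_i + 1
        gene_rows[[length(gene_rows) + 1L]] <-
          data.frame(gene_id = sprintf("G:%04d", gene_i),
                     term_id = sample(unplanted_terms, 1),
                     species_id = h, stringsAsFactors = FALSE)
      }
    }
    gene_map <- if (length(gene_rows) > 0) {
      gene_annotation_map(do.call(rbind, gene_rows), graph = graph)
    } else {
      gene_annotation_map(data.frame(gene_id = character(0), term_id = character(0),
                                     species_id = character(0)))
    }
    # Dirichlet(1) baselines; planted features are reset to the median
    # baseline so the planted fold is the controlled effect size and never
    # compounds with a randomly dominant baseline draw.
    base_terms <- stats::rexp(nrow(graph$terms))
    base_terms[match(used, graph$terms$id)] <- stats::median(base_terms)
    base_terms <- stats::setNames(base_terms / sum(base_terms), graph$terms$id)
    base_species <- stats::rexp(n_species)
    planted_ids <- vapply(planted_species, `[[`, "", "species_id")
    base_species[match(planted_ids, species_ids)] <- stats::median(base_species)
    base_species <- stats::setNames(base_species / sum(base_species), species_ids)
    structure(
      list(ontology = graph, biomes = biomes, planted_spheres = planted,
           planted_species = planted_species, gene_map = gene_map,
           baseline_terms = base_terms, baseline_species = base_species,
           effect = effect, seed = as.integer(seed)),
      class = "planted_truth"
    )
  })
}

#' Simulate biome-labeled abundance tables from a planted truth
#'
#' For each sample of biome `b`, expected proportions are the baseline with
#' that biome's planted features multiplied by their effect; sample-level
#' proportions are drawn `Dirichlet(concentration * expected)` and counts
#' `Multinomial(depth, proportions)`. `concentration = Inf` gives the
#' multinomial limit (no between-sample overdispersion). Column sums of
#' every sample equal `depth` exactly.
#'
#' As in real metagenome profiles, an unannotated/unclassified mass pool is
#' carried alongside the named features (rows `UNANNOTATED` for terms,
#' `UNCLASSIFIED` for species): the extra reads gained by planted features in
#' their biome are drawn from this pool rather than proportionally from every
#' other feature, so non-planted features keep identical expected proportions
#' in every biome. Without such a pool, renormalization would make every
#' neutral feature look systematically enriched in whichever biome carries
#' the least planted mass.
#'
#' @param truth a [plant_truth()] object.
#' @param samples_per_biome samples simulated per biome (default 30).
#' @param depth total reads per sample (default 5e4).
#' @param concentration Dirichlet concentration scale (> 0 or `Inf`;
#'   default 1e6, close to the multinomial limit under which the
#'   hypergeometric urn of the mining stage is calibrated).
#' @param unannotated baseline fraction of each sample left unannotated
#'   (default 0.3); must exceed the planted extra mass of every biome.
#' @param seed integer seed.
#' @return list with `terms` and `species` [abundance_table()]s at stage
#'   `"count"`, the sample `meta` data.frame and the truth's `gene_map`.
#' @export
simulate_dataset <- function(truth, samples_per_biome = 30, depth = 5e4,
                             concentration = 1e6, unannotated = 0.3, seed = 1) {
  stopifnot(inherits(truth, "planted_truth"))
  if (!is_count_scalar(samples_per_biome) || samples_per_biome < 1) {
    stop("samples_per_biome must be a positive integer")
  }
  if (!is_count_scalar(depth) || depth < 1) stop("depth must be >= 1")
  if (!(concentration > 0)) stop("concentration must be > 0")
  if (!(unannotated >= 0 && unannotated < 1)) stop("unannotated must be in [0, 1)")
  biomes <- truth$biomes
  n_samp <- samples_per_biome * length(biomes)
  sample_ids <- sprintf("S%04d", seq_len(n_samp))
  sample_biome <- rep(biomes, each = samples_per_biome)
  term_expect <- expected_proportions(truth$baseline_terms, truth$planted_spheres,
                                      biomes, members_field = "members",
                                      unannotated = unannotated,
                                      filler_id = "UNANNOTATED")
  species_expect <- expected_proportions(truth$baseline_species, truth$planted_species,
                                         biomes, members_field = "species_id",
                                         unannotated = unannotated,
                                         filler_id = "UNCLASSIFIED")
  withr::with_seed(as.integer(seed), {
    term_mat <- vapply(seq_len(n_samp), function(j) {
      draw_sample_counts(term_expect[, sample_biome[j]], depth, concentration)
    }, numeric(nrow(term_expect)))
    species_mat <- vapply(seq_len(n_samp), function(j) {
      draw_sample_counts(species_expect[, sample_biome[j]], depth, concentration)
    }, numeric(nrow(species_expect)))
  })
  dimnames(term_mat) <- list(rownames(term_expect), sample_ids)
  dimnames(species_mat) <- list(rownames(species_expect), sample_ids)
  meta <- data.frame(sample_id = sample_ids, biome = sample_biome,
                     read_depth = depth, stringsAsFactors = FALSE)
  list(
    terms = abundance_table(term_mat, meta, kind = "go_term", stage = "count"),
    species = abundance_table(species_mat, meta, kind = "species", stage = "count"),
    meta = meta,
    gene_map = truth$gene_map
  )
}

# Per-biome expected proportion matrix. Named features occupy
# (1 - unannotated) of each sample at baseline; planted features of a biome
# are multiplied by their effect there, with the extra mass drawn from the
# unannotated pool so that non-planted features keep identical expected
# proportions in every biome.
expected_proportions <- function(baseline, planted, biomes, members_field,
                                 unannotated, filler_id) {
  base <- baseline * (1 - unannotated)
  out <- matrix(rep(base, length(biomes)), ncol = length(biomes),
                dimnames = list(names(baseline), biomes))
  for (p in planted) {
    feats <- p[[members_field]]
    out[feats, p$biome] <- out[feats, p$biome] * p$effect
  }
  filler <- 1 - colSums(out)
  if (any(filler < 0)) {
    stop("planted effect mass exceeds the unannotated pool; ",
         "raise `unannotated` or lower the effect")
  }
  rbind(out, matrix(filler, nrow = 1, dimnames = list(filler_id, biomes)))
}

draw_sample_counts <- function(expected, depth, concentration) {
  p <- if (is.finite(concentration)) {
    g <- stats::rgamma(length(expected), shape = concentration * expected)
    if (sum(g) == 0) expected else g / sum(g)
  } else {
    expected
  }
  as.vector(stats::rmultinom(1, size = depth, prob = p))
}

#' Score a recovered sphere model against the planted truth
#'
#' Each planted sphere is matched to the recovered sphere of the same biome
#' with the largest member overlap; member precision/recall/F1 are computed
#' on matched pairs. Unmatched planted spheres score recall 0 and, by
#' convention, precision 0. Host metrics compare the matched sphere's linked
#' species with the sphere's planted species.
#'
#' @param recovered a `sphere_model`.
#' @param truth a `planted_truth`.
#' @return object of class `recovery_report` with per-sphere rows and
#'   aggregate means.
#' @export
score_recovery <- function(recovered, truth) {
  stopifnot(inherits(recovered, "sphere_model"), inherits(truth, "planted_truth"))
  rows <- lapply(seq_along(truth$planted_spheres), function(i) {
    pl <- truth$planted_spheres[[i]]
    cand <- Filter(function(s) s$biome == pl$biome, recovered$spheres)
    if (length(cand) == 0) {
      return(data.frame(sphere = i, biome = pl$biome, matched = FALSE,
                        precision = 0, recall = 0, f1 = 0,
                        host_precision = 0, host_recall = 0,
                        stringsAsFactors = FALSE))
    }
    ov <- vapply(cand, function(s) length(intersect(s$members, pl$members)), 0L)
    best <- cand[[which.max(ov)]]
    tp <- length(intersect(best$members, pl$members))
    prec <- if (length(best$members) > 0) tp / length(best$members) else 0
    rec <- tp / length(pl$members)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    true_hosts <- vapply(Filter(function(q) q$biome == pl$biome, truth$planted_species),
                         `[[`, "", "species_id")
    # hosts planted for this sphere: those with a gene on its members
    true_hosts <- intersect(true_hosts,
                            truth$gene_map$species_id[truth$gene_map$term_id %in% pl$members])
    got_hosts <- best$host_species$species_id
    htp <- length(intersect(got_hosts, true_hosts))
    hp <- if (length(got_hosts) > 0) htp / length(got_hosts) else 0
    hr <- if (length(true_hosts) > 0) htp / length(true_hosts) else 0
    data.frame(sphere = i, biome = pl$biome, matched = tp > 0,
               precision = prec, recall = rec, f1 = f1,
               host_precision = hp, host_recall = hr, stringsAsFactors = FALSE)
  })
  per_sphere <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sphere = integer(0), biome = character(0), matched = logical(0),
               precision = numeric(0), recall = numeric(0), f1 = numeric(0),
               host_precision = numeric(0), host_recall = numeric(0))
  structure(
    list(
      per_sphere = per_sphere,
      mean_precision = if (nrow(per_sphere)) mean(per_sphere$precision) else NA_real_,
      mean_recall = if (nrow(per_sphere)) mean(per_sphere$recall) else NA_real_,
      mean_f1 = if (nrow(per_sphere)) mean(per_sphere$f1) else NA_real_,
      mean_host_precision = if (nrow(per_sphere)) mean(per_sphere$host_precision) else NA_real_,
      mean_host_recall = if (nrow(per_sphere)) mean(per_sphere$host_recall) else NA_real_
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery: precision %.3f, recall %.3f, F1 %.3f (hosts: P %.3f / R %.3f)\n",
              x$mean_precision, x$mean_recall, x$mean_f1,
              x$mean_host_precision, x$mean_host_recall))
  invisible(x)
}
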