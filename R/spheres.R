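#' Sphere-level pooled hypergeometric probability
#'
#' Joint enrichment test for a set of terms in one biome under the central
#' multivariate hypergeometric urn (one color per member term plus a pooled
#' "other" color, draw size = biome total). The test statistic is the total
#' member count observed in the biome; by the pooling identity its upper-tail
#' probability equals the univariate tail on the pooled counts,
#' `P(X >= sum k_m)` with `X ~ Hypergeometric(N, sum K_m, n)`. This closed
#' form is exact; a Monte-Carlo urn sampler is kept in the test suite as an
#' independent check.
#'
#' @param members character vector of member term ids (nonempty, all present
#'   in `counts`).
#' @param counts a [biome_counts()] urn for the term features.
#' @param biome biome label (a column of `counts`).
#' @return upper-tail probability of the pooled member count.
#' @export
sphere_pvalue <- function(members, counts, biome) {
  stopifnot(inherits(counts, "biome_counts"))
  if (length(members) == 0) stop("`members` must be nonempty")
  absent <- setdiff(members, rownames(counts$counts))
  if (length(absent) > 0) {
    stop("member term(s) absent from counts: ", paste(absent, collapse = ", "))
  }
  if (!biome %in% colnames(counts$counts)) stop("unknown biome: ", biome)
  k <- sum(counts$counts[members, biome])
  K <- sum(counts$totals_per_feature[members])
  hypergeom_tail(k, K, counts$totals_per_biome[[biome]], counts$grand_total)
}

#' Grow an enrichment sphere from an enriched seed term
#'
#' Greedy expansion over the ontology graph. Starting from an enriched seed,
#' each step considers the frontier of the current sphere: terms adjacent
#' (distance-1 `is_a`, either direction) to any member, within the seed's
#' namespace, present in the count table, and themselves univariately
#' enriched in the biome at `alpha`. The candidate minimizing the pooled
#' sphere p-value is added if that p-value stays below `alpha`; expansion
#' stops when no candidate passes (the failing candidate is not included).
#' Ties are broken by lexicographically smallest term id, so the procedure is
#' fully deterministic.
#'
#' @param seed an enriched term id (univariate p < alpha in `biome`).
#' @param graph an [ontology_graph()] containing `seed`.
#' @param counts a [biome_counts()] urn for terms.
#' @param biome biome label.
#' @param alpha significance threshold for both the membership filter and the
#'   pooled gate (default 0.01).
#' @return object of class `function_sphere`: biome, members in addition
#'   order (seed first), pooled `p_value`, namespace, expansion `trace`
#'   (step, candidate, p) and an empty host slot filled by [link_hosts()].
#' @export
expand_sphere <- function(seed, graph, counts, biome, alpha = 0.01) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(counts, "biome_counts"))
  if (!seed %in% graph$terms$id) stop("seed term absent from ontology: ", seed)
  if (!seed %in% rownames(counts$counts)) stop("seed term absent from counts: ", seed)
  seed_p <- univariate_p(seed, counts, biome)
  if (!(seed_p < alpha)) {
    stop(sprintf("seed '%s' is not enriched in biome '%s' (p = %.4g >= alpha)",
                 seed, biome, seed_p))
  }
  ns <- graph$terms$namespace[match(seed, graph$terms$id)]
  members <- seed
  p_cur <- seed_p
  trace <- data.frame(step = 0L, candidate = seed, p = seed_p,
                      stringsAsFactors = FALSE)
  repeat {
    cand <- setdiff(unique(unlist(lapply(members, neighbors, graph = graph))), members)
    cand <- cand[graph$terms$namespace[match(cand, graph$terms$id)] == ns]
    cand <- intersect(cand, rownames(counts$counts))
    cand <- cand[vapply(cand, function(tm) univariate_p(tm, counts, biome) < alpha, TRUE)]
    if (length(cand) == 0) break
    cand <- sort(cand)
    ps <- vapply(cand, function(tm) sphere_pvalue(c(members, tm), counts, biome), 0)
    best <- which.min(ps) # first minimum = lexicographically smallest on ties
    if (!(ps[best] < alpha)) break
    members <- c(members, cand[best])
    p_cur <- unname(ps[best])
    trace <- rbind(trace, data.frame(step = length(members) - 1L,
                                     candidate = cand[best], p = p_cur,
                                     stringsAsFactors = FALSE))
  }
  function_sphere(biome = biome, members = members, p_value = p_cur,
                  namespace = ns, trace = trace)
}

univariate_p <- function(term, counts, biome) {
  K <- counts$totals_per_feature[[term]]
  if (K == 0) return(1)
  hypergeom_tail(counts$counts[term, biome], K,
                 counts$totals_per_biome[[biome]], counts$grand_total)
}

#' @rdname expand_sphere
#' @param biome,members,p_value,namespace,trace,host_species sphere fields;
#'   used by readers and the generator, rarely called directly.
#' @export
function_sphere <- function(biome, members, p_value, namespace,
                            trace = NULL, host_species = NULL) {
  if (is.null(host_species)) {
    host_species <- data.frame(species_id = character(0), p_value = numeric(0),
                               stringsAsFactors = FALSE)
  }
  structure(
    list(biome = biome, members = members, p_value = p_value,
         namespace = namespace, host_species = host_species, trace = trace),
    class = "function_sphere"
  )
}

#' @export
print.function_sphere <- function(x, ...) {
  cat(sprintf("function_sphere [%s / %s]: %d term(s), p = %.3g, %d host(s)\n",
              x$biome, x$namespace, length(x$members), x$p_value,
              nrow(x$host_species)))
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Merge overlapping spheres within one biome and namespace
#'
#' Spheres sharing at least one member term are unioned and the union's
#' pooled p-value recomputed; the union replaces its parts only when it still
#' passes the gate (`p < alpha`), otherwise the pre-merge spheres are kept.
#' Repeats to a fixed point. Exact duplicates collapse to one sphere.
#'
#' @param spheres list of `function_sphere` objects from one biome and
#'   namespace.
#' @param counts the term [biome_counts()] urn.
#' @param alpha gate threshold.
#' @return list of `function_sphere` objects.
#' @export
merge_spheres <- function(spheres, counts, alpha = 0.01) {
  if (length(spheres) <= 1) return(spheres)
  stopifnot(all(vapply(spheres, inherits, TRUE, "function_sphere")))
  if (length(unique(vapply(spheres, `[[`, "", "biome"))) != 1 ||
      length(unique(vapply(spheres, `[[`, "", "namespace"))) != 1) {
    stop("merge_spheres expects spheres from a single biome and namespace")
  }
  repeat {
    merged <- FALSE
    n <- length(spheres)
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        a <- spheres[[i]]; b <- spheres[[j]]
        if (length(intersect(a$members, b$members)) == 0) next
        union_members <- c(a$members, setdiff(b$members, a$members))
        p_union <- sphere_pvalue(union_members, counts, a$biome)
        if (p_union < alpha) {
          spheres[[i]] <- function_sphere(a$biome, union_members, p_union,
                                          a$namespace, trace = NULL)
          spheres[[j]] <- NULL
          merged <- TRUE
        } else if (identical(sort(a$members), sort(b$members))) {
          spheres[[j]] <- NULL # duplicate that fails only at the boundary
          merged <- TRUE
        }
        if (merged) break
      }
      if (merged) break
    }
    if (!merged) break
  }
  spheres
}

#' Attach enriched host species to a sphere
#'
#' Candidate hosts are species carrying at least one gene annotated to a
#' member term of the sphere. Each candidate's full abundance is tested for
#' enrichment in the sphere's biome with the univariate hypergeometric tail;
#' hosts with `p < alpha` are attached, sorted by p-value then species id.
#'
#' @param sphere a `function_sphere`.
#' @param gene_map a [gene_annotation_map()].
#' @param species_counts a [biome_counts()] urn for species.
#' @param alpha host-enrichment threshold.
#' @return the sphere with its `host_species` slot filled.
#' @export
link_hosts <- function(sphere, gene_map, species_counts, alpha = 0.01) {
  stopifnot(inherits(sphere, "function_sphere"),
            inherits(species_counts, "biome_counts"))
  if (is.null(gene_map) || nrow(gene_map) == 0) {
    sphere$host_species <- data.frame(species_id = character(0),
                                      p_value = numeric(0),
                                      stringsAsFactors = FALSE)
    return(sphere)
  }
  candidates <- sort(unique(gene_map$species_id[gene_map$term_id %in% sphere$members]))
  absent <- setdiff(candidates, rownames(species_counts$counts))
  if (length(absent) > 0) {
    stop("species in gene map absent from species counts: ",
         paste(absent, collapse = ", "))
  }
  if (length(candidates) == 0) {
    sphere$host_species <- data.frame(species_id = character(0),
                                      p_value = numeric(0),
                                      stringsAsFactors = FALSE)
    return(sphere)
  }
  p <- vapply(candidates, function(sp) univariate_p(sp, species_counts, sphere$biome), 0)
  keep <- p < alpha
  hosts <- data.frame(species_id = candidates[keep], p_value = unname(p[keep]),
                      stringsAsFactors = FALSE)
  hosts <- hosts[order(hosts$p_value, hosts$species_id), , drop = FALSE]
  rownames(hosts) <- NULL
  sphere$host_species <- hosts
  sphere
}

#' Assemble the full enrichment sphere model
#'
#' Runs the whole mining procedure: univariate enrichment scans on terms and
#' species, greedy sphere expansion from every enriched term not already
#' absorbed into an earlier sphere (seeds processed in ascending univariate
#' p, ties by term id), overlap merging per biome and namespace, and host
#' linkage per sphere.
#'
#' @param graph an [ontology_graph()].
#' @param term_counts [biome_counts()] urn for GO terms.
#' @param species_counts [biome_counts()] urn for species (optional; without
#'   it no hosts are linked).
#' @param gene_map a [gene_annotation_map()] (optional).
#' @param alpha significance threshold used at every stage (default 0.01).
#' @return object of class `sphere_model`: `spheres` (list of
#'   `function_sphere`), `term_enrichment` and `species_enrichment` scans,
#'   and the `parameters` record.
#' @export
build_sphere_model <- function(graph, term_counts, species_counts = NULL,
                               gene_map = NULL, alpha = 0.01) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(term_counts, "biome_counts"))
  term_enr <- scan_enrichment(term_counts, alpha = alpha)
  species_enr <- if (!is.null(species_counts)) {
    scan_enrichment(species_counts, alpha = alpha)
  }
  seeds <- term_enr[term_enr$enriched & term_enr$feature_id %in% graph$terms$id, ]
  seeds <- seeds[order(seeds$p_value, seeds$feature_id, seeds$biome), ]
  spheres <- list()
  absorbed <- list() # biome -> character vector of member terms already used
  for (i in seq_len(nrow(seeds))) {
    b <- seeds$biome[i]
    tm <- seeds$feature_id[i]
    if (tm %in% absorbed[[b]]) next
    sp <- expand_sphere(tm, graph, term_counts, b, alpha = alpha)
    spheres[[length(spheres) + 1L]] <- sp
    absorbed[[b]] <- c(absorbed[[b]], sp$members)
  }
  # merge overlaps within each (biome, namespace) group
  if (length(spheres) > 0) {
    key <- vapply(spheres, function(s) paste(s$biome, s$namespace, sep = "\r"), "")
    groups <- split(spheres, key)
    spheres <- unlist(lapply(groups[order(names(groups))], merge_spheres,
                             counts = term_counts, alpha = alpha),
                      recursive = FALSE, use.names = FALSE)
  }
  if (!is.null(species_counts) && !is.null(gene_map)) {
    spheres <- lapply(spheres, link_hosts, gene_map = gene_map,
                      species_counts = species_counts, alpha = alpha)
  }
  # deterministic model order: biome, namespace, first member id
  if (length(spheres) > 0) {
    ord <- order(vapply(spheres, `[[`, "", "biome"),
                 vapply(spheres, `[[`, "", "namespace"),
                 vapply(spheres, function(s) s$members[1], ""))
    spheres <- spheres[ord]
  }
  structure(
    list(
      spheres = spheres,
      term_enrichment = term_enr,
      species_enrichment = species_enr,
      parameters = list(alpha = alpha,
                        package_version = as.character(utils::packageVersion("enrichsphere")))
    ),
    class = "sphere_model"
  )
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf("sphere_model: %d sphere(s), alpha = %g\n",
              length(x$spheres), x$parameters$alpha))
  for (s in x$spheres) {
    cat(sprintf("  [%s/%s] %d terms, p = %.3g, %d hosts\n", s$biome, s$namespace,
                length(s$members), s$p_value, nrow(s$host_species)))
  }
  invisible(x)
}

#' Select the biome for homolog supplementation
#'
#' Given per-biome homolog counts for a protein family, picks the biome with
#' the strictly largest count as the supplementation source; the supplemented
#' total is the reference-database count plus the selected biome's count. A
#' tie for the maximum yields no selection.
#'
#' @param homolog_counts named non-negative integer vector (names = biomes,
#'   at least two).
#' @param reference_count homolog count already in the reference database.
#' @return list with `biome`, `count`, `supplemented_total`, `tie`.
#' @export
select_supplement_biome <- function(homolog_counts, reference_count) {
  if (is.null(names(homolog_counts)) || length(homolog_counts) < 2) {
    stop("`homolog_counts` must be a named vector covering >= 2 biomes")
  }
  if (any(homolog_counts < 0) || any(homolog_counts != floor(homolog_counts))) {
    stop("homolog counts must be non-negative integers")
  }
  if (!is_count_scalar(reference_count)) {
    stop("`reference_count` must be a non-negative integer")
  }
  if (all(homolog_counts == 0)) stop("no homologs in any biome")
  mx <- max(homolog_counts)
  at_max <- names(homolog_counts)[homolog_counts == mx]
  if (length(at_max) > 1) {
    return(list(biome = NA_character_, count = NA_real_,
                supplemented_total = NA_real_, tie = TRUE))
  }
  list(biome = at_max, count = unname(mx),
       supplemented_total = unname(reference_count + mx), tie = FALSE)
}
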