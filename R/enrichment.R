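#' Exact upper-tail hypergeometric probability
#'
#' Returns `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: the probability
#' of drawing at least `k` marked items in `n` draws without replacement from
#' an urn of `N` items of which `K` are marked. This is the one-sided
#' over-representation test used throughout the enrichment scans. Computed
#' exactly through the stable log-space routine underlying
#' [stats::phyper()], never by normal approximation.
#'
#' @param k observed count of the feature in the biome (successes drawn).
#' @param K total count of the feature over all biomes (marked items).
#' @param n total count of the biome over all features (draw size).
#' @param N grand total over all features and biomes (urn size).
#' @return probability in `[0, 1]`. Vectorized over its arguments.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  args <- list(k = k, K = K, n = n, N = N)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      stop("`", nm, "` must be a non-negative integer")
    }
  }
  len <- max(lengths(args))
  k <- rep_len(k, len); K <- rep_len(K, len)
  n <- rep_len(n, len); N <- rep_len(N, len)
  if (any(N < 1)) stop("`N` must be >= 1")
  if (any(K > N)) stop("`K` exceeds N")
  if (any(n > N)) stop("`n` exceeds N")
  if (any(k > pmin(K, n))) stop("`k` exceeds min(K, n)")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Scan every feature against every biome for enrichment
#'
#' One one-sided hypergeometric test per (feature, biome) cell of a
#' [biome_counts()] urn: `k` = feature count in the biome, `K` = feature
#' total, `n` = biome total, `N` = grand total. A feature is called enriched
#' in a biome when `p < alpha` (strict). Features with zero counts everywhere
#' are retained with `p = 1` and `skipped = TRUE`.
#'
#' @param counts a [biome_counts()] object.
#' @param alpha significance threshold for the enriched call (default 0.01).
#' @return data.frame of class `enrichment_result`, ordered feature-major
#'   (feature order x biome order), with columns `feature_id`, `biome`, `k`,
#'   `K`, `n`, `N`, `p_value`, `enriched`, `fold`, `skipped`.
#' @export
scan_enrichment <- function(counts, alpha = 0.01) {
  stopifnot(inherits(counts, "biome_counts"))
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)")
  N <- counts$grand_total
  if (N == 0) stop("grand total N is 0; nothing to test")
  features <- rownames(counts$counts)
  biomes <- colnames(counts$counts)
  grid <- expand.grid(biome = biomes, feature_id = features,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("feature_id", "biome")]
  k <- as.vector(t(counts$counts))
  K <- rep(counts$totals_per_feature, each = length(biomes))
  n <- rep(counts$totals_per_biome, times = length(features))
  skipped <- K == 0
  p <- rep(1, nrow(grid))
  p[!skipped] <- hypergeom_tail(k[!skipped], K[!skipped], n[!skipped], N)
  fold <- ifelse(K == 0 | n == 0, 0, (k / n) / (K / N))
  res <- data.frame(
    feature_id = grid$feature_id, biome = grid$biome,
    k = k, K = K, n = n, N = N,
    p_value = p, enriched = p < alpha & !skipped,
    fold = fold, skipped = skipped,
    stringsAsFactors = FALSE
  )
  attr(res, "alpha") <- alpha
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment over an enrichment scan
#'
#' Adds a `q_value` column computed jointly over all (feature, biome) tests.
#' The `enriched` flag is left on the raw-p rule unless `use_q = TRUE`, in
#' which case it becomes `q < alpha`. Skipped (all-zero) features keep
#' `q = 1` and are never called.
#'
#' @param results an `enrichment_result` from [scan_enrichment()].
#' @param alpha threshold used when `use_q = TRUE`.
#' @param use_q recall the `enriched` flag from q-values.
#' @return the augmented `enrichment_result`.
#' @export
adjust_bh <- function(results, alpha = 0.01, use_q = FALSE) {
  stopifnot(inherits(results, "enrichment_result"))
  idx <- !results$skipped
  q <- rep(1, nrow(results))
  q[idx] <- stats::p.adjust(results$p_value[idx], method = "BH")
  results$q_value <- q
  if (use_q) results$enriched <- q < alpha & idx
  results
}
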