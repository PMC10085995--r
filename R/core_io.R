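#' Construct an abundance table
#'
#' An `abundance_table` holds a feature x sample matrix of either relative
#' abundance proportions (`stage = "proportion"`) or prepared integer counts
#' (`stage = "count"`), together with per-sample metadata (biome label and
#' total read depth).
#'
#' @param values numeric matrix, features in rows, samples in columns. Row
#'   names are feature ids, column names sample ids.
#' @param meta data.frame with columns `sample_id`, `biome`, `read_depth`,
#'   one row per column of `values`, matched by `sample_id`.
#' @param kind feature kind: `"go_term"`, `"species"` or `"domain"`.
#' @param stage `"proportion"` or `"count"`; if `NULL`, inferred: any
#'   non-integer entry means proportions.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, meta, kind = c("go_term", "species", "domain"),
                            stage = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative value at feature '%s', sample '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  }
  meta <- validate_sample_meta(meta)
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing) > 0) {
    stop("no metadata for sample(s): ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (is.null(stage)) {
    stage <- if (any(values != floor(values))) "proportion" else "count"
  }
  stage <- match.arg(stage, c("proportion", "count"))
  if (stage == "proportion") {
    sums <- colSums(values)
    bad <- which(sums > 1 + 1e-6)
    if (length(bad) > 0) {
      stop(sprintf("proportions in sample '%s' sum to %.8f (> 1)",
                   colnames(values)[bad[1]], sums[bad[1]]))
    }
  } else if (any(values != floor(values))) {
    stop("stage = 'count' but matrix has non-integer entries")
  }
  structure(
    list(values = values, meta = meta, kind = kind, stage = stage),
    class = "abundance_table"
  )
}

validate_sample_meta <- function(meta) {
  need <- c("sample_id", "biome", "read_depth")
  if (!is.data.frame(meta) || !all(need %in% names(meta))) {
    stop("metadata must be a data.frame with columns sample_id, biome, read_depth")
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$biome <- as.character(meta$biome)
  meta$read_depth <- as.numeric(meta$read_depth)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  if (any(is.na(meta$read_depth)) || any(meta$read_depth < 0) ||
      any(meta$read_depth != floor(meta$read_depth))) {
    stop("read_depth must be a non-negative integer for every sample")
  }
  meta[, need]
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d %s features x %d samples (stage = %s)\n",
              nrow(x$values), x$kind, ncol(x$values), x$stage))
  cat("biomes:", paste(sort(unique(x$meta$biome)), collapse = ", "), "\n")
  invisible(x)
}

read_tsv_plain <- function(path) {
  # Dialect: tab-separated, UTF-8, '#' comment lines ignored, no quoting.
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read a feature x sample abundance TSV with its sample metadata
#'
#' The abundance file has a header row of sample ids and feature ids in the
#' first column. The metadata file has columns `sample_id`, `biome`,
#' `read_depth`. Stage is inferred: any non-integer value means the table
#' holds relative-abundance proportions.
#'
#' @param path path to the abundance TSV.
#' @param kind feature kind (see [abundance_table()]).
#' @param meta_path path to the sample metadata TSV.
#' @return an `abundance_table`.
#' @export
read_abundance_table <- function(path, kind = c("go_term", "species", "domain"),
                                 meta_path) {
  kind <- match.arg(kind)
  df <- read_tsv_plain(path)
  if (ncol(df) < 2) stop("abundance table needs a feature column and >= 1 sample")
  features <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric abundance values in ", path)
  rownames(mat) <- features
  meta <- read_tsv_plain(meta_path)
  abundance_table(mat, meta, kind = kind)
}

#' Read a gene annotation map
#'
#' A gene map links genes to ontology terms and to the host species carrying
#' them, as `(gene_id, term_id, species_id)` records.
#'
#' @param path TSV with columns `gene_id`, `term_id`, `species_id`.
#' @param graph optional [ontology_graph()]; when supplied, every `term_id`
#'   must exist in it.
#' @return data.frame of class `gene_annotation_map`.
#' @export
read_gene_map <- function(path, graph = NULL) {
  df <- read_tsv_plain(path)
  gene_annotation_map(df, graph = graph)
}

#' @rdname read_gene_map
#' @param records data.frame with columns `gene_id`, `term_id`, `species_id`.
#' @export
gene_annotation_map <- function(records, graph = NULL) {
  need <- c("gene_id", "term_id", "species_id")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("gene map must have columns gene_id, term_id, species_id")
  }
  records <- records[, need]
  for (cn in need) records[[cn]] <- as.character(records[[cn]])
  if (anyDuplicated(records)) {
    stop("duplicate (gene_id, term_id, species_id) records in gene map")
  }
  if (!is.null(graph)) {
    unknown <- setdiff(unique(records$term_id), graph$terms$id)
    if (length(unknown) > 0) {
      stop("gene map references term(s) absent from ontology: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  rownames(records) <- NULL
  class(records) <- c("gene_annotation_map", "data.frame")
  records
}

#' Convert per-sample proportions to integer counts
#'
#' Each cell becomes `round(proportion * read_depth)` using
#' round-half-away-from-zero, so prepared counts are reproducible across
#' platforms. Tables already at `stage = "count"` pass through unchanged.
#'
#' @param table an `abundance_table` at stage `"proportion"`.
#' @return the table at stage `"count"`.
#' @export
prepare_counts <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$stage == "count") return(table)
  depth <- table$meta$read_depth
  if (any(depth <= 0)) {
    stop("read_depth is 0 for sample(s): ",
         paste(table$meta$sample_id[depth <= 0], collapse = ", "))
  }
  counts <- round_half_away(sweep(table$values, 2, depth, `*`))
  abundance_table(counts, table$meta, kind = table$kind, stage = "count")
}

#' Aggregate prepared counts into per-biome totals
#'
#' Sums counts over all samples of each biome, producing the urn quantities
#' for the hypergeometric scans: per-cell counts `k`, per-feature totals `K`,
#' per-biome totals `n` and the grand total `N`.
#'
#' @param table an `abundance_table` at stage `"count"`.
#' @return an object of class `biome_counts`.
#' @export
aggregate_by_biome <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$stage != "count") {
    stop("table is at stage 'proportion'; run prepare_counts() first")
  }
  biomes <- unique(table$meta$biome)
  if (length(biomes) < 1) stop("no biome labels present")
  counts <- sapply(biomes, function(b) {
    rowSums(table$values[, table$meta$biome == b, drop = FALSE])
  })
  counts <- matrix(counts, nrow = nrow(table$values),
                   dimnames = list(rownames(table$values), biomes))
  biome_counts(counts)
}

#' Construct a biome-count urn
#'
#' @param counts integer matrix, features x biomes.
#' @return object of class `biome_counts` with components `counts`,
#'   `totals_per_biome` (n), `totals_per_feature` (K) and `grand_total` (N).
#' @export
biome_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) stop("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have feature row names and biome column names")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("biome counts must be non-negative integers")
  }
  structure(
    list(
      counts = counts,
      totals_per_biome = colSums(counts),
      totals_per_feature = rowSums(counts),
      grand_total = sum(counts)
    ),
    class = "biome_counts"
  )
}

#' Write an abundance table, sample metadata or gene map as TSV
#'
#' Inverses of [read_abundance_table()] and [read_gene_map()] in the
#' package's TSV dialect (tab-separated, UTF-8, no quoting).
#'
#' @param table an `abundance_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(feature_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_abundance_table
#' @param meta a sample-metadata data.frame (`sample_id`, `biome`,
#'   `read_depth`).
#' @export
write_sample_meta <- function(meta, path) {
  meta <- validate_sample_meta(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_abundance_table
#' @param gene_map a [gene_annotation_map()].
#' @export
write_gene_map <- function(gene_map, path) {
  stopifnot(inherits(gene_map, "gene_annotation_map"))
  utils::write.table(as.data.frame(gene_map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.biome_counts <- function(x, ...) {
  cat(sprintf("biome_counts: %d features x %d biomes, N = %s\n",
              nrow(x$counts), ncol(x$counts),
              format(x$grand_total, big.mark = ",")))
  invisible(x)
}
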