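#' Bundled reference tables
#'
#' Small plain-text tables shipped with the package: per-biome metagenome
#' homolog counts for unsolved Pfam families (with their reference-database
#' counts), used by the homolog-supplementation example, and the
#' per-namespace counts of GO annotations retrieved from the four-biome
#' metagenome cohort.
#'
#' @param which `"pfam_homologs"` or `"go_namespaces"`.
#' @return a data.frame.
#' @export
#' @examples
#' h <- bundled_table("pfam_homologs")
#' counts <- unlist(h[h$family == "PF12597", c("Soil", "Freshwater", "Gut", "Engineered")])
#' select_supplement_biome(counts, h$reference_count[h$family == "PF12597"])
bundled_table <- function(which = c("pfam_homologs", "go_namespaces")) {
  which <- match.arg(which)
  fname <- switch(which,
    pfam_homologs = "pfam_homolog_counts.tsv",
    go_namespaces = "go_namespace_counts.tsv"
  )
  path <- system.file("extdata", fname, package = "enrichsphere", mustWork = TRUE)
  read_tsv_plain(path)
}
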