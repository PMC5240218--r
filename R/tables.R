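#' Published Pseudoalteromonas summary tables
#'
#' Accessors for the three small published summary tables bundled with the
#' package as plain TSV: per-genome assembly statistics for the 38
#' Pseudoalteromonas strains (assembly size, ORF count, GC content,
#' pigmentation), per-strain mobile-genetic-element gene counts from the
#' ACLAME-based mobilome screen (plasmid/virus/prophage and their total),
#' and the published core/accessory/unique partition counts for the genus,
#' the pigmented group and the P. haloplanktis group. These are printed
#' inputs, not results computed by this package; they feed
#' [dataset_summary()], [percent_of_total()] and worked examples.
#'
#' @return A `data.frame`.
#' @name pseudoalteromonas_tables
NULL

#' @rdname pseudoalteromonas_tables
#' @export
pseudoalteromonas_genome_stats <- function() {
  read_tsv_hash(system.file("extdata", "pseudoalteromonas_genome_stats.tsv",
                            package = "pangevo", mustWork = TRUE))
}

#' @rdname pseudoalteromonas_tables
#' @export
pseudoalteromonas_mge_counts <- function() {
  read_tsv_hash(system.file("extdata", "pseudoalteromonas_mge_counts.tsv",
                            package = "pangevo", mustWork = TRUE))
}

#' @rdname pseudoalteromonas_tables
#' @export
pseudoalteromonas_partition_counts <- function() {
  read_tsv_hash(system.file("extdata", "pseudoalteromonas_partition_counts.tsv",
                            package = "pangevo", mustWork = TRUE))
}
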