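#' Bidirectional best hit (BBH) gene pairs
#'
#' From a table of cross-genome similarity hits, keeps the unordered gene
#' pairs that are reciprocal best hits: `b` is `a`'s best hit among all hits
#' into `b`'s genome and `a` is `b`'s best hit among all hits into `a`'s
#' genome. "Best" means lowest e-value, ties broken by highest bit score,
#' then by lexicographically smallest subject gene id, so the result is
#' deterministic.
#'
#' @param hits Similarity-hit data.frame as produced by
#'   [all_vs_all_similarity()] or [read_blast_tab()].
#' @return Data.frame of unordered pairs with columns `genome_a`, `gene_a`,
#'   `genome_b`, `gene_b`, sorted canonically.
#' @export
bbh_pairs <- function(hits) {
  need <- c("query_genome", "query_gene", "subject_genome", "subject_gene",
            "score", "evalue")
  stopifnot(all(need %in% names(hits)))
  if (nrow(hits) == 0) {
    return(data.frame(genome_a = character(0), gene_a = character(0),
                      genome_b = character(0), gene_b = character(0)))
  }
  hits <- hits[hits$query_genome != hits$subject_genome, , drop = FALSE]
  ord <- order(hits$query_genome, hits$query_gene, hits$subject_genome,
               hits$evalue, -hits$score, hits$subject_gene)
  h <- hits[ord, , drop = FALSE]
  key <- paste(h$query_genome, h$query_gene, h$subject_genome, sep = "\r")
  best <- h[!duplicated(key), , drop = FALSE]
  fwd <- paste(best$query_genome, best$query_gene,
               best$subject_genome, best$subject_gene, sep = "\r")
  rev_ <- paste(best$subject_genome, best$subject_gene,
                best$query_genome, best$query_gene, sep = "\r")
  reciprocal <- best[fwd %in% rev_, , drop = FALSE]
  a_first <- paste(reciprocal$query_genome, reciprocal$query_gene) <
    paste(reciprocal$subject_genome, reciprocal$subject_gene)
  out <- data.frame(
    genome_a = ifelse(a_first, reciprocal$query_genome, reciprocal$subject_genome),
    gene_a = ifelse(a_first, reciprocal$query_gene, reciprocal$subject_gene),
    genome_b = ifelse(a_first, reciprocal$subject_genome, reciprocal$query_genome),
    gene_b = ifelse(a_first, reciprocal$subject_gene, reciprocal$query_gene),
    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$genome_a, out$gene_a, out$genome_b, out$gene_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build gene families from BBH pairs
#'
#' Families are the connected components of the BBH graph over all genes of
#' all genomes; genes with no BBH edge become singleton families. Family ids
#' are canonical: components are ordered by their sorted member lists, so
#' permuting the genome input order changes no membership and no id.
#'
#' @param genomes Named list of `AAStringSet` per genome (only gene
#'   inventories are used).
#' @param bbh BBH pair data.frame from [bbh_pairs()].
#' @return List with `families` (data.frame `family_id`, `genome_id`,
#'   `gene_id`) and `matrix` (binary family x genome presence matrix).
#' @export
build_families <- function(genomes, bbh) {
  stopifnot(is.list(genomes), !is.null(names(genomes)))
  inventory <- do.call(rbind, lapply(sort(names(genomes)), function(g) {
    data.frame(genome_id = g, gene_id = names(genomes[[g]]),
               stringsAsFactors = FALSE)
  }))
  vertex <- paste(inventory$genome_id, inventory$gene_id, sep = "\r")
  if (anyDuplicated(vertex)) stop("duplicate gene id within a genome")
  if (nrow(bbh) > 0) {
    ea <- paste(bbh$genome_a, bbh$gene_a, sep = "\r")
    eb <- paste(bbh$genome_b, bbh$gene_b, sep = "\r")
    missing <- setdiff(unique(c(ea, eb)), vertex)
    if (length(missing)) {
      stop("BBH pairs reference gene(s) absent from the genomes: ",
           paste(gsub("\r", "|", utils::head(missing, 5)), collapse = ", "))
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = ea, to = eb, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = vertex, stringsAsFactors = FALSE))
  } else {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(vertex), name = vertex)
  }
  comp <- igraph::components(g)$membership
  comp <- comp[vertex]  # align to inventory order
  # canonical ids: order components by their lexicographically smallest member
  first_member <- tapply(vertex, comp, min)
  rank <- match(comp, names(first_member)[order(first_member)])
  ids <- sprintf("F%05d", rank)
  families <- data.frame(family_id = ids,
                         genome_id = inventory$genome_id,
                         gene_id = inventory$gene_id,
                         stringsAsFactors = FALSE)
  families <- families[order(families$family_id, families$genome_id,
                             families$gene_id), , drop = FALSE]
  rownames(families) <- NULL
  list(families = families,
       matrix = family_matrix(families, names(genomes)))
}

#' Gene-family presence/absence matrix
#'
#' @param families Membership data.frame (`family_id`, `genome_id`,
#'   `gene_id`).
#' @param genome_ids Genome ids defining the column set and order; defaults
#'   to the genomes present in `families`.
#' @return Binary integer matrix, families as rows, genomes as columns;
#'   `1` iff the family has at least one member gene in the genome.
#' @export
family_matrix <- function(families, genome_ids = sort(unique(families$genome_id))) {
  fams <- sort(unique(families$family_id))
  m <- matrix(0L, nrow = length(fams), ncol = length(genome_ids),
              dimnames = list(fams, genome_ids))
  idx <- cbind(match(families$family_id, fams),
               match(families$genome_id, genome_ids))
  if (anyNA(idx[, 2])) stop("family membership references unknown genome id")
  m[idx] <- 1L
  m
}

#' Cluster genomes into gene families end to end
#'
#' Convenience wrapper: all-vs-all similarity (or supplied precomputed
#' hits, which take precedence), BBH pairs, then connected-component
#' families.
#'
#' @param genomes Named list of `AAStringSet` per genome.
#' @param hits Optional precomputed similarity-hit data.frame.
#' @return As [build_families()].
#' @export
cluster_genomes <- function(genomes, hits = NULL) {
  if (is.null(hits)) hits <- all_vs_all_similarity(genomes)
  build_families(genomes, bbh_pairs(hits))
}
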