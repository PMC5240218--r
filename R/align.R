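# Local-alignment similarity backend.
#
# Smith-Waterman over BLOSUM62 with affine gaps (open 11, extend 1) via
# Biostrings::pairwiseAlignment, scored into bits and an e-value with fixed
# Karlin-Altschul constants (the standard gapped BLOSUM62 pair
# lambda = 0.267, K = 0.041). Percent similarity counts aligned positions
# with a positive substitution score; identity counts exact matches; both
# are taken over the alignment length including gap columns. Coverage is
# always computed on the query.

ka_lambda <- 0.267
ka_K <- 0.041

.align_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.align_cache$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_cache$mat <- get("BLOSUM62", envir = e)
  }
  .align_cache$mat
}

bits_from_raw <- function(s) (ka_lambda * s - log(ka_K)) / log(2)

# Align one query against a set of subjects; returns a data.frame of
# per-subject alignment statistics (no thresholding beyond evalue_max).
# Statistics come from the C-level PairwiseAlignments accessors: alignment
# length (nchar), identities (nmatch), positive-scoring substitutions
# (mismatchTable against BLOSUM62) and the aligned spans on each original
# sequence (residues consumed between alignment start and end).
align_one_vs_set <- function(query, subjects, evalue_max = 10) {
  mat <- blosum62()
  aln <- Biostrings::pairwiseAlignment(subjects, query, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 11, gapExtension = 1)
  raw <- Biostrings::score(aln)
  bits <- bits_from_raw(raw)
  qlen <- Biostrings::nchar(query)
  slen <- Biostrings::width(subjects)
  evalue <- as.numeric(qlen) * as.numeric(slen) * 2^(-bits)
  keep <- which(evalue <= evalue_max & raw > 0)
  if (length(keep) == 0) {
    return(data.frame(subject = character(0), score = numeric(0),
                      evalue = numeric(0), query_coverage = numeric(0),
                      subject_coverage = numeric(0), similarity = numeric(0),
                      identity = numeric(0)))
  }
  lens <- Biostrings::nchar(aln)                       # alignment length
  ident <- Biostrings::nmatch(aln)
  mt <- Biostrings::mismatchTable(aln)
  pos_mis <- integer(length(aln))
  if (nrow(mt) > 0) {
    ok <- mat[cbind(as.character(mt$PatternSubstring),
                    as.character(mt$SubjectSubstring))] > 0
    tab <- table(factor(mt$PatternId[ok], levels = seq_along(aln)))
    pos_mis <- as.integer(tab)
  }
  q_span <- Biostrings::end(Biostrings::subject(aln)) -
    Biostrings::start(Biostrings::subject(aln)) + 1L
  s_span <- Biostrings::end(Biostrings::pattern(aln)) -
    Biostrings::start(Biostrings::pattern(aln)) + 1L
  data.frame(subject = names(subjects)[keep],
             score = bits[keep],
             evalue = evalue[keep],
             query_coverage = 100 * q_span[keep] / qlen,
             subject_coverage = 100 * s_span[keep] / slen[keep],
             similarity = 100 * (ident + pos_mis)[keep] / lens[keep],
             identity = 100 * ident[keep] / lens[keep],
             stringsAsFactors = FALSE)
}

validate_protein_set <- function(x, genome_id) {
  chars <- unique(strsplit(paste(as.character(x), collapse = ""), "")[[1]])
  bad <- setdiff(chars, c(strsplit("ACDEFGHIKLMNPQRSTVWYBZX*", "")[[1]]))
  if (length(bad)) {
    stop("non-amino-acid characters ", paste(bad, collapse = ""),
         " in genome ", genome_id, call. = FALSE)
  }
  invisible(TRUE)
}

#' All-vs-all protein similarity hits between genomes
#'
#' Computes local-alignment hits for every cross-genome gene pair using the
#' built-in Smith-Waterman backend (BLOSUM62, affine gaps 11/1, fixed
#' Karlin-Altschul e-value). Self-genome comparisons are excluded. Each
#' alignment is computed once per unordered genome pair and reported in both
#' directions, with coverage recomputed on each direction's query.
#'
#' @param genomes Named list of `AAStringSet`, one per genome (a
#'   `genome_set`); names are genome ids and sequence names are gene ids.
#' @param evalue_max Hit-significance cutoff: report hits with e-value at
#'   or below this. The default (1e-5) is the conventional cutoff for
#'   best-hit orthology, where insignificant hits between genes whose true
#'   orthologs are missing from the partner genome would otherwise create
#'   spurious reciprocal-best pairs.
#' @return A data.frame of similarity hits with columns `query_genome`,
#'   `query_gene`, `subject_genome`, `subject_gene`, `score` (bits),
#'   `evalue`, `query_coverage`, `similarity`, `identity` (percent).
#' @export
all_vs_all_similarity <- function(genomes, evalue_max = 1e-5) {
  stopifnot(is.list(genomes), !is.null(names(genomes)), length(genomes) >= 2)
  empty <- vapply(genomes, length, 0L) == 0
  if (any(empty)) {
    warning("skipping empty genome(s): ",
            paste(names(genomes)[empty], collapse = ", "))
    genomes <- genomes[!empty]
  }
  stopifnot(length(genomes) >= 2)
  for (g in names(genomes)) validate_protein_set(genomes[[g]], g)
  ids <- names(genomes)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      ga <- ids[i]; gb <- ids[j]
      for (qi in seq_along(genomes[[ga]])) {
        q <- genomes[[ga]][[qi]]
        qname <- names(genomes[[ga]])[qi]
        h <- align_one_vs_set(q, genomes[[gb]], evalue_max)
        if (nrow(h) == 0) next
        fwd <- data.frame(query_genome = ga, query_gene = qname,
                          subject_genome = gb, subject_gene = h$subject,
                          score = h$score, evalue = h$evalue,
                          query_coverage = h$query_coverage,
                          similarity = h$similarity, identity = h$identity,
                          stringsAsFactors = FALSE)
        rev_ <- data.frame(query_genome = gb, query_gene = h$subject,
                           subject_genome = ga, subject_gene = qname,
                           score = h$score, evalue = h$evalue,
                           query_coverage = h$subject_coverage,
                           similarity = h$similarity, identity = h$identity,
                           stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- fwd
        out[[length(out) + 1L]] <- rev_
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(query_genome = character(0), query_gene = character(0),
                      subject_genome = character(0), subject_gene = character(0),
                      score = numeric(0), evalue = numeric(0),
                      query_coverage = numeric(0), similarity = numeric(0),
                      identity = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Similarity of a gene set against a labeled reference set
#'
#' Same backend as [all_vs_all_similarity()], but each gene of each genome
#' is aligned against one reference protein set (used by the annotation
#' screens).
#'
#' @param genomes Named list of `AAStringSet` per genome.
#' @param reference `AAStringSet` of reference proteins.
#' @param evalue_max Reporting cutoff.
#' @return Hit data.frame with columns `genome`, `gene`, `ref_id`, `score`,
#'   `evalue`, `coverage` (query coverage), `similarity`, `identity`.
#' @export
reference_similarity <- function(genomes, reference, evalue_max = 10) {
  stopifnot(length(reference) > 0)
  out <- list()
  for (g in names(genomes)) {
    for (qi in seq_along(genomes[[g]])) {
      h <- align_one_vs_set(genomes[[g]][[qi]], reference, evalue_max)
      if (nrow(h) == 0) next
      out[[length(out) + 1L]] <-
        data.frame(genome = g, gene = names(genomes[[g]])[qi],
                   ref_id = h$subject, score = h$score, evalue = h$evalue,
                   coverage = h$query_coverage, similarity = h$similarity,
                   identity = h$identity, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(genome = character(0), gene = character(0),
                      ref_id = character(0), score = numeric(0),
                      evalue = numeric(0), coverage = numeric(0),
                      similarity = numeric(0), identity = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read precomputed BLAST tabular hits
#'
#' Ingests 12-column BLAST tabular output (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`), optionally
#' with a 13th column giving percent similarity (positives). The tabular
#' dialect has no similarity column, so when it is absent identity is used
#' as similarity and a warning is issued. Query coverage is computed as
#' `(qend - qstart + 1) / query length`; query lengths are taken from the
#' supplied genomes.
#'
#' @param path BLAST tabular file.
#' @param genomes Named list of `AAStringSet` per genome, used to resolve
#'   which genome each gene belongs to and the query lengths.
#' @return A similarity-hit data.frame in the [all_vs_all_similarity()]
#'   layout.
#' @export
read_blast_tab <- function(path, genomes) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (!ncol(raw) %in% c(12L, 13L)) {
    stop("expected 12- or 13-column BLAST tabular input, got ", ncol(raw))
  }
  gene2genome <- unlist(lapply(names(genomes), function(g) {
    stats::setNames(rep(g, length(genomes[[g]])), names(genomes[[g]]))
  }))
  glen <- unlist(lapply(names(genomes), function(g) {
    stats::setNames(Biostrings::width(genomes[[g]]), names(genomes[[g]]))
  }))
  unknown <- setdiff(unique(c(raw[[1]], raw[[2]])), names(gene2genome))
  if (length(unknown)) {
    stop("hit table references unknown gene(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  sim <- if (ncol(raw) == 13L) raw[[13]] else {
    warning("no similarity column in BLAST tabular input; using identity")
    raw[[3]]
  }
  data.frame(query_genome = unname(gene2genome[raw[[1]]]),
             query_gene = raw[[1]],
             subject_genome = unname(gene2genome[raw[[2]]]),
             subject_gene = raw[[2]],
             score = raw[[12]], evalue = raw[[11]],
             query_coverage = 100 * (raw[[8]] - raw[[7]] + 1) /
               unname(glen[raw[[1]]]),
             similarity = sim, identity = raw[[3]],
             stringsAsFactors = FALSE)
}
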