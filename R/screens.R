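#' Configuration of a first-best-hit annotation screen
#'
#' Threshold presets for the FBH screens. The generic triple (mobilome,
#' resistance, transport) requires e-value strictly below `1e-20`, query
#' coverage strictly above 30% and similarity strictly above 60%. The
#' cold-adaptation-protein preset tightens the e-value to `1e-30` and
#' applies no coverage or similarity floor. Presets are configuration
#' entries, not code paths; every field can be overridden.
#'
#' @param preset One of `"mobilome"`, `"bacmet"`, `"tcdb"`, `"cap"`,
#'   `"custom"`.
#' @param evalue_max Accept hits with `evalue < evalue_max` (strict).
#' @param coverage_min Accept hits with `coverage > coverage_min` (strict).
#' @param similarity_min Accept hits with `similarity > similarity_min`
#'   (strict).
#' @param categories Declared category label set; `NULL` for free-form.
#'   The mobilome preset declares `plasmid`, `virus`, `prophage`.
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(preset = c("mobilome", "bacmet", "tcdb", "cap",
                                     "custom"),
                          evalue_max = NULL, coverage_min = NULL,
                          similarity_min = NULL, categories = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    cap = list(evalue_max = 1e-30, coverage_min = -Inf,
               similarity_min = -Inf, categories = NULL),
    mobilome = list(evalue_max = 1e-20, coverage_min = 30,
                    similarity_min = 60,
                    categories = c("plasmid", "virus", "prophage")),
    list(evalue_max = 1e-20, coverage_min = 30, similarity_min = 60,
         categories = NULL))
  cfg <- list(preset = preset,
              evalue_max = evalue_max %||% defaults$evalue_max,
              coverage_min = coverage_min %||% defaults$coverage_min,
              similarity_min = similarity_min %||% defaults$similarity_min,
              categories = categories %||% defaults$categories)
  stopifnot(is.finite(cfg$evalue_max))
  structure(cfg, class = "screen_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign genes to reference categories by first best hit
#'
#' Ranks each gene's reference hits (lowest e-value, then highest score,
#' then lexicographically smallest reference id) and assigns the gene to
#' its top hit's category if and only if that hit passes every threshold
#' strictly (`evalue < evalue_max`, `coverage > coverage_min`,
#' `similarity > similarity_min`). A gene gets at most one category, from
#' its first best hit, even when later hits belong to other categories.
#'
#' @param hits Hit data.frame from [reference_similarity()] (columns
#'   `genome`, `gene`, `ref_id`, `score`, `evalue`, `coverage`,
#'   `similarity`).
#' @param category_map Data.frame `ref_id`, `category`.
#' @param config A [screen_config()].
#' @return Data.frame with one row per gene with at least one hit:
#'   `genome`, `gene`, `ref_id`, `category`, `evalue`, `coverage`,
#'   `similarity`, `pass`.
#' @export
fbh_assign <- function(hits, category_map, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"),
            all(c("ref_id", "category") %in% names(category_map)))
  if (!is.null(config$categories)) {
    bad <- setdiff(unique(category_map$category), config$categories)
    if (length(bad)) {
      stop("categories outside the declared label set: ",
           paste(bad, collapse = ", "))
    }
  }
  if (nrow(hits) == 0) {
    return(data.frame(genome = character(0), gene = character(0),
                      ref_id = character(0), category = character(0),
                      evalue = numeric(0), coverage = numeric(0),
                      similarity = numeric(0), pass = logical(0)))
  }
  ord <- order(hits$genome, hits$gene, hits$evalue, -hits$score, hits$ref_id)
  h <- hits[ord, , drop = FALSE]
  top <- h[!duplicated(paste(h$genome, h$gene, sep = "\r")), , drop = FALSE]
  cat_of <- stats::setNames(category_map$category, category_map$ref_id)
  top$category <- unname(cat_of[top$ref_id])
  top$pass <- top$evalue < config$evalue_max &
    top$coverage > config$coverage_min &
    top$similarity > config$similarity_min &
    !is.na(top$category)
  top$category[!top$pass] <- NA_character_
  rownames(top) <- NULL
  top[, c("genome", "gene", "ref_id", "category", "evalue", "coverage",
          "similarity", "pass")]
}

#' Run a first-best-hit screen against a labeled reference set
#'
#' Aligns every gene of every genome against the reference proteins with
#' the built-in backend, then applies [fbh_assign()]. Per-genome counts per
#' category (and their total) are tabulated in the shape of a per-strain
#' mobilome table.
#'
#' @param genomes Named list of `AAStringSet` per genome.
#' @param reference `AAStringSet` of reference proteins.
#' @param category_map Data.frame `ref_id`, `category`.
#' @param config A [screen_config()].
#' @return Object of class `screen_result`: list with `assignments` (from
#'   [fbh_assign()]), `counts` (data.frame genome x category counts with a
#'   `total` column) and `config`.
#' @export
fbh_screen <- function(genomes, reference, category_map,
                       config = screen_config()) {
  stopifnot(length(reference) > 0)
  hits <- reference_similarity(genomes, reference,
                               evalue_max = max(config$evalue_max, 1e-3))
  assignments <- fbh_assign(hits, category_map, config)
  categories <- config$categories %||% sort(unique(category_map$category))
  counts <- screen_counts(assignments, names(genomes), categories)
  structure(list(assignments = assignments, counts = counts,
                 config = config),
            class = "screen_result")
}

#' Per-genome category counts of screen assignments
#'
#' @param assignments [fbh_assign()] output.
#' @param genome_ids All genome ids (genomes without assigned genes get
#'   zero rows).
#' @param categories Category columns to tabulate.
#' @return Data.frame `genome`, one column per category, `total`.
#' @export
screen_counts <- function(assignments, genome_ids, categories) {
  passed <- assignments[assignments$pass, , drop = FALSE]
  tab <- table(factor(passed$genome, levels = genome_ids),
               factor(passed$category, levels = categories))
  out <- data.frame(genome = genome_ids, as.data.frame.matrix(tab),
                    row.names = NULL, check.names = FALSE)
  out$total <- rowSums(out[, categories, drop = FALSE])
  out
}

#' Partition the panmobilome
#'
#' Families with at least one member gene assigned to a mobile-element
#' category form the panmobilome; they are partitioned into core, accessory
#' and unique mobilome with the same presence rule as the pangenome
#' partition, over all genomes of the matrix.
#'
#' @param families Membership data.frame (`family_id`, `genome_id`,
#'   `gene_id`).
#' @param matrix Binary family x genome presence matrix.
#' @param screen A `screen_result` computed on the same genomes.
#' @return A [pangenome_partition()] restricted to mobile families, with an
#'   extra `n_mge_families` field.
#' @export
panmobilome <- function(families, matrix, screen) {
  stopifnot(inherits(screen, "screen_result"))
  genomes_screen <- unique(screen$assignments$genome)
  if (length(setdiff(genomes_screen, colnames(matrix)))) {
    stop("screen genomes are not a subset of the matrix genomes")
  }
  passed <- screen$assignments[screen$assignments$pass, , drop = FALSE]
  key_gene <- paste(families$genome_id, families$gene_id, sep = "\r")
  key_hit <- paste(passed$genome, passed$gene, sep = "\r")
  mge_families <- sort(unique(families$family_id[key_gene %in% key_hit]))
  sub <- matrix[rownames(matrix) %in% mge_families, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("no families carry a passing mobile-element assignment")
  }
  part <- pangenome_partition(sub)
  part$n_mge_families <- length(mge_families)
  part
}

#' Hierarchical clustering of a binary presence/absence matrix
#'
#' Agglomerative clustering of strains over binary feature profiles,
#' Jaccard distance and average linkage by default (both configurable).
#' Ties are resolved by input row order, so the dendrogram is
#' deterministic. A constant matrix has all-zero distances; a star
#' dendrogram is returned with a warning.
#'
#' @param matrix Binary strain x feature matrix (strains as rows).
#' @param linkage `hclust` agglomeration method.
#' @param distance `"jaccard"` (via the binary distance) or any
#'   [stats::dist()] method.
#' @return List of class `presence_dendrogram`: `phylo` (an `ape::phylo`
#'   with merge heights as branch lengths), `hclust` (or `NULL` for the
#'   degenerate star), `distance`, `linkage`.
#' @export
presence_cluster <- function(matrix, linkage = "average",
                             distance = "jaccard") {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2,
            all(matrix %in% c(0, 1)))
  method <- if (distance == "jaccard") "binary" else distance
  d <- stats::dist(matrix, method = method)
  d[is.na(d)] <- 0  # binary distance of two all-zero rows
  if (all(d == 0)) {
    warning("all pairwise distances are zero; returning a star dendrogram")
    star <- ape::read.tree(
      text = paste0("(", paste(rownames(matrix), collapse = ","), ");"))
    star$edge.length <- rep(0, nrow(star$edge))
    return(structure(list(phylo = star, hclust = NULL, distance = distance,
                          linkage = linkage),
                     class = "presence_dendrogram"))
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(phylo = ape::as.phylo(hc), hclust = hc,
                 distance = distance, linkage = linkage),
            class = "presence_dendrogram")
}

# non-trivial bipartitions of a tree as canonical strings
bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  labels <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    if (length(side) < 2 || length(side) > n_tip - 2) next
    if (labels[1] %in% side) side <- setdiff(labels, side)
    out <- c(out, paste(side, collapse = "\r"))
  }
  unique(out)
}

#' Shared bipartitions between two trees
#'
#' Robinson-Foulds-style comparison: counts the non-trivial bipartitions
#' (internal edges splitting off 2 to n-2 leaves) shared between two trees
#' on the same leaf set. Quantifies how closely e.g. a presence/absence
#' dendrogram follows a phylogeny.
#'
#' @param a,b Trees (`phylo` or `presence_dendrogram`).
#' @return List with `shared`, `total_a`, `total_b`.
#' @export
compare_topologies <- function(a, b) {
  if (inherits(a, "presence_dendrogram")) a <- a$phylo
  if (inherits(b, "presence_dendrogram")) b <- b$phylo
  stopifnot(inherits(a, "phylo"), inherits(b, "phylo"))
  if (length(setdiff(a$tip.label, b$tip.label)) ||
      length(setdiff(b$tip.label, a$tip.label))) {
    stop("trees have different leaf sets")
  }
  ba <- bipartitions(a)
  bb <- bipartitions(b)
  list(shared = length(intersect(ba, bb)),
       total_a = length(ba), total_b = length(bb))
}
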