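#' Partition a family matrix into core, accessory and unique genomes
#'
#' Restricted to the selected genome group, a family present in every
#' genome of the group is core, a family present in exactly one genome is
#' unique, and anything in between is accessory. Families absent from all
#' group genomes are excluded. Percentages are integers, rounded half-up,
#' computed on the group's family total.
#'
#' @param matrix Binary family x genome presence matrix.
#' @param group Genome ids to partition over; defaults to all columns.
#' @return Object of class `pangenome_partition`: list with `core`,
#'   `accessory`, `unique` (family-id character vectors), `counts`,
#'   `percent` (named integer vectors), `total` and `n_genomes`.
#' @export
pangenome_partition <- function(matrix, group = colnames(matrix)) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  unknown <- setdiff(group, colnames(matrix))
  if (length(unknown)) {
    stop("unknown genome id(s): ", paste(unknown, collapse = ", "))
  }
  stopifnot(length(group) >= 2)
  sub <- matrix[, group, drop = FALSE]
  n <- rowSums(sub)
  core <- rownames(sub)[n == length(group)]
  uniq <- rownames(sub)[n == 1]
  acc <- rownames(sub)[n > 1 & n < length(group)]
  counts <- c(core = length(core), accessory = length(acc),
              unique = length(uniq))
  total <- sum(counts)
  structure(list(core = core, accessory = acc, unique = uniq,
                 counts = counts,
                 percent = if (total > 0) percent_of_total(counts, total)
                           else c(core = 0L, accessory = 0L, unique = 0L),
                 total = total, n_genomes = length(group)),
            class = "pangenome_partition")
}

#' @export
print.pangenome_partition <- function(x, ...) {
  cat(sprintf("Pangenome partition over %d genomes: %d families\n",
              x$n_genomes, x$total))
  for (k in c("core", "accessory", "unique")) {
    cat(sprintf("  %-9s %6d (%d%%)\n", k, x$counts[[k]], x$percent[[k]]))
  }
  invisible(x)
}

#' Cumulative pangenome curve along one genome ordering
#'
#' Adds genomes one by one in the given order and records, at each step,
#' the cumulative pangenome size, core size and the number of new families
#' contributed by the genome just added (Tettelin-style new-gene
#' accounting). Within one ordering the pangenome size is non-decreasing,
#' the core size non-increasing, and each step's new-gene count equals the
#' step's pangenome increment.
#'
#' @param matrix Binary family x genome presence matrix.
#' @param ordering Genome ids in the order added.
#' @return Data.frame with columns `step`, `genome`, `pangenome_size`,
#'   `core_size`, `new_genes`.
#' @export
accumulate_curve <- function(matrix, ordering) {
  stopifnot(all(ordering %in% colnames(matrix)))
  pan <- core <- new <- integer(length(ordering))
  seen <- rep(FALSE, nrow(matrix))
  incore <- rep(TRUE, nrow(matrix))
  for (i in seq_along(ordering)) {
    col <- matrix[, ordering[i]] == 1L
    new[i] <- sum(col & !seen)
    seen <- seen | col
    incore <- incore & col
    pan[i] <- sum(seen)
    core[i] <- sum(incore)
  }
  data.frame(step = seq_along(ordering), genome = ordering,
             pangenome_size = pan, core_size = core, new_genes = new,
             stringsAsFactors = FALSE)
}

#' Rarefaction of the pangenome by random genome combinations
#'
#' For every combination size `N` and replicate, samples `N` distinct
#' genomes uniformly without replacement in a random order and records the
#' pangenome size (families present in at least one sampled genome), the
#' core size (families present in all `N`), and the number of new genes
#' contributed by the last genome in the sampled order (families absent
#' from the preceding `N - 1`). The published sampling scheme draws `N`
#' from 2 upward with 10 replicates; rows for `N = 1` are also emitted
#' (flagged by the `extended` column) since they are the natural curve
#' anchor.
#'
#' @param matrix Binary family x genome presence matrix.
#' @param replicates Random combinations per `N` (default 10). When fewer
#'   distinct combinations exist (e.g. `N` equal to the genome count), the
#'   same combination necessarily recurs across replicates; a notice is
#'   emitted.
#' @param n_max Largest combination size; defaults to the genome count.
#' @param seed Integer seed making the table deterministic.
#' @return Data.frame of class `rarefaction_table` with columns `n`,
#'   `replicate`, `pangenome_size`, `core_size`, `new_genes`, `extended`.
#' @export
rarefy <- function(matrix, replicates = 10L, n_max = ncol(matrix), seed = 1L) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2, replicates >= 1)
  genomes <- colnames(matrix)
  n_max <- min(n_max, length(genomes))
  short <- vapply(seq_len(n_max), function(n) choose(length(genomes), n) < replicates,
                  logical(1))
  if (any(short)) {
    message("fewer distinct combinations than replicates for N = ",
            paste(which(short), collapse = ", "),
            "; combinations recur across replicates")
  }
  rows <- with_seed(seed, {
    out <- vector("list", n_max * replicates)
    k <- 0L
    for (n in seq_len(n_max)) {
      for (r in seq_len(replicates)) {
        sel <- sample(genomes, n)
        col_any <- rowSums(matrix[, sel, drop = FALSE]) > 0
        col_all <- rowSums(matrix[, sel, drop = FALSE]) == n
        new <- if (n == 1) sum(matrix[, sel] == 1L) else {
          prev <- rowSums(matrix[, sel[-n], drop = FALSE]) > 0
          sum(matrix[, sel[n]] == 1L & !prev)
        }
        k <- k + 1L
        out[[k]] <- data.frame(n = n, replicate = r,
                               pangenome_size = sum(col_any),
                               core_size = sum(col_all), new_genes = new)
      }
    }
    do.call(rbind, out)
  })
  rows$extended <- rows$n < 2L
  attr(rows, "seed") <- as.integer(seed)
  class(rows) <- c("rarefaction_table", "data.frame")
  rows
}

#' Functional-category distribution per pangenome section
#'
#' Assigns each family the majority functional category of its member genes
#' (ties resolve to `"unassigned"`, as do families with no annotated
#' member), then tabulates counts and integer percentages per pangenome
#' section (core/accessory/unique). Every declared category is reported,
#' zeros included.
#'
#' @param families Membership data.frame (`family_id`, `genome_id`,
#'   `gene_id`).
#' @param partition A [pangenome_partition()] of the matching matrix.
#' @param annotations Data.frame `gene_id`, `category`; genes without a row
#'   are unannotated.
#' @param categories Declared label set (default the 25 COG one-letter
#'   classes); `"unassigned"` is always appended.
#' @return Data.frame with columns `section`, `category`, `count`,
#'   `percent`.
#' @export
category_distribution <- function(families, partition, annotations,
                                  categories = cog_category_labels()) {
  stopifnot(inherits(partition, "pangenome_partition"))
  categories <- union(categories, "unassigned")
  if (!is.null(annotations) && nrow(annotations) > 0) {
    bad <- setdiff(unique(annotations$category), categories)
    if (length(bad)) {
      stop("annotation categories outside the declared label set: ",
           paste(bad, collapse = ", "))
    }
    fam_cat <- tapply(
      annotations$category[match(families$gene_id, annotations$gene_id)],
      families$family_id,
      function(v) {
        v <- v[!is.na(v)]
        if (length(v) == 0) return("unassigned")
        tab <- sort(table(v), decreasing = TRUE)
        if (length(tab) > 1 && tab[1] == tab[2]) "unassigned" else names(tab)[1]
      })
  } else {
    fam_ids <- unique(families$family_id)
    fam_cat <- stats::setNames(rep("unassigned", length(fam_ids)), fam_ids)
  }
  out <- list()
  for (section in c("core", "accessory", "unique")) {
    fams <- partition[[section]]
    cats <- fam_cat[fams]
    tab <- table(factor(cats, levels = categories))
    pct <- if (sum(tab) > 0) percent_of_total(as.numeric(tab)) else
      rep(0L, length(tab))
    out[[section]] <- data.frame(section = section,
                                 category = categories,
                                 count = as.integer(tab),
                                 percent = pct,
                                 stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summary statistics of a genome dataset table
#'
#' Arithmetic mean, minimum and maximum of assembly length, ORF count and
#' GC content over a per-genome statistics table, with means reported both
#' raw and rounded to integer (GC rounded to the nearest percent).
#'
#' @param stats Data.frame with numeric columns `length`, `orfs`, `gc` and
#'   one row per genome.
#' @return List with one element per column: `mean`, `mean_rounded`, `min`,
#'   `max`; plus `n_genomes`.
#' @export
dataset_summary <- function(stats) {
  need <- c("length", "orfs", "gc")
  stopifnot(is.data.frame(stats), nrow(stats) >= 1, all(need %in% names(stats)))
  for (col in need) {
    v <- stats[[col]]
    if (!is.numeric(v) || anyNA(suppressWarnings(as.numeric(v)))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric value in column '", col, "' at row ", bad)
    }
    stopifnot(all(v > 0))
  }
  out <- lapply(need, function(col) {
    v <- as.numeric(stats[[col]])
    list(mean = mean(v), mean_rounded = round_half_up(mean(v)),
         min = min(v), max = max(v))
  })
  names(out) <- need
  out$n_genomes <- nrow(stats)
  out
}
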