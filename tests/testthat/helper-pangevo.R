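# Shared fixtures and independent oracles.

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# genome_set from a named list of named character vectors
make_genomes <- function(x) {
  out <- lapply(x, function(v) {
    ss <- Biostrings::AAStringSet(unname(v))
    names(ss) <- names(v)
    ss
  })
  structure(out, class = "genome_set")
}

# true-family labels and clustering labels aligned over all genes of a
# simulated genome set (gene ids encode "<genome>_<family>")
clustering_vs_truth <- function(genomes, clustering) {
  key <- unlist(lapply(names(genomes), function(g) {
    paste(g, names(genomes[[g]]), sep = "\r")
  }))
  truth <- unlist(lapply(names(genomes), function(g) {
    sub(paste0("^", g, "_"), "", names(genomes[[g]]))
  }))
  pred <- clustering$families$family_id[
    match(key, paste(clustering$families$genome_id,
                     clustering$families$gene_id, sep = "\r"))]
  list(truth = truth, pred = pred)
}

# Exhaustive minimum-cost gain/loss assignment: enumerates every internal
# state combination; returns the lexicographic minimum of (cost, events).
# Independent of the package's dynamic programming.
oracle_gain_loss <- function(tree, pattern, gain_cost = 2, loss_cost = 1) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  edges <- tree$edge
  best_cost <- Inf
  best_events <- Inf
  for (mask in 0:(2^n_int - 1)) {
    st <- c(unname(pattern[tree$tip.label]),
            as.integer(intToBits(mask))[seq_len(n_int)])
    cost <- 0
    events <- 0L
    for (e in seq_len(nrow(edges))) {
      p <- st[edges[e, 1]]
      ch <- st[edges[e, 2]]
      if (p == 0 && ch == 1) { cost <- cost + gain_cost; events <- events + 1L }
      if (p == 1 && ch == 0) { cost <- cost + loss_cost; events <- events + 1L }
    }
    if (cost < best_cost || (cost == best_cost && events < best_events)) {
      best_cost <- cost
      best_events <- events
    }
  }
  list(cost = best_cost, events = best_events)
}

# Brute-force reciprocal-best-hit pairs straight from the definition,
# checking every ordered gene pair independently of bbh_pairs().
oracle_bbh <- function(hits) {
  keys <- unique(paste(hits$query_genome, hits$query_gene, sep = "\r"))
  best_of <- function(qg, qn, sg) {
    h <- hits[hits$query_genome == qg & hits$query_gene == qn &
                hits$subject_genome == sg, , drop = FALSE]
    if (nrow(h) == 0) return(NA_character_)
    h <- h[order(h$evalue, -h$score, h$subject_gene), , drop = FALSE]
    h$subject_gene[1]
  }
  out <- character(0)
  for (k in keys) {
    parts <- strsplit(k, "\r")[[1]]
    for (sg in setdiff(unique(hits$subject_genome), parts[1])) {
      b <- best_of(parts[1], parts[2], sg)
      if (is.na(b)) next
      back <- best_of(sg, b, parts[1])
      if (identical(back, parts[2])) {
        pair <- sort(c(paste(parts[1], parts[2]), paste(sg, b)))
        out <- c(out, paste(pair, collapse = "\r"))
      }
    }
  }
  sort(unique(out))
}

# random similarity-hit table over a few genomes
random_hit_table <- function(n_genomes = 3, genes_per = 6, p_hit = 0.6) {
  genomes <- paste0("G", seq_len(n_genomes))
  rows <- list()
  for (qg in genomes) for (sg in setdiff(genomes, qg)) {
    for (qi in seq_len(genes_per)) for (si in seq_len(genes_per)) {
      if (runif(1) > p_hit) next
      rows[[length(rows) + 1]] <- data.frame(
        query_genome = qg, query_gene = paste0(qg, "_", qi),
        subject_genome = sg, subject_gene = paste0(sg, "_", si),
        score = round(runif(1, 20, 200)),
        evalue = 10^-sample(5:30, 1),
        query_coverage = runif(1, 10, 100),
        similarity = runif(1, 30, 100), identity = runif(1, 20, 100),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# all non-trivial bipartitions of a phylo, computed by explicit recursion
# over the edge matrix (independent of ape::prop.part)
oracle_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  labels <- sort(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_below))
  }
  out <- character(0)
  for (node in (n_tip + 1):(n_tip + tree$Nnode)) {
    side <- sort(tips_below(node))
    if (length(side) < 2 || length(side) > n_tip - 2) next
    if (labels[1] %in% side) side <- setdiff(labels, side)
    out <- c(out, paste(side, collapse = "\r"))
  }
  sort(unique(out))
}
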