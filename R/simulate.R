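#' Configuration for the synthetic genome-set generator
#'
#' Bundles the parameters of the gene-family birth/death simulator used for
#' end-to-end validation of the pipeline. Defaults describe a small open
#' pangenome: six genomes, a moderately sized core, and enough gene gain
#' along the tree that rarefaction keeps discovering new families.
#'
#' @param n_genomes Number of genomes (tree leaves), `>= 2`.
#' @param n_core_families Families present at the root and never lost.
#' @param gain_rate Gain events per unit branch length (Poisson intensity).
#' @param loss_rate Per-family loss intensity per unit branch length; a
#'   non-core family present at the top of a branch is lost on it with
#'   probability `1 - exp(-loss_rate * length)`.
#' @param mean_new_per_gain Mean number of families introduced per gain
#'   event (each event introduces `1 + Poisson(mean_new_per_gain - 1)`).
#' @param seq_length Protein length in residues for emitted sequences.
#' @param per_branch_substitution_rate Substitutions per site per unit
#'   branch length; each site substitutes on a branch with probability
#'   `1 - exp(-rate * length)`.
#' @param mobile_fraction Fraction of families labeled as mobile (the
#'   ground-truth subset recovered by the screen stage), in `[0, 1]`.
#' @param branch_mean Mean of the exponential branch-length distribution.
#' @param seed Integer seed; identical config and seed give bit-identical
#'   trees, matrices and FASTA output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genomes = 6L,
                       n_core_families = 40L,
                       gain_rate = 25,
                       loss_rate = 2,
                       mean_new_per_gain = 1,
                       seq_length = 100L,
                       per_branch_substitution_rate = 0.3,
                       mobile_fraction = 0.1,
                       branch_mean = 0.1,
                       seed = 42L) {
  cfg <- list(n_genomes = as.integer(n_genomes),
              n_core_families = as.integer(n_core_families),
              gain_rate = gain_rate, loss_rate = loss_rate,
              mean_new_per_gain = mean_new_per_gain,
              seq_length = as.integer(seq_length),
              per_branch_substitution_rate = per_branch_substitution_rate,
              mobile_fraction = mobile_fraction,
              branch_mean = branch_mean,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genomes >= 2, n_core_families >= 0,
              is.finite(gain_rate), gain_rate >= 0,
              is.finite(loss_rate), loss_rate >= 0,
              mean_new_per_gain >= 1, seq_length > 0,
              is.finite(per_branch_substitution_rate),
              per_branch_substitution_rate >= 0,
              mobile_fraction >= 0, mobile_fraction <= 1,
              branch_mean > 0)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a random rooted binary phylogeny
#'
#' Generates a coalescent-like topology by repeatedly joining two uniformly
#' chosen lineages, with independent exponential branch lengths. Leaf labels
#' are `g01, g02, ...`.
#'
#' @param n_leaves Number of leaves, `>= 2`.
#' @param seed Integer seed.
#' @param branch_mean Mean branch length.
#' @return A rooted `ape::phylo` with strictly positive branch lengths.
#' @export
simulate_tree <- function(n_leaves, seed = 1L, branch_mean = 0.1) {
  n_leaves <- as.integer(n_leaves)
  if (is.na(n_leaves) || n_leaves < 2) {
    stop("n_leaves must be an integer >= 2")
  }
  with_seed(seed, {
    labels <- sprintf("g%02d", seq_len(n_leaves))
    # Node numbering follows the ape convention: tips 1..n, root n+1.
    n_nodes <- 2L * n_leaves - 1L
    parent <- integer(0)
    child <- integer(0)
    active <- seq_len(n_leaves)
    next_internal <- n_nodes  # assign internal ids downward, root gets n+1
    while (length(active) > 1) {
      pick <- sample(length(active), 2L)
      anc <- next_internal
      next_internal <- next_internal - 1L
      parent <- c(parent, anc, anc)
      child <- c(child, active[pick])
      active <- c(active[-pick], anc)
    }
    # Remap internal ids so the root is n_leaves + 1 (ape convention):
    # internal ids were assigned downward in join order, so the last one
    # created (the root) carries the smallest id and must become n+1.
    internal_old <- sort(unique(parent), decreasing = TRUE)
    map <- integer(n_nodes)
    map[seq_len(n_leaves)] <- seq_len(n_leaves)
    map[internal_old] <- n_leaves + rev(seq_along(internal_old))
    edge <- cbind(map[parent], map[child])
    lens <- rexp(nrow(edge), rate = 1 / branch_mean)
    tr <- structure(list(edge = edge, edge.length = lens,
                         Nnode = n_leaves - 1L, tip.label = labels),
                    class = "phylo")
    tr <- ape::reorder.phylo(tr, "cladewise")
    tr
  })
}

#' Simulate gene-family presence/absence along a tree
#'
#' Places gene-family gain events on branches as a Poisson process with
#' intensity `gain_rate` per unit branch length, and loses non-core families
#' independently per branch with probability `1 - exp(-loss_rate * length)`.
#' Core families are present at the root and never lost, so they are core by
#' construction. Presence at the leaves is obtained by replaying the events
#' from the root down.
#'
#' @param tree A rooted `phylo`; leaves define the genomes.
#' @param config A [sim_config()]. Its `n_genomes` is ignored in favour of
#'   the tree's leaf count.
#' @return An object of class `sim_truth`: a list with `tree`, `families`
#'   (ids), `origin` (named vector: child-node id of the branch where each
#'   family was gained, or `0` for root/core families), `losses` (named list
#'   of child-node ids of loss branches), `mobile` (ids of mobile-labeled
#'   families), and `presence` (binary family x genome matrix).
#' @export
simulate_families <- function(tree, config = sim_config()) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  n_tip <- length(tree$tip.label)
  stopifnot(n_tip >= 2)
  with_seed(derive_seed(config$seed, "families"), {
    root <- n_tip + 1L
    edges <- tree$edge
    lens <- tree$edge.length
    fam_ids <- character(0)
    origin <- integer(0)
    if (config$n_core_families > 0) {
      core_ids <- sprintf("C%04d", seq_len(config$n_core_families))
      fam_ids <- core_ids
      origin <- rep(0L, length(core_ids))
    }
    # gains per edge, in cladewise edge order for determinism
    for (e in seq_len(nrow(edges))) {
      n_events <- rpois(1, config$gain_rate * lens[e])
      n_new <- if (n_events > 0) {
        sum(1L + rpois(n_events, config$mean_new_per_gain - 1))
      } else 0L
      if (n_new > 0) {
        ids <- sprintf("G%04d", sum(origin != 0L) + seq_len(n_new))
        fam_ids <- c(fam_ids, ids)
        origin <- c(origin, rep(edges[e, 2L], n_new))
      }
    }
    names(origin) <- fam_ids
    # losses: walk edges root-to-leaf (cladewise order guarantees parents
    # are visited before children); track presence at every node
    n_nodes <- n_tip + tree$Nnode
    pres <- matrix(0L, nrow = length(fam_ids), ncol = n_nodes,
                   dimnames = list(fam_ids, NULL))
    pres[origin == 0L, root] <- 1L
    losses <- vector("list", length(fam_ids))
    names(losses) <- fam_ids
    is_core <- origin == 0L
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; chi <- edges[e, 2L]
      state <- pres[, par]
      p_loss <- 1 - exp(-config$loss_rate * lens[e])
      lose <- state == 1L & !is_core & runif(length(state)) < p_loss
      state[lose] <- 0L
      state[origin == chi] <- 1L
      pres[, chi] <- state
      for (f in which(lose)) losses[[f]] <- c(losses[[f]], chi)
    }
    presence <- pres[, seq_len(n_tip), drop = FALSE]
    colnames(presence) <- tree$tip.label
    # drop families that never reach a leaf (gained then fully lost)
    keep <- rowSums(presence) > 0
    fam_ids <- fam_ids[keep]
    presence <- presence[keep, , drop = FALSE]
    origin <- origin[keep]
    losses <- losses[keep]
    n_mobile <- round(config$mobile_fraction * length(fam_ids))
    mobile <- if (n_mobile > 0) sort(sample(fam_ids, n_mobile)) else character(0)
    structure(list(tree = tree, families = fam_ids, origin = origin,
                   losses = losses, mobile = mobile, presence = presence,
                   config = config),
              class = "sim_truth")
  })
}

#' Replay recorded gain/loss events over the tree
#'
#' Reconstructs the leaf presence/absence matrix from the recorded origins
#' and loss branches alone. Used as a conservation check: the result must
#' equal `truth$presence` exactly.
#'
#' @param truth A [simulate_families()] result.
#' @return Binary family x genome matrix.
#' @export
replay_events <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  tree <- truth$tree
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  edges <- tree$edge
  n_nodes <- n_tip + tree$Nnode
  pres <- matrix(0L, nrow = length(truth$families), ncol = n_nodes,
                 dimnames = list(truth$families, NULL))
  pres[truth$origin == 0L, root] <- 1L
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; chi <- edges[e, 2L]
    state <- pres[, par]
    lost <- vapply(truth$losses, function(l) chi %in% l, logical(1))
    state[lost] <- 0L
    state[truth$origin == chi] <- 1L
    pres[, chi] <- state
  }
  out <- pres[, seq_len(n_tip), drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}

# uniform random protein of length n over the 20 standard residues
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# substitute each site with prob p, drawing a different residue uniformly
mutate_protein <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    repl <- vapply(chars[hit], function(ch) sample(setdiff(aa, ch), 1), "")
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

#' Emit per-genome protein sequences for a simulated family history
#'
#' Draws one ancestral random protein per family at the family's origin node
#' and evolves copies down the tree, substituting each site on a branch with
#' probability `1 - exp(-rate * length)`. Gene identifiers encode the
#' (genome, family) ground truth as `<genome>_<family>` so downstream tests
#' can score clustering against the simulator.
#'
#' @param truth A [simulate_families()] result.
#' @param config The [sim_config()] used (for `seq_length` and the
#'   substitution rate).
#' @return A named list of `Biostrings::AAStringSet`, one per genome
#'   (class `genome_set`).
#' @export
sim_sequences <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  tree <- truth$tree
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  edges <- tree$edge
  lens <- tree$edge.length
  rate <- config$per_branch_substitution_rate
  with_seed(derive_seed(config$seed, "sequences"), {
    n_nodes <- n_tip + tree$Nnode
    # seqs[[node]][family] = sequence of the family at that node (if present)
    seqs <- vector("list", n_nodes)
    anc <- vapply(truth$families, function(f) random_protein(config$seq_length), "")
    # place ancestral sequences at origin nodes
    at_root <- names(anc)[truth$origin == 0L]
    seqs[[root]] <- anc[at_root]
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; chi <- edges[e, 2L]
      p_sub <- 1 - exp(-rate * lens[e])
      inherited <- seqs[[par]]
      if (length(inherited)) {
        # restrict to families actually present at the child (loss pruning)
        present_chi <- if (chi <= n_tip) {
          rownames(truth$presence)[truth$presence[, chi] == 1L]
        } else {
          # presence at internal nodes: recompute from origin/losses path;
          # simpler: keep all inherited not lost on this edge
          names(inherited)[!vapply(names(inherited),
                                   function(f) chi %in% truth$losses[[f]],
                                   logical(1))]
        }
        keep <- intersect(names(inherited), present_chi)
        inherited <- inherited[keep]
        inherited <- vapply(inherited, mutate_protein, "", p = p_sub)
      }
      born <- names(truth$origin)[truth$origin == chi]
      newborn <- anc[born]
      seqs[[chi]] <- c(inherited, newborn)
    }
    out <- lapply(seq_len(n_tip), function(tip) {
      fams <- names(seqs[[tip]])
      ss <- Biostrings::AAStringSet(unlist(seqs[[tip]], use.names = FALSE))
      names(ss) <- paste0(tree$tip.label[tip], "_", fams)
      ss
    })
    names(out) <- tree$tip.label
    structure(out, class = "genome_set")
  })
}

#' Write simulated genomes as per-genome FASTA files
#'
#' One protein FASTA per genome (file stem = genome id), a newick file with
#' the true tree, a truth table TSV (family origins, losses, mobile labels)
#' and a run-manifest TSV recording the seed and parameters.
#'
#' @param truth A [simulate_families()] result.
#' @param config The matching [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
emit_sequences <- function(truth, config = truth$config, dir) {
  genomes <- sim_sequences(truth, config)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  paths <- character(0)
  for (g in names(genomes)) {
    p <- file.path(dir, paste0(g, ".faa"))
    Biostrings::writeXStringSet(genomes[[g]], p)
    paths[g] <- p
  }
  tree_path <- file.path(dir, "true_tree.nwk")
  ape::write.tree(truth$tree, tree_path)
  truth_df <- data.frame(
    family = truth$families,
    origin_node = unname(truth$origin),
    loss_nodes = vapply(truth$losses, function(l)
      if (is.null(l)) "" else paste(l, collapse = ","), ""),
    mobile = as.integer(truth$families %in% truth$mobile))
  truth_path <- file.path(dir, "truth_families.tsv")
  write_tsv_hash(truth_df, truth_path)
  manifest <- data.frame(key = c("seed", "n_genomes", "n_core_families",
                                 "gain_rate", "loss_rate", "seq_length",
                                 "per_branch_substitution_rate",
                                 "mobile_fraction"),
                         value = c(config$seed, length(genomes),
                                   config$n_core_families, config$gain_rate,
                                   config$loss_rate, config$seq_length,
                                   config$per_branch_substitution_rate,
                                   config$mobile_fraction))
  manifest_path <- file.path(dir, "manifest.tsv")
  write_tsv_hash(manifest, manifest_path)
  invisible(list(genomes = paths, tree = tree_path, truth = truth_path,
                 manifest = manifest_path))
}

#' Build a screen reference set from the simulated mobile families
#'
#' The reference holds one representative (the ancestral sequence) per
#' mobile-labeled family plus an equal number of decoy proteins unrelated to
#' any family, with a label table assigning each representative to a
#' mobilome category (plasmid, virus or prophage).
#'
#' @param truth A [simulate_families()] result with at least one mobile
#'   family.
#' @param config The matching [sim_config()].
#' @param dir Optional directory; when given, the reference FASTA and label
#'   TSV are written there.
#' @return List with `reference` (`AAStringSet`, representatives then
#'   decoys) and `categories` (data.frame `ref_id`, `category` for the
#'   representatives only).
#' @export
emit_screen_reference <- function(truth, config = truth$config, dir = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (length(truth$mobile) == 0) {
    stop("no mobile-labeled families in this simulation (mobile_fraction too low)")
  }
  with_seed(derive_seed(config$seed, "screen_reference"), {
    # representatives must be the ancestral draws; regenerate them with the
    # same derived seed the sequence emitter uses
    anc <- with_seed(derive_seed(config$seed, "sequences"), {
      vapply(truth$families, function(f) random_protein(config$seq_length), "")
    })
    reps <- anc[truth$mobile]
    n <- length(reps)
    decoys <- vapply(seq_len(n), function(i) random_protein(config$seq_length), "")
    ref <- Biostrings::AAStringSet(c(unname(reps), unname(decoys)))
    names(ref) <- c(paste0("ref_", truth$mobile),
                    sprintf("decoy_%03d", seq_len(n)))
    cats <- data.frame(
      ref_id = paste0("ref_", truth$mobile),
      category = sample(c("plasmid", "virus", "prophage"), n, replace = TRUE))
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      Biostrings::writeXStringSet(ref, file.path(dir, "screen_reference.faa"))
      write_tsv_hash(cats, file.path(dir, "screen_reference_categories.tsv"))
    }
    list(reference = ref, categories = cats)
  })
}
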