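#' Gain/loss cost scheme for weighted parsimony
#'
#' Event costs for the presence/absence parsimony reconstruction. The
#' default encodes "losses twice as probable as gains" through the standard
#' cost/probability duality: the more probable event is the cheaper one, so
#' `gain_cost = 2`, `loss_cost = 1`.
#'
#' @param gain_cost Cost of a 0 to 1 transition along a branch (`> 0`).
#' @param loss_cost Cost of a 1 to 0 transition (`> 0`).
#' @return Object of class `cost_scheme`.
#' @export
cost_scheme <- function(gain_cost = 2, loss_cost = 1) {
  stopifnot(is.numeric(gain_cost), gain_cost > 0,
            is.numeric(loss_cost), loss_cost > 0)
  structure(list(gain_cost = gain_cost, loss_cost = loss_cost),
            class = "cost_scheme")
}

#' Root an unrooted tree on an outgroup clade
#'
#' Mirrors rooting a phylogeny on a designated clade (e.g. the pigmented
#' strains): the tree is rooted on the branch separating the outgroup
#' labels from the rest.
#'
#' @param tree An `ape::phylo`.
#' @param outgroup Character vector of tip labels forming the outgroup.
#' @return A rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"), all(outgroup %in% tree$tip.label))
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# lexicographic minimum over (cost, events), elementwise on matrices;
# returns list(cost, events, pick) where pick is TRUE when the second
# candidate wins strictly
lex_min2 <- function(c1, e1, c2, e2) {
  pick2 <- (c2 < c1) | (c2 == c1 & e2 < e1)
  list(cost = ifelse(pick2, c2, c1),
       events = ifelse(pick2, e2, e1),
       pick2 = pick2)
}

#' Weighted-parsimony reconstruction of gene gains and losses
#'
#' Sankoff dynamic programming over a rooted (possibly multifurcating)
#' tree, per gene family, under asymmetric event costs: a 0 to 1 change on
#' a branch costs `gain_cost`, a 1 to 0 change costs `loss_cost`, and the
#' root state itself is free. Among minimum-cost assignments, ties are
#' broken by the fewest total events and then by preferring absence, so the
#' reconstruction is deterministic. Branch lengths play no role (costs are
#' per event).
#'
#' @param matrix Binary family x genome presence matrix; column names must
#'   equal the tree's tip labels as a set.
#' @param tree A rooted `ape::phylo`.
#' @param costs A [cost_scheme()].
#' @return Object of class `gain_loss_reconstruction`: list with `states`
#'   (family x node binary matrix over all nodes, tips first), `edges`
#'   (data.frame `parent`, `child`, `gains`, `losses` summed over
#'   families), `node_sizes` (ancestral genome size per node),
#'   `node_labels`, `total_cost`, `tree` and `costs`.
#' @export
reconstruct_gain_loss <- function(matrix, tree, costs = cost_scheme()) {
  stopifnot(is.matrix(matrix), inherits(tree, "phylo"),
            inherits(costs, "cost_scheme"))
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted (root it, e.g. with root_on_outgroup())")
  }
  sd_ <- c(setdiff(tree$tip.label, colnames(matrix)),
           setdiff(colnames(matrix), tree$tip.label))
  if (length(sd_)) {
    stop("tree tips and matrix genomes differ: ", paste(sd_, collapse = ", "))
  }
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  n_fam <- nrow(matrix)
  tipstate <- matrix[, tree$tip.label, drop = FALSE]
  gc_ <- costs$gain_cost
  lc <- costs$loss_cost
  # DP tables: minimal (cost, events) of the subtree below each node given
  # the node's own state
  inf <- Inf
  C0 <- matrix(0, n_fam, n_nodes); C1 <- matrix(0, n_fam, n_nodes)
  E0 <- matrix(0, n_fam, n_nodes); E1 <- matrix(0, n_fam, n_nodes)
  C0[, seq_len(n_tip)] <- ifelse(tipstate == 1L, inf, 0)
  C1[, seq_len(n_tip)] <- ifelse(tipstate == 1L, 0, inf)
  tree_po <- ape::reorder.phylo(tree, "postorder")
  edges <- tree_po$edge
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; chi <- edges[e, 2L]
    # contribution of this child to parent state 0: child stays 0 (free) or
    # is gained on the branch
    m0 <- lex_min2(C0[, chi], E0[, chi], C1[, chi] + gc_, E1[, chi] + 1)
    # to parent state 1: child stays 1 (free) or is lost on the branch
    m1 <- lex_min2(C1[, chi], E1[, chi], C0[, chi] + lc, E0[, chi] + 1)
    C0[, par] <- C0[, par] + m0$cost; E0[, par] <- E0[, par] + m0$events
    C1[, par] <- C1[, par] + m1$cost; E1[, par] <- E1[, par] + m1$events
  }
  root <- n_tip + 1L
  states <- matrix(0L, n_fam, n_nodes,
                   dimnames = list(rownames(matrix), NULL))
  pick_root <- (C1[, root] < C0[, root]) |
    (C1[, root] == C0[, root] & E1[, root] < E0[, root])
  states[, root] <- as.integer(pick_root)
  total_cost <- sum(ifelse(pick_root, C1[, root], C0[, root]))
  # traceback root-to-leaf: cladewise edge order visits parents first
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tree_cw$edge))) {
    par <- tree_cw$edge[e, 1L]; chi <- tree_cw$edge[e, 2L]
    p <- states[, par]
    # candidate child state 0: transition cost lc if parent 1 else 0
    cand0 <- C0[, chi] + ifelse(p == 1L, lc, 0)
    ev0 <- E0[, chi] + ifelse(p == 1L, 1, 0)
    cand1 <- C1[, chi] + ifelse(p == 0L, gc_, 0)
    ev1 <- E1[, chi] + ifelse(p == 0L, 1, 0)
    pick1 <- (cand1 < cand0) | (cand1 == cand0 & ev1 < ev0)
    states[, chi] <- as.integer(pick1)
  }
  edge_df <- as.data.frame(tree_cw$edge)
  names(edge_df) <- c("parent", "child")
  edge_df$gains <- vapply(seq_len(nrow(edge_df)), function(e) {
    sum(states[, edge_df$parent[e]] == 0L & states[, edge_df$child[e]] == 1L)
  }, 0)
  edge_df$losses <- vapply(seq_len(nrow(edge_df)), function(e) {
    sum(states[, edge_df$parent[e]] == 1L & states[, edge_df$child[e]] == 0L)
  }, 0)
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label) &&
                  all(nzchar(tree$node.label))) tree$node.label
              else sprintf("N%02d", n_tip + seq_len(tree$Nnode)))
  structure(list(states = states, edges = edge_df,
                 node_sizes = colSums(states), node_labels = labels,
                 total_cost = total_cost, tree = tree, costs = costs),
            class = "gain_loss_reconstruction")
}

#' @export
print.gain_loss_reconstruction <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  cat(sprintf(paste0("Gain/loss reconstruction: %d families, %d genomes, ",
                     "total cost %.1f\n"),
              nrow(x$states), n_tip, x$total_cost))
  cat(sprintf("  LCA (root) genome size: %d families\n",
              x$node_sizes[n_tip + 1L]))
  cat(sprintf("  total gains %d, total losses %d\n",
              sum(x$edges$gains), sum(x$edges$losses)))
  invisible(x)
}

#' Per-node ancestral genome sizes and branch events
#'
#' One row per node: the ancestral genome size (families in state 1), and
#' the gains and losses on the branch leading to the node (zero for the
#' root). Leaf rows equal the observed genome family counts; the root row
#' is labeled `LCA`.
#'
#' @param recon A [reconstruct_gain_loss()] result.
#' @return Data.frame with columns `node`, `label`, `type`, `size`,
#'   `gains`, `losses`.
#' @export
ancestral_size_profile <- function(recon) {
  stopifnot(inherits(recon, "gain_loss_reconstruction"))
  n_tip <- length(recon$tree$tip.label)
  n_nodes <- n_tip + recon$tree$Nnode
  root <- n_tip + 1L
  gains <- losses <- numeric(n_nodes)
  gains[recon$edges$child] <- recon$edges$gains
  losses[recon$edges$child] <- recon$edges$losses
  labels <- recon$node_labels
  labels[root] <- "LCA"
  type <- rep("internal", n_nodes)
  type[seq_len(n_tip)] <- "leaf"
  type[root] <- "root"
  data.frame(node = seq_len(n_nodes), label = labels, type = type,
             size = unname(recon$node_sizes),
             gains = gains, losses = losses,
             stringsAsFactors = FALSE)
}

#' Annotated newick with per-branch gains and losses
#'
#' Writes the reconstruction's tree with `[gains/losses]` comments attached
#' to each node label.
#'
#' @param recon A [reconstruct_gain_loss()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotated_tree <- function(recon, path) {
  tr <- recon$tree
  n_tip <- length(tr$tip.label)
  prof <- ancestral_size_profile(recon)
  note <- sprintf("%s_+%d_-%d_n%d", prof$label, prof$gains, prof$losses,
                  prof$size)
  tr$tip.label <- note[seq_len(n_tip)]
  tr$node.label <- note[(n_tip + 1L):nrow(prof)]
  ape::write.tree(tr, path)
  invisible(path)
}
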