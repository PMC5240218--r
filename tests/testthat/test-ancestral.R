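quartet <- function() ape::read.tree(text = "((A:1,B:1)X:1,(C:1,D:1)Y:1)R;")

pattern_matrix <- function(patterns, tips) {
  m <- do.call(rbind, patterns)
  colnames(m) <- tips
  rownames(m) <- sprintf("F%03d", seq_len(nrow(m)))
  m
}

test_that("uniform families need no events and fill every ancestral node", {
  tr <- quartet()
  m <- pattern_matrix(list(c(1L, 1L, 1L, 1L), c(0L, 0L, 0L, 0L)),
                      tr$tip.label)
  rec <- reconstruct_gain_loss(m, tr)
  expect_equal(sum(rec$edges$gains), 0)
  expect_equal(sum(rec$edges$losses), 0)
  expect_true(all(rec$states["F001", ] == 1L))
  expect_true(all(rec$states["F002", ] == 0L))
  expect_equal(rec$total_cost, 0)
})

test_that("a clade-restricted family resolves to one loss under 2:1 costs", {
  tr <- quartet()
  m <- pattern_matrix(list(c(A = 1L, B = 1L, C = 0L, D = 0L)), tr$tip.label)
  rec <- reconstruct_gain_loss(m, tr, cost_scheme(gain_cost = 2, loss_cost = 1))
  expect_equal(rec$total_cost, 1)
  expect_equal(sum(rec$edges$gains), 0)
  expect_equal(sum(rec$edges$losses), 1)
  n_tip <- 4
  root <- n_tip + 1
  expect_equal(unname(rec$states[1, root]), 1L)  # root present
  # the loss sits on the branch to C,D's ancestor
  y <- rec$edges$child[rec$edges$losses == 1]
  expect_true(y > n_tip)
})

test_that("a single-leaf family resolves to one recent gain by the tie rule", {
  tr <- quartet()
  m <- pattern_matrix(list(c(A = 1L, B = 0L, C = 0L, D = 0L)), tr$tip.label)
  rec <- reconstruct_gain_loss(m, tr)
  # two cost-2 optima exist (gain on the terminal branch vs root presence
  # with two losses); fewest-events tie-breaking picks the single gain
  expect_equal(rec$total_cost, 2)
  expect_equal(sum(rec$edges$gains), 1)
  expect_equal(sum(rec$edges$losses), 0)
  gain_edge <- rec$edges[rec$edges$gains == 1, ]
  expect_equal(gain_edge$child, which(tr$tip.label == "A"))
  expect_equal(unname(rec$states[1, 5]), 0L)  # root absent
  prof <- ancestral_size_profile(rec)
  expect_equal(prof$size[prof$label == "LCA"], 0)
})

test_that("dynamic programming equals exhaustive enumeration on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    n_leaves <- sample(3:6, 1)
    tr <- simulate_tree(n_leaves, seed = seed)
    pats <- matrix(sample(0:1, 100 * n_leaves, replace = TRUE), nrow = 100)
    colnames(pats) <- tr$tip.label
    rownames(pats) <- sprintf("F%03d", 1:100)
    rec <- reconstruct_gain_loss(pats, tr)
    gc_ <- 2; lc <- 1
    per_family_cost <- vapply(seq_len(nrow(pats)), function(i) {
      st <- rec$states[i, ]
      sum(vapply(seq_len(nrow(rec$edges)), function(e) {
        p <- st[rec$edges$parent[e]]; ch <- st[rec$edges$child[e]]
        if (p == 0 && ch == 1) gc_ else if (p == 1 && ch == 0) lc else 0
      }, 0))
    }, 0)
    oracle <- vapply(seq_len(nrow(pats)), function(i) {
      oracle_gain_loss(tr, pats[i, ])$cost
    }, 0)
    expect_equal(per_family_cost, oracle)
    expect_equal(rec$total_cost, sum(oracle))
  }
})

test_that("equal costs reproduce the Fitch minimum-change count", {
  for (seed in 1:10) {
    set.seed(seed)
    tr <- simulate_tree(5, seed = seed + 100)
    pats <- matrix(sample(0:1, 20 * 5, replace = TRUE), nrow = 20)
    colnames(pats) <- tr$tip.label
    rownames(pats) <- sprintf("F%02d", 1:20)
    rec <- reconstruct_gain_loss(pats, tr, cost_scheme(1, 1))
    oracle <- sum(vapply(seq_len(nrow(pats)), function(i) {
      oracle_gain_loss(tr, pats[i, ], gain_cost = 1, loss_cost = 1)$cost
    }, 0))
    expect_equal(rec$total_cost, oracle)
  }
})

test_that("state changes along every path match the recorded branch events", {
  tr <- simulate_tree(6, seed = 3)
  truth <- simulate_families(tr, sim_config(seed = 3))
  rec <- reconstruct_gain_loss(truth$presence, tr)
  # leaf states equal the input matrix
  expect_identical(unname(rec$states[, seq_len(6)]),
                   unname(truth$presence[, tr$tip.label]))
  # per edge: net size change = gains - losses
  for (e in seq_len(nrow(rec$edges))) {
    par <- rec$edges$parent[e]; chi <- rec$edges$child[e]
    expect_equal(rec$node_sizes[chi] - rec$node_sizes[par],
                 rec$edges$gains[e] - rec$edges$losses[e])
  }
})

test_that("raising the gain cost never increases the number of inferred gains", {
  for (seed in 1:8) {
    set.seed(seed)
    tr <- simulate_tree(5, seed = seed + 50)
    pats <- matrix(sample(0:1, 30 * 5, replace = TRUE), nrow = 30)
    colnames(pats) <- tr$tip.label
    rownames(pats) <- sprintf("F%02d", 1:30)
    gains <- vapply(c(1, 2, 4), function(g) {
      sum(reconstruct_gain_loss(pats, tr, cost_scheme(g, 1))$edges$gains)
    }, 0)
    expect_true(all(diff(gains) <= 0))
  }
})

test_that("parsimony cost never exceeds the true event history's cost", {
  for (seed in 1:10) {
    tr <- simulate_tree(6, seed = seed)
    truth <- simulate_families(tr, sim_config(loss_rate = 0, seed = seed))
    costs <- cost_scheme(2, 1)
    rec <- reconstruct_gain_loss(truth$presence, tr, costs)
    true_cost <- sum((truth$origin != 0) * costs$gain_cost) +
      sum(lengths(truth$losses)) * costs$loss_cost
    expect_lte(rec$total_cost, true_cost)
  }
})

test_that("size profile labels the root LCA and matches leaf family counts", {
  tr <- quartet()
  m <- pattern_matrix(list(c(1L, 1L, 1L, 1L), c(1L, 0L, 0L, 0L)),
                      tr$tip.label)
  rec <- reconstruct_gain_loss(m, tr)
  prof <- ancestral_size_profile(rec)
  expect_equal(prof$size[prof$type == "leaf"],
               unname(colSums(m)[tr$tip.label]))
  expect_equal(prof$label[prof$type == "root"], "LCA")
  expect_equal(prof$size[prof$label == "LCA"], 1)  # the core family only
})

test_that("mismatched leaf sets and unrooted trees are rejected", {
  tr <- quartet()
  m <- pattern_matrix(list(c(1L, 1L, 1L, 1L)), c("A", "B", "C", "Z"))
  expect_error(reconstruct_gain_loss(m, tr), "differ")
  unrooted <- ape::unroot(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:1);"))
  m2 <- pattern_matrix(list(c(1L, 1L, 0L, 0L, 0L)), unrooted$tip.label)
  expect_error(reconstruct_gain_loss(m2, unrooted), "rooted")
  rooted <- root_on_outgroup(unrooted, "E")
  expect_true(ape::is.rooted(rooted))
  expect_silent(reconstruct_gain_loss(m2, rooted))
})
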