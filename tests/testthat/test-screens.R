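mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(genome = r[[1]], gene = r[[2]], ref_id = r[[3]],
               score = as.numeric(r[[4]]), evalue = as.numeric(r[[5]]),
               coverage = as.numeric(r[[6]]), similarity = as.numeric(r[[7]]),
               identity = as.numeric(r[[7]]), stringsAsFactors = FALSE)
  }))
}

cats <- data.frame(ref_id = c("r_plas", "r_vir", "r_pro"),
                   category = c("plasmid", "virus", "prophage"),
                   stringsAsFactors = FALSE)

test_that("threshold boundaries are strict on all three quantities", {
  cfg <- screen_config("mobilome")
  # exactly at the thresholds: all rejected
  at <- mk_hits(list("g1", "a", "r_plas", 300, 1e-20, 80, 80),
                list("g1", "b", "r_plas", 300, 1e-30, 30, 80),
                list("g1", "c", "r_plas", 300, 1e-30, 80, 60))
  got <- fbh_assign(at, cats, cfg)
  expect_false(any(got$pass))
  # strictly better on every axis: accepted
  ok <- mk_hits(list("g1", "d", "r_plas", 300, 0.99e-20, 30.01, 60.01))
  expect_true(fbh_assign(ok, cats, cfg)$pass)
})

test_that("assignment follows the single first best hit", {
  cfg <- screen_config("mobilome")
  h <- mk_hits(list("g1", "a", "r_vir", 200, 1e-40, 90, 90),
               list("g1", "a", "r_plas", 400, 1e-35, 95, 95))
  got <- fbh_assign(h, cats, cfg)
  expect_equal(nrow(got), 1)
  expect_equal(got$category, "virus")  # lowest e-value wins despite score
  # e-value tie: higher score, then lexicographic reference id
  h2 <- mk_hits(list("g1", "a", "r_pro", 200, 1e-40, 90, 90),
                list("g1", "a", "r_plas", 200, 1e-40, 90, 90))
  expect_equal(fbh_assign(h2, cats, cfg)$ref_id, "r_plas")
})

test_that("relaxing thresholds never loses assigned genes", {
  set.seed(1)
  h <- do.call(rbind, lapply(1:50, function(i) {
    mk_hits(list("g1", paste0("x", i), sample(cats$ref_id, 1), 300,
                 10^-runif(1, 15, 35), runif(1, 10, 100), runif(1, 40, 100)))
  }))
  strict <- sum(fbh_assign(h, cats, screen_config("mobilome"))$pass)
  lax <- sum(fbh_assign(h, cats, screen_config("mobilome",
                                               evalue_max = 1e-10,
                                               coverage_min = 5,
                                               similarity_min = 30))$pass)
  expect_gte(lax, strict)
})

test_that("the CAP preset applies only the tightened e-value", {
  cap <- screen_config("cap")
  expect_equal(cap$evalue_max, 1e-30)
  h <- mk_hits(list("g1", "a", "r_plas", 300, 1e-31, 5, 10),
               list("g1", "b", "r_plas", 300, 1e-29, 100, 100))
  got <- fbh_assign(h, cats, cap)
  expect_true(got$pass[got$gene == "a"])    # poor coverage is fine for CAPs
  expect_false(got$pass[got$gene == "b"])   # e-value 1e-29 is not < 1e-30
})

test_that("per-genome totals equal the sum of the category counts", {
  mge <- pseudoalteromonas_mge_counts()
  expect_equal(mge$total, mge$plasmid + mge$virus + mge$prophage)
  tac125 <- mge[mge$strain == "P. haloplanktis TAC125 uid58431", ]
  expect_equal(tac125$total, 577)
  # the same conservation holds for counts computed by the package
  a <- mk_hits(list("g1", "a", "r_plas", 300, 1e-40, 90, 90),
               list("g1", "b", "r_vir", 300, 1e-40, 90, 90),
               list("g2", "c", "r_pro", 300, 1e-40, 90, 90))
  got <- fbh_assign(a, cats, screen_config("mobilome"))
  counts <- screen_counts(got, c("g1", "g2", "g3"), cats$category)
  expect_equal(counts$total,
               rowSums(counts[, c("plasmid", "virus", "prophage")]))
  expect_equal(counts$total[counts$genome == "g3"], 0)
})

test_that("the screen recovers exactly the mobile genes on clean sequences", {
  tr <- simulate_tree(4, seed = 9)
  cfg <- sim_config(n_core_families = 20, gain_rate = 0, loss_rate = 0,
                    per_branch_substitution_rate = 0, seq_length = 80,
                    mobile_fraction = 0.2, seed = 33)
  truth <- simulate_families(tr, cfg)
  gs <- sim_sequences(truth, cfg)
  ref <- emit_screen_reference(truth, cfg)
  scr <- fbh_screen(gs, ref$reference, ref$categories)
  hitgenes <- scr$assignments[scr$assignments$pass, ]
  expect_setequal(unique(sub("^g[0-9]+_", "", hitgenes$gene)), truth$mobile)
  expect_equal(nrow(hitgenes), length(truth$mobile) * 4)
  # determinism
  scr2 <- fbh_screen(gs, ref$reference, ref$categories)
  expect_identical(scr$assignments, scr2$assignments)
})

test_that("sequences diverged to ~50% similarity fall below the screen thresholds", {
  # fixed depths so every root-to-leaf path carries the same divergence;
  # rate chosen so within-family similarity sits around 50%
  tr <- ape::read.tree(text = "(g01:0.2,(g02:0.1,g03:0.1):0.1);")
  cfg <- sim_config(n_core_families = 10, gain_rate = 0, loss_rate = 0,
                    per_branch_substitution_rate = 5, seq_length = 80,
                    mobile_fraction = 0.3, seed = 35)
  truth <- simulate_families(tr, cfg)
  gs <- sim_sequences(truth, cfg)
  ref <- emit_screen_reference(truth, cfg)
  scr <- fbh_screen(gs, ref$reference, ref$categories)
  expect_equal(sum(scr$assignments$pass), 0)
})

test_that("panmobilome partitions mobile families by the pangenome rule", {
  tr <- simulate_tree(4, seed = 9)
  cfg <- sim_config(n_core_families = 20, gain_rate = 0, loss_rate = 0,
                    per_branch_substitution_rate = 0, seq_length = 80,
                    mobile_fraction = 0.2, seed = 33)
  truth <- simulate_families(tr, cfg)
  gs <- sim_sequences(truth, cfg)
  cl <- cluster_genomes(gs)
  ref <- emit_screen_reference(truth, cfg)
  scr <- fbh_screen(gs, ref$reference, ref$categories)
  mob <- panmobilome(cl$families, cl$matrix, scr)
  # all families are core here (no gain/loss), so the mobilome is all core
  expect_equal(unname(mob$counts[["core"]]), length(truth$mobile))
  expect_equal(unname(mob$counts[["accessory"]]), 0)
  expect_equal(unname(mob$counts[["unique"]]), 0)
})

test_that("presence clustering separates block-structured strain groups", {
  m <- rbind(s1 = c(1, 1, 1, 0, 0, 0), s2 = c(1, 1, 1, 0, 0, 0),
             s3 = c(1, 1, 0, 0, 0, 0), s4 = c(0, 0, 0, 1, 1, 1),
             s5 = c(0, 0, 1, 1, 1, 1), s6 = c(0, 0, 0, 1, 1, 0))
  dend <- presence_cluster(m)
  expect_s3_class(dend$phylo, "phylo")
  parts <- pangevo:::bipartitions(dend$phylo)
  expect_true(paste(sort(c("s4", "s5", "s6")), collapse = "\r") %in% parts ||
                paste(sort(c("s1", "s2", "s3")), collapse = "\r") %in% parts)
  # identical rows merge at height zero
  two <- rbind(a = c(1, 0, 1), b = c(1, 0, 1), c = c(0, 1, 0))
  d2 <- presence_cluster(two)
  expect_equal(min(d2$hclust$height), 0)
  # constant matrix: star with warning
  flat <- matrix(1, 3, 4, dimnames = list(c("x", "y", "z"), NULL))
  expect_warning(star <- presence_cluster(flat), "star")
  expect_equal(star$phylo$Nnode, 1)
})

test_that("topology comparison counts shared bipartitions exactly", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,(E,F))));")
  expect_equal(compare_topologies(t1, t1)$shared,
               compare_topologies(t1, t1)$total_a)
  cater <- ape::read.tree(text = "(A,(B,(C,(D,(E,F)))));")
  balanced <- ape::read.tree(text = "(((A,B),C),((D,E),F));")
  got <- compare_topologies(cater, balanced)
  o1 <- oracle_bipartitions(cater)
  o2 <- oracle_bipartitions(balanced)
  expect_equal(got$shared, length(intersect(o1, o2)))
  expect_equal(got$total_a, length(o1))
  expect_equal(got$total_b, length(o2))
  # leaf-relabeled derangement
  perm <- cater
  perm$tip.label <- c("B", "C", "D", "E", "F", "A")
  gp <- compare_topologies(cater, perm)
  expect_equal(gp$shared,
               length(intersect(o1, oracle_bipartitions(perm))))
  t3 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(compare_topologies(t1, t3), "leaf")
})

test_that("mobile-family structure shows up in the dendrogram's top split", {
  # two clades; clade-specific mobile features make the presence profiles
  # mirror the phylogeny's root bipartition
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,((d:1,e:1):1,f:1):1);")
  m <- rbind(a = c(1, 1, 1, 0, 0), b = c(1, 1, 1, 0, 0), c = c(1, 1, 0, 0, 0),
             d = c(0, 0, 0, 1, 1), e = c(0, 0, 0, 1, 1), f = c(0, 0, 1, 1, 1))
  dend <- presence_cluster(m)
  cmp <- compare_topologies(dend, tr)
  root_split <- paste(sort(c("d", "e", "f")), collapse = "\r")
  expect_true(root_split %in% pangevo:::bipartitions(dend$phylo))
  expect_gte(cmp$shared, 1)
})
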