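test_that("identical sequences give reciprocal full-coverage identical hits", {
  seq <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  gs <- make_genomes(list(A = c(a1 = seq), B = c(b1 = seq)))
  hits <- all_vs_all_similarity(gs)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$query_genome, c("A", "B"))
  expect_equal(hits$identity, c(100, 100))
  expect_equal(hits$similarity, c(100, 100))
  expect_equal(hits$query_coverage, c(100, 100))
  expect_true(all(hits$evalue < 1e-10))
})

test_that("query coverage reflects the aligned fraction of the query", {
  block <- strrep("W", 30)
  filler <- strrep("P", 30)
  gs <- make_genomes(list(A = c(long = paste0(block, filler)),
                          B = c(short = block)))
  hits <- all_vs_all_similarity(gs)
  h <- hits[hits$query_gene == "long", ]
  expect_equal(h$query_coverage, 50)
  h2 <- hits[hits$query_gene == "short", ]
  expect_equal(h2$query_coverage, 100)
})

test_that("residues outside the scoring alphabet are rejected with the genome named", {
  gs <- make_genomes(list(A = c(a1 = "MKTUAY"), B = c(b1 = "MKTAY")))
  expect_error(all_vs_all_similarity(gs), "genome A")
})

test_that("bbh_pairs keeps exactly the reciprocal best pairs", {
  base <- data.frame(
    query_genome = c("A", "A", "B", "B"),
    query_gene = c("a1", "a1", "b1", "b2"),
    subject_genome = c("B", "B", "A", "A"),
    subject_gene = c("b1", "b2", "a1", "a1"),
    score = c(100, 90, 100, 90),
    evalue = c(1e-30, 1e-20, 1e-30, 1e-20),
    stringsAsFactors = FALSE)
  got <- bbh_pairs(base)
  expect_equal(nrow(got), 1)
  expect_equal(got$gene_a, "a1")
  expect_equal(got$gene_b, "b1")

  # a's best is b1 but b1's best in A is a2: no pair
  asym <- data.frame(
    query_genome = c("A", "B"), query_gene = c("a1", "b1"),
    subject_genome = c("B", "A"), subject_gene = c("b1", "a2"),
    score = c(100, 100), evalue = c(1e-30, 1e-40),
    stringsAsFactors = FALSE)
  expect_equal(nrow(bbh_pairs(asym)), 0)
})

test_that("bbh_pairs matches the brute-force reciprocal-best definition", {
  for (seed in 1:5) {
    set.seed(seed)
    hits <- random_hit_table()
    got <- bbh_pairs(hits)
    got_keys <- sort(paste(paste(got$genome_a, got$gene_a),
                           paste(got$genome_b, got$gene_b), sep = "\r"))
    expect_identical(got_keys, oracle_bbh(hits))
  }
})

test_that("families are connected components with singletons preserved", {
  gs <- make_genomes(list(A = c(a1 = "M", a2 = "M"), B = c(b1 = "M"),
                          C = c(c1 = "M")))
  bbh <- data.frame(genome_a = c("A", "B"), gene_a = c("a1", "b1"),
                    genome_b = c("B", "C"), gene_b = c("b1", "c1"),
                    stringsAsFactors = FALSE)
  res <- build_families(gs, bbh)
  fam_of <- function(g, gene) {
    res$families$family_id[res$families$genome_id == g &
                             res$families$gene_id == gene]
  }
  # transitive closure: a1-b1 and b1-c1 merge into one family
  expect_equal(length(unique(c(fam_of("A", "a1"), fam_of("B", "b1"),
                               fam_of("C", "c1")))), 1)
  # unlinked gene is a singleton in exactly one genome
  singleton <- fam_of("A", "a2")
  expect_equal(sum(res$families$family_id == singleton), 1)
  expect_equal(sum(res$matrix[singleton, ]), 1)
  # partition property: every gene in exactly one family
  expect_equal(nrow(res$families), 4)
  expect_equal(anyDuplicated(paste(res$families$genome_id,
                                   res$families$gene_id)), 0)
})

test_that("BBH pairs referencing unknown genes fail loudly", {
  gs <- make_genomes(list(A = c(a1 = "M"), B = c(b1 = "M")))
  bad <- data.frame(genome_a = "A", gene_a = "ghost",
                    genome_b = "B", gene_b = "b1", stringsAsFactors = FALSE)
  expect_error(build_families(gs, bad), "absent")
})

test_that("genome input order changes no family membership", {
  tr <- simulate_tree(4, seed = 5)
  cfg <- sim_config(n_core_families = 8, gain_rate = 10,
                    per_branch_substitution_rate = 0.1, seq_length = 60,
                    seed = 23)
  truth <- simulate_families(tr, cfg)
  gs <- sim_sequences(truth, cfg)
  res1 <- cluster_genomes(gs)
  res2 <- cluster_genomes(structure(rev(unclass(gs)), class = "genome_set"))
  expect_identical(res1$families, res2$families)
  expect_identical(res1$matrix, res2$matrix[rownames(res1$matrix),
                                            colnames(res1$matrix)])
})

test_that("clustering recovers the simulated family partition", {
  tr <- simulate_tree(4, seed = 11)
  cfg <- sim_config(n_core_families = 10, gain_rate = 10,
                    per_branch_substitution_rate = 0.1, seq_length = 60,
                    seed = 31)
  truth <- simulate_families(tr, cfg)
  gs <- sim_sequences(truth, cfg)
  res <- cluster_genomes(gs)
  cmp <- clustering_vs_truth(gs, res)
  expect_equal(ari(cmp$truth, cmp$pred), 1.0)
  # zero-divergence members hit each other at 100% similarity
  cfg0 <- sim_config(n_core_families = 4, gain_rate = 0, loss_rate = 0,
                     per_branch_substitution_rate = 0, seq_length = 60,
                     seed = 31)
  truth0 <- simulate_families(tr, cfg0)
  gs0 <- sim_sequences(truth0, cfg0)
  hits0 <- all_vs_all_similarity(gs0)
  same_family <- sub("^g[0-9]+_", "", hits0$query_gene) ==
    sub("^g[0-9]+_", "", hits0$subject_gene)
  expect_true(all(hits0$similarity[same_family] == 100))
})

test_that("BLAST tabular hits are ingested with identity standing in for similarity", {
  gs <- make_genomes(list(A = c(a1 = strrep("M", 50)),
                          B = c(b1 = strrep("M", 50))))
  tab <- data.frame("a1", "b1", 98.0, 50, 1, 0, 1, 50, 1, 50, 1e-30, 180)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expect_warning(hits <- read_blast_tab(path, gs), "similarity")
  expect_equal(hits$similarity, 98)
  expect_equal(hits$query_coverage, 100)
  expect_equal(hits$query_genome, "A")
  expect_equal(hits$subject_genome, "B")
})
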