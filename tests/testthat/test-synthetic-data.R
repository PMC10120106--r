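test_that("sim_config validates its fields and names the offender", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(root_leaf_richness_ratio = 1.2), "root_leaf_richness_ratio")
  expect_error(sim_config(root_leaf_richness_ratio = 0), "root_leaf_richness_ratio")
  expect_error(sim_config(target_core_shell_cloud = c(0.5, 0.5, 0.5)),
               "target_core_shell_cloud")
  expect_error(sim_config(hypothetical_fraction = -0.1), "hypothetical_fraction")
  expect_error(sim_config(depth_per_sample = 0), "depth_per_sample")
})

test_that("simulate_metadata yields two samples per genotype with positive reads", {
  m <- simulate_metadata(sim_config(seed = 1))
  expect_equal(nrow(m), 12)
  expect_setequal(unique(m$genotype), c("BB", "MB", "MT", "MS", "DC", "FH"))
  expect_true(all(table(m$genotype) == 2))
  expect_true(all(m$reads > 0))
  expect_setequal(m$sample[m$genotype == "BB"], c("BBL", "BBR"))
  m1 <- simulate_metadata(sim_config(seed = 1, genotypes = "BB"))
  expect_equal(nrow(m1), 2)
})

test_that("simulators are byte-identical under the same seed", {
  cfg <- sim_config(seed = 42, n_clusters = 50, n_taxa_pool = 40,
                    depth_per_sample = 2000)
  expect_identical(serialize(simulate_communities(cfg), NULL),
                   serialize(simulate_communities(cfg), NULL))
  expect_identical(serialize(simulate_pangenome(cfg), NULL),
                   serialize(simulate_pangenome(cfg), NULL))
  expect_identical(serialize(simulate_go(cfg), NULL),
                   serialize(simulate_go(cfg), NULL))
  t1 <- simulate_gene_trees(cfg)
  t2 <- simulate_gene_trees(cfg)
  expect_identical(
    vapply(t1$trees, function(e) ape::write.tree(e$tree), character(1)),
    vapply(t2$trees, function(e) ape::write.tree(e$tree), character(1))
  )
})

test_that("leaf communities are subsets of their paired root pools", {
  cfg <- sim_config(seed = 3, n_taxa_pool = 60, root_leaf_richness_ratio = 0.3,
                    depth_per_sample = 5000)
  comm <- simulate_communities(cfg)
  pools <- attr(comm$truth, "pools")
  for (g in cfg$genotypes) {
    leaf <- comm$meta$sample[comm$meta$genotype == g & comm$meta$tissue == "leaf"]
    root <- comm$meta$sample[comm$meta$genotype == g & comm$meta$tissue == "root"]
    expect_true(all(pools[[leaf]] %in% pools[[root]]))
    obs_leaf <- sum(comm$abundance[, leaf] > 0)
    expect_lte(obs_leaf, length(pools[[root]]))
  }
})

test_that("core_taxon_fraction = 1 makes all samples share one taxon set", {
  cfg <- sim_config(seed = 5, n_taxa_pool = 30, core_taxon_fraction = 1,
                    depth_per_sample = 5000)
  comm <- simulate_communities(cfg)
  pools <- attr(comm$truth, "pools")
  ref <- sort(pools[[1]])
  for (p in pools) expect_identical(sort(p), ref)
  expect_true(all(comm$truth$category == "core"))
})

test_that("root communities are more diverse than leaf communities across seeds", {
  wins <- 0L
  for (s in 1:20) {
    cfg <- sim_config(seed = s, n_taxa_pool = 80, depth_per_sample = 4000)
    comm <- simulate_communities(cfg)
    h <- apply(comm$abundance, 2, alpha_diversity, index = "shannon")
    root <- comm$meta$sample[comm$meta$tissue == "root"]
    leaf <- comm$meta$sample[comm$meta$tissue == "leaf"]
    if (mean(h[root]) > mean(h[leaf])) wins <- wins + 1L
  }
  expect_gte(wins, 19)
})

test_that("pangenome categories are apportioned exactly and patterns honour them", {
  cfg <- sim_config(seed = 1, n_clusters = 1000,
                    target_core_shell_cloud = c(0.1, 0.3, 0.6))
  pan <- simulate_pangenome(cfg)
  expect_equal(as.vector(table(pan$truth$category)[c("core", "shell", "cloud")]),
               c(100, 300, 600))
  pres <- rowSums(pan$clusters$counts >= 1)
  n_s <- ncol(pan$clusters$counts)
  expect_true(all(pres[pan$truth$category == "core"] == n_s))
  expect_true(all(pres[pan$truth$category == "cloud"] == 1))
  shell <- pres[pan$truth$category == "shell"]
  expect_true(all(shell >= 2 & shell < n_s))
})

test_that("hypothetical_fraction = 0 gives no group_ placeholder clusters", {
  pan <- simulate_pangenome(sim_config(seed = 2, n_clusters = 100,
                                       hypothetical_fraction = 0))
  expect_false(any(grepl("^group_", pan$clusters$gene_name)))
  pan62 <- simulate_pangenome(sim_config(seed = 2, n_clusters = 200))
  expect_equal(sum(pan62$clusters$annotation == "hypothetical protein"), 124)
})

test_that("simulated GO DAG is rooted, acyclic, and terms reach the root", {
  go <- simulate_go(sim_config(seed = 9, n_go_terms = 60, go_depth = 4))
  u <- go$universe
  root <- u$terms[lengths(u$parents) == 0]
  expect_length(root, 1)
  for (t in u$terms) {
    anc <- endopan:::term_ancestors(u, t)
    if (t != root) expect_true(root %in% anc)
  }
  expect_true(all(unlist(go$universe$gene2terms) %in% u$terms))
  expect_true(all(go$truth$enriched_terms %in% u$terms))
})

test_that("gene tree leaf labels parse and planted trees carry all genotypes", {
  cfg <- sim_config(seed = 4, n_clusters = 20, frac_phylosymbiotic = 0.5,
                    n_seq_per_genotype = 2)
  tr <- simulate_gene_trees(cfg)
  expect_equal(length(tr$trees), 20)
  for (e in tr$trees) {
    info <- parse_leaf_labels(e$tree$tip.label)
    expect_setequal(unique(info$genotype), cfg$genotypes)
    expect_equal(nrow(info), 12)
  }
})

test_that("hit simulator plants recoverable taxa and respects the e-value rule", {
  cfg <- sim_config(seed = 6, n_taxa_pool = 40, depth_per_sample = 2000)
  sc <- simulate_hits_and_scaffolds(cfg, n_scaffolds_per_sample = 20, epsilon = 0)
  tax <- bin_scaffolds(sc$hits, sc$scaffolds$scaffold_id)
  expect_identical(unname(tax[sc$scaffolds$scaffold_id]), sc$scaffolds$true_taxon)

  # hit-free scaffolds bin as unclassified, in the exact planted fraction
  sc2 <- simulate_hits_and_scaffolds(cfg, n_scaffolds_per_sample = 50,
                                     frac_hit_free = 0.3)
  tax2 <- bin_scaffolds(sc2$hits, sc2$scaffolds$scaffold_id)
  n_free <- sum(!(sc2$scaffolds$scaffold_id %in% sc2$hits$query))
  expect_equal(sum(tax2 == "unclassified"), n_free)

  # decoys forced above the threshold can never win
  sc3 <- simulate_hits_and_scaffolds(cfg, n_scaffolds_per_sample = 20,
                                     decoys_above_threshold = TRUE, n_decoy = 3)
  tax3 <- bin_scaffolds(sc3$hits, sc3$scaffolds$scaffold_id)
  expect_identical(unname(tax3[sc3$scaffolds$scaffold_id]), sc3$scaffolds$true_taxon)
})
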