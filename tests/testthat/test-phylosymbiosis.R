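test_that("genotype_distances averages patristic distances per genotype pair", {
  # one leaf per genotype: entries are plain path lengths
  tr <- ape::read.tree(text = "((A|c|s:1,B|c|s:1):1,C|c|s:2);")
  D <- genotype_distances(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  expect_true(all(diag(D) == 0))
  expect_equal(D, t(D))
  # two leaves per genotype at equal depth: hand cophenetic values
  tr2 <- ape::read.tree(
    text = "((A|c|1:1,A|c|2:1):1,(B|c|1:1,B|c|2:1):1);")
  D2 <- genotype_distances(tr2)
  expect_equal(D2["A", "B"], 4)  # every cross pair travels 1+1+1+1
  # zero-length star tree is degenerate
  star <- ape::read.tree(text = "(A|c|s:0,B|c|s:0,C|c|s:0);")
  expect_error(genotype_distances(star), "degenerate")
})

test_that("UPGMA solves the 3-taxon case, ties, and recovers ultrametric input", {
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  u <- upgma(D)
  expect_equal(u$clades[[1]], c("A", "B"))
  expect_equal(u$heights, c(1, 3))
  # all-equal distances: deterministic caterpillar by the tie-break rule
  De <- matrix(4, 4, 4) - diag(4) * 4
  dimnames(De) <- list(c("d", "b", "c", "a"), c("d", "b", "c", "a"))
  ue <- upgma(De)
  expect_equal(ue$clades[[1]], c("a", "b"))
  expect_equal(ue$clades[[2]], c("a", "b", "c"))
  # ultrametric input: topology and heights recovered exactly
  set.seed(14)
  for (r in 1:5) {
    t0 <- ape::rcoal(6)
    C <- ape::cophenetic.phylo(t0)
    u0 <- upgma(C)
    orig <- lapply(endopan:::phylo_clades(t0), sort)
    rec <- u0$clades
    key <- function(l) sort(vapply(l, paste, character(1), collapse = "|"))
    expect_equal(key(rec), key(orig))
    expect_equal(sort(u0$heights), sort(unname(ape::branching.times(t0))),
                 tolerance = 1e-9)
  }
  Dna <- D; Dna[1, 2] <- NA; Dna[2, 1] <- NA
  expect_error(upgma(Dna), "NA")
})

test_that("matches_host requires every host clade, invariant to leaf rotation", {
  ref <- host_reference(ape::read.tree(text = host_newick))
  expect_equal(length(ref$required_clades), 3)
  good <- ape::read.tree(text = "(((BB:1,MB:1):1,MT:2):2,((DC:2,FH:2):1,MS:3):1);")
  expect_true(as.logical(matches_host(good, ref)))
  bad <- ape::read.tree(text = "(((BB:1,DC:1):1,MT:2):2,((MB:2,FH:2):1,MS:3):1);")
  res_bad <- matches_host(bad, ref)
  expect_false(as.logical(res_bad))
  expect_named(attr(res_bad, "clades"))
  # rotation of children in the newick string does not change the verdict
  rot <- ape::read.tree(text = "((MS:3,(FH:2,DC:2):1):1,(MT:2,(MB:1,BB:1):1):2);")
  expect_true(as.logical(matches_host(rot, ref)))
  incomplete <- ape::read.tree(text = "((BB:1,MB:1):1,MT:2);")
  expect_error(matches_host(incomplete, ref), "missing")
})

test_that("the host clades derived from the default tree are the field set", {
  ref <- host_reference()
  keys <- vapply(ref$required_clades, paste, character(1), collapse = ",")
  expect_setequal(keys, c("BB,MB", "BB,MB,MT", "DC,FH"))
})

test_that("eligibility keeps exactly the clusters covering every genotype", {
  cfg <- sim_config(seed = 15, n_clusters = 6, n_seq_per_genotype = 1)
  tr <- simulate_gene_trees(cfg)
  entries <- unclass(tr$trees)
  # drop genotype MS from half the trees
  for (i in c(1, 3, 5)) {
    t <- entries[[i]]$tree
    drop <- grep("^MS\\|", t$tip.label, value = TRUE)
    entries[[i]]$tree <- ape::drop.tip(t, drop)
  }
  mixed <- gene_tree_set(entries)
  elig <- eligible_clusters(mixed, sim_config()$genotypes)
  expect_setequal(names(elig), names(entries)[c(2, 4, 6)])
  expect_error(eligible_clusters(mixed, character(0)), "non-empty")
})

test_that("screen recovers planted clusters perfectly at zero branch noise", {
  cfg <- sim_config(seed = 16, n_clusters = 60, frac_phylosymbiotic = 1,
                    branch_noise_sigma = 0, n_seq_per_genotype = 2)
  tr <- simulate_gene_trees(cfg)
  rep <- screen_phylosymbiosis(tr$trees, host_reference())
  expect_equal(rep$n_eligible, 60)
  expect_equal(rep$n_matched, 60)
  expect_equal(rep$fraction_matched, 100.0)
  # tallies conserve leaf counts over matched clusters
  total_leaves <- sum(vapply(tr$trees, function(e) length(e$tree$tip.label),
                             numeric(1)))
  expect_equal(sum(rep$taxon_tally), total_leaves)
  expect_equal(sum(rep$gene_tally), total_leaves)
  expect_equal(sum(rep$triples$count), total_leaves)
})

test_that("screen sensitivity degrades with branch noise but not below null", {
  sens <- vapply(c(0, 0.3, 1.2), function(sig) {
    cfg <- sim_config(seed = 17, n_clusters = 40, frac_phylosymbiotic = 1,
                      branch_noise_sigma = sig, n_seq_per_genotype = 1)
    tr <- simulate_gene_trees(cfg)
    screen_phylosymbiosis(tr$trees, host_reference())$n_matched / 40
  }, numeric(1))
  expect_equal(sens[1], 1)
  expect_true(sens[3] <= sens[1])
  expect_lt(sens[3], 0.9)
})

test_that("an empty eligible set yields a zero report without error", {
  cfg <- sim_config(seed = 18, n_clusters = 3, n_seq_per_genotype = 1)
  tr <- simulate_gene_trees(cfg)
  entries <- lapply(unclass(tr$trees), function(e) {
    e$tree <- ape::drop.tip(e$tree, grep("^BB\\|", e$tree$tip.label, value = TRUE))
    e
  })
  rep <- screen_phylosymbiosis(gene_tree_set(entries), host_reference())
  expect_equal(rep$n_eligible, 0)
  expect_equal(rep$n_matched, 0)
  expect_true(is.na(rep$fraction_matched))
})

test_that("uniform topology generator is uniform over 4-leaf rooted topologies", {
  # 15 labeled rooted binary topologies on 4 leaves; chi-square on 1500 draws
  set.seed(19)
  keys <- replicate(1500, {
    nwk <- endopan:::uniform_ultrametric_newick(c("a", "b", "c", "d"))
    t <- ape::read.tree(text = nwk)
    paste(sort(vapply(endopan:::phylo_clades(t), paste, character(1),
                      collapse = "")), collapse = "/")
  })
  tab <- table(keys)
  expect_equal(length(tab), 15)
  chi <- sum((tab - 100)^2 / 100)
  expect_lt(chi, stats::qchisq(0.999, df = 14))
})
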