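make_cm <- function(counts, gene = NULL, ann = NULL) {
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  cluster_matrix(counts,
                 cluster_id = sprintf("c%02d", seq_len(nrow(counts))),
                 gene_name = gene %||% sprintf("c%02d", seq_len(nrow(counts))),
                 annotation = ann %||% rep("", nrow(counts)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("partition classifies all-core, all-cloud, and the mixed hand case", {
  allc <- make_cm(matrix(1L, 4, 3))
  p <- pangenome_partition(allc)
  expect_equal(unname(p$counts), c(4L, 0L, 0L))
  ident <- make_cm(diag(3) * 1L)
  p2 <- pangenome_partition(ident)
  expect_equal(unname(p2$counts), c(0L, 0L, 3L))
  # presence counts {3,3,2,2,1,1} over 3 samples -> core 2, shell 2, cloud 2
  m <- rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 0), c(0, 1, 1), c(1, 0, 0), c(0, 0, 1))
  p3 <- pangenome_partition(make_cm(m))
  expect_equal(unname(p3$counts), c(2L, 2L, 2L))
  expect_equal(unname(p3$pct), c(33.33, 33.33, 33.33))
  expect_error(pangenome_partition(allc, samples = character(0)), "non-empty")
  expect_error(pangenome_partition(allc, samples = "nope"), "unknown")
})

test_that("partition sets are disjoint, cover present clusters, report absents", {
  set.seed(11)
  for (r in 1:10) {
    m <- matrix(rbinom(40, 1, 0.4), 8, 5)
    cm <- make_cm(m)
    p <- pangenome_partition(cm)
    ids <- c(p$core, p$shell, p$cloud)
    expect_equal(anyDuplicated(ids), 0)
    expect_equal(length(ids) + p$n_absent, 8)
    expect_setequal(ids, rownames(m <- cm$counts)[rowSums(m >= 1) > 0])
  }
})

test_that("partition recovers the planted categories exactly", {
  cfg <- sim_config(seed = 21, n_clusters = 500)
  pan <- simulate_pangenome(cfg)
  p <- pangenome_partition(pan$clusters)
  truth <- split(pan$truth$cluster_id, pan$truth$category)
  expect_setequal(p$core, truth$core)
  expect_setequal(p$shell, truth$shell)
  expect_setequal(p$cloud, truth$cloud)
})

test_that("pan_overlap enumerates regions whose counts reconstruct the sets", {
  r <- pan_overlap(list(A = 1:3, B = 4:6))
  expect_equal(unname(r[c("A", "B", "A&B")]), c(3L, 3L, 0L))
  r2 <- pan_overlap(list(A = 1:3, B = 1:3))
  expect_equal(unname(r2[c("A", "B", "A&B")]), c(0L, 0L, 3L))
  r3 <- pan_overlap(list(A = c(1, 2, 3), B = c(2, 3, 4), C = 3))
  expect_equal(unname(r3[c("A", "B", "C", "A&B", "A&C", "B&C", "A&B&C")]),
               c(1L, 1L, 0L, 1L, 0L, 0L, 1L))
  expect_equal(sum(r3), 4L)  # |union|
  # region sums reconstruct each input set's cardinality
  set.seed(12)
  sets <- lapply(1:4, function(i) sample(1:30, sample(5:15, 1)))
  names(sets) <- LETTERS[1:4]
  r4 <- pan_overlap(sets)
  for (nm in names(sets)) {
    in_region <- grepl(paste0("(^|&)", nm, "(&|$)"), names(r4))
    expect_equal(sum(r4[in_region]), length(unique(sets[[nm]])))
  }
  expect_error(pan_overlap(list(a = 1)), "between 2 and 7")
  expect_error(pan_overlap(as.list(setNames(1:8, letters[1:8]))), "between 2 and 7")
})

test_that("consolidation merges variant suffixes and drops placeholders", {
  m <- matrix(c(1, 0, 0,
                0, 1, 0,
                0, 0, 1,
                1, 1, 0,
                0, 1, 1,
                1, 0, 0), 6, 3, byrow = TRUE)
  cm <- make_cm(m, gene = c("adhP_1", "adhP_2", "adhP_3", "group_42", "xerC", "abc_1_2"),
                ann = c("", "", "", "hypothetical protein", "recombinase", ""))
  out <- consolidate_clusters(cm)
  expect_setequal(out$gene_name, c("adhP", "xerC", "abc_1"))
  expect_equal(unname(out$counts["adhP", ]), c(1, 1, 1))  # merged by OR/sum
  expect_false("group_42" %in% out$gene_name)
  # unsuffixed names unchanged; only one suffix stripped
  expect_true("abc_1" %in% out$gene_name)
  # drop_hypothetical removes by annotation before merging
  cm2 <- make_cm(m[1:2, , drop = FALSE], gene = c("adhP_1", "adhP_2"),
                 ann = c("Hypothetical Protein", "alcohol dehydrogenase"))
  out2 <- consolidate_clusters(cm2, drop_hypothetical = TRUE)
  expect_equal(nrow(out2$counts), 1)
  expect_equal(unname(out2$counts["adhP", ]), c(0, 1, 0))
  # idempotence
  again <- consolidate_clusters(out)
  expect_equal(again$counts, out$counts)
  # merging never decreases a presence cell
  expect_true(all((out$counts["adhP", ] >= 1) >= (m[1, ] >= 1)))
  # synonym hook
  out3 <- consolidate_clusters(cm, synonym_map = c(xerC = "xerD"))
  expect_true("xerD" %in% out3$gene_name)
})

test_that("top_shared ranks by hand-summed totals and honours tissue subsets", {
  counts <- rbind(g1 = c(5, 5, 0, 0), g2 = c(9, 9, 9, 9), g3 = c(1, 0, 0, 0),
                  g4 = c(3, 3, 3, 3), g5 = c(0, 0, 2, 2))
  colnames(counts) <- c("AR", "BR", "AL", "BL")
  cm <- cluster_matrix(counts, cluster_id = rownames(counts),
                       gene_name = rownames(counts),
                       annotation = rep("", 5))
  meta <- data.frame(sample = c("AR", "BR", "AL", "BL"),
                     tissue = c("root", "root", "leaf", "leaf"))
  r <- top_shared(cm, meta, n = 5)
  expect_equal(r$ranking$gene, c("g2", "g4", "g1", "g5", "g3"))
  # shared among roots, absent from leaves: g1 only (g5 is leaf-only)
  rr <- suppressWarnings(top_shared(cm, meta, n = 5, shared_in = "root"))
  expect_equal(rr$ranking$gene, "g1")
  rl <- suppressWarnings(top_shared(cm, meta, n = 5, shared_in = "leaf"))
  expect_equal(rl$ranking$gene, "g5")
  expect_warning(top_shared(cm, meta, n = 50), "truncating")
  single <- cluster_matrix(matrix(3, 1, 2, dimnames = list("only", c("a", "b"))),
                           gene_name = "only", annotation = "")
  expect_equal(top_shared(single, n = 1)$ranking$rank, 1L)
})
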