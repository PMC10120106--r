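# Independent brute-force oracles, written as direct textbook sums so they
# share no code with the package implementations they check.

oracle_shannon <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  s <- 0
  for (pi in p) s <- s - pi * log(pi)
  s
}

oracle_simpson <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  s <- 0
  for (pi in p) s <- s + pi * pi
  1 - s
}

oracle_chao1 <- function(counts) {
  pos <- counts[counts > 0]
  f1 <- sum(pos == 1); f2 <- sum(pos == 2)
  length(pos) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_bray <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

# expected rarefied richness at depth d (hypergeometric closed form)
oracle_rarefaction <- function(counts, d) {
  N <- sum(counts)
  sum(vapply(counts, function(n) 1 - choose(N - n, d) / choose(N, d), numeric(1)))
}

# upper-tail hypergeometric by explicit sum
oracle_hyper_upper <- function(k, study_n, K, N) {
  js <- k:min(K, study_n)
  sum(choose(K, js) * choose(N - K, study_n - js)) / choose(N, study_n)
}

# Welch t-test from first principles
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# PERMANOVA pseudo-F computed directly from the definition
oracle_permanova_F <- function(D, groups) {
  N <- nrow(D)
  levs <- unique(groups)
  a <- length(levs)
  sst <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) sst <- sst + D[i, j]^2
  sst <- sst / N
  ssw <- 0
  for (lev in levs) {
    idx <- which(groups == lev)
    s <- 0
    if (length(idx) > 1) {
      for (ii in 1:(length(idx) - 1)) for (jj in (ii + 1):length(idx)) {
        s <- s + D[idx[ii], idx[jj]]^2
      }
    }
    ssw <- ssw + s / length(idx)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (N - a))
}

# all distinct 2-group assignments of sizes (n1, n2), as label vectors
oracle_two_group_assignments <- function(n1, n2) {
  N <- n1 + n2
  lapply(utils::combn(N, n1, simplify = FALSE), function(idx) {
    g <- rep("b", N); g[idx] <- "a"; g
  })
}

# a small ultrametric tree over the six genotypes, host topology
host_newick <- "((((BB:1,MB:1):1,MT:2):1,MS:3):1,(DC:3.5,FH:3.5):0.5);"

# quick builder for gene-tree-set entries from newick strings
tree_entry <- function(cluster_id, newick, gene_name = "genX") {
  list(cluster_id = cluster_id, gene_name = gene_name,
       tree = ape::read.tree(text = newick))
}
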