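# Uniform-random rooted binary topology on the given labels, by sequential
# leaf insertion: leaf k+1 is grafted onto one of the 2k-1 positions (2k-2
# edges plus the root stem) chosen uniformly, which makes all (2n-3)!!
# labeled rooted topologies equally likely. Returned as a newick string
# with ultrametric branch lengths (internal node heights grow by Exp(1)
# increments above their children), so UPGMA recovers the topology.
uniform_ultrametric_newick <- function(labels) {
  n <- length(labels)
  if (n == 1) return(paste0(labels, ":0;"))
  # nested-list tree: leaf = label string; internal = list(left, right)
  tree <- labels[1]
  count_edges <- function(t) if (is.character(t)) 1L else 1L + count_edges(t[[1]]) + count_edges(t[[2]])
  insert_at <- function(t, pos, leaf) {
    # pos 1 = the stem above t; then recurse left subtree edges, right
    if (pos == 1) return(list(list(t, leaf), 0L))
    pos <- pos - 1L
    nl <- count_edges(t[[1]])
    if (pos <= nl) {
      r <- insert_at(t[[1]], pos, leaf)
      return(list(list(r[[1]], t[[2]]), 0L))
    }
    r <- insert_at(t[[2]], pos - nl, leaf)
    list(list(t[[1]], r[[1]]), 0L)
  }
  for (k in 2:n) {
    n_pos <- if (is.character(tree)) 1L else count_edges(tree)
    pos <- sample.int(n_pos, 1)
    tree <- insert_at(tree, pos, labels[k])[[1]]
  }
  # heights: leaves 0, internal = max(children) + Exp(1)
  build <- function(t) {
    if (is.character(t)) return(list(nwk = t, h = 0))
    l <- build(t[[1]]); r <- build(t[[2]])
    h <- max(l$h, r$h) + stats::rexp(1)
    list(nwk = sprintf("(%s:%.10g,%s:%.10g)", l$nwk, h - l$h, r$nwk, h - r$h), h = h)
  }
  paste0(build(tree)$nwk, ";")
}

# Serialize the host tree replacing each genotype tip by an ultrametric
# coalescent subtree of `n_seq` strain leaves of fixed height `h_sub`, so
# the genotype-mean patristic distances equal the host cophenetic
# distances exactly.
host_shaped_newick <- function(host, tip_labels, n_seq, h_sub) {
  n_tip <- length(host$tip.label)
  kids <- split(host$edge[, 2], host$edge[, 1])
  elen <- stats::setNames(host$edge.length, host$edge[, 2])
  subtree_nwk <- function(labs, root_len) {
    if (length(labs) == 1) return(sprintf("%s:%.10g", labs, root_len))
    t <- ape::rcoal(length(labs))
    t$tip.label <- labs
    height <- max(ape::node.depth.edgelength(t))
    t$edge.length <- t$edge.length * (h_sub / height)
    sprintf("%s:%.10g", sub(";$", "", ape::write.tree(t)), root_len - h_sub)
  }
  build <- function(node) {
    if (node <= n_tip) {
      g <- host$tip.label[node]
      return(subtree_nwk(tip_labels[[g]], elen[[as.character(node)]]))
    }
    parts <- vapply(kids[[as.character(node)]], build, character(1))
    inner <- sprintf("(%s)", paste(parts, collapse = ","))
    root_edge <- elen[as.character(node)]
    if (is.na(root_edge)) inner else sprintf("%s:%.10g", inner, root_edge)
  }
  paste0(build(n_tip + 1L), ";")
}

#' Simulate per-cluster gene trees with a planted phylosymbiotic fraction
#'
#' Generates `n_clusters` rooted gene trees over
#' `genotypes x n_seq_per_genotype` strain sequences. A planted fraction
#' (`frac_phylosymbiotic`) of clusters carries the host signal: the tree
#' is the host topology with each genotype tip replaced by a random
#' coalescent subtree of `n_seq_per_genotype` strain leaves of equal
#' height, so at zero branch noise the genotype-mean patristic distances
#' equal the host cophenetic distances and the concordance screen
#' recovers the cluster with certainty. The remaining clusters are
#' non-phylosymbiotic: in `"permute"` mode the genotype labels of a
#' host-shaped tree are randomly shuffled across its leaves; in
#' `"uniform"` mode a uniform-random rooted topology (ultrametric, random
#' heights) is drawn instead. All branch lengths are finally perturbed by
#' multiplicative log-normal noise with sigma `branch_noise_sigma`. Leaf
#' labels follow the `genotype|cluster|strain` scheme; a fraction of
#' strain fields is `"unbinned"` (sequences without a taxonomic match).
#'
#' @param config A [sim_config()] object.
#' @param host_tree Rooted host phylo whose tip labels are exactly the
#'   configured genotype codes (default [musa_host_tree()]).
#' @param unbinned_prob Probability that a leaf's strain field is
#'   `"unbinned"` (default 0.46).
#' @return List with `trees` (a [gene_tree_set()]) and `truth`
#'   (data.frame `cluster_id`, `phylosymbiotic`).
#' @export
simulate_gene_trees <- function(config, host_tree = musa_host_tree(),
                                unbinned_prob = 0.46) {
  validate_sim_config(config)
  if (config$n_seq_per_genotype < 1) config_error("n_seq_per_genotype must be >= 1")
  if (!setequal(host_tree$tip.label, config$genotypes)) {
    data_error("host tree leaves must be exactly the configured genotype codes")
  }
  local_seed(sub_seed(config$seed, .SIM_STREAM[["trees"]]), {
    n <- config$n_clusters
    n_seq <- config$n_seq_per_genotype
    genotypes <- host_tree$tip.label
    tip_edges <- host_tree$edge.length[host_tree$edge[, 2] <= length(genotypes)]
    h_sub <- 0.5 * min(tip_edges)
    n_phy <- round(config$frac_phylosymbiotic * n)
    phy <- rep(FALSE, n)
    if (n_phy > 0) phy[sample.int(n, n_phy)] <- TRUE
    taxa_pool <- sprintf("t%05d", seq_len(3L * config$n_taxa_pool))
    symbols <- sim_gene_symbol_pool(64)

    entries <- vector("list", n)
    for (i in seq_len(n)) {
      cid <- sprintf("tcl%05d", i)
      strain_of <- function(m) {
        ifelse(stats::runif(m) < unbinned_prob, "unbinned",
               sample(taxa_pool, m, replace = TRUE))
      }
      labels_for <- function(genos) {
        sprintf("%s|%s|%s", genos, cid, strain_of(length(genos)))
      }
      if (phy[i] || config$null_tree_mode == "permute") {
        tip_labels <- lapply(genotypes, function(g) labels_for(rep(g, n_seq)))
        names(tip_labels) <- genotypes
        nwk <- host_shaped_newick(host_tree, tip_labels, n_seq, h_sub)
        tree <- ape::read.tree(text = nwk)
        if (!phy[i]) {
          # null cluster: shuffle the genotype fields across all leaves
          info <- parse_leaf_labels(tree$tip.label)
          tree$tip.label <- sprintf("%s|%s|%s", sample(info$genotype),
                                    info$sample, info$strain)
        }
      } else {
        genos <- rep(genotypes, each = n_seq)
        nwk <- uniform_ultrametric_newick(labels_for(genos))
        tree <- ape::read.tree(text = nwk)
      }
      if (config$branch_noise_sigma > 0) {
        tree$edge.length <- tree$edge.length *
          stats::rlnorm(length(tree$edge.length), 0, config$branch_noise_sigma)
      }
      gene <- if (stats::runif(1) < 0.1) {
        sprintf("group_%d", i)
      } else {
        sample(symbols, 1)
      }
      entries[[i]] <- list(cluster_id = cid, gene_name = gene, tree = tree)
    }
    list(trees = gene_tree_set(entries),
         truth = data.frame(cluster_id = sprintf("tcl%05d", seq_len(n)),
                            phylosymbiotic = phy, stringsAsFactors = FALSE))
  })
}
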