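#' Parse the genotype/sample/strain components of gene-tree leaf labels
#'
#' Gene-tree leaves are labelled `genotype|sample|strain`; the strain
#' field holds the taxon bin of the source sequence, or `"unbinned"` when
#' the sequence had no taxonomic match.
#'
#' @param labels Character vector of leaf labels.
#' @return data.frame with columns `label`, `genotype`, `sample`, `strain`.
#' @export
parse_leaf_labels <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) {
    data_error(paste("malformed leaf label(s):",
                     paste(utils::head(labels[bad], 5), collapse = ", ")))
  }
  m <- do.call(rbind, parts)
  data.frame(label = labels, genotype = m[, 1], sample = m[, 2],
             strain = m[, 3], stringsAsFactors = FALSE)
}

#' Mean patristic distances between host genotypes on a gene tree
#'
#' Reduces a multi-copy gene tree to a genotype-level distance matrix:
#' entry (g, h) is the mean patristic (sum of branch lengths along the
#' path) distance over all leaf pairs with one leaf from genotype g and
#' one from genotype h. The diagonal is zero and the matrix is symmetric.
#'
#' @param tree An `ape` phylo object with branch lengths.
#' @param leaf_genotype Named character vector mapping each tip label to a
#'   genotype code; by default parsed from `genotype|sample|strain` labels.
#' @return Symmetric genotype x genotype numeric matrix.
#' @export
genotype_distances <- function(tree, leaf_genotype = NULL) {
  if (is.null(leaf_genotype)) {
    info <- parse_leaf_labels(tree$tip.label)
    leaf_genotype <- stats::setNames(info$genotype, info$label)
  }
  missing <- setdiff(tree$tip.label, names(leaf_genotype))
  if (length(missing) > 0) {
    data_error(paste("no genotype mapping for tip(s):",
                     paste(utils::head(missing, 5), collapse = ", ")))
  }
  if (is.null(tree$edge.length)) data_error("tree has no branch lengths")
  P <- ape::cophenetic.phylo(tree)
  if (max(P) <= 0) data_error("degenerate tree: all patristic distances zero")
  geno <- leaf_genotype[rownames(P)]
  gs <- sort(unique(geno))
  # group means over leaf pairs: average rows then columns by genotype
  agg <- rowsum(P, geno) / as.vector(table(geno)[sort(unique(geno))])
  agg <- t(rowsum(t(agg), geno) / as.vector(table(geno)[sort(unique(geno))]))
  D <- as.matrix(agg)[gs, gs]
  diag(D) <- 0
  (D + t(D)) / 2
}

#' UPGMA dendrogram with a deterministic tie-break
#'
#' Average-linkage agglomerative clustering of a distance matrix. At each
#' step the pair of clusters at minimum average distance is merged at
#' height d/2; among exactly tied pairs, the pair whose (lexicographically
#' smallest member, then second member) sorts first is chosen, making the
#' dendrogram deterministic on degenerate inputs. On an ultrametric input
#' the source topology and heights are recovered exactly.
#'
#' @param D Symmetric non-negative matrix with zero diagonal and labels.
#' @return Object of class `upgma_tree`: `labels`, `heights` (merge
#'   heights), `clades` (list of member-label sets, one per internal
#'   node, root last), and `newick` (with branch lengths from heights).
#' @examples
#' D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(D)$newick  # ((A,B),C) shape
#' @export
upgma <- function(D) {
  D <- as.matrix(D)
  if (any(is.na(D))) data_error("distance matrix contains NA")
  D <- check_distance_matrix(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(D)))
  n <- nrow(D)
  members <- as.list(labels)           # label sets per active cluster
  sizes <- rep(1L, n)
  nwk <- labels                        # newick fragment per active cluster
  height <- rep(0, n)                  # height of each active cluster's root
  active <- seq_len(n)
  d <- D
  clades <- list()
  merge_heights <- numeric(0)

  rep_key <- function(i) sort(members[[i]])[1]
  while (length(active) > 1) {
    best <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        i <- active[ii]; j <- active[jj]
        dij <- d[i, j]
        key <- sort(c(rep_key(i), rep_key(j)))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    k <- length(members) + 1
    members[[k]] <- sort(c(members[[i]], members[[j]]))
    sizes[k] <- sizes[i] + sizes[j]
    nwk[k] <- sprintf("(%s:%.10g,%s:%.10g)",
                      nwk[i], h - height[i], nwk[j], h - height[j])
    height[k] <- h
    clades[[length(clades) + 1]] <- members[[k]]
    merge_heights <- c(merge_heights, h)
    # average linkage update (weighted by cluster sizes = UPGMA)
    d <- rbind(cbind(d, 0), 0)
    for (m in setdiff(active, c(i, j))) {
      d[k, m] <- d[m, k] <- (sizes[i] * d[i, m] + sizes[j] * d[j, m]) / sizes[k]
    }
    active <- c(setdiff(active, c(i, j)), k)
  }
  structure(list(labels = labels, heights = merge_heights, clades = clades,
                 newick = paste0(nwk[length(nwk)], ";")),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, root height %.4g\n",
              length(x$labels), max(x$heights)))
  cat(" ", x$newick, "\n")
  invisible(x)
}

# All internal-node clades of a rooted phylo, as sorted label sets.
phylo_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    sort(unlist(lapply(kids[[as.character(node)]], below)))
  }
  internal <- sort(unique(tree$edge[, 1]))
  lapply(internal, below)
}
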