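#' Gene tree set container
#'
#' A list of per-cluster gene trees with their metadata: each entry has
#' `cluster_id`, `gene_name`, `tree` (an `ape` phylo with
#' `genotype|sample|strain` tip labels).
#'
#' @param entries List of entries as above.
#' @return Object of class `gene_tree_set`.
#' @export
gene_tree_set <- function(entries) {
  ids <- vapply(entries, `[[`, character(1), "cluster_id")
  if (anyDuplicated(ids)) data_error("duplicate cluster ids in gene tree set")
  structure(entries, class = "gene_tree_set", names = ids)
}

#' @export
print.gene_tree_set <- function(x, ...) {
  cat(sprintf("<gene_tree_set> %d clusters\n", length(x)))
  invisible(x)
}

#' Default host phylogeny for the six banana genotypes
#'
#' The rooted ultrametric host topology
#' `((((BB,MB),MT),MS),(DC,FH))` relating the six *Musa* genotypes: the
#' two *M. balbisiana* accessions (BB, MB) are sisters, *M. textilis*
#' (MT) joins them, *M. sikkimensis* (MS) is next, and the cultivated
#' Dwarf Cavendish (DC) and FHIA-25 (FH) form the other side of the
#' root.
#'
#' @return An `ape` phylo object.
#' @export
musa_host_tree <- function() {
  ape::read.tree(text = "((((BB:1,MB:1):1,MT:2):1,MS:3):1,(DC:3.5,FH:3.5):0.5);")
}

#' Host reference for concordance screening
#'
#' Wraps a rooted host tree and the clade sets a concordant gene tree
#' must reproduce. By default the required clades are derived from the
#' host tree itself: every internal clade of 2 or 3 genotypes (excluding
#' the full leaf set). For [musa_host_tree()] this yields `{BB,MB}`,
#' `{BB,MB,MT}` and `{DC,FH}`.
#'
#' @param tree Rooted host phylo over genotype codes.
#' @param required_clades Optional list of character vectors overriding
#'   the derived clades.
#' @return Object of class `host_reference` with `tree`, `genotypes`,
#'   `required_clades`.
#' @export
host_reference <- function(tree = musa_host_tree(), required_clades = NULL) {
  genotypes <- sort(tree$tip.label)
  if (is.null(required_clades)) {
    all_clades <- phylo_clades(tree)
    required_clades <- Filter(function(cl) {
      length(cl) >= 2 && length(cl) <= 3 && length(cl) < length(genotypes)
    }, all_clades)
  }
  required_clades <- lapply(required_clades, sort)
  bad <- vapply(required_clades,
                function(cl) !all(cl %in% genotypes) || length(cl) >= length(genotypes),
                logical(1))
  if (any(bad)) data_error("required clades must be proper subsets of the host genotypes")
  structure(list(tree = tree, genotypes = genotypes,
                 required_clades = required_clades),
            class = "host_reference")
}

#' @export
print.host_reference <- function(x, ...) {
  cat("<host_reference>", length(x$genotypes), "genotypes:",
      paste(x$genotypes, collapse = ", "), "\n")
  for (cl in x$required_clades) {
    cat("  required clade: {", paste(cl, collapse = ","), "}\n")
  }
  invisible(x)
}

#' Gene trees containing every host genotype
#'
#' Restricts a gene tree set to the clusters eligible for the
#' concordance screen: those retaining at least one leaf for every
#' listed genotype.
#'
#' @param trees A [gene_tree_set()].
#' @param genotypes Character vector of genotype codes.
#' @return The eligible subset, still a `gene_tree_set`.
#' @export
eligible_clusters <- function(trees, genotypes) {
  if (length(genotypes) == 0) data_error("genotype list must be non-empty")
  keep <- vapply(trees, function(e) {
    g <- parse_leaf_labels(e$tree$tip.label)$genotype
    all(genotypes %in% g)
  }, logical(1))
  gene_tree_set(unclass(trees)[keep])
}

#' Does a dendrogram reproduce the host clades?
#'
#' TRUE iff every required clade of the host reference appears as an
#' exact monophyletic clade of the genotype dendrogram. A per-clade
#' verdict is attached for auditing.
#'
#' @param dend A [upgma()] result or a rooted phylo over genotype codes.
#' @param host_ref A [host_reference()].
#' @return Logical scalar with attribute `clades` (named logical, one per
#'   required clade).
#' @export
matches_host <- function(dend, host_ref) {
  clades <- if (inherits(dend, "upgma_tree")) {
    dend$clades
  } else {
    phylo_clades(dend)
  }
  leaves <- if (inherits(dend, "upgma_tree")) dend$labels else dend$tip.label
  missing <- setdiff(unlist(host_ref$required_clades), leaves)
  if (length(missing) > 0) {
    data_error(paste("dendrogram is missing genotype(s):",
                     paste(missing, collapse = ", ")))
  }
  keys <- vapply(clades, paste, character(1), collapse = "|")
  per <- vapply(host_ref$required_clades, function(cl) {
    paste(sort(cl), collapse = "|") %in% keys
  }, logical(1))
  names(per) <- vapply(host_ref$required_clades, paste, character(1), collapse = ",")
  structure(all(per), clades = per)
}

#' Screen gene trees for phylosymbiosis with the host phylogeny
#'
#' For every eligible cluster (all host genotypes represented) the screen
#' computes genotype-mean patristic distances, builds a UPGMA genotype
#' dendrogram, and tests whether it reproduces every required host clade
#' ([matches_host()]). The report tallies matched clusters, their leaf
#' taxa (strain bins, with `"unbinned"` counted separately), gene names,
#' and host-genotype x taxon x gene triple counts ready for a Sankey
#' diagram.
#'
#' @param trees A [gene_tree_set()].
#' @param host_ref A [host_reference()].
#' @return Object of class `screen_report`: counts
#'   (`n_clusters_total`, `n_eligible`, `n_matched`), `fraction_matched`
#'   (percent of eligible, 1 decimal), `matched_ids`, `per_cluster`
#'   (data.frame with the per-clade verdicts), `taxon_tally`,
#'   `gene_tally`, `triples` (data.frame genotype/taxon/gene/count).
#' @export
screen_phylosymbiosis <- function(trees, host_ref) {
  elig <- eligible_clusters(trees, host_ref$genotypes)
  verdicts <- logical(length(elig))
  clade_mat <- matrix(NA, nrow = length(elig),
                      ncol = length(host_ref$required_clades))
  for (i in seq_along(elig)) {
    e <- elig[[i]]
    res <- tryCatch({
      D <- genotype_distances(e$tree)
      matches_host(upgma(D), host_ref)
    }, error = function(err) {
      data_error(sprintf("cluster %s: %s", e$cluster_id, conditionMessage(err)))
    })
    verdicts[i] <- as.logical(res)
    clade_mat[i, ] <- attr(res, "clades")
  }
  matched_ids <- names(elig)[verdicts]

  taxon_tally <- integer(0)
  gene_tally <- integer(0)
  triples <- data.frame(genotype = character(0), taxon = character(0),
                        gene = character(0), count = integer(0),
                        stringsAsFactors = FALSE)
  if (length(matched_ids) > 0) {
    rows <- do.call(rbind, lapply(unclass(elig)[matched_ids], function(e) {
      info <- parse_leaf_labels(e$tree$tip.label)
      info$gene <- e$gene_name
      info
    }))
    tt <- table(rows$strain)
    taxon_tally <- stats::setNames(as.integer(tt), names(tt))
    gt <- table(rows$gene)
    gene_tally <- stats::setNames(as.integer(gt), names(gt))
    agg <- stats::aggregate(list(count = rep(1L, nrow(rows))),
                            by = list(genotype = rows$genotype,
                                      taxon = rows$strain, gene = rows$gene),
                            FUN = sum)
    triples <- agg[order(-agg$count, agg$genotype, agg$taxon, agg$gene), ]
    rownames(triples) <- NULL
  }
  per_cluster <- data.frame(
    cluster_id = names(elig),
    matched = verdicts,
    stringsAsFactors = FALSE
  )
  if (length(elig) > 0) {
    colnames(clade_mat) <- vapply(host_ref$required_clades, paste,
                                  character(1), collapse = ",")
    per_cluster <- cbind(per_cluster, as.data.frame(clade_mat))
  }
  structure(list(
    n_clusters_total = length(trees),
    n_eligible = length(elig),
    n_matched = length(matched_ids),
    fraction_matched = if (length(elig) > 0) {
      fmt_percent(length(matched_ids), length(elig), 1)
    } else {
      NA_real_
    },
    matched_ids = matched_ids,
    per_cluster = per_cluster,
    taxon_tally = taxon_tally,
    gene_tally = gene_tally,
    triples = triples
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d clusters, %d eligible, %d matched (%.1f%%)\n",
              x$n_clusters_total, x$n_eligible, x$n_matched,
              ifelse(is.na(x$fraction_matched), 0, x$fraction_matched)))
  if (length(x$taxon_tally) > 0) {
    top <- utils::head(sort(x$taxon_tally, decreasing = TRUE), 5)
    cat("  top taxa:", paste(sprintf("%s (%d)", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}
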