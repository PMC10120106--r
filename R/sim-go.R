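#' Simulate a GO universe with planted enrichment
#'
#' Builds a random rooted DAG of `n_go_terms` terms: term depths cycle
#' through `1..go_depth` and every non-root term draws 1-2 `is_a` parents
#' from strictly shallower terms, so every term reaches the root. Each of
#' the `n_genes` genes is annotated directly to exactly one childless
#' ("leaf-ish") term chosen uniformly, so specific terms only share genes
#' through their common ancestors; planted terms are drawn among terms
#' with at least `min(genes_per_term, 20)` annotated genes.
#' A study set of `round(study_fraction * n)` genes is then sampled
#' without replacement with sampling weight `enrichment_odds` for genes
#' annotated to any of the `n_enriched_terms` planted terms and weight 1
#' otherwise; with `enrichment_odds = 1` the study set is a uniform draw
#' and planted terms carry no signal.
#'
#' @param config A [sim_config()] object.
#' @return List with `universe` (an unpropagated [go_universe()]),
#'   `study_genes` (character), and `truth` (list with
#'   `enriched_terms`).
#' @export
simulate_go <- function(config) {
  validate_sim_config(config)
  if (config$go_depth < 1) config_error("go_depth must be >= 1")
  local_seed(sub_seed(config$seed, .SIM_STREAM[["go"]]), {
    n <- config$n_go_terms
    ids <- sprintf("GO:%07d", seq_len(n))
    depth <- c(0L, rep(seq_len(config$go_depth), length.out = n - 1))
    depth <- sort(depth)  # ids ordered shallow -> deep
    parents <- vector("list", n)
    names(parents) <- ids
    parents[[1]] <- character(0)
    for (i in seq(2, n)) {
      shallower <- ids[depth < depth[i]]
      k <- min(length(shallower), sample(1:2, 1))
      parents[[i]] <- sample(shallower, k)
    }
    has_child <- ids %in% unlist(parents)
    leafish <- ids[!has_child]
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    # each gene is directly annotated to exactly one most-specific term, so
    # leaf-level annotation sets are disjoint (terms only share genes
    # through their common ancestors)
    gene_term <- sample(leafish, length(genes), replace = TRUE)
    term2genes <- split(genes, gene_term)
    gene2terms <- as.list(stats::setNames(gene_term, genes))
    universe_genes <- sort(genes)

    # plant enrichment in well-populated terms (the signal must be
    # carried by enough genes to be recoverable)
    big <- names(term2genes)[lengths(term2genes) >=
                               min(config$genes_per_term, 20)]
    if (length(big) < config$n_enriched_terms) {
      big <- names(sort(lengths(term2genes), decreasing = TRUE))
    }
    enriched <- sort(sample(big, min(config$n_enriched_terms, length(big))))
    in_planted <- universe_genes %in% unlist(term2genes[enriched])
    w <- ifelse(in_planted, config$enrichment_odds, 1)
    study_n <- max(1L, round(config$study_fraction * length(universe_genes)))
    study <- sample(universe_genes, study_n, prob = w)

    u <- go_universe(
      parents = parents,
      name = stats::setNames(paste("term", seq_len(n)), ids),
      namespace = stats::setNames(rep("biological_process", n), ids),
      gene2terms = gene2terms
    )
    list(universe = u, study_genes = sort(study),
         truth = list(enriched_terms = enriched))
  })
}
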