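#' Gene Ontology universe
#'
#' Bundles an `is_a` DAG with a gene-to-term annotation map. The DAG is
#' validated to be acyclic at construction (a cycle raises an error
#' naming one of its members), and every annotated term must exist in
#' the DAG.
#'
#' @param parents Named list: term id -> character vector of `is_a`
#'   parent term ids (roots have `character(0)`).
#' @param name,namespace Optional named character vectors of term names
#'   and namespaces.
#' @param gene2terms Named list: gene symbol -> character vector of
#'   directly annotated term ids.
#' @return Object of class `go_universe` with fields `terms`, `parents`,
#'   `children`, `depth` (longest path to a root), `gene2terms`,
#'   `universe_genes`, `ann` (term -> genes, `NULL` until
#'   [propagate_annotations()]), `propagated`.
#' @export
go_universe <- function(parents, name = NULL, namespace = NULL,
                        gene2terms = list()) {
  terms <- names(parents)
  if (is.null(terms)) data_error("parents must be a named list of terms")
  unknown_parents <- setdiff(unlist(parents), terms)
  if (length(unknown_parents) > 0) {
    data_error(paste("is_a parents not defined as terms:",
                     paste(utils::head(unknown_parents, 5), collapse = ", ")))
  }
  depth <- dag_depth(parents)  # also detects cycles
  bad_terms <- setdiff(unlist(gene2terms), terms)
  if (length(bad_terms) > 0) {
    data_error(paste("annotated term(s) absent from DAG:",
                     paste(utils::head(bad_terms, 5), collapse = ", ")))
  }
  children <- split(
    rep(names(parents), lengths(parents)),
    unlist(parents)
  )
  structure(list(
    terms = terms, parents = parents, children = children, depth = depth,
    name = name, namespace = namespace,
    gene2terms = gene2terms, universe_genes = sort(names(gene2terms)),
    ann = NULL, propagated = FALSE
  ), class = "go_universe")
}

#' @export
print.go_universe <- function(x, ...) {
  cat(sprintf("<go_universe> %d terms (max depth %d), %d annotated genes%s\n",
              length(x$terms), max(x$depth), length(x$universe_genes),
              if (x$propagated) ", propagated" else ""))
  invisible(x)
}

# Longest-path-to-root depth per term; errors on a cycle, naming a member.
dag_depth <- function(parents) {
  terms <- names(parents)
  depth <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  visiting <- stats::setNames(rep(FALSE, length(terms)), terms)
  visit <- function(t) {
    if (!is.na(depth[[t]])) return(depth[[t]])
    if (visiting[[t]]) data_error(paste("cycle in is_a graph involving term", t))
    visiting[[t]] <<- TRUE
    p <- parents[[t]]
    d <- if (length(p) == 0) 0L else max(vapply(p, visit, integer(1))) + 1L
    visiting[[t]] <<- FALSE
    depth[[t]] <<- d
    d
  }
  for (t in terms) visit(t)
  depth
}

# All ancestors (transitive is_a closure, excluding the term itself).
term_ancestors <- function(universe, term) {
  out <- character(0)
  frontier <- universe$parents[[term]]
  while (length(frontier) > 0) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(universe$parents[frontier])), out)
  }
  out
}

#' Apply the true-path rule over the DAG
#'
#' Closes the term annotation sets under ancestry: a gene directly
#' annotated to a term is annotated to all its ancestors. Gene sets are
#' proper sets, so a gene reaching an ancestor through two paths (a
#' diamond) is counted once.
#'
#' @param universe A [go_universe()].
#' @return The universe with `ann` populated (term -> sorted gene
#'   vector) and `propagated = TRUE`.
#' @export
propagate_annotations <- function(universe) {
  stopifnot(inherits(universe, "go_universe"))
  ann <- stats::setNames(vector("list", length(universe$terms)), universe$terms)
  for (t in universe$terms) ann[[t]] <- character(0)
  for (g in names(universe$gene2terms)) {
    direct <- unique(universe$gene2terms[[g]])
    hit <- unique(c(direct, unlist(lapply(direct, term_ancestors,
                                          universe = universe))))
    for (t in hit) ann[[t]] <- c(ann[[t]], g)
  }
  universe$ann <- lapply(ann, function(v) sort(unique(v)))
  universe$propagated <- TRUE
  universe
}

#' Upper-tail hypergeometric p-value for one term
#'
#' `P(X >= k)` for `X ~ Hypergeometric(universe_N, K, study_n)`: the
#' chance of seeing at least `k` study genes annotated to a term with
#' `K` annotated genes in a universe of `universe_N`, when `study_n`
#' genes are drawn.
#'
#' @param k Annotated genes in the study set.
#' @param study_n Study set size.
#' @param K Annotated genes in the universe.
#' @param universe_N Universe size.
#' @return p-value in (0, 1].
#' @export
fisher_term <- function(k, study_n, K, universe_N) {
  if (k < 0 || K < 0 || study_n < 0 || universe_N < 0 ||
      k > min(study_n, K) || K > universe_N || study_n > universe_N) {
    data_error("inconsistent counts for hypergeometric test")
  }
  stats::phyper(k - 1, m = K, n = universe_N - K, k = study_n,
                lower.tail = FALSE)
}

#' GO term enrichment with optional elim decorrelation
#'
#' Tests every term for over-representation of study genes with the
#' upper-tail hypergeometric test ([fisher_term()]). `algorithm =
#' "classic"` tests each term independently on the propagated
#' annotation sets. `algorithm = "elim"` decorrelates the DAG: terms are
#' processed in order of decreasing depth (longest path to the root;
#' ties in lexicographic term order), and whenever a term's current
#' p-value falls below `alpha_elim` its currently annotated genes are
#' removed from the annotation sets of all its ancestors before those
#' are tested. This concentrates signal in the most specific terms and
#' yields approximately decorrelated p-values, so no multiple-testing
#' correction is applied by default.
#'
#' @param study_genes Character vector of study gene symbols; genes
#'   absent from the universe are dropped with a warning.
#' @param universe A [go_universe()]; propagated automatically if needed.
#' @param algorithm `"elim"` (default) or `"classic"`.
#' @param alpha_elim Elimination threshold (default 0.01).
#' @return data.frame with one row per term with at least one annotated
#'   gene: `term`, `name`, `K` (annotated in universe), `k` (annotated
#'   in study), `expected`, `p_classic`, `p_decorrelated`; sorted by
#'   `p_decorrelated` then term id. For `"classic"`, `p_decorrelated`
#'   equals `p_classic`.
#' @export
go_enrich <- function(study_genes, universe, algorithm = c("elim", "classic"),
                      alpha_elim = 0.01) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(universe, "go_universe"))
  if (!universe$propagated) universe <- propagate_annotations(universe)
  absent <- setdiff(study_genes, universe$universe_genes)
  if (length(absent) > 0) {
    warning(sprintf("%d study gene(s) absent from the universe were dropped: %s",
                    length(absent),
                    paste(utils::head(absent, 5), collapse = ", ")))
    study_genes <- intersect(study_genes, universe$universe_genes)
  }
  study_genes <- unique(study_genes)
  N <- length(universe$universe_genes)
  n_study <- length(study_genes)
  terms <- universe$terms[vapply(universe$ann[universe$terms], length, integer(1)) > 0]

  p_classic <- vapply(terms, function(t) {
    K <- length(universe$ann[[t]])
    k <- sum(study_genes %in% universe$ann[[t]])
    fisher_term(k, n_study, K, N)
  }, numeric(1))

  if (algorithm == "elim") {
    current <- universe$ann
    ord <- terms[order(-universe$depth[terms], terms)]
    p_elim <- stats::setNames(numeric(length(terms)), terms)
    for (t in ord) {
      genes_t <- current[[t]]
      K <- length(genes_t)
      k <- sum(study_genes %in% genes_t)
      p <- if (K == 0) 1 else fisher_term(k, n_study, K, N)
      p_elim[[t]] <- p
      if (p < alpha_elim && K > 0) {
        for (a in term_ancestors(universe, t)) {
          current[[a]] <- setdiff(current[[a]], genes_t)
        }
      }
    }
  } else {
    p_elim <- p_classic
  }

  K_all <- vapply(universe$ann[terms], length, integer(1))
  k_all <- vapply(terms, function(t) sum(study_genes %in% universe$ann[[t]]),
                  integer(1))
  out <- data.frame(
    term = terms,
    name = if (!is.null(universe$name)) unname(universe$name[terms]) else NA_character_,
    K = K_all, k = k_all,
    expected = n_study * K_all / N,
    p_classic = unname(p_classic),
    p_decorrelated = unname(p_elim[terms]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_decorrelated, out$term), ]
  rownames(out) <- NULL
  out
}

#' Merge gene-to-GO mapping tables into one universe
#'
#' Unions `(gene, term)` pair tables from several sources into a single
#' curated mapping: gene symbols are keyed case-insensitively (the first
#' seen spelling is kept), synonyms are rewritten first through the
#' optional user map, pairs whose term is absent from the DAG are
#' dropped with a warning count, and a per-source provenance count is
#' retained.
#'
#' @param tables List of data.frames with columns `gene` and `term`.
#' @param parents DAG parent list (as for [go_universe()]).
#' @param synonym_map Optional named character vector mapping alternate
#'   gene symbols to canonical ones.
#' @param name,namespace Passed through to [go_universe()].
#' @return A [go_universe()] with attribute `provenance` (pairs kept per
#'   source table).
#' @export
merge_mappings <- function(tables, parents, synonym_map = NULL,
                           name = NULL, namespace = NULL) {
  if (is.null(names(tables))) names(tables) <- paste0("source", seq_along(tables))
  canon <- character(0)  # lowercase -> first-seen spelling
  pairs <- list()
  provenance <- stats::setNames(integer(length(tables)), names(tables))
  dropped <- 0L
  for (src in names(tables)) {
    tab <- tables[[src]]
    gene <- as.character(tab$gene)
    if (!is.null(synonym_map)) {
      hit <- gene %in% names(synonym_map)
      gene[hit] <- unname(synonym_map[gene[hit]])
    }
    term <- as.character(tab$term)
    ok <- term %in% names(parents)
    dropped <- dropped + sum(!ok)
    gene <- gene[ok]; term <- term[ok]
    key <- tolower(gene)
    new <- !(key %in% names(canon))
    canon[key[new]] <- gene[new]
    pairs[[src]] <- unique(data.frame(gene = unname(canon[key]), term = term,
                                      stringsAsFactors = FALSE))
    provenance[[src]] <- nrow(pairs[[src]])
  }
  if (dropped > 0) {
    warning(sprintf("%d mapping pair(s) dropped: term absent from DAG", dropped))
  }
  all_pairs <- unique(do.call(rbind, pairs))
  gene2terms <- if (nrow(all_pairs) > 0) {
    split(all_pairs$term, all_pairs$gene)
  } else {
    list()
  }
  u <- go_universe(parents, name = name, namespace = namespace,
                   gene2terms = gene2terms)
  attr(u, "provenance") <- provenance
  u
}
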