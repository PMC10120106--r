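#' Configuration for the synthetic endosphere study generator
#'
#' Collects every tunable of the synthetic-data module in one validated
#' object. Defaults describe a sympatric multi-genotype endosphere study:
#' six host genotypes sampled in paired leaf and root tissue, leaf
#' communities drawn as subsets of their paired root communities, a
#' pangenome dominated by unannotated ("hypothetical protein") clusters,
#' a handful of planted enriched GO terms, and a small planted fraction of
#' gene trees whose topology mirrors the host phylogeny.
#'
#' @param seed Integer; fully determines every simulated output.
#' @param genotypes Character vector of genotype codes (default the six
#'   banana genotypes `BB, MB, MT, MS, DC, FH`).
#' @param tissues Length-2 character vector, leaf then root.
#' @param n_taxa_pool Size of the per-sample root taxon pool.
#' @param root_leaf_richness_ratio Fraction in (0, 1]: each leaf pool is a
#'   subset of its paired root pool of size `ceiling(ratio * n_taxa_pool)`.
#' @param core_taxon_fraction Fraction of the global pool forced into every
#'   sample (the core community).
#' @param abundance_lognormal_mu,abundance_lognormal_sigma Log-normal
#'   parameters for relative taxon abundances before renormalization.
#' @param depth_per_sample Reads drawn per sample (multinomial depth).
#' @param n_clusters Number of ortholog gene clusters.
#' @param target_core_shell_cloud Length-3 fractions (core, shell, cloud)
#'   summing to 1; clusters are assigned to categories in these exact
#'   proportions.
#' @param hypothetical_fraction Fraction of clusters named `group_k` and
#'   annotated "hypothetical protein" (default 0.62).
#' @param n_genes Number of genes in the GO universe.
#' @param n_go_terms,go_depth Size and depth of the simulated GO DAG.
#' @param genes_per_term Mean genes directly annotated per leaf-ish term.
#' @param n_enriched_terms,enrichment_odds Planted enrichment signal: number
#'   of terms whose genes are over-represented in the study set, and the
#'   odds multiplier applied to them.
#' @param study_fraction Fraction of the gene universe sampled into the
#'   study set.
#' @param n_seq_per_genotype Strain sequences per genotype in each gene tree.
#' @param frac_phylosymbiotic Fraction of gene trees planted with the host
#'   topology.
#' @param branch_noise_sigma Multiplicative log-normal branch-length noise
#'   (sigma, >= 0) applied to gene trees.
#' @param null_tree_mode `"permute"` (genotype labels shuffled on a
#'   host-shaped tree) or `"uniform"` (uniform-random rooted topology) for
#'   non-phylosymbiotic trees.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$genotypes
#' @export
sim_config <- function(seed = 1L,
                       genotypes = c("BB", "MB", "MT", "MS", "DC", "FH"),
                       tissues = c("L", "R"),
                       n_taxa_pool = 400L,
                       root_leaf_richness_ratio = 0.3,
                       core_taxon_fraction = 0.05,
                       abundance_lognormal_mu = 0,
                       abundance_lognormal_sigma = 1.5,
                       depth_per_sample = 50000L,
                       n_clusters = 2000L,
                       target_core_shell_cloud = c(0.014, 0.39, 0.596),
                       hypothetical_fraction = 0.62,
                       n_genes = 2000L,
                       n_go_terms = 150L,
                       go_depth = 5L,
                       genes_per_term = 30L,
                       n_enriched_terms = 5L,
                       enrichment_odds = 5,
                       study_fraction = 0.15,
                       n_seq_per_genotype = 3L,
                       frac_phylosymbiotic = 0.054,
                       branch_noise_sigma = 0.1,
                       null_tree_mode = c("permute", "uniform")) {
  null_tree_mode <- match.arg(null_tree_mode)
  cfg <- list(
    seed = as.integer(seed),
    genotypes = as.character(genotypes),
    tissues = as.character(tissues),
    n_taxa_pool = as.integer(n_taxa_pool),
    root_leaf_richness_ratio = root_leaf_richness_ratio,
    core_taxon_fraction = core_taxon_fraction,
    abundance_lognormal_mu = abundance_lognormal_mu,
    abundance_lognormal_sigma = abundance_lognormal_sigma,
    depth_per_sample = as.integer(depth_per_sample),
    n_clusters = as.integer(n_clusters),
    target_core_shell_cloud = as.numeric(target_core_shell_cloud),
    hypothetical_fraction = hypothetical_fraction,
    n_genes = as.integer(n_genes),
    n_go_terms = as.integer(n_go_terms),
    go_depth = as.integer(go_depth),
    genes_per_term = as.integer(genes_per_term),
    n_enriched_terms = as.integer(n_enriched_terms),
    enrichment_odds = enrichment_odds,
    study_fraction = study_fraction,
    n_seq_per_genotype = as.integer(n_seq_per_genotype),
    frac_phylosymbiotic = frac_phylosymbiotic,
    branch_noise_sigma = branch_noise_sigma,
    null_tree_mode = null_tree_mode
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  frac_fields <- c(
    "root_leaf_richness_ratio", "core_taxon_fraction",
    "hypothetical_fraction", "frac_phylosymbiotic", "study_fraction"
  )
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      config_error(sprintf("sim_config field '%s' must be a fraction in [0, 1]", f))
    }
  }
  if (cfg$root_leaf_richness_ratio <= 0) {
    config_error("sim_config field 'root_leaf_richness_ratio' must be in (0, 1]")
  }
  if (length(cfg$genotypes) < 1 || anyDuplicated(cfg$genotypes)) {
    config_error("sim_config field 'genotypes' must be a non-empty set of unique codes")
  }
  if (length(cfg$tissues) != 2) {
    config_error("sim_config field 'tissues' must name exactly two tissues (leaf, root)")
  }
  t <- cfg$target_core_shell_cloud
  if (length(t) != 3 || any(t < 0) || abs(sum(t) - 1) > 1e-9) {
    config_error("sim_config field 'target_core_shell_cloud' must be 3 non-negative fractions summing to 1")
  }
  pos_fields <- c(
    "n_taxa_pool", "depth_per_sample", "n_clusters", "n_genes",
    "n_go_terms", "genes_per_term", "n_seq_per_genotype"
  )
  for (f in pos_fields) {
    if (cfg[[f]] < 1) config_error(sprintf("sim_config field '%s' must be >= 1", f))
  }
  if (cfg$go_depth < 1) config_error("sim_config field 'go_depth' must be >= 1")
  if (cfg$branch_noise_sigma < 0) {
    config_error("sim_config field 'branch_noise_sigma' must be >= 0")
  }
  if (cfg$enrichment_odds <= 0) {
    config_error("sim_config field 'enrichment_odds' must be positive")
  }
  if (cfg$n_enriched_terms < 0 || cfg$n_enriched_terms > cfg$n_go_terms) {
    config_error("sim_config field 'n_enriched_terms' must be between 0 and n_go_terms")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  genotypes:", paste(x$genotypes, collapse = ", "), "\n")
  cat("  samples:", 2L * length(x$genotypes),
      sprintf("(%s/%s per genotype)", x$tissues[1], x$tissues[2]), "\n")
  cat("  taxa pool:", x$n_taxa_pool,
      " leaf/root richness ratio:", x$root_leaf_richness_ratio, "\n")
  cat("  clusters:", x$n_clusters, " core/shell/cloud:",
      paste(x$target_core_shell_cloud, collapse = "/"), "\n")
  cat("  GO terms:", x$n_go_terms, " planted enriched:", x$n_enriched_terms, "\n")
  cat("  phylosymbiotic fraction:", x$frac_phylosymbiotic, "\n")
  invisible(x)
}
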