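# Sub-stream offsets: one fixed offset per simulated output kind, so that
# e.g. enlarging the taxon pool never reshuffles the gene trees.
.SIM_STREAM <- c(
  metadata = 1L, communities = 2L, pangenome = 3L,
  go = 4L, trees = 5L, scaffolds = 6L
)

#' Simulate the sample sheet of a paired leaf/root endosphere study
#'
#' One leaf and one root sample per host genotype. Sample codes are the
#' genotype code plus the tissue letter (e.g. `BBL`, `BBR`); in field
#' datasets the below-ground letter is sometimes `C` (corm) rather than
#' `R`, which can be reproduced through the `tissues` field of
#' [sim_config()]. Read totals are drawn log-normally around
#' `depth_per_sample` to mimic the several-fold spread of sequencing
#' output across libraries.
#'
#' @param config A [sim_config()] object.
#' @return A data.frame with columns `sample`, `genotype`, `tissue`
#'   (`"leaf"`/`"root"`), and `reads` (positive integer).
#' @examples
#' simulate_metadata(sim_config(seed = 1))
#' @export
simulate_metadata <- function(config) {
  validate_sim_config(config)
  local_seed(sub_seed(config$seed, .SIM_STREAM[["metadata"]]), {
    g <- config$genotypes
    meta <- data.frame(
      sample = as.vector(t(outer(g, config$tissues, paste0))),
      genotype = rep(g, each = 2),
      tissue = rep(c("leaf", "root"), times = length(g)),
      stringsAsFactors = FALSE
    )
    meta$reads <- pmax(1L, as.integer(round(
      config$depth_per_sample * exp(stats::rnorm(nrow(meta), 0, 0.5))
    )))
    meta
  })
}

#' Simulate taxon abundance profiles with leaf/root richness structure
#'
#' Draws a community for every sample of [simulate_metadata()]. Each
#' genotype's root community is a pool of `n_taxa_pool` taxa from a global
#' pool (three times the per-sample pool size); its paired leaf community
#' is a random subset of that root pool of size
#' `ceiling(root_leaf_richness_ratio * n_taxa_pool)`, which makes root
#' communities strictly richer than leaf communities in expectation. A core
#' fraction of taxa is present in every sample. Relative abundances within a
#' sample are i.i.d. log-normal, renormalized, and observed counts are a
#' multinomial draw of `depth_per_sample` reads.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{abundance}{integer matrix, taxa x samples, raw read counts.}
#'     \item{meta}{the sample sheet used.}
#'     \item{truth}{data.frame `taxon`, `category` (one of `core`,
#'       `genotype_specific`, `tissue_specific`, `shared`); plus the
#'       per-sample pools in `attr(truth, "pools")`.}
#'   }
#' @export
simulate_communities <- function(config) {
  validate_sim_config(config)
  if (config$depth_per_sample <= 0) config_error("depth_per_sample must be positive")
  meta <- simulate_metadata(config)
  local_seed(sub_seed(config$seed, .SIM_STREAM[["communities"]]), {
    n <- config$n_taxa_pool
    n_core <- min(n, ceiling(config$core_taxon_fraction * n))
    pool_global <- sprintf("t%05d", seq_len(3L * n))
    core_taxa <- pool_global[seq_len(n_core)]
    noncore <- setdiff(pool_global, core_taxa)
    n_leaf <- min(n, ceiling(config$root_leaf_richness_ratio * n))

    pools <- vector("list", nrow(meta))
    names(pools) <- meta$sample
    for (g in config$genotypes) {
      extra <- if (n > n_core) sample(noncore, n - n_core) else character(0)
      root_pool <- c(core_taxa, extra)
      n_extra_leaf <- max(n_leaf - n_core, 0L)
      leaf_pool <- c(core_taxa,
                     if (n_extra_leaf > 0) sample(extra, min(n_extra_leaf, length(extra)))
                     else character(0))
      pools[[meta$sample[meta$genotype == g & meta$tissue == "root"]]] <- root_pool
      pools[[meta$sample[meta$genotype == g & meta$tissue == "leaf"]]] <- leaf_pool
    }

    taxa <- sort(unique(unlist(pools)))
    tab <- matrix(0L, nrow = length(taxa), ncol = nrow(meta),
                  dimnames = list(taxa, meta$sample))
    for (s in meta$sample) {
      pool <- pools[[s]]
      w <- stats::rlnorm(length(pool), config$abundance_lognormal_mu,
                         config$abundance_lognormal_sigma)
      counts <- stats::rmultinom(1, size = config$depth_per_sample, prob = w / sum(w))
      tab[pool, s] <- as.integer(counts)
    }

    # Truth label per taxon, assigned with fixed precedence so every taxon
    # gets exactly one category.
    geno_of <- lapply(config$genotypes, function(g) {
      unique(unlist(pools[meta$sample[meta$genotype == g]]))
    })
    names(geno_of) <- config$genotypes
    in_leaf <- unique(unlist(pools[meta$sample[meta$tissue == "leaf"]]))
    category <- vapply(taxa, function(t) {
      if (t %in% core_taxa) return("core")
      n_geno <- sum(vapply(geno_of, function(p) t %in% p, logical(1)))
      if (n_geno == 1L) return("genotype_specific")
      if (!(t %in% in_leaf)) return("tissue_specific")
      "shared"
    }, character(1))
    truth <- data.frame(taxon = taxa, category = unname(category),
                        stringsAsFactors = FALSE)
    attr(truth, "pools") <- pools
    attr(tab, "normalized") <- FALSE
    list(abundance = tab, meta = meta, truth = truth)
  })
}
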