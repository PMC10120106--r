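# Base gene-symbol pool used for simulated cluster names. Mixes symbols
# commonly recovered from plant-endosphere metagenomes with generated
# filler symbols.
.GENE_SYMBOLS <- c(
  "adhP", "xerC", "mdtA", "mdtB", "rhaS", "hcaB", "malT", "rbsA", "gsiD",
  "mopR", "ompR", "trg", "butA", "cspA", "betA", "ctpF", "ttgB", "clpB",
  "acdS", "nifH", "pilA", "chiA", "fliC", "cheA", "exoP", "katG", "sodB",
  "pqqC", "iaaM", "budC", "phzF", "hcnB", "acoR", "gabD", "puuA", "speB"
)

sim_gene_symbol_pool <- function(n) {
  if (n <= length(.GENE_SYMBOLS)) return(.GENE_SYMBOLS[seq_len(n)])
  extra <- sprintf("yf%s%s",
                   letters[((seq_len(n - length(.GENE_SYMBOLS)) - 1) %/% 26) %% 26 + 1],
                   letters[(seq_len(n - length(.GENE_SYMBOLS)) - 1) %% 26 + 1])
  c(.GENE_SYMBOLS, make.unique(extra, sep = ""))
}

# Largest-remainder apportionment of n items to fractions (exact when the
# fractions are multiples of 1/n, e.g. 1000 x (0.1, 0.3, 0.6) -> 100/300/600).
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate an ortholog cluster presence matrix with planted partition labels
#'
#' Assigns each of `n_clusters` clusters a category (core, shell, cloud) in
#' the exact proportions of `target_core_shell_cloud` (largest-remainder
#' apportionment), then samples a presence pattern conditional on the
#' category: core clusters are present in every sample, cloud clusters in
#' exactly one uniformly chosen sample, and shell clusters get independent
#' Bernoulli(0.5) presence per sample, rejection-sampled until the presence
#' count lies in `[2, n_samples)`. Counts for present cells are
#' `1 + Poisson(0.7)` gene copies. A `hypothetical_fraction` of clusters is
#' named `group_<k>` with annotation `"hypothetical protein"`; the rest
#' carry gene symbols with Roary-style variant suffixes (`adhP_1`,
#' `adhP_2`, ...).
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `clusters` (a [cluster_matrix()]), `meta`
#'   (sample sheet) and `truth` (data.frame `cluster_id`, `category`).
#' @export
simulate_pangenome <- function(config) {
  validate_sim_config(config)
  meta <- simulate_metadata(config)
  n_samples <- nrow(meta)
  if (n_samples < 2) config_error("simulate_pangenome needs >= 2 samples")
  local_seed(sub_seed(config$seed, .SIM_STREAM[["pangenome"]]), {
    n <- config$n_clusters
    counts_per_cat <- apportion(n, config$target_core_shell_cloud)
    category <- rep(c("core", "shell", "cloud"), times = counts_per_cat)

    presence <- matrix(0L, nrow = n, ncol = n_samples,
                       dimnames = list(NULL, meta$sample))
    for (i in seq_len(n)) {
      presence[i, ] <- switch(category[i],
        core = rep(1L, n_samples),
        cloud = {
          v <- integer(n_samples)
          v[sample.int(n_samples, 1)] <- 1L
          v
        },
        shell = {
          repeat {
            v <- stats::rbinom(n_samples, 1L, 0.5)
            if (sum(v) >= 2 && sum(v) < n_samples) break
          }
          v
        }
      )
    }
    counts <- presence * (1L + matrix(stats::rpois(n * n_samples, 0.7), n, n_samples))

    n_hyp <- round(config$hypothetical_fraction * n)
    is_hyp <- rep(FALSE, n)
    if (n_hyp > 0) is_hyp[sample.int(n, n_hyp)] <- TRUE
    gene_name <- character(n)
    annotation <- character(n)
    gene_name[is_hyp] <- sprintf("group_%d", seq_len(sum(is_hyp)))
    annotation[is_hyp] <- "hypothetical protein"
    n_named <- sum(!is_hyp)
    if (n_named > 0) {
      symbols <- sim_gene_symbol_pool(max(1L, ceiling(n_named / 4)))
      base <- sample(symbols, n_named, replace = TRUE)
      # Roary-style disambiguation: repeated symbols get _1, _2, ... suffixes.
      idx <- stats::ave(seq_along(base), base, FUN = seq_along)
      dup <- stats::ave(seq_along(base), base, FUN = length) > 1
      gene_name[!is_hyp] <- ifelse(dup, paste0(base, "_", idx), base)
      annotation[!is_hyp] <- paste(base, "family protein")
    }

    cm <- cluster_matrix(counts,
                         cluster_id = sprintf("cl%05d", seq_len(n)),
                         gene_name = gene_name, annotation = annotation)
    truth <- data.frame(cluster_id = cm$cluster_id, category = category,
                        stringsAsFactors = FALSE)
    list(clusters = cm, meta = meta, truth = truth)
  })
}
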