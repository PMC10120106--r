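#' Alpha diversity indices
#'
#' Computes a single diversity index from a vector of taxon counts, from
#' the textbook formulas:
#' \describe{
#'   \item{observed}{number of taxa with count > 0 (S_obs).}
#'   \item{shannon}{H = -sum p_i log p_i, natural log by default,
#'     p_i = n_i / N over taxa with n_i > 0.}
#'   \item{simpson}{D = 1 - sum p_i^2 (Gini-Simpson, in \[0, 1\]).}
#'   \item{chao1}{bias-corrected: S_obs + F1 (F1 - 1) / (2 (F2 + 1)),
#'     where F_k is the number of taxa observed exactly k times.}
#'   \item{ace}{abundance-based coverage estimator with rare cutoff 10:
#'     S_abund + S_rare / C_ace + (F1 / C_ace) gamma^2, with sample
#'     coverage C_ace = 1 - F1 / N_rare and the squared coefficient of
#'     variation gamma^2 estimated from the rare class.}
#' }
#'
#' @param counts Non-negative numeric vector of per-taxon counts.
#' @param index One of `"shannon"`, `"simpson"`, `"chao1"`, `"ace"`,
#'   `"observed"`.
#' @param base Logarithm base for Shannon (default `exp(1)`).
#' @param rare_cutoff ACE rare-abundance cutoff (default 10).
#' @return A single numeric value.
#' @examples
#' alpha_diversity(c(5, 5, 5, 5), "shannon")   # log(4)
#' alpha_diversity(c(1, 1, 2, 3), "chao1")     # 4.5
#' @export
alpha_diversity <- function(counts,
                            index = c("shannon", "simpson", "chao1", "ace", "observed"),
                            base = exp(1), rare_cutoff = 10) {
  index <- match.arg(index)
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(is.na(counts))) data_error("counts must be non-negative")
  N <- sum(counts)
  if (N <= 0) data_error("all-zero count vector: diversity undefined")
  pos <- counts[counts > 0]
  s_obs <- length(pos)
  switch(index,
    observed = s_obs,
    shannon = {
      p <- pos / N
      -sum(p * log(p, base = base))
    },
    simpson = {
      p <- pos / N
      1 - sum(p^2)
    },
    chao1 = {
      f1 <- sum(pos == 1)
      f2 <- sum(pos == 2)
      s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    },
    ace = {
      rare <- pos[pos <= rare_cutoff]
      abund <- pos[pos > rare_cutoff]
      s_rare <- length(rare)
      if (s_rare == 0) return(length(abund))
      n_rare <- sum(rare)
      f1 <- sum(rare == 1)
      c_ace <- 1 - f1 / n_rare
      if (c_ace <= 0) {
        data_error("ACE undefined: all rare taxa are singletons (coverage 0)")
      }
      fk <- tabulate(rare, nbins = rare_cutoff)
      g2 <- max(
        (s_rare / c_ace) * sum(seq_len(rare_cutoff) * (seq_len(rare_cutoff) - 1) * fk) /
          (n_rare * (n_rare - 1)) - 1,
        0
      )
      length(abund) + s_rare / c_ace + (f1 / c_ace) * g2
    }
  )
}

#' Per-sample diversity table
#'
#' Convenience wrapper computing several indices for every column of an
#' abundance table.
#'
#' @param table Numeric matrix taxa x samples.
#' @param indices Character vector of indices (see [alpha_diversity()]).
#' @return data.frame with a `sample` column and one column per index.
#' @export
diversity_table <- function(table,
                            indices = c("observed", "shannon", "simpson", "chao1", "ace")) {
  out <- data.frame(sample = colnames(table), stringsAsFactors = FALSE)
  for (ix in indices) {
    out[[ix]] <- apply(table, 2, alpha_diversity, index = ix)
  }
  out
}

#' Rarefaction curve by random subsampling
#'
#' Mean observed richness of random subsamples drawn without replacement
#' at each requested depth. Subsampling uses a sequential hypergeometric
#' draw, equivalent to sampling `depth` reads without replacement from the
#' pooled reads.
#'
#' @param counts Non-negative integer vector of per-taxon read counts.
#' @param depths Integer vector of subsample sizes (each <= `sum(counts)`).
#' @param reps Number of random subsamples per depth (default 100).
#' @param seed Integer seed.
#' @return data.frame with columns `depth` and `richness` (mean observed
#'   taxa over `reps` draws).
#' @export
rarefaction_curve <- function(counts, depths, reps = 100, seed = 1) {
  counts <- as.numeric(counts)
  N <- sum(counts)
  if (any(depths > N)) data_error("subsample depth exceeds total reads")
  if (any(depths < 1)) data_error("subsample depths must be >= 1")
  local_seed(seed, {
    rich <- vapply(depths, function(d) {
      mean(vapply(seq_len(reps), function(r) {
        sum(rhyper_counts(counts, d) > 0)
      }, numeric(1)))
    }, numeric(1))
    data.frame(depth = depths, richness = rich)
  })
}

# Multivariate hypergeometric draw: subsample `size` reads without
# replacement from per-taxon totals, by sequential rhyper calls.
rhyper_counts <- function(counts, size) {
  remaining <- sum(counts)
  out <- numeric(length(counts))
  left <- size
  for (i in seq_along(counts)) {
    if (left == 0) break
    remaining <- remaining - counts[i]
    out[i] <- stats::rhyper(1, m = counts[i], n = remaining, k = left)
    left <- left - out[i]
  }
  out
}
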