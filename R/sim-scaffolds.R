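#' Simulate scaffolds, alignment hits and read counts
#'
#' Fixture generator for the binning and abundance stages. Scaffolds are
#' assigned a planted true taxon drawn from the sample's simulated
#' community (probability proportional to abundance), log-normal lengths
#' and coverages, and read counts proportional to `coverage x length`.
#' Each scaffold with hits gets one row for its true taxon plus `n_decoy`
#' decoy rows with lower bitscores; with probability `epsilon` a decoy
#' outscores the true taxon. All qualifying e-values fall below 1e-5
#' unless `decoys_above_threshold` forces decoy e-values above it.
#'
#' @param config A [sim_config()] object.
#' @param n_scaffolds_per_sample Scaffolds simulated per sample.
#' @param epsilon Probability a decoy takes the top bitscore.
#' @param frac_hit_free Fraction of scaffolds generated without any hit
#'   (they bin as `"unclassified"`).
#' @param n_decoy Decoy hit rows per scaffold.
#' @param decoys_above_threshold Force decoy e-values above 1e-5.
#' @return List with `hits` (outfmt-6-style data.frame), `scaffolds`
#'   (scaffold_id, sample, length, coverage, true_taxon), `reads`
#'   (scaffold_id, reads), and `meta`.
#' @export
simulate_hits_and_scaffolds <- function(config, n_scaffolds_per_sample = 100,
                                        epsilon = 0, frac_hit_free = 0,
                                        n_decoy = 2,
                                        decoys_above_threshold = FALSE) {
  validate_sim_config(config)
  comm <- simulate_communities(config)
  local_seed(sub_seed(config$seed, .SIM_STREAM[["scaffolds"]]), {
    meta <- comm$meta
    scaffolds <- do.call(rbind, lapply(meta$sample, function(s) {
      ab <- comm$abundance[, s]
      present <- names(ab)[ab > 0]
      data.frame(
        scaffold_id = sprintf("%s_sc%04d", s, seq_len(n_scaffolds_per_sample)),
        sample = s,
        length = pmax(200L, as.integer(round(stats::rlnorm(n_scaffolds_per_sample, 7.5, 0.8)))),
        coverage = stats::rlnorm(n_scaffolds_per_sample, 1.5, 0.9),
        true_taxon = sample(present, n_scaffolds_per_sample, replace = TRUE,
                            prob = ab[present]),
        stringsAsFactors = FALSE
      )
    }))
    rownames(scaffolds) <- NULL
    reads <- data.frame(
      scaffold_id = scaffolds$scaffold_id,
      reads = pmax(1L, as.integer(round(scaffolds$coverage * scaffolds$length / 150))),
      stringsAsFactors = FALSE
    )
    n_sc <- nrow(scaffolds)
    hit_free <- stats::runif(n_sc) < frac_hit_free
    taxa_pool <- sprintf("t%05d", seq_len(3L * config$n_taxa_pool))
    hit_rows <- lapply(which(!hit_free), function(i) {
      true_bs <- 200 + stats::rexp(1, 0.05)
      decoy_bs <- stats::runif(n_decoy, 50, true_bs - 1)
      if (epsilon > 0 && stats::runif(1) < epsilon && n_decoy > 0) {
        decoy_bs[1] <- true_bs + stats::runif(1, 1, 50)
      }
      e_true <- 10^(-stats::runif(1, 10, 50))
      e_decoy <- if (decoys_above_threshold) {
        10^(-stats::runif(n_decoy, 1, 4.9))  # all above 1e-5
      } else {
        10^(-stats::runif(n_decoy, 6, 30))
      }
      decoy_taxa <- sample(setdiff(taxa_pool, scaffolds$true_taxon[i]), n_decoy)
      data.frame(
        query = scaffolds$scaffold_id[i],
        subject_taxon = c(scaffolds$true_taxon[i], decoy_taxa),
        percent_identity = round(stats::runif(1 + n_decoy, 60, 100), 1),
        align_length = sample.int(500, 1 + n_decoy) + 50L,
        mismatch = sample.int(40, 1 + n_decoy),
        gapopen = sample.int(5, 1 + n_decoy) - 1L,
        qstart = 1L, qend = 300L, sstart = 1L, send = 300L,
        e_value = c(e_true, e_decoy),
        bitscore = round(c(true_bs, decoy_bs), 1),
        stringsAsFactors = FALSE
      )
    })
    hits <- if (length(hit_rows) > 0) do.call(rbind, hit_rows) else
      data.frame(query = character(0), subject_taxon = character(0),
                 percent_identity = numeric(0), align_length = integer(0),
                 mismatch = integer(0), gapopen = integer(0),
                 qstart = integer(0), qend = integer(0), sstart = integer(0),
                 send = integer(0), e_value = numeric(0), bitscore = numeric(0))
    rownames(hits) <- NULL
    list(hits = hits, scaffolds = scaffolds, reads = reads, meta = meta)
  })
}
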