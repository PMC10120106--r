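#' Assign a scaffold to a taxon from its alignment hits
#'
#' Best-hit taxonomic binning: among the hits passing the e-value
#' threshold, the scaffold is assigned the subject taxon of the maximum
#' bitscore. Ties are broken by smaller e-value, then lexicographically
#' smaller taxon name, so binning is deterministic. A scaffold with no
#' qualifying hit is `"unclassified"`.
#'
#' @param hits data.frame of hit rows for one scaffold with columns
#'   `query`, `subject_taxon`, `e_value`, `bitscore` (extra columns
#'   ignored).
#' @param e_threshold Maximum e-value for a hit to qualify (default 1e-5).
#' @return A single taxon name, or `"unclassified"`.
#' @examples
#' h <- data.frame(query = "s1", subject_taxon = c("A", "B"),
#'                 e_value = c(1e-10, 1e-12), bitscore = c(80, 95))
#' assign_scaffold_taxon(h)  # "B"
#' @export
assign_scaffold_taxon <- function(hits, e_threshold = 1e-5) {
  if (is.null(hits) || nrow(hits) == 0) return("unclassified")
  if (length(unique(hits$query)) > 1) {
    data_error(paste("hits for a single scaffold expected; got queries:",
                     paste(unique(hits$query), collapse = ", ")))
  }
  ok <- hits$e_value <= e_threshold
  if (!any(ok)) return("unclassified")
  h <- hits[ok, , drop = FALSE]
  h <- h[order(-h$bitscore, h$e_value, h$subject_taxon), , drop = FALSE]
  h$subject_taxon[1]
}

#' Bin many scaffolds at once
#'
#' Applies [assign_scaffold_taxon()] per query of a full hit table.
#' Scaffolds listed in `scaffold_ids` but absent from the hit table are
#' `"unclassified"`.
#'
#' @param hits Hit table for any number of scaffolds.
#' @param scaffold_ids Optional character vector of all scaffolds expected.
#' @param e_threshold Passed to [assign_scaffold_taxon()].
#' @return Named character vector scaffold -> taxon.
#' @export
bin_scaffolds <- function(hits, scaffold_ids = NULL, e_threshold = 1e-5) {
  by_query <- split(hits, hits$query)
  taxon <- vapply(by_query, assign_scaffold_taxon, character(1),
                  e_threshold = e_threshold)
  if (!is.null(scaffold_ids)) {
    out <- stats::setNames(rep("unclassified", length(scaffold_ids)), scaffold_ids)
    known <- intersect(names(taxon), scaffold_ids)
    out[known] <- taxon[known]
    out
  } else {
    taxon
  }
}

#' Build a taxon abundance table from binned scaffolds and read counts
#'
#' Sums the reads mapped to each sample's scaffolds into the taxon each
#' scaffold was binned to. Reads are conserved: every column total equals
#' the total input reads for that sample. `"unclassified"` is kept as a
#' row.
#'
#' @param scaffolds data.frame with columns `scaffold_id`, `sample`,
#'   `taxon` (and optionally `length`, `coverage`).
#' @param reads data.frame with columns `scaffold_id`, `reads`.
#' @return Integer matrix taxa x samples with attribute `normalized = FALSE`.
#' @export
build_abundance <- function(scaffolds, reads) {
  unknown <- setdiff(reads$scaffold_id, scaffolds$scaffold_id)
  if (length(unknown) > 0) {
    data_error(paste("read counts reference unknown scaffolds:",
                     paste(utils::head(unknown, 10), collapse = ", ")))
  }
  idx <- match(reads$scaffold_id, scaffolds$scaffold_id)
  taxon <- scaffolds$taxon[idx]
  sample <- scaffolds$sample[idx]
  agg <- stats::aggregate(reads$reads,
                          by = list(taxon = taxon, sample = sample), FUN = sum)
  taxa <- sort(unique(agg$taxon))
  samples <- sort(unique(scaffolds$sample))
  tab <- matrix(0L, nrow = length(taxa), ncol = length(samples),
                dimnames = list(taxa, samples))
  tab[cbind(match(agg$taxon, taxa), match(agg$sample, samples))] <-
    as.integer(agg$x)
  attr(tab, "normalized") <- FALSE
  tab
}

#' Scale each sample to the median library size
#'
#' Multiplies each column of an abundance table by
#' `median(column totals) / column total`, so that all normalized column
#' totals equal the median sample read count. The transform is idempotent.
#'
#' @param table Numeric matrix, taxa x samples.
#' @return Matrix of the same shape with attributes `normalized = TRUE`
#'   and `scale_factors` (named per sample).
#' @examples
#' m <- cbind(a = c(60, 40), b = c(150, 50), c = c(300, 100))
#' colSums(normalize_to_median(m))  # all equal 200
#' @export
normalize_to_median <- function(table) {
  table <- as.matrix(table)
  if (ncol(table) < 1) data_error("abundance table has no samples")
  totals <- colSums(table)
  zero <- totals == 0
  if (any(zero)) {
    data_error(paste("sample(s) with zero total reads:",
                     paste(colnames(table)[zero], collapse = ", ")))
  }
  med <- stats::median(totals)
  factors <- med / totals
  out <- sweep(table, 2, factors, "*")
  attr(out, "normalized") <- TRUE
  attr(out, "scale_factors") <- factors
  out
}

#' Subsample scaffolds from a coverage-ordered list
#'
#' Equalizes sampling effort across samples before set comparisons: for
#' each sample, scaffolds are sorted by coverage (descending; ties broken
#' by larger length, then lexicographic id) and the top
#' `ceiling(f_s * n_s)` are retained, where
#' `f_s = min(read_totals) / read_total_s`. Lower-coverage scaffolds are
#' thus removed in inverse proportion to the sample's relative read count;
#' the sample with the fewest reads keeps everything.
#'
#' @param scaffolds data.frame with columns `scaffold_id`, `sample`,
#'   `length`, `coverage` (plus any others, carried through).
#' @param read_totals Named numeric vector of total reads per sample.
#' @return The retained subset of `scaffolds` (row order: by sample, then
#'   coverage rank).
#' @export
subsample_scaffolds_by_coverage <- function(scaffolds, read_totals) {
  samples <- unique(scaffolds$sample)
  missing <- setdiff(samples, names(read_totals))
  if (length(missing) > 0) {
    data_error(paste("missing read totals for sample(s):",
                     paste(missing, collapse = ", ")))
  }
  if (any(read_totals[samples] <= 0)) data_error("read totals must be positive")
  r_min <- min(read_totals[samples])
  kept <- lapply(samples, function(s) {
    sub <- scaffolds[scaffolds$sample == s, , drop = FALSE]
    sub <- sub[order(-sub$coverage, -sub$length, sub$scaffold_id), , drop = FALSE]
    f <- r_min / read_totals[[s]]
    sub[seq_len(ceiling(f * nrow(sub))), , drop = FALSE]
  })
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}
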