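#' Ortholog cluster matrix
#'
#' Container for a Roary-style gene presence/absence matrix: one row per
#' ortholog cluster with a gene name and annotation, one column per sample,
#' cells holding gene copy counts (presence is `count >= 1`).
#'
#' @param counts Non-negative integer matrix, clusters x samples, with
#'   sample names as column names.
#' @param cluster_id Unique cluster identifiers (default `rownames(counts)`).
#' @param gene_name Gene symbol per cluster (Roary uses `group_<k>` for
#'   clusters without a symbol).
#' @param annotation Free-text product annotation per cluster.
#' @return An object of class `cluster_matrix`.
#' @export
cluster_matrix <- function(counts, cluster_id = rownames(counts),
                           gene_name = cluster_id,
                           annotation = rep("", nrow(counts))) {
  counts <- as.matrix(counts)
  if (is.null(cluster_id)) cluster_id <- sprintf("cl%05d", seq_len(nrow(counts)))
  if (anyDuplicated(cluster_id)) data_error("cluster_id values must be unique")
  if (is.null(colnames(counts))) data_error("counts must have sample column names")
  if (any(counts < 0)) data_error("counts must be non-negative")
  if (length(gene_name) != nrow(counts) || length(annotation) != nrow(counts)) {
    data_error("gene_name and annotation must have one entry per cluster")
  }
  rownames(counts) <- cluster_id
  structure(list(counts = counts, cluster_id = as.character(cluster_id),
                 gene_name = as.character(gene_name),
                 annotation = as.character(annotation)),
            class = "cluster_matrix")
}

#' @export
print.cluster_matrix <- function(x, ...) {
  cat(sprintf("<cluster_matrix> %d clusters x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  samples:", paste(colnames(x$counts), collapse = ", "), "\n")
  n_hyp <- sum(tolower(x$annotation) == "hypothetical protein")
  cat(sprintf("  hypothetical protein clusters: %d (%.1f%%)\n",
              n_hyp, 100 * n_hyp / max(1, nrow(x$counts))))
  invisible(x)
}

#' @export
dim.cluster_matrix <- function(x) dim(x$counts)

#' Partition gene clusters into core, shell and cloud sets
#'
#' Over the chosen samples, a cluster is *core* when present in every
#' sample, *cloud* when present in exactly one, and *shell* otherwise
#' (present in at least two but not all). Clusters absent from every chosen
#' sample are excluded from the partition and reported separately.
#' Percentages are computed with [fmt_percent()] (round half-to-even,
#' 2 decimals).
#'
#' @param x A [cluster_matrix()] or a presence/count matrix with sample
#'   column names.
#' @param samples Character vector of sample columns to consider (default
#'   all).
#' @return An object of class `pangenome_partition`: lists `core`, `shell`,
#'   `cloud` of cluster ids, a `counts` vector, a `pct` vector (of the total
#'   present clusters), and `n_absent`.
#' @examples
#' sim <- simulate_pangenome(sim_config(seed = 1, n_clusters = 200))
#' pangenome_partition(sim$clusters)
#' @export
pangenome_partition <- function(x, samples = NULL) {
  counts <- if (inherits(x, "cluster_matrix")) x$counts else as.matrix(x)
  if (is.null(samples)) samples <- colnames(counts)
  if (length(samples) == 0) data_error("sample subset must be non-empty")
  missing <- setdiff(samples, colnames(counts))
  if (length(missing) > 0) {
    data_error(paste("unknown samples:", paste(missing, collapse = ", ")))
  }
  pres <- counts[, samples, drop = FALSE] >= 1
  n_pres <- rowSums(pres)
  ids <- rownames(counts)
  core <- ids[n_pres == length(samples)]
  cloud <- ids[n_pres == 1 & length(samples) > 1]
  if (length(samples) == 1) cloud <- character(0) # single sample: all-present = core
  shell <- ids[n_pres >= 2 & n_pres < length(samples)]
  absent <- ids[n_pres == 0]
  total <- length(core) + length(shell) + length(cloud)
  res <- list(
    core = core, shell = shell, cloud = cloud,
    counts = c(core = length(core), shell = length(shell), cloud = length(cloud)),
    pct = if (total > 0) {
      c(core = fmt_percent(length(core), total),
        shell = fmt_percent(length(shell), total),
        cloud = fmt_percent(length(cloud), total))
    } else {
      c(core = NA_real_, shell = NA_real_, cloud = NA_real_)
    },
    n_total = total, n_absent = length(absent), samples = samples
  )
  class(res) <- "pangenome_partition"
  res
}

#' @export
print.pangenome_partition <- function(x, ...) {
  cat(sprintf("<pangenome_partition> %d clusters over %d samples (%d absent everywhere)\n",
              x$n_total, length(x$samples), x$n_absent))
  for (k in c("core", "shell", "cloud")) {
    cat(sprintf("  %-5s %7d  (%.2f%%)\n", k, x$counts[[k]], x$pct[[k]]))
  }
  invisible(x)
}

#' Venn region counts for 2-7 item sets
#'
#' Counts the items falling in every non-empty intersection region of the
#' given sets (2^g - 1 regions). Region names join the member set names
#' with `&`. Region counts always sum to the size of the union.
#'
#' @param sets Named list of 2-7 vectors (coerced to sets).
#' @return Named integer vector of region counts, one per region.
#' @examples
#' pan_overlap(list(A = 1:3, B = 2:4, C = 3))
#' @export
pan_overlap <- function(sets) {
  g <- length(sets)
  if (g < 2 || g > 7) data_error("pan_overlap supports between 2 and 7 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_len(g)]
  }
  sets <- lapply(sets, unique)
  items <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) items %in% s, logical(length(items)))
  if (length(items) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  # enumerate all 2^g - 1 regions so empty regions are reported as 0
  combos <- unlist(lapply(seq_len(g), function(k) {
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)
  }))
  counts <- stats::setNames(integer(length(combos)), combos)
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Consolidate diverged gene-cluster variants by gene name
#'
#' Reduces a cluster matrix to gene level: strips one trailing
#' `_<integer>` variant suffix from each gene name (`adhP_2` becomes
#' `adhP`; `abc_1_2` becomes `abc_1`), removes clusters whose stripped
#' name is a `group_<k>` placeholder (no functional annotation), and
#' merges rows sharing a stripped name by summing copy counts (presence
#' is the logical OR). Optionally removes clusters annotated
#' `"hypothetical protein"` (exact string, case-insensitive) before
#' merging, and rewrites names through a user synonym map first.
#' Consolidation is defined on raw cluster matrices and is idempotent: a
#' matrix that has already been consolidated is returned unchanged (its
#' gene names are already canonical, even when a stripped name like
#' `abc_1` still carries an underscore-digit tail).
#'
#' @param x A [cluster_matrix()].
#' @param drop_hypothetical Remove `"hypothetical protein"` clusters.
#' @param synonym_map Optional named character vector mapping alternate
#'   symbols to canonical ones, applied after suffix stripping.
#' @return A [cluster_matrix()] keyed by consolidated gene name.
#' @export
consolidate_clusters <- function(x, drop_hypothetical = FALSE, synonym_map = NULL) {
  stopifnot(inherits(x, "cluster_matrix"))
  if (isTRUE(x$consolidated)) return(x)
  keep <- rep(TRUE, nrow(x$counts))
  if (drop_hypothetical) {
    keep <- keep & tolower(x$annotation) != "hypothetical protein"
  }
  keep <- keep & !grepl("^group_?[0-9]+$", x$gene_name)
  name <- sub("_[0-9]+$", "", x$gene_name)
  if (!is.null(synonym_map)) {
    hit <- name %in% names(synonym_map)
    name[hit] <- unname(synonym_map[name[hit]])
  }
  keep <- keep & !grepl("^group_?[0-9]+$", name)
  counts <- x$counts[keep, , drop = FALSE]
  name <- name[keep]
  ann <- x$annotation[keep]
  if (nrow(counts) == 0) {
    out <- cluster_matrix(matrix(integer(0), 0, ncol(x$counts),
                                 dimnames = list(NULL, colnames(x$counts))),
                          cluster_id = character(0), gene_name = character(0),
                          annotation = character(0))
    out$consolidated <- TRUE
    return(out)
  }
  merged <- rowsum(counts, group = name, reorder = TRUE)
  first_ann <- tapply(ann, name, function(a) a[1])
  out <- cluster_matrix(merged, cluster_id = rownames(merged),
                        gene_name = rownames(merged),
                        annotation = as.character(first_ann[rownames(merged)]))
  out$consolidated <- TRUE
  out
}

#' Rank the most abundant shared genes
#'
#' Ranks genes by total copy number across samples and emits per-sample
#' relative copy numbers (each cell divided by its sample's total copies),
#' the data behind a top-N shared-gene heatmap. With `shared_in = "root"`
#' the table is restricted to genes present in every root sample and absent
#' from all leaf samples (and symmetrically for `"leaf"`).
#'
#' @param x A [cluster_matrix()] with copy counts.
#' @param meta Sample sheet with columns `sample` and `tissue` (required for
#'   `shared_in`).
#' @param n Number of top genes to keep (default 100); truncated with a
#'   warning when fewer genes qualify.
#' @param shared_in One of `"all"`, `"root"`, `"leaf"`.
#' @return A list: `ranking` (data.frame `gene`, `total`, `rank`) and
#'   `relative` (matrix of per-sample relative copy numbers for the ranked
#'   genes).
#' @export
top_shared <- function(x, meta = NULL, n = 100, shared_in = c("all", "root", "leaf")) {
  stopifnot(inherits(x, "cluster_matrix"))
  shared_in <- match.arg(shared_in)
  counts <- x$counts
  rownames(counts) <- x$gene_name
  if (shared_in != "all") {
    if (is.null(meta)) data_error("tissue metadata required for shared_in subset")
    inside <- meta$sample[meta$tissue == ifelse(shared_in == "root", "root", "leaf")]
    outside <- meta$sample[meta$tissue == ifelse(shared_in == "root", "leaf", "root")]
    pres <- counts >= 1
    keep <- rowSums(pres[, inside, drop = FALSE]) == length(inside) &
      rowSums(pres[, outside, drop = FALSE]) == 0
    counts <- counts[keep, , drop = FALSE]
  }
  if (nrow(counts) == 0) {
    return(list(ranking = data.frame(gene = character(0), total = numeric(0),
                                     rank = integer(0)),
                relative = counts))
  }
  total <- rowSums(counts)
  if (n > length(total)) {
    warning(sprintf("requested top %d genes but only %d qualify; truncating",
                    n, length(total)))
    n <- length(total)
  }
  ord <- order(-total, rownames(counts))[seq_len(n)]
  sample_tot <- colSums(x$counts)
  rel <- sweep(counts[ord, , drop = FALSE], 2, pmax(sample_tot, 1), "/")
  list(
    ranking = data.frame(gene = rownames(counts)[ord], total = total[ord],
                         rank = seq_len(n), row.names = NULL,
                         stringsAsFactors = FALSE),
    relative = rel
  )
}
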