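#' Read a Roary gene_presence_absence.csv
#'
#' Parses the quoted-CSV dialect of Roary's `gene_presence_absence.csv`:
#' a `"Gene"` column, an `"Annotation"` column, the fixed block of
#' cluster metadata columns, then one column per sample. A non-empty
#' sample cell means presence; cells holding several tab-joined sequence
#' ids count as that many gene copies.
#'
#' @param path Path to the CSV (gzip-transparent).
#' @return A [cluster_matrix()] with copy counts.
#' @export
read_roary_csv <- function(path) {
  if (!file.exists(path)) data_error(paste("file not found:", path))
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!("Gene" %in% colnames(df))) {
    data_error(sprintf("%s: missing 'Gene' column (line 1)", path))
  }
  if (!("Annotation" %in% colnames(df))) {
    data_error(sprintf("%s: missing 'Annotation' column (line 1)", path))
  }
  meta_cols <- c(
    "Gene", "Non-unique Gene name", "Annotation", "No. isolates",
    "No. sequences", "Avg sequences per isolate", "Genome Fragment",
    "Order within Fragment", "Accessory Fragment",
    "Accessory Order with Fragment", "QC", "Min group size nuc",
    "Max group size nuc", "Avg group size nuc"
  )
  sample_cols <- setdiff(colnames(df), meta_cols)
  if (length(sample_cols) == 0) data_error(paste(path, "has no sample columns"))
  counts <- vapply(sample_cols, function(s) {
    cell <- df[[s]]
    ifelse(is.na(cell) | cell == "", 0L,
           lengths(strsplit(cell, "\t", fixed = TRUE)))
  }, integer(nrow(df)))
  counts <- matrix(counts, nrow = nrow(df),
                   dimnames = list(NULL, sample_cols))
  cluster_matrix(counts, cluster_id = df$Gene, gene_name = df$Gene,
                 annotation = df$Annotation)
}

#' Write a cluster matrix in the Roary CSV dialect
#'
#' @param x A [cluster_matrix()].
#' @param path Output path.
#' @export
write_roary_csv <- function(x, path) {
  stopifnot(inherits(x, "cluster_matrix"))
  samples <- colnames(x$counts)
  cells <- lapply(samples, function(s) {
    vapply(seq_len(nrow(x$counts)), function(i) {
      k <- x$counts[i, s]
      if (k == 0) "" else paste(sprintf("%s_%s_%02d", x$cluster_id[i], s, seq_len(k)),
                                collapse = "\t")
    }, character(1))
  })
  df <- data.frame(
    Gene = x$gene_name, `Non-unique Gene name` = "", Annotation = x$annotation,
    `No. isolates` = rowSums(x$counts >= 1), `No. sequences` = rowSums(x$counts),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (i in seq_along(samples)) df[[samples[i]]] <- cells[[i]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a minimal OBO ontology file
#'
#' Parses `[Term]` stanzas with `id`, `name`, `namespace` and `is_a`
#' tags (trailing `! comment` text stripped). Obsolete terms are
#' skipped. Cyclic `is_a` graphs are rejected.
#'
#' @param path Path to the OBO file (gzip-transparent).
#' @return List with `parents` (named list), `name`, `namespace`, ready
#'   for [go_universe()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) data_error(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  parents <- list(); nm <- character(0); ns <- character(0)
  cur_id <- NULL; cur_parents <- character(0)
  cur_name <- NA_character_; cur_ns <- NA_character_
  in_term <- FALSE; obsolete <- FALSE
  flush <- function() {
    if (!is.null(cur_id) && !obsolete) {
      parents[[cur_id]] <<- cur_parents
      nm[cur_id] <<- cur_name
      ns[cur_id] <<- cur_ns
    }
  }
  for (line in lines) {
    line <- trimws(line)
    if (line == "[Term]") {
      flush()
      cur_id <- NULL; cur_parents <- character(0)
      cur_name <- NA_character_; cur_ns <- NA_character_
      in_term <- TRUE; obsolete <- FALSE
    } else if (grepl("^\\[", line)) {
      flush(); in_term <- FALSE; cur_id <- NULL
    } else if (in_term && grepl("^id:", line)) {
      cur_id <- trimws(sub("^id:", "", line))
    } else if (in_term && grepl("^name:", line)) {
      cur_name <- trimws(sub("^name:", "", line))
    } else if (in_term && grepl("^namespace:", line)) {
      cur_ns <- trimws(sub("^namespace:", "", line))
    } else if (in_term && grepl("^is_a:", line)) {
      v <- trimws(sub("!.*$", "", sub("^is_a:", "", line)))
      cur_parents <- c(cur_parents, v)
    } else if (in_term && grepl("^is_obsolete:\\s*true", line)) {
      obsolete <- TRUE
    }
  }
  flush()
  # drop is_a references to terms not kept (e.g. obsolete parents)
  parents <- lapply(parents, function(p) intersect(p, names(parents)))
  dag_depth(parents)  # cycle check
  list(parents = parents, name = nm, namespace = ns)
}

#' Write a minimal OBO ontology file
#'
#' @param dag List with `parents` and optional `name`, `namespace`
#'   (as returned by [read_obo()] or held in a [go_universe()]).
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in names(dag$parents)) {
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste("id:", t), con)
    if (!is.null(dag$name) && !is.na(dag$name[t])) {
      writeLines(paste("name:", dag$name[t]), con)
    }
    if (!is.null(dag$namespace) && !is.na(dag$namespace[t])) {
      writeLines(paste("namespace:", dag$namespace[t]), con)
    }
    for (p in dag$parents[[t]]) writeLines(paste("is_a:", p), con)
  }
  invisible(path)
}

#' Read a multi-newick gene tree file
#'
#' Each line holds `cluster_id<TAB>gene_name<TAB>newick`. Leaf labels
#' follow the `genotype|sample|strain` scheme; when `genotypes` is
#' given, an unknown genotype prefix raises an error naming the cluster.
#'
#' @param path Path (gzip-transparent).
#' @param genotypes Optional vector of valid genotype codes.
#' @return A [gene_tree_set()].
#' @export
read_gene_trees <- function(path, genotypes = NULL) {
  if (!file.exists(path)) data_error(paste("file not found:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  entries <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3) {
      data_error(sprintf("%s line %d: expected cluster_id<TAB>gene_name<TAB>newick",
                         path, i))
    }
    tree <- tryCatch(ape::read.tree(text = parts[3]),
                     error = function(e) NULL,
                     warning = function(w) NULL)
    if (is.null(tree)) {
      data_error(sprintf("%s line %d (cluster %s): malformed newick",
                         path, i, parts[1]))
    }
    info <- tryCatch(parse_leaf_labels(tree$tip.label), error = function(e) {
      data_error(sprintf("%s line %d (cluster %s): %s", path, i, parts[1],
                         conditionMessage(e)))
    })
    if (!is.null(genotypes)) {
      bad <- setdiff(info$genotype, genotypes)
      if (length(bad) > 0) {
        data_error(sprintf("cluster %s: unknown genotype prefix(es): %s",
                           parts[1], paste(bad, collapse = ", ")))
      }
    }
    list(cluster_id = parts[1], gene_name = parts[2], tree = tree)
  })
  gene_tree_set(entries)
}

#' Write a gene tree set as a multi-newick file
#'
#' @param trees A [gene_tree_set()].
#' @param path Output path.
#' @export
write_gene_trees <- function(trees, path) {
  lines <- vapply(trees, function(e) {
    paste(e$cluster_id, e$gene_name, ape::write.tree(e$tree), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write headered TSV tables and outfmt-6 hit tables
#'
#' `read_tsv_table`/`write_tsv_table` handle headered tab-separated
#' tables (abundance matrices use the first column as row names when
#' `rownames_col` is set). `read_hits_tsv` reads the 12-column
#' header-less outfmt-6 dialect (qseqid, sseqid/taxon, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#'
#' @param path File path (gzip-transparent via [utils::read.table()]).
#' @param rownames_col Column name to use as row names (matrix output).
#' @return data.frame, or matrix when `rownames_col` is set.
#' @export
read_tsv_table <- function(path, rownames_col = NULL) {
  if (!file.exists(path)) data_error(paste("file not found:", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(rownames_col)) {
    if (!(rownames_col %in% colnames(df))) {
      data_error(sprintf("%s: missing column '%s'", path, rownames_col))
    }
    m <- as.matrix(df[setdiff(colnames(df), rownames_col)])
    rownames(m) <- df[[rownames_col]]
    return(m)
  }
  df
}

#' @rdname read_tsv_table
#' @param x data.frame or matrix to write.
#' @export
write_tsv_table <- function(x, path, rownames_col = NULL) {
  if (!is.null(rownames_col)) {
    x <- data.frame(stats::setNames(list(rownames(x)), rownames_col),
                    as.data.frame(x), check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_tsv_table
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) data_error(paste("file not found:", path))
  cols <- c("query", "subject_taxon", "percent_identity", "align_length",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "e_value", "bitscore")
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) != 12) {
    data_error(sprintf("%s: expected 12 outfmt-6 columns, found %d", path, ncol(df)))
  }
  colnames(df) <- cols
  df
}

#' @rdname read_tsv_table
#' @param hits Hit table to write (12 outfmt-6 columns).
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write every simulated pipeline input to a directory
#'
#' Materializes one full synthetic study on disk in the external
#' formats the pipeline reads: sample metadata TSV, abundance TSV,
#' scaffold/hit/read tables, Roary-dialect CSV, multi-newick gene tree
#' file, OBO ontology, gene-to-GO mapping TSV and the study gene list,
#' plus TSVs of the ground-truth labels.
#'
#' @param config A [sim_config()] object.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sim_inputs <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  comm <- simulate_communities(config)
  pan <- simulate_pangenome(config)
  go <- simulate_go(config)
  trees <- simulate_gene_trees(config)
  sc <- simulate_hits_and_scaffolds(config)

  write_tsv_table(comm$meta, p("samples.tsv"))
  write_tsv_table(comm$abundance, p("abundance.tsv"), rownames_col = "taxon")
  write_tsv_table(comm$truth, p("taxon_truth.tsv"))
  write_roary_csv(pan$clusters, p("gene_presence_absence.csv"))
  write_tsv_table(pan$truth, p("cluster_truth.tsv"))
  write_obo(list(parents = go$universe$parents, name = go$universe$name,
                 namespace = go$universe$namespace), p("ontology.obo"))
  g2t <- data.frame(
    gene = rep(names(go$universe$gene2terms), lengths(go$universe$gene2terms)),
    term = unlist(go$universe$gene2terms), row.names = NULL
  )
  write_tsv_table(g2t, p("gene2go.tsv"))
  writeLines(go$study_genes, p("study_genes.txt"))
  writeLines(go$truth$enriched_terms, p("enriched_truth.txt"))
  write_gene_trees(trees$trees, p("gene_trees.tsv"))
  write_tsv_table(trees$truth, p("tree_truth.tsv"))
  writeLines(ape::write.tree(musa_host_tree()), p("host_tree.nwk"))
  write_tsv_table(sc$scaffolds, p("scaffolds.tsv"))
  write_tsv_table(sc$reads, p("reads.tsv"))
  write_hits_tsv(sc$hits, p("hits.tsv"))
  invisible(stats::setNames(
    file.path(outdir, c("samples.tsv", "abundance.tsv", "taxon_truth.tsv",
                        "gene_presence_absence.csv", "cluster_truth.tsv",
                        "ontology.obo", "gene2go.tsv", "study_genes.txt",
                        "enriched_truth.txt", "gene_trees.tsv",
                        "tree_truth.tsv", "host_tree.nwk", "scaffolds.tsv",
                        "reads.tsv", "hits.tsv")),
    c("samples", "abundance", "taxon_truth", "roary", "cluster_truth",
      "obo", "gene2go", "study", "enriched_truth", "trees", "tree_truth",
      "host", "scaffolds", "reads", "hits")
  ))
}
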