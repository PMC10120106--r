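#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarity between samples (columns):
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`. Identical samples have
#' distance 0, samples with disjoint taxa have distance 1.
#'
#' @param table Non-negative numeric matrix, taxa x samples (>= 2 samples).
#' @return Symmetric numeric matrix with zero diagonal and sample labels.
#' @examples
#' bray_curtis(cbind(a = c(2, 1), b = c(1, 3)))["a", "b"]  # 3/7
#' @export
bray_curtis <- function(table) {
  table <- as.matrix(table)
  if (ncol(table) < 2) data_error("need at least 2 samples")
  if (any(table < 0)) data_error("counts must be non-negative")
  totals <- colSums(table)
  if (any(totals == 0)) {
    data_error(paste("sample(s) with zero total:",
                     paste(colnames(table)[totals == 0], collapse = ", ")))
  }
  n <- ncol(table)
  D <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sum(abs(table[, i] - table[, j])) / (totals[i] + totals[j])
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

check_distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) data_error("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-12) data_error("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) data_error("distance matrix must have zero diagonal")
  D
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the Gower double-centred matrix
#' `B = -1/2 J D^2 J` with `J = I - 11'/n`. Axes are ordered by
#' eigenvalue; only axes with positive eigenvalues contribute
#' coordinates, but all eigenvalues (including negative ones, which arise
#' for non-Euclidean dissimilarities such as Bray-Curtis) are reported.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @return List with `points` (n x k coordinate matrix, k = number of
#'   positive eigenvalues), `eigenvalues` (all n, sorted decreasing) and
#'   `prop_explained` (positive eigenvalues over their sum).
#' @export
pcoa <- function(D) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  pts <- if (length(pos) > 0) {
    sweep(e$vectors[, pos, drop = FALSE], 2, sqrt(e$values[pos]), "*")
  } else {
    matrix(0, n, 0)
  }
  rownames(pts) <- rownames(D)
  if (ncol(pts) > 0) colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  list(points = pts, eigenvalues = e$values,
       prop_explained = if (length(pos)) e$values[pos] / sum(e$values[pos]) else numeric(0))
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1,
#' `sqrt(sum (d_ij - dhat_ij)^2 / sum d_ij^2)`, over k-dimensional
#' configurations. Disparities `dhat` are the isotonic (monotone)
#' regression of configuration distances on the rank order of the input
#' dissimilarities; the configuration is updated by the Guttman transform
#' (iterative majorization) until the stress improvement falls below
#' `tol`. The best of `n_starts` random starts plus one PCoA start is
#' returned.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param k Target dimension (default 2).
#' @param n_starts Random restarts (default 20).
#' @param max_iter Majorization iterations per start (default 300).
#' @param tol Convergence tolerance on stress (default 1e-6).
#' @param seed Integer seed for the random starts.
#' @return List with `points` (n x k), `stress` (Kruskal stress-1) and
#'   `converged`.
#' @export
nmds <- function(D, k = 2, n_starts = 20, max_iter = 300, tol = 1e-6, seed = 1) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  if (n < k + 1) data_error("need at least k + 1 samples")
  lower <- D[lower.tri(D)]
  if (stats::sd(lower) == 0) {
    data_error("degenerate dissimilarity matrix: all off-diagonal values equal")
  }
  ord <- order(lower)
  pair_i <- row(D)[lower.tri(D)]
  pair_j <- col(D)[lower.tri(D)]

  run_start <- function(X) {
    stress <- Inf
    for (it in seq_len(max_iter)) {
      d <- sqrt(rowSums((X[pair_i, , drop = FALSE] - X[pair_j, , drop = FALSE])^2))
      fit <- stats::isoreg(d[ord])
      dhat <- numeric(length(d))
      dhat[ord] <- fit$yf
      new_stress <- sqrt(sum((d - dhat)^2) / sum(d^2))
      # Guttman transform with ratios dhat/d (0 distances guarded)
      ratio <- ifelse(d > 1e-12, dhat / d, 0)
      B <- matrix(0, n, n)
      B[cbind(pair_i, pair_j)] <- -ratio
      B[cbind(pair_j, pair_i)] <- -ratio
      diag(B) <- -rowSums(B)
      X_new <- B %*% X / n
      if (is.finite(stress) && stress - new_stress < tol) {
        return(list(points = X, stress = new_stress, converged = TRUE))
      }
      stress <- new_stress
      X <- X_new
    }
    list(points = X, stress = stress, converged = FALSE)
  }

  local_seed(seed, {
    starts <- vector("list", n_starts + 1)
    p <- pcoa(D)
    X0 <- cbind(p$points, matrix(0, n, max(0, k - ncol(p$points))))[, seq_len(k), drop = FALSE]
    starts[[1]] <- X0
    for (s in seq_len(n_starts)) {
      starts[[s + 1]] <- matrix(stats::rnorm(n * k), n, k)
    }
    best <- NULL
    for (X in starts) {
      res <- run_start(scale(X, center = TRUE, scale = FALSE))
      if (is.null(best) || res$stress < best$stress) best <- res
    }
    rownames(best$points) <- rownames(D)
    colnames(best$points) <- paste0("NMDS", seq_len(k))
    best
  })
}
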