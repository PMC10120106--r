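#' Permutational multivariate analysis of variance (one factor)
#'
#' PERMANOVA on a dissimilarity matrix for a single grouping factor, the
#' distance-based pseudo-F of Anderson's method:
#' `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `F = ((SS_total - SS_within) / (a - 1)) / (SS_within / (N - a))`.
#' Significance comes from permuting group labels. When the number of
#' distinct label arrangements is at most `exhaustive_limit` the exact
#' permutation distribution is enumerated and
#' `p = #(F_perm >= F_obs) / n_arrangements` (the observed arrangement
#' included); otherwise `n_perm` random permutations give
#' `p = (1 + #(F_perm >= F_obs)) / (n_perm + 1)`.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param groups Factor-like vector of group labels, one per sample.
#' @param n_perm Random permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exhaustive_limit Enumerate exactly when the number of distinct
#'   arrangements is at most this (default 10000); set 0 to force sampling.
#' @return List with `pseudo_F`, `p`, `n_perm_used`, `exhaustive`,
#'   `ss_total`, `ss_within`.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = 1, exhaustive_limit = 10000) {
  D <- check_distance_matrix(D)
  groups <- as.factor(groups)
  if (length(groups) != nrow(D)) data_error("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2) data_error("need at least 2 groups")
  groups <- droplevels(groups)
  if (any(table(groups) == 0)) data_error("empty group")
  N <- nrow(D)
  a <- nlevels(groups)
  D2 <- D^2
  ss_total <- sum(D2[lower.tri(D2)]) / N

  ss_within_for <- function(g) {
    s <- 0
    for (lev in levels(groups)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        sub <- D2[idx, idx]
        s <- s + sum(sub[lower.tri(sub)]) / length(idx)
      }
    }
    s
  }
  f_for <- function(g) {
    ssw <- ss_within_for(g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (N - a))
  }
  f_obs <- f_for(groups)

  sizes <- table(groups)
  n_arrange <- exp(lgamma(N + 1) - sum(lgamma(sizes + 1)))
  if (exhaustive_limit > 0 && n_arrange <= exhaustive_limit + 0.5) {
    perms <- enumerate_assignments(as.integer(sizes))
    fs <- vapply(perms, function(assign) {
      f_for(factor(levels(groups)[assign], levels = levels(groups)))
    }, numeric(1))
    p <- sum(fs >= f_obs - 1e-12) / length(fs)
    return(list(pseudo_F = f_obs, p = p, n_perm_used = length(fs),
                exhaustive = TRUE, ss_total = ss_total,
                ss_within = ss_within_for(groups)))
  }
  local_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      g <- groups[sample.int(N)]
      if (f_for(g) >= f_obs - 1e-12) exceed <- exceed + 1L
    }
    list(pseudo_F = f_obs, p = (1 + exceed) / (n_perm + 1),
         n_perm_used = n_perm, exhaustive = FALSE,
         ss_total = ss_total, ss_within = ss_within_for(groups))
  })
}

# All distinct assignments of N = sum(sizes) items to groups with the given
# sizes, as integer vectors of group indices (1-based). Recursive over
# combinations; used by the exhaustive PERMANOVA mode.
enumerate_assignments <- function(sizes) {
  N <- sum(sizes)
  out <- list()
  rec <- function(remaining, g, assign) {
    if (g == length(sizes)) {
      assign[remaining] <- g
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes[g], simplify = FALSE)
    for (p in picks) {
      a <- assign
      a[p] <- g
      rec(setdiff(remaining, p), g + 1, a)
    }
  }
  rec(seq_len(N), 1, integer(N))
  out
}

#' Welch's t-test and one-way ANOVA from formulas
#'
#' `kind = "welch_t"`: two-sample Welch t statistic
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Satterthwaite degrees
#' of freedom and a two-sided p-value. `kind = "anova"`: one-way ANOVA
#' `F = (SSB / (a - 1)) / (SSW / (N - a))` with the upper-tail p-value.
#' Groups with zero between-group variance give statistic 0 and p 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation.
#' @param kind `"welch_t"` (exactly 2 groups, >= 2 values each) or
#'   `"anova"`.
#' @return List with `statistic`, `p`, `df` (Welch df, or c(df1, df2) for
#'   ANOVA).
#' @examples
#' group_tests(c(1, 2, 3, 4, 3, 4, 5, 6), rep(c("a", "b"), each = 4), "welch_t")
#' @export
group_tests <- function(values, groups, kind = c("welch_t", "anova")) {
  kind <- match.arg(kind)
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  split_vals <- split(as.numeric(values), groups)
  if (kind == "welch_t") {
    if (length(split_vals) != 2) data_error("welch_t requires exactly 2 groups")
    if (any(lengths(split_vals) < 2)) data_error("welch_t requires >= 2 values per group")
    x <- split_vals[[1]]; y <- split_vals[[2]]
    vx <- stats::var(x) / length(x)
    vy <- stats::var(y) / length(y)
    if (vx + vy == 0) {
      if (mean(x) == mean(y)) return(list(statistic = 0, p = 1, df = NA_real_))
      data_error("zero variance in both groups with unequal means")
    }
    t <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    list(statistic = t, p = 2 * stats::pt(-abs(t), df), df = df)
  } else {
    a <- length(split_vals)
    if (a < 2) data_error("anova requires >= 2 groups")
    N <- length(values)
    if (N - a < 1) data_error("anova requires residual degrees of freedom")
    grand <- mean(as.numeric(values))
    ssb <- sum(vapply(split_vals, function(v) length(v) * (mean(v) - grand)^2,
                      numeric(1)))
    ssw <- sum(vapply(split_vals, function(v) sum((v - mean(v))^2), numeric(1)))
    if (ssw == 0 && ssb == 0) return(list(statistic = 0, p = 1, df = c(a - 1, N - a)))
    f <- (ssb / (a - 1)) / (ssw / (N - a))
    list(statistic = f, p = stats::pf(f, a - 1, N - a, lower.tail = FALSE),
         df = c(a - 1, N - a))
  }
}
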