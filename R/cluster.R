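# Cluster-based permutation test over time: per-timepoint paired t statistics,
# suprathreshold clustering with mass = sum of t, and a max-|mass| null built
# by sign-flipping each participant's condition-difference trace (equivalent
# to swapping condition labels within participant, the exact permutation
# scheme for a paired design).

#' Permutation-test configuration
#'
#' @param n_permutations Monte-Carlo draws (default 1000).
#' @param mode `"monte_carlo"` (random sign flips) or `"exhaustive"` (all
#'   `2^P` flip patterns; only allowed for `P <= exhaustive_cap`).
#' @param alpha_cluster two-sided per-timepoint threshold used to form
#'   clusters (default .05).
#' @param alpha_final per-locking significance level; the default .017 is the
#'   Bonferroni-corrected .05/3 for the three time-lockings.
#' @param seed RNG seed for the Monte-Carlo flips (required for
#'   reproducibility; recorded in the result).
#' @param exhaustive_cap largest P for which exhaustive enumeration is allowed.
#' @return list of class `artidelta_permutation_spec`.
#' @export
permutation_spec <- function(n_permutations = 1000L,
                             mode = c("monte_carlo", "exhaustive"),
                             alpha_cluster = 0.05,
                             alpha_final = 0.017,
                             seed = 1L,
                             exhaustive_cap = 16L) {
  mode <- match.arg(mode)
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (alpha_cluster <= 0 || alpha_cluster >= 1 || alpha_final <= 0 || alpha_final >= 1)
    stop("alpha levels must lie strictly inside (0, 1)")
  structure(list(n_permutations = as.integer(n_permutations), mode = mode,
                 alpha_cluster = alpha_cluster, alpha_final = alpha_final,
                 seed = as.integer(seed), exhaustive_cap = as.integer(exhaustive_cap)),
            class = "artidelta_permutation_spec")
}

#' Per-timepoint paired t statistics
#'
#' For each timepoint (column), `t = mean(d) / (sd(d) / sqrt(P))` over the
#' participant differences `d = early - late`, with `df = P - 1`. Columns with
#' zero variance yield t = 0 when the mean is also 0 (0/0 by convention;
#' cannot seed clusters) and signed `Inf` otherwise; the latter are flagged in
#' `degenerate` and remain suprathreshold in clustering (a noise-free constant
#' offset is detected, with infinite cluster mass).
#'
#' @param matrix_ep,matrix_lp P x T matrices of per-participant mean traces.
#' @param grid_times optional length-T time vector carried through.
#' @return list of class `artidelta_t_series`: `grid_times`, `t_values`, `df`,
#'   `degenerate`.
#' @export
paired_t_series <- function(matrix_ep, matrix_lp, grid_times = NULL) {
  if (!all(dim(matrix_ep) == dim(matrix_lp)))
    stop("matrices must have identical dimensions")
  P <- nrow(matrix_ep)
  if (P < 2L) stop("paired t requires at least 2 participants")
  D <- matrix_ep - matrix_lp
  m <- colMeans(D)
  v <- colSums(sweep(D, 2L, m)^2) / (P - 1L)
  t_values <- ifelse(v > 0, m / sqrt(v / P), ifelse(m == 0, 0, sign(m) * Inf))
  degenerate <- which(v <= 0 & m != 0)
  structure(list(grid_times = grid_times %||% seq_along(m),
                 t_values = t_values, df = P - 1L, degenerate = degenerate),
            class = "artidelta_t_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cluster masses of one t vector: maximal runs of contiguous suprathreshold
# same-sign timepoints. Signed infinities (zero-variance, nonzero-mean
# columns) are suprathreshold like any other value; NaN (0/0 columns) counts
# as 0 and cannot seed a cluster. Shared by the observed path and the
# permutation loop.
scan_clusters <- function(t_values, t_crit) {
  tv <- ifelse(is.nan(t_values), 0, t_values)
  lab <- integer(length(tv))
  lab[tv > t_crit] <- 1L
  lab[tv < -t_crit] <- -1L
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep))
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      sign = integer(0), mass = numeric(0)))
  s <- starts[keep]; e <- ends[keep]
  mass <- vapply(seq_along(s), function(i) sum(tv[s[i]:e[i]]), 0)
  data.frame(start_idx = s, end_idx = e, sign = r$values[keep], mass = mass)
}

#' Form suprathreshold clusters from a t series
#'
#' Timepoints with `|t|` above the two-sided critical value at `alpha_cluster`
#' (df from the series) are grouped into maximal runs of contiguous same-sign
#' timepoints; single-timepoint clusters are allowed. Cluster mass is the sum
#' of member t values (the "SumT" statistic).
#'
#' @param tseries an `artidelta_t_series`.
#' @param alpha_cluster two-sided per-timepoint alpha (default .05).
#' @return data.frame with `start_idx`, `end_idx`, `start_time`, `end_time`,
#'   `sign` (+1/-1), `mass`, `n_timepoints`; zero rows if nothing is
#'   suprathreshold.
#' @export
form_clusters <- function(tseries, alpha_cluster = 0.05) {
  stopifnot(inherits(tseries, "artidelta_t_series"))
  t_crit <- stats::qt(1 - alpha_cluster / 2, tseries$df)
  cl <- scan_clusters(tseries$t_values, t_crit)
  cl$start_time <- tseries$grid_times[cl$start_idx]
  cl$end_time <- tseries$grid_times[cl$end_idx]
  cl$n_timepoints <- cl$end_idx - cl$start_idx + 1L
  cl[, c("start_idx", "end_idx", "start_time", "end_time", "sign", "mass", "n_timepoints")]
}

# All 2^P sign patterns as a (2^P) x P matrix of +/-1.
exhaustive_signs <- function(P) {
  n <- 2L^P
  S <- matrix(1, n, P)
  for (j in seq_len(P)) {
    S[, j] <- rep(rep(c(1, -1), each = 2L^(P - j)), length.out = n)
  }
  S
}

#' Permutation null distribution of the maximum cluster mass
#'
#' Each permutation flips the sign of each participant's difference trace
#' (equivalently swaps the condition labels within that participant),
#' recomputes the paired t series and its clusters, and records the maximum
#' `|mass|` over clusters (0 when no timepoint is suprathreshold). A single
#' symmetric max-`|mass|` null serves both positive and negative observed
#' clusters. The per-permutation t series exploits the fact that flipping
#' signs leaves each column's sum of squares unchanged, so the whole null is
#' computed with one matrix product.
#'
#' @param differences P x T matrix of participant difference traces.
#' @param spec a [permutation_spec()].
#' @return numeric vector of max-|mass| values (length `n_permutations`, or
#'   `2^P` in exhaustive mode) with attributes `t_crit` and `mode`.
#' @export
permutation_null <- function(differences, spec = permutation_spec()) {
  stopifnot(is.matrix(differences))
  P <- nrow(differences)
  if (P < 2L) stop("permutation test requires at least 2 participants")
  if (spec$mode == "exhaustive") {
    if (P > spec$exhaustive_cap)
      stop("exhaustive enumeration with P = ", P, " exceeds the cap (",
           spec$exhaustive_cap, "); use monte_carlo mode")
    S <- exhaustive_signs(P)
  } else {
    set.seed(spec$seed)
    S <- matrix(sample(c(-1, 1), spec$n_permutations * P, replace = TRUE),
                spec$n_permutations, P)
  }
  Tn <- ncol(differences)
  css <- colSums(differences^2)             # invariant under sign flips
  M <- (S %*% differences) / P
  V <- sweep(-P * M^2, 2L, css, "+") / (P - 1L)
  V[V < 0] <- 0                             # guard tiny negative rounding
  Tm <- M / sqrt(V / P)
  Tm[is.nan(Tm)] <- 0
  t_crit <- stats::qt(1 - spec$alpha_cluster / 2, P - 1L)
  null <- vapply(seq_len(nrow(S)), function(i) {
    cl <- scan_clusters(Tm[i, ], t_crit)
    if (nrow(cl) == 0L) 0 else max(abs(cl$mass))
  }, 0)
  attr(null, "t_crit") <- t_crit
  attr(null, "mode") <- spec$mode
  null
}

#' Cluster-based permutation test between two conditions
#'
#' Runs the full statistic: per-timepoint paired t-tests between the two
#' condition matrices, suprathreshold clustering at `alpha_cluster`, and a
#' Monte-Carlo (or exhaustive) sign-flip null of the maximum cluster `|mass|`.
#' In Monte-Carlo mode each cluster's p value uses the positively biased
#' `(1 + k) / (1 + n)` estimator (k = null draws at least as large as the
#' observed `|mass|`, ties counting as larger), which cannot return 0; in
#' exhaustive mode the exact proportion over all `2^P` patterns (which include
#' the identity) is used. A cluster is significant when `p < alpha_final`.
#'
#' @param matrix_ep,matrix_lp P x T condition matrices.
#' @param grid_times length-T time vector.
#' @param spec a [permutation_spec()].
#' @return list of class `artidelta_cluster_result`: `tseries`, `clusters`
#'   (with `p_value` and `significant`), `null` (the max-|mass| draws), and
#'   the spec.
#' @export
cluster_test <- function(matrix_ep, matrix_lp, grid_times = NULL,
                         spec = permutation_spec()) {
  ts <- paired_t_series(matrix_ep, matrix_lp, grid_times)
  clusters <- form_clusters(ts, spec$alpha_cluster)
  null <- permutation_null(matrix_ep - matrix_lp, spec)
  n_null <- length(null)
  p <- vapply(clusters$mass, function(m) {
    am <- abs(m)
    k <- if (is.finite(am)) sum(null >= am - 1e-12 * max(1, am))  # ties count as >=
         else sum(is.infinite(null))
    if (spec$mode == "exhaustive") k / n_null else (1 + k) / (1 + n_null)
  }, 0)
  clusters$p_value <- p
  clusters$significant <- p < spec$alpha_final
  structure(list(tseries = ts, clusters = clusters, null = null, spec = spec),
            class = "artidelta_cluster_result")
}

#' @export
print.artidelta_cluster_result <- function(x, ...) {
  cat("Cluster-based permutation test (", x$spec$mode, ", ",
      length(x$null), " permutations, alpha_final = ", x$spec$alpha_final,
      ")\n", sep = "")
  if (nrow(x$clusters) == 0L) {
    cat("No suprathreshold clusters.\n")
  } else {
    df <- x$clusters
    df$mass <- round(df$mass, 1)
    print(df[, c("start_time", "end_time", "sign", "mass", "p_value", "significant")],
          row.names = FALSE)
  }
  invisible(x)
}
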