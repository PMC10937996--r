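#' Euclidean straight-line null trajectory between weighted networks
#'
#' Equally spaced points from `W0` toward `WT`:
#' `W^t = W0 + t (WT - W0) / n_points` for `t = 1..n_points`; the last point
#' equals `WT` exactly. Serves as the null model against which the Ricci flow
#' trajectory is compared.
#'
#' @param W0,WT [edge_field()]s of start and end weights on a shared edge set.
#' @param n_points number of points (default 150).
#' @return list of [edge_field()]s of length `n_points`.
#' @export
linear_trajectory <- function(W0, WT, n_points = 150L) {
  check_same_edges(W0, WT)
  step <- (WT$values - W0$values) / n_points
  lapply(seq_len(n_points), function(t) {
    out <- W0
    # pin the endpoint exactly; floating-point t*step need not land on WT
    out$values <- if (t == n_points) WT$values else W0$values + t * step
    out
  })
}

#' Euclidean distance between two edge fields
#'
#' L2 norm over the unique undirected edges (each edge counted once; the
#' full-symmetric-matrix distance is this times `sqrt(2)`, a monotone
#' rescaling that leaves closest-pass orderings unchanged).
#'
#' @param Wa,Wb [edge_field()]s on a shared edge set.
#' @return scalar distance.
#' @export
edge_distance <- function(Wa, Wb) {
  check_same_edges(Wa, Wb)
  sqrt(sum((Wa$values - Wb$values)^2))
}

#' Closest-pass ordering of true samples along a trajectory
#'
#' For each true weighted network, finds the trajectory point minimising the
#' Euclidean edge distance (ties broken toward the smallest iteration), then
#' correlates the closest-pass iteration with the true time via Pearson's
#' test (two-sided, significance conventionally at the 5% level).
#'
#' The main statistic uses the intermediate time points only (flagged by
#' `intermediate`); `pearson_r_all`/`p_value_all` additionally report the
#' variant that includes every supplied point (by construction the final time
#' point sits at the last iteration, so including it can only inflate the
#' correlation).
#'
#' @param trajectory a `flow_trajectory` (its predicted weight fields
#'   `1/d_r`, `r = 1..n_iter`, are used) or a list of [edge_field()]s.
#' @param truths list of true weighted-network [edge_field()]s.
#' @param true_times numeric vector of the truths' measurement times.
#' @param intermediate logical vector flagging which truths are intermediate
#'   time points; default all of them.
#' @return object of class `ordering_result`: `closest_pass`, `min_distance`,
#'   `pearson_r`, `p_value` (intermediate points), `pearson_r_all`,
#'   `p_value_all` (all points), `n_points`.
#' @export
closest_pass_ordering <- function(trajectory, truths, true_times,
                                  intermediate = rep(TRUE, length(truths))) {
  if (inherits(trajectory, "flow_trajectory"))
    trajectory <- trajectory_weights(trajectory)
  if (!length(trajectory)) stop("trajectory is empty")
  stopifnot(length(truths) == length(true_times),
            length(intermediate) == length(truths))
  iters <- as.integer(names(trajectory))
  if (any(is.na(iters))) iters <- seq_along(trajectory)

  dist_mat <- vapply(truths, function(tr)
    vapply(trajectory, edge_distance, numeric(1), Wb = tr),
    numeric(length(trajectory)))
  best <- apply(dist_mat, 2, which.min)  # ties: earliest pass
  closest <- iters[best]
  min_d <- dist_mat[cbind(best, seq_along(truths))]

  cor_or_na <- function(a, b) {
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0)
      return(list(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(a, b, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  mid <- cor_or_na(closest[intermediate], true_times[intermediate])
  all_pts <- cor_or_na(closest, true_times)

  structure(
    list(closest_pass = closest, min_distance = min_d,
         pearson_r = mid$r, p_value = mid$p,
         pearson_r_all = all_pts$r, p_value_all = all_pts$p,
         n_points = length(trajectory)),
    class = "ordering_result")
}

#' @export
print.ordering_result <- function(x, ...) {
  cat("closest-pass ordering over", x$n_points, "trajectory points\n")
  cat("  closest pass:", paste(x$closest_pass, collapse = ", "), "\n")
  cat(sprintf("  Pearson r = %.4f (p = %.3g) on intermediate points\n",
              x$pearson_r, x$p_value))
  invisible(x)
}

#' Correlation between network entropy and total curvature across samples
#'
#' @param entropy numeric vector of entropy rates, one per sample.
#' @param curvature numeric vector of total Forman-Ricci curvatures.
#' @return list with `r` (Pearson correlation) and `p` (two-sided,
#'   t-distribution).
#' @export
correlate_entropy_curvature <- function(entropy, curvature) {
  stopifnot(length(entropy) == length(curvature))
  if (length(entropy) < 3) stop("need at least 3 samples")
  ct <- stats::cor.test(entropy, curvature, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Compare two independent Pearson correlations via Fisher's z
#'
#' Two-sided test of `r1 == r2` for correlations estimated on independent
#' groups: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param r1,r2 sample correlations, strictly inside (-1, 1).
#' @param n1,n2 group sizes, each > 3.
#' @return two-sided p-value.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("both group sizes must exceed 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("correlations must lie in (-1, 1)")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * stats::pnorm(-abs(z))
}
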