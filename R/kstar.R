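#' Closed-form network entropy of the k-star toy network
#'
#' The k-star has one hub connected to `k` leaves; all nodes carry weight 1
#' except one distinguished leaf with weight `eps > 0`. Only the hub has
#' positive local entropy, and the hub's stationary probability is 1/2
#' regardless of `k` and `eps`, giving
#'
#' \deqn{S_R = -\tfrac12\Big[\tfrac{\epsilon}{k+\epsilon-1}
#'   \log\tfrac{\epsilon}{k+\epsilon-1} + \tfrac{k-1}{k+\epsilon-1}
#'   \log\tfrac{1}{k+\epsilon-1}\Big]}
#'
#' maximal at `eps = 1` (value `log(k)/2`) for every `k`.
#'
#' @param k integer >= 2, number of leaves.
#' @param eps positive weight of the distinguished leaf (vectorised).
#' @return entropy rate(s) in nats.
#' @export
#' @examples
#' star_entropy(3, 1)  # log(3)/2
star_entropy <- function(k, eps) {
  check_star_params(k, eps)
  K <- k + eps - 1
  -0.5 * (eps / K * log(eps / K) + (k - 1) / K * log(1 / K))
}

#' Closed-form total Forman-Ricci curvature of the k-star
#'
#' Stationary-weighted mean of the nodal curvatures, assembled from the
#' per-edge half-terms `r_F(l|i) = 1`,
#' `r_F(i|l) = (3 - k - sqrt(eps))/k` and
#' `r_F(i|j) = (1 - (k-1)/sqrt(eps))/k`:
#'
#' \deqn{R_F = \tfrac{1}{2k}\big[k + \tfrac1k(1-(k-1)\epsilon^{-1/2}) +
#'   \tfrac{k-1}{k}(3-k-\sqrt\epsilon)\big] +
#'   \tfrac{\epsilon}{2(k+\epsilon-1)}\big[1 +
#'   \tfrac1k(1-(k-1)\epsilon^{-1/2})\big] +
#'   \tfrac{k-1}{2(k+\epsilon-1)}\big[1 + \tfrac1k(3-k-\sqrt\epsilon)\big]}
#'
#' The leaf nodal curvature is `1 + (3 - k - sqrt(eps))/k` (one incident
#' edge, so the nodal mean is that edge's curvature).
#'
#' @inheritParams star_entropy
#' @return total curvature(s).
#' @export
#' @examples
#' star_total_curvature(2, 1)  # exactly 1
star_total_curvature <- function(k, eps) {
  check_star_params(k, eps)
  K <- k + eps - 1
  hub <- (1 / k) * (k + (1 / k) * (1 - (k - 1) / sqrt(eps)) +
                      ((k - 1) / k) * (3 - k - sqrt(eps)))
  leaf_j <- 1 + (1 / k) * (1 - (k - 1) / sqrt(eps))
  leaf_l <- 1 + (1 / k) * (3 - k - sqrt(eps))
  0.5 * hub + eps / (2 * K) * leaf_j + (k - 1) / (2 * K) * leaf_l
}

#' Closed-form stationary distribution of the k-star
#'
#' @inheritParams star_entropy
#' @return list with components `hub` (= 1/2), `leaf` (plain leaf,
#'   `1/(2(k+eps-1))`) and `j` (distinguished leaf, `eps/(2(k+eps-1))`).
#' @export
star_stationary <- function(k, eps) {
  check_star_params(k, eps)
  K <- k + eps - 1
  list(hub = rep(0.5, length(eps)), leaf = 1 / (2 * K), j = eps / (2 * K))
}

check_star_params <- function(k, eps) {
  if (length(k) != 1 || k != round(k) || k < 2)
    stop("k must be a single integer >= 2")
  if (any(eps <= 0)) stop("eps must be positive")
  invisible(TRUE)
}

#' Regime scan of entropy and curvature over the k-star parameter space
#'
#' Evaluates the closed forms on a dense `eps` grid for each `k` and reports
#' the local sign of the entropy-curvature association via grid derivatives
#' (`d S_R / d eps * d R_F / d eps`): +1 where the two move together, -1
#' where they oppose. Derivatives on the grid, rather than sampled Pearson
#' correlations, make the regime boundary crisp.
#'
#' @param k_range integer vector of `k` values (default 2..20).
#' @param eps_grid increasing grid of positive `eps` values (default
#'   `[0.01, 10]` in steps of 0.001).
#' @return data.frame with columns `k`, `eps` (interval midpoints), `S_R`,
#'   `R_F` and `assoc_sign`.
#' @export
regime_scan <- function(k_range = 2:20,
                        eps_grid = seq(0.01, 10, by = 0.001)) {
  do.call(rbind, lapply(k_range, function(k) {
    S <- star_entropy(k, eps_grid)
    R <- star_total_curvature(k, eps_grid)
    dS <- diff(S)
    dR <- diff(R)
    mid <- (eps_grid[-1] + eps_grid[-length(eps_grid)]) / 2
    data.frame(k = k, eps = mid,
               S_R = (S[-1] + S[-length(S)]) / 2,
               R_F = (R[-1] + R[-length(R)]) / 2,
               assoc_sign = sign(dS * dR))
  }))
}

#' Anticorrelated eps-range above 1, per k
#'
#' Summarises a [regime_scan()]: for each `k`, the `eps > 1` region where
#' entropy and total curvature move in opposite directions (entropy falls
#' while curvature still rises — the "one for many" signalling regime). For
#' `k = 2` this region is empty (both measures peak at `eps = 1`); for
#' `k >= 3` it is nonempty and widens with `k`.
#'
#' @param scan a data.frame from [regime_scan()].
#' @return data.frame with one row per `k`: `eps_lo`, `eps_hi`, `width` (0
#'   and `NA` bounds when the region is empty).
#' @export
#' @examples
#' anticorrelated_range(regime_scan(k_range = c(2, 5, 20)))
anticorrelated_range <- function(scan) {
  do.call(rbind, lapply(split(scan, scan$k), function(s) {
    anti <- s$assoc_sign < 0 & s$eps > 1
    step <- diff(s$eps[1:2])
    data.frame(k = s$k[1],
               eps_lo = if (any(anti)) min(s$eps[anti]) else NA_real_,
               eps_hi = if (any(anti)) max(s$eps[anti]) else NA_real_,
               width = sum(anti) * step)
  }))
}
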