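# Pairwise-coalescent TMRCA posterior decoding over windows.

#' Posterior TMRCA grid for a haplotype pair
#'
#' Hidden Markov model over consecutive windows of a haplotype pair: the
#' hidden state of window `w` is its coalescence-time bin `T_j`
#' (generations); the emission for an observed pairwise difference count `k`
#' is `Poisson(2 * mu * L * T_j)`; at each window boundary the chain stays
#' on its bin with probability `1 - switch_prob` and otherwise switches to a
#' bin drawn from the prior.  Posteriors come from scaled forward-backward
#' and sum to one per window.
#'
#' @param diff_counts Integer vector: pairwise differences per window.
#' @param L Window length in bp.
#' @param mu Mutation rate per bp per generation.
#' @param time_bins Strictly increasing vector (>= 2) of TMRCA bin values in
#'   generations.
#' @param prior Prior over bins (default uniform); must not be all zero.
#' @param switch_prob Probability of resampling the bin at a window boundary
#'   (default 0.1).
#' @return A `tmrca_grid`: posterior matrix (windows x bins), `bins`,
#'   `posterior_mean` per window, and the model settings.
#' @export
pairwise_tmrca_posterior <- function(diff_counts, L, mu, time_bins,
                                     prior = NULL, switch_prob = 0.1) {
  if (any(diff_counts < 0)) abort("difference counts must be >= 0")
  if (length(time_bins) < 2 || any(diff(time_bins) <= 0)) {
    abort("`time_bins` must be >= 2 strictly increasing values")
  }
  prior <- prior %||% rep(1 / length(time_bins), length(time_bins))
  if (all(prior == 0)) abort("prior must not be all zero")
  prior <- prior / sum(prior)
  if (switch_prob < 0 || switch_prob > 1) abort("`switch_prob` in [0,1]")

  n <- length(diff_counts)
  nb <- length(time_bins)
  lambda <- 2 * mu * L * time_bins
  B <- vapply(seq_len(nb), function(j) dpois(diff_counts, lambda[j]),
              numeric(n))
  B <- matrix(B, nrow = n)
  A <- (1 - switch_prob) * diag(nb) +
    switch_prob * matrix(prior, nb, nb, byrow = TRUE)

  alpha <- matrix(0, n, nb)
  beta <- matrix(0, n, nb)
  scale <- numeric(n)
  a <- prior * B[1, ]
  scale[1] <- sum(a)
  if (scale[1] == 0) abort("zero likelihood in first window: check mu, L, bins")
  alpha[1, ] <- a / scale[1]
  if (n >= 2) {
    for (t in 2:n) {
      a <- as.numeric(alpha[t - 1, ] %*% A) * B[t, ]
      scale[t] <- sum(a)
      alpha[t, ] <- a / scale[t]
    }
  }
  beta[n, ] <- 1
  if (n >= 2) {
    for (t in (n - 1):1) {
      b <- A %*% (B[t + 1, ] * beta[t + 1, ])
      beta[t, ] <- b / scale[t + 1]
    }
  }
  post <- alpha * beta
  post <- post / rowSums(post)

  structure(
    list(posterior = post, bins = time_bins,
         posterior_mean = as.numeric(post %*% time_bins),
         diff_counts = diff_counts, L = L, mu = mu, prior = prior,
         switch_prob = switch_prob, loglik = sum(log(scale))),
    class = "tmrca_grid"
  )
}

#' @export
print.tmrca_grid <- function(x, ...) {
  cat(sprintf(
    "<tmrca_grid> %d windows x %d time bins (%.3g - %.3g generations)\n",
    nrow(x$posterior), length(x$bins), min(x$bins), max(x$bins)))
  invisible(x)
}

#' Fraction of TMRCA posterior mass below a recent-time threshold
#'
#' A sweep compresses coalescence times among carrier haplotypes, so an
#' excess of posterior mass on recent bins is a sweep signal.
#'
#' @param grid A `tmrca_grid`.
#' @param recent_threshold Threshold in generations (within the bin range).
#' @return List with `per_window` (score in `[0, 1]` per window) and
#'   `aggregate` (their mean).
#' @export
sweep_score <- function(grid, recent_threshold) {
  if (!inherits(grid, "tmrca_grid")) abort("`grid` must be a tmrca_grid")
  if (recent_threshold < min(grid$bins) ||
      recent_threshold > max(grid$bins)) {
    abort("`recent_threshold` must lie within the bin range")
  }
  recent <- grid$bins < recent_threshold
  per_window <- as.numeric(grid$posterior[, recent, drop = FALSE] %*%
                             rep(1, sum(recent)))
  list(per_window = per_window, aggregate = mean(per_window))
}
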