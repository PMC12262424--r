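# Two-state windowed HMM over private-variant counts.
#
# State 1 ("modern") and state 2 ("archaic") emit Poisson counts with rates
# lambda * callable_fraction; forward-backward uses per-window normalization
# constants so posteriors stay finite for arbitrarily long chromosomes.

#' Construct HMM parameters for introgression detection
#'
#' @param init Length-2 initial state probabilities (modern, archaic).
#' @param trans 2x2 transition matrix, rows summing to 1.
#' @param lambda Length-2 Poisson emission rates (expected private variants
#'   per fully callable window) for the modern and archaic states.
#' @return An object of class `hmm_params`.
#' @examples
#' hmm_params(c(0.95, 0.05), rbind(c(0.999, 0.001), c(0.02, 0.98)),
#'            c(0.3, 4))
#' @export
hmm_params <- function(init, trans, lambda) {
  trans <- matrix(as.numeric(trans), 2, 2)
  if (length(init) != 2 || length(lambda) != 2) {
    abort("two states expected: modern and archaic")
  }
  if (any(init < 0 | init > 1) || abs(sum(init) - 1) > 1e-8) {
    abort("`init` must be probabilities summing to 1")
  }
  if (any(trans < 0 | trans > 1) || any(abs(rowSums(trans) - 1) > 1e-8)) {
    abort("`trans` rows must be probabilities summing to 1")
  }
  if (any(lambda < 0)) abort("`lambda` must be non-negative")
  structure(list(init = as.numeric(init), trans = trans,
                 lambda = as.numeric(lambda),
                 states = c("modern", "archaic")),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> lambda:", sprintf("%.4g", x$lambda),
      "| stay:", sprintf("%.5g", diag(x$trans)),
      "| init:", sprintf("%.3g", x$init), "\n")
  invisible(x)
}

# Emission probability matrix (n x 2), linear scale.
emission_matrix <- function(count, callable, lambda) {
  cbind(dpois(count, lambda[1] * callable),
        dpois(count, lambda[2] * callable))
}

# Scaled forward-backward.  Returns per-window posteriors, the data
# log-likelihood, and the expected transition counts needed by Baum-Welch.
forward_backward <- function(count, callable, params,
                             want_xi = FALSE) {
  n <- length(count)
  B <- emission_matrix(count, callable, params$lambda)
  A <- params$trans
  alpha <- matrix(0, n, 2)
  beta <- matrix(0, n, 2)
  scale <- numeric(n)

  a <- params$init * B[1, ]
  scale[1] <- sum(a)
  alpha[1, ] <- a / scale[1]
  if (n >= 2) {
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% A) * B[t, ]
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

  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)

  xi_sum <- NULL
  if (want_xi) {
    xi_sum <- matrix(0, 2, 2)
    for (t in seq_len(n - 1)) {
      xi <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A / scale[t + 1]
      xi_sum <- xi_sum + xi
    }
  }
  list(gamma = gamma, loglik = sum(log(scale)), xi_sum = xi_sum)
}

default_hmm_init <- function(count, callable) {
  rate <- count / pmax(callable, 1e-9)
  q <- quantile(rate, 0.9)
  lo <- mean(rate[rate <= q])
  hi <- mean(rate[rate > q])
  if (!is.finite(hi) || hi <= lo) hi <- lo * 5 + 1
  hmm_params(c(0.95, 0.05),
             rbind(c(0.999, 0.001), c(0.02, 0.98)),
             c(max(lo, 1e-4), hi))
}

#' Fit the introgression HMM by Baum-Welch
#'
#' Expectation-maximization over windowed private-variant counts.  Emission
#' rates are scaled by each window's callable fraction.  The log-likelihood
#' is non-decreasing across iterations; fitting stops when the improvement
#' drops below `tol` or after `max_iter` iterations.  States are relabelled
#' if needed so that the archaic state always has the larger rate.
#'
#' @param obs Data frame of windowed observations with columns `count` and
#'   (optionally) `callable` (default 1); at least 100 windows.
#' @param init Optional [hmm_params()] starting values; a data-driven
#'   default is used otherwise.
#' @param max_iter,tol EM stopping rule.
#' @return An object of class `intro_hmm`: fitted `params`, `loglik`,
#'   per-iteration `trace`, `iterations`, `converged`, and `degenerate`
#'   (TRUE when the data carry no rate variation and `init` is returned
#'   unchanged, with a warning).
#' @export
fit_hmm <- function(obs, init = NULL, max_iter = 100, tol = 1e-6) {
  obs <- as_tibble(obs)
  if (!"count" %in% names(obs)) abort("`obs` needs a `count` column")
  count <- obs$count
  callable <- col_or(obs, "callable", rep(1, length(count)))
  if (length(count) < 100) abort("need at least 100 windows to fit")
  if (is.null(init)) init <- default_hmm_init(count, callable)
  if (!inherits(init, "hmm_params")) abort("`init` must be hmm_params")

  if (length(unique(count)) == 1L) {
    warn("degenerate observations (all counts equal): returning `init`")
    return(structure(list(params = init, loglik = NA_real_,
                          trace = numeric(0), iterations = 0L,
                          converged = FALSE, degenerate = TRUE,
                          n_windows = length(count)),
                     class = "intro_hmm"))
  }

  params <- init
  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fb <- forward_backward(count, callable, params, want_xi = TRUE)
    trace <- c(trace, fb$loglik)
    g <- fb$gamma
    denom <- colSums(g[-nrow(g), , drop = FALSE])
    A <- fb$xi_sum / denom
    A <- A / rowSums(A)
    lambda <- colSums(g * count) / pmax(colSums(g * callable), 1e-12)
    params <- hmm_params(g[1, ], A, lambda)
    if (is.finite(prev_ll) && fb$loglik - prev_ll < tol) {
      converged <- TRUE
      break
    }
    prev_ll <- fb$loglik
  }
  # canonical state order: archaic is the high-rate state
  if (params$lambda[1] > params$lambda[2]) {
    params <- hmm_params(rev(params$init), params$trans[2:1, 2:1],
                         rev(params$lambda))
  }
  final <- forward_backward(count, callable, params)
  structure(list(params = params, loglik = final$loglik, trace = trace,
                 iterations = length(trace), converged = converged,
                 degenerate = FALSE, n_windows = length(count)),
            class = "intro_hmm")
}

#' @export
print.intro_hmm <- function(x, ...) {
  cat("<intro_hmm>", x$n_windows, "windows |",
      if (x$degenerate) "degenerate" else
        sprintf("logLik %.2f after %d iterations%s", x$loglik, x$iterations,
                if (x$converged) " (converged)" else ""), "\n")
  print(x$params)
  invisible(x)
}

#' Posterior decoding of introgressed segments
#'
#' Runs forward-backward under `params` and merges maximal runs of windows
#' whose archaic-state posterior is at least `cutoff` into segment calls.
#'
#' @param obs Windowed observations (columns `chrom`, `start`, `end`,
#'   `count`, optional `callable`).
#' @param params An [hmm_params()] or a fitted `intro_hmm`.
#' @param cutoff Posterior cutoff in (0.5, 1); default 0.8.
#' @param hap Haplotype id recorded on the calls.
#' @return Tibble of segment calls: `chrom`, `start`, `end`, `hap`,
#'   `n_windows`, `mean_posterior`, `source = "hmm"`.
#' @export
decode_segments <- function(obs, params, cutoff = 0.8, hap = NA_character_) {
  obs <- as_tibble(obs)
  if (inherits(params, "intro_hmm")) params <- params$params
  if (!inherits(params, "hmm_params")) abort("`params` must be hmm_params")
  if (cutoff <= 0.5 || cutoff >= 1) abort("`cutoff` must be in (0.5, 1)")
  count <- obs$count
  callable <- col_or(obs, "callable", rep(1, length(count)))
  fb <- forward_backward(count, callable, params)
  post <- fb$gamma[, 2]
  flag <- post >= cutoff
  if (!any(flag)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  hap = character(), n_windows = integer(),
                  mean_posterior = numeric(), source = character()))
  }
  chrom_col <- col_or(obs, "chrom", rep(NA_character_, nrow(obs)))
  r <- rle(flag)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  keep <- which(r$values)
  purrr::map_dfr(keep, function(k) {
    i <- idx_start[k]:idx_end[k]
    tibble(chrom = chrom_col[i[1]],
           start = obs$start[i[1]],
           end = obs$end[i[length(i)]],
           hap = hap,
           n_windows = length(i),
           mean_posterior = mean(post[i]),
           source = "hmm")
  })
}

#' Window posteriors from the introgression HMM
#'
#' @inheritParams decode_segments
#' @return The input windows with `posterior_archaic` added.
#' @export
window_posteriors <- function(obs, params) {
  obs <- as_tibble(obs)
  if (inherits(params, "intro_hmm")) params <- params$params
  callable <- col_or(obs, "callable", rep(1, nrow(obs)))
  fb <- forward_backward(obs$count, callable, params)
  obs |> mutate(posterior_archaic = fb$gamma[, 2])
}
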