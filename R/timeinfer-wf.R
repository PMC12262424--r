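# Piecewise Wright-Fisher selection inference on a frequency grid.
#
# The hidden state is the population derived-allele frequency discretized on
# a regular grid; per-generation transitions are Gaussian with mean
# increment s*p*(1-p)/(1+s*p) and variance p*(1-p)/(2N), integrated over
# grid-cell boundaries, with absorbing boundaries at 0 and 1.  Emissions are
# binomial draws at the observation times.  Multi-generation propagators are
# formed by repeated squaring and cached, so replicate studies and grid
# optimizations reuse them.

.wf_cache <- new.env(parent = emptyenv())

#' Observed allele trajectory
#'
#' @param times Generations before present of each observation (will be
#'   sorted oldest-first; must be distinct and >= 0).
#' @param counts Derived-allele counts at each time.
#' @param sizes Sample sizes (haplotypes) at each time.
#' @param N Diploid effective population size.
#' @return A `trajectory_observations` object.
#' @export
trajectory_observations <- function(times, counts, sizes, N) {
  if (length(times) != length(counts) || length(times) != length(sizes)) {
    abort("`times`, `counts`, `sizes` must have equal length")
  }
  if (any(times < 0)) abort("`times` must be >= 0 (generations before present)")
  if (anyDuplicated(times)) abort("`times` must be distinct")
  if (any(counts < 0 | counts > sizes)) abort("counts must lie in [0, size]")
  stopifnot_scalar_number(N, "N", min = 1)
  o <- order(times, decreasing = TRUE)
  structure(list(times = times[o], counts = counts[o], sizes = sizes[o],
                 N = N),
            class = "trajectory_observations")
}

# Per-generation transition matrix for coefficient s (genic parameterization).
wf_step_matrix <- function(s, N, n_grid) {
  key <- paste("step", format(s, digits = 12), N, n_grid)
  hit <- get0(key, envir = .wf_cache)
  if (!is.null(hit)) return(hit)
  p <- seq(0, 1, length.out = n_grid)
  bounds <- (p[-1] + p[-n_grid]) / 2
  M <- matrix(0, n_grid, n_grid)
  M[1, 1] <- 1
  M[n_grid, n_grid] <- 1
  for (i in 2:(n_grid - 1)) {
    pi_ <- p[i]
    m <- pi_ + s * pi_ * (1 - pi_) / (1 + s * pi_)
    sdv <- sqrt(pi_ * (1 - pi_) / (2 * N))
    cdf <- pnorm(bounds, mean = m, sd = sdv)
    M[i, ] <- diff(c(0, cdf, 1))
  }
  assign(key, M, envir = .wf_cache)
  M
}

mat_pow <- function(M, t) {
  out <- NULL
  P <- M
  while (t > 0) {
    if (t %% 2 == 1) out <- if (is.null(out)) P else out %*% P
    P <- P %*% P
    t <- t %/% 2
  }
  out %||% diag(nrow(M))
}

wf_propagator <- function(s, N, dt, n_grid) {
  if (dt == 0) return(diag(n_grid))
  key <- paste("prop", format(s, digits = 12), N, dt, n_grid)
  hit <- get0(key, envir = .wf_cache)
  if (!is.null(hit)) return(hit)
  P <- mat_pow(wf_step_matrix(s, N, n_grid), dt)
  if (length(ls(.wf_cache)) > 400) {
    rm(list = ls(.wf_cache), envir = .wf_cache)
  }
  assign(key, P, envir = .wf_cache)
  P
}

# Selection schedule: constant coefficient, or piecewise with change times in
# generations before present (older epochs first).
schedule_segments <- function(s_schedule, from, to) {
  # returns tibble(gens, s) covering the interval (from, to], from > to
  if (is.numeric(s_schedule) && length(s_schedule) == 1) {
    return(tibble(gens = from - to, s = s_schedule))
  }
  ct <- s_schedule$change_times
  sv <- s_schedule$s
  if (length(sv) != length(ct) + 1) {
    abort("piecewise schedule needs one more `s` than change times")
  }
  edges <- c(Inf, sort(ct, decreasing = TRUE), -Inf)
  segs <- list()
  for (i in seq_along(sv)) {
    hi <- min(edges[i], from)
    lo <- max(edges[i + 1], to)
    if (hi > lo) segs[[length(segs) + 1L]] <- tibble(gens = hi - lo, s = sv[i])
  }
  bind_rows(segs)
}

#' Wright-Fisher log-likelihood of an allele trajectory
#'
#' Forward likelihood of the observed counts under a constant or piecewise
#' selection coefficient, starting from a uniform prior over the frequency
#' grid at the oldest observation time.
#'
#' @param obs A [trajectory_observations()].
#' @param s_schedule A single selection coefficient, or
#'   `list(s = c(s_old, ..., s_recent), change_times = c(...))` with change
#'   times in generations before present.
#' @param N Diploid population size (default: from `obs`).
#' @param n_grid Frequency grid resolution (>= 100; default 201).
#' @return Log-likelihood (scalar).
#' @export
wf_loglik <- function(obs, s_schedule, N = obs$N, n_grid = 201) {
  if (!inherits(obs, "trajectory_observations")) {
    abort("`obs` must be trajectory_observations")
  }
  if (n_grid < 100) abort("`n_grid` must be >= 100")
  p <- seq(0, 1, length.out = n_grid)
  v <- rep(1 / n_grid, n_grid)
  ll <- 0
  K <- length(obs$times)
  for (j in seq_len(K)) {
    if (j > 1) {
      segs <- schedule_segments(s_schedule, obs$times[j - 1], obs$times[j])
      for (i in seq_len(nrow(segs))) {
        v <- as.numeric(v %*% wf_propagator(segs$s[i], N, segs$gens[i],
                                            n_grid))
      }
    }
    e <- dbinom(obs$counts[j], obs$sizes[j], p)
    v <- v * e
    tot <- sum(v)
    if (tot == 0) return(-Inf)
    ll <- ll + log(tot)
    v <- v / tot
  }
  ll
}

#' Default selection-coefficient grid
#'
#' Zero plus log-spaced magnitudes between 1e-4 and 0.5 on both signs.
#'
#' @param per_decade Grid points per decade of |s| (default 13).
#' @return Sorted numeric vector of candidate coefficients.
#' @export
default_s_grid <- function(per_decade = 13) {
  n <- ceiling(log10(0.5 / 1e-4) * per_decade)
  mags <- 10 ^ seq(log10(1e-4), log10(0.5), length.out = n)
  sort(unique(c(0, mags, -mags)))
}

#' Fit a selection coefficient by maximum likelihood
#'
#' Maximizes [wf_loglik()] over a grid of coefficients (single epoch), or
#' over (s_old, s_recent, change time) for the two-epoch piecewise model.
#' The null is `s = 0` throughout.  The likelihood-ratio statistic
#' `2 * (ll_alt - ll_null)` is compared to a chi-squared distribution with
#' 1 (single epoch) or 3 (two epochs with a free change time) degrees of
#' freedom.
#'
#' @param obs A [trajectory_observations()].
#' @param model `"single_epoch"` or `"piecewise"` (two epochs).
#' @param s_grid Candidate coefficients (default [default_s_grid()]).
#' @param change_times Candidate change times for the piecewise model
#'   (default: the interior observation times).
#' @param N,n_grid See [wf_loglik()].
#' @param refine Single-epoch only: refine the grid optimum with a local
#'   continuous search (default TRUE).
#' @return A `selection_fit`: MLE parameters, `ll_alt`, `ll_null`,
#'   `lrt_stat`, `df`, `p_value`.
#' @export
fit_selection <- function(obs, model = c("single_epoch", "piecewise"),
                          s_grid = default_s_grid(), change_times = NULL,
                          N = obs$N, n_grid = 201, refine = TRUE) {
  model <- match.arg(model)
  ll_null <- wf_loglik(obs, 0, N = N, n_grid = n_grid)
  s_grid <- sort(unique(c(0, s_grid)))
  ll_grid <- vapply(s_grid, function(s) wf_loglik(obs, s, N, n_grid),
                    numeric(1))
  best <- which.max(ll_grid)
  s_hat <- s_grid[best]
  ll_single <- ll_grid[best]

  if (model == "single_epoch") {
    if (refine && is.finite(ll_single)) {
      lo <- s_grid[max(best - 1, 1)]
      hi <- s_grid[min(best + 1, length(s_grid))]
      if (hi > lo) {
        opt <- optimize(function(s) wf_loglik(obs, s, N, n_grid),
                        interval = c(lo, hi), maximum = TRUE,
                        tol = max(abs(s_hat) * 1e-3, 1e-6))
        if (opt$objective > ll_single) {
          s_hat <- opt$maximum
          ll_single <- opt$objective
        }
      }
    }
    params <- tibble(term = "s", estimate = s_hat)
    ll_alt <- ll_single
    df <- 1L
  } else {
    change_times <- change_times %||% {
      int <- obs$times[-c(1, length(obs$times))]
      if (!length(int)) abort("need interior observation times for piecewise")
      int
    }
    cand <- sort(unique(c(s_grid, s_hat)))
    best_fit <- list(ll = -Inf)
    for (ct in change_times) {
      for (s1 in cand) {
        lls <- vapply(cand, function(s2) {
          wf_loglik(obs, list(s = c(s1, s2), change_times = ct), N, n_grid)
        }, numeric(1))
        b <- which.max(lls)
        if (lls[b] > best_fit$ll) {
          best_fit <- list(ll = lls[b], s1 = s1, s2 = cand[b], ct = ct)
        }
      }
    }
    params <- tibble(term = c("s_old", "s_recent", "change_time"),
                     estimate = c(best_fit$s1, best_fit$s2, best_fit$ct))
    ll_alt <- max(best_fit$ll, ll_single)  # nesting: piecewise >= single
    if (ll_single > best_fit$ll) {
      params <- tibble(term = c("s_old", "s_recent", "change_time"),
                       estimate = c(s_hat, s_hat, change_times[1]))
    }
    df <- 3L
  }

  lrt <- max(0, 2 * (ll_alt - ll_null))
  structure(
    list(model = model, params = params, ll_alt = ll_alt, ll_null = ll_null,
         lrt_stat = lrt, df = df, p_value = chi2_sf(lrt, df),
         s_grid = s_grid, n_grid = n_grid, N = N),
    class = "selection_fit"
  )
}

#' @export
print.selection_fit <- function(x, ...) {
  est <- paste(sprintf("%s = %.4g", x$params$term, x$params$estimate),
               collapse = ", ")
  cat(sprintf(
    "<selection_fit> %s: %s | LRT = %.4g (df = %d), p = %.4g\n",
    x$model, est, x$lrt_stat, x$df, x$p_value))
  invisible(x)
}

#' Simulate a Wright-Fisher allele trajectory with sampling
#'
#' Forward binomial Wright-Fisher dynamics with genic selection, sampled at
#' the requested times; the companion of [fit_selection()] for calibration
#' and recovery experiments.
#'
#' @param s Selection coefficient (constant) or schedule list as in
#'   [wf_loglik()].
#' @param N Diploid size.
#' @param p0 Initial derived frequency at `start_gen` generations before
#'   present.
#' @param start_gen Start of the simulation (generations before present).
#' @param sample_times Observation times (generations before present).
#' @param sample_sizes Haplotypes sampled at each time.
#' @param seed Seed.
#' @return A [trajectory_observations()] with attribute `trajectory` (the
#'   full per-generation frequency path, oldest first).
#' @export
simulate_trajectory <- function(s, N, p0, start_gen, sample_times,
                                sample_sizes, seed) {
  sample_sizes <- rep_len(sample_sizes, length(sample_times))
  with_seed(child_seed(seed, "wf_traj"), {
    gens <- start_gen:0
    p <- numeric(length(gens))
    p[1] <- p0
    for (i in seq_along(gens)[-1]) {
      g <- gens[i]
      s_now <- if (is.numeric(s)) s else {
        idx <- sum(g < sort(s$change_times, decreasing = TRUE)) + 1L
        s$s[min(idx, length(s$s))]
      }
      pp <- p[i - 1]
      mean_p <- pp + s_now * pp * (1 - pp) / (1 + s_now * pp)
      p[i] <- rbinom(1, 2 * N, min(max(mean_p, 0), 1)) / (2 * N)
    }
    counts <- vapply(seq_along(sample_times), function(j) {
      pj <- p[match(sample_times[j], gens)]
      rbinom(1, sample_sizes[j], pj)
    }, numeric(1))
    obs <- trajectory_observations(sample_times, counts, sample_sizes, N)
    attr(obs, "trajectory") <- p
    obs
  })
}
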