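test_that("two-bin TMRCA posterior matches direct Bayes arithmetic", {
  g <- pairwise_tmrca_posterior(0, L = 20000, mu = 1e-8,
                                time_bins = c(1000, 10000))
  # lambda = 0.4 and 4; P(T=1000 | k=0) = e^-0.4 / (e^-0.4 + e^-4)
  expect_equal(g$posterior[1, 1], exp(-0.4) / (exp(-0.4) + exp(-4)),
               tolerance = 1e-9)

  # point prior pins the posterior to its bin
  g2 <- pairwise_tmrca_posterior(c(4, 5), L = 20000, mu = 1e-8,
                                 time_bins = c(1000, 5000, 10000),
                                 prior = c(0, 1, 0))
  expect_equal(g2$posterior[, 2], c(1, 1))

  expect_error(pairwise_tmrca_posterior(1, 1000, 1e-8, c(1000, 10000),
                                        prior = c(0, 0)), "prior")
  expect_error(pairwise_tmrca_posterior(1, 1000, 1e-8, 1000), "time_bins")
})

test_that("TMRCA decoding matches exhaustive path enumeration", {
  withr::with_seed(61, {
    bins <- c(500, 2000, 8000, 30000)
    prior <- c(0.4, 0.3, 0.2, 0.1)
    rho <- 0.25
    L <- 10000; mu <- 5e-8
    counts <- rpois(8, 2 * mu * L * sample(bins, 8, replace = TRUE))
    g <- pairwise_tmrca_posterior(counts, L, mu, bins, prior = prior,
                                  switch_prob = rho)
    A <- (1 - rho) * diag(4) + rho * matrix(prior, 4, 4, byrow = TRUE)
    oracle <- enum_hmm_posterior(counts, prior, A,
                                 function(k, s, t) dpois(k, 2 * mu * L * bins[s]))
    expect_equal(g$posterior, oracle, tolerance = 1e-9)
    expect_equal(rowSums(g$posterior), rep(1, 8), tolerance = 1e-9)
  })
})

test_that("TMRCA posterior means recover simulated window times", {
  withr::with_seed(62, {
    bins <- 10 ^ seq(3, 5.3, length.out = 24)
    true_t <- 10 ^ runif(100, 4, 5)
    L <- 20000; mu <- 1.25e-8
    counts <- rpois(100, 2 * mu * L * true_t)
    g <- pairwise_tmrca_posterior(counts, L, mu, bins, switch_prob = 1)
    err <- abs(log10(g$posterior_mean) - log10(true_t))
    expect_lte(mean(err), 0.35)
  })
})

test_that("sweep scores integrate posterior mass below the threshold", {
  g <- pairwise_tmrca_posterior(0, L = 20000, mu = 1e-7,
                                time_bins = c(100, 50000))
  # high mutation load: k=0 forces recent TMRCA
  expect_gt(sweep_score(g, 10000)$aggregate, 0.95)

  # uniform posterior over 10 bins, threshold covering 3
  g3 <- list(posterior = matrix(rep(0.1, 10), 1), bins = (1:10) * 100)
  class(g3) <- "tmrca_grid"
  expect_equal(sweep_score(g3, 350)$aggregate, 0.3)
  expect_error(sweep_score(g3, 5000), "bin range")
})

test_that("swept pairs score recenter than neutral pairs", {
  withr::with_seed(63, {
    bins <- 10 ^ seq(2, 5, length.out = 20)
    L <- 20000; mu <- 1.25e-8
    swept <- replicate(30, {
      t <- 10 ^ runif(1, 2, 3)       # recent coalescence under the sweep
      g <- pairwise_tmrca_posterior(rpois(20, 2 * mu * L * t), L, mu, bins)
      sweep_score(g, 2000)$aggregate
    })
    neutral <- replicate(30, {
      t <- 10 ^ runif(1, 3.8, 5)
      g <- pairwise_tmrca_posterior(rpois(20, 2 * mu * L * t), L, mu, bins)
      sweep_score(g, 2000)$aggregate
    })
    expect_lt(introscan:::mwu_test(swept, neutral)$p, 0.01)
  })
})

test_that("WF likelihood at s=0 with one observation equals the grid marginal", {
  obs <- trajectory_observations(times = 0, counts = 12, sizes = 40,
                                 N = 1e4)
  ll <- wf_loglik(obs, 0, n_grid = 201)
  p <- seq(0, 1, length.out = 201)
  oracle <- log(sum(dbinom(12, 40, p) / 201))
  expect_equal(ll, oracle, tolerance = 1e-10)
  expect_error(wf_loglik(obs, 0, n_grid = 50), "n_grid")
})

test_that("a wildly wrong selection coefficient is strongly disfavoured", {
  # frequency falling from 0.9 to 0.1 cannot have s = +0.5
  obs <- trajectory_observations(times = c(300, 150, 0),
                                 counts = c(45, 25, 5),
                                 sizes = c(50, 50, 50), N = 1e4)
  expect_lt(wf_loglik(obs, 0.5), wf_loglik(obs, 0))
})

test_that("selection MLE recovers a deterministic logistic trajectory", {
  # dense observations from a logistic path at s = 0.01
  s <- 0.01; N <- 5e4
  times <- seq(600, 0, by = -100)
  p <- 0.1
  traj <- numeric(length(times))
  for (i in seq_along(times)) {
    traj[i] <- p
    if (i < length(times)) {
      for (g in 1:100) p <- p + s * p * (1 - p) / (1 + s * p)
    }
  }
  obs <- trajectory_observations(times, counts = round(traj * 200),
                                 sizes = rep(200, length(times)), N = N)
  fit <- fit_selection(obs, "single_epoch")
  expect_gte(fit$params$estimate[1], 0.005)
  expect_lte(fit$params$estimate[1], 0.02)
  expect_gte(fit$ll_alt, fit$ll_null)
  expect_gte(fit$lrt_stat, 0)
})

test_that("the piecewise fit nests the single-epoch fit", {
  obs <- simulate_trajectory(list(s = c(0.016, 0.005), change_times = 100),
                             N = 1e4, p0 = 0.1, start_gen = 300,
                             sample_times = c(300, 200, 100, 50, 0),
                             sample_sizes = 60, seed = 71)
  single <- fit_selection(obs, "single_epoch", refine = FALSE)
  piece <- fit_selection(obs, "piecewise",
                         s_grid = default_s_grid(per_decade = 4),
                         change_times = c(100, 50))
  expect_gte(piece$ll_alt, single$ll_alt - 1e-9)
  expect_equal(piece$df, 3L)
})

test_that("chi-squared tails reproduce printed worked examples", {
  expect_equal(chi2_sf(0, 1), 1)
  expect_equal(round(chi2_sf(5.16, 1), 3), 0.023)
  expect_equal(round(chi2_sf(10.84, 3), 4), 0.0126)
  expect_lt(abs(chi2_sf(6.8468, 1) - 0.0088), 1e-4)
  expect_error(chi2_sf(-1, 1), "statistic")
})

test_that("chi-squared tails match a series/recursion oracle to 1e-10", {
  for (df in 1:10) {
    for (x in c(0.1, 0.5, 1, 2, 5, 10, 20, 35, 50)) {
      expect_equal(chi2_sf(x, df), chi2_sf_oracle(x, df),
                   tolerance = 1e-10)
    }
  }
})

test_that("QV conversions reproduce assembly-table worked values", {
  expect_equal(signif(phred_convert(44.5, "qv_to_error"), 2), 3.5e-5)
  expect_equal(round(phred_convert(3.29e-5, "error_to_qv"), 1), 44.8)
  expect_equal(phred_convert(10, "qv_to_error"), 0.1)
  expect_equal(phred_convert(0.1, "error_to_qv"), 10)
  expect_warning(q0 <- phred_convert(0, "error_to_qv"), "infinite")
  expect_true(is.infinite(q0))
})

test_that("divergence windows count mismatches over aligned columns", {
  a <- strrep("ACGT", 5000)
  expect_equal(pairwise_divergence(a, a)$divergence, 0)

  b <- a
  # plant 20 mismatches in 20,000 columns
  pos <- seq(100, by = 997, length.out = 20)
  for (p in pos) substr(b, p, p) <- chartr("ACGT", "TGCA", substr(b, p, p))
  res <- pairwise_divergence(a, b, window = 20000)
  expect_equal(res$divergence, 0.001)
  res_jc <- pairwise_divergence(a, b, window = 20000, jc_correct = TRUE)
  expect_equal(res_jc$divergence, -0.75 * log(1 - 4 * 0.001 / 3),
               tolerance = 1e-9)

  # saturation flag at d >= 0.75
  set.seed(1)
  c1 <- strrep("A", 1000)
  c2 <- paste(sample(c("C", "G", "T"), 1000, TRUE), collapse = "")
  sat <- pairwise_divergence(c1, c2, window = 1000, jc_correct = TRUE)
  expect_equal(sat$flag, "saturated")

  # gap columns drop out of numerator and denominator
  ga <- "ACGTACGTAC"
  gb <- "ACG-ACGTAC"
  res_g <- pairwise_divergence(ga, gb, window = 10)
  expect_equal(res_g$aligned, 9L)
  expect_equal(res_g$divergence, 0)
})

test_that("HOR mutation-rate estimation is exact on closed-form input", {
  est <- hor_mutation_rate(0.004, 5e5, 1e4, g = 25)
  expect_equal(est$mean_mu, 5e-8)
  expect_equal(hor_mutation_rate(0, 5e5, 1e4)$mean_mu, 0)

  # homogeneity: doubling divergences doubles every estimate exactly
  withr::with_seed(81, {
    d <- runif(20, 0.001, 0.01)
    e1 <- hor_mutation_rate(d, c(4e5, 7e5), c(5e3, 2e4))
    e2 <- hor_mutation_rate(2 * d, c(4e5, 7e5), c(5e3, 2e4))
    expect_equal(e2$estimates$mu, 2 * e1$estimates$mu)
    expect_equal(e2$mean_mu, 2 * e1$mean_mu)
  })
  expect_error(hor_mutation_rate(1.2, 5e5, 1e4), "divergences")
})

test_that("trajectory observations validate and order their inputs", {
  obs <- trajectory_observations(c(0, 100, 50), c(1, 2, 3), c(10, 10, 10),
                                 N = 1000)
  expect_equal(obs$times, c(100, 50, 0))
  expect_equal(obs$counts, c(2, 3, 1))
  expect_error(trajectory_observations(c(0, 0), c(1, 1), c(5, 5), 100),
               "distinct")
  expect_error(trajectory_observations(0, 6, 5, 100), "counts")
})
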