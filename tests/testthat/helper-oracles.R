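# Independent oracles used across the suite.  Each deliberately re-derives
# the quantity by brute force / closed form, never through the package's own
# code path.

# Exhaustive-path posterior for an HMM with Poisson emissions: enumerate all
# state paths (any number of states), tolerable for <= ~12 windows.
enum_hmm_posterior <- function(count, init, trans, emit_fun) {
  # emit_fun(k, state, window_index) -> emission probability
  n <- length(count)
  S <- length(init)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  w <- apply(paths, 1, function(z) {
    p <- init[z[1]] * emit_fun(count[1], z[1], 1)
    if (n >= 2) {
      for (t in 2:n) {
        p <- p * trans[z[t - 1], z[t]] * emit_fun(count[t], z[t], t)
      }
    }
    p
  })
  post <- matrix(0, n, S)
  for (t in seq_len(n)) {
    for (s in seq_len(S)) post[t, s] <- sum(w[paths[, t] == s])
  }
  post / rowSums(post)
}

# One-sided (enrichment) Fisher p from hypergeometric tail.
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b          # introgressed
  k <- a + c          # near gene
  n_tot <- a + b + c + d
  xs <- a:min(m, k)
  sum(stats::dhyper(xs, m, n_tot - m, k))
}

# Chi-squared upper tail via the textbook recursion
#   Q(x; df) = Q(x; df-2) + (x/2)^(df/2-1) exp(-x/2) / Gamma(df/2)
# with base cases df = 1 (Gaussian tail) and df = 2 (exponential).
chi2_sf_oracle <- function(x, df) {
  if (df == 1) return(2 * stats::pnorm(-sqrt(x)))
  if (df == 2) return(exp(-x / 2))
  chi2_sf_oracle(x, df - 2) +
    (x / 2) ^ (df / 2 - 1) * exp(-x / 2) / gamma(df / 2)
}

# O(n^2) single-linkage SV merging: returns cluster membership ids.
brute_merge_clusters <- function(svs, reciprocal = 0.5, ins_window = 500) {
  n <- nrow(svs)
  linked <- function(i, j) {
    if (svs$chrom[i] != svs$chrom[j] || svs$type[i] != svs$type[j]) {
      return(FALSE)
    }
    if (svs$type[i] == "INS") {
      abs(svs$start[i] - svs$start[j]) <= ins_window &&
        min(svs$length[i], svs$length[j]) /
          max(svs$length[i], svs$length[j]) >= reciprocal
    } else {
      ov <- min(svs$end[i], svs$end[j]) - max(svs$start[i], svs$start[j])
      ov >= reciprocal * svs$length[i] && ov >= reciprocal * svs$length[j]
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (comp[i] != comp[j] && linked(i, j)) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Naive per-position window rescan for archaic-specific k-mer counts.
naive_window_counts <- function(seqc, kmers, k, window) {
  L <- nchar(seqc)
  starts <- seq(0L, max(L - 1L, 0L), by = window)
  rc1 <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  vapply(starts, function(ws) {
    we <- min(ws + window, L)
    hits <- 0L
    ss <- seq_len(max(we - k + 1 - ws, 0))
    for (off in ss) {
      km <- substr(seqc, ws + off, ws + off + k - 1)
      can <- min(km, rc1(km))
      if (can %in% kmers) hits <- hits + 1L
    }
    hits
  }, integer(1))
}

# Markov-chain + Poisson emission simulation of HMM observations.
simulate_hmm_counts <- function(n, init, trans, lambda, seed) {
  withr::with_seed(seed, {
    z <- integer(n)
    z[1] <- sample(1:2, 1, prob = init)
    for (t in 2:n) z[t] <- sample(1:2, 1, prob = trans[z[t - 1], ])
    tibble::tibble(chrom = "chr1",
                   start = (seq_len(n) - 1L) * 1000L,
                   end = seq_len(n) * 1000L,
                   count = rpois(n, lambda[z]),
                   callable = 1,
                   state = z)
  })
}
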