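# Selection and introgression statistics: Hudson FST, PBS, f_D, LD, and
# simulation-based empirical p-values.

# Hudson estimator components: numerator and denominator per site.
hudson_components <- function(p1, n1, p2, n2) {
  num <- (p1 - p2) ^ 2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Hudson's FST estimator for one site
#'
#' `((p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)) /
#'  (p1(1-p2) + p2(1-p1))`.  Vectorised over sites.  Returns `NaN` (flagged
#' undefined) where the denominator is zero; slightly negative estimates at
#' finite sample size are legitimate.
#'
#' @param p1,p2 Derived-allele frequencies in the two populations.
#' @param n1,n2 Haplotype sample sizes (>= 2).
#' @return FST estimate(s).
#' @examples
#' hudson_fst(1, 100, 0, 100)  # 1
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  if (any(n1 <= 1) || any(n2 <= 1)) abort("sample sizes must be >= 2")
  h <- hudson_components(p1, n1, p2, n2)
  ifelse(h$den == 0, NaN, h$num / h$den)
}

#' Population branch statistic
#'
#' `PBS = (T(fst_fs) + T(fst_fo) - T(fst_so)) / 2` with
#' `T(x) = -log(1 - x)`, isolating allele-frequency change on the focal
#' branch (fs: focal-sister, fo: focal-outgroup, so: sister-outgroup).
#' Any FST equal to 1 makes the statistic undefined (`NA`, flagged).
#'
#' @param fst_fs,fst_fo,fst_so Pairwise FST values.
#' @return PBS value(s).
#' @examples
#' pbs(0.5, 0.5, 0)  # log(2)
#' @export
pbs <- function(fst_fs, fst_fo, fst_so) {
  tt <- function(x) ifelse(x >= 1, NA_real_, -log(1 - pmax(x, -Inf)))
  out <- (tt(fst_fs) + tt(fst_fo) - tt(fst_so)) / 2
  out
}

check_freq_table <- function(freq_table) {
  freq_table <- as_tibble(freq_table)
  need <- c("pos", "p_focal", "n_focal", "p_sister", "n_sister", "p_out",
            "n_out")
  if (!all(need %in% names(freq_table))) {
    abort(paste("frequency table needs columns:", paste(need, collapse = ", ")))
  }
  freq_table
}

#' PBS scan over non-overlapping 100-SNV segments
#'
#' Splits the (position-sorted) frequency table into consecutive
#' non-overlapping blocks of exactly `segment_size` SNVs (trailing remainder
#' dropped) and computes each block's PBS from block-averaged pairwise FST
#' (ratio of averages: mean Hudson numerator over mean denominator per
#' population pair, then the branch-length transform).
#'
#' @param freq_table Per-site table (see [cohort_frequencies()]): `pos`,
#'   `p_focal`/`n_focal`, `p_sister`/`n_sister`, `p_out`/`n_out`.
#' @param segment_size SNVs per segment (default 100).
#' @return Tibble per segment: `segment`, `start`, `end`, `n_snvs`,
#'   `fst_fs`, `fst_fo`, `fst_so`, `pbs`.
#' @export
segment_scan <- function(freq_table, segment_size = 100) {
  ft <- check_freq_table(freq_table) |> arrange(pos)
  n_seg <- floor(nrow(ft) / segment_size)
  if (n_seg == 0) {
    warn(sprintf("fewer than %d SNVs: empty scan", segment_size))
    return(tibble(segment = integer(), start = integer(), end = integer(),
                  n_snvs = integer(), fst_fs = numeric(), fst_fo = numeric(),
                  fst_so = numeric(), pbs = numeric()))
  }
  ft <- ft[seq_len(n_seg * segment_size), ]
  ft$segment <- rep(seq_len(n_seg), each = segment_size)

  block_fst <- function(p_a, n_a, p_b, n_b, seg) {
    h <- hudson_components(p_a, n_a, p_b, n_b)
    num <- tapply(h$num, seg, mean)
    den <- tapply(h$den, seg, mean)
    ifelse(den == 0, NaN, num / den)
  }
  fst_fs <- block_fst(ft$p_focal, ft$n_focal, ft$p_sister, ft$n_sister,
                      ft$segment)
  fst_fo <- block_fst(ft$p_focal, ft$n_focal, ft$p_out, ft$n_out, ft$segment)
  fst_so <- block_fst(ft$p_sister, ft$n_sister, ft$p_out, ft$n_out,
                      ft$segment)
  starts <- tapply(ft$pos, ft$segment, min)
  ends <- tapply(ft$pos, ft$segment, max)
  tibble(segment = seq_len(n_seg), start = as.integer(starts),
         end = as.integer(ends) + 1L, n_snvs = segment_size,
         fst_fs = as.numeric(fst_fs), fst_fo = as.numeric(fst_fo),
         fst_so = as.numeric(fst_so),
         pbs = pbs(fst_fs, fst_fo, fst_so))
}

#' Per-SV population branch statistic
#'
#' Single-site PBS on an SV's carrier frequencies, one row per SV.
#'
#' @param sv_frequencies Tibble with `p_focal`, `n_focal`, `p_sister`,
#'   `n_sister`, `p_out`, `n_out` and optionally `sv_id`.
#' @return Input with `fst_fs`, `fst_fo`, `fst_so`, `pbs_sv` added.
#' @export
pbs_sv <- function(sv_frequencies) {
  sv <- as_tibble(sv_frequencies)
  sv |>
    mutate(
      fst_fs = hudson_fst(p_focal, n_focal, p_sister, n_sister),
      fst_fo = hudson_fst(p_focal, n_focal, p_out, n_out),
      fst_so = hudson_fst(p_sister, n_sister, p_out, n_out),
      pbs_sv = pbs(fst_fs, fst_fo, fst_so)
    )
}

#' Windowed f_D introgression statistic
#'
#' ABBA-BABA-style estimator of the admixture fraction for one window of
#' sites.  With `S(a, b, c, d) = sum((1-p_a) p_b p_c (1-p_d) -
#' p_a (1-p_b) p_c (1-p_d))`, `f_D = S(P1, P2, P3, O) / S(P1, PD, PD, O)`
#' where `PD` is, per site, whichever of P2/P3 has the larger derived
#' frequency.  P1 is the sister (non-admixed) population, P2 the focal
#' population, P3 the archaic donor and O the ancestral state.
#'
#' @param freq_table Window of sites with `p_sister` (P1), `p_focal` (P2),
#'   `p_arch` (P3) and optionally `p_anc` (O; defaults to 0, i.e. alleles
#'   already polarized).
#' @return One-row tibble: `fd`, `numerator`, `denominator`, `n_sites`;
#'   `fd` is `NA` (flagged) when the denominator is zero.
#' @export
fd <- function(freq_table) {
  ft <- as_tibble(freq_table)
  need <- c("p_sister", "p_focal", "p_arch")
  if (!all(need %in% names(ft))) {
    abort(paste("f_D needs columns:", paste(need, collapse = ", ")))
  }
  if (!nrow(ft)) abort("window has no sites")
  p1 <- ft$p_sister; p2 <- ft$p_focal; p3 <- ft$p_arch
  pO <- col_or(ft, "p_anc", rep(0, nrow(ft)))
  s_term <- function(pa, pb, pc, pd) {
    (1 - pa) * pb * pc * (1 - pd) - pa * (1 - pb) * pc * (1 - pd)
  }
  pD <- pmax(p2, p3)
  num <- sum(s_term(p1, p2, p3, pO))
  den <- sum(s_term(p1, pD, pD, pO))
  tibble(fd = if (den == 0) NA_real_ else num / den,
         numerator = num, denominator = den, n_sites = nrow(ft))
}

#' Linkage disequilibrium between two biallelic loci
#'
#' @param hap_a,hap_b Equal-length 0/1 haplotype vectors, both polymorphic.
#' @return One-row tibble: `d`, `r2`, `dprime`, `p_a`, `p_b`, `n`.
#' @examples
#' ld_stats(rep(c(1, 1, 0, 0), 25), rep(c(1, 0, 1, 0), 25))
#' @export
ld_stats <- function(hap_a, hap_b) {
  if (length(hap_a) != length(hap_b)) abort("haplotype vectors differ in length")
  p_a <- mean(hap_a); p_b <- mean(hap_b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    abort("both loci must be polymorphic")
  }
  p_ab <- mean(hap_a == 1 & hap_b == 1)
  D <- p_ab - p_a * p_b
  r2 <- D ^ 2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  dmax <- if (D > 0) {
    min(p_a * (1 - p_b), (1 - p_a) * p_b)
  } else {
    min(p_a * p_b, (1 - p_a) * (1 - p_b))
  }
  dprime <- if (D == 0) 0 else D / dmax
  tibble(d = D, r2 = r2, dprime = dprime, p_a = p_a, p_b = p_b,
         n = length(hap_a))
}

#' Empirical p-value against a simulated null
#'
#' `p = (1 + #(null >= observed)) / (1 + n_null)`: never zero, bounded below
#' by `1 / (n_null + 1)`.
#'
#' @param observed Observed statistic(s).
#' @param null A `null_distribution` from [simulate_null()] or a numeric
#'   vector of null draws.
#' @return Empirical p-value(s).
#' @export
empirical_p <- function(observed, null) {
  draws <- if (inherits(null, "null_distribution")) null$draws else
    as.numeric(null)
  if (!length(draws)) abort("null distribution is empty")
  vapply(observed, function(o) {
    (1 + sum(draws >= o)) / (1 + length(draws))
  }, numeric(1))
}

# Neutral per-site frequencies under the model: ancestral frequency from a
# 1/p spectrum, Balding-Nichols drift per population, binomial sampling.
sim_neutral_freqs <- function(model, n_sites, sample_sizes) {
  pops <- names(sample_sizes)
  p_anc <- 0.01 * 99 ^ runif(n_sites)
  out <- tibble(pos = seq_len(n_sites) - 1L)
  for (p in pops) {
    f <- model$populations$drift[model$populations$name == p]
    if (!length(f)) abort(sprintf("population `%s` not in model", p))
    p_pop <- if (f > 0) {
      rbeta(n_sites, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    } else {
      p_anc
    }
    n <- sample_sizes[[p]]
    out[[paste0("p_", p)]] <- rbinom(n_sites, n, p_pop) / n
    out[[paste0("n_", p)]] <- n
  }
  out
}

#' Simulate a null distribution for a scan statistic
#'
#' Each replicate draws a neutral region with the same SNV count and sample
#' sizes as the observed unit from the demographic model (shared ancestral
#' frequency spectrum, Balding-Nichols drift per population) and computes
#' the statistic through the same code path as observed data
#' ([segment_scan()] for PBS, [fd()] for f_D).  Replicates where the
#' statistic is undefined are redrawn (count logged).
#'
#' @param model A [demographic_model()].
#' @param statistic `"pbs"` or `"fd"`.
#' @param n_rep Number of replicates (>= 100).
#' @param seed Seed.
#' @param n_snvs SNVs per replicate region (default 100, matching the
#'   100-SNV scan segments).
#' @param sample_sizes Named haplotype sample sizes; for `"pbs"` names
#'   `focal`, `sister`, `out`; `"fd"` additionally ignores `out` and uses an
#'   archaic reference frequency drawn as a drifted Bernoulli.
#' @param focal,sister,outgroup Population names in the model.
#' @return A `null_distribution`: sorted `draws`, `n_rep`, `statistic`,
#'   `n_redrawn`, `seed`.
#' @export
simulate_null <- function(model, statistic = c("pbs", "fd"), n_rep, seed,
                          n_snvs = 100,
                          sample_sizes = c(focal = 30, sister = 30, out = 30),
                          focal = "PNG", sister = "EAS", outgroup = "AFR") {
  statistic <- match.arg(statistic)
  if (n_rep < 100) abort("`n_rep` must be >= 100")
  pop_map <- c(focal = focal, sister = sister, out = outgroup)
  sizes <- setNames(sample_sizes[c("focal", "sister", "out")],
                    pop_map[c("focal", "sister", "out")])

  draws <- numeric(0)
  n_redrawn <- 0L
  with_seed(child_seed(seed, paste0("null_", statistic)), {
    while (length(draws) < n_rep) {
      ft <- sim_neutral_freqs(model, n_snvs, sizes)
      ft <- ft |> rename(p_focal = paste0("p_", focal),
                         n_focal = paste0("n_", focal),
                         p_sister = paste0("p_", sister),
                         n_sister = paste0("n_", sister),
                         p_out = paste0("p_", outgroup),
                         n_out = paste0("n_", outgroup))
      val <- if (statistic == "pbs") {
        segment_scan(ft, segment_size = n_snvs)$pbs[1]
      } else {
        ft$p_arch <- rbinom(n_snvs, 1, 0.05)
        fd(ft)$fd[1]
      }
      if (is.na(val) || !is.finite(val)) {
        n_redrawn <- n_redrawn + 1L
      } else {
        draws <- c(draws, val)
      }
    }
  })
  structure(list(statistic = statistic, draws = sort(draws),
                 n_rep = as.integer(n_rep), n_redrawn = n_redrawn,
                 model_id = paste(model$populations$name, collapse = "-"),
                 seed = as.integer(seed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s: %d draws (median %.4g), %d redrawn\n",
              x$statistic, x$n_rep, stats::median(x$draws), x$n_redrawn))
  invisible(x)
}
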