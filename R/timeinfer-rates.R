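# Chi-squared tails, Phred conversions, satellite divergence and
# Kimura-style mutation-rate estimation.

#' Upper-tail probability of the chi-squared distribution
#'
#' @param statistic Test statistic (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return `P(X >= statistic)` for `X ~ chi-squared(df)`.
#' @examples
#' chi2_sf(6.8468, 1)  # 0.0088
#' chi2_sf(10.84, 3)   # 0.0126
#' @export
chi2_sf <- function(statistic, df) {
  if (any(statistic < 0)) abort("`statistic` must be >= 0")
  if (any(df < 1)) abort("`df` must be >= 1")
  pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Convert between Phred-scaled quality (QV) and error rate
#'
#' `error = 10^(-QV/10)`; `QV = -10 log10(error)`.
#'
#' @param value QV or error rate, depending on `direction`.
#' @param direction `"qv_to_error"` or `"error_to_qv"`.
#' @return Converted value(s); an error rate of 0 gives `Inf` QV with a
#'   warning.
#' @examples
#' phred_convert(44.5, "qv_to_error")     # 3.5e-5
#' phred_convert(3.29e-5, "error_to_qv")  # 44.8
#' @export
phred_convert <- function(value, direction = c("qv_to_error", "error_to_qv")) {
  direction <- match.arg(direction)
  if (direction == "qv_to_error") {
    if (any(value < 0)) abort("QV must be >= 0")
    10 ^ (-value / 10)
  } else {
    if (any(value < 0 | value > 1)) abort("error rate must be in [0, 1]")
    if (any(value == 0)) warn("error rate 0: QV is infinite")
    -10 * log10(value)
  }
}

#' Windowed pairwise divergence between two sequences
#'
#' Computes raw divergence (mismatches / aligned columns) in fixed-size
#' windows over an alignment of the two sequences; alignment columns with a
#' gap are excluded from both numerator and denominator.  Sequences of equal
#' length are treated as already aligned; otherwise a global alignment is
#' computed first.  Windows with fewer than half their columns aligned are
#' flagged missing, and (with `jc_correct`) divergences at or beyond the
#' Jukes-Cantor saturation point `d >= 0.75` are flagged saturated.
#'
#' @param seq_a,seq_b Sequences (character or DNAString); `-` denotes gaps.
#' @param window Window size in alignment columns (default 20000).
#' @param jc_correct Apply the Jukes-Cantor correction
#'   `-(3/4) log(1 - (4/3) d)` (default FALSE).
#' @return Tibble per window: `start`, `end`, `aligned`, `mismatches`,
#'   `divergence`, `flag` (`"ok"`, `"missing"`, `"saturated"`).
#' @export
pairwise_divergence <- function(seq_a, seq_b, window = 20000,
                                jc_correct = FALSE) {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  if (nchar(a) != nchar(b)) {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                         Biostrings::DNAString(b),
                                         type = "global")
    a <- as.character(Biostrings::alignedPattern(aln))
    b <- as.character(Biostrings::alignedSubject(aln))
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca)
  starts <- seq(1L, n, by = window)
  purrr::map_dfr(starts, function(s) {
    e <- min(s + window - 1L, n)
    wa <- ca[s:e]; wb <- cb[s:e]
    aligned <- wa != "-" & wb != "-"
    n_aln <- sum(aligned)
    mm <- sum(wa[aligned] != wb[aligned])
    d <- if (n_aln > 0) mm / n_aln else NA_real_
    flag <- "ok"
    if (n_aln < (e - s + 1) / 2) flag <- "missing"
    if (jc_correct && !is.na(d)) {
      if (d >= 0.75) {
        flag <- "saturated"
      } else {
        d <- -0.75 * log(1 - 4 * d / 3)
      }
    }
    tibble(start = s - 1L, end = e, aligned = n_aln, mismatches = mm,
           divergence = d, flag = flag)
  })
}

#' Estimate the alpha-satellite mutation rate from windowed divergence
#'
#' Under a neutral divergence model, the expected divergence between two
#' lineages separated `t` generations ago from an ancestral population of
#' diploid size `N_anc` is `d = mu * (2 t + 4 N_anc)` (the `4 N_anc` term is
#' the expected coalescent time of the ancestral lineages).  Given per-window
#' divergences and ranges for the divergence time `T` (years) and `N_anc`,
#' each (window, T, N_anc) grid point yields `mu = d / (2 T / g + 4 N_anc)`.
#'
#' @param divergence_per_window Numeric vector of per-window divergences in
#'   `[0, 1)`.
#' @param T_years_range Divergence-time values in years (e.g.
#'   `c(4e5, 7e5)` for the human-archaic split).
#' @param N_anc_range Ancestral diploid sizes.
#' @param g Generation time in years (default 29).
#' @return A `mutation_rate_estimate`: tibble `estimates` (window, T, N_anc,
#'   mu) plus `mean_mu` and `sd_mu` across all estimates.
#' @examples
#' hor_mutation_rate(0.004, 5e5, 1e4, g = 25)$mean_mu  # 5e-8
#' @export
hor_mutation_rate <- function(divergence_per_window, T_years_range,
                              N_anc_range, g = 29) {
  d <- divergence_per_window
  if (any(d < 0 | d >= 1)) abort("divergences must lie in [0, 1)")
  if (!length(T_years_range) || !length(N_anc_range)) {
    abort("T and N_anc ranges must be non-empty")
  }
  grid <- tidyr::expand_grid(
    window = seq_along(d),
    T_years = T_years_range,
    N_anc = N_anc_range
  ) |>
    mutate(
      d = d[window],
      t_gens = T_years / g,
      mu = d / (2 * t_gens + 4 * N_anc),
      flagged = d >= 0.75
    )
  structure(
    list(estimates = grid, mean_mu = mean(grid$mu), sd_mu = sd(grid$mu),
         g = g),
    class = "mutation_rate_estimate"
  )
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<mutation_rate_estimate> mu = %.3g +/- %.3g per bp per generation (%d estimates)\n",
    x$mean_mu, if (is.na(x$sd_mu)) 0 else x$sd_mu, nrow(x$estimates)))
  invisible(x)
}
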