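#' Specify a demographic model for cohort simulation
#'
#' Bundles the population, split, and admixture-pulse parameters used by
#' [simulate_cohort()] and [simulate_null()].  Sizes are diploid effective
#' sizes; times are in generations before present; rates are per base pair
#' per generation.
#'
#' @param populations Data frame with columns `name`, `size` (diploid Ne) and
#'   optionally `drift`, the Balding-Nichols fixation index of each
#'   population relative to the shared ancestral allele-frequency pool.  When
#'   `drift` is absent it is filled from the population's oldest split time
#'   `t` as `t / (2 * size)`, capped at 0.5.
#' @param split_times Data frame with columns `pop_a`, `pop_b`, `time`
#'   (generations).  Optional; used for validation and drift defaults.
#' @param pulses Data frame of admixture pulses with columns `donor`,
#'   `recipient`, `time` (generations before present) and `fraction`
#'   (admixture proportion `m`, strictly between 0 and 1).  Donors may be
#'   archaic lineages absent from `populations` (e.g. `"NDL"`, `"DNS"`).
#' @param recomb_rate Recombination rate `r` per bp per generation.
#' @param mut_rate Mutation rate `mu` per bp per generation.
#' @param generation_time Generation time in years (default 29, so that 200
#'   generations corresponds to roughly 5,800 years).
#'
#' @return An object of class `demographic_model`.
#' @examples
#' m <- demographic_model(
#'   populations = data.frame(name = c("AFR", "PNG"), size = c(20000, 10000)),
#'   split_times = data.frame(pop_a = "AFR", pop_b = "PNG", time = 3500),
#'   pulses = data.frame(donor = "DNS", recipient = "PNG",
#'                       time = 1200, fraction = 0.04)
#' )
#' m$pulses
#' @export
demographic_model <- function(populations, split_times = NULL, pulses = NULL,
                              recomb_rate = 1e-8, mut_rate = 1.25e-8,
                              generation_time = 29) {
  populations <- as_tibble(populations)
  if (!all(c("name", "size") %in% names(populations))) {
    abort("`populations` needs columns `name` and `size`")
  }
  if (any(populations$size <= 0)) abort("all population sizes must be > 0")
  if (anyDuplicated(populations$name)) abort("population names must be unique")
  stopifnot_scalar_number(recomb_rate, "recomb_rate", min = 0)
  stopifnot_scalar_number(mut_rate, "mut_rate", min = 0)
  stopifnot_scalar_number(generation_time, "generation_time", min = 0,
                          strict_min = TRUE)

  if (!is.null(split_times)) {
    split_times <- as_tibble(split_times)
    if (any(split_times$time <= 0)) abort("split times must be > 0")
  }
  if (!is.null(pulses)) {
    pulses <- as_tibble(pulses)
    if (any(pulses$fraction <= 0 | pulses$fraction >= 1)) {
      abort("pulse fractions must lie strictly between 0 and 1")
    }
    if (any(pulses$time <= 0)) abort("pulse times must be > 0")
    if (!is.null(split_times)) {
      for (i in seq_len(nrow(pulses))) {
        rec <- pulses$recipient[i]
        rel <- split_times$time[split_times$pop_a == rec |
                                  split_times$pop_b == rec]
        if (length(rel) && any(rel <= pulses$time[i])) {
          abort(sprintf(
            "pulse into %s at %g generations predates a split involving it",
            rec, pulses$time[i]))
        }
      }
    }
  } else {
    pulses <- tibble(donor = character(), recipient = character(),
                     time = numeric(), fraction = numeric())
  }

  if (!"drift" %in% names(populations)) {
    drift <- rep(0.1, nrow(populations))
    if (!is.null(split_times)) {
      for (i in seq_len(nrow(populations))) {
        nm <- populations$name[i]
        rel <- split_times$time[split_times$pop_a == nm |
                                  split_times$pop_b == nm]
        if (length(rel)) {
          drift[i] <- min(0.5, max(rel) / (2 * populations$size[i]))
        }
      }
    }
    populations$drift <- drift
  }
  if (any(populations$drift < 0 | populations$drift >= 1)) {
    abort("`drift` values must lie in [0, 1)")
  }

  structure(
    list(populations = populations, split_times = split_times,
         pulses = pulses, recomb_rate = recomb_rate, mut_rate = mut_rate,
         generation_time = generation_time),
    class = "demographic_model"
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model>\n")
  cat(sprintf("  r = %g /bp/gen, mu = %g /bp/gen, g = %g y\n",
              x$recomb_rate, x$mut_rate, x$generation_time))
  cat("  populations:\n")
  print(x$populations)
  if (nrow(x$pulses)) {
    cat("  admixture pulses:\n")
    print(x$pulses)
  }
  invisible(x)
}

#' Default three-population demography with two archaic pulses
#'
#' An African outgroup (AFR), an East Asian sister group (EAS) and a
#' Papua-New-Guinea-like focal group (PNG) receiving a Neanderthal (NDL)
#' pulse and a larger Denisovan (DNS) pulse.  The published Papuan
#' demographies behind the original analyses are not printed in full
#' anywhere, so these values are explicit, configurable placeholders chosen
#' to give realistic tract-length scales (mean 1/(r t) of roughly 50-80 kbp).
#'
#' @param ndl_fraction,dns_fraction Pulse admixture proportions.
#' @param ndl_time,dns_time Pulse times in generations before present.
#' @return A [demographic_model()].
#' @examples
#' png_demography()$pulses
#' @export
png_demography <- function(ndl_fraction = 0.02, dns_fraction = 0.04,
                           ndl_time = 2000, dns_time = 1200) {
  demographic_model(
    populations = tibble(
      name = c("AFR", "EAS", "PNG"),
      size = c(20000, 10000, 10000),
      drift = c(0.05, 0.12, 0.15)
    ),
    split_times = tibble(
      pop_a = c("AFR", "AFR", "EAS"),
      pop_b = c("EAS", "PNG", "PNG"),
      time = c(3500, 3500, 2100)
    ),
    pulses = tibble(
      donor = c("NDL", "DNS"),
      recipient = c("PNG", "PNG"),
      time = c(ndl_time, dns_time),
      fraction = c(ndl_fraction, dns_fraction)
    )
  )
}

#' Expected introgressed tract length
#'
#' Under recombination at rate `r` per bp per generation, a tract introduced
#' `t` generations ago has mean surviving length `1 / (r * t)` bp.
#'
#' @param r Recombination rate per bp per generation (> 0).
#' @param t Generations since admixture (> 0).
#' @return Mean tract length in bp.
#' @examples
#' expected_tract_length(1e-8, 2000)  # 50,000 bp
#' @export
expected_tract_length <- function(r, t) {
  stopifnot_scalar_number(r, "r", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(t, "t", min = 0, strict_min = TRUE)
  1 / (r * t)
}

#' Specify an alpha-satellite higher-order-repeat array
#'
#' @param monomer_length Monomer length in bp (canonically 171).
#' @param monomers_per_hor Monomers per higher-order-repeat (HOR) unit.
#' @param copies HOR copy number in the array.
#' @param substitution_rate Per-site substitution probability applied
#'   independently to each HOR copy (in `[0, 1)`).
#' @param flank_length Total flanking unique sequence in bp (split across the
#'   two sides of the array).
#' @return An object of class `satellite_spec`.
#' @examples
#' satellite_spec(171, 12, 10)
#' @export
satellite_spec <- function(monomer_length = 171, monomers_per_hor = 12,
                           copies = 10, substitution_rate = 0,
                           flank_length = 0) {
  stopifnot_scalar_number(monomer_length, "monomer_length", min = 1)
  stopifnot_scalar_number(monomers_per_hor, "monomers_per_hor", min = 1)
  stopifnot_scalar_number(copies, "copies", min = 1)
  stopifnot_scalar_number(substitution_rate, "substitution_rate", min = 0)
  if (substitution_rate >= 1) abort("`substitution_rate` must be < 1")
  stopifnot_scalar_number(flank_length, "flank_length", min = 0)
  structure(
    list(monomer_length = as.integer(monomer_length),
         monomers_per_hor = as.integer(monomers_per_hor),
         copies = as.integer(copies),
         substitution_rate = substitution_rate,
         flank_length = as.integer(flank_length)),
    class = "satellite_spec"
  )
}
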