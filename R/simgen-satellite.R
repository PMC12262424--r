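# Alpha-satellite higher-order-repeat array synthesis.

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    shift <- sample.int(3, length(hit), replace = TRUE)
    chars[hit] <- bases[(match(chars[hit], bases) - 1L + shift) %% 4L + 1L]
  }
  paste(chars, collapse = "")
}

#' Synthesize an alpha-satellite higher-order-repeat array
#'
#' Builds an ancestral HOR unit of `monomers_per_hor` random monomers, tiles
#' `copies` independently mutated copies of it, and pads with unique flanking
#' sequence.  Each copy acquires substitutions independently at
#' `substitution_rate` per site, so two copies of the same ancestor differ at
#' about `2 * rate` of sites.
#'
#' @param spec A [satellite_spec()].
#' @param seed Seed (same seed, same sequence).
#' @return An object of class `satellite_array`: list with `sequence`
#'   (character), `hor_units` (tibble of 0-based half-open copy intervals
#'   that tile the array exactly), `spec` and `seed`.
#' @examples
#' arr <- synthesize_satellite_array(satellite_spec(171, 12, 10), seed = 1)
#' nchar(arr$sequence)  # 171 * 12 * 10
#' @export
synthesize_satellite_array <- function(spec, seed) {
  if (!inherits(spec, "satellite_spec")) abort("`spec` must be a satellite_spec")
  with_seed(child_seed(seed, "satellite"), {
    hor_len <- spec$monomer_length * spec$monomers_per_hor
    ancestral <- paste(
      vapply(seq_len(spec$monomers_per_hor),
             function(i) random_dna(spec$monomer_length), character(1)),
      collapse = ""
    )
    copies <- vapply(seq_len(spec$copies),
                     function(i) mutate_seq(ancestral, spec$substitution_rate),
                     character(1))
    left <- floor(spec$flank_length / 2)
    right <- spec$flank_length - left
    seqn <- paste0(
      if (left > 0) random_dna(left) else "",
      paste(copies, collapse = ""),
      if (right > 0) random_dna(right) else ""
    )
    hor_units <- tibble(
      copy = seq_len(spec$copies),
      start = left + (seq_len(spec$copies) - 1L) * hor_len,
      end = left + seq_len(spec$copies) * hor_len
    )
    structure(list(sequence = seqn, hor_units = hor_units, spec = spec,
                   seed = as.integer(seed)),
              class = "satellite_array")
  })
}

#' @export
print.satellite_array <- function(x, ...) {
  cat(sprintf(
    "<satellite_array> %d bp: %d x (%d-monomer HOR of %d bp), %d bp flank\n",
    nchar(x$sequence), x$spec$copies, x$spec$monomers_per_hor,
    x$spec$monomer_length * x$spec$monomers_per_hor, x$spec$flank_length))
  invisible(x)
}
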