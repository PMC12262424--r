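# Windowed private-variant observable for the introgression HMM.

#' Count private derived variants in tiling windows
#'
#' The HMM observable: in each fixed-size window, the number of derived
#' alleles carried by the focal haplotype at sites where the outgroup panel
#' carries no derived allele ("private variants").
#'
#' @param focal_variants Positions (0-based) of derived alleles on the focal
#'   haplotype; a numeric vector or a data frame with a `pos` column.
#' @param outgroup_variants Positions at which the outgroup panel carries a
#'   derived allele (vector or data frame with `pos`).  Must describe a
#'   non-empty panel: pass the full position set even if no site is derived
#'   is impossible in practice, but `NULL` is refused because every focal
#'   variant would count as private.
#' @param chrom_length Chromosome length in bp (windows tile `[0,
#'   chrom_length)`).
#' @param window_size Window size in bp (>= 1000; default 1000).
#' @param callable Callable fraction per window, recycled (default 1).
#' @param chrom Chromosome name.
#' @return Tibble of windows: `chrom`, `start`, `end`, `count`, `callable`.
#' @examples
#' window_private_variants(c(10, 1500), outgroup_variants = 10,
#'                         chrom_length = 2000)
#' @export
window_private_variants <- function(focal_variants, outgroup_variants,
                                    chrom_length, window_size = 1000,
                                    callable = 1, chrom = "chr1") {
  pos_of <- function(x) {
    if (is.data.frame(x)) x$pos else as.numeric(x)
  }
  if (is.null(outgroup_variants)) {
    abort("an outgroup panel is required: with none, every variant is private")
  }
  stopifnot_scalar_number(window_size, "window_size", min = 1000)
  stopifnot_scalar_number(chrom_length, "chrom_length", min = window_size)
  focal <- pos_of(focal_variants)
  outg <- pos_of(outgroup_variants)
  private <- setdiff(focal, outg)

  starts <- seq(0L, chrom_length - 1L, by = window_size)
  ends <- pmin(starts + window_size, chrom_length)
  idx <- findInterval(private, starts)
  count <- tabulate(idx, nbins = length(starts))
  tibble(chrom = chrom, start = as.integer(starts), end = as.integer(ends),
         count = as.integer(count),
         callable = rep_len(callable, length(starts)))
}
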