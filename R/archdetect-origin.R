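# Archaic-origin classification of introgressed segments by match rate.

#' Match-rate profile of a segment against archaic genomes
#'
#' Informative sites are the focal haplotype's private derived alleles inside
#' the segment (absent from the outgroup panel).  For each archaic genome,
#' sites it does not cover are excluded from its informative count, and the
#' match rate is the fraction of covered informative sites at which it
#' carries the derived allele.
#'
#' @param segment One segment: a list or one-row data frame with `start` and
#'   `end` (0-based half-open).
#' @param focal_variants Derived-allele positions on the focal haplotype.
#' @param archaic_geno Data frame with a `pos` column plus one 0/1 column per
#'   archaic genome (`NA` = site not covered by that genome).  Positions
#'   absent from the table are treated as uncovered by every archaic genome.
#' @param outgroup_variants Positions with any derived allele in the outgroup
#'   panel.
#' @return Tibble (`archaic`, `informative`, `matched`, `rate`); `rate` is
#'   `NA` when a genome covers no informative site.
#' @export
match_rate <- function(segment, focal_variants, archaic_geno,
                       outgroup_variants) {
  seg <- as.list(segment)
  if (is.null(seg$start) || is.null(seg$end) || seg$start >= seg$end) {
    abort("`segment` needs start < end")
  }
  focal <- if (is.data.frame(focal_variants)) focal_variants$pos else
    as.numeric(focal_variants)
  outg <- if (is.data.frame(outgroup_variants)) outgroup_variants$pos else
    as.numeric(outgroup_variants)
  inform_pos <- setdiff(focal[focal >= seg$start & focal < seg$end], outg)

  arch_cols <- setdiff(names(archaic_geno), "pos")
  purrr::map_dfr(arch_cols, function(a) {
    hit <- match(inform_pos, archaic_geno$pos)
    val <- archaic_geno[[a]][hit]        # NA when absent or uncovered
    covered <- !is.na(val)
    n_inf <- sum(covered)
    n_match <- sum(val[covered] == 1)
    tibble(archaic = a, informative = n_inf, matched = n_match,
           rate = if (n_inf > 0) n_match / n_inf else NA_real_)
  })
}

#' Classify the archaic origin of a match-rate profile
#'
#' The low-affinity rule removes segments whose derived alleles match every
#' archaic genome at a rate below `low` (default 10%): such segments are
#' labelled `REJECTED`.  A segment matching exactly one archaic genome at or
#' above `high` (and the rest below it) takes that genome's label; anything
#' else is ambiguous (`AMB`).  Undefined profiles (no informative sites) are
#' `REJECTED`.
#'
#' @param profile A [match_rate()] tibble (`archaic`, `rate`).
#' @param low Rejection cutoff (default 0.1).
#' @param high Assignment cutoff (default 0.3, following common practice for
#'   matching against archaic-specific alleles).
#' @return A single origin label: one of the archaic names, `"AMB"` or
#'   `"REJECTED"`.
#' @examples
#' classify_origin(data.frame(archaic = c("NDL", "DNS"), rate = c(0.7, 0.1)))
#' @export
classify_origin <- function(profile, low = 0.1, high = 0.3) {
  rates <- profile$rate
  if (length(rates) == 0 || any(is.na(rates))) return("REJECTED")
  if (all(rates < low)) return("REJECTED")
  hits <- which(rates >= high)
  if (length(hits) == 1) return(profile$archaic[hits])
  "AMB"
}

#' Consensus of two segment sets by interval intersection
#'
#' Intersects every overlapping pair of intervals from the two sets (e.g. the
#' HMM calls and an externally supplied reference-free call set), dropping
#' intersections shorter than `min_overlap_bp`.  When variant data are
#' supplied, the match-rate profile and origin are recomputed on each
#' intersected span.
#'
#' @param set_a,set_b Segment tibbles (`start`, `end`, optionally `chrom`,
#'   `hap`) on the same haplotype and coordinates.
#' @param min_overlap_bp Minimum intersection length kept (default 1).
#' @param focal_variants,archaic_geno,outgroup_variants Optional inputs for
#'   recomputing [match_rate()] on each intersection.
#' @param low,high Cutoffs passed to [classify_origin()].
#' @return Tibble of consensus segments with `source = "consensus"` and, when
#'   recomputed, one `rate_*` column per archaic genome plus `origin`.
#' @export
consensus_segments <- function(set_a, set_b, min_overlap_bp = 1,
                               focal_variants = NULL, archaic_geno = NULL,
                               outgroup_variants = NULL, low = 0.1,
                               high = 0.3) {
  set_a <- as_tibble(set_a)
  set_b <- as_tibble(set_b)
  if (!nrow(set_a) || !nrow(set_b)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  hap = character(), source = character()))
  }
  out <- purrr::map_dfr(seq_len(nrow(set_a)), function(i) {
    a <- set_a[i, ]
    hits <- set_b |> filter(start < a$end, end > a$start)
    if (!nrow(hits)) return(NULL)
    tibble(chrom = col_or(a, "chrom", NA_character_),
           start = pmax(a$start, hits$start),
           end = pmin(a$end, hits$end),
           hap = col_or(a, "hap", NA_character_))
  })
  if (is.null(out) || !nrow(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  hap = character(), source = character()))
  }
  out <- out |>
    filter(end - start >= min_overlap_bp) |>
    distinct() |>
    arrange(start) |>
    mutate(source = "consensus")
  if (!is.null(focal_variants) && !is.null(archaic_geno)) {
    prof <- purrr::map(seq_len(nrow(out)), function(i) {
      match_rate(out[i, ], focal_variants, archaic_geno, outgroup_variants)
    })
    arch_names <- unique(purrr::map_dfr(prof, identity)$archaic)
    for (a in arch_names) {
      out[[paste0("rate_", a)]] <- purrr::map_dbl(prof, function(p) {
        p$rate[p$archaic == a]
      })
    }
    out$origin <- purrr::map_chr(prof, classify_origin, low = low,
                                 high = high)
  }
  out
}
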