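# End-to-end introgression scan over a cohort, plus truth benchmarking.

#' Archaic reference genotypes of a cohort as a table
#'
#' @param cohort A `synthetic_cohort`.
#' @return Tibble with `pos` and one 0/1 column per archaic donor reference.
#' @export
archaic_genotype_table <- function(cohort) {
  donors <- colnames(cohort$arch)
  if (identical(donors, "none")) {
    return(tibble(pos = cohort$variants$pos))
  }
  out <- tibble(pos = cohort$variants$pos)
  for (d in donors) out[[d]] <- as.integer(cohort$arch[, d])
  out
}

#' Scan a cohort for introgressed segments
#'
#' Builds windowed private-variant counts for every focal haplotype, fits a
#' single HMM to the pooled windows, decodes segments per haplotype, and
#' classifies each segment's archaic origin by match rate.
#'
#' @param cohort A `synthetic_cohort`.
#' @param window_size Window size in bp (default 1000).
#' @param cutoff Posterior cutoff for segment calls (default 0.8).
#' @param low,high Origin-classification cutoffs (see [classify_origin()]).
#' @param init,max_iter,tol Passed to [fit_hmm()].
#' @param haps Haplotypes to scan (default: all focal haplotypes).
#' @return A list of class `introgression_scan`: `segments` (calls with
#'   per-archaic `rate_*` columns and `origin`), `fit` (the `intro_hmm`),
#'   and `windows` (per-haplotype observation tibbles).
#' @export
detect_introgression <- function(cohort, window_size = 1000, cutoff = 0.8,
                                 low = 0.1, high = 0.3, init = NULL,
                                 max_iter = 50, tol = 1e-4, haps = NULL) {
  focal_haps <- haps %||%
    cohort$samples$hap[cohort$samples$pop == cohort$params$focal]
  outg <- panel_positions(cohort)
  arch_tab <- archaic_genotype_table(cohort)

  wins <- purrr::map(setNames(focal_haps, focal_haps), function(h) {
    window_private_variants(hap_variant_positions(cohort, h), outg,
                            cohort$chrom_length, window_size,
                            chrom = cohort$chrom)
  })
  fit <- fit_hmm(bind_rows(wins), init = init, max_iter = max_iter,
                 tol = tol)

  segments <- purrr::map_dfr(focal_haps, function(h) {
    segs <- decode_segments(wins[[h]], fit, cutoff = cutoff, hap = h)
    if (!nrow(segs)) return(segs)
    focal_pos <- hap_variant_positions(cohort, h)
    prof <- purrr::map(seq_len(nrow(segs)), function(i) {
      match_rate(segs[i, ], focal_pos, arch_tab, outg)
    })
    for (a in setdiff(names(arch_tab), "pos")) {
      segs[[paste0("rate_", a)]] <- purrr::map_dbl(prof, function(p) {
        p$rate[p$archaic == a]
      })
      segs[[paste0("informative_", a)]] <- purrr::map_int(prof, function(p) {
        as.integer(p$informative[p$archaic == a])
      })
    }
    segs$origin <- purrr::map_chr(prof, classify_origin, low = low,
                                  high = high)
    segs
  })
  structure(list(segments = segments, fit = fit, windows = wins),
            class = "introgression_scan")
}

#' @export
print.introgression_scan <- function(x, ...) {
  cat("<introgression_scan>", nrow(x$segments), "segments on",
      length(x$windows), "haplotypes\n")
  print(x$fit)
  invisible(x)
}

# Merge possibly-overlapping intervals into disjoint ones.
merge_intervals <- function(start, end) {
  if (!length(start)) return(tibble(start = integer(), end = integer()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

intersect_bp <- function(a, b) {
  # total overlap between two merged interval sets
  if (!nrow(a) || !nrow(b)) return(0)
  total <- 0
  j <- 1L
  for (i in seq_len(nrow(a))) {
    while (j <= nrow(b) && b$end[j] <= a$start[i]) j <- j + 1L
    k <- j
    while (k <= nrow(b) && b$start[k] < a$end[i]) {
      total <- total + max(0, min(a$end[i], b$end[k]) -
                             max(a$start[i], b$start[k]))
      k <- k + 1L
    }
  }
  total
}

#' Base-level precision, recall and F1 of segment calls against truth
#'
#' @param segments Called segments (`hap`, `start`, `end`); `REJECTED` calls
#'   are excluded if an `origin` column is present.
#' @param truth Truth tracts (`hap`, `start`, `end`).
#' @param haps Haplotypes to evaluate (default: union of both sets).
#' @return One-row tibble: `tp`, `called_bp`, `truth_bp`, `precision`,
#'   `recall`, `f1`.
#' @export
segment_f1 <- function(segments, truth, haps = NULL) {
  segments <- as_tibble(segments)
  if ("origin" %in% names(segments)) {
    segments <- segments |> filter(origin != "REJECTED")
  }
  haps <- haps %||% union(unique(segments$hap), unique(truth$hap))
  tp <- called <- truthbp <- 0
  for (h in haps) {
    sa <- segments |> filter(hap == h)
    tb <- truth |> filter(hap == h)
    ma <- merge_intervals(sa$start, sa$end)
    mb <- merge_intervals(tb$start, tb$end)
    called <- called + sum(ma$end - ma$start)
    truthbp <- truthbp + sum(mb$end - mb$start)
    tp <- tp + intersect_bp(ma, mb)
  }
  precision <- if (called > 0) tp / called else NA_real_
  recall <- if (truthbp > 0) tp / truthbp else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  tibble(tp = tp, called_bp = called, truth_bp = truthbp,
         precision = precision, recall = recall, f1 = f1)
}
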