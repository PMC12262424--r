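# Genic enrichment of introgressed SVs, and genotype-set concordance.

# Is each interval within `flank` bp of a merged gene interval?
near_gene <- function(chrom, start, end, genes, flank) {
  out <- logical(length(start))
  for (ch in unique(chrom)) {
    g <- genes |> filter(chrom == ch)
    idx <- which(chrom == ch)
    if (!nrow(g)) next
    m <- merge_intervals(g$start, g$end)
    cmax <- cummax(m$end)
    S <- start[idx] - flank
    E <- end[idx] + flank
    j <- findInterval(E - 1L, m$start)     # last gene starting before E
    hit <- j >= 1 & ifelse(j >= 1, cmax[pmax(j, 1L)] > S, FALSE)
    out[idx] <- hit
  }
  out
}

odds_ratio_2x2 <- function(a, b, c, d) {
  corrected <- FALSE
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  list(or = (a * d) / (b * c), corrected = corrected)
}

#' Genic enrichment of introgressed SVs
#'
#' Tests whether introgressed SVs sit within `flank` bp of genes more often
#' than non-introgressed SVs: a one-sided Fisher's exact test on the 2x2
#' table (introgressed x near-gene), plus a permutation test that reshuffles
#' SV positions uniformly within their chromosome (lengths and introgression
#' flags preserved) and compares the permuted odds ratios to the observed
#' one, `p = (1 + #(perm >= obs)) / (1 + n_perm)`.
#'
#' @param svs SV tibble with `chrom`, `start`, `end` and logical
#'   `introgressed`.
#' @param genes Gene intervals (`chrom`, `start`, `end`); overlapping
#'   intervals are merged internally.
#' @param flank Distance cutoff in bp (default 1000).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation null.
#' @param chrom_lengths Named vector of chromosome lengths for the shuffle
#'   (default: max coordinate seen per chromosome).
#' @return An `enrichment_result`: odds ratio (cross-product, with
#'   Haldane-Anscombe correction flagged on zero margins), one-sided Fisher
#'   p, permutation p, permutation count and the 2x2 table.
#' @export
genic_enrichment <- function(svs, genes, flank = 1000, n_perm = 1000, seed,
                             chrom_lengths = NULL) {
  svs <- as_tibble(svs)
  genes <- as_tibble(genes)
  if (!"introgressed" %in% names(svs)) {
    abort("`svs` needs a logical `introgressed` column")
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- c(tapply(c(svs$end, genes$end), c(svs$chrom,
                                                       genes$chrom), max))
  }
  near <- near_gene(svs$chrom, svs$start, svs$end, genes, flank)
  a <- sum(svs$introgressed & near)
  b <- sum(svs$introgressed & !near)
  c_ <- sum(!svs$introgressed & near)
  d <- sum(!svs$introgressed & !near)
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(c("introgressed", "background"),
                                c("near_gene", "far")))
  or <- odds_ratio_2x2(a, b, c_, d)
  fisher_p <- fisher.test(tab, alternative = "greater")$p.value

  lens <- svs$end - svs$start
  perm_stats <- with_seed(child_seed(seed, "genic_perm"), {
    vapply(seq_len(n_perm), function(i) {
      span <- chrom_lengths[svs$chrom] - lens
      new_start <- floor(runif(nrow(svs)) * pmax(span, 1))
      pn <- near_gene(svs$chrom, new_start, new_start + lens, genes, flank)
      pa <- sum(svs$introgressed & pn); pb <- sum(svs$introgressed & !pn)
      pc <- sum(!svs$introgressed & pn); pd <- sum(!svs$introgressed & !pn)
      odds_ratio_2x2(pa, pb, pc, pd)$or
    }, numeric(1))
  })
  perm_p <- (1 + sum(perm_stats >= or$or)) / (1 + n_perm)

  structure(
    list(odds_ratio = or$or, fisher_p = fisher_p, perm_p = perm_p,
         n_perm = n_perm, table = tab, corrected = or$corrected),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> OR = %.3f%s | Fisher p = %.4g | perm p = %.4g (%d perms)\n",
    x$odds_ratio, if (x$corrected) " (Haldane-Anscombe corrected)" else "",
    x$fisher_p, x$perm_p, x$n_perm))
  print(x$table)
  invisible(x)
}

normalize_gt <- function(gt) {
  parts <- strsplit(gt, "[|/]")
  vapply(parts, function(p) {
    if (any(p == "." | is.na(p))) NA_character_ else
      paste(sort(p), collapse = "/")
  }, character(1))
}

#' Genotype concordance between a truth set and a test set
#'
#' Compares diploid genotypes (phase-insensitive) at shared variant keys
#' (`chrom`, `pos`, `ref`, `alt`, `sample`), stratified by variant class and
#' by SV length bin.  Missing genotypes on either side are excluded from the
#' denominator.
#'
#' @param truth,test Long genotype tibbles with columns `chrom`, `pos`,
#'   `ref`, `alt`, `class`, `sample`, `gt` and optionally `length`.
#' @param size_bins Breaks (bp) for SV length stratification.
#' @return Tibble (`sample`, `class`, `size_bin`, `n`, `concordant`,
#'   `concordance`).
#' @export
genotype_concordance <- function(truth, test,
                                 size_bins = c(0, 50, 250, 1000, Inf)) {
  truth <- as_tibble(truth)
  test <- as_tibble(test)
  key <- c("chrom", "pos", "ref", "alt", "sample")
  joined <- inner_join(truth, test, by = key, suffix = c("_truth", "_test"))
  if (!nrow(joined)) abort("no shared variant keys between the two sets")
  if (!"length_truth" %in% names(joined)) joined$length_truth <- NA_real_
  joined |>
    mutate(
      g1 = normalize_gt(gt_truth), g2 = normalize_gt(gt_test),
      class = class_truth,
      size_bin = if_else(
        class %in% c("INS", "DEL", "INV") & !is.na(length_truth),
        as.character(cut(length_truth, breaks = size_bins)),
        NA_character_)
    ) |>
    filter(!is.na(g1), !is.na(g2)) |>
    group_by(sample, class, size_bin) |>
    summarise(n = n(), concordant = sum(g1 == g2),
              concordance = concordant / n, .groups = "drop")
}
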