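# Alignment-free archaic-specific k-mer screening.
#
# K-mers are stored in canonical form (lexicographic min of a k-mer and its
# reverse complement, A < C < G < T), so counting is strand-invariant.

#' Build the archaic-specific k-mer set
#'
#' Collects canonical k-mers seen at least `min_archaic_occurrences` times
#' across the archaic input sequences and removes every canonical k-mer
#' present anywhere in the outgroup (modern African) sequences.  K-mers
#' containing `N` are excluded.
#'
#' @param archaic_seqs Character vector (or [Biostrings::DNAStringSet]) of
#'   archaic sequences.
#' @param outgroup_seqs Outgroup sequences used for subtraction (assemblies
#'   or read sets; only k-mer presence matters).
#' @param k Odd k-mer length (default 31).
#' @param min_archaic_occurrences Minimum total occurrences across archaic
#'   inputs (default 2; suppresses error k-mers from archaic reads).
#' @return An object of class `kmer_set`: sorted canonical `kmers`, `k`, and
#'   provenance counts.
#' @export
build_archaic_specific_kmers <- function(archaic_seqs, outgroup_seqs,
                                         k = 31, min_archaic_occurrences = 2) {
  stopifnot_scalar_number(k, "k", min = 1)
  if (k %% 2 == 0) abort("`k` must be odd (canonical form must be unique)")
  archaic_seqs <- as.character(archaic_seqs)
  outgroup_seqs <- as.character(outgroup_seqs)
  if (!length(archaic_seqs) || all(nchar(archaic_seqs) < k)) {
    warn("no archaic input of length >= k: empty k-mer set")
    return(structure(list(kmers = character(0), k = as.integer(k),
                          n_archaic_input = length(archaic_seqs),
                          n_outgroup_input = length(outgroup_seqs)),
                     class = "kmer_set"))
  }
  clean <- function(km) km[!grepl("[^ACGT]", km)]
  arch <- canonicalize(clean(unlist(lapply(archaic_seqs, seq_kmers, k = k))))
  counts <- table(arch)
  keep <- names(counts)[counts >= min_archaic_occurrences]
  outg <- unique(canonicalize(clean(unlist(
    lapply(outgroup_seqs, seq_kmers, k = k)))))
  structure(
    list(kmers = sort(setdiff(keep, outg)), k = as.integer(k),
         n_archaic_input = length(archaic_seqs),
         n_outgroup_input = length(outgroup_seqs)),
    class = "kmer_set"
  )
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> %d canonical %d-mers (archaic-specific)\n",
              length(x$kmers), x$k))
  invisible(x)
}

#' Write / read a k-mer set as plain ACGT lines
#'
#' @param kset A `kmer_set`.
#' @param path File path.
#' @return `path` (write) or a `kmer_set` (read).
#' @export
write_kmer_set <- function(kset, path) {
  writeLines(c(sprintf("#k=%d", kset$k), kset$kmers), path)
  invisible(path)
}

#' @rdname write_kmer_set
#' @export
read_kmer_set <- function(path) {
  lines <- readLines(path)
  k <- as.integer(sub("#k=", "", lines[1], fixed = TRUE))
  structure(list(kmers = lines[-1], k = k, n_archaic_input = NA_integer_,
                 n_outgroup_input = NA_integer_),
            class = "kmer_set")
}

#' Count archaic-specific k-mers in tiling windows
#'
#' Each window's count is the number of k-mer start positions in
#' `[w_start, w_end - k + 1)` whose canonical k-mer belongs to the set
#' (k-mers straddling a window boundary are not counted).
#'
#' @param assembly_seq One assembly/haplotype sequence (character or
#'   DNAString).
#' @param kmer_set A `kmer_set`.
#' @param window Window size in bp (default 2000; must be >= k).
#' @param assembly Assembly/haplotype id recorded on the track.
#' @return A `window_count_track` tibble: `assembly`, `start`, `end`,
#'   `count`, with `k` and `window` as attributes.
#' @export
count_kmers_in_windows <- function(assembly_seq, kmer_set, window = 2000,
                                   assembly = "asm") {
  if (!inherits(kmer_set, "kmer_set")) abort("`kmer_set` must be a kmer_set")
  k <- kmer_set$k
  if (window < k) abort("`window` must be >= k")
  seqc <- as.character(assembly_seq)
  L <- nchar(seqc)
  starts <- seq(0L, max(L - 1L, 0L), by = window)
  ends <- pmin(starts + window, L)

  hit_pos <- integer(0)
  if (L >= k && length(kmer_set$kmers)) {
    km <- seq_kmers(seqc, k)
    hits <- canonicalize(km) %in% kmer_set$kmers
    hit_pos <- which(hits) - 1L            # 0-based k-mer start positions
  }
  count <- vapply(seq_along(starts), function(i) {
    hi <- ends[i] - k + 1L                 # exclusive upper bound on starts
    sum(hit_pos >= starts[i] & hit_pos < hi)
  }, numeric(1))

  out <- tibble(assembly = assembly, start = as.integer(starts),
                end = as.integer(ends), count = as.integer(count))
  attr(out, "k") <- k
  attr(out, "window") <- as.integer(window)
  class(out) <- c("window_count_track", class(out))
  out
}

#' Calibrate a k-mer count cutoff to the genome-wide introgression fraction
#'
#' Returns the smallest threshold `t` among the observed count values (plus 0
#' and `max + 1`) such that the fraction of windows with `count >= t` does
#' not exceed `genome_introgression_fraction`.  When even flagging no window
#' cannot reach the target fraction (fraction below `1 / n_windows`),
#' `max + 1` is returned with a warning.
#'
#' @param track A `window_count_track` (or any tibble with `count`).
#' @param genome_introgression_fraction Target flagged fraction in (0, 1].
#' @return Integer count cutoff.
#' @examples
#' calibrate_threshold(data.frame(count = c(0, 0, 1, 5, 9, 10)), 1 / 3)  # 9
#' @export
calibrate_threshold <- function(track, genome_introgression_fraction) {
  f <- genome_introgression_fraction
  stopifnot_scalar_number(f, "genome_introgression_fraction", min = 0,
                          strict_min = TRUE, max = 1)
  counts <- track$count
  if (!length(counts)) abort("`track` is empty")
  cand <- sort(unique(c(0L, counts, max(counts) + 1L)))
  frac <- vapply(cand, function(t) mean(counts >= t), numeric(1))
  ok <- which(frac <= f)
  t <- cand[ok[1]]
  if (t > max(counts)) {
    warn("target fraction below 1/n_windows: no window passes the cutoff")
  }
  as.integer(t)
}

# Mann-Whitney U with midranks.  Exact p by full enumeration of group
# assignments when the assignment space is enumerable; tie-corrected normal
# approximation otherwise.
mwu_test <- function(x, y, max_enumeration = 2e5) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) abort("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n1 + n2, n1) <= max_enumeration) {
    vals <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    r_all <- rank(vals)
    us <- apply(combs, 2, function(idx) {
      sum(r_all[idx]) - n1 * (n1 + 1) / 2
    })
    p <- mean(us >= U)
    method <- "exact enumeration"
  } else {
    N <- n1 + n2
    ties <- table(r)
    tie_corr <- sum(ties ^ 3 - ties) / (N * (N - 1))
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * (N + 1 - tie_corr)
    p <- pnorm((U - mu) / sqrt(sigma2), lower.tail = FALSE)
    method <- "normal approximation (midranks, tie-corrected)"
  }
  list(U = U, p = p, n1 = n1, n2 = n2, method = method)
}

#' Are archaic-specific k-mer counts enriched in introgressed segments?
#'
#' One-sided Mann-Whitney U test comparing window counts that overlap
#' introgressed segments against non-overlapping windows (alternative:
#' overlapping windows are stochastically greater).  Exact enumeration is
#' used when both groups have at most 8 windows, a tie-corrected midrank
#' normal approximation otherwise.
#'
#' @param track A `window_count_track`.
#' @param segments Introgressed segments (`start`, `end`), on the same
#'   assembly coordinates as the track.
#' @return Tibble: `U`, `p`, `n_overlap`, `n_background`, `method`.
#' @export
enrichment_test <- function(track, segments) {
  segments <- as_tibble(segments)
  if (!nrow(segments)) abort("`segments` is empty")
  m <- merge_intervals(segments$start, segments$end)
  cmax <- cummax(m$end)
  j <- findInterval(track$end - 1L, m$start)
  overlap <- j >= 1 & ifelse(j >= 1, cmax[pmax(j, 1L)] > track$start, FALSE)
  if (all(overlap) || !any(overlap)) {
    abort("need both overlapping and non-overlapping windows")
  }
  res <- mwu_test(track$count[overlap], track$count[!overlap])
  tibble(U = res$U, p = res$p, n_overlap = res$n1, n_background = res$n2,
         method = res$method)
}

#' Best-hit window identity between two sequences
#'
#' Slides fixed-size windows (with a step) along the query, locally aligns
#' each window to the full target (match +1, mismatch -1, gap -1, linear),
#' and keeps the single best target location per query window.  Identity
#' counts both substitutions and indels:
#' `matches / (matches + mismatches + indel bases) * 100`.
#'
#' @param query_seq,target_seq Sequences (character or DNAString).
#' @param window Query window size in bp (default 20000).
#' @param step Query step in bp (default 1000).
#' @return An `identity_matrix` tibble: `query_start`, `query_end`,
#'   `target_start`, `target_end`, `score`, `identity` (percent).
#' @export
window_identity <- function(query_seq, target_seq, window = 20000,
                            step = 1000) {
  query_seq <- as.character(query_seq)
  target_seq <- as.character(target_seq)
  if (window > nchar(query_seq)) abort("`window` exceeds query length")
  starts <- seq(0L, nchar(query_seq) - window, by = step)
  target <- Biostrings::DNAString(target_seq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  out <- purrr::map_dfr(starts, function(s) {
    qwin <- Biostrings::DNAString(substr(query_seq, s + 1L, s + window))
    aln <- Biostrings::pairwiseAlignment(
      qwin, target, type = "local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 1)
    nm <- Biostrings::nmatch(aln)
    nmm <- Biostrings::nmismatch(aln)
    ind <- Biostrings::nindel(aln)
    indel_bases <- sum(Biostrings::insertion(ind)[, "WidthSum"],
                       Biostrings::deletion(ind)[, "WidthSum"])
    denom <- nm + nmm + indel_bases
    tgt <- Biostrings::subject(aln)
    tibble(query_start = s, query_end = s + window,
           target_start = Biostrings::start(tgt) - 1L,
           target_end = Biostrings::end(tgt),
           score = Biostrings::score(aln),
           identity = if (denom > 0) 100 * nm / denom else NA_real_)
  })
  class(out) <- c("identity_matrix", class(out))
  out
}
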