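# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream.  All stochastic entry points funnel through here so that a master
# seed reproduces byte-identical output.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) {
    abort("a `seed` is required: stochastic results must be reproducible")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Derive a per-stage child seed from a master seed.  Keeps every derived seed
# a valid 32-bit integer so the same master seed always expands to the same
# stream family.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                    strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %g", name, min))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %g", name, min))
  }
  if (x > max) abort(sprintf("`%s` must be <= %g", name, max))
  invisible(x)
}

# 0-based half-open BED <-> 1-based inclusive VCF position conversions.
bed_to_vcf_pos <- function(pos0) as.integer(pos0) + 1L
vcf_to_bed_pos <- function(pos1) as.integer(pos1) - 1L

# Reverse complement for plain character DNA (vectorised).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Canonical form of a k-mer: lexicographic min of itself and its reverse
# complement (A < C < G < T).
canonicalize <- function(kmers) {
  rc <- revcomp(kmers)
  if_else(kmers <= rc, kmers, rc)
}

# All k-mer substrings of one sequence, in order of start position.
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Stable content hash used by determinism checks.
content_hash <- function(x) rlang::hash(x)

# Column accessor with default for optional tibble columns.
col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}
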