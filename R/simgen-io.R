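# Cohort sequence realization and on-disk formats (FASTA / VCF / BED).
#
# All internal coordinates are 0-based half-open; conversion to 1-based
# happens only at the VCF boundary.  Tract and SV BED files use the
# haplotype id as the sequence key (coordinates are on the shared reference
# frame), with the donor / SV-type label in column 4.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

apply_svs_to_chars <- function(chars, svs) {
  if (!nrow(svs)) return(chars)
  svs <- svs |> arrange(dplyr::desc(start))
  for (i in seq_len(nrow(svs))) {
    s <- svs$start[i]; e <- svs$end[i]
    if (svs$type[i] == "DEL") {
      chars <- chars[-((s + 1L):e)]
    } else if (svs$type[i] == "INV") {
      chars[(s + 1L):e] <- unname(COMPLEMENT[rev(chars[(s + 1L):e])])
    } else if (svs$type[i] == "INS") {
      ins <- strsplit(svs$insert[i], "", fixed = TRUE)[[1]]
      chars <- append(chars, ins, after = s)
    }
  }
  chars
}

#' Realize cohort sequences as a DNAStringSet
#'
#' Generates the reference chromosome from the cohort seed, writes each
#' variant's reference allele into it, then builds every haplotype (SNV
#' substitutions plus any carried SVs) and one pseudo-haploid sequence per
#' archaic donor reference (derived alleles wherever the archaic reference
#' carries them).
#'
#' @param cohort A `synthetic_cohort`.
#' @param include Which sequences to build: haplotypes, archaic references,
#'   and/or the reference chromosome.
#' @return A [Biostrings::DNAStringSet] (cached results are reused when the
#'   cohort was read from disk).
#' @export
cohort_sequences <- function(cohort,
                             include = c("haplotypes", "archaic",
                                         "reference")) {
  if (!is.null(cohort$sequences)) return(cohort$sequences)
  include <- match.arg(include, several.ok = TRUE)
  L <- cohort$chrom_length
  refchars <- with_seed(child_seed(cohort$seed, "reference"),
                        sample(c("A", "C", "G", "T"), L, replace = TRUE))
  pos1 <- cohort$variants$pos + 1L
  refchars[pos1] <- cohort$variants$ref

  out <- list()
  if ("haplotypes" %in% include) {
    for (h in cohort$samples$hap) {
      chars <- refchars
      carried <- cohort$geno[, h] == 1L
      chars[pos1[carried]] <- cohort$variants$alt[carried]
      if (nrow(cohort$svs)) {
        mine <- cohort$svs |>
          filter(purrr::map_lgl(carriers, ~ h %in% .x))
        chars <- apply_svs_to_chars(chars, mine)
      }
      out[[h]] <- paste(chars, collapse = "")
    }
  }
  if ("archaic" %in% include && ncol(cohort$arch) &&
      colnames(cohort$arch)[1] != "none") {
    for (d in colnames(cohort$arch)) {
      chars <- refchars
      carried <- cohort$arch[, d] == 1L
      chars[pos1[carried]] <- cohort$variants$alt[carried]
      out[[paste0(d, "_ref")]] <- paste(chars, collapse = "")
    }
  }
  if ("reference" %in% include) {
    out[["reference"]] <- paste(refchars, collapse = "")
  }
  Biostrings::DNAStringSet(unlist(out))
}

sv_info_string <- function(sv) {
  base <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", sv$type,
                  if (sv$type == "DEL") -sv$length else sv$length,
                  sv$end)
  if (sv$type == "INS" && !is.na(sv$insert)) {
    base <- paste0(base, ";INSSEQ=", sv$insert)
  }
  base
}

#' Write a cohort to disk (FASTA + VCF + BED)
#'
#' Emits `haplotypes.fa` (one record per haplotype plus archaic references
#' and the reference chromosome), `cohort.vcf` (VCF v4.2, phased `GT`,
#' archaic references as extra samples, SVs as symbolic alleles with
#' `SVTYPE`/`SVLEN`/`END`/`INSSEQ`), `tracts.bed` (haplotype, start, end,
#' donor) and `svs.bed` (haplotype, start, end, type label).  Writing a
#' cohort read back with [read_cohort()] reproduces the files byte for byte.
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create `%s`", out_dir))

  seqs <- cohort_sequences(cohort)
  Biostrings::writeXStringSet(seqs, file.path(out_dir, "haplotypes.fa"))

  samp <- unique(cohort$samples$sample)
  donors <- if (colnames(cohort$arch)[1] == "none") character(0) else
    colnames(cohort$arch)
  donor_cols <- paste0(donors, "_ref")

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", cohort$chrom, cohort$chrom_length),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end (1-based inclusive of last affected base)\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Inserted sequence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samp, donor_cols), collapse = "\t")
  )

  gt_for <- function(presence) {
    # presence: 0/1 vector indexed by haplotype column order
    vapply(samp, function(s) {
      idx <- which(cohort$samples$sample == s)
      paste(presence[idx], collapse = "|")
    }, character(1))
  }

  rows <- character(0)
  keys <- numeric(0)
  if (nrow(cohort$variants)) {
    v <- cohort$variants
    gts <- matrix("", nrow(v), length(samp))
    for (j in seq_along(samp)) {
      idx <- which(cohort$samples$sample == samp[j])
      gts[, j] <- paste0(cohort$geno[, idx[1]], "|", cohort$geno[, idx[2]])
    }
    dgt <- if (length(donors)) {
      vapply(donors, function(d) paste0(cohort$arch[, d], "|",
                                        cohort$arch[, d]), character(nrow(v)))
    } else {
      matrix("", nrow(v), 0)
    }
    snv_rows <- vapply(seq_len(nrow(v)), function(i) {
      paste(c(v$chrom[i], bed_to_vcf_pos(v$pos[i]), ".", v$ref[i], v$alt[i],
              ".", ".", ".", "GT", gts[i, ],
              if (length(donors)) dgt[i, ] else NULL), collapse = "\t")
    }, character(1))
    rows <- c(rows, snv_rows)
    keys <- c(keys, v$pos + 0.0)
  }
  if (nrow(cohort$svs)) {
    sv_rows <- vapply(seq_len(nrow(cohort$svs)), function(i) {
      sv <- cohort$svs[i, ]
      pres <- as.integer(cohort$samples$hap %in% sv$carriers[[1]])
      paste(c(sv$chrom, bed_to_vcf_pos(sv$start), sv$sv_id, "N",
              sprintf("<%s>", sv$type), ".", ".", sv_info_string(sv),
              "GT", gt_for(pres),
              if (length(donors)) rep("0|0", length(donors)) else NULL),
            collapse = "\t")
    }, character(1))
    rows <- c(rows, sv_rows)
    keys <- c(keys, cohort$svs$start + 0.5)  # SV after SNV at same position
  }
  writeLines(c(header, rows[order(keys)]), file.path(out_dir, "cohort.vcf"))

  readr::write_tsv(
    cohort$tracts |>
      mutate(start = as.integer(start), end = as.integer(end)) |>
      select(hap, start, end, donor),
    file.path(out_dir, "tracts.bed"), col_names = FALSE)

  sv_bed <- if (nrow(cohort$svs)) {
    cohort$svs |>
      tidyr::unnest_longer(carriers, values_to = "hap") |>
      mutate(label = if_else(type == "INS", sprintf("INS:%d", length), type),
             start = as.integer(start), end = as.integer(end)) |>
      select(hap, start, end, label)
  } else {
    tibble(hap = character(), start = integer(), end = integer(),
           label = character())
  }
  readr::write_tsv(sv_bed, file.path(out_dir, "svs.bed"), col_names = FALSE)

  invisible(out_dir)
}

parse_info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `haplotypes.fa`, `cohort.vcf`,
#'   `tracts.bed` and `svs.bed`.
#' @return A `synthetic_cohort` whose sequences come from the FASTA (variant
#'   `class`/`donor` annotations, which are not serialized, are `NA`).
#' @export
read_cohort <- function(dir) {
  fa <- Biostrings::readDNAStringSet(file.path(dir, "haplotypes.fa"))
  vcf <- vcfR::read.vcfR(file.path(dir, "cohort.vcf"), verbose = FALSE)

  meta <- vcf@meta
  contig <- grep("^##contig", meta, value = TRUE)[1]
  chrom <- sub('.*ID=([^,>]+).*', "\\1", contig)
  chrom_length <- as.integer(sub(".*length=([0-9]+).*", "\\1", contig))

  gt <- vcf@gt
  sample_cols <- setdiff(colnames(gt), "FORMAT")
  donor_cols <- grep("_ref$", sample_cols, value = TRUE)
  samp <- setdiff(sample_cols, donor_cols)
  donors <- sub("_ref$", "", donor_cols)

  samples <- tibble(
    sample = rep(samp, each = 2), pop = rep(sub("[0-9]+$", "", samp), each = 2),
    hap_index = rep(1:2, length(samp))
  ) |>
    mutate(hap = sprintf("%s_hap%d", sample, hap_index)) |>
    select(hap, sample, pop, hap_index)

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_row <- nrow(fix)
  is_sv <- if (n_row) startsWith(fix$ALT, "<") else logical(0)

  # SNVs
  vi <- which(!is_sv)
  variants <- tibble(
    chrom = if (length(vi)) fix$CHROM[vi] else character(),
    pos = if (length(vi)) vcf_to_bed_pos(as.integer(fix$POS[vi])) else integer(),
    ref = if (length(vi)) fix$REF[vi] else character(),
    alt = if (length(vi)) fix$ALT[vi] else character(),
    type = rep("SNV", length(vi)),
    class = rep(NA_character_, length(vi)),
    donor = rep(NA_character_, length(vi)),
    origin_hap = rep(NA_character_, length(vi))
  )

  geno <- matrix(0L, length(vi), nrow(samples),
                 dimnames = list(NULL, samples$hap))
  if (length(vi)) {
    for (j in seq_along(samp)) {
      parts <- strsplit(gt[vi, samp[j]], "|", fixed = TRUE)
      geno[, 2 * j - 1] <- as.integer(vapply(parts, `[`, character(1), 1))
      geno[, 2 * j] <- as.integer(vapply(parts, `[`, character(1), 2))
    }
  }
  arch <- matrix(0L, length(vi), max(1L, length(donors)),
                 dimnames = list(NULL, if (length(donors)) donors else "none"))
  if (length(vi) && length(donors)) {
    for (d in donors) {
      arch[, d] <- as.integer(substr(gt[vi, paste0(d, "_ref")], 1, 1))
    }
  }

  # SVs
  si <- which(is_sv)
  svs <- if (length(si)) {
    purrr::map_dfr(si, function(i) {
      info <- fix$INFO[i]
      type <- parse_info_field(info, "SVTYPE")
      len <- abs(as.integer(parse_info_field(info, "SVLEN")))
      start <- vcf_to_bed_pos(as.integer(fix$POS[i]))
      carriers <- unlist(lapply(seq_along(samp), function(j) {
        al <- strsplit(gt[i, samp[j]], "|", fixed = TRUE)[[1]]
        samples$hap[c(2 * j - 1, 2 * j)][al == "1"]
      }))
      tibble(sv_id = fix$ID[i], chrom = fix$CHROM[i], start = start,
             end = as.integer(parse_info_field(info, "END")), type = type,
             length = len, insert = parse_info_field(info, "INSSEQ"),
             carriers = list(carriers), source = "truth")
    })
  } else {
    empty_svs()
  }

  tracts_path <- file.path(dir, "tracts.bed")
  tracts <- if (file.size(tracts_path) > 0) {
    readr::read_tsv(tracts_path, col_names = c("hap", "start", "end", "donor"),
                    col_types = "ciic", progress = FALSE) |>
      mutate(chrom = chrom) |>
      select(chrom, hap, start, end, donor)
  } else {
    tibble(chrom = character(), hap = character(), start = integer(),
           end = integer(), donor = character())
  }

  structure(
    list(chrom = chrom, chrom_length = chrom_length, samples = samples,
         variants = variants, geno = geno, arch = arch, tracts = tracts,
         svs = svs, sv_truth = empty_sv_truth(), model = NULL, seed = NA,
         params = list(), sequences = fa),
    class = "synthetic_cohort"
  )
}
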