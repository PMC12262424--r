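# Thin readers/writers for external interchange formats.

#' Read an externally supplied segment set (BED)
#'
#' For consensus refinement against reference-free callers whose output is a
#' BED of putative introgressed segments (0-based half-open), optionally
#' keyed by haplotype in column 4 and donor label in column 5.
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `hap` and
#'   `origin`; `source = "external"`.
#' @export
read_segments_bed <- function(path) {
  first <- readLines(path, n = 1)
  n_col <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  cols <- c("chrom", "start", "end", "hap", "origin")[seq_len(min(n_col, 5))]
  out <- readr::read_tsv(path, col_names = cols,
                         col_types = paste(c("c", "i", "i", "c", "c")
                                           [seq_len(min(n_col, 5))],
                                           collapse = ""),
                         progress = FALSE)
  out$source <- "external"
  out
}

#' Read structural variants from a VCF
#'
#' Accepts symbolic alleles (`<DEL>`, `<INS>`, `<INV>`) with
#' `SVTYPE`/`SVLEN`/`END` INFO keys.  Carrier haplotypes are taken from
#' phased `GT` fields as `SAMPLE_hapK`.
#'
#' @param path VCF file path.
#' @return SV tibble suitable for [merge_svs()] / [project_svs()].
#' @export
read_sv_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  samp <- setdiff(colnames(gt), "FORMAT")
  keep <- which(startsWith(fix$ALT, "<"))
  if (!length(keep)) return(empty_svs())
  purrr::map_dfr(keep, function(i) {
    info <- fix$INFO[i]
    type <- parse_info_field(info, "SVTYPE")
    len <- abs(as.integer(parse_info_field(info, "SVLEN")))
    start <- vcf_to_bed_pos(as.integer(fix$POS[i]))
    end_raw <- parse_info_field(info, "END")
    end <- if (type == "INS") start + 1L else
      if (!is.na(end_raw)) as.integer(end_raw) else start + len
    carriers <- unlist(lapply(samp, function(s) {
      al <- strsplit(gt[i, s], "[|/]")[[1]]
      idx <- which(al == "1")
      if (!length(idx)) return(character(0))
      paste0(s, "_hap", idx)
    }))
    tibble(sv_id = if (fix$ID[i] %in% c(".", NA)) sprintf("sv%05d", i) else
             fix$ID[i],
           chrom = fix$CHROM[i], start = start, end = end, type = type,
           length = len,
           insert = parse_info_field(info, "INSSEQ"),
           carriers = list(carriers), source = basename(path))
  })
}

#' Write a window count track as bedGraph
#'
#' @param track A `window_count_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, path) {
  readr::write_tsv(
    tibble(chrom = track$assembly, start = track$start, end = track$end,
           count = track$count),
    path, col_names = FALSE)
  invisible(path)
}
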