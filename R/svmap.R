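# SV merging, projection onto introgressed segments, tallies, enrichment.

normalize_svs <- function(svs) {
  svs <- as_tibble(svs)
  need <- c("chrom", "start", "end", "type", "length")
  if (!all(need %in% names(svs))) {
    abort(paste("SV table needs columns:", paste(need, collapse = ", ")))
  }
  bad <- svs$length < 50 |
    (svs$type %in% c("DEL", "INV") & svs$end - svs$start != svs$length) |
    (svs$type == "INS" & svs$end - svs$start != 1L) |
    !svs$type %in% c("INS", "DEL", "INV")
  if (any(bad)) {
    warn(sprintf("dropping %d malformed SV records", sum(bad)))
    svs <- svs[!bad, ]
  }
  if (!"sv_id" %in% names(svs)) {
    svs$sv_id <- sprintf("sv%05d", seq_len(nrow(svs)))
  }
  if (!"carriers" %in% names(svs)) svs$carriers <- list(character(0))
  if (!"source" %in% names(svs)) svs$source <- "calls"
  arrange(svs, chrom, start, end)
}

# Reciprocal-overlap linkage for DEL/INV; breakpoint-window + size-ratio
# linkage for INS.
sv_pairs_linked <- function(svs, reciprocal, ins_window) {
  n <- nrow(svs)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (svs$chrom[j] != svs$chrom[i]) break
      if (svs$type[i] == "INS") {
        if (svs$start[j] - svs$start[i] > ins_window) break
        ratio <- min(svs$length[i], svs$length[j]) /
          max(svs$length[i], svs$length[j])
        if (abs(svs$start[j] - svs$start[i]) <= ins_window &&
            ratio >= reciprocal) {
          pairs[[length(pairs) + 1L]] <- c(i, j)
        }
      } else {
        if (svs$start[j] >= svs$end[i]) break
        ov <- min(svs$end[i], svs$end[j]) - max(svs$start[i], svs$start[j])
        if (ov >= reciprocal * svs$length[i] &&
            ov >= reciprocal * svs$length[j]) {
          pairs[[length(pairs) + 1L]] <- c(i, j)
        }
      }
    }
  }
  if (!length(pairs)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

#' Merge structural-variant call sets by reciprocal overlap
#'
#' SVs of the same type whose intervals overlap by at least `reciprocal`
#' (default 50%) of *both* lengths are linked; merge clusters are the
#' connected components of this relation (single linkage).  Insertions,
#' whose reference interval is a breakpoint, are instead linked when their
#' breakpoints lie within `ins_window` bp and their size ratio is at least
#' `reciprocal`.  Each cluster is represented by its longest member (ties:
#' leftmost start, then lexicographic source name).
#'
#' @param call_sets A single SV tibble or a list of them (columns `chrom`,
#'   `start`, `end`, `type`, `length`, optional `carriers`, `source`,
#'   `sv_id`).
#' @param reciprocal Reciprocal-overlap fraction (default 0.5).
#' @param ins_window Insertion breakpoint window in bp (default 500).
#' @return Tibble of merged SVs: representative coordinates plus `cluster`,
#'   `n_members`, `members` (list of member sv_ids) and the union `carriers`.
#' @export
merge_svs <- function(call_sets, reciprocal = 0.5, ins_window = 500) {
  if (is.data.frame(call_sets)) call_sets <- list(call_sets)
  svs <- purrr::imap_dfr(call_sets, function(x, nm) {
    x <- as_tibble(x)
    if (!"source" %in% names(x)) {
      x$source <- if (is.character(nm) && nzchar(nm)) nm else
        paste0("set", nm)
    }
    x
  })
  svs <- normalize_svs(svs)
  svs <- svs |> mutate(.row = row_number())

  merged <- purrr::map_dfr(split(svs, paste(svs$chrom, svs$type)),
                           function(grp) {
    grp <- arrange(grp, start, end)
    links <- sv_pairs_linked(grp, reciprocal, ins_window)
    if (nrow(links)) {
      g <- igraph::make_graph(as.vector(t(links)), n = nrow(grp),
                              directed = FALSE)
      grp$cluster_local <- igraph::components(g)$membership
    } else {
      grp$cluster_local <- seq_len(nrow(grp))
    }
    grp |>
      group_by(cluster_local) |>
      summarise(
        chrom = first(chrom), type = first(type),
        n_members = n(),
        members = list(sv_id),
        carriers = list(sort(unique(unlist(carriers)))),
        rep_idx = {
          o <- order(-length, start, source)
          o[1]
        },
        start = start[rep_idx], end = end[rep_idx],
        length = length[rep_idx], sv_id = sv_id[rep_idx],
        source = source[rep_idx],
        insert = if ("insert" %in% names(grp)) insert[rep_idx] else
          NA_character_,
        .groups = "drop"
      ) |>
      select(-cluster_local, -rep_idx)
  })
  merged |>
    arrange(chrom, start, end) |>
    mutate(cluster = row_number()) |>
    select(cluster, sv_id, chrom, start, end, type, length, insert,
           n_members, members, carriers, source)
}

#' Project merged SVs onto introgressed segments
#'
#' An SV is introgressed on haplotype `h` when `h` carries it and the SV's
#' breakpoint interval is fully contained in (or, with `mode = "overlap"`,
#' overlaps) a non-`REJECTED` segment called on `h`; it inherits that
#' segment's origin.
#'
#' @param merged_svs SV tibble with `carriers` list-column (haplotype ids).
#' @param segments Segment calls (`hap`, `start`, `end`, optional `origin`).
#' @param mode Containment rule (default `"contained"`, the conservative
#'   mirror of mapping SVs to introgressed segments).
#' @return An `introgression_map`: one row per (SV, carrier haplotype) with
#'   `introgressed`, the matched segment coordinates and inherited `origin`.
#' @export
project_svs <- function(merged_svs, segments,
                        mode = c("contained", "overlap")) {
  mode <- match.arg(mode)
  merged_svs <- as_tibble(merged_svs)
  segments <- as_tibble(segments)
  if (!"origin" %in% names(segments)) segments$origin <- NA_character_
  segments <- segments |>
    filter(is.na(origin) | origin != "REJECTED")

  rows <- purrr::map_dfr(seq_len(nrow(merged_svs)), function(i) {
    sv <- merged_svs[i, ]
    carr <- sv$carriers[[1]]
    if (!length(carr)) return(NULL)
    purrr::map_dfr(carr, function(h) {
      segs <- segments |> filter(hap == h)
      hit <- if (mode == "contained") {
        segs |> filter(start <= sv$start, end >= sv$end)
      } else {
        segs |> filter(start < sv$end, end > sv$start)
      }
      tibble(sv_id = sv$sv_id, chrom = sv$chrom, start = sv$start,
             end = sv$end, type = sv$type, length = sv$length, hap = h,
             introgressed = nrow(hit) > 0,
             seg_start = if (nrow(hit)) hit$start[1] else NA_integer_,
             seg_end = if (nrow(hit)) hit$end[1] else NA_integer_,
             origin = if (nrow(hit)) hit$origin[1] else NA_character_)
    })
  })
  if (is.null(rows) || !nrow(rows)) {
    rows <- tibble(sv_id = character(), chrom = character(),
                   start = integer(), end = integer(), type = character(),
                   length = integer(), hap = character(),
                   introgressed = logical(), seg_start = integer(),
                   seg_end = integer(), origin = character())
  }
  structure(rows, class = c("introgression_map", class(rows)))
}

#' Tally introgressed SV bases per genome and origin
#'
#' Inserted bases are the summed insert lengths of introgressed insertions;
#' deleted bases the summed lengths of introgressed deletions.  Haplotypes
#' are grouped into genomes by their sample name (`SAMPLE_hapK`).
#'
#' @param map An `introgression_map` from [project_svs()].
#' @return Tibble (`sample`, `origin`, `ins_bases`, `del_bases`,
#'   `inv_bases`, `n_svs`).
#' @export
tally_bases <- function(map) {
  map <- as_tibble(map)
  if (!nrow(map)) {
    return(tibble(sample = character(), origin = character(),
                  ins_bases = numeric(), del_bases = numeric(),
                  inv_bases = numeric(), n_svs = integer()))
  }
  map |>
    filter(introgressed) |>
    mutate(sample = sub("_hap[0-9]+$", "", hap)) |>
    distinct(sv_id, sample, .keep_all = TRUE) |>
    group_by(sample, origin) |>
    summarise(
      ins_bases = sum(length[type == "INS"]),
      del_bases = sum(length[type == "DEL"]),
      inv_bases = sum(length[type == "INV"]),
      n_svs = n(), .groups = "drop"
    )
}
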