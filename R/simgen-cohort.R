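# Synthetic cohort generation: haplotypes, variants, introgressed tracts.
#
# The generator is a direct copying/renewal model rather than a full
# coalescent: introgressed tracts enter each focal haplotype as an
# alternating renewal process whose tract lengths are Exponential with mean
# 1/(r*t) and whose stationary occupied fraction equals the pulse fraction m;
# background allele frequencies drift from a shared ancestral pool under a
# Balding-Nichols model; archaic donor lineages carry private "tag" alleles
# at a fixed density which focal haplotypes expose only inside tracts.
# Ground truth (tracts, SV placement) is recorded, never re-inferred.

# Alternating renewal process of archaic tracts on [0, L).
sim_tracts <- function(chrom_length, mean_len, m) {
  if (m <= 0) {
    return(tibble(start = integer(), end = integer()))
  }
  gap_mean <- mean_len * (1 - m) / m
  starts <- numeric(0)
  ends <- numeric(0)
  pos <- 0
  in_tract <- runif(1) < m
  # memoryless residual: if we start inside a tract it begins at 0
  while (pos < chrom_length) {
    if (in_tract) {
      len <- rexp(1, rate = 1 / mean_len)
      starts <- c(starts, pos)
      ends <- c(ends, min(pos + len, chrom_length))
      pos <- pos + len
    } else {
      pos <- pos + rexp(1, rate = 1 / gap_mean)
    }
    in_tract <- !in_tract
  }
  keep <- ends - starts >= 1
  tibble(start = as.integer(floor(starts[keep])),
         end = as.integer(ceiling(ends[keep])))
}

# Drop overlap between a new set of tracts and an existing set (trim the new
# tract's start forward past any previously claimed interval).
trim_overlaps <- function(tracts) {
  if (nrow(tracts) < 2) return(tracts)
  tracts <- arrange(tracts, start)
  keep_start <- tracts$start
  keep_end <- tracts$end
  out <- list()
  last_end <- -1L
  for (i in seq_len(nrow(tracts))) {
    s <- max(keep_start[i], last_end)
    e <- keep_end[i]
    if (e > s) {
      out[[length(out) + 1L]] <- tracts[i, ] |> mutate(start = s)
      last_end <- e
    }
  }
  bind_rows(out)
}

#' Simulate a multi-population cohort with known introgression truth
#'
#' Generates phased haplotypes for an outgroup, a sister group and a focal
#' group, places archaic introgressed tracts on focal haplotypes for every
#' admixture pulse in `model`, and builds a variant table with three variant
#' classes: shared `background` SNPs (drifted from an ancestral pool, and
#' postdating the human-archaic split, so archaic references carry the
#' ancestral allele), archaic `tag` alleles private to a donor lineage
#' (density `tag_density`, carried by focal haplotypes only inside tracts of
#' that donor), and `private` singleton noise on focal haplotypes.
#'
#' @param model A [demographic_model()].
#' @param chrom_length Chromosome length in bp (>= 1e5).
#' @param n_per_pop Named integer vector of haplotype counts per population
#'   (each >= 2 and even, two haplotypes per diploid sample).
#' @param seed Master seed (required; identical seeds give byte-identical
#'   cohorts).
#' @param focal,outgroup,sister Population names (defaults PNG/AFR/EAS).
#' @param tag_density Donor-private tag-allele density per bp (default 1e-3,
#'   i.e. 1 per kbp, the order implied by ~600 kya archaic divergence at
#'   mu = 1.25e-8).
#' @param private_density Density of focal-private singleton noise per bp.
#' @param background_density Density of shared background SNPs per bp.
#' @param match_donor Probability that the sampled donor archaic reference
#'   genome carries a given tag allele of its own lineage.
#' @param match_other Probability that the other archaic reference carries it
#'   (shared archaic ancestry).
#' @param chrom Chromosome name used in all outputs.
#'
#' @return An object of class `synthetic_cohort`: a list with tibbles
#'   `samples` (haplotype -> sample -> population), `variants`, `tracts`
#'   (truth, 0-based half-open), `svs`/`sv_truth` (empty until
#'   [implant_svs()]), a 0/1 genotype matrix `geno` (variants x haplotypes),
#'   an archaic reference presence matrix `arch` (variants x donors), and the
#'   generating `model`, `seed` and parameters.
#' @examples
#' co <- simulate_cohort(png_demography(), 2e5,
#'                       c(AFR = 4, EAS = 4, PNG = 4), seed = 1)
#' co$tracts
#' @export
simulate_cohort <- function(model, chrom_length, n_per_pop, seed,
                            focal = "PNG", outgroup = "AFR", sister = "EAS",
                            tag_density = 1e-3, private_density = 1e-4,
                            background_density = 1e-3,
                            match_donor = 0.8, match_other = 0.15,
                            chrom = "chr1") {
  if (!inherits(model, "demographic_model")) {
    abort("`model` must be a demographic_model")
  }
  stopifnot_scalar_number(chrom_length, "chrom_length", min = 1e5)
  chrom_length <- as.integer(chrom_length)
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: cohorts must be reproducible")
  }
  pops <- model$populations$name
  if (is.null(names(n_per_pop)) || !all(names(n_per_pop) %in% pops)) {
    abort("`n_per_pop` must be named with population names from the model")
  }
  if (any(n_per_pop < 2) || any(n_per_pop %% 2 != 0)) {
    abort("each population needs an even haplotype count >= 2")
  }
  if (!focal %in% names(n_per_pop) || !outgroup %in% names(n_per_pop)) {
    abort("`focal` and `outgroup` populations must be sampled")
  }

  samples <- purrr::map_dfr(names(n_per_pop), function(p) {
    ns <- n_per_pop[[p]] / 2
    tibble(
      sample = sprintf("%s%02d", p, rep(seq_len(ns), each = 2)),
      pop = p,
      hap_index = rep(1:2, ns)
    )
  }) |>
    mutate(hap = sprintf("%s_hap%d", sample, hap_index)) |>
    select(hap, sample, pop, hap_index)

  haps <- samples$hap
  focal_haps <- samples$hap[samples$pop == focal]
  donors <- unique(model$pulses$donor)

  # --- truth tracts -------------------------------------------------------
  tracts <- with_seed(child_seed(seed, "tracts"), {
    purrr::map_dfr(focal_haps, function(h) {
      per_pulse <- purrr::map_dfr(seq_len(nrow(model$pulses)), function(i) {
        pl <- model$pulses[i, ]
        sim_tracts(chrom_length,
                   expected_tract_length(model$recomb_rate, pl$time),
                   pl$fraction) |>
          mutate(donor = pl$donor)
      })
      trim_overlaps(per_pulse) |> mutate(hap = h)
    })
  })
  if (nrow(tracts) == 0) {
    tracts <- tibble(hap = character(), start = integer(), end = integer(),
                     donor = character())
  }
  tracts <- tracts |>
    mutate(chrom = chrom) |>
    select(chrom, hap, start, end, donor) |>
    arrange(hap, start)

  # --- variant positions (all classes drawn jointly, guaranteeing unique,
  # sorted positions) ------------------------------------------------------
  counts <- with_seed(child_seed(seed, "counts"), {
    list(
      bg = rpois(1, background_density * chrom_length),
      tag = setNames(rpois(length(donors), tag_density * chrom_length),
                     donors),
      priv = setNames(rpois(length(focal_haps),
                            private_density * chrom_length), focal_haps)
    )
  })
  n_total <- counts$bg + sum(counts$tag) + sum(counts$priv)
  pos_all <- with_seed(child_seed(seed, "positions"),
                       sort(sample.int(chrom_length, n_total) - 1L))
  # deterministic interleaving of classes across the sorted positions
  class_idx <- with_seed(child_seed(seed, "classes"), {
    lab <- c(rep("background", counts$bg),
             rep(names(counts$tag), counts$tag),
             rep(names(counts$priv), counts$priv))
    sample(lab, length(lab))
  })

  is_bg <- class_idx == "background"
  variants <- tibble(
    chrom = chrom,
    pos = pos_all,
    class = if_else(is_bg, "background",
                    if_else(class_idx %in% donors, "tag", "private")),
    donor = if_else(class_idx %in% donors, class_idx, NA_character_),
    origin_hap = if_else(class_idx %in% focal_haps, class_idx, NA_character_)
  )

  # --- genotypes ----------------------------------------------------------
  geno <- matrix(0L, nrow = n_total, ncol = length(haps),
                 dimnames = list(NULL, haps))
  arch <- matrix(0L, nrow = n_total, ncol = max(1L, length(donors)),
                 dimnames = list(NULL, if (length(donors)) donors else "none"))

  # background: Balding-Nichols drift per population, binomial haplotypes
  if (counts$bg > 0) {
    bg_rows <- which(is_bg)
    geno_bg <- with_seed(child_seed(seed, "background"), {
      p_anc <- 0.01 * 99 ^ runif(length(bg_rows))
      g <- matrix(0L, length(bg_rows), length(haps))
      for (p in pops) {
        f <- model$populations$drift[model$populations$name == p]
        p_pop <- if (f > 0) {
          rbeta(length(bg_rows), p_anc * (1 - f) / f,
                (1 - p_anc) * (1 - f) / f)
        } else {
          p_anc
        }
        cols <- which(samples$pop == p)
        for (j in cols) g[, j] <- rbinom(length(bg_rows), 1L, p_pop)
      }
      g
    })
    geno[bg_rows, ] <- geno_bg
  }

  # tags: archaic reference carriage + focal carriage inside donor tracts
  if (length(donors)) {
    with_seed(child_seed(seed, "tags"), {
      for (d in donors) {
        rows <- which(variants$class == "tag" & variants$donor == d)
        if (!length(rows)) next
        arch[rows, d] <- rbinom(length(rows), 1L, match_donor)
        for (o in setdiff(donors, d)) {
          arch[rows, o] <- rbinom(length(rows), 1L, match_other)
        }
        for (h in focal_haps) {
          tr <- tracts |> filter(hap == h, donor == d)
          if (!nrow(tr)) next
          pv <- variants$pos[rows]
          idx <- findInterval(pv, tr$start)
          inside <- idx >= 1 & pv < tr$end[pmax(idx, 1L)]
          geno[rows[inside], h] <- 1L
        }
      }
    })
  }

  # private singleton noise on focal haplotypes
  priv_rows <- which(variants$class == "private")
  if (length(priv_rows)) {
    for (h in focal_haps) {
      rows <- priv_rows[variants$origin_hap[priv_rows] == h]
      geno[rows, h] <- 1L
    }
  }

  # ref/alt alleles
  alleles <- with_seed(child_seed(seed, "alleles"), {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_total, replace = TRUE)
    shift <- sample.int(3, n_total, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
    list(ref = ref, alt = alt)
  })
  variants <- variants |>
    mutate(ref = alleles$ref, alt = alleles$alt, type = "SNV") |>
    select(chrom, pos, ref, alt, type, class, donor, origin_hap)

  structure(
    list(
      chrom = chrom, chrom_length = chrom_length,
      samples = samples, variants = variants,
      geno = geno, arch = arch, tracts = tracts,
      svs = empty_svs(), sv_truth = empty_sv_truth(),
      model = model, seed = as.integer(seed),
      params = list(focal = focal, outgroup = outgroup, sister = sister,
                    tag_density = tag_density,
                    private_density = private_density,
                    background_density = background_density,
                    match_donor = match_donor, match_other = match_other)
    ),
    class = "synthetic_cohort"
  )
}

empty_svs <- function() {
  tibble(sv_id = character(), chrom = character(), start = integer(),
         end = integer(), type = character(), length = integer(),
         insert = character(), carriers = list(), source = character())
}

empty_sv_truth <- function() {
  tibble(sv_id = character(), hap = character(), introgressed = logical(),
         donor = character())
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", x$chrom, sprintf("(%d bp)", x$chrom_length), "\n")
  cat(sprintf("  %d haplotypes, %d variants, %d truth tracts, %d SVs\n",
              nrow(x$samples), nrow(x$variants), nrow(x$tracts),
              nrow(x$svs)))
  invisible(x)
}

#' Derived-allele positions carried by one haplotype
#'
#' @param cohort A `synthetic_cohort`.
#' @param hap Haplotype id.
#' @return Sorted integer vector of 0-based positions at which `hap` carries
#'   the derived allele.
#' @export
hap_variant_positions <- function(cohort, hap) {
  if (!hap %in% colnames(cohort$geno)) abort(sprintf("unknown hap `%s`", hap))
  cohort$variants$pos[cohort$geno[, hap] == 1L]
}

#' Positions at which a population panel carries any derived allele
#'
#' @param cohort A `synthetic_cohort`.
#' @param pop Population name (default: the outgroup used at simulation).
#' @return Sorted integer vector of 0-based positions.
#' @export
panel_positions <- function(cohort, pop = cohort$params$outgroup) {
  cols <- cohort$samples$hap[cohort$samples$pop == pop]
  if (!length(cols)) abort(sprintf("no haplotypes for population `%s`", pop))
  cohort$variants$pos[rowSums(cohort$geno[, cols, drop = FALSE]) > 0]
}

#' Per-site derived-allele frequency table for selection statistics
#'
#' @param cohort A `synthetic_cohort`.
#' @param focal,sister,outgroup Population names.
#' @param archaic Donor label whose reference genotype supplies the archaic
#'   derived-allele frequency (first pulse donor by default).
#' @return Tibble with one row per variant: `chrom`, `pos`, derived
#'   frequencies and haplotype sample sizes for the three populations
#'   (`p_focal`/`n_focal`, ...), the archaic reference frequency `p_arch`,
#'   and the variant `class`.  Ancestral alleles are known by construction,
#'   so frequencies are already polarized.
#' @export
cohort_frequencies <- function(cohort, focal = cohort$params$focal,
                               sister = cohort$params$sister,
                               outgroup = cohort$params$outgroup,
                               archaic = NULL) {
  freq_of <- function(pop) {
    cols <- cohort$samples$hap[cohort$samples$pop == pop]
    if (!length(cols)) abort(sprintf("no haplotypes for `%s`", pop))
    list(p = rowMeans(cohort$geno[, cols, drop = FALSE]), n = length(cols))
  }
  ff <- freq_of(focal); fs <- freq_of(sister); fo <- freq_of(outgroup)
  if (is.null(archaic)) archaic <- colnames(cohort$arch)[1]
  tibble(
    chrom = cohort$variants$chrom, pos = cohort$variants$pos,
    p_focal = ff$p, n_focal = ff$n,
    p_sister = fs$p, n_sister = fs$n,
    p_out = fo$p, n_out = fo$n,
    p_arch = as.numeric(cohort$arch[, archaic]),
    class = cohort$variants$class
  )
}

#' Implant structural variants on cohort haplotypes
#'
#' Adds typed SVs (insertions, deletions, inversions, all >= 50 bp) at the
#' given density, one carrier haplotype per SV, rejecting and resampling any
#' SV that would run past the chromosome end or overlap an existing SV on the
#' same haplotype.  Truth records whether each SV's breakpoint interval lies
#' inside an introgressed tract of its carrier.
#'
#' @param cohort A `synthetic_cohort`.
#' @param sv_density Expected SVs per bp (Poisson; >= 0).
#' @param length_distribution Function `n -> n` SV lengths (bp, >= 50).
#' @param seed Seed for SV placement.
#' @param type_probs Named sampling weights over `INS`, `DEL`, `INV`.
#' @param placement `"uniform"` over the chromosome, or `"in_tract"` to place
#'   every SV wholly inside an introgressed truth tract of a focal haplotype.
#' @param n_sv Exact SV count, overriding the Poisson draw (used for
#'   controlled experiments).
#' @param carrier_haps Candidate carrier haplotypes (default: all).
#' @return The cohort with `svs` and `sv_truth` filled.
#' @export
implant_svs <- function(cohort, sv_density, length_distribution = NULL,
                        seed, type_probs = c(INS = 0.45, DEL = 0.45,
                                             INV = 0.10),
                        placement = c("uniform", "in_tract"), n_sv = NULL,
                        carrier_haps = NULL) {
  placement <- match.arg(placement)
  stopifnot_scalar_number(sv_density, "sv_density", min = 0)
  if (is.null(length_distribution)) {
    length_distribution <- function(n) {
      pmax(50L, as.integer(round(rlnorm(n, log(300), 0.7))))
    }
  }
  L <- cohort$chrom_length
  haps <- carrier_haps %||% cohort$samples$hap
  if (placement == "in_tract") {
    haps <- intersect(haps, unique(cohort$tracts$hap))
    if (!length(haps)) abort("no haplotypes carry tracts")
  }

  out <- with_seed(child_seed(seed, "svs"), {
    n <- n_sv %||% rpois(1, sv_density * L)
    if (n == 0) {
      return(list(svs = empty_svs(), truth = empty_sv_truth()))
    }
    types <- sample(names(type_probs), n, replace = TRUE, prob = type_probs)
    lens <- length_distribution(n)
    if (any(lens < 50)) abort("SV lengths must be >= 50 bp")
    placed <- vector("list", n)
    occupied <- setNames(vector("list", length(haps)), haps)
    for (i in seq_len(n)) {
      for (try in 1:200) {
        h <- sample(haps, 1)
        if (placement == "in_tract") {
          tr <- cohort$tracts |> filter(hap == h)
          tr <- tr |> filter(end - start > lens[i] + 1L)
          if (!nrow(tr)) next
          row <- sample.int(nrow(tr), 1, prob = tr$end - tr$start)
          span_max <- tr$end[row] - lens[i] - 1L
          start <- tr$start[row] +
            sample.int(span_max - tr$start[row] + 1L, 1) - 1L
        } else {
          start <- sample.int(L, 1) - 1L
        }
        end <- if (types[i] == "INS") start + 1L else start + lens[i]
        if (end > L) next  # overlaps chromosome end: reject, resample
        occ <- occupied[[h]]
        if (!is.null(occ) && nrow(occ) &&
            any(start < occ$end & end > occ$start)) next
        occupied[[h]] <- bind_rows(occ, tibble(start = start, end = end))
        placed[[i]] <- tibble(type = types[i], length = lens[i],
                              start = as.integer(start), end = as.integer(end),
                              hap = h)
        break
      }
      if (is.null(placed[[i]])) abort("could not place SV without overlap")
    }
    svs <- bind_rows(placed) |>
      arrange(start) |>
      mutate(
        sv_id = sprintf("sv%05d", row_number()),
        chrom = cohort$chrom,
        insert = if_else(type == "INS",
                         purrr::map_chr(length, random_dna), NA_character_),
        carriers = purrr::map(hap, identity),
        source = "truth"
      )
    truth <- svs |>
      select(sv_id, hap, start, end) |>
      mutate(purrr::map_dfr(seq_len(nrow(svs)), function(i) {
        tr <- cohort$tracts |>
          filter(hap == svs$hap[i], start <= svs$start[i],
                 end >= svs$end[i])
        tibble(introgressed = nrow(tr) > 0,
               donor = if (nrow(tr)) tr$donor[1] else NA_character_)
      })) |>
      select(sv_id, hap, introgressed, donor)
    list(svs = svs |> select(sv_id, chrom, start, end, type, length,
                             insert, carriers, source),
         truth = truth)
  })
  cohort$svs <- out$svs
  cohort$sv_truth <- out$truth
  cohort
}
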