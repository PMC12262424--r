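test_that("expected tract length follows 1/(r t) and rejects bad input", {
  expect_equal(expected_tract_length(1e-8, 2000), 50000)
  expect_equal(expected_tract_length(1e-8, 1000), 100000)
  expect_lt(expected_tract_length(1e-8, 1e12), 1)  # monotone toward zero
  expect_error(expected_tract_length(0, 100))
  expect_error(expected_tract_length(1e-8, -5))
})

test_that("demographic model enforces its invariants", {
  expect_error(demographic_model(data.frame(name = "A", size = -1)),
               "sizes")
  expect_error(
    demographic_model(data.frame(name = "A", size = 100),
                      pulses = data.frame(donor = "X", recipient = "A",
                                          time = 100, fraction = 1.2)),
    "fraction")
  expect_error(
    demographic_model(
      data.frame(name = c("A", "B"), size = c(100, 100)),
      split_times = data.frame(pop_a = "A", pop_b = "B", time = 50),
      pulses = data.frame(donor = "X", recipient = "B", time = 100,
                          fraction = 0.05)),
    "predates")
})

test_that("introgressed fraction matches the pulse fraction m", {
  # one pulse, m = 0.04; mean over replicate haplotypes within 3 SE of m
  m <- demographic_model(
    populations = data.frame(name = c("AFR", "PNG"), size = c(2e4, 1e4),
                             drift = c(0.05, 0.15)),
    pulses = data.frame(donor = "DNS", recipient = "PNG", time = 2000,
                        fraction = 0.04)
  )
  fracs <- vapply(1:25, function(i) {
    co <- simulate_cohort(m, 1e6, c(AFR = 2, PNG = 4), seed = 1000 + i,
                          background_density = 1e-5, tag_density = 1e-5,
                          private_density = 0)
    sum(co$tracts$end - co$tracts$start) / (4 * 1e6)
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.04), 3 * se + 1e-9)
})

test_that("no admixture pulses mean no truth tracts", {
  m0 <- demographic_model(
    populations = data.frame(name = c("AFR", "PNG"), size = c(2e4, 1e4)))
  co <- simulate_cohort(m0, 2e5, c(AFR = 2, PNG = 2), seed = 3)
  expect_equal(nrow(co$tracts), 0)
})

test_that("tract lengths are exponential with mean 1/(r t)", {
  mean_len <- 25000
  lens <- withr::with_seed(99, {
    unlist(lapply(1:12, function(i) {
      tr <- introscan:::sim_tracts(1e7, mean_len, 0.25)
      # drop tracts censored by the chromosome ends
      tr <- tr[tr$start > 0 & tr$end < 1e7, ]
      tr$end - tr$start
    }))
  })
  expect_gt(length(lens), 500)
  ks <- suppressWarnings(ks.test(lens, "pexp", rate = 1 / mean_len))
  expect_gt(ks$p.value, 0.01)
})

test_that("truth tracts are non-overlapping and half-open within haplotype", {
  co <- simulate_cohort(png_demography(ndl_fraction = 0.1,
                                       dns_fraction = 0.15),
                        2e6, c(AFR = 4, EAS = 2, PNG = 4), seed = 21)
  by_hap <- split(co$tracts, co$tracts$hap)
  for (tr in by_hap) {
    tr <- tr[order(tr$start), ]
    expect_true(all(tr$end > tr$start))
    if (nrow(tr) > 1) {
      expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))
    }
  }
})

test_that("cohorts are byte-identical under the same seed", {
  m <- png_demography()
  a <- simulate_cohort(m, 2e5, c(AFR = 4, EAS = 2, PNG = 2), seed = 7)
  b <- simulate_cohort(m, 2e5, c(AFR = 4, EAS = 2, PNG = 2), seed = 7)
  expect_identical(introscan:::content_hash(a), introscan:::content_hash(b))
  c2 <- simulate_cohort(m, 2e5, c(AFR = 4, EAS = 2, PNG = 2), seed = 8)
  expect_false(identical(introscan:::content_hash(a),
                         introscan:::content_hash(c2)))
})

test_that("tag alleles appear at the configured in-tract density", {
  co <- simulate_cohort(png_demography(dns_fraction = 0.3),
                        2e6, c(AFR = 4, EAS = 2, PNG = 2), seed = 31,
                        tag_density = 1e-3)
  h <- "PNG01_hap1"
  tr <- co$tracts[co$tracts$hap == h & co$tracts$donor == "DNS", ]
  tract_bp <- sum(tr$end - tr$start)
  skip_if(tract_bp < 2e5, "too little tract sequence drawn at this seed")
  pos <- hap_variant_positions(co, h)
  tag_pos <- co$variants$pos[co$variants$class == "tag" &
                               co$geno[, h] == 1]
  idx <- findInterval(tag_pos, tr$start)
  inside <- sum(idx >= 1 & tag_pos < tr$end[pmax(idx, 1)])
  dens <- inside / tract_bp
  expect_gt(dens, 0.7e-3)
  expect_lt(dens, 1.3e-3)
})

test_that("SV implantation respects density, typing and truth bookkeeping", {
  m <- png_demography()
  co <- simulate_cohort(m, 3e5, c(AFR = 2, EAS = 2, PNG = 2), seed = 5)
  expect_equal(nrow(implant_svs(co, 0, seed = 1)$svs), 0)

  co_del <- implant_svs(co, 0, n_sv = 100, seed = 2,
                        length_distribution = function(n) rep(100L, n),
                        type_probs = c(DEL = 1),
                        carrier_haps = "PNG01_hap1")
  expect_equal(nrow(co_del$svs), 100)
  expect_true(all(co_del$svs$type == "DEL"))
  expect_equal(sum(co_del$svs$length), 10000)
  expect_true(all(co_del$svs$end <= co$chrom_length))
  # determinism
  co_del2 <- implant_svs(co, 0, n_sv = 100, seed = 2,
                         length_distribution = function(n) rep(100L, n),
                         type_probs = c(DEL = 1),
                         carrier_haps = "PNG01_hap1")
  expect_identical(co_del$svs, co_del2$svs)
})

test_that("satellite arrays have exact geometry and seeded reproducibility", {
  spec <- satellite_spec(171, 12, 10, substitution_rate = 0)
  arr <- synthesize_satellite_array(spec, seed = 1)
  expect_equal(nchar(arr$sequence), 171 * 12 * 10)
  expect_equal(nrow(arr$hor_units), 10)
  expect_equal(arr$hor_units$start, seq(0, 9) * 2052)
  expect_equal(arr$hor_units$end, seq(1, 10) * 2052)
  units <- substring(arr$sequence, arr$hor_units$start + 1,
                     arr$hor_units$end)
  expect_equal(length(unique(units)), 1)  # zero substitution: identical copies

  arr2 <- synthesize_satellite_array(spec, seed = 1)
  expect_identical(arr$sequence, arr2$sequence)

  # flanks enter the total length
  spec_f <- satellite_spec(171, 2, 3, flank_length = 100)
  expect_equal(nchar(synthesize_satellite_array(spec_f, 2)$sequence),
               100 + 171 * 2 * 3)
})

test_that("mutated HOR copies diverge by about twice the substitution rate", {
  spec <- satellite_spec(171, 12, 10, substitution_rate = 0.01)
  arr <- synthesize_satellite_array(spec, seed = 42)
  units <- substring(arr$sequence, arr$hor_units$start + 1,
                     arr$hor_units$end)
  chars <- lapply(units, function(u) strsplit(u, "")[[1]])
  ids <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    ids <- c(ids, mean(chars[[i]] == chars[[j]]))
  }
  expect_gt(mean(ids), 0.975)   # expected identity ~ 1 - 2 * 0.01
  expect_lt(mean(ids), 0.985)
})

test_that("cohort writing follows VCF/BED conventions and round-trips", {
  m <- png_demography()
  co <- simulate_cohort(m, 1.5e5, c(AFR = 2, EAS = 2, PNG = 2), seed = 13)
  co <- implant_svs(co, 0, n_sv = 5, seed = 4)
  d1 <- withr::local_tempdir()
  write_cohort(co, d1)

  vcf_lines <- readLines(file.path(d1, "cohort.vcf"))
  body <- vcf_lines[!startsWith(vcf_lines, "#")]
  # 0-based internal position 10 would be POS 11; check the convention on
  # the first SNV generally
  first_snv <- strsplit(body[1], "\t")[[1]]
  expect_equal(as.integer(first_snv[2]), co$variants$pos[1] + 1L)

  co_r <- read_cohort(d1)
  expect_equal(co_r$variants$pos, co$variants$pos)
  expect_equal(unname(co_r$geno), unname(co$geno))
  expect_equal(co_r$tracts$start, co$tracts$start)
  expect_equal(nrow(co_r$svs), nrow(co$svs))

  d2 <- withr::local_tempdir()
  write_cohort(co_r, d2)
  for (f in c("haplotypes.fa", "cohort.vcf", "tracts.bed", "svs.bed")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("an empty cohort writes a header-only VCF", {
  m0 <- demographic_model(
    populations = data.frame(name = c("AFR", "PNG"), size = c(2e4, 1e4)))
  co <- simulate_cohort(m0, 1e5, c(AFR = 2, PNG = 2), seed = 3,
                        background_density = 0, tag_density = 0,
                        private_density = 0)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  lines <- readLines(file.path(d, "cohort.vcf"))
  expect_true(all(startsWith(lines, "#")))
  expect_match(lines[1], "VCFv4.2")
})

test_that("BED and VCF coordinate conversions are mutual inverses", {
  pos0 <- c(0L, 10L, 999L)
  expect_identical(introscan:::vcf_to_bed_pos(
    introscan:::bed_to_vcf_pos(pos0)), pos0)
  expect_identical(introscan:::bed_to_vcf_pos(10L), 11L)
})

test_that("a seed is required for every stochastic entry point", {
  m <- png_demography()
  expect_error(simulate_cohort(m, 1e5, c(AFR = 2, EAS = 2, PNG = 2)),
               "seed")
})
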