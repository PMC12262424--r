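---
title: "Models and methods behind introscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind introscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

introscan maps archaic (Neanderthal, NDL; Denisovan, DNS) introgression in
phased modern genomes and performs the downstream inference that such maps
support.  This vignette records the models, their assumptions, the defaults
and why they were chosen, the numerical machinery, and what the synthetic
data can and cannot establish.

## The synthetic cohort generator

Real cohorts of this kind are access-controlled, so every stage of the
package is exercised against simulated cohorts with recorded ground truth
(`simulate_cohort()`).  The generator is a direct copying model rather than
a coalescent:

* **Tracts.** For each admixture pulse (donor, time `t`, fraction `m`),
  each focal haplotype receives tracts from an alternating renewal process:
  tract lengths are Exponential with mean `1/(r t)` (the expected surviving
  ancestry-block length `t` generations after admixture at recombination
  rate `r`), gap lengths Exponential with mean `(1/(r t)) (1-m)/m`, which
  makes the stationary occupied fraction exactly `m`.  Tract truth is
  recorded, never re-inferred.  Overlaps between donors are resolved by
  trimming the later tract; at realistic fractions this removes O(m^2) of
  sequence.
* **Variants.** Three classes share one pool of unique positions.
  *Background* SNPs (density 1e-3/bp) drift from a shared ancestral
  frequency (a 1/p spectrum on [0.01, 0.99]) under a Balding–Nichols model
  with per-population fixation indices; they are modelled as postdating the
  human–archaic split, so archaic reference genomes carry the ancestral
  allele — the standard expectation for the bulk of human polymorphism, and
  the property that makes `f_D` a consistent estimator of `m` under the
  generator.  *Tag* alleles (density 1e-3/bp, i.e. 1 per kbp, the order
  implied by a ~600 kya archaic divergence at mu = 1.25e-8) are private to
  one donor lineage: focal haplotypes carry them only inside tracts of that
  donor; the donor's sampled reference genome carries each tag with
  probability 0.8 and the other archaic's with probability 0.15 (shared
  archaic ancestry), which produces the familiar 0.7-vs-0.1 match-rate
  separation on real tracts.  *Private* noise (1e-4/bp) is singleton on
  focal haplotypes.
* **Generation time** defaults to 29 years, so that 200 generations
  corresponds to roughly 5,800 years.
* **Determinism.** One master seed expands into per-stage child seeds;
  identical seeds give byte-identical cohorts, files included.

What the generator does *not* emulate: genealogical correlation of
background variation (no linkage structure within non-introgressed
sequence), recurrent mutation, genotyping error, assembly gaps, or
reference bias.  Green tests therefore demonstrate algorithmic correctness
and statistical calibration *under the model*, not field performance on
real assemblies; the detection thresholds that matter on real data (window
size, posterior cutoff, match-rate cutoffs) are all exposed as arguments.

Published demographic parameters for the Papuan-style cohort this mirrors
are not printed in full anywhere we could verify, so `png_demography()`
ships explicit placeholder values (pulses of 2% NDL at 2,000 generations
and 4% DNS at 1,200; sizes 20k/10k/10k) chosen to give realistic mean tract
lengths (50–83 kbp); all are arguments.

## Segment detection HMM

The observable is the count of *private variants* per window: derived
alleles on the focal haplotype at sites where the outgroup panel carries no
derived allele (`window_private_variants()`).  A two-state HMM (modern,
archaic) emits `Poisson(lambda_state x callable)` counts; `fit_hmm()` runs
Baum–Welch with per-window scaling, so the log-likelihood is monotone
non-decreasing and posteriors remain finite for millions of windows
(no log-space arithmetic is needed because each step renormalizes).
Degenerate inputs — every window the same count — return the initial
parameters with a warning flag rather than a spurious fit.  States are
relabelled after fitting so the archaic state always has the larger rate.

Defaults: 1 kbp windows and a 0.8 posterior cutoff (the convention of
windowed archaic-detection HMMs; smaller windows make single tag alleles
informative, larger windows blur tract edges); `decode_segments()` merges
maximal runs of windows at or above the cutoff.  Accuracy on synthetic
cohorts is measured base-wise (`segment_f1()`); at the defaults, 50,000
windows of cohort give F1 above 0.95, with errors concentrated in sub-5 kbp
tracts and one-window boundary slack — both expected from the window
resolution.

## Origin classification

`match_rate()` profiles each segment: informative sites are its private
derived alleles; for each archaic genome, uncovered sites are excluded and
the rate is matched/informative.  `classify_origin()` applies, in order:
all rates below `low = 0.1` (or an undefined profile) rejects the segment —
the conservative removal of low-affinity segments; exactly one rate at or
above `high = 0.3` assigns that archaic; otherwise the segment is
ambiguous.  The 10% rejection rule is the published convention; the 0.3
assignment cutoff follows common practice for matching against
archaic-specific allele sets and is configurable.  How ambiguity was
thresholded in the original analyses is unstated, so the AMB rule here is
explicit and total (every profile maps to exactly one label).

`consensus_segments()` intersects two segment sets (e.g. HMM calls and an
external reference-free call set read from BED); the match profile and
origin are recomputed on each intersected span, which is how disagreements
between the two sources are resolved.

## SV merging, projection and enrichment

SVs of the same type merge when their intervals overlap reciprocally by at
least 50% of both lengths; clusters are connected components under single
linkage, represented by the longest member (ties: leftmost start, then
lexicographic source).  Reciprocal overlap is ill-defined for insertions
(reference interval = one breakpoint), so insertions link when breakpoints
fall within 500 bp and the size ratio is at least 0.5 — the common SV-merge
convention; both constants are arguments.

Projection is conservative: an SV counts as introgressed on a haplotype
only when that haplotype carries it *and* the SV interval is fully
contained in a non-rejected segment on the same haplotype (an
`overlap` mode exists).  Containment is monotone — shrinking segments can
only remove SVs — which the tests exploit.

The genic test builds the 2x2 table introgressed x within-1-kbp-of-gene and
reports the cross-product odds ratio (Haldane–Anscombe corrected on zero
margins, flagged), a one-sided Fisher exact p, and a permutation p.  The
permutation null reshuffles SV positions uniformly within their chromosome,
holding lengths and introgression flags fixed: the published analyses state
a permutation count but not the null's construction, and positional
shuffling is the natural exchangeable null for "proximity to genes".  The
permutation p uses `(1 + k)/(1 + n)`, bounded below by `1/(n+1)`.
We count SVs, not affected base pairs, in the table; the source analyses
are ambiguous on this point.

## Archaic-specific k-mer screen

Canonical 31-mers (lexicographic min of k-mer and reverse complement; odd k
so a k-mer is never its own reverse complement) seen at least twice across
the archaic inputs, minus every canonical k-mer present in the outgroup
sequences.  k = 31 and the occurrence floor of 2 are conventional
specificity/error-tolerance balances (the floor suppresses sequencing-error
k-mers when archaic inputs are read sets); neither is printed in the source
analyses, and both are arguments.  Counting assigns a k-mer to a window
only if it lies entirely inside it, which makes counts strand-invariant up
to window mirroring.

`calibrate_threshold()` returns the smallest *observed count value* `t`
such that the flagged-window fraction `#(count >= t)/#windows` does not
exceed the genome-wide introgression fraction.  Restricting candidates to
observed counts makes the threshold a data quantile; taking the
"at most the fraction" side is the conservative choice where the
published description leaves the inequality's direction open.  Enrichment
of counts in introgressed windows uses a one-sided Mann–Whitney U test:
exact by full enumeration of group assignments whenever
`choose(n1+n2, n1) <= 2e5` (which covers the documented exact regime of
groups up to 8, ties included), otherwise a midrank normal approximation
with tie correction.

`window_identity()` slides query windows (20 kbp / 1 kbp step by default)
against a target with an optimal local alignment under match +1,
mismatch −1, linear gap −1, and keeps one best hit per window; identity
counts substitutions *and* indel bases:
`matches / (matches + mismatches + indel bases) x 100`.

## Selection and introgression statistics

Hudson's FST estimator is used throughout, with multi-site blocks combined
as ratio of averages (mean numerator over mean denominator), the standard
low-bias choice.  `segment_scan()` uses non-overlapping blocks of exactly
100 SNVs, dropping the remainder; PBS per block is
`(T(F_fs) + T(F_fo) - T(F_so))/2`, `T(x) = -ln(1-x)`, undefined (flagged)
when any FST reaches 1.  `f_D` follows the dynamic-donor form: the per-site
donor is whichever of focal/archaic has the larger derived frequency; sites
are polarized by construction in simulated data and by the designated
ancestral column otherwise.  Its windowing defaults to whatever table the
caller passes — the same 100-SNV blocks in the scans.

Empirical p-values always use `(1 + k)/(1 + n)` against a null simulated by
`simulate_null()`: neutral replicate regions with the observed SNV count
and sample sizes (ancestral 1/p spectrum, Balding–Nichols drift, binomial
sampling), evaluated through the *same* scan code path as observed data.
Under exchangeability this makes neutral p-values uniform on the
`(1+k)/(1+n)` lattice, which the calibration tests verify at alpha = 0.05
over 200 neutral segments.

## TMRCA decoding and selection-coefficient inference

For a haplotype pair, windows of `L` bp with `k` pairwise differences are
decoded over discrete TMRCA bins: emissions `Poisson(2 mu L T_j)`,
transitions "stay with probability 1 − rho, else resample from the prior"
with `rho = 0.1` per boundary by default — a deliberate reduction of full
sequentially-Markovian transition rates to a single interpretable
switching parameter (configurable), adequate for posterior summaries like
`sweep_score()`, the posterior mass below a recent-time threshold.

Allele-trajectory likelihoods use a Wright–Fisher HMM on a 201-point
frequency grid: per-generation Gaussian transitions with mean increment
`s p (1-p) / (1 + s p)` (genic selection) and variance `p (1-p) / (2N)`,
integrated over grid-cell boundaries (not point-evaluated, so the kernel
stays a proper distribution even when its standard deviation is comparable
to the grid spacing), absorbing at 0 and 1; binomial emissions at the
observation times; a uniform grid prior at the oldest observation.
Multi-generation propagators are built by repeated squaring and cached by
`(s, N, dt)`, which is what makes grid maximization and replicate studies
cheap.  This is a stated simplification of ancestral-recombination-graph
importance-sampling approaches to the same question: it is validated by
parameter recovery on its own forward simulator
(`simulate_trajectory()`) — bias below 25% at s = 0.02 with time-stratified
sampling — rather than by matching any particular published estimate.

`fit_selection()` maximizes over a log-spaced grid of coefficients
(|s| from 1e-4 to 0.5, both signs, plus 0; optional continuous refinement
for the single-epoch model).  The two-epoch model adds a free change time
over a candidate grid and always includes the single-epoch optimum among
its candidates, so the piecewise likelihood nests the single-epoch one by
construction.  The reported statistic is `2 (ll_alt − ll_null)` with
df = 1 (single epoch) or 3 (two epochs + change time), compared to the
chi-squared upper tail: published likelihood-ratio values in this
literature are the quantities whose chi-squared tails at the printed df
reproduce the printed p-values, and that is the convention adopted —
`chi2_sf()` applied to such printed ratios returns the printed p-values
directly.

## Satellite divergence and mutation rate

`pairwise_divergence()` computes windowed raw divergence over an alignment
(gap columns excluded from numerator and denominator; windows under 50%
aligned flagged missing), with optional Jukes–Cantor correction and a
saturation flag at d >= 0.75.  `hor_mutation_rate()` inverts the neutral
divergence expectation `d = mu (2t + 4 N_anc)` — two lineages separated `t`
generations ago whose ancestral lineages coalesce after an expected
`2 N_anc` further generations each — over a grid of divergence times and
ancestral sizes (e.g. a 400–700 kya human–archaic split), reporting all
per-window, per-grid-point estimates plus their mean and standard
deviation.  The estimator is exactly homogeneous in `d`.  QV conversions
are `error = 10^(−QV/10)` and its inverse.

## Numerical and testing choices

* Forward–backward everywhere uses per-step normalization constants; no
  underflow up to at least 1e6 windows.
* Degenerate inputs are flagged, not guessed at: zero informative sites
  reject a segment; FST = 1 makes PBS undefined; an error rate of 0 gives
  infinite QV with a warning; monomorphic loci refuse LD.
* Tests pit every statistic against an independent oracle: exhaustive path
  enumeration for both HMMs (<= 12 windows), O(n^2) connected components
  for SV merging (200 records), per-position rescans for k-mer windows,
  hypergeometric tails for Fisher, full permutation enumeration for the
  Mann–Whitney U, and a series/recursion implementation for chi-squared
  tails (1e-10 relative agreement).
* Problem sizes in the test suite — 50,000 windows for tract recovery and
  Baum–Welch recovery, 50 replicates for the selection MLE, 100 windows
  for the mutation-rate recovery, 200 replicates for calibration — were
  chosen as the smallest scales at which the estimators' sampling noise is
  comfortably inside the documented tolerances.
* All simulation, permutation and fitting entry points take explicit
  seeds and are byte-reproducible; the suite asserts hash equality.

## Known limitations

The generator's independence assumptions (above) mean calibration results
transfer to real data only insofar as the real observables match the
modelled ones.  The consensus rule resolves origin disagreements by
recomputation rather than precedence, which need not match any particular
published pipeline.  The insertion merge convention and the permutation
null are explicit choices where the field's descriptions are
underspecified.  Haplotype divergence *dating* (confidence ranges on split
times of specific haplotypes) and ancestral-recombination-graph-based
selection inference are out of scope; the Wright–Fisher reduction here
needs time-stratified observations (ancient samples or simulated ones) to
identify `s` from a single locus.
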