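---
title: "Migration–selection balance and diversity at linked neutral sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Migration–selection balance and diversity at linked neutral sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladsim)
library(dplyr)
```

## The question

Local adaptation maintains divergently selected polymorphisms against the
homogenizing effect of migration. What does that equilibrium do to neutral
variation *within* populations at sites linked to the selected locus?
Depending on the balance of migration and selection, the answer is opposite
things: at very low migration, immigrant haplotypes are purged quickly, the
neutral neighbourhood of the selected locus coalesces within the local
patch, and within-population nucleotide diversity (pi_w) shows a **trough**
reaching far along the chromosome; at higher (but subcritical) migration,
locally adapted haplotypes recurrently enter the "wrong" patch and linger
for a few generations before selection removes them, transiently importing
deeply diverged haplotypes and piling up a sharp **peak** of pi_w and F_ST
around the selected site. `ladsim` is a forward-time individual-based
simulator plus analysis toolkit for exploring exactly this parameter space.

## The model

Diploid Wright–Fisher metapopulations of `d` patches with `N` individuals
each, discrete non-overlapping generations, and soft selection (constant
patch sizes). A single additive trait is under Gaussian stabilizing
selection towards the local optimum `theta_p`:

    W(z) = exp(-(z - theta_p)^2 / (2 * V_S))

with phenotype `z` the sum of both allelic effect values over all selected
loci (no dominance, no epistasis). `V_S` sets the strength of selection
(default 5; `1e9` is the neutral control). Relative fitness within a patch
is `W` scaled by the patch mean — a no-op for fitness-proportional parent
sampling, so the engine skips the division and `fitness_gaussian()` exposes
it only for reporting.

Each generation, for every offspring slot in patch `p`:

1. a source patch is drawn from the backward migration matrix
   (`migration_matrix()`): two patches exchange migrants at rate `m`; for
   `d >= 3` patches form a linear stepping stone where an interior patch
   receives `m/2` from each neighbour and a terminal patch `m/2` from its
   single neighbour — so interior patches receive twice the immigrant
   influx of terminal ones;
2. two parents are drawn (with replacement; selfing allowed at the usual
   `1/N` rate) from the source patch with probability proportional to
   fitness. By default (`selection_on = "natal"`) fitness is evaluated
   against the *source* patch optimum — viability selection in the natal
   patch, before dispersal. The alternative
   `selection_on = "destination"` weighs candidate parents by fitness
   against the optimum of the offspring's patch, which is equivalent to
   juveniles dispersing first and surviving viability selection where they
   land; it enriches migrant gametes for genotypes pre-adapted to the
   destination. The two orders agree to first order in `m`; the natal
   default keeps selection and dispersal cleanly separable;
3. each parent contributes one recombined gamete: a random starting
   haplotype with independent per-interval switches (probability
   `r = min(d_cM/100, 0.5)` per interval, no interference, no map
   function). The linear conversion is deliberate: it renders the 50 cM
   complement gap exactly unlinked (`r = 0.5`), which a map function with
   interference-free crossovers (e.g. Haldane) never reaches;
4. mutation: neutral diallelic loci flip `0 <-> 1` at `mu_neutral`
   (default `1e-5`); selected loci either receive a Normal(0, 1) increment
   to the allelic value (continuum of alleles) or flip to the opposite
   allele (house of cards, diallelic models) at `mu_adaptive`.

Backward (offspring-samples-source) migration is used instead of literal
forward dispersal so patch censuses stay exactly `N`; for `m << 1` the two
formulations agree to first order.

### Genetic architectures

* **Single-locus continuum** — one multiallelic selected locus,
  real-valued allelic effects, mutational kernel Normal(0, 1).
* **Multilocus nonredundant** — `l` diallelic loci with effects
  `±1/(2l)`: every locus must be homozygous optimal to reach the optimum
  (±1), so per-locus selection weakens as `l` grows.
* **Multilocus redundant** — diallelic effects ±0.25 regardless of `l`:
  any two optimal homozygous loci reach the optimum, so many allele
  combinations are phenotypically equivalent.

### The genetic map

`build_flanking_map()` flanks each selected locus symmetrically with 37
neutral loci per side at distances log10-evenly spaced from `1e-3` to `10`
cM (74 flanks, 75 loci per complement). The exact flank positions of the
original study design are not published; even log spacing is the natural
reading of "on a log10 scale" and is documented here as an approximation.
Complements sit 50 cM apart, hence unlinked. `add_background_loci()`
extends a single-complement map so each side carries exactly 100 neutral
loci evenly spaced in the 9–10 cM band (the locus already at 10 cM is kept,
99 are added per side), used to calibrate genome-wide background diversity
under the neutral control.

### Initialization

Neutral loci start with every allele copy Bernoulli(0.5) — maximal standing
variation. Diallelic selected loci start Bernoulli(0.5) over the two effect
states. For continuum selected loci the package defaults to the same
standing-variation philosophy: every initial allele copy is drawn from the
mutational kernel Normal(0, 1) (`continuum_init = "standing"`), so each
patch can assemble a near-optimal genotype from day one. The alternative
`"monomorphic"` start (all effects 0) is available but not the default,
for a reason worth spelling out: from a monomorphic start at
`mu_adaptive = 1e-5` the local allele pool is extremely granular. A patch
whose best available allele overshoots the optimum (say effect 1.2 against
optimum +1) settles into a heterozygote-advantage balanced polymorphism
with a small-effect allele, and escaping it requires a rare mutation of
just the right size. These long-lived balanced states inflate pi_w near the
selected locus in some replicates while the recurrent "refinement" sweeps
they cause erode it below `4*N*mu` in others — both artefacts of allele
granularity rather than of migration–selection balance, and both strong
enough at desk scales to erase the low-migration trough. With the standing
start, near-locus diversity at low migration settles at the single-deme
neutral expectation, which is the regime the analysis targets.

## Diversity metrics

All statistics are census statistics over all `2N` haplotypes per patch
(no subsampling):

* `nuc_div()` — Nei's pi with the unbiased `n/(n-1)` correction,
  `pi = n/(n-1) * (1 - sum x_i^2)`; states are compared by exact value, so
  multiallelic continuum loci are handled.
* `dxy()` — between-population average pairwise difference,
  `1 - sum_s fA(s) fB(s)`, no sample-size correction (a deliberate
  asymmetry with pi_w, matching standard usage).
* `fst_wc()` — the Weir–Cockerham variance-components estimator for
  haploid-sampled allele counts (`theta = a/(a+b)`; the within-individual
  component of the diploid formula is identically zero for haplotype
  sampling). Multiallelic loci and multi-locus aggregation
  (`fst_wc_global()`) use ratios of summed components. Slightly negative
  estimates are retained, never truncated.
* `ld_r2()` — squared Pearson correlation between a neutral 0/1 allele and
  the selected-locus allele class across pooled haplotypes; continuum
  alleles are dichotomized by effect sign (>= 0 vs < 0).

`locus_metrics()` emits everything as a tidy tibble (`generation`, `patch`,
`locus_id`, `distance_cM`, `metric`, `value`), computed at every sampling
point (`N*d/2` generations by default) over the `25*N*d`-generation
horizon. After that horizon populations have typically approached a steady
state, though at very low migration true equilibrium is approached much
more slowly — "quasi-equilibrium" is the honest term.

## Signature analyses

* `dd_slope()` — OLS of a per-locus metric on log10 map distance, pooling
  both flanks (averaging mirrored loci first is available via
  `average_flanks`). Positive slope = trough, negative = peak. The t-test
  p-value uses alpha = 0.05 wherever the package needs a significance
  call; the underlying study said only "significant".
* `near_far_contrast()` — mean metric at the exact 1e-3 cM loci vs the
  exact 10 cM loci.
* `background_level()` — mean pi_w over 9–10 cM loci of neutral-control
  runs (`V_S = 1e9`) on the extended map.
* `detect_peak()` — significantly negative dd-slope AND at least 25% of
  neutral loci above 1.1x background.
* `peak_width()` — the diversity *excess over background* of all loci
  above background is regressed on linear cM distance; twice the
  x-intercept is the peak width. Two documented readings were possible
  here: regressing raw diversity and taking its zero crossing, or
  regressing the excess (equivalently, intersecting the fitted line with
  the background level). Only the latter yields a width of 1.0 cM for the
  canonical triangular test profile `bg + max(0, 1 - d/0.5)` at any
  background level, and an intercept on the linear cM scale is directly a
  distance, so that is what the package implements.
* `adaptive_differentiation()` — fraction of adaptive loci with
  `|p1 - p2| >= 0.95`.
* `critical_migration()` — largest grid migration rate at which local
  adaptation is maintained by majority vote across replicates.
  "Maintained" defaults to phenotypic divergence: the patch-mean phenotype
  difference between extreme patches exceeding half the optimum gap at the
  final sampling point; an allele-frequency criterion
  (`|dp| >= 0.5` at the selected locus) is available in
  `maintained_local_adaptation()` as a sensitivity alternative, since no
  published criterion exists to follow.
* `summarize_adaptive_alleles()` — continuum allele classes per patch by
  rounding effects to 0.05 (the resolution is an argument and is recorded
  in the output).

`summarize_replicates()` reports mean, median and 5/25/75/95% quantiles
side by side. The mean is the headline statistic, but at very low
migration it is dominated by rare replicates that recently received a
migrant (a single immigrant haplotype can carry deep divergence), while
the median tracks the typical replicate; both are therefore always
emitted.

## Experiment orchestration

`expand_sim_grid()` builds the designed parameter grids — migration from
`1e-5` to `10^-0.5` at four steps per decade plus `m = 0`
(`migration_grid()`, 20 values), selection strengths
{2, 5, 10, 25, 100, 1e9}, patch sizes {500, 1000, 2000, 10000}, locus
numbers {1, 2, 4, 10, 20, 50, 100} (nonredundant) / {4, 10, 20, 50, 100}
(redundant), adaptive mutation `1e-5` or `1e-2/N` (scaled) or `1e-4`
(redundant) — and rejects combinations outside the design. Per-cell,
per-replicate seeds derive deterministically from `base_seed`. A single
`scale` factor shrinks `N` and the `25*N*d` horizon together, preserving
the drift time scale. `run_experiment()` drives a YAML config
(`schema: 1`; see `inst/extdata/smoke.yaml`) to per-cell tidy TSVs with a
signature table and an MD5 manifest; existing cell outputs are kept
(resume), never overwritten.

The replicate count of the original study is unpublished; the package
default for scaled desk runs is 10 (20 for the regime-map checks), chosen
as the smallest count at which across-replicate t-tests on dd-slopes have
reasonable power.

## Desk scaling: what the tests run, and what that shows

The test-suite problem sizes are the package's own desk scale, chosen so
the whole suite stays interactive:

* trough-regime contrast (`m = 10^-3.5`): N = 1000 at the full
  50,000-generation horizon, 12 replicates, with the per-locus profile
  averaged over the sampling points in the final fifth of the horizon
  (every 2,500 generations from 40,000 on). The full patch size is needed
  because the far-locus (10 cM) diversity is rescued by rare migrants at
  `N*m ~ 0.3`, an effect that vanishes at `N*m ~ 0.08`; the plateau
  averaging is needed because the far estimate rests on two loci whose
  diversity at `4*N*mu = 0.04` is dominated by rare polymorphic excursions
  — sampling points 2,500 generations apart are nearly independent
  genealogically (decorrelation time ~ 2N) and multiply the effective
  sample several-fold;
* peak widths: N = 1000 (the published width band is a full-size quantity:
  smaller patches maintain linkage over longer recombination distances and
  broaden the peak several-fold), 5 replicates per migration rate with the
  same plateau averaging, against a shared neutral-control background.
  Peaks are detected robustly in this regime, but the simulated
  near-locus excess is confined to ~0.01-0.05 cM while the chromosome-wide
  baseline floats slightly above the neutral control, so width estimates
  from the excess regression are unstable and much larger than the peak
  itself — treat absolute width values from desk runs with caution;
* regime map: N = 500 with the proportional 25,000-generation horizon, 20
  replicates per migration rate — the smallest scale at which the
  trough-regime slope is positive at the stated grid point `m = 10^-3.5`
  (at N = 250, `N*m` drops below ~0.1 and the trough flattens into the
  `m = 0` regime);
* critical migration and redundant differentiation: N = 250 with the
  proportional 12,500-generation horizon, 10 replicates (selected-locus
  quantities are invariant to the neutral flank count, so these use
  minimal maps);
* unit and property tests: N = 20–500, hundreds of generations.

Scaling N at fixed `m` moves `N*m`, so desk-scaled runs sit deeper in the
low-migration regime than their full-size counterparts at the same grid
point; the qualitative regime map survives this, the exact transition
points do not. The synthetic runs also idealize real data in known ways:
diallelic neutral sites with symmetric mutation, free of sequencing error
and missing data; a rigid log-spaced map; exactly equal patch sizes.
Passing tests therefore demonstrate the internal consistency of the
machinery and the reproducibility of the simulated regimes, not that any
empirical genome scan will show these signatures.

## Numerical choices

* Crossovers are sampled by cumulative-hazard inversion
  (`h_i = -log(1 - r_i)`, exponential clock, binary search), exactly
  equivalent to independent per-interval Bernoulli draws but costing
  ~`1 + E[#crossovers]` RNG draws per gamete instead of 74.
* Mutation counts are drawn once per generation as
  Binomial(copies, mu) and placed on distinct uniformly chosen copies.
* Fitness-proportional sampling uses cumulative sums with binary search;
  if a patch's total fitness underflows to zero (unreachable for bounded
  phenotypes) parent choice falls back to uniform with a warning.
* F_ST is reported as missing for pooled-monomorphic loci; `r2` as missing
  when either locus is monomorphic; `pi` as missing for samples of one.
* The engine RNG is a 64-bit Mersenne Twister seeded via splitmix64 from
  the run seed; R-side initialization uses R's RNG under the same seed.
  Byte-identical reruns from a seed are part of the tested contract.

## Known limitations

* No dominance, epistasis, unequal patch sizes, extinction/recolonization,
  or continuous space; hermaphroditic Wright–Fisher mating only.
* The continuum-of-alleles model at desk scales is sensitive to the
  initial allele pool (see *Initialization*); conclusions about the
  monomorphic start should be drawn only at full population sizes.
* Peak widths are only defined when a peak is detected and the excess
  regression crosses background; degenerate profiles return missing
  values rather than extrapolations.
* The analytical two-population heterozygosity prediction referenced in
  the literature is deliberately not evaluated here; the signature
  functions accept any per-locus table, so an external prediction can be
  compared by the user.
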