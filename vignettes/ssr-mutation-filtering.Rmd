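---
title: "Property-grouped filtering and odds modeling of SSR mutations"
author: "ssrmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Property-grouped filtering and odds modeling of SSR mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
    library(GenomicRanges)
    library(ssrmut)
})
```

## The problem

Simple sequence repeats (SSRs, microsatellites) mutate by polymerase
slippage, gaining or losing motif copies at rates orders of magnitude above
the point-mutation rate — especially when the mismatch-repair (MMR) system
is compromised, as in yeast strains lacking the MutS&beta; component Msh3p.
Measuring those rates genome-wide from mutation-accumulation (MA)
sequencing is hard for one specific reason: the same slippage process that
mutates an SSR in vivo also produces PCR stutter in the sequencing library,
so *genotyping error is correlated with true mutability*. A single
genome-wide confidence cutoff therefore filters the most mutable loci
hardest and biases any downstream comparison of locus classes.

`ssrmut` implements an analysis chain that confronts this directly:

1. **Catalog** (`findSSRs`, `mergeCatalogs`, `annotateGenic`): exhaustive
   string search for maximal perfect repeats of primitive 1–4 bp motifs,
   merged with external repeat-finder loci and annotated against gene
   bodies.
2. **Call handling** (`computeDeltaGL`, `applyMasks`): every locus in every
   strain — mutant or not — carries a confidence value &Delta;GL, the gap
   between the log10-scaled likelihoods of the two best alleles (for
   unmutated loci the runner-up is the synthetic one-motif-copy-shorter
   allele). Calls near telomeres/centromeres/LTRs (&le;100 bp), in
   rDNA/mitochondrial regions, or below 10&times; depth are removed.
3. **Property-grouped thresholding** (`buildThresholds`,
   `applyThresholds`, `stabilityScan`, `selectMutations`): the core
   method, described below.
4. **Odds model** (`fitOddsModel`, `lrTest`, `profileCI`): per-bp mutation
   odds with a log-length offset.
5. **Spectrum** (`classifyMutation`, `deletionBiasTest`,
   `genicEnrichment`): deletion/insertion balance and genic placement.
6. **Simulator** (`simulationConfig`, `simulateCallSet`): synthetic
   catalogs, cohorts and noisy call sets with known truth.

## Property-grouped &Delta;GL thresholding

Calls are grouped by (i) motif length, (ii) A/T-proportion bin (<25%,
25–75%, >75%) and (iii) a copy-number window of &plusmn;2.5 motif copies
around each focal copy number. Within each group the &Delta;GL values of
*all* calls — pooled across strains, mutant and non-mutant alike — form an
empirical distribution, and the cutoff is its lower quantile (inverse
ECDF; a call passes when &Delta;GL &ge; cutoff, so ties never remove more
than the nominal fraction). Groups spanning 25 or fewer distinct loci give
no cutoff; their loci are dropped as unthresholdable rather than
thresholded against an unstable distribution. Because the cutoff is a pure
function of locus properties and &Delta;GL values, permuting mutation
labels changes nothing ("mutation-agnostic"), and cutoffs at a higher
quantile dominate those at a lower one, so passing call sets nest exactly.

Why a quantile per group rather than one global cutoff? If stutter-prone
(mutable) loci systematically receive lower &Delta;GL, a global cutoff
removes a larger share of their calls, deflating their apparent rate. A
per-group quantile removes the *same fraction* of calls in every group, so
class comparisons are unbiased even though individual mutation calls are
sacrificed.

The **stability scan** (`stabilityScan`) sweeps the quantile from 0 to
0.95 (step 0.05) and reports the mutant fraction among passing calls.
False positives concentrate at low &Delta;GL, so the curve starts
inflated, falls as the quantile rises, and flattens once false positives
are exhausted; at very high quantiles the few surviving mutations make the
estimate noisy again. The reported plateau is the longest run of
consecutive grid points agreeing pairwise within 10% relative — a
diagnostic, not an enforcement: the default working quantile stays at
0.35, the low end of the stable range, because a laxer cutoff preserves
more called loci and hence more power downstream.

## The per-bp odds model

For locus of length $n$ bp, the odds of mutating over the experiment are

$$O_\text{mut} = n \cdot O_\text{base} \cdot \prod_i \theta_i$$

— a binomial GLM on the logit scale with offset $\log n$, intercept
$\log O_\text{base}$ and one coefficient per term: `long` (locus &ge;8 bp),
`motif_length` (per +1 bp), `at_proportion` (per unit), and `genotype`
(MMR-deficient vs wild type). The offset encodes the assumption that
every base pair is an independent opportunity for a slippage-initiating
mismatch; the `long` indicator captures the biology that mismatches within
a few base pairs of the polymerase can be repaired by the polymerase
itself, making MMR (and its loss) matter mostly in longer loci.

Fitting is iteratively reweighted least squares with step-halving on the
likelihood, on a design aggregated to unique covariate rows (binomial
weights), which makes cohort-scale fits and profiling fast. Convergence is
declared at a relative log-likelihood change below 1e-10 (&le;100
iterations); a coefficient beyond &plusmn;15 log-odds units marks complete
separation — the estimate is reported as 0/&infin; on the odds scale with
`converged = FALSE` for that term only. Nested models are compared by
likelihood-ratio chi-square tests (`lrTest`); following the published
analysis, SSR-property terms are tested against the long/short null, and
the long/short term against the offset-only null.

Confidence intervals come from likelihood profiling (`profileCI`): the
bound is where the profiled deviance rises by the &chi;&sup2;(1) quantile,
located by geometric bracket expansion from the MLE and 60-step bisection
(tolerance 1e-4 log-odds). Under separation — e.g. zero mutations among
wild-type strains — the anchor is found by walking the profiled
likelihood outward until flat, the divergent side returns &infin;, and the
other side still yields a finite, meaningful bound. This reproduces the
characteristic "(finite, Inf)" genotype interval of MMR-deficient MA
cohorts.

## What the simulator emulates (and what it does not)

`simulationConfig()` defaults are the bundled preset, chosen once to
represent an MA study of this design at desk scale:

* **Cohort**: 34 MMR-deficient + 5 wild-type haploid strains, 200
  generations (metadata only — mutations are drawn per cohort, not per
  transfer).
* **Catalog**: 15,000 loci on one synthetic chromosome. Motif lengths
  1–4 at probabilities 0.86/0.07/0.05/0.02 with geometric copy-number
  tails — a short-homopolymer-dominated census, as in real yeast where
  homopolymers vastly outnumber di-/tri-/tetranucleotide repeats and
  loci of &ge;8 bp are a small minority. Motif bases are A/T-biased
  (0.62), matching an AT-rich genome. With 34 mutant strains this yields
  ~5&times;10^5 mutant locus–strain outcomes per cohort.
* **Genic model**: trinucleotide loci genic with probability 0.80,
  others 0.72, multiplied by 0.35 at &ge;10 copies (non-trinucleotides
  only) — encoding selection against frameshift-prone long repeats in
  coding sequence.
* **Mutation process**: the odds model used generatively with
  &theta;_long = 33, &theta;_motif = 0.9, &theta;_AT = 0.5 and a genotype
  effect of 1.7&times;10^7 (wild-type mutations effectively absent — the
  separated regime). The baseline odds `o_base = 7e-6` was calibrated
  once so the expected true yield is ~2.8 mutations/strain, the value
  implied by an observed ~1.06 filtered mutations/strain at 63%
  callability and a 40% false-negative filter. The spectrum is
  deletion-biased (75%) and single-copy-dominated (88/8/4% for
  |&Delta;copies| = 1/2/3), with 10% in-SSR substitutions.
* **Calls**: per-strain callability Beta-distributed around 0.63;
  negative-binomial depth (median ~62&times;); &Delta;GL log-normal with
  location increasing in motif length and A/T proportion and decreasing
  in copy number (the empirical confidence trends), sd 0.6. False
  positives occur at non-mutated called loci with probability
  2&times; the locus's own mutation probability (stutter–mutability
  correlation) and draw &Delta;GL from the same family shifted down 1.5
  — low enough that the 35% group quantile removes ~95% of them while
  costing ~35–40% of true mutations (the false-negative regime of the
  real analysis).

Not emulated: read-level errors (no FASTQ/BAM), alignment artifacts,
locus-specific stutter idiosyncrasies beyond the location shift,
transfer-by-transfer MA dynamics, diploidy/heterozygosity. Passing tests
on this simulator therefore demonstrate correctness of the *estimation
machinery* under the assumed noise structure, not robustness to every
failure mode of real short-read data.

## Numerical choices and edge cases

* Lower empirical quantile with ties passing (&ge; cutoff); quantile 0 is
  a -&infin; cutoff (keep everything).
* ">25 distinct loci" is strict: 26 loci or more.
* "Within 100 bp" of a masked feature is inclusive of exactly 100.
* SNM clustering ("within 50 bp") is inclusive single-linkage; any
  cluster carrying &ge;2 distinct strains is removed wholesale.
* Rate intervals are exact Poisson (Garwood); two-rate comparison is the
  exact conditional binomial given total count, two-sided by minimum
  likelihood; Fisher tests are two-sided by the same convention.
* Overlapping catalog loci with different motifs are split at the
  boundary maximizing the summed alignment score (+2 per base inside a
  complete in-phase motif copy, 0 for partial-copy bases — the repeat
  finder's default match weight); ties break toward the longer left
  locus. Split pieces keep their original phase; motifs are reported as
  rotations when a piece starts mid-phase.
* Fewer than two allele likelihoods make &Delta;GL undefined (`NA`); such
  calls are excluded from thresholding with a warning.

## Design choices that were genuinely open

* **Pooling across strains** when building group &Delta;GL distributions:
  we pool, since confidence structure is a property of the locus and
  library chemistry, not the strain; per-strain pooling would also starve
  small groups.
* **Which likelihoods define &Delta;GL** when more than two alleles are
  emitted: all emitted alternatives compete and the top two define the
  gap.
* **Property-term testing**: A/T proportion and motif length are each
  added singly to the long/short null; their individual likelihood-ratio
  p-values are reported.
* **A/T bins** place the boundaries inside the middle bin
  (0.25 &le; x &le; 0.75).
* **Window membership**: a call contributes to every copy-number window
  that contains it but is thresholded once, by its own focal copy
  number's cutoff.
* Problem sizes in tests (catalogs of 1.5k–30k loci, cohorts of 6–34
  strains, 50–100 fit replicates) were chosen as the smallest sizes at
  which the checked statistical properties are stable.

## Known limitations

* The thresholding strategy trades individual-call sensitivity for
  unbiased rate estimation; at stringent quantiles the false-negative
  rate is high by construction.
* Haploid calls only: heterozygous and homozygous calls have inherently
  different &Delta;GL levels, so the grouping logic does not transfer to
  diploids directly.
* Loci with motifs >4 bp enter only through an external catalog; the
  string search does not discover them.
* The odds model treats locus–strain outcomes as independent Bernoulli
  trials; per-strain random effects are out of scope.

## A worked run

```{r example, eval = FALSE}
cfg <- runConfig(seed = 1,
                 simulate = simulationConfig(n_loci = 2500, n_msh3d = 10,
                                             n_wt = 2, o_base = 5e-5,
                                             seed = 1))
rep <- runPipeline(cfg)
rep$counts
rep$scan
rep$odds$estimates
```

The report carries per-stage counts (every removed call attributed to one
reason), the stability-scan curve with its plateau, odds-model estimates
with profile intervals (the genotype term flagged when separated), and the
spectrum and genic-enrichment tables. `writeReport()` serializes it to
JSON.
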