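---
title: "Modelling negative selection on tumor karyotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling negative selection on tumor karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyosel)
```

## The scientific problem

Colorectal cancers are typically grossly aneuploid, yet multi-region and
longitudinal sampling shows that an individual tumor's pattern of copy-number
alterations (CNAs) — its "core karyotype" — is remarkably stable across
space, time, metastasis and treatment, while single-cell assays show that new
CNAs arise constantly. One resolution is negative (purifying) selection: CNAs
keep occurring, but lineages that stray from a locally optimal karyotype are
less fit and never expand to detectable clones. This package implements a
gland-level model of that hypothesis, likelihood-free inference to compare it
against neutral evolution, and the cohort statistics used to characterise CNA
heterogeneity in bin-level copy-number data.

## The birth–death model

Individuals are tumor *glands* (crypt-like units of a few thousand closely
related cells), the natural unit of selection in colorectal cancer. A gland's
karyotype is a vector of integer copy numbers over `C` genomic bins. Its
birth and death rates derive from a single-peak fitness landscape with
optimum `G0`:

$$ b_i - d_i \;=\; \frac{b_0 - d_0}{1 + \alpha\, d(G_i, G_0)} , $$

with `d` the L1 distance over bins. `alpha = 0` is a flat landscape (all
karyotypes equally fit); increasing `alpha` makes fitness fall away from the
optimum more steeply. The fitness change can be absorbed by the birth rate
(death fixed at `d0`; the default) or by the death rate — only the net growth
rate is constrained by the relation, and end-point karyotype data cannot
distinguish the two, so the choice is exposed as `mode` in
`fitness_landscape()`.

At each division, each daughter independently draws `Poisson(mu)` CNA
events. An event picks a uniform start bin, a length from a pluggable
sampler, a direction (gain or loss, probability 1/2 each) and changes the
covered bins by one copy, truncated at chromosome ends (events never span
two chromosomes). Whether one or both daughters mutate is a switch
(`both_daughters`, default both). Copy numbers are capped (`max_cn`, default
8) and a bin at zero copies cannot be regained.

Defaults and units:

| parameter | meaning | default | note |
|---|---|---|---|
| `b0`, `d0` | optimal birth/death rate per unit time | 1, 0.2 | only the ratio and `alpha` are identifiable from end-point karyotypes; absolute values set the time scale |
| `mu` | CNAs per gland division | — | empirical lower bound ~0.1 from single-cell data |
| `alpha` | selection strength | — | `0` = neutral |
| `max_cn` | copy cap per bin | 8 | |
| length sampler | CNA sizes in bins | mixture: whole chromosome w.p. 0.3, else 1 + Geometric(mean 20) | the study drew sizes from its observed CNAs, which cannot be bundled; `cna_length_sampler(lengths=)` accepts an empirical vector |

`simulate_cin()` is an exact Gillespie simulation. Glands sharing a
karyotype lineage are grouped into *clones* with per-clone aggregate rates;
this is statistically identical to tracking every gland (rates depend only
on the karyotype) and is what makes pure-R runs to 5,000–100,000 glands
practical. The genealogy is therefore recorded at clone resolution: each
clone stores its parent and the events that created it, every karyotype can
be replayed exactly from the founder (`replay_karyotype()`), and
`as_event_tree()` converts a sampled gland set into a rooted tree with
per-node karyotypes (a `founder` outgroup tip makes the trunk observable).

Two practical guards: extinction is a reported outcome, not an error; and a
`max_events` budget marks runs as `"stalled"` when the population cannot
reach the target size in bounded effort. The stall guard matters because at
high CNA rates (`mu` near 1) even the optimal clone loses its karyotype
faster than it reproduces, so strongly selective landscapes become
near-critical — biologically, such parameters do not produce growing
tumors, and the inference machinery treats them as non-viable draws.

## Inference: rejection ABC and DIC model selection

`summarize_profiles()` reduces a gland set to six statistics: mean pairwise
proportion of the aberrant genome subclonal (the "divergence" statistic),
mean pairwise genetic distance, mean and SD of the percentage genome
altered, the proportion of the altered genome that is subclonal, and the
mean segment count. `abc_fit()` draws `(mu, alpha)` from the priors
(`mu ~ U(0.1, 1)`, the lower bound being the empirical single-cell floor on
the CNA rate; `alpha` log-uniform on `[1e-3, 10]`), simulates a gland set at
each draw, standardises each statistic by its across-simulation MAD, and
accepts the closest fraction (default 10%) in Euclidean distance. The
reference table can be precomputed (`abc_reference()`) and reused across
observed datasets, the standard reference-table formulation of rejection
ABC.

Model comparison uses a deviance information criterion. The deviance of a
parameter draw is `-2 log` of a Gaussian synthetic likelihood of the
observed statistics whose mean and (diagonal, ridge-regularised) variance
are estimated from the `k = 20` reference simulations nearest to the draw
in standardised parameter space. `DIC = 2 * mean(D) - D(posterior point)`.
Estimating the deviance from the reference table rather than from fresh
replicate runs makes the criterion a deterministic function of the fit
and, at desk scale, dramatically reduces its variance; the construction is
isolated behind `dic()` so an alternative estimator can be swapped in.

The decision rule needs care because the models are effectively nested:
along the `mu`-`alpha` ridge the selection model reproduces neutral data,
and the unidentifiable extra parameter contributes almost nothing to the
DIC's complexity penalty, so on neutral data the DIC difference is not
centred at zero and a fixed symmetric threshold would over-call selection.
`model_select()` therefore calibrates the selection-call cutoff from the
null itself (`dic_null_cutoff()`): neutral reference simulations with CNA
rate near the fitted value are treated as held-out pseudo-observations,
both models are refit to each, and the 90th percentile of the resulting
DIC differences is the bar the observed difference must clear before the
selection model is called. Differences below that bar (and above `-2`) are
reported as indistinguishable.

Two caveats are inherent and worth stating. First, `mu` and `alpha` are
jointly unidentifiable from end-point karyotypes: more mutation and stronger
selection trade off, visible as a positive ridge in the accepted `(mu,
alpha)` draws (`plot_abc_posterior()`). The informative lower bound on `mu`
is what gives the model comparison its power: below-floor heterogeneity
cannot be explained neutrally. Second, the DIC here is a pragmatic
likelihood-free construction, not an exact Bayesian quantity; it is used
comparatively, between two models fitted with the same budget.

**Problem sizes.** The packaged experiments run at desk scale, chosen so the
full suite completes on one CPU: simulator experiments use the 10-Mb
default grid (278 bins) with populations of 5,000 glands and 77 sampled;
the ABC uses a 25-Mb grid (104 bins), populations of 2,000 with 77 glands
sampled, and 300-draw reference tables per model, shared across observed
datasets. At these sizes the recovery harness (10 datasets per generating
model) selects the negative-selection model on all selection-generated
datasets and the neutral-or-indistinguishable outcome on at least 8/10
neutral datasets. Larger populations sharpen the separation (the neutral
floor of divergence rises with the number of generations while selection
saturates) at roughly linear cost in events.

## Divergence metrics

All metrics call gain/loss/baseline states against each sample's own
baseline ploidy — the lower median of its integer copy numbers — so a
clonally genome-doubled pair is compared on equal footing (a shared
baseline is available via the `baseline` argument). `FracDiffBins` divides
discordant-state bins by all bins; `FracDiffAltBins` (the headline
"proportion of aberrant genome subclonal") divides by bins altered in at
least one of the pair; the GeneDose variants weight bins by gene content;
`GeneticDistance` sums absolute integer differences; and
`BreakpointDivergence` compares the positions where the state changes
(exact-position matching, no slack window). Discordance is judged on
three-level states, not integers, for the Frac* metrics — the integer
alternative is `GeneticDistance`. `divergence()` averages a metric over
cross pairs of two sample groups (or unordered within-group pairs),
which is how between-timepoint and within-lesion comparisons are made.

## Genome-doubling classification

The published linear classifier calls a sample genome-doubled when
`0.000355 * NS + PGA - 0.432 > 0`, with `NS` the number of copy-number
segments and `PGA` the fraction of bins off the sample's baseline ploidy.
The coefficients are constants of the published model (trained elsewhere on
consortium segment calls; retraining is out of scope). Around the decision
boundary a margin of half the intercept's magnitude (0.216 score units, the
reading adopted for the stated "±0.5 of the intercept" zone; configurable)
yields an `ambiguous` call. Patient-level logic: clonal GD / clonal non-GD
when only one confident call type occurs, subclonal GD when both occur;
ambiguous samples are corrected to the clonal call, or in subclonal
patients to the majority confident call with ties going to GD. Patients
whose samples are all ambiguous are reported `unresolved` (a case the
published rules leave undefined). Segment counts are maximal runs of equal
copy number within chromosomes, so a constant genome counts one segment
per chromosome; note the margin-free sign of the score is what the
published accuracy figures refer to, and `gd_classifier(ambiguous_margin
= 0)` reproduces that behavior.

## Multi-sample ploidy fitting

Shallow WGS yields only log2 ratios; absolute copy number requires a
purity/ploidy solution. Following the allele-free reading of the ASCAT
transformation, `cn = (2^logr (2(1-ρ) + ρψ) - 2(1-ρ))/ρ`, the fitter grid
searches ploidy 1.5–4 (step 0.05) and purity (step 0.01; floor 0.5 for
microdissected region samples, 0.2 for bulk), scoring each candidate ploidy
by (a) the mean per-sample squared deviation of implied copy numbers from
integers and (b) the mean pairwise Euclidean distance of ploidy-normalised
integer profiles across samples, excluding bins with log2 ratio above 1
(an amplification guard so focal amplifications do not dominate the
distance). Both scores are min–max scaled over the ploidy grid and ranked
by distance from the origin, so the chosen ploidy fits well within samples
*and* gives mutually consistent profiles. Purity ties (aliased integral
solutions at low purity) break toward the highest purity. Manual curation
is deliberate and explicit: `call_absolute_cn(choice = 2)` selects the
second-ranked solution and `psi_offsets` applies per-sample ±0.4-style
adjustments with the purity refit.

An identifiability caveat is inherent to log-ratio-only fitting: a
whole-genome +1 reinterpretation of the data at a suitably lower purity
reproduces the log2 ratios exactly, so when every sample's aliased purity
stays inside the allowed range the one-copy-higher solution can rank
first. This is the same ambiguity that required manual curation of aliased
patients in practice; `tidy()` on the fit exposes the full ranked table
and `call_absolute_cn(choice = 2)` selects the alternative explicitly.

One convention deserves emphasis: median-centring a log2-ratio profile
renormalises it to the sample's modal copy state, so the ploidy recoverable
from centred data is the baseline (median) copy number. The synthetic
generator's `gen_logr()` median-centres by default (matching real sWGS
pipelines) and offers `center = FALSE` when the normalisation constant
itself must be recoverable.

## Tree events and SNP phasing

`classify_events()` takes a rooted tree whose nodes carry karyotypes
(simulator truth, or an external reconstruction such as a minimum-event
copy-number tree) and classifies branch events as clonal (root-to-MRCA of
the tumor leaves), intermediate (internal branches below the MRCA) or tip
(pendant branches). An event is a maximal contiguous run of bins changed in
the same direction, counted once regardless of magnitude. Ancestral
reconstruction itself is out of scope — karyotypes are inputs.
`event_frequency()` reports per-bin gain/loss frequencies across patients;
clonal frequencies are measured against the rounded patient ploidy
(round half up) so uniformly triploid or tetraploid genomes do not read as
all-gained.

`phase_snps()` phases germline SNPs to major/minor haplotypes from their
mean B-allele frequency across deep-sequenced glands within
copy-imbalanced segments (a trisomy puts them near 0.67 and 0.33 at purity
1); SNPs within 0.05 of 0.5 stay unphased, and balanced segments cannot be
phased. Pooling across glands by the mean is a design choice (per-gland
phasing is possible but noisier at realistic depths). Imbalance in shallow
samples is then tested per segment: an exact binomial test against 0.5, and
a Fisher exact test of observed major/minor counts against the expectation
scaled from the inferred allele-specific copy number — the 2x2
construction (expected row scaled to the observed total and rounded) is one
concrete reading of a null "based on the inferred copy number" and is
isolated in `segment_phase_test()`. Purity shifts the expected BAF toward
0.5 via `expected_baf()`.

## The synthetic cohort generator

`gen_cohort()` produces multi-region integer copy-number cohorts with full
ground truth: trunk (clonal) events accrued on a diploid genome until a
target clonal PGA is reached, optional whole-genome doubling applied
part-way through the trunk, then region-private events until a target
proportion of subclonal alterations is met. Stage presets encode the
progression regimes — adenomas with low PGA (target 0.085) but high
subclonality (0.60), carcinomas the reverse (0.272 / 0.25), early cancers
in between (0.253 / 0.40) — with genome-doubling probabilities at the
observed cohort frequencies (1/19, 16/81, 13/39). PGA targets come from
the published cohort means; the subclonality targets are this package's
choices (no cohort numbers exist for them), set so the adenoma and
carcinoma regimes occupy the opposite corners of the PGA-versus-
subclonality phase space and the carcinoma value is consistent with a
cohort-wide primary-region divergence near 0.24. Genome-doubled patients
draw their PGA target doubled (capped at 0.9): doubling both re-baselines
pre-existing alterations and is empirically associated with a much larger
altered fraction, which is precisely the signature the GD classifier
exploits — without it, synthetic GD and non-GD genomes would be
statistically identical and the classifier would have nothing to detect.

`gen_logr()` adds the ASCAT-inverse transformation plus Gaussian noise
(default SD 0.05, typical of 500-kb sWGS bins) and `gen_baf_fixture()`
draws binomial allele counts at the BAF implied by allele-specific copy
number and purity. Everything is seed-deterministic end to end.

What the generator does *not* emulate: wave/GC artefacts and segmentation
errors in log ratios, FFPE noise, subclonal mixtures within a sample
(regions are pure clones at the CN level), allele-specific events, or
recurrent, positionally biased CNAs (events land uniformly). Passing tests
on this generator therefore demonstrates correctness of the statistics and
recoverability under idealised noise, not robustness to every artefact of
archival sWGS data.

## Numerical choices and degenerate inputs

- Baseline ploidy uses the lower median, so the baseline is always an
  attained copy number; `FracDiffAltBins` is defined as 0 when neither
  sample has an altered bin, and `BreakpointDivergence` as 0 when neither
  has a breakpoint.
- Consensus regions drop segments shorter than 4 bins by default (2 is the
  single-cell setting); chromosome boundaries always break segments and
  regions, with a switch (`chrom_breaks`) exposing the alternative.
- The Fisher and binomial tests delegate to R's exact implementations; the
  test suite verifies them against full enumeration oracles.
- In the ABC, statistics with zero MAD fall back to the SD, then to 1;
  extinct or stalled simulations are excluded from scaling and can never be
  accepted.
- Ploidy-grid rank ties break toward the lower ploidy; purity ties toward
  the higher purity.
- Gillespie runs are bit-reproducible given a seed; all cohort generation
  derives per-patient seeds from a single cohort seed.

## Known limitations

The simulator is non-spatial and ignores within-gland cell dynamics (the
per-gland CNA rate is taken equal to the per-cell rate; the mapping between
the two depends on intra-gland selection and is deliberately not modelled).
Whole-genome doubling is not an event type in the evolutionary model (it is
present in the cohort generator). The DIC construction is a documented
substitute for an unavailable exact likelihood, and event classification
relies on supplied ancestral karyotypes. Full-scale replications of the
study-scale simulations (populations of 100,000 over hundreds of bins with
thousands of ABC draws) are a matter of compute budget, not of code paths:
the same functions run them unchanged.
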