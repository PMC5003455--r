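---
title: "Discovering CNV regions from pooled SNP-array data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering CNV regions from pooled SNP-array data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolcnv)
```

## The problem

Genome-wide CNV scans of individually genotyped subjects are expensive at
the discovery stage. A DNA-pooling design mixes equal DNA amounts from
many subjects (here 25 per pool) and hybridises each pool as a single
array sample — for a 200-case / 200-control study, sixteen arrays instead
of four hundred. The price is signal: the Log R ratio (LRR) of a pool at
a marker no longer reflects one genome's copy number but the *mean* copy
number of the pool,

$$\mathrm{LRR} \approx \log_2\!\frac{\bar c}{2},
  \qquad \bar c = \frac{1}{25}\sum_{i=1}^{25} c_i .$$

A single duplication carrier ($c_i = 3$) among 25 subjects moves the pool
mean from 2 to 2.04, an LRR shift of $\log_2(1.02) \approx 0.0286$; a
single hemizygous deletion moves it by $-0.0291$. Everything in this
package is shaped by that number: events of interest sit barely above the
noise floor, so the workflow leans on aggressive marker- and region-level
filtering to keep the false-positive rate controllable, and on exact
small-sample tests for the final 8-vs-8 pool comparisons.

## The signal simulator

Because raw pooled-array data of this kind are not publicly deposited,
the package ships a generator (`simulate_dataset()`) that produces
datasets with known truth, used by every downstream test.

* **Design defaults**: 8 case and 8 control pools of 25 subjects — the
  pooling layout the workflow targets.
* **LRR model**: $\log_2(\bar c/2)$ plus pool-level Gaussian noise.
  The default noise SD of 0.15 is a deliberate choice, not a measured
  value: no pool-level noise estimate is available for this array and
  design, so the default is set where singleton events (shift 0.029) are
  *below* the detection edge, which is the regime a pooling study must
  assume. Analyses that need a detectable signal either raise the carrier
  count or lower `lrr_noise_sd`; the bundled demo and the recovery tests
  use 0.01, where a 60-marker singleton event is comfortably callable.
* **BAF model**: a per-marker population B-allele frequency drawn from
  Uniform(0.05, 0.95), a binomial allele proportion over the pool's
  chromosome count (adjusted for carrier dosage), and small truncated
  Gaussian jitter. This is intentionally simple: the caller uses LRR
  only, because a 1-in-25 carrier perturbs the pooled allele proportion
  by at most ~2%, well inside the jitter.
* **Defects**: missing signals, failed probes (GC score exactly 0) and
  whole-marker intensity artifacts (LRR pushed above +1 or below −5) are
  injected at configurable rates to exercise the QC rules.

What the generator does **not** emulate: Illumina normalisation
chemistry, GC-content waves along the genome, batch effects between
arrays, and subject-level genotypes. Passing tests therefore demonstrate
that the pipeline's rules behave as specified on data obeying the stated
signal model — not that the caller would reach any particular sensitivity
on a real pooled intensity file.

Coordinates are 1-based inclusive everywhere in memory; files on disk use
the BED 0-based half-open dialect, converted at the I/O boundary. With a
fixed seed the generator's output files are byte-identical across runs.

## Marker QC

Three filters, applied in a fixed order, each to the survivors of the
previous one:

1. drop markers with a missing signal in **any** pool, and markers on
   chromosomes X/Y (pool sex composition makes their LRR uninterpretable);
2. drop markers whose GC (genotype-confidence) score is exactly 0 in
   **more than three** of the 16 pools;
3. drop markers whose median LRR across all 16 pools (cases and controls
   jointly) is **above +1 or below −5** — intensities in that range are
   array artifacts, not copy number.

All inequalities are strict, so a marker sitting exactly on a bound is
retained; the median of the 16 pools is the mean of the 8th and 9th order
statistics. The missing-signal rule counts a missing value in any of the
three fields (LRR, BAF, GC score) — the narrower reading (LRR only) would
let half-failed probes through to the caller. A marker failing several
rules is attributed to the first failing rule, which makes the QC
report's removal counts additive and testable.

## The caller

Per pool and per chromosome, a three-state (loss / normal / gain) hidden
Markov model is decoded by the Viterbi algorithm in log space. This is a
deliberately simplified stand-in for full CNV callers such as PennCNV,
and is documented as such; the simplifications and their rationale:

* **LRR-only Gaussian emissions** (state means −0.03 / 0 / +0.03 on the
  pooled scale, bracketing the singleton-carrier shift): pooled BAF is
  nearly uninformative at 1-in-25 carrier dosage.
* **Three states, not six copy-number states**: downstream logic only
  needs gain / normal / loss.
* **Distance-independent transitions**: each state keeps probability
  $1 - 2s$ and switches with $s$ to each alternative
  (`switch_prob`, default $10^{-4}$ — about a 9.2-nat penalty per
  breakpoint). At the near-uniform marker spacing the simulator produces,
  distance dependence buys nothing; the parameter is exposed for anyone
  who disagrees.
* **Emission SD estimated per pool** as MAD × 1.4826 of the pool's LRR
  track, robust to the small fraction of markers inside true events.
* Segment coordinates are the first and last marker positions of the
  run — the simplest defensible convention (PennCNV reports the same).

The decode is checked against exhaustive path enumeration for tracks of
up to 8 markers, where all $3^n$ paths can be scored directly.

## Region rules

Applied to the raw calls in this order (merged calls are not re-subjected
to the earlier filters, the simplest reading of the workflow's sequence):

1. **Minimum 20 markers** per call; short HMM segments are
   false-positive-enriched.
2. **Gain quality**: gain calls with mean LRR < 0.02 (indistinguishable
   from diploid) or LRR SD > 0.2 (noisy region) are dropped. Losses are
   exempt — the gain excess, not the loss set, is where the false calls
   concentrate.
3. **Gap merge**: within one pool/chromosome/status track, neighbouring
   calls merge when gap / (sum of the two lengths) < 0.2. The merged
   call's marker count, mean and SD are the exact pooled moments of its
   parts; markers inside the gap are *excluded* (they were, after all,
   decoded as normal). The sweep lets a merged call merge again, so
   fragment chains collapse in one pass, and the operation is idempotent.
4. **Cross-pool union**: single-linkage clustering of all pools' calls
   under any-overlap (≥ 1 bp); each cluster becomes one region spanning
   min start to max end, with per-pool presence and status recorded.
   "Union" admits several readings; single linkage is the one that makes
   regions disjoint and comparable across pools, which is the point of
   the step. Per-group unique-region counts (used by the burden table)
   re-run the union within each group separately.

## Classification against a reference CNV map

Each unioned region gets exactly one category, evaluated in this order:

* **different status** — present in both groups with disjoint status sets;
* **important in cases** — case pools only, absent from the reference map
  (novel, disease-group-specific);
* **important in controls** — control pools only, present in the map
  (known population variation the cases lack);
* **enriched in cases / controls** — present in both, pool-frequency
  difference ≥ 3 (configurable);
* **uninformative** otherwise.

The status-conflict rule is evaluated first because it is the only rule
not determined by the two counts; the others are mutually exclusive. The
enrichment boundary is genuinely ambiguous in the source workflow (the
criteria list says "> 3" where the worked results describe a difference
of exactly three as enriched); the package defaults to ≥ 3 and exposes
`freq_diff_threshold`. Map membership is any-overlap — no
reciprocal-overlap fraction — because map entries and pooled regions have
incommensurate breakpoint resolution. The reference map is an input file;
assembling a real population map (e.g. HapMap CHB plus published Han
Chinese maps) is the user's task, and the bundled map is synthetic and
named accordingly.

## Association testing

* **Burden**: per-pool call counts, stratified by status (both / gain /
  loss) and minimum length (≥ 100 kb, ≥ 500 kb), compared by the exact
  rank-sum test; unique-region counts per group from within-group unions.
  A stratum with no calls anywhere reports `NA`.
* **Per-region signal**: each pool reduced to the median LRR of the
  QC-retained markers in the region; 8-vs-8 comparison by a two-sided
  Welch $t$-test and the exact rank-sum test. Welch rather than Student
  because nothing guarantees equal variance across groups (with equal
  sample spreads the two coincide anyway). Screening (p < 0.2) and
  significance (p < 0.05) thresholds are configuration values; no
  multiple-testing correction is applied at this stage, which mirrors the
  screening character of the design — raw p-values are reported and the
  caller of the pipeline decides.
* **Exact rank-sum**: all $\binom{16}{8} = 12870$ group assignments are
  enumerated; ties take mid-ranks, and the enumeration conditions on the
  observed rank vector, so tied data remain exact. The two-sided p is the
  fraction of assignments with $|W - E(W)| \ge |w_{obs} - E(W)|$. The
  smallest attainable two-sided p is $2/12870 \approx 1.55\times10^{-4}$
  — worth knowing before interpreting any "p < 0.001" ambition at this
  sample size.
* **Power**: exact two-sided two-sample $t$ power via the noncentral $t$
  distribution. This is the generic design tool; at a 2-SD standardised
  effect with 8 pools per group it returns 0.96, and it reproduces a
  Monte-Carlo rejection rate to three decimals.

### A note on calibration checks

Under null simulations the Welch-$t$ p-values on per-pool medians are
checked for uniformity with a Kolmogorov–Smirnov test. The exact rank-sum
p cannot be checked that way: its null distribution is discrete on the
attainable values $k/12870$ (with large steps near 1), so a continuous KS
test would reject even a perfectly exact test. For it the package's tests
assert validity instead: $P(p \le \alpha) \le \alpha$ at several levels.

## Problem sizes in the test-suite

The suite runs entirely on generated data: oracle-equivalence checks use
tracks of ≤ 8 markers (full path enumeration), call sets of ≤ 20
(transitive-closure clustering) and the full $\binom{16}{8}$ assignment
enumeration; recovery checks use 1000-marker datasets with a ~60-marker
embedded event at noise SD 0.01; calibration uses 500 null datasets of 25
markers and a 100,000-replicate Monte-Carlo power oracle. These sizes were
chosen so each property is checked against an exhaustive or
high-replicate reference while the whole suite stays comfortably
interactive.

## Known limitations

* The caller is a stand-in: no distance-dependent transitions, no
  BAF-informed states, no six-state copy-number output. Real pooled
  intensity data would also carry GC waves and batch structure the
  simulator does not produce.
* Pooling forbids covariate adjustment and subject-level follow-up within
  the same data; the workflow is a discovery screen, and anything it
  reports needs individual-level validation.
* The burden and signal tests inherit the resolution limits of 8-vs-8
  comparisons; the exact-p floor above is the hard ceiling on attainable
  evidence.
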