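---
title: "ctlong: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctlong: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctlong)
```

`ctlong` analyses patient-specific somatic variants in circulating tumour
DNA (ctDNA) from serial plasma exome sequencing: filtering candidate
calls, detecting localized hypermutation, refitting mutational
signatures, estimating tumour fraction and copy states from binned read
depth, and reconstructing longitudinal clonal structure. This vignette
documents the statistical models, the defaults and why they were chosen,
the synthetic-data generator the package is validated against, and the
limits of what that validation shows.

## Data model

A variant table is a plain data.frame with one row per candidate variant
per sample: `chrom`, 1-based `pos`, single-base `ref`/`alt`, per-strand
read counts (`ref_fwd`, `ref_rev`, `alt_fwd`, `alt_rev`), the mean base
quality of alt-supporting reads, and optional annotation columns (COSMIC
and dbSNP identifiers, exonic function, population allele frequencies,
gene, driver class, trinucleotide context). The variant allele fraction
(VAF) is `alt / depth`. Chromosome names are normalized to the
"chr"-prefixed dialect on read; BED intervals (0-based half-open) are
converted to 1-based closed coordinates at the boundary, so a BED record
`chr1 100 200` covers positions 101..200. Indels are accepted by the
parser but flagged `unsupported` and excluded from kataegis and signature
analyses, whose definitions (inter-mutational distance, trinucleotide
context) are SNV-specific.

## The filtering cascade

Plasma calling keeps a record with at least 3 alt-supporting reads and at
least one on each strand; a record with as little as 1 alt read is
rescued when the same locus/allele carries ≥ 3 alt reads in the matched
tumour. "3 reads" is interpreted as *alt-supporting* reads, not total
depth — the strand clause attaches naturally to the same reads — and the
interpretation is a config switch (`filtering$min_alt_reads`,
`rescue_min_*`).

Eight set filters follow, each a pure per-variant predicate given its
side inputs (germline table, control tables, blacklist, the called-set
locus census), which makes their order irrelevant — a property the test
suite checks by permutation:

1. **dbSNP-only**: drop iff no COSMIC id and a dbSNP id is present.
2. **Exonic function**: drop `synonymous` and `unknown`; missing
   annotations are treated as unknown and counted separately.
3. **Base quality**: drop `mean_alt_bq` < 25.
4. **Germline**: keep iff the matched germline covers the locus at ≥ 20x
   with zero alt reads. Loci *under* 20x are dropped by default
   (`germline_undercovered = "drop"`): a germline origin cannot be
   excluded at an unverifiable site, and keeping such loci would admit
   germline leakage. The permissive behaviour is available as `"keep"`.
5. **Benign controls**: drop any locus/allele with ≥ 1 alt read in any
   chronic-pancreatitis (CP) control plasma. With no controls supplied
   the filter is vacuous and warns.
6. **Multi-allelic / serial consistency**: drop every allele at loci with
   more than one distinct alt across the patient's called plasma set. The
   locus census is computed on the *called* set (not the current
   survivor set) so the stage commutes with the others.
7. **Blacklist**: drop positions inside the supplied intervals.
8. **Strand bias**: two-sided Fisher exact test on
   `[[ref_fwd, ref_rev], [alt_fwd, alt_rev]]`; drop iff p < 0.01 *and*
   the minor-strand alt fraction is below 0.1. Requiring both conditions
   spares low-depth variants, where the test is underpowered and a small
   imbalance is expected. This reimplements the published false-positive
   filter's intent as a self-contained rule; the thresholds are config
   keys, since the original accessory script does not document its own.

Population allele-frequency hits (any of 1000G/gnomAD/HapMap > 0) are
*flagged*, not removed, matching the described pipeline; a config switch
(`pop_af_action = "drop"`) tightens this. Each stage records input and
output counts and the dropped variant keys, so every removal is
attributable.

## Kataegis

Within each chromosome, consecutive SNVs join a cluster while the gap to
the previous SNV satisfies log10(IMD) ≤ 4; a closed cluster is a kataegis
event iff it has ≥ 6 members with mean inter-mutational distance ≤ 1000
bp. Grouping is greedy left-to-right with no merging across a gap above
10^4 bp and no trimming of outlier members — the simplest rule consistent
with the stated bounds. Detection runs by default on the combined
all-timepoint plasma set of a patient (duplicate loci collapsed), which
is where recurrent events are most visible; per-sample runs are a matter
of subsetting the input. The sliding-window hypermutation score is the
observed/expected rate ratio `H = (count/window) / background_rate` with
an upper-tail binomial p-value; windows are flagged at H ≥ 5 and
p < 0.05. The exact scoring formula of the referenced sliding-window
tool is not published; the rate-ratio form is the natural reading of a
"hypermutation score" with the stated threshold of 5. Substitution
spectra are pyrimidine-normalized (purine-reference sites complemented)
over the six classes C>A, C>G, C>T, T>A, T>C, T>G.

## Mutational signatures

Spectra are 96-channel trinucleotide counts; contexts are supplied as a
table column (the reference trinucleotide on the `ref` strand), so no
genome needs to be bundled; purine-reference records are
reverse-complemented including flanks. Refitting is forward-selection
non-negative least squares: starting from the empty set, the signature
whose inclusion (weights re-solved by NNLS with total weight ≤ 1) most
reduces the squared error is added, until the relative improvement falls
below 1e-3; weights below the discard threshold 0.06 are zeroed and the
support re-solved. Both tolerances follow the conventions of the
established refitting tools and are config keys. The ≤ 1 simplex bound is
enforced, when active, by a heavily weighted sum-to-one penalty row in
the NNLS system; for exact mixtures the unconstrained solution already
satisfies it, so recovery is exact to numerical precision. Instability
labels map post-discard weights to DSBR (signature 3), MMR (signatures
6, 15, 20, 21, 26) and POLN (signature 9); the catalogue is a user input,
so absent ids yield an undetermined label with a warning.

## Copy number and tumour fraction

Read counts in non-overlapping 1 Mb bins are corrected by a LOESS fit of
count on GC fraction (span 0.5, fitted on unmasked autosomal bins) for
the sample and the matched normal separately; when mappability varies, a
second LOESS of the ratio on mappability is applied. Bins with
mappability < 0.9 or zero normal count are masked. The log2 ratio is
centred on its genome-wide median — the majority of bins is assumed
copy-neutral, which mildly biases heavily aberrant genomes (a known
limitation shared by median-centring callers).

Segmentation is a 6-state HMM over HOMD, HETD, NEUT, GAIN, AMP, HLAMP
(copy numbers 0..5; the HLAMP ≥ 5 / AMP = 4 / GAIN = 3 boundaries follow
the usual convention and are config-exposed) with Gaussian emissions
centred at `expected_logr(c, t) = log2((t·c + 2(1−t))/2)`, floored at −8.
The emission SD is the Gaussian-scaled median absolute deviation of the
log ratios. Self-transition probability is 0.99; leaving a state
distributes the remaining mass over the other states in proportion to a
state prior (0.01, 0.2, 0.5, 0.2, 0.05, 0.04 for HOMD..HLAMP). The prior
matters: without it, a hemizygous loss at tumour fraction `t` is exactly
as likely as a homozygous loss at roughly `t/2`, and the model is
unidentifiable from a single aberration; making extreme states a priori
rare resolves the degeneracy the way practical callers do. Tumour
fraction is estimated by maximizing the Viterbi path likelihood over the
grid `1 − {0.2, 0.35, 0.5, 0.65, 0.8, 0.9, 0.99}` of
normal-contamination initializations, refined by golden-section search
around the best grid point (tolerance 1e-3); this is a clonal-only model
with a single aberrant population and no subclonal fraction parameter.
When the best decode is entirely neutral the tumour fraction is
unidentifiable; the fit is flagged `no_evidence` and reported at the grid
minimum with an all-neutral segmentation. Pathology cellularity, when
known (tissue samples), can be passed as `fixed_t` to skip estimation.

## Longitudinal clonal inference

Variants are clustered across the joint timepoint space with a binomial
mixture: cluster k has a mean VAF `phi[k, j]` per timepoint, and variant
i contributes `Binomial(depth[i, j], phi[k, j])` likelihood at its
observed alt count at *every* timepoint. Zero alt reads at a covered
site is therefore evidence of absence rather than missing data, which is
what separates a clone that cleared from one that was never sampled. EM
runs from 20 k-means++ initializations per candidate k (seeded, so
results are deterministic), the per-iteration log-likelihood is asserted
non-decreasing, and k is selected by BIC with `k·J + (k−1)` free
parameters. Variants never detected at any timepoint are excluded and
reported.

Cluster prevalences are `U = min(2·phi, 1)` under the heterozygous,
copy-neutral model; loci inside non-neutral copy segments can be
excluded from the clustering input when segments are supplied. On this
scale `U` is the clone's prevalence within *total* cfDNA (it carries the
tumour-fraction factor), which has a consequence for the tree search: the
germline root's prevalence is taken as the per-timepoint *maximum
cluster prevalence* rather than 1. A root fixed at 1 would never
constrain children that sum to at most a tumour fraction of ~0.3, and
the root constraint — a single founding clone bounding its siblings — is
the strongest piece of structure in the data. This is the usual purity
normalization expressed directly in the constraint.

All rooted trees over the clusters plus the germline root are enumerated
via Prüfer sequences (exact for the default cap of 10 clusters) and
scored by total sum-condition violation: for every clone and timepoint,
`max(0, sum(children U) − parent U)`. When the clustering supplies
standard errors (pooled binomial SEs of each cluster-timepoint mean),
each constraint tolerates an excess of 2 combined SEs, so sampling noise
does not flip feasibility decisions. Among minimal-violation trees, ties
are broken by an attachment-density score, `sum over clones of
−log(parent prevalence)`: under a generative model in which a child
occupies a uniformly random share of its parent's headroom, the
likelihood of observing a given child is inversely proportional to the
parent's prevalence, so the maximum-a-posteriori attachment is the
smallest clone that can contain it. Trajectory correlation was
considered and rejected as a tie-break: all clone trajectories share the
global tumour-fraction trend, so correlations hover near 1 and carry
almost no attachment information. Remaining ties resolve
lexicographically. Because the search is exhaustive, whenever a
zero-violation tree exists one is returned.

Derived calls: per-timepoint clonal proportions are child-subtracted
prevalences floored at 0; the stem clone is the cluster with the highest
mean prevalence (ties go to the earliest id and are flagged); a clone is
*emergent* if below the detection floor (0.005 on the prevalence scale)
at baseline and above it later, *declining* if it loses ≥ 50% of its
prevalence between consecutive timepoints (restricted to
treatment-spanning intervals when treatment dates are given), else
*stable*.

## Tracking summaries

The mean-MAF series averages `alt/(alt+ref)` over the patient's candidate
locus set at each timepoint; a locus undetected at a covered site counts
as 0, keeping the series sensitive to clearance (a `"drop"` switch
averages detected loci only). CA19-9 measurements join by nearest day
within ±14 days of the plasma draw. Tumour–plasma concordance is the
fraction of tumour variants recovered at baseline and in the union of
all timepoints; the combined overlap dominates the baseline one by
construction, a property fuzz-tested over random set systems. Pathway
enrichment is the upper-tail hypergeometric probability with
Benjamini–Hochberg adjustment across pathways (the mildest standard
correction; nothing stronger is implied by the model). Fragment-size
profiling reports the 1-bp histogram argmax with ties resolved to the
smallest length and flagged. The actionability report classifies genes
against a catalogue table (a small synthetic stand-in for clinical
annotation services ships in `extdata`) and flags variants detected in
≥ 2 serial plasma samples as trackable.

## The synthetic-data generator

`simulate_patient()` draws, under a single seeded RNG: a rooted clone
tree (each later clone attaches to a uniformly random earlier one);
per-timepoint cellular prevalences allocated top-down so the sum
condition holds exactly; per-mutation read counts
`alt ~ Binomial(depth, 0.5·t_j·U[c, j])` with a fair strand split,
Poisson depths around the target, and truncated-Normal(35, 3) base
qualities; a matched tumour (pathology cellularity in place of `t`),
germline and CP controls; one labelled artifact cohort per filter class;
kataegis clusters with uniform(100, 1000) spacing; signature-driven
substitution types and trinucleotide contexts; and cfDNA fragment
lengths.

Defaults are the emulated study conditions: 5 clones × 40 mutations, 4
plasma timepoints at 1000x, germline at 100x, tumour at 60x with
cellularity 0.6, 3 CP controls, tumour fractions (0.30, 0.10, 0.20,
0.25) — a baseline, a post-treatment nadir and a partial rebound — and a
167 bp modal fragment size with a dinucleosomal shoulder.

Two generator choices deserve explanation:

- **Asynchronous clone trajectories.** Each clone's share of its parent's
  headroom peaks at a distinct timepoint (share ~ U(0.7, 0.95) at the
  peak, U(0.03, 0.2) elsewhere), emulating subclones that expand and
  collapse under successive treatment lines. This is not merely
  cosmetic: with temporally flat shares, a random 5-clone tree is
  identifiable from 4 per-timepoint marginal constraints in only ~a
  quarter of draws — many attachments are compatible with the sum
  condition — whereas asynchronous dynamics create the trajectory
  crossings that make wrong attachments infeasible.
- **Resolvability rejection.** Configurations in which any clone pair
  stays within 0.02 on the plasma VAF scale at every timepoint, or any
  clone never reaches 0.02 (~7 binomial SEs at 1000x), are redrawn:
  sub-resolution clones cannot carry tree information and would be merged
  by any method. At realistic tumour fractions this disfavours deep
  linear chains, whose terminal clones are unobservable in plasma.

The mononucleosomal fragment component is a discretized Laplace rather
than a Gaussian: published cfDNA length profiles show a sharp cusp at the
mode, and a Gaussian makes the 1-bp histogram argmax a coin flip between
adjacent bins even at 10^5 fragments.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: sequencing error beyond the explicit
artifact channels; CHIP-derived (clonal haematopoiesis) variants and
copy-number structure in plasma, whose bin noise here is i.i.d.
Gaussian; copy-number-aware VAFs (the clustering assumes heterozygous
copy-neutral loci, as does the prevalence transform); mutation
multiplicity; library-preparation batch effects; and real annotation
databases (the bundled COSMIC-style matrix, gene catalogue and pathway
table are small synthetic stand-ins).

## Validation scale and determinism

The acceptance checks run, on one CPU, at the following problem sizes —
chosen so that every estimate has a meaningful denominator while the
whole suite stays interactive: 100 kataegis injection and 100
background-only genomes at 1 SNV/Mb; 50 signature refits of 2000
mutations against a 10-signature catalogue; 30 copy-number simulations at
tumour fractions 0.1/0.25/0.5 with three aberrant chromosomes; 200
5-clone patients for tree recovery; 1000 fuzzed set pairs for the
concordance property; 10^5 fragments for the modal size. The full
pipeline is bitwise deterministic given a seed: two runs of
`run_pipeline()` with the same configuration produce identical output
files.

## Known limitations

- The filtering thresholds are fixed rules, not error models; there is no
  joint calibration of, e.g., the strand-bias p-value against depth.
- Tumour-fraction estimation assumes a single clonal aberrant population;
  subclonal copy number biases `t` downward.
- The exhaustive tree search is exponential in the cluster count
  (`(k+1)^(k-1)` trees) and refuses k > 10 by default.
- Cellular prevalence and clonal proportion are both reported; on the
  ctDNA scale they are only proportional to their tissue counterparts,
  with the per-timepoint tumour fraction as the factor.
- CA19-9 alignment uses a fixed ±14-day window; irregular sampling wider
  than that simply yields missing marker values.
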