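---
title: "Models and methods behind paleogen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paleogen)
```

`paleogen` implements the analysis arc of a low-coverage ancient-DNA skeletal
study — authentication, sex and contamination, uniparental haplogroups,
population structure, and radiocarbon chronology — together with a
synthetic-data generator that provides ground truth for every stage. This
vignette records the models, the defaults and why they were chosen, the
numerical choices, and what the tests do and do not demonstrate.

## The synthetic-data generator

The generator is first-class, tested code: it is the package's substitute for
unreleased read data, and every estimator is validated against its recorded
truth.

**Genome layout.** One synthetic contig per compartment — `auto`, `X`, `Y`,
`MT` — with configurable lengths (defaults 100 kb / 30 kb / 12 kb / 8 kb).
Real genomes are five orders of magnitude larger; working at desk scale keeps
the whole suite inside minutes while preserving every statistical structure
the estimators rely on (depth ratios, fragment-length spectra, damage
gradients, allele-frequency drift).

**Read model.** A sample is a mixture of endogenous molecules and an
undamaged modern contaminant. Reads are allocated to compartments with
probability proportional to length × copy number: autosomes count twice, X
twice in females and once in males, Y once in males only, and the
mitochondrion `mt_copy_number` times (default 100, which reproduces the
~50-fold MT-over-nuclear coverage excess typical of skeletal samples).
Fragment lengths are lognormal with CV 0.25, truncated to ≥ 30 bp — molecules
shorter than that never survive adapter trimming upstream, so they are part
of the discarded raw fraction, not of the alignments — with the location
parameter calibrated numerically so the *truncated* mean equals the
configured mean. The lognormal family is a choice (the fragment-length family
of degraded DNA is not settled); it is configurable through `fragment_cv`.

**Deamination.** Single-strand 5′ C→T at rate `δ · decay^(p−1)` at 5′ offset
`p`, with the mirrored 3′ G→A expected from blunt-end double-stranded
libraries. Two parameters reproduce the observable the screening rule needs —
the position-1 C→T percentage — and its characteristic exponential fall-off.
Defaults mirror screening-run values from poorly preserved northern-European
skeletons: δ between 0.189 and 0.298 across samples, decay 0.55, fragment
means 39–45.5 bp, endogenous fractions 0.1–14.7 %, contamination below 3 %.

**Contaminant.** A single modern female haplotype at fixed divergence from
the reference (default 1 substitution / 100 bp, all transversions). The
transversion choice makes contamination identifiable in the presence of
damage: deamination can never convert an endogenous base into a contaminant
allele. Real contaminant mixtures are more diverse; the mitochondrial mixture
model accepts an arbitrary candidate panel.

**Raw-read accounting.** `coverage_x` fixes the autosomal depth; the raw
(pre-mapping) total is back-computed from the configured endogenous fraction,
counting injected PCR duplicates as raw reads, and the emitted mapped total
is binomial around it. Emitted reads are confident alignments (MAPQ ≥ 30);
sub-threshold alignments are conceptually part of the discarded remainder.
Endogenous content is therefore measured on the *pre-duplicate-collapse*
filtered set, the way mapping software reports it, while damage profiles and
all downstream calls use the collapsed set.

**Reproducibility.** One root seed; every per-sample or per-stage stream is
derived by hashing the stream name (`derive_seed`), so results do not depend
on the order in which samples are processed, and regeneration is
byte-identical.

## Screening and damage

Reads are kept at MAPQ ≥ 30 and length ≥ 30 bp (inclusive). Duplicates share
(contig, 5′ alignment position, strand, length) — start-position semantics
appropriate for single-end data; the highest summed base quality survives,
ties broken by lexicographic sequence. The damage profile re-orients
reverse-strand reads into molecule coordinates and reports per-position C→T
(5′) and G→A (3′) frequencies over a 25-position window (no standard window
exists; 25 covers the signal at any plausible decay), with zero-opportunity
positions reported as missing rather than zero.

A sample passes screening when endogenous content ≥ 0.5 % **and** position-1
5′ C→T ≥ 10 %. The published rule is stated as an exclusion ("< 0.5 % and
< 10 %"); the boundaries here are the inclusive complement. Damage is
profiled after duplicate collapse (the choice is not forced; collapse only
removes copies, so the frequency is nearly invariant to it).

## Sex and contamination

`Ry = nY / (nX + nY)` with the normal-approximation CI
`Ry ± 1.96·√(Ry(1−Ry)/n)`; XY when the whole CI exceeds 0.075, XX when it is
below 0.016 — the published thresholds of the shotgun sex-typing method. The
CI is degenerate at `Ry = 0`; with thousands of sex-chromosome reads this is
immaterial, and the test suite shows 100/100 correct assignments at ≥ 5,000
such reads.

**Mitochondrial mixture.** The consensus is a per-site majority over reads
trimmed 7 bp at each end, requiring depth ≥ 3 (ties and thin sites yield N).
Contamination is the mixing weight `c` in a per-read two-component
likelihood: reads come from the consensus with probability `1 − c` or from
the mean of a candidate contaminant panel with probability `c`, compared only
at *discriminating* sites (where some panel haplotype differs from the
consensus), with a symmetric per-base error ε (match `1 − ε`, mismatch
`ε/3`). ε defaults to an estimate from non-discriminating sites with
deamination-type mismatches excluded; read termini are trimmed so residual
damage cannot pose as contaminant alleles. The estimate is the grid maximiser
over `c ∈ {0, 0.001, …, 1}` and the 95 % CI is the profile-likelihood region
(drop of 1.92 log units; the mixture log-likelihood is concave in `c`). A
Bayesian posterior is the other defensible choice here; the profile interval
was preferred for transparency, and its empirical coverage is ≥ 90 % across
the tested range (c = 0.007, 0.02, 0.2).

**Male X method of moments.** A male is hemizygous on X, so minor-allele
reads at known polymorphic sites indicate contamination or error:
`ĉ = (m_poly − m_mono) / mean(2f(1−f))`, where `m_poly` aggregates
minor-allele fractions at sites with population frequency `f`, `m_mono` is
the per-allele mismatch rate at monomorphic control sites, and the
denominator is the expected allele difference between the sample and a random
contaminant. Filters are MAPQ ≥ 30 and base quality ≥ 20. Only sites with at
least two passing reads are informative — one read can never exhibit a minor
allele — so the estimator needs X depth of roughly 2× or more even though the
applicability gate in the pipeline is the conventional 0.5×; at screening
depths it correctly refuses ("insufficient sites") rather than returning
noise. The CI is a site-level bootstrap (200 resamples). This transparent
moments estimator replaces likelihood-based tooling on the same inputs and
filters; that substitution is deliberate and documented.

## Haplogroups

Defining variants live on the branches of a rooted haplogroup tree (Newick +
TSV). Variant status from reads uses base quality ≥ 30: derived/ancestral
when all passing reads agree, conflict when both alleles appear, missing when
uncovered. With `damage_mask` on, C→T and G→A defining variants are masked —
in unrepaired libraries deamination can fake their derived state. Masking
defaults on for read-level (Y) calls and is unnecessary for consensus-based
mtDNA calls, where the majority vote already suppresses sporadic damage.

mtDNA haplogroups are scored Kulczynski-style: for candidate `h` with
expected path-variant set `E`, observed derived set `O` and covered set `C`,
`score = (|E∩O|/|E∩C| + |E∩O|/|O|)/2` — completeness of the expected motif
among testable sites, balanced against unexplained derived variants. The full
rank heuristics of dedicated mtDNA classifiers (hotspot weighting, private
mutation penalties) are out of scope, so these scores are not comparable to
published "quality" percentages.

Tree placement is by parsimony: maximise (derived support − conflicts) along
root-to-node paths. Internal nodes are legitimate calls, which is how a rare
basal lineage should be reported at low coverage; ties prefer the shallower
node (conservative) then the name. Parsimony here replaces maximum-likelihood
phylogenetic placement with a reference alignment — same inputs and outputs,
no model fitting, appropriate for transversion-defined synthetic trees and
small variant sets.

## Population structure

Pseudohaploid genotypes: at each biallelic transversion panel site, one base
is sampled uniformly among passing bases (MAPQ ≥ 30, BQ ≥ 30) matching ref or
alt; everything else is missing. Transversions-only ascertainment makes the
calls immune to deamination artefacts. IBS distances are
`1 − (#identical shared sites)/(#shared sites)`; pairs under `min_overlap`
(default 500; no published floor exists, and below a few hundred sites the
distance is noise) are flagged and excluded from MDS. Panel diploids are
haploidized (one random allele per site, seeded) before being mixed with
pseudohaploid ancients — IBS between a diploid and a haploid callset is
biased, so ploidy is made uniform first. Classical MDS is Torgerson double
centring (`stats::cmdscale`) with a deterministic sign convention (first
nonzero loading of each axis positive).

Admixture is the standard binomial model: individual `i`'s alt count at site
`j` is `Binomial(c_ij, Σ_k Q_ik F_kj)` with `c_ij = 2` (diploid) or 1
(pseudohaploid); missing entries are omitted (missing at random). It is fit
by EM block relaxation, whose log-likelihood provably never decreases — the
quasi-Newton acceleration used by the reference tool converges faster but
offers no such guarantee, and monotonicity is asserted in the tests at every
iteration. `F` is clipped to `[1e−6, 1−1e−6]` to avoid `log(0)`; convergence
is relative log-likelihood change < `1e−6` (cap 2000 iterations, warning on
non-convergence). Replicates are aligned by greedy correlation matching of Q
columns; replicates within aligned-Q RMSE 0.05 form a mode, the major mode is
the largest (ties by mean log-likelihood) and its highest-likelihood member
is the representative. Recovery at K = 3 with 60 individuals and 10,000 SNPs
puts mean |Q − Q*| under 0.05 with at least 8 of 10 replicates in the major
mode.

## Chronology and diet

Calibration is a grid posterior:
`p(θ) ∝ exp(−(m − μ(θ))² / 2(σ² + σ_curve(θ)²))` with linear curve
interpolation at 1-year steps, normalised on the grid. The 95.4 % region is
the highest-posterior-density set — the smallest set of grid cells reaching
the mass, density ties included, merged into intervals with endpoints rounded
outward to whole years. HPD (rather than quantile) intervals match the
multi-interval output style of standard calibration software: a monotone
curve yields one interval, wiggles may split it, and the interval masses sum
to within [0.954, 0.97] by construction. Calendar BCE uses the 1950 CE datum,
older bound printed first. Replicate dates are pooled by Ward–Wilson
inverse-variance weighting with a χ² consistency test at 5 %.

Diet: marine protein fraction `α` is linear two-endpoint mixing of collagen
δ¹³C between −22 ‰ (fully terrestrial, C3 northern Europe) and −10 ‰ (fully
marine), clamped to [0, 1]; the reservoir correction subtracts `α · 273` yr
and propagates `α · 18` yr in quadrature. Typical coastal-Neolithic values of
δ¹³C ≈ −19.2…−19.7 ‰ give α ≈ 0.19–0.23 and offsets of ~52–64 yr — close to,
but not exactly, the "c. 45–60 yr" sometimes quoted for such values, which
implies slightly different (unstated) endpoints; the endpoints are therefore
explicit `diet_model()` parameters rather than constants. Similarly, a
published marine-protein estimate of "15–20 %" for that δ¹³C range conflicts
with the −22/−10 endpoints (which give 19–25 %); the package reports what the
stated endpoints imply.

The synthetic curve is the identity mapping plus a smoothed random wiggle of
configurable standard deviation, with constant curve σ. With `wiggle_sd = 0`
it is exactly the identity, giving closed-form expectations (a 3000 ± 30 BP
date calibrates to exactly 2940–3060 cal BP at 95.4 %). Real IntCal curves
are supported through `read_calcurve()` (standard 3-column layout, comma or
whitespace separated) but are not bundled — they are distributed under their
own terms; supply `intcal13.14c` to calibrate published dates.

## Pipeline

`run_pipeline()` drives the stage order QC → screening → sex/contamination →
haplogroups → genotyping → IBS/MDS → admixture → calibration, with stages
after screening restricted to passing samples. Gates follow the conventions
above: mitochondrial contamination requires MT depth > 5×, male X
contamination requires X depth > 0.5×. Every stage failure is caught and
recorded, leaving a partial report. Reports carry the seed and a
configuration hash, and re-running an identical configuration writes
byte-identical tables. The shell-level entry points are deliberately thin
R functions; scripts and the test suite are the interface.

## Problem sizes and limitations

The test suite and the acceptance script run at desk scale: genomes of
10⁴–10⁵ bp, panels of 5,000–10,000 SNPs, 50–150 simulated samples or
replicates per property, minutes of total compute. What passing tests show is
that each estimator recovers the generator's truth under the generator's
assumptions at these scales — binomial read sampling, uniform fragment
starts, a single divergent contaminant, site-independent drift. What they do
not show: robustness to alignment artefacts (reads arrive aligned; gapped and
clipped alignments are rejected), reference bias, UDG-treated or
single-stranded library chemistries, indel errors, linkage disequilibrium
(sites are simulated independently; no LD pruning is implemented), selection
of K by cross-validation, or formal ancestry tests — all deliberately out of
scope. The mitochondrial mixture assumes the consensus is the endogenous
haplotype; above ~30–40 % contamination that assumption degrades and the
estimator should be read as a lower bound.
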