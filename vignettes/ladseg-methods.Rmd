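---
title: "Calling and annotating lamina-associated chromatin domains with ladseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and annotating lamina-associated chromatin domains with ladseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(ladseg.quiet = TRUE)
library(ladseg)
```

## The problem

Heterochromatin in mammalian nuclei is organized in megabase-scale
lamina-associated domains (LADs) that contact the nuclear envelope through
the lamins and the lamin B receptor, and carry the repressive histone mark
H3K9me2. ladseg implements the computational side of mapping and
interpreting that organization from spike-in controlled CUT&RUN profiling of
lamina proteins (lamin B1, LAP2β) and H3K9 methylation, together with the
image-based quantification of peripheral heterochromatin. Because the
interesting guarantees of such a pipeline — does segmentation recover the
true domains, are the overlap taxonomies exact partitions, is the enrichment
statistic computed correctly — are only checkable when the truth is known,
the package ships a synthetic-data generator as a first-class, tested
module, and every downstream stage is exercised end-to-end against planted
ground truth.

## Spike-in normalization and binned coverage

CUT&RUN yield depends on how much target-bound DNA is released, so samples
are placed on a common quantitative scale with a fixed exogenous spike-in.
The scale factor for a sample is

\[ s = C / n_\mathrm{spikein}, \]

a per-antibody constant divided by the number of properly paired spike-in
reads (`compute_scale_factor()`; constants 3,000 for H3K9me2, 7,000 for
H3K9me3, 8,000 for LAP2β/LB1). A spike-in count of zero is an error — no
pseudo-count is applied, because a sample with no spike-in signal cannot be
calibrated.

Fragments are binned into RPKM coverage (`bin_rpkm()`) by assigning each
fragment to exactly one bin through its midpoint. This is a deliberate
simplification relative to per-base coverage tools: midpoint assignment
conserves the total fragment count exactly, which gives the operation a
trivially testable contract (the binned counts always sum to M minus the
fragments landing in masked bins), and the downstream segmentation only
consumes bin-level aggregate signal at 10 kb, where the two dialects are
practically indistinguishable. RPKM uses the actual bin length, so short
final bins are not deflated. Blacklisted bins are masked invalid rather
than zeroed — zeros would be indistinguishable from real background and
would bias the background state of the HMM — and masked bins are excluded
from normalization, averaging and training alike.

## Two-state HMM segmentation

Domains are called with a hidden Markov model over the normalized 10 kb
signal. Emissions are univariate Gaussians on the signal values directly;
an optional `log2(x + 1)` transform flag exists because RPKM is
heavy-tailed, but the default mirrors a plain-Normal emission model.
Each chromosome — and each maximal run of valid bins within it — is an
independent observation sequence, so no transition is modeled across
blacklist gaps; a gap carries no adjacency information.

Training is standard Baum–Welch (`fit_hmm()`), with these numerical
choices:

* initialization: state means at a quantile spread of the data (25th/75th
  percentile for two states), all standard deviations at the sample sd,
  transition matrix diagonal 0.95, uniform initial distribution;
* convergence at an absolute log-likelihood increment below `tol = 1e-4`,
  capped at 500 iterations;
* standard deviations floored at 1e-3 of the pooled sample sd so a state
  cannot collapse onto a point mass;
* degenerate fits (a state's posterior weight vanishing) trigger a
  jittered restart, deterministic given the seed, up to 5 times;
* the log-likelihood is asserted non-decreasing at every iteration — a
  decrease beyond numerical noise stops the fit with an error rather than
  returning a silently broken model.

States are always relabeled in ascending mean order, so "state K" is the
high-signal state by construction. Model order is chosen by fitting K = 2–5
and comparing AIC = 2p − 2lnL and BIC = p·ln(n) − 2lnL with
p = K² + 2K − 1 free parameters (`select_model()`). On clean two-state
Gaussian tracks BIC reliably recovers K = 2. On negative-binomial count
data, which is what real CUT&RUN resembles, BIC often prefers K = 3 because
extra Gaussian components absorb the overdispersed tail; the two-state
model is nevertheless the one used for domain calls — its two states are
interpretable as background and contact — and the selection table is
reported alongside so that choice is visible, matching how the analysis is
normally practiced.

Decoding is Viterbi (`decode()`), with path-score ties broken toward the
lower state index for determinism. Maximal runs of non-background states
become bin-aligned intervals, clipped to chromosome ends, and invalid bins
break intervals. Replicate calls are intersected base-pair-wise and
bookended pieces merged (`consensus_domains()`), keeping only regions
supported by every replicate.

Both the forward log-likelihood and the Viterbi path are verified in the
test suite against exhaustive enumeration over all K^T hidden paths on
short sequences, and the full simulate → normalize → fit → decode →
consensus chain is required to recover planted domains at base-pair Jaccard
≥ 0.9 under the default study conditions.

## Domain taxonomy, gene classes and expression

A gene belongs to a domain when at least 90% of its gene body (the
configurable `gene_overlap_fraction`, inclusive: exactly 90% is a member)
is covered by the union of the mark's domain intervals — coverage is
against the union, not the largest single domain, so a gene spanning a
blacklist gap between two domain pieces is treated fairly. Multi-mark
membership patterns are named by a class scheme: in the naive (mES) state,
LAD = LB1 ∧ LAP2β ∧ H3K9me2, LB1+LAP2β = both lamina marks without
H3K9me2, KOD = H3K9me2 alone, non-LAD = none, and residual patterns keep
systematic mark-list names rather than being forced into a named class.
The primed (EpiLC) scheme uses only LB1 and H3K9me2, because LAP2β is not
a reliable lamina fiducial in that state. Naive→primed transitions are
labeled cLAD, cKOD, newKOD, LAD→LB1-only and constitutive non-LAD, with an
explicit "other" bucket so the labels always partition the gene universe.

Genome-level overlap accounting (`overlap_accounting()`) disjoins the
union of all mark domains and reports Mb per boolean pattern; the pattern
masses provably sum to the union.

Expression summaries use a strict TPM > 5 cut. The threshold appears in
two slightly different verbal forms in common usage ("greater than five"
vs "a minimum of five"), which conflict exactly at TPM = 5; strict `>` is
the default and a `tpm_ge` toggle switches to `>=`. Differential
expression is consumed, not estimated: a gene is up when log2FC strictly
exceeds log2(2) with adjusted p strictly below 0.05 (so a gene at exactly
twofold is unchanged). Enrichment of DEGs in a domain class is a two-sided
exact test on the 2×2 table, summing hypergeometric probabilities no
larger than the observed table's (relative tolerance 1 + 1e-12); a zero
margin returns p = 1 by convention, and sample odds ratios of 0 or ∞ are
reported as such rather than being continuity-corrected.

## Transposon-family enrichment

Per-family signal is the unweighted mean over copies of the
replicate-averaged per-copy RPKM (a length-weighted mean is available).
The enrichment statistic is the modified z-score

\[ z_i = 0.6745\,(x_i - \mathrm{median}) / \mathrm{MAD}, \]

with the MAD left unscaled — the 0.6745 consistency constant is applied
explicitly in the formula, so using R's default scaled MAD would correct
twice. A family is enriched when z strictly exceeds 2 on at least one of
the lamina/H3K9me2 marks (and/or rule). MAD = 0 (for example, all families
identical) makes every z undefined and is raised as an explicit degenerate
error, never silently divided through.

## Imaging: radial shells and envelope ratios

Nucleus images are single central z-slices with a binary mask. Radial
position is defined by the Euclidean distance transform to the mask
complement: normalized depth r = 1 − EDT/max(EDT) is 0 at the deepest
pixel and approaches 1 at the boundary, and pixel shells are
k = min(⌈r·n⌉, n) with n = 25 shells by default, shell 25 peripheral. This
depth-normalized construction was chosen over concentric scaled ellipses
because it follows irregular mask shapes and makes the profile invariant
under translation and 90° rotation (both asserted in tests). Per shell the
profile reports the fraction of total intensity, the fraction of mask
area, and the area-normalized mean — the fraction-of-total and
area-normalized views answer different questions and both are exported.
Masks thinner than one interior pixel cannot be profiled and are an error.
No background subtraction is applied; raw sums are reported.

The TEM-style quantification integrates signal in squares of 0.2 µm
(rounded to pixels, minimum 1 px) centred on nuclear-envelope and
nucleoplasm coordinates — 40 per region by default — and reports the ratio
of region means. Points can be supplied manually (as in practice) or
sampled reproducibly from depth bands (`sample_region_points()`: envelope
r > 0.9, nucleoplasm r < 0.6). A square crossing the image boundary is an
error naming the offending point, and a zero nucleoplasm mean is an error
rather than an infinite ratio.

## What the synthetic data emulates — and what it does not

`sim_params()` defaults describe the desk-scale study conditions used
throughout the tests and the acceptance script:

* genome: 2 chromosomes × 50 Mb at 10 kb bins (10,000 bins) — large enough
  for stable HMM estimates while a full pipeline run stays near a minute;
* domain structure: a first-order Markov chain over background/domain with
  stay probabilities 0.995/0.995, giving geometrically distributed domains
  with 2 Mb mean length, i.e. the kilobase-to-megabase scale of real LADs;
  KODs are drawn independently and carved out of non-LAD space, so
  H3K9me2 = LAD ∪ KOD while the lamina marks cover LADs only;
* counts: negative binomial per bin (mean 20 background / 80 domain,
  dispersion 20) — overdispersed like sequencing counts, with Poisson as
  the dispersion → ∞ limit; three replicates, Poisson spike-in counts with
  expectation 3,000 (so wild-type H3K9me2 scale factors sit near 1). The
  published analyses give no quantitative emission statistics for LAD vs
  background RPKM, so these are free generator parameters, chosen to put
  the state separation in a regime (d′ ≥ 3) where segmentation should
  succeed, and must not be read as measured values;
* genotype effects: a contact-loss factor scales domain signal *above
  background* (factor 1 = wild type, 0 = complete loss, making domain bins
  statistically indistinguishable from background);
* expression: class-dependent expressed probabilities (non-LAD 0.6,
  KOD 0.35, LAD 0.1 — free parameters reflecting that LAD genes are mostly
  silent), with a planted derepressed LAD-gene subset in the mutant DE
  table;
* TE table: ~1,200 families; a family's two mark signals share a latent
  level (correlation 0.8, since lamina-proximal families carry both marks)
  and a planted 5% subset is shifted by 10 null-MADs on both marks;
* images: elliptical masks with a peripheral ring (wild-type-like),
  interior Gaussian foci (tether-loss-like) or uniform fill, plus optional
  clipped Gaussian noise.

The generator does **not** model read-level artifacts (mappability,
duplicates, fragment-length structure), chromatin-state autocorrelation
beyond first order, partial or graded lamina association, 3-D image
stacks, or segmentation errors in the nucleus mask. Passing tests
therefore demonstrate the correctness and statistical behaviour of the
algorithms under the stated generative model, not performance on any
particular real dataset.

## Reproducibility

Every stochastic operation takes an explicit seed, and a single global
seed is expanded into per-stage substreams keyed by stage name
(`run_pipeline()`), so adding a stage does not perturb the randomness of
earlier ones. Identical (params, seed) pairs produce bit-identical
outputs; the run manifest records the config snapshot, seed and md5
digests of every output file.

## A worked miniature

```{r mini, eval = FALSE}
p <- sim_params()
truth <- simulate_genome(p, seed = 11)
cutrun <- simulate_cutrun(truth, p, mark = "H3K9me2", seed = 11)
cfg <- pipeline_config()
tracks <- lapply(cutrun$replicates, function(fs)
  normalize_track(bin_rpkm(fs, truth$genome, cfg$bin_size),
                  compute_scale_factor("H3K9me2", fs$n_spikein, cfg)))
model <- fit_hmm(do.call(c, lapply(tracks, track_sequences)), K = 2, seed = 1)
cons <- consensus_domains(lapply(tracks, function(t)
  decode(model, t, mark = "H3K9me2")))
cons
```

The numbered scripts under `analysis/` run exactly this workflow —
simulation, normalization, segmentation, annotation, TE scoring and
imaging — writing their tables under `results/`, and
`scripts/acceptance.R` recomputes the headline quantities from scratch
into a JSON report.

## Known limitations

* The HMM assumes Gaussian emissions; on strongly skewed tracks the
  log-transform flag should be preferred, and model selection on
  overdispersed data will rank K > 2 higher even when two biological
  states exist.
* Consensus by strict all-replicate intersection is conservative: one
  noisy replicate can erode domain edges. No minimum-domain-length filter
  is applied by default (a configurable post-filter exists).
* Midpoint binning differs at the margins from per-base coverage tools;
  bin-level agreement is excellent at 10 kb but single-fragment placements
  at bin boundaries differ by construction.
* The imaging module is strictly 2-D, single-nucleus, mask-supplied;
  it does not segment nuclei or handle stacks.
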