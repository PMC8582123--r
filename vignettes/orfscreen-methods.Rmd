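---
title: "Methods: from probe intensities to an ORF similarity map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from probe intensities to an ORF similarity map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfscreen)
```

## The experiment this package models

A functional overexpression screen transduces a cell line with one ORF at a
time (typically in triplicate), lets stable cultures form, and profiles each
culture's transcriptome on microarrays. Empty-vector transductions define
the null condition. Two platforms may be used — a targeted exon-level array
with up to ~8 probes per gene and a genome-wide bead array with 1–3 — and
processing happens in batches, so the analysis must deal with probe-level
noise, platform heterogeneity and batch structure before it can ask the
scientific question: *which ORFs change which genes, and which ORFs act
alike?*

## Preprocessing

All analysis happens on the log2 scale.

* **Background correction** (`normexp_background_correct`, raw scale): the
  observed intensity is modeled as exponential signal plus Gaussian
  background; the corrected value is E[signal | observed], which is strictly
  positive and monotone in the observation. Parameters come from
  negative-control probes (method of moments) when available, otherwise
  from a per-sample maximum-likelihood fit (`limma::normexp.fit`). A
  zero-variance sample cannot support the fit; the fallback subtracts the
  per-sample minimum plus 0.5 and warns.
* **Between-sample normalization**: cyclic loess
  (`cyclic_loess_normalize`; span 0.7, 3 iterations by default — common
  loess defaults, exposed in `screen_config`) removes intensity-dependent
  differences; the all-pairs variant is the textbook algorithm and the
  "fast" variant (each sample against the mean array) is used by the
  fitted pipeline because it scales linearly in samples. For bead-array
  style raw data, `quantile_normalize_with_offset` forces a common
  distribution and applies log2(x + 16); the offset damps near-background
  variance. One caveat worth knowing: loess spans resolve distortions
  whose wavelength is comparable to the span, so a very wiggly
  intensity-dependent artifact needs a smaller span than the default.
* **Batch adjustment** (`combat_adjust`): the standard location/scale
  empirical-Bayes model — probe-wise standardization, per-batch mean and
  variance estimates shrunk toward normal / inverse-gamma priors with
  method-of-moments hyperparameters, then removed. With
  `parametric_eb = FALSE` the observed per-batch location and scale are
  removed exactly (useful as a closed-form check). When an experiment was
  run in parts, each split into batches, the `part` argument combines
  batches within each part first and then combines the parts. Only *known*
  batches are adjusted; surrogate-variable style correction of unknown
  artifacts is deliberately out of scope (a published method orthogonal to
  this pipeline), and the same argument accepts externally estimated
  nuisance groupings if the user has them. Note that batch adjustment can
  only remove the *systematic* component of a shift: per-probe batch means
  retain their within-batch sampling noise, which is irreducible.
* **Detection flooring** (`truncate_translate`): log2 intensities are
  truncated at a per-platform floor and translated down by the same
  amount, so everything at or below the floor becomes exactly 0. Both
  floors are interpreted on the log2 scale (defaults used throughout the
  package: 8.0 for the exon-array-like platform, 3.5 for the bead-array
  platform, i.e. raw 2^3.5) — the HIT statistic operates on log2 data and
  only log2-scale floors make two platforms commensurate. A probe is
  "detected" iff its floored baseline (median over samples) is > 0; this
  gives the otherwise vague notion of a detection threshold a concrete,
  testable definition. Flooring an already-floored matrix is a no-op, so
  the operation is idempotent.
* **Collapse** (`collapse_duplicates`): duplicated probe ids are combined
  by the arithmetic mean of log2 values (geometric mean of intensities);
  probes annotated `bad`/`no_match` are removed; re-run QC samples flagged
  `is_repeat` are dropped rather than averaged (the conservative reading
  when provenance of a re-run is unclear).

## The HIT statistic

Each ORF perturbs few genes, so the whole screen is its own null
reference. Per probe: baseline *b* = median log2 over **all** samples, and
scale = MAD over all samples. Per ORF and probe:

$$Z = (\bar{x} - b)\frac{\sqrt{n}}{\mathrm{MAD}}$$

with \(\bar{x}\) the replicate mean and \(n\) the replicate count (3 for
most ORFs; ORFs retained with \(n = 2\) simply use \(\sqrt{2}\)). A probe
is a HIT iff \(|\bar{x} - b| > 1\) (fold effect > 2) **and** \(|Z| > 4\);
a gene is a HIT iff at least one of its probes on either platform is. The
double threshold means a precise but small shift never qualifies, nor does
a large but noisy one.

Design points that were genuinely open:

* The baseline includes the tested ORF's own samples. With dozens of
  conditions the self-contribution to a median over all samples is
  negligible, and using one common baseline keeps every condition —
  including the empty vector — scored identically. (The median is robust
  up to 50% contamination, so even a signature shared by six ORFs, 18 of
  ~100 samples, leaves baseline and MAD essentially untouched.)
* The MAD is plain (no 1.4826 consistency factor) by default:
  `mad_scaled = TRUE` exposes the scaled variant, which simply rescales Z
  by 1/1.4826 and would call fewer probes at the same threshold.
* Probes with MAD = 0 (typically floored-flat probes) have no defined Z;
  they are flagged degenerate and their call falls back to the deviation
  criterion alone. Undetected probes are never HITs.
* Gene direction is the sign of the hit probe with the largest
  |deviation|; conflicting probe directions are resolved the same way and
  reported. Both gene-level and probe-level hit counts are emitted, since
  the two conventions genuinely differ.

**False-positive rate.** `estimate_false_positive_hits` repeatedly
partitions the empty-vector samples into disjoint groups of 3, scores each
group as a pseudo-ORF, and counts gene HITs — a fresh random partition per
resample, fully seeded. Under the package's default noise conditions the
mean count is far below one gene per pseudo-ORF (the replicate-mean noise
would have to exceed a full 2-fold deviation *and* 4 MADs).

## Effect matrix and similarity

The probe set for effect estimation is the union of probes flagged HIT in
*any* condition. Per gene and ORF the effect is the mean log2 deviation of
those probes (geometric mean of fold effects), pooled across platforms
with equal weight per probe — the simplest faithful reading of
"probes were averaged"; a per-platform-average-then-average variant is
exposed (`per_platform_average`). Every ORF keeps a column, including ORFs
(and the empty vector) for which a gene was not a HIT: those entries are
the small estimated effects that similarity scoring needs.

The similarity of source \(s\) to reference \(r\) over the reference's HIT
genes \(H(r)\) is

$$\mathrm{score}(s, r) = \frac{\sum_{g \in H(r)} e_s(g)\, e_r(g)}
                              {\sum_{g \in H(r)} e_r(g)^2}.$$

The denominator is the unique scaling that makes every reference score
exactly 1 on itself, which is the defining property of the score; it is
linear in the source, asymmetric (only the reference's HIT list enters),
and negative when the source opposes the reference's program. Only ORFs
with ≥ 20 gene HITs serve as references (enough genes for the projection
to be meaningful); any ORF may be a source. Directed edges keep positive
scores strictly above 0.6.

## Embedding

The reference ORFs' effect vectors are embedded in 2-D with t-SNE. The
package implements exact t-SNE (perplexity-calibrated Gaussian
neighborhoods via per-point binary search; Student-t low-dimensional
kernel; early exaggeration, momentum and adaptive gains): reference sets
in this kind of screen are tens of ORFs, where the exact \(O(n^2)\)
algorithm is both appropriate and fast, and implementing it in-package
keeps the averaging scheme fully reproducible. Because t-SNE solutions
differ between initializations, 30 independent runs are averaged and the
average initializes a final refinement run. Averaging raw runs would
cancel structure — each run is an arbitrary rotation/reflection of the
others — so runs 2..k are first Procrustes-aligned (rotation, reflection,
scale; `vegan::procrustes`) to run 1. Perplexity must stay below
(n − 1)/3; the dataset-scale default is 10, and analyses of the 12
reference ORFs of the packaged fixture use 3 for the same reason.

## Enrichment and validation statistics

HIT lists are tested for gene-set over-representation with the upper-tail
hypergeometric probability, Benjamini–Hochberg adjusted (within a call,
and jointly across ORFs in `enrich_hit_lists`) — a transparent, fully
reproducible stand-in for web-service profilers whose databases and
correction schemes move over time. The universe is the set of genes
detected in the screen (floored baseline > 0), per standard
over-representation practice.

The validation-figure statistics: `exact_separation_pvalue(n_a, n_b)` =
\(2/\binom{n_a+n_b}{n_a}\), the exact two-sided p-value when two groups
separate completely (0.1 for two triplets — the strongest evidence three
datapoints per condition can give); `interval_coverage(n)` =
\(P(|T_{n-1}| \le 1)\), the coverage of geometric-mean ± SEM intervals for
the median under a lognormal model (57.7% ≈ 58% at n = 3, approaching 68.3%
for large n); and `qpcr_normalize`, which references each sample to an
endogenous control gene and removes plate (and optionally cell-line)
effects by mean-centering per gene — median-centering via `robust_plate`
is left to the caller's judgment of when between-condition variation is
large, since no principled cutoff exists.

## The synthetic screen generator

`simulate_screen` draws, per platform, probes per gene uniformly from a
platform-specific range (1–8 exon-array-like, 1–3 bead-array-like),
per-probe baselines around gene-level means, and sample values

$$x = \beta_p + e(g, o) + \mu_b + \sigma_b\,\varepsilon,
  \qquad \varepsilon \sim N(0, \mathrm{noise\_sd}^2)$$

— Gaussian noise on the log2 scale (the lognormal working hypothesis that
also motivates the MAD-based statistic) and additive/multiplicative batch
structure, exactly the model the batch-adjustment stage assumes. Ground
truth (every planted (ORF, gene) effect) is returned and written alongside
the data, enabling recall/specificity assertions.

`default_fixture()` is the package's reference condition set, chosen once
as a realistic desk-scale screen: 300 genes; 30 ORFs — two clusters of 6
sharing signatures of 40 and 30 genes (|log2| effects 2–3) plus 5 private
effect genes each, and 18 null ORFs, two of them with n = 2 to exercise
the \(\sqrt{2}\) path; triplicates otherwise; 12 empty vectors; 3 batches
with shifts −0.5/0/+0.5 log2 and noise scales 0.95/1/1.05; replicate noise
sd 0.25 log2 (on the heavier side of what well-run arrays show). Baselines
are N(10, 1.5) with planted-effect genes drawn between floor + 3.5 and
floor + 6 — planted effects sit on well-expressed genes, as real HITs do,
so flooring does not silently truncate them.

What the generator does *not* emulate: probe cross-hybridization, spatial
array artifacts, intensity-dependent variance beyond the floor, sample
identity mix-ups, or the manual QC that real screens need. Passing tests
on the fixture therefore demonstrate the statistical machinery — recall of
planted effects, null behavior of the thresholds, cluster recovery — not
robustness to every failure mode of physical arrays.

## Numerical choices and problem sizes

* Ties and degenerate inputs: medians/MADs use standard midpoint
  conventions; MAD = 0 probes are flagged rather than producing infinite
  Z; zero-variance probes pass through batch adjustment unchanged; a
  single batch, a single sample, or an already-floored matrix are handled
  as identities (with warnings where surprising).
* EB shrinkage solves the usual coupled posterior equations iteratively
  (relative tolerance 1e-4, as in common implementations).
* All randomness flows from explicit seeds; a run seed fans out to fixed
  per-stage child seeds so stages re-run alone reproduce the full-run
  results.
* Test and acceptance workloads are sized for a laptop-class single CPU:
  the 30-ORF fixture (~1,950 probes × 100 samples per platform), 500
  empty-vector resamples, 10^6 Monte-Carlo triplets, and 5 embedding
  seeds × 30 t-SNE runs all together run in about a minute.

## Known limitations

* The HIT criterion is a fixed double threshold, not a p-value; no
  per-probe multiple-testing correction is attempted (by design — the
  empty-vector resampling quantifies the realized false-positive rate
  instead).
* Gene-level merging ignores isoform structure: exon-level probes of one
  gene are averaged even if they track different transcripts.
* Known batches only; unknown systematic artifacts need external surrogate
  variables.
* The similarity score is linear in the source, so a source whose effects
  are a scaled-up copy of the reference scores above 1; interpretation
  should focus on comparisons against the self-score of 1.
* The t-SNE map, as always, preserves neighborhoods rather than global
  distances; the directed score network, not the map, carries the
  quantitative similarity.
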