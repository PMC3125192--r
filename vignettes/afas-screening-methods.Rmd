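---
title: "Antisense screening with artificial antisense tiling probes: models and methods"
author: "afasScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antisense screening methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afasScreen)
```

## The problem

Most catalogues of natural antisense transcripts (cis-NATs) are built by
mapping cDNA sequences, which requires a poly(A) tail for oligo-dT-primed
library construction. A large share of antisense RNAs lack poly(A) tails and
are invisible to that approach. The strategy implemented here sidesteps cDNA
evidence entirely: for each well-annotated (typically cancer-related) gene,
60-mer *artificial antisense* (AFAS) probes are tiled every 500 bases along
the antisense strand of the spliced exonic sequence. Hybridizing such an
array with targets labelled by **both** oligo-dT and random priming turns the
priming contrast into a poly(A)-status assay: transcripts seen under random
priming but not under oligo-dT are inferred poly(A)−.

On top of detection, the package screens **expression-balance reversals**
between paired tumour and adjacent normal tissue: loci where the dominant
strand flips between the two tissue states, a pattern reported for regulatory
antisense RNAs such as the p15/p15AS pair in leukemia.

## Data model and design

An `expression_matrix` holds a probes × samples intensity matrix plus sample
metadata (`patient_id`, `tissue` ∈ {normal, cancer}, `priming` ∈
{oligo_dT, random}). The canonical design is 6 patients × 2 tissues × 2
priming methods = 24 arrays; a design is *complete* when every patient has
all four combinations. A `probe_annotation` table links every AFAS probe to
its gene's single sense probe; every AFAS probe of a gene pairs with that
sense probe (multi-probe genes yield several pairs).

## Probe design

`tile_afas_probes()` places one fixed-length probe at the start of every
`tile_step` window of the spliced transcript, as long as a full probe fits
(`L - w >= probe_length`); terminal partial windows keep their probe, genes
shorter than one probe are excluded with a report. The emitted sequence is
the reverse complement of the sense mRNA window (the antisense-strand 60-mer
5'→3'). Windows crossing an exon–exon junction map to more than one genomic
block and are flagged **truncated**; such probes would hybridize only partly
to an unspliced antisense transcript, so they are excluded from
detection-fraction summaries (but retained in output). Where the original
platform delegated within-window placement to vendor tools, this
implementation uses deterministic start-of-window placement (`--placement
center` is available); placement does not affect any downstream statistic.
Windows containing `N` are emitted with a `has_ambiguity` flag rather than
dropped, so probe counts stay a function of gene length alone. Coordinates
are 0-based half-open internally; GFF3 input is converted on read.

## Normalization and detection

`global_mean_scale()` multiplies each array by `mean(reference)/mean(array)`.
The original study scaled to an external brain-tissue reference array; that
array is not available offline, so the reference defaults to the first
oligo-dT normal sample and is a parameter. One consequence matters and is
deliberate: **detection-fraction comparisons between priming methods are made
on unnormalized data**. Oligo-dT arrays have genuinely lower global signal
(most antisense signal is absent there); forcing all arrays to a common mean
would inflate oligo-dT arrays and erase the very contrast under study.
Screens, in contrast, compare within one priming method and operate on
normalized data.

A probe is *detected* when its intensity is at or above the conservative
threshold of 100 (inclusive). Probe-level summaries score the **median
across patients** for one (tissue, priming) group — with 6 patients the
median is the mean of the 3rd and 4th order statistics — and a gene is
antisense-positive when any non-truncated AFAS probe passes on its median.
A `per_sample = TRUE` variant averages per-array fractions instead, since
published percentage tables do not state which convention was used; both are
provided, the median reading is the default because the gene-level rule is
stated in terms of "median expression level".

## Screens

All ratios floor numerator and denominator at `intensity_floor` (default 1)
so they stay finite. With margin `m` (default 0.10), patient `p` supports a
sense-up/antisense-down **balance reversal** when all four hold:

1. `sense_cancer >= (1+m) * afas_cancer` — sense dominant in cancer;
2. `afas_normal >= (1+m) * sense_normal` — balance reversed in normal;
3. `sense_cancer >= (1+m) * sense_normal` — sense up in cancer;
4. `afas_normal >= (1+m) * afas_cancer` — antisense down in cancer.

A pair is reported with support ≥ `min_support` (default 3 of 6) patients;
the opposite direction swaps the two transcripts' roles. Raising the margin
can only shrink the result set, giving the characteristic cascade of counts
at 10/20/30%. Design choices worth stating:

* "at least 10%" is **multiplicative and inclusive**; because `1.1` is not
  representable in binary floating point, the comparison is implemented as
  `x >= (1+m) * y * (1 - 1e-9)` so an exactly-10% difference passes.
* Conditions 1–2 carry the same margin as 3–4 (the screen's one-parameter
  reading); a per-call `margin` override preserves the alternative.
* "more than twofold" in the fold-change screen is **strict** (`ratio > 2`
  or `< 0.5`); antisense dominance ("three times") is **inclusive** in both
  tissues.
* A pair supported in both directions (possible only in degenerate data) is
  reported twice with a `conflict` flag.
* The change-only (`cdna_pair_screen`) preset applies conditions 3–4 alone in
  both directions, the rule used for cDNA-identified sense–antisense pairs.
* Ties (ratio exactly 1 after flooring) are excluded from the
  concerted-change count; its expectation is
  `N * (p_up^S * p_up^A + p_down^S * p_down^A)` from the marginal direction
  frequencies, compared via a chi-square goodness of fit. This treats pairs
  and patients as independent — a rough approximation, as the original
  analysis itself notes.

Three priming modes feed the pair screens: `random` (default; antisense
transcripts are best seen under random priming), `dt`, and `mixed`
(sense from oligo-dT, antisense from random priming).

## Permutation null

The "random shuffling test" is under-specified in the source; the
implementation chooses a scheme that preserves every probe's value multiset
and the patient pairing while destroying exactly the cancer/normal signal:
per probe row and per patient, the normal/cancer labels are re-assigned
uniformly at random (a fair coin swap), coherently across the two priming
methods. The screen count is recomputed per shuffle; the result reports the
null mean, the population SD, and an empirical p with +1 smoothing
(`(1 + #{count >= observed}) / (n_shuffles + 1)`). An alternative null
(`pair_partners`) permutes the antisense probes' gene assignments instead.
Default 1000 shuffles; the seed is mandatory in reports. Because the
published analysis's shuffling unit and shuffle count are unknown, its
expected counts (e.g. 50.14 ± 6.13) are not reproduced here numerically.

Statistical kernels are implemented directly: chi-square goodness of fit
(`sum((O-E)^2/E)`, k−1 df), and a two-sided Mann–Whitney U with exact
enumeration of rank assignments for small samples (tie-safe) and a
tie-corrected, continuity-corrected normal approximation otherwise.

## Clustering and display

`build_ratio_matrix()` forms `log2(max(sense, floor)/max(afas, floor))` per
pair and (patient, tissue) column, normals before cancers. Clustering is
agglomerative with explicit determinism: the minimal-distance pair is merged,
ties broken toward the smaller original row index, with average (default),
complete or single linkage via the Lance–Williams recurrences. The default
distance is correlation (1 − Pearson), which clusters ratio *patterns*;
constant rows get the maximal correlation distance 1 with a warning.
`stats::hclust` is deliberately not used for the computation (its tie
behaviour is input-order dependent) but serves as a test oracle on tie-free
data. Heat maps saturate at |log2 ratio| = log2 3 — full green at
threefold-or-more sense excess, full red at threefold-or-more antisense
excess — and the clip affects display copies only. The dendrogram is
exported as Newick with internal nodes at their merge heights (branch length
= parent height − child height), so the tree re-parses to the same heights.
Rows only are clustered; the column order is fixed by the design.

## The synthetic world

`simulate_dataset()` generates the statistical structure the analysis
assumes, with ground truth, so the whole pipeline is testable offline:

* **Design**: 6 patients × 2 tissues × 2 primings; 501 genes (the platform
  scale) with one sense probe and uniform 1–12 AFAS probes each. (The real
  platform averaged ~4.7 AFAS probes/gene; the uniform 1–12 default covers
  that range.)
* **Intensities**: log-normal base levels (`meanlog = log 200`, `sdlog =
  1.5`) for expressed probes; background log-normal (`log 30`, 0.7) for
  silent ones; per-array scale factor (sd 0.1 on the log scale — what global
  mean scaling removes; modelled per array, not per patient, since a factor
  shared by all of a patient's arrays would cancel out of every screen); and
  multiplicative measurement noise with `noise_cv = 0.2`. These defaults
  give ≈ 68% sense detection and ≈ 30%/8% AFAS detection under
  random/oligo-dT priming, the qualitative pattern of the real platform.
* **Poly(A) status**: 40% of AFAS probes are expressed at all; 90% of those
  are poly(A)−, visible under oligo-dT only through a 5% leak
  (`dt_leak`). Sense transcripts are priming-neutral.
* **Planted reversals** are gene-level events: an antisense transcript
  spanning the gene flips balance with its sense partner, so *every* AFAS
  probe of a planted gene is a planted pair (multi-probe concordance is a
  feature of real data). Genes are drawn until the target fraction of pairs
  (default 5%) is covered. The planted fold `f` (default 3) is split
  symmetrically: in the sense-up direction the sense means are `B/sqrt(f)`
  (normal) and `B*sqrt(f)` (cancer) and the antisense means are the mirror
  image. This realizes the prescribed per-transcript fold *and* the
  dominance reversal; applying the fold from a common baseline would leave
  the normal-tissue balance un-reversed and no screen could recover it.

What a green test does **not** establish: the generator has independent
noise across probes and patients (no correlation structure, no
intensity-dependent variance, no spatial artefacts, no cross-hybridization),
planted effects are homogeneous in fold, and background is priming-neutral.
Recovery and calibration results transfer to real arrays only qualitatively.

## Calibration of the null (what the tests check)

On signal-free data (no planted pairs, no tissue effect) the observed screen
count must sit inside the shuffle null. The calibration world for this test
uses a narrower baseline spread (`sdlog` 0.5), higher noise (`cv` 0.6), all
antisense probes expressed and no poly(A) effect — chosen once so null
counts are non-degenerate (fold-change screen null ≈ 9 ± 2.6 on ~160 probes)
rather than pinned at zero, where coverage would be vacuous. Coverage is
`observed` within `null_mean ± 3·null_sd` in ≥ 95 of 100 seeded replicates.
Uniformity of the empirical p is checked on a *randomized* PIT
(`(#{>obs} + U·(1 + #{=obs}))/(n+1)`, `U ~ Unif(0,1)`), which is exactly
uniform under exchangeability despite the discreteness of counts; the
reported p keeps the conservative +1 smoothing.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `detection_threshold` | 100 | inclusive intensity cut-off for "expressed" |
| `fold_change` | 2 | strict cancer/normal change cut-off |
| `dominance_fold` | 3 | inclusive antisense/sense dominance cut-off |
| `margin` | 0.10 | "at least 10%" relative margin of the balance screen |
| `min_support` | 3 | patients that must support a pair |
| `n_patients` | 6 | paired patients in the design |
| `tile_step` / `probe_length` | 500 / 60 | bases; tiling geometry |
| `intensity_floor` | 1.0 | pseudocount for all ratios |
| `n_shuffles` | 1000 | permutation null size |

## Known limitations

* Headline counts of the original study are not reproduced numerically: they
  require the deposited microarray series and depend on interpretation
  choices (shuffling unit, margin strictness) the source does not state.
* GEO SOFT parsing, vendor detection flags, probe placement optimization,
  cross-hybridization screening and GO enrichment are out of scope.
* No multiple-testing correction is applied, matching the original analysis;
  the permutation null is the calibration instrument.
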