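---
title: "Post-identification immunopeptidomics: models, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-identification immunopeptidomics: models, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Scope

`immunopepR` implements the computational work that follows database search in
an HLA immunopeptidomics experiment: deciding which identified peptides are
proteolytic degradation artifacts rather than HLA ligands, validating
identifications (including neoepitopes) against isotope-labelled synthetic
peptide spectra, assembling benign reference peptidomes, and profiling
tumor cohorts for tumor-exclusive peptides and their presentation
frequencies. Everything upstream — acquisition, chromatography, search-engine
scoring and decoy FDR — is out of scope; the package consumes peptide
identification tables, FASTA proteomes and MGF peak lists.

Because real deposited datasets and external predictors are not required, the
package ships seeded generators that emulate the statistical structure of
immunopeptidome cohorts with full ground-truth bookkeeping; all tests and the
acceptance analyses run against that ground truth.

# Peptide identity

All set comparisons use one identity convention: the modification-stripped
uppercase sequence (`canonical_sequence()`). Leucine and isoleucine are
isobaric and indistinguishable by standard fragmentation, so an opt-in
`il_collapse` flag maps every I to L before comparison. The flag defaults to
off — sequences are compared as searched — because collapsing is a lossy
choice the analyst should make explicitly; cohorts and benign references
record which convention they use and refuse to be mixed.

Positions are 1-based inclusive throughout, matching the
`PROTEIN_START-END` notation used in mutation identifiers such as
`SFPQ_HUMAN_304-313_ I308V`.

# Proteolytic-artifact classification

Degradation by endogenous peptidases produces nested, overlapping "ladders"
of fragments, concentrated on a few proteins, that need not fit any of the
sample's HLA binding motifs. The classifier turns this phenomenology into
three per-peptide scores, all oriented so that larger = more artifact-like:

* **protein coverage ratio** `s_prot`: for each source protein, the fraction
  of its residues covered by the union of all identified peptides mapping to
  it; the peptide takes the maximum over its source proteins. Exhaustively
  degraded proteins are covered far above the sparse coverage that antigen
  presentation produces.
* **peptide coverage ratio** `s_pep`: the fraction of the peptide's own
  residues (at its best placement) also covered by at least one *other*
  identified peptide. Ladder members are mutually overlapping, so this
  approaches 1; a lone ligand scores 0.
* **non-ligand propensity** `s_hla`: one minus the best ligand-likeness over
  the sample's allotypes under a pluggable predictor. The built-in predictor
  scores a peptide against per-allotype position weight matrices (anchor
  positions 2 and 9 of a 9-residue core, mild secondary preferences
  elsewhere); peptides of other lengths map their four terminal residues to
  the core flanks and the middle to the central column. Externally computed
  predictions can be substituted through `table_predictor()` without touching
  any consumer.

Only the names of the three scores are fixed by the methodology this package
follows; the formulas above are this package's committed interpretations,
each isolated behind its own operation so an alternative definition can be
swapped in.

For each score the per-sample score population is deconvolved into two
Gaussian components by expectation-maximization (`fit_gaussian_mixture()`),
the lower-mean component read as the ligand-like null and the upper as
artifact-like. The cutoff is the smallest `t` with model FDR

$$\mathrm{FDR}(t) = \frac{w_0 S_0(t)}{w_0 S_0(t) + w_1 S_1(t)} \le \alpha,
\qquad \alpha = 0.05,$$

where $S_k$ are Gaussian upper-tail survival functions (`fdr_threshold()`,
solved by bisection in log space). A peptide is called proteolytic when it
strictly exceeds at least two of the three thresholds — the two-of-three rule
makes the call robust to any single noisy score.

Numerical choices:

* EM is initialized by a deterministic median split with moment matching, so
  fits are reproducible without a seed; optional seeded random restarts guard
  against local optima, and a regression test checks the deterministic fit
  attains the likelihood an independent fitter (mclust) reaches.
* Component variances are floored at `1e-6`. A fit is flagged collapsed
  (`converged = FALSE`) only when *both* components degenerate (e.g. all
  values identical). One pinned component is deliberately allowed: `s_pep` is
  zero-inflated (most ligands have no overlapping neighbour), and a spike
  null plus a spread signal component is the correct deconvolution of such a
  score. Flooring one component and discarding the fit instead would silently
  disable the score.
* "Exceeds" is strict (`>`): a peptide sitting exactly on a threshold is not
  called. Thresholds are fitted per sample by default (matching per-sample
  artifact percentages); cohort pooling is available by flag.

# Spectral validation

Fragment ions are computed as singly charged b/y series
(`b_i = \sum_{1..i} m + p`, `y_j = \sum_{n-j+1..n} m + w + p` with proton
`p = 1.007276` Da and water `w = 18.010565` Da); complementary pairs satisfy
`b_i + y_{n-i} = M + 2p` exactly. A heavy-isotope label adds its delta mass
to every ion whose span contains the labelled residue.

`spectral_correlation()` matches theoretical ions against both spectra —
labels applied only on the synthetic side — within
`min(20 ppm, 0.02 Da)`, pairs intensities by ion identity, and reports the
Pearson `r` and `R² = r²`. Choices the upstream convention leaves open, made
explicit here:

* only ions matched in **both** spectra enter the statistic (intersection,
  not zero-filled union — zero-filling inflates `r` when many ions are
  absent); a `pairing = "union"` switch exposes the alternative;
* raw intensities, no log or rank transform (switchable);
* only b/y ions enter `R²`; internal ions are display-only and not modelled;
* fragment-to-peak ties break toward the lower-m/z peak;
* fewer than two shared ions yields an undefined-result flag, never a crash.

Neoepitope windows are cut from the protein with `extract_neoepitope()` after
checking the reference residue, so a transcript/proteome mismatch surfaces as
an error rather than a silently wrong peptide.

# Benign references and comparative profiling

A benign reference is the union of canonicalized identities from any number
of datasets after per-dataset filter rules (binder-strength whitelists,
metadata equality filters), with per-peptide provenance retained. Exclusion
is sequence-level only; HLA restriction enters solely through
allotype-restricted frequency denominators. A sample is positive for a
peptide if *any* technical replicate contains it. Cohort-wide frequency is
positives over cohort size; allotype-restricted frequency divides by the
number of samples carrying that allotype. The display filter retains
peptides at exactly the 5% boundary (only strictly-below is dropped), and the
broad-presentation threshold (default 20%) is strict in the other direction.

# The synthetic-data generator

The generator emulates, per seed and byte-reproducibly:

* a background proteome (i.i.d. residues from a vertebrate-like composition);
* motif-consistent ligands: windows are planted into the proteome by
  overwriting them with PWM draws, so every ligand is an exact proteome
  substring; class I lengths are drawn at weights 8:0.10, **9:0.70**,
  10:0.14, 11:0.06 (the canonical 9-mer-dominated class I distribution);
* proteolytic ladders: at least 4 overlapping fragments with start steps of
  at most 3 residues inside hotspot windows, all of a sample's ladders
  degrading one short protein (~5% of sample peptides by default);
* technical replicates: each assigned peptide is detected per replicate with
  probability `p_detect = 0.8`, conditioned on at least one detection so the
  sample union equals the assigned set (three replicates by default);
* cohorts: a shared housekeeping pool (every member forced into at least one
  benign sample) plus planted tumor-exclusive peptides placed in *exactly*
  `round(f·n)` eligible tumor samples — exact-count planting, so profiling
  recovery is testable with zero error; a Bernoulli mode is not used for
  acceptance because it conflates set-logic bugs with sampling noise.
  Default plants span the display (0.05) and broad (0.20) boundaries, with
  two allotype-restricted plants;
* spectrum pairs: shared log-normal fragment intensities, per-spectrum
  multiplicative noise, Poisson-count random noise peaks, and the label shift
  (+6.02013 Da, a ¹³C₆ residue) on the synthetic side.

What it does **not** emulate: instrument physics (ion mobility, retention
time, CCS), chromatographic co-elution, search-engine score distributions,
real motif complexity (only anchor-plus-secondary PWMs), shared peptides
between unrelated proteins, or inter-sample batch effects. Passing tests
therefore demonstrate the correctness of the statistical machinery under a
controlled model of the data, not performance on any real dataset: headline
percentages from real cohorts (artifact rates, exclusivity fractions, GRAVY
medians) depend on deposited raw data and external predictors and are
deliberately not reproduced here.

# Problem sizes and defaults

The simulated study uses 400 proteins of 300–600 residues, 380 ligands per
sample, 10 proteolysis samples, 10 benign and 20 tumor profiling samples, and
8 planted exclusives — large enough for the mixture fits to be stable
(hundreds of points per score) and small enough that the full pipeline runs
in seconds. Key tunables, with defaults:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | per-score mixture-model FDR level |
| `tol_ppm` / `tol_da` | 20 / 0.02 | fragment matching tolerance (min of both) |
| `min_f` | 0.05 | display filter, boundary retained |
| `broad_f` | 0.20 | broad-presentation threshold, strict |
| `p_detect` | 0.8 | per-replicate detection probability |
| `artifact_fraction` | 0.05 | planted ladder share of a sample |
| `il_collapse` | off | I/L-collapsed identity comparison |

# Known limitations

* The three proteolysis scores are interpretations of named scores whose
  reference formulas live outside this package; alternates may shift
  per-sample percentages.
* The spike-null reading of zero-inflated scores assumes the point mass is
  the null; a dataset whose artifacts also score exactly zero would defeat it.
* PWM scoring is length-tolerant but crude for class II, where the binding
  core can sit anywhere in a long peptide; the predictor interface is the
  intended extension point.
* Population coverage assumes Hardy-Weinberg equilibrium and independent
  loci, the standard assumption of coverage calculators; linkage
  disequilibrium between HLA loci violates it in real populations.

# Reproducing the analyses

The numbered drivers under `analysis/` run each stage on the simulated study
and print what they find; `scripts/acceptance.R --seed <s> --out <path>`
recomputes every headline quantity from scratch. For example:

```{r, eval = FALSE}
library(immunopepR)
summary <- run_pipeline(generator_config(seed = 1), out_dir = "results/pipeline")
```

Rerunning with the same seed reproduces every output byte for byte; the
summary carries the package version and a hash of the full configuration.
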