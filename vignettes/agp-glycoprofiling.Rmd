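---
title: "Site-specific AGP N-glycosylation profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-specific AGP N-glycosylation profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agpglyco)
```

## The measurement problem

Alpha-1-acid glycoprotein (AGP, orosomucoid) is an acute-phase plasma
glycoprotein carrying five N-linked complex glycans (canonically numbered
Asn-33, -56, -72, -93 and -103 in UniProt precursor coordinates). It is
encoded twice — AGP1, with the close genetic variants F1, F2 and S, and AGP2
— and the variants differ in a handful of residues (F1: Gln-38/Val-174, F2:
Gln-38/Met-174, S: Arg-38/Val-174). After tryptic digestion, the five sites
across these protein forms produce **eight** distinct sequon-bearing
glycopeptides, because variant residues fall inside or adjacent to the
site-bearing peptides. `agpglyco` implements the full computational path from
raw LC-MS1 data of such digests to per-site glycoform fractions, derived
glycosylation traits, and cohort-level statistics.

## The glycopeptide analyte library

`enumerate_glycopeptide_groups()` digests each protein form in silico
(Trypsin/P dialect: cleavage after every Lys/Arg, including before proline,
mirroring the common search-engine setting), locates the tryptic peptide
covering each declared site, and collapses identical peptides across forms.
Groups are named by site roman numeral plus a subscript for the carrying
protein(s): `I_1`, `I_12`, `II_12`, `III_12`, `IV_1`, `IV_2`, `V_1`, `V_2`
(underscored plain text for file-format safety).

Two genuinely open mapping choices are resolved as follows and documented
here rather than guessed silently:

* **Site I subscripts.** The AGP1*S variant (Arg-38) truncates the site-I
  peptide to `QIPLCANLVPVPITNATLDR`; the Gln-38 forms share the longer
  `QIPLCANLVPVPITNATLDQITGK`. The library assigns the S-specific peptide to
  `I_1` and the shared peptide to `I_12`, which requires Gln at position 38
  in AGP2 — the convention adopted by the bundled FASTA.
* **AGP2 backbone.** The bundled AGP2 entry is flagged as a synthetic
  reconstruction: the five glycopeptide regions match the reported AGP2
  tryptic glycopeptides (verified against their monoisotopic masses), while
  the backbone outside those regions follows AGP1. Only the glycopeptide
  regions matter for any computation in this package.

The site-IV peptides from AGP1 (`QDQCIYNTTYLNVQR`, 1914.889 Da with
carbamidomethyl-Cys) and AGP2 (`QNQCFYNSSYLNVQR`, 1919.858 Da) differ at four
of fifteen residues but by only ~5 Da in mass, so the heavier peptide's
monoisotopic peak falls onto the sixth isotope of the lighter one while both
coelute. The library encodes the standard remedy: the heavier group (`IV_2`)
is excluded from quantification and the lighter one is capped at its first
six isotopologues, which still cover >90% of the theoretical envelope for
the dominant analytes (the largest poly-LacNAc species dip to ~85%). This
rule is applied generically: any same-site peptide pair closer than ~6 Da
triggers exclusion of the heavier member and a cap of `round(dm) + 1`
isotopes on the lighter.

Glycan compositions use the `N#H#S#[F#]` nomenclature (HexNAc, hexose,
NeuAc, fucose). The bundled per-site composition sets (96 glycoforms: 12,
12, 8, 11, 21, 15 and 17 across the seven quantified groups) are a curated
fixture chosen to represent the highly branched, highly sialylated repertoire
of AGP — bi- to tetraantennary, poly-LacNAc up to one repeat, up to two
fucoses — and to span the full derived-trait panel below. Where source
descriptions of the site-IV repertoire disagree (21 vs 24 structures), the
set uses 21, consistent with the 96 total.

All masses are derived from elemental compositions with IUPAC monoisotopic
element masses, so mass and isotope model can never disagree.
Carbamidomethylation of cysteine is a fixed modification; N-terminal
pyroglutamate (loss of NH~3~ from Gln) is available for the site-I/IV
peptides that exhibit it, but the quantified library uses the unmodified
forms, reflecting the practice of quantifying only the most intense peptide
per site.

## Theoretical isotope patterns

`theoretical_isotope_pattern()` computes aggregated isotopologue
distributions (by neutron-count offset, no fine structure — the resolution
regime of a Q-TOF) by per-element polynomial convolution with binary
exponentiation, truncated and renormalized at `n_iso` isotopologues. The
implementation is validated against naive one-atom-at-a-time polynomial
expansion. Extraction selects isotopologues greedily by theoretical
abundance until 90% cumulative coverage (configurable), subject to the
per-analyte cap.

## Targeted extraction and its quality metrics

`integrate_analyte()` builds per-isotopologue XICs inside a ±`tol_ppm`
window (default 20 ppm — the upstream tool's tolerance is not documented, so
this is an explicit, configurable choice) over a calibrant-anchored
retention-time window (default apex ±0.5 min after alignment), integrates
by the trapezoid rule, and reports three QC metrics per analyte × charge:

* `ppm_error` — intensity-weighted mean apex mass error across
  isotopologues;
* `ipq` — isotopic pattern quality, the L1 deviation
  $\sum_k |o_k - t_k|$ between observed and theoretical envelope fractions
  normalized over the selected isotopologues (the metric is named but not
  defined upstream; L1 on normalized envelopes is the convention of
  targeted glycomics extraction tools);
* `snr` — apex peak height over a robust noise level, estimated as
  1.4826 × MAD of intensities sampled in flanking m/z bands at
  *half-integer* positions of the isotopologue comb. The half-integer
  placement matters: near-isobaric neighbouring glycoforms (e.g. ±2 Da/z)
  sit on integer comb offsets, and a naive flanking band would count their
  envelopes as noise and crater S/N in dense spectra.

Retention-time alignment (`align_rt()`) detects calibrant XIC apexes and
fits a monotone piecewise-linear observed→reference map, extending end
segments linearly. Diagnostic-ion screening (`screen_diagnostic_ions()`)
locates glycopeptide elution windows from MS2 scans using the oxonium ions
204.087, 274.092, 292.103, 366.140 and 657.235.

Missing analytes produce flagged zero-area records rather than errors, so
batch-level curation sees completeness.

## Curation and normalization

QC is a **batch-level** decision: metrics are averaged per analyte × charge
across all samples (flagged-missing records excluded) and thresholded at
mean mass error within ±30 ppm, mean IPQ < 0.25, mean S/N > 15. Averaging
is per charge state, not pooled across charges — the pooled variant is a
plausible alternative reading of the upstream description; per-charge is
the stricter and more informative choice. Retained charge states are summed
per analyte and normalized to the total integrated area per glycosylation
site, yielding glycoform fractions that sum to 1 per sample × site.
Normalization is idempotent and invariant to per-sample scaling.

Near-isobaric coincidences are a real feature of this analyte panel — e.g.
N7H8S1 sits 2.016 Da above N5H6S3F1 (2 HexNAc + 2 Hex vs 2 NeuAc + 1 Fuc),
and cross-charge overlaps such as a 3+ isotope landing on a 4+ monoisotope
occur within ~13 ppm. The batch QC is precisely the mechanism that removes
the affected charge states; traits whose member glycoforms lose all charge
states become missing rather than biased, mirroring how a real study's trait
panel shrinks when fewer glycopeptides pass QC.

## Derived glycosylation traits

Within each site, glycoforms are grouped by shared structure
(`enumerate_traits()`):

* **Branching** — antennae = min(HexNAc − 2, 4): `BiAnt`, `TriAnt`,
  `TetraAnt`. HexNAc beyond the tetraantennary count is interpreted as
  poly-LacNAc repeats, so N7H8S4 is tetraantennary with one repeat. The
  branching classes partition each site (fractions sum to 1).
* **Fucosylation** — one `F` trait per site with any fucosylated member;
  members are all fucosylated compositions.
* **Sialylation** — sialic acids per antennary galactose, with the *capped*
  antenna count as denominator, reduced to lowest terms: `S1/1`, `S3/4`,
  `S2/3`, `S1/2`, `S1/3`, `S1/4` (and `S0` for asialo species, none of
  which occur in the bundled library). The capped denominator makes
  N7H8S4 classify as fully sialylated (`S1/1`); compositions where
  H − 3 differs from the capped antenna count are exactly the poly-LacNAc
  species and are covered by this documented rule. The sialylation classes
  also partition each site.

On the bundled library this yields exactly 63 traits across the seven
quantified groups; a trait value is the sum of its members' fractions, and a
missing member makes the trait missing (no zero-imputation).

## Cohort statistics

* **Batch correction** (`batch_correct()`): log-transform, then the ComBat
  parametric empirical-Bayes location/scale adjustment with plate as the
  only batch term (via the sva package), back-transformed by default.
  Plates need ≥2 samples; a single batch is the identity.
* **Rank-based inverse normal transform** (`rank_int()`):
  $z_i = \Phi^{-1}((r_i - 0.5)/n)$ with average ranks for ties (the
  GenABEL `rntransform` convention; the Blom offset 3/8 is available via
  `offset`). Every transformed trait has the same standardized variance, so
  logistic coefficients are per-SD log odds ratios comparable across
  traits. How ties and case/control imbalance interact with INT is not
  specified upstream; average ranks over the pooled sample is the
  documented choice here.
* **Association** (`associate_traits()`): per trait,
  `outcome ~ rank-INT(trait) + age + sex` by IRLS logistic regression
  (`stats::glm`), Wald p-values, Benjamini-Hochberg FDR across the traits
  that converged; separation/non-convergence is flagged and excluded from
  the FDR family with a warning.
* **Stability** (`stability_summary()`): three CV categories per trait —
  technical duplicates (per replicate pair), intraindividual (per subject
  across time points) and interindividual (per time point across subjects)
  — summarized as median and IQR, with technical replicates averaged before
  the biological CVs. Note that a CV from a duplicate *pair* (n = 2) is a
  noisy, downward-biased estimate of the technical CV (E[sd] ≈ 0.80σ, the
  median ≈ 0.67σ), so per-trait duplicate medians sit below the generating
  technical noise; the root-mean-square across pairs is the unbiased
  summary and is what the test suite checks for recovery.
* **ROC comparison** (`roc_models()`): four predictive logistic models —
  age + sex; age + sex + BMI + family history; both again with the selected
  glycan traits — compared by AUC computed from fitted probabilities with
  the Mann-Whitney rank statistic. No AUC confidence intervals are
  produced.

## Synthetic data: what it emulates, and what it does not

`simulate_run()` emulates the MS1 acquisition: Gaussian elution profiles
(default sd 0.08 min, scan interval 0.025 min) of full theoretical isotope
envelopes at 3+/4+, ppm-scale calibration bias plus per-peak jitter,
multiplicative intensity noise, and uniform decoy peaks with exponential
intensities to stress tolerances and the noise estimator. Ground truth
(site fractions, bias, shift) is attached to the run. It does **not**
simulate chromatographic tailing, profile-mode peak shapes, charge-state
correlation, or real MS2 fragmentation (only diagnostic-ion stubs), so
passing recovery tests demonstrate correctness of the extraction arithmetic
under the stated model, not robustness to every instrumental artefact.

`simulate_cohort()` draws each trait from a latent standard normal, shifted
in cases by the trait's per-SD log odds ratio — the retrospective-sampling
equivalence that makes the logistic coefficient directly controllable — and
maps latent values monotonically onto a positive trait scale, with
multiplicative plate shifts and independent covariates. Rank-INT logistic
regression is invariant to the monotone mapping, which is exactly why the
generator controls the estimand. The cohort defaults (59 cases / 49
controls across two plates) and the stability defaults (14 subjects × 3
time points with 8 duplicate pairs) reproduce the two study designs this
pipeline is built for; stability noise defaults (inter 0.12, intra 0.04,
technical 0.015-0.02 log-units) are chosen to match the reported regime
where interindividual variation clearly dominates intraindividual variation,
which in turn sits at or above the technical baseline.

## Numerical choices and degenerate inputs

* Extraction tolerance 20 ppm, coverage 0.90, window ±0.5 min — all
  configurable per call.
* Isotope patterns default to 10 modeled isotopologues; patterns are
  renormalized after truncation, so envelope fractions always sum to 1.
* Zero site totals normalize to missing (with a warning), never to 0/0.
* `cv()` refuses n < 2 or zero mean; `rank_int()` refuses n < 3 or constant
  input; alignment refuses <2 detected calibrants and non-monotone
  calibrant order; batch correction refuses non-positive values and
  single-sample batches.
* All simulators are bit-reproducible under a fixed seed; the pipeline
  derives per-sample seeds from the configured base seed.

## Problem sizes in the test and acceptance suites

The suites run the full 96-analyte library end to end on one simulated run,
two-site subsets for fast extraction properties, a 1000-replicate null for
type-I calibration at n = 100, 25-60 replicate power/recovery studies at
the 59/49 pilot layout, and the 14 × 3 (+8 duplicates) stability design
over the 60-trait panel. These sizes were chosen as the smallest designs
that pin down each property with comfortable statistical margin.

## Known limitations

* Compositions, not structures: no linkage-level sialic acid or antenna
  placement of fucose; structural isomers are indistinguishable.
* Hybrid and oligomannose classes are not modeled (AGP's repertoire is
  essentially complex-type, highly branched and sialylated).
* The IV_1/IV_2 overlap is handled by exclusion + isotope cap, not by
  chimeric deconvolution.
* Single-charge-retained analytes carry a small charge-summation bias when
  one charge state fails QC; the affected glycoforms are the minor,
  overlap-prone ones, and the bias is bounded by the dropped charge's
  intensity share.
* mzML writing is MS1-only and uncompressed — sufficient for simulation
  round-trips, not a general-purpose converter.
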