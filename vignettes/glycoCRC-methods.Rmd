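---
title: "Methods: paired tumor/NAT intact N-glycopeptide analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired tumor/NAT intact N-glycopeptide analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

glycoCRC analyses quantitative intact N-glycopeptide (IGP) data from
paired tumor and normal-adjacent-tissue (NAT) cohorts, the study design
typical of clinical glycoproteomics of colorectal cancer. An IGP is a
peptide quantified together with its attached, unreleased N-glycan; the
analysis unit is `protein.site.glycan`, e.g. `APMAP.N196.4200` (the
glycan Hex[4]HexNAc[2]NeuAc[0]Fuc[0] on Asn-196). The package covers the
computational chain from composition parsing to biomarker panels; raw
mass-spectrometry processing and search-engine output (identification,
FDR control) are upstream and out of scope.

# The glycoform taxonomy

Each glycan composition is assigned exactly one of five classes:

| class | rule |
|-------|------|
| FA | contains sialic acid **and** fucose |
| A  | contains sialic acid, no fucose |
| F  | contains fucose, no sialic acid |
| H  | exactly 2 HexNAc and every other residue a hexose (high mannose) |
| N  | everything else (high HexNAc) |

The rules are applied with precedence FA > A > F > H > N, which turns
overlapping membership conditions ("any glycan containing sialic acid")
into a true partition; a unit test enumerates the full grid hex 0–15,
HexNAc 0–10, NeuAc 0–4, Fuc 0–3 against an independently written rule
table. "Sialic acid" counts NeuAc together with NeuGc-type residues, as
the rule names the residue class rather than one acid. The H class has
no minimum hexose count: 2 HexNAc plus only hexoses suffices. Any
residue outside {Hex, HexNAc, sialic acids, Fuc} excludes a composition
from H and pushes it to N.

# Preprocessing

The fixed order is detection filter, per-sample minimum imputation,
protein normalization, log2 transform, batch centering.

* **Detection filter** — keep features observed in strictly more than
  `min_fraction` (default 0.30) of the samples. The threshold is over
  samples, not patients; a patient-pooled reading would change boundary
  cases only and can be emulated by prefiltering.
* **Imputation** — each missing cell takes the smallest observed
  intensity of its own sample, the left-censoring-motivated convention
  for intensity-dependent missingness. Imputation is recorded per cell,
  and AUC screening later uses observed cells only.
* **Protein normalization** — IGP intensity divided cell-wise by the
  parent protein's abundance in the same sample, removing protein-level
  dynamics so glycosylation changes are read directly. Imputation
  precedes normalization by default (the alternative order is a switch,
  `impute_after_normalize`); with per-sample minimum imputation both
  orders give scale-invariant ratios, and the default keeps denominators
  complete.
* **Batch centering** — a two-way means model: per feature, tissue-group
  means are removed, batch means are estimated on the residuals and
  subtracted. This protects the tumor/NAT contrast by construction and is
  exact for additive batch offsets under balanced designs; tests verify
  agreement with limma's `removeBatchEffect` under a protected design
  matrix. Single batch reduces to the identity.

# Differential statistics

Per feature on log2 values: a Brown–Forsythe (median-centered Levene)
test decides pooled vs Welch t-test (Welch when Levene p < 0.05); a
Wilcoxon rank-sum p is reported alongside; the fold change is the ratio
of group medians on linear scale. Significance uses the raw rule
p < 0.05 and |FC| > 2 — no multiplicity correction in the flag, matching
the original screening convention — while BH q-values are emitted as an
extra column. Wilcoxon p-values are exact for small untied samples and
use the tie/continuity-corrected normal approximation otherwise; a test
compares them to a brute-force enumeration of the U distribution for all
group sizes up to 8.

Glycoproteins are then classified into six groups: direction
{Up, Down, NoChange} by the two-thirds rule over their IGP log2 fold
changes (fraction ≥ 2/3 counts, so 2-of-3 positive is Up; zero fold
changes count toward neither side), crossed with dominance {S, Hm} by
counting sialylated IGPs (A + FA) against high-mannose IGPs (H), ties
going to S. Direction uses all IGP fold changes, not only significant
ones. The protein → site → glycan tree is exported as SIF plus a node
attribute table for Cytoscape-class viewers.

# The glycoform ratio score

Each sample is summarised by the median abundance of its IGPs per class,
computed on protein-normalized, imputed, linear-scale intensities (the
median of per-IGP values, not of per-protein sums; a summed variant
would weight large proteins). All ordered pairs of disjoint non-empty
class subsets define ratio scores — $3^k - 2\cdot2^k + 1$ combinations,
180 for five classes — each scored by the Mann–Whitney AUC
$P(\text{score}_T > \text{score}_N) + \tfrac12 P(\text{tie})$ with tumor
positive. The AUC is reported raw, without folding to ≥ 0.5: the
enumeration contains each ratio's reciprocal, so folding would only
duplicate information. For a *named* score such as H/(A+N), however, the
discrimination figure quoted alongside is `auc_directed = max(a, 1−a)`,
the automatic-direction convention of standard ROC software (pROC),
because a ratio whose value *drops* in tumors discriminates exactly as
well as its reciprocal. Under this package's default simulation —
sialylated classes rising faster than high mannose — H/(A+N) falls in
tumors, so its raw AUC is near 0 and its directed AUC near 1; both are
reported. Youden-optimal cutoffs scan midpoints of sorted unique scores
and break ties toward the lower threshold.

# Biomarker screening

Per-feature AUCs are computed on observed (non-imputed) cells.
Glycoprotein shortlisting ranks by number of distinct IGPs per protein
by default (`rank_by = "abundance"` ranks by total IGP intensity
instead, both readings being plausible for "most glycosylated"), takes
the top k (default 10), and keeps proteins detected in more than 90% of
samples. Panels are combined by ridge-penalized logistic regression fit
with iteratively reweighted least squares: predictors are standardized
internally, the intercept is unpenalized, the default penalty 1e-4
guards against complete separation, and coefficients are reported on the
original scale; tests check the penalized score equations at the optimum
and parameter recovery on simulated data. Train/test splitting (7:3 by
default) and cross-validation operate on patients, never samples, so a
tumor is never evaluated against its own patient's NAT — stricter than
plain sample-wise splitting and the package's deliberate choice.

# Motif analysis

Sites are summarised as 15-residue windows (±7 around the asparagine,
`-`-padded at sequence ends; non-N centers are flagged, not dropped).
Enrichment compares position-wise residue percentages between a
foreground and a background window set (percentage-point difference,
two-proportion z-test), with pads excluded from denominators. This is a
transparent stand-in for logo-tool statistics, not a bit-exact
re-implementation. The background defaults to all valid sequons
(N-X-S/T/C, X ≠ P) in the supplied FASTA and is an explicit input, since
"the proteome" is release-dependent.

# The synthetic cohort

`generate_cohort()` simulates the study conditions end-to-end: 45
tumor/NAT pairs; ~300 glycoproteins with 1–9 sites and 1–12 glycans per
site (≈3300 IGPs); glycoform mixture A 15%, F 38%, FA 10%, H 30%, N 7%
(fucosylated and high-mannose forms dominating, as in CRC tissue);
log-normal abundances (log2 baseline mean 20, sd 2, the usual MS
intensity scale); per-class tumor log2 effects A 1.5 > N 1.2 > F = FA
1.0 > H 0.4, i.e. sialylation rising fastest and high mannose slowest,
with per-IGP noise sd 0.5; protein abundance itself unshifted in tumors
but negatively coupled (coefficient −0.5) to the *mean* log2 deviation
of the protein's own IGPs — the mean rather than the raw sum keeps the
coupling magnitude independent of how many glycans a protein carries;
patient loading effects (sd 0.3, modest enough that unpaired two-sample
tests stay near-nominal); three batches with additive offsets (sd 0.3)
shared by both tissues of a patient; and MNAR missingness
$P(\text{missing}) = \mathrm{logistic}(6.6 - 0.4\,\log_2 I)$, about 20%
of cells at the default intensity scale. Effects act at the IGP level,
not the protein level, so the protein-normalized analysis can recover
them. Each random stage (hierarchy, batches, abundances, missingness)
draws from its own named substream of the single seed, making outputs
bit-reproducible and stages mutually independent.

What the simulator does *not* emulate: charge states and PSM-level
aggregation, retention-time structure, interference/ratio compression,
shared peptides, correlated glycan co-regulation within a site, and
non-additive batch effects. Passing recovery tests therefore shows the
pipeline implements its contracts and recovers known structure under its
own assumptions — not that those assumptions hold in any particular real
cohort.

Free parameters above that the emulated design does not pin down (noise
and loading sds, MNAR constants, the mixture weights and effect
magnitudes beyond their ordering) were fixed once at the values a
practitioner would call typical for HILIC-enriched tissue data and are
not tuned thereafter.

# Numerical choices and degenerate inputs

* Zero intensity is a measured value; only empty/"NA" cells are missing.
  Zero protein denominators make the normalized cell missing.
* A constant feature yields fold change 0, p = 1, not significant.
  Levene with zero within-group spread returns p = 1 when spreads are
  identical, p = 0 otherwise; an all-tied Wilcoxon returns p = 1.
* IRLS stops on a relative coefficient step < 1e-10 or a deviance
  plateau; weights are floored at 1e-10.
* Tables are written at 6 significant digits and round-trip through the
  matching readers at that precision.
* Ranking ties: enumerated combinations lexicographically; protein
  shortlists by accession; Youden thresholds toward the lower value.

# Problem sizes used in the test suite

Structural unit tests use miniature fixtures built in code; recovery and
calibration tests use cohorts of 10–45 pairs and 40–300 proteins
(roughly 400–3300 IGPs), sizes at which every Monte-Carlo check in the
suite is stable under its fixed seeds and the whole suite runs in a few
minutes on one core.

# Known limitations

* The six-group dominance rule counts IGPs, not abundance; a protein
  with many faint sialylated glycans counts as S-dominant.
* The score/ROC machinery treats the 90 samples as independent,
  standard ROC practice but ignoring pairing; the biomarker module's
  patient-level splitting addresses the leakage concern where it
  matters most.
* The "PTM ratio" (total IGP over total protein intensity per sample)
  is one reasonable formalisation of overall glycosylation load; other
  definitions exist and none is canonical.
* The batch model is additive means only — no empirical-Bayes shrinkage
  or scale adjustment.
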