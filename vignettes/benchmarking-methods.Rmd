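---
title: "Benchmarking label-free proteomics workflows: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking label-free proteomics workflows: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Multicenter round-robin studies distribute aliquots of one pooled sample
(plasma, CSF) to several laboratories, each measuring ~10 technical
replicates with its own sample preparation and LC–MS setup, in one or
more measurement rounds. All raw data are searched centrally with one
engine, so the remaining variation is the workflows themselves. The
analytical questions are descriptive but precise: how many protein
groups, peptides and precursors does each workflow identify; how
complete and how precise are those identifications across replicates;
and how reproducible are protein detections *between* laboratories?

`mqbench` implements this downstream analysis from the search engine's
result tables. This vignette documents the model behind each metric, the
parameters that matter, the numerical choices made where the field's
conventions leave room, and what the synthetic data generator does and
does not emulate.

# Data model

One **data set** is a lab × LC system × MS instrument × acquisition mode
× time point combination with its replicates. Run labels follow
`<T#>_<Lab>_<LC>_<MS>[_<DDA|DIA>]_R<n>`; the acquisition segment is
optional in input and defaults to DDA (both conventions occur in
practice), while rendering always writes it, so structures round-trip
exactly.

The container (`MQDataset`) wraps two `SummarizedExperiment`s — protein
groups and peptides as features × runs intensity matrices with flag
columns in `rowData` — plus a long-format evidence table (one row per
precursor observation). Two conventions are applied at read time and
used consistently everywhere downstream:

- **Zero intensity ≡ missing.** MaxQuant writes 0 for absent
  quantification; presence/absence logic needs one convention, so zeros
  and empty cells become `NA` on input and are written back as `0`.
- **Quantification column preference.** `LFQ intensity <label>` columns
  are used when present for all runs, otherwise `Intensity <label>`;
  the choice is recorded in the bundle's metadata and the JSON report.

A **precursor** is a peptide sequence including its charge state. The
field is ambiguous about whether the modified or the stripped sequence
defines identity; the default here is the modified sequence (finer, so
two modified forms at one charge stay distinct), with
`precursor_by = "stripped"` available on every precursor-level function.
Peptide-level metrics always use distinct (stripped) sequences.

# Filtering and outlier screening

Before any metric: decoy (`Reverse`) rows, potential contaminants,
protein groups only identified by modified-site evidence, and iRT
spike-in identifications (default pattern `"PROCAL"`, matched against
accessions and sequences) are removed at all levels. Each removed row is
tallied once, under the *first* matching category in the order reverse →
contaminant → only-by-site → spike-in, so the report's counts always sum
to the input row count. Filtering is idempotent. Spike-ins are filtered
*before* any total used in relative metrics — the alternative (counting
them in totals) is not reproducible from published descriptions, and
filtering first keeps every denominator consistent.

Round-robin practice removes occasional catastrophic replicates "based
on the achieved number of IDs", a manual judgment. `mqbench` makes the
criterion explicit and reproducible: a replicate is flagged when its ID
count (protein-group level by default) falls strictly below
`min_fraction` (default 0.5) of the median count over all replicates.
The default is deliberately conservative: a replicate losing half its
identifications is unambiguously broken, while ordinary count variation
(a few percent) never triggers. Detection requires ≥ 3 replicates (a
median over fewer is not a robust reference) and never mutates the data;
removal (`dropReplicates()`) is separate and logged, so the decision is
always visible in the report.

# Intra-laboratory metrics

**Identification counts.** A feature counts in a replicate iff it has a
non-missing quantification there (protein group, peptide) or at least
one evidence row (precursor). Medians over replicates summarize a data
set.

**Data completeness.** Features are binned by the number of replicates
k in which they appear; a feature present in all n replicates is a
*full profile*, and the full-profile percentage is
100 · count(k = n) / Σ count(k). Features observed in zero replicates do
not exist as rows, so the denominator is the identified union.

**Missed cleavages.** Tallied over distinct identified peptide
sequences; percent zero = 100 · n₀ / total. With zero peptides the
percentage is reported missing, never 0 — an empty data set has no
digestion efficiency.

**Precision.** Per feature, CV = 100 · s / x̄ with the sample (n−1)
standard deviation — the conventional, slightly conservative choice at
n ≈ 10 (the population SD would bias CVs low by ~5 % at n = 10).
Features with fewer than two non-missing values are *excluded from the
denominator*, not counted as failing: precision is a statement about
measurable features. Thresholds are strict inequalities (CV < 5 % for
retention time at the precursor level, CV < 20 % for LFQ intensity at
the protein-group level), so boundary values count as not-below. When a
precursor has several evidence rows in one replicate, its
retention time there is their median, which resists split-peak
artifacts; intensities are summed (consistent with peptide intensity
being the sum of its precursors).

# Inter-laboratory comparisons

**Scaled round comparison.** For one metric, the medians over the data
sets of rounds A and B are both divided by the larger of the two and
multiplied by 100; the difference (B − A, percentage points) is
comparable across metrics with very different ranges. The operation is
scale invariant, and with published CSF protein-ID medians 613 (T1) and
707 (T2) yields +13.3 points.

**Overlap saturation.** Interlaboratory reproducibility is computed on
accessions expanded from each full-profile group's majority IDs: an
accession is present in a data set iff *some* group listing it is a full
profile. Laboratories group proteins differently, and accession
expansion is the only rule symmetric under regrouping — comparing group
strings directly would punish grouping differences rather than detection
differences. This is a deliberate, documented reading; it can only
enlarge per-lab sets relative to stricter rules. Relaxing completeness
uses a ceiling rule on replicates ("at least 80 %" of 10 replicates
means ≥ 8), and the curve ordering is an explicit input (the study
design order by default) because intermediate values — unlike the
terminal intersection and union — depend on it.

**Biomarker matching.** Panel accessions are matched exactly (no
isoform stripping — P02768-2 is not P02768) against full-profile
accession sets. When several full-profile groups carry the same
accession, the group quantified in the most replicates (ties: higher
median intensity) provides the reported LFQ CV and the ambiguity is
flagged. Presence per accession is the percentage of data sets with a
match, overall and per time point; the replicate dimension is already
absorbed by the full-profile requirement. Unmatched panel members are
reported with presence 0, never dropped.

# The synthetic study generator

The generator exists so that every stage — parsing, filtering, each
metric, the comparisons — can be validated against known truth without
raw data. It emulates the *statistical structure* the metrics measure:

- proteins split into a shared core (visible to all labs) and
  lab-private remainders, which plants a known terminal overlap;
- peptides per protein ~ Poisson (λ = 4, min 1), missed-cleavage classes
  multinomial (default 0.80/0.15/0.05, matching the > 80 % zero-MC
  performance of good in-solution digests);
- precursors with one charge state (0.7/0.25/0.05 over 2+/3+/4+) plus a
  second with probability 0.2;
- detection independent across replicates with per-precursor probability
  from Beta(4, 2) for DDA and Beta(12, 2) for DIA — DIA tighter and
  higher, emulating the reported completeness contrast between the
  modes — or a fixed `p_det` for closed-form checks;
- base log-intensities Normal(log 10⁶, 1.5); replicate noise lognormal
  with σ = sqrt(log(1 + CV²)) so the intensity CV is exactly the
  configured target (default 10 %);
- retention times uniform on a 60-min gradient with homoscedastic
  Gaussian jitter (default SD 0.15 min, i.e. per-precursor RT CVs well
  under 5 % — realistic for modern nano-LC);
- flagged decoy/contaminant/only-by-site rows, PROCAL spike-ins
  (always detected), and occasional two-accession majority groups to
  exercise the expansion logic.

Under fixed `p_det = p` and n replicates the full-profile percentage has
the closed form 100 · pⁿ / (1 − (1−p)ⁿ) (presence-conditional), e.g.
10.74 % at p = 0.8, n = 10 — a sharp end-to-end check on the
completeness machinery.

What it does **not** emulate, hence what passing tests cannot show:
MaxLFQ normalization (protein intensities are sums of member peptides),
match-between-runs (detections are independent across replicates,
whereas MBR induces correlated presence), intensity-dependent
missingness (detection probability is independent of abundance), peak
shapes, and any search-engine behavior. Conclusions about those belong
to the upstream tools; `mqbench` only consumes their tables.

# Determinism and problem sizes

Every simulated study regenerates bit-identically from (config, seed),
and repeated pipeline runs on fixed input produce byte-identical
reports (no timestamps in outputs; the JSON report embeds the design
checksum and package version instead). The test suite validates the
metrics against independent brute-force reimplementations on hundreds
of randomized small bundles (≤ 20 features, ≤ 5 replicates) where
exhaustive loops are feasible, and parameter recovery on studies of
200–500 proteins × 10 replicates — large enough for exact-binomial 99 %
bounds to be tight (a few thousand peptides/precursors), small enough
to run in seconds.

# Known limitations

- Accession expansion can report an overlap accession that no two labs
  quantified in the *same* group; this is intended (detection-level
  reproducibility) but should not be read as quantitative agreement.
- The outlier rule is univariate (ID counts); drifting-but-complete
  replicates (e.g. RT drift without losses) are not flagged by it —
  they surface in the precision metrics instead.
- Only the MaxQuant table dialect is parsed; other engines' reports
  would need a thin conversion layer.
- No normalization, imputation or differential abundance: the metrics
  are descriptive by design.
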