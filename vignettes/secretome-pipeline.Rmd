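---
title: "Methods: secretome mapping and biomarker statistics"
author: "secretomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secretome mapping and biomarker statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secretomap)
```

# Scope and model

`secretomap` charts the set of proteins a placenta exports to the
maternal circulation and evaluates candidates from that map as serum
biomarkers of pregnancy complications. The pipeline is a composition of
filters and statistics over tabular inputs; this vignette states each
rule precisely, explains every tunable parameter, documents the
numerical conventions, and describes what the synthetic-data generator
does and does not emulate.

# Detection evidence

A detection stream is a proteins × samples matrix of MS peak areas.
Presence is defined as a peak area strictly greater than a configurable
floor, default 0: label-free MS at this stage is treated as
presence/absence, because peak areas across runs are not directly
comparable without the internal-standard normalization applied later to
the targeted plasma data. A protein is carried forward when present in
at least *k* of *n* replicate samples (defaults *k* = 4, *n* = 5). The
filter is monotone in *k* and conserves counts
(input = retained + dropped), both asserted by tests. How to treat a
protein detected in exactly *k* samples but at near-noise intensities
is genuinely open; we default to no intensity floor and expose it as a
parameter rather than guessing a threshold.

Accessions map to gene ids through an explicit table; accessions
without a mapping are reported, never silently dropped, and an
accession mapping to several genes contributes all of them (losslessness
— downstream set logic is unaffected, and the ambiguity is logged).
Expression verification keeps genes whose placental expression meets a
floor; the pipeline default is any positive value (`1e-9`), since the
synthetic expression tables encode "not expressed" as an exact zero and
public RNA compendia publish no universal cutoff.

# Ortholog consensus

Assertions from several sources are pooled and each mouse gene is
classified by the number of **distinct** human partners asserted across
all sources: one → `one_to_one`, several → `one_to_many`, none →
`unmapped`. Two design points deserve emphasis:

* Cross-source conflict (source A says H1, source B says H2) is
  `one_to_many` and therefore excluded. The identity of the ortholog is
  ambiguous, and the conservative reading costs only sensitivity, never
  specificity, in the shared map.
* Many-to-one relations (two mouse genes, one human gene) are allowed:
  classification is per mouse gene.

Ids are compared after trimming whitespace and stripping trailing
version suffixes, because source dialects differ. The classification
partitions the universe, is invariant to assertion order, and can only
move monotonically (unmapped → one_to_one → one_to_many) as assertions
accumulate; all three are property-tested.

# Secretion classification

A gene is secreted iff

```
(signal_peptide AND NOT er_lumen)  OR  (go_terms ∩ secretion_terms ≠ ∅)
```

The first clause is the conventional ER/Golgi route: a predicted signal
peptide counts only when the protein is not an ER-lumen resident, since
the peptide then targets the protein to a compartment it never leaves.
The second captures unconventional (leaderless, e.g. exosomal) export
through direct GO membership. The default term set is the canonical
extracellular compartment quartet — GO:0005576 (extracellular region),
GO:0005615 (extracellular space), GO:0070062 (extracellular exosome),
GO:0044421 (extracellular region part) — configurable as a plain
character vector. GO matching is direct annotation, not ancestor
propagation: the annotation tables consumed here are expected to be
pre-propagated, and implementing graph propagation would drag in an
ontology dependency for no testable gain. Genes absent from the
annotation table land in an explicit `unannotated` bucket.

# Map integration and overlays

The per-stream secreted gene lists are unioned into one entry per gene,
recording which streams contributed. An entry is *shared with human*
when it has a one-to-one ortholog whose human placental expression
passes the floor (default: any positive value); otherwise it is
mouse-only. Venn region counts over 2–5 sets are computed by direct
membership-pattern enumeration and must sum back to each set's
cardinality.

Tissue enrichment calls a gene enriched when its target-tissue
expression exceeds `fold` (default 10) times the **maximum** over all
other tissues. The maximum is the strictest standard comparator; the
mean is available (`comparator = "mean"`) but the default is the one
that cannot be satisfied by a single co-expressing tissue. Genes with
zero target expression are never enriched, whatever the other tissues
do.

Complication overlays flag entries whose human ortholog appears in a
differential-expression set for PE, GDM, IUGR, SGA or LGA, and report
genes unique to one complication and genes shared by ≥ k (default 4)
complications. Over-representation uses the exact upper-tail
hypergeometric probability with Benjamini–Hochberg adjustment across
categories; q-values are monotone in p-rank and never below their p.

# Plasma screen

Targeted peak areas are divided column-wise by the spiked
internal-standard row, which removes run-to-run intensity scale — the
normalization is exactly invariant to per-column rescaling, asserted at
1e-12. Fold change is the ratio of group central values (arithmetic
mean by default, median by option) of pregnant over non-pregnant
animals; zeros are replaced by half the smallest positive value in the
matrix first (the standard pseudo-floor, so a protein undetected in the
non-pregnant group yields a large finite fold rather than a division by
zero). The classification threshold defaults to 1.5-fold and is
inclusive: the observed range of pregnancy-elevated proteins starts at
1.5-fold, so the boundary case is classified as elevated.

Row Z-scores use the population (divide-by-*n*) standard deviation —
the convention is declared so heat-map matrices are bit-reproducible —
and constant rows map to zeros with a warning.

Clustering is agglomerative average linkage under
d = 1 − Spearman rank correlation, applied to rows or columns. Spearman
distance makes the tree invariant to any strictly monotone transform of
the values. Because rank correlations on short vectors tie easily, the
implementation breaks ties deterministically: all pairs within 1e-9 of
the minimal inter-cluster distance are candidates, and the pair whose
sorted minimal leaf labels are lexicographically smallest merges first.
The 1e-9 tolerance makes the tie set itself robust to floating-point
noise, so an independent implementation of the same rule reproduces the
tree exactly. Constant vectors have undefined rank correlation and are
rejected by name. Merge heights are non-decreasing (average linkage is
reducible), and trees export to Newick via `ape`.

# Biomarker statistics

MoM (multiple of the median) divides each concentration by the median
of the reference group — healthy subjects at the same gestational week
and analyte, the standard obstetric-screening convention (an
all-subjects reference is available). The reference-group MoM median is
exactly 1 per stratum by construction, and MoM statistics are invariant
to per-analyte unit rescaling. Medians of even-sized groups are the
midpoint of the two central order statistics.

MoM ratios are per-subject quotients of two analytes' MoM values;
subjects missing either analyte are excluded and counted. Effects are
summarized as percent increase, 100·(mean_case − mean_ref)/mean_ref.
The two-sample *t* test defaults to the pooled (Student) variant with
Welch as an option; degenerate zero-variance comparisons with equal
means return p = 1 with a warning instead of erroring mid-pipeline.
The two-way ANOVA fits group × week with interaction and reports Type
II sums of squares, which remain interpretable in unbalanced cohorts;
when the week factor has one level the model reduces to a one-way
ANOVA whose F equals the squared pooled *t*. The two weekly samples
per subject are treated as independent observations — a documented
limitation, since no repeated-measures structure is modeled. A
summary-statistics *t* test (mean, SEM, n per group) recovers SD as
SEM·√n and supports both variants.

# TF networks

Promoters cover −1000…+100 bp around the TSS, delivered strand-resolved
in FASTA. PWM scanning slides the motif over both strands and scores
windows by Σ log₂(p_base/bg_base); windows containing N score −∞;
positions are 0-based window starts on the forward sequence. The
default hit threshold is 60 % of the motif's maximal achievable score.
Motif enrichment dichotomizes promoters by "has ≥ 1 hit" and applies a
two-sided Fisher exact test to the foreground/background 2×2 table with
BH adjustment across motifs — a declared approximation of rank-based
enrichment tools, whose internals (scoring, threshold, background
model) are not public and are not reconstructed here. The TF funnel
then requires each TF to be (i) predicted by both the motif route and
the upstream-regulator route (targets pooled by union), (ii) expressed
in the syncytiotrophoblast with at least one target in the
STB-expressed secretome, and (iii) linked to a pregnancy complication;
every filter is idempotent. The final network flags TF nodes by
complication and target nodes by differential expression, and exports
as a TSV edge list and GraphML.

# Synthetic-data generator

`generate_study()` emulates every input with planted truth:

* **Abundances** are log-normal; **detection** is Bernoulli per
  (protein, sample) with abundance-independent dropout (default 0.15).
  This is the simplest model supporting a presence/absence filter; it
  deliberately omits the abundance-dependence of real MS dropout, so
  passing tests certify the set logic, not detection-efficiency
  modeling.
* **Orthology** plants one-to-one (78 %), one-to-many (10 %, split
  between single-source multi-partner and cross-source conflict
  flavors) and unmapped (12 %) classes, with each source asserting a
  true pair with probability 0.9.
* **Secretion annotations** give every true-secreted gene conventional,
  unconventional or both evidence; 10 % of non-secreted genes carry the
  signal-peptide-plus-ER-lumen trap, exercising the exclusion clause.
* **Expression** plants 20 placenta-enriched genes at 12× the maximum
  of the other tissues against a 2× background, flanking the 10-fold
  threshold from both sides.
* **Plasma** plants 24 of 45 proteins with pregnancy folds drawn
  log-uniformly from [1.5, 52] and the rest from [0.8, 1.25], with 3
  non-pregnant and 8 pregnant animals.
* **Serum cohort** (10 healthy / 6 GDM by default, weeks 12 and 28)
  draws log-normal concentrations (σ = 0.3) around week-specific
  healthy medians, with GDM multipliers sFLT1 3.1, ANGPT2 1.97, MIF
  and IGF2 1 — so the expected MoM-ratio percent increases are 210 %
  and 97 %. Because group means of log-normal ratios at n = 6/10 are
  noisy, planted-effect recovery is asserted at n = 200 per group over
  20 seeds, within ±15 %.
* **Promoters and motifs**: three PWMs (85 % consensus concentration,
  length 10) over 1101-bp promoters; one motif is planted in 60 % of
  foreground and 5 % of background promoters, one occurs at background
  rates everywhere, and one is absent from the upstream-regulator
  table, so the both-tools consensus, the STB filter and the
  complication filter each remove something. Motif length 10 keeps the
  chance-hit probability per promoter at the 60 %-of-max threshold to a
  few percent; shorter motifs at this threshold produce chance hits in
  most 1.1-kb promoters, which would mask any planted occurrence-rate
  contrast.

The ground truth is written as a separate JSON file the pipeline never
reads. Identical configuration and seed reproduce every file
byte-identically. With dropout and abundance noise at zero, every stage
recovers its planted set exactly, and the composed pipeline's shared
secretome equals the planted one with zero discrepancies (asserted at
500 genes).

What the generator does **not** emulate: peptide-to-protein inference,
abundance-correlated dropout, correlated expression across tissues,
batch effects, assay drift between gestational weeks, linkage
disequilibrium of TF binding sites, or promoter base composition beyond
uniform — so green tests validate the rules and statistics, not
robustness to those real-data pathologies.

# Numerical choices and calibration

* Exact discrete tests (hypergeometric, Fisher) have **super-uniform**
  p-values: P(p ≤ α) ≤ α with deficits bounded by the local atom of the
  null distribution. Raw Kolmogorov–Smirnov uniformity therefore fails
  for them by construction, at any sample size. Calibration is asserted
  as: continuous tests (t, ANOVA) pass KS at α = 0.001 and hold type-I
  error within 0.05 ± 0.01 at 10⁴ replicates; discrete tests hold the
  same type-I window where their support allows it, and their
  rejection-rate curve is verified to be never anti-conservative with
  deficits within the analytically computed modal atom.
* Problem sizes in the test suite are chosen for tight feedback:
  brute-force oracle comparisons run on ≥ 100 random instances of ≤ 10
  elements; end-to-end recovery on 500 genes; null calibrations at 10⁴
  replicates; enrichment power at 200 replicates of 50 + 50 promoters
  of 150 bp.
* Manifest determinism relies on writing all outputs with fixed
  formatting and hashing them in sorted filename order; the
  configuration hash covers every analysis constant.

# Known limitations

* GO matching is direct; annotations must be pre-propagated.
* The Fisher threshold-hit enrichment is an approximation, not a
  reconstruction, of rank-based motif enrichment.
* The ANOVA ignores the repeated-measures structure of two weeks per
  subject.
* The published study-scale counts (hundreds of secreted proteins,
  77→33→10 TF funnels) are not reproducible without the original raw
  MS data, external expression compendia and proprietary regulator
  predictions; the synthetic studies validate the machinery, not those
  numbers.
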