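---
title: "Tracking panel and variant-knowledgebase evolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking panel and variant-knowledgebase evolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelwatch)
```

## The measurement

`panelwatch` measures the growth of clinically significant knowledge for a
condition served by a versioned virtual gene panel. The unit of time is the
calendar month; the quantity of interest at month $m$ is

$$V(m) = \sum_{g \,\in\, D(m) \cap M} \mathrm{plp}_g(m),$$

where $D(m)$ is the set of diagnostic-grade genes on the panel version that
represents month $m$, $M$ is the set of genes whose Ensembl ID resolves to
an NCBI GeneID present in the ClinVar summary for that month, and
$\mathrm{plp}_g(m)$ is the P/LP allele count ClinVar reports for gene $g$
in month $m$. Everything else in the package exists to make $D$, $M$ and
$\mathrm{plp}$ well defined and auditable.

### Monthly snapshot rule

A panel's representative version for month $m$ is the latest version whose
creation timestamp is on or before the last day of $m$ at 23:59:59.
Timestamps are interpreted in UTC throughout: panel APIs serialise version
timestamps in UTC, and a fixed zone keeps the month-end cutoff a pure
function of the data. Months without a new version carry the previous
snapshot forward — a panel that is updated annually still has a
well-defined state every month. The selection is monotone: advancing the
cutoff by a month can never select an older version.

### Gene identity and change classification

Genes are tracked across versions by Ensembl stable ID when present,
falling back to symbol. A symbol rename with a stable Ensembl ID is
therefore not a change event. Between consecutive monthly snapshots every
gene lands in exactly one of six disjoint categories (added or removed at
diagnostic or non-diagnostic grade, upgraded, downgraded), and the
bookkeeping satisfies the conservation identity
$\Delta\mathrm{diag} = |\mathrm{added}| + |\mathrm{upgraded}| -
|\mathrm{downgraded}| - |\mathrm{removed}|$ by construction; the test suite
asserts it on every fixture. A gene removed and later re-added counts as a
fresh addition — panel curation histories do not define re-entry semantics,
and treating re-entries as new events is the conservative reading for
re-analysis triggering.

Entries whose entity type is not `gene` (short tandem repeats, CNV regions)
are parsed and retained in snapshots but excluded from every count.
Confidence levels map as: 3 ("Green") is diagnostic; 2, 1, 0 and absent are
non-diagnostic. Absent levels are treated as 0 rather than rejected because
early panel versions omit the field.

### The variant matrix: missing is not zero

ClinVar's monthly `gene_specific_summary` files omit genes with no
submissions. A gene absent from a month's file is therefore recorded as
*missing*, never as a zero count: sums skip missing cells and report how
many genes were missing, so schema drift or a failed download cannot
silently masquerade as biological decline. Rows with GeneID −1 (unassigned)
or with P/LP > total alleles are dropped and tallied in a per-file parse
report. Column names are matched case-insensitively after stripping `#` and
whitespace, with an explicit legacy-name mapping hook, because header
spellings drift across five years of archive files.

One caveat is inherited from the source data and documented rather than
repaired: the P/LP column excludes variants that overlap other genes while
the total-allele column does not, so P/LP-to-total ratios are approximate.
Counts are *not* assumed monotone over time — real genes lose P/LP variants
when submissions are withdrawn or reclassified — and no monotonicity is
asserted anywhere.

### File-to-month assignment

Monthly summary files carry their date in the filename (default: a
`YYYY-MM` or `YYYY-MM-DD` prefix). Each analysis month takes the file whose
date is nearest the month's last day; a month-only date is anchored to its
month end, so conventionally renamed archives map to themselves. Exact ties
break to the earlier file, and a month with no file within 45 days is an
error naming the month. The 45-day tolerance admits either first-of-month
or last-of-month archive conventions while still catching a missing month.

### Identifier reconciliation

Panels speak Ensembl; ClinVar speaks NCBI GeneID. A two-column
BioMart-export table provides the raw correspondence, which can be
many-to-many or one-sided. Resolution precedence is:

1. **manual** — an override from a curated review table always wins;
2. **unique** — a single candidate is taken as-is;
3. **largest_count** — among several candidates, the one with the largest
   total-allele count at the latest month all candidates appear in (falling
   back to the latest month any appears in); exact ties break to the
   numerically smaller NCBI ID, purely for determinism;
4. **unmatched** — no candidate: the resolution is `NA`, a value rather
   than an error, and the gene is reported in the matched-versus-total dual
   counts downstream.

Total alleles at the latest shared month is used as the ambiguity evidence
because the most recent data best reflects current gene-model annotation.
The chosen NCBI ID is fixed per gene for the whole analysis — resolution is
not recomputed per month — so a gene's identity cannot flap between
candidates as counts drift.

### Join modes

*Static* mode crosses a frozen, annotated gene list with every month of the
matrix (the view behind "how did evidence for this fixed list grow").
*Evolving* mode recomputes the diagnostic set from each month's own
snapshot and sums that month's counts (the view behind "what did a curator
actually have available"). On a panel with zero change events the two modes
agree month for month; the test suite asserts this equivalence, as well as
additivity (the joined sum equals the sum of its per-gene cells) and
responsiveness (upgrading a gene with $c$ P/LP variants at month $k$ raises
$V(k)$ by exactly $c$).

### Change metrics

The change between two counts is the plain percentage increase
$100\,(e-s)/s$; a zero start is undefined (`NA` with a warning), never a
division error. Internal values stay unrounded; rounding to integer percent
for reports is a separately named step using round-half-away-from-zero,
with truncation available as a configuration, since published tables are
consistent with either rule depending on the cell. Month-over-month deltas
are summarised by their arithmetic mean, median and range — arithmetic
because "average change per month" is the natural reading — with a
geometric (compounding) mean available as an option. A *burst* is a month
whose absolute percentage change strictly exceeds a threshold, default
5%/month; the absolute value is used so that large declines (which do occur,
e.g. mass reclassifications) are surfaced too, and detection is monotone in
the threshold. The threshold is illustrative, not derived, and is a
first-class configuration knob. Pearson correlation between aligned series
uses the standard product-moment coefficient, with constant series and
fewer than three points returning `NA` under a warning.

## The synthetic data generator

The generator writes the same three file families the real pipeline
consumes — panel version JSON documents, monthly summary TSVs with
`#`-prefixed headers, and a BioMart-style mapping table — plus a
machine-readable log of every injected event with its realised count delta.

What it emulates:

* geometric per-gene P/LP growth with multiplicative log-normal noise,
  mean 1.8%/month — the scale of growth real ClinVar P/LP series show —
  with benign counts growing alongside so P/LP never exceeds total alleles;
* panel events (add/upgrade/downgrade/remove) realised as new panel
  versions mid-month, so the monthly snapshot rule is exercised;
* count steps and declines on single genes, compounding into later months;
* identifier pathologies: one-sided mapping rows, injected unmatched genes,
  and many-to-one clashes with an evidence-poor decoy candidate.

Panel composition is deterministic given the spec fractions (gene $i$ of
$n$ launches diagnostic, non-diagnostic, or off-panel by index); the seed
drives only the stochastic count series. This makes event schedules in
tests easy to write against a known starting state, and makes byte-level
reproducibility of the generated files trivially checkable — which the
suite does check.

What it does not emulate, and what passing tests therefore do not show:
submission-level ClinVar dynamics (review status, star ratings,
per-submitter churn), real gene symbols or real panel curation rationale,
panel renames or merges, and the heavy-tailed distribution of real
per-gene counts (SCN1A-like outliers). Full-recovery of the event log on
fixtures demonstrates the pipeline's bookkeeping is exact; it does not
validate scientific claims about any real panel, which require the live
archives.

## Problem sizes and numerical choices

The test suite and acceptance script run fixtures of 50 genes × 24 months
(full pipeline recovery) and 10–30 genes × 3–18 months (per-module checks),
sizes at which brute-force oracles — re-deriving snapshot selection by
scanning all versions, re-sorting rankings, recomputing sums by hand — are
feasible and exact. All fixture assertions are exact integer comparisons;
the only tolerance in the suite is on recovering a planted correlation of
0.9 from 60 noisy points (±0.1, several sampling standard deviations).
Degenerate inputs have defined behaviour rather than errors wherever a
value can be meaningful: empty snapshots are legal, zero starts give `NA`
percents, unmatched genes give `NA` resolutions; errors are reserved for
structurally unusable input (missing required columns, a window preceding
the first panel version, a month with no summary file) and always name the
offending field, month or file.

## Known limitations

* Variant-level deduplication across genes is impossible from the per-gene
  summary files; overlapping-gene variants are counted once per gene they
  are reported under, as in the source data.
* The union diagnostic list deduplicates by Ensembl ID when present, else
  symbol; two panels naming the same locus with different identifiers and
  no shared Ensembl ID would be counted twice.
* The fetch helper lists (and optionally downloads) live PanelApp and
  ClinVar archive URLs, but endpoint layouts change; it is a convenience,
  not a tested contract, and nothing else in the package depends on it.
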