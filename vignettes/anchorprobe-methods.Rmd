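---
title: "Anchor-gene selection and riboprobe design: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-gene selection and riboprobe design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorprobe)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and where the genuinely open design decisions
landed. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. The problem

A developing organ profiled compartment-by-compartment (laser-capture
microdissection or FACS, replicate microarrays per compartment) yields a
probeset × sample matrix in raw fluorescent units (RFU). An *anchor gene*
is one whose expression is restricted to exactly one temporospatial
compartment; a *marker* (enriched) gene is expressed there plus elsewhere.
Anchors are rare, and the cost of validating a prediction by section in
situ hybridisation (SISH) is high, so the selection must be stringent and
the validation probe must interrogate the same transcript region as the
array probeset, or the comparison is confounded by transcript complexity.

## 2. Selection cascade

### 2.1 Statistics

Replicates are averaged per compartment by the arithmetic mean (the
conventional summary; the aggregation step is otherwise unconstrained by
the source analysis). For probeset $g$ and target compartment $c$:

* `raw` $= \bar{x}_{g,c}$, the target-compartment mean (RFU);
* `median_other` $= \mathrm{median}_{k \ne c}\ \bar{x}_{g,k}$ — the target
  is **excluded** from the reference median;
* `fold_change` $= \mathrm{raw}/\mathrm{median\_other}$, on the **linear**
  scale. Published tables of this design print linear ratios (e.g.
  916.2/74.5 = 12.3) even where figure legends mention a log scale; the
  table arithmetic is authoritative here. An optional `log2_fold_change`
  column is available for reporting. Degenerate limits: ratio of a
  positive signal to a zero median is `Inf`; 0/0 is defined as 1.
* Significance: Welch's heteroscedastic one-way F across the replicate
  groups of all compartments (one test per probeset), with
  Satterthwaite-type denominator degrees of freedom, delegated to
  `stats::oneway.test(var.equal = FALSE)`; Benjamini–Hochberg correction
  across probesets via `stats::p.adjust`. The test suite re-derives both
  from the textbook formulas as independent oracles.

Zero-variance replicate groups make Welch's weights infinite;
`welch_anova()` refuses them (classed degenerate-input error) rather than
jittering data silently. The pipeline wrapper
`compute_specificity_stats(..., degenerate = "resolve")` instead assigns
the limiting p-value (0 if any group means differ, 1 if the probeset is
flat). This convention exists so that noise-free synthetic data — where
*every* group is degenerate — remains usable; real data essentially never
triggers it.

### 2.2 Filters, exclusion, ranking

Defaults in `selection_config()`:

| parameter | default | unit | meaning |
|---|---|---|---|
| `p_threshold` | 0.01 | probability | cut on BH-adjusted q |
| `fold_min` | 2 | ratio | minimum fold-change, strict `>` |
| `raw_min` | 100 | RFU | minimum target-compartment signal, strict `>` |
| `median_max` | 200 | RFU | ranking preference ceiling on `median_other` |
| `cross_fold_exclude` | 2 | ratio | disqualifying fold in any other compartment, `>=` |
| `per_compartment_fold_min` | EPT = 10 | ratio | per-compartment overrides |

Decisions that were genuinely open:

* **Strict inequalities.** "Minimum of 2-fold and 100 RFU" is read as
  `> 2` and `> 100` (matching the "fold-change > 2" phrasing); boundary
  rows are excluded. Tests pin this convention.
* **`median_max` is a preference, not a filter.** The published final
  anchor list contains rows with reference medians well above 200 RFU
  (e.g. 1129 RFU), so a hard filter would contradict the published
  outcome; instead such candidates are flagged (`high_median`) and sink to
  the bottom of their list.
* **The q-scale carries the 0.01 cut.** The source pipeline applies
  "P < 0.01 plus BH correction" without saying on which scale the cut
  lands; filtering on adjusted q < 0.01 is the stricter and more
  defensible reading.
* **Exclusion order.** Cross-expression exclusion is applied after the
  filters and before ranking; because both are row-wise predicates the
  result is order-independent, which a test asserts explicitly.
* A subset analysis over fewer compartments is supported by passing a
  restricted sample table — there is no separate code path.

### 2.3 The bundled reference table

The final published anchor list (37 probesets, 6 compartments) ships as a
plain-TSV fixture. Its printed fold-change column is rounded to the
precision printed — several rows to whole numbers — so
`load_table1_fixture()` recomputes `fold_change = raw / median_other` (the
invariant the rest of the package relies on) and keeps the printed value
in `fold_change_printed`. `printed_fold_concordance()` audits the two at
the printed precision; 36 of 37 rows agree within ±0.2 (the one
exception, Ugt2b37, prints 179 where raw/median gives 177.8 — plausibly
derived from normalised rather than raw values upstream; the package does
not guess). The underlying arrays are not bundled, so `p_anova`/`q_bh`
are `NA` and must be asserted by the caller before running the table
through `apply_filters()`.

## 3. SISH pattern classification

Per-gene compartment calls (graded `weak`/`present`/`strong` collapse to
detected; grading is preserved for reporting only) map to five labels:
`specific` (target only), `enriched` (target plus some but not all),
`ubiquitous` (all annotated compartments), `not_detected` (none),
`non_specific` (somewhere, but not the target). Two boundary readings were
fixed deliberately: *ubiquitous* requires detection in **all** annotated
compartments (broad-but-partial patterns are enriched), and a gene
detected in the target plus an unexpected compartment is *enriched*, not
non-specific, following the "correct compartment and at least one other"
definition. The classifier never infers unobserved compartments — a gene
expressed in a structure outside the annotation set must be encoded by the
caller as an extra call column. `validation_summary()` reports counts,
percentages (1 decimal) and the combined specific + enriched rate.

## 4. Probe mapping and template selection

Probes are 25-mers; matching is **exact** (the pipeline describes
matching, not alignment, and at transcript scale a direct scan is
sufficient — `Biostrings::vmatchPattern` does the search). Array probes
may be antisense to the mRNA, so both orientations are searched by default
and reported. All coordinates are 0-based half-open (BED-native) in
transcript space. The 80 %-of-probes rule generalises to
`coverage >= 0.8` of the probeset's size, counting distinct probes hit
anywhere on the transcript (the contiguity question is left to template
selection, which must contain the hits anyway). Where several probesets
interrogate one locus, ranking prefers coverage, then the 3′-most probe
span — a transcript-space approximation of exonic-overlap prioritisation,
noted as a simplification since no genome annotation is consumed.

Template selection takes the smallest interval containing every hit,
extends it to 500 bp preferring the 3′ direction (riboprobes target the
3′ UTR region), clips at transcript bounds, and falls back to the 3′-most
800 bp window maximising contained probes when the span itself exceeds
800 bp. Transcripts shorter than 500 nt are rejected with a length error.

## 5. Primer design and in-silico PCR

The primer search is self-contained and deterministic. Defaults
(`primer_constraints()`): product 500–800 bp; primer length 18–27 nt; Tm
52–68 °C, optimum 60 °C; GC 40–60 %; homopolymer runs ≤ 4; canonical T7
promoter tag `TAATACGACTCACTATAGGG` prepended to the reverse primer. Tm
and GC are computed on the primer **core** (the tag does not anneal in
early cycles). The Tm model is the Wallace rule
$T_m = 2(A{+}T) + 4(G{+}C)$, chosen for hand-verifiability; it is a
pluggable strategy (`tm_fun`), so a nearest-neighbour model can be swapped
in without touching the search.

The scan enumerates every valid (start, length) primer site — Tm, GC and
homopolymer feasibility are computed with cumulative sums, and candidates
are grouped by Tm (under the Wallace rule a small set of even integers),
which makes the pair search over
score $= |T_f - 60| + |T_r - 60| + |T_f - T_r|$ exact and fast. Ties
break toward the larger product end (3′ preference), then the shorter
product, then shorter primers — the last two tie levels are package
conventions, fixed so that identical inputs always yield identical
primers.

One deviation from the most literal pipeline reading proved necessary: a
template extended only to the 500 bp minimum admits a 500–800 bp product
only with primers at its exact edges, which fails on random sequence more
often than not. `design_riboprobes()` therefore searches a window extended
(3′-preferring) around the template up to one maximum product length,
while constraining the amplicon to contain the covered probe span — the
designed riboprobe still overlaps the full probeset, which is the point of
transcript-centric design. `design_primers()` exposes this as the optional
`contain` argument; called directly on a comfortable region (say 700 bp)
it behaves as the plain constrained scan.

In-silico PCR is a brute-force specificity check: exact sense occurrences
of the forward primer paired with exact downstream occurrences of the
reverse core's reverse complement on the same transcript, convergent and
non-overlapping, product capped at 4000 bp by default. Exact 3′-end
matching (0 mismatches) is required; there is deliberately no mismatch
allowance by default. A clean design yields exactly one amplicon on its
source transcript set.

## 6. Synthetic data and what it does (not) show

`generate_expression_fixture()` emulates the atlas structure: 11
compartments (kidney codes CM … RC), 3 replicate arrays each (replicate
counts are unstated in the source; 3 is a realistic microarray design),
200 background probesets at 50 RFU with Gaussian noise (sd 5 RFU,
truncated at 0) and 5 planted anchors at fold 20. Background sits below
the 100 RFU floor so background probesets are doubly excluded; raising
`background_level` stresses the fold filter alone. The generator records
its truth, and recovery is monotone in fold and anti-monotone in noise
(tested). What it does **not** emulate: probe-level intensity models,
correlated probeset noise, compartment cross-contamination, or
cell-density-dependent signal — so perfect recovery on fixtures bounds
algorithmic correctness, not performance on real arrays.

`generate_transcript_fixture()` plants 11 non-overlapping 25-mers per
probeset in a window ending ~100 nt from a random transcript's 3′ end
(so template selection exercises its 3′-extension and boundary-clipping
paths), storing 2 of 11 probes antisense by default. Problem sizes
throughout the suite (hundreds of probesets, kilobase transcripts, 20
fixture seeds) are chosen so the full test run completes in well under a
minute while still exercising every code path.

## 7. Known limitations

* Exact matching only: a probe with a single mismatch to the transcript
  set is invisible, unlike BLAST/BLAT-based pipelines.
* Transcript-space specificity: in-silico PCR cannot reveal genomic
  off-target amplification outside the supplied transcript set.
* Wallace-rule Tm is crude for primers above ~25 nt; use `tm_fun` for
  thermodynamic accuracy.
* No dimer/hairpin screening; a wet-lab pipeline should re-check chosen
  pairs.
* The ANOVA assumes within-compartment replicates are exchangeable;
  batch structure must be handled upstream.
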