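---
title: "Methods: tissue-specific transcript calling and co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specific transcript calling and co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuespec)
library(dplyr)
```

## The analysis model

`tissuespec` implements the downstream arm of a multi-tissue transcriptome
survey in which each tissue is sequenced as technical replicates at
independent sites, but biological replicates are unavailable. Without
biological replication there is no defensible variance estimate per
transcript and tissue, so the design deliberately avoids significance
testing for specificity and relies on (i) aggressive filtering of weak
expressors and (ii) a plain fold-change criterion, with reliability coming
from replicate concordance rather than from p-values.

All analysis operates on `log2(FPKM + c)` with pseudocount `c = 0.1`. The
pseudocount is intentionally large: for a transcript with FPKM near zero,
`(x + 0.1)/(y + 0.1)` is pulled toward 1, so weak expressors cannot
produce large fold changes. A much smaller pseudocount makes low-expressor
fold changes unstable; a larger one blunts genuine signals. The value 0.1
is a convention for FPKM-scale data and is exposed as a parameter
everywhere it enters.

### Preprocessing

Technical replicates are collapsed to one column per tissue by the
geometric mean of `(FPKM + c)` minus `c`, floored at zero. On the log2
scale this is exactly the arithmetic mean of the replicate log values, so
every downstream log-scale statistic is a replicate average; an arithmetic
FPKM mean is available as an alternative. The low-expression filter then
keeps a transcript iff the geometric mean of `(value + c)` across tissues
is at least 1, with the boundary inclusive (a transcript at exactly 1 is
kept). One useful closed form: with 13 tissues at zero and one at `x`,
retention requires `(x + 0.1) ≥ 10^13`, i.e. the filter essentially never
keeps single-tissue expressors on the tissue-aggregated matrix —
tissue-specific calling therefore happens among transcripts with broad
baseline expression, which is what the pseudocounted fold change is
designed for.

Expressed-transcript detection is a separate path on purpose: a transcript
counts as expressed in a library when its **raw** FPKM is ≥ 1 — no
pseudocount, no aggregation — so detection counts are invariant to the
transform parameters. Replicate concordance is Spearman's rank correlation
(average ranks for ties, which are common at FPKM 0) per tissue, split
into coding vs noncoding when an annotation is bound.

### Biotype merging

Raw Ensembl biotypes are merged by an ordered rule list (first match
wins): anything containing `pseudogene` → `pseudogene` (this precedes the
prefix rules, so `IG_pseudogene` is a pseudogene, not an IG gene), `TR_*`
→ `TR_gene`, `IG_*` → `IG_gene`, `protein_coding` → itself, everything
else → itself. The rules are a data frame that can be read from and
written to TSV, so other annotation releases can be remapped without code
changes, and the number of noncoding classes is emergent from the input
rather than hard-coded. Class tables report the coding/noncoding split as
a percentage of all transcripts (one decimal) and each noncoding class as
a percentage of noncoding (nearest integer), matching the usual reporting
precision for such tables.

### Specificity calling

With tissue values `v_t = x_t + c`, a transcript is specific to its argmax
tissue `t*` iff `v_{t*} / max_{t ≠ t*} v_t ≥ F` with `F = 2`. The
comparison is inclusive ("at least two times"); an exact tie at the
maximum means no tissue strictly dominates and the transcript is never
specific — a conservative, order-independent convention. At most one
tissue can satisfy the criterion, which the code asserts on every run.
Raising `F` can only remove calls (monotonicity), and the pseudocount
guarantees measured fold ≤ true FPKM-scale fold for low expressors. Calls
are labelled TSCT or TSNT by merged class. For heatmaps, the log-scale
tissue profiles of the calls are Z-scored per transcript (sample sd), with
zero-variance rows dropped with a warning rather than emitting NaNs, and
rows grouped into tissue blocks ordered by descending call count.

### Co-expression network

The network is built from scratch on log2 expression across **all
libraries** (tissue × site), not the aggregated columns — the correlations
gain degrees of freedom and the replicate structure is shared by all
transcripts, so it does not bias pairwise correlation. Adjacency is the
unsigned soft threshold `a_ij = |cor_ij|^β` with β = 20; the unsigned form
treats strong negative co-regulation as connection, and β = 20 suppresses
moderate correlations (0.9²⁰ ≈ 0.12). Scanning β against a scale-free fit
index is out of scope; β is a parameter with a stated default.

Topological overlap is the standard unsigned form

TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij),

implemented with matrix products and checked in the tests against a
brute-force triple loop at 1e−12. Modules are branches of the
average-linkage dendrogram of `1 − TOM` cut at a fixed height (default
0.995) with at least `min_module_size` (default 60) leaves; everything
else is module 0 ("gray"). This is the static-height tree cut: the
dynamic-hybrid algorithm adapts the cut per branch and can rescue modules
on messy dendrograms, but it has many interacting heuristics; for this
package's scope the fixed cut is transparent, deterministic, and fully
testable, and the cut height is exposed. Average linkage is monotone, so
the only height-order issue is float noise, which is clamped (and bounded
at 1e−8). Module labels are integers by decreasing size. Hubs are each
module's top `n_hubs` (default 30, mirroring a 30-hub module report in the
motivating design) members by intramodular connectivity `Σ` of
within-module adjacency, exported as VisANT-style edge lists.

### Enrichment

Over-representation of a query (one tissue's calls) in each gene set uses
the exact hypergeometric upper tail `P(X ≥ overlap)` on a configurable
universe (default: all retained transcripts), with Benjamini–Hochberg
adjustment across sets. DAVID-style tools use the EASE-modified Fisher
score and curated databases; their p-values are therefore not comparison
targets — the hypergeometric tail was chosen because it is exact,
dependency-free, and reproducible offline.

### Sample reports

PCA is computed on transcript-centred (not Z-scored) log2 values — only
the location of each transcript is removed, so highly expressed
transcripts retain their larger leverage, as in standard expression PCA.
Component signs are fixed by making the largest-magnitude loading
positive. Sample clustering uses `1 − Pearson` with average linkage, with
samples sorted lexicographically first so merge-height ties resolve
deterministically.

## The synthetic-data generator

`simulate_expression()` emulates the statistical structure of the study
design so every stage can be validated against known truth. On the log2
scale, transcript *i* in library *s* is

baseline_i + spike_i · 1[s ∈ tissue(i)] + λ_i · f_{m(i)}(tissue(s)) + ε_is

- `baseline_i ~ N(3, 1.5²)` log2-FPKM: a heavy-tailed FPKM distribution
  with median ~8 FPKM; all planted structure sits on expressed
  transcripts, as in a filtered survey.
- `spike = log2(specific_fold)` (default fold 8) for the
  `n_specific_per_tissue` (default 40) planted specifics of each tissue.
- Co-expression blocks: `module_size_per_tissue` (default 80) members per
  tissue share a latent per-tissue factor `f_m ~ N(0, module_factor_sd²)`
  (default sd 0.5) with member loadings `λ ~ U(0.75, 1.25)`. The factor
  value is a property of the tissue, shared by its replicates — so with
  zero replicate noise a tissue's two site columns are identical, and the
  factor contributes to between-tissue, not within-pair, variation. The
  factor's top-tissue excursion is capped at 0.6 log2 above the runner-up:
  a block is defined as *co-expressed*, not *tissue-specific*, and with
  loadings ≤ 1.25 the cap keeps every member's tissue gap below 1 log2, so
  block membership can never masquerade as a 2-fold specificity call.
  Planted specifics and block members are disjoint sets: under an unsigned
  `|cor|^20` adjacency, a spike pattern (high in 2 of 28 libraries) and a
  factor pattern correlate only ~0.5–0.8, which β = 20 crushes to ~0, so
  one module cannot contain both kinds of signal.
- `ε ~ N(0, 0.1²)` per library: technical site noise, reproducing high
  replicate concordance without modelling site-specific bias.
- A `dropout_fraction` (default 0.15) of unplanted transcripts is set to
  FPKM 0 in every library to exercise the low-expression filter.
- Biotypes: coding transcripts are `protein_coding`; noncoding raw
  biotypes are multinomial with defaults dominated by processed
  transcripts (56%), lincRNAs (20%), and pseudogene variants, including
  `IG_pseudogene`-style composites so the merge precedence is exercised.

The RNG draw order is fixed and the whole simulation runs under a local
seed, so identical configurations are byte-identical and the caller's RNG
state is untouched. `simulate_gene_sets()` builds one marker set per
tissue (that tissue's planted specifics plus ~10 random decoys) and random
background sets.

What the generator does **not** emulate: library-size differences (FPKM is
treated as already normalized, and no between-sample normalization is
applied — matching the analysis it feeds), isoform-level quantification
uncertainty, site-specific bias (noise is exchangeable across sites),
correlated biological variation between related tissues, and any
read-level process. Passing recovery tests on this generator therefore
shows the pipeline's operations are correct and well-calibrated under the
stated model, not that the model captures every property of real tissue
panels.

## Problem sizes and numerical choices

The reference validation configuration is 14 tissues × 2 sites, 5,000
transcripts, 40 planted specifics per tissue at fold 8, blocks of 80,
noise sd 0.1, seed 42 — large enough that per-tissue recovery statistics
are stable, small enough that the full suite (including a 1,120-node
network) runs in well under a minute. Recovery expectations under this
configuration, all recomputed at run time by the tests and
`scripts/acceptance.R`: specificity sensitivity ≈ 0.98 (the ~2% shortfall
is planted specifics whose baseline falls below the filter boundary — the
sensitivity denominator deliberately includes them), precision ≈ 1,
planted-module ARI ≈ 1, and every tissue's marker set top-ranked by
adjusted p.

Other numeric conventions: the filter and specificity comparisons are
inclusive at their boundaries; ties at the specificity maximum are
non-calls; TOM values are clamped to [0, 1] and symmetrized against float
noise; `cutree` heights are clamped monotone (tolerance 1e−8);
zero-variance rows are an error for adjacency (the caller must filter)
but a warned drop for Z-scoring; BH adjustment validates `p ∈ (0, 1]`
before delegating to the standard step-up implementation.

## Known limitations

- The static-height tree cut can shred loosely attached modules that the
  dynamic-hybrid cut would rescue; on clean block structure they agree.
- Fold-change specificity has no error control; it is only as reliable as
  the filtering and replicate concordance that precede it.
- The hypergeometric test treats transcripts as exchangeable and ignores
  transcript–gene multiplicity unless the caller maps identifiers first.
- With the default `min_module_size = 60`, call-based networks from
  designs with fewer than ~60 specifics per tissue leave everything gray;
  lower the threshold (as `run_pipeline(min_module_size = )` allows) for
  such designs.
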