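---
title: "Integrative DEG, network-hub and TAP-MS analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative DEG, network-hub and TAP-MS analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degnet)
```

# The analysis this package implements

`degnet` re-implements, as tested reusable code, an integrative analysis of
how overexpressing the selective-autophagy receptor NBR1 reshapes a plant's
response to sulfur deficit. The analysis has four statistical stages that
this package treats as first-class, composable operations:

1. **DEG calling.** Per-gene fixed-effects 3-way ANOVA over the crossed
   factors genotype × sulfur condition × tissue, followed by a joint filter:
   linear fold change of at least ±1.5 *and* p < 0.05 for the
   deficient-vs-sufficient contrast.
2. **Set algebra.** Venn partitioning of DEG sets (two genotypes) and of
   condition-specific interactomes (three growth conditions), with overlap
   percentages; plus 1-based inclusive residue-interval arithmetic for
   mapped protein interaction regions.
3. **Conditioned hub analysis.** For every node of a protein–protein
   interaction network, its total degree and its degree *within* a query set
   (DEGs, or bait co-purifying proteins). Hubs are nodes whose conditioned
   degree reaches 10; differential hubs differ between two conditioned
   networks by at least 9 partners *and* at least 20% relative to each
   other.
4. **TAP-MS scoring.** Semiquantitative scoring of bait-vs-control
   purifications: abundance = mean detected bait intensity / molecular
   weight; specificity = mean bait intensity / mean control intensity, with
   the control background set to the arbitrary value 1 for proteins never
   detected in the control.

Because the original raw data are not bundled, a synthetic-data module
generates all four inputs (expression matrix, edge list, intensity tables,
family annotation) with *planted* structure, so every downstream stage can
be scored against known truth.

# The per-gene ANOVA and the DEG filter

For gene $g$ with log2 expression $y$ the model is the full factorial

$$y_{ijkr} = \mu + \alpha_i + \beta_j + \gamma_k + (\alpha\beta)_{ij} +
(\alpha\gamma)_{ik} + (\beta\gamma)_{jk} + (\alpha\beta\gamma)_{ijk} +
\varepsilon_{ijkr},\qquad \varepsilon \sim N(0, \sigma_g^2)$$

fitted by ordinary least squares. The design matrix is shared by all genes,
so the package QR-decomposes it once and projects every gene through it;
with a balanced design and sum-to-zero contrasts the sequential sums of
squares equal the marginal ones, and the per-term F tests match a textbook
cell-means computation (this is asserted in the tests to 1e-8 relative
error against an independent from-scratch oracle).

Which p-value gates a DEG is a genuine design choice: the filter could use
the condition main effect or a contrast local to one genotype and tissue.
We default to the **per-contrast comparison** — the stressed-minus-reference
cell-mean difference within the relevant genotype and tissue, tested as a
linear contrast under the fitted model (pooled residual variance, residual
degrees of freedom) — because DEG sets are reported separately per genotype
and tissue, which a global main effect cannot deliver. The alternative is
exposed as `p_source = "condition_main_effect"`.

Fold change is computed on the linear scale as
$2^{\bar y_{-S} - \bar y_{nS}}$ and sign-coded as $-1/\text{ratio}$ when the
ratio is below 1, so the "at least ±1.5" rule is symmetric; the boundary
value exactly 1.5 passes. No multiple-testing correction is applied by
default because the filter is defined on raw p-values;
`correct = "BH"` is available. Zero-variance genes report p = 1 and fold
change 1 rather than erroring; genes with missing values are dropped (with
a count) before fitting.

# Set partitions and percentages

Partitions are exact set algebra over whitespace-stripped, case-sensitive
identifiers; duplicated IDs within one input collapse with a warning. The
two-way common fraction is $100\,|A\cap B| / |A\cup B|$; the three-way
summary is the triple-intersection percentage
$100\,|A\cap B\cap C| / |A\cup B\cup C|$. Percentages are returned exact
and rendered with `round_half_up()`, since banker's rounding (R's default)
disagrees with how such tables are conventionally reported.

Residue coordinates are 1-based and inclusive at both ends, so a region
from residue 92 to residue 405 spans `405 - 92 + 1 = 314` amino acids.

```{r residues}
region_length(residue_interval(92, 405))
```

# Family overrepresentation

The categorization-server step of the original workflow is replaced by an
explicit one-sided hypergeometric test: for a family of size $m$ in a
universe of size $N$, a query of size $n$ overlapping it in $k$ genes gets
$p = P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, m, n)$, flagged at
p < 0.01 by default. The universe defaults to all annotated genes and can
be overridden (e.g. to all genes on the array). Raw p-values are used, to
match threshold-style reporting; BH adjustment is optional. Tests verify
the tail against explicit binomial-coefficient enumeration for
universes up to 25 genes.

# Conditioned degrees, hubs, differential hubs

`conditioned_degrees()` flattens the interaction database to one undirected
edge per unordered ID pair (self-loops dropped, evidence multiplicity
collapsed) and counts, per node, total partners and partners inside each
query set. Choices worth stating:

* **Threshold semantics.** Hub selection is inclusive ("equal 10 or
  higher"); a secondary annotation tier at degree ≥ 3 supports plot
  labeling. Ties in the ranking are broken by node ID so output is
  deterministic.
* **Relative difference denominator.** "At least 20% in relation to each
  other" is ambiguous; we fix the denominator to $\max(d_1, d_2)$ — the
  symmetric, conservative reading, under which a call flagged one way is
  flagged the other way too — and expose `rel_denominator = "min"`/`"mean"`.
  When both degrees are 0 the relative difference is defined as 0.
* **Bait exclusion.** In proteomic-hub analysis the bait trivially touches
  every prey, so `conditioned_degrees(..., exclude = bait)` removes it from
  the query sets (not from the network). This is off by default and the
  caller decides.
* **Candidate nodes.** For the proteomic arm, candidates are the
  co-purifying proteins plus their first neighbors
  (`expand_first_neighbors()`), applied before conditioning.

The differential rule is conjunctive: flagged iff
$|d_1-d_2| \ge 9$ **and** $|d_1-d_2|/\max(d_1,d_2) \ge 0.20$. Swapping the
two networks flips every direction but preserves the flagged set (tested).

# TAP-MS scoring

"Not detected" is encoded as `NA`, never 0, so the background rule has an
unambiguous trigger. Abundance averages over *detected* replicates only
("two or one"). Specificity divides mean bait by mean control intensity;
for control-absent proteins the background is the arbitrary constant 1, so
their specificity numerically equals the mean bait intensity. A documented
consequence is scale covariance: rescaling all intensities by $c$ leaves
control-detected specificities unchanged but scales control-absent ones by
$c$ — which is why `score_tap()` also reports `detected_in_control`, letting
users filter on presence instead of on a scale-dependent number. A control
intensity recorded as detected-at-0 is floored to the smallest positive
detected intensity in the table (logged) rather than divided by.

No interactome-defining cutoff is stated in the original report;
`call_interactome()` therefore makes the choice explicit: control-detected
proteins need specificity ≥ 2 (configurable), control-absent proteins pass
on presence alone (toggleable). Calls are monotone in the threshold.

# The synthetic world

The generators' defaults *are* the stated study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| design | 2 genotypes × 2 conditions × 2 tissues × 3 replicates | the factorial layout of the emulated microarray study |
| baseline log2 expression | Normal(8, 2) per gene | typical of normalized array data |
| planted DEG fraction / effect / noise | 0.10, log2FC = 2, sd = 0.25 | the operating point at which recovery is scored (≥ 95% recovery, ≤ 7% false calls) |
| network background | power-law fitness, exponent 2.5 | mimics PPI degree heavy tails |
| background mean degree | 3 | sparse PPI-like connectivity |
| planted hubs | degree ≥ 20 vs selection threshold 10 | separation that makes 100% recovery the correct answer |
| TAP intensities | log-normal around 1e6, 2 replicates | MaxQuant-like intensity magnitudes; duplicate runs |

One numerical note: a pure $k^{-2.5}$ degree law has mean ≈ 1.95, which
cannot honor an arbitrary `background_degree_mean`. The generator therefore
draws power-law *fitness* scores (igraph's static fitness model) and sets
the edge count to `n_nodes * background_degree_mean / 2`: the tail shape
comes from the power law, the mean from the parameter.

What the synthetic world deliberately does **not** emulate: probe-level
effects, normalization artifacts, correlated genes, peptide-level evidence,
missing-not-at-random dropout in MS, or evidence-type structure in the
network. A green recovery test therefore establishes that the pipeline's
logic is correct under its stated model, not that thresholds are optimal
for any real dataset.

Determinism: every generator consumes one user seed through R's RNG stream;
identical seed and parameters give byte-identical outputs (tested).
`run_pipeline()` derives per-stage seeds as small fixed offsets of the
master seed; its stage outputs and `summary.json` are byte-reproducible,
while `manifest.json` carries a timestamp and is exempt from that contract.

# A short worked run

```{r pipeline}
out <- file.path(tempdir(), "degnet-demo")
s <- run_pipeline(run_config(seed = 1), out)
vapply(s$deg_recovery, function(r) r$recovery, numeric(1))
s$hubs$planted_hub_recovery
s$tap$planted_specific_recovery
```

# Known limitations

* The ANOVA path assumes a complete, balanced (or near-balanced) crossed
  design; severely unbalanced designs change the equivalence between
  sequential and marginal sums of squares.
* Specificity for control-absent proteins is intensity-scale dependent by
  definition of the background-1 convention; compare such values only
  within one acquisition.
* Hub analysis inherits the reference interaction database's ascertainment
  bias; no significance test is attached to hub calls (thresholds only), a
  permutation null being a possible future extension.
* ID namespaces (gene vs protein identifiers) are the caller's
  responsibility; the pipeline's synthetic world sidesteps this by placing
  the network over the gene namespace.
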