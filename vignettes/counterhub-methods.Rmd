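---
title: "Methods: counter-regulation signatures and focus-hub ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counter-regulation signatures and focus-hub ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`counterhub` implements a transcriptome-to-target workflow used in
disease/treatment expression studies: given probe-level expression for a
control group, a disease group and one or more curative-treatment groups,
plus a gene-interaction graph, it

1. summarizes probes to transcripts (quantile normalization + median polish),
2. calls disease differential expression with the rank-product statistic and
   permutation p-values,
3. extracts the treatment **counter-regulated** signature — transcripts the
   treatments move in the direction opposite their disease change — via
   K-means binning of fold-change profiles plus a magnitude/significance
   filter, and
4. nominates candidate therapeutic targets as **focus hubs**: the
   highest-degree nodes of a merged, enrichment-scored set of
   signature-seeded subnetworks.

A synthetic-data generator with planted ground truth makes every stage
testable end to end without external data.

# Normalization and summarization

Inputs are log2-scale probe intensities (`probe_matrix`), several probes per
transcript (11 by default in the generator, the typical scale for 3'
oligonucleotide arrays). `quantile_normalize()` forces all sample columns to
a common distribution (the across-column mean of sorted values; ties share
the mean of the reference values at their rank positions — the
`limma::normalizeQuantiles` convention, chosen for determinism).
`median_polish_summarize()` then fits, per transcript, the robust additive
model

$$y_{ps} = \mu + \alpha_p + \beta_s + \varepsilon_{ps}$$

by iterated median sweeps (rows first, tolerance $10^{-6}$ on the relative
change in the sum of absolute residuals, at most 20 iterations) and reports
$\hat\mu + \hat\beta_s$ as the transcript's signal, i.e. the summarization
step of the RMA workflow. Background adjustment is deliberately **not**
implemented: the pipeline accepts probe- or transcript-level tables that are
assumed background-clean, which is what the generator produces. Transcripts
with a single probe pass through unchanged.

Two numerical notes. Median polish on even-sized blocks can stop at
`max_iter` without meeting the tolerance; the summarizer then emits a single
summary warning rather than failing (the fit is still the standard 20-sweep
RMA-style fit). And quantile normalization is a fixed point only when
columns already share a distribution — planted group shifts violate that by
construction, so the exact zero-noise recovery tests run summarization
without it; with noise, the distortion is negligible relative to the 2-fold
threshold and the full pipeline includes it.

# Rank-product differential expression

For a contrast (numerator group vs denominator group) with $n_1 \times n_2 =
k$ between-group sample pairs, each pair ranks all $G$ transcripts by the
pairwise log2 difference (rank 1 = most up-regulated for the up statistic,
most down-regulated for the down statistic; ties get average ranks). The
rank product is the geometric mean of a transcript's ranks across the $k$
pairs, computed in log space so $G = 50{,}000$, $k = 16$ does not overflow.

Significance uses the original rank-product null: each of `n_permutations`
(default 100) replicates assigns uniformly random rank permutations to each
pairwise comparison, and the null rank products are pooled across
transcripts and permutations:

$$p = \frac{1 + \#\{\text{null rp} \le \text{observed rp}\}}{1 + n_{perm} G}.$$

This null was chosen over sample-label permutation because with duplicate-
scale designs (2-4 replicates per group) the label-permutation space is too
small to be useful. A transcript is called in the disease signature iff
$|\text{signed FC}| > 2$ and $\min(p_{up}, p_{down}) \le 0.05$ — the
two-sided call uses the minimum without doubling, because the filter is
applied jointly with an absolute fold-change cut; doubling would be an
arbitrary extra choice.

Fold changes use the symmetric signed convention of published expression
tables: the linear ratio $r = 2^{\bar{x}_{num} - \bar{x}_{den}}$ is reported
as $r$ if $r \ge 1$ and $-1/r$ otherwise, computed from group means of log2
values (a geometric-mean ratio on the linear scale; mean-of-ratios vs
ratio-of-means is not distinguishable from published tables, and this choice
is the standard one).

# Counter-regulation

The analysis is restricted to the disease signature. Each signature
transcript gets a fold-change profile over the contrasts [disease vs
control, treatment$_i$ vs disease]. Profiles are clustered by Euclidean
K-means into `n_bins` bins (default 20; raw log2 columns, unstandardized —
all columns share the log2 scale; k-means++-style behavior comes from 50
random restarts under a fixed seed, best fit by total within-bin sum of
squares). A bin is **counter-regulated** iff its centroid's disease
component and every treatment component have strictly opposite signs; a
zero component fails (conservative boundary). The published procedure says
only that bins "manifesting counter-regulation" were kept, so the strict
sign rule is a documented reconstruction and `bin_filter = FALSE` runs the
pure gene-level filter instead. By construction the binned result is a
subset of the unbinned one.

The final gene-level filter requires, per treatment: opposite sign to the
disease change, $|\text{FC}| > 2$ (strict), and $p < 0.05$ (strict, as
printed in the source convention; the DE filter uses $\le$, also as
printed). `classify_counter_regulation()` additionally accepts `fc_tol`, a
*measurement* tolerance for classifying published tables that print fold
changes rounded to one decimal: rows printed as exactly 2.0 belonged to the
original set selected at full precision, so the worked-example
classification passes `fc_tol = 0.05` (half the printed least significant
digit). `fc_tol` defaults to 0 and is never used on computed fold changes.

# Networks and focus hubs

The proprietary knowledge-base tooling used in the source studies is
unpublished; this package provides an open, documented surrogate and never
claims to replicate its output (the study's 53%/32%/score values are
consequently not treated as reproducible targets).

*Subnetwork growth.* Over a user-supplied undirected simple graph (SIF or
two-column TSV), subnetworks are grown greedily: seed at the unassigned
signature gene of highest degree; repeatedly add the best connected
candidate until `max_subnetwork_size` (default 35, the size scale of
published knowledge-base networks) or no connected candidate remains.
Candidate priority is (1) unassigned signature genes, (2) most edges into
the current member set, (3) lexicographic. Signature preference outranks
edge count deliberately: with edge count first, growth drifts into the
background graph and subnetworks carry almost no signature genes, which
defeats the enrichment scoring. Non-signature "white" connector nodes are
recruited only when no signature gene is connected, and may appear in
several subnetworks; each signature gene belongs to at most one.

*Scoring.* A subnetwork's score is $-\log_{10} p$ of the hypergeometric
(Fisher exact) upper tail: the probability of at least the observed number
of signature genes among its members when drawing that many nodes from a
universe of `universe_size` genes (default: the parent network's node
count, configurable because the appropriate universe depends on the source
of the interaction graph).

*Merging and ranking.* Subnetworks with score $\ge$ `min_network_score`
(default 15) are sorted by score and the top `n_networks_to_merge` (default
7) are merged: the parent-graph subgraph induced on the union of their
members. `rank_hubs()` ranks nodes of the merged network by **degree of
connectivity** (distinct neighbors within the merged network; ties broken
lexicographically for determinism) and reports each node's
signature-connection fraction: the percentage of signature genes present in
the merged network adjacent to it.

A caveat established during validation: after score-filtered merging, the
signature genes that survive are biased toward hub-adjacent ones (isolated
or background-diluted subnetworks fail the score filter), so the
signature-connection fraction measured on a merged network overestimates a
hub's wiring fraction. The generator-recovery tests therefore check the
fraction on the full planted graph, where it is exact, and check rank-1
recovery on both the planted and the merged graph.

# Synthetic data: what it emulates, what it does not

`simulate_expression()` draws
$y = \text{baseline}(t) + \text{probe offset}(p) + \text{shift}(t, g) +
\varepsilon$, with baselines $\mathcal N(8, 1.5^2)$ (a typical log2
intensity range), probe offsets $\mathcal N(0, 0.5^2)$ drawn once per probe
and shared across samples (exactly the additive structure median polish
fits), i.i.d. Gaussian noise on the log2 scale (default sd 0.25, a
realistic replicate-level dispersion for summarized arrays; the source
gives no noise model), and planted shifts: DE transcripts move
$\pm$`effect_log2fc` (default 2, i.e. 4-fold — comfortably above the 2-fold
filter) in disease vs control; counter-regulated transcripts return to the
control level under every treatment (`reversal_magnitude = 1` so the
treatment-vs-disease filter is satisfiable by construction); the remaining
DE transcripts keep their disease shift under treatment. Group sizes
default to 4 replicates each for control, disease and two treatments — the
published design states only "at least in duplicate", so 4 is a
conservative artifact choice. One reversed subset is shared by all
treatments, mirroring the "counter-regulated by both treatments" design.
All randomness flows from `rng_seed`.

Not emulated: scanner-level background (hence no background adjustment),
probe-sequence effects, intensity-dependent variance, correlated biological
variation between transcripts, and partial reversal heterogeneity. A green
recovery test therefore establishes that the statistics recover a planted
additive signal at realistic noise — not that they are robust to every
artifact of real arrays.

`simulate_network()` wires signature plus background genes as an
Erdős–Rényi graph at a stated mean degree (default 4, the sparse regime of
curated interactomes) and attaches one designated hub to
`round(hub_target_fraction × |signature|)` signature genes. The hub is made
the unique maximum-degree node by dropping background edges of any rival —
degenerate worlds where this is impossible (hub degree 1) produce a warning
instead. Real interactomes are scale-free and modular; the ER background is
deliberately the simplest null against which planted-hub recovery is
meaningful.

# Pipeline, configuration, determinism

`run_pipeline()` wires the stages together from a `pipeline_config` (flat
`key = value` file; unknown keys are errors to catch typos). The design's
first group is the control, the second the disease group, the rest
treatments; the disease contrast is group2 vs group1 and each treatment is
contrasted against the disease group — the same rank-product test is used
for the treatment contrasts (the source names the test only for the disease
contrast; reusing it is the parsimonious choice). Every output TSV carries
`#`-prefixed metadata (contrast, permutations, seed), and `manifest.json`
records the config, md5 checksums and versions; rerunning an identical
config on identical inputs reproduces byte-identical tables.

`hierarchical_order()` provides the heatmap leaf order: average-linkage
agglomerative clustering on correlation distance ($1 - r$), with items
pre-sorted by id so the order is invariant to input permutation; the
linkage/distance pair is a documented surrogate (the original figures do
not state theirs). Zero-variance rows are an error by name. Rendering is
out of scope; `heatmap_export()` writes the row-standardized, reordered
matrix for any plotter.

The CLI (`exec/counterhub`, or `counterhub_main()`) exposes `simulate`,
`normalize`, `order` and the pipeline; because the downstream stages share
all upstream inputs, the `de`, `counterreg` and `hubs` subcommands run the
pipeline through `run-all` in this release.

# Known limitations

- The subnetwork-growth surrogate is a reconstruction; absolute scores and
  memberships will not match proprietary tools, only the qualitative
  behavior (signature-dense, connector-bridged networks).
- Rank-product p-values are raw permutation tails (the published filter);
  no multiplicity correction is offered.
- The counter-regulation bin filter depends on K-means geometry; with very
  small signatures the saturated-bin path (every distinct profile its own
  bin) is used and the gene-level filter dominates.
- Transcripts are not collapsed to unique genes before counting (the
  published counts do not state whether they were).
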