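# counterhub

Counter-regulated gene signatures and network focus-hub ranking.

## The problem

In treatment studies of disease models (the motivating setting is
transcriptional profiling of tissues from diabetic mice cured by short-term
immunomodulatory regimens), a natural way to nominate therapeutic targets
is:

1. find the transcripts that change at disease onset (**disease
   signature**): rank-product differential expression with permutation
   p-values, filtered at |FC| > 2 and p ≤ 0.05;
2. find the subset the curative treatments push back toward the healthy
   state (**counter-regulated signature**): K-means binning of fold-change
   profiles over [disease vs control, treatment vs disease], keeping bins
   whose centroids show sign opposition, then a per-gene filter (opposite
   sign, |FC| > 2, p < 0.05 for every treatment);
3. on a gene-interaction graph, grow subnetworks around the
   counter-regulated genes, score each by the hypergeometric (Fisher exact)
   enrichment of signature genes among its members (score = −log10 p),
   merge the top-scoring subnetworks, and rank nodes by **degree of
   connectivity**. The top-ranked **focus hubs** — typically inflammatory
   regulators — are the candidate targets.

`counterhub` implements this pipeline for R, with a synthetic-data generator
(planted DE transcripts, planted treatment reversal, planted network hub)
so every stage is testable against known ground truth, and a CLI for
file-based runs. The statistics at the core:

- rank product of transcript g over the k = n1·n2 between-group sample
  pairs: RP(g) = (∏ᵢ rᵢ(g))^{1/k}, ranks by pairwise log2 difference,
  computed in log space; p-values from a pooled null of uniformly random
  rank assignments, p = (1 + #{null ≤ observed}) / (1 + n_perm·G);
- signed fold change: r = 2^{Δlog2} reported as r if r ≥ 1 else −1/r;
- subnetwork score: upper-tail hypergeometric probability of the observed
  signature overlap, −log10-transformed;
- hub fraction: percent of signature genes in the analyzed network adjacent
  to the node.

## Worked example

Simulate a 1,000-transcript study (4 groups × 4 replicates, 11 probes per
transcript, 10% DE at 4-fold, half of those reversed by both treatments),
then run the stages:

```r
library(counterhub)

sim <- simulate_expression(sim_config(n_transcripts = 1000, rng_seed = 1))
em  <- median_polish_summarize(quantile_normalize(sim$probes))
de  <- list(
  DIA_vs_NOR = rankprod_de(em, "DIA", "NOR", n_perm = 100, seed = 2),
  TRT1       = rankprod_de(em, "TRT1", "DIA", n_perm = 100, seed = 3),
  TRT2       = rankprod_de(em, "TRT2", "DIA", n_perm = 100, seed = 4))

sig <- de_signature(de$DIA_vs_NOR)
#> signature_set 'DE signature': 50 up, 49 down

prof <- build_fc_profiles(de, sig)
bins <- kmeans_bins(prof, k = 20, seed = 5)
cr   <- counterreg_signature(prof, bins, de)
cr$all
#> signature_set 'counter-regulated (all treatments)': 17 up, 32 down
head(cr$table[, c("transcript_id", "fc_disease", "fc_TRT1", "fc_TRT2",
                  "status_all")], 3)
#>   transcript_id fc_disease  fc_TRT1  fc_TRT2 status_all
#> 1       TX00274  -4.961761 3.926424 3.909745       TRUE
#> 2       TX00754  -4.509955 1.084497 1.099855      FALSE
#> 3       TX00166  -4.430638 1.006518 1.028775      FALSE
```

The simulation planted 100 DE transcripts (the signature recovers 99) and
50 reversed ones (49 recovered). `cr$table` is the tabular report, sorted
by disease fold change: TX00274 is 5-fold down in disease and ~4-fold up
under both treatments, hence counter-regulated; the next rows were disease
DE but not reversed, and fail.

Network stage, on a simulated interactome with a hub wired to 53% of the
counter-regulated genes:

```r
net <- simulate_network(signature_ids(cr$all),
                        net_sim_config(n_background_nodes = 300,
                                       hub_target_fraction = 0.53,
                                       rng_seed = 6))
subs   <- build_seeded_subnetworks(net$network, cr$all)
merged <- merge_top_networks(subs, net$network, n_top = 7, min_score = 15)
rank_hubs(merged, cr$all, n_top = 5)
#>      node degree signature_fraction rank
#> 1    HUB1     26          78.787879    1
#> 2 BG00110      4          12.121212    2
#> 3 TX00858      3           3.030303    3
#> 4 TX00011      2           3.030303    4
#> 5 TX00052      2           3.030303    5
```

The planted hub is ranked 1 by degree of connectivity. Note the
signature-connection fraction inside a score-filtered merge is biased
upward (only signature-dense subnetworks survive the merge; see the methods
vignette); measured on the full planted graph, `rank_hubs(net$network,
cr$all)` reports the exact planted 53%.

File-based runs use the CLI:

```sh
exec/counterhub simulate --seed 1 --out data/
exec/counterhub run-all --expression data/probes.tsv --design data/design.tsv \
    --network data/network.sif --seed 1 --out results/
```

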