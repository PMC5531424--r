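# hspcfate

Early fate commitment in human cord-blood CD34+ hematopoietic stem and
progenitor cells (HSPCs) is not a clean binary switch: after cytokine
stimulation, cells pass through a promiscuous *multilineage-primed*
transcriptional state, two lineage-primed expression patterns emerge within
the (unusually long) first cell cycle, and individual cells reach their
stable phenotype at variable times — some fluctuating between a polarised,
motile morphology and a round, committed-progenitor morphology over several
cycles. `hspcfate` is an R package for analysing this process from the two
data streams such experiments produce, and for simulating both streams with
known ground truth:

* **Single-cell qRT-PCR** (Biomark-style Ct exports, ~90-gene panels, two
  spike-in channels per cell): quality filtering, spike-referenced
  normalisation `dCt = sqrt(Ct_sp1 * Ct_sp4) − Ct_gene` with a −17 floor,
  k-means population structure with gap-statistic selection of the cluster
  number, t-SNE/PCA embeddings, per-component gene contributions, and a
  **correlation-burst indicator**: the count of gene pairs with Pearson
  r > 0.8 per cell group, whose transient rise marks an imminent state
  transition.
* **Time-lapse lineage trees** (per-cell birth/division records plus
  round/polarised morphology intervals): per-cell dynamic phenotype
  parameters (roundness, switch frequency, cycle length), classification
  into stable-polarised / frequent-switcher / stable-round (P/S/R),
  mother-to-daughter phenotype-inheritance matrices, sister-pair
  similar/divergent comparison, exact MLE of the two-state morphology
  switching rates, per-generation cycle statistics, and Newick export of
  clone topologies.
* **Simulators** for both: a latent-factor expression-state generator
  (quiescent, multiprimed, two lineage-primed states, a transition state
  with a correlation burst) and a branching-pedigree generator with a
  truncated log-normal first cycle (median 58 h, range 35–80 h), ~21 h later
  cycles, continuous-time Markov morphology switching and heritable P/S/R
  phenotypes with an absorbing round state.

Everything is tidyverse-shaped: functions take a data frame first and return
tibbles, results have `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Simulate the 48-h two-lineage population, normalise it, and recover its
structure:

```r
library(hspcfate)
library(dplyr)

sim  <- simulate_expression(expression_sim_config(seed = 1),
                            c(lineage1 = 100, lineage2 = 100))
expr <- normalize_cts(qc_filter(sim$ct))

gap <- select_k_gap(expr, k_max = 6, n_refs = 50, seed = 1)
gap
#> Gap statistic over k = 1..6 (50 reference sets)
#> Selected k = 2
#> # A tibble: 6 × 5
#>       k log_w e_log_w   gap      se
#>   <int> <dbl>   <dbl> <dbl>   <dbl>
#> 1     1  8.04    8.28 0.244 0.00770
#> 2     2  7.72    8.20 0.486 0.00564
#> 3     3  7.70    8.18 0.478 0.00522
#> 4     4  7.69    8.17 0.479 0.00500
#> 5     5  7.68    8.15 0.476 0.00498
#> 6     6  7.67    8.14 0.474 0.00499
```

The gap curve peaks at k = 2 (the smallest k with
gap(k) ≥ gap(k+1) − s₍k+1₎): the two lineage-primed expression patterns.
The correlation-burst indicator separates the uncoordinated multiprimed
state from the transition state, whose module genes co-fluctuate through a
shared latent factor:

```r
cfg <- expression_sim_config(seed = 1, dropout_fail_rate = 0)
sim <- simulate_expression(cfg, c(multiprimed = 100, lineage1 = 100,
                                  transition = 100))
expr <- normalize_cts(qc_filter(sim$ct))
expr$state <- sim$truth$state[match(expr$cell_id, sim$truth$cell_id)]
glance(correlation_burst(expr, group = "state"))
#> # A tibble: 3 × 5
#>   state       n_cells n_genes_used n_edges   mean_r
#>   <chr>         <int>        <int>   <int>    <dbl>
#> 1 lineage1        100           90       0  0.0110
#> 2 multiprimed     100           90       0 -0.00151
#> 3 transition      100           90     120  0.0233
```

120 gene pairs exceed r = 0.8 in the transition state — the burst — while
the mean pairwise correlation barely moves: the indicator sees the tail, not
the mean. On the lineage side, simulate 400 clones and estimate phenotype
inheritance and cycle statistics:

```r
ped <- simulate_pedigrees(pedigree_sim_config(n_clones = 400, seed = 1))
transition_frequencies(ped$cells, ped$truth$phenotypes)
#> Mother-to-daughter phenotype transitions (2400 edges)
#>       daughter
#> mother     P     S     R
#>      P 0.579 0.265 0.156
#>      S 0.000 0.243 0.757
#>      R 0.000 0.000 1.000

cycle_length_stats(ped$cells)
#> # A tibble: 3 × 8
#>   generation     n mean_h median_h q25_h q75_h min_h max_h
#>        <int> <int>  <dbl>    <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1          1   400   57.9     57.0  50.9  64.6  38.7  79.7
#> 2          2   800   21.1     21.0  19.8  22.3  14.8  26.8
#> 3          3  1600   21.1     21.1  19.7  22.4  14.0  27.7
```

The estimated S→S conservation (0.243) recovers the generating 0.25; the
round row is exactly (0, 0, 1) — round mothers only make round daughters, so
the round phenotype accumulates. Founder cycles are long (median ≈ 58 h,
range within 35–80 h); later generations cycle in ~21 h.

The whole chain — simulate → normalize → cluster → correlate → lineage →
report — also runs as one call (`run_pipeline(pipeline_config(...))`) or
from a shell via `Rscript inst/scripts/hspcfate.R <subcommand> [options]`,
writing TSV/JSON/Newick outputs plus a `manifest.json` and a Markdown
report.

See `vignettes/fate-commitment-dynamics.Rmd` for the models, parameter
choices, simulator assumptions and known limitations.

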