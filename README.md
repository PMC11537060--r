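# spongenet

Community-ecology analysis of sponge holobiont microbiomes: who is
abundant, how wide a niche each symbiont occupies, and how tightly the
community is wired.

Marine sponges host two contrasting symbiotic phenotypes:
high-microbial-abundance (HMA) sponges with rich, even, temporally stable
and tightly co-varying communities, and low-microbial-abundance (LMA)
sponges with fewer, dominance-skewed taxa, faster turnover and more
exchange with the surrounding seawater. `spongenet` provides the
statistical toolkit used to characterize that contrast from 16S ASV count
tables sampled over time, plus a synthetic community generator so the whole
pipeline runs, and is tested, with no external data.

## What it computes

* **Abundance classes** — each ASV is labelled from the minimum *m* and
  maximum *M* of its per-sample relative abundance with thresholds
  u = 1% and l = 0.01%: abundant (AT: m ≥ l, M ≥ u), dominant
  (DT: m < l, M ≥ u), rare (RT: m < l, M < u) and moderate
  (MT: m ≥ l, M < u).
* **Diversity and structure** — alpha diversity (Shannon H = −Σ pᵢ ln pᵢ,
  inverse Simpson 1/Σ pᵢ², Pielou), Bray–Curtis dissimilarity, UPGMA
  dendrograms, and seeded permutation tests (ANOSIM, PERMANOVA, MRPP,
  Mantel) with VIF > 20 screening of environmental covariates.
* **Levins niche breadth** — Bᵢ = 1 / Σⱼ Pᵢⱼ², from specialist (B = 1) to
  uniform generalist (B = r states), averaged over the community.
* **Molecular ecological networks** — Spearman co-occurrence graphs with
  the correlation cutoff chosen by random matrix theory: the smallest
  threshold at which the nearest-neighbour spacing distribution of the
  unfolded eigenvalue spectrum becomes Poisson (uncorrelated) rather than
  Wigner–Dyson; topology (N, L, L/N, avgK = 2L/N, modularity,
  connectedness, betweenness), 100-network Maslov–Sneppen degree-preserving
  null ensembles with Z-scores, and top-10 keystone taxa by combined
  degree/betweenness rank.
* **Bipartite local similarity analysis (LSA)** — for sponge × seawater
  time series, a dynamic program finds the strongest contiguous, possibly
  lagged, co-varying segment of two normal-score-transformed series
  (|LS| ≤ 1), with permutation p-values and Benjamini–Hochberg q-values.
* **Synthetic data** — Dirichlet-multinomial communities with module-shared
  lognormal temporal dynamics, seasonal environmental drivers, a shared
  seawater ASV pool, and latent-copula count tables with planted
  correlation networks for recovery testing.

## Worked example

```r
library(spongenet)

ds <- generate_holobiont_dataset(seed = 2, depth = 10000)
ds$combined
#> ASV table: 1764 ASVs x 60 samples, 600,000 reads

classify_table(to_relative(ds$groups$Spongia_like$table))
#> Abundance classes (u = 0.01, l = 0.0001) over 500 ASVs:
#>  label n_asv frac_asvs  frac_reads
#>     AT    56     0.112 0.349826667
#>     DT     1     0.002 0.004433333
#>     MT   260     0.520 0.493946667
#>     RT   183     0.366 0.151793333

community_niche_width(ds$groups$Spongia_like$table)   # HMA-like host
#> Levins niche breadth over 15 states: mean B = 9.443 (SE 0.091, 500 ASVs)
community_niche_width(ds$groups$Tedania_like$table)   # LMA-like host
#> Levins niche breadth over 15 states: mean B = 5.916 (SE 0.205, 129 ASVs)

tab <- filter_prevalence(ds$groups$Spongia_like$table, 0.5)
cm  <- spearman_matrix(tab)
th  <- rmt_threshold(cm)
th
#> RMT threshold s_t = 0.88 (Poisson GOF alpha = 0.05, 70 thresholds scanned)

topo <- network_topology(build_network(cm, th))
topo
#> Network: N = 358, L = 1418, L/N = 3.96, avgK = 7.92, M = 0.801, Con = 0.934

null_ensemble(build_network(cm, th), n = 100, seed = 1)
#> Null ensemble of 100 degree-preserving rewirings:
#>          metric  observed null_mean     null_sd         z
#>  links_per_node 3.9608939 3.9608939 0.000000000        NA
#>            avgK 7.9217877 7.9217877 0.000000000        NA
#>      modularity 0.8009718 0.3071770 0.005561623 88.786090
#>   connectedness 0.9340876 0.9934388 0.008935480 -6.642195
```

Reading the output: the HMA-like host carries a wider mean niche breadth
than the LMA-like host (9.4 vs 5.9 over 15 sample-states); its
co-occurrence network at the RMT-selected cutoff (s_t = 0.88) has average
connectivity ≈ 7.9 and a modularity of 0.80 that sits ~89 null standard
deviations above degree-matched rewired networks — the hallmark of strongly
modular, non-random community structure. avgK has an undefined Z because
degree-preserving rewiring conserves it by construction.

The full workflow (classes → diversity → permutation tests → shared ASVs →
niche breadth → per-host networks → bipartite LSA) is one call:

```r
report <- run_full_analysis(pipeline_config(), seed = 1, out_dir = "out")
```

or from a shell, `Rscript inst/scripts/spongenet-cli.R all --seed 1
--out-dir out` (use subcommand `simulate` to write the synthetic study as
TSV files).

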