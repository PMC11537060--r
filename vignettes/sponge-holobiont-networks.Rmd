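---
title: "Diversity, niche breadth and co-occurrence networks of sponge holobiont microbiomes"
author: "spongenet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, niche breadth and co-occurrence networks of sponge holobiont microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongenet)
```

# Scope

`spongenet` implements a community-ecology workflow for 16S ASV tables from
sponge hosts and surrounding seawater sampled repeatedly over time. Marine
sponges fall into two symbiotic phenotypes — high-microbial-abundance (HMA)
sponges whose dense mesohyl hosts rich, stable, tightly interacting
communities, and low-microbial-abundance (LMA) sponges with sparser,
dominance-skewed communities that exchange more taxa with the water column.
The package quantifies that contrast along four axes: diversity and
community structure, abundance-class membership, Levins niche breadth, and
interaction-network architecture; and it ships a synthetic generator that
emulates the HMA/LMA/seawater contrast so the whole workflow is exercisable
and testable without any external data.

The workflow starts from an ASV count table; read denoising, chimera
removal and taxonomy assignment are upstream concerns of dedicated tools
and are out of scope.

# Data model and normalization

The universal input is an `asv_table`: a validated non-negative integer
matrix, ASVs in rows, samples in columns, unique identifiers on both
margins. TSV (ASV rows, `asv_id` first column) and BIOM-JSON v1.0 are read
and written. Sample metadata carry host, phenotype (`HMA`/`LMA`), habitat
(`sponge`/`seawater`), month and replicate, plus an environmental vector
(temperature, salinity, DO, pH and nutrient concentrations).

Counts are converted to per-sample relative abundances by closure
(columns sum to 1). Where libraries must be equalized, `rarefy_table()`
subsamples without replacement to a fixed depth (seeded, via
`vegan::rrarefy`); rarefaction was chosen because it is the standard
normalization for amplicon diversity work and keeps the relative-abundance
thresholds of the classification comparable across libraries. Before any
network construction, `filter_prevalence()` keeps ASVs detected in strictly
more than half of the samples of the group being analyzed. The prevalence
rule is applied per analysis group (per host species), because networks are
built per host; an argument exposes the cutoff for the alternative
whole-study reading.

# Abundance classes

Each ASV is classified from the minimum *m* and maximum *M* of its
per-sample relative abundance, with an upper threshold `u = 1%` and lower
threshold `l = 0.01%`, both inclusive:

| class | condition | reading |
|-------|-----------|---------|
| AT (abundant)  | m ≥ l and M ≥ u | never rare, reaches abundance |
| DT (dominant)  | m < l and M ≥ u | conditionally dominant |
| RT (rare)      | m < l and M < u | rare somewhere, never abundant |
| MT (moderate)  | m ≥ l and M < u | never rare, never abundant |

The three named classes do not cover the always-moderate cell of the
(m, M) plane; rather than silently forcing such ASVs into AT or RT, the
package reports them as an explicit `MT` label. The four labels partition
the plane, so class counts always sum to the number of ASVs.

# Diversity, permutation tests and environmental screening

Alpha diversity (richness, Shannon with natural logarithm, Simpson,
inverse Simpson, Pielou evenness `H/ln S`) is computed with vegan. The
natural-log convention was chosen because it is the ecology default and
matches the magnitude of Shannon values usually reported for sponge
symbionts. The inverse Simpson index doubles as the effective species
number `neff`, which feeds the published heuristic for choosing a pairwise
association method: local similarity analysis is appropriate when the
composition is not high-diversity (`neff < 13` fails the check), the table
is less than 50% sparse, and samples form a time series
(`choose_correlation_method()` reports any failing criterion).

Between-sample structure uses Bray–Curtis dissimilarity and UPGMA
(average-linkage) dendrograms; the linkage was an open choice and UPGMA was
fixed as the common default for community dendrograms. Group separation is
tested with ANOSIM, PERMANOVA (Anderson's pseudo-F computed from the
distance matrix) and MRPP, and community–environment association with
Mantel tests (Spearman by default; the correlation type was unstated in
the source analyses). All permutation tests default to 999 permutations,
are seeded, and report add-one p-values, so `p >= 1/(n_perm+1)` always.
Before constrained analyses, environmental variables are screened by
iteratively dropping the largest variance inflation factor until all
VIF ≤ 20; constant or aliased variables (infinite VIF) are dropped first.
With only five monthly time points at most four linearly independent
environmental covariates can survive this screen — an inherent limit of
the design, not of the implementation.

# Levins niche breadth

For ASV *i* with distribution `P_ij` over *r* resource states,
`B_i = 1 / sum_j P_ij^2`, ranging from 1 (single-state specialist) to *r*
(uniform generalist); the community value is the arithmetic mean over
included ASVs. Resource states default to the individual samples of the
analysis group, replicates kept separate, which matches the magnitudes
usually reported for sponge communities; a `states` mapping allows coarser
groupings, in which case `P_ij` derives from the mean relative abundance of
the ASV over the samples of each state, renormalized across states. Only
detected ASVs enter the average (occupancy threshold exposed), since
absent taxa have no defined breadth.

# Co-occurrence networks with an RMT threshold

Within each host group, Spearman correlations are computed between all
prevalent ASVs (non-log-transformed abundances, average ranks for ties).
The correlation cutoff is chosen by the random-matrix-theory criterion:
for each candidate threshold *s* the matrix is hard-thresholded, its
eigenvalue spectrum deduplicated (exact duplicates arise from isolated
rows) and unfolded, and the nearest-neighbour spacing distribution (NNSD)
is tested against the Poisson law `P(d) = exp(-d)` by chi-square on
equal-probability bins. Correlated structure produces Wigner–Dyson level
repulsion; the selected `s_t` is the smallest scanned threshold whose NNSD
is Poisson-consistent (p > 0.05) and remains so for the next two scan
steps, a persistence requirement that guards against single-step false
transitions. Numerical choices: scan 0.30–0.99 in steps of 0.01;
duplicate tolerance 1e-8; unfolding by a cubic smoothing spline fitted to
the cumulative spectral distribution with `df ~ n/5` (bounded to [4, 20]);
about 20 equal-probability bins (fewer for short spectra, at least five
counts expected per bin). Matrices under 50 nodes trigger a warning — the
spacing statistics of short spectra are unstable.

Two desk-scale caveats are worth stating plainly. First, with *n* samples
the Spearman noise floor is about `1/sqrt(n-1)`, and the NNSD transition
tracks the percolation of the noise graph: at n = 50 the method accepts
near s ≈ 0.4, so weaker thresholds cannot be selected no matter how clean
the signal — spurious noise dyads above that floor are then unavoidable in
the thresholded graph. Second, deep in the fragmented regime the spectrum
degenerates into mirrored dyad clusters piled just above the threshold
boundary, where the spacing test loses its meaning; the scan reports `NA`
there and the pipeline falls back (with a flag and warning) to the
best-fitting scanned threshold when no persistent Poisson window exists.

Network topology reports N, L, L/N, average connectivity `avgK = 2L/N`,
modularity `M` of the greedy modularity-maximizing partition (deterministic
and seedless; the module detector was an open choice), connectedness `Con`
(fraction of node pairs joined by a path), and per-node degree and
betweenness (normalized by `(N-1)(N-2)/2`). Thresholding and topology use
`|r|`; the sign is kept on every edge for positive/negative fraction
reporting. Network reliability is judged against 100 Maslov–Sneppen
rewired networks: repeated double-edge swaps that reject self-loops and
multi-edges, preserving the degree sequence exactly. The swap budget is
100×L proposal *trials* (igraph's semantics; rejected proposals consume
budget — the budget is generous enough that the distinction is
immaterial). Metrics fully determined by the degree sequence (avgK, L/N)
have zero null variance and are flagged with an undefined Z-score.
Keystone taxa are the top 10 nodes by the mean of the degree rank and the
betweenness rank, ties broken lexicographically — one ranking per host
network.

# Bipartite local similarity analysis

Associations between sponge and seawater ASV time series use local
similarity analysis. Replicates are averaged per time point (the
alternative of concatenating replicates is left to the caller), each
series is transformed to rank-based normal scores and scaled to unit
population variance, and a dynamic program finds the highest-scoring
contiguous run of aligned products over offsets `|d| <= D`:
`P_i = max(0, P_{i-1} + x_i y_{i+d})` for the positive chain and the
mirrored recursion for the negative chain. The score is the best chain
divided by the series length (so `|LS| <= 1`, and a series against itself
scores exactly 1), signed by which chain won; the positive chain is
preferred on exact ties. `D` defaults to one time step — with five time
points larger lags are not interpretable. Significance is a two-sided
permutation test on `|LS|` (999 seeded time permutations shared across
pairs, add-one correction) with Benjamini–Hochberg adjustment across all
pairs; the theoretical asymptotic p-value approximation is deliberately
not implemented. Note the arithmetic of short series: five time points
admit only 120 orderings, so permutation p-values floor near 0.01 and a
BH-corrected `q <= 0.05` over thousands of pairs is rarely attainable —
corrected edge counts from five-point series should be read as
conservative, and the uncorrected sign balance is also reported.

# The synthetic generator

`generate_community()` draws a base composition from a Dirichlet
distribution (gamma shape = `evenness`), perturbs log-abundances per time
point, and samples counts multinomially at the configured depth. The
perturbation has three parts: a module-shared latent factor (one factor
per co-response module per time point, weight `assoc_strength`), an
idiosyncratic part (weight `sqrt(1 - assoc_strength^2)`), both scaled by
`turnover`; an environmental response `env_response` of the top-decile
ASVs to the standardized seasonal temperature driver; and small
replicate-level jitter. A fraction `seawater_share` of the ASV identifiers
is drawn from the seawater pool so shared-ASV (Venn) logic is meaningful.
The environmental series has a seasonal temperature sinusoid (≈14–30 °C,
peaking mid-series), dissolved oxygen anti-correlated with temperature,
and lognormal nutrients.

The presets are the package's standing description of the three community
types — chosen once, from the qualitative contrasts the phenotypes are
known for, at the study's own design (5 months × 3 replicates, ~10⁴ reads
per sample):

| parameter | HMA | LMA | seawater |
|---|---|---|---|
| richness | 500 | 150 | 1200 |
| evenness (Dirichlet shape) | 2 | 0.25 | 1.2 |
| turnover (log-sd / time point) | 1.0 | 1.5 | 0.5 |
| assoc_strength (shared fraction) | 0.98 | 0.4 | 0.3 |
| module size | 25 | 15 | 25 |
| env_response (top decile) | 0.2 | 0.6 | 0.8 |
| seawater_share | 0.2 | 0.45 | 1 |
| replicate noise (log-sd) | 0.03 | 0.2 | 0.15 |

The HMA preset expresses "tight, regulated symbiosis" as highly coherent
module dynamics (high `assoc_strength`, low replicate noise); the LMA
preset expresses environmental openness as large, mostly idiosyncratic
fluctuations and a high shared fraction with seawater. With only 15
samples per host, rank correlations carry a noise floor of ≈0.27, so the
coherence of HMA modules must be strong to be recoverable — the presets
reflect that measurement reality. One emergent behaviour deserves note:
in dominance-skewed LMA communities, closure (relative abundances summing
to one) itself induces diffuse correlations when dominant taxa fluctuate;
this is a real feature of compositional data, not an artifact of the
generator.

For network-recovery oracles, `generate_correlated_counts()` uses a latent
Gaussian copula: unit normals with ±ρ on planted edges, pushed through a
monotone lognormal map (rank correlations are preserved exactly by
monotone maps) and multinomial sampling. Requested edge sets that break
positive definiteness (e.g. two strong edges sharing a node) are thinned
at random with a warning; planting a matching avoids thinning entirely.

What the generator does *not* emulate: taxonomy (placeholder lineages
only), absolute microbial densities (the HMA/LMA biomass difference
itself), phylogenetic signal, overdispersion beyond
Dirichlet-multinomial, and true cross-habitat dynamical coupling other
than the shared temperature driver. Passing tests therefore demonstrate
correctness of the statistical machinery under a plausible generative
model, not biological validity on real sponge data.

# Pipeline and problem sizes

`run_full_analysis()` sequences the stages (data, classes, community
statistics, shared ASVs, niche breadth, per-group networks, bipartite
LSA) with per-stage error reporting, a single master seed from which all
stage seeds derive, and a JSON/TSV/GraphML/newick report written by
`write_report()`; reruns with the same configuration and seed are
byte-identical. Default sizes are the package's choices for a desk-scale
study: 60 samples (4 groups × 5 months × 3 replicates), 10⁴ reads per
sample, networks on up to 500 prevalent ASVs per group, 100-network null
ensembles, 999 permutations throughout, and LSA on the top 100 prevalent
ASVs per side. A thin command-line wrapper
(`inst/scripts/spongenet-cli.R`, subcommands `simulate` and `all`) drives
the same functions on files.

# Known limitations

* The RMT criterion cannot select thresholds below the sample-size-driven
  noise floor (see above); with few samples the resulting networks include
  noise dyads near that floor, and precision against a planted truth
  degrades even while recall stays high.
* Spacing statistics of sub-50-node matrices are unreliable; the scan
  warns and the pipeline's fallback may engage.
* Permutation-only LSA p-values are floor-limited by the factorial of the
  number of time points.
* VIF screening with five time points retains at most four environmental
  covariates.
* Modularity uses the unweighted greedy algorithm; weighted and
  resolution-tuned variants are out of scope.
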