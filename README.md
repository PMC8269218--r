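# symbionet

Phylogeny-informed analysis of coral–Symbiodiniaceae interaction networks.

Reef-building corals associate with dinoflagellate symbionts (family
Symbiodiniaceae), and the structure of the global host–symbiont network —
who partners with whom, how often, and how that maps onto host traits like
bleaching susceptibility — is a question for community ecologists and coral
biologists. `symbionet` implements the full analysis chain for compiled
association records, where one record is one observation of a single ITS2
phylotype in one coral species:

- **Frequency-weighted bipartite network**: link weight
  `W[i,j] = A[i,j] / Σ_j A[i,j]`, so each coral's outgoing weights sum
  to 1; connectance, web asymmetry, one-mode projections and per-component
  eigenvector centrality.
- **Modularity**: Barber's bipartite
  `Q = (1/F) Σ_ij (A_ij − k_i d_j / F) δ(g_i, g_j)` optimized by a
  stochastic stitch hill-climb (compiled kernel; default 10⁶ stitches ×
  1,000 restarts, the most modular run among those with the fewest
  modules), significance as a z-score against Patefield marginal-preserving
  null networks, and Olesen-style node roles from within-module degree *z*
  and participation `c = 1 − Σ_t (s_t/s)²`, averaged over repeated
  partitions.
- **Assemblage statistics** per coral: rarefied richness
  `E[S_k] = S − Σ_j C(N−N_j, k)/C(N, k)` at depths 10/15/20, Blüthgen's
  specialisation d′, Bray–Curtis and unweighted UniFrac beta diversity,
  frequency-weighted mean thermotolerance (mean-TT) with its weighted
  standard error, thermotolerance bins, and bleaching-response (taxon-BRI)
  thirds.
- **Phylogenetic comparative statistics** written from first principles:
  Pagel's λ by profile ML, PGLS with jointly estimated λ and signed effect
  size `R = sign(slope)·√R²`, simulation-based phylogenetic ANOVA,
  Firth-type phylogenetic logistic regression, Mantel-style matrix
  correlations, and permutation t tests of within- versus between-module
  phylogenetic distances.
- **Sensitivity analyses**: metahaplotype collapsing of intragenomic
  variants into host-specific nodes, sampling-intensity regressions, and
  record-depth subsets.
- **A synthetic-data generator** (`simulate_network()`) that emulates a
  152-coral × 385-phylotype compilation with ~16,000 records, heavy-tailed
  phylotype degrees, planted modules partially aligned with transmission
  mode, and Brownian traits with tunable Pagel's λ — with the planted truth
  returned for ground-truth validation and never read by the analyses.

## Worked example

```r
library(symbionet)

sim <- simulate_network(synthetic_spec(seed = 42))
net <- build_network(sim$interactions)
net
#> frequency-weighted bipartite network: 152 corals x 385 phylotypes, 4156 links, 16015 records
round(connectance(net), 3); round(web_asymmetry(net), 3)
#> [1] 0.071
#> [1] -0.434

fnet <- filter_for_modularity(net, 3)          # drop phylotypes with < 3 records
part <- optimize_modules_best(fnet, n_restarts = 5, n_stitches = 2e5, seed = 1)
part
#> module partition: 7 modules, Q = 0.6193 (152 corals, 368 phylotypes)
z <- modularity_zscore(fnet, part, n_null = 50, seed = 2, null_stitches = 2e4)
#> z = 142.7 (null mean 0.144, sd 0.0033)
```

The partition recovers the seven planted modules, and the observed Q sits
~140 null standard deviations above the marginal-preserving expectation —
strong modular structure, as in real coral–symbiont networks.

```r
st <- assemblage_stats(net, sim$coral_traits, sim$symbiont_traits)
head(st[, c("coral", "n_records", "RD10", "dprime", "mean_TT", "bri_group")], 4)
#>       coral n_records RD10 dprime mean_TT bri_group
#> 1 coral_001        39 6.35  0.598    52.7       low
#> 2 coral_002        30 8.43  0.447    44.7       mid
#> 3 coral_003        60 4.60  0.600    25.3       low

bri  <- setNames(st$taxon_BRI, st$coral)
rd10 <- setNames(st$RD10, st$coral)
pgls(bri, rd10, sim$coral_tree)
#> PGLS taxon-BRI ~ RD10: slope -0.423 (p = 0.694), lambda = 0.73, R = -0.032
pagel_lambda_ml(bri, sim$coral_tree)
#> lambda = 0.726 (LRT p = 2.3e-18)
```

`RD10` is each coral's expected phylotype richness in a random subsample of
10 records (corals with fewer records are `NA`); `dprime` is 0 for a coral
using symbionts in proportion to availability and 1 for an exclusive
specialist; `mean_TT` averages partner thermotolerance percentiles by
interaction frequency. Here no richness–BRI association was planted, and
PGLS correctly finds none (p = 0.69), while the estimated λ ≈ 0.73 recovers
the generator's planted phylogenetic signal (λ = 0.7). The full battery —
beta-diversity correlation grids, PGLS/PLR/PANOVA tables, λ estimates,
permutation distance tests and sensitivity re-runs, with a JSON manifest —
runs end-to-end via `run_full(sim, analysis_config(...), outdir = "out")`.

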