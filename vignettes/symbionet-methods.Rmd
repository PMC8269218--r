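---
title: "Methods: phylogeny-informed analysis of coral-Symbiodiniaceae networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeny-informed analysis of coral-Symbiodiniaceae networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbionet)
```

## The problem

Reef-building corals host assemblages of dinoflagellate symbionts
(family Symbiodiniaceae), and which symbionts a coral harbours shapes its
thermal resilience. Compilations of association records — one observation of
one ITS2-defined phylotype in one coral species — define a bipartite
host-symbiont network. `symbionet` implements the complete analysis chain
for such data: building a frequency-weighted network, detecting and testing
modular structure, scoring node roles, summarising each coral's assemblage
(richness, specialisation, beta diversity, thermotolerance), and relating
those summaries to host traits with comparative methods that respect the
phylogenetic non-independence of species. Every stage can be exercised on
synthetic data with planted ground truth.

## The network model

Each coral's outgoing link weights are its record counts divided by its
total records, so weights measure the *frequency of interaction* from the
host's point of view and each coral's weights sum to one. Whole-network
descriptors are connectance (realized fraction of possible links) and web
asymmetry ((corals − phylotypes)/(corals + phylotypes); the coral-minus-
symbiont sign convention is recorded in the output, and makes the value
negative in symbiont-rich networks). Eigenvector centrality is computed on
a one-mode projection whose edge weight between two same-side nodes is the
sum over shared partners of the product of the two frequency weights; a
minimum rule is available as a sensitivity switch because no single
projection convention is canonical. Centrality is scaled to a maximum of 1
per connected component — real compilations contain isolated peripheral
nodes, and per-component scaling keeps their scores comparable — with
isolated nodes scored 0.

## Modularity

Modularity uses Barber's bipartite Q,
\(Q = \tfrac{1}{F}\sum_{ij}\left(A_{ij} - k_i d_j / F\right)\,
\delta(g_i, g_j)\), evaluated by default on the frequency-weight matrix
(consistent with the frequency-weighted network; raw counts sit behind a
switch because either matrix is defensible). Optimization is a stochastic
hill-climb: phylotypes start as singleton modules, each coral is seeded
into the module of its strongest-weight phylotype, and a large number of
random "stitches" — move a node into a neighbouring module, or merge the
two endpoint modules of a random link — are accepted iff Q does not
decrease (strict hill-climbing; simulated annealing is out of scope). The
default budget is 10^6 stitches per run and 1,000 restarts, with the run
selected as the most modular among those attaining the minimum module
count. Because the optimizer is stochastic, node roles (below) are averaged
over 100 partitions by default. Phylotypes with fewer than 3 records are
excluded from the modularity analysis (they stay in every other analysis);
they carry almost no module information and their inclusion only adds
noise.

Significance is assessed against null networks that preserve the count
matrix's row and column totals (Patefield's algorithm via `r2dtable`),
each re-optimized with a reduced stitch budget (10^4 by default): at 1,000
nulls a full budget would be prohibitive, and in synthetic calibration the
z-score is insensitive to the null budget because null Q distributions are
tight. A z-score far above 3 indicates genuine modular structure; a
marginal-preserving shuffle of a random network scores |z| < 3.

Node roles use the within-module degree z (a phylotype's strength into its
own module, standardised over that module's phylotypes, 0 where the module
sd is zero) and the participation score c = 1 − Σ_t (s_t/s)². Weighted
strengths are the default, binary degrees a switch. Thresholds default to
the conventional (c\*, z\*) = (0.6, 2), or can be recomputed as the 95th
percentile over marginal-preserving null networks. Quadrants classify nodes
as peripheral, module hub, connector, or network hub.

## Assemblage metrics

*Rarefied richness* at depth k is the hypergeometric expectation
\(E[S_k] = S - \sum_j \binom{N - N_j}{k}/\binom{N}{k}\) (computed via
`vegan::rarefy`); a Monte Carlo resampling mode exists for fidelity to
resampling-based protocols and the two agree within Monte Carlo error.
Corals with fewer than k records are excluded (returned as `NA`), at the
default depths 10/15/20.

*Specialisation d′* is the standardised Kullback–Leibler divergence of a
node's interaction proportions from partner availability. The lower
extreme is 0 (use proportional to availability); the upper extreme d_max is
the most specialised allocation achievable given the marginals. Because any
capped allocation of the focal node's total extends to a full
marginal-preserving table, d_max is a maximum of a convex function over a
capped simplex: it sits at a vertex, every vertex is a fill-to-cap prefix
of some partner ordering, and the implementation enumerates orderings
exactly for up to 7 partners and uses a candidate set of orderings above
that (each partner first, remainder by ascending availability). A plain
"fill the rarest partner first" rule is not sufficient: when the rarest
partners have tiny capacity, filling them spreads the distribution toward
availability and *lowers* d.

*Beta diversity* uses Bray–Curtis dissimilarity on frequency weights and
unweighted UniFrac on the symbiont tree (presence = any nonzero frequency,
no minimum-frequency cutoff; branches with no present tip contribute
nothing, so no pruning is required).

*Thermotolerance*: mean-TT is the frequency-weighted mean of partner TT
scores over TT-known phylotypes only (weights renormalised; phylotypes with
missing TT are excluded, never imputed). Its standard error uses the
unbiased weighted variance \(s^2 = \sum \tilde w_j (TT_j - \bar{TT})^2 /
(1 - \sum \tilde w_j^2)\) divided by the effective sample size
\(n_{\mathrm{eff}} = 1/\sum \tilde w_j^2\), and needs at least two TT-known
partners. TT-bin masses use left-open right-closed bins with edges
10/20/30/40 (the first bin closed at 0) and are not renormalised, so they
sum to the TT-known frequency mass.

*Bleaching-response thirds*: corals are ranked by taxon-BRI and the top and
bottom thirds labelled high/low. The third size defaults to ceiling(n/3)
and is configurable (floor, or a fixed count); published group sizes that
match no rounding rule can be reproduced with the fixed rule. Ties break by
stable table order and a fully tied table triggers a warning.

*Matrix correlations* (beta diversity against ΔBRI or phylogenetic
distance) are Pearson correlations over upper triangles with Mantel-style
significance: rows and columns of the second matrix are permuted jointly,
and the two-sided empirical p uses the +1 correction, so p ≥ 1/(n_perm+1).
With B permutations p-values live on the grid k/(B+1); calibration at level
α is exact when α(B+1) is an integer (e.g. B = 199, 999 for α = 0.05).

## Phylogenetic comparative methods

The Brownian covariance C has entries equal to shared root-to-tip branch
length; Pagel's λ scales its off-diagonals. λ is estimated by profile ML
over [0, 1] (σ² and the mean profiled out analytically through a Cholesky
GLS), with an LRT against λ = 0 referred to χ²₁ — conservative at the
boundary. On a star phylogeny λ is unidentifiable and is returned as 0 with
a flag. PGLS estimates λ jointly by ML by default (REML is not used), and
reports the signed effect size R = sign(slope)·√R²_GLS with R² computed
against the V-weighted intercept-only model, matching the convention of
signed-effect heatmaps. With λ fixed at 0, PGLS reproduces OLS exactly.

The phylogenetic ANOVA is simulation-based: the observed one-way F is
compared with F statistics from Brownian simulations of the trait on the
tree (μ and σ² from the observed ML fit), rather than a λ-GLS group test —
the simulation null directly encodes "group differences no larger than
shared ancestry produces".

Phylogenetic logistic regression follows the Ives–Garland idea: a logistic
model whose working residual correlation decays along the tree as
exp(−α·D) with D the patristic distance scaled to unit maximum. α is
chosen on a grid by the Gaussian working likelihood of the IRLS
pseudo-response; when the best α sits at the no-signal boundary the fit
falls back *exactly* to Firth-penalised logistic regression and is flagged.
Firth's hat-value correction keeps estimates finite under complete
separation (flagged as such).

Permutation distance tests compare within-group and between-group pairwise
phylogenetic distances with a Welch t statistic; the null permutes node
labels (node-level exchangeability; permuting pair assignments is the noted
alternative and is not implemented). On ultrametric trees the distance
matrix has few distinct values, which can make the test mildly conservative
— never anticonservative.

All empirical p-values use the +1 correction and are strictly positive.
Non-ultrametric trees are accepted as-is; no ultrametricisation is applied.
Likelihoods are evaluated via Cholesky factorisations and agree with
brute-force determinant/inverse evaluation to 1e-8 on small instances
(tested).

## The synthetic generator

`synthetic_spec()` defaults emulate the scale of the global
coral-Symbiodiniaceae compilation: 152 corals × 385 phylotypes, ~16,000
records, seven planted modules, ~30% vertically transmitting corals with
module alignment 0.8, a Pareto-tailed phylotype attractiveness (tail
exponent 2, capped at 100×) producing a few super-generalists, log-normal
per-coral record totals (sd 1 on the log scale, floor 10 records), and
thermotolerance known only for the most-recorded ~19% of phylotypes — the
same shape as the real compilation, where a fifth of phylotypes carry
three-quarters of the records. Trait defaults plant substantial
phylogenetic signal (λ = 0.7) on both trees.

Records are generated per coral: a binomial split places a fraction μ of
records outside the coral's module (default μ = 0.25, which yields Q near
0.6, comparable to published reef networks); within the module,
frequencies are Dirichlet-multinomial with total concentration 3 so that
assemblage evenness — and hence d′ and rarefied richness — varies
realistically among corals; outside the module, leakage is a plain
multinomial by attractiveness, deliberately diffuse so it cannot plant
spurious module signal that contradicts a phylotype's own label. Every
phylotype is anchored to one primary host inside its module with 1–2
seeded records, because a phylotype appears in a compiled dataset only if
it was recorded somewhere; this keeps the observed phylotype pool equal to
the nominal 385.

BRI and TT are drawn on the latent Brownian scale and mapped affinely to
[0, 100]; λ is defined on the latent scale and the bounded mapping can
attenuate measured λ slightly. The optional planted effect adds a slope
(in latent SDs per SD of rarefied richness at depth 10) to the BRI of VT
corals only; rarefied rather than raw richness is used because raw
richness mostly reflects sampling effort and is nearly orthogonal to what
the analysis measures. The planted partition, variant map and latent
traits are returned for scoring and never read by any analysis stage.

What the generator does *not* emulate: ITS2 sequence evolution, bleaching
time series, spatial structure, or correlated missingness beyond the
abundance-ranked TT rule. Passing tests demonstrate that the pipeline
recovers structure it was designed to detect under a known generative
model, not that the model captures every feature of real reef data.

## Sensitivity procedures

The metahaplotype collapse merges, within each coral, intragenomic variants
(IGVs) that co-occur with their ancestral phylotype into a host-specific
node `ancestor@coral`; a variant's records in hosts lacking the ancestor
are dropped (a switch keeps them), and variants with no ancestral
co-occurrence anywhere are eliminated. Under the default rule the collapse
is idempotent and conserves records exactly up to the dropped variant rows.
Host-specific metahaplotype nodes inherit the ancestor's TT score, since
ancestors are chosen to have known thermotolerance. Which sequences count
as variants of which ancestor is an *input table*, not an inference; the
generator plants a known map for testing. Sampling-intensity checks regress
each assemblage metric on log10 record count with PGLS, and depth subsets
re-run analyses on corals with at least 10/15/20 records.

## Problem sizes and numerical choices

The test suite and the acceptance script run the optimizer at 5–8 restarts
of 2×10^5 stitches on the 152×385 network (the default 1,000 × 10^6 budget
is for final analyses of real data; on synthetic networks of this size the
partition stabilises well below that), 100 null networks for z-scores,
50–100 replicates for recovery checks, and 199 permutations inside
calibration loops. Optimizer acceptance uses ΔQ ≥ 0; stored Q is always
recomputed from scratch from the final partition. Random draws go through
R's RNG everywhere, including inside the compiled stitch kernel, so a
single seed reproduces every result byte-for-byte.

## Known limitations

- The stitch optimizer is a hill-climb; on weakly modular networks
  different restarts find different local optima, which is why role scores
  are replicate-averaged and the minimum-module-count selection rule is
  applied across restarts.
- The PLR signal parameter α is chosen on a finite grid by a working
  likelihood, not by exact ML; boundary fits are flagged and collapse to
  Firth logistic regression.
- The LRT for λ uses the χ²₁ reference despite the boundary, which is
  conservative.
- d′'s candidate-ordering search above 7 partners is exact in all cases we
  enumerated but is not proven exhaustive; the exact search is used
  wherever partner counts allow.
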