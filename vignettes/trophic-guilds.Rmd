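---
title: "Delineating trophic guilds from gut contents and phylogeny: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating trophic guilds from gut contents and phylogeny: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical methods implemented in
`trophoguild`, the assumptions behind them, the tunable parameters, and
the deliberate design choices made where several defensible options
existed. It states no empirical result; all quantitative claims about the
package's behaviour are established by the test suite and the acceptance
script, which recompute them from scratch.

## 1. From gut contents to a diet matrix

The raw input is a table of individual gut contents: one row per
(individual, prey item) with the fraction of gut volume or frequency the
item contributed. Standardization proceeds in three steps.

1. **Crosswalk.** Raw prey labels are mapped onto 38 canonical prey
   groups (`prey_groups()`), mostly at phylum/class rank, with
   crustaceans at order/superorder and three ecological groups
   (`detritus`, `inorganic`, `zooplankton` — the latter holding all eggs
   and larvae regardless of taxonomy). Composite labels may be split
   across two groups with weights summing to 1 (the classic
   "Algae & Detritus" item is divided equally between `benthic autotroph`
   and `detritus`); non-informative or redundant labels are discarded
   explicitly. Crosswalks can extend labels but never the group list, so
   every diet matrix is comparable.
2. **Sampling filter.** Species with fewer than `min_guts` (default 10)
   non-empty guts are dropped: diet proportions estimated from a handful
   of guts are dominated by accidental prey.
3. **Aggregation.** Each individual's retained fractions are renormalized
   to sum to 1 — so discarded material does not deflate the rest — and
   individuals are averaged with equal weight into the consumer profile.
   Consumers are keyed either by species (pooling all individuals
   globally) or by species × location. Equal weight per individual is the
   neutral choice where the aggregation scheme is not dictated by the
   data; a gut-volume-weighted pooling would over-weight large
   individuals, and location-equal weighting is available simply by
   building the by-location matrix and averaging its rows. Row sums are
   enforced to 1 within 1e-9; raw per-individual sums are accepted up to
   1 + 1e-6.

## 2. Guilds as modules of the bipartite diet network

The diet matrix *is* a weighted bipartite network: consumers on one side,
prey groups on the other, edge weights the proportional diet
contributions. Because rows sum to 1, rare or accidental prey carry
little weight and cannot drive the module structure; no additional
prevalence thresholding is applied.

Modules jointly partition consumers and prey by maximizing Barber's
weighted bipartite modularity

$$Q = \frac{1}{m}\sum_{ij}\left(W_{ij} - \frac{r_i c_j}{m}\right)
      \,\delta(g_i, h_j),$$

with $m$ the total weight, $r_i$ and $c_j$ row and column strengths, and
$\delta$ indicating co-membership. The all-in-one-module partition scores
exactly 0, so any reported $Q > 0$ reflects genuine structure.

The optimizer is a weighted bipartite label propagation with a greedy
module-merge refinement, in the spirit of LPAwb+: consumers start from a
random label assignment (the stochastic step that motivates consensus),
consumers and prey alternately adopt the module with the largest local
modularity gain, and module pairs are merged greedily while $Q$
increases. Node sweeps follow input order; label ties break toward the
smallest module id; a node whose best gain is negative opens its own
module. The optimizer is deterministic given its seed. Label propagation
was preferred over simulated annealing for speed and per-seed
reproducibility; stochastic exploration is supplied by restarts instead.
The module count is always an output, never a parameter.

Because restarts can land in different local optima, the pipeline runs
the maximization `n_runs` times (default 500) and keeps the **medoid**
partition: the run minimizing the summed variation of information
$\mathrm{VI} = H(X) + H(Y) - 2I(X;Y)$ (natural logarithms) to all other
runs, ties broken toward the earliest run. VI is a true metric on
partitions and is 0 iff two partitions coincide up to relabeling, which
makes "the ensemble agreed" a checkable statement (`VI = 0` to a planted
truth) rather than an impression.

Regional structure is assessed before pooling: the by-location network is
partitioned and `cross_location_consistency()` reports the fraction of
multi-location species whose location nodes share a module. When that
fraction is high, the global (pooled) network is the appropriate basis
for guild definition.

## 3. Expert agreement

Independent classification schemes are standardized onto five broad
guilds (herbivores and detritivores, invertivores, omnivores,
planktivores, piscivores). Schemes lacking a category are compared only
across the categories both schemes define; pairs sharing fewer than
`min_shared` species (default 50) are skipped. Agreement is the fraction
of shared species with identical labels; per-guild agreement is computed
row-wise from each scheme of a pair and pooled over both orderings
(direction-free), then averaged over pairs without weighting by
shared-species count — pair-weighted averages are available from the
per-pair table if wanted. Within-scheme duplicate species keep the last
entry, with a warning.

## 4. Phylogenetic signal: the delta statistic

Conservatism of the guild trait is measured from the certainty of
ancestral-state reconstructions. Marginal ancestral probabilities are
computed under an equal-rates Mk model with the transition rate fitted by
maximum likelihood (an up–down pruning pass with the closed-form ER
transition kernel; verified against enumeration and `ape::ace`). Each
internal node's probability vector is collapsed to a linearized
uncertainty in (0,1) — 1 at a uniform vector, 0 at a point mass — and the
node uncertainties are modelled as Beta($\alpha$, $\beta$) with
exponential priors; the statistic is $\delta = \beta/\alpha$. Conserved
traits give confident reconstructions, hence small uncertainties and
large $\delta$; its absolute magnitude grows with tree size and category
count and is not comparable across datasets, so inference always uses the
shuffle null: $\delta$ recomputed after permuting trait values across
tips (default 100 times), with
$p = (1 + \#\{\delta_{\mathrm{null}} \ge \delta_{\mathrm{obs}}\}) /
(1 + n_{\mathrm{shuffles}})$.

Two deliberate simplifications, both flagged:

* node probabilities come from deterministic marginal ML reconstruction
  rather than Bayesian sampling of rate and histories — a deterministic,
  fast stand-in with the same entropy structure;
* the Beta parameters default to their posterior mode (`method = "mle"`,
  deterministic); `method = "mcmc"` provides the Metropolis posterior
  mean of $\beta/\alpha$.

Zero-length branches are clamped to 1e-8 with a warning; a constant trait
leaves $\delta$ undefined and is an error.

## 5. The multinomial phylogenetic model

Guild membership is modelled with a reference-category logit
($\mu_1 = 0$):

$$\mu_k = \beta_{0k} + \beta_{1k}\,\ln(\mathrm{size_{max}}) +
\gamma_{s,k}, \qquad k = 2, \dots, K,$$

where per category the species effects $\gamma_{\cdot,k}$ are zero-mean
Gaussian with covariance $\sigma_k^2\,C$; $C$ is the Brownian
phylogenetic correlation (shared path length from the root divided by
tree depth, unit diagonal). Per-category scales $\sigma_k$ are
independent; cross-category correlation of the phylogenetic effects is
not modelled. The reference category is the first factor level of the
trait (the first module id, unless the user releveles).

Priors are weakly informative rather than flat so the posterior is
proper: Normal(0, 5) on intercepts and slopes, half-Normal(0, 2.5) on
$\sigma_k$. ln-size is centered at the training mean internally (slopes
are unaffected; the center is stored and reused in prediction).

Sampling uses Hamiltonian Monte Carlo on the non-centered
parameterization ($\gamma_k = \sigma_k L z_k$, $L$ the Cholesky factor of
$C$ with 1e-8 jitter), with dual-averaging step-size adaptation during
warmup (target acceptance 0.8) and leapfrog lengths drawn uniformly up to
`max_leapfrog` (default 20). The default schedule is 3 chains × 6,000
iterations with 1,000 warmup. Split-$\hat R$ is computed for every stored
parameter; any value above 1.05 triggers a warning, never silence.
Sampling is deterministic given the seed.

Fitted and extrapolated probabilities are summarized per species by the
per-guild posterior mean and SD, the argmax guild, the **negentropy**
$1 - H(p)/\ln K \in [0,1]$ (certainty of assignment; normalization by
$\ln K$ is chosen so the bounds hold for any $K$ — an unnormalized
"entropy minus one" would go negative), and the **total SD**
$\sqrt{\sum_k \mathrm{sd}_k^2}$. The argmax of the posterior mean
probabilities defines the predicted guild (rather than a per-draw
majority vote; with well-mixed chains the two rarely differ, and the mean
is the quantity reported anyway).

### Extrapolation to unsampled species

For a species not in the training set, each posterior draw proceeds as:
sample one tree from the supplied set (accommodating topological
uncertainty from stochastically resolved trees), take that draw's
$\gamma$ at the training tips, estimate the new tip's $\gamma$ by
re-rooting the tree at the tip's parent edge and computing the Brownian
maximum-likelihood ancestral estimate at that node, then push
$\beta_0, \beta_1, \ln(\mathrm{size_{max}})$ and the estimated $\gamma$
through the softmax. The re-rooting estimate is a linear combination of
training-tip values whose weights depend only on the tree, so weights are
cached per (tree, species); the estimator agrees with
`picante::phyEstimate` to numerical precision (tested), and a tip
attached by a zero-length branch provably inherits its neighbour's
prediction. The default is 2,000 draws; `use_all_draws = TRUE` cycles
every posterior draw once for deterministic summaries.

Leave-one-out cross-validation refits the model once per held-out species
and extrapolates to it. A reduced per-fold schedule (1 chain, 800
iterations, 300 warmup, 500 extrapolation draws) is the default and is an
explicit approximation — the full protocol is available by passing the
full schedule. A guild represented by a single species cannot be
predicted for its own fold (its category is absent from training), which
bounds attainable LOO accuracy; the confusion matrix makes such cases
visible.

## 6. Interaction prediction

Pairwise consumer × prey-group interactions are labelled from the pooled
diet matrix: 1 where the pooled proportion exceeds `presence_threshold`
(default 0 — any recorded consumption; a detection floor can be imposed),
0 elsewhere, over the full cartesian grid. Features are phylogenetic
eigenvector map coordinates (principal coordinates of the patristic
distance matrix; positive-eigenvalue axes only, by default the smallest
set explaining 95% of positive-eigenvalue variance), ln(max size), and a
one-hot prey-group encoding — a single stacked model across prey groups
shares phylogenetic structure rather than fitting 38 separate models. PEM
coordinates must come from one decomposition covering training and
prediction species alike (compute them on the full tree up front).

The ensemble stacks three base learners — a histogram extreme-gradient
booster, a classical stochastic booster (shallow trees, learning rate
0.05, 50% subsampling), and a probability random forest, each with
`n_trees` (default 2,000) trees — under a binomial GLM super-learner
fitted **only** on out-of-fold predictions from a common 10-fold plan;
the base learners are then refitted on the full data for prediction.
Evaluation reports the rank-statistic AUC (midranks for ties; equal to
the pairwise-comparison probability) and the true skill statistic
TSS = sensitivity + specificity − 1 at a threshold chosen by maximizing
TSS on the model's *calibration* (out-of-fold) predictions, never on test
data. Transferability is assessed by leave-one-region-out validation.

## 7. The synthetic-data generator

`simulate_dataset()` emulates the structure the analyses assume, with
defaults matching a global multi-location gut-content compilation: 615
consumer species on an ultrametric unit-depth Yule tree; 8 guilds evolved
by an equal-rates Mk process (rate `q = 0.3` per unit branch length —
strongly conserved at that tree size); ln sizes as guild means (5–80 cm,
log-spaced) plus Brownian deviations (sd 0.4); a Dirichlet hierarchy
guild profile → species profile (concentration 50) → individual gut
(concentration 20) over the 38 prey groups, which produces both
guild-level structure and individual-level accidental prey; 6 locations
with 16% of species sampled in more than one; 10–40 guts per species; and
33 expert schemes with per-species relabel probability 0.12 (two
independent such schemes agree on about
$(1-\varepsilon)^2 + \varepsilon^2/(K-1) \approx 78\%$ of species).
A master seed is split into per-stage seeds
(`split_seed()`), so any stage can be regenerated independently and the
whole dataset is bit-reproducible.

What the generator does **not** emulate: heterogeneous prey taxonomies
across historical datasets, ontogenetic or seasonal diet shifts, observer
bias, gappy size data, and non-ultrametric or misestimated phylogenies.
Tests passing on synthetic data therefore establish that the machinery is
correct under its stated assumptions, not that any particular empirical
dataset satisfies them.

Validation-oriented trait simulations additionally condition on every
guild containing a minimum number of species
(`min_state_count`): guilds are groups of species, and a "guild" of one
tip carries no permutation information for the signal test, and cannot be
predicted in leave-one-out folds.

## 8. Problem sizes and numerical choices in the shipped tests

The test-suite and acceptance-script problem sizes are the package's
choices for routine validation, kept at desk scale: exhaustive modularity
oracles on networks of up to 10 nodes; planted-guild recovery with 3
guilds × 20 species over 500-restart ensembles; delta calibration on a
fixed 64-tip tree (100 shuffled replicates, 100-shuffle nulls) and power
at Mk rate 0.4 with every guild holding at least 5 species; parameter
recovery with K = 4, 150 tips, 20 replicates at a 2-chain × 900-iteration
schedule; leave-one-out over 64 tips and 8 guilds at the fast per-fold
schedule; ensembles with a few hundred trees. The full-scale defaults
(500 restarts, 3 × 6,000 iterations, 2,000 trees, 2,000 draws) remain the
function defaults.

Numerical conventions collected in one place: proportion tolerances 1e-6
(raw) and 1e-9 (post-normalization); Cholesky jitter 1e-8; zero-length
branches clamped to 1e-8; node-uncertainty clamp 1e-8 away from {0,1};
modularity merge threshold 1e-12; softmax is log-sum-exp stabilized;
0·log 0 := 0 throughout; p-values use the (1 + exceedances)/(1 + n)
convention; all RNG flows from explicit seeds, with `split_seed()`
deriving stage seeds below 2^31.

## 9. Known limitations

* The Mk ancestral machinery assumes equal rates; strongly asymmetric
  guild transitions would call for an ARD variant.
* The HMC sampler uses a unit mass matrix; posteriors with extreme scale
  separation may need longer warmup (watch the $\hat R$ warning).
* LOO accuracy is bounded above when guilds contain singletons (their
  folds lose the category entirely).
* The interaction model shares one stack across prey groups; per-prey
  models may win when prey-specific feature interactions dominate.
* Expert-agreement machinery assumes one label per species per scheme;
  multi-label schemes must be resolved upstream.
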