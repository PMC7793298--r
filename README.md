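# trophoguild

Quantitative delineation of consumer trophic guilds from gut-content
data, and prediction of guilds and pairwise trophic interactions from
phylogeny and body size.

Trophic guilds in diverse communities (the motivating system is tropical
reef fishes) are usually assigned by expert opinion, and experts
disagree. `trophoguild` implements a reproducible alternative built on
empirical diet data:

1. **Standardization** — individual gut-content records are crosswalked
   onto 38 canonical prey groups, species with fewer than 10 sampled guts
   are dropped, and per-individual proportions are renormalized and
   averaged into a consumer × prey-group diet matrix.
2. **Guild delineation** — the diet matrix is a weighted bipartite
   network; guilds are consumer-side modules maximizing Barber's
   modularity
   `Q = (1/m) Σ_ij (W_ij − r_i c_j / m) δ(g_i, h_j)`,
   with 500 seeded restarts consolidated by the variation-of-information
   medoid. Cross-location consistency of modules is quantified before
   pooling regions.
3. **Expert agreement** — independent classification schemes are
   standardized to five broad guilds and compared pairwise with confusion
   matrices over shared species.
4. **Phylogenetic signal** — conservatism of the guild trait is measured
   with the entropy-based δ statistic (Beta model on ancestral-state
   uncertainties, δ = β/α) against a trait-shuffling null.
5. **Guild model** — a Bayesian multinomial logistic regression with
   reference category (`mu_1 = 0`,
   `mu_k = β0_k + β1_k ln(sizemax) + γ_phy[s,k]`, `γ` Brownian on the
   tree), sampled by Hamiltonian Monte Carlo; guild probabilities for
   unsampled species are extrapolated by re-rooting ancestral estimation
   of the phylogenetic effect across a set of trees, summarized with
   per-guild means/SDs, negentropy and total SD, and validated by
   leave-one-out cross-validation.
6. **Interaction model** — pairwise species × prey-group interaction
   probabilities from phylogenetic eigenvector maps, ln size and prey
   identity, via a stacked ensemble (two gradient-boosting variants + a
   random forest under a GLM super-learner trained on out-of-fold
   predictions), evaluated by AUC and TSS, including leave-one-region-out
   transfer.

A synthetic-data generator (`simulate_dataset()`) reproduces the
statistical structure of a multi-location gut-content compilation (Yule
tree, Mk guild trait, Brownian log sizes, Dirichlet diet hierarchy,
overlapping regions, noisy expert schemes) so the entire pipeline is
testable without any external data.

## Worked example

```r
library(trophoguild)

# a 60-species community with 3 conserved guilds and known diet profiles
tree   <- simulate_tree(60, seed = 42)
guilds <- simulate_guilds(tree, K = 3, q = 0.3, seed = 7,
                          ensure_all_states = TRUE, min_state_count = 12,
                          max_tries = 500)
d    <- simulate_diets(guilds, default_guild_profiles(3),
                       concentration = 200, kappa = 20,
                       guts_min = 10, guts_max = 20, seed = 2)
diet <- build_diet_matrix(filter_min_guts(d$records, 10))  # rows sum to 1

med <- select_medoid(modularity_ensemble(diet, n_runs = 500, base_seed = 1))
med
#> module_partition: 3 modules, 60 consumers, 38 prey; Q = 0.5661
variation_of_information(med$consumers, guilds[names(med$consumers)])
#> [1] 0

sig <- delta_null_test(tree, guilds, n_shuffles = 100, seed = 1)
sig
#> delta = 22.13 | null median = 0.02767 (95% CI 0.003976 - 0.1616 ) | p = 0.009901
```

The medoid of 500 restarts recovers exactly the three planted guilds
(variation of information 0 to the truth) at modularity Q ≈ 0.57, and
the guild trait's δ exceeds its shuffle null by three orders of
magnitude (p at the resolution floor of 100 shuffles) — the same two
statistics the real analysis reads off empirical data.

A command-line wrapper for the data stages ships in
`inst/cli/trophoguild.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","trophoguild.R",package="trophoguild"))')" \
    simulate --n-species 60 --guilds 3 --seed 42 --out simdata
```

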