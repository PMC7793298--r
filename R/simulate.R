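# Synthetic multi-location gut-content datasets with known truth.
#
# The generator follows the structure the downstream analyses assume: an
# ultrametric Yule phylogeny; a discrete guild trait evolved on it under an
# equal-rates Mk process (the transition rate is the conservatism knob); a
# log body size evolved as guild mean + Brownian deviation; a Dirichlet
# hierarchy guild profile -> species profile -> individual gut over the 38
# canonical prey groups (the individual level supplies the "accidental
# prey" noise real gut contents show); several sampling locations with
# overlapping species sets; and noisy expert relabelings of the guilds.

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulation configuration
#'
#' Defaults emulate the structure of a global compilation of reef-fish
#' gut-content datasets: 615 consumer species across 6 locations with
#' roughly 16% of species sampled in more than one location, 10-40 guts per
#' species (about 23 on average), 38 prey groups, 8 trophic guilds with
#' strong phylogenetic conservatism, and 33 expert classification schemes
#' whose per-species relabel probability of 0.12 yields a median pairwise
#' agreement near 78%.
#'
#' @param n_species number of consumer species (tree tips).
#' @param K number of trophic guilds.
#' @param q equal-rates Mk transition rate (per unit branch length on the
#'   unit-depth tree); smaller = more phylogenetically conserved guilds.
#' @param concentration Dirichlet concentration of species profiles around
#'   their guild profile.
#' @param kappa Dirichlet concentration of individual guts around the
#'   species profile.
#' @param guts_min,guts_max per-species gut count range (uniform).
#' @param n_regions number of sampling locations.
#' @param share_fraction fraction of species sampled in >1 location.
#' @param epsilon expert per-species relabel probability.
#' @param n_experts number of expert schemes.
#' @param signature_mass diet mass a guild concentrates on its signature
#'   prey groups.
#' @param size_log_means per-guild mean of ln(max size, cm); default spreads
#'   guild means between 5 cm and 80 cm.
#' @param size_sd Brownian standard deviation of ln size over the tree.
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 615, K = 8, q = 0.3,
                       concentration = 50, kappa = 20,
                       guts_min = 10, guts_max = 40,
                       n_regions = 6, share_fraction = 0.16,
                       epsilon = 0.12, n_experts = 33,
                       signature_mass = 0.9,
                       size_log_means = seq(log(5), log(80),
                                            length.out = K),
                       size_sd = 0.4, seed = 1) {
  stopifnot(n_species >= 3, K >= 2, q >= 0, epsilon >= 0, epsilon <= 1,
            n_regions >= 1, length(size_log_means) == K)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric Yule tree with unit depth
#'
#' @param n_species number of tips (labelled sp001, sp002, ...).
#' @param seed RNG seed.
#' @return a `phylo` tree, ultrametric, root-to-tip depth 1.
#' @export
simulate_tree <- function(n_species, seed = 1) {
  stopifnot(n_species >= 3)
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tr
}

#' Evolve a discrete guild trait on a tree (equal-rates Mk)
#'
#' States evolve from a uniformly drawn root state with symmetric
#' transition rate `q` between every ordered state pair.  With
#' `ensure_all_states = TRUE` the simulation is redrawn (up to `max_tries`)
#' until every one of the K states is realized at the tips, which the
#' guild-modelling stages require.
#'
#' @param tree a `phylo` tree.
#' @param K number of states.
#' @param q transition rate per unit branch length (between each pair).
#' @param seed RNG seed.
#' @param ensure_all_states redraw until all K states appear at tips?
#' @param min_state_count with `ensure_all_states`, additionally require
#'   at least this many tips in the rarest state (guilds are groups of
#'   species, so validation traits should not be singleton categories).
#' @param max_tries redraw budget.
#' @return named integer vector of tip states in 1..K.
#' @export
simulate_guilds <- function(tree, K, q, seed = 1,
                            ensure_all_states = FALSE,
                            min_state_count = 1, max_tries = 200) {
  stopifnot(q >= 0, K >= 2)
  set.seed(seed)
  draw <- function() {
    root <- sample.int(K, 1)
    if (q == 0) {
      st <- rep(root, length(tree$tip.label))
      names(st) <- tree$tip.label
      return(st)
    }
    x <- ape::rTraitDisc(tree, model = "ER", k = K, rate = q,
                         states = seq_len(K), root.value = root,
                         ancestor = FALSE)
    st <- as.integer(as.character(x))
    names(st) <- names(x)
    st
  }
  ok <- function(st) {
    tab <- tabulate(st, nbins = K)
    all(tab > 0) && min(tab) >= min_state_count
  }
  st <- draw()
  if (ensure_all_states) {
    tries <- 1
    while (!ok(st) && tries < max_tries) {
      st <- draw()
      tries <- tries + 1
    }
    if (!ok(st)) {
      warning("could not realize all ", K, " states (>= ",
              min_state_count, " tips each) in ", max_tries, " draws")
    }
  }
  st
}

#' Simulate maximum body sizes (guild mean + Brownian deviation)
#'
#' ln(sizemax) for each species is its guild's mean log size plus a
#' zero-mean Brownian deviation evolved along the tree with standard
#' deviation `sd` per unit branch length.
#'
#' @param tree a `phylo` tree.
#' @param trait named guild vector (1..K) for the tips.
#' @param guild_means length-K vector of mean ln(size, cm) per guild.
#' @param sd Brownian sd; 0 gives sizes exactly exp(guild mean).
#' @param seed RNG seed.
#' @param family_size number of consecutive tips grouped under one
#'   synthetic family label (for extrapolation-pool filters).
#' @return `species_attributes` data.frame: species, max_size_cm, family.
#' @export
simulate_sizes <- function(tree, trait, guild_means, sd = 0.4, seed = 1,
                           family_size = 8) {
  stopifnot(length(guild_means) >= max(trait))
  set.seed(seed)
  dev <- if (sd > 0) ape::rTraitCont(tree, model = "BM", sigma = sd,
                                     root.value = 0)
         else setNames(rep(0, length(tree$tip.label)), tree$tip.label)
  sp <- tree$tip.label
  lsize <- guild_means[trait[sp]] + dev[sp]
  fam <- sprintf("fam%02d", ((seq_along(sp) - 1) %/% family_size) + 1)
  structure(data.frame(species = sp, max_size_cm = exp(lsize),
                       family = fam, stringsAsFactors = FALSE),
            class = c("species_attributes", "data.frame"))
}

#' Default guild diet profiles over the canonical prey groups
#'
#' Each guild receives a disjoint block of signature prey groups carrying
#' `signature_mass` of its diet (split evenly), with the remaining mass
#' spread evenly over all other groups - well separated profiles in the
#' sense that guilds dominate different prey.
#'
#' @param K number of guilds.
#' @param groups prey group names (default the canonical 38).
#' @param signature_mass total mass on the signature block.
#' @return K x length(groups) matrix, rows summing to 1.
#' @export
default_guild_profiles <- function(K, groups = prey_groups(),
                                   signature_mass = 0.9) {
  G <- length(groups)
  stopifnot(K <= G)
  block <- split(seq_len(G), cut(seq_len(G), K, labels = FALSE))
  P <- matrix((1 - signature_mass) / G, nrow = K, ncol = G,
              dimnames = list(paste0("guild", seq_len(K)), groups))
  for (k in seq_len(K)) {
    P[k, block[[k]]] <- P[k, block[[k]]] +
      signature_mass / length(block[[k]])
  }
  P / rowSums(P)
}

#' Allocate species to sampling regions with overlap
#'
#' Every species gets one home region (uniform); a fraction
#' `share_fraction` of species is additionally sampled in one extra
#' region, mirroring compilations where most species occur in a single
#' location.
#'
#' @param species species names.
#' @param n_regions number of regions (named loc1, loc2, ...).
#' @param share_fraction fraction of species present in >1 region.
#' @param seed RNG seed.
#' @return named list: per species, the character vector of its regions.
#' @export
simulate_regions <- function(species, n_regions, share_fraction = 0.16,
                             seed = 1) {
  stopifnot(n_regions >= 1, share_fraction >= 0, share_fraction <= 1)
  set.seed(seed)
  regs <- sprintf("loc%d", seq_len(n_regions))
  home <- sample(regs, length(species), replace = TRUE)
  out <- as.list(home)
  names(out) <- species
  if (n_regions > 1 && share_fraction > 0) {
    shared <- runif(length(species)) < share_fraction
    for (i in which(shared)) {
      out[[i]] <- c(out[[i]], sample(setdiff(regs, out[[i]]), 1))
    }
  }
  out
}

#' Simulate individual gut-content records
#'
#' Dirichlet hierarchy: species profile ~ Dir(concentration x guild
#' profile); each individual gut ~ Dir(kappa x species profile).  When a
#' region allocation is supplied, a species' guts are spread across its
#' regions (at least `guts_min` per region so the per-location filter is
#' meaningful), all drawn from the same species profile unless
#' `region_noise_kappa` is finite, in which case each region uses its own
#' profile ~ Dir(region_noise_kappa x species profile).
#'
#' @param trait named guild vector for the species.
#' @param profiles K x G guild profile matrix (rows sum to 1).
#' @param concentration species-level Dirichlet concentration.
#' @param kappa individual-level Dirichlet concentration.
#' @param guts_min,guts_max per-species gut count range.
#' @param regions optional [simulate_regions()] allocation.
#' @param region_noise_kappa finite value adds regional diet noise;
#'   `Inf` (default) makes regional diets identical in expectation.
#' @param seed RNG seed.
#' @return list: `records` (a `gut_records` table) and `species_profiles`
#'   (truth, species x G).
#' @export
simulate_diets <- function(trait, profiles, concentration = 50, kappa = 20,
                           guts_min = 10, guts_max = 40, regions = NULL,
                           region_noise_kappa = Inf, seed = 1) {
  stopifnot(all(abs(rowSums(profiles) - 1) < 1e-8))
  set.seed(seed)
  sp <- names(trait)
  G <- ncol(profiles)
  groups <- colnames(profiles)
  if (is.null(regions)) regions <- setNames(as.list(rep("loc1",
                                                        length(sp))), sp)
  sp_prof <- matrix(NA_real_, length(sp), G, dimnames = list(sp, groups))
  recs <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    s <- sp[i]
    prof <- rdirichlet(1, concentration * profiles[trait[[s]], ])[1, ]
    sp_prof[s, ] <- prof
    regs <- regions[[s]]
    n_guts <- sample(seq(guts_min, guts_max), 1)
    per_reg <- pmax(guts_min, floor(n_guts / length(regs)))
    rows <- vector("list", length(regs))
    for (r in seq_along(regs)) {
      rprof <- if (is.finite(region_noise_kappa)) {
        rdirichlet(1, region_noise_kappa * prof)[1, ]
      } else prof
      guts <- rdirichlet(per_reg[1], kappa * rprof)
      ids <- sprintf("%s_%s_i%03d", s, regs[r], seq_len(nrow(guts)))
      rows[[r]] <- data.frame(
        individual_id = rep(ids, each = G),
        species = s, location = regs[r],
        prey_item = rep(groups, times = nrow(guts)),
        value = as.vector(t(guts)), stringsAsFactors = FALSE)
    }
    recs[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, recs)
  out <- out[out$value > 0, , drop = FALSE]
  list(records = gut_records(out), species_profiles = sp_prof)
}

#' Simulate noisy expert classification schemes
#'
#' Each expert relabels each species with probability `epsilon`; the
#' replacement is drawn from the guild-specific row of `confusion_kernel`
#' (default: uniform over the other guilds), which lets some guild pairs be
#' confused more often than others, as real expert schemes are.
#'
#' @param trait named true guild vector (1..K).
#' @param n_experts number of schemes.
#' @param epsilon relabel probability in \[0,1\].
#' @param confusion_kernel optional K x K row-stochastic matrix of
#'   replacement probabilities (diagonal ignored/renormalized away).
#' @param seed RNG seed.
#' @return list of `classification_scheme` objects.
#' @export
simulate_expert_schemes <- function(trait, n_experts, epsilon,
                                    confusion_kernel = NULL, seed = 1) {
  stopifnot(epsilon >= 0, epsilon <= 1, n_experts >= 1)
  set.seed(seed)
  K <- max(trait)
  if (is.null(confusion_kernel)) {
    confusion_kernel <- matrix(1 / (K - 1), K, K)
    diag(confusion_kernel) <- 0
  } else {
    diag(confusion_kernel) <- 0
    confusion_kernel <- confusion_kernel / rowSums(confusion_kernel)
  }
  vocab <- paste0("guild", seq_len(K))
  lapply(seq_len(n_experts), function(e) {
    lab <- trait
    flip <- runif(length(trait)) < epsilon
    for (i in which(flip)) {
      lab[i] <- sample.int(K, 1, prob = confusion_kernel[trait[i], ])
    }
    classification_scheme(setNames(vocab[lab], names(trait)),
                          scheme_id = sprintf("expert%02d", e),
                          vocabulary = vocab)
  })
}

#' Simulate a full synthetic study
#'
#' Runs every generator stage from one master seed (split into per-stage
#' seeds with [split_seed()]), returning data plus all truth tables.
#'
#' @param config a [sim_config()].
#' @return list with `tree`, `guilds`, `attrs`, `profiles`,
#'   `species_profiles`, `records`, `regions`, `schemes`, `config`, `seeds`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- split_seed(config$seed,
                      c("tree", "guilds", "sizes", "regions", "diets",
                        "experts"))
  tree <- simulate_tree(config$n_species, seeds[["tree"]])
  guilds <- simulate_guilds(tree, config$K, config$q, seeds[["guilds"]],
                            ensure_all_states = TRUE)
  attrs <- simulate_sizes(tree, guilds, config$size_log_means,
                          sd = config$size_sd, seed = seeds[["sizes"]])
  profiles <- default_guild_profiles(config$K,
                                     signature_mass = config$signature_mass)
  regions <- simulate_regions(tree$tip.label, config$n_regions,
                              config$share_fraction, seeds[["regions"]])
  diets <- simulate_diets(guilds, profiles,
                          concentration = config$concentration,
                          kappa = config$kappa,
                          guts_min = config$guts_min,
                          guts_max = config$guts_max,
                          regions = regions, seed = seeds[["diets"]])
  schemes <- simulate_expert_schemes(guilds, config$n_experts,
                                     config$epsilon,
                                     seed = seeds[["experts"]])
  list(tree = tree, guilds = guilds, attrs = attrs, profiles = profiles,
       species_profiles = diets$species_profiles,
       records = diets$records, regions = regions, schemes = schemes,
       config = config, seeds = seeds)
}
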