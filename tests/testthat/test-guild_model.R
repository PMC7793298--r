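test_that("phylogenetic correlation matrix has the Brownian structure", {
  # star tree: no shared history, identity correlation
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(unname(phylo_covariance(star)), diag(3))
  # sisters splitting at 90% depth share 0.9 correlation
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.9,C:1);")
  C <- phylo_covariance(tr)
  expect_equal(C["A", "B"], 0.9)
  expect_equal(diag(C), setNames(rep(1, 3), c("A", "B", "C")))
  # PSD across random Yule trees
  for (s in 1:10) {
    Cs <- phylo_covariance(simulate_tree(25, seed = s))
    expect_gte(min(eigen(Cs, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
  }
  expect_warning(phylo_covariance(ape::read.tree(text = "((A:1,B:2):1,C:4);")),
                 "ultrametric")
})

test_that("softmax link obeys its closed forms and invariances", {
  expect_equal(guild_probability(rep(0, 8)), rep(1 / 8, 8))
  expect_equal(guild_probability(c(0, log(3))), c(0.25, 0.75))
  mu <- c(0, 1.3, -0.4, 2.2)
  expect_equal(guild_probability(mu), guild_probability(mu + 5))
  expect_equal(sum(guild_probability(mu)), 1)
  M <- rbind(mu, mu + 1)
  expect_equal(guild_probability(M)[1, ], guild_probability(mu))
})

test_that("negentropy and total SD closed forms", {
  expect_equal(negentropy(rep(1 / 8, 8)), 0)
  expect_equal(negentropy(c(1, rep(0, 7))), 1)
  expect_equal(negentropy(c(0.5, 0.5, rep(0, 6))), 2 / 3)
  expect_equal(total_sd(c(3, 4, rep(0, 6))), 5)
  expect_equal(total_sd(rep(0, 8)), 0)
  expect_equal(total_sd(c(1, 2, 3)), total_sd(c(3, 1, 2)))
})

test_that("the sampler recovers generating parameters and is seeded", {
  dat <- simulate_guild_model_data(n = 100, K = 3, seed = 21,
                                   b0 = c(0.4, -0.3), b1 = c(1.0, -0.8),
                                   sig = c(0.6, 0.6))
  m <- suppressWarnings(
    fit_guild_model(dat$trait, dat$attrs, dat$tree, chains = 2,
                    iterations = 800, warmup = 300, seed = 5))
  expect_s3_class(m, "guild_model")
  expect_lte(max(m$rhat, na.rm = TRUE), 1.1)
  ci <- apply(m$beta1, 2, quantile, c(0.05, 0.95))
  # slopes of this strongly-informed fit should bracket the truth
  expect_true(all(dat$b1 >= ci[1, ] & dat$b1 <= ci[2, ]))
  m2 <- suppressWarnings(
    fit_guild_model(dat$trait, dat$attrs, dat$tree, chains = 2,
                    iterations = 800, warmup = 300, seed = 5))
  expect_identical(m$beta1, m2$beta1)
  expect_identical(m$gamma, m2$gamma)
  expect_error(
    fit_guild_model(setNames(1:3, c("x", "y", "z")), dat$attrs, dat$tree),
    "overlap")
})

test_that("fitted probabilities normalize and track strong signal", {
  st <- planted_diet_study(n_per_guild = 12, K = 3, seed = 31)
  attrs <- simulate_sizes(st$tree, st$guilds,
                          seq(log(5), log(80), length.out = 3),
                          sd = 0.2, seed = 32)
  m <- suppressWarnings(
    fit_guild_model(st$guilds, attrs, st$tree, chains = 1,
                    iterations = 700, warmup = 250, seed = 6))
  fp <- fitted_probabilities(m)
  expect_equal(unname(rowSums(fp$p_mean)), rep(1, nrow(fp)),
               tolerance = 1e-6)
  expect_gte(mean(fp$guild == as.character(st$guilds[fp$species])), 0.9)
  expect_true(all(fp$negentropy_mean >= 0 & fp$negentropy_mean <= 1))
  expect_true(all(fp$total_sd >= 0))
})

test_that("zero-variance phylogenetic regime concentrates sigma near 0", {
  set.seed(44)
  tree <- simulate_tree(80, seed = 44)
  x <- rnorm(80, 0, 1)
  # guilds depend on size only; no phylogenetic effect at all
  eta <- cbind(0, -0.2 + 1.5 * x)
  pr <- exp(eta) / rowSums(exp(eta))
  y <- apply(pr, 1, function(p) sample.int(2, 1, prob = p))
  trait <- setNames(y, tree$tip.label)
  attrs <- data.frame(species = tree$tip.label, max_size_cm = exp(x + 3),
                      family = "f")
  m <- suppressWarnings(
    fit_guild_model(trait, attrs, tree, chains = 1, iterations = 700,
                    warmup = 250, seed = 7))
  expect_lt(median(m$sigma), 1)
  expect_lt(quantile(m$sigma, 0.25), 0.5)
})

test_that("extrapolation matches picante's re-rooting estimator", {
  skip_if_not_installed("picante")
  tree <- simulate_tree(25, seed = 51)
  set.seed(52)
  vals <- setNames(rnorm(25), tree$tip.label)
  for (tip in c("sp003", "sp017", "sp025")) {
    train <- setdiff(tree$tip.label, tip)
    w <- trophoguild:::reroot_tip_weights(tree, tip, train)
    est <- sum(w * vals[train])
    ref <- picante::phyEstimate(tree, vals[train])[tip, "estimate"]
    expect_equal(est, unname(ref), tolerance = 1e-8)
  }
})

test_that("a zero-length attached tip inherits its neighbor's prediction", {
  dat <- simulate_guild_model_data(n = 40, K = 3, seed = 61,
                                   b0 = c(0.3, -0.2), b1 = c(0.9, -0.6),
                                   sig = c(0.7, 0.7))
  neighbor <- "sp007"
  tree_aug <- phytools::bind.tip(
    dat$tree, "newsp", edge.length = 1e-10,
    where = which(dat$tree$tip.label == neighbor), position = 1e-10)
  m <- suppressWarnings(
    fit_guild_model(dat$trait, dat$attrs, dat$tree, chains = 1,
                    iterations = 600, warmup = 200, seed = 8))
  fp <- fitted_probabilities(m, max_draws = Inf)
  na <- data.frame(
    species = "newsp",
    max_size_cm = dat$attrs$max_size_cm[dat$attrs$species == neighbor],
    family = "f")
  ex <- extrapolate_guilds(m, tree_aug, na, use_all_draws = TRUE)
  expect_lt(max(abs(ex$p_mean[1, ] - fp[neighbor, ]$p_mean)), 1e-3)
  expect_equal(unname(rowSums(ex$p_mean)), 1, tolerance = 1e-6)
  # determinism of the sampled-draw path
  e1 <- extrapolate_guilds(m, tree_aug, na, n_draws = 50, seed = 3)
  e2 <- extrapolate_guilds(m, tree_aug, na, n_draws = 50, seed = 3)
  expect_identical(e1, e2)
  expect_error(extrapolate_guilds(m, dat$tree, na), "missing from tree")
})

test_that("extrapolation pool filter applies family and size rules", {
  attrs <- data.frame(
    species = paste0("s", 1:6),
    max_size_cm = c(10, 2.5, 40, 15, 8, 80),
    family = c("famA", "famA", "famA", "famB", "famC", "famC"))
  pool <- extrapolation_pool(attrs)
  # famB is a singleton family; s2 fails the 3 cm size floor
  expect_setequal(pool$species, c("s1", "s3", "s5", "s6"))
  pool2 <- extrapolation_pool(attrs, family_exceptions = "famB")
  expect_true("s4" %in% pool2$species)
})
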