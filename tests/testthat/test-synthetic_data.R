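test_that("simulated trees are ultrametric with unit depth", {
  tr <- simulate_tree(50, seed = 1)
  expect_equal(length(tr$tip.label), 50)
  expect_false(anyDuplicated(tr$tip.label) > 0)
  depths <- ape::node.depth.edgelength(tr)[1:50]
  expect_equal(depths, rep(1, 50), tolerance = 1e-10)
  expect_identical(ape::write.tree(simulate_tree(50, seed = 1)),
                   ape::write.tree(tr))
})

test_that("Mk guild simulation spans the conservatism gradient", {
  tr <- simulate_tree(40, seed = 2)
  # q = 0: every tip inherits the root state
  g0 <- simulate_guilds(tr, K = 4, q = 0, seed = 3)
  expect_equal(length(unique(g0)), 1)
  # small q: expected number of tip-pattern changes follows the Poisson
  # rate q * (K-1)/... checked loosely via state diversity ordering
  g_lo <- simulate_guilds(tr, K = 4, q = 0.1, seed = 4)
  g_hi <- simulate_guilds(tr, K = 4, q = 20, seed = 4)
  expect_lte(length(unique(g_lo)), length(unique(g_hi)))
  expect_named(g_lo, tr$tip.label, ignore.order = TRUE)
  expect_identical(simulate_guilds(tr, K = 4, q = 0.5, seed = 9),
                   simulate_guilds(tr, K = 4, q = 0.5, seed = 9))
})

test_that("expected Mk change count matches the Poisson oracle", {
  # on a tree of total length T, small-q ER expects ~ q*(K-1)*T state
  # changes; with K=2 compare realized tip disagreement count loosely
  tr <- simulate_tree(60, seed = 5)
  Ttot <- sum(tr$edge.length)
  q <- 0.05
  n_states <- vapply(1:40, function(r) {
    length(unique(simulate_guilds(tr, K = 2, q = q, seed = 500 + r)))
  }, numeric(1))
  # P(at least one change somewhere) ~ 1 - exp(-q * 1 * Ttot)
  p_poly <- mean(n_states > 1)
  expect_lt(abs(p_poly - (1 - exp(-q * Ttot))), 0.25)
})

test_that("size simulation respects guild means", {
  tr <- simulate_tree(120, seed = 6)
  g <- setNames(rep(1:3, length.out = 120), tr$tip.label)
  means <- c(log(5), log(20), log(80))
  a0 <- simulate_sizes(tr, g, means, sd = 0, seed = 7)
  expect_equal(a0$max_size_cm[g[a0$species] == 2], rep(20, 40))
  a1 <- simulate_sizes(tr, g, means, sd = 0.3, seed = 8)
  expect_true(all(a1$max_size_cm > 0))
  for (k in 1:3) {
    expect_lt(abs(mean(log(a1$max_size_cm[g[a1$species] == k])) -
                    means[k]), 0.5)
  }
})

test_that("diet hierarchy produces valid per-individual guts", {
  tr <- simulate_tree(12, seed = 9)
  g <- setNames(rep(1:2, each = 6), tr$tip.label)
  d <- simulate_diets(g, default_guild_profiles(2), concentration = 1e7,
                      kappa = 30, guts_min = 5, guts_max = 8, seed = 10)
  sums <- tapply(d$records$value, d$records$individual_id, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
  # near-infinite concentration pins species profiles to guild profiles
  expect_lt(max(abs(d$species_profiles -
                      default_guild_profiles(2)[g, ])), 0.01)
})

test_that("region allocation covers species with the requested overlap", {
  sp <- sprintf("sp%03d", 1:300)
  regs <- simulate_regions(sp, 4, share_fraction = 0.3, seed = 11)
  expect_named(regs, sp)
  expect_true(all(lengths(regs) >= 1))
  frac_multi <- mean(lengths(regs) > 1)
  expect_lt(abs(frac_multi - 0.3), 0.08)
  all_one <- simulate_regions(sp, 3, share_fraction = 1, seed = 12)
  expect_true(all(lengths(all_one) == 2))
})

test_that("expert scheme noise matches its closed-form agreement", {
  set.seed(13)
  trait <- setNames(sample.int(5, 300, replace = TRUE),
                    sprintf("sp%03d", 1:300))
  sch0 <- simulate_expert_schemes(trait, 4, epsilon = 0, seed = 14)
  s0 <- agreement_summary(sch0, min_shared = 50)
  expect_equal(s0$median_agreement, 1)
  expect_identical(simulate_expert_schemes(trait, 3, 0.2, seed = 15),
                   simulate_expert_schemes(trait, 3, 0.2, seed = 15))
})

test_that("one master seed reproduces the full dataset bit-identically", {
  cfg <- sim_config(n_species = 30, K = 3, q = 0.5, n_regions = 2,
                    n_experts = 3, guts_min = 5, guts_max = 8, seed = 99,
                    size_log_means = c(log(5), log(20), log(80)))
  d1 <- suppressMessages(simulate_dataset(cfg))
  d2 <- suppressMessages(simulate_dataset(cfg))
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$guilds, d2$guilds)
  expect_identical(d1$records, d2$records)
  expect_identical(d1$attrs, d2$attrs)
  expect_identical(lapply(d1$schemes, `[[`, "labels"),
                   lapply(d2$schemes, `[[`, "labels"))
})

test_that("stage seeds are valid and independent of each other", {
  s <- split_seed(123, c("a", "b", "c"))
  expect_named(s, c("a", "b", "c"))
  expect_true(all(s >= 0 & s < 2^31))
  expect_false(any(duplicated(s)))
  expect_identical(split_seed(123, c("a", "b", "c")), s)
})
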