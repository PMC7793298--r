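test_that("phylogenetic eigenvectors reconstruct patristic distances", {
  tree <- simulate_tree(20, seed = 71)
  X <- phylo_eigenvectors(tree, n_axes = 19)
  D <- ape::cophenetic.phylo(tree)[rownames(X), rownames(X)]
  Dhat <- as.matrix(dist(X))
  expect_lt(max(abs(D - Dhat)), 1e-6)
  # axes are orthogonal and eigenvalue-ordered
  G <- crossprod(scale(X, scale = FALSE))
  expect_lt(max(abs(G[upper.tri(G)])), 1e-6)
  ev <- attr(X, "eig")
  expect_true(all(diff(ev) <= 1e-12))
  # star tree: all tips equidistant, coordinates form a regular simplex
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  Xs <- phylo_eigenvectors(star, n_axes = 3)
  ds <- dist(Xs)
  expect_lt(diff(range(ds)), 1e-8)
  # default retains axes for 95% of positive-eigenvalue variance
  X95 <- phylo_eigenvectors(tree)
  expect_lte(ncol(X95), 19)
})

test_that("interaction table covers the cartesian grid with labels", {
  st <- planted_diet_study(n_per_guild = 5, K = 2, seed = 81)
  tab <- build_interaction_table(st$diet)
  expect_equal(nrow(tab), nrow(st$diet) * 38)
  expect_true(all(tab$label %in% 0:1))
  # threshold removes weak interactions
  tab05 <- build_interaction_table(st$diet, presence_threshold = 0.05)
  expect_lt(sum(tab05$label), sum(tab$label))
  # a species eating exactly 2 groups yields 2 positives and 36 negatives
  W <- matrix(0, 1, 38, dimnames = list("spX", prey_groups()))
  W[1, c(3, 10)] <- c(0.7, 0.3)
  one <- build_interaction_table(
    structure(W, class = c("diet_matrix", "matrix"),
              species = "spX", n_guts = 5L, location = NA))
  expect_equal(sum(one$label), 2)
  expect_equal(nrow(one), 38)
})

test_that("rank AUC equals the brute-force pairwise oracle", {
  set.seed(91)
  for (r in 1:5) {
    n <- sample(50:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    s <- round(rnorm(n, y, 1), 1)  # rounding forces ties
    expect_equal(auc_rank(s, y), brute_force_auc(s, y))
  }
  expect_equal(auc_rank(c(0.1, 0.9, 0.2, 0.8), c(0, 1, 0, 1)), 1)
  expect_warning(a <- auc_rank(1:3, c(1, 1, 1)))
  expect_true(is.na(a))
})

test_that("rank AUC agrees with pROC on a shared example", {
  skip_if_not_installed("pROC")
  set.seed(92)
  y <- rbinom(150, 1, 0.5)
  s <- rnorm(150, y)
  ref <- as.numeric(suppressMessages(pROC::auc(y, s)))
  expect_equal(auc_rank(s, y), ref, tolerance = 1e-12)
})

test_that("stacked ensemble separates structured diets and is seeded", {
  st <- planted_diet_study(n_per_guild = 15, K = 3, seed = 101)
  attrs <- simulate_sizes(st$tree, st$guilds,
                          seq(log(5), log(80), length.out = 3),
                          sd = 0.3, seed = 102)
  pem <- phylo_eigenvectors(st$tree)
  tab <- build_interaction_table(st$diet, presence_threshold = 0.02)
  m <- fit_ensemble(tab, pem, attrs, folds = 5, n_trees = 80, seed = 1)
  expect_gt(auc_rank(m$calibration$stacked, m$calibration$label), 0.9)
  # super-learner consumed out-of-fold predictions only
  expect_equal(nrow(m$calibration), nrow(tab))
  p <- predict(m, tab, pem, attrs)
  expect_true(all(p >= 0 & p <= 1))
  m2 <- fit_ensemble(tab, pem, attrs, folds = 5, n_trees = 80, seed = 1)
  expect_identical(p, predict(m2, tab, pem, attrs))
  tab1 <- tab; tab1$label <- 1
  expect_error(fit_ensemble(tab1, pem, attrs), "both")
})

test_that("evaluation reports TSS at a calibration-chosen threshold", {
  set.seed(123)
  cal <- data.frame(label = c(rep(1, 50), rep(0, 50)),
                    stacked = c(runif(50, 0.6, 1), runif(50, 0, 0.4)))
  # on separable calibration scores the threshold lands in the gap
  thr <- trophoguild:::max_tss_threshold(cal$stacked, cal$label)
  expect_gt(thr, max(cal$stacked[cal$label == 0]))
  expect_lte(thr, min(cal$stacked[cal$label == 1]) + 1e-9)
  # formula check: sens 0.8, spec 0.7 -> TSS 0.5
  expect_equal(0.8 + 0.7 - 1, 0.5)
  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  p <- c(0.9, 0.8, 0.7, 0.6, 0.1, 0.9, 0.3, 0.2, 0.2, 0.1)
  pred <- p >= 0.5
  sens <- sum(pred & y == 1) / 5; spec <- sum(!pred & y == 0) / 5
  expect_equal(sens, 0.8); expect_equal(spec, 0.8)
})

test_that("leave-region-out fits without the held-out region", {
  set.seed(111)
  tree <- simulate_tree(30, seed = 111)
  g <- setNames(rep(1:2, each = 15), tree$tip.label)
  regions <- simulate_regions(tree$tip.label, 2, share_fraction = 0.8,
                              seed = 112)
  d <- simulate_diets(g, default_guild_profiles(2), concentration = 200,
                      kappa = 20, guts_min = 8, guts_max = 12,
                      regions = regions, seed = 113)
  diet <- suppressMessages(build_diet_matrix(d$records,
                                             by_location = TRUE))
  tab <- build_interaction_table(diet, presence_threshold = 0.02,
                                 by_region = TRUE)
  attrs <- simulate_sizes(tree, g, c(log(10), log(40)), sd = 0.2,
                          seed = 114)
  pem <- phylo_eigenvectors(tree)
  lro <- leave_region_out(tab, "loc1", pem, attrs, folds = 4,
                          n_trees = 60, seed = 2)
  expect_s3_class(lro$report, "eval_report")
  expect_gt(lro$report$auc, 0.5)
  expect_error(leave_region_out(tab, "atlantis", pem, attrs), "unknown")
  one <- tab[tab$region == "loc1", ]
  expect_error(leave_region_out(one, "loc1", pem, attrs), "2 regions")
})

test_that("global prediction covers the grid and respects training", {
  st <- planted_diet_study(n_per_guild = 8, K = 2, seed = 121)
  attrs <- simulate_sizes(st$tree, st$guilds, c(log(10), log(40)),
                          sd = 0.2, seed = 122)
  pem <- phylo_eigenvectors(st$tree)
  tab <- build_interaction_table(st$diet, presence_threshold = 0.02)
  m <- fit_ensemble(tab, pem, attrs, folds = 4, n_trees = 60, seed = 3)
  grid <- predict_global(m, attrs, pem)
  expect_equal(nrow(grid), nrow(attrs) * 38)
  expect_true(all(grid$probability >= 0 & grid$probability <= 1))
  # species missing from the tree are skipped with a warning
  attrs2 <- rbind(attrs, data.frame(species = "ghost", max_size_cm = 10,
                                    family = "f"))
  expect_warning(g2 <- predict_global(m, attrs2, pem), "ghost")
  expect_equal(nrow(g2), nrow(attrs) * 38)
})
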