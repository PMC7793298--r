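# shared fixtures and independent oracles used across the test files

# tiny raw gut-content table written to a temp CSV
write_toy_records <- function(path, percent = FALSE) {
  f <- if (percent) 100 else 1
  df <- data.frame(
    individual_id = c("i1", "i1", "i2", "i2", "i3"),
    species = c("spA", "spA", "spA", "spA", "spB"),
    location = "loc1",
    prey_item = c("shrimp", "algae", "shrimp", "fish", "shrimp"),
    value = c(0.6, 0.4, 0.5, 0.5, 1.0) * f)
  write.csv(df, path, row.names = FALSE)
  df
}

toy_crosswalk <- function() {
  prey_crosswalk(data.frame(
    label = c("shrimp", "algae", "fish", "Algae & Detritus",
              "Algae & Detritus", "unidentified fragments"),
    group = c("Decapoda", "benthic autotroph", "Actinopterygii",
              "detritus", "benthic autotroph", NA),
    weight = c(1, 1, 1, 0.5, 0.5, 1),
    discard = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)))
}

# guilds as K monophyletic-ish blocks: cut the ultrametric tree's
# dendrogram into K groups (exact for ultrametric trees)
clade_guilds <- function(tree, K) {
  hc <- stats::hclust(stats::as.dist(ape::cophenetic.phylo(tree)),
                      method = "average")
  ct <- stats::cutree(hc, k = K)
  setNames(as.integer(ct), names(ct))[tree$tip.label]
}

# exhaustive maximum Barber modularity over all joint set partitions
# (restricted-growth-string enumeration); feasible for <= 10 nodes
brute_force_max_modularity <- function(W) {
  n <- nrow(W); p <- ncol(W); N <- n + p
  m <- sum(W)
  B <- W - outer(rowSums(W), colSums(W)) / m
  best <- -Inf
  a <- integer(N)
  rec <- function(i, maxl) {
    if (i > N) {
      g <- a[seq_len(n)]; h <- a[n + seq_len(p)]
      q <- sum(B[outer(g, h, "==")]) / m
      if (q > best) best <<- q
      return(invisible())
    }
    for (l in seq_len(maxl + 1L)) {
      a[i] <<- l
      rec(i + 1L, max(maxl, l))
    }
  }
  rec(1L, 0L)
  best
}

# pairwise-comparison AUC (oracle for the rank implementation)
brute_force_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (x in sp) tot <- tot + sum(x > sn) + 0.5 * sum(x == sn)
  tot / (length(sp) * length(sn))
}

# small well-separated planted-guild diet study
planted_diet_study <- function(n_per_guild = 20, K = 3, seed = 1,
                               concentration = 200, kappa = 20) {
  tree <- simulate_tree(n_per_guild * K, seed = seed)
  g <- setNames(rep(seq_len(K), each = n_per_guild), tree$tip.label)
  prof <- default_guild_profiles(K)
  d <- simulate_diets(g, prof, concentration = concentration,
                      kappa = kappa, guts_min = 10, guts_max = 20,
                      seed = seed + 1)
  diet <- suppressMessages(build_diet_matrix(d$records))
  list(tree = tree, guilds = g, diet = diet, profiles = prof)
}

# multinomial phylogenetic data generated from the model itself
simulate_guild_model_data <- function(n = 150, K = 4, seed = 1,
                                      b0 = c(0.3, -0.4, 0.2),
                                      b1 = c(0.8, -0.5, 0.3),
                                      sig = c(0.8, 0.6, 0.7)) {
  set.seed(seed)
  tree <- simulate_tree(n, seed = seed)
  C <- phylo_covariance(tree)
  L <- t(chol(C + diag(1e-8, n)))
  x <- rnorm(n, 0, 0.8)
  eta <- matrix(0, n, K)
  for (k in 2:K) {
    eta[, k] <- b0[k - 1] + b1[k - 1] * x +
      sig[k - 1] * as.numeric(L %*% rnorm(n))
  }
  P <- exp(eta) / rowSums(exp(eta))
  y <- apply(P, 1, function(pr) sample.int(K, 1, prob = pr))
  list(tree = tree,
       trait = setNames(y, tree$tip.label),
       attrs = data.frame(species = tree$tip.label,
                          max_size_cm = exp(x + 3), family = "f",
                          stringsAsFactors = FALSE),
       b0 = b0, b1 = b1, sig = sig)
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_path <- function() system.file("cli", "trophoguild.R",
                                   package = "trophoguild")
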