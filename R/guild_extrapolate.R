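# Extrapolating guild probabilities to species outside the training set.
#
# The phylogenetic effect of a new species is estimated by ancestral-state
# estimation: the tree is re-rooted at the parent edge of the new tip and
# the Brownian maximum-likelihood root estimate at that node is taken as
# the species' effect.  That estimate is a fixed linear combination of the
# training-tip values (weights depend only on the tree), so one weight
# vector per (tree, new species) serves every posterior draw and category.

# Brownian ML root-state estimate as weights over tips, via Felsenstein
# contraction; handles multifurcations and zero-length terminal branches
# (weight concentrates on the zero-distance tip).
root_estimate_weights <- function(tree, eps = 1e-12) {
  po <- stats::reorder(tree, "postorder")
  n <- length(po$tip.label); m <- po$Nnode
  Wt <- matrix(0, n + m, n)
  Wt[cbind(seq_len(n), seq_len(n))] <- 1
  vlen <- numeric(n + m)
  num <- matrix(0, n + m, n)
  denom <- numeric(n + m)
  edge <- po$edge
  done <- c(rep(TRUE, n), rep(FALSE, m))
  for (r in seq_len(nrow(edge))) {
    ch <- edge[r, 2]; pa <- edge[r, 1]
    if (!done[ch]) {
      Wt[ch, ] <- num[ch, ] / denom[ch]
      vlen[ch] <- 1 / denom[ch]
      done[ch] <- TRUE
    }
    vv <- max(po$edge.length[r] + vlen[ch], eps)
    num[pa, ] <- num[pa, ] + Wt[ch, ] / vv
    denom[pa] <- denom[pa] + 1 / vv
  }
  root <- n + 1L
  w <- num[root, ] / denom[root]
  setNames(w, po$tip.label)
}

# weights for the re-rooting estimate of one new tip from training tips
reroot_tip_weights <- function(tree, new_tip, train_tips) {
  keep <- c(train_tips, new_tip)
  t2 <- prune_to(tree, keep)
  tipno <- match(new_tip, t2$tip.label)
  parent <- t2$edge[t2$edge[, 2] == tipno, 1]
  root_node <- length(t2$tip.label) + 1L
  rt <- if (parent == root_node) t2 else
    ape::root(t2, node = parent, resolve.root = FALSE)
  rt2 <- ape::drop.tip(rt, new_tip, trim.internal = TRUE,
                       collapse.singles = TRUE)
  w <- root_estimate_weights(rt2)
  w[train_tips]
}

#' Extrapolate guild probabilities to new species
#'
#' Per draw: one tree is sampled from `trees` and one posterior draw from
#' the model; each new species' phylogenetic effect is the re-rooting
#' Brownian ancestral estimate from the training species' effects on that
#' tree, combined with that draw's intercepts, size slopes and the
#' species' ln(max size) through the softmax link.  Draws are summarized
#' as in [fitted_probabilities()].
#'
#' @param model fitted `guild_model`.
#' @param trees a `phylo` or list of `phylo`; every tree must contain all
#'   training species and all new species as tips.
#' @param new_attrs `species_attributes` rows for the new species.
#' @param n_draws number of (tree, posterior draw) samples (default 2000).
#' @param seed RNG seed.
#' @param use_all_draws use every posterior draw exactly once (cycling
#'   through the trees) instead of sampling; deterministic.
#' @return `guild_prediction` data.frame for the new species.
#' @export
extrapolate_guilds <- function(model, trees, new_attrs, n_draws = 2000,
                               seed = 1, use_all_draws = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1, nrow(new_attrs) >= 1)
  new_sp <- new_attrs$species
  for (ti in seq_along(trees)) {
    miss <- setdiff(c(new_sp, model$species), trees[[ti]]$tip.label)
    if (length(miss)) {
      stop("species missing from tree ", ti, ": ",
           paste(head(miss, 5), collapse = ", "), call. = FALSE)
    }
  }
  set.seed(seed)
  S <- nrow(model$beta0)
  if (use_all_draws) {
    n_draws <- S
    draw_idx <- seq_len(S)
    tree_idx <- rep_len(seq_along(trees), S)
  } else {
    tree_idx <- sample.int(length(trees), n_draws, replace = TRUE)
    draw_idx <- sample.int(S, n_draws, replace = TRUE)
  }
  x_new <- log(new_attrs$max_size_cm) - model$x_center
  Km1 <- model$K - 1
  # weight cache: one matrix (new species x training species) per tree
  wcache <- vector("list", length(trees))
  get_weights <- function(ti) {
    if (is.null(wcache[[ti]])) {
      W <- t(vapply(new_sp, function(s) {
        reroot_tip_weights(trees[[ti]], s, model$species)
      }, numeric(length(model$species))))
      wcache[[ti]] <<- W
    }
    wcache[[ti]]
  }
  P <- array(NA_real_, c(n_draws, length(new_sp), model$K))
  for (d in seq_len(n_draws)) {
    W <- get_weights(tree_idx[d])
    s <- draw_idx[d]
    eta <- matrix(0, length(new_sp), model$K)
    for (k in seq_len(Km1)) {
      g_hat <- as.numeric(W %*% model$gamma[s, , k])
      eta[, k + 1] <- model$beta0[s, k] + model$beta1[s, k] * x_new + g_hat
    }
    P[d, , ] <- guild_probability(eta)
  }
  out <- summarize_guild_draws(P, model$levels)
  rownames(out) <- new_sp
  out$species <- new_sp
  class(out) <- c("guild_prediction", "data.frame")
  out
}

#' Leave-one-out cross-validation of the extrapolation
#'
#' Each species is held out in turn: the model is refitted without it
#' (by default at a reduced MCMC schedule, an explicit approximation of
#' the full per-fold protocol) and its guild is predicted by
#' [extrapolate_guilds()]; the argmax guild is compared to the truth.
#'
#' @param trait,attrs,trees as in [fit_guild_model()] /
#'   [extrapolate_guilds()] (`trees` may be a single `phylo`).
#' @param chains,iterations,warmup per-fold MCMC schedule; the default
#'   (1 chain, 800/300) is the fast approximation.
#' @param n_draws extrapolation draws per fold.
#' @param seed RNG seed.
#' @param species optional subset of species to hold out (default: all).
#' @return list: `accuracy`, `confusion` (truth x predicted, K x K),
#'   `per_guild_accuracy`, `predictions` (data.frame).
#' @export
loo_cv_guilds <- function(trait, attrs, trees, chains = 1,
                          iterations = 800, warmup = 300, n_draws = 500,
                          seed = 1, species = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  lv <- levels(factor(trait))
  if (any(table(factor(trait, lv)) < 2)) {
    warning("some guilds have < 2 species; their LOO folds cannot be ",
            "predicted from a congener")
  }
  sp_all <- names(trait)
  held <- species %||% sp_all
  preds <- character(length(held)); names(preds) <- held
  for (i in seq_along(held)) {
    s <- held[i]
    tr_fold <- trait[setdiff(sp_all, s)]
    # guard: a fold may lose a whole category; refactor levels then
    mod <- suppressWarnings(
      fit_guild_model(tr_fold, attrs[attrs$species != s, ],
                      prune_to(trees[[1]], setdiff(sp_all, s)),
                      chains = chains, iterations = iterations,
                      warmup = warmup, seed = seed + i))
    pr <- extrapolate_guilds(mod, trees, attrs[attrs$species == s, ],
                             n_draws = n_draws, seed = seed + i)
    preds[s] <- pr$guild[1]
  }
  truth <- factor(as.character(factor(trait[held])), levels = lv)
  phat <- factor(preds, levels = lv)
  conf <- table(truth = truth, predicted = phat)
  acc <- mean(as.character(truth) == as.character(phat))
  per_guild <- diag(conf) / pmax(rowSums(conf), 1)
  list(accuracy = acc, confusion = conf, per_guild_accuracy = per_guild,
       predictions = data.frame(species = held,
                                truth = as.character(truth),
                                predicted = preds,
                                stringsAsFactors = FALSE))
}

#' Filter a species table down to the extrapolation pool
#'
#' Applies the standard pool rule: keep species in families with more than
#' one representative (plus any declared single-species exceptions) and
#' with a maximum length above `min_size_cm`.
#'
#' @param attrs `species_attributes` (species, max_size_cm, family).
#' @param min_size_cm size floor (default 3 cm).
#' @param family_exceptions families kept even with a single species.
#' @return filtered `species_attributes`.
#' @export
extrapolation_pool <- function(attrs, min_size_cm = 3,
                               family_exceptions = character()) {
  n_fam <- table(attrs$family)
  fams <- c(names(n_fam)[n_fam > 1], family_exceptions)
  out <- attrs[attrs$family %in% fams &
                 attrs$max_size_cm > min_size_cm, , drop = FALSE]
  rownames(out) <- NULL
  out
}
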