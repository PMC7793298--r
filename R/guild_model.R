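# Bayesian multinomial phylogenetic regression for trophic guilds.
#
# Guild membership of species s follows a categorical logit with the first
# guild as reference:
#   mu_1 = 0,   mu_k = beta0_k + beta1_k * ln(sizemax_s) + gamma_{s,k}
# where per category k the species effects gamma_{.,k} are zero-mean
# Gaussian with covariance sigma_k^2 * C, C the Brownian phylogenetic
# correlation matrix.  Posterior draws come from a Hamiltonian Monte Carlo
# sampler with a non-centered parameterization (gamma = sigma * L z,
# L = chol(C)) and dual-averaging step-size adaptation during warmup.

#' Brownian phylogenetic correlation matrix
#'
#' C_ij = shared root-to-tip path length of species i and j divided by the
#' tree depth; the diagonal is 1.  For clearly non-ultrametric trees the
#' variance-covariance matrix is rescaled to a correlation matrix with a
#' warning.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @return species x species correlation matrix.
#' @export
phylo_covariance <- function(tree) {
  V <- ape::vcv(tree)
  d <- diag(V)
  if (max(d) - min(d) > 1e-6 * max(d)) {
    warning("tree is not ultrametric; rescaling to a correlation matrix")
    C <- stats::cov2cor(V)
  } else {
    C <- V / max(d)
    diag(C) <- 1
  }
  C
}

#' Guild probabilities from a linear predictor (reference-category softmax)
#'
#' @param mu numeric K-vector (or matrix with K columns) of linear
#'   predictors whose first component is the reference (conventionally 0;
#'   softmax is translation invariant either way).
#' @return probabilities summing to 1 (rowwise for matrices); log-sum-exp
#'   stabilized.
#' @export
guild_probability <- function(mu) {
  if (is.matrix(mu)) {
    e <- exp(mu - apply(mu, 1, max))
    return(e / rowSums(e))
  }
  e <- exp(mu - max(mu))
  e / sum(e)
}

#' Negentropy (assignment certainty) of a probability vector
#'
#' 1 minus the Shannon entropy normalized by its maximum log(K), so a
#' uniform vector scores 0 and a point mass scores 1.
#'
#' @param p probability vector summing to 1 (0 log 0 taken as 0).
#' @return value in \[0, 1\].
#' @export
negentropy <- function(p) {
  stopifnot(abs(sum(p) - 1) < 1e-6)
  k <- length(p)
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz]))
  1 - h / log(k)
}

#' Total standard deviation across guild categories
#'
#' Square root of the quadratic sum of per-category standard deviations.
#'
#' @param sds nonnegative K-vector of per-guild standard deviations.
#' @return scalar total SD.
#' @export
total_sd <- function(sds) {
  stopifnot(all(sds >= 0))
  sqrt(sum(sds^2))
}

# --- HMC internals ---------------------------------------------------------

# parameter packing: theta = c(beta0[2..K], beta1[2..K], tau[2..K], z)
# with z an n x (K-1) matrix column-stacked; tau = log sigma.
gm_logpost_grad <- function(theta, env) {
  n <- env$n; Km1 <- env$Km1
  b0 <- theta[seq_len(Km1)]
  b1 <- theta[Km1 + seq_len(Km1)]
  tau <- theta[2 * Km1 + seq_len(Km1)]
  sig <- exp(tau)
  Z <- matrix(theta[3 * Km1 + seq_len(n * Km1)], n, Km1)
  LZ <- env$L %*% Z
  eta <- matrix(0, n, Km1 + 1)
  for (k in seq_len(Km1)) {
    eta[, k + 1] <- b0[k] + b1[k] * env$x + sig[k] * LZ[, k]
  }
  mx <- apply(eta, 1, max)
  ex <- exp(eta - mx)
  sx <- rowSums(ex)
  P <- ex / sx
  ll <- sum(eta[cbind(seq_len(n), env$y)]) - sum(mx + log(sx))
  lp <- ll - 0.5 * sum(b0^2) / env$b_scale^2 -
    0.5 * sum(b1^2) / env$b_scale^2 -
    0.5 * sum(sig^2) / env$s_scale^2 + sum(tau) -
    0.5 * sum(Z^2)
  R <- -P
  R[cbind(seq_len(n), env$y)] <- R[cbind(seq_len(n), env$y)] + 1
  Rk <- R[, -1, drop = FALSE]
  g_b0 <- colSums(Rk) - b0 / env$b_scale^2
  g_b1 <- as.numeric(crossprod(env$x, Rk)) - b1 / env$b_scale^2
  LtR <- crossprod(env$L, Rk)
  g_Z <- sweep(LtR, 2, sig, "*") - Z
  g_tau <- sig * colSums(Rk * LZ) - sig^2 / env$s_scale^2 + 1
  list(lp = lp, grad = c(g_b0, g_b1, g_tau, as.numeric(g_Z)))
}

gm_hmc_chain <- function(env, iterations, warmup, seed, eps0 = 0.1,
                         max_leapfrog = 20, target_accept = 0.8) {
  set.seed(seed)
  d <- 3 * env$Km1 + env$n * env$Km1
  theta <- c(rnorm(3 * env$Km1, 0, 0.1), rnorm(env$n * env$Km1, 0, 0.1))
  cur <- gm_logpost_grad(theta, env)
  # dual averaging (Nesterov) for the step size
  mu_da <- log(10 * eps0); log_eps <- log(eps0); log_eps_bar <- 0
  H_bar <- 0; gam <- 0.05; t0 <- 10; kap <- 0.75
  n_keep <- iterations - warmup
  draws <- matrix(NA_real_, n_keep, d)
  accepts <- 0
  for (it in seq_len(iterations)) {
    eps <- exp(if (it <= warmup) log_eps else log_eps_bar)
    nl <- sample.int(max_leapfrog, 1)
    p0 <- rnorm(d)
    th <- theta; p <- p0; gr <- cur$grad
    p <- p + 0.5 * eps * gr
    for (s in seq_len(nl)) {
      th <- th + eps * p
      new <- gm_logpost_grad(th, env)
      if (!is.finite(new$lp)) break
      p <- p + (if (s < nl) eps else 0.5 * eps) * new$grad
    }
    a <- if (is.finite(new$lp)) {
      min(1, exp(new$lp - 0.5 * sum(p^2) - (cur$lp - 0.5 * sum(p0^2))))
    } else 0
    if (runif(1) < a) {
      theta <- th; cur <- new; accepts <- accepts + (it > warmup)
    }
    if (it <= warmup) {
      m <- it
      H_bar <- (1 - 1 / (m + t0)) * H_bar +
        (target_accept - a) / (m + t0)
      log_eps <- mu_da - sqrt(m) / gam * H_bar
      w <- m^(-kap)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
    } else {
      draws[it - warmup, ] <- theta
    }
  }
  list(draws = draws, accept_rate = accepts / n_keep,
       step_size = exp(log_eps_bar))
}

split_rhat <- function(mat_list) {
  # mat_list: one draws-matrix per chain (iterations x params)
  halves <- list()
  for (m in mat_list) {
    h <- floor(nrow(m) / 2)
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[h + seq_len(h), , drop = FALSE]))
  }
  n <- nrow(halves[[1]]); mch <- length(halves)
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(h) apply(h, 2, var))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1)
  }
  B <- n * apply(means, 1, var)
  Wv <- rowMeans(vars)
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

#' Fit the multinomial phylogenetic guild model
#'
#' @param trait named guild vector (factor/integer); the first level is
#'   the reference category with mu = 0.
#' @param attrs `species_attributes` (columns `species`, `max_size_cm`).
#' @param tree rooted, (near-)ultrametric `phylo` containing all species.
#' @param chains,iterations,warmup MCMC schedule (defaults 3 chains x
#'   6000 iterations with 1000 warmup, iterations counted inclusive of
#'   warmup).
#' @param seed RNG seed (chain c uses `seed + c - 1`).
#' @param thin keep every `thin`-th post-warmup draw.
#' @param prior_scale_beta Normal prior SD on intercepts and slopes
#'   (default 5, weakly informative).
#' @param prior_scale_sigma half-Normal prior SD on the phylogenetic
#'   effect scales (default 2.5).
#' @param max_leapfrog leapfrog steps are drawn uniformly from
#'   1..max_leapfrog.
#' @return object of class `guild_model`: posterior draws of `beta0`,
#'   `beta1` (draws x K-1), `sigma` (draws x K-1), `gamma`
#'   (draws x n x K-1), plus data, tree covariance and convergence
#'   diagnostics (`rhat`, with a warning when any split-Rhat > 1.05).
#' @export
fit_guild_model <- function(trait, attrs, tree, chains = 3,
                            iterations = 6000, warmup = 1000, seed = 1,
                            thin = 1, prior_scale_beta = 5,
                            prior_scale_sigma = 2.5, max_leapfrog = 20) {
  stopifnot(iterations > warmup, chains >= 1)
  common <- intersect(intersect(names(trait), attrs$species),
                      tree$tip.label)
  if (length(common) < 3) stop("species sets of trait, attributes and ",
                               "tree barely overlap", call. = FALSE)
  tree <- prune_to(tree, common)
  sp <- tree$tip.label
  yf <- factor(trait[sp])
  K <- nlevels(yf)
  if (K < 2) stop("need at least 2 guild categories", call. = FALSE)
  sizes <- setNames(attrs$max_size_cm, attrs$species)[sp]
  x_raw <- log(sizes)
  x_center <- mean(x_raw)
  C <- phylo_covariance(tree)[sp, sp]
  L <- t(chol(C + diag(1e-8, length(sp))))
  env <- list(n = length(sp), Km1 = K - 1, y = as.integer(yf),
              x = x_raw - x_center, L = L,
              b_scale = prior_scale_beta, s_scale = prior_scale_sigma)
  chains_out <- lapply(seq_len(chains), function(cc) {
    gm_hmc_chain(env, iterations, warmup, seed = seed + cc - 1,
                 max_leapfrog = max_leapfrog)
  })
  keep <- seq(1, iterations - warmup, by = thin)
  mats <- lapply(chains_out, function(ch) ch$draws[keep, , drop = FALSE])
  rhat <- tryCatch(split_rhat(mats), error = function(e) NULL)
  if (!is.null(rhat) && any(rhat > 1.05, na.rm = TRUE)) {
    warning(sum(rhat > 1.05, na.rm = TRUE),
            " parameter(s) with split-Rhat > 1.05 (max ",
            format(max(rhat, na.rm = TRUE), digits = 4),
            "); consider longer chains")
  }
  all_draws <- do.call(rbind, mats)
  Km1 <- K - 1; n <- length(sp); S <- nrow(all_draws)
  beta0 <- all_draws[, seq_len(Km1), drop = FALSE]
  beta1 <- all_draws[, Km1 + seq_len(Km1), drop = FALSE]
  sigma <- exp(all_draws[, 2 * Km1 + seq_len(Km1), drop = FALSE])
  gamma <- array(NA_real_, c(S, n, Km1))
  for (k in seq_len(Km1)) {
    Zk <- all_draws[, 3 * Km1 + (k - 1) * n + seq_len(n), drop = FALSE]
    gamma[, , k] <- (Zk %*% t(L)) * sigma[, k]
  }
  structure(list(K = K, levels = levels(yf), species = sp,
                 y = as.integer(yf), x = env$x, x_center = x_center,
                 beta0 = beta0, beta1 = beta1, sigma = sigma,
                 gamma = gamma, C = C, tree = tree, rhat = rhat,
                 accept_rates = vapply(chains_out, `[[`, numeric(1),
                                       "accept_rate"),
                 seed = seed, chains = chains),
            class = "guild_model")
}

#' @export
print.guild_model <- function(x, ...) {
  cat("guild_model:", length(x$species), "species,", x$K, "guilds,",
      nrow(x$beta0), "posterior draws\n")
  if (!is.null(x$rhat)) {
    cat("max split-Rhat:", format(max(x$rhat, na.rm = TRUE), digits = 4),
        "| mean acceptance:",
        format(mean(x$accept_rates), digits = 3), "\n")
  }
  invisible(x)
}

# linear predictors for one posterior draw; returns n x K matrix
gm_eta_draw <- function(model, s, x = model$x, gamma = model$gamma[s, , ,
                                                                   drop = FALSE]) {
  n <- length(x); Km1 <- model$K - 1
  g <- array(gamma, c(n, Km1))
  eta <- matrix(0, n, model$K)
  for (k in seq_len(Km1)) {
    eta[, k + 1] <- model$beta0[s, k] + model$beta1[s, k] * x + g[, k]
  }
  eta
}

summarize_guild_draws <- function(P, levels) {
  # P: draws x species x K array of probabilities
  pm <- apply(P, c(2, 3), mean)
  ps <- apply(P, c(2, 3), sd)
  colnames(pm) <- colnames(ps) <- levels
  ne <- apply(P, c(1, 2), function(p) negentropy(p / sum(p)))
  data.frame(
    guild = levels[max.col(pm)],
    negentropy_mean = colMeans(ne),
    negentropy_sd = apply(ne, 2, sd),
    total_sd = apply(ps, 1, total_sd),
    p_mean = I(pm), p_sd = I(ps))
}

#' Posterior fitted guild probabilities for the training species
#'
#' Per posterior draw, species probabilities follow the softmax of the
#' fitted linear predictors; draws are then summarized per species by the
#' per-guild posterior mean and SD, the argmax guild, the negentropy
#' (mean and SD over draws) and the total SD.
#'
#' @param model a fitted `guild_model`.
#' @param max_draws cap on the number of draws used (evenly subsampled);
#'   `Inf` uses all.
#' @return `guild_prediction` data.frame keyed by species, with matrix
#'   columns `p_mean` and `p_sd`.
#' @export
fitted_probabilities <- function(model, max_draws = 4000) {
  S <- nrow(model$beta0)
  use <- if (S > max_draws) round(seq(1, S, length.out = max_draws)) else
    seq_len(S)
  n <- length(model$species)
  P <- array(NA_real_, c(length(use), n, model$K))
  for (i in seq_along(use)) {
    P[i, , ] <- guild_probability(gm_eta_draw(model, use[i]))
  }
  out <- summarize_guild_draws(P, model$levels)
  rownames(out) <- model$species
  out$species <- model$species
  class(out) <- c("guild_prediction", "data.frame")
  out
}
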