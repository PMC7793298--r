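# Phylogenetic conservatism of a discrete guild trait.
#
# The delta statistic measures how certain ancestral guild states are:
# marginal ancestral-state probabilities are computed under an equal-rates
# Mk model (rate fitted by maximum likelihood), each internal node's
# probability vector is collapsed to a linearized uncertainty in (0,1),
# the uncertainties are modelled as Beta(a, b), and delta = b/a.  Strongly
# conserved traits give confident (low-uncertainty) ancestral states and
# hence large delta; the trait-shuffling null gives near-maximal
# uncertainty and delta close to zero.  Significance comes from comparing
# the observed delta to deltas of tip-shuffled traits.

prep_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait must be named by species",
                                  call. = FALSE)
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss)) stop("trait missing for tips: ",
                         paste(head(miss, 5), collapse = ", "),
                         call. = FALSE)
  x <- factor(trait[tree$tip.label])
  if (nlevels(x) < 2) stop("trait is constant: delta undefined",
                           call. = FALSE)
  as.integer(x)
}

clamp_edges <- function(tree, min_bl = 1e-8) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  if (any(tree$edge.length <= 0)) {
    warning("non-positive branch lengths clamped to ", min_bl)
    tree$edge.length <- pmax(tree$edge.length, min_bl)
  }
  tree
}

# Pruning-algorithm machinery for the equal-rates Mk model.  The ER chain
# has the closed-form channel  msg(s) = e * L(s) + (1 - e) * sum(L) / k
# with e = exp(-k q t), which keeps the whole likelihood in vector ops.
mk_er_loglik <- function(tree_po, states, k, q) {
  edge <- tree_po$edge
  n_tip <- length(tree_po$tip.label)
  n_node <- tree_po$Nnode
  L <- matrix(1, n_tip + n_node, k)
  L[seq_len(n_tip), ] <- 0
  L[cbind(seq_len(n_tip), states)] <- 1
  ee <- exp(-k * q * tree_po$edge.length)
  logfac <- 0
  for (r in seq_len(nrow(edge))) {
    ch <- edge[r, 2]; pa <- edge[r, 1]
    msg <- ee[r] * L[ch, ] + (1 - ee[r]) * sum(L[ch, ]) / k
    f <- sum(msg)
    L[pa, ] <- L[pa, ] * (msg / f)
    logfac <- logfac + log(f)
  }
  root <- n_tip + 1L
  log(sum(L[root, ]) / k) + logfac
}

#' Marginal ancestral state probabilities under an equal-rates Mk model
#'
#' The per-pair transition rate is estimated by maximum likelihood unless
#' supplied, then marginal (up-down) reconstruction yields one probability
#' vector per internal node.  Non-positive branch lengths are clamped to
#' 1e-8 with a warning.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param trait named vector (factor/character/integer) of tip states.
#' @param rate optional fixed transition rate; `NULL` estimates it.
#' @return list: `prob` (internal-node x state matrix, rows sum to 1,
#'   states in factor-level order), `rate`, `loglik`, `levels`.
#' @export
ancestral_state_probabilities <- function(tree, trait, rate = NULL) {
  tree <- clamp_edges(tree)
  states <- prep_trait(tree, trait)
  k <- max(states)
  lv <- levels(factor(trait[tree$tip.label]))
  po <- stats::reorder(tree, "postorder")
  # tip order is preserved by reorder, so states still index tips 1..n
  if (is.null(rate)) {
    opt <- optimize(function(lq) -mk_er_loglik(po, states, k, exp(lq)),
                    c(log(1e-4), log(1e3)), tol = 1e-4)
    rate <- exp(opt$minimum)
    ll <- -opt$objective
  } else {
    ll <- mk_er_loglik(po, states, k, rate)
  }
  edge <- po$edge
  n_tip <- length(po$tip.label)
  n_all <- n_tip + po$Nnode
  D <- matrix(1, n_all, k)
  D[seq_len(n_tip), ] <- 0
  D[cbind(seq_len(n_tip), states)] <- 1
  ee <- exp(-k * rate * po$edge.length)
  MSG <- matrix(NA_real_, nrow(edge), k)
  for (r in seq_len(nrow(edge))) {
    ch <- edge[r, 2]; pa <- edge[r, 1]
    msg <- ee[r] * D[ch, ] + (1 - ee[r]) * sum(D[ch, ]) / k
    msg <- msg / sum(msg)
    MSG[r, ] <- msg
    D[pa, ] <- D[pa, ] * msg
    # guard against underflow on large trees
    D[pa, ] <- D[pa, ] / sum(D[pa, ])
  }
  U <- matrix(NA_real_, n_all, k)
  root <- n_tip + 1L
  U[root, ] <- 1 / k
  for (r in rev(seq_len(nrow(edge)))) {
    ch <- edge[r, 2]; pa <- edge[r, 1]
    A <- U[pa, ] * D[pa, ] / MSG[r, ]
    u <- ee[r] * A + (1 - ee[r]) * sum(A) / k
    U[ch, ] <- u / sum(u)
  }
  P <- D * U
  P <- P / rowSums(P)
  P <- P[(n_tip + 1L):n_all, , drop = FALSE]
  colnames(P) <- lv
  # map rows back to the standard internal-node numbering of `tree`
  rownames(P) <- as.character((n_tip + 1L):n_all)
  list(prob = P, rate = rate, loglik = ll, levels = lv)
}

# Linearized per-node uncertainty of an ancestral probability vector:
# entries above 1/k are mapped (p - 1) / (1 - k), i.e. linearly from
# [1/k, 1] down to [1/k, 0]; summing over states gives 1 at a uniform
# vector and 0 at a point mass.
node_uncertainty <- function(prob, eps = 1e-8) {
  k <- ncol(prob)
  hi <- prob > 1 / k
  prob[hi] <- (prob[hi] - 1) / (1 - k)
  u <- rowSums(prob)
  pmin(pmax(u, eps), 1 - eps)
}

beta_loglik <- function(a, b, x) {
  length(x) * (lgamma(a + b) - lgamma(a) - lgamma(b)) +
    (a - 1) * sum(log(x)) + (b - 1) * sum(log(1 - x))
}

delta_from_uncertainty <- function(x, method = "mle", lambda0 = 0.1,
                                   se = 0.5, sim = 10000, thin = 10,
                                   burn = 100) {
  if (method == "mle") {
    # posterior mode under Exp(lambda0) priors; deterministic
    obj <- function(p) -(beta_loglik(exp(p[1]), exp(p[2]), x) -
                           lambda0 * (exp(p[1]) + exp(p[2])))
    fit <- optim(c(0, 0), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
    return(exp(fit$par[2]) / exp(fit$par[1]))
  }
  # Metropolis-Hastings on log(a), log(b), two chains
  lp <- function(a, b) beta_loglik(a, b, x) - lambda0 * (a + b)
  run_chain <- function() {
    a <- rexp(1) + 0.5; b <- rexp(1) + 0.5
    keep <- matrix(NA_real_, floor((sim - burn) / thin), 2)
    kk <- 0
    for (i in seq_len(sim)) {
      a1 <- exp(rnorm(1, log(a), se))
      if (log(runif(1)) < lp(a1, b) - lp(a, b)) a <- a1
      b1 <- exp(rnorm(1, log(b), se))
      if (log(runif(1)) < lp(a, b1) - lp(a, b)) b <- b1
      if (i > burn && (i - burn) %% thin == 0) {
        kk <- kk + 1; keep[kk, ] <- c(a, b)
      }
    }
    keep[seq_len(kk), , drop = FALSE]
  }
  ch <- rbind(run_chain(), run_chain())
  mean(ch[, 2] / ch[, 1])
}

#' Delta statistic of phylogenetic signal for a discrete trait
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param trait named tip states (>= 2 categories).
#' @param method `"mle"` (default; deterministic posterior-mode fit of the
#'   Beta uncertainty model) or `"mcmc"` (Metropolis posterior mean; set a
#'   seed for reproducibility).
#' @param lambda0 exponential prior rate on the Beta parameters.
#' @param rate optional fixed Mk rate (estimated by ML when NULL).
#' @param ... further arguments to the mcmc mode (`se`, `sim`, `thin`,
#'   `burn`).
#' @return delta >= 0; larger values mean stronger conservatism.
#' @export
compute_delta <- function(tree, trait, method = c("mle", "mcmc"),
                          lambda0 = 0.1, rate = NULL, ...) {
  method <- match.arg(method)
  asr <- ancestral_state_probabilities(tree, trait, rate = rate)
  x <- node_uncertainty(asr$prob)
  delta_from_uncertainty(x, method = method, lambda0 = lambda0, ...)
}

#' Trait-shuffling significance test for delta
#'
#' Recomputes delta after randomly permuting the trait values across tips
#' `n_shuffles` times.  The p-value uses the rank convention
#' p = (1 + #\{null >= observed\}) / (1 + n_shuffles).
#'
#' @param tree rooted `phylo`.
#' @param trait named tip states.
#' @param n_shuffles number of permutations (default 100).
#' @param seed RNG seed for the permutations.
#' @param method delta inference mode (see [compute_delta()]).
#' @return object of class `signal_result`: list with `delta_obs`,
#'   `null_values`, `null_median`, `null_ci` (2.5/97.5 percentiles),
#'   `p_value`, `n_shuffles`.
#' @export
delta_null_test <- function(tree, trait, n_shuffles = 100, seed = 1,
                            method = "mle") {
  stopifnot(n_shuffles >= 1)
  obs <- compute_delta(tree, trait, method = method)
  set.seed(seed)
  vals <- names(trait)
  nulls <- vapply(seq_len(n_shuffles), function(i) {
    sh <- setNames(sample(unname(trait)), vals)
    compute_delta(tree, sh, method = method)
  }, numeric(1))
  structure(list(delta_obs = obs, null_values = nulls,
                 null_median = median(nulls),
                 null_ci = quantile(nulls, c(0.025, 0.975), names = FALSE),
                 p_value = (1 + sum(nulls >= obs)) / (1 + n_shuffles),
                 n_shuffles = n_shuffles),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat("delta =", format(x$delta_obs, digits = 4),
      "| null median =", format(x$null_median, digits = 4),
      "(95% CI", format(x$null_ci[1], digits = 4), "-",
      format(x$null_ci[2], digits = 4), ")",
      "| p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
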