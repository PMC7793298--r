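# Trophic guilds as modules of the weighted bipartite consumer-prey
# network.
#
# The network is the diet matrix itself: consumers in rows, prey groups in
# columns, weights = proportional diet contributions (rows sum to 1, so
# rare/accidental prey carry little weight by construction).  Guilds are
# found by maximizing Barber's weighted bipartite modularity
#   Q = (1/m) * sum_ij (W_ij - r_i c_j / m) * [module(i) == module(j)]
# with a label-propagation optimizer plus greedy module merging, repeated
# over many seeded restarts; the consensus partition is the medoid under
# the variation-of-information metric.

as_weight_matrix <- function(net) {
  W <- unclass(net)
  stopifnot(is.matrix(W), all(W >= 0))
  if (any(rowSums(W) == 0)) stop("all-zero consumer rows in network",
                                 call. = FALSE)
  W <- W[, colSums(W) > 0, drop = FALSE]
  W
}

#' Barber modularity of a joint bipartite partition
#'
#' @param net consumer x prey weight matrix (a `diet_matrix` works).
#' @param partition a `module_partition`, or a list with named integer
#'   vectors `consumers` and `prey`.
#' @return the modularity Q in \[-1, 1\].
#' @export
bipartite_modularity <- function(net, partition) {
  W <- as_weight_matrix(net)
  g <- partition$consumers[rownames(W)]
  h <- partition$prey[colnames(W)]
  if (anyNA(g) || anyNA(h)) {
    stop("partition does not cover all network nodes", call. = FALSE)
  }
  m <- sum(W)
  B <- W - outer(rowSums(W), colSums(W)) / m
  sum(B[outer(g, h, "==")]) / m
}

relabel_partition <- function(g, h, Q = NA_real_, seed = NA_integer_) {
  lab <- unique(c(unname(g), unname(h)))
  gg <- setNames(match(unname(g), lab), names(g))
  hh <- setNames(match(unname(h), lab), names(h))
  structure(list(consumers = gg, prey = hh, Q = Q, seed = seed,
                 n_modules = length(lab)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:", x$n_modules, "modules,",
      length(x$consumers), "consumers,", length(x$prey), "prey; Q =",
      format(x$Q, digits = 4), "\n")
  invisible(x)
}

#' Maximize weighted bipartite modularity
#'
#' Weighted label propagation: consumers start from a random label
#' assignment (the stochastic initial step), then consumers and prey
#' alternately adopt the module with the largest local modularity gain
#' (ties broken toward the smallest module id; a node whose best gain is
#' negative opens its own module), followed by a greedy module-merge
#' refinement; the two stages alternate until Q stops improving.
#' Deterministic given `seed`.
#'
#' @param net consumer x prey weight matrix.
#' @param seed RNG seed for the random initialization.
#' @param max_sweeps cap on label-propagation sweeps per stage.
#' @return a `module_partition` with its modularity `Q`.
#' @export
maximize_modularity <- function(net, seed = 1, max_sweeps = 100) {
  W <- as_weight_matrix(net)
  n <- nrow(W); p <- ncol(W)
  m <- sum(W)
  B <- W - outer(rowSums(W), colSums(W)) / m
  set.seed(seed)
  g <- sample.int(n, n, replace = TRUE)     # consumer labels
  h <- rep(NA_integer_, p)                  # prey labels
  next_label <- n + 1L

  sweep_once <- function(g, h, next_label) {
    # prey adopt the consumer-side module with the largest gain
    M <- rowsum(B, group = g)               # modules x p, labels sorted
    labs <- as.integer(rownames(M))
    tM <- t(M)
    bm <- max.col(tM, ties.method = "first")  # lowest label on ties
    val <- tM[cbind(seq_len(p), bm)]
    h <- labs[bm]
    solo <- val < 0                          # better off alone
    if (any(solo)) {
      h[solo] <- next_label + seq_len(sum(solo)) - 1L
      next_label <- next_label + sum(solo)
    }
    # consumers adopt the prey-side module with the largest gain
    Mc <- rowsum(t(B), group = h)
    labs <- as.integer(rownames(Mc))
    tM <- t(Mc)
    bm <- max.col(tM, ties.method = "first")
    val <- tM[cbind(seq_len(n), bm)]
    g <- labs[bm]
    solo <- val < 0
    if (any(solo)) {
      g[solo] <- next_label + seq_len(sum(solo)) - 1L
      next_label <- next_label + sum(solo)
    }
    list(g = g, h = h, next_label = next_label)
  }

  q_of <- function(g, h) sum(B[outer(g, h, "==")]) / m

  canon <- function(g, h) {
    joint <- c(g, h)
    paste(match(joint, unique(joint)), collapse = ",")
  }
  repeat {
    # label propagation until the partition structure is stable
    key <- canon(g, h)
    for (it in seq_len(max_sweeps)) {
      st <- sweep_once(g, h, next_label)
      g <- st$g; h <- st$h; next_label <- st$next_label
      key_new <- canon(g, h)
      if (identical(key, key_new)) break
      key <- key_new
    }
    q0 <- q_of(g, h)
    # greedy merge of module pairs while it improves Q
    repeat {
      labs <- sort(unique(c(g, h)))
      if (length(labs) < 2) break
      gf <- factor(g, levels = labs); hf <- factor(h, levels = labs)
      Rg <- t(sapply(labs, function(l) colSums(B[g == l, , drop = FALSE])))
      # S[a,b] = sum of B over (rows in a, cols in b)
      S <- sapply(labs, function(l) {
        rowSums(Rg[, h == l, drop = FALSE])
      })
      if (is.null(dim(S))) S <- matrix(S, nrow = length(labs))
      D <- (S + t(S)) / m
      diag(D) <- -Inf
      best <- max(D)
      if (best <= 1e-12) break
      idx <- which(D == best, arr.ind = TRUE)[1, ]
      a <- labs[min(idx)]; b <- labs[max(idx)]
      g[g == b] <- a; h[h == b] <- a
    }
    q1 <- q_of(g, h)
    if (q1 <= q0 + 1e-12) { q_final <- q1; break }
  }
  names(g) <- rownames(W); names(h) <- colnames(W)
  relabel_partition(g, h, Q = q_final, seed = seed)
}

#' Run the modularity maximization over many seeded restarts
#'
#' @param net consumer x prey weight matrix.
#' @param n_runs number of restarts (default 500).
#' @param base_seed seed of the first run; run r uses `base_seed + r - 1`.
#' @return list of `module_partition` objects.
#' @export
modularity_ensemble <- function(net, n_runs = 500, base_seed = 1) {
  stopifnot(n_runs >= 1)
  lapply(seq_len(n_runs), function(r) {
    maximize_modularity(net, seed = base_seed + r - 1L)
  })
}

vi_from_vectors <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  tab <- table(x, y) / n
  px <- rowSums(tab); py <- colSums(tab)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
  max(0, hx + hy - 2 * mi)
}

#' Variation of information between two partitions
#'
#' VI = H(X) + H(Y) - 2 I(X;Y) in nats; a metric on partitions that is 0
#' iff the two coincide up to relabeling.  Accepts `module_partition`
#' objects (compared on their joint consumer+prey node set, matched by
#' name) or plain membership vectors of equal length.
#'
#' @param p1,p2 partitions.
#' @return nonnegative VI value.
#' @export
variation_of_information <- function(p1, p2) {
  if (inherits(p1, "module_partition") && inherits(p2, "module_partition")) {
    n1 <- c(names(p1$consumers), names(p1$prey))
    n2 <- c(names(p2$consumers), names(p2$prey))
    if (!setequal(n1, n2)) stop("partitions cover different node sets",
                                call. = FALSE)
    x <- c(p1$consumers, p1$prey)[n1]
    y <- c(p2$consumers, p2$prey)[n1]
    return(vi_from_vectors(unname(x), unname(y)))
  }
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) {
      stop("partitions cover different node sets", call. = FALSE)
    }
    p2 <- p2[names(p1)]
  }
  vi_from_vectors(unname(p1), unname(p2))
}

#' Select the medoid partition of an ensemble
#'
#' The medoid minimizes the summed variation of information to every other
#' ensemble member; ties break toward the lowest run index.
#'
#' @param partitions nonempty list of partitions.
#' @return the medoid element of `partitions`.
#' @export
select_medoid <- function(partitions) {
  stopifnot(length(partitions) >= 1)
  n <- length(partitions)
  if (n == 1) return(partitions[[1]])
  # group relabel-identical partitions so VI is computed once per pair of
  # distinct clusterings (restart ensembles are usually highly redundant)
  key_of <- function(p) {
    x <- if (inherits(p, "module_partition")) c(p$consumers, p$prey) else p
    paste(match(x, unique(x)), collapse = ",")
  }
  keys <- vapply(partitions, key_of, character(1))
  uk <- unique(keys)
  cls <- match(keys, uk)
  cnt <- tabulate(cls, nbins = length(uk))
  rep_idx <- match(seq_along(uk), cls)      # first member of each class
  m <- length(uk)
  D <- matrix(0, m, m)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        D[i, j] <- D[j, i] <- variation_of_information(
          partitions[[rep_idx[i]]], partitions[[rep_idx[j]]])
      }
    }
  }
  tot <- as.numeric(D %*% cnt)              # summed VI to all members
  best_cls <- which(tot == min(tot))
  # ties broken by lowest run index over members of the tied classes
  partitions[[min(which(cls %in% best_cls))]]
}

#' Cross-location module consistency
#'
#' For a partition of a species-by-location network, the fraction of
#' species sampled in more than one location whose location nodes all fall
#' in the same module.
#'
#' @param partition a `module_partition` whose consumer nodes are
#'   species-location pairs.
#' @param species character vector, parallel to `partition$consumers`,
#'   giving the species of each consumer node (defaults to the part of the
#'   node name before `"@@"`).
#' @return fraction in \[0,1\], or `NA` (with a warning) when no species
#'   occurs in more than one location.
#' @export
cross_location_consistency <- function(partition, species = NULL) {
  g <- partition$consumers
  if (is.null(species)) species <- sub("@@.*$", "", names(g))
  mods_by_sp <- split(unname(g), species)
  multi <- mods_by_sp[lengths(mods_by_sp) > 1]
  if (!length(multi)) {
    warning("no species found in more than one location")
    return(NA_real_)
  }
  mean(vapply(multi, function(x) length(unique(x)) == 1L, logical(1)))
}

#' Composition of each trophic guild
#'
#' Per consumer module: the mean prey profile of its consumers (rows sum
#' to 1) and, when species attributes are given, the tally of consumer
#' families.
#'
#' @param partition a `module_partition`.
#' @param net the consumer x prey weight matrix it was fitted on.
#' @param attrs optional `species_attributes` with a `family` column.
#' @return list: `prey_profile` (module x prey matrix), `n_consumers`,
#'   `family_shares` (list of named proportion vectors, or NULL).
#' @export
guild_composition <- function(partition, net, attrs = NULL) {
  W <- as_weight_matrix(net)
  g <- partition$consumers[rownames(W)]
  mods <- sort(unique(unname(g)))
  prof <- t(vapply(mods, function(l) {
    colMeans(W[g == l, , drop = FALSE])
  }, numeric(ncol(W))))
  rownames(prof) <- paste0("module", mods)
  fam <- NULL
  if (!is.null(attrs)) {
    sp <- sub("@@.*$", "", rownames(W))
    fmap <- setNames(attrs$family, attrs$species)
    fam <- lapply(mods, function(l) {
      tab <- table(fmap[sp[g == l]])
      tab / sum(tab)
    })
    names(fam) <- rownames(prof)
  }
  list(prey_profile = prof,
       n_consumers = setNames(as.integer(table(factor(g, mods))),
                              rownames(prof)),
       family_shares = fam)
}
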