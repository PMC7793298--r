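# Pairwise consumer x prey-group interaction prediction.
#
# Features are phylogenetic eigenvector map (PEM) coordinates of the
# consumer, its ln(max size), and a one-hot encoding of the prey group.
# Three base learners (a histogram extreme-gradient booster, a classical
# stochastic booster, and a random forest) are calibrated with k-fold
# cross-validation; a binomial GLM super-learner is fitted on their
# out-of-fold predictions only, so the stack never sees in-fold leakage.

#' Phylogenetic eigenvector maps
#'
#' Principal-coordinate decomposition of the double-centered patristic
#' distance matrix; axes are ordered by decreasing eigenvalue and only
#' positive-eigenvalue axes are retained.
#'
#' @param tree `phylo` with branch lengths.
#' @param n_axes fixed number of axes, or `NULL` to keep the smallest set
#'   explaining `var_fraction` of the positive-eigenvalue variance.
#' @param var_fraction variance fraction (default 0.95) when `n_axes` is
#'   `NULL`.
#' @return species x axes coordinate matrix (columns `PEM1`, `PEM2`, ...),
#'   with the eigenvalues in attribute `eig`.
#' @export
phylo_eigenvectors <- function(tree, n_axes = NULL, var_fraction = 0.95) {
  D <- ape::cophenetic.phylo(tree)
  pc <- cmdscale(D, k = nrow(D) - 1, eig = TRUE)
  pos <- pc$eig > max(pc$eig) * 1e-9
  X <- pc$points[, seq_len(sum(pos)), drop = FALSE]
  ev <- pc$eig[pos]
  if (is.null(n_axes)) {
    n_axes <- which(cumsum(ev) / sum(ev) >= var_fraction)[1]
  }
  n_axes <- min(n_axes, ncol(X))
  X <- X[, seq_len(n_axes), drop = FALSE]
  colnames(X) <- paste0("PEM", seq_len(n_axes))
  attr(X, "eig") <- ev[seq_len(n_axes)]
  X
}

#' Build the pairwise interaction table from a diet matrix
#'
#' Full cartesian coverage: one row per (consumer species, prey group),
#' labelled 1 when the species' pooled diet proportion for that group
#' exceeds `presence_threshold`, else 0.  Rows of a by-location diet
#' matrix are pooled per species with weights proportional to gut counts;
#' with `by_region = TRUE` the cartesian table is instead built per
#' (species, location) and tagged with a `region` column.
#'
#' @param diet a `diet_matrix`.
#' @param presence_threshold minimum pooled proportion counted as an
#'   interaction (default 0, i.e. any recorded consumption).
#' @param by_region emit one labelled table per location?
#' @return data.frame: `species`, `prey_group`, `label` (0/1) and,
#'   if `by_region`, `region`.
#' @export
build_interaction_table <- function(diet, presence_threshold = 0,
                                    by_region = FALSE) {
  W <- unclass(diet)
  sp <- attr(diet, "species") %||% rownames(W)
  ng <- attr(diet, "n_guts") %||% rep(1L, nrow(W))
  loc <- attr(diet, "location")
  groups <- colnames(W)
  if (by_region) {
    if (is.null(loc) || all(is.na(loc))) {
      stop("by_region requires a by-location diet matrix", call. = FALSE)
    }
    out <- data.frame(
      species = rep(sp, each = length(groups)),
      prey_group = rep(groups, times = length(sp)),
      label = as.integer(as.vector(t(W)) > presence_threshold),
      region = rep(loc, each = length(groups)),
      stringsAsFactors = FALSE)
    return(out)
  }
  usp <- unique(sp)
  pooled <- t(vapply(usp, function(s) {
    i <- which(sp == s)
    colSums(W[i, , drop = FALSE] * ng[i]) / sum(ng[i])
  }, numeric(length(groups))))
  data.frame(species = rep(usp, each = length(groups)),
             prey_group = rep(groups, times = length(usp)),
             label = as.integer(as.vector(t(pooled)) > presence_threshold),
             stringsAsFactors = FALSE)
}

# numeric feature matrix for (species, prey_group) rows
interaction_features <- function(species, prey_group, pem, attrs,
                                 groups = NULL) {
  groups <- groups %||% sort(unique(prey_group))
  miss <- setdiff(unique(species), rownames(pem))
  if (length(miss)) stop("species without PEM coordinates: ",
                         paste(head(miss, 5), collapse = ", "),
                         call. = FALSE)
  sizes <- setNames(attrs$max_size_cm, attrs$species)
  if (anyNA(sizes[unique(species)])) stop("species without size data",
                                          call. = FALSE)
  onehot <- matrix(0, length(species), length(groups),
                   dimnames = list(NULL,
                                   make.names(paste0("prey_", groups))))
  onehot[cbind(seq_along(prey_group), match(prey_group, groups))] <- 1
  cbind(pem[species, , drop = FALSE], ln_size = log(sizes[species]),
        onehot)
}

fit_base_learners <- function(X, y, n_trees, seed) {
  d <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgb1 <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", tree_method = "hist",
                  nthread = 1, seed = seed),
    data = d, nrounds = n_trees, verbose = 0)
  xgb2 <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.05,
                  max_depth = 3, subsample = 0.5, nthread = 1,
                  seed = seed + 1),
    data = d, nrounds = n_trees, verbose = 0)
  df <- data.frame(y = factor(y, levels = 0:1), X, check.names = FALSE)
  rf <- ranger::ranger(y ~ ., data = df, num.trees = n_trees,
                       probability = TRUE, seed = seed + 2,
                       num.threads = 1)
  list(xgb_hist = xgb1, xgb_stochastic = xgb2, random_forest = rf)
}

predict_base_learners <- function(learners, X) {
  dm <- xgboost::xgb.DMatrix(X, nthread = 1)
  cbind(
    xgb_hist = predict(learners$xgb_hist, dm),
    xgb_stochastic = predict(learners$xgb_stochastic, dm),
    random_forest = predict(learners$random_forest,
                            data.frame(X, check.names = FALSE),
                            num.threads = 1)$predictions[, "1"])
}

#' Fit the stacked interaction ensemble
#'
#' Base learners are cross-validated on a common fold plan to produce
#' out-of-fold predictions, the binomial GLM super-learner is fitted on
#' those three out-of-fold columns, and the base learners are then
#' refitted on the full data for prediction.
#'
#' @param data interaction table ([build_interaction_table()]).
#' @param pem PEM coordinates covering every species in `data` (and any
#'   species to be predicted later, if computed on the full tree).
#' @param attrs `species_attributes` with sizes.
#' @param folds number of cross-validation folds (default 10).
#' @param n_trees trees per base learner (default 2000).
#' @param seed RNG seed (fold plan and learners).
#' @return object of class `interaction_ensemble`.
#' @export
fit_ensemble <- function(data, pem, attrs, folds = 10, n_trees = 2000,
                         seed = 1) {
  stopifnot(all(data$label %in% 0:1))
  if (length(unique(data$label)) < 2) {
    stop("both interaction classes must be present", call. = FALSE)
  }
  groups <- sort(unique(data$prey_group))
  X <- interaction_features(data$species, data$prey_group, pem, attrs,
                            groups)
  y <- data$label
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = nrow(X)))
  oof <- matrix(NA_real_, nrow(X), 3,
                dimnames = list(NULL, c("xgb_hist", "xgb_stochastic",
                                        "random_forest")))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    bl <- fit_base_learners(X[tr, , drop = FALSE], y[tr], n_trees,
                            seed + 100 * f)
    oof[!tr, ] <- predict_base_learners(bl, X[!tr, , drop = FALSE])
  }
  sl_df <- data.frame(y = y, oof)
  super <- glm(y ~ xgb_hist + xgb_stochastic + random_forest,
               data = sl_df, family = binomial())
  full <- fit_base_learners(X, y, n_trees, seed)
  oof_stack <- as.numeric(predict(super, newdata = data.frame(oof),
                                  type = "response"))
  structure(list(learners = full, super = super, groups = groups,
                 pem_cols = colnames(pem), folds = folds,
                 n_trees = n_trees, seed = seed,
                 calibration = data.frame(label = y, stacked = oof_stack,
                                          oof),
                 feature_names = colnames(X)),
            class = "interaction_ensemble")
}

#' Predict stacked interaction probabilities
#'
#' @param object an `interaction_ensemble`.
#' @param data interaction table rows (`species`, `prey_group`).
#' @param pem,attrs feature sources covering the requested species.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.interaction_ensemble <- function(object, data, pem, attrs, ...) {
  X <- interaction_features(data$species, data$prey_group, pem, attrs,
                            object$groups)
  X <- X[, object$feature_names, drop = FALSE]
  base <- predict_base_learners(object$learners, X)
  as.numeric(predict(object$super, newdata = data.frame(base),
                     type = "response"))
}

#' Rank-statistic AUC
#'
#' Mann-Whitney AUC with midranks for ties; equals the probability that a
#' random positive outscores a random negative (ties counting 1/2).
#'
#' @param scores numeric predictions.
#' @param labels 0/1 labels (both classes required).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined with a single class")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# threshold maximizing sensitivity + specificity on calibration data
max_tss_threshold <- function(scores, labels) {
  th <- sort(unique(scores))
  if (length(th) > 512) th <- quantile(scores, seq(0, 1, length.out = 512),
                                       names = FALSE)
  tss <- vapply(th, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, numeric(1))
  th[which.max(tss)]
}

#' Evaluate interaction predictions
#'
#' AUC by rank statistic; sensitivity, specificity, false-positive rate
#' and TSS at a threshold chosen by `threshold_rule` on the model's
#' calibration (out-of-fold) predictions - never on the test data.
#'
#' @param model an `interaction_ensemble`.
#' @param test interaction table with labels.
#' @param pem,attrs feature sources for the test species.
#' @param threshold_rule `"max_tss"` (default) or a fixed numeric
#'   threshold.
#' @return object of class `eval_report`: list with `auc`, `tss`,
#'   `sensitivity`, `specificity`, `fpr`, `threshold`, `n`.
#' @export
evaluate_interactions <- function(model, test, pem, attrs,
                                  threshold_rule = "max_tss") {
  p <- predict(model, test, pem, attrs)
  y <- test$label
  auc <- auc_rank(p, y)
  thr <- if (is.numeric(threshold_rule)) threshold_rule else
    max_tss_threshold(model$calibration$stacked, model$calibration$label)
  pred <- p >= thr
  sens <- sum(pred & y == 1) / max(sum(y == 1), 1)
  spec <- sum(!pred & y == 0) / max(sum(y == 0), 1)
  structure(list(auc = auc, tss = sens + spec - 1, sensitivity = sens,
                 specificity = spec, fpr = 1 - spec, threshold = thr,
                 n = length(y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "AUC = %.3f | TSS = %.3f | sens = %.3f | spec = %.3f | FPR = %.3f\n",
    x$auc, x$tss, x$sensitivity, x$specificity, x$fpr))
  invisible(x)
}

#' Leave-one-region-out validation
#'
#' Fits the ensemble on every region except `held_out_region` and
#' evaluates it on the held-out region's pairs.
#'
#' @param data interaction table with a `region` column.
#' @param held_out_region region name to withhold.
#' @param pem,attrs feature sources.
#' @param ... passed to [fit_ensemble()].
#' @return list: `report` (an `eval_report`) and `model`.
#' @export
leave_region_out <- function(data, held_out_region, pem, attrs, ...) {
  if (is.null(data$region)) stop("data has no region column",
                                 call. = FALSE)
  regs <- unique(data$region)
  if (length(regs) < 2) stop("need at least 2 regions", call. = FALSE)
  if (!held_out_region %in% regs) {
    stop("unknown region: ", held_out_region, call. = FALSE)
  }
  train <- data[data$region != held_out_region, , drop = FALSE]
  test <- data[data$region == held_out_region, , drop = FALSE]
  model <- fit_ensemble(train, pem, attrs, ...)
  list(report = evaluate_interactions(model, test, pem, attrs),
       model = model)
}

#' Predict the global species x prey-group probability table
#'
#' @param model an `interaction_ensemble`.
#' @param attrs `species_attributes` for the target species.
#' @param pem PEM coordinates from the full tree (must cover the target
#'   species; species without coordinates are skipped with a warning).
#' @return data.frame: species x prey-group grid with a `probability`
#'   column.
#' @export
predict_global <- function(model, attrs, pem) {
  sp <- attrs$species
  off <- setdiff(sp, rownames(pem))
  if (length(off)) {
    warning(length(off), " species without tree positions skipped: ",
            paste(head(off, 5), collapse = ", "))
    sp <- setdiff(sp, off)
  }
  grid <- data.frame(species = rep(sp, each = length(model$groups)),
                     prey_group = rep(model$groups, times = length(sp)),
                     stringsAsFactors = FALSE)
  grid$probability <- predict(model, grid, pem, attrs)
  grid
}
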