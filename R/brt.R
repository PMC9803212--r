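# Boosted regression trees for a Bernoulli (presence/background) response.
#
# The model is the standard stagewise additive logistic formulation:
#   F(x) = intercept + lr * sum_m T_m(x)
# where each T_m is a small regression tree (at most `tc` splits, grown
# best-first) fitted to the current gradient residuals y - p on a fresh
# random bag of rows, with terminal values given by the Newton step for the
# Bernoulli deviance.  Predictions are plogis(F).

# Internal: predictor matrix in schema order with log transforms applied.
.model_matrix <- function(data, schema) {
  miss <- setdiff(schema$vars, names(data))
  if (length(miss))
    stop("missing predictor column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(data)[, schema$vars, drop = FALSE])
  storage.mode(X) <- "double"
  for (v in intersect(schema$log_vars, schema$vars)) {
    j <- match(v, schema$vars)
    X[, j] <- log(pmax(X[, j], 1e-6))
  }
  X
}

#' Fit a single regression tree to a working response
#'
#' Grows one regression tree best-first: the leaf offering the largest
#' squared-error reduction is split repeatedly until `tc` splits have been
#' made or no admissible split remains.  Terminal values are the Newton
#' step for the Bernoulli deviance, `sum(z) / sum(w)`, where `z` are
#' gradient residuals (`y - p`) and `w` the curvature weights
#' (`p * (1 - p)`).  A constant working response yields a single-leaf tree.
#'
#' This is the inner step of boosting, exposed for inspection and testing.
#'
#' @param X Numeric predictor matrix.
#' @param z Working response (gradient residuals), one per row of `X`.
#' @param w Curvature weights, one per row of `X`.
#' @param tc Tree complexity: maximum number of splits.
#' @param min_node Minimum rows in a terminal node.
#' @return A `regression_tree`: the flat node matrix with columns `var`
#'   (1-based split variable, 0 = leaf), `threshold`, `left`, `right`
#'   (1-based child rows), `value` (leaf value, link scale), `gain`.
#' @export
fit_tree <- function(X, z, w = rep(0.25, length(z)), tc = 5, min_node = 10) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (nrow(X) != length(z) || length(z) != length(w))
    stop("X, z and w must agree in length")
  tree <- .cpp_fit_tree(X, as.numeric(z), as.numeric(w),
                        as.integer(tc), as.integer(min_node))
  colnames(tree) <- c("var", "threshold", "left", "right", "value", "gain")
  class(tree) <- c("regression_tree", class(tree))
  tree
}

#' Fit a boosted regression tree model
#'
#' @param train A `training_set` (or any data frame) containing a 0/1
#'   `response` column and the predictor columns.
#' @param tc Tree complexity (splits per tree); 5 allows up to fifth-order
#'   interactions.
#' @param lr Learning rate (shrinkage) applied to every tree's
#'   contribution.
#' @param bag_fraction Fraction of rows drawn (without replacement) for
#'   each boosting stage.
#' @param n_trees Number of boosting stages to fit.
#' @param min_node Minimum rows per terminal node.
#' @param vars Predictor columns to use; defaults to the intersection of
#'   [predictor_names()] with the columns of `train`.
#' @param log_vars Predictors log-transformed before fitting (and,
#'   identically, before prediction); defaults to the strongly
#'   right-skewed flow, width and sinuosity covariates.
#' @param seed Integer seed governing the per-stage bagging.
#' @param valid Optional data frame (same schema, with `response`) on
#'   which staged deviance is monitored every `step` trees; fitting stops
#'   early after `patience` consecutive non-improving evaluations.
#' @param step,patience Monitoring grid and early-stopping patience (only
#'   used when `valid` is supplied).
#' @return A `brt_fit` list: `intercept`, `trees`, `lr`, `tc`,
#'   `bag_fraction`, `min_node`, `n_trees`, `schema`, `seed`, and (when
#'   `valid` was given) `valid_trees`/`valid_dev`.
#' @export
fit_brt <- function(train, tc = 5, lr = 0.01, bag_fraction = 0.75,
                    n_trees = 1000, min_node = 10,
                    vars = NULL, log_vars = c("MeanFlow", "WidthQ50",
                                              "segSinuosity"),
                    seed = 1, valid = NULL, step = 50, patience = 5) {
  if (!"response" %in% names(train)) stop("train must have a response column")
  y <- as.numeric(train$response)
  if (!all(y %in% c(0, 1))) stop("response must be 0/1")
  if (length(unique(y)) < 2)
    stop("response contains a single class; both classes are required")
  if (lr <= 0) stop("lr must be positive")
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop("bag_fraction must lie in (0, 1]")
  if (is.null(vars)) {
    vars <- intersect(predictor_names(), names(train))
    if (!length(vars))
      vars <- setdiff(names(train), c("reach_id", "response"))
  }
  schema <- list(vars = vars, log_vars = log_vars)
  X <- .model_matrix(train, schema)

  if (is.null(valid)) {
    Xv <- matrix(numeric(0), 0, length(vars))
    yv <- numeric(0)
  } else {
    Xv <- .model_matrix(valid, schema)
    yv <- as.numeric(valid$response)
  }

  set.seed(seed)
  fit <- .cpp_fit_brt(X, y, as.integer(n_trees), as.integer(tc), lr,
                      bag_fraction, as.integer(min_node),
                      Xv, yv, as.integer(step), as.integer(patience))
  structure(list(intercept = fit$intercept, trees = fit$trees,
                 lr = lr, tc = tc, bag_fraction = bag_fraction,
                 min_node = min_node, n_trees = fit$n_trees,
                 schema = schema, seed = seed,
                 valid_trees = fit$valid_trees, valid_dev = fit$valid_dev),
            class = "brt_fit")
}

#' Predict relative likelihood of occurrence from a fitted BRT
#'
#' @param object A `brt_fit`.
#' @param newdata Data frame with the model's predictor columns (raw
#'   scale; the fitted log transforms are applied internally).
#' @param n_trees Number of leading trees to use (defaults to all).
#' @param type `"response"` for probabilities in (0,1), `"link"` for the
#'   additive logit-scale fit.
#' @param ... Unused.
#' @return Numeric vector, one prediction per row of `newdata`.
#' @export
predict.brt_fit <- function(object, newdata, n_trees = object$n_trees,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- .model_matrix(newdata, object$schema)
  eta <- .cpp_predict_brt(object$trees, object$intercept, object$lr,
                          X, as.integer(n_trees))
  if (type == "response") plogis(eta) else eta
}

#' @export
print.brt_fit <- function(x, ...) {
  cat("Boosted regression tree fit\n")
  cat("  trees:", x$n_trees, " tc:", x$tc, " lr:", x$lr,
      " bag:", x$bag_fraction, "\n")
  cat("  predictors:", length(x$schema$vars),
      "(log:", paste(x$schema$log_vars, collapse = ", "), ")\n")
  invisible(x)
}

#' Mean Bernoulli deviance
#'
#' `mean(-2 * (y*log(p) + (1-y)*log(1-p)))` with `p` clamped to
#' `[eps, 1-eps]`.  With `p = 0.5` everywhere the deviance is `2*log(2)`.
#'
#' @param y 0/1 response vector.
#' @param p Predicted probabilities.
#' @param eps Clamping constant.
#' @return Mean deviance per observation (non-negative).
#' @export
bernoulli_deviance <- function(y, p, eps = 1e-12) {
  if (length(y) != length(p)) stop("y and p must have equal length")
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-2 * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Proportion of null deviance explained
#'
#' `1 - D(model) / D(null)` where the null model predicts the base rate.
#'
#' @inheritParams bernoulli_deviance
#' @return Fraction in (-Inf, 1]; 0 for the null model itself.
#' @export
deviance_explained <- function(y, p) {
  d0 <- bernoulli_deviance(y, rep(mean(y), length(y)))
  1 - bernoulli_deviance(y, p) / d0
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Tie-aware pairwise form: the proportion of (presence, background) pairs
#' in which the presence scores higher, counting ties as half.  Computed
#' via midranks in O(n log n).
#'
#' @param y 0/1 response vector (both classes must be present).
#' @param p Score vector.
#' @return AUC in `[0, 1]`; 0.5 means no better than random.
#' @export
auc <- function(y, p) {
  if (length(y) != length(p)) stop("y and p must have equal length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(p)   # midranks handle ties as half-concordant
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Ten-fold cross-validation for the optimal number of trees
#'
#' Partitions the rows into `folds` disjoint, response-stratified folds;
#' for each fold, boosts on the remaining folds while recording the
#' withheld-fold deviance every `step` trees (stopping a fold after
#' `patience` consecutive non-improving evaluations, or at `max_trees`).
#' The mean withheld deviance across folds is minimized over the common
#' tree-count grid.
#'
#' @inheritParams fit_brt
#' @param folds Number of cross-validation folds (>= 2).
#' @param max_trees Upper bound on boosting stages per fold.
#' @return A `cv_trace` list: `trees` (grid), `mean_dev`, `fold_dev`
#'   (grid x folds matrix), `optimal_trees`, and the settings used.
#' @export
cv_optimal_ntrees <- function(train, tc = 5, lr = 0.01, bag_fraction = 0.75,
                              folds = 10, step = 50, max_trees = 5000,
                              min_node = 10, patience = 5,
                              vars = NULL, log_vars = c("MeanFlow",
                                                        "WidthQ50",
                                                        "segSinuosity"),
                              seed = 1) {
  if (folds < 2) stop("folds must be >= 2")
  y <- as.numeric(train$response)
  if (min(sum(y == 1), sum(y == 0)) < folds)
    stop("cannot stratify: a class has fewer rows than folds")
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cls in c(0, 1)) {
    rows <- which(y == cls)
    fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }

  traces <- vector("list", folds)
  grids <- vector("list", folds)
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    fit <- fit_brt(train[!hold, , drop = FALSE], tc = tc, lr = lr,
                   bag_fraction = bag_fraction, n_trees = max_trees,
                   min_node = min_node, vars = vars, log_vars = log_vars,
                   seed = seed + k, valid = train[hold, , drop = FALSE],
                   step = step, patience = patience)
    traces[[k]] <- fit$valid_dev
    grids[[k]] <- fit$valid_trees
  }
  ngrid <- min(lengths(traces))
  if (ngrid == 0) stop("cross-validation produced no evaluations; ",
                       "increase max_trees or decrease step")
  dev <- vapply(traces, function(tr) tr[seq_len(ngrid)], numeric(ngrid))
  dev <- matrix(dev, nrow = ngrid)
  grid <- grids[[1]][seq_len(ngrid)]
  mean_dev <- rowMeans(dev)
  structure(list(trees = grid, mean_dev = mean_dev, fold_dev = dev,
                 optimal_trees = grid[which.min(mean_dev)],
                 folds = folds, step = step, tc = tc, lr = lr,
                 fold_id = fold_id),
            class = "cv_trace")
}

#' Relative influence of each predictor
#'
#' For every split in every tree, the squared-error reduction is credited
#' to the split variable; totals are normalized to sum to 100.
#'
#' @param model A `brt_fit`.
#' @return Named numeric vector (percent), sorted decreasing.  All zeros
#'   (with a warning) for a model with no splits.
#' @export
relative_influence <- function(model) {
  vars <- model$schema$vars
  infl <- setNames(numeric(length(vars)), vars)
  for (tree in model$trees) {
    splits <- tree[, 1] > 0
    if (any(splits)) {
      g <- tapply(tree[splits, 6], tree[splits, 1], sum)
      infl[as.integer(names(g))] <- infl[as.integer(names(g))] + g
    }
  }
  tot <- sum(infl)
  if (tot == 0) {
    warning("model contains no splits; all influences are zero")
    return(infl)
  }
  sort(100 * infl / tot, decreasing = TRUE)
}

#' Partial dependence of the fitted function on one or two predictors
#'
#' For each grid point, the target predictor(s) are overwritten across all
#' rows of `data` and the model predictions averaged (the standard
#' marginal-average partial dependence).  With `at_means = TRUE` the
#' remaining predictors are instead held at their means and a single
#' prediction taken per grid point.
#'
#' @param model A `brt_fit`.
#' @param vars One or two predictor names.
#' @param data Data frame of rows to average over (e.g. the training set).
#' @param grid_size Points per variable when `grid` is not supplied.
#' @param grid Optional list of grid value vectors (one per variable);
#'   defaults to equally spaced quantiles of `data`.
#' @param scale `"link"` (additive logit scale, the natural scale for
#'   fitted-function plots) or `"response"`.
#' @param at_means Use the at-means variant instead of marginal averaging.
#' @return Data frame with the grid columns and a `fit` column.
#' @export
partial_dependence <- function(model, vars, data, grid_size = 25,
                               grid = NULL, scale = c("link", "response"),
                               at_means = FALSE) {
  scale <- match.arg(scale)
  if (!length(vars) %in% 1:2) stop("vars must name one or two predictors")
  unknown <- setdiff(vars, model$schema$vars)
  if (length(unknown))
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "))
  if (is.null(grid)) {
    grid <- lapply(vars, function(v)
      unique(quantile(data[[v]], seq(0.02, 0.98, length.out = grid_size),
                      names = FALSE)))
  }
  names(grid) <- vars
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)

  if (at_means) {
    base <- as.data.frame(lapply(data[model$schema$vars], mean))
    work <- base[rep(1L, nrow(pts)), , drop = FALSE]
    for (v in vars) work[[v]] <- pts[[v]]
    pts$fit <- predict(model, work, type = scale)
    return(pts)
  }
  fit <- numeric(nrow(pts))
  work <- data
  for (i in seq_len(nrow(pts))) {
    for (v in vars) work[[v]] <- pts[[v]][i]
    fit[i] <- mean(predict(model, work, type = scale))
  }
  pts$fit <- fit
  pts
}

#' Pairwise interaction strength of two predictors
#'
#' Builds the joint partial-dependence surface of the pair on a
#' `grid_size` x `grid_size` quantile grid (link scale), removes the best
#' additive (row + column effects) approximation by least squares, and
#' reports `1000 *` the mean squared residual.  Zero indicates a purely
#' additive (non-interacting) pair; the statistic is symmetric in the
#' argument order.
#'
#' @param model A `brt_fit`.
#' @param pair Character vector of two predictor names.
#' @param data Data frame averaged over when building the surface.
#' @param grid_size Grid points per axis.
#' @return Non-negative scalar.
#' @export
interaction_strength <- function(model, pair, data, grid_size = 10) {
  if (length(pair) != 2) stop("pair must name exactly two predictors")
  unknown <- setdiff(pair, model$schema$vars)
  if (length(unknown))
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "))
  for (v in pair) {
    if (length(unique(data[[v]])) < 2) {
      warning("predictor ", v, " is constant; interaction strength is 0")
      return(0)
    }
  }
  pair <- sort(pair)      # symmetry in argument order, explicitly
  pd <- partial_dependence(model, pair, data, grid_size = grid_size,
                           scale = "link")
  z <- matrix(pd$fit, nrow = length(unique(pd[[pair[1]]])))
  # balanced two-way layout: least-squares additive fit = row + col means
  add <- outer(rowMeans(z), colMeans(z), "+") - mean(z)
  1000 * mean((z - add)^2)
}

#' Fit a bootstrapped BRT ensemble
#'
#' Fits `n_sims` models, each to a random 80% of the training rows
#' (response-stratified withhold of `holdout`), reusing the structure of
#' the full model (`tc`, `lr`, `n_trees`).  Each member's withheld 20% is
#' scored for AUC and deviance explained, giving the spread used for
#' prediction-uncertainty summaries.  Member seeds are derived
#' deterministically from the master seed.
#'
#' @inheritParams fit_brt
#' @param n_sims Number of ensemble members (the full analysis uses 200; a
#'   few dozen suffice for desk-scale validation).
#' @param holdout Fraction of rows withheld from each member's fit.
#' @param n_trees Trees per member (normally the cross-validated optimum
#'   of the full model).
#' @param reselect_trees If `TRUE`, each member re-runs cross-validation
#'   to select its own tree count (slower; off by default).
#' @param bootstrap If `TRUE`, each member fits to a with-replacement
#'   resample of its 80% fitting rows instead of the rows themselves.
#' @param cv_folds,cv_step,cv_max_trees Settings used when
#'   `reselect_trees = TRUE`.
#' @return A `brt_ensemble`: list with `members` (each: `fit`,
#'   `withheld_ids`, `auc`, `dev_expl`, `n_trees`), shared settings, and
#'   the master seed.
#' @export
fit_ensemble <- function(train, n_sims = 200, holdout = 0.2,
                         tc = 5, lr = 0.01, bag_fraction = 0.75,
                         n_trees = 1000, min_node = 10,
                         vars = NULL, log_vars = c("MeanFlow", "WidthQ50",
                                                   "segSinuosity"),
                         seed = 1, reselect_trees = FALSE, bootstrap = FALSE,
                         cv_folds = 10, cv_step = 50, cv_max_trees = 5000) {
  if (n_sims < 2) stop("n_sims must be >= 2")
  if (holdout <= 0 || holdout >= 1) stop("holdout must lie in (0, 1)")
  y <- train$response
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (floor(n1 * (1 - holdout)) < 1 || floor(n0 * (1 - holdout)) < 1)
    stop("holdout is so large that a class vanishes from the fitting set")
  set.seed(seed)
  member_seeds <- sample.int(2^20, n_sims)

  members <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    set.seed(member_seeds[i])
    hold <- logical(length(y))
    for (cls in c(0, 1)) {
      rows <- which(y == cls)
      hold[sample(rows, ceiling(holdout * length(rows)))] <- TRUE
    }
    fit_rows <- which(!hold)
    if (bootstrap) fit_rows <- sample(fit_rows, replace = TRUE)
    fit_dat <- train[fit_rows, , drop = FALSE]

    nt <- n_trees
    if (reselect_trees) {
      nt <- cv_optimal_ntrees(fit_dat, tc = tc, lr = lr,
                              bag_fraction = bag_fraction, folds = cv_folds,
                              step = cv_step, max_trees = cv_max_trees,
                              min_node = min_node, vars = vars,
                              log_vars = log_vars,
                              seed = member_seeds[i])$optimal_trees
    }
    fit <- fit_brt(fit_dat, tc = tc, lr = lr, bag_fraction = bag_fraction,
                   n_trees = nt, min_node = min_node, vars = vars,
                   log_vars = log_vars, seed = member_seeds[i])
    wd <- train[hold, , drop = FALSE]
    p <- predict(fit, wd)
    members[[i]] <- list(fit = fit,
                         withheld_ids = wd$reach_id,
                         auc = auc(wd$response, p),
                         dev_expl = deviance_explained(wd$response, p),
                         n_trees = nt)
  }
  structure(list(members = members, n_sims = n_sims, holdout = holdout,
                 tc = tc, lr = lr, bag_fraction = bag_fraction,
                 n_trees = n_trees, seed = seed,
                 schema = members[[1]]$fit$schema),
            class = "brt_ensemble")
}

#' @export
print.brt_ensemble <- function(x, ...) {
  aucs <- vapply(x$members, `[[`, numeric(1), "auc")
  des <- vapply(x$members, `[[`, numeric(1), "dev_expl")
  cat("BRT ensemble:", x$n_sims, "members, holdout", x$holdout, "\n")
  cat(sprintf("  withheld AUC %.3f +/- %.3f; deviance explained %.1f +/- %.1f%%\n",
              mean(aucs), sd(aucs), 100 * mean(des), 100 * sd(des)))
  invisible(x)
}

#' Per-member predictions from an ensemble
#'
#' @param object A `brt_ensemble`.
#' @param newdata Data frame with the predictor columns.
#' @param ... Unused.
#' @return Numeric matrix, rows = rows of `newdata`, one column per
#'   ensemble member, values on the probability scale.
#' @export
predict.brt_ensemble <- function(object, newdata, ...) {
  vapply(object$members, function(m) predict(m$fit, newdata),
         numeric(nrow(newdata)))
}
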