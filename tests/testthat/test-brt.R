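test_that("a constant working response yields a single Newton-step leaf", {
  X <- matrix(runif(40), 20)
  z <- rep(0.25, 20); w <- rep(0.25, 20)
  tree <- fit_tree(X, z, w, tc = 5, min_node = 2)
  expect_equal(nrow(tree), 1L)
  expect_equal(tree[1, "var"], c(var = 0))
  expect_equal(unname(tree[1, "value"]), sum(z) / sum(w))
})

test_that("a perfect binary separator is found with closed-form leaves", {
  # y in {0,0,1,1} at base rate 0.5: z = y - 0.5, w = 0.25
  X <- matrix(c(0, 0, 1, 1), 4)
  z <- c(-0.5, -0.5, 0.5, 0.5); w <- rep(0.25, 4)
  tree <- fit_tree(X, z, w, tc = 5, min_node = 1)
  splits <- sum(tree[, "var"] > 0)
  expect_equal(splits, 1L)
  leaf_vals <- sort(tree[tree[, "var"] == 0, "value"])
  # Newton step per group: sum(z)/sum(w) = (+-1)/0.5 = +-2
  expect_equal(unname(leaf_vals), c(-2, 2))
})

test_that("tree growth respects the terminal-node bound", {
  set.seed(40)
  for (tc in c(1, 3, 5, 9)) {
    X <- matrix(runif(600), 100)
    z <- rnorm(100); w <- rep(0.25, 100)
    tree <- fit_tree(X, z, w, tc = tc, min_node = 5)
    expect_lte(sum(tree[, "var"] == 0), tc + 1)
    # every row routes to exactly one leaf: prediction well-defined
    expect_equal(sum(tree[, "var"] > 0) + 1, sum(tree[, "var"] == 0))
  }
})

test_that("zero trees predict the training base rate", {
  train <- toy_train(n = 200, seed = 2)
  fit <- fit_brt(train, n_trees = 0, log_vars = character(0), seed = 1)
  p <- predict(fit, train)
  expect_equal(p, rep(mean(train$response), 200))
})

test_that("full-bag boosting monotonically reduces training deviance", {
  train <- toy_train(n = 300, seed = 3)
  fit <- fit_brt(train, tc = 2, lr = 0.1, bag_fraction = 1, n_trees = 80,
                 log_vars = character(0), seed = 4)
  devs <- vapply(seq(0, 80, by = 10), function(k)
    bernoulli_deviance(train$response, predict(fit, train, n_trees = k)),
    numeric(1))
  expect_true(all(diff(devs) <= 1e-10))
})

test_that("deep fits separate noiseless labels", {
  set.seed(41)
  n <- 200
  x <- runif(n)
  train <- data.frame(reach_id = 1:n, response = as.integer(x > 0.5),
                      x1 = x, x2 = runif(n))
  fit <- fit_brt(train, tc = 2, lr = 0.2, bag_fraction = 1, n_trees = 150,
                 min_node = 5, log_vars = character(0), seed = 6)
  expect_gt(auc(train$response, predict(fit, train)), 0.999)
})

test_that("degenerate fits are rejected with clear messages", {
  train <- toy_train(n = 100, seed = 5)
  train$response <- 1L
  expect_error(fit_brt(train, seed = 1), "single class")
  train2 <- toy_train(n = 100, seed = 6)
  expect_error(fit_brt(train2, lr = -0.01, seed = 1), "lr")
  expect_error(fit_brt(train2, bag_fraction = 0, seed = 1), "bag_fraction")
})

test_that("prediction requires the fitted schema and names missing columns", {
  fit <- toy_model()
  nd <- toy_train(n = 20, seed = 9)
  nd$x2 <- NULL
  expect_error(predict(fit, nd), "x2")
})

test_that("hand-built model predictions match direct evaluation", {
  # two stumps on x1: tree A splits at 0.5 (values -1 / +1), tree B splits
  # at 0.25 (values -2 / +0.5); intercept 0.3, lr 0.1
  tree_a <- matrix(c(1, 0.5, 2, 3, 0, 1,
                     0, 0, 0, 0, -1, 0,
                     0, 0, 0, 0,  1, 0), 3, 6, byrow = TRUE)
  tree_b <- matrix(c(1, 0.25, 2, 3, 0, 1,
                     0, 0, 0, 0, -2, 0,
                     0, 0, 0, 0, 0.5, 0), 3, 6, byrow = TRUE)
  fit <- structure(list(intercept = 0.3, trees = list(tree_a, tree_b),
                        lr = 0.1, tc = 1, bag_fraction = 1, min_node = 1,
                        n_trees = 2L,
                        schema = list(vars = "x1",
                                      log_vars = character(0)),
                        seed = 1L),
                   class = "brt_fit")
  nd <- data.frame(x1 = c(0.1, 0.4, 0.9))
  expected <- plogis(0.3 + 0.1 * c(-1 + -2, -1 + 0.5, 1 + 0.5))
  expect_equal(predict(fit, nd), expected)
  expect_equal(predict(fit, nd, type = "link"),
               qlogis(expected), tolerance = 1e-12)
})

test_that("Bernoulli deviance matches its closed forms", {
  y <- c(0, 1, 1, 0)
  expect_equal(bernoulli_deviance(y, rep(0.5, 4)), 2 * log(2))
  expect_lt(bernoulli_deviance(y, y), 1e-10)
  expect_equal(deviance_explained(y, rep(mean(y), 4)), 0)
  expect_error(bernoulli_deviance(c(0, 1), 0.5), "equal length")
})

test_that("AUC matches closed forms and the pairwise oracle", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.4)), 1)
  expect_equal(auc(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)
  set.seed(42)
  y <- rbinom(200, 1, 0.4)
  p <- round(runif(200), 2)   # rounding forces ties
  expect_equal(auc(y, p), oracle_auc(y, p))
  expect_error(auc(rep(1, 5), runif(5)), "both classes")
})

test_that("cross-validation partitions rows and selects on the grid", {
  train <- toy_train(n = 240, seed = 7)
  cv <- cv_optimal_ntrees(train, tc = 2, lr = 0.1, folds = 4, step = 20,
                          max_trees = 200, log_vars = character(0),
                          seed = 8)
  expect_setequal(unique(cv$fold_id), 1:4)
  expect_length(cv$fold_id, 240)
  # stratification: every fold holds both classes
  for (k in 1:4)
    expect_gt(min(table(train$response[cv$fold_id == k])), 0)
  expect_equal(cv$optimal_trees %% 20, 0)
  expect_equal(cv$mean_dev[match(cv$optimal_trees, cv$trees)],
               min(cv$mean_dev))
})

test_that("null data keeps cross-validated model size small", {
  smallest <- 0L; largest <- 0L
  for (s in 1:4) {
    set.seed(s)
    train <- data.frame(reach_id = 1:160,
                        response = rep(c(0L, 1L), 80),
                        x1 = runif(160), x2 = runif(160))
    cv <- cv_optimal_ntrees(train, tc = 2, lr = 0.1, folds = 4, step = 25,
                            max_trees = 250, patience = 10,
                            log_vars = character(0), seed = s)
    smallest <- smallest + (cv$optimal_trees == min(cv$trees))
    largest <- largest + (cv$optimal_trees == max(cv$trees))
  }
  expect_gt(smallest, largest)
})

test_that("relative influence is a normalized split-gain decomposition", {
  train <- toy_train(n = 300, seed = 10)
  train$x_const <- 1   # cannot be split on
  fit <- fit_brt(train, tc = 2, lr = 0.1, bag_fraction = 1, n_trees = 50,
                 log_vars = character(0), seed = 11)
  ri <- relative_influence(fit)
  expect_equal(sum(ri), 100, tolerance = 1e-9)
  expect_equal(unname(ri["x_const"]), 0)
})

test_that("one informative predictor dominates nine noise predictors", {
  set.seed(12)
  n <- 400
  X <- matrix(runif(n * 10), n)
  colnames(X) <- paste0("x", 1:10)
  y <- rbinom(n, 1, plogis(8 * (X[, 1] - 0.5)))
  train <- data.frame(reach_id = 1:n, response = y, X)
  fit <- fit_brt(train, tc = 1, lr = 0.1, bag_fraction = 1, n_trees = 150,
                 log_vars = character(0), seed = 13)
  ri <- relative_influence(fit)
  expect_gt(unname(ri["x1"]), 80)
})

test_that("partial dependence matches brute-force grid averaging", {
  fit <- toy_model()
  data <- toy_train(n = 50, seed = 14)
  grid <- seq(0.1, 0.9, length.out = 7)
  pd <- partial_dependence(fit, "x1", data, grid = list(grid))
  manual <- vapply(grid, function(v) {
    d <- data; d$x1 <- v
    mean(predict(fit, d, type = "link"))
  }, numeric(1))
  expect_equal(pd$fit, manual, tolerance = 1e-12)
  # intercept-only model is flat
  fit0 <- fit_brt(toy_train(n = 100, seed = 15), n_trees = 0,
                  log_vars = character(0), seed = 1)
  pd0 <- partial_dependence(fit0, "x1", data, grid = list(grid))
  expect_equal(diff(range(pd0$fit)), 0)
  expect_error(partial_dependence(fit, "nope", data), "unknown")
})

test_that("interaction strength separates additive from interacting truths", {
  set.seed(16)
  n <- 500
  X <- matrix(runif(n * 3), n)
  colnames(X) <- paste0("x", 1:3)
  y_add <- rbinom(n, 1, plogis(2.5 * (X[, 1] - 0.5) + 2.5 * (X[, 2] - 0.5)))
  y_int <- rbinom(n, 1, plogis(8 * (X[, 1] - 0.5) * (X[, 2] - 0.5)))
  d <- data.frame(X)
  # a stump ensemble is additive by construction: the statistic's exact
  # zero anchor
  fit_stump <- fit_brt(data.frame(reach_id = 1:n, response = y_add, X),
                       tc = 1, lr = 0.1, bag_fraction = 1, n_trees = 80,
                       log_vars = character(0), seed = 17)
  expect_lt(interaction_strength(fit_stump, c("x1", "x2"), d,
                                 grid_size = 8), 1e-6)
  fit_add <- fit_brt(data.frame(reach_id = 1:n, response = y_add, X),
                     tc = 3, lr = 0.1, bag_fraction = 1, n_trees = 80,
                     log_vars = character(0), seed = 17)
  fit_int <- fit_brt(data.frame(reach_id = 1:n, response = y_int, X),
                     tc = 3, lr = 0.1, bag_fraction = 1, n_trees = 80,
                     log_vars = character(0), seed = 17)
  s_add <- interaction_strength(fit_add, c("x1", "x2"), d, grid_size = 8)
  s_int <- interaction_strength(fit_int, c("x1", "x2"), d, grid_size = 8)
  expect_gt(s_int, s_add)
  expect_equal(interaction_strength(fit_int, c("x2", "x1"), d, grid_size = 8),
               s_int)
  d2 <- d; d2$x3 <- 1
  expect_warning(out <- interaction_strength(fit_int, c("x1", "x3"), d2),
                 "constant")
  expect_equal(out, 0)
})

test_that("ensembles withhold the right rows and reproduce exactly", {
  train <- toy_train(n = 200, seed = 18)
  ens <- fit_ensemble(train, n_sims = 4, holdout = 0.2, tc = 2, lr = 0.1,
                      n_trees = 40, log_vars = character(0), seed = 19)
  for (m in ens$members) {
    expect_equal(length(m$withheld_ids),
                 ceiling(0.2 * sum(train$response == 1)) +
                   ceiling(0.2 * sum(train$response == 0)))
    # withheld rows were not fitted: model trained on the complement only
    expect_true(all(m$withheld_ids %in% train$reach_id))
  }
  ens2 <- fit_ensemble(train, n_sims = 4, holdout = 0.2, tc = 2, lr = 0.1,
                       n_trees = 40, log_vars = character(0), seed = 19)
  expect_identical(vapply(ens$members, `[[`, numeric(1), "auc"),
                   vapply(ens2$members, `[[`, numeric(1), "auc"))
  expect_error(fit_ensemble(train, n_sims = 1, seed = 1), "n_sims")
  expect_error(fit_ensemble(train, n_sims = 3, holdout = 0.999, seed = 1),
               "holdout")
})

test_that("log-transformed predictors are handled identically at fit and predict", {
  set.seed(22)
  n <- 300
  flow <- rlnorm(n, 0, 1.5)
  y <- rbinom(n, 1, plogis(1.5 * (log(flow))))
  train <- data.frame(reach_id = 1:n, response = y, MeanFlow = flow,
                      x2 = runif(n))
  fit <- fit_brt(train, tc = 2, lr = 0.1, bag_fraction = 1, n_trees = 60,
                 vars = c("MeanFlow", "x2"), log_vars = "MeanFlow",
                 seed = 23)
  # monotone response in flow once other predictor is fixed
  nd <- data.frame(MeanFlow = quantile(flow, c(0.1, 0.5, 0.9)), x2 = 0.5)
  p <- predict(fit, nd)
  expect_true(all(diff(p) >= 0))
})

test_that("ensemble serialization round-trips exactly", {
  train <- toy_train(n = 150, seed = 24)
  ens <- fit_ensemble(train, n_sims = 3, holdout = 0.2, tc = 2, lr = 0.1,
                      n_trees = 30, log_vars = character(0), seed = 25)
  path <- tempfile(fileext = ".txt")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(back$n_sims, ens$n_sims)
  expect_identical(back$schema, ens$schema)
  nd <- toy_train(n = 40, seed = 26)
  expect_identical(predict(ens, nd), predict(back, nd))
  for (i in seq_along(ens$members)) {
    expect_identical(ens$members[[i]]$fit$trees, back$members[[i]]$fit$trees)
    expect_identical(ens$members[[i]]$withheld_ids,
                     back$members[[i]]$withheld_ids)
  }
})
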