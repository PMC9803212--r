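# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

small_config <- function() riverscape_config(n_reaches = 400, n_outlets = 2)

small_net <- function() fixture("small_net", function() {
  generate_network(400, 2, seed = 42)
})

small_pair <- function() fixture("small_pair", function() {
  generate_predictors(small_net(), small_config(), seed = 43)
})

small_truth <- function() fixture("small_truth", function() {
  occupancy_truth(small_net(), small_pair(), small_config(), seed = 44)
})

# Generic two-signal logistic toy data for BRT tests: x1 and x2 carry the
# signal, x3..x6 are noise.
toy_train <- function(n = 400, seed = 1, beta = c(3, -2), noise = 4) {
  set.seed(seed)
  X <- matrix(runif(n * (2 + noise)), n)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  eta <- beta[1] * (X[, 1] - 0.5) + beta[2] * (X[, 2] - 0.5)
  y <- rbinom(n, 1, plogis(eta))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  out <- data.frame(reach_id = seq_len(n), response = y, X)
  class(out) <- c("training_set", "data.frame")
  out
}

toy_model <- function() fixture("toy_model", function() {
  fit_brt(toy_train(), tc = 2, lr = 0.1, bag_fraction = 1, n_trees = 60,
          min_node = 10, log_vars = character(0), seed = 5)
})

# Brute-force oracle: upstream length-weighted mean by explicit traversal
# of the downstream links (quadratic; independent of the package's
# accumulation path).
oracle_upstream_mean <- function(net, values) {
  idx <- match(net$downstream_id, net$reach_id)
  n <- nrow(net)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ups <- i
    repeat {
      more <- setdiff(which(idx %in% ups), ups)
      if (!length(more)) break
      ups <- c(ups, more)
    }
    out[i] <- sum(net$length_m[ups] * values[ups]) / sum(net$length_m[ups])
  }
  out
}

# O(n^2) pairwise AUC oracle with half credit for ties.
oracle_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}
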