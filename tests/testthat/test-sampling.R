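test_that("kernel density peaks at a lone presence point", {
  pts <- matrix(c(0, 0), 1)
  ev <- rbind(c(0, 0), c(1, 0), c(0, 2), c(3, 3))
  s <- kernel_density_surface(pts, ev, bandwidth = 0.7)
  expect_equal(which.max(s$density), 1L)
  expect_true(all(s$density >= 0))
})

test_that("kernel density integrates to one over the plane", {
  set.seed(20)
  pts <- cbind(rnorm(12), rnorm(12))
  g <- seq(-8, 8, by = 0.1)
  grid <- as.matrix(expand.grid(g, g))
  s <- kernel_density_surface(pts, grid, bandwidth = 0.6)
  expect_equal(sum(s$density) * 0.1^2, 1, tolerance = 0.01)
})

test_that("smoothing cannot raise the density maximum", {
  set.seed(21)
  pts <- cbind(runif(30), runif(30))
  s1 <- kernel_density_surface(pts, pts, bandwidth = 0.2)
  s2 <- kernel_density_surface(pts, pts, bandwidth = 0.4)
  expect_lte(max(s2$density), max(s1$density))
})

test_that("bad kernel inputs are rejected", {
  expect_error(kernel_density_surface(matrix(1:2, 1), matrix(1:2, 1),
                                      bandwidth = 0), "bandwidth")
  expect_error(kernel_density_surface(matrix(numeric(0), 0, 2),
                                      matrix(1:2, 1)), "presence")
})

test_that("background selection enforces the design constraints", {
  net <- small_net()
  tr <- small_truth()
  pres <- simulate_presences(tr, "predation", 1500, seed = 30)
  surf <- kernel_density_surface(
    cbind(net$x, net$y)[match(pres, net$reach_id), , drop = FALSE],
    cbind(net$x, net$y))
  ts <- select_background(pres, net, surf, density_quantile = 0.05,
                          seed = 31)
  bg <- ts$reach_id[ts$response == 0]
  expect_equal(sum(ts$response == 1), sum(ts$response == 0))
  expect_length(intersect(bg, pres), 0)
  thr <- quantile(surf$density[match(pres, net$reach_id)], 0.05,
                  names = FALSE)
  expect_true(all(surf$density[match(bg, net$reach_id)] >= thr))
  # reseeding changes membership, never the counts or constraints
  ts2 <- select_background(pres, net, surf, density_quantile = 0.05,
                           seed = 32)
  expect_false(identical(sort(ts2$reach_id[ts2$response == 0]), sort(bg)))
  expect_equal(sum(ts2$response == 0), length(pres))
})

test_that("an infinite-bandwidth, zero-quantile design is uniform sampling", {
  net <- generate_network(30, 1, seed = 33)
  pres <- net$reach_id[1:10]
  surf <- kernel_density_surface(
    cbind(net$x, net$y)[1:10, , drop = FALSE], cbind(net$x, net$y),
    bandwidth = 1e9)
  seen <- integer(0)
  for (s in 1:60) {
    ts <- select_background(pres, net, surf, density_quantile = 0,
                            seed = s)
    seen <- union(seen, ts$reach_id[ts$response == 0])
  }
  expect_setequal(seen, setdiff(net$reach_id, pres))
})

test_that("an insufficient background pool raises a named shortfall", {
  net <- generate_network(12, 1, seed = 34)
  pres <- net$reach_id[1:8]
  surf <- kernel_density_surface(
    cbind(net$x, net$y)[1:8, , drop = FALSE], cbind(net$x, net$y),
    bandwidth = 1e9)   # every reach eligible: shortfall is exactly 8 - 4
  expect_error(select_background(pres, net, surf, density_quantile = 0,
                                 seed = 1),
               "shortfall 4")
})

test_that("training sets align predictors to reaches", {
  net <- small_net(); pair <- small_pair(); tr <- small_truth()
  pres <- simulate_presences(tr, "predation", 800, seed = 36)
  ts <- select_background(pres, net, NULL, seed = 37)
  full <- build_training_set(ts, pair$contemporary)
  expect_true(all(predictor_names() %in% names(full)))
  i <- sample(nrow(full), 1)
  j <- match(full$reach_id[i], pair$contemporary$reach_id)
  expect_equal(unlist(full[i, predictor_names()], use.names = FALSE),
               unlist(pair$contemporary[j, predictor_names()],
                      use.names = FALSE))
})
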