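ref2 <- function() {
  # two covariates with reference ranges [0,10] and [2,4]
  data.frame(a = c(0, 5, 10, 2, 7), b = c(2, 3, 4, 2.5, 3.5))
}

test_that("NT1 is zero inside the reference ranges and additive outside", {
  r <- ref2()
  inside <- data.frame(a = 5, b = 3)
  expect_equal(nt1(r, inside)$nt1, 0)
  # one covariate 10% below range: UD = -1/10 / ... = -0.1
  low_a <- data.frame(a = -1, b = 3)
  expect_equal(nt1(r, low_a)$nt1, -0.1)
  # two covariates each 10% below their range: sums to -0.2
  low_ab <- data.frame(a = -1, b = 1.8)
  expect_equal(nt1(r, low_ab)$nt1, -0.2)
  # above-range overshoot scales the same way
  hi_a <- data.frame(a = 12, b = 3)
  expect_equal(nt1(r, hi_a)$nt1, -0.2)
})

test_that("NT2 is normalized Mahalanobis distance", {
  set.seed(60)
  ref <- as.data.frame(matrix(rnorm(200 * 5), 200))
  proj <- as.data.frame(matrix(rnorm(50 * 5), 50))
  names(proj) <- names(ref)
  got <- nt2(ref, proj)
  # explicit-inverse oracle
  S <- cov(as.matrix(ref))
  mu <- colMeans(ref)
  d2 <- apply(as.matrix(proj), 1, function(x)
    t(x - mu) %*% solve(S) %*% (x - mu))
  dref <- apply(as.matrix(ref), 1, function(x)
    t(x - mu) %*% solve(S) %*% (x - mu))
  expect_equal(got, unname(d2 / max(dref)), tolerance = 1e-10)
  # the reference mean scores zero; the farthest reference point scores one
  expect_equal(nt2(ref, as.data.frame(t(mu))), 0, tolerance = 1e-12)
  expect_equal(max(nt2(ref, ref)), 1, tolerance = 1e-12)
})

test_that("the combined ExDet value follows the NT1/NT2 rule", {
  expect_equal(exdet_combined(-0.3, 0.4), -0.3)
  expect_equal(exdet_combined(0, 0.7), 0.7)
  expect_equal(exdet_combined(0, 1.8), 1.8)
  expect_equal(exdet_combined(c(-0.1, 0), c(5, 0.2)), c(-0.1, 0.2))
})

test_that("most influential covariate identification", {
  r <- ref2()
  proj <- data.frame(a = c(5, -4, 5), b = c(3, 3, 9))
  res <- exdet(r, proj)
  expect_equal(res$mic, c("none", "a", "b"))
  # NT2-novel point: agrees with exhaustive leave-one-out reduction
  set.seed(61)
  z <- matrix(rnorm(400), 200)
  z[, 2] <- z[, 1] + rnorm(200, 0, 0.1)    # strong correlation
  ref <- data.frame(a = z[, 1], b = z[, 2])
  novel <- data.frame(a = 2, b = -2)       # within ranges, combination novel
  res2 <- exdet(ref, novel)
  expect_gt(res2$exdet, 1)
  S <- cov(as.matrix(ref)); mu <- colMeans(ref)
  x <- c(2, -2)
  full <- mahalanobis(t(x), mu, S)
  reductions <- vapply(1:2, function(j)
    full - mahalanobis(t(x[-j]), mu[-j], S[-j, -j, drop = FALSE]),
    numeric(1))
  expect_equal(res2$mic, c("a", "b")[which.max(reductions)])
})

test_that("extrapolation percentages partition correctly", {
  res <- data.frame(exdet = c(-0.5, -0.2, -0.1, 1.5, rep(0.5, 6)))
  pct <- percent_extrapolating(res)
  expect_equal(pct$total, 40)
  expect_equal(pct$univariate, 30)
  expect_equal(pct$combinational, 10)
  all_ok <- data.frame(exdet = rep(0.4, 10))
  expect_equal(percent_extrapolating(all_ok)$total, 0)
})

test_that("ExDet is invariant to joint affine rescaling of a covariate", {
  set.seed(62)
  ref <- as.data.frame(matrix(runif(60 * 3), 60))
  proj <- as.data.frame(matrix(runif(30 * 3, -0.4, 1.4), 30))
  names(proj) <- names(ref)
  res <- exdet(ref, proj)
  ref2 <- ref; proj2 <- proj
  ref2[[2]] <- ref2[[2]] * 37 - 5
  proj2[[2]] <- proj2[[2]] * 37 - 5
  res2 <- exdet(ref2, proj2)
  expect_equal(res2$nt1, res$nt1, tolerance = 1e-10)
  expect_equal(res2$nt2, res$nt2, tolerance = 1e-8)
})

test_that("reference points evaluated as projections are analogue", {
  set.seed(63)
  ref <- as.data.frame(matrix(rnorm(80 * 4), 80))
  res <- exdet(ref, ref)
  expect_true(all(res$exdet >= 0 & res$exdet <= 1 + 1e-12))
})

test_that("zero-range covariates are dropped with a warning", {
  ref <- data.frame(a = c(1, 2, 3, 4), b = 7)
  proj <- data.frame(a = c(2, -10), b = c(7, 100))
  expect_warning(nt1(ref, proj), "zero-range")
  res <- suppressWarnings(exdet(ref, proj))
  expect_equal(res$nt1, c(0, -11 / 3))
})
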