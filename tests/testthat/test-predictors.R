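test_that("temperature seasonality matches hand-computed cases", {
  # identical z-scores cancel exactly
  expect_equal(temp_seasonality(c(1, 2, 3), c(4, 5, 6)), c(0, 0, 0))
  # opposing gradients: z-scores are (-1,0,1) and (1,0,-1), sigma_S = 1
  expect_equal(temp_seasonality(c(1, 2, 3), c(6, 5, 4)), c(-2, 0, 2))
  # location invariance in W and in S
  W <- c(2.3, 5.1, 4.4, 7.9); S <- c(11, 14.2, 12.8, 16)
  expect_equal(temp_seasonality(W + 10, S), temp_seasonality(W, S))
  expect_equal(temp_seasonality(W, S - 3.7), temp_seasonality(W, S))
})

test_that("temperature seasonality rejects degenerate inputs", {
  expect_error(temp_seasonality(c(1, 1, 1), c(2, 3, 4)), "zero variance")
  expect_error(temp_seasonality(c(1, 2), c(3, 3)), "zero variance")
  expect_error(temp_seasonality(1, 2), "two reaches")
  expect_error(temp_seasonality(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("upstream forest accumulation equals the brute-force traversal", {
  net <- generate_network(120, 3, seed = 5)
  set.seed(6)
  forest <- runif(120)
  expect_equal(upstream_length_weighted_mean(net, forest),
               oracle_upstream_mean(net, forest), tolerance = 1e-12)
})

test_that("zero conversion makes the two epochs identical", {
  net <- generate_network(150, 2, seed = 11)
  cfg <- riverscape_config(n_reaches = 150, conversion_fraction = 0)
  pair <- generate_predictors(net, cfg, seed = 12)
  expect_identical(pair$contemporary, pair$prehuman)
})

test_that("conversion only degrades the substituted covariates", {
  pair <- small_pair()
  expect_true(any(pair$converted))
  expect_true(all(pair$prehuman$segIndigenousForest >=
                    pair$contemporary$segIndigenousForest))
  expect_true(all(pair$prehuman$segShade >= pair$contemporary$segShade))
  expect_true(all(pair$contemporary$segTempSummer >=
                    pair$prehuman$segTempSummer))
  # non-substituted columns are identical between epochs
  untouched <- setdiff(predictor_names(), substitution_set())
  expect_identical(pair$contemporary[untouched], pair$prehuman[untouched])
  # substituted columns differ only at converted reaches (the shared
  # climatology pins unconverted reaches' values)
  conv <- pair$converted
  for (cl in substitution_set()) {
    if (cl == "usIndigenousForest") next  # accumulates over converted areas
    expect_equal(pair$contemporary[[cl]][!conv], pair$prehuman[[cl]][!conv],
                 info = cl)
  }
})

test_that("generated tables satisfy the schema and range invariants", {
  pair <- small_pair()
  expect_silent(validate_predictors(pair$contemporary))
  expect_silent(validate_predictors(pair$prehuman))
})

test_that("predictor medians fall inside the national ranges", {
  national <- list(
    segTempSummer = c(8.28, 25.82), segTempSeasonality = c(-7.2, 5.25),
    segSinuosity = c(1, 8.89), segSlope = c(-0.85, 2.1),
    segSlopeCatchment = c(0, 61.8), Feb = c(0.22, 1.71),
    FRE3 = c(1.81, 40.94), segFlowStability = c(-0.1, 0.63),
    MeanFlow = c(0, 1327.78), Order = c(1, 8), WidthQ50 = c(0.01, 136.11),
    segIndigenousForest = c(0, 1), usIndigenousForest = c(0, 1),
    segShade = c(0, 0.8), segHabitat = c(1, 6.9), segSediment = c(1, 6.79),
    segGravelCobble = c(0.14, 0.83))
  tab <- small_pair()$contemporary
  for (nm in predictor_names()) {
    m <- median(tab[[nm]])
    expect_gte(m, national[[nm]][1])
    expect_lte(m, national[[nm]][2])
  }
})

test_that("predictor generation is deterministic and rejects empty input", {
  net <- generate_network(80, 2, seed = 3)
  cfg <- riverscape_config(n_reaches = 80)
  expect_identical(generate_predictors(net, cfg, seed = 4),
                   generate_predictors(net, cfg, seed = 4))
  expect_error(generate_predictors(net[0, ], cfg, seed = 4), "empty")
})
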