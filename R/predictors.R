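#' Temperature seasonality index
#'
#' Winter air temperature normalized with respect to summer air temperature:
#' the difference between the winter and summer z-scores, rescaled back to
#' summer-temperature units:
#' \deqn{((W - \bar W)/\sigma_W - (S - \bar S)/\sigma_S)\,\sigma_S.}
#' The index is invariant to adding a constant to all winter (or all summer)
#' temperatures.  Standard deviations use the n-1 denominator.
#'
#' @param W Winter air temperature per reach (degrees C).
#' @param S Summer air temperature per reach (degrees C).
#' @param ref Optional list with elements `mW`, `sW`, `mS`, `sS` giving the
#'   normalization constants; by default they are the sample statistics of
#'   `W` and `S`.  Supplying fixed constants lets two epochs share one
#'   climatology.
#' @return Numeric vector of seasonality values, one per reach.
#' @export
temp_seasonality <- function(W, S, ref = NULL) {
  if (length(W) != length(S)) stop("W and S must have equal length")
  if (length(W) < 2) stop("at least two reaches are required")
  if (is.null(ref))
    ref <- list(mW = mean(W), sW = sd(W), mS = mean(S), sS = sd(S))
  if (!all(is.finite(c(ref$sW, ref$sS))) || ref$sW <= 0 || ref$sS <= 0)
    stop("degenerate input: zero variance in W or S")
  ((W - ref$mW) / ref$sW - (S - ref$mS) / ref$sS) * ref$sS
}

#' Length-weighted upstream mean of a reach covariate
#'
#' For every reach, the mean of `values` over its full upstream reach set
#' (the reach itself plus all reaches draining into it), weighted by reach
#' length.  This is how local land cover (`segIndigenousForest`) is
#' aggregated into its upstream-catchment counterpart
#' (`usIndigenousForest`).  Computed in O(n) by accumulation in
#' headwater-first order.
#'
#' @param net A `river_network`.
#' @param values Numeric vector aligned with `net$reach_id`.
#' @return Numeric vector of upstream length-weighted means.
#' @export
upstream_length_weighted_mean <- function(net, values) {
  if (length(values) != nrow(net))
    stop("values must have one entry per reach")
  .upstream_sum(net, net$length_m * values) / .upstream_sum(net, net$length_m)
}

#' Default settings for the synthetic riverscape generator
#'
#' Bundles every tunable of the synthetic study system: network size and
#' shape, the two latent environmental gradients, the extent of simulated
#' land conversion, the climate shift on cleared land, the ground-truth
#' occupancy coefficients, the predation refuge rule, and survey effort.
#' Defaults emulate a whio-like river specialist: pre-human indigenous
#' forest almost everywhere, post-settlement clearance concentrated in
#' lowland reaches, and surviving (post-predation) populations confined to
#' scattered protected river sections within otherwise suitable habitat.
#'
#' @param n_reaches,n_outlets,mean_length_m,length_cv Passed to
#'   [generate_network()].
#' @param conversion_fraction Probability that a lowland reach was cleared
#'   of indigenous forest after settlement.
#' @param lowland_elev Relative-elevation threshold (0-1 scale) below which
#'   a reach counts as lowland and is exposed to conversion.
#' @param forest_remnant_max Cleared reaches retain a
#'   `runif(0, forest_remnant_max)` fraction of their pre-human forest.
#' @param warming_summer,warming_winter Additive warming (degrees C) of
#'   summer and winter air temperature on cleared reaches.
#' @param refuge_style How predation refuges are drawn.  `"reserves"`
#'   (default): randomly chosen headwater subcatchments among reaches with
#'   suitable contemporary habitat, emulating survivor populations inside
#'   protected catchments whose locations are idiosyncratic (predator
#'   control history) rather than a function of the habitat covariates --
#'   the condition under which observed presences remain representative
#'   of suitable habitat.  `"terrain"`: a deterministic
#'   high-slope/high-forest rule (see `refuge_slope_quantile`).
#' @param refuge_fraction Under `"reserves"`, protected sections are
#'   accumulated until they hold this fraction of the
#'   suitability-weighted habitat.
#' @param refuge_radius Network radius (reaches, both flow directions) of
#'   each protected section.
#' @param refuge_p_min Minimum contemporary occupancy probability for a
#'   reach to count as suitable when building reserves.
#' @param refuge_slope_quantile,refuge_forest_min Under `"terrain"`, a
#'   reach is a refuge when its catchment slope is at or above this
#'   quantile of `segSlopeCatchment` and its local indigenous forest
#'   exceeds `refuge_forest_min`.
#' @param coefficients Named numeric vector of ground-truth occupancy
#'   coefficients on the logit scale; names are `(Intercept)` plus
#'   predictor names.
#' @param viability_threshold Occupancy probabilities below this value are
#'   set to zero in every regime (populations in marginal habitat are not
#'   viable).  0 disables the threshold; the null validation experiment
#'   uses it to make occupancy truly binary.
#' @param n_records Number of occurrence records drawn by
#'   [simulate_presences()] (records, not unique reaches).
#' @return A list of class `riverscape_config`.
#' @export
riverscape_config <- function(n_reaches = 3000, n_outlets = 6,
                              mean_length_m = 700, length_cv = 0.5,
                              conversion_fraction = 0.95,
                              lowland_elev = 0.5,
                              forest_remnant_max = 0.12,
                              warming_summer = 1.2,
                              warming_winter = 0.5,
                              refuge_style = c("reserves", "terrain"),
                              refuge_fraction = 0.1,
                              refuge_radius = 6,
                              refuge_p_min = 0.5,
                              refuge_slope_quantile = 0.95,
                              refuge_forest_min = 0.5,
                              coefficients = NULL,
                              viability_threshold = 0,
                              n_records = 2000) {
  if (is.null(coefficients)) {
    coefficients <- c("(Intercept)" = -2.5,
                      segIndigenousForest = 7.0,
                      usIndigenousForest  = 2.5,
                      segShade            = 3.0,
                      segFlowStability    = 3.5,
                      segTempSeasonality  = 0.35,
                      segTempSummer       = -0.3)
  }
  structure(list(n_reaches = n_reaches, n_outlets = n_outlets,
                 mean_length_m = mean_length_m, length_cv = length_cv,
                 conversion_fraction = conversion_fraction,
                 lowland_elev = lowland_elev,
                 forest_remnant_max = forest_remnant_max,
                 warming_summer = warming_summer,
                 warming_winter = warming_winter,
                 refuge_style = match.arg(refuge_style),
                 refuge_fraction = refuge_fraction,
                 refuge_radius = refuge_radius,
                 refuge_p_min = refuge_p_min,
                 refuge_slope_quantile = refuge_slope_quantile,
                 refuge_forest_min = refuge_forest_min,
                 coefficients = coefficients,
                 viability_threshold = viability_threshold,
                 n_records = n_records),
            class = "riverscape_config")
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate paired contemporary / pre-human predictor tables
#'
#' Derives the 17 reach-scale covariates from two latent, spatially
#' autocorrelated gradients -- relative elevation (distance toward the
#' headwaters) and wetness (a random walk along the network) -- plus
#' independent reach-level noise, so that forest cover, slope, temperature
#' and flow stability co-vary.  The pre-human epoch carries near-complete
#' indigenous forest; the contemporary epoch is derived from it by clearing
#' a configurable fraction of lowland reaches (forest and riparian shade
#' collapse, summer and winter temperatures rise), after which the
#' upstream forest covariate is re-accumulated and temperature seasonality
#' recomputed.  Only the five substitution-set covariates differ between
#' epochs.
#'
#' @param net A `river_network` from [generate_network()].
#' @param config A [riverscape_config()].
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list of class `epoch_pair` with elements `contemporary` and
#'   `prehuman` (data frames: `reach_id` + the 17 predictors),
#'   `substitution_set`, and auxiliary attributes `elevation`, `wetness`,
#'   `converted` (logical), and `winter` temperatures per epoch.
#' @export
generate_predictors <- function(net, config = riverscape_config(), seed = 1) {
  if (nrow(net) == 0) stop("network is empty")
  n <- nrow(net)
  set.seed(seed)

  # latent gradients -------------------------------------------------------
  dn <- .distance_to_outlet_km(net)
  comp <- .component_id(net)
  compmax <- ave(dn, comp, FUN = max)
  E <- (dn / pmax(compmax, 1e-9))^0.7            # relative elevation, (0,1]
  E <- .clip(E + rnorm(n, 0, 0.03), 0, 1)

  idx <- .downstream_index(net)
  walk <- numeric(n)
  walk[is.na(idx)] <- rnorm(sum(is.na(idx)), 0, 1)
  steps <- rnorm(n, 0, 0.25)
  for (i in order(dn)) {                          # downstream-first
    if (!is.na(idx[i])) walk[i] <- walk[idx[i]] + steps[i]
  }
  wetness <- plogis(0.8 * walk)                   # (0,1)

  # pre-human covariates: gradients follow the mild occupied-vs-national
  # contrasts typical of reach-scale predictor tables (temperature and
  # slope separate weakly; forest and flow stability separate strongly)
  S_pre <- .clip(17.5 - 3.5 * E - 1.5 * wetness + rnorm(n, 0, 1.5),
                 8.28, 25.82)
  W_pre <- S_pre - 9 - 3 * E + rnorm(n, 0, 0.6)
  ref_clim <- list(mW = mean(W_pre), sW = sd(W_pre),
                   mS = mean(S_pre), sS = sd(S_pre))

  stab <- .clip(0.1 + 0.35 * E + 0.1 * (wetness - 0.5) + rnorm(n, 0, 0.06),
                -0.1, 0.63)
  forest_pre <- plogis(1.6 + 1.2 * E + 0.8 * (wetness - 0.5) + rnorm(n, 0, 0.9))
  shade_mult <- runif(n, 0.75, 1)

  up_len_km <- .upstream_sum(net, net$length_m) / 1000
  meanflow <- .clip(0.012 * up_len_km^1.35 *
                      exp(0.6 * (wetness - 0.5) + rnorm(n, 0, 0.3)),
                    1e-3, 1327.78)

  base <- data.frame(
    reach_id = net$reach_id,
    segTempSummer = S_pre,
    segTempSeasonality = temp_seasonality(W_pre, S_pre, ref_clim),
    segSinuosity = .clip(1 + rlnorm(n, log(0.08), 0.8), 1, 8.89),
    segSlope = .clip(0.02 + 0.1 * E^2 + rnorm(n, 0, 0.1), -0.85, 2.1),
    segSlopeCatchment = .clip(3 + 14 * E^1.5 + rnorm(n, 0, 2.5), 0, 61.8),
    Feb = .clip(0.45 + 0.55 * stab + 0.1 * (wetness - 0.5) +
                  rnorm(n, 0, 0.08), 0.22, 1.71),
    FRE3 = .clip(11 + 9 * E + rnorm(n, 0, 3), 1.81, 40.94),
    segFlowStability = stab,
    MeanFlow = meanflow,
    Order = .strahler_order(net),
    WidthQ50 = .clip(4.5 * meanflow^0.4 * exp(rnorm(n, 0, 0.25)),
                     0.01, 136.11),
    segIndigenousForest = forest_pre,
    usIndigenousForest = upstream_length_weighted_mean(net, forest_pre),
    segShade = .clip(0.8 * forest_pre * shade_mult, 0, 0.8),
    segHabitat = .clip(3.1 + 2.2 * E + rnorm(n, 0, 0.45), 1, 6.9),
    segSediment = .clip(2.8 + 2.8 * E + rnorm(n, 0, 0.5), 1, 6.79),
    segGravelCobble = .clip(0.38 + 0.3 * E + rnorm(n, 0, 0.09), 0.14, 0.83)
  )
  prehuman <- base[, c("reach_id", predictor_names())]

  # contemporary epoch: lowland conversion ---------------------------------
  lowland <- E < config$lowland_elev
  converted <- lowland & (runif(n) < config$conversion_fraction)
  remnant <- runif(n, 0, config$forest_remnant_max)

  forest_cont <- forest_pre
  forest_cont[converted] <- forest_pre[converted] * remnant[converted]
  S_cont <- S_pre + ifelse(converted, config$warming_summer, 0)
  W_cont <- W_pre + ifelse(converted, config$warming_winter, 0)

  contemporary <- prehuman
  contemporary$segIndigenousForest <- forest_cont
  contemporary$usIndigenousForest <-
    upstream_length_weighted_mean(net, forest_cont)
  contemporary$segShade <- .clip(0.8 * forest_cont * shade_mult, 0, 0.8)
  contemporary$segTempSummer <- S_cont
  # same climatology (normalization constants) for both epochs, so that
  # conversion only perturbs converted reaches' covariate values
  contemporary$segTempSeasonality <- temp_seasonality(W_cont, S_cont, ref_clim)

  structure(list(contemporary = contemporary, prehuman = prehuman,
                 substitution_set = substitution_set(),
                 elevation = E, wetness = wetness, converted = converted,
                 winter = list(contemporary = W_cont, prehuman = W_pre)),
            class = "epoch_pair")
}

# Internal: id of the outlet each reach ultimately drains to.
.component_id <- function(net) {
  idx <- .downstream_index(net)
  comp <- rep(NA_integer_, nrow(net))
  comp[is.na(idx)] <- which(is.na(idx))
  repeat {
    todo <- which(is.na(comp) & !is.na(comp[idx]))
    if (!length(todo)) break
    comp[todo] <- comp[idx[todo]]
  }
  comp
}

#' Validate a predictor table
#'
#' Checks the schema (all 17 predictors present), absence of missing
#' values, proportion covariates in their admissible ranges
#' (`segFlowStability` may be slightly negative), positive integer stream
#' order, and non-negative flow and width covariates.
#'
#' @param tab A predictor table (`reach_id` + 17 predictor columns).
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_predictors <- function(tab) {
  miss <- setdiff(c("reach_id", predictor_names()), names(tab))
  if (length(miss)) stop("predictor table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(tab[predictor_names()])) stop("predictor table contains NAs")
  props <- c("segIndigenousForest", "usIndigenousForest", "segShade",
             "segGravelCobble")
  for (p in props)
    if (any(tab[[p]] < 0 | tab[[p]] > 1))
      stop(p, " must lie in [0, 1]")
  if (any(tab$segFlowStability < -0.1 | tab$segFlowStability > 1))
    stop("segFlowStability must lie in [-0.1, 1]")
  if (any(tab$Order < 1 | tab$Order != round(tab$Order)))
    stop("Order must be a positive integer")
  for (p in c("MeanFlow", "WidthQ50", "FRE3"))
    if (any(tab[[p]] < 0)) stop(p, " must be non-negative")
  invisible(TRUE)
}
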