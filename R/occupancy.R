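#' Ground-truth occupancy probabilities under three generative regimes
#'
#' Evaluates the known logistic occupancy model on both epochs of a
#' synthetic riverscape and returns, per reach, the true occupancy
#' probability under three regimes: `pristine` (pre-human covariates),
#' `converted` (contemporary covariates, i.e. after land conversion), and
#' `predation` (contemporary covariates with occupancy zeroed outside
#' predation refuges, emulating fragmented survivor populations).
#'
#' The coefficient signs in [riverscape_config()] are aligned with the
#' direction of simulated degradation (forest and shade enter positively,
#' summer temperature negatively), so the three regimes are nested
#' reach-wise: `predation <= converted <= pristine`.
#'
#' @param net A `river_network`.
#' @param pair An `epoch_pair` from [generate_predictors()].
#' @param config The [riverscape_config()] holding coefficients and the
#'   refuge rule.
#' @param seed Integer seed for the refuge draw (only used by the
#'   `"reserves"` refuge style).
#' @return A data frame of class `occupancy_truth` with columns `reach_id`,
#'   `p_pristine`, `p_converted`, `p_predation`, `refuge` (logical), and
#'   attribute `coefficients`.
#' @export
occupancy_truth <- function(net, pair, config = riverscape_config(),
                            seed = 1) {
  coefs <- config$coefficients
  if (any(!is.finite(coefs))) stop("truth coefficients must be finite")

  eta <- function(tab) {
    v <- rep(coefs[["(Intercept)"]], nrow(tab))
    for (nm in setdiff(names(coefs), "(Intercept)")) {
      if (!nm %in% names(tab)) stop("unknown coefficient name: ", nm)
      v <- v + coefs[[nm]] * tab[[nm]]
    }
    v
  }
  p_pristine  <- plogis(eta(pair$prehuman))
  p_converted <- plogis(eta(pair$contemporary))
  vt <- config$viability_threshold
  if (!is.null(vt) && vt > 0) {
    # populations below the viability threshold are absent, not rare
    p_pristine[p_pristine < vt] <- 0
    p_converted[p_converted < vt] <- 0
  }
  refuge <- refuge_mask(net, pair$contemporary, config,
                        p_suitable = p_converted, seed = seed)
  p_predation <- ifelse(refuge, p_converted, 0)

  out <- data.frame(reach_id = net$reach_id,
                    p_pristine = p_pristine,
                    p_converted = p_converted,
                    p_predation = p_predation,
                    refuge = refuge)
  attr(out, "coefficients") <- coefs
  class(out) <- c("occupancy_truth", "data.frame")
  out
}

#' Predation refuge mask
#'
#' Marks the reaches where a population survives introduced mammalian
#' predators.
#'
#' Under the default `"reserves"` style, refuges are contiguous protected
#' river sections: centre reaches are drawn uniformly at random among
#' suitable reaches (contemporary occupancy probability at least
#' `refuge_p_min`) and each centre contributes its network neighbourhood
#' within `refuge_radius` reaches (in both flow directions), until the
#' selected suitable reaches hold `refuge_fraction` of the
#' suitability-weighted habitat (`sum(p * length)`).  Because the draw is
#' random given suitability, surviving populations span the same
#' environmental space as suitable habitat at large -- the situation in
#' which an SDM trained on survivor presences still measures habitat
#' preference rather than the predation footprint.
#'
#' Under `"terrain"`, a reach is a refuge when its catchment slope is at or
#' above the `refuge_slope_quantile` quantile of `segSlopeCatchment` and
#' local indigenous forest exceeds `refuge_forest_min` ("forested mountain
#' catchments").  This deterministic variant makes the predation filter a
#' function of the model covariates, which an SDM can learn outright; it is
#' kept for studying exactly that failure mode.
#'
#' @param net A `river_network`.
#' @param tab Contemporary predictor table.
#' @param config A [riverscape_config()].
#' @param p_suitable Contemporary occupancy probabilities (required for
#'   `"reserves"`).
#' @param seed Integer seed for the reserve draw.
#' @return Logical vector, `TRUE` at refuge reaches.
#' @export
refuge_mask <- function(net, tab, config = riverscape_config(),
                        p_suitable = NULL, seed = 1) {
  if (config$refuge_style == "terrain") {
    thr <- quantile(tab$segSlopeCatchment, config$refuge_slope_quantile,
                    names = FALSE)
    return(tab$segSlopeCatchment >= thr &
             tab$segIndigenousForest > config$refuge_forest_min)
  }
  if (is.null(p_suitable))
    stop("reserve-style refuges need the suitability probabilities")
  n <- nrow(net)
  len_km <- net$length_m / 1000
  suitable <- p_suitable >= config$refuge_p_min
  mass <- p_suitable * len_km
  target <- config$refuge_fraction * sum(mass)
  if (!any(suitable)) return(rep(FALSE, n))

  # undirected adjacency for neighbourhood expansion: a reserve is a
  # contiguous river section around its centre, not only the upstream
  # subtree (which would skew refuges toward headwaters)
  idx <- .downstream_index(net)
  up <- split(seq_len(n)[!is.na(idx)], idx[!is.na(idx)])
  neighbourhood <- function(centre, radius) {
    seen <- rep(FALSE, n)
    seen[centre] <- TRUE
    frontier <- centre
    for (r in seq_len(radius)) {
      nxt <- c(idx[frontier],
               unlist(up[as.character(frontier)], use.names = FALSE))
      nxt <- unique(nxt[!is.na(nxt)])
      nxt <- nxt[!seen[nxt]]
      if (!length(nxt)) break
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    which(seen)
  }

  set.seed(seed)
  candidates <- sample(which(suitable))
  refuge <- rep(FALSE, n)
  for (centre in candidates) {
    if (sum(mass[refuge & suitable]) >= target) break
    if (refuge[centre]) next
    refuge[neighbourhood(centre, config$refuge_radius)] <- TRUE
  }
  refuge & suitable
}

#' Simulate occurrence records from a known occupancy surface
#'
#' Draws `n_records` occurrence records with replacement, with per-reach
#' probability proportional to the true occupancy probability of the chosen
#' regime, then collapses multiple records on the same reach to a single
#' presence (as survey databases are de-duplicated to avoid
#' pseudo-replication).
#'
#' @param truth An `occupancy_truth` table.
#' @param regime One of `"pristine"`, `"converted"`, `"predation"`.
#' @param n_records Number of records to draw (before de-duplication).
#' @param seed Integer seed.
#' @return Sorted integer vector of presence `reach_id`s.
#' @export
simulate_presences <- function(truth, regime = c("predation", "converted",
                                                 "pristine"),
                               n_records = 2000, seed = 1) {
  regime <- match.arg(regime)
  p <- truth[[paste0("p_", regime)]]
  if (all(p == 0))
    stop("no reach has positive occupancy under regime '", regime,
         "': cannot draw presences")
  set.seed(seed)
  recs <- sample(truth$reach_id, size = n_records, replace = TRUE, prob = p)
  sort(unique(recs))
}
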