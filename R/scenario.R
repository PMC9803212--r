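#' Scenario specification
#'
#' Three scenarios are used to partition range contraction:
#' `potential_contemporary` (contemporary covariates everywhere, predators
#' assumed controlled), `potential_prehuman` (the five land-cover/climate
#' covariates substituted with their pre-human values -- the hindcast), and
#' `observed_contemporary` (the potential-contemporary predictions
#' restricted to the reaches where the species was actually observed,
#' predators assumed to occupy everywhere else).
#'
#' @param name One of `"potential_contemporary"`, `"potential_prehuman"`,
#'   `"observed_contemporary"`.
#' @param presences Presence `reach_id`s; required for
#'   `observed_contemporary`.
#' @return A `scenario_spec` list with `name`, `substitution` (character
#'   vector of substituted predictors) and `restrict` (reach ids or `NULL`).
#' @export
scenario_spec <- function(name = c("potential_contemporary",
                                   "potential_prehuman",
                                   "observed_contemporary"),
                          presences = NULL) {
  name <- match.arg(name)
  substitution <- if (name == "potential_prehuman") substitution_set()
                  else character(0)
  restrict <- NULL
  if (name == "observed_contemporary") {
    if (is.null(presences))
      stop("observed_contemporary requires the presence reach ids")
    restrict <- presences
  }
  structure(list(name = name, substitution = substitution,
                 restrict = restrict), class = "scenario_spec")
}

#' Build the predictor table for a scenario
#'
#' Takes the substituted columns from the pre-human table and every other
#' column from the contemporary table.  An empty substitution list returns
#' the contemporary table unchanged; substituting twice restores it.
#'
#' @param pair An `epoch_pair`.
#' @param spec A `scenario_spec` (or a character vector of column names to
#'   substitute).
#' @return A predictor table.
#' @export
apply_scenario <- function(pair, spec) {
  cols <- if (inherits(spec, "scenario_spec")) spec$substitution else spec
  tab <- pair$contemporary
  if (!length(cols)) return(tab)
  miss <- setdiff(cols, intersect(names(pair$contemporary),
                                  names(pair$prehuman)))
  if (length(miss))
    stop("substitution column(s) absent from an epoch table: ",
         paste(miss, collapse = ", "))
  tab[cols] <- pair$prehuman[cols]
  tab
}

#' Per-reach RLO predictions for a set of scenarios
#'
#' Predicts the relative likelihood of occurrence for every reach and every
#' ensemble member under each scenario, and summarizes across members
#' (mean, sample sd, coefficient of variation).
#'
#' @param ensemble A `brt_ensemble`.
#' @param pair An `epoch_pair`.
#' @param specs List of `scenario_spec`s; defaults to the two potential
#'   scenarios (add `observed_contemporary` by passing specs built with
#'   the presence set).
#' @return Named list of `rlo_prediction` objects, each a list with
#'   `scenario`, `reach_id`, `rlo` (reach x member matrix) and `summary`
#'   (data frame: `reach_id`, `mean_rlo`, `sd_rlo`, `cv`).
#' @export
predict_scenarios <- function(ensemble, pair,
                              specs = list(
                                scenario_spec("potential_contemporary"),
                                scenario_spec("potential_prehuman"))) {
  if (!inherits(ensemble, "brt_ensemble") || !length(ensemble$members))
    stop("ensemble is not a fitted brt_ensemble")
  out <- list()
  # cache: observed_contemporary restricts the potential_contemporary
  # predictions rather than re-predicting
  pot_cont <- NULL
  for (spec in specs) {
    if (spec$name == "observed_contemporary") next
    tab <- apply_scenario(pair, spec)
    rlo <- predict(ensemble, tab)
    pred <- .rlo_prediction(spec$name, tab$reach_id, rlo)
    out[[spec$name]] <- pred
    if (spec$name == "potential_contemporary") pot_cont <- pred
  }
  for (spec in specs) {
    if (spec$name != "observed_contemporary") next
    if (is.null(pot_cont)) {
      tab <- apply_scenario(pair, scenario_spec("potential_contemporary"))
      pot_cont <- .rlo_prediction("potential_contemporary", tab$reach_id,
                                  predict(ensemble, tab))
    }
    keep <- pot_cont$reach_id %in% spec$restrict
    out[[spec$name]] <- .rlo_prediction(
      "observed_contemporary", pot_cont$reach_id[keep],
      pot_cont$rlo[keep, , drop = FALSE])
  }
  out
}

.rlo_prediction <- function(name, reach_id, rlo) {
  if (is.null(dim(rlo))) rlo <- matrix(rlo, ncol = 1)
  sd_rlo <- if (ncol(rlo) >= 2) apply(rlo, 1, sd) else rep(0, nrow(rlo))
  structure(list(scenario = name, reach_id = reach_id, rlo = rlo,
                 summary = data.frame(reach_id = reach_id,
                                      mean_rlo = rowMeans(rlo),
                                      sd_rlo = sd_rlo,
                                      cv = uncertainty_cv(rlo))),
            class = "rlo_prediction")
}

#' Coefficient of variation of per-reach predictions across members
#'
#' `sd / mean` with the sample (n-1) standard deviation.  Reaches whose
#' mean RLO falls below `floor` get `NA`: the ratio is numerically
#' meaningless there.
#'
#' @param rlo An `rlo_prediction` or a reach x member matrix.
#' @param floor Mean-RLO floor below which the CV is reported missing.
#' @return Numeric vector of CVs (NA where flagged).
#' @export
uncertainty_cv <- function(rlo, floor = 1e-6) {
  m <- if (inherits(rlo, "rlo_prediction")) rlo$rlo else rlo
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)
  mu <- rowMeans(m)
  s <- if (ncol(m) >= 2) apply(m, 1, sd) else rep(0, nrow(m))
  ifelse(mu < floor, NA_real_, s / mu)
}
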