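#' Full pipeline configuration
#'
#' Bundles generator, sampling, model and scenario settings for a single
#' reproducible end-to-end run.  The default profile is desk-scale (a few
#' thousand reaches, a few dozen ensemble members); the full analysis
#' scale is obtained with `n_sims = 200` and a larger network.
#'
#' @param riverscape A [riverscape_config()].
#' @param regime Generative regime the presence records are drawn from
#'   (`"predation"` reproduces the study system: survivors confined to
#'   refuges).
#' @param bandwidth Kernel bandwidth for the background constraint
#'   (`NULL` = Silverman's rule).
#' @param density_quantile Quantile of presence-reach density forming the
#'   background eligibility threshold.
#' @param tc,lr,bag_fraction,min_node BRT settings (tree complexity 5,
#'   learning rate 0.01 are the standard workflow values).
#' @param folds,step,max_trees,patience Cross-validation settings for
#'   selecting the optimal tree count.
#' @param n_trees Fixed tree count for ensemble members; `NULL` selects it
#'   by ten-fold cross-validation on the full training set.
#' @param n_sims,holdout Ensemble size and per-member withheld fraction.
#' @param substitution Predictors substituted under the pre-human
#'   scenario.
#' @param write_member_matrix Also write the wide per-member RLO matrices
#'   when an output directory is given.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(riverscape = riverscape_config(),
                            regime = "predation",
                            bandwidth = NULL, density_quantile = 0.05,
                            tc = 5, lr = 0.01, bag_fraction = 0.75,
                            min_node = 10, folds = 10, step = 50,
                            max_trees = 3000, patience = 5,
                            n_trees = NULL, n_sims = 25, holdout = 0.2,
                            substitution = substitution_set(),
                            write_member_matrix = FALSE) {
  structure(list(riverscape = riverscape, regime = regime,
                 bandwidth = bandwidth,
                 density_quantile = density_quantile, tc = tc, lr = lr,
                 bag_fraction = bag_fraction, min_node = min_node,
                 folds = folds, step = step, max_trees = max_trees,
                 patience = patience, n_trees = n_trees, n_sims = n_sims,
                 holdout = holdout, substitution = substitution,
                 write_member_matrix = write_member_matrix),
            class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Returns (rather than raises) the list of violations so callers can
#' report them all at once; an empty character vector means the
#' configuration is valid.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of violation messages (empty when ok).
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!is.null(config$bandwidth) && config$bandwidth <= 0)
    add("bandwidth: must be positive (or NULL for Silverman's rule)")
  if (config$density_quantile < 0 || config$density_quantile >= 1)
    add("density_quantile: must lie in [0, 1)")
  if (config$lr <= 0) add("lr: must be positive")
  if (config$bag_fraction <= 0 || config$bag_fraction > 1)
    add("bag_fraction: must lie in (0, 1]")
  if (config$folds < 2) add("folds: must be >= 2")
  if (config$holdout <= 0 || config$holdout > 0.5)
    add("holdout: must lie in (0, 0.5]")
  if (config$n_sims < 2) add("n_sims: must be >= 2")
  if (config$tc < 1) add("tc: must be >= 1")
  if (!is.null(config$n_trees) && config$n_trees < 1)
    add("n_trees: must be >= 1 when fixed")
  unknown <- setdiff(config$substitution, predictor_names())
  if (length(unknown))
    add(paste0("substitution: unknown predictor(s) ",
               paste(unknown, collapse = ", ")))
  rs <- config$riverscape
  if (rs$n_outlets > rs$n_reaches)
    add("riverscape: n_outlets exceeds n_reaches")
  if (rs$conversion_fraction < 0 || rs$conversion_fraction > 1)
    add("riverscape: conversion_fraction must lie in [0, 1]")
  if (rs$refuge_style == "reserves" &&
      (rs$refuge_fraction <= 0 || rs$refuge_fraction > 1))
    add("riverscape: refuge_fraction must lie in (0, 1]")
  if (rs$refuge_style == "reserves" &&
      (rs$refuge_p_min < 0 || rs$refuge_p_min >= 1))
    add("riverscape: refuge_p_min must lie in [0, 1)")
  if (!"(Intercept)" %in% names(rs$coefficients))
    add("riverscape: coefficients must include an (Intercept)")
  if (rs$viability_threshold < 0 || rs$viability_threshold >= 1)
    add("riverscape: viability_threshold must lie in [0, 1)")
  v
}

#' Configuration for the null (no-degradation) validation experiment
#'
#' A pipeline configuration under which both drivers are absent, so the
#' estimated partition should be approximately 0/0: no land conversion
#' (identical epochs) and no predation filter.  The experiment must hold
#' the estimator inside its operating assumptions, which the default
#' species would violate once degradation is switched off (it would
#' occupy most of the network, making equal background sampling
#' impossible and saturating surveys unattainable).  The null species is
#' therefore sharply range-restricted (occupancy coefficients scaled by
#' 48, intercept -365) with a 0.5 viability threshold so occupancy is
#' truly binary -- marginal, rarely-occupied reaches would otherwise
#' accumulate presence records over an intensive survey and read as
#' phantom habitat.  Survey effort (10,000 records) near-exhaustively
#' covers the occupied range, the background constraint is open
#' (`density_quantile = 0`, matching the network-wide survey), and the
#' learning rate is 0.02 so the boosting link saturates within the tree
#' budget.
#'
#' @param n_sims Ensemble members for the null run.
#' @return A [pipeline_config()].
#' @export
null_pipeline_config <- function(n_sims = 20) {
  co <- riverscape_config()$coefficients * 48
  co[["(Intercept)"]] <- -365
  pipeline_config(
    riverscape = riverscape_config(conversion_fraction = 0,
                                   coefficients = co,
                                   viability_threshold = 0.5,
                                   refuge_fraction = 1, refuge_p_min = 0,
                                   n_records = 10000),
    regime = "converted", n_sims = n_sims, lr = 0.02, max_trees = 2000,
    density_quantile = 0)
}

#' Run the full simulate-sample-fit-predict-exdet-partition pipeline
#'
#' Executes every stage on a synthetic riverscape: network and paired
#' predictor generation, ground-truth occupancy and presence simulation,
#' kernel-constrained background sampling, cross-validated BRT fitting and
#' the bootstrap ensemble, scenario prediction (potential contemporary,
#' potential pre-human, observed contemporary), ExDet extrapolation
#' screening, effective-habitat computation and the driver partition with
#' its ground-truth recovery report.  All stage seeds derive from the
#' master seed, so a stored configuration plus seed reproduces the run
#' exactly.
#'
#' @param config A [pipeline_config()].
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, every stage output is
#'   written there as plain CSV (plus the serialized ensemble, a JSON
#'   partition report, and a run log with per-stage timings and seeds).
#' @return A `pipeline_result` list with all stage objects: `net`, `pair`,
#'   `truth`, `presences`, `train`, `cv`, `ensemble`, `predictions`,
#'   `exdet`, `extrapolation`, `eh`, `partition`, `recovery`, `seeds`,
#'   `timings`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = NULL) {
  violations <- validate_config(config)
  if (length(violations))
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))

  seeds <- list(network = seed + 1L, predictors = seed + 2L,
                refuges = seed + 3L, presences = seed + 4L,
                background = seed + 5L, cv = seed + 6L,
                ensemble = seed + 7L)
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  rs <- config$riverscape

  net <- clock("simulate_network",
               generate_network(rs$n_reaches, rs$n_outlets,
                                rs$mean_length_m, rs$length_cv,
                                seed = seeds$network))
  pair <- clock("simulate_predictors",
                generate_predictors(net, rs, seed = seeds$predictors))
  truth <- clock("occupancy_truth",
                 occupancy_truth(net, pair, rs, seed = seeds$refuges))
  presences <- clock("simulate_presences",
                     simulate_presences(truth, config$regime,
                                        n_records = rs$n_records,
                                        seed = seeds$presences))
  train <- clock("sample_background", {
    surface <- kernel_density_surface(
      cbind(net$x, net$y)[match(presences, net$reach_id), , drop = FALSE],
      cbind(net$x, net$y), bandwidth = config$bandwidth)
    frame <- select_background(presences, net, surface,
                               config$density_quantile,
                               seed = seeds$background)
    build_training_set(frame, pair$contemporary)
  })

  cv <- NULL
  n_trees <- config$n_trees
  if (is.null(n_trees)) {
    cv <- clock("cv_tree_selection",
                cv_optimal_ntrees(train, tc = config$tc, lr = config$lr,
                                  bag_fraction = config$bag_fraction,
                                  folds = config$folds, step = config$step,
                                  max_trees = config$max_trees,
                                  min_node = config$min_node,
                                  patience = config$patience,
                                  seed = seeds$cv))
    n_trees <- cv$optimal_trees
  }
  ensemble <- clock("fit_ensemble",
                    fit_ensemble(train, n_sims = config$n_sims,
                                 holdout = config$holdout, tc = config$tc,
                                 lr = config$lr,
                                 bag_fraction = config$bag_fraction,
                                 n_trees = n_trees,
                                 min_node = config$min_node,
                                 seed = seeds$ensemble))

  specs <- list(scenario_spec("potential_contemporary"),
                scenario_spec("potential_prehuman"),
                scenario_spec("observed_contemporary",
                              presences = presences))
  predictions <- clock("predict_scenarios",
                       predict_scenarios(ensemble, pair, specs))

  exdet_res <- clock("exdet", {
    ref <- pair$contemporary[match(presences, pair$contemporary$reach_id),
                             predictor_names()]
    lapply(list(potential_contemporary = pair$contemporary,
                potential_prehuman = apply_scenario(pair,
                                                    config$substitution)),
           function(tab) exdet(ref, tab[predictor_names()]))
  })
  extrapolation <- lapply(exdet_res, percent_extrapolating)

  part <- clock("partition", {
    eh <- lapply(predictions, effective_habitat, net = net)
    partition_drivers(eh$potential_prehuman, eh$potential_contemporary,
                      eh$observed_contemporary)
  })
  eh <- lapply(predictions, effective_habitat, net = net)
  recovery <- recovery_report(part, truth, net)

  result <- structure(list(net = net, pair = pair, truth = truth,
                           presences = presences, train = train, cv = cv,
                           ensemble = ensemble, predictions = predictions,
                           exdet = exdet_res, extrapolation = extrapolation,
                           eh = eh, partition = part, recovery = recovery,
                           n_trees = n_trees, seeds = seeds,
                           timings = timings, config = config, seed = seed),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("rangedrivers pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("  reaches:", nrow(x$net), " presences:", length(x$presences),
      " ensemble:", x$ensemble$n_sims, "members x", x$n_trees, "trees\n")
  aucs <- vapply(x$ensemble$members, `[[`, numeric(1), "auc")
  cat(sprintf("  withheld AUC %.3f +/- %.3f\n", mean(aucs), sd(aucs)))
  for (nm in names(x$eh))
    cat(sprintf("  EH %s: %.0f +/- %.0f km\n", nm, x$eh[[nm]]$mean,
                x$eh[[nm]]$sd))
  print(x$partition)
  cat("  recovery vs truth:\n")
  print(x$recovery)
  invisible(x)
}

#' Write every stage output of a pipeline run to a directory
#'
#' Plain CSV throughout (UTF-8, '.' decimal separator, no row index), a
#' text-serialized ensemble, a JSON partition report and a run log.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(as.data.frame(result$net), "reaches.csv")
  w(result$pair$contemporary, "predictors_contemporary.csv")
  w(result$pair$prehuman, "predictors_prehuman.csv")
  w(data.frame(reach_id = result$presences), "presences.csv")
  w(as.data.frame(result$truth), "truth.csv")
  w(as.data.frame(result$train), "training_set.csv")
  for (nm in names(result$predictions)) {
    pred <- result$predictions[[nm]]
    w(pred$summary, paste0("rlo_", nm, ".csv"))
    if (isTRUE(result$config$write_member_matrix))
      w(data.frame(reach_id = pred$reach_id, pred$rlo),
        paste0("rlo_members_", nm, ".csv"))
  }
  for (nm in names(result$exdet))
    w(cbind(reach_id = result$net$reach_id, result$exdet[[nm]]),
      paste0("exdet_", nm, ".csv"))
  write_ensemble(result$ensemble, file.path(out_dir, "ensemble.txt"))

  report <- list(
    seed = result$seed,
    n_reaches = nrow(result$net),
    n_presences = length(result$presences),
    n_sims = result$ensemble$n_sims,
    n_trees = result$n_trees,
    eh_km = lapply(result$eh, function(e) list(mean = e$mean, sd = e$sd)),
    habitat_loss_pct = list(mean = unname(result$partition$habitat["mean"]),
                            sd = unname(result$partition$habitat["sd"])),
    predation_loss_pct = list(
      mean = unname(result$partition$predation["mean"]),
      sd = unname(result$partition$predation["sd"])),
    habitat_loss_pct_ratio_of_means =
      result$partition$habitat_ratio_of_means,
    predation_loss_pct_ratio_of_means =
      result$partition$predation_ratio_of_means,
    extrapolation = result$extrapolation,
    recovery = result$recovery,
    seeds = result$seeds)
  jsonlite::write_json(report, file.path(out_dir, "partition_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log <- c(sprintf("rangedrivers run, master seed %d", result$seed),
           sprintf("stage %-20s %8.2f s", names(result$timings),
                   unlist(result$timings)),
           sprintf("stage seeds: %s",
                   paste(names(result$seeds), unlist(result$seeds),
                         sep = "=", collapse = " ")))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
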