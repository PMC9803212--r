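#' Gaussian kernel density of presence locations at reach midpoints
#'
#' Evaluates an isotropic bivariate Gaussian kernel density estimate of the
#' presence point pattern at arbitrary evaluation points (normally every
#' reach midpoint).  Used to delimit the geographically constrained area
#' from which background ("pseudo-absence") reaches are drawn, so that
#' background points come from the landscape actually surveyed rather than
#' the whole network.
#'
#' @param presence_coords Two-column matrix (x, y) of presence midpoints.
#' @param eval_coords Two-column matrix of evaluation points.
#' @param bandwidth Positive kernel standard deviation in coordinate units;
#'   default is Silverman's rule-of-thumb averaged over the two axes.
#' @return A list of class `density_surface`: `density` (one non-negative
#'   value per evaluation point, integrating to ~1 over the plane) and
#'   `bandwidth`.
#' @export
kernel_density_surface <- function(presence_coords, eval_coords,
                                   bandwidth = NULL) {
  presence_coords <- as.matrix(presence_coords)
  eval_coords <- as.matrix(eval_coords)
  if (nrow(presence_coords) < 1) stop("at least one presence point required")
  if (is.null(bandwidth)) {
    bandwidth <- mean(c(bw.nrd0(presence_coords[, 1]),
                        bw.nrd0(presence_coords[, 2])))
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")

  h2 <- bandwidth^2
  norm <- 1 / (2 * pi * h2 * nrow(presence_coords))
  dens <- numeric(nrow(eval_coords))
  # chunk the evaluation points to bound the distance-matrix size
  chunk <- max(1L, floor(2e6 / nrow(presence_coords)))
  starts <- seq(1L, nrow(eval_coords), by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, nrow(eval_coords))
    dx <- outer(eval_coords[s:e, 1], presence_coords[, 1], "-")
    dy <- outer(eval_coords[s:e, 2], presence_coords[, 2], "-")
    dens[s:e] <- norm * rowSums(exp(-(dx^2 + dy^2) / (2 * h2)))
  }
  structure(list(density = dens, bandwidth = bandwidth),
            class = "density_surface")
}

#' Select background reaches and assemble the model-fitting dataset
#'
#' Draws exactly as many background reaches as there are presence reaches
#' (equal presence/background weighting for machine-learning presence-only
#' models), uniformly without replacement from the geographically
#' constrained area: non-presence reaches whose presence-kernel density is
#' at or above the `density_quantile` quantile of the density observed at
#' the presence reaches themselves.  Background reaches are treated as
#' absences (response 0).
#'
#' @param presences Integer vector of presence `reach_id`s.
#' @param net A `river_network` (supplies reach ids and midpoints).
#' @param surface A `density_surface` evaluated at every reach of `net`,
#'   or `NULL` to compute one with the default bandwidth.
#' @param density_quantile Quantile (in `[0, 1)`) of density at presence
#'   reaches used as the eligibility threshold; 0 keeps every reach with
#'   density at least the minimum seen at a presence.
#' @param seed Integer seed for the uniform draw.
#' @return Data frame of class `training_frame` with columns `reach_id` and
#'   `response` (1 = presence, 0 = background).
#' @export
select_background <- function(presences, net, surface = NULL,
                              density_quantile = 0.05, seed = 1) {
  if (density_quantile < 0 || density_quantile >= 1)
    stop("density_quantile must lie in [0, 1)")
  if (!length(presences)) stop("no presence reaches supplied")
  if (!all(presences %in% net$reach_id))
    stop("presences contain reach ids not in the network")
  pres_idx <- match(presences, net$reach_id)
  if (is.null(surface)) {
    surface <- kernel_density_surface(
      cbind(net$x, net$y)[pres_idx, , drop = FALSE], cbind(net$x, net$y))
  }
  dens <- surface$density
  if (length(dens) != nrow(net))
    stop("density surface is not aligned with the network")

  thr <- quantile(dens[pres_idx], density_quantile, names = FALSE)
  eligible <- setdiff(net$reach_id[dens >= thr], presences)
  n_pres <- length(presences)
  if (length(eligible) < n_pres)
    stop("insufficient eligible background reaches: need ", n_pres,
         ", only ", length(eligible),
         " non-presence reaches meet the density threshold ",
         "(shortfall ", n_pres - length(eligible), ")")
  set.seed(seed)
  background <- sample(eligible, n_pres)

  out <- data.frame(reach_id = c(presences, background),
                    response = rep(c(1L, 0L), each = n_pres))
  class(out) <- c("training_frame", "data.frame")
  out
}

#' Attach predictor values to a presence/background frame
#'
#' @param frame A `training_frame` from [select_background()].
#' @param predictors A predictor table (`reach_id` + 17 predictors),
#'   normally the contemporary epoch.
#' @return The frame with the 17 predictor columns appended, class
#'   `training_set`.
#' @export
build_training_set <- function(frame, predictors) {
  idx <- match(frame$reach_id, predictors$reach_id)
  if (anyNA(idx)) stop("training frame contains reaches without predictors")
  out <- cbind(frame, predictors[idx, predictor_names(), drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("training_set", "data.frame")
  out
}
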