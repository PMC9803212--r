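# Extrapolation detection (ExDet): where are model predictions made in
# environmental conditions unlike those at the reference (presence)
# reaches?  NT1 <= 0 measures univariate range overshoot, NT2 >= 0
# (normalized Mahalanobis distance) measures novel covariate combinations
# within the univariate ranges.

#' Univariate extrapolation (NT1)
#'
#' For each projection point and covariate j, the univariate dissimilarity
#' is `UD_ij = min(p_ij - min_j, max_j - p_ij, 0) / (max_j - min_j)`
#' (0 inside the reference range, negative outside, scaled by the range);
#' NT1 is the sum over covariates.  NT1 = 0 means the point is inside
#' every reference range.
#'
#' @param reference Matrix/data frame of covariates at reference
#'   (presence) points.
#' @param projection Matrix/data frame of covariates at projection points
#'   (same columns).
#' @return List: `nt1` (per-point sum, <= 0) and `ud` (point x covariate
#'   matrix of dissimilarities).
#' @export
nt1 <- function(reference, projection) {
  z <- .exdet_align(reference, projection)
  lo <- apply(z$ref, 2, min)
  hi <- apply(z$ref, 2, max)
  rng <- hi - lo
  ud <- sweep(pmin(sweep(z$proj, 2, lo), sweep(-z$proj, 2, -hi)), 2, rng, "/")
  ud <- pmin(ud, 0)
  list(nt1 = rowSums(ud), ud = ud)
}

#' Combinational novelty (NT2)
#'
#' Squared Mahalanobis distance of each projection point from the
#' reference mean (reference covariance, n-1 normalization), divided by
#' the maximum such distance over the reference points themselves.  Values
#' <= 1 are within the reference cloud's spread; values > 1 are novel
#' covariate combinations.  A singular covariance is ridge-regularized
#' with a logged warning.
#'
#' @inheritParams nt1
#' @return Numeric vector of NT2 values (>= 0).
#' @export
nt2 <- function(reference, projection) {
  z <- .exdet_align(reference, projection)
  if (nrow(z$ref) <= ncol(z$ref))
    stop("NT2 needs more reference rows than covariates")
  mu <- colMeans(z$ref)
  S <- cov(z$ref)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok) {
    eps <- 1e-8 * sum(diag(S)) / ncol(S)
    warning("singular reference covariance; ridge-regularizing with eps = ",
            signif(eps, 3))
    S <- S + diag(eps, ncol(S))
  }
  d_proj <- mahalanobis(z$proj, mu, S)
  d_ref <- mahalanobis(z$ref, mu, S)
  d_proj / max(d_ref)
}

#' Full ExDet analysis of a projection table
#'
#' Combines NT1 and NT2 into the single ExDet value (NT1 where NT1 < 0,
#' otherwise NT2: negative = univariate novelty, 0-1 = analogue
#' conditions, > 1 = combinational novelty) and identifies the most
#' influential covariate (MIC) for every novel point: the covariate with
#' the most negative univariate dissimilarity for NT1-novel points, and
#' the covariate whose removal most reduces the Mahalanobis distance for
#' NT2-novel points; `"none"` at analogue points.
#'
#' Covariates with zero range at the reference points cannot contribute
#' and are dropped with a warning.
#'
#' @inheritParams nt1
#' @return An `exdet_result` data frame: `nt1`, `nt2`, `exdet`, `mic`.
#' @export
exdet <- function(reference, projection) {
  r1 <- nt1(reference, projection)
  r2 <- nt2(reference, projection)
  combined <- exdet_combined(r1$nt1, r2)

  mic <- rep("none", length(combined))
  uni <- which(combined < 0)
  if (length(uni)) {
    cols <- colnames(r1$ud)
    mic[uni] <- cols[apply(r1$ud[uni, , drop = FALSE], 1, which.min)]
  }
  comb <- which(combined > 1)
  if (length(comb))
    mic[comb] <- .nt2_mic(reference, projection, comb)

  out <- data.frame(nt1 = r1$nt1, nt2 = r2, exdet = combined, mic = mic,
                    stringsAsFactors = FALSE)
  class(out) <- c("exdet_result", "data.frame")
  out
}

#' Combine NT1 and NT2 into the ExDet value
#'
#' @param nt1 Per-point NT1 (<= 0).
#' @param nt2 Per-point NT2 (>= 0).
#' @return NT1 where NT1 < 0, else NT2.
#' @export
exdet_combined <- function(nt1, nt2) {
  if (length(nt1) != length(nt2)) stop("nt1 and nt2 must be aligned")
  ifelse(nt1 < 0, nt1, nt2)
}

# MIC for NT2-novel points: leave-one-covariate-out reduction in
# Mahalanobis distance.
.nt2_mic <- function(reference, projection, rows) {
  z <- .exdet_align(reference, projection)
  mu <- colMeans(z$ref)
  S <- cov(z$ref)
  full <- mahalanobis(z$proj[rows, , drop = FALSE], mu, S)
  k <- ncol(z$ref)
  drop_d <- matrix(NA_real_, length(rows), k)
  for (j in seq_len(k)) {
    Sj <- S[-j, -j, drop = FALSE]
    drop_d[, j] <- mahalanobis(z$proj[rows, -j, drop = FALSE], mu[-j], Sj)
  }
  # largest reduction = smallest remaining distance
  colnames(z$ref)[apply(full - drop_d, 1, which.max)]
}

#' Percentage of projection points where the model extrapolates
#'
#' @param result An `exdet_result`.
#' @return List with `total`, `univariate` (`exdet < 0`) and
#'   `combinational` (`exdet > 1`) percentages; the parts sum to the
#'   total.
#' @export
percent_extrapolating <- function(result) {
  n <- nrow(result)
  uni <- 100 * sum(result$exdet < 0) / n
  comb <- 100 * sum(result$exdet > 1) / n
  list(total = uni + comb, univariate = uni, combinational = comb)
}

# Align reference and projection matrices, dropping zero-range covariates.
.exdet_align <- function(reference, projection) {
  reference <- as.matrix(as.data.frame(reference))
  projection <- as.matrix(as.data.frame(projection))
  common <- intersect(colnames(reference), colnames(projection))
  if (!length(common)) stop("reference and projection share no covariates")
  if (nrow(reference) < 2) stop("reference needs at least two rows")
  reference <- reference[, common, drop = FALSE]
  projection <- projection[, common, drop = FALSE]
  rng <- apply(reference, 2, function(v) diff(range(v)))
  if (any(rng == 0)) {
    warning("dropping zero-range reference covariate(s): ",
            paste(common[rng == 0], collapse = ", "))
    reference <- reference[, rng > 0, drop = FALSE]
    projection <- projection[, rng > 0, drop = FALSE]
  }
  list(ref = reference, proj = projection)
}
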