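#' Generate a synthetic branching river network
#'
#' Builds a directed forest of reaches (confluence-to-confluence segments)
#' by random recursive attachment: the first `n_outlets` reaches are outlet
#' (root) reaches of independent catchments, and every subsequent reach
#' attaches upstream of a uniformly chosen existing reach.  This yields the
#' branching confluence trees typical of a digital river network, where the
#' average reach is about 700 m long.
#'
#' Reach lengths are log-normal with the requested mean and a coefficient of
#' variation of `length_cv`.  Midpoint coordinates are laid out by a spatial
#' random walk away from each outlet, so headwater reaches of one catchment
#' are geographically clustered -- a property the kernel-density background
#' constraint downstream of this generator relies on.
#'
#' @param n_reaches Total number of reaches (positive integer).
#' @param n_outlets Number of independent catchments; each contributes one
#'   outlet reach whose `downstream_id` is `NA`.
#' @param mean_length_m Mean reach length in metres (default 700).
#' @param length_cv Coefficient of variation of reach lengths (default 0.5).
#' @param seed Integer seed; the network is deterministic given the seed.
#' @return A `river_network`: a data frame with columns `reach_id`,
#'   `downstream_id` (`NA` at outlets), `length_m`, `x`, `y` (planar
#'   midpoint coordinates in kilometres).
#' @export
generate_network <- function(n_reaches, n_outlets = 1, mean_length_m = 700,
                             length_cv = 0.5, seed = 1) {
  if (n_reaches < 1) stop("n_reaches must be a positive integer")
  if (n_outlets < 1) stop("n_outlets must be a positive integer")
  if (n_outlets > n_reaches)
    stop("n_outlets (", n_outlets, ") exceeds n_reaches (", n_reaches, ")")
  if (mean_length_m <= 0) stop("mean_length_m must be positive")
  set.seed(seed)

  downstream <- rep(NA_integer_, n_reaches)
  if (n_reaches > n_outlets) {
    for (i in seq(n_outlets + 1L, n_reaches)) {
      downstream[i] <- sample.int(i - 1L, 1L)
    }
  }

  # log-normal lengths with the requested mean and CV
  sdlog <- sqrt(log(1 + length_cv^2))
  meanlog <- log(mean_length_m) - sdlog^2 / 2
  length_m <- rlnorm(n_reaches, meanlog, sdlog)

  # outlets scattered over a square whose side scales with network size;
  # children drift upstream from their parent (km units)
  side <- max(5, sqrt(n_reaches) * mean_length_m / 1000)
  x <- y <- numeric(n_reaches)
  x[seq_len(n_outlets)] <- runif(n_outlets, 0, side)
  y[seq_len(n_outlets)] <- runif(n_outlets, 0, side)
  step_sd <- mean_length_m / 1000
  if (n_reaches > n_outlets) {
    for (i in seq(n_outlets + 1L, n_reaches)) {
      p <- downstream[i]
      x[i] <- x[p] + rnorm(1, 0, step_sd)
      y[i] <- y[p] + rnorm(1, 0, step_sd)
    }
  }

  net <- data.frame(reach_id = seq_len(n_reaches),
                    downstream_id = downstream,
                    length_m = length_m, x = x, y = y)
  class(net) <- c("river_network", "data.frame")
  net
}

#' Validate the structural invariants of a river network
#'
#' Checks that reach ids are unique, every non-missing `downstream_id`
#' exists, following downstream links always terminates at an outlet (no
#' cycles), and all lengths are positive.
#'
#' @param net A `river_network` data frame.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_network <- function(net) {
  req <- c("reach_id", "downstream_id", "length_m", "x", "y")
  miss <- setdiff(req, names(net))
  if (length(miss)) stop("network is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(net$reach_id)) stop("reach_id values are not unique")
  if (any(net$length_m <= 0)) stop("all reach lengths must be positive")
  ds <- net$downstream_id
  known <- !is.na(ds)
  if (!all(ds[known] %in% net$reach_id))
    stop("downstream_id refers to unknown reaches")
  # cycle check: iteratively peel reaches whose downstream path is resolved
  idx <- match(ds, net$reach_id)
  n <- nrow(net)
  depth <- rep(NA_real_, n)
  depth[is.na(idx)] <- 0
  repeat {
    todo <- which(is.na(depth) & !is.na(depth[idx]))
    if (!length(todo)) break
    depth[todo] <- depth[idx[todo]] + 1
  }
  if (anyNA(depth))
    stop("network contains a cycle: some reaches never reach an outlet")
  invisible(TRUE)
}

#' Number of connected components (catchments) of a network
#'
#' In a forest every component contains exactly one outlet, so this equals
#' the number of reaches with no downstream neighbour.
#'
#' @param net A `river_network`.
#' @return Integer count of outlets/components.
#' @export
n_outlets <- function(net) sum(is.na(net$downstream_id))

# Internal: positional index of each reach's downstream reach (NA at outlets).
.downstream_index <- function(net) match(net$downstream_id, net$reach_id)

# Internal: reaches ordered so that every reach appears before its
# downstream neighbour (headwaters first).  Accumulating over this order
# propagates upstream sums toward the outlets in O(n).
.upstream_first_order <- function(net) {
  idx <- .downstream_index(net)
  depth <- rep(NA_integer_, nrow(net))   # reach count to the outlet
  depth[is.na(idx)] <- 0L
  repeat {
    todo <- which(is.na(depth) & !is.na(depth[idx]))
    if (!length(todo)) break
    depth[todo] <- depth[idx[todo]] + 1L
  }
  order(depth, decreasing = TRUE)
}

# Internal: per-reach distance to its outlet along the flow path, in km.
.distance_to_outlet_km <- function(net) {
  idx <- .downstream_index(net)
  d <- rep(NA_real_, nrow(net))
  d[is.na(idx)] <- net$length_m[is.na(idx)] / 2000
  repeat {
    todo <- which(is.na(d) & !is.na(d[idx]))
    if (!length(todo)) break
    d[todo] <- d[idx[todo]] + net$length_m[todo] / 1000
  }
  d
}

# Internal: accumulate a per-reach quantity over the full upstream reach set
# (including the reach itself).  Returns the per-reach upstream sums.
.upstream_sum <- function(net, values) {
  idx <- .downstream_index(net)
  acc <- values
  for (i in .upstream_first_order(net)) {
    if (!is.na(idx[i])) acc[idx[i]] <- acc[idx[i]] + acc[i]
  }
  acc
}

# Internal: Strahler stream order, capped at `cap`.
.strahler_order <- function(net, cap = 8L) {
  idx <- .downstream_index(net)
  n <- nrow(net)
  children <- split(seq_len(n)[!is.na(idx)], idx[!is.na(idx)])
  ord <- integer(n)
  for (i in .upstream_first_order(net)) {
    kids <- children[[as.character(i)]]
    if (is.null(kids)) {
      ord[i] <- 1L
    } else {
      ko <- ord[kids]
      m <- max(ko)
      ord[i] <- if (sum(ko == m) > 1L) m + 1L else m
    }
  }
  pmin(ord, cap)
}
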