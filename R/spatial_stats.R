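# Coordinate accessor: accepts a data.frame with x/y columns or a 2-col matrix.
coords <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) >= 2)
    list(x = p[, 1], y = p[, 2], n = nrow(p))
  } else {
    stopifnot(all(c("x", "y") %in% names(p)))
    list(x = p$x, y = p$y, n = nrow(p))
  }
}

# Squared cross-distance matrix (chunked over ref rows to bound memory).
cross_dist2 <- function(rx, ry, tx, ty) {
  outer(rx, tx, "-")^2 + outer(ry, ty, "-")^2
}

# Apply f(d2_chunk, ref_row_indices) over row chunks of the cross-distance
# matrix; chunk size keeps each matrix under ~8e6 doubles.
chunked_rows <- function(rx, ry, tx, ty, f) {
  n <- length(rx)
  chunk <- max(1L, floor(8e6 / max(length(tx), 1L)))
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, n)
    f(cross_dist2(rx[idx], ry[idx], tx, ty), idx)
  }
}

#' Nearest-neighbor distances between two cell sets
#'
#' For every reference cell, the Euclidean distance to the closest target
#' cell. When reference and target are the same set (e.g. T cell to nearest
#' T cell), pass `exclude_self = TRUE` so a cell is not its own neighbor;
#' `ref` and `target` must then be the identical set in the same row order.
#'
#' @param ref,target Data frames with `x`, `y` columns (um), or 2-column
#'   matrices.
#' @param exclude_self Exclude the i-i pair when the two sets coincide.
#' @return Numeric vector, one distance per reference cell; `NULL` (a
#'   missing-metric signal, not an error) if there is no eligible target.
#' @examples
#' nn_distances(data.frame(x = 0, y = 0), data.frame(x = c(3, 10), y = c(4, 0)))
#' @export
nn_distances <- function(ref, target, exclude_self = FALSE) {
  r <- coords(ref); t <- coords(target)
  if (r$n == 0) return(numeric(0))
  if (t$n == 0 || (exclude_self && t$n == 1)) return(NULL)
  if (exclude_self && r$n != t$n) {
    stop("exclude_self requires ref and target to be the same set")
  }
  out <- numeric(r$n)
  chunked_rows(r$x, r$y, t$x, t$y, function(d2, idx) {
    if (exclude_self) d2[cbind(seq_along(idx), idx)] <- Inf
    jmin <- max.col(-d2, ties.method = "first")
    out[idx] <<- sqrt(d2[cbind(seq_len(nrow(d2)), jmin)])
  })
  out
}

#' Engagement of reference cells with a target type
#'
#' A reference cell is *engaged* when at least one target cell lies within
#' `radius` um center-to-center (boundary inclusive). Returns the percent of
#' engaged reference cells and, among engaged cells only, the mean number of
#' simultaneous target contacts.
#'
#' @inheritParams nn_distances
#' @param radius Contact radius (um); default 40.
#' @return List with `engaged_pct`, `mean_contacts` (NA when no cell is
#'   engaged), `n_engaged`. An empty target yields `engaged_pct = 0`,
#'   `mean_contacts = NA`.
#' @export
engagement_stats <- function(ref, target, radius = 40, exclude_self = FALSE) {
  r <- coords(ref); t <- coords(target)
  stopifnot(r$n >= 1, radius > 0)
  if (t$n == 0 || (exclude_self && t$n == 1)) {
    return(list(engaged_pct = 0, mean_contacts = NA_real_, n_engaged = 0L))
  }
  if (exclude_self && r$n != t$n) {
    stop("exclude_self requires ref and target to be the same set")
  }
  contacts <- integer(r$n)
  r2 <- radius^2
  chunked_rows(r$x, r$y, t$x, t$y, function(d2, idx) {
    if (exclude_self) d2[cbind(seq_along(idx), idx)] <- Inf
    contacts[idx] <<- as.integer(rowSums(d2 <= r2))
  })
  engaged <- contacts >= 1L
  list(
    engaged_pct = 100 * mean(engaged),
    mean_contacts = if (any(engaged)) mean(contacts[engaged]) else NA_real_,
    n_engaged = sum(engaged)
  )
}

#' Kaplan-Meier estimate of a distance distribution under boundary censoring
#'
#' Product-limit estimator of `P(D <= r)` from nearest-neighbor distances
#' `d` observed inside a bounded window: when a cell's boundary distance
#' `cens` is smaller than its observed nearest-neighbor distance, the true
#' nearest neighbor may lie outside the window, so the observation is treated
#' as right-censored at `cens`. This removes the downward bias of the naive
#' empirical CDF near the core edge.
#'
#' @param d Observed nearest-neighbor distances (um).
#' @param cens Censoring distances (um), typically [edge_distance()] of the
#'   reference cells; same length as `d`.
#' @param r_grid Distances at which to evaluate the CDF.
#' @return Estimated CDF values in `[0, 1]`, nondecreasing along `r_grid`.
#' @export
km_distance_cdf <- function(d, cens, r_grid) {
  stopifnot(length(d) == length(cens), length(d) >= 1,
            all(is.finite(d)), all(is.finite(cens)), all(d >= 0), all(cens >= 0))
  t_obs <- pmin(d, cens)
  event <- d <= cens
  if (!any(event)) return(rep(0, length(r_grid)))
  ord <- order(t_obs)
  t_sorted <- t_obs[ord]
  ev_sorted <- event[ord]
  evt <- t_sorted[ev_sorted]
  ts <- unique(evt)
  n_event <- tabulate(match(evt, ts))
  n_risk <- length(t_obs) - findInterval(ts, t_sorted, left.open = TRUE)
  surv <- cumprod(1 - n_event / n_risk)
  idx <- findInterval(r_grid, ts)
  g <- ifelse(idx == 0, 0, 1 - surv[pmax(idx, 1L)])
  pmin(pmax(g, 0), 1)
}

g_curve <- function(r, g, ref_phenotype = NA, target_phenotype = NA,
                    n_ref = NA_integer_, n_target = NA_integer_,
                    correction = "km") {
  stopifnot(length(r) == length(g), !is.unsorted(r, strictly = TRUE), r[1] >= 0)
  structure(
    list(r = r, g = g, ref_phenotype = ref_phenotype,
         target_phenotype = target_phenotype,
         n_ref = n_ref, n_target = n_target, correction = correction),
    class = "g_curve"
  )
}

#' @export
print.g_curve <- function(x, ...) {
  cat(sprintf("<g_curve> %s -> %s (%s), n_ref=%s n_target=%s, r in [%g, %g] um\n",
              x$ref_phenotype, x$target_phenotype, x$correction,
              x$n_ref, x$n_target, min(x$r), max(x$r)))
  invisible(x)
}

#' Cross-type nearest-neighbor G-function with Kaplan-Meier edge correction
#'
#' Estimates `G(r) = P(nearest target-type cell within r of a reference-type
#' cell)`. Each reference cell contributes its nearest-target distance,
#' censored at its distance to the window boundary ([km_distance_cdf()]).
#' Under complete spatial randomness of the targets, `G(r)` has the closed
#' form `1 - exp(-lambda * pi * r^2)` ([poisson_g()]); the area under the
#' estimated curve up to 60 um ([curve_auc()]) summarises how fast the two
#' populations mix.
#'
#' @inheritParams nn_distances
#' @param window A `tme_window` containing all reference cells.
#' @param r_grid Evaluation grid (um), strictly increasing from 0; default
#'   0..60 in 1 um steps.
#' @param ref_phenotype,target_phenotype Optional labels carried on the
#'   result.
#' @return A `g_curve`, or `NULL` (missing-metric signal) if either set is
#'   empty.
#' @export
cross_g_km <- function(ref, target, window, r_grid = seq(0, 60, by = 1),
                       exclude_self = FALSE,
                       ref_phenotype = NA, target_phenotype = NA) {
  r <- coords(ref); t <- coords(target)
  if (r$n == 0 || t$n == 0) return(NULL)
  d <- nn_distances(ref, target, exclude_self = exclude_self)
  if (is.null(d)) return(NULL)
  cens <- edge_distance(window, r$x, r$y)
  g <- km_distance_cdf(d, cens, r_grid)
  g_curve(r_grid, g, ref_phenotype, target_phenotype,
          n_ref = r$n, n_target = t$n, correction = "km")
}

#' @describeIn cross_g_km Uncorrected estimator: the empirical CDF of the
#'   observed nearest-neighbor distances, ignoring boundary censoring. Kept
#'   for comparison; biased downward near the core edge.
#' @export
cross_g_ecdf <- function(ref, target, r_grid = seq(0, 60, by = 1),
                         exclude_self = FALSE,
                         ref_phenotype = NA, target_phenotype = NA) {
  r <- coords(ref); t <- coords(target)
  if (r$n == 0 || t$n == 0) return(NULL)
  d <- nn_distances(ref, target, exclude_self = exclude_self)
  if (is.null(d)) return(NULL)
  g <- stats::ecdf(d)(r_grid)
  g_curve(r_grid, g, ref_phenotype, target_phenotype,
          n_ref = r$n, n_target = t$n, correction = "none")
}

#' Theoretical G-function of a homogeneous Poisson process
#'
#' Under complete spatial randomness of the target type with intensity
#' `lambda` (cells per square um), the probability of a target cell within
#' distance `r` of any fixed location is `1 - exp(-lambda * pi * r^2)`.
#'
#' @param lambda Target intensity (um^-2), >= 0.
#' @param r Distance (um), >= 0; vectorised.
#' @return Probability in `[0, 1]`.
#' @examples
#' poisson_g(log(2) / (pi * 60^2), 60)  # 0.5 by construction
#' @export
poisson_g <- function(lambda, r) {
  if (any(lambda < 0) || any(r < 0)) stop("lambda and r must be nonnegative")
  1 - exp(-lambda * pi * r^2)
}

#' Area under a G curve
#'
#' Trapezoidal integral of the curve over `[0, r_max]`; in um, bounded by
#' `r_max` since G is a probability. Higher AUC means the curve rises faster,
#' i.e. stronger mixing of the two cell populations.
#'
#' @param curve A `g_curve`, or a list with numeric `r` and `g`.
#' @param r_max Upper integration limit (um); default 60. The curve's grid
#'   must cover `[0, r_max]`.
#' @return AUC in `[0, r_max]` (um).
#' @export
curve_auc <- function(curve, r_max = 60) {
  r <- curve$r; g <- curve$g
  stopifnot(length(r) == length(g), r_max > 0)
  if (min(r) > 0 || max(r) < r_max) {
    stop("r_grid must cover [0, ", r_max, "]")
  }
  if (max(r) > r_max) {
    g_at <- stats::approx(r, g, xout = r_max)$y
    keep <- r < r_max
    r <- c(r[keep], r_max); g <- c(g[keep], g_at)
  }
  sum(diff(r) * (utils::head(g, -1) + utils::tail(g, -1)) / 2)
}
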