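#' Observation windows for TMA cores
#'
#' A window describes the observed region of a core: a circle (the usual TMA
#' punch, 0.6 mm diameter so 300 um radius) or an axis-aligned rectangle.
#' Distances are in microns throughout.
#'
#' @param cx,cy Circle center (um).
#' @param r Circle radius (um), > 0.
#' @return An object of class `tme_window`.
#' @examples
#' w <- circle_window(0, 0, 300)
#' edge_distance(w, 0, 250)
#' @export
circle_window <- function(cx, cy, r) {
  stopifnot(is.finite(cx), is.finite(cy), is.finite(r), r > 0)
  structure(list(shape = "circle", cx = cx, cy = cy, r = r), class = "tme_window")
}

#' @rdname circle_window
#' @param x0,x1,y0,y1 Rectangle extents (um), `x0 < x1`, `y0 < y1`.
#' @export
rect_window <- function(x0, x1, y0, y1) {
  stopifnot(is.finite(x0), is.finite(x1), is.finite(y0), is.finite(y1),
            x0 < x1, y0 < y1)
  structure(list(shape = "rect", x0 = x0, x1 = x1, y0 = y0, y1 = y1),
            class = "tme_window")
}

#' @export
print.tme_window <- function(x, ...) {
  if (x$shape == "circle") {
    cat(sprintf("<tme_window> circle center (%.1f, %.1f) radius %.1f um\n",
                x$cx, x$cy, x$r))
  } else {
    cat(sprintf("<tme_window> rect [%.1f, %.1f] x [%.1f, %.1f] um\n",
                x$x0, x$x1, x$y0, x$y1))
  }
  invisible(x)
}

#' Distance from points to the window boundary
#'
#' Used as the censoring distance in the Kaplan-Meier edge correction: a
#' nearest neighbor farther away than the boundary could lie outside the
#' observed core and is treated as censored.
#'
#' @param window A [circle_window()] or [rect_window()].
#' @param x,y Point coordinates (um), vectorised.
#' @return Nonnegative distances (um); 0 for points on or outside the boundary.
#' @export
edge_distance <- function(window, x, y) {
  stopifnot(inherits(window, "tme_window"))
  d <- if (window$shape == "circle") {
    window$r - sqrt((x - window$cx)^2 + (y - window$cy)^2)
  } else {
    pmin(x - window$x0, window$x1 - x, y - window$y0, window$y1 - y)
  }
  pmax(d, 0)
}

#' @rdname edge_distance
#' @param tol Numerical slack (um) for boundary membership.
#' @return `in_window()`: logical vector.
#' @export
in_window <- function(window, x, y, tol = 1e-8) {
  stopifnot(inherits(window, "tme_window"))
  if (window$shape == "circle") {
    (x - window$cx)^2 + (y - window$cy)^2 <= (window$r + tol)^2
  } else {
    x >= window$x0 - tol & x <= window$x1 + tol &
      y >= window$y0 - tol & y <= window$y1 + tol
  }
}

#' Infer a circular window from cell coordinates
#'
#' When a cell table carries no window geometry, the core is taken to be a
#' circle of the nominal TMA punch radius centered at the centroid of its
#' cells, expanded just enough to contain every cell.
#'
#' @param x,y Cell coordinates (um).
#' @param radius Nominal core radius (um); default 300 (a 0.6 mm punch).
#' @return A [circle_window()].
#' @export
infer_window <- function(x, y, radius = 300) {
  stopifnot(length(x) >= 1, length(x) == length(y))
  cx <- mean(x); cy <- mean(y)
  need <- max(sqrt((x - cx)^2 + (y - cy)^2))
  circle_window(cx, cy, max(radius, need * (1 + 1e-9)))
}

window_area <- function(window) {
  if (window$shape == "circle") pi * window$r^2
  else (window$x1 - window$x0) * (window$y1 - window$y0)
}
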