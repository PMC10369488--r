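#' Perpendicular distance from a point to a line
#'
#' Distance from `point` to the infinite line through `seg_a` and `seg_b`,
#' computed with the cross-product formula. Degenerate chords
#' (`seg_a == seg_b`) fall back to the Euclidean point distance.
#'
#' @param point,seg_a,seg_b Length-2 numeric `(x, y)` vectors.
#' @return Non-negative distance.
#' @export
perpendicular_distance <- function(point, seg_a, seg_b) {
  perp_dist(point[1], point[2], seg_a[1], seg_a[2], seg_b[1], seg_b[2])
}

# vectorized over (px, py)
perp_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len <- sqrt(dx * dx + dy * dy)
  if (len == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  abs(dx * (py - ay) - dy * (px - ax)) / len
}

#' Ramer-Douglas-Peucker polyline simplification
#'
#' Classic recursive RDP: find the point farthest (perpendicular distance)
#' from the chord between the first and last points; if that maximum
#' distance is strictly larger than `epsilon` the point is kept and the
#' algorithm recurses on the two sub-polylines on either side, otherwise
#' all interior points of the span are dropped. Ties for the farthest point
#' are broken toward the lowest index, so the retained set is
#' deterministic. Endpoints are always retained.
#'
#' @param x,y Numeric coordinate vectors of equal length `>= 2`; `x`
#'   strictly increasing.
#' @param epsilon Tolerance `>= 0` in the polyline's geometric units.
#' @param normalize_x If `TRUE`, rescale `x` to `[0, 1]` before measuring
#'   distances so that the result does not depend on the unit of the
#'   control coordinate; default `FALSE` here (raw geometry), `TRUE` in the
#'   scan/selection layer.
#' @return Sorted integer vector of retained 1-based indices.
#' @export
rdp <- function(x, y, epsilon, normalize_x = FALSE) {
  check_polyline(x, y)
  if (!(is.numeric(epsilon) && length(epsilon) == 1L && epsilon >= 0)) {
    stop("epsilon must be a single value >= 0", call. = FALSE)
  }
  if (normalize_x) x <- rescale01(x)
  n <- length(x)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE

  recurse <- function(i, j) {
    if (j - i < 2L) return(invisible())
    mid <- (i + 1L):(j - 1L)
    d <- perp_dist(x[mid], y[mid], x[i], y[i], x[j], y[j])
    k <- mid[which.max(d)]          # which.max: first maximum -> lowest index
    if (max(d) > epsilon) {
      keep[k] <<- TRUE
      recurse(i, k)
      recurse(k, j)
    }
    invisible()
  }
  recurse(1L, n)
  which(keep)
}

check_polyline <- function(x, y, min_len = 2L) {
  if (length(x) != length(y) || length(x) < min_len) {
    stop(sprintf("polyline needs >= %d (x, y) pairs of equal length", min_len),
         call. = FALSE)
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("polyline coordinates must be finite", call. = FALSE)
  }
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  invisible(TRUE)
}

rescale01 <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Piecewise-linear interpolation of a simplified polyline
#'
#' Evaluates the polyline through the retained points vertically at every
#' original abscissa: eliminated points are projected onto the simplified
#' polyline, which is what turns a geometric tolerance into an energy-unit
#' error measure.
#'
#' @param x,y Original polyline.
#' @param retained Sorted indices from [rdp()]; must include the first and
#'   last points.
#' @return Numeric vector of interpolated `y` at every original `x`
#'   (retained abscissae reproduce their `y` exactly).
#' @export
interpolate_on_retained <- function(x, y, retained) {
  check_polyline(x, y)
  retained <- sort(unique(as.integer(retained)))
  if (!(1L %in% retained) || !(length(x) %in% retained)) {
    stop("retained set must include the first and last points", call. = FALSE)
  }
  stats::approx(x[retained], y[retained], xout = x, method = "linear")$y
}

#' RMSE between a polyline and its simplification
#'
#' Root-mean-square vertical deviation between the original points and the
#' interpolated simplified polyline, averaged over all `M` original points
#' (retained points contribute zero). This converts the unit-less RDP
#' tolerance into an energy-unit accuracy measure.
#'
#' @inheritParams interpolate_on_retained
#' @return Non-negative RMSE in the units of `y`.
#' @export
rdp_rmse <- function(x, y, retained) {
  yhat <- interpolate_on_retained(x, y, retained)
  sqrt(mean((y - yhat)^2))
}

#' Tolerance scan of the RDP simplification
#'
#' Runs RDP over the tolerance grid `{0, step, 2*step, ..., eps_max}`
#' where `eps_max` is the largest perpendicular distance of any point to
#' the chord between the first and last points — the tolerance at which the
#' whole polyline would collapse onto that single chord. Each row records
#' the retained set and the interpolated RMSE, turning the geometric
#' tolerance into an energy-unit accuracy table.
#'
#' @inheritParams rdp
#' @param step Tolerance increment `> 0`; default 0.01 (adequate once `x`
#'   is normalised to `[0, 1]`, the default here).
#' @return An object of class `"rdp_scan"`: data frame with columns
#'   `epsilon`, `n_retained`, `rmse`, plus the list of retained index sets
#'   as attribute `"retained"`.
#' @export
epsilon_scan <- function(x, y, step = 0.01, normalize_x = TRUE) {
  check_polyline(x, y)
  if (!(is.numeric(step) && length(step) == 1L && step > 0)) {
    stop("step must be > 0", call. = FALSE)
  }
  xs <- if (normalize_x) rescale01(x) else x
  n <- length(x)
  eps_max <- if (n == 2L) 0 else {
    max(perp_dist(xs[2:(n - 1)], y[2:(n - 1)], xs[1], y[1], xs[n], y[n]))
  }
  grid <- seq(0, eps_max, by = step)
  if (grid[length(grid)] < eps_max) grid <- c(grid, eps_max)

  retained <- lapply(grid, function(e) rdp(xs, y, e))
  tab <- data.frame(
    epsilon = grid,
    n_retained = vapply(retained, length, integer(1)),
    rmse = vapply(retained, function(r) rdp_rmse(x, y, r), numeric(1))
  )
  structure(tab, class = c("rdp_scan", "data.frame"),
            retained = retained, normalize_x = normalize_x, eps_max = eps_max)
}

#' @export
print.rdp_scan <- function(x, ...) {
  cat(sprintf("RDP tolerance scan: %d rows, eps_max = %.6g%s\n", nrow(x),
              attr(x, "eps_max"),
              if (isTRUE(attr(x, "normalize_x"))) " (x normalised to [0,1])" else ""))
  print.data.frame(utils::head(as.data.frame(x), 12), row.names = FALSE, digits = 5)
  if (nrow(x) > 12) cat(sprintf("  ... %d more rows\n", nrow(x) - 12))
  invisible(x)
}

#' Select a minimal point subset at a target RMSE
#'
#' From the tolerance scan, returns the smallest retained set whose
#' interpolated RMSE does not exceed `rmse_tolerance`, subject to a minimum
#' of 3 points: a simplification consisting of a single straight chord
#' cannot represent the sigmoidal shape of a typical reaction profile, so
#' when only the 2-endpoint set qualifies the farthest interior point is
#' added back and the override is flagged. Ties in retained-set size are
#' resolved toward the smaller tolerance (lower RMSE).
#'
#' @inheritParams epsilon_scan
#' @param rmse_tolerance Maximum acceptable RMSE `>= 0` in the units of `y`.
#' @return An object of class `"rdp_selection"`: list with `retained`
#'   (indices), `epsilon`, `rmse`, `n_retained`, `min3_override` flag, the
#'   convention note `rmse_denominator = "all points"`, and the full `scan`.
#' @export
select_points <- function(x, y, rmse_tolerance, step = 0.01, normalize_x = TRUE) {
  check_polyline(x, y, min_len = 3L)
  if (!(is.numeric(rmse_tolerance) && length(rmse_tolerance) == 1L && rmse_tolerance >= 0)) {
    stop("rmse_tolerance must be >= 0", call. = FALSE)
  }
  scan <- epsilon_scan(x, y, step = step, normalize_x = normalize_x)
  sets <- attr(scan, "retained")
  ok <- scan$rmse <= rmse_tolerance

  min3 <- FALSE
  cand <- which(ok & scan$n_retained >= 3L)
  if (length(cand) > 0L) {
    # smallest set; ties (same size) -> smallest epsilon. Scan rows are in
    # increasing epsilon, so the first row at the minimum size wins.
    best <- cand[which.min(scan$n_retained[cand])]
    retained <- sets[[best]]
    eps <- scan$epsilon[best]; rmse <- scan$rmse[best]
  } else {
    # only chord-like sets meet the tolerance: add back the farthest
    # interior point (lowest index on ties)
    min3 <- TRUE
    best <- which(ok)[1]
    if (is.na(best)) best <- 1L   # unreachable: the eps = 0 row has rmse 0
    xs <- if (normalize_x) rescale01(x) else x
    n <- length(x)
    d <- perp_dist(xs[2:(n - 1)], y[2:(n - 1)], xs[1], y[1], xs[n], y[n])
    far <- which.max(d) + 1L
    retained <- sort(unique(c(sets[[best]], far)))
    eps <- scan$epsilon[best]
    rmse <- rdp_rmse(x, y, retained)
  }

  structure(
    list(retained = retained, epsilon = eps, rmse = rmse,
         n_retained = length(retained), n_total = length(x),
         min3_override = min3,
         rmse_denominator = "all points", scan = scan),
    class = "rdp_selection"
  )
}

#' @export
print.rdp_selection <- function(x, ...) {
  cat(sprintf("RDP selection: %d of %d points at epsilon %.6g (RMSE %.6g)%s\n",
              x$n_retained, x$n_total, x$epsilon, x$rmse,
              if (x$min3_override) "  [minimum-3 override applied]" else ""))
  cat("  retained indices:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}
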