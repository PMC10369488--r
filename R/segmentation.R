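#' Stationary points of a discrete energy profile
#'
#' Scans the finite differences `E[j+1] - E[j]` of the total-energy series
#' and reports every index where their sign changes, plus both endpoints.
#' These are the discrete analogues of minima, maxima and (in an IRC
#' context) transition states: reactant, TS, product. Detection acts on the
#' computed geometries only — no interpolation or smoothing — because the
#' downstream analysis selects among existing geometries.
#'
#' Exact zero differences (plateaus) inherit the preceding trend and never
#' spawn segments of their own; when an extremum is attained over a tie of
#' equal values the first index of the tie is reported.
#'
#' @param e_total Numeric vector of length `M >= 2`.
#' @return Sorted integer vector of 1-based stationary indices, always
#'   containing `1` and `M`.
#' @export
find_stationary_points <- function(e_total) {
  e <- as.numeric(e_total)
  m <- length(e)
  if (m < 2L) stop("need at least 2 points", call. = FALSE)
  sgn <- sign(diff(e))
  nz <- which(sgn != 0)
  if (length(nz) < 2L) return(c(1L, m))            # monotone or constant
  interior <- nz[which(diff(sgn[nz]) != 0)] + 1L   # first index of each extremum
  sort(unique(c(1L, interior, m)))
}

#' Split a PES into segments between stationary points
#'
#' A segment is the portion of the profile between two subsequent
#' stationary points; it is the unit on which REG slopes are computed,
#' because a single strongest term cannot represent a profile that first
#' rises and then falls. Consecutive segments share exactly their boundary
#' index and jointly cover the whole grid.
#'
#' @param x A [reg_dataset()] or a numeric total-energy vector.
#' @return An object of class `"reg_segments"`: data frame with columns
#'   `segment`, `start`, `end` (1-based, inclusive), `direction`
#'   (`"rising"`/`"falling"` by endpoint comparison) and `n_points`.
#'   Segments with fewer than 3 points carry `TRUE` in `too_short`; the
#'   regression layer refuses them.
#' @export
split_segments <- function(x) {
  e <- if (inherits(x, "reg_dataset")) x$e_total else as.numeric(x)
  sp <- find_stationary_points(e)
  k <- length(sp) - 1L
  seg <- data.frame(
    segment = seq_len(k),
    start = sp[-length(sp)],
    end = sp[-1],
    stringsAsFactors = FALSE
  )
  seg$direction <- ifelse(e[seg$end] > e[seg$start], "rising", "falling")
  seg$n_points <- seg$end - seg$start + 1L
  seg$too_short <- seg$n_points < 3L
  structure(seg, class = c("reg_segments", "data.frame"))
}

#' @export
print.reg_segments <- function(x, ...) {
  cat(sprintf("%d PES segment(s):\n", nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
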