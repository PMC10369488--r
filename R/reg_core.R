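#' Mean-translate an energy series over a segment
#'
#' Both the total energy and every partitioned term are translated over
#' their respective means before regression; this makes profiles of very
#' different absolute magnitude comparable and forces the fitted intercept
#' to zero, so the slope alone carries the information.
#'
#' @param series Numeric vector.
#' @param indices Indices of the segment's points (default: all). At least
#'   3 points are required, matching the regression layer's minimum.
#' @return The translated values at `indices`, with mean zero.
#' @export
mean_center <- function(series, indices = seq_along(series)) {
  v <- as.numeric(series)[indices]
  if (length(v) < 3L) stop("segment too short: need >= 3 points", call. = FALSE)
  v - mean(v)
}

#' REG coefficient of one term on one segment
#'
#' The relative energy gradient of term `i` is the ordinary least-squares
#' slope of the mean-translated term energy against the mean-translated
#' total energy over the segment's points:
#' `m_i = cov(E_i, E_tot) / var(E_tot)`.
#' It depends only on the energy values at the segment's geometries, never
#' on the control-coordinate values themselves, so it is invariant under
#' any strictly monotone reparameterisation of `s`.
#'
#' @param term_series,total_series Numeric vectors over the full grid.
#' @param indices Segment point indices (default: all); `>= 3` required.
#' @return The dimensionless slope `m_i`.
#' @export
reg_value <- function(term_series, total_series, indices = seq_along(total_series)) {
  y <- mean_center(term_series, indices)
  x <- mean_center(total_series, indices)
  vx <- sum(x * x)
  if (vx == 0) {
    stop("degenerate segment: total energy has zero variance", call. = FALSE)
  }
  sum(x * y) / vx
}

#' Pearson correlation of one term with the total energy on one segment
#'
#' The error metric attached to every REG coefficient: terms whose linear
#' relationship with the total energy breaks down (low `|R|`) should not be
#' interpreted through their slope.
#'
#' @inheritParams reg_value
#' @return `R_i` in `[-1, 1]`.
#' @export
reg_pearson <- function(term_series, total_series, indices = seq_along(total_series)) {
  y <- mean_center(term_series, indices)
  x <- mean_center(total_series, indices)
  sx <- sqrt(sum(x * x)); sy <- sqrt(sum(y * y))
  if (sx == 0 || sy == 0) {
    stop("Pearson correlation undefined: a series has zero variance on the segment",
         call. = FALSE)
  }
  r <- sum(x * y) / (sx * sy)
  min(1, max(-1, r))
}

#' REG analysis of one segment
#'
#' Computes the (REG, Pearson) pair for every term in the dataset over the
#' segment's points and ranks the terms from most positive to most negative
#' REG. Terms with `|R| < r_threshold` are flagged as discarded but kept in
#' the output (so either reporting convention can be reproduced); zero-
#' variance terms get `R = NA` and are flagged likewise. The sum of REG
#' coefficients over all terms is reported as a completeness diagnostic —
#' it equals 1 exactly whenever the decomposition is additive and complete.
#'
#' @param dataset A [reg_dataset()] with at least one term.
#' @param segment One row of [split_segments()] output, or an integer pair
#'   `c(start, end)` of 1-based inclusive indices.
#' @param r_threshold Pearson cutoff in `[0, 1)` below which a term is
#'   flagged; default 0.7.
#' @return An object of class `"reg_result"`: list with `segment`,
#'   `entries` (data frame: `rank`, `label`, `kind`, `reg`, `pearson`,
#'   `discarded`, sorted by REG descending, ties broken by canonical label
#'   order), `r_threshold`, `sum_of_reg` (all terms) and `sum_of_reg_kept`
#'   (surviving terms only).
#' @export
analyze_segment <- function(dataset, segment, r_threshold = 0.7) {
  stopifnot(inherits(dataset, "reg_dataset"))
  if (n_terms(dataset) < 1L) stop("dataset has no terms to analyze", call. = FALSE)
  if (!(is.numeric(r_threshold) && length(r_threshold) == 1L &&
        r_threshold >= 0 && r_threshold < 1)) {
    stop("r_threshold must lie in [0, 1)", call. = FALSE)
  }
  seg <- as_segment_indices(segment, n_points(dataset))
  idx <- seg$start:seg$end
  if (length(idx) < 3L) {
    stop(sprintf("segment [%d, %d] has %d point(s); REG needs >= 3 (2 points always give |R| = 1)",
                 seg$start, seg$end, length(idx)), call. = FALSE)
  }

  tot <- mean_center(dataset$e_total, idx)
  vtot <- sum(tot * tot)
  if (vtot == 0) {
    stop("degenerate segment: total energy has zero variance", call. = FALSE)
  }
  stot <- sqrt(vtot)

  labels <- colnames(dataset$terms)
  reg <- numeric(length(labels)); pearson <- numeric(length(labels))
  for (k in seq_along(labels)) {
    y <- dataset$terms[idx, k]; y <- y - mean(y)
    reg[k] <- sum(tot * y) / vtot
    sy <- sqrt(sum(y * y))
    pearson[k] <- if (sy == 0) NA_real_ else min(1, max(-1, sum(tot * y) / (stot * sy)))
  }
  discarded <- is.na(pearson) | abs(pearson) < r_threshold

  ord <- order(-reg, labels, method = "radix")
  entries <- data.frame(
    label = labels[ord],
    kind = dataset$term_info$kind[match(labels[ord], dataset$term_info$label)],
    reg = reg[ord],
    pearson = pearson[ord],
    discarded = discarded[ord],
    stringsAsFactors = FALSE
  )
  entries$rank <- NA_integer_
  entries$rank[!entries$discarded] <- seq_len(sum(!entries$discarded))
  entries <- entries[, c("rank", "label", "kind", "reg", "pearson", "discarded")]

  structure(
    list(segment = seg, entries = entries, r_threshold = r_threshold,
         sum_of_reg = sum(reg),
         sum_of_reg_kept = sum(reg[!discarded])),
    class = "reg_result"
  )
}

as_segment_indices <- function(segment, m) {
  if (is.data.frame(segment)) {
    stopifnot(nrow(segment) == 1L, all(c("start", "end") %in% names(segment)))
    out <- list(start = as.integer(segment$start), end = as.integer(segment$end),
                direction = if ("direction" %in% names(segment)) segment$direction else NA_character_)
  } else if (is.numeric(segment) && length(segment) == 2L) {
    out <- list(start = as.integer(segment[1]), end = as.integer(segment[2]),
                direction = NA_character_)
  } else {
    stop("segment must be a one-row segment table or c(start, end)", call. = FALSE)
  }
  if (out$start < 1L || out$end > m || out$end - out$start < 1L) {
    stop(sprintf("invalid segment [%d, %d] for %d points", out$start, out$end, m),
         call. = FALSE)
  }
  out
}

#' @export
print.reg_result <- function(x, top = 10L, ...) {
  cat(sprintf("REG analysis of segment [%d, %d]%s  (|R| threshold %.2f)\n",
              x$segment$start, x$segment$end,
              if (is.na(x$segment$direction)) "" else paste0(" ", x$segment$direction),
              x$r_threshold))
  cat(sprintf("  sum of REG over all %d terms: %.6f (kept terms: %.6f)\n",
              nrow(x$entries), x$sum_of_reg, x$sum_of_reg_kept))
  n <- nrow(x$entries)
  show <- if (n > 2 * top) {
    rbind(utils::head(x$entries, top), utils::tail(x$entries, top))
  } else {
    x$entries
  }
  print.data.frame(show, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Segment-wise REG analysis of a whole dataset
#'
#' Splits the PES at its stationary points and runs [analyze_segment()] on
#' each piece. Segments too short to regress (fewer than 3 points) yield an
#' error entry; the remaining segments are still analysed.
#'
#' @inheritParams analyze_segment
#' @return An object of class `"reg_analysis"`: a list with one
#'   [analyze_segment()] result (or a `list(segment=, error=)` stub) per
#'   segment, plus the segment table as attribute `"segments"`.
#' @export
reg_analyze <- function(dataset, r_threshold = 0.7) {
  stopifnot(inherits(dataset, "reg_dataset"))
  segs <- split_segments(dataset)
  out <- lapply(seq_len(nrow(segs)), function(i) {
    tryCatch(
      analyze_segment(dataset, segs[i, ], r_threshold = r_threshold),
      error = function(e) list(segment = list(start = segs$start[i], end = segs$end[i]),
                               error = conditionMessage(e))
    )
  })
  structure(out, class = "reg_analysis", segments = segs)
}

#' @export
print.reg_analysis <- function(x, ...) {
  for (res in x) {
    if (!is.null(res$error)) {
      cat(sprintf("Segment [%d, %d]: skipped (%s)\n",
                  res$segment$start, res$segment$end, res$error))
    } else {
      print(res, ...)
    }
    cat("\n")
  }
  invisible(x)
}
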