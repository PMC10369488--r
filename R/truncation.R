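#' Atoms within a sphere around a center atom
#'
#' Biased "lite system" selection: all atoms whose Euclidean distance to a
#' chosen center atom is within `radius` Angstrom. Membership uses the
#' closed ball (distance `<= radius`) so that boundary atoms at exactly the
#' chosen radius are included deterministically; the center atom is always
#' a member.
#'
#' @param geometry An `"xyz_geometry"` from [read_xyz()] (or a data frame
#'   with `label`, `x`, `y`, `z`).
#' @param center_label Label of the center atom (e.g. `"o66"`).
#' @param radius Sphere radius in Angstrom, `>= 0`.
#' @return Character vector of selected atom labels, in file order.
#' @export
sphere_select <- function(geometry, center_label, radius) {
  stopifnot(all(c("label", "x", "y", "z") %in% names(geometry)))
  if (!(is.numeric(radius) && length(radius) == 1L && radius >= 0)) {
    stop("radius must be >= 0", call. = FALSE)
  }
  center_label <- tolower(center_label)
  i <- match(center_label, geometry$label)
  if (is.na(i)) {
    stop(sprintf("unknown center atom '%s'", center_label), call. = FALSE)
  }
  d <- sqrt((geometry$x - geometry$x[i])^2 +
            (geometry$y - geometry$y[i])^2 +
            (geometry$z - geometry$z[i])^2)
  geometry$label[d <= radius | seq_along(d) == i]
}

#' Restrict a dataset to terms inside an atom subset
#'
#' Keeps exactly the terms whose every atom belongs to the subset — the
#' intra-atomic terms of the subset atoms plus the pair terms internal to
#' the subset. For a complete decomposition and a subset of `k` atoms this
#' retains `k^2` terms. The control coordinate and the total energy are
#' left untouched: in the biased protocol the full-system wave-function
#' energies remain the reference, only the bookkept terms shrink.
#'
#' @param dataset A [reg_dataset()].
#' @param atom_subset Non-empty character vector of atom labels.
#' @return A `"reg_dataset"` with the filtered term collection.
#' @export
filter_terms <- function(dataset, atom_subset) {
  stopifnot(inherits(dataset, "reg_dataset"))
  atom_subset <- tolower(atom_subset)
  if (length(atom_subset) == 0L) stop("atom subset must be non-empty", call. = FALSE)
  info <- dataset$term_info
  keep <- info$atom_a %in% atom_subset &
    (info$atom_b == "" | info$atom_b %in% atom_subset)
  out <- dataset
  out$terms <- dataset$terms[, keep, drop = FALSE]
  out$term_info <- info[keep, , drop = FALSE]
  rownames(out$term_info) <- NULL
  out$source <- paste0(dataset$source,
                       sprintf(" [filtered to %d atoms]", length(unique(atom_subset))))
  out
}

#' Lite-versus-full profile agreement metrics
#'
#' Assesses how faithfully a truncated ("lite") system's energy profile
#' reproduces the full system's profile on the same grid, via three values
#' that all equal 1 for a perfect truncation:
#' \describe{
#'   \item{`m`}{OLS slope of the mean-translated lite energies against the
#'     mean-translated full energies — how similar the shapes of the two
#'     curves are point by point.}
#'   \item{`r2`}{squared Pearson correlation (coefficient of
#'     determination) — goodness of the linear fit, more discriminating
#'     between candidate subsets than `R` itself.}
#'   \item{`de_ratio`}{`(lite_end - lite_start) / (full_end - full_start)`
#'     over the assessed segment — the ratio of activation energies when
#'     the segment runs from a reactant to a transition state; it confirms
#'     the recovered gradients have the right overall magnitude.}
#' }
#' A candidate can match `m` and `r2` while failing `de_ratio`, meaning its
#' gradients are systematically compressed; all three must be near unity.
#'
#' @param full_profile,lite_profile Numeric energy vectors on an identical
#'   grid, or two-column data frames `(s, e)` whose `s` grids must agree.
#' @param segment Optional `c(start, end)` pair of 1-based indices over
#'   which the metrics are computed; default is the whole profile.
#' @return An object of class `"truncation_metrics"`: list with `m`, `r2`,
#'   `de_ratio` and `n_points`.
#' @export
truncation_metrics <- function(full_profile, lite_profile, segment = NULL) {
  full <- profile_energy(full_profile)
  lite <- profile_energy(lite_profile)
  if (length(full) != length(lite)) {
    stop("profiles must have the same number of points", call. = FALSE)
  }
  sf <- profile_grid(full_profile); sl <- profile_grid(lite_profile)
  if (!is.null(sf) && !is.null(sl) && !isTRUE(all.equal(sf, sl))) {
    stop("profiles are not on the same control-coordinate grid", call. = FALSE)
  }
  m_pts <- length(full)
  idx <- if (is.null(segment)) seq_len(m_pts) else {
    seg <- as_segment_indices(segment, m_pts)
    seg$start:seg$end
  }
  if (length(idx) < 3L) stop("need >= 3 points to assess a truncation", call. = FALSE)

  f <- full[idx] - mean(full[idx])
  l <- lite[idx] - mean(lite[idx])
  vf <- sum(f * f)
  if (vf == 0) stop("full profile has zero variance on the segment", call. = FALSE)
  m <- sum(f * l) / vf
  vl <- sum(l * l)
  r2 <- if (vl == 0) 0 else (sum(f * l)^2) / (vf * vl)
  de_full <- full[idx[length(idx)]] - full[idx[1]]
  if (de_full == 0) {
    stop("delta-E of the full profile is zero on the segment; de_ratio undefined",
         call. = FALSE)
  }
  de_ratio <- (lite[idx[length(idx)]] - lite[idx[1]]) / de_full

  structure(list(m = m, r2 = min(1, max(0, r2)), de_ratio = de_ratio,
                 n_points = length(idx)),
            class = "truncation_metrics")
}

profile_energy <- function(p) {
  if (is.data.frame(p)) {
    col <- intersect(c("e", "energy", "E"), names(p))[1]
    if (is.na(col)) stop("profile data frame needs an energy column (e/energy)", call. = FALSE)
    as.numeric(p[[col]])
  } else {
    as.numeric(p)
  }
}

profile_grid <- function(p) {
  if (is.data.frame(p) && "s" %in% names(p)) as.numeric(p$s) else NULL
}

#' @export
print.truncation_metrics <- function(x, ...) {
  cat(sprintf("m = %.4f, R^2 = %.4f, dE_lite/dE_full = %.4f  (%d points)\n",
              x$m, x$r2, x$de_ratio, x$n_points))
  invisible(x)
}

#' Rank candidate truncations by closeness to unity
#'
#' Computes [truncation_metrics()] for every candidate lite profile and
#' ranks candidates by the largest deviation of the triple from 1
#' (`max(|m - 1|, |r2 - 1|, |de_ratio - 1|)`), ascending, so the most
#' faithful truncation comes first. Candidates that fail (grid mismatch,
#' degenerate profile) are reported with their error and ranked last.
#'
#' @param full_profile Full-system profile (vector or `(s, e)` data frame).
#' @param lite_profiles Named list of candidate lite profiles.
#' @param segment Optional segment passed through to [truncation_metrics()].
#' @param n_atoms Optional integer vector (same length as `lite_profiles`)
#'   recording each candidate's atom count, carried into the table.
#' @return Data frame with columns `name`, `n_atoms`, `m`, `r2`,
#'   `de_ratio`, `max_dev`, `error`, sorted by `max_dev`.
#' @export
assess_truncations <- function(full_profile, lite_profiles, segment = NULL,
                               n_atoms = NULL) {
  stopifnot(is.list(lite_profiles), length(lite_profiles) > 0L)
  nms <- names(lite_profiles)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- paste0("candidate_", seq_along(lite_profiles))
  }
  if (is.null(n_atoms)) n_atoms <- rep(NA_integer_, length(lite_profiles))

  rows <- lapply(seq_along(lite_profiles), function(i) {
    res <- tryCatch(truncation_metrics(full_profile, lite_profiles[[i]], segment),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(name = nms[i], n_atoms = n_atoms[i], m = NA_real_, r2 = NA_real_,
                 de_ratio = NA_real_, max_dev = Inf,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(name = nms[i], n_atoms = n_atoms[i], m = res$m, r2 = res$r2,
                 de_ratio = res$de_ratio,
                 max_dev = max(abs(res$m - 1), abs(res$r2 - 1), abs(res$de_ratio - 1)),
                 error = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$max_dev, out$name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
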