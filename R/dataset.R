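#' Energy-decomposition dataset along a control coordinate
#'
#' The REG input object: `M` geometries indexed by a strictly increasing
#' control coordinate `s` (an IRC arc length, a scanned bond distance, ...),
#' the total wave-function energy at each geometry, and one energy series
#' per partitioned term. Term series are held as an `M x n_terms` matrix
#' whose column names are canonical term-label strings (see [term_label()]).
#'
#' Missing `(term, point)` values are a construction error, never implicit
#' zeros: silent zero-filling would corrupt the sum-rule diagnostic that
#' every REG analysis reports (the slopes of a complete decomposition sum
#' to one on every segment).
#'
#' @param s Numeric vector of control-coordinate values, strictly increasing.
#' @param e_total Numeric vector of total energies, same length as `s`.
#' @param terms Named list of numeric vectors (names are canonical label
#'   strings) or an `M x n_terms` numeric matrix with such column names.
#'   May be empty.
#' @param unit Energy unit tag carried as metadata; `"kJ/mol"` (default) or
#'   `"hartree"`.
#' @param source Free-text provenance note.
#' @return An object of class `"reg_dataset"`.
#' @export
reg_dataset <- function(s, e_total, terms = list(), unit = "kJ/mol", source = "") {
  s <- as.numeric(s)
  e_total <- as.numeric(e_total)
  m <- length(s)
  if (m < 2L) stop("a dataset needs at least 2 points", call. = FALSE)
  if (anyNA(s) || any(!is.finite(s))) stop("control coordinate must be finite", call. = FALSE)
  if (any(diff(s) <= 0)) {
    stop("control coordinate must be strictly increasing (duplicate abscissae rejected)",
         call. = FALSE)
  }
  if (length(e_total) != m) stop("e_total length must match s", call. = FALSE)
  if (anyNA(e_total) || any(!is.finite(e_total))) {
    stop("total energies must be finite", call. = FALSE)
  }

  if (is.list(terms)) {
    if (length(terms) > 0L && is.null(names(terms))) {
      stop("terms list must be named by canonical label strings", call. = FALSE)
    }
    tm <- matrix(numeric(0), nrow = m, ncol = 0L)
    if (length(terms) > 0L) {
      lens <- vapply(terms, length, integer(1))
      if (any(lens != m)) {
        bad <- names(terms)[lens != m][1]
        stop(sprintf("term '%s' has %d points, expected %d (ragged series)",
                     bad, lens[lens != m][1], m), call. = FALSE)
      }
      tm <- do.call(cbind, lapply(terms, as.numeric))
      colnames(tm) <- names(terms)
    }
  } else if (is.matrix(terms)) {
    if (nrow(terms) != m) stop("term matrix must have one row per point", call. = FALSE)
    if (ncol(terms) > 0L && is.null(colnames(terms))) {
      stop("term matrix columns must be named by canonical label strings", call. = FALSE)
    }
    tm <- terms
  } else {
    stop("terms must be a named list or a matrix", call. = FALSE)
  }

  if (ncol(tm) > 0L) {
    # re-canonicalize names (catches V(b,a) spellings) and reject duplicates
    labels <- lapply(colnames(tm), parse_term_label)
    canon <- vapply(labels, format, character(1))
    if (anyDuplicated(canon)) {
      stop(sprintf("duplicate term label '%s'", canon[duplicated(canon)][1]), call. = FALSE)
    }
    colnames(tm) <- canon
    if (anyNA(tm) || any(!is.finite(tm))) stop("term energies must be finite", call. = FALSE)
  } else {
    labels <- list()
  }
  unit <- match.arg(unit, c("kJ/mol", "hartree"))

  structure(
    list(s = s, e_total = e_total, terms = tm,
         term_info = term_info_table(labels),
         unit = unit, source = source),
    class = "reg_dataset"
  )
}

term_info_table <- function(labels) {
  if (length(labels) == 0L) {
    return(data.frame(label = character(0), kind = character(0),
                      atom_a = character(0), atom_b = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    label = vapply(labels, format, character(1)),
    kind = vapply(labels, function(l) l$kind, character(1)),
    atom_a = vapply(labels, function(l) l$atoms[1], character(1)),
    atom_b = vapply(labels, function(l) if (length(l$atoms) == 2L) l$atoms[2] else "", character(1)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.reg_dataset <- function(x, ...) {
  cat(sprintf("REG dataset: %d points, %d terms [%s]\n",
              n_points(x), n_terms(x), x$unit))
  cat(sprintf("  s in [%g, %g]; E_tot in [%g, %g]\n",
              min(x$s), max(x$s), min(x$e_total), max(x$e_total)))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Number of points along the control coordinate
#' @param dataset A [reg_dataset()].
#' @return Integer count.
#' @export
n_points <- function(dataset) length(dataset$s)

#' Number of partitioned terms held in a dataset
#' @param dataset A [reg_dataset()].
#' @return Integer count.
#' @export
n_terms <- function(dataset) ncol(dataset$terms)

#' kJ/mol per hartree
#' @export
HARTREE_TO_KJMOL <- 2625.4996394799

#' Convert the energy unit of a dataset
#'
#' Rescales the total energy and every term series between hartree and
#' kJ/mol. The control coordinate is untouched.
#'
#' @param dataset A [reg_dataset()].
#' @param to Target unit, `"kJ/mol"` or `"hartree"`.
#' @return A converted `"reg_dataset"`.
#' @export
convert_unit <- function(dataset, to = c("kJ/mol", "hartree")) {
  to <- match.arg(to)
  if (identical(dataset$unit, to)) return(dataset)
  f <- if (to == "kJ/mol") HARTREE_TO_KJMOL else 1 / HARTREE_TO_KJMOL
  dataset$e_total <- dataset$e_total * f
  dataset$terms <- dataset$terms * f
  dataset$unit <- to
  dataset
}
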