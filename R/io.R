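#' Read a long-format term table
#'
#' The interchange format is a delimited UTF-8 text file (comma by default,
#' tab accepted) with a header row and columns `point_index` (0-based
#' integer), `s` (float), `kind` (`total`, `intra`, `cl` or `xc`), `atom_a`
#' (empty for `total`), `atom_b` (empty for `total` and `intra`) and
#' `energy` (float). Every label, including `total`, must supply exactly one
#' value at every point: ragged or duplicated series are rejected rather
#' than filled.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) sniffs comma vs tab from the
#'   header line.
#' @param unit Energy unit tag of the file, `"kJ/mol"` (default) or
#'   `"hartree"`.
#' @return A [reg_dataset()].
#' @export
read_dataset <- function(path, sep = NULL, unit = "kJ/mol") {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          colClasses = c(point_index = "integer", s = "numeric",
                                         kind = "character", atom_a = "character",
                                         atom_b = "character", energy = "numeric"),
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          na.strings = character(0))
  need <- c("point_index", "s", "kind", "atom_a", "atom_b", "energy")
  if (!all(need %in% names(df))) {
    stop(sprintf("missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")), call. = FALSE)
  }
  bad_kind <- setdiff(unique(df$kind), c("total", "intra", "cl", "xc"))
  if (length(bad_kind) > 0L) {
    stop(sprintf("unknown kind token '%s'", bad_kind[1]), call. = FALSE)
  }

  pts <- sort(unique(df$point_index))
  m <- length(pts)
  if (!identical(pts, 0:(m - 1L))) {
    stop("point_index values must cover 0..M-1 without gaps", call. = FALSE)
  }

  # control coordinate: one consistent s per point, strictly increasing
  s <- vapply(pts, function(p) {
    sv <- unique(df$s[df$point_index == p])
    if (length(sv) != 1L) {
      stop(sprintf("inconsistent s values at point_index %d", p), call. = FALSE)
    }
    sv
  }, numeric(1))

  row_label <- character(nrow(df))
  is_total <- df$kind == "total"
  if (any(nzchar(df$atom_a[is_total])) || any(nzchar(df$atom_b[is_total]))) {
    stop("'total' rows must have empty atom columns", call. = FALSE)
  }
  row_label[is_total] <- "total"
  for (i in which(!is_total)) {
    b <- if (nzchar(df$atom_b[i])) df$atom_b[i] else NULL
    row_label[i] <- format(term_label(df$kind[i], df$atom_a[i], b))
  }
  if (anyDuplicated(paste(row_label, df$point_index))) {
    d <- paste(row_label, df$point_index)[duplicated(paste(row_label, df$point_index))][1]
    stop(sprintf("duplicate entry for (%s) — pairwise spellings V(a,b)/V(b,a) count as one term",
                 sub(" ", ", point ", d)), call. = FALSE)
  }

  counts <- table(row_label)
  if (!"total" %in% names(counts)) stop("no 'total' rows found", call. = FALSE)
  if (any(counts != m)) {
    bad <- names(counts)[counts != m][1]
    stop(sprintf("series '%s' has %d of %d points (missing values are an error, not zeros)",
                 bad, counts[[bad]], m), call. = FALSE)
  }

  ord <- order(df$point_index)
  df <- df[ord, ]; row_label <- row_label[ord]
  e_total <- df$energy[row_label == "total"]
  term_names <- sort(setdiff(unique(row_label), "total"), method = "radix")
  terms <- lapply(term_names, function(lb) df$energy[row_label == lb])
  names(terms) <- term_names

  reg_dataset(s, e_total, terms, unit = unit, source = path)
}

#' Write a dataset as a long-format term table
#'
#' Inverse of [read_dataset()]: the round trip preserves every value (17
#' significant digits are written). Output row order is fixed — total rows
#' first, then terms in canonical label order, points ascending within each
#' series — so rewriting the same dataset is byte-stable.
#'
#' @param dataset A [reg_dataset()].
#' @param path Output path.
#' @param sep Field separator (`","` default).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "reg_dataset"))
  m <- n_points(dataset)
  fmt <- function(v) sprintf("%.17g", v)
  lines <- paste(c("point_index", "s", "kind", "atom_a", "atom_b", "energy"),
                 collapse = sep)
  lines <- c(lines, paste(0:(m - 1L), fmt(dataset$s), "total", "", "",
                          fmt(dataset$e_total), sep = sep))
  if (n_terms(dataset) > 0L) {
    info <- dataset$term_info
    ord <- order(info$label, method = "radix")
    for (k in ord) {
      lines <- c(lines, paste(0:(m - 1L), fmt(dataset$s), info$kind[k],
                              info$atom_a[k], info$atom_b[k],
                              fmt(dataset$terms[, info$label[k]]), sep = sep))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a standard XYZ geometry file
#'
#' Line 1 is the atom count, line 2 a free comment, then one `element x y z`
#' row per atom (coordinates in Angstrom). Atom labels default to the
#' lowercase element symbol plus the 1-based file position (`"o1"`, `"h2"`,
#' ...), matching the labelling convention of term tables.
#'
#' @param path File path.
#' @return An object of class `"xyz_geometry"`: a data frame with columns
#'   `label`, `element`, `x`, `y`, `z` and a `"comment"` attribute.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  raw <- readLines(path)
  raw <- raw[seq_len(max(which(nzchar(trimws(raw))), 0L))]  # drop trailing blanks
  if (length(raw) < 2L) stop("truncated XYZ file", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(raw[1])))
  if (is.na(n) || n < 1L) stop("first line must be a positive atom count", call. = FALSE)
  if (length(raw) != n + 2L) {
    stop(sprintf("header declares %d atoms but file has %d atom rows", n, length(raw) - 2L),
         call. = FALSE)
  }
  fields <- strsplit(trimws(raw[-(1:2)]), "[[:space:]]+")
  if (any(vapply(fields, length, integer(1)) < 4L)) {
    stop("each atom row needs: element x y z", call. = FALSE)
  }
  element <- vapply(fields, `[`, character(1), 1L)
  coords <- vapply(fields, function(f) suppressWarnings(as.numeric(f[2:4])), numeric(3))
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("non-numeric or non-finite coordinate in XYZ file", call. = FALSE)
  }
  geo <- data.frame(
    label = paste0(tolower(element), seq_len(n)),
    element = element,
    x = coords[1, ], y = coords[2, ], z = coords[3, ],
    stringsAsFactors = FALSE
  )
  structure(geo, class = c("xyz_geometry", "data.frame"), comment = raw[2])
}

#' Write a geometry as a standard XYZ file
#'
#' @param geometry An `"xyz_geometry"` (or any data frame with `element`,
#'   `x`, `y`, `z` columns).
#' @param path Output path.
#' @param comment Comment line (line 2).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geometry, path, comment = "") {
  stopifnot(all(c("element", "x", "y", "z") %in% names(geometry)))
  rows <- sprintf("%-3s %.10f %.10f %.10f",
                  geometry$element, geometry$x, geometry$y, geometry$z)
  writeLines(c(as.character(nrow(geometry)), comment, rows), path)
  invisible(path)
}
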