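#' Canonical identity of one partitioned energy term
#'
#' An additive atomic energy partitioning (e.g. interacting quantum atoms,
#' IQA) produces three families of terms: intra-atomic self energies
#' (`"intra"`, one atom), classical electrostatic interatomic energies
#' (`"cl"`, a pair) and exchange-correlation interatomic energies (`"xc"`,
#' a pair). Pairwise terms are symmetric, so `V(a, b)` and `V(b, a)` denote
#' the same quantity; `term_label()` stores the pair in lexicographic order
#' so both spellings map to one canonical identity.
#'
#' Atom labels are a lowercase element symbol followed by a positive integer
#' index (`"o66"`, `"h100"`). Input is case-insensitive; labels are stored
#' lowercase because geometry files typically capitalise element symbols
#' while term tables do not.
#'
#' @param kind One of `"intra"`, `"cl"`, `"xc"`.
#' @param atom_a Atom label.
#' @param atom_b Second atom label for pairwise kinds; must be absent for
#'   `"intra"` and distinct from `atom_a` otherwise.
#' @return An object of class `"term_label"` with fields `kind` and `atoms`
#'   (length 1 or 2, canonically ordered).
#' @examples
#' term_label("xc", "o66", "c58")    # xc(c58,o66)
#' term_label("intra", "H1")         # intra(h1)
#' @export
term_label <- function(kind, atom_a, atom_b = NULL) {
  kind <- match.arg(kind, c("intra", "cl", "xc"))
  atom_a <- validate_atom_label(atom_a)
  if (kind == "intra") {
    if (!is.null(atom_b)) {
      stop("an 'intra' term has exactly one atom; atom_b must be absent", call. = FALSE)
    }
    atoms <- atom_a
  } else {
    if (is.null(atom_b)) {
      stop(sprintf("a '%s' term needs two atom labels", kind), call. = FALSE)
    }
    atom_b <- validate_atom_label(atom_b)
    if (identical(atom_a, atom_b)) {
      stop(sprintf("pairwise term atoms must be distinct (got '%s' twice)", atom_a),
           call. = FALSE)
    }
    # radix sort: locale-independent lexicographic canonical order
    atoms <- sort(c(atom_a, atom_b), method = "radix")
  }
  structure(list(kind = kind, atoms = atoms), class = "term_label")
}

validate_atom_label <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("atom label must be a single character string", call. = FALSE)
  }
  x <- tolower(trimws(x))
  if (!grepl("^[a-z]{1,2}[0-9]+$", x)) {
    stop(sprintf("malformed atom label '%s' (expected element symbol + index, e.g. 'o66')", x),
         call. = FALSE)
  }
  x
}

#' @export
format.term_label <- function(x, ...) {
  paste0(x$kind, "(", paste(x$atoms, collapse = ","), ")")
}

#' @export
print.term_label <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.term_label <- function(x, ...) format(x)

#' Parse the canonical string form of a term label
#'
#' Inverse of `format()` on a [term_label()]: `"xc(c58,o66)"` parses back to
#' the same object. Used by the file reader and the CLI.
#'
#' @param x Character string such as `"intra(h1)"` or `"cl(h100,o36)"`.
#' @return A `"term_label"` object.
#' @export
parse_term_label <- function(x) {
  m <- regmatches(x, regexec("^(intra|cl|xc)\\(([^,()]+)(?:,([^,()]+))?\\)$", x))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("cannot parse term label string '%s'", x), call. = FALSE)
  }
  b <- if (m[4] == "") NULL else m[4]
  term_label(m[2], m[3], b)
}
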