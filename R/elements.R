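# Element tables and molecular-formula arithmetic.
#
# The element space is fixed: C, H, N, O, S, Na, Mg, Cl. Formulas are held
# either as named integer vectors or, for populations, as integer matrices
# with one column per element in this canonical order.

#' Supported elements in canonical order
#' @keywords internal
ELEMENT_ORDER <- c("C", "H", "N", "O", "S", "Na", "Mg", "Cl")

#' Monoisotopic atomic masses (Da)
#'
#' Masses of the most abundant isotope of each supported element.
#' @keywords internal
ATOMIC_MASS <- c(
  C  = 12,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.9720707,
  Na = 22.98976928,
  Mg = 23.9850417,
  Cl = 34.96885268
)

# Valences used by the senior rules. Sulfur is treated as divalent and
# magnesium with coordination number 4.
VALENCE <- c(C = 4, H = 1, N = 3, O = 2, S = 2, Na = 1, Mg = 4, Cl = 1)

#' Mass of the electron (Da)
#' @keywords internal
ELECTRON_MASS <- 0.00054858

#' Normalize a formula to a full-length named integer vector
#'
#' Accepts a molecular-formula string (e.g. `"C6H6O"`), a named numeric
#' vector with element-symbol names, or an already-complete vector over the
#' supported element space. Unknown element symbols are an error.
#'
#' @param f formula string or named vector of element counts
#' @return named integer vector over `C, H, N, O, S, Na, Mg, Cl`
#' @export
as_formula <- function(f) {
  if (is.character(f)) {
    stopifnot(length(f) == 1L)
    f <- parse_formula(f)
  }
  if (is.null(names(f))) stop("formula vector must have element names")
  unknown <- setdiff(names(f), ELEMENT_ORDER)
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  out <- stats::setNames(integer(length(ELEMENT_ORDER)), ELEMENT_ORDER)
  out[names(f)] <- as.integer(f)
  if (any(out < 0)) stop("negative element count in formula")
  if (sum(out) == 0) stop("formula has no atoms")
  out
}

#' Parse a molecular formula string into element counts
#'
#' @param s formula string such as `"C10H14O3"` or `"CH4"`
#' @return named integer vector of counts for the symbols present
#' @export
parse_formula <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula string: ", s)
  }
  sym <- sub("[0-9]+$", "", toks)
  num <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(num == "", 1L, suppressWarnings(as.integer(num)))
  counts <- tapply(cnt, sym, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Format element counts as a Hill-order formula string
#'
#' Hill order: C first, H second, remaining elements alphabetically.
#' Accepts a single formula (vector) or a formula matrix (one row each).
#'
#' @param f named count vector, formula string, or formula matrix
#' @return character vector of canonical formula strings
#' @export
formula_string <- function(f) {
  m <- formula_matrix(f)
  hill <- c("C", "H", sort(setdiff(ELEMENT_ORDER, c("C", "H"))))
  apply(m[, hill, drop = FALSE], 1L, function(cnt) {
    keep <- cnt > 0
    paste0(hill[keep], ifelse(cnt[keep] > 1L, cnt[keep], ""), collapse = "")
  })
}

#' Coerce formulas to an integer matrix over the canonical element space
#'
#' @param f formula string(s), a named count vector, or a matrix with
#'   element-named columns
#' @return integer matrix with columns `C, H, N, O, S, Na, Mg, Cl`
#' @export
formula_matrix <- function(f) {
  if (is.matrix(f)) {
    unknown <- setdiff(colnames(f), ELEMENT_ORDER)
    if (length(unknown) > 0) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    }
    out <- matrix(0L, nrow(f), length(ELEMENT_ORDER),
                  dimnames = list(rownames(f), ELEMENT_ORDER))
    out[, colnames(f)] <- as.integer(f)
    return(out)
  }
  if (is.character(f)) {
    rows <- lapply(f, function(s) as_formula(s))
    return(do.call(rbind, rows))
  }
  matrix(as_formula(f), nrow = 1L, dimnames = list(NULL, ELEMENT_ORDER))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times monoisotopic atomic masses.
#'
#' @param f formula string, named count vector, or formula matrix
#' @return numeric vector of neutral monoisotopic masses in Da
#' @examples
#' monoisotopic_mass("H2O")        # 18.0105646
#' monoisotopic_mass("C2H5NO2")    # glycine, 75.0320284
#' @export
monoisotopic_mass <- function(f) {
  m <- formula_matrix(f)
  as.numeric(m %*% ATOMIC_MASS[colnames(m)])
}

#' Elemental difference g - f
#' @keywords internal
formula_delta <- function(f, g) {
  as_full <- function(x) {
    out <- stats::setNames(integer(length(ELEMENT_ORDER)), ELEMENT_ORDER)
    x <- if (is.character(x)) parse_formula(x) else x
    out[names(x)] <- as.integer(x)
    out
  }
  as_full(g) - as_full(f)
}
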