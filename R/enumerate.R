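# Formula enumeration, senior-rule validation and composition filters.

#' Element-count bounds and elemental-ratio filters
#'
#' The defaults are deliberately conservative choices for CHNOS(+Na)
#' small-molecule space: C 1-100, H 0-200, N 0-6, O 0-40, S 0-10 (so that
#' polysulfur series up to S9 remain reachable), Na/Mg/Cl 0-1, with ratio
#' filters H/C in \[0.25, 3.2\], O/C <= 1.2, N/C <= 1.3, S/C <= 0.8.
#' All are configurable.
#'
#' @param c_range,h_range,n_range,o_range,s_range,na_range,mg_range,cl_range
#'   two-element integer vectors `c(min, max)` per element
#' @param hc_range allowed H/C ratio range
#' @param oc_max,nc_max,sc_max maximal O/C, N/C, S/C ratios
#' @return object of class `element_bounds`
#' @export
element_bounds <- function(c_range = c(1L, 100L), h_range = c(0L, 200L),
                           n_range = c(0L, 6L), o_range = c(0L, 40L),
                           s_range = c(0L, 10L), na_range = c(0L, 1L),
                           mg_range = c(0L, 1L), cl_range = c(0L, 1L),
                           hc_range = c(0.25, 3.2), oc_max = 1.2,
                           nc_max = 1.3, sc_max = 0.8) {
  lo <- c(c_range[1], h_range[1], n_range[1], o_range[1], s_range[1],
          na_range[1], mg_range[1], cl_range[1])
  hi <- c(c_range[2], h_range[2], n_range[2], o_range[2], s_range[2],
          na_range[2], mg_range[2], cl_range[2])
  if (any(lo > hi) || any(lo < 0)) stop("element bounds must satisfy 0 <= min <= max")
  structure(list(lo = stats::setNames(as.integer(lo), ELEMENT_ORDER),
                 hi = stats::setNames(as.integer(hi), ELEMENT_ORDER),
                 hc_range = hc_range, oc_max = oc_max,
                 nc_max = nc_max, sc_max = sc_max),
            class = "element_bounds")
}

#' Senior-rule validation and double-bond equivalents
#'
#' DBE is computed as `1 + sum(n_i (v_i - 2)) / 2` with valences C 4, H 1,
#' N 3, O 2, S 2, Na 1, Cl 1 and Mg 4 (coordination number). A composition
#' passes when (a) DBE is a non-negative integer, (b) the total count of
#' odd-valence atoms (H, N, Na, Cl) is even, and (c) the total valence is at
#' least `2 (n_atoms - 1)`, i.e. a connected graph is possible.
#'
#' @param f formula string, named count vector, or formula matrix
#' @return data frame with columns `passes` (logical) and `dbe` (numeric,
#'   possibly half-integer when the rule fails)
#' @examples
#' senior_check("C6H6")   # passes, dbe 4
#' senior_check("CH3")    # fails: half-integer dbe, odd H count
#' @export
senior_check <- function(f) {
  m <- formula_matrix(f)
  v <- VALENCE[colnames(m)]
  dbe <- 1 + as.numeric(m %*% (v - 2)) / 2
  odd_sum <- rowSums(m[, c("H", "N", "Na", "Cl"), drop = FALSE])
  total_valence <- as.numeric(m %*% v)
  n_atoms <- rowSums(m)
  passes <- abs(dbe - round(dbe)) < 1e-9 & dbe > -1e-9 &
    odd_sum %% 2 == 0 &
    total_valence >= 2 * (n_atoms - 1)
  data.frame(passes = passes, dbe = dbe)
}

#' Enumerate elemental compositions for a neutral mass
#'
#' Exhaustively enumerates, within the element-count bounds, every
#' composition whose monoisotopic mass lies inside the ppm window around
#' `neutral_mass`. The search loops over heteroatoms with cumulative-mass
#' pruning and solves the feasible C/H range per branch. Ratio and
#' senior-rule filters are *not* applied here (see [apply_filters()]).
#'
#' @param neutral_mass target neutral monoisotopic mass (Da)
#' @param tol_ppm half-width of the mass window in ppm
#' @param bounds an [element_bounds()] object
#' @return data frame with columns `formula` (Hill string), the eight
#'   element counts, `mass` and `error_ppm`, sorted by `abs(error_ppm)`
#' @export
enumerate_formulas <- function(neutral_mass, tol_ppm = 0.2,
                               bounds = element_bounds()) {
  stopifnot(neutral_mass > 0, tol_ppm >= 0)
  res <- .enumerate_cpp(neutral_mass, tol_ppm, bounds$lo, bounds$hi)
  cm <- res$counts
  err <- (res$mass - neutral_mass) / neutral_mass * 1e6
  ord <- order(abs(err))
  cm <- cm[ord, , drop = FALSE]
  out <- data.frame(formula = if (nrow(cm)) formula_string(cm) else character(0),
                    cm, mass = res$mass[ord], error_ppm = err[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply senior-rule and elemental-ratio filters to candidate compositions
#'
#' Removes candidates that fail the senior rules or any configured ratio
#' bound, and records which rule fired for each candidate.
#'
#' @param candidates data frame with element-count columns (as produced by
#'   [enumerate_formulas()]) or a formula matrix / character vector
#' @param bounds an [element_bounds()] object supplying the ratio filters
#' @return list with `retained` (filtered data frame, `dbe` column added)
#'   and `flags` (character vector per input candidate: `"ok"` or the name
#'   of the first rule violated: `"senior"`, `"H/C"`, `"O/C"`, `"N/C"`,
#'   `"S/C"`)
#' @export
apply_filters <- function(candidates, bounds = element_bounds()) {
  if (is.character(candidates) || is.matrix(candidates)) {
    m <- formula_matrix(candidates)
    candidates <- data.frame(formula = formula_string(m), m,
                             stringsAsFactors = FALSE)
  }
  m <- as.matrix(candidates[, ELEMENT_ORDER, drop = FALSE])
  sc <- senior_check(m)
  C <- pmax(m[, "C"], 1L)  # ratio guards; C = 0 candidates fail H/C anyway
  flags <- rep("ok", nrow(m))
  hc <- m[, "H"] / C
  oc <- m[, "O"] / C
  nc <- m[, "N"] / C
  scr <- m[, "S"] / C
  # ratio flags take precedence over "senior" in the report; a candidate
  # violating both is most usefully described by the ratio that excludes it
  flags[!sc$passes] <- "senior"
  flags[scr > bounds$sc_max] <- "S/C"
  flags[nc > bounds$nc_max] <- "N/C"
  flags[oc > bounds$oc_max] <- "O/C"
  flags[m[, "C"] == 0 | hc < bounds$hc_range[1] | hc > bounds$hc_range[2]] <- "H/C"
  retained <- candidates[flags == "ok", , drop = FALSE]
  retained$dbe <- sc$dbe[flags == "ok"]
  rownames(retained) <- NULL
  list(retained = retained, flags = flags)
}
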