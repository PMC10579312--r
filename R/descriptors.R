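# Per-formula compositional descriptors: elemental ratios, double-bond
# equivalents, aromaticity equivalents, chemical families, van Krevelen
# coordinates, homologous-series structure and nominal-mass profiles.

#' Compositional descriptors for molecular formulas
#'
#' Computes H/C and O/C ratios, double-bond equivalents (DBE), the
#' aromaticity equivalent Xc, the chemical family, nominal mass, mass
#' defect and the CH2-based Kendrick mass defect.
#'
#' Xc is defined as `(3 (DBE - m O - n S) - 2) / (DBE - m O - n S)` where
#' `m` and `n` are the fractions of oxygen and sulfur atoms assumed engaged
#' in pi bonds (default 0.5 each); when `DBE <= 0` or the corrected term is
#' not positive, Xc is 0 (aliphatic). Xc >= 2.5 flags aromatics and
#' Xc >= 2.71 condensed aromatics.
#'
#' @param f formula string(s), named count vector, or formula matrix
#' @param xc_m,xc_n fraction of O (resp. S) atoms counted as pi-bonded in
#'   the Xc correction; defaults 0.5
#' @return data frame with one row per formula: `formula`, element counts,
#'   `mass`, `hc_ratio`, `oc_ratio`, `dbe`, `xc`, `family`,
#'   `nominal_mass`, `mass_defect`, `kendrick_mass_defect`
#' @examples
#' compute_descriptors("C6H6")     # benzene: dbe 4, Xc 2.5
#' compute_descriptors("C16H10")   # pyrene: dbe 12, Xc 2.8333
#' @export
compute_descriptors <- function(f, xc_m = 0.5, xc_n = 0.5) {
  m <- formula_matrix(f)
  if (any(m[, "C"] < 1)) stop("descriptors require at least one carbon atom")
  mass <- monoisotopic_mass(m)
  sc <- senior_check(m)
  dbe <- sc$dbe
  corr <- dbe - xc_m * m[, "O"] - xc_n * m[, "S"]
  xc <- ifelse(dbe <= 0 | corr <= 0, 0, (3 * corr - 2) / corr)
  nominal <- round(mass)
  kendrick_mass <- mass * 14 / monoisotopic_mass("CH2")
  kmd <- round(kendrick_mass) - kendrick_mass
  out <- data.frame(formula = formula_string(m), m,
                    mass = mass,
                    hc_ratio = m[, "H"] / m[, "C"],
                    oc_ratio = m[, "O"] / m[, "C"],
                    dbe = dbe, xc = xc,
                    family = classify_family(m),
                    nominal_mass = as.integer(nominal),
                    mass_defect = mass - nominal,
                    kendrick_mass_defect = kmd,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chemical-family label of a formula
#'
#' Concatenates the elements present in the fixed order C, H, N, O, S and
#' appends `"Na"` when sodium is present (e.g. `CHNO`, `CHOSNa`).
#' Magnesium-containing formulas are labeled `"Mg-organic"`.
#'
#' @param f formula string(s), named count vector, or formula matrix
#' @return character vector of family labels
#' @export
classify_family <- function(f) {
  m <- formula_matrix(f)
  lab <- vapply(seq_len(nrow(m)), function(i) {
    if (m[i, "Mg"] > 0) return("Mg-organic")
    base <- paste0(c("C", "H", "N", "O", "S")[m[i, c("C", "H", "N", "O", "S")] > 0],
                   collapse = "")
    if (m[i, "Na"] > 0) base <- paste0(base, "Na")
    base
  }, character(1))
  lab
}

#' Detect homologous series under a fixed elemental step
#'
#' Partitions the population into maximal chains under repeated addition of
#' `step` (default CH2): a formula with no predecessor in the set starts a
#' chain, which is extended while the next member exists. Every formula
#' belongs to exactly one maximal chain; chains of length >= 2 are
#' reported.
#'
#' @param formulas character vector of formula strings or a formula matrix
#' @param step elemental step as formula string or named counts (default
#'   `"CH2"`)
#' @return data frame with one row per series: `base_formula`, `length`,
#'   and `members` (list column of formula strings in chain order)
#' @export
detect_series <- function(formulas, step = "CH2") {
  m <- formula_matrix(formulas)
  keys <- formula_string(m)
  if (anyDuplicated(keys)) m <- m[!duplicated(keys), , drop = FALSE]
  keys <- formula_string(m)
  step_v <- as_formula(step)
  if (monoisotopic_mass(step) <= 0) stop("step must have positive mass")

  shift_key <- function(mm, sgn) {
    shifted <- sweep(mm, 2, sgn * step_v, "+")
    ok <- rowSums(shifted < 0) == 0
    out <- rep(NA_character_, nrow(mm))
    if (any(ok)) out[ok] <- formula_string(shifted[ok, , drop = FALSE])
    out
  }
  pred <- shift_key(m, -1L)
  has_pred <- !is.na(pred) & pred %in% keys
  succ_key <- shift_key(m, +1L)
  succ_idx <- match(succ_key, keys)

  bases <- which(!has_pred)
  series <- lapply(bases, function(b) {
    chain <- b
    nxt <- succ_idx[b]
    while (!is.na(nxt)) {
      chain <- c(chain, nxt)
      nxt <- succ_idx[nxt]
    }
    chain
  })
  series <- series[lengths(series) >= 2]
  data.frame(base_formula = vapply(series, function(ch) keys[ch[1]], character(1)),
             length = lengths(series),
             members = I(lapply(series, function(ch) keys[ch])),
             stringsAsFactors = FALSE)
}

#' CH4-vs-O substitution pairs within nominal mass classes
#'
#' Finds pairs (f, g) with `g = f - CH4 + O`: the classic fine-structure
#' split inside one nominal mass, with an exact monoisotopic spacing of
#' `mass(CH4) - mass(O) = 0.0363855 Da` (36.3855 mDa).
#'
#' @param formulas character vector of formula strings or formula matrix
#' @return data frame with columns `from`, `to` (formula strings),
#'   `spacing_mda` (exact spacing in mDa) and `nominal_mass`
#' @export
ch4_o_substitution_pairs <- function(formulas) {
  m <- formula_matrix(formulas)
  keys <- formula_string(m)
  if (anyDuplicated(keys)) {
    m <- m[!duplicated(keys), , drop = FALSE]
    keys <- formula_string(m)
  }
  delta <- as_formula("CH4") - as_formula("O")  # subtracting this from f gives g
  shifted <- sweep(m, 2, delta, "-")
  ok <- rowSums(shifted < 0) == 0
  target <- rep(NA_character_, nrow(m))
  if (any(ok)) target[ok] <- formula_string(shifted[ok, , drop = FALSE])
  hit <- !is.na(target) & target %in% keys
  spacing <- (monoisotopic_mass("CH4") - monoisotopic_mass("O")) * 1000
  out <- data.frame(from = keys[hit], to = target[hit],
                    spacing_mda = rep(spacing, sum(hit)),
                    nominal_mass = as.integer(round(monoisotopic_mass(
                      m[hit, , drop = FALSE]))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Nominal-mass profiles of a peak list
#'
#' Groups peaks by nominal mass (`round(mz)`) and returns, per group, the
#' peaks ordered by mass defect together with their intensities. Purely
#' descriptive; used to inspect the within-nominal-mass signal structure.
#'
#' @param pl a [peaklist]
#' @return named list (names = nominal masses) of data frames with columns
#'   `mz`, `mass_defect`, `intensity`
#' @export
nominal_mass_profile <- function(pl) {
  stopifnot(inherits(pl, "peaklist"))
  if (nrow(pl) == 0) return(stats::setNames(list(), character(0)))
  nominal <- round(pl$mz)
  defect <- pl$mz - nominal
  groups <- split(data.frame(mz = pl$mz, mass_defect = defect,
                             intensity = pl$intensity), nominal)
  lapply(groups, function(d) {
    d <- d[order(d$mass_defect), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

#' van Krevelen diagram of a descriptor table
#'
#' Scatter of H/C against O/C, point size proportional to intensity when
#' supplied, colored by chemical family.
#'
#' @param desc data frame from [compute_descriptors()], optionally with an
#'   `intensity` column
#' @param main plot title
#' @param palette named vector family -> color; unlisted families are grey
#' @export
plot_van_krevelen <- function(desc, main = "van Krevelen diagram",
                              palette = c(CHO = "#1f77b4", CHNO = "#ff7f0e",
                                          CHOS = "#2ca02c", CHNOS = "#d62728",
                                          CH = "#555555", CHN = "#9467bd",
                                          CHS = "#8c564b")) {
  col <- palette[desc$family]
  col[is.na(col)] <- "grey60"
  cex <- if ("intensity" %in% names(desc)) {
    0.3 + 1.7 * sqrt(desc$intensity / max(desc$intensity))
  } else 0.7
  graphics::plot(desc$oc_ratio, desc$hc_ratio, col = col, pch = 16,
                 cex = cex, xlab = "O/C", ylab = "H/C", main = main)
  fams <- intersect(names(palette), unique(desc$family))
  if (length(fams)) {
    graphics::legend("topright", legend = fams, col = palette[fams],
                     pch = 16, cex = 0.8, bty = "n")
  }
  invisible(desc)
}
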