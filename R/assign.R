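# Batch molecular-formula assignment of peak lists.
#
# Each peak is tried under every ion type of its ionization mode; neutral
# candidate compositions are enumerated inside the ppm window and validated
# by the senior rules and elemental-ratio filters. Among the survivors the
# primary candidate is chosen by elemental parsimony first (fewest atoms of
# the rare elements Na, Mg, Cl counted over the whole ion, adduct included),
# then by smallest absolute mass error. Without the parsimony preference,
# rare-element compositions and chloride-adduct reinterpretations are mass-
# degenerate with plain CHNOS formulas often enough to dominate the error
# ranking, which is chemically implausible for natural organic mixtures.

#' Assign molecular formulas to every peak of a peak list
#'
#' @param pl a [peaklist]
#' @param tol_ppm mass-accuracy window in ppm (default 0.2)
#' @param bounds an [element_bounds()] object
#' @param ion_types ion-type labels to try; defaults to the ionization
#'   mode's standard set (`esi_neg`: `[M-H]-`, `[M+Cl]-`; `esi_pos`:
#'   `[M+H]+`, `[M+Na]+`; `appi_pos`: `[M+H]+`, `M+.`)
#' @param isotope_check when `TRUE`, run [isotope_verify()] on every
#'   candidate and promote isotope-confirmed candidates over unverified
#'   ones when their mass errors are within 0.02 ppm of each other
#' @return an `assignment_table`: data frame with one row per surviving
#'   candidate (columns `peak`, `mz`, `intensity`, `snr`, `ion_type`,
#'   `formula`, element counts, `neutral_mass`, `error_ppm`, `dbe`,
#'   `family`, `n_candidates`, `is_primary`, `isotope_status`), with
#'   attributes `sample_id` and `ionization_mode`
#' @export
assign_peaklist <- function(pl, tol_ppm = 0.2, bounds = element_bounds(),
                            ion_types = NULL, isotope_check = FALSE) {
  stopifnot(inherits(pl, "peaklist"))
  mode <- attr(pl, "ionization_mode")
  if (is.null(ion_types)) ion_types <- default_ion_types(mode)

  # an adduct element cannot also appear in the neutral it attaches to
  bounds_for_ion <- function(it) {
    b <- bounds
    if (it == "[M+Na]+") b$hi["Na"] <- 0L
    if (it == "[M+Cl]-") b$hi["Cl"] <- 0L
    b
  }

  rows <- vector("list", nrow(pl))
  for (i in seq_len(nrow(pl))) {
    cand_all <- list()
    for (it in ion_types) {
      nm <- tryCatch(neutral_mass_from_mz(pl$mz[i], it), error = function(e) NULL)
      if (is.null(nm)) next
      b_it <- bounds_for_ion(it)
      cand <- enumerate_formulas(nm, tol_ppm, b_it)
      if (nrow(cand) == 0) next
      filt <- apply_filters(cand, b_it)
      cand <- filt$retained
      if (nrow(cand) == 0) next
      cand$ion_type <- it
      cand$neutral_mass <- cand$mass
      # signed error of the observed m/z against the candidate's ion mass
      cand$error_ppm <- (pl$mz[i] - ion_mz(cand$mass, it)) /
        ion_mz(cand$mass, it) * 1e6
      cand_all[[length(cand_all) + 1L]] <- cand
    }
    if (length(cand_all) == 0) next
    cand <- do.call(rbind, cand_all)
    parsimony <- cand$Na + cand$Mg + cand$Cl +
      (cand$ion_type %in% c("[M+Cl]-", "[M+Na]+"))
    cand <- cand[order(parsimony, abs(cand$error_ppm)), , drop = FALSE]
    cand$peak <- i
    cand$mz <- pl$mz[i]
    cand$intensity <- pl$intensity[i]
    cand$snr <- pl$snr[i]
    cand$n_candidates <- nrow(cand)
    cand$is_primary <- c(TRUE, rep(FALSE, nrow(cand) - 1L))
    rows[[i]] <- cand
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) {
    tab <- data.frame(peak = integer(0), mz = numeric(0),
                      intensity = numeric(0), snr = numeric(0),
                      ion_type = character(0), formula = character(0),
                      neutral_mass = numeric(0), error_ppm = numeric(0),
                      dbe = numeric(0), family = character(0),
                      n_candidates = integer(0), is_primary = logical(0),
                      isotope_status = character(0))
  } else {
    tab$family <- classify_family(as.matrix(tab[, ELEMENT_ORDER]))
    tab$isotope_status <- "unchecked"
    cols <- c("peak", "mz", "intensity", "snr", "ion_type", "formula",
              ELEMENT_ORDER, "neutral_mass", "error_ppm", "dbe", "family",
              "n_candidates", "is_primary", "isotope_status")
    tab <- tab[, cols]
    rownames(tab) <- NULL
  }
  out <- structure(tab,
                   sample_id = attr(pl, "sample_id"),
                   ionization_mode = mode,
                   class = c("assignment_table", "data.frame"))
  if (isotope_check && nrow(out) > 0) {
    out <- isotope_verify(out, pl, tol_ppm = max(tol_ppm, 0.5))
    out <- promote_confirmed(out)
  }
  out
}

#' @export
print.assignment_table <- function(x, ...) {
  n_peaks <- length(unique(x$peak))
  cat(sprintf("Assignment table '%s': %d peaks assigned, %d candidates (%d primary)\n",
              attr(x, "sample_id"), n_peaks, nrow(x), sum(x$is_primary)))
  invisible(x)
}

#' Extract the primary assignments of a table
#'
#' @param tab an `assignment_table`
#' @return data frame restricted to the primary candidate of each peak
#' @export
primary_assignments <- function(tab) {
  out <- tab[tab$is_primary, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- isotopologue verification ------------------------------------------

C13_DELTA <- 1.0033548   # 13C - 12C
S34_DELTA <- 1.9957959   # 34S - 32S
C13_ABUND <- 0.0107      # expected companion/parent ratio per C atom
S34_ABUND <- 0.0442      # per S atom

#' Verify assignments against isotopologue companion peaks
#'
#' For each candidate, searches the peak list for the +1.0033548 Da 13C
#' companion (and the +1.9957959 Da 34S companion when the formula contains
#' sulfur). A companion whose intensity ratio to the parent lies within a
#' factor-2 band of `n_C * 0.0107` (resp. `n_S * 0.0442`) confirms the
#' assignment; a companion outside the band contradicts it. When no
#' companion is found, the assignment is contradicted only if the companion
#' was confidently expected (`n_C >= 10` and parent S/N >= 30), otherwise it
#' stays unchecked.
#'
#' @param tab an `assignment_table` (or a single-row slice of one)
#' @param pl the [peaklist] the table was assigned from
#' @param tol_ppm match tolerance for the companion m/z (default 0.5)
#' @return the table with `isotope_status` updated to `"confirmed"`,
#'   `"contradicted"` or `"unchecked"`
#' @export
isotope_verify <- function(tab, pl, tol_ppm = 0.5) {
  if (nrow(tab) == 0) return(tab)
  status <- tab$isotope_status
  for (i in seq_len(nrow(tab))) {
    st <- check_companion(tab$mz[i], tab$intensity[i], tab$snr[i],
                          n_atoms = tab$C[i], delta = C13_DELTA,
                          abund = C13_ABUND, pl = pl, tol_ppm = tol_ppm,
                          strong_n = 10)
    if (st == "unchecked" && tab$S[i] >= 1) {
      st <- check_companion(tab$mz[i], tab$intensity[i], tab$snr[i],
                            n_atoms = tab$S[i], delta = S34_DELTA,
                            abund = S34_ABUND, pl = pl, tol_ppm = tol_ppm,
                            strong_n = Inf)
    }
    status[i] <- st
  }
  tab$isotope_status <- status
  tab
}

check_companion <- function(mz, intensity, snr, n_atoms, delta, abund,
                            pl, tol_ppm, strong_n) {
  if (n_atoms < 1) return("unchecked")
  target <- mz + delta
  err <- abs(pl$mz - target) / target * 1e6
  j <- which.min(err)
  expected <- n_atoms * abund
  if (length(j) == 1 && err[j] <= tol_ppm) {
    ratio <- pl$intensity[j] / intensity
    if (ratio >= expected / 2 && ratio <= expected * 2) return("confirmed")
    return("contradicted")
  }
  # absent companion: contradicts only when it should have been visible
  if (n_atoms >= strong_n && snr >= 30) return("contradicted")
  "unchecked"
}

# Re-rank candidates per peak: an isotope-confirmed candidate is promoted
# over an unverified one when their absolute mass errors agree within
# 0.02 ppm and it is no less parsimonious than the current primary.
promote_confirmed <- function(tab) {
  if (nrow(tab) == 0) return(tab)
  pieces <- split(seq_len(nrow(tab)), tab$peak)
  for (idx in pieces) {
    if (length(idx) < 2) next
    sub <- tab[idx, ]
    pars <- sub$Na + sub$Mg + sub$Cl +
      (sub$ion_type %in% c("[M+Cl]-", "[M+Na]+"))
    prim <- which(sub$is_primary)
    if (sub$isotope_status[prim] == "confirmed") next
    near <- which(abs(abs(sub$error_ppm) - abs(sub$error_ppm[prim])) <= 0.02 &
                    sub$isotope_status == "confirmed" &
                    pars <= pars[prim])
    if (length(near) > 0) {
      best <- near[which.min(abs(sub$error_ppm[near]))]
      tab$is_primary[idx] <- FALSE
      tab$is_primary[idx[best]] <- TRUE
    }
  }
  tab
}

# ---- assignment-table I/O -----------------------------------------------

#' Write an assignment table to TSV
#' @param tab an `assignment_table`
#' @param path output path
#' @export
write_assignments <- function(tab, path) {
  df <- as.data.frame(tab)
  df$sample_id <- attr(tab, "sample_id")
  df$ionization_mode <- attr(tab, "ionization_mode")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an assignment table written by [write_assignments()]
#' @param path input path
#' @return an `assignment_table`
#' @export
read_assignments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sample_id <- if (nrow(df) > 0) df$sample_id[1] else "sample"
  mode <- if (nrow(df) > 0) df$ionization_mode[1] else "esi_neg"
  df$sample_id <- NULL
  df$ionization_mode <- NULL
  structure(df, sample_id = sample_id, ionization_mode = mode,
            class = c("assignment_table", "data.frame"))
}
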