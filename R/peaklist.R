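# Peak-list I/O, S/N filtering and mass recalibration.
#
# A peak list is the I/O boundary of the pipeline: a table of (mz,
# intensity, snr) rows sorted by m/z, tagged with a sample id and an
# ionization mode. File dialect: tab-separated, header row with columns
# `mz`, `intensity`, `snr` (extra columns ignored), `#` comment lines.

IONIZATION_MODES <- c("esi_neg", "esi_pos", "appi_pos")

#' Construct a peak list
#'
#' @param mz numeric vector of mass-to-charge values (Da, charge 1)
#' @param intensity non-negative abundances
#' @param snr non-negative signal-to-noise ratios
#' @param sample_id text label for the sample
#' @param ionization_mode one of `"esi_neg"`, `"esi_pos"`, `"appi_pos"`
#' @param extraction_solvent optional solvent label
#' @return object of class `peaklist`: a data frame of peaks sorted by mz
#'   with attributes `sample_id`, `ionization_mode`, `extraction_solvent`.
#'   Duplicate identical mz values are merged by summing intensity and
#'   keeping the maximum snr.
#' @export
peaklist <- function(mz, intensity, snr, sample_id = "sample",
                     ionization_mode = "esi_neg",
                     extraction_solvent = NA_character_) {
  ionization_mode <- match.arg(ionization_mode, IONIZATION_MODES)
  stopifnot(length(mz) == length(intensity), length(mz) == length(snr))
  if (length(mz) > 0) {
    if (any(!is.finite(mz)) || any(mz <= 0)) stop("mz must be finite and > 0")
    if (any(intensity < 0)) stop("intensity must be >= 0")
    if (any(snr < 0)) stop("snr must be >= 0")
  }
  df <- data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity),
                   snr = as.numeric(snr))
  if (anyDuplicated(df$mz)) {
    df <- do.call(rbind, lapply(split(df, df$mz), function(d) {
      data.frame(mz = d$mz[1], intensity = sum(d$intensity), snr = max(d$snr))
    }))
  }
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            sample_id = sample_id,
            ionization_mode = ionization_mode,
            extraction_solvent = extraction_solvent,
            class = c("peaklist", "data.frame"))
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("Peak list '%s' (%s): %d peaks",
              attr(x, "sample_id"), attr(x, "ionization_mode"), nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(", m/z %.4f-%.4f", min(x$mz), max(x$mz)))
  }
  cat("\n")
  invisible(x)
}

#' Read a peak list from a delimited text file
#'
#' Expects a tab-separated file with a header naming at least the columns
#' `mz`, `intensity` and `snr`; extra columns are ignored and lines starting
#' with `#` are treated as comments.
#'
#' @param path file path
#' @inheritParams peaklist
#' @return a [peaklist]
#' @export
read_peaklist <- function(path, sample_id = basename(path),
                          ionization_mode = "esi_neg",
                          extraction_solvent = NA_character_) {
  if (!file.exists(path)) stop("peak-list file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = TRUE)
  needed <- c("mz", "intensity", "snr")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("peak-list file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num <- lapply(needed, function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "' at data line ", bad[1],
           " of ", path)
    }
    v
  })
  names(num) <- needed
  peaklist(num$mz, num$intensity, num$snr, sample_id = sample_id,
           ionization_mode = ionization_mode,
           extraction_solvent = extraction_solvent)
}

#' Write a peak list to a tab-separated file
#'
#' m/z values are serialized with 7 decimal places so that read/write
#' round-trips are lossless at sub-ppb precision.
#'
#' @param pl a [peaklist]
#' @param path output file path
#' @export
write_peaklist <- function(pl, path) {
  stopifnot(inherits(pl, "peaklist"))
  df <- data.frame(mz = sprintf("%.7f", pl$mz),
                   intensity = sprintf("%.6g", pl$intensity),
                   snr = sprintf("%.6g", pl$snr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a peak list on signal-to-noise ratio
#'
#' Retains exactly the peaks with `snr >= threshold` (boundary inclusive,
#' matching the usual S/N >= 3 peak-export convention); order is preserved.
#'
#' @param pl a [peaklist]
#' @param threshold non-negative S/N cutoff (default 3)
#' @return filtered [peaklist]
#' @export
filter_snr <- function(pl, threshold = 3) {
  stopifnot(inherits(pl, "peaklist"), threshold >= 0)
  keep <- pl$snr >= threshold
  out <- pl[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("sample_id", "ionization_mode", "extraction_solvent")] <-
    attributes(pl)[c("sample_id", "ionization_mode", "extraction_solvent")]
  class(out) <- c("peaklist", "data.frame")
  out
}

#' Internal mass recalibration against reference masses
#'
#' Matches each supplied reference (a neutral monoisotopic mass plus the ion
#' type under which it is expected) to the nearest peak within `tol_ppm`,
#' fits the ppm error as a constant offset or as a linear function of m/z,
#' and applies the inverse correction to every peak.
#'
#' @param pl a [peaklist]
#' @param reference_masses data frame with columns `neutral_mass` (Da) and
#'   `ion_type` (label understood by [ion_mz()])
#' @param tol_ppm match tolerance in ppm (default 1)
#' @param model_kind `"constant_ppm"` or `"linear_ppm"`
#' @return list with elements `peaklist` (corrected) and `fit` (a
#'   `calibration_fit` with the model kind, coefficients in ppm, the number
#'   of matched references and the post-correction residual RMS in ppm)
#' @export
recalibrate <- function(pl, reference_masses, tol_ppm = 1,
                        model_kind = c("constant_ppm", "linear_ppm")) {
  stopifnot(inherits(pl, "peaklist"))
  model_kind <- match.arg(model_kind)
  stopifnot(all(c("neutral_mass", "ion_type") %in% names(reference_masses)))

  exp_mz <- mapply(ion_mz, reference_masses$neutral_mass,
                   reference_masses$ion_type)
  # nearest-peak match within tolerance
  idx <- vapply(exp_mz, function(m) {
    err <- abs(pl$mz - m) / m * 1e6
    i <- which.min(err)
    if (length(i) == 1 && err[i] <= tol_ppm) i else NA_integer_
  }, integer(1))
  matched <- !is.na(idx)
  n_req <- if (model_kind == "constant_ppm") 1L else 2L
  if (sum(matched) < n_req) {
    stop("recalibrate: only ", sum(matched), " of ", length(exp_mz),
         " reference masses matched within ", tol_ppm,
         " ppm (need >= ", n_req, ")")
  }
  obs <- pl$mz[idx[matched]]
  expd <- exp_mz[matched]
  ppm_err <- (obs - expd) / expd * 1e6

  if (model_kind == "constant_ppm") {
    coefs <- c(offset = mean(ppm_err))
    pred <- function(mz) rep(coefs[["offset"]], length(mz))
  } else {
    fit <- stats::lm(ppm_err ~ obs)
    coefs <- c(offset = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]))
    pred <- function(mz) coefs[["offset"]] + coefs[["slope"]] * mz
  }
  corrected <- pl$mz / (1 + pred(pl$mz) * 1e-6)
  resid_ppm <- (corrected[idx[matched]] - expd) / expd * 1e6
  fit_out <- structure(
    list(model_kind = model_kind, coefficients = coefs,
         n_reference_points = sum(matched),
         residual_rms_ppm = sqrt(mean(resid_ppm^2))),
    class = "calibration_fit")

  out <- pl
  out$mz <- corrected
  ord <- order(out$mz)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("sample_id", "ionization_mode", "extraction_solvent")] <-
    attributes(pl)[c("sample_id", "ionization_mode", "extraction_solvent")]
  class(out) <- c("peaklist", "data.frame")
  list(peaklist = out, fit = fit_out)
}

#' Example internal-calibration reference series
#'
#' A saturated CHO fatty-acid homologous series (C8-C26, even carbon
#' numbers) as deprotonated ions, usable as the `reference_masses` argument
#' of [recalibrate()] for negative-mode spectra of organic mixtures. The
#' calibrant set is user-replaceable; this one ships as a worked example.
#'
#' @return data frame with columns `name`, `formula`, `neutral_mass`,
#'   `ion_type`
#' @export
example_calibrants <- function() {
  path <- system.file("extdata", "cho_fatty_acid_calibrants.tsv",
                      package = "somatlas", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration (%s): %s; %d reference points, residual RMS %.4f ppm\n",
              x$model_kind,
              paste(sprintf("%s = %.4f", names(x$coefficients),
                            x$coefficients), collapse = ", "),
              x$n_reference_points, x$residual_rms_ppm))
  invisible(x)
}
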