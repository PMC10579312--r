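# Synthetic formula populations, peak lists and multi-sample studies with
# planted ground truth. Every pipeline stage can be validated against what
# the generator planted: assignment recovery against planted formulas,
# series detection against planted chains, network edges against planted
# CH2/O/H2 neighbours, classification against planted class structure.

#' Configuration of a synthetic formula population
#'
#' Defaults emulate a CHNOS(+Na) soluble-organic-matter population:
#' nitrogen-bearing families dominate, followed by CHO and CHOS, with minor
#' CH and CHS; formulas are organised in CH2 homologous series in the mass
#' range 120-700 Da; optional polysulfur chains carry S counts 3 through 9.
#'
#' @param family_proportions named fractions per chemical family (must sum
#'   to 1)
#' @param series optional list of explicitly planted series, each a list
#'   with `base` (formula string), `step` (default `"CH2"`) and `length`
#' @param sulfur_series also plant polysulfur chains with S3-S9
#' @param mass_range numeric `c(min, max)` in Da
#' @param n_formulas target population size
#' @param seed integer RNG seed
#' @return object of class `population_config`
#' @export
population_config <- function(family_proportions = c(CHNO = 0.30, CHN = 0.12,
                                                     CHNOS = 0.08, CHO = 0.27,
                                                     CHOS = 0.15, CH = 0.06,
                                                     CHS = 0.02),
                              series = list(), sulfur_series = FALSE,
                              mass_range = c(120, 700), n_formulas = 1000,
                              seed = 1) {
  if (abs(sum(family_proportions) - 1) > 1e-9) {
    stop("family proportions must sum to 1")
  }
  if (mass_range[1] >= mass_range[2]) stop("mass_range min must be < max")
  structure(list(family_proportions = family_proportions, series = series,
                 sulfur_series = sulfur_series, mass_range = mass_range,
                 n_formulas = n_formulas, seed = seed),
            class = "population_config")
}

FAMILY_ELEMENTS <- list(
  CH = c(N = 0, O = 0, S = 0), CHO = c(N = 0, O = 1, S = 0),
  CHN = c(N = 1, O = 0, S = 0), CHS = c(N = 0, O = 0, S = 1),
  CHNO = c(N = 1, O = 1, S = 0), CHOS = c(N = 0, O = 1, S = 1),
  CHNOS = c(N = 1, O = 1, S = 1)
)

# Draw one random base formula of a family that passes the senior rules and
# the default ratio filters inside the mass range. Returns NULL on failure.
random_base_formula <- function(family, mass_range, bounds, s_count = NULL,
                                max_tries = 200) {
  need <- FAMILY_ELEMENTS[[family]]
  if (is.null(need)) stop("unsupported family in generator: ", family)
  for (try in seq_len(max_tries)) {
    C <- sample(5:40, 1)
    N <- if (need["N"] > 0) sample(1:4, 1) else 0L
    O <- if (need["O"] > 0) sample(1:10, 1) else 0L
    S <- if (!is.null(s_count)) s_count else if (need["S"] > 0) sample(1:3, 1) else 0L
    hc <- stats::runif(1, 0.6, 2.0)
    H <- round(hc * C)
    if ((H + N) %% 2 == 1) H <- H + 1L  # senior parity
    f <- c(C = C, H = H, N = N, O = O, S = S)
    m <- monoisotopic_mass(formula_matrix(f))
    if (m < mass_range[1] || m > mass_range[2]) next
    filt <- apply_filters(formula_matrix(f), bounds)
    if (nrow(filt$retained) == 1) return(f)
  }
  NULL
}

#' Generate a synthetic molecular-formula population
#'
#' Formulas are generated family by family as CH2 homologous series whose
#' bases are random valid compositions; every member passes the senior
#' rules and the default elemental-ratio filters and lies inside the mass
#' range. Explicitly requested series are planted in full, and with
#' `sulfur_series` enabled one chain per sulfur count S3-S9 is added.
#' Output is deterministic given the seed.
#'
#' @param cfg a [population_config()]
#' @param bounds an [element_bounds()] object used for validation
#' @return character vector of unique formula strings; attributes
#'   `family` (parallel label vector) and `planted_series` (list of
#'   member vectors for the explicitly planted chains)
#' @export
generate_population <- function(cfg, bounds = element_bounds()) {
  stopifnot(inherits(cfg, "population_config"))
  set.seed(cfg$seed)
  ch2 <- as_formula("CH2")
  ch2_mass <- monoisotopic_mass("CH2")
  seen <- character(0)
  fam_out <- character(0)
  planted <- list()

  add_chain <- function(base, family, max_len) {
    f <- as_formula(base)
    members <- character(0)
    for (k in seq_len(max_len)) {
      m <- monoisotopic_mass(formula_matrix(f))
      if (m > cfg$mass_range[2]) break
      key <- formula_string(f)
      if (!(key %in% seen)) {
        seen <<- c(seen, key)
        fam_out <<- c(fam_out, family)
        members <- c(members, key)
      }
      f <- f + ch2
    }
    members
  }

  # explicitly requested series are planted verbatim
  for (sp in cfg$series) {
    step <- if (is.null(sp$step)) "CH2" else sp$step
    stepv <- as_formula(step)
    f <- as_formula(sp$base)
    members <- character(0)
    for (k in seq_len(sp$length)) {
      key <- formula_string(f)
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        fam_out <- c(fam_out, classify_family(formula_matrix(f)))
      }
      members <- c(members, key)
      f <- f + stepv
    }
    planted[[length(planted) + 1L]] <- members
  }

  if (cfg$sulfur_series) {
    for (s in 3:9) {
      base <- random_base_formula("CHOS", cfg$mass_range, bounds, s_count = s)
      if (is.null(base)) {
        stop("infeasible config: no valid S", s, " base formula in mass range")
      }
      add_chain(base, "CHOS", max_len = sample(3:6, 1))
    }
  }

  targets <- round(cfg$family_proportions * cfg$n_formulas)
  for (family in names(targets)) {
    n_target <- targets[[family]]
    got <- sum(fam_out == family)
    guard <- 0
    while (got < n_target) {
      guard <- guard + 1
      if (guard > 50 * cfg$n_formulas) {
        stop("infeasible config: cannot reach ", n_target,
             " valid formulas for family ", family)
      }
      base <- random_base_formula(family, cfg$mass_range, bounds)
      if (is.null(base)) {
        stop("infeasible config: no valid base formula for family ", family)
      }
      len <- sample(3:8, 1)
      # cap the chain so the family does not overshoot its allocation
      members <- add_chain(base, family, max_len = min(len, n_target - got))
      got <- got + length(members)
    }
  }
  structure(seen, family = fam_out, planted_series = planted)
}

#' Simulate a peak list from a formula population
#'
#' Each formula is ionized under the mode's primary ion type, its m/z
#' jittered by a zero-mean normal error at the stated ppm scale, and given
#' a log-normal intensity; S/N is tied to intensity through a constant
#' noise floor. Noise peaks are placed by rejection sampling so that they
#' lie at least `noise_min_ppm` away from every assignable composition: a
#' candidate noise mass is discarded if formula enumeration (with filters)
#' finds any hit within that window, guaranteeing a clean false-positive
#' measurement downstream.
#'
#' @param population character vector of formula strings
#' @param mode ionization mode (default `"esi_neg"`)
#' @param ppm_sigma standard deviation of the relative mass error in ppm
#' @param noise_fraction fraction of the final peak list that is noise
#' @param intensities optional per-formula intensities (overrides the
#'   log-normal draw; used for multi-sample studies)
#' @param intensity_meanlog,intensity_sdlog log-normal intensity model
#' @param noise_min_ppm exclusion radius of noise peaks around assignable
#'   masses (default 0.5 ppm)
#' @param bounds bounds used for the noise rejection oracle
#' @param seed integer RNG seed
#' @return list with `peaklist` (a [peaklist]) and `ground_truth` (data
#'   frame `peak`, `mz`, `formula`, `ion_type`; noise rows have `NA`
#'   formula)
#' @export
simulate_peaklist <- function(population, mode = "esi_neg", ppm_sigma = 0.05,
                              noise_fraction = 0, intensities = NULL,
                              intensity_meanlog = log(1e6),
                              intensity_sdlog = 1, noise_min_ppm = 0.5,
                              bounds = element_bounds(), seed = 1) {
  stopifnot(ppm_sigma >= 0, noise_fraction >= 0, noise_fraction < 1)
  set.seed(seed)
  n <- length(population)
  it <- default_ion_types(mode)[1]
  neutral <- monoisotopic_mass(formula_matrix(population))
  mz_true <- ion_mz(neutral, it)
  mz <- mz_true * (1 + stats::rnorm(n, 0, ppm_sigma) * 1e-6)
  if (is.null(intensities)) {
    intensities <- stats::rlnorm(n, intensity_meanlog, intensity_sdlog)
  }
  stopifnot(length(intensities) == n)
  noise_floor <- exp(intensity_meanlog) / 30
  snr <- intensities / noise_floor

  n_noise <- round(n * noise_fraction / (1 - noise_fraction))
  noise_mz <- numeric(0)
  if (n_noise > 0) {
    lo <- min(mz_true); hi <- max(mz_true)
    guard <- 0
    while (length(noise_mz) < n_noise) {
      guard <- guard + 1
      if (guard > 200 * n_noise) stop("noise rejection sampling stalled")
      cand <- stats::runif(1, lo, hi)
      assignable <- FALSE
      for (ion in default_ion_types(mode)) {
        nm <- neutral_mass_from_mz(cand, ion)
        hits <- enumerate_formulas(nm, noise_min_ppm, bounds)
        if (nrow(hits) > 0 && nrow(apply_filters(hits, bounds)$retained) > 0) {
          assignable <- TRUE
          break
        }
      }
      if (!assignable) noise_mz <- c(noise_mz, cand)
    }
  }
  all_mz <- c(mz, noise_mz)
  all_int <- c(intensities,
               stats::rlnorm(n_noise, intensity_meanlog - 2, intensity_sdlog / 2))
  all_snr <- c(snr, stats::runif(n_noise, 3, 10))
  all_formula <- c(population, rep(NA_character_, n_noise))
  ord <- order(all_mz)
  pl <- peaklist(all_mz[ord], all_int[ord], all_snr[ord],
                 sample_id = "synthetic", ionization_mode = mode)
  truth <- data.frame(peak = seq_along(ord), mz = all_mz[ord],
                      formula = all_formula[ord],
                      ion_type = ifelse(is.na(all_formula[ord]), NA, it),
                      stringsAsFactors = FALSE)
  list(peaklist = pl, ground_truth = truth)
}

#' Simulate a two-class multi-sample study with planted discrimination
#'
#' Emulates the multi-sample design used for work/prediction-set PCA: every
#' sample shares one formula population; a discriminating subset of
#' formulas is multiplied by `effect` in class B; per-sample multiplicative
#' log-normal noise is applied throughout. The default shape is 36 samples
#' split into a 25-sample work set and an 11-sample prediction set.
#'
#' @param population character vector of formula strings
#' @param n_samples total number of samples (default 36)
#' @param n_work size of the work (training) set (default 25)
#' @param class_fraction fraction of samples in class B (default 0.5)
#' @param discriminating_fraction fraction of formulas carrying the class
#'   effect (default 0.1)
#' @param effect fold change applied to discriminating formulas in class B
#'   (> 1, or exactly 1 for a null study)
#' @param noise_sigma sd of the per-entry log-normal noise (log scale)
#' @param level `"intensity"` returns the intensity matrix directly;
#'   `"peaklist"` additionally renders one synthetic peak list per sample
#' @param ppm_sigma mass jitter for `level = "peaklist"`
#' @param seed integer RNG seed
#' @return object of class `simulated_study`: list with `intensity`
#'   (an [intensity_matrix]), `class_assignments`, `work_ids`,
#'   `prediction_ids`, `discriminating_formulas`, `seed`, and (peaklist
#'   level only) `peak_lists` and `ground_truth`
#' @export
generate_two_class_study <- function(population, n_samples = 36, n_work = 25,
                                     class_fraction = 0.5,
                                     discriminating_fraction = 0.1,
                                     effect = 4, noise_sigma = 0.3,
                                     level = c("intensity", "peaklist"),
                                     ppm_sigma = 0.05, seed = 1) {
  level <- match.arg(level)
  stopifnot(effect >= 1, n_work < n_samples, length(population) > 1)
  set.seed(seed)
  ids <- sprintf("sample_%02d", seq_len(n_samples))
  n_b <- round(class_fraction * n_samples)
  classes <- stats::setNames(sample(c(rep("A", n_samples - n_b), rep("B", n_b))),
                             ids)
  # work set must contain both classes to orient the model
  repeat {
    work <- sort(sample(ids, n_work))
    if (length(unique(classes[work])) == 2) break
  }
  pred <- setdiff(ids, work)
  n_disc <- max(1L, round(discriminating_fraction * length(population)))
  disc <- sample(population, n_disc)

  base <- stats::rlnorm(length(population), log(1e6), 1)
  x <- matrix(0, n_samples, length(population), dimnames = list(ids, population))
  for (i in seq_len(n_samples)) {
    mult <- ifelse(classes[ids[i]] == "B" & population %in% disc, effect, 1)
    x[i, ] <- base * mult * stats::rlnorm(length(population), 0, noise_sigma)
  }
  out <- list(intensity = intensity_matrix(x, class_labels = classes),
              class_assignments = classes, work_ids = work,
              prediction_ids = pred, discriminating_formulas = disc,
              seed = seed)
  if (level == "peaklist") {
    pls <- vector("list", n_samples)
    gts <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      sim <- simulate_peaklist(population, mode = "esi_neg",
                               ppm_sigma = ppm_sigma,
                               intensities = x[i, ],
                               seed = seed + 1000L + i)
      attr(sim$peaklist, "sample_id") <- ids[i]
      pls[[i]] <- sim$peaklist
      gts[[i]] <- sim$ground_truth
    }
    names(pls) <- names(gts) <- ids
    out$peak_lists <- pls
    out$ground_truth <- gts
  }
  structure(out, class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(paste0("Simulated two-class study: %d samples ",
                     "(%d work / %d prediction), %d formulas, ",
                     "%d discriminating\n"),
              length(x$class_assignments), length(x$work_ids),
              length(x$prediction_ids), ncol(x$intensity),
              length(x$discriminating_formulas)))
  invisible(x)
}
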