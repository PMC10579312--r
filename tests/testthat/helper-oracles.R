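# Independent oracles and small generators shared across the test files.

# Exhaustive nested-loop formula enumerator: every composition inside the
# element-count bounds is generated and the mass window applied last.
# Deliberately brute force and independent of the package's pruned search.
brute_force_enumerate <- function(target, tol_ppm, bounds) {
  lo <- bounds$lo; hi <- bounds$hi
  grid <- expand.grid(C = lo["C"]:hi["C"], H = lo["H"]:hi["H"],
                      N = lo["N"]:hi["N"], O = lo["O"]:hi["O"],
                      S = lo["S"]:hi["S"], Na = lo["Na"]:hi["Na"],
                      Mg = lo["Mg"]:hi["Mg"], Cl = lo["Cl"]:hi["Cl"])
  masses <- as.matrix(grid) %*% c(12, 1.0078250319, 14.0030740052,
                                  15.9949146221, 31.9720707, 22.98976928,
                                  23.9850417, 34.96885268)
  win <- abs(masses - target) <= tol_ppm * 1e-6 * target
  m <- as.matrix(grid[win, , drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

# Tiny bounds keeping the brute-force grid tractable.
small_bounds <- function() {
  element_bounds(c_range = c(0L, 12L), h_range = c(0L, 24L),
                 n_range = c(0L, 3L), o_range = c(0L, 6L),
                 s_range = c(0L, 2L), na_range = c(0L, 1L),
                 mg_range = c(0L, 1L), cl_range = c(0L, 1L))
}

# Canonical sorted formula-string set for comparing enumerations.
formula_set <- function(m) sort(unname(formula_string(m)))

# Random valid peak list for round-trip properties.
random_peaklist <- function(n = 30, seed = 1) {
  set.seed(seed)
  peaklist(mz = sort(runif(n, 100, 900)),
           intensity = rlnorm(n, 10, 1),
           snr = runif(n, 0, 100),
           sample_id = "random", ionization_mode = "esi_neg")
}

# Classify held-out samples by nearest class-mean PC1 score of the work set.
classify_by_pc1 <- function(fit, study) {
  work_scores <- fit$scores[, 1]
  cls <- study$class_assignments[study$work_ids]
  mA <- mean(work_scores[cls == "A"])
  mB <- mean(work_scores[cls == "B"])
  new_scores <- predict(fit, unclass(study$intensity)[study$prediction_ids,
                                                      , drop = FALSE])[, 1]
  ifelse(abs(new_scores - mA) < abs(new_scores - mB), "A", "B")
}

# Assignment recovery of a simulated peak list: fraction of planted
# formulas recovered as primary, and count of noise peaks assigned.
recovery_stats <- function(sim, tab) {
  prim <- primary_assignments(tab)
  gt <- sim$ground_truth
  got <- prim$formula[match(gt$peak, prim$peak)]
  planted <- !is.na(gt$formula)
  hit <- !is.na(got[planted]) & got[planted] == gt$formula[planted]
  list(recovery = mean(hit),
       n_noise_assigned = sum(!is.na(got[!planted])),
       n_noise = sum(!planted))
}
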