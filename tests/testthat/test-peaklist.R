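test_that("peak lists sort by mz, merge duplicates, and validate inputs", {
  pl <- peaklist(c(150.1, 200.2, 180.0), c(1, 2, 3), c(10, 10, 10))
  expect_equal(pl$mz, c(150.1, 180.0, 200.2))
  expect_equal(pl$intensity, c(1, 3, 2))

  # duplicate mz: intensity summed, max snr kept
  pl2 <- peaklist(c(100, 100, 200), c(5, 7, 1), c(3, 9, 4))
  expect_equal(nrow(pl2), 2)
  expect_equal(pl2$intensity[1], 12)
  expect_equal(pl2$snr[1], 9)

  expect_error(peaklist(-1, 1, 1), "mz")
  expect_error(peaklist(100, -1, 1), "intensity")
  expect_error(peaklist(1, 1, 1, ionization_mode = "esi_weird"))
})

test_that("peak-list file round trips are lossless and errors are named", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  pl <- random_peaklist(40, seed = 3)
  write_peaklist(pl, tmp)
  back <- read_peaklist(tmp, sample_id = "random", ionization_mode = "esi_neg")
  expect_equal(back$mz, pl$mz, tolerance = 1e-9)
  expect_equal(back$intensity, pl$intensity, tolerance = 1e-6)
  expect_equal(back$snr, pl$snr, tolerance = 1e-6)

  # empty data section is fine
  writeLines("mz\tintensity\tsnr", tmp)
  expect_equal(nrow(read_peaklist(tmp)), 0)

  # missing column named in the error
  writeLines(c("mz\tintensity", "100\t5"), tmp)
  expect_error(read_peaklist(tmp), "snr")

  # non-numeric cell reported with its line
  writeLines(c("mz\tintensity\tsnr", "100\tfoo\t5"), tmp)
  expect_error(read_peaklist(tmp), "intensity")
})

test_that("filter_snr keeps the >= boundary, is idempotent, matches recount", {
  pl <- peaklist(c(100, 110, 120), c(1, 1, 1), c(2.9, 3.0, 10))
  expect_equal(nrow(filter_snr(pl, 3)), 2)          # 3.0 retained
  expect_equal(filter_snr(pl, 0)$mz, pl$mz)         # identity at 0

  rpl <- random_peaklist(100, seed = 5)
  for (t in c(1, 10, 50)) {
    expect_equal(nrow(filter_snr(rpl, t)), sum(rpl$snr >= t))
  }
  f1 <- filter_snr(rpl, 20)
  expect_equal(filter_snr(f1, 20), f1)
})

test_that("recalibrate removes a planted constant ppm shift", {
  ref_masses <- monoisotopic_mass(c("C10H16O2", "C14H24O2", "C18H32O2",
                                    "C22H40O2", "C26H48O2"))
  true_mz <- ion_mz(ref_masses, "[M-H]-")
  shifted <- true_mz * (1 + 0.30e-6)
  pl <- peaklist(shifted, rep(1, 5), rep(50, 5))
  refs <- data.frame(neutral_mass = ref_masses, ion_type = "[M-H]-")

  res <- recalibrate(pl, refs, tol_ppm = 1, model_kind = "constant_ppm")
  expect_equal(res$fit$coefficients[["offset"]], 0.30, tolerance = 1e-6)
  expect_lt(max(abs(res$peaklist$mz - true_mz) / true_mz * 1e6), 1e-4)
  expect_equal(res$fit$n_reference_points, 5)

  # zero-error input: offset 0, masses unchanged
  pl0 <- peaklist(true_mz, rep(1, 5), rep(50, 5))
  res0 <- recalibrate(pl0, refs, tol_ppm = 1)
  expect_equal(res0$fit$coefficients[["offset"]], 0, tolerance = 1e-9)
  expect_equal(res0$peaklist$mz, true_mz, tolerance = 1e-12)
})

test_that("recalibrate fits a planted linear ppm drift", {
  masses <- seq(150, 700, by = 25)
  drift <- 0.1 + (masses - 150) / (700 - 150) * 0.4   # 0.1 -> 0.5 ppm
  shifted <- masses * (1 + drift * 1e-6)
  pl <- peaklist(shifted, rep(1, length(masses)), rep(50, length(masses)))
  refs <- data.frame(neutral_mass = masses - ion_mz(0.0, "[M-H]-"),
                     ion_type = "[M-H]-")
  res <- recalibrate(pl, refs, tol_ppm = 1, model_kind = "linear_ppm")
  expect_lt(res$fit$residual_rms_ppm, 0.02)

  # recalibrating an already calibrated list moves nothing beyond the RMS
  res2 <- recalibrate(res$peaklist, refs, tol_ppm = 1,
                      model_kind = "linear_ppm")
  shift_ppm <- abs(res2$peaklist$mz - res$peaklist$mz) / res$peaklist$mz * 1e6
  expect_lt(max(shift_ppm), res$fit$residual_rms_ppm + 1e-6)
})

test_that("the shipped fatty-acid calibrant series recalibrates a shifted list", {
  cal <- example_calibrants()
  expect_equal(cal$neutral_mass,
               monoisotopic_mass(cal$formula), tolerance = 1e-6)
  true_mz <- ion_mz(cal$neutral_mass, "[M-H]-")
  pl <- peaklist(true_mz * (1 - 0.15e-6), rep(1e6, nrow(cal)),
                 rep(80, nrow(cal)))
  res <- recalibrate(pl, cal, tol_ppm = 1)
  expect_equal(res$fit$coefficients[["offset"]], -0.15, tolerance = 1e-5)
  expect_lt(max(abs(res$peaklist$mz - true_mz) / true_mz * 1e6), 1e-3)
})

test_that("recalibrate errors when too few references match", {
  pl <- peaklist(c(100, 200), c(1, 1), c(5, 5))
  refs <- data.frame(neutral_mass = 500, ion_type = "[M-H]-")
  expect_error(recalibrate(pl, refs, tol_ppm = 0.5), "0 of 1")
})

test_that("filter_snr commutes with recalibrate", {
  set.seed(8)
  ref_masses <- monoisotopic_mass(c("C10H16O2", "C18H32O2", "C26H48O2"))
  true_mz <- ion_mz(ref_masses, "[M-H]-")
  other <- runif(20, 150, 600)
  mz <- c(true_mz * (1 + 0.2e-6), other)
  snr <- c(rep(50, 3), runif(20, 1, 40))   # references survive the filter
  pl <- peaklist(mz, rep(1, length(mz)), snr)
  refs <- data.frame(neutral_mass = ref_masses, ion_type = "[M-H]-")

  a <- filter_snr(recalibrate(pl, refs, tol_ppm = 1)$peaklist, 10)
  b <- recalibrate(filter_snr(pl, 10), refs, tol_ppm = 1)$peaklist
  expect_equal(a$mz, b$mz, tolerance = 1e-10)
})
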