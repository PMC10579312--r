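make_tables <- function() {
  t1 <- structure(data.frame(peak = 1:3, mz = c(100, 200, 300),
                             intensity = c(10, 20, 30), snr = 10,
                             ion_type = "[M-H]-",
                             formula = c("C6H6O", "C7H8O", "C6H6O2"),
                             is_primary = TRUE),
                  sample_id = "s1", ionization_mode = "esi_neg",
                  class = c("assignment_table", "data.frame"))
  t2 <- structure(data.frame(peak = 1, mz = 200, intensity = 5, snr = 10,
                             ion_type = "[M-H]-", formula = "C7H8O",
                             is_primary = TRUE),
                  sample_id = "s2", ionization_mode = "esi_neg",
                  class = c("assignment_table", "data.frame"))
  list(t1, t2)
}

test_that("matrix assembly unions formulas and zero-fills absences", {
  m <- assemble_matrix(make_tables())
  expect_equal(dim(m), c(2, 3))
  expect_equal(sort(colnames(m)), c("C6H6O", "C6H6O2", "C7H8O"))
  expect_equal(sum(unclass(m) == 0), 2)
  expect_equal(m["s2", "C7H8O"], 5)

  # same table under two ids gives identical rows
  tt <- make_tables()
  attr(tt[[2]], "sample_id") <- "s1"
  expect_error(assemble_matrix(tt), "duplicate sample_id")
  t3 <- make_tables()[[1]]
  attr(t3, "sample_id") <- "s3"
  m2 <- assemble_matrix(list(make_tables()[[1]], t3))
  expect_equal(unname(unclass(m2)[1, ]), unname(unclass(m2)[2, ]))
})

test_that("preprocessing yields unit-variance columns and replays on new data", {
  set.seed(21)
  x <- matrix(rlnorm(10 * 20, 10, 1), 10, 20,
              dimnames = list(paste0("s", 1:10), paste0("f", 1:20)))
  x[, 3] <- 7   # constant column must be dropped and recorded
  pre <- preprocess(intensity_matrix(x))
  expect_equal(unname(colMeans(pre$x)), rep(0, ncol(pre$x)), tolerance = 1e-10)
  expect_equal(unname(apply(pre$x, 2, var)), rep(1, ncol(pre$x)),
               tolerance = 1e-10)
  expect_equal(pre$record$dropped_columns, "f3")

  # replay on the same raw rows reproduces the transform exactly
  replay <- somatlas:::apply_preprocessing(x, pre$record)
  expect_equal(replay, pre$x, tolerance = 1e-12)
})

test_that("full-rank NIPALS reproduces the matrix and matches SVD", {
  set.seed(33)
  x <- matrix(rlnorm(5 * 8, 8, 1), 5, 8,
              dimnames = list(paste0("s", 1:5), paste0("f", 1:8)))
  pre <- preprocess(intensity_matrix(x))
  fit <- fit_pca(pre$x, n_components = 4, record = pre$record)
  expect_equal(fit$r2x_cum[4], 1, tolerance = 1e-8)
  expect_lt(max(abs(fit$scores %*% t(fit$loadings) - pre$x)), 1e-6)
  # loadings are orthonormal
  g <- crossprod(fit$loadings)
  expect_equal(g, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
  # r2x_cum is non-decreasing and bounded by 1
  expect_true(all(diff(fit$r2x_cum) >= -1e-12))
  expect_lte(fit$r2x_cum[4], 1 + 1e-9)
  # agreement with the SVD solution up to sign
  sv <- svd(pre$x)
  for (k in 1:2) {
    expect_equal(abs(sum(fit$loadings[, k] * sv$v[, k])), 1,
                 tolerance = 1e-6)
  }
  expect_error(fit_pca(pre$x, 5, record = pre$record), "n_components")
})

test_that("a planted two-class shift separates on PC1 with zero overlap", {
  cfg <- population_config(n_formulas = 300, seed = 51)
  pop <- generate_population(cfg)
  st <- generate_two_class_study(pop, effect = 4, noise_sigma = 0.2,
                                 seed = 52)
  fit <- fit_pca(st$intensity, n_components = 2)
  sc <- fit$scores[, 1]
  a <- sc[st$class_assignments == "A"]
  b <- sc[st$class_assignments == "B"]
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("projection is idempotent on training rows and centers the mean", {
  set.seed(61)
  x <- matrix(rlnorm(12 * 30, 9, 1), 12, 30,
              dimnames = list(paste0("s", 1:12), paste0("f", 1:30)))
  fit <- fit_pca(intensity_matrix(x), n_components = 3)
  proj <- predict(fit, x)
  expect_equal(proj, fit$scores, tolerance = 1e-8)

  # the column-mean raw profile in log space projects to the origin
  logx <- log10(1 + x)
  mean_profile <- matrix(10^(colMeans(logx)) - 1, 1,
                         dimnames = list("m", colnames(x)))
  expect_equal(unname(predict(fit, mean_profile)[1, ]), rep(0, 3),
               tolerance = 1e-8)

  # missing formulas are treated as zero intensity
  partial <- x[1:2, 1:10, drop = FALSE]
  expect_silent(predict(fit, partial))
})

test_that("Q2 is non-positive on noise, high on planted structure, below R2X", {
  set.seed(71)
  xn <- matrix(abs(rnorm(30 * 150)), 30, 150,
               dimnames = list(paste0("s", 1:30), paste0("f", 1:150)))
  pre <- preprocess(intensity_matrix(xn))
  cv <- q2_cv(pre$x, n_components = 2, n_folds = 7)
  expect_lt(cv$q2_cum[1], 0.05)
  expect_lt(cv$q2_cum[2], 0.05)

  # strong rank-1 structure
  set.seed(72)
  t1 <- rnorm(30); p1 <- rnorm(150)
  xs <- outer(t1, p1) + matrix(rnorm(30 * 150, 0, 0.3), 30, 150)
  xs <- scale(xs)
  dimnames(xs) <- dimnames(xn)
  cvs <- q2_cv(xs, n_components = 2, n_folds = 7)
  expect_gt(cvs$q2_per_component[1], 0.5)

  # optimism inequality against the fitted model
  fit <- fit_pca(pre$x, n_components = 2, record = pre$record)
  expect_lte(cv$q2_cum[2], fit$r2x_cum[2] + 1e-9)
  expect_error(q2_cv(pre$x, 2, n_folds = 1), "folds")
})

test_that("top loadings recover planted discriminating formulas", {
  cfg <- population_config(n_formulas = 300, seed = 81)
  pop <- generate_population(cfg)
  st <- generate_two_class_study(pop, effect = 4, noise_sigma = 0.2,
                                 seed = 82)
  fit <- fit_pca(st$intensity, n_components = 2)
  n_disc <- length(st$discriminating_formulas)
  pos <- top_loadings(fit, 1, k = n_disc, sign = "positive")
  neg <- top_loadings(fit, 1, k = n_disc, sign = "negative")
  overlap <- max(mean(pos$formula %in% st$discriminating_formulas),
                 mean(neg$formula %in% st$discriminating_formulas))
  expect_gte(overlap, 0.9)

  # sign inversion flips the lists
  flipped <- fit
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  pos_f <- top_loadings(flipped, 1, k = n_disc, sign = "negative")
  expect_setequal(pos$formula, pos_f$formula)

  # k larger than the formula count truncates with a warning
  expect_warning(top_loadings(fit, 1, k = 1e6), "formula count")

  # k = all returns every formula ordered by loading
  all_l <- top_loadings(fit, 1, k = ncol(st$intensity), sign = "positive")
  expect_equal(nrow(all_l), nrow(fit$loadings))
  expect_true(!is.unsorted(-all_l$loading))
})

test_that("the 25/11 work-prediction protocol classifies held-out samples", {
  cfg <- population_config(n_formulas = 300, seed = 91)
  pop <- generate_population(cfg)
  st <- generate_two_class_study(pop, n_samples = 36, n_work = 25,
                                 effect = 4, seed = 92)
  expect_equal(length(st$work_ids), 25)
  expect_equal(length(st$prediction_ids), 11)
  fit <- fit_pca(st$intensity[st$work_ids, , drop = FALSE], n_components = 2)
  pred <- classify_by_pc1(fit, st)
  expect_equal(unname(pred),
               unname(st$class_assignments[st$prediction_ids]))
})
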