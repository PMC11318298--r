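test_that("phantom generation is deterministic under its seed", {
  spec <- phantom_spec(dims = c(8, 8, 2), snr = 40, seed = 19)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$series$data, b$series$data)
  spec2 <- phantom_spec(dims = c(8, 8, 2), snr = 40, seed = 20)
  expect_false(identical(generate_phantom(spec2)$series$data, a$series$data))
})

test_that("noiseless phantom voxels follow the bi-exponential model exactly", {
  spec <- phantom_spec(dims = c(8, 8, 2), snr = Inf)
  ph <- generate_phantom(spec)
  vox <- which(ph$masks$muscle, arr.ind = TRUE)[1, ]
  sig <- ph$series$data[vox[1], vox[2], vox[3], ]
  expected <- 100 * ivim_signal(ph$truth$muscle, ph$series$meta$b)
  expect_equal(sig, expected, tolerance = 1e-12)
  b0vol <- ph$series$data[, , , 1]
  expect_true(all(b0vol[ph$masks$background] == 0))
})

test_that("phantom construction rejects overlapping regions and missing seeds", {
  m <- array(FALSE, c(8, 8, 1)); m[2:5, 2:5, ] <- TRUE
  spec <- phantom_spec(dims = c(8, 8, 1),
                       regions = list(
                         a = list(mask = m,
                                  params = ivim_params(0.1, 30e-3, 1.3e-3),
                                  S0 = 100),
                         b = list(mask = m,
                                  params = ivim_params(0.2, 40e-3, 1.1e-3),
                                  S0 = 100)),
                       snr = Inf)
  expect_error(generate_phantom(spec), "overlap")
  expect_error(phantom_spec(dims = c(8, 8, 1), snr = 40), "seed")
})

test_that("truth maps carry the generating parameters inside each region", {
  spec <- phantom_spec(dims = c(12, 12, 2), snr = Inf)
  ph <- generate_phantom(spec)
  expect_true(all(ph$truth_maps$f[ph$masks$muscle] == 0.11))
  expect_true(all(is.na(ph$truth_maps$f[ph$masks$background])))
})

test_that("cohort truths follow the template distribution", {
  co0 <- make_cohort(5, between_subject_sd = c(f = 0, Dstar = 0, D = 0),
                     seed = 21)
  expect_true(all(co0$truth$f == 0.11))
  expect_true(all(co0$truth$Dstar == 28.4e-3))
  co <- make_cohort(15, seed = 22)
  expect_true(all(co$truth$f >= 0 & co$truth$f <= 0.5))
  # cohort means within 3 SE of the template centre
  for (p in c("f", "Dstar", "D")) {
    tmpl <- switch(p, f = 0.11, Dstar = 28.4e-3, D = 1.36e-3)
    se <- co$between_subject_sd[[p]] / sqrt(15)
    expect_lt(abs(mean(co$truth[[p]]) - tmpl), 3 * se)
  }
})

test_that("cohort visits share truths and differ only in noise", {
  co <- make_cohort(2, seed = 23)
  v1 <- cohort_phantom(co, subject = 1, visit = 1, dims = c(6, 6, 2), snr = Inf)
  v2 <- cohort_phantom(co, subject = 1, visit = 2, dims = c(6, 6, 2), snr = Inf)
  expect_identical(v1$truth, v2$truth)
  expect_identical(v1$series$data, v2$series$data)  # noiseless: identical
  n1 <- cohort_phantom(co, subject = 1, visit = 1, dims = c(6, 6, 2), snr = 40)
  n2 <- cohort_phantom(co, subject = 1, visit = 2, dims = c(6, 6, 2), snr = 40)
  expect_false(identical(n1$series$data, n2$series$data))
})

test_that("cohort curves are reproducible and scale noise with voxel count", {
  co <- make_cohort(3, seed = 24)
  a <- cohort_curves(co, n_replicates = 4, snr = 45, n_voxels = 100, seed = 25)
  b <- cohort_curves(co, n_replicates = 4, snr = 45, n_voxels = 100, seed = 25)
  expect_identical(a, b)
  expect_length(a, 3)
  expect_length(a[[1]], 4)
  set.seed(26)
  wide <- cohort_curves(co, 200, snr = 45, n_voxels = 1, seed = 27)
  narrow <- cohort_curves(co, 200, snr = 45, n_voxels = 100, seed = 27)
  sd_wide <- sd(vapply(wide[[1]], function(cv) cv$signal[13], 0))
  sd_narrow <- sd(vapply(narrow[[1]], function(cv) cv$signal[13], 0))
  expect_gt(sd_wide / sd_narrow, 5)  # ~sqrt(100) in expectation
})

test_that("high-SNR phantoms keep nearly all muscle voxels after exclusions", {
  spec <- phantom_spec(dims = c(14, 14, 2), snr = 80, seed = 28)
  ph <- generate_phantom(spec)
  maps <- fit_voxelwise(ph$series, ph$masks$muscle, methods = "nlls3")
  expect_gte(maps$inclusion$nlls3$fraction_included, 0.95)
})
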