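test_that("WS-CV matches hand computations", {
  # identical replicates: no variability
  expect_identical(ws_cv(rbind(c(5, 5, 5), c(2, 2, 2))), 0)
  # one subject, replicates (90, 110): s = 14.142, m = 100
  expect_equal(ws_cv(c(90, 110)), 100 * sd(c(90, 110)) / 100,
               tolerance = 1e-12)
  expect_equal(ws_cv(c(90, 110)), 14.1421356, tolerance = 1e-6)
  # two subjects with per-subject CVs of 10% and 20%
  s1 <- c(100 - 10 / sqrt(2), 100 + 10 / sqrt(2))   # CV exactly 10%
  s2 <- c(100 - 20 / sqrt(2), 100 + 20 / sqrt(2))   # CV exactly 20%
  expect_equal(ws_cv(rbind(s1, s2)), sqrt((0.01 + 0.04) / 2) * 100,
               tolerance = 1e-10)
  expect_equal(ws_cv(rbind(s1, s2)), 15.8113883, tolerance = 1e-6)
})

test_that("WS-CV is scale-invariant and handles degenerate input", {
  set.seed(29)
  vals <- matrix(runif(12, 50, 150), 3, 4)
  expect_equal(ws_cv(vals), ws_cv(vals * 7.3), tolerance = 1e-12)
  # single-subject WS-CV equals that subject's CV
  expect_equal(ws_cv(vals[1, ]), 100 * sd(vals[1, ]) / mean(vals[1, ]),
               tolerance = 1e-12)
  expect_error(ws_cv(c(-5, 5)), "non-positive")
  expect_error(suppressMessages(ws_cv(list(c(1)))), "no subject")
  # pooled variant: sqrt(mean within-subject variance) / grand mean
  expect_equal(ws_cv(vals, type = "pooled"),
               100 * sqrt(mean(apply(vals, 1, var))) / mean(rowMeans(vals)),
               tolerance = 1e-12)
})

test_that("temporal stability is zero for identical repeats and permutation-invariant", {
  cv <- noiseless_curve(0.11, 28.4e-3, 1.36e-3)
  subj <- list(list(cv, cv, cv, cv), list(cv, cv, cv, cv))
  ts <- temporal_stability(subj, methods = c("nlls1", "nlls3"))
  expect_true(all(ts$report$wscv < 1e-6))
  expect_true(all(ts$report$mean_resid_sq_norm < 1e-6))
  # single subject still yields a report
  ts1 <- temporal_stability(subj[1], methods = "nlls3")
  expect_identical(nrow(ts1$report), 4L)
  # subject order does not change the summary
  set.seed(30)
  co <- make_cohort(4, seed = 31)
  curves <- cohort_curves(co, 4, snr = 45, n_voxels = 100, seed = 32)
  ta <- temporal_stability(curves, methods = "nlls3")
  tb <- temporal_stability(rev(curves), methods = "nlls3")
  expect_equal(sort(ta$report$wscv), sort(tb$report$wscv), tolerance = 1e-10)
  expect_equal(ta$report$wscv, tb$report$wscv, tolerance = 1e-10)
})

test_that("spatial consistency equals hand-computed per-segment WS-CVs", {
  # 1 subject, 2 segments x 4 slices, constructed values
  vals <- c(10, 11, 9, 10, 20, 22, 18, 20)
  slice_fits <- data.frame(subject = 1, slice = 1:8, method = "nlls3",
                           f = vals, Dstar = vals, D = vals, fDstar = vals,
                           resid_sq_norm = 0, converged = TRUE)
  seg_map <- data.frame(slice = 1:8, segment = rep(c("L1", "L2"), each = 4))
  sp <- spatial_consistency(slice_fits, seg_map)
  cv1 <- 100 * sd(vals[1:4]) / mean(vals[1:4])
  cv2 <- 100 * sd(vals[5:8]) / mean(vals[5:8])
  per <- sp$per_segment[sp$per_segment$parameter == "f", ]
  expect_equal(per$wscv[per$segment == "L1"], cv1, tolerance = 1e-10)
  expect_equal(per$wscv[per$segment == "L2"], cv2, tolerance = 1e-10)
  expect_equal(sp$report$wscv_mean[sp$report$parameter == "f"],
               mean(c(cv1, cv2)), tolerance = 1e-10)
  # identical slice values: zero everywhere
  flat <- slice_fits; flat[, c("f", "Dstar", "D", "fDstar")] <- 7
  sp0 <- spatial_consistency(flat, seg_map)
  expect_true(all(sp0$report$wscv_mean == 0))
})

test_that("spatial WS-CV falls as SNR rises", {
  co <- make_cohort(6, between_subject_sd = c(f = 0, Dstar = 0, D = 0),
                    seed = 33)
  seg_map <- data.frame(slice = 1:20, segment = rep(paste0("L", 1:5), each = 4))
  wscv_at <- function(snr, seed) {
    curves <- cohort_curves(co, 20, snr = snr, n_voxels = 25, seed = seed)
    fits <- fit_slice_curves(curves, methods = "nlls3")
    sp <- spatial_consistency(fits, seg_map)
    sp$report$wscv_mean[sp$report$parameter == "D"]
  }
  w <- c(wscv_at(25, 34), wscv_at(50, 34), wscv_at(100, 34))
  expect_true(all(diff(w) < 0))
})

test_that("inter-session WS-CV matches the paired hand formula", {
  v1 <- data.frame(subject = 1:3, method = "nlls3",
                   f = c(0.10, 0.12, 0.11), Dstar = c(0.03, 0.028, 0.031),
                   D = c(1.3e-3, 1.4e-3, 1.35e-3), fDstar = c(3e-3, 3.4e-3, 3.4e-3))
  expect_true(all(intersession_repeatability(v1, v1)$wscv < 1e-12))
  # one subject, visit2 = 1.1 x visit1: CV of the pair (x, 1.1x)
  v1a <- v1[1, ]; v2a <- v1a
  v2a[, c("f", "Dstar", "D", "fDstar")] <-
    v2a[, c("f", "Dstar", "D", "fDstar")] * 1.1
  rep1 <- intersession_repeatability(v1a, v2a)
  pair_cv <- 100 * sd(c(1, 1.1)) / mean(c(1, 1.1))
  expect_equal(rep1$wscv, rep(pair_cv, 4), tolerance = 1e-10)
  # subjects missing one visit are excluded
  v2 <- v1[1:2, ]
  expect_message(intersession_repeatability(v1, v2), "excluding")
})
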