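# Reproducibility statistics: masking, outliers, Bland-Altman, CVs,
# sample sizes, SNR maps, ROI means.

test_that("CSF mask keeps MD <= 0.9 and excludes strictly greater values", {
  md <- array(c(0.7, 0.9, 0.91, 3.0, NaN), c(5, 1, 1))
  m <- csf_mask(md)
  expect_equal(as.logical(m), c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("scaled-MAD outlier rule matches the hand-evaluated example", {
  r <- remove_outliers(c(10, 11, 12, 13, 100))
  expect_equal(r$removed, 5L)
  expect_equal(r$kept, c(10, 11, 12, 13))
  # threshold arithmetic: median 12, MAD 1, scaled 1.4826, k = 3
  expect_equal(stats::mad(c(10, 11, 12, 13, 100)), 1.4826)
  expect_equal(length(remove_outliers(rep(5, 6))$removed), 0L)
  expect_warning(r2 <- remove_outliers(c(1, 1, 1, 1, 5)), "zero MAD")
  expect_equal(r2$removed, 5L)
  expect_error(remove_outliers(c(1, 2)), "at least 3")
})

test_that("Bland-Altman bias and limits of agreement", {
  x <- c(1, 2, 3, 4)
  expect_equal(bland_altman(x, x)[c("bias", "loa_low", "loa_high")],
               list(bias = 0, loa_low = 0, loa_high = 0))
  ba <- bland_altman(c(0, 2), c(1, 1))   # diffs -1, +1
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  # translation equivariance
  ba2 <- bland_altman(x, x + 0.5)
  expect_equal(ba2$bias, -0.5)
  expect_error(bland_altman(1, 2), "2 finite pairs")
})

test_that("between-subject CV: session-wise SD/mean averaged over sessions", {
  v <- c(0.9, 1.0, 1.1)
  expect_equal(cv_between(v, v), 10.0, tolerance = 1e-9)
  expect_equal(cv_between(rep(2, 5), rep(2, 5)), 0)
  # scale invariance
  expect_equal(cv_between(3 * v, 3 * v), cv_between(v, v))
  expect_error(cv_between(c(-1, 1), c(-1, 1)), "non-positive")
})

test_that("within-subject CV uses the two-point SD", {
  expect_equal(cv_within(1.0, 1.1),
               100 * (0.1 / sqrt(2)) / 1.05, tolerance = 1e-9)  # 6.734
  expect_equal(cv_within(c(1, 2, 3), c(1, 2, 3)), 0)
  # symmetric in the session labels
  t1 <- c(1.0, 1.2, 0.9); t2 <- c(1.1, 1.15, 0.95)
  expect_equal(cv_within(t1, t2), cv_within(t2, t1))
})

test_that("voxel-wise CV maps recover degenerate and masked cases", {
  dims <- c(3, 3, 1)
  maps <- replicate(5, array(1.0, dims), simplify = FALSE)
  out <- voxelwise_cv(maps, maps)
  expect_true(all(out$between == 0))
  expect_true(all(out$within == 0))
  mask <- array(TRUE, dims); mask[1, 1, 1] <- FALSE
  out2 <- voxelwise_cv(maps, maps, mask = mask)
  expect_true(is.nan(out2$between[1, 1, 1]))
  # between map non-negative wherever defined
  set.seed(3)
  mapsA <- replicate(6, array(runif(9, 0.5, 1.5), dims), simplify = FALSE)
  mapsB <- replicate(6, array(runif(9, 0.5, 1.5), dims), simplify = FALSE)
  out3 <- voxelwise_cv(mapsA, mapsB)
  expect_true(all(out3$between >= 0, na.rm = TRUE))
})

test_that("sample-size formulas hit the van Belle anchors", {
  expect_equal(sample_size_between(0.10, 0.10), 16L)
  expect_equal(sample_size_between(0.05, 0.10), 4L)
  # non-increasing in delta
  deltas <- c(0.04, 0.06, 0.08, 0.10, 0.12)
  ns <- vapply(deltas, function(d) sample_size_between(0.10, d), integer(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(sample_size_between(0.1, 0), "delta")

  expect_equal(sample_size_within(0.08, 1.0, 0.08), 8L)
  expect_equal(sample_size_within(0, 1.0, 0.05), 2L)
  # doubling sd_diff quadruples n: 7.8489 * 4 -> 32, * 16 -> 126
  expect_equal(sample_size_within(0.1, 1, 0.05), 32L)
  expect_equal(sample_size_within(0.2, 1, 0.05), 126L)
})

test_that("SNR maps follow the sqrt(N) averaging law", {
  set.seed(7)
  dims <- c(60, 60, 1)
  n_dir <- 4
  sig <- array(1, c(dims, n_dir))
  bg <- array(FALSE, dims); bg[1:60, 1:30, 1] <- TRUE
  sig[rep(bg, n_dir)] <- 0
  cx1 <- simulate_complex_acquisition(sig, sigma = 0.1, n_averages = 1,
                                      seed = 2)
  out1 <- snr_map(cx1, bg)
  # SNR ~ S / (sigma / sqrt(n_avg n_dir)) = 1 / (0.1 / 2) = 20
  expect_equal(mean(out1$snr[!bg]), 1 / (0.1 / sqrt(n_dir)),
               tolerance = 0.03)
  cx4 <- simulate_complex_acquisition(sig, sigma = 0.1, n_averages = 4,
                                      seed = 2)
  out4 <- snr_map(cx4, bg)
  expect_equal(mean(out4$snr[!bg]) / mean(out1$snr[!bg]), 2,
               tolerance = 0.03)
  # zero-signal voxels sit at the Rayleigh floor, not zero
  expect_gt(mean(out1$snr[bg]), 0)
  expect_error(snr_map(cx1, array(FALSE, dims)), "empty")
})

test_that("ROI means erode 6-connectively except exempt labels", {
  labels <- array(0L, c(5, 5, 5))
  labels[2:4, 2:4, 2:4] <- 1L   # 3x3x3 cube
  metric <- array(2.5, c(5, 5, 5))
  out <- roi_means(metric, labels, c(A = 1L), exempt = character(0))
  expect_equal(out$n_voxels, 1L)  # erosion leaves the centre voxel
  expect_equal(out$mean, 2.5)
  out2 <- roi_means(metric, labels, c(A = 1L), exempt = "A")
  expect_equal(out2$n_voxels, 27L)
  # homogeneous map: mean unchanged by erosion
  expect_equal(out$mean, out2$mean)
  # empty after erosion is reported missing
  labels2 <- array(0L, c(5, 5, 5)); labels2[2:3, 2:4, 2:4] <- 1L
  out3 <- roi_means(metric, labels2, c(A = 1L), exempt = character(0))
  expect_equal(out3$n_voxels, 0L)
  expect_true(is.na(out3$mean))
})

test_that("repro_report assembles per-ROI statistics from a table", {
  set.seed(5)
  subj <- 1:12
  tab <- NULL
  for (r in c("CC", "CX")) {
    base <- if (r == "CC") 1.0 else 0.8
    v_t <- base * (1 + rnorm(12, 0, 0.1))
    v_r <- v_t * (1 + rnorm(12, 0, 0.05))
    tab <- rbind(tab,
                 data.frame(subject = subj, session = "test", roi = r,
                            value = v_t),
                 data.frame(subject = subj, session = "retest", roi = r,
                            value = v_r))
  }
  rep_ <- repro_report(tab)
  expect_equal(nrow(rep_), 2L)
  expect_true(all(rep_$loa_low <= rep_$bias & rep_$bias <= rep_$loa_high))
  expect_true(all(rep_$cv_between >= 0 & rep_$cv_within >= 0))
  expect_true(all(as.matrix(rep_[, grep("^n_(between|within)_",
                                        names(rep_))]) >= 2))
  # sample size decreases with effect size
  expect_true(all(rep_$n_between_4 >= rep_$n_between_12))
})
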