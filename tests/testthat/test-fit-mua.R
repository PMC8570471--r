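# Powder averaging and the joint constrained kurtosis fit.

test_that("powder average groups shells and matches direct means", {
  lay <- uniform_layout(stick_substrate(2))
  sch <- build_protocol("mua", seed = 7)
  ds <- generate_dataset(lay, sch)
  p <- powder_average(ds)
  expect_equal(nrow(p$shells), 5L)
  # coherent stick, b = 2 LTE shell: mean over the same 30 directions
  vols <- sch$volumes
  sel <- vols$label == "lte" & abs(vols$bval - 2) < 1e-9
  manual <- mean(vapply(which(sel), function(i)
    substrate_signal(lay$substrates$CC, sch$btensors[[i]]), numeric(1)))
  shell <- which(p$shells$encoding == "lte" & p$shells$bval == 2)
  vox <- which(array(TRUE, p$dims))[1]
  expect_equal(p$mean_signal[vox, shell], manual, tolerance = 1e-12)
  # b0 volumes collapse into one shared shell
  expect_equal(sum(p$shells$encoding == "b0"), 1L)
  expect_equal(p$shells$n_dirs[p$shells$encoding == "b0"], 8L)
})

test_that("powder averaging validates its inputs", {
  lay <- uniform_layout(iso_substrate())
  ds <- generate_dataset(lay, build_protocol("ogse", seed = 1))
  expect_error(powder_average(ds), "lte and ste")
})

test_that("joint fit is exact for monoexponential (isotropic) signals", {
  lay <- uniform_layout(iso_substrate(0.7))
  ds <- generate_dataset(lay, build_protocol("mua", seed = 2))
  fit <- joint_kurtosis_fit(powder_average(ds))
  expect_equal(fit$D[4, 4, 1], 0.7, tolerance = 1e-8)
  expect_equal(fit$K_lte[4, 4, 1], 0, tolerance = 1e-8)
  expect_equal(fit$K_ste[4, 4, 1], 0, tolerance = 1e-8)
  expect_equal(fit$muA[4, 4, 1], 0, tolerance = 1e-8)
  expect_equal(fit$s0[4, 4, 1], 1, tolerance = 1e-8)
})

test_that("joint fit recovers mixture kurtosis in the cumulant regime", {
  sch <- small_b_mua_protocol(bvals = c(0.2, 0.1))
  ds <- generate_dataset(uniform_layout(two_iso_substrate()), sch)
  fit <- joint_kurtosis_fit(powder_average(ds))
  expect_equal(fit$K_lte[4, 4, 1], 1 / 3, tolerance = 0.01)
  expect_equal(fit$K_ste[4, 4, 1], 1 / 3, tolerance = 0.01)
  expect_equal(fit$muA[4, 4, 1], 0, tolerance = 1e-6)
})

test_that("joint fit recovers stick kurtosis and muA at scaled-down b", {
  # uniformly dispersed sticks: each volume's signal is the exact sphere
  # powder mean, so the only systematic error left is the documented
  # cumulant truncation (about -2.6% on K and muA^2 at b <= 0.2)
  m <- analytic_moments(stick_substrate(2))
  sch <- small_b_mua_protocol(bvals = c(0.2, 0.1))
  ds <- generate_dataset(uniform_layout(stick_substrate(2, "uniform")), sch,
                         n_orient_samples = 4096)
  fit <- joint_kurtosis_fit(powder_average(ds))
  expect_equal(fit$K_lte[4, 4, 1], m$K_lte, tolerance = 0.03)  # 2.4
  expect_equal(fit$K_ste[4, 4, 1], 0, tolerance = 1e-6)
  # muA^2 = 0.4 Dbar^2 in the stick limit
  expect_equal(fit$muA[4, 4, 1]^2, 0.4 * m$Dbar^2, tolerance = 0.03)
  expect_equal(fit$muFA[4, 4, 1], 1, tolerance = 0.01)
  expect_equal(fit$D[4, 4, 1], m$Dbar, tolerance = 1e-3)
})

test_that("constraints hold under noise: muA >= 0 and muFA in [0, 1]", {
  lay <- uniform_layout(two_iso_substrate())
  ds <- generate_dataset(lay, build_protocol("mua", seed = 4))
  dn <- add_rician_noise(ds, snr_b0 = 15, seed = 10)
  fit <- joint_kurtosis_fit(powder_average(dn))
  ok <- !fit$flagged
  expect_true(all(fit$muA[ok] >= 0))
  expect_true(all(fit$muFA[ok] >= 0 & fit$muFA[ok] <= 1))
  expect_true(all(fit$K_lte[ok] >= fit$K_ste[ok] - 1e-12))
  expect_true(all(fit$K_ste[ok] >= -1e-12))
  expect_true(all(fit$D[ok] >= 0))
})

test_that("mua_from_fit inverts the kurtosis difference and clips", {
  fit <- list(D = array(1.5, c(2, 1, 1)),
              K_lte = array(c(0.6, 0.2), c(2, 1, 1)),
              K_ste = array(c(0.2, 0.6), c(2, 1, 1)))
  expect_message(mua <- mua_from_fit(fit), "clipped")
  expect_equal(mua[1, 1, 1], sqrt(1.5^2 * 0.4 / 6), tolerance = 1e-12)
  expect_equal(mua[2, 1, 1], 0)
  # K_lte = K_ste gives exactly zero
  fit$K_ste <- fit$K_lte
  expect_equal(max(mua_from_fit(fit)), 0)
})

test_that("direct muA inverts its own definition and matches the oracle", {
  # synthetic signals with known muA^2 = 0.1 at b = 2
  b <- 2; D <- 1; mua2 <- 0.1
  S_ste <- exp(-b * D)
  S_lte <- exp(-b * D + b^2 * mua2)
  expect_equal(direct_mua(S_lte, S_ste, b), sqrt(0.1), tolerance = 1e-12)
  expect_equal(direct_mua(S_ste, S_ste, b), 0)
  # stick substrate at b = 0.4: finite-b truncation biases muA down by
  # about 3% relative to the analytic small-b limit
  s <- stick_substrate(2)
  m <- analytic_moments(s)
  b_small <- 0.4
  dirs <- fibonacci_directions(20000)
  S_l <- mean(exp(-b_small * 2 * dirs[, 3]^2))
  S_s <- substrate_signal(s, btensor_spherical(b_small))
  expect_equal(direct_mua(S_l, S_s, b_small), m$muA, tolerance = 0.03)
})

test_that("direct muA and the joint fit agree in the cumulant regime", {
  s <- stick_substrate(2, "uniform")
  sch <- small_b_mua_protocol(bvals = c(0.2, 0.1))
  ds <- generate_dataset(uniform_layout(s), sch, n_orient_samples = 4096)
  p <- powder_average(ds)
  fit <- joint_kurtosis_fit(p)
  shells <- p$shells
  i_l <- which(shells$encoding == "lte" & shells$bval == 0.2)
  i_s <- which(shells$encoding == "ste" & shells$bval == 0.2)
  vox <- 1
  d_est <- direct_mua(p$mean_signal[vox, i_l], p$mean_signal[vox, i_s], 0.2)
  expect_equal(fit$muA[1, 1, 1], d_est, tolerance = 0.01)
})

test_that("muFA formula: stick limit, half-variance point, monotonicity", {
  D <- array(1, c(3, 1, 1))
  mua <- array(sqrt(c(0, 0.2, 0.4)), c(3, 1, 1))
  out <- mufa(mua, D)
  expect_equal(out[1, 1, 1], 0)
  expect_equal(out[2, 1, 1], sqrt(0.75), tolerance = 1e-12)  # 0.8660
  expect_equal(out[3, 1, 1], 1, tolerance = 1e-12)
  # strictly increasing in muA at fixed D
  grid <- seq(0, 0.6, length.out = 50)
  vals <- mufa(array(grid, c(50, 1, 1)), array(1, c(50, 1, 1)))
  expect_true(all(diff(as.numeric(vals)) > 0))
  expect_true(is.nan(mufa(array(0.1, c(1, 1, 1)), array(0, c(1, 1, 1)))[1]))
})

test_that("the max_b flag excludes high-b shells from the fit", {
  sch <- build_protocol("mua", config = list(bvals = c(2, 1, 0.5),
                                             n_dir = c(30L, 12L, 12L),
                                             n_b0 = 8L), seed = 9)
  ds <- generate_dataset(uniform_layout(two_iso_substrate()), sch)
  p <- powder_average(ds)
  fit_all <- joint_kurtosis_fit(p)
  fit_low <- joint_kurtosis_fit(p, max_b = 1)
  # excluding the strongest shell reduces the truncation bias on K
  expect_gt(fit_low$K_lte[4, 4, 1], fit_all$K_lte[4, 4, 1])
  expect_error(joint_kurtosis_fit(p, max_b = 0.6), "3 b-values")
})
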