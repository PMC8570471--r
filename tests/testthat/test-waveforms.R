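# Gradient waveforms: numeric b-values against closed forms, b-tensor
# properties, padding, spectra.

test_that("PGSE numeric b matches the closed form across parameters", {
  grid <- expand.grid(delta = c(2, 5, 11), Delta = c(11, 13.8, 20),
                      G = c(50, 100, 300))
  grid <- grid[grid$delta <= grid$Delta, ]
  for (i in seq_len(nrow(grid))) {
    w <- make_pgse(grid$delta[i], grid$Delta[i], grid$G[i])
    expect_equal(waveform_b(w),
                 pgse_bvalue(grid$delta[i], grid$Delta[i], grid$G[i]),
                 tolerance = 1e-4)
  }
  # the study's PGSE timing, amplitude solved for b = 0.8 ms/um^2
  G <- pgse_amplitude(11, 13.8, 0.8)
  expect_equal(waveform_b(make_pgse(11, 13.8, G)), 0.8, tolerance = 1e-4)
})

test_that("PGSE degenerate cases: zero amplitude and back-to-back lobes", {
  w0 <- make_pgse(5, 10, 0)
  expect_equal(compute_btensor(w0)$matrix, matrix(0, 3, 3))
  # delta = Delta: b = gamma^2 G^2 delta^3 * (2/3)
  w <- make_pgse(6, 6, 80)
  gam <- ogmua:::GAMMA_H
  expect_equal(waveform_b(w), gam^2 * 80^2 * 6^3 * 2 / 3, tolerance = 1e-4)
  expect_error(make_pgse(-1, 5, 10), "positive")
  expect_error(make_pgse(8, 5, 10), "exceed")
})

test_that("cosine OGSE numeric b matches the sinusoidal closed form", {
  gam <- ogmua:::GAMMA_H
  for (f in c(50, 100, 145, 190)) {
    for (np in 1:3) {
      w <- make_ogse_cosine(f, np, 60)
      t_total <- 2 * np * 1000 / f
      b_cf <- (gam * 60 / (2 * pi * f / 1000))^2 * t_total / 2
      expect_equal(waveform_b(w), b_cf, tolerance = 1e-4)
    }
  }
  expect_equal(waveform_b(make_ogse_cosine(100, 2, 0)), 0)
  expect_error(make_ogse_cosine(-5, 1, 10), "frequency")
  expect_error(make_ogse_cosine(50, 2, 10, max_encoding_time = 30),
               "exceeds")
})

test_that("zero-padding preserves the b-tensor and total duration", {
  w <- make_ogse_cosine(145, 2, 80)
  b0 <- waveform_b(w)
  w50 <- make_ogse_cosine(50, 1, 80)   # the longest lobe sets the TE
  target <- waveform_duration(w50)
  wp <- pad_to_duration(w, target)
  expect_equal(waveform_duration(wp), target)
  expect_equal(waveform_b(wp), b0, tolerance = 1e-9)
  expect_identical(pad_to_duration(w, waveform_duration(w))$samples,
                   w$samples)
  expect_error(pad_to_duration(w, 1), "shorter")
})

test_that("STE b-tensor is isotropic with eigenvalues b/3", {
  w <- make_ste(12, 60)
  B <- compute_btensor(w)
  ev <- eigen(B$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(ev) - min(ev), 1e-6 * B$bval)
  expect_equal(ev, rep(B$bval / 3, 3), tolerance = 1e-6)
  expect_identical(B$shape_label, "spherical")
  expect_equal(compute_btensor(make_ste(12, 0))$matrix, matrix(0, 3, 3))
})

test_that("signal under an STE equals exp(-b MD) for any single tensor", {
  w <- scale_to_b(make_ste(12, 60), 2.0)
  B <- compute_btensor(w)
  s <- substrate(compartment(1, 1.7, 0.3, orientation = "coherent",
                             mu = c(1, 2, 2) / 3))
  md <- (1.7 + 2 * 0.3) / 3
  expect_equal(substrate_signal(s, B), exp(-2.0 * md), tolerance = 1e-6)
})

test_that("b-tensor transforms as a covariance under rotation", {
  w <- make_pgse(5, 10, 100)
  B <- compute_btensor(w)$matrix
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Br <- compute_btensor(rotate_waveform(w, R))$matrix
  expect_equal(Br, R %*% B %*% t(R), tolerance = 1e-9)
  # PGSE along x: off-diagonals negligible, rank 1
  expect_lt(max(abs(B[upper.tri(B)])), 1e-9 * sum(diag(B)))
})

test_that("b-tensor is invariant under time reversal of the waveform", {
  for (w in list(make_pgse(4, 9, 120), make_ogse_cosine(100, 2, 80))) {
    g_rev <- w$samples[rev(seq_len(nrow(w$samples))), , drop = FALSE]
    w_rev <- gradient_waveform(g_rev, w$dt,
                               nrow(g_rev) - w$refocus_index,
                               w$label, w$nominal_frequency)
    expect_equal(compute_btensor(w_rev)$matrix, compute_btensor(w)$matrix,
                 tolerance = 1e-6)
  }
})

test_that("power spectra peak at the nominal frequency and obey Parseval", {
  for (f in c(100, 190)) {
    w <- make_ogse_cosine(f, 4, 60)
    ps <- power_spectrum(w)
    bin_native <- 1000 / waveform_duration(w)   # intrinsic resolution, Hz
    f_peak <- ps$frequencies[which.max(ps$power)]
    expect_lt(abs(f_peak - f), bin_native)
    expect_equal(sum(ps$power), waveform_b(w), tolerance = 1e-3)
  }
  # PGSE: diffusion-time-weighted spectrum concentrated at low frequency
  wp <- make_pgse(11, 13.8, 100)
  psp <- power_spectrum(wp)
  expect_lt(psp$frequencies[which.max(psp$power)],
            1000 / waveform_duration(wp))
  expect_equal(sum(psp$power), waveform_b(wp), tolerance = 1e-3)
})

test_that("padded and unpadded spectra agree at the nominal frequency", {
  w <- make_ogse_cosine(145, 3, 70)
  wp <- pad_to_duration(w, waveform_duration(w) + 12)
  # evaluate both on an identical frequency grid via matched zero-fill
  n_target <- 2^14
  ps1 <- power_spectrum(w, pad_factor = n_target / nrow(w$samples))
  ps2 <- power_spectrum(wp, pad_factor = n_target / nrow(wp$samples))
  expect_equal(ps1$frequencies, ps2$frequencies)
  k <- which.min(abs(ps1$frequencies - 145))
  expect_equal(ps1$power[k], ps2$power[k], tolerance = 1e-6)
})

test_that("FTB waveform refocuses and keeps its b under the bipolar option", {
  w0 <- make_ftb(50, 1, 100)
  expect_identical(w0$label, "ftb")
  expect_silent(compute_btensor(w0))
  wb <- make_ftb(50, 1, 100, bipolar_periods = 1L)
  expect_silent(compute_btensor(wb))
  expect_gt(waveform_b(wb), waveform_b(w0))  # extra lobes add weighting
})

test_that("non-refocused waveforms are rejected", {
  g <- cbind(rep(100, 200), 0, 0)  # single lobe, nothing after refocus
  w <- gradient_waveform(g, 0.01, refocus_index = 200, label = "pgse")
  expect_error(compute_btensor(w), "refocus")
})
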