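# Gradient waveform construction and b-tensor computation.
#
# Internal unit conventions (chosen so that b * D is dimensionless):
#   time            ms
#   gradient        mT/m
#   b-value         ms/um^2   (2000 s/mm^2 == 2.0 ms/um^2)
#   diffusivity     um^2/ms
#   frequency       Hz at the interface (converted internally)
#
# A waveform stores the *physical* gradient samples; the 180-degree
# refocusing pulse at `refocus_index` implicitly negates everything after
# it, and all integrals (q, B, spectra) are taken over that effective
# waveform.

# gyromagnetic ratio of 1H, expressed so that q = gamma * G * t is in
# rad/um when G is in mT/m and t in ms: 2.6752218744e8 rad s^-1 T^-1
GAMMA_H <- 2.6752218744e-4

#' Construct a gradient waveform object
#'
#' Low-level constructor; most users should call [make_pgse()],
#' [make_ogse_cosine()], [make_ftb()] or [make_ste()]. Samples are
#' piecewise-constant gradient values over consecutive intervals of
#' length `dt`; the gradient sign after `refocus_index` is implicitly
#' reversed by the 180-degree pulse.
#'
#' @param samples numeric matrix (n x 3), gradient amplitude per axis in
#'   mT/m, one row per time interval of length `dt`.
#' @param dt sample interval in ms.
#' @param refocus_index integer; the 180-degree pulse sits at the boundary
#'   between samples `refocus_index` and `refocus_index + 1`.
#' @param label one of `"pgse"`, `"ogse"`, `"ftb"`, `"lte"`, `"ste"`.
#' @param nominal_frequency oscillation frequency in Hz (0 for
#'   pgse/lte/ste).
#' @return an object of class `gradient_waveform`.
#' @export
gradient_waveform <- function(samples, dt, refocus_index, label,
                              nominal_frequency = 0) {
  if (is.vector(samples)) samples <- cbind(samples, 0, 0)
  samples <- as.matrix(samples)
  dimnames(samples) <- NULL
  stopifnot(ncol(samples) == 3)
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar")
  label <- match.arg(label, c("pgse", "ogse", "ftb", "lte", "ste"))
  refocus_index <- as.integer(refocus_index)
  if (refocus_index < 0L || refocus_index > nrow(samples))
    stop("refocus_index outside the waveform")
  structure(
    list(samples = samples, dt = dt, refocus_index = refocus_index,
         label = label, nominal_frequency = nominal_frequency),
    class = "gradient_waveform")
}

#' @export
print.gradient_waveform <- function(x, ...) {
  cat(sprintf("<gradient_waveform %s: %d samples, dt = %g ms, %.2f ms, f = %g Hz>\n",
              x$label, nrow(x$samples), x$dt,
              nrow(x$samples) * x$dt, x$nominal_frequency))
  invisible(x)
}

#' Total duration of a waveform in ms
#' @param w a `gradient_waveform`.
#' @export
waveform_duration <- function(w) nrow(w$samples) * w$dt

# Effective gradient: physical samples with sign reversed after the
# refocusing pulse.
effective_gradient <- function(w) {
  g <- w$samples
  if (w$refocus_index < nrow(g))
    g[(w$refocus_index + 1L):nrow(g), ] <- -g[(w$refocus_index + 1L):nrow(g), ]
  g
}

# First moment q(t) = gamma * integral of the effective gradient,
# evaluated at interval midpoints (exact for piecewise-constant g up to
# the midpoint rule, which integrates piecewise-linear q exactly).
q_of_t <- function(w) {
  g <- effective_gradient(w)
  cs <- apply(g, 2, cumsum)
  GAMMA_H * w$dt * (cs - g / 2)
}

check_refocused <- function(w, tol = 1e-9) {
  g <- effective_gradient(w)
  q_end <- GAMMA_H * w$dt * colSums(g)
  q <- q_of_t(w)
  peak <- max(sqrt(rowSums(q^2)), .Machine$double.eps)
  if (any(abs(q_end) > tol * peak))
    stop("waveform does not refocus: residual zeroth moment ",
         format(max(abs(q_end)) / peak, digits = 3), " of peak q")
  invisible(TRUE)
}

#' Pulsed gradient spin echo (PGSE) waveform
#'
#' Two rectangular gradient lobes of duration `delta` with lobe-onset
#' spacing `Delta` (the diffusion time), one on each side of the
#' refocusing pulse.
#'
#' @param delta gradient (lobe) duration, ms.
#' @param Delta diffusion time (lobe onset separation), ms; `Delta >= delta`.
#' @param amplitude gradient amplitude, mT/m (applied along x).
#' @param dt sample interval, ms.
#' @param label stored label; `"pgse"` (default) or `"lte"` when the same
#'   shape is used as the linear-encoding arm of the muA protocol.
#' @return a `gradient_waveform`.
#' @export
make_pgse <- function(delta, Delta, amplitude, dt = 0.01, label = "pgse") {
  if (!is.finite(delta) || !is.finite(Delta) || delta <= 0 || Delta <= 0)
    stop("delta and Delta must be positive")
  if (delta > Delta) stop("delta must not exceed Delta")
  n_lobe <- round(delta / dt)
  if (n_lobe < 1L || abs(n_lobe * dt - delta) > dt)
    stop("dt must divide delta to within one sample")
  gap <- round((Delta - delta) / dt)
  n <- 2L * n_lobe + gap
  g <- numeric(n)
  g[seq_len(n_lobe)] <- amplitude
  g[(n_lobe + gap + 1L):n] <- amplitude
  gradient_waveform(cbind(g, 0, 0), dt,
                    refocus_index = n_lobe + max(gap %/% 2L, 0L),
                    label = label, nominal_frequency = 0)
}

#' Cosine-modulated oscillating gradient (OGSE) waveform
#'
#' Cosine lobes of an integer number of oscillation periods on each side
#' of the refocusing pulse; q(t) returns to zero at every lobe end.
#'
#' @param frequency oscillation frequency, Hz.
#' @param n_periods_per_lobe integer >= 1 full periods per lobe.
#' @param amplitude gradient amplitude, mT/m (along x).
#' @param dt sample interval, ms.
#' @param separation gap between the two lobes (around the 180-degree
#'   pulse), ms.
#' @param max_encoding_time optional cap on the total encoding duration,
#'   ms; exceeding it is an error.
#' @param label stored label, default `"ogse"`.
#' @return a `gradient_waveform`.
#' @export
make_ogse_cosine <- function(frequency, n_periods_per_lobe, amplitude,
                             dt = 0.01, separation = 5.5,
                             max_encoding_time = NULL, label = "ogse") {
  if (!is.finite(frequency) || frequency <= 0) stop("frequency must be > 0")
  n_periods_per_lobe <- as.integer(n_periods_per_lobe)
  if (n_periods_per_lobe < 1L) stop("n_periods_per_lobe must be >= 1")
  t_lobe <- n_periods_per_lobe * 1000 / frequency   # ms
  n_lobe <- round(t_lobe / dt)
  gap <- round(separation / dt)
  total <- (2L * n_lobe + gap) * dt
  if (!is.null(max_encoding_time) && total > max_encoding_time)
    stop(sprintf("encoding duration %.2f ms exceeds maximum %.2f ms",
                 total, max_encoding_time))
  omega <- 2 * pi * frequency / 1000                # rad/ms
  t_mid <- (seq_len(n_lobe) - 0.5) * dt
  lobe <- amplitude * cos(omega * t_mid)
  g <- c(lobe, numeric(gap), lobe)
  gradient_waveform(cbind(g, 0, 0), dt,
                    refocus_index = n_lobe + gap %/% 2L,
                    label = label, nominal_frequency = frequency)
}

#' Frequency-tuned bipolar (FTB) style low-frequency waveform
#'
#' Represented as a cosine lobe at the nominal frequency with an optional
#' bipolar pre/post segment; with `bipolar_periods = 0` it coincides with
#' the cosine OGSE shape. Downstream metric computation consumes only the
#' (frequency, b) pair, so the exact lobe shape is isolated here.
#'
#' @inheritParams make_ogse_cosine
#' @param bipolar_periods number of extra sine (bipolar) periods prepended
#'   to lobe 1 and appended to lobe 2; 0 (default) disables them.
#' @return a `gradient_waveform` with label `"ftb"`.
#' @export
make_ftb <- function(frequency, n_periods_per_lobe = 1L, amplitude,
                     dt = 0.01, separation = 5.5, bipolar_periods = 0L) {
  w <- make_ogse_cosine(frequency, n_periods_per_lobe, amplitude,
                        dt = dt, separation = separation, label = "ftb")
  if (bipolar_periods > 0L) {
    omega <- 2 * pi * frequency / 1000
    n_bi <- round(bipolar_periods * 1000 / frequency / dt)
    t_mid <- (seq_len(n_bi) - 0.5) * dt
    seg <- amplitude * sin(omega * t_mid)  # integer sine periods: zero area
    pre <- cbind(seg, 0, 0)
    g <- rbind(pre, w$samples, pre)
    w <- gradient_waveform(g, dt, refocus_index = w$refocus_index + n_bi,
                           label = "ftb", nominal_frequency = frequency)
  }
  w
}

#' Spherical tensor encoding (STE) waveform
#'
#' Three-axis waveform whose numeric b-tensor is isotropic. Each lobe is
#' split into three consecutive single-axis cosine segments carrying equal
#' diffusion weighting; because q on each axis returns to zero before the
#' next axis plays, the off-diagonal b-tensor entries vanish exactly and
#' each eigenvalue equals b/3.
#'
#' @param duration per-lobe encoding duration, ms (split over the three
#'   axes).
#' @param amplitude_scale gradient amplitude, mT/m, used on each axis.
#' @param dt sample interval, ms.
#' @param separation gap between the two lobes, ms.
#' @param n_periods_per_axis integer periods of the cosine within each
#'   per-axis segment.
#' @return a `gradient_waveform` with label `"ste"`.
#' @export
make_ste <- function(duration, amplitude_scale, dt = 0.01, separation = 5.5,
                     n_periods_per_axis = 1L) {
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  t_seg <- duration / 3
  n_seg <- round(t_seg / dt)
  if (n_seg < 4L) stop("duration too short for the sample interval")
  omega <- 2 * pi * n_periods_per_axis / t_seg      # rad/ms within segment
  t_mid <- (seq_len(n_seg) - 0.5) * dt
  seg <- amplitude_scale * cos(omega * t_mid)
  zero <- numeric(n_seg)
  lobe <- rbind(cbind(seg, zero, zero),
                cbind(zero, seg, zero),
                cbind(zero, zero, seg))
  gap <- matrix(0, round(separation / dt), 3)
  g <- rbind(lobe, gap, lobe)
  gradient_waveform(g, dt, refocus_index = nrow(lobe) + nrow(gap) %/% 2L,
                    label = "ste", nominal_frequency = 0)
}

#' Pad a waveform with zeros to a target encoding duration
#'
#' Zero samples are prepended before the first lobe and appended after the
#' second, as done to equalize TE across OGSE frequencies; the b-tensor is
#' unchanged.
#'
#' @param w a `gradient_waveform`.
#' @param target_encoding_time target total duration, ms (must be >= the
#'   current duration).
#' @return a padded `gradient_waveform`.
#' @export
pad_to_duration <- function(w, target_encoding_time) {
  n_target <- round(target_encoding_time / w$dt)
  pad <- n_target - nrow(w$samples)
  if (pad < 0L) stop("target duration shorter than the waveform")
  if (pad == 0L) return(w)
  n_pre <- pad - pad %/% 2L
  n_post <- pad %/% 2L
  g <- rbind(matrix(0, n_pre, 3), w$samples, matrix(0, n_post, 3))
  gradient_waveform(g, w$dt, refocus_index = w$refocus_index + n_pre,
                    label = w$label, nominal_frequency = w$nominal_frequency)
}

#' Rotate a waveform's gradient axes
#' @param w a `gradient_waveform`.
#' @param R a 3x3 rotation matrix.
#' @export
rotate_waveform <- function(w, R) {
  w$samples <- w$samples %*% t(R)
  w
}

#' Construct a b-tensor object
#'
#' @param matrix symmetric 3x3 matrix, ms/um^2.
#' @param shape_label optional; inferred from the eigenvalues when `NULL`.
#' @return an object of class `btensor` with fields `matrix`,
#'   `shape_label` and `bval` (the trace).
#' @export
btensor <- function(matrix, shape_label = NULL) {
  matrix <- (matrix + t(matrix)) / 2
  dimnames(matrix) <- NULL
  b <- sum(diag(matrix))
  ev <- eigen(matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9 * max(abs(ev), 1e-12))
    stop("b-tensor must be positive semidefinite")
  if (is.null(shape_label)) {
    shape_label <- if (b <= 1e-12) "spherical"
    else if (max(ev) - min(ev) < 1e-6 * b) "spherical"
    else if (sum(ev > 1e-6 * b) == 1L) "linear"
    else "general"
  }
  structure(list(matrix = matrix, shape_label = shape_label, bval = b),
            class = "btensor")
}

#' Linear (rank-1) b-tensor along a direction
#' @param b scalar b-value, ms/um^2.
#' @param n unit direction vector.
#' @export
btensor_linear <- function(b, n) {
  n <- n / sqrt(sum(n^2))
  btensor(b * tcrossprod(n), "linear")
}

#' Spherical (isotropic) b-tensor
#' @param b scalar b-value, ms/um^2.
#' @export
btensor_spherical <- function(b) btensor(diag(b / 3, 3), "spherical")

#' Numeric b-tensor of a waveform
#'
#' B = integral of q(t) q(t)^T dt over the effective (refocused) waveform,
#' with q(t) the gamma-scaled first moment of the gradient.
#'
#' @param w a refocused `gradient_waveform`.
#' @return a `btensor`.
#' @export
compute_btensor <- function(w) {
  check_refocused(w)
  q <- q_of_t(w)
  btensor(w$dt * crossprod(q))
}

#' Scalar b-value of a waveform
#' @param w a `gradient_waveform`.
#' @export
waveform_b <- function(w) compute_btensor(w)$bval

#' Rescale a waveform's amplitude to reach a target b-value
#'
#' b scales with the square of the gradient amplitude, so the samples are
#' multiplied by sqrt(b_target / b_current).
#'
#' @param w a `gradient_waveform` with non-zero amplitude.
#' @param b target b-value, ms/um^2.
#' @export
scale_to_b <- function(w, b) {
  b0 <- waveform_b(w)
  if (b0 <= 0) stop("cannot rescale a zero waveform")
  w$samples <- w$samples * sqrt(b / b0)
  w
}

#' Closed-form PGSE b-value
#'
#' b = gamma^2 G^2 delta^2 (Delta - delta/3) for rectangular lobes.
#'
#' @param delta,Delta lobe duration and diffusion time, ms.
#' @param amplitude gradient amplitude, mT/m.
#' @return b in ms/um^2.
#' @export
pgse_bvalue <- function(delta, Delta, amplitude) {
  GAMMA_H^2 * amplitude^2 * delta^2 * (Delta - delta / 3)
}

#' PGSE amplitude achieving a target b-value
#' @inheritParams pgse_bvalue
#' @param b target b-value, ms/um^2.
#' @export
pgse_amplitude <- function(delta, Delta, b) {
  sqrt(b / (GAMMA_H^2 * delta^2 * (Delta - delta / 3)))
}

#' Gradient modulation power spectrum |F(f)|^2 of q(t)
#'
#' Discrete Fourier spectrum of the effective first moment q(t),
#' normalized so that the total (one-sided) power equals the b-value
#' (Parseval). The trailing zero region implied by refocusing permits
#' zero-padding for finer frequency resolution.
#'
#' @param w a refocused `gradient_waveform`.
#' @param pad_factor zero-padding factor for frequency resolution.
#' @return list with `frequencies` (Hz, one-sided) and `power`
#'   (summed over axes; `sum(power)` equals b).
#' @export
power_spectrum <- function(w, pad_factor = 4) {
  check_refocused(w)
  q <- q_of_t(w)
  n <- nrow(q)
  m <- 2^ceiling(log2(n * pad_factor))
  qp <- rbind(q, matrix(0, m - n, 3))
  F <- stats::mvfft(qp)
  pw <- rowSums(Mod(F)^2) * w$dt / m
  half <- m %/% 2L
  folded <- pw[1:(half + 1L)]
  if (half > 1L) folded[2:half] <- folded[2:half] + pw[m:(m - half + 2L)]
  freqs <- (0:half) / (m * w$dt) * 1000   # Hz
  list(frequencies = freqs, power = folded)
}
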