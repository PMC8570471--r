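# Image phantoms and test-retest cohorts emulating the study's mouse
# acquisition: rectangular ROI bands (corpus callosum, internal capsule,
# hippocampus, cortex, thalamus) inside a CSF border, signal synthesis
# from substrates, Rician noise, and between/within-subject parameter
# variability.

#' Default per-region substrates
#'
#' Tissue regions are mixtures of two axially-symmetric Gaussian
#' sub-compartments with the same shape but mean diffusivities split by
#' +/-20% (cell-size heterogeneity, giving a small positive isotropic
#' kurtosis K_STE as observed in brain) plus a small CSF partial-volume
#' fraction; white-matter-like coherent anisotropy in the corpus
#' callosum / internal capsule, dispersed (Watson / uniform) geometry in
#' gray matter, and free water for the CSF border. Dispersion rates sit
#' in the range observed in mouse brain (about 0.005-0.007
#' um^2 ms^-1 Hz^-1/2); CSF carries a negative rate to emulate flow.
#'
#' @return named list of [substrate()] objects (CC, IC, HC, CX, TH, CSF).
#' @export
default_substrates <- function() {
  tissue <- function(ad, rd, orientation, mu = c(0, 0, 1), kappa = 2,
                     lambda_c = 0.006, csf = 0.01, split = 0.2) {
    substrate(list(
      compartment(0.5, ad * (1 + split), rd * (1 + split), orientation,
                  mu = mu, kappa = kappa, lambda_c = lambda_c),
      compartment(0.5, ad * (1 - split), rd * (1 - split), orientation,
                  mu = mu, kappa = kappa, lambda_c = lambda_c)),
      csf_fraction = csf)
  }
  list(
    CC = tissue(1.40, 0.25, "coherent", mu = c(1, 0, 0),
                lambda_c = 0.0055, csf = 0.005),
    IC = tissue(1.30, 0.30, "coherent", mu = c(0, 1, 0),
                lambda_c = 0.0051, csf = 0.005),
    HC = tissue(1.10, 0.45, "watson", mu = c(0, 0, 1),
                lambda_c = 0.0070, csf = 0.02),
    CX = tissue(1.05, 0.50, "watson", mu = c(1, 0, 0),
                lambda_c = 0.0060, csf = 0.01),
    TH = tissue(1.10, 0.45, "uniform", lambda_c = 0.0055, csf = 0.015),
    CSF = substrate(compartment(1, ad = 3.0, rd = 3.0,
                                orientation = "uniform",
                                lambda_c = -0.002))
  )
}

#' Rectangular multi-ROI phantom layout
#'
#' A one-voxel CSF border encloses five tissue bands stacked along y.
#' Label values: CC = 1, IC = 2, HC = 3, CX = 4, TH = 5, CSF = 6.
#'
#' @param nx,ny,nz grid size in voxels (default 16 x 16 x 4).
#' @param substrates named list of substrates; defaults to
#'   [default_substrates()].
#' @return list with integer `labels` array, `roi_names`,
#'   `substrates`, and `voxel_size` (mm).
#' @export
phantom_layout <- function(nx = 16, ny = 16, nz = 4,
                           substrates = default_substrates()) {
  if (nx < 7 || ny < 7 || nz < 1) stop("phantom grid too small")
  labels <- array(0L, c(nx, ny, nz))
  labels[1, , ] <- 6L; labels[nx, , ] <- 6L
  labels[, 1, ] <- 6L; labels[, ny, ] <- 6L
  inner <- ny - 2
  # proportional band heights for CC, HC, CX, TH (3 each of 14) and IC (2)
  props <- c(CC = 3, HC = 3, CX = 3, TH = 3, IC = 2) / 14
  sizes <- stats::setNames(pmax(1L, floor(props * inner)), names(props))
  while (sum(sizes) < inner) sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
  while (sum(sizes) > inner) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  ids <- c(CC = 1L, HC = 3L, CX = 4L, TH = 5L, IC = 2L)
  y0 <- 2L
  for (nm in names(sizes)) {
    labels[2:(nx - 1), y0:(y0 + sizes[nm] - 1L), ] <- ids[[nm]]
    y0 <- y0 + sizes[nm]
  }
  list(labels = labels,
       roi_names = c(CC = 1L, IC = 2L, HC = 3L, CX = 4L, TH = 5L, CSF = 6L),
       substrates = substrates,
       voxel_size = c(0.175, 0.200, 0.500))
}

#' Construct a diffusion dataset container
#'
#' @param signal 4D array (x, y, z, volume), magnitude data.
#' @param scheme an `encoding_scheme` with one entry per volume.
#' @param voxel_size length-3 voxel size, mm.
#' @param noise_sigma per-channel Gaussian sigma of the underlying
#'   complex data, if known.
#' @export
diffusion_dataset <- function(signal, scheme, voxel_size = c(0.175, 0.2, 0.5),
                              noise_sigma = NULL) {
  stopifnot(length(dim(signal)) == 4, dim(signal)[4] == n_volumes(scheme))
  if (any(signal < 0)) stop("magnitude signal must be non-negative")
  structure(list(signal = signal, scheme = scheme,
                 voxel_size = voxel_size, noise_sigma = noise_sigma),
            class = "diffusion_dataset")
}

#' @export
print.diffusion_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<diffusion_dataset: %d x %d x %d voxels, %d volumes%s>\n",
              d[1], d[2], d[3], d[4],
              if (is.null(x$noise_sigma)) "" else
                sprintf(", sigma = %.4g", x$noise_sigma)))
  invisible(x)
}

# Signals per ROI label for every volume of a scheme: matrix
# [n_labels x n_volumes].
roi_signal_table <- function(substrates_by_label, scheme,
                             n_orient_samples = 512L) {
  vols <- scheme$volumes
  out <- matrix(0, length(substrates_by_label), nrow(vols))
  for (li in seq_along(substrates_by_label)) {
    s <- substrates_by_label[[li]]
    for (v in seq_len(nrow(vols))) {
      out[li, v] <- substrate_signal(s, scheme$btensors[[v]],
                                     frequency = vols$frequency_hz[v],
                                     n_orient_samples = n_orient_samples)
    }
  }
  out
}

#' Synthesize a noiseless phantom dataset
#'
#' Every voxel of a label carries that region's substrate signal (S0 = 1).
#'
#' @param layout a [phantom_layout()] (optionally with perturbed
#'   substrates).
#' @param scheme an `encoding_scheme`.
#' @param n_orient_samples orientation grid size for dispersed substrates.
#' @return a `diffusion_dataset`.
#' @export
generate_dataset <- function(layout, scheme, n_orient_samples = 512L) {
  labs <- layout$labels
  ids <- layout$roi_names
  subs <- layout$substrates[names(ids)]
  tab <- roi_signal_table(subs, scheme, n_orient_samples)
  nv <- n_volumes(scheme)
  sig <- array(0, c(dim(labs), nv))
  flat <- as.integer(labs)
  idx_by_label <- lapply(ids, function(id) which(flat == id))
  nvox <- length(flat)
  for (li in seq_along(ids)) {
    vox <- idx_by_label[[li]]
    if (!length(vox)) next
    for (v in seq_len(nv)) sig[vox + (v - 1L) * nvox] <- tab[li, v]
  }
  diffusion_dataset(sig, scheme, layout$voxel_size)
}

#' Add Rician noise to a dataset
#'
#' The magnitude of (S + n_re) + i n_im with independent zero-mean
#' Gaussian channels of sigma = S_b0 / snr_b0, where S_b0 is the mean
#' noiseless b0 signal over the phantom.
#'
#' @param data a `diffusion_dataset`.
#' @param snr_b0 SNR at b = 0; `Inf` returns the input unchanged.
#' @param seed integer seed for reproducibility.
#' @return a `diffusion_dataset` with `noise_sigma` recorded.
#' @export
add_rician_noise <- function(data, snr_b0, seed = 1L) {
  if (snr_b0 <= 0) stop("snr_b0 must be > 0")
  if (!is.finite(snr_b0)) return(data)
  b0 <- data$scheme$volumes$bval == 0
  s_b0 <- mean(data$signal[, , , b0, drop = FALSE])
  sigma <- s_b0 / snr_b0
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- length(data$signal)
  noisy <- sqrt((data$signal + stats::rnorm(n, 0, sigma))^2 +
                  stats::rnorm(n, 0, sigma)^2)
  data$signal <- array(noisy, dim(data$signal))
  data$noise_sigma <- sigma
  data
}

#' Synthetic complex multi-average acquisition
#'
#' Complex per-average volumes with independent Gaussian channels around
#' the (real) noiseless signal; used to exercise the SNR-map analysis,
#' standing in for complex scanner data.
#'
#' @param signal 4D noiseless magnitude array (x, y, z, direction).
#' @param sigma per-channel Gaussian noise sigma.
#' @param n_averages number of repeated averages.
#' @param seed integer seed.
#' @return 5D complex array (x, y, z, direction, average).
#' @export
simulate_complex_acquisition <- function(signal, sigma, n_averages, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  d <- c(dim(signal), n_averages)
  n <- prod(d)
  re <- as.numeric(signal) + stats::rnorm(n, 0, sigma)
  im <- stats::rnorm(n, 0, sigma)
  array(complex(real = re, imaginary = im), d)
}

#' Specify a test-retest cohort
#'
#' Each subject draws, per ROI, a multiplicative diffusivity scale and a
#' dispersion-rate scale from lognormals with median 1 and coefficient of
#' variation `cv_between`; each session re-draws about the subject value
#' with `cv_within`. Scaling AD and RD jointly preserves compartment
#' shape, so every diffusivity-derived ground-truth parameter inherits
#' the nominal CV exactly.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param cv_between between-subject coefficient of variation (fraction).
#' @param cv_within session-to-session coefficient of variation.
#' @param snr_b0 SNR at b = 0 (`Inf` for noiseless).
#' @param layout a [phantom_layout()].
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_subjects = 12L, cv_between = 0.10,
                        cv_within = 0.05, snr_b0 = 40,
                        layout = phantom_layout(), seed = 1L) {
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (cv_between < 0 || cv_within < 0) stop("cv values must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 cv_between = cv_between, cv_within = cv_within,
                 snr_b0 = snr_b0, layout = layout, seed = as.integer(seed)),
            class = "cohort_spec")
}

# lognormal multiplicative factor with median 1 and coefficient of
# variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + cv^2)))
}

scale_substrate <- function(s, d_scale, lambda_scale) {
  s$compartments <- lapply(s$compartments, function(cc) {
    cc$ad <- cc$ad * d_scale
    cc$rd <- cc$rd * d_scale
    cc$lambda_c <- cc$lambda_c * lambda_scale
    cc
  })
  s
}

#' Ground-truth metric table for a set of substrates
#'
#' @param substrates named list of substrates.
#' @param f_max highest OGSE frequency (Hz) for the Delta-MD entry.
#' @return data.frame with per-ROI MD0, lambda, dMD, muA, muFA, K_lte,
#'   K_ste, FA.
#' @export
ground_truth_table <- function(substrates, f_max = 190) {
  do.call(rbind, lapply(names(substrates), function(nm) {
    s <- substrates[[nm]]
    m <- analytic_moments(s)
    lam <- sum(vapply(s$compartments, function(cc) cc$fraction * cc$lambda_c,
                      numeric(1)))
    st <- substrate_tensor(s)
    data.frame(roi = nm, MD0 = m$Dbar, lambda = lam,
               dMD = lam * sqrt(f_max), muA = m$muA, muFA = m$muFA,
               K_lte = m$K_lte, K_ste = m$K_ste, FA = st$FA)
  }))
}

#' Generate a test-retest cohort
#'
#' @param spec a [cohort_spec()].
#' @param schemes named list of `encoding_scheme`s to synthesize (e.g.
#'   `list(ogse = ..., mua = ...)`).
#' @param n_orient_samples orientation grid size for signal synthesis.
#' @return list with `subjects` (nested: subject -> session -> named
#'   datasets), `ground_truth` (data.frame of the per-subject/session true
#'   parameter scales and metric values), and the `spec`.
#' @export
generate_cohort <- function(spec, schemes, n_orient_samples = 256L) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  ids <- spec$layout$roi_names
  roi_nms <- names(ids)
  nroi <- length(roi_nms)
  subjects <- vector("list", spec$n_subjects)
  gt <- NULL
  noise_seeds <- sample.int(.Machine$integer.max - 1L,
                            spec$n_subjects * 2L * length(schemes))
  ns_i <- 0L
  for (s_i in seq_len(spec$n_subjects)) {
    d_subj <- rlnorm_cv(nroi, spec$cv_between)
    l_subj <- rlnorm_cv(nroi, spec$cv_between)
    sessions <- vector("list", 2L)
    for (sess in 1:2) {
      d_sess <- d_subj * rlnorm_cv(nroi, spec$cv_within)
      l_sess <- l_subj * rlnorm_cv(nroi, spec$cv_within)
      subs <- spec$layout$substrates[roi_nms]
      for (r in seq_len(nroi))
        subs[[r]] <- scale_substrate(subs[[r]], d_sess[r], l_sess[r])
      layout_s <- spec$layout
      layout_s$substrates <- subs
      gt_s <- ground_truth_table(subs)
      gt_s$subject <- s_i
      gt_s$session <- c("test", "retest")[sess]
      gt_s$d_scale <- d_sess
      gt_s$lambda_scale <- l_sess
      gt <- rbind(gt, gt_s)
      dsets <- list()
      for (p in names(schemes)) {
        ds <- generate_dataset(layout_s, schemes[[p]], n_orient_samples)
        ns_i <- ns_i + 1L
        ds <- add_rician_noise(ds, spec$snr_b0, seed = noise_seeds[ns_i])
        dsets[[p]] <- ds
      }
      sessions[[sess]] <- dsets
    }
    names(sessions) <- c("test", "retest")
    subjects[[s_i]] <- sessions
  }
  list(subjects = subjects, ground_truth = gt, spec = spec)
}
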