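# Generative tissue model: mixtures of axially symmetric Gaussian
# compartments with an orientation distribution and a sqrt(f) frequency
# dependence of each compartment's mean diffusivity.

#' Define a tissue compartment
#'
#' An axially symmetric Gaussian diffusion compartment. Its mean
#' diffusivity follows the power law MD(f) = MD0 + lambda_c * sqrt(f)
#' (f in Hz), applied as an isotropic scaling of the tensor so the shape
#' (and so the anisotropy) is frequency-independent.
#'
#' @param fraction signal fraction in `[0, 1]`.
#' @param ad axial diffusivity, um^2/ms.
#' @param rd radial diffusivity, um^2/ms (`0 <= rd <= ad`).
#' @param orientation `"coherent"`, `"watson"` or `"uniform"`.
#' @param mu mean axis (unit 3-vector) for coherent/watson models.
#' @param kappa Watson concentration (larger = less dispersed).
#' @param lambda_c dispersion rate of the compartment MD,
#'   um^2 ms^-1 Hz^-1/2; negative values emulate flow (CSF).
#' @return object of class `compartment`.
#' @export
compartment <- function(fraction, ad, rd, orientation = "coherent",
                        mu = c(0, 0, 1), kappa = 2, lambda_c = 0) {
  orientation <- match.arg(orientation, c("coherent", "watson", "uniform"))
  if (fraction < 0) stop("fraction must be non-negative")
  if (rd < 0 || rd > ad) stop("need 0 <= rd <= ad")
  mu <- mu / sqrt(sum(mu^2))
  structure(list(fraction = fraction, ad = ad, rd = rd,
                 orientation = orientation, mu = mu, kappa = kappa,
                 lambda_c = lambda_c),
            class = "compartment")
}

#' Define a substrate (compartment mixture)
#'
#' @param compartments list of [compartment()] objects; fractions must sum
#'   to 1 (a `csf_fraction` > 0 rescales them to `1 - csf_fraction` and
#'   appends an isotropic CSF compartment).
#' @param csf_fraction fraction of free CSF-like water.
#' @param md_csf CSF diffusivity, um^2/ms.
#' @param lambda_csf CSF dispersion rate (negative emulates flow).
#' @return object of class `substrate`.
#' @export
substrate <- function(compartments, csf_fraction = 0, md_csf = 3.0,
                      lambda_csf = -0.002) {
  if (inherits(compartments, "compartment")) compartments <- list(compartments)
  fsum <- sum(vapply(compartments, `[[`, numeric(1), "fraction"))
  if (csf_fraction > 0) {
    compartments <- lapply(compartments, function(cc) {
      cc$fraction <- cc$fraction / fsum * (1 - csf_fraction)
      cc
    })
    compartments <- c(compartments, list(
      compartment(csf_fraction, md_csf, md_csf, "uniform",
                  lambda_c = lambda_csf)))
  } else if (abs(fsum - 1) > 1e-9) {
    stop("compartment fractions must sum to 1")
  }
  structure(list(compartments = compartments), class = "substrate")
}

comp_md0 <- function(cc) (cc$ad + 2 * cc$rd) / 3

#' Analytic powder-averaged cumulants of a substrate
#'
#' Exact moments of the Gaussian mixture after powder averaging
#' (independent of each compartment's orientation model):
#' mean diffusivity `Dbar`, the variances of the directional (LTE) and
#' isotropic (STE) diffusivity distributions, the corresponding kurtoses
#' `K = 3 Var / Dbar^2`, the microscopic anisotropy
#' `muA = sqrt((Var_lte - Var_ste)/2)` and its normalized counterpart
#' `muFA = sqrt(1.5 muA^2 / (muA^2 + 0.2 Dbar^2))`.
#'
#' For one axially symmetric compartment the directional variance about
#' its own mean is (4/45)(AD - RD)^2, which is what separates LTE from
#' STE weighting.
#'
#' @param s a `substrate`.
#' @param frequency evaluate at this OGSE frequency (Hz); compartment
#'   diffusivities are scaled to MD0 + lambda_c sqrt(f).
#' @return list with `Dbar`, `Var_lte`, `Var_ste`, `K_lte`, `K_ste`,
#'   `muA`, `muFA`.
#' @export
analytic_moments <- function(s, frequency = 0) {
  f <- vapply(s$compartments, `[[`, numeric(1), "fraction")
  ad <- vapply(s$compartments, `[[`, numeric(1), "ad")
  rd <- vapply(s$compartments, `[[`, numeric(1), "rd")
  lam <- vapply(s$compartments, `[[`, numeric(1), "lambda_c")
  md0 <- (ad + 2 * rd) / 3
  scale <- 1 + lam * sqrt(frequency) / md0
  if (any(scale < 0)) stop("negative scaled diffusivity at this frequency")
  ad <- ad * scale; rd <- rd * scale; md <- md0 * scale
  Dbar <- sum(f * md)
  if (Dbar <= 0) stop("mean diffusivity is zero: kurtosis undefined")
  Var_ste <- sum(f * (md - Dbar)^2)
  Var_lte <- Var_ste + sum(f * (4 / 45) * (ad - rd)^2)
  muA2 <- (Var_lte - Var_ste) / 2
  list(Dbar = Dbar, Var_lte = Var_lte, Var_ste = Var_ste,
       K_lte = 3 * Var_lte / Dbar^2, K_ste = 3 * Var_ste / Dbar^2,
       muA = sqrt(muA2),
       muFA = sqrt(1.5 * muA2 / (muA2 + 0.2 * Dbar^2)))
}

# Deterministic orientation samples (directions + weights) for a
# compartment's orientation model. Watson weights ~ exp(kappa (mu.n)^2)
# on a Fibonacci grid (full sphere via antipodal symmetry of nn^T).
orientation_samples <- function(cc, n_samples = 512L) {
  switch(cc$orientation,
    coherent = list(dirs = matrix(cc$mu, 1), w = 1),
    uniform = {
      d <- fibonacci_directions(n_samples)
      list(dirs = d, w = rep(1 / n_samples, n_samples))
    },
    watson = {
      d <- fibonacci_directions(n_samples)
      w <- exp(cc$kappa * (d %*% cc$mu)^2)
      list(dirs = d, w = as.numeric(w / sum(w)))
    })
}

# Mean diffusion tensor of a compartment over its orientation
# distribution (used for ground-truth FA).
mean_tensor <- function(cc, n_samples = 2048L) {
  os <- orientation_samples(cc, n_samples)
  M <- matrix(0, 3, 3)
  for (i in seq_len(nrow(os$dirs)))
    M <- M + os$w[i] * tcrossprod(os$dirs[i, ])
  cc$rd * diag(3) + (cc$ad - cc$rd) * M
}

#' Ground-truth voxel-scale diffusion tensor and FA of a substrate
#'
#' The orientation-averaged (voxel-scale) tensor confounds microstructural
#' anisotropy with orientation dispersion, which is exactly what separates
#' FA from muFA.
#'
#' @param s a `substrate`.
#' @param n_samples orientation grid size for dispersed compartments.
#' @return list with the 3x3 `tensor`, `MD` and `FA`.
#' @export
substrate_tensor <- function(s, n_samples = 2048L) {
  D <- matrix(0, 3, 3)
  for (cc in s$compartments)
    D <- D + cc$fraction * mean_tensor(cc, n_samples)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  list(tensor = D, MD = mean(ev), FA = fa_from_eigenvalues(ev))
}

fa_from_eigenvalues <- function(ev) {
  ev <- pmax(ev, 0)
  m <- mean(ev)
  denom <- sum(ev^2)
  if (denom <= 0) return(0)
  sqrt(1.5 * sum((ev - m)^2) / denom)
}

#' Noiseless normalized signal of a substrate under a b-tensor
#'
#' S/S0 = sum_i f_i E_n[exp(-B : D_i(n, f))], with the orientation
#' expectation taken over each compartment's orientation model by
#' deterministic weighted sampling, and D_i scaled isotropically so its
#' MD follows MD0 + lambda_c sqrt(f).
#'
#' @param s a `substrate`.
#' @param B a `btensor` (or plain 3x3 matrix, ms/um^2).
#' @param frequency OGSE frequency, Hz.
#' @param n_orient_samples orientation grid size for dispersed models.
#' @return scalar normalized signal.
#' @export
substrate_signal <- function(s, B, frequency = 0, n_orient_samples = 512L) {
  Bm <- if (inherits(B, "btensor")) B$matrix else B
  trB <- sum(diag(Bm))
  S <- 0
  for (cc in s$compartments) {
    md0 <- comp_md0(cc)
    scale <- 1 + cc$lambda_c * sqrt(frequency) / md0
    if (scale < 0) stop("negative scaled diffusivity at f = ", frequency)
    ad <- cc$ad * scale; rd <- cc$rd * scale
    if (trB <= 0) {
      S <- S + cc$fraction
    } else if (ad == rd) {
      S <- S + cc$fraction * exp(-trB * ad)
    } else {
      os <- orientation_samples(cc, n_orient_samples)
      quad <- rowSums((os$dirs %*% Bm) * os$dirs)  # n^T B n per direction
      S <- S + cc$fraction *
        sum(os$w * exp(-(rd * trB + (ad - rd) * quad)))
    }
  }
  S
}

#' Brute-force powder-averaged cumulants (oracle)
#'
#' Estimates Dbar and the LTE/STE variances by direct averaging of
#' per-direction diffusivities over a large uniform direction sample;
#' serves as an independent check of [analytic_moments()].
#'
#' @param s a `substrate`.
#' @param n_dirs number of uniformly sampled directions.
#' @return list matching [analytic_moments()].
#' @export
brute_force_moments <- function(s, n_dirs = 1e5) {
  dirs <- fibonacci_directions(n_dirs)
  f <- vapply(s$compartments, `[[`, numeric(1), "fraction")
  # per (compartment, direction) apparent diffusivity n^T D n for a
  # randomized orientation of each compartment axis: by symmetry we can
  # instead orient the compartment along +z and sample directions.
  Dbar <- 0; E2_lte <- 0
  md <- numeric(length(f))
  for (i in seq_along(s$compartments)) {
    cc <- s$compartments[[i]]
    cth2 <- dirs[, 3]^2
    dapp <- cc$rd + (cc$ad - cc$rd) * cth2
    md[i] <- (cc$ad + 2 * cc$rd) / 3
    Dbar <- Dbar + f[i] * mean(dapp)
    E2_lte <- E2_lte + f[i] * mean(dapp^2)
  }
  Var_lte <- E2_lte - Dbar^2
  Var_ste <- sum(f * (md - Dbar)^2)
  muA2 <- (Var_lte - Var_ste) / 2
  list(Dbar = Dbar, Var_lte = Var_lte, Var_ste = Var_ste,
       K_lte = 3 * Var_lte / Dbar^2, K_ste = 3 * Var_ste / Dbar^2,
       muA = sqrt(max(0, muA2)),
       muFA = sqrt(1.5 * muA2 / (muA2 + 0.2 * Dbar^2)))
}
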