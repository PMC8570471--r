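# Microscopic anisotropy from powder-averaged LTE/STE signals: joint
# non-negative least-squares kurtosis fit with a diffusivity shared
# between the two encodings.
#
# Model per encoding X in {LTE, STE}:
#   ln S_X(b) = c - b D + (b^2 / 6) w_X,     w_X = D^2 K_X
# with shared intercept c and diffusivity D, subject to
#   D >= 0,  w_LTE >= w_STE >= 0.
# Then muA^2 = D^2 (K_LTE - K_STE) / 6 = (w_LTE - w_STE) / 6 and
# muFA = sqrt(1.5 muA^2 / (muA^2 + 0.2 D^2)).

#' Powder-average a muA-protocol dataset
#'
#' Arithmetic mean of the magnitude signal over directions per
#' (encoding, b-value); all b0 volumes are averaged into a shared b = 0
#' point.
#'
#' @param data a `diffusion_dataset` whose scheme labels volumes
#'   `lte` / `ste` / b0.
#' @return object of class `powder_series`: list with data.frame `shells`
#'   (`encoding`, `bval`, `n_dirs`) and matrix `mean_signal`
#'   (voxels x shells), plus the voxel `dims`.
#' @export
powder_average <- function(data) {
  vols <- data$scheme$volumes
  enc <- ifelse(vols$bval == 0, "b0", vols$label)
  if (!any(enc == "lte") || !any(enc == "ste"))
    stop("powder averaging needs both lte and ste volumes")
  if (!any(enc == "b0")) stop("powder averaging needs b0 volumes")
  key <- paste(enc, round(vols$bval, 9))
  groups <- split(seq_len(nrow(vols)), key)
  dims <- dim(data$signal)[1:3]
  S <- matrix(data$signal, prod(dims), nrow(vols))
  shells <- NULL
  M <- NULL
  for (g in groups) {
    shells <- rbind(shells, data.frame(
      encoding = enc[g[1]], bval = vols$bval[g[1]], n_dirs = length(g)))
    M <- cbind(M, rowMeans(S[, g, drop = FALSE]))
  }
  o <- order(shells$encoding, shells$bval)
  structure(list(shells = shells[o, ], mean_signal = M[, o, drop = FALSE],
                 dims = dims),
            class = "powder_series")
}

# Design matrix rows for the joint fit, in parameters
# theta = (c, D, w_S, dw) with w_L = w_S + dw.
joint_design <- function(shells) {
  b <- shells$bval
  is_lte <- shells$encoding == "lte"
  # b0 rows contribute to both encodings identically
  cbind(1, -b, b^2 / 6, (b^2 / 6) * as.numeric(is_lte))
}

# Exact solution of min ||A theta - y||^2 s.t. theta[2:4] >= 0 by
# enumeration of the 2^3 active sets: convex QP with 3 bound
# constraints, so the optimum is the feasible reduced least-squares
# solution with the smallest residual.
solve_bounded_ls <- function(solvers, y) {
  best <- NULL; best_ss <- Inf
  for (s in solvers) {
    theta <- numeric(4)
    th <- s$solve %*% y
    theta[s$free] <- th
    if (any(theta[2:4] < -1e-12)) next
    r <- y - s$A_free %*% th
    ss <- sum(r^2)
    if (ss < best_ss - 1e-12) { best_ss <- ss; best <- pmax(theta, c(-Inf, 0, 0, 0)) }
  }
  best
}

precompute_solvers <- function(A) {
  free_sets <- list(1:4, c(1, 2, 3), c(1, 2, 4), c(1, 3, 4),
                    c(1, 2), c(1, 3), c(1, 4), 1)
  lapply(free_sets, function(fr) {
    Af <- A[, fr, drop = FALSE]
    list(free = fr, A_free = Af,
         solve = solve(crossprod(Af)) %*% t(Af))
  })
}

#' Joint constrained kurtosis fit of powder-averaged LTE/STE signals
#'
#' Fits the cumulant (kurtosis) signal representation jointly to the two
#' encodings with shared intercept and diffusivity, under the
#' non-negativity constraints D >= 0 and w_LTE >= w_STE >= 0 (the
#' ordering enforces muA^2 >= 0). The problem is linear in
#' (ln S0, D, w_STE, w_LTE - w_STE) and solved exactly per voxel by
#' active-set enumeration.
#'
#' @param p a `powder_series` with at least 3 b-values per encoding
#'   including b = 0.
#' @param d_floor D below this value (um^2/ms) flags the voxel and sets
#'   its kurtosis/muFA maps to NaN.
#' @param max_b optionally exclude shells with b above this value
#'   (noise-floor mitigation; not applied by default).
#' @return object of class `mua_fit`: 3D arrays `s0`, `D`, `K_lte`,
#'   `K_ste`, `muA`, `muFA`, logical `flagged`, and `n_clipped` (voxels
#'   where the LTE-STE ordering constraint was active).
#' @export
joint_kurtosis_fit <- function(p, d_floor = 0.1, max_b = NULL) {
  shells <- p$shells
  keep <- rep(TRUE, nrow(shells))
  if (!is.null(max_b)) keep <- shells$bval <= max_b | shells$bval == 0
  shells <- shells[keep, ]
  for (e in c("lte", "ste")) {
    nb <- length(unique(shells$bval[shells$encoding %in% c(e, "b0")]))
    if (nb < 3L) stop("need at least 3 b-values (incl. b = 0) per encoding")
  }
  A <- joint_design(shells)
  solvers <- precompute_solvers(A)
  M <- p$mean_signal[, keep, drop = FALSE]
  nvox <- nrow(M)
  out <- matrix(NaN, nvox, 4)
  bad <- rowSums(M <= 0) > 0
  n_clip <- 0L
  for (v in which(!bad)) {
    theta <- solve_bounded_ls(solvers, log(M[v, ]))
    if (theta[4] <= 1e-12) n_clip <- n_clip + 1L
    out[v, ] <- theta
  }
  D <- out[, 2]
  w_s <- out[, 3]; dw <- out[, 4]
  K_lte <- ifelse(D > d_floor, 6 * (w_s + dw) / (6 * D^2), NaN)
  K_ste <- ifelse(D > d_floor, 6 * w_s / (6 * D^2), NaN)
  muA <- sqrt(pmax(0, dw / 6))
  # clamp at 1: cumulant truncation can push muA^2 slightly past the
  # stick limit 0.4 D^2
  muFA <- ifelse(D > d_floor,
                 pmin(1, sqrt(1.5 * (dw / 6) / (dw / 6 + 0.2 * D^2))), NaN)
  dims <- p$dims
  structure(list(
    s0 = array(exp(out[, 1]), dims), D = array(D, dims),
    K_lte = array(K_lte, dims), K_ste = array(K_ste, dims),
    muA = array(muA, dims), muFA = array(muFA, dims),
    flagged = array(bad | !(D > d_floor), dims),
    n_clipped = n_clip), class = "mua_fit")
}

#' Microscopic anisotropy from a joint fit
#'
#' muA = sqrt(max(0, D^2 (K_LTE - K_STE) / 6)); negative arguments are
#' clipped (the fit's ordering constraint already guarantees
#' non-negativity, so clips only arise on externally supplied maps).
#'
#' @param fit a `mua_fit` (or any list with `D`, `K_lte`, `K_ste`).
#' @return 3D muA array.
#' @export
mua_from_fit <- function(fit) {
  arg <- fit$D^2 * (fit$K_lte - fit$K_ste) / 6
  n_clip <- sum(arg < 0, na.rm = TRUE)
  if (n_clip > 0)
    message(n_clip, " voxels with negative muA^2 clipped to 0")
  sqrt(pmax(arg, 0))  # array first: pmax keeps its attributes
}

#' Two-point microscopic anisotropy estimate
#'
#' Direct evaluation of muA^2 = ln(S_LTE / S_STE) / b^2 from
#' powder-averaged signals at a single shared b-value (the closed-form
#' counterpart of the joint fit, exact when the diffusivities of the two
#' encodings cancel).
#'
#' @param S_lte,S_ste powder-averaged signals (arrays of equal shape).
#' @param b shared b-value, ms/um^2.
#' @return array of muA values.
#' @export
direct_mua <- function(S_lte, S_ste, b) {
  if (b <= 0) stop("b must be > 0")
  sqrt(pmax(0, log(S_lte / S_ste)) / b^2)
}

#' Microscopic fractional anisotropy from muA and D
#'
#' muFA = sqrt(1.5 muA^2 / (muA^2 + 0.2 D^2)); equals 1 in the stick
#' limit muA^2 = 0.4 D^2 and 0 for isotropic substrates.
#'
#' @param mua_map muA array.
#' @param d_map diffusivity array (same shape); D = 0 yields NaN.
#' @return muFA array in `[0, 1]`.
#' @export
mufa <- function(mua_map, d_map) {
  out <- pmin(sqrt(1.5 * mua_map^2 / (mua_map^2 + 0.2 * d_map^2)), 1)
  out[d_map <= 0] <- NaN
  out
}
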