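# Per-frequency diffusion tensor fitting, Delta-MD and the diffusion
# dispersion rate Lambda: MD(f) = MD0 + Lambda * sqrt(f), f in Hz.

linear_labels <- c("pgse", "ogse", "ftb", "lte")

#' Log-linear diffusion tensor fit for one frequency subset
#'
#' Ordinary (unweighted) log-linear least squares of the single-shell
#' tensor model per voxel, using the b0 volumes plus the
#' linearly-encoded volumes at `frequency`. MD is the tensor trace / 3;
#' FA uses the standard eigenvalue formula with negative eigenvalues
#' clamped to zero (for FA only).
#'
#' @param data a `diffusion_dataset`.
#' @param frequency which frequency subset to fit (Hz); 0 selects
#'   PGSE/LTE volumes.
#' @param labels restrict to these volume labels (default: any linear
#'   encoding).
#' @param bval optionally restrict the shell (ms/um^2); e.g. 1.0 to use
#'   only the b = 1 LTE arm of the muA protocol.
#' @return list with 3D arrays `MD`, `FA`, `S0` and logical `flagged`
#'   (voxels with non-positive signal, set to NaN in the maps).
#' @export
fit_tensor <- function(data, frequency = 0, labels = linear_labels,
                       bval = NULL) {
  vols <- data$scheme$volumes
  sel <- vols$bval > 0 & vols$frequency_hz == frequency &
    vols$label %in% labels & !is.na(vols$gx)
  if (!is.null(bval)) sel <- sel & abs(vols$bval - bval) < 1e-9
  b0 <- vols$bval == 0
  dirs <- as.matrix(vols[sel, c("gx", "gy", "gz")])
  if (sum(sel) < 6L || nrow(unique(round(abs(dirs), 6))) < 6L)
    stop("tensor fit needs at least 6 unique directions plus b0 volumes")
  if (!any(b0)) stop("tensor fit needs at least one b0 volume")
  use <- which(b0 | sel)
  bv <- vols$bval[use]
  g <- as.matrix(vols[use, c("gx", "gy", "gz")])
  g[is.na(g)] <- 0
  X <- cbind(1, -bv * g[, 1]^2, -bv * g[, 2]^2, -bv * g[, 3]^2,
             -2 * bv * g[, 1] * g[, 2], -2 * bv * g[, 1] * g[, 3],
             -2 * bv * g[, 2] * g[, 3])
  dims <- dim(data$signal)[1:3]
  nvox <- prod(dims)
  S <- matrix(data$signal, nvox, dim(data$signal)[4])[, use, drop = FALSE]
  bad <- rowSums(S <= 0) > 0
  Slog <- log(pmax(S, .Machine$double.xmin))
  beta <- solve(crossprod(X), crossprod(X, t(Slog)))  # 7 x nvox
  md <- colSums(beta[2:4, , drop = FALSE]) / 3
  fa <- numeric(nvox)
  for (v in which(!bad)) {
    D <- matrix(c(beta[2, v], beta[5, v], beta[6, v],
                  beta[5, v], beta[3, v], beta[7, v],
                  beta[6, v], beta[7, v], beta[4, v]), 3, 3)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    fa[v] <- fa_from_eigenvalues(ev)
  }
  md[bad] <- NaN; fa[bad] <- NaN
  s0 <- exp(beta[1, ]); s0[bad] <- NaN
  list(MD = array(md, dims), FA = array(fa, dims), S0 = array(s0, dims),
       flagged = array(bad, dims))
}

#' Per-frequency MD maps of an OGSE dataset
#'
#' @param data a `diffusion_dataset` acquired with the OGSE protocol.
#' @return object of class `md_series`: list with sorted `frequencies`
#'   (Hz) and `md_maps` (list of 3D arrays), plus the 0 Hz `FA` map as a
#'   DTI reference.
#' @export
md_series <- function(data) {
  freqs <- sort(unique(data$scheme$volumes$frequency_hz[
    data$scheme$volumes$bval > 0]))
  fits <- lapply(freqs, function(f) fit_tensor(data, frequency = f))
  structure(list(frequencies = freqs,
                 md_maps = lapply(fits, `[[`, "MD"),
                 fa0 = fits[[which(freqs == 0)[1]]]$FA),
            class = "md_series")
}

#' Delta-MD map: MD at the highest frequency minus MD at 0 Hz
#'
#' @param series an `md_series` containing f = 0 and the maximum
#'   frequency.
#' @return 3D array.
#' @export
delta_md <- function(series) {
  f <- series$frequencies
  if (!any(f == 0)) stop("series must contain the f = 0 (PGSE) map")
  series$md_maps[[which.max(f)]] - series$md_maps[[which(f == 0)[1]]]
}

#' Voxel-wise dispersion fit MD(f) = MD0 + Lambda sqrt(f)
#'
#' Ordinary least squares of MD against sqrt(f) per voxel.
#'
#' @param series an `md_series` with at least 2 distinct frequencies.
#' @return list with 3D arrays `md0_map`, `lambda_map` and
#'   `residual_map` (RMS residual).
#' @export
fit_dispersion <- function(series) {
  f <- series$frequencies
  if (length(unique(f)) < 2L) stop("need at least 2 distinct frequencies")
  X <- cbind(1, sqrt(f))
  dims <- dim(series$md_maps[[1]])
  Y <- matrix(unlist(lapply(series$md_maps, as.numeric)),
              nrow = prod(dims))                                # nvox x nf
  beta <- t(solve(crossprod(X), crossprod(X, t(Y))))            # nvox x 2
  resid <- Y - beta %*% t(X)
  list(md0_map = array(beta[, 1], dims),
       lambda_map = array(beta[, 2], dims),
       residual_map = array(sqrt(rowMeans(resid^2)), dims))
}

#' ROI-level dispersion analysis
#'
#' ROI means of MD are taken first at each frequency (the first
#' non-signal parameter computed), then Delta-MD and Lambda are obtained
#' from the ROI means — the ROI-averaging convention of the study.
#'
#' @param series an `md_series`.
#' @param labels integer ROI label array (0 = background).
#' @param mask optional logical array of voxels to keep (e.g. the CSF
#'   mask); ROIs empty after masking are dropped.
#' @param roi_names optional named integer vector mapping names to label
#'   values.
#' @return data.frame with one row per ROI: `roi`, `n_voxels`, mean MD
#'   per frequency (`md_<f>`), `dMD`, `md0`, `lambda`.
#' @export
roi_dispersion <- function(series, labels, mask = NULL, roi_names = NULL) {
  f <- series$frequencies
  ids <- if (is.null(roi_names)) {
    u <- sort(setdiff(unique(as.integer(labels)), 0L))
    stats::setNames(u, paste0("roi", u))
  } else roi_names
  keep <- if (is.null(mask)) rep(TRUE, length(labels)) else as.logical(mask)
  X <- cbind(1, sqrt(f))
  out <- NULL
  for (nm in names(ids)) {
    vox <- which(as.integer(labels) == ids[[nm]] & keep)
    if (!length(vox)) next
    mds <- vapply(series$md_maps, function(m) mean(m[vox]), numeric(1))
    beta <- solve(crossprod(X), crossprod(X, mds))
    row <- data.frame(roi = nm, n_voxels = length(vox))
    for (i in seq_along(f)) row[[paste0("md_", f[i])]] <- mds[i]
    row$dMD <- if (any(f == 0)) mds[which.max(f)] - mds[which(f == 0)[1]] else NA_real_
    row$md0 <- beta[1]; row$lambda <- beta[2]
    out <- rbind(out, row)
  }
  out
}
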