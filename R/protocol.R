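# Acquisition schemes: per-volume encoding descriptions for the
# multifrequency OGSE protocol and the LTE/STE microscopic-anisotropy
# protocol.

#' Deterministic quasi-uniform direction set
#'
#' Fibonacci-sphere points, antipodally reduced to a hemisphere, with an
#' optional seeded random rotation applied to the whole set (diffusion
#' encoding is antipodally symmetric, so the hemisphere reduction loses
#' nothing).
#'
#' @param n number of directions.
#' @param seed optional integer; when given, a uniformly random rotation
#'   drawn from this seed is applied to the set.
#' @return n x 3 matrix of unit row vectors.
#' @export
fibonacci_directions <- function(n, seed = NULL) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  # z restricted to [0, 1): hemisphere sampling, antipodally reduced
  z <- i / n
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  if (!is.null(seed)) {
    R <- random_rotation(seed)
    dirs <- dirs %*% t(R)
  }
  dirs / sqrt(rowSums(dirs^2))
}

# Uniformly random rotation matrix from a seed (QR of a Gaussian matrix,
# sign-corrected to det +1).
random_rotation <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Construct an encoding scheme
#'
#' @param volumes data.frame with columns `index`, `label`,
#'   `frequency_hz`, `bval` (ms/um^2), `gx`, `gy`, `gz` (unit direction,
#'   NA for b0 and ste volumes).
#' @param btensors list of `btensor` objects, one per volume.
#' @return object of class `encoding_scheme`.
#' @export
encoding_scheme <- function(volumes, btensors) {
  stopifnot(nrow(volumes) == length(btensors))
  dwi <- volumes$bval > 0
  dirs <- as.matrix(volumes[, c("gx", "gy", "gz")])
  has_dir <- dwi & !is.na(dirs[, 1])
  if (any(has_dir)) {
    norms <- sqrt(rowSums(dirs[has_dir, , drop = FALSE]^2))
    if (any(abs(norms - 1) > 1e-9))
      stop("encoding directions must be unit norm")
  }
  for (i in which(dwi)) {
    if (abs(btensors[[i]]$bval - volumes$bval[i]) >
        1e-6 * max(volumes$bval[i], 1e-12))
      stop("b-tensor trace disagrees with bval at volume ", i)
  }
  structure(list(volumes = volumes, btensors = btensors,
                 n_b0 = sum(!dwi)),
            class = "encoding_scheme")
}

#' @export
print.encoding_scheme <- function(x, ...) {
  cat(sprintf("<encoding_scheme: %d volumes (%d b0)>\n",
              nrow(x$volumes), x$n_b0))
  print(table(label = x$volumes$label,
              b = round(x$volumes$bval, 3)))
  invisible(x)
}

#' Number of volumes in a scheme
#' @param x an `encoding_scheme`.
#' @export
n_volumes <- function(x) nrow(x$volumes)

# Intersperse n_b0 zero rows evenly through n_dwi weighted rows: a b0 is
# placed at the start of each of n_b0 evenly sized blocks.
intersperse_b0 <- function(dwi_rows, n_b0) {
  n_dwi <- nrow(dwi_rows)
  block <- ceiling(n_dwi / n_b0)
  out <- NULL
  taken <- 0L
  for (k in seq_len(n_b0)) {
    b0row <- data.frame(label = "b0", frequency_hz = 0, bval = 0,
                        gx = NA_real_, gy = NA_real_, gz = NA_real_)
    hi <- min(taken + block, n_dwi)
    blockrows <- if (taken < hi) dwi_rows[(taken + 1L):hi, , drop = FALSE] else NULL
    out <- rbind(out, b0row, blockrows)
    taken <- hi
  }
  if (taken < n_dwi) out <- rbind(out, dwi_rows[(taken + 1L):n_dwi, , drop = FALSE])
  out
}

#' Build one of the study's acquisition schemes
#'
#' `kind = "ogse"`: PGSE (0 Hz) plus cosine OGSE at 50 (FTB-labelled),
#' 100, 145 and 190 Hz, 10 directions each at b = 0.8 ms/um^2, with 10
#' interspersed b0 volumes (60 volumes total). `kind = "mua"`: LTE and
#' STE at b = 2.0 ms/um^2 (30 directions each) and b = 1.0 ms/um^2 (12
#' each), with 8 interspersed b0 volumes (92 volumes total). Direction
#' sets are deterministic given `seed`.
#'
#' @param kind `"ogse"` or `"mua"`.
#' @param config optional list overriding protocol constants; recognized
#'   entries for `"ogse"`: `frequencies`, `bval`, `n_dir`, `n_b0`; for
#'   `"mua"`: `bvals`, `n_dir` (same length as `bvals`), `n_b0`.
#' @param seed integer controlling the direction-set orientation.
#' @return an `encoding_scheme`.
#' @export
build_protocol <- function(kind, config = list(), seed = 1L) {
  kind <- match.arg(kind, c("ogse", "mua"))
  if (kind == "ogse") {
    frequencies <- config$frequencies %||% c(0, 50, 100, 145, 190)
    bval <- config$bval %||% 0.8
    n_dir <- config$n_dir %||% 10L
    n_b0 <- config$n_b0 %||% 10L
    rows <- NULL
    for (f in frequencies) {
      dirs <- fibonacci_directions(n_dir, seed = seed + round(f))
      lab <- if (f == 0) "pgse" else if (f == 50) "ftb" else "ogse"
      rows <- rbind(rows, data.frame(
        label = lab, frequency_hz = f, bval = bval,
        gx = dirs[, 1], gy = dirs[, 2], gz = dirs[, 3]))
    }
  } else {
    bvals <- config$bvals %||% c(2.0, 1.0)
    n_dir <- config$n_dir %||% c(30L, 12L)
    n_b0 <- config$n_b0 %||% 8L
    rows <- NULL
    for (i in seq_along(bvals)) {
      dirs <- fibonacci_directions(n_dir[i], seed = seed + i)
      rows <- rbind(rows,
        data.frame(label = "lte", frequency_hz = 0, bval = bvals[i],
                   gx = dirs[, 1], gy = dirs[, 2], gz = dirs[, 3]),
        data.frame(label = "ste", frequency_hz = 0, bval = bvals[i],
                   gx = rep(NA_real_, n_dir[i]), gy = NA_real_,
                   gz = NA_real_))
    }
  }
  vols <- intersperse_b0(rows, n_b0)
  vols <- cbind(index = seq_len(nrow(vols)), vols)
  rownames(vols) <- NULL
  btensors <- lapply(seq_len(nrow(vols)), function(i) {
    if (vols$bval[i] == 0) {
      btensor(matrix(0, 3, 3), "spherical")
    } else if (vols$label[i] == "ste") {
      btensor_spherical(vols$bval[i])
    } else {
      btensor_linear(vols$bval[i], c(vols$gx[i], vols$gy[i], vols$gz[i]))
    }
  })
  encoding_scheme(vols, btensors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
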