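# File interfaces (NIfTI volumes, encoding tables, FSL bval/bvec, JSON
# reports) and the end-to-end pipeline: simulate -> fit -> reproducibility
# statistics.

#' Write a diffusion dataset to disk
#'
#' Writes `<prefix>.nii.gz` (4D signal), `<prefix>_encoding.tsv` (the
#' per-volume table, b-values in s/mm^2), and FSL-style `<prefix>.bval` /
#' `<prefix>.bvec` covering the linearly encoded and b0 volumes.
#'
#' @param data a `diffusion_dataset`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(data, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  nii <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(data$signal)
  RNifti::pixdim(img) <- c(data$voxel_size, 1)
  RNifti::writeNifti(img, nii)
  vols <- data$scheme$volumes
  tab <- data.frame(index = vols$index, label = vols$label,
                    frequency_hz = vols$frequency_hz,
                    bval_s_mm2 = round(vols$bval * 1000, 6),
                    gx = vols$gx, gy = vols$gy, gz = vols$gz)
  tsv <- paste0(prefix, "_encoding.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  # FSL files: b0s and linear volumes (ste has no single direction)
  lin <- vols$label != "ste" | vols$bval == 0
  bv <- vols$bval[lin] * 1000
  g <- t(as.matrix(vols[lin, c("gx", "gy", "gz")]))
  g[is.na(g)] <- 0
  bvalf <- paste0(prefix, ".bval"); bvecf <- paste0(prefix, ".bvec")
  writeLines(paste(format(bv, trim = TRUE), collapse = " "), bvalf)
  writeLines(apply(format(g, trim = TRUE, digits = 10), 1, paste,
                   collapse = " "), bvecf)
  invisible(c(nii = nii, tsv = tsv, bval = bvalf, bvec = bvecf))
}

#' Read a diffusion dataset written by [write_dataset()]
#'
#' Cross-checks volume counts and, when bval/bvec files are present,
#' their agreement with the encoding table (tolerance 1 s/mm^2).
#'
#' @param prefix path prefix used at write time.
#' @return a `diffusion_dataset`.
#' @export
read_dataset <- function(prefix) {
  nii <- paste0(prefix, ".nii.gz")
  tsv <- paste0(prefix, "_encoding.tsv")
  if (!file.exists(nii)) stop("missing image file: ", nii)
  if (!file.exists(tsv)) stop("missing encoding table: ", tsv)
  img <- RNifti::readNifti(nii)
  sig <- array(as.numeric(img), dim(img))
  tab <- utils::read.table(tsv, header = TRUE, sep = "\t",
                           na.strings = c("NA", ""))
  nv <- dim(sig)[4]
  if (nrow(tab) != nv)
    stop(sprintf("encoding table has %d rows but image has %d volumes; first missing volume index: %d",
                 nrow(tab), nv, min(nrow(tab), nv) + 1L))
  vols <- data.frame(index = tab$index, label = tab$label,
                     frequency_hz = tab$frequency_hz,
                     bval = tab$bval_s_mm2 / 1000,
                     gx = tab$gx, gy = tab$gy, gz = tab$gz)
  bvalf <- paste0(prefix, ".bval")
  if (file.exists(bvalf)) {
    bv <- scan(bvalf, quiet = TRUE)
    lin <- vols$label != "ste" | vols$bval == 0
    ref <- vols$bval[lin] * 1000
    if (length(bv) != sum(lin) || any(abs(bv - ref) > 1))
      stop("bval file disagrees with the encoding table at volume ",
           vols$index[lin][which(abs(bv - ref) > 1)[1]])
  }
  btensors <- lapply(seq_len(nrow(vols)), function(i) {
    if (vols$bval[i] == 0) btensor(matrix(0, 3, 3), "spherical")
    else if (vols$label[i] == "ste") btensor_spherical(vols$bval[i])
    else btensor_linear(vols$bval[i], c(vols$gx[i], vols$gy[i], vols$gz[i]))
  })
  vx <- RNifti::pixdim(img)[1:3]
  if (is.null(vx) || !length(vx)) vx <- c(0.175, 0.2, 0.5)
  diffusion_dataset(sig, encoding_scheme(vols, btensors), voxel_size = vx)
}

#' Write a label map as integer NIfTI
#' @param labels integer 3D array.
#' @param path output `.nii.gz` path.
#' @export
write_labels <- function(labels, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(labels, datatype = "int16"), path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Protocol constants (frequencies, b-values, direction and b0 counts),
#' phantom geometry, cohort variability, masking thresholds and
#' statistics options, reproducing the study's design by default.
#'
#' @param seed master seed for the run.
#' @return a named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n_subjects = 12L,
    cv_between = 0.10, cv_within = 0.05, snr_b0 = 40,
    phantom = list(nx = 16L, ny = 16L, nz = 4L),
    ogse = list(frequencies = c(0, 50, 100, 145, 190), bval = 0.8,
                n_dir = 10L, n_b0 = 10L),
    mua = list(bvals = c(2.0, 1.0), n_dir = c(30L, 12L), n_b0 = 8L),
    csf_threshold = 0.9, mad_k = 3,
    alpha = 0.05, power = 0.80,
    effect_sizes = c(0.04, 0.06, 0.08, 0.10, 0.12),
    n_orient_samples = 256L,
    protocols = c("ogse", "mua")
  )
}

# Per-subject/session metric table rows for one cohort entry.
fit_session_metrics <- function(dsets, layout, csf_threshold = 0.9) {
  ids <- layout$roi_names
  tissue_ids <- ids[names(ids) != "CSF"]
  rows <- NULL
  add <- function(rows, metric, df) {
    rbind(rows, data.frame(metric = metric, roi = df$roi, value = df$mean))
  }
  if (!is.null(dsets$ogse)) {
    series <- md_series(dsets$ogse)
    mask <- csf_mask(series$md_maps[[which(series$frequencies == 0)]],
                     csf_threshold)
    roi_d <- roi_dispersion(series, layout$labels, mask = mask,
                            roi_names = tissue_ids)
    rows <- add(rows, "MD0", data.frame(roi = roi_d$roi, mean = roi_d$md0))
    rows <- add(rows, "lambda", data.frame(roi = roi_d$roi, mean = roi_d$lambda))
    rows <- add(rows, "dMD", data.frame(roi = roi_d$roi, mean = roi_d$dMD))
    f0 <- which(series$frequencies == 0)
    rows <- add(rows, "MD_pgse",
                roi_means(series$md_maps[[f0]], layout$labels, tissue_ids,
                          mask = mask, erode = FALSE))
    rows <- add(rows, "FA_pgse",
                roi_means(series$fa0, layout$labels, tissue_ids, mask = mask,
                          erode = FALSE))
  }
  if (!is.null(dsets$mua)) {
    fit <- joint_kurtosis_fit(powder_average(dsets$mua))
    # CSF rule needs an MD0 map; from the muA protocol use the fitted D
    mask <- csf_mask(fit$D, csf_threshold)
    for (m in c("muA", "muFA", "K_lte", "K_ste", "D")) {
      rows <- add(rows, m,
                  roi_means(fit[[m]], layout$labels, tissue_ids, mask = mask,
                            erode = FALSE))
    }
  }
  rows
}

#' Run the full simulation-to-report pipeline
#'
#' Simulates a test-retest cohort, fits the OGSE and muA metrics per
#' subject and session, assembles per-metric test-retest tables, and
#' computes the reproducibility report (Bland-Altman, CVs, sample sizes)
#' per metric and ROI. Identical config and seed give identical output.
#'
#' @param config a [default_config()]-style list.
#' @param out_dir optional directory; when given, the resolved config,
#'   per-metric tables (TSV) and the JSON summary are written there.
#' @return list with `tables` (per-metric test-retest data.frames),
#'   `report` (per-metric reproducibility data.frames), `ground_truth`,
#'   and `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  layout <- phantom_layout(config$phantom$nx, config$phantom$ny,
                           config$phantom$nz)
  schemes <- list()
  if ("ogse" %in% config$protocols)
    schemes$ogse <- build_protocol("ogse", config$ogse, seed = config$seed)
  if ("mua" %in% config$protocols)
    schemes$mua <- build_protocol("mua", config$mua, seed = config$seed)
  spec <- cohort_spec(config$n_subjects, config$cv_between,
                      config$cv_within, config$snr_b0, layout,
                      seed = config$seed)
  cohort <- generate_cohort(spec, schemes,
                            n_orient_samples = config$n_orient_samples)
  rows <- NULL
  for (s_i in seq_along(cohort$subjects)) {
    for (sess in c("test", "retest")) {
      mt <- fit_session_metrics(cohort$subjects[[s_i]][[sess]], layout,
                                config$csf_threshold)
      mt$subject <- s_i
      mt$session <- sess
      rows <- rbind(rows, mt)
    }
  }
  tables <- split(rows, rows$metric)
  report <- lapply(tables, repro_report,
                   effect_sizes = config$effect_sizes,
                   alpha = config$alpha, power = config$power,
                   mad_k = config$mad_k)
  res <- list(tables = tables, report = report,
              ground_truth = cohort$ground_truth, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(res$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (m in names(res$tables)) {
    utils::write.table(res$tables[[m]],
                       file.path(out_dir, sprintf("table_%s.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format_report(res$report[[m]]),
                       file.path(out_dir, sprintf("report_%s.tsv", m)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- lapply(res$report, function(df) {
    lapply(split(df, df$roi), function(r) as.list(r[setdiff(names(r), "roi")]))
  })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}

# percentages with one decimal in tabular output
format_report <- function(df) {
  for (cl in c("cv_between", "cv_within"))
    df[[cl]] <- sprintf("%.1f", df[[cl]])
  df
}
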