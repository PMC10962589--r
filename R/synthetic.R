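#' Gaussian noise specification
#'
#' SNR is defined on the equilibrium measurement (bf = 0, shortest mixing
#' time, b = 0): the per-volume noise standard deviation is
#' `S_eq / snr`, with `S_eq` the noise-free equilibrium signal.
#'
#' @param snr target signal-to-noise ratio (> 0).
#' @param kind noise family; only `"gaussian"` is supported (the reference
#'   simulations use additive Gaussian noise, not Rician).
#' @param seed integer seed for reproducible draws.
#' @export
noise_spec <- function(snr, kind = "gaussian", seed = NULL) {
  stopifnot(is.numeric(snr), snr > 0)
  kind <- match.arg(kind, "gaussian")
  structure(list(snr = snr, kind = kind, seed = seed), class = "noise_spec")
}

#' Add measurement noise to a signal vector
#'
#' Draws i.i.d. zero-mean Gaussian noise with per-volume standard deviation
#' `S_eq / snr`, where `S_eq` is the noise-free equilibrium signal (bf = 0,
#' smallest tm, b = 0) of `signals`. With `average_reps = TRUE` (default)
#' each scheme row represents the average of its `n_rep` acquired volumes,
#' so the row receives the mean of `n_rep` independent per-volume noise
#' draws (standard deviation `S_eq / (snr * sqrt(n_rep))`); with
#' `average_reps = FALSE` every row gets one per-volume draw regardless of
#' `n_rep`. Deterministic given `spec$seed`; the caller's RNG state is left
#' untouched when a seed is supplied.
#'
#' @param signals noise-free signal vector on the absolute
#'   (equilibrium-referenced) scale, one value per scheme row.
#' @param scheme a [fexi_scheme()] containing the equilibrium measurement.
#' @param spec a [noise_spec()].
#' @param average_reps treat rows as `n_rep`-volume averages (see above).
#' @return Noisy signal vector.
#' @export
add_noise <- function(signals, scheme, spec, average_reps = TRUE) {
  stopifnot(inherits(spec, "noise_spec"), length(signals) == nrow(scheme))
  if (is.infinite(spec$snr)) return(signals)
  eq <- which(scheme$bf == 0 & scheme$b == 0)
  if (!length(eq))
    stop("scheme lacks the equilibrium measurement (bf = 0, b = 0)")
  eq <- eq[which.min(scheme$tm[eq])]
  sd_vol <- signals[eq] / spec$snr
  sd_row <- if (average_reps) sd_vol / sqrt(scheme$n_rep)
            else rep(sd_vol, nrow(scheme))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
  }
  signals + stats::rnorm(length(signals), 0, sd_row)
}

#' Digital FEXI phantom
#'
#' A labelled 3D grid with one tissue parameter set per nonzero label
#' (0 = background) and an acquisition scheme; [generate_phantom()] turns it
#' into a 4D signal series. The default is a two-tissue slice emulating a
#' single-slice acquisition: label 1 = white matter, label 2 = grey matter.
#'
#' @param dim integer length-3 grid dimensions.
#' @param label_map integer array of `dim` with tissue labels; default
#'   splits the slice into WM (left half) and GM (right half).
#' @param params named list mapping label (as character) to
#'   [tissue_params()]; defaults to the WM/GM literature presets.
#' @param scheme a [fexi_scheme()].
#' @return A `fexi_phantom` list.
#' @export
fexi_phantom <- function(dim = c(10, 10, 1), label_map = NULL,
                         params = list(`1` = tissue_preset("wm"),
                                       `2` = tissue_preset("gm")),
                         scheme = default_scheme()) {
  stopifnot(length(dim) == 3)
  if (is.null(label_map)) {
    label_map <- array(0L, dim)
    half <- dim[1] %/% 2
    label_map[seq_len(half), , ] <- 1L
    label_map[seq(half + 1, dim[1]), , ] <- 2L
  }
  stopifnot(all(dim(label_map) == dim))
  labels <- setdiff(sort(unique(as.integer(label_map))), 0L)
  missing <- setdiff(as.character(labels), names(params))
  if (length(missing))
    stop("no tissue parameters for label(s): ", paste(missing, collapse = ", "))
  structure(list(dim = dim, label_map = label_map, params = params,
                 scheme = scheme),
            class = "fexi_phantom")
}

#' Generate the 4D signal series of a phantom
#'
#' Computes per-voxel finite-relaxation forward signals on the absolute
#' scale (equilibrium signal = 1), one volume per scheme measurement, and
#' optionally adds Gaussian noise per voxel. Background voxels are zero in
#' every volume. When `path` is given the series, label map and ground-truth
#' parameter maps are written as NIfTI files with a JSON metadata sidecar
#' and a scheme CSV sidecar.
#'
#' @param phantom a [fexi_phantom()].
#' @param noise a [noise_spec()] or `NULL` for noise-free.
#' @param path optional output prefix (files `<path>_series.nii.gz`,
#'   `<path>_labels.nii.gz`, `<path>_scheme.csv`, `<path>_meta.json`,
#'   `<path>_truth_<param>.nii.gz`).
#' @return A 4D array (x, y, z, measurement), invisibly carrying the
#'   attribute `scheme`.
#' @export
generate_phantom <- function(phantom, noise = NULL, path = NULL) {
  stopifnot(inherits(phantom, "fexi_phantom"))
  sch <- phantom$scheme
  nvol <- nrow(sch)
  series <- array(0, c(phantom$dim, nvol))
  labels <- setdiff(sort(unique(as.integer(phantom$label_map))), 0L)
  clean_by_label <- lapply(labels, function(l)
    signal_2cmr(phantom$params[[as.character(l)]], sch,
                normalize = "equilibrium"))
  names(clean_by_label) <- labels
  voxels <- which(phantom$label_map != 0L, arr.ind = TRUE)
  if (!is.null(noise) && !is.null(noise$seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(noise$seed)
  }
  for (v in seq_len(nrow(voxels))) {
    ijk <- voxels[v, ]
    lab <- as.character(phantom$label_map[ijk[1], ijk[2], ijk[3]])
    sig <- clean_by_label[[lab]]
    if (!is.null(noise)) {
      vox_spec <- noise_spec(noise$snr)  # seed handled once above
      sig <- add_noise(sig, sch, vox_spec)
    }
    series[ijk[1], ijk[2], ijk[3], ] <- sig
  }
  attr(series, "scheme") <- sch
  if (!is.null(path)) write_phantom_files(phantom, series, noise, path)
  invisible(series)
}

write_phantom_files <- function(phantom, series, noise, path) {
  RNifti::writeNifti(RNifti::asNifti(series), paste0(path, "_series.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$label_map + 0),
                     paste0(path, "_labels.nii.gz"))
  write_scheme(phantom$scheme, paste0(path, "_scheme.csv"))
  for (par in c("fi_eq", "De", "Di", "k")) {
    m <- array(0, phantom$dim)
    for (l in names(phantom$params))
      m[phantom$label_map == as.integer(l)] <- phantom$params[[l]][[par]]
    RNifti::writeNifti(RNifti::asNifti(m),
                       paste0(path, "_truth_", par, ".nii.gz"))
  }
  meta <- list(snr = if (is.null(noise)) NULL else noise$snr,
               seed = if (is.null(noise)) NULL else noise$seed,
               n_volumes = dim(series)[4],
               software = paste0("bbbfexi ",
                                 as.character(utils::packageVersion("bbbfexi"))))
  jsonlite::write_json(meta, paste0(path, "_meta.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
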