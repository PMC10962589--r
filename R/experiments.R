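# Noise-free bias experiments and the Monte-Carlo accuracy/precision study.
# All generate ground-truth signals with the finite-relaxation model (2CMr)
# and fit a (possibly misspecified) paradigm to quantify the induced bias in
# the exchange rate.

#' Signed percent relative error
#'
#' `100 * (k_fit - k_gt) / k_gt`.
#'
#' @param k_fit fitted value(s).
#' @param k_gt ground truth (nonzero).
#' @export
percent_relative_error <- function(k_fit, k_gt) {
  if (any(k_gt == 0)) stop("ground truth must be nonzero")
  100 * (k_fit - k_gt) / k_gt
}

# shared ground truth of the relaxation-time experiments
relaxation_base_params <- function() {
  tissue_params(fi_eq = 0.05, De = 1, Di = 10, k = 3)
}

# scheme actually fitted for a paradigm: AXR fits use the b in {0, 250}
# subset (as in vivo); compartmental fits use the full scheme.
fit_subset <- function(scheme, model) {
  if (model == "axr") subset_scheme(scheme, "axr") else scheme
}

# ground-truth initial values for a paradigm
truth_init <- function(p, model, bf = 250) {
  if (model == "axr") {
    a <- equivalent_axr_params(p, bf)
    list(ADC = a$ADC, sigma = a$sigma, AXR = a$AXR)
  } else list(De = p$De, Di = p$Di, k = p$k)
}

# generate noise-free 2CMr signals on `scheme`, fit `model` once from the
# ground truth, and return the fitted exchange rate
fit_noise_free <- function(p_true, model, scheme,
                           fixed = NULL, bounds = NULL) {
  sch <- fit_subset(scheme, model)
  dat <- signal_2cmr(p_true, sch, normalize = "group")
  if (is.null(fixed))
    fixed <- if (model == "axr") list() else list(fi_eq = p_true$fi_eq)
  cfg <- fit_config(model = model, bounds = bounds, fixed = fixed,
                    n_starts = 1L, init_mode = "ground_truth")
  ft <- fexi_fit(dat, sch, cfg, init = truth_init(p_true, model))
  ft$params[[exchange_name(model)]]
}

#' Exchange-rate bias at the in vivo relaxation points
#'
#' Generates noise-free signals with the finite-relaxation model at the
#' literature WM/GM relaxation values (blood T1 = 1.65 s, T2 = 0.18 s;
#' tissue T1 = 0.90/1.50 s, T2 = 0.070/0.095 s for WM/GM) with only the
#' `which` relaxation family finite, then fits a paradigm that assumes
#' infinite relaxation and returns the signed percent error in its exchange
#' rate.
#'
#' @param which `"T1"` or `"T2"`: which relaxation family is finite in the
#'   generative model (the other is infinite).
#' @param tissue `"wm"` or `"gm"` extravascular relaxation point.
#' @param model fitted paradigm, `"axr"` or `"2cm"`.
#' @param scheme acquisition scheme (default [default_scheme()]).
#' @return Signed percent relative error in the fitted exchange rate.
#' @export
relaxation_point_bias <- function(which = c("T1", "T2"),
                                  tissue = c("wm", "gm"),
                                  model = c("axr", "2cm"),
                                  scheme = default_scheme()) {
  which <- match.arg(which)
  tissue <- match.arg(tissue)
  model <- match.arg(model)
  base <- relaxation_base_params()
  p <- if (which == "T1")
    update_params(base, T1i = 1.65, T1e = if (tissue == "wm") 0.90 else 1.50)
  else
    update_params(base, T2i = 0.18, T2e = if (tissue == "wm") 0.070 else 0.095)
  percent_relative_error(fit_noise_free(p, model, scheme), p$k)
}

#' Bias surface over a grid of compartmental relaxation times
#'
#' For each point of a `grid_n` x `grid_n` grid over (T1i, T1e) or
#' (T2i, T2e), generates noise-free finite-relaxation signals (all other
#' parameters: fi_eq = 0.05, De = 1, Di = 10 um^2/ms, k = 3 s^-1) and fits
#' the chosen infinite-relaxation paradigm from a single ground-truth start.
#' Default ranges are 0.7-2.5 s for T1 and 0.05-0.20 s for T2.
#'
#' @param which `"T1"` or `"T2"`.
#' @param model `"axr"` or `"2cm"`.
#' @param grid_n grid points per axis (50 x 50 = 2500 combinations at the
#'   reference resolution; use a small value for quick looks).
#' @param range relaxation-time range (s), length 2.
#' @param scheme acquisition scheme.
#' @return A `BiasTable` data frame with columns `Ti`, `Te` (the
#'   intravascular/extravascular relaxation times of the swept family, s),
#'   `model`, `k_gt`, `k_fit`, `error` (signed percent).
#' @export
relaxation_bias_grid <- function(which = c("T1", "T2"),
                                 model = c("axr", "2cm"),
                                 grid_n = 50,
                                 range = NULL,
                                 scheme = default_scheme()) {
  which <- match.arg(which)
  model <- match.arg(model)
  if (is.null(range)) range <- if (which == "T1") c(0.7, 2.5) else c(0.05, 0.20)
  vals <- seq(range[1], range[2], length.out = grid_n)
  grid <- expand.grid(Ti = vals, Te = vals)
  base <- relaxation_base_params()
  kfit <- vapply(seq_len(nrow(grid)), function(i) {
    p <- if (which == "T1")
      update_params(base, T1i = grid$Ti[i], T1e = grid$Te[i])
    else
      update_params(base, T2i = grid$Ti[i], T2e = grid$Te[i])
    fit_noise_free(p, model, scheme)
  }, numeric(1))
  data.frame(which = which, Ti = grid$Ti, Te = grid$Te, model = model,
             k_gt = base$k, k_fit = kfit,
             error = percent_relative_error(kfit, base$k))
}

#' Sensitivity of relaxation-time bias to sequence settings
#'
#' Sweeps the extravascular relaxation time (blood fixed at T1 = 1.65 s /
#' T2 = 0.18 s) and records the exchange-rate bias of the
#' infinite-relaxation paradigms, for either three maximum mixing times
#' (`tm_max` in \{0.3, 0.4, 0.5\} s; T1 sweep) or three echo-time pairs
#' (`TEf/TE` in \{20/40, 38/62, 60/80\} ms; T2 sweep).
#'
#' @param which `"tm_max"` (T1 sensitivity) or `"TE"` (T2 sensitivity).
#' @param models paradigms to fit.
#' @param n_points sweep resolution of the extravascular relaxation time.
#' @param Te_values optional explicit extravascular relaxation times (s),
#'   overriding the uniform sweep.
#' @return A `BiasTable` data frame with the sequence setting, the swept
#'   extravascular relaxation time `Te`, its offset `dT` from the blood
#'   value, `model`, `k_fit`, `error`.
#' @export
sequence_sensitivity_sweep <- function(which = c("TE", "tm_max"),
                                       models = c("axr", "2cm"),
                                       n_points = 11, Te_values = NULL) {
  which <- match.arg(which)
  base <- relaxation_base_params()
  if (which == "tm_max") {
    settings <- data.frame(tm_max = c(0.3, 0.4, 0.5))
    Te <- seq(0.7, 2.5, length.out = n_points)
    Ti_blood <- 1.65
  } else {
    settings <- data.frame(TEf = c(0.020, 0.038, 0.060),
                           TE = c(0.040, 0.062, 0.080))
    Te <- seq(0.05, 0.20, length.out = n_points)
    Ti_blood <- 0.18
  }
  if (!is.null(Te_values)) Te <- Te_values
  out <- list()
  for (i in seq_len(nrow(settings))) {
    scheme <- if (which == "tm_max")
      default_scheme(tm_max = settings$tm_max[i])
    else
      default_scheme(TEf = settings$TEf[i], TE = settings$TE[i])
    for (model in models) {
      kfit <- vapply(Te, function(te) {
        p <- if (which == "tm_max")
          update_params(base, T1i = Ti_blood, T1e = te)
        else
          update_params(base, T2i = Ti_blood, T2e = te)
        fit_noise_free(p, model, scheme)
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        which = which, setting = paste(format(settings[i, ], trim = TRUE),
                                       collapse = "/"),
        settings[i, , drop = FALSE], Te = Te, dT = Te - Ti_blood,
        model = model, k_gt = base$k, k_fit = kfit,
        error = percent_relative_error(kfit, base$k), row.names = NULL)
    }
  }
  do.call(rbind, out)
}

# Table of fixed-parameter sweep definitions: ground-truth range of the
# swept quantity and the (wrong) value the fit holds fixed.
fixed_param_ranges <- function(target, tissue) {
  switch(paste(target, tissue, sep = "."),
    fi_eq.wm = list(range = c(0.015, 0.045), fixed = 0.030),
    fi_eq.gm = list(range = c(0.025, 0.075), fixed = 0.050),
    T1e.wm = list(range = c(0.77, 1.04), fixed = 0.90),
    T1e.gm = list(range = c(1.28, 1.73), fixed = 1.50),
    T2e.wm = list(range = c(0.06, 0.08), fixed = 0.070),
    T2e.gm = list(range = c(0.08, 0.11), fixed = 0.095))
}

#' Exchange-rate bias from fixing a parameter at the wrong value
#'
#' Sweeps the ground truth of one normally-fixed parameter (the blood signal
#' fraction `fi_eq` over +/-50% of its fixed value, or the extravascular
#' relaxation time `T1e`/`T2e` over +/-15%) while the fit holds it at the
#' nominal WM/GM value, and records the induced signed error in the
#' exchange rate. Signals are generated noise-free with the
#' finite-relaxation model at the in vivo relaxation point of the chosen
#' tissue; fits start from the ground truth. The `"2cm"` fit assumes
#' infinite relaxation (so only the `fi_eq` target applies); the `"2cmr"`
#' fit fixes all non-swept relaxation times at their true values.
#'
#' @param target `"fi_eq"`, `"T1e"` or `"T2e"`.
#' @param tissue `"wm"` or `"gm"`.
#' @param model `"2cm"` or `"2cmr"`.
#' @param n_points sweep resolution (endpoints included).
#' @param scheme acquisition scheme.
#' @return A `BiasTable` data frame with the swept ground-truth value, the
#'   fixed value, `k_fit` and signed `error`.
#' @export
fixed_param_bias <- function(target = c("fi_eq", "T1e", "T2e"),
                             tissue = c("wm", "gm"),
                             model = c("2cm", "2cmr"),
                             n_points = 21,
                             scheme = default_scheme()) {
  target <- match.arg(target)
  tissue <- match.arg(tissue)
  model <- match.arg(model)
  if (model == "2cm" && target != "fi_eq")
    stop("the relaxation-free model cannot express a ", target, " sweep")
  def <- fixed_param_ranges(target, tissue)
  sweep <- seq(def$range[1], def$range[2], length.out = n_points)
  base <- tissue_preset(tissue)
  kfit <- vapply(sweep, function(v) {
    p_true <- do.call(update_params, c(list(base), stats::setNames(list(v), target)))
    fixed <- if (model == "2cm") list(fi_eq = base$fi_eq)
    else {
      fx <- list(fi_eq = p_true$fi_eq, T1i = p_true$T1i, T1e = p_true$T1e,
                 T2i = p_true$T2i, T2e = p_true$T2e)
      fx[[if (target == "fi_eq") "fi_eq" else target]] <- def$fixed
      fx
    }
    if (target == "fi_eq") fixed$fi_eq <- def$fixed
    fit_noise_free(p_true, model, scheme, fixed = fixed)
  }, numeric(1))
  data.frame(target = target, tissue = tissue, model = model,
             value_gt = sweep, value_fixed = def$fixed,
             k_gt = base$k, k_fit = kfit,
             error = percent_relative_error(kfit, base$k))
}

#' Monte-Carlo accuracy and precision of exchange-rate estimates
#'
#' For every combination of `fi_eq`, `k` and `snr`, generates noise-free
#' finite-relaxation signals at the GM relaxation point (T1 = 1.65/1.50 s,
#' T2 = 0.18/0.095 s blood/tissue; De = 1, Di = 10 um^2/ms), adds `n_noise`
#' independent Gaussian noise realizations (SNR defined on the equilibrium
#' measurement; repetition averaging per the scheme's `n_rep`), fits each
#' paradigm with `n_starts` uniform starts (exchange-rate starts in truth
#' +/- 50%), discards extreme fits (exchange rate >= 40 s^-1), and
#' summarizes accuracy (percent error of the median retained estimate) and
#' precision (interquartile range).
#'
#' The reference study uses a 10 x 10 grid over fi_eq in \[0.01, 0.10\] and
#' k in \[0.5, 20\] s^-1 with 1000 noise replicates at SNR 60 and 100;
#' desk-scale runs reduce the grid and `n_noise` (reported in the output).
#'
#' @param fi_eq,k,snr numeric vectors defining the study grid.
#' @param models paradigms to evaluate.
#' @param n_noise noise replicates per cell.
#' @param n_starts optimization starts per fit.
#' @param seed integer; every cell/replicate seed derives from it.
#' @param scheme acquisition scheme; AXR fits use its AXR subset.
#' @param init_mode start policy passed to [fit_config()]; the reference
#'   study uses `"uniform_k_pm50"`.
#' @return A list of class `fexi_apstudy`: `table` (per-cell accuracy,
#'   precision, `n_discarded`) and `fits` (one row per retained fit with all
#'   fitted parameters).
#' @export
accuracy_precision_study <- function(fi_eq = 0.05, k = 3, snr = 100,
                                     models = c("axr", "2cm", "2cmr"),
                                     n_noise = 100, n_starts = 20,
                                     seed = 1, scheme = default_scheme(),
                                     init_mode = "uniform_k_pm50") {
  grid <- expand.grid(fi_eq = fi_eq, k = k, snr = snr,
                      model = models, stringsAsFactors = FALSE)
  fits <- list()
  table <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- update_params(tissue_preset("gm"), fi_eq = g$fi_eq, k = g$k)
    sch <- fit_subset(scheme, g$model)
    clean <- signal_2cmr(p, sch, normalize = "equilibrium")
    fixed <- if (g$model == "axr") list()
    else if (g$model == "2cm") list(fi_eq = g$fi_eq)
    else list(fi_eq = g$fi_eq, T1i = p$T1i, T1e = p$T1e,
              T2i = p$T2i, T2e = p$T2e)
    init <- truth_init(p, g$model)
    cell_seed <- (seed * 1103L + i * 7919L) %% 2147483629L
    cfg <- fit_config(model = g$model, fixed = fixed, n_starts = n_starts,
                      init_mode = init_mode)
    kname <- exchange_name(g$model)
    res <- vector("list", n_noise)
    for (r in seq_len(n_noise)) {
      ns <- noise_spec(snr = g$snr, seed = (cell_seed + r) %% 2147483629L)
      noisy <- add_noise(clean, sch, ns)
      dat <- normalize_signals(noisy, sch)
      cfg$seed <- (cell_seed + 2L * r + 1L) %% 2147483629L
      res[[r]] <- fexi_fit(dat, sch, cfg, init = init)
    }
    kept <- discard_extremes(res, cfg$extreme_threshold)
    kvals <- vapply(kept, function(f) f$params[[kname]], numeric(1))
    table[[i]] <- data.frame(
      fi_eq = g$fi_eq, k_gt = g$k, snr = g$snr, model = g$model,
      n_noise = n_noise,
      n_discarded = attr(kept, "n_discarded"),
      accuracy = percent_relative_error(stats::median(kvals), g$k),
      precision = stats::IQR(kvals))
    if (length(kept))
      fits[[i]] <- data.frame(
        fi_eq = g$fi_eq, k_gt = g$k, snr = g$snr, model = g$model,
        do.call(rbind, lapply(kept, function(f) as.data.frame(f$params))),
        row.names = NULL)
  }
  # AXR and compartmental fits carry different parameter columns; align on
  # the union before binding
  all_cols <- unique(unlist(lapply(fits, names)))
  fits <- lapply(fits, function(f) {
    f[setdiff(all_cols, names(f))] <- NA_real_
    f[all_cols]
  })
  structure(list(table = do.call(rbind, table),
                 fits = do.call(rbind, fits),
                 seed = seed, n_starts = n_starts),
            class = "fexi_apstudy")
}

#' @export
print.fexi_apstudy <- function(x, ...) {
  cat("FEXI accuracy/precision study (seed ", x$seed, ", ",
      x$n_starts, " starts)\n", sep = "")
  print(x$table, ...)
  invisible(x)
}
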