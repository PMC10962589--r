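# Forward models. Unit convention: b in s/mm^2, D in um^2/ms; the product
# b*D is made dimensionless by the factor 1e-3 (um^2/ms = 1e-3 mm^2/s).
bd <- function(b, D) b * D * 1e-3

#' Compartment signal fractions immediately after the diffusion filter
#'
#' The filter block attenuates each compartment by `exp(-bf * D)`; the
#' post-filter intravascular fraction is the renormalized mixture
#' `fi0 = fi_eq e^(-bf Di) / (fe_eq e^(-bf De) + fi_eq e^(-bf Di))`.
#' With `Di > De` the filter suppresses the intravascular pool: `fi0 <= fi_eq`.
#'
#' @param p a [tissue_params()].
#' @param bf filter b-value(s) (s/mm^2).
#' @return A list with vectors `fi0` and `fe0 = 1 - fi0`.
#' @export
post_filter_fractions <- function(p, bf) {
  stopifnot(all(bf >= 0))
  wi <- p$fi_eq * exp(-bd(bf, p$Di))
  we <- p$fe_eq * exp(-bd(bf, p$De))
  fi0 <- wi / (wi + we)
  list(fi0 = fi0, fe0 = 1 - fi0)
}

#' Exchange-driven recovery of the intravascular fraction over mixing
#'
#' `fi(tm) = fi_eq - (fi_eq - fi0) * exp(-k * tm)`: mono-exponential return
#' of the filtered fraction toward equilibrium at the total exchange rate.
#'
#' @param fi0 post-filter intravascular fraction.
#' @param fi_eq equilibrium intravascular fraction.
#' @param k total exchange rate (s^-1).
#' @param tm mixing time(s) (s).
#' @return Recovered fraction(s), same length as `tm` (or `fi0`).
#' @export
fraction_recovery <- function(fi0, fi_eq, k, tm) {
  stopifnot(all(tm >= 0))
  fi_eq - (fi_eq - fi0) * exp(-k * tm)
}

#' Relaxation-free two-compartment FEXI signal (2CM)
#'
#' Normalized signal `S(bf, tm, b) / S(bf, tm, 0) =
#' (1 - fi(tm)) e^(-b De) + fi(tm) e^(-b Di)`, composing
#' [post_filter_fractions()] and [fraction_recovery()]. Echo times are
#' ignored: relaxation is assumed infinitely slow.
#'
#' @param p a [tissue_params()] (relaxation fields unused).
#' @param scheme a [fexi_scheme()].
#' @return Numeric vector of normalized signals, one per measurement;
#'   exactly 1 wherever `b = 0`.
#' @export
signal_2cm <- function(p, scheme) {
  fi0 <- post_filter_fractions(p, scheme$bf)$fi0
  fitm <- fraction_recovery(fi0, p$fi_eq, p$k, scheme$tm)
  (1 - fitm) * exp(-bd(scheme$b, p$De)) + fitm * exp(-bd(scheme$b, p$Di))
}

# exp(-A t) for a real 2x2 matrix with real spectrum, by closed-form
# eigendecomposition; near-degenerate spectra fall back to the first-order
# limit form (the eigen formula divides by the eigenvalue gap).
expm2_neg <- function(A, t) {
  tr <- A[1L] + A[4L]
  det <- A[1L] * A[4L] - A[3L] * A[2L]
  disc <- tr * tr - 4 * det
  I2 <- c(1, 0, 0, 1)
  if (disc < 1e-14) {
    lam <- tr / 2
    matrix(exp(-lam * t) * (I2 - t * (A - lam * I2)), 2L, 2L)
  } else {
    s <- sqrt(disc)
    l1 <- (tr + s) / 2
    l2 <- (tr - s) / 2
    matrix((exp(-l1 * t) * (A - l2 * I2) - exp(-l2 * t) * (A - l1 * I2)) /
             (l1 - l2), 2L, 2L)
  }
}

# Generator of the mixing-period evolution: R1 + K acting on M = (mi, me).
mixing_generator <- function(p) {
  c(1 / p$T1i + p$kie, -p$kie, -p$kei, 1 / p$T1e + p$kei)
}

#' Longitudinal mixing-period evolution of the magnetization
#'
#' Evolves `M = (mi, me)` over the mixing time under T1 relaxation and
#' exchange: `M(tm) = exp(-(R1 + K) tm) M0` with `R1 = diag(1/T1i, 1/T1e)`
#' and `K = [[kie, -kei], [-kie, kei]]`. The spoiled equilibrium term is
#' identically zero (dephasing gradients around the storage pulses remove all
#' non-coherent pathways, including inflow). Computed via the closed-form
#' 2x2 eigendecomposition.
#'
#' @param M0 numeric length-2 magnetization `(mi, me)`.
#' @param p a [tissue_params()].
#' @param tm mixing time (s), scalar.
#' @return Length-2 magnetization at `tm`.
#' @export
mixing_evolution <- function(M0, p, tm) {
  if (!all(is.finite(M0))) stop("non-finite input magnetization")
  stopifnot(tm >= 0)
  if (tm == 0) return(as.numeric(M0))
  as.numeric(expm2_neg(mixing_generator(p), tm) %*% M0)
}

# Raw (unnormalized) two-compartment signal with relaxation, one value per
# scheme row: filter decay -> mixing evolution -> encoding decay, starting
# from M0 = (fi_eq, fe_eq). Propagators are cached per unique (tm) since a
# scheme has few distinct mixing times.
signal_2cmr_raw <- function(p, scheme) {
  R2 <- c(1 / p$T2i, 1 / p$T2e)
  D <- c(p$Di, p$De)
  A <- mixing_generator(p)
  tms <- unique(scheme$tm)
  props <- lapply(tms, function(t) expm2_neg(A, t))
  out <- numeric(nrow(scheme))
  for (j in seq_len(nrow(scheme))) {
    M <- c(p$fi_eq, p$fe_eq) * exp(-bd(scheme$bf[j], D) - scheme$TEf[j] * R2)
    M <- props[[match(scheme$tm[j], tms)]] %*% M
    out[j] <- sum(M * exp(-bd(scheme$b[j], D) - scheme$TE[j] * R2))
  }
  out
}

#' Two-compartment FEXI signal with finite relaxation (2CMr)
#'
#' Block-wise solution of the two-site exchange system: per-compartment
#' filter decay `exp(-bf D - TEf/T2)` applied to `M0 = (fi_eq, fe_eq)`,
#' longitudinal [mixing_evolution()] over `tm` (T1 and exchange), then
#' encoding decay `exp(-b D - TE/T2)`; the detected signal is the summed
#' magnetization. Exchange during the (short) filter and encoding blocks is
#' neglected; it acts only during the mixing time. With all relaxation times
#' infinite the model reduces exactly to [signal_2cm()].
#'
#' @param p a [tissue_params()].
#' @param scheme a [fexi_scheme()].
#' @param normalize `"group"` divides each measurement by the same pipeline
#'   evaluated at `b = 0` within its (bf, tm) group (the convention used for
#'   fitting); `"equilibrium"` scales so the equilibrium measurement
#'   (bf = 0, smallest tm, b = 0) equals 1 (absolute scale used for noise);
#'   `"none"` returns raw summed magnetization with unit total at `M0`.
#' @return Numeric vector of signals, one per measurement.
#' @export
signal_2cmr <- function(p, scheme, normalize = c("group", "equilibrium", "none")) {
  normalize <- match.arg(normalize)
  raw <- signal_2cmr_raw(p, scheme)
  switch(normalize,
    none = raw,
    equilibrium = {
      eq <- which(scheme$bf == 0 & scheme$b == 0)
      if (!length(eq)) stop("scheme lacks an equilibrium (bf = 0, b = 0) measurement")
      eq <- eq[which.min(scheme$tm[eq])]
      raw / raw[eq]
    },
    group = {
      grp <- scheme_groups(scheme)
      ref <- vapply(split(seq_len(nrow(scheme)), grp), function(i) {
        i0 <- i[scheme$b[i] == 0]
        if (!length(i0)) stop("scheme group lacks a b = 0 measurement")
        mean(raw[i0])
      }, numeric(1))
      unname(raw / ref[as.character(grp)])
    })
}

#' AXR-model FEXI signal
#'
#' Unfiltered measurements (bf = 0) decay as `exp(-b ADC)`; filtered
#' measurements as `exp(-b ADC'(tm))` with the mixing-time-dependent
#' `ADC'(tm) = ADC (1 - sigma exp(-tm AXR))`.
#'
#' @param a an [axr_params()].
#' @param scheme a [fexi_scheme()].
#' @return Numeric vector of normalized signals; 1 wherever `b = 0`.
#' @export
signal_axr <- function(a, scheme) {
  adc_tm <- ifelse(scheme$bf == 0, a$ADC,
                   a$ADC * (1 - a$sigma * exp(-scheme$tm * a$AXR)))
  exp(-bd(scheme$b, adc_tm))
}

#' Filter efficiency of a diffusion filter
#'
#' `sigma = (De - Di) (fe_eq - fe0) / ADC`, the fractional initial reduction
#' of the ADC produced by a filter of weighting `bf`, with `fe0` from
#' [post_filter_fractions()] and ADC from [equilibrium_adc()]. Zero at
#' `bf = 0` or `Di = De`; in (0, 1\] when `Di > De`.
#'
#' @param p a [tissue_params()].
#' @param bf filter b-value(s) (s/mm^2).
#' @return Filter efficiency (unitless).
#' @export
filter_efficiency <- function(p, bf) {
  stopifnot(all(bf >= 0))
  fe0 <- post_filter_fractions(p, bf)$fe0
  (p$De - p$Di) * (p$fe_eq - fe0) / equilibrium_adc(p)
}

#' Forward signal for any modeling paradigm
#'
#' Dispatcher used by the fitting engine and drivers.
#'
#' @param params a [tissue_params()] (for `"2cm"`, `"2cmr"`) or
#'   [axr_params()] (for `"axr"`).
#' @param scheme a [fexi_scheme()].
#' @param model `"axr"`, `"2cm"` or `"2cmr"`.
#' @param ... passed on (e.g. `normalize` for `"2cmr"`).
#' @return Numeric vector of signals.
#' @export
fexi_signal <- function(params, scheme, model = c("2cmr", "2cm", "axr"), ...) {
  model <- match.arg(model)
  switch(model,
         axr = signal_axr(params, scheme),
         `2cm` = signal_2cm(params, scheme),
         `2cmr` = signal_2cmr(params, scheme, ...))
}
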