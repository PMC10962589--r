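#' Two-compartment tissue parameters
#'
#' Ground-truth or fitted state of the two-site exchange system: an
#' intravascular (blood) compartment with equilibrium signal fraction
#' `fi_eq` and pseudo-diffusivity `Di`, an extravascular compartment with
#' fraction `1 - fi_eq` and diffusivity `De`, total water exchange rate
#' `k = kie + kei` (s^-1), and per-compartment relaxation times (s), which may
#' be `Inf`. Detailed balance fixes the directional rates as
#' `kie = k * fe_eq` and `kei = k * fi_eq`, so that the exchange matrix
#' annihilates the equilibrium magnetization.
#'
#' @param fi_eq equilibrium intravascular signal fraction, in (0, 1).
#' @param De extravascular diffusivity (um^2/ms).
#' @param Di intravascular pseudo-diffusivity (um^2/ms).
#' @param k total exchange rate kie + kei (s^-1).
#' @param T1i,T1e,T2i,T2e longitudinal/transverse relaxation times (s);
#'   `Inf` means no relaxation (rate exactly 0).
#' @return A `tissue_params` list with derived fields `fe_eq`, `kie`, `kei`.
#' @examples
#' gm <- tissue_params(fi_eq = 0.05, De = 1, Di = 10, k = 3,
#'                     T1i = 1.65, T1e = 1.5, T2i = 0.18, T2e = 0.095)
#' @export
tissue_params <- function(fi_eq, De, Di, k, T1i = Inf, T1e = Inf,
                          T2i = Inf, T2e = Inf) {
  stopifnot(is.numeric(fi_eq), fi_eq > 0, fi_eq < 1,
            De > 0, Di > 0, k >= 0,
            T1i > 0, T1e > 0, T2i > 0, T2e > 0)
  fe_eq <- 1 - fi_eq
  structure(list(fi_eq = fi_eq, fe_eq = fe_eq, De = De, Di = Di, k = k,
                 kie = k * fe_eq, kei = k * fi_eq,
                 T1i = T1i, T1e = T1e, T2i = T2i, T2e = T2e),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("tissue_params: fi_eq=%.3g De=%.3g Di=%.3g um^2/ms k=%.3g /s\n",
              x$fi_eq, x$De, x$Di, x$k))
  cat(sprintf("  T1 (i/e) = %.3g/%.3g s; T2 (i/e) = %.3g/%.3g s\n",
              x$T1i, x$T1e, x$T2i, x$T2e))
  invisible(x)
}

#' Update selected fields of a tissue parameter set
#'
#' Rebuilds the object through [tissue_params()] so derived fields and
#' invariants stay consistent.
#'
#' @param p a [tissue_params()].
#' @param ... named replacement values among fi_eq, De, Di, k, T1i, T1e,
#'   T2i, T2e.
#' @export
update_params <- function(p, ...) {
  new <- utils::modifyList(p[c("fi_eq", "De", "Di", "k",
                               "T1i", "T1e", "T2i", "T2e")], list(...))
  do.call(tissue_params, new)
}

#' Literature tissue presets at 3 T
#'
#' In vivo relaxation times and blood fractions used throughout the
#' simulation experiments: blood T1 = 1.65 s and T2 = 0.18 s in both tissues;
#' extravascular T1/T2 = 0.90/0.070 s with fi_eq = 0.03 in white matter and
#' 1.50/0.095 s with fi_eq = 0.05 in grey matter. Diffusivities default to
#' De = 1 and Di = 10 um^2/ms.
#'
#' @param tissue `"gm"` or `"wm"`.
#' @param k total exchange rate (s^-1).
#' @param De,Di diffusivities (um^2/ms).
#' @return A [tissue_params()].
#' @export
tissue_preset <- function(tissue = c("gm", "wm"), k = 3, De = 1, Di = 10) {
  tissue <- match.arg(tissue)
  if (tissue == "gm")
    tissue_params(fi_eq = 0.05, De = De, Di = Di, k = k,
                  T1i = 1.65, T1e = 1.50, T2i = 0.18, T2e = 0.095)
  else
    tissue_params(fi_eq = 0.03, De = De, Di = Di, k = k,
                  T1i = 1.65, T1e = 0.90, T2i = 0.18, T2e = 0.070)
}

#' AXR model parameters
#'
#' The apparent-exchange-rate description of FEXI data: an equilibrium
#' apparent diffusion coefficient `ADC`, the filter efficiency `sigma`
#' (fractional initial ADC reduction produced by the diffusion filter), and
#' the mono-exponential recovery rate `AXR` of the filtered ADC toward
#' equilibrium.
#'
#' @param ADC apparent diffusion coefficient (um^2/ms).
#' @param sigma filter efficiency, in \[0, 1\].
#' @param AXR apparent exchange rate (s^-1).
#' @export
axr_params <- function(ADC, sigma, AXR) {
  stopifnot(ADC > 0, sigma >= 0, sigma <= 1, AXR >= 0)
  structure(list(ADC = ADC, sigma = sigma, AXR = AXR), class = "axr_params")
}

#' @export
print.axr_params <- function(x, ...) {
  cat(sprintf("axr_params: ADC=%.4g um^2/ms sigma=%.4g AXR=%.4g /s\n",
              x$ADC, x$sigma, x$AXR))
  invisible(x)
}

#' Equilibrium ADC of a two-compartment system
#'
#' `ADC = fe_eq * De + fi_eq * Di`, the signal-fraction-weighted diffusivity
#' observed without filtering.
#'
#' @param p a [tissue_params()].
#' @return ADC in um^2/ms.
#' @export
equilibrium_adc <- function(p) p$fe_eq * p$De + p$fi_eq * p$Di

#' Equivalent AXR parameters of a two-compartment system
#'
#' Maps compartmental ground truth to the AXR description: ADC from
#' [equilibrium_adc()], sigma from [filter_efficiency()] at the scheme's
#' nonzero filter b-value, and AXR = k (exact in the relaxation-free
#' two-compartment limit).
#'
#' @param p a [tissue_params()].
#' @param bf filter b-value at which sigma is evaluated (s/mm^2).
#' @return An [axr_params()].
#' @export
equivalent_axr_params <- function(p, bf = 250) {
  axr_params(ADC = equilibrium_adc(p),
             sigma = max(0, min(1, filter_efficiency(p, bf))),
             AXR = p$k)
}
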