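# Shared fixtures built in code.

# random tissue parameter set within the fitting bounds (well inside, so
# truth-started fits are not pinned to a boundary)
random_tissue_params <- function(relaxation = FALSE) {
  tissue_params(
    fi_eq = runif(1, 0.02, 0.10),
    De = runif(1, 0.5, 2.0),
    Di = runif(1, 5, 20),
    k = runif(1, 0.5, 10),
    T1i = if (relaxation) runif(1, 0.8, 2.2) else Inf,
    T1e = if (relaxation) runif(1, 0.8, 2.2) else Inf,
    T2i = if (relaxation) runif(1, 0.06, 0.20) else Inf,
    T2e = if (relaxation) runif(1, 0.06, 0.20) else Inf)
}

# numerically integrate dM/dt = -(q^2 D + R + K) M through the three
# sequence blocks with deSolve; independent oracle for the closed-form
# block solution. b-weighting is spread uniformly over each block's
# duration so the cumulative weighting matches bf (resp. b).
ode_2cmr_signal <- function(p, m) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  deriv <- function(t, M, parms) {
    A <- parms$A
    list(c(-(A[1, 1] * M[1] + A[1, 2] * M[2]),
           -(A[2, 1] * M[1] + A[2, 2] * M[2])))
  }
  evolve <- function(M0, A, duration) {
    if (duration == 0) return(M0)
    out <- deSolve::ode(y = M0, times = c(0, duration), func = deriv,
                        parms = list(A = A), method = "lsoda",
                        rtol = 1e-12, atol = 1e-14)
    as.numeric(out[2, 2:3])
  }
  K <- matrix(c(p$kie, -p$kie, -p$kei, p$kei), 2, 2)
  R2 <- diag(c(1 / p$T2i, 1 / p$T2e))
  R1 <- diag(c(1 / p$T1i, 1 / p$T1e))
  D <- diag(c(p$Di, p$De)) * 1e-3
  # filter block: q_f^2 D + R2 over TEf, exchange neglected
  M <- evolve(c(p$fi_eq, p$fe_eq), (m$bf / m$TEf) * D + R2, m$TEf)
  # mixing: R1 + K over tm
  M <- evolve(M, R1 + K, m$tm)
  # encoding: q^2 D + R2 over TE
  M <- evolve(M, (m$b / m$TE) * D + R2, m$TE)
  sum(M)
}

# brute-force normalized 2CMr signals on a scheme via the ODE oracle
ode_2cmr_normalized <- function(p, scheme) {
  raw <- vapply(seq_len(nrow(scheme)),
                function(i) ode_2cmr_signal(p, scheme[i, ]), numeric(1))
  normalize_signals(raw, scheme)
}
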