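# Scalar reference values below are computed in place by direct evaluation
# of the closed-form expressions (independent of the package's vectorized
# implementations); the dynamics are cross-checked against an adaptive ODE
# integration of the underlying two-site system.

gm_norelax <- tissue_params(fi_eq = 0.05, De = 1, Di = 10, k = 3)

test_that("post-filter fractions match direct evaluation and limits", {
  # direct scalar composition of the filtered-mixture ratio
  wi <- 0.05 * exp(-250 * 10 * 1e-3)
  we <- 0.95 * exp(-250 * 1 * 1e-3)
  expect_equal(post_filter_fractions(gm_norelax, 250)$fi0, wi / (wi + we),
               tolerance = 1e-12)
  expect_equal(post_filter_fractions(gm_norelax, 250)$fi0, 0.0055167,
               tolerance = 1e-4)
  expect_equal(post_filter_fractions(gm_norelax, 0)$fi0, 0.05)
  same_d <- tissue_params(fi_eq = 0.05, De = 2, Di = 2, k = 3)
  expect_equal(post_filter_fractions(same_d, 700)$fi0, 0.05)
  # stronger filters suppress more intravascular signal when Di > De
  fr <- post_filter_fractions(gm_norelax, c(0, 100, 250, 500))$fi0
  expect_true(all(diff(fr) < 0))
})

test_that("mixing recovers filtered fractions mono-exponentially", {
  fi0 <- post_filter_fractions(gm_norelax, 250)$fi0
  expect_equal(fraction_recovery(fi0, 0.05, 3, 0), fi0)
  expect_equal(fraction_recovery(fi0, 0.05, 3, 1e6), 0.05)
  # direct scalar evaluation at tm = 200 ms
  expect_equal(fraction_recovery(fi0, 0.05, 3, 0.2),
               0.05 - (0.05 - fi0) * exp(-0.6), tolerance = 1e-12)
  expect_equal(fraction_recovery(fi0, 0.05, 3, 0.2), 0.025587,
               tolerance = 1e-4)
  tms <- seq(0, 1, 0.05)
  expect_true(all(diff(fraction_recovery(fi0, 0.05, 3, tms)) > 0))
})

test_that("relaxation-free signal composes filter, mixing and encoding", {
  m <- fexi_scheme(bf = 250, tm = 0.2, b = 1000, TEf = 0.038, TE = 0.062)
  # spreadsheet-style composition
  fi0 <- (0.05 * exp(-2.5)) / (0.05 * exp(-2.5) + 0.95 * exp(-0.25))
  fitm <- 0.05 - (0.05 - fi0) * exp(-3 * 0.2)
  expected <- (1 - fitm) * exp(-1) + fitm * exp(-10)
  expect_equal(signal_2cm(gm_norelax, m), expected, tolerance = 1e-12)

  sch <- default_scheme()
  s <- signal_2cm(gm_norelax, sch)
  expect_equal(s[sch$b == 0], rep(1, sum(sch$b == 0)))
  # single-compartment limit
  tiny <- tissue_params(fi_eq = 1e-12, De = 1.3, Di = 10, k = 3)
  expect_equal(signal_2cm(tiny, sch), exp(-sch$b * 1.3e-3), tolerance = 1e-9)
  # monotone non-increasing in b within each filter block
  for (g in split(seq_len(nrow(sch)), interaction(sch$bf, sch$tm))) {
    o <- g[order(sch$b[g])]
    expect_true(all(diff(s[o]) <= 0))
  }
})

test_that("mixing evolution matches limits and the ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- tissue_params(fi_eq = 0.05, De = 1, Di = 10, k = 3,
                     T1i = 1.65, T1e = 1.5)
  M0 <- c(0.0055, 0.9945)
  expect_equal(mixing_evolution(M0, p, 0), M0)
  # decoupled mono-exponentials when exchange is off
  p0 <- tissue_params(fi_eq = 0.05, De = 1, Di = 10, k = 0,
                      T1i = 1.65, T1e = 1.5)
  expect_equal(mixing_evolution(M0, p0, 0.4),
               M0 * exp(-0.4 / c(1.65, 1.5)), tolerance = 1e-12)
  # adaptive ODE integration oracle
  deriv <- function(t, M, parms)
    list(as.numeric(-parms %*% M))
  A <- matrix(c(1 / 1.65 + p$kie, -p$kie, -p$kei, 1 / 1.5 + p$kei), 2, 2)
  ode <- deSolve::ode(y = M0, times = c(0, 0.4), func = deriv, parms = A,
                      rtol = 1e-12, atol = 1e-14)
  expect_equal(mixing_evolution(M0, p, 0.4), as.numeric(ode[2, 2:3]),
               tolerance = 1e-9)
  expect_error(mixing_evolution(c(NA, 1), p, 0.1), "finite")
})

test_that("mixing propagator is a semigroup and conserves magnetization", {
  set.seed(42)
  for (i in 1:20) {
    p <- random_tissue_params(relaxation = i %% 2 == 0)
    M0 <- runif(2)
    t1 <- runif(1, 0, 0.5); t2 <- runif(1, 0, 0.5)
    expect_equal(mixing_evolution(mixing_evolution(M0, p, t1), p, t2),
                 mixing_evolution(M0, p, t1 + t2), tolerance = 1e-12)
  }
  # without relaxation, exchange only redistributes magnetization
  p <- random_tissue_params(relaxation = FALSE)
  M0 <- c(p$fi_eq, p$fe_eq)
  Mt <- mixing_evolution(M0, p, 0.37)
  expect_equal(sum(Mt), sum(M0), tolerance = 1e-12)
  # and the equilibrium state is a fixed point (detailed balance)
  expect_equal(Mt, M0, tolerance = 1e-12)
})

test_that("finite-relaxation model reduces to the relaxation-free model", {
  sch <- default_scheme()
  set.seed(7)
  for (i in 1:100) {
    p <- random_tissue_params(relaxation = FALSE)
    expect_lt(max(abs(signal_2cmr(p, sch, normalize = "group") -
                        signal_2cm(p, sch))), 1e-10)
  }
})

test_that("finite-relaxation signal matches piecewise ODE integration", {
  skip_if_not_installed("deSolve")
  gm <- tissue_preset("gm")
  m <- fexi_scheme(bf = c(250, 250), tm = 0.2, b = c(250, 0),
                   TEf = 0.038, TE = 0.062)
  s_pkg <- signal_2cmr(gm, m, normalize = "group")
  s_ode <- ode_2cmr_normalized(gm, m)
  expect_equal(s_pkg[1], s_ode[1], tolerance = 1e-9)
  # a handful of random parameter sets over the full protocol
  set.seed(13)
  sch <- default_scheme()[c(1, 4, 6, 8, 11, 15, 16, 20), ]
  class(sch) <- c("fexi_scheme", "data.frame")
  for (i in 1:3) {
    p <- random_tissue_params(relaxation = TRUE)
    expect_equal(signal_2cmr(p, sch, normalize = "group"),
                 ode_2cmr_normalized(p, sch), tolerance = 1e-9)
  }
})

test_that("normalization modes of the finite-relaxation model are consistent", {
  gm <- tissue_preset("gm")
  sch <- default_scheme()
  raw <- signal_2cmr(gm, sch, normalize = "none")
  eq <- signal_2cmr(gm, sch, normalize = "equilibrium")
  expect_equal(eq, raw / raw[sch$bf == 0 & sch$tm == 0.020 & sch$b == 0][1])
  expect_equal(signal_2cmr(gm, sch, normalize = "group"),
               normalize_signals(raw, sch))
  expect_equal(eq[sch$bf == 0 & sch$tm == 0.020 & sch$b == 0], 1)
})

test_that("AXR model signal, ADC consistency and filter efficiency", {
  a <- axr_params(ADC = 1.45, sigma = 0.276, AXR = 3)
  sch <- default_scheme()
  s <- signal_axr(a, sch)
  expect_equal(s[sch$b == 0], rep(1, sum(sch$b == 0)))
  # direct scalar evaluation at (bf=250, tm=0.2, b=250)
  expect_equal(s[sch$bf == 250 & sch$tm == 0.2 & sch$b == 250],
               exp(-0.25 * 1.45 * (1 - 0.276 * exp(-0.6))),
               tolerance = 1e-12)
  # unfiltered decay is exactly mono-exponential at the ADC
  unf <- sch$bf == 0 & sch$b > 0
  expect_equal(-log(s[unf]) / (sch$b[unf] * 1e-3), rep(1.45, sum(unf)),
               tolerance = 1e-10)
  # filtered ADC recovers to the equilibrium ADC at long mixing times
  long <- fexi_scheme(bf = 250, tm = 50, b = 250, TEf = 0.038, TE = 0.062)
  expect_equal(signal_axr(a, long), exp(-0.25 * 1.45), tolerance = 1e-9)

  expect_equal(filter_efficiency(gm_norelax, 0), 0)
  same_d <- tissue_params(fi_eq = 0.05, De = 2, Di = 2, k = 3)
  expect_equal(filter_efficiency(same_d, 250), 0)
  expect_equal(filter_efficiency(gm_norelax, 250), 0.27610,
               tolerance = 1e-4)
  # sigma as defined equals the relative initial ADC reduction
  fi0 <- post_filter_fractions(gm_norelax, 250)$fi0
  adc0 <- (1 - fi0) * 1 + fi0 * 10
  adc_eq <- equilibrium_adc(gm_norelax)
  expect_equal(filter_efficiency(gm_norelax, 250), (adc_eq - adc0) / adc_eq,
               tolerance = 1e-12)
})

test_that("AXR equals the total exchange rate in the small-b limit", {
  # fit the AXR model to noise-free relaxation-free compartmental signals
  # at weak encoding, where the mono-exponential approximation holds
  p <- gm_norelax
  sch <- fexi_scheme(bf = rep(c(0, 250, 250, 250), each = 2),
                     tm = rep(c(0.02, 0.02, 0.2, 0.4), each = 2),
                     b = rep(c(0, 25), 4), TEf = 0.038, TE = 0.062)
  dat <- signal_2cm(p, sch)
  cfg <- fit_config("axr", n_starts = 1, init_mode = "ground_truth")
  ft <- fexi_fit(dat, sch, cfg,
                 init = list(ADC = equilibrium_adc(p),
                             sigma = filter_efficiency(p, 250), AXR = p$k))
  expect_equal(ft$params$AXR, p$k, tolerance = 0.02)
})
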