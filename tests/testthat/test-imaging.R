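test_that("repeatability statistics match the closed-form definitions", {
  # hand calculation: d = (1, -1), sigma_w^2 = 0.5, RC = 1.96*sqrt(2)*sqrt(0.5)
  r <- repeatability(c(2, 4), c(3, 3))
  expect_equal(r$sigma_w, sqrt(0.5))
  expect_equal(r$RC, 1.96, tolerance = 1e-12)
  expect_equal(r$bias, 0)
  expect_equal(r$CoV, 100 * sqrt(0.5) / 3)
  # identical scans
  r0 <- repeatability(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$RC, 0)
  expect_equal(r0$bias, 0)
  expect_equal(r0$loa, c(0, 0))
  expect_error(repeatability(1, 1), "at least 2")
  expect_error(repeatability(c(1, 2), c(1, 2, 3)), "unpaired")
})

test_that("voxel-wise SNR estimation follows the replicate convention", {
  a <- array(1, c(2, 2, 1))
  expect_error(estimate_snr(list(a)), "at least 2")
  # identical replicates: infinite SNR sentinel
  est <- estimate_snr(list(a, a, a))
  expect_true(all(is.infinite(est$snr_map)))
  expect_true(is.infinite(est$mean_snr))
  # known mean/sd
  b <- a; b[] <- 2
  est2 <- estimate_snr(list(a, b))
  expect_equal(unique(as.numeric(est2$snr_map)), 1.5 / sd(c(1, 2)))
})

test_that("ROI medians use valid voxels only and tolerate empty labels", {
  maps <- structure(list(
    k = array(c(3, 3, 3, 100, NA, 2), c(3, 2, 1)),
    objective = array(0, c(3, 2, 1)),
    extreme = array(c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE), c(3, 2, 1)),
    failed = array(c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE), c(3, 2, 1)),
    model = "2cm"), class = "fexi_parameter_maps")
  labels <- array(c(1L, 1L, 1L, 1L, 2L, 3L), c(3, 2, 1))
  tab <- roi_median(maps, labels)
  # extreme voxel (value 100) excluded from label 1
  expect_equal(tab$median[tab$label == 1 & tab$parameter == "k"], 3)
  expect_equal(tab$n_voxels[tab$label == 1 & tab$parameter == "k"], 3)
  # failed-only label reported empty, not an error
  expect_equal(tab$n_voxels[tab$label == 2], 0)
  expect_true(is.na(tab$median[tab$label == 2]))
  expect_equal(tab$median[tab$label == 3], 2)
})

test_that("image fitting recovers a noise-free phantom and flags bad voxels", {
  sch <- default_scheme()
  lab <- array(c(1L, 2L, 0L, 2L), c(2, 2, 1))
  ph <- fexi_phantom(dim = c(2, 2, 1), label_map = lab, scheme = sch)
  series <- generate_phantom(ph)
  gm <- tissue_preset("gm")
  # 2cm fit with per-label fixed fi_eq; truth-started at the GM values
  cfg <- fit_config("2cm", fixed = list(fi_eq = 0.05), n_starts = 1,
                    init_mode = "ground_truth")
  maps <- fit_image(series, sch, cfg, mask = lab != 0, labels = lab,
                    init = list(De = 1, Di = 10, k = 3))
  expect_s3_class(maps, "fexi_parameter_maps")
  # background voxel untouched
  expect_true(is.na(maps$k[1, 2, 1]))
  expect_false(maps$failed[1, 2, 1])
  # GM voxels: relaxation-time bias in k is a few percent, not more
  expect_equal(maps$k[2, 1, 1], gm$k, tolerance = 0.15)
  expect_equal(maps$k[2, 1, 1], maps$k[2, 2, 1], tolerance = 1e-6)
  # all-zero voxel inside the mask is flagged failed
  series2 <- series
  series2[2, 2, 1, ] <- 0
  maps2 <- fit_image(series2, sch, cfg, mask = lab != 0, labels = lab,
                     init = list(De = 1, Di = 10, k = 3))
  expect_true(maps2$failed[2, 2, 1])
  expect_true(is.na(maps2$k[2, 2, 1]))
  tab <- roi_median(maps2, lab)
  expect_equal(tab$n_voxels[tab$label == 2 & tab$parameter == "k"], 1)
  # shape mismatches and empty masks raise
  expect_error(fit_image(series[, , , 1:3, drop = FALSE], sch, cfg),
               "volumes")
  expect_error(fit_image(series, sch, cfg, mask = array(FALSE, c(2, 2, 1))),
               "empty mask")
})

test_that("matched-model image fitting is exact on a noise-free phantom", {
  # small scheme keeps the per-voxel finite-relaxation fits quick
  sch <- default_scheme()
  wm <- tissue_preset("wm")
  lab <- array(1L, c(2, 1, 1))
  ph <- fexi_phantom(dim = c(2, 1, 1), label_map = lab,
                     params = list(`1` = wm), scheme = sch)
  series <- generate_phantom(ph)
  cfg <- fit_config("2cmr",
                    fixed = list(fi_eq = wm$fi_eq, T1i = wm$T1i, T1e = wm$T1e,
                                 T2i = wm$T2i, T2e = wm$T2e),
                    n_starts = 1, init_mode = "ground_truth")
  maps <- fit_image(series, sch, cfg, mask = lab != 0,
                    init = list(De = wm$De, Di = wm$Di, k = wm$k))
  expect_equal(maps$k[1, 1, 1], wm$k, tolerance = 1e-3)
  expect_equal(maps$De[1, 1, 1], wm$De, tolerance = 1e-3)
  expect_equal(maps$Di[1, 1, 1], wm$Di, tolerance = 1e-3)
})

test_that("scan-rescan phantom repeatability is on the Monte-Carlo scale", {
  # two independently noised phantoms with identical truth: the per-scan GM
  # median exchange rates should differ by much less than the spread of
  # single-voxel estimates
  sch <- subset_scheme(default_scheme(), "compartmental")
  gm <- tissue_preset("gm")
  lab <- array(2L, c(3, 3, 1))
  ph <- fexi_phantom(dim = c(3, 3, 1), label_map = lab,
                     params = list(`2` = gm), scheme = sch)
  cfg <- fit_config("2cm", fixed = list(fi_eq = 0.05), n_starts = 1,
                    init_mode = "ground_truth")
  med <- function(seed) {
    series <- generate_phantom(ph, noise = noise_spec(66, seed = seed))
    maps <- fit_image(series, sch, cfg, mask = lab != 0,
                      init = list(De = 1, Di = 10, k = 3))
    tab <- roi_median(maps, lab)
    tab$median[tab$parameter == "k"]
  }
  k1 <- med(31); k2 <- med(32)
  expect_lt(abs(k1 - k2), 2)
  expect_equal(mean(c(k1, k2)), gm$k, tolerance = 0.5)
})
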