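# Pretreatment chain: smoothing, baseline, second derivative, regions,
# averaging, band semi-quantification, stage ordering.

test_that("Savitzky-Golay smoothing reproduces low-degree signals exactly", {
  g <- wavenumber_grid()
  flat <- ftir_spectrum(g, rep(0.3, length(g)))
  expect_equal(sg_smooth(flat)$absorbance, rep(0.3, length(g)))
  line <- ftir_spectrum(g, 0.001 * as.numeric(g) - 1)
  expect_equal(sg_smooth(line)$absorbance, line$absorbance, tolerance = 1e-9)
  expect_error(sg_smooth(flat, window_points = 8), "odd")
  expect_error(sg_smooth(flat, window_points = 9, poly_order = 9),
               "smaller than the window")
  short <- ftir_spectrum(wavenumber_grid(1000, 1028, 4), rep(1, 8))
  expect_error(sg_smooth(short, window_points = 11), "exceeds")
})

test_that("smoothing reduces white-noise variance", {
  g <- wavenumber_grid()
  sds <- with_seed_test(11, replicate(20, {
    s <- ftir_spectrum(g, rnorm(length(g), 0, 0.05))
    sd(sg_smooth(s)$absorbance)
  }))
  expect_true(all(sds < 0.05))
})

test_that("baseline correction is offset-invariant and flattens ramps", {
  g <- wavenumber_grid()
  nu <- as.numeric(g)
  peak <- exp(-(nu - 1650)^2 / (2 * 20^2))
  for (method in c("rubberband", "polynomial")) {
    s <- ftir_spectrum(g, peak)
    s_off <- ftir_spectrum(g, peak + 5)
    expect_equal(baseline_correct(s, method)$absorbance,
                 baseline_correct(s_off, method)$absorbance,
                 tolerance = 1e-9)
    ramp <- ftir_spectrum(g, 0.002 * nu + 1)
    expect_equal(baseline_correct(ramp, method)$absorbance,
                 rep(0, length(g)), tolerance = 1e-9)
  }
  # band on a linear ramp: peak height recovered within 2% of the
  # ramp-free truth (rubberband)
  ramped <- ftir_spectrum(g, peak + 0.0005 * nu)
  corr <- baseline_correct(ramped, "rubberband")
  h_true <- band_quant(ftir_spectrum(g, peak), 1650)$value
  h_corr <- band_quant(ftir_spectrum(corr$wavenumber, corr$absorbance,
                                     stage = "raw"), 1650)$value
  expect_lt(abs(h_corr - h_true) / h_true, 0.02)
  # rubberband output never dips below zero
  expect_gte(min(corr$absorbance), -1e-12)
})

test_that("second derivative obeys its closed forms and is linear", {
  g <- wavenumber_grid()
  nu <- as.numeric(g)
  line <- ftir_spectrum(g, 3 * nu + 2)
  expect_equal(second_derivative(line)$absorbance, rep(0, length(g)),
               tolerance = 1e-9)
  quad <- ftir_spectrum(g, nu^2)
  d2 <- second_derivative(quad)$absorbance
  interior <- 5:(length(g) - 4)
  expect_equal(d2[interior], rep(2, length(interior)), tolerance = 1e-6)
  # linearity: D(alpha a + beta b) = alpha D(a) + beta D(b)
  a <- ftir_spectrum(g, sin(nu / 100)); b <- ftir_spectrum(g, cos(nu / 70))
  lhs <- second_derivative(ftir_spectrum(g, 2 * a$absorbance - 3 * b$absorbance))
  expect_equal(lhs$absorbance,
               2 * second_derivative(a)$absorbance -
                 3 * second_derivative(b)$absorbance,
               tolerance = 1e-9)
  # a positive gaussian band dips most at its centre
  bandspec <- ftir_spectrum(g, exp(-(nu - 1456)^2 / (2 * 15^2)))
  dd <- second_derivative(bandspec)
  expect_equal(as.numeric(dd$wavenumber[which.min(dd$absorbance)]), 1456)
  expect_error(second_derivative(quad, poly_order = 1), "poly_order >= 2")
})

test_that("region extraction follows the published windows", {
  g <- wavenumber_grid()
  s <- ftir_spectrum(g, as.numeric(g))  # absorbance = wavenumber, easy check
  pr <- extract_region(s, "proteins")
  expect_true(all(pr$wavenumber >= 1480 & pr$wavenumber <= 1800))
  expect_equal(length(pr$wavenumber), 81)
  li <- extract_region(s, "lipids")
  expect_true(all((li$wavenumber >= 1300 & li$wavenumber <= 1480) |
                    (li$wavenumber >= 2800 & li$wavenumber <= 3000)))
  expect_false(any(li$wavenumber > 1480 & li$wavenumber < 2800))
  nc <- extract_region(s, "nucleic_carbo")
  expect_true(all(nc$wavenumber >= 900 & nc$wavenumber <= 1300))
  # region tiling of [900, 1800]: proteins + nucleic + lipid low window
  # double-count exactly the two shared boundary points (1300, 1480)
  n_li_low <- sum(li$wavenumber <= 1480)
  n_900_1800 <- sum(g >= 900 & g <= 1800)
  expect_equal(length(pr$wavenumber) + length(nc$wavenumber) + n_li_low - 2,
               n_900_1800)
  # full-span custom window reproduces the input
  full <- extract_region(s, spectral_region("all", list(c(600, 4000))))
  expect_equal(full$absorbance, s$absorbance)
  expect_error(extract_region(s, spectral_region("off", list(c(100, 200)))),
               "does not intersect")
  expect_error(spectral_region("nope"), "unknown region")
})

test_that("average spectrum is the pointwise mean with label propagation", {
  set1 <- clean_set(1)
  expect_equal(average_spectrum(set1)$absorbance, set1$absorbance[1, ])
  g <- wavenumber_grid()
  a <- rnorm(length(g))
  pm <- ftir_set(g, rbind(a, -a), c("p", "m"), group = "x")
  avg <- average_spectrum(pm)
  expect_equal(avg$absorbance, rep(0, length(g)))
  expect_identical(avg$group, "x")
  # zero-noise population mean equals the noiseless model render
  set <- synth_population(10, default_band_model("control"),
                          wavenumber_grid(), no_noise())
  truth <- render_bands(default_band_model("control"), wavenumber_grid())
  expect_equal(average_spectrum(set)$absorbance, truth, tolerance = 1e-12)
  expect_error(bind_sets(clean_set(2),
                         set_from_spectra(list(render_spectrum(
                           default_band_model("control"), tiny_grid(),
                           no_noise())))),
               "share grid")
})

test_that("band semi-quantification is baseline-local and linear", {
  g <- wavenumber_grid()
  nu <- as.numeric(g)
  zero <- ftir_spectrum(g, rep(0, length(g)))
  expect_equal(band_quant(zero, 1650, "peak_height")$value, 0)
  expect_equal(band_quant(zero, 1650, "integrated_area")$value, 0)
  peak <- ftir_spectrum(g, exp(-4 * log(2) * (nu - 1652)^2 / 30^2))
  expect_equal(band_quant(peak, 1652, "peak_height", 60)$value, 1,
               tolerance = 0.01)
  dbl <- ftir_spectrum(g, 2 * peak$absorbance)
  for (metric in c("peak_height", "integrated_area")) {
    expect_equal(band_quant(dbl, 1652, metric, 60)$value,
                 2 * band_quant(peak, 1652, metric, 60)$value,
                 tolerance = 1e-12)
  }
  expect_error(band_quant(peak, 4000, window_halfwidth = 50), "beyond")
})

test_that("stage ordering is enforced, inputs never mutated", {
  s <- render_spectrum(default_band_model("control"), wavenumber_grid(),
                       no_noise())
  sm <- sg_smooth(s)
  expect_identical(s$stage, "raw")  # input untouched
  expect_error(sg_smooth(sm), "already at stage")
  d2 <- second_derivative(sm)
  expect_error(baseline_correct(d2), "already at stage")
  expect_error(rmie_emsc(d2), "already at stage")
  # forward skip is allowed: derivative straight from raw
  expect_identical(second_derivative(s)$stage, "second_derivative")
})

test_that("l2 normalisation yields unit-norm traces", {
  set <- quick_population(4)
  nrm <- l2_normalize(set)
  expect_equal(unname(sqrt(rowSums(nrm$absorbance^2))), rep(1, 4))
  zero <- ftir_spectrum(wavenumber_grid(), rep(0, 851))
  expect_error(l2_normalize(zero), "all-zero")
})
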