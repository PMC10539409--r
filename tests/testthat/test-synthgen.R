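# Synthetic single-cell spectrum generator: band model, rendering,
# Mie forward model, population generation.

test_that("wavenumber grid validates monotonicity, spacing and length", {
  g <- wavenumber_grid()
  expect_length(g, 851)
  expect_equal(g[1], 600)
  expect_equal(g[length(g)], 4000)
  expect_error(validate_grid(c(1, 2, 3)), "at least 8")
  expect_error(validate_grid(seq(8, 1)), "ascending")
  expect_error(validate_grid(c(1:7, 9.5)), "uniformly spaced")
})

test_that("default band model carries the canonical assignments", {
  m <- default_band_model("control", 0.3)
  centers <- vapply(m$bands, `[[`, 0, "center")
  expect_setequal(centers, c(2920, 2850, 1740, 1650, 1545, 1456, 1390,
                             1084, 984))
  amide1 <- m$bands[[which(centers == 1650)]]
  expect_identical(amide1$assignment, "Amide I")
  expect_equal(amide1$amplitude, 1.0)
  expect_error(default_band_model("aged"), "unknown group label")
  expect_error(default_band_model("control", -1), "non-negative")
})

test_that("effect size scales senescent amplitudes and vanishes at zero", {
  ctrl <- default_band_model("control", 0.5)
  amp_of <- function(m, c0) {
    ctr <- vapply(m$bands, `[[`, 0, "center")
    m$bands[[which(ctr == c0)]]$amplitude
  }
  # zero effect: senescent band-by-band equals control, 1740 present at 0
  s0 <- default_band_model("senescent", 0)
  for (c0 in c(2920, 2850, 1740, 1650, 1545, 1456, 1390, 1084, 984)) {
    expect_equal(amp_of(s0, c0), amp_of(ctrl, c0))
  }
  expect_equal(amp_of(s0, 1740), 0)
  # positive effect: (1 + e*w) scaling on responsive bands
  s <- default_band_model("senescent", 0.5)
  expect_equal(amp_of(s, 2920), amp_of(ctrl, 2920) * 1.5)   # lipid, w = 1
  expect_equal(amp_of(s, 1650), amp_of(ctrl, 1650) * 1.25)  # protein, w = .5
  expect_equal(amp_of(s, 1390), amp_of(ctrl, 1390))         # unresponsive
  expect_gt(amp_of(s, 1740), 0)                             # ester grows in
  # monotone growth of the ester band
  amps <- vapply(c(0, .1, .3, .5),
                 function(e) amp_of(default_band_model("senescent", e), 1740),
                 0)
  expect_true(all(diff(amps) > 0))
})

test_that("noiseless render peaks at the band amplitude on the grid point", {
  m <- band_model(list(band(1100, 30, 0.7)), "control")
  s <- render_spectrum(m, tiny_grid(), no_noise())
  expect_equal(max(s$absorbance), 0.7)
  expect_equal(s$wavenumber[which.max(s$absorbance)], 1100)
  expect_error(render_spectrum(band_model(list(), "control"), tiny_grid(),
                               no_noise()),
               "no bands")
})

test_that("rendering is deterministic and responds to the noise law", {
  m <- default_band_model("control")
  a <- render_spectrum(m, wavenumber_grid(), noise_model(), seed = 42)
  b <- render_spectrum(m, wavenumber_grid(), noise_model(), seed = 42)
  expect_identical(a$absorbance, b$absorbance)
  c <- render_spectrum(m, wavenumber_grid(), noise_model(), seed = 43)
  expect_false(identical(a$absorbance, c$absorbance))
  # white-noise-only trace recovers the configured sd within 10%
  nm <- noise_model(additive_sd = 0.05, baseline_poly_degree = 0,
                    baseline_coeff_sd = 0, cell_amplitude_cv = 0)
  zero <- band_model(list(band(2000, 30, 0)), "control")
  g <- wavenumber_grid(0, 3999, 1)  # 4000 points
  tr <- render_spectrum(zero, g, nm, seed = 7)
  expect_lt(abs(sd(tr$absorbance) - 0.05) / 0.05, 0.1)
})

test_that("van de Hulst extinction matches hand-checked closed-form values", {
  rho <- c(0.5, 1.0, pi / 2, pi, 2 * pi)
  expected <- c(0.123274700920, 0.472906837296, 1.074659848807,
                2.810569469139, 2.000000000000)
  expect_equal(vdh_extinction(rho), expected, tolerance = 1e-9)
  # series limit: Q -> 0 as rho -> 0, continuous across the switch
  expect_equal(vdh_extinction(0), 0)
  expect_equal(vdh_extinction(9.9e-5), vdh_extinction(1.01e-4),
               tolerance = 1e-6)
})

test_that("Mie distortion adds a non-collinear oscillatory component", {
  s <- render_spectrum(default_band_model("control"), wavenumber_grid(),
                       no_noise())
  d <- apply_mie_distortion(s, mie_params(radius = 5, n_ref = 1.3))
  q <- attr(d, "mie_extinction")
  expect_length(q, length(s$absorbance))
  expect_lt(cor(d$absorbance, s$absorbance), 1)
  expect_gt(diff(range(q)), 0.5)  # broad oscillation, not a flat offset
  # radius -> 0: rho -> 0, Q -> 0, output = alpha * input + gamma
  d0 <- apply_mie_distortion(s, mie_params(radius = 1e-9, n_ref = 1.3),
                             alpha = 2, gamma = 0.1)
  expect_equal(d0$absorbance, 2 * s$absorbance + 0.1, tolerance = 1e-9)
  expect_error(mie_params(radius = -1), "radius")
  expect_error(mie_params(n_ref = 0.9), "n_ref")
})

test_that("synthetic populations are labelled, sized and reproducible", {
  set <- quick_population(40, "senescent", seed = 5)
  expect_equal(n_cells(set), 40)
  expect_true(all(set$group == "senescent"))
  expect_equal(anyDuplicated(set$cell_id), 0L)
  again <- quick_population(40, "senescent", seed = 5)
  expect_identical(set$absorbance, again$absorbance)
  expect_error(synth_population(1, default_band_model("control")), ">= 2")
  # zero noise collapses all cells onto the model spectrum
  still <- synth_population(2, default_band_model("control"),
                            wavenumber_grid(), no_noise())
  expect_identical(still$absorbance[1, ], still$absorbance[2, ])
})

test_that("inter-group separation grows with effect size", {
  mean_sep <- function(effect, seed) {
    a <- synth_population(8, default_band_model("control", effect),
                          wavenumber_grid(), noise_model(), seed = seed)
    b <- synth_population(8, default_band_model("senescent", effect),
                          wavenumber_grid(), noise_model(), seed = seed + 500)
    a <- second_derivative(a); b <- second_derivative(b)
    mean(inter_group_distances(a, b)$values)
  }
  effects <- c(0, 0.1, 0.3, 0.5)
  seps <- sapply(effects, function(e) {
    mean(sapply(1:20, function(s) mean_sep(e, s)))
  })
  # non-decreasing over the sweep, one-sided tolerance of 2%
  expect_true(all(diff(seps) > -0.02 * seps[-length(seps)]))
  # and strictly larger at the top than at the null
  expect_gt(seps[4], seps[1])
})

test_that("zero effect leaves in-group and inter-group distances exchangeable", {
  pvals <- sapply(1:5, function(s) {
    a <- synth_population(12, default_band_model("control", 0),
                          wavenumber_grid(), noise_model(), seed = s)
    b <- synth_population(12, default_band_model("senescent", 0),
                          wavenumber_grid(), noise_model(), seed = s + 900)
    a <- second_derivative(a); b <- second_derivative(b)
    dm <- distance_matrix(a, b)
    heterogeneity_report(in_group_distances(a), inter_group_distances(a, b),
                         pooled = dm, seed = s)$test$p_value
  })
  # allow the nominal false-positive rate: not every p need exceed 0.01,
  # but wholesale rejection would mean manufactured separation
  expect_gte(sum(pvals > 0.01), 4)
})
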