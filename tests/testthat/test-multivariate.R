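# PCA, confidence ellipses, ellipse classification, sensitivity/specificity.

test_that("PCA finds a planted dominant axis and satisfies its algebra", {
  # 2-D cloud along y = x plus tiny noise, embedded on a small grid
  g <- tiny_grid()
  n <- 30
  X <- with_seed_test(2, {
    t <- rnorm(n, 0, 3)
    cbind(t, t) + matrix(rnorm(2 * n, 0, 0.01), n, 2)
  })
  emb <- cbind(X, matrix(0, n, length(g) - 2))
  set <- ftir_set(g, emb, sprintf("c%02d", 1:n), group = "g")
  p <- spectral_pca(set, 2)
  expect_gt(p$explained_variance_ratio[1], 0.99)
  # scores = (data - centre) %*% t(loadings)
  recon <- sweep(set$absorbance, 2, p$center) %*% t(p$loadings)
  expect_equal(unname(recon), unname(p$scores), tolerance = 1e-8)
  # loadings orthonormal, scores centred
  expect_equal(p$loadings %*% t(p$loadings), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(colMeans(p$scores)), c(0, 0), tolerance = 1e-8)
  # explained variance non-increasing, sums <= 1
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(p$explained_variance_ratio), 1 + 1e-9)
  # duplicating every cell leaves loadings unchanged (sign-fixed)
  dup <- ftir_set(g, rbind(emb, emb), sprintf("c%02d", 1:(2 * n)),
                  group = "g")
  p2 <- spectral_pca(dup, 2)
  expect_equal(abs(p2$loadings), abs(p$loadings), tolerance = 1e-6)
  # degenerate input rejected
  same <- ftir_set(g, matrix(1, 5, length(g)), sprintf("s%d", 1:5))
  expect_error(spectral_pca(same), "identical")
  expect_error(spectral_pca(set, 40), "more cells than components")
})

test_that("full-rank PCA reconstructs the data and ignores cell order", {
  set <- random_set(10, npts = 12, seed = 5)
  p <- spectral_pca(set, 9)
  recon <- p$scores %*% p$loadings +
    matrix(p$center, 10, 12, byrow = TRUE)
  expect_equal(unname(recon), unname(set$absorbance), tolerance = 1e-8)
  perm <- with_seed_test(6, sample(10))
  setp <- ftir_set(set$wavenumber, set$absorbance[perm, ],
                   set$cell_id[perm], set$group[perm])
  expect_equal(spectral_pca(setp, 5)$explained_variance_ratio,
               spectral_pca(set, 5)$explained_variance_ratio,
               tolerance = 1e-10)
})

test_that("loading traces localise a planted spectral feature", {
  # two groups differing only in the 1740 band
  g <- wavenumber_grid()
  mk <- function(has_band, n, seed, label) {
    bands <- list(band(1650, 40, 1.0), band(1740, 25, if (has_band) 0.4 else 0))
    synth_population(n, band_model(bands, label), g,
                     noise_model(additive_sd = 0.002,
                                 baseline_poly_degree = 0,
                                 baseline_coeff_sd = 0,
                                 cell_amplitude_cv = 0.05), seed = seed)
  }
  pool <- bind_sets(mk(FALSE, 15, 1, "control"), mk(TRUE, 15, 2, "senescent"))
  p <- spectral_pca(pool, 2)
  tr <- pca_loading_trace(p, 1)
  expect_equal(sqrt(sum(tr$loading^2)), 1, tolerance = 1e-8)
  in_win <- tr$wavenumber >= 1700 & tr$wavenumber <= 1780
  expect_gt(max(abs(tr$loading[in_win])),
            stats::median(abs(tr$loading[!in_win])))
  expect_error(pca_loading_trace(p, 3), "out of range")
  # CSV round trip of the trace
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(tr, tmp, row.names = FALSE)
  back <- utils::read.csv(tmp)
  expect_equal(back$loading, tr$loading)
})

test_that("confidence ellipse uses the chi-squared geometry", {
  scores <- with_seed_test(8, matrix(rnorm(4000), 2000, 2))
  e <- confidence_ellipse(scores, 0.95)
  # isotropic standard-normal scores: a near-circle of radius sqrt(chi2)
  expect_equal(e$scale, sqrt(qchisq(0.95, 2)), tolerance = 1e-12)
  expect_equal(e$scale, 2.4477, tolerance = 1e-3)
  expect_equal(unname(e$center), c(0, 0), tolerance = 0.1)
  # Monte-Carlo coverage at several levels from the fitted gaussian
  ch <- chol(e$covariance)
  draws <- with_seed_test(9, matrix(rnorm(20000), 10000, 2) %*% ch +
                            matrix(e$center, 10000, 2, byrow = TRUE))
  for (lev in c(0.90, 0.95, 0.99)) {
    el <- confidence_ellipse(scores, lev)
    cov_frac <- mean(in_ellipse(el, draws))
    expect_lt(abs(cov_frac - lev), 0.01)
  }
  # affine equivariance of membership
  A <- matrix(c(2, 0.5, -1, 1.5), 2, 2); b <- c(3, -2)
  mapped <- scores %*% t(A) + matrix(b, nrow(scores), 2, byrow = TRUE)
  em <- confidence_ellipse(mapped, 0.95)
  pts <- draws[1:500, ]
  pts_m <- pts %*% t(A) + matrix(b, 500, 2, byrow = TRUE)
  expect_identical(in_ellipse(e, pts), in_ellipse(em, pts_m))
  expect_error(confidence_ellipse(scores[1:2, ]), ">= 3")
  expect_error(confidence_ellipse(cbind(1:5, 2 * (1:5))), "singular")
  expect_error(confidence_ellipse(scores, 1.2), "level")
})

test_that("ellipse classification applies membership then mahalanobis", {
  e1 <- confidence_ellipse(with_seed_test(1, matrix(rnorm(100), 50, 2)),
                           fitted_on = "control")
  shifted <- with_seed_test(2, matrix(rnorm(100), 50, 2) + 10)
  e2 <- confidence_ellipse(shifted, fitted_on = "senescent")
  ells <- list(control = e1, senescent = e2)
  # centre of the control ellipse -> control
  cls <- classify_by_ellipse(rbind(e1$center), ells)
  expect_identical(cls$predicted, "control")
  # far outside both, closer to senescent -> senescent
  cls2 <- classify_by_ellipse(rbind(c(25, 25)), ells)
  expect_identical(cls2$predicted, "senescent")
  # outside_control variant: anything beyond the control ellipse is called
  cls3 <- classify_by_ellipse(rbind(e1$center, c(25, 25), c(10, 10)),
                              ells, rule = "outside_control")
  expect_identical(cls3$predicted, c("control", "senescent", "senescent"))
  expect_error(classify_by_ellipse(rbind(c(0, 0)), list(a = e1)),
               "two ftir_ellipse")
})

test_that("sensitivity and specificity follow their defining ratios", {
  # printed-table worked example: tp 39, fn 0, fp 1, tn 40
  perf <- sensitivity_specificity(confusion_matrix(tp = 39, fp = 1,
                                                   fn = 0, tn = 40))
  expect_equal(perf$sensitivity, 100)
  expect_equal(round(perf$specificity, 1), 97.6)
  # perfect prediction
  lab <- rep(c("senescent", "non-senescent"), each = 10)
  p_perf <- sensitivity_specificity(lab, lab)
  expect_equal(p_perf$sensitivity, 100)
  expect_equal(p_perf$specificity, 100)
  # degenerate all-positive classifier
  p_all <- sensitivity_specificity(rep("senescent", 20), lab)
  expect_equal(p_all$sensitivity, 100)
  expect_equal(p_all$specificity, 0)
  expect_error(sensitivity_specificity(c("senescent", "weird", "none"),
                                       c("senescent", "senescent", "none")),
               "two-class")
  expect_error(sensitivity_specificity(lab, lab[1:5]), "length")
  expect_error(confusion_matrix(-1, 0, 0, 0), "non-negative")
})
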