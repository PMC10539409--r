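## Synthetic single-cell FTIR forward model: band rendering with per-cell
## amplitude jitter, additive baseline drift and white noise, and an
## optional resonant Mie scattering distortion (van de Hulst extinction
## with Kramers-Kronig coupling of the real refractive index to the
## absorbance).  This is the ground-truth oracle every preprocessing and
## analysis stage is tested against.

#' Stochastic nuisance model for synthetic spectra
#'
#' @param additive_sd Standard deviation of white instrumental noise (AU).
#' @param baseline_poly_degree Degree of the random additive baseline
#'   polynomial (>= 0; evaluated on the grid rescaled to `[-1, 1]`).
#' @param baseline_coeff_sd Standard deviation of each baseline coefficient
#'   (AU); scalar or one value per coefficient.
#' @param cell_amplitude_cv Coefficient of variation of the per-cell,
#'   per-band lognormal amplitude jitter (biological variability).
#' @param seed Integer seed used when no explicit seed is supplied to the
#'   rendering functions.
#' @return A list of class `"ftir_noise"`.
#' @export
noise_model <- function(additive_sd = 0.002, baseline_poly_degree = 2,
                        baseline_coeff_sd = 0.01, cell_amplitude_cv = 0.15,
                        seed = 1L) {
  if (additive_sd < 0 || any(baseline_coeff_sd < 0) || cell_amplitude_cv < 0) {
    stop("noise scales must be >= 0", call. = FALSE)
  }
  if (baseline_poly_degree < 0 || baseline_poly_degree != round(baseline_poly_degree)) {
    stop("baseline_poly_degree must be a non-negative integer", call. = FALSE)
  }
  structure(list(additive_sd = additive_sd,
                 baseline_poly_degree = as.integer(baseline_poly_degree),
                 baseline_coeff_sd = baseline_coeff_sd,
                 cell_amplitude_cv = cell_amplitude_cv,
                 seed = as.integer(seed)),
            class = "ftir_noise")
}

#' Zero-noise model (deterministic rendering)
#' @return An `ftir_noise` with all scales 0.
#' @export
no_noise <- function() noise_model(0, 0, 0, 0, seed = 1L)

#' Mie scattering parameters
#'
#' @param radius Sphere (cell) radius in micrometres (> 0; plausible 2--8).
#' @param n_ref Baseline real refractive index (> 1; plausible 1.1--1.5).
#' @param resonant If `TRUE`, the real refractive index is perturbed by the
#'   Kramers-Kronig transform of the absorbance (resonant Mie regime).
#' @param kk_amp Peak magnitude of the Kramers-Kronig refractive-index
#'   perturbation, as a fraction of `n_ref - 1`.
#' @return A list of class `"ftir_mie"`.
#' @export
mie_params <- function(radius = 5, n_ref = 1.3, resonant = TRUE,
                       kk_amp = 0.1) {
  if (radius <= 0) stop("Mie radius must be > 0", call. = FALSE)
  if (n_ref <= 1) stop("Mie n_ref must be > 1", call. = FALSE)
  structure(list(radius = radius, n_ref = n_ref, resonant = isTRUE(resonant),
                 kk_amp = kk_amp),
            class = "ftir_mie")
}

#' Van de Hulst extinction efficiency
#'
#' The anomalous-diffraction approximation to the Mie extinction efficiency
#' of a homogeneous sphere, `Q = 2 - (4/rho) sin(rho) + (4/rho^2)(1 -
#' cos(rho))`, with phase parameter `rho = 4 pi r nu (n - 1)` (radius `r` in
#' cm, wavenumber `nu` in cm^-1). A series expansion is used for small
#' `rho` where the closed form is numerically unstable.
#'
#' @param rho Non-negative phase parameter (vectorised).
#' @return Extinction efficiency values.
#' @export
vdh_extinction <- function(rho) {
  q <- numeric(length(rho))
  small <- abs(rho) < 1e-4
  r2 <- rho[small]^2
  q[small] <- r2 / 2 - r2^2 / 36  # Taylor expansion about rho = 0
  r <- rho[!small]
  q[!small] <- 2 - 4 * sin(r) / r + 4 * (1 - cos(r)) / r^2
  q
}

# rho(nu) for radius in um, nu in 1/cm, n dimensionless (vectorised over nu)
mie_rho <- function(radius_um, nu, n) {
  4 * pi * (radius_um * 1e-4) * nu * (n - 1)
}

#' Discrete Kramers-Kronig dispersion transform
#'
#' Computes the real refractive-index fluctuation implied by an absorbance
#' spectrum via the principal-value Kramers-Kronig relation,
#' `dn(nu) = (2/pi) P∫ s A(s) / (s^2 - nu^2) ds`, evaluated as a direct
#' Maclaurin-type sum that skips the singular point. The result is returned
#' unscaled; callers normalise it to a physically chosen magnitude.
#'
#' @param grid Wavenumber grid (cm^-1).
#' @param absorbance Absorbance values on the grid.
#' @return Numeric vector, the dispersion-shaped fluctuation.
#' @export
kramers_kronig <- function(grid, absorbance) {
  nu <- as.numeric(grid)
  ds <- grid_spacing(grid)
  sA <- nu * absorbance
  n <- length(nu)
  out <- numeric(n)
  nu2 <- nu^2
  for (i in seq_len(n)) {
    w <- sA / (nu2 - nu2[i])
    w[i] <- 0
    out[i] <- sum(w)
  }
  out * 2 * ds / pi
}

#' Apply a Mie scattering distortion to a spectrum
#'
#' Forward model for the scatter artefact that resonant-Mie EMSC correction
#' removes. The extinction curve `Q(nu)` follows [vdh_extinction()]; with
#' `resonant = TRUE` the refractive index is `n(nu) = n_ref + dn(nu)` where
#' `dn` is the [kramers_kronig()] transform of the input absorbance scaled
#' to peak magnitude `kk_amp * (n_ref - 1)`. The output trace is
#' `alpha * A + beta * Q + gamma`; the extinction curve is attached as
#' attribute `"mie_extinction"`.
#'
#' @param spectrum An `ftir_spectrum`.
#' @param mie An [mie_params()] object.
#' @param alpha,beta,gamma Mixing coefficients: multiplicative distortion of
#'   the chemical absorbance, scatter contribution amplitude (AU per unit
#'   Q), and additive offset (AU).
#' @return The distorted `ftir_spectrum` (stage unchanged) with the
#'   extinction curve in `attr(, "mie_extinction")`.
#' @export
apply_mie_distortion <- function(spectrum, mie, alpha = 1, beta = 0.1,
                                 gamma = 0) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  if (!inherits(mie, "ftir_mie")) mie <- do.call(mie_params, as.list(mie))
  nu <- spectrum$wavenumber
  n <- rep(mie$n_ref, length(nu))
  if (mie$resonant) {
    dn <- kramers_kronig(nu, spectrum$absorbance)
    m <- max(abs(dn))
    if (m > 0) dn <- dn / m * mie$kk_amp * (mie$n_ref - 1)
    n <- n + dn
  }
  q <- vdh_extinction(mie_rho(mie$radius, nu, n))
  out <- spectrum
  out$absorbance <- alpha * spectrum$absorbance + beta * q + gamma
  attr(out, "mie_extinction") <- q
  out
}

#' Render one synthetic cell spectrum
#'
#' Draws per-band lognormal amplitude jitter, an additive random baseline
#' polynomial and white noise, all from a private RNG stream so the result
#' is a pure function of `(model, grid, noise, cell_id, seed)`.
#'
#' @param model An `ftir_band_model` (non-empty).
#' @param grid A wavenumber grid.
#' @param noise An [noise_model()].
#' @param cell_id Cell identifier stored on the spectrum.
#' @param seed Integer seed; defaults to `noise$seed`.
#' @return An `ftir_spectrum` at stage `"raw"`.
#' @export
render_spectrum <- function(model, grid, noise = noise_model(),
                            cell_id = "cell_1", seed = NULL) {
  stopifnot(inherits(model, "ftir_band_model"))
  if (length(model$bands) == 0) {
    stop("band model has no bands; cannot render a spectrum", call. = FALSE)
  }
  grid <- validate_grid(grid)
  if (is.null(seed)) seed <- noise$seed
  base_amp <- vapply(model$bands, `[[`, 0, "amplitude")
  with_seed(seed, {
    amp <- base_amp
    if (noise$cell_amplitude_cv > 0) {
      sdlog <- sqrt(log(1 + noise$cell_amplitude_cv^2))
      amp <- base_amp * exp(stats::rnorm(length(base_amp),
                                         -sdlog^2 / 2, sdlog))
    }
    a <- render_bands(model, grid, amp)
    if (noise$baseline_poly_degree >= 0 && any(noise$baseline_coeff_sd > 0)) {
      nc <- noise$baseline_poly_degree + 1
      csd <- rep_len(noise$baseline_coeff_sd, nc)
      co <- stats::rnorm(nc, 0, csd)
      t <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
      a <- a + drop(outer(t, 0:(nc - 1), `^`) %*% co)
    }
    if (noise$additive_sd > 0) {
      a <- a + stats::rnorm(length(grid), 0, noise$additive_sd)
    }
    ftir_spectrum(grid, a, cell_id = cell_id, group = model$group_label)
  })
}

#' Generate a synthetic cell population
#'
#' Renders `n_cells` spectra from one band model; per-cell randomness is
#' derived from `(seed, cell index)` so any subset of cells is reproducible
#' independently of the others. When `mie` is supplied every cell receives
#' the same scatter geometry (one sphere size/index per run) unless
#' `mie_jitter > 0`, which perturbs the radius per cell.
#'
#' @param n_cells Number of cells (>= 2; distance analyses are undefined
#'   below that).
#' @param model An `ftir_band_model`.
#' @param grid A wavenumber grid.
#' @param noise An [noise_model()].
#' @param mie Optional [mie_params()]; `NULL` for no scatter distortion.
#' @param seed Integer master seed.
#' @param beta Scatter mixing amplitude passed to [apply_mie_distortion()].
#' @param mie_jitter Relative sd of per-cell radius variation.
#' @param id_prefix Prefix for generated cell ids.
#' @return An `ftir_set` at stage `"raw"`.
#' @export
synth_population <- function(n_cells, model, grid = wavenumber_grid(),
                             noise = noise_model(), mie = NULL, seed = 1L,
                             beta = 0.1, mie_jitter = 0.1,
                             id_prefix = model$group_label) {
  if (n_cells < 2) {
    stop("n_cells must be >= 2 (pairwise distance analyses are undefined ",
         "for a single cell)", call. = FALSE)
  }
  grid <- validate_grid(grid)
  spectra <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    s <- render_spectrum(model, grid, noise,
                         cell_id = sprintf("%s_%02d", id_prefix, i),
                         seed = derive_seed(seed, i))
    if (!is.null(mie)) {
      r_i <- mie$radius
      if (mie_jitter > 0) {
        r_i <- with_seed(derive_seed(seed + 1L, i),
                         mie$radius * exp(stats::rnorm(1, 0, mie_jitter)))
      }
      m_i <- mie_params(r_i, mie$n_ref, mie$resonant, mie$kk_amp)
      s <- apply_mie_distortion(s, m_i, beta = beta)
    }
    spectra[[i]] <- s
  }
  set_from_spectra(spectra)
}
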