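## Parametric absorption-band model used to synthesize single-cell spectra.
##
## The band table below is the single source of truth for all synthetic
## fixtures.  Positions follow the standard biochemical assignments for
## cellular mid-IR spectra; amplitudes are expressed relative to Amide I
## (= 1.0 AU) and FWHMs are set by band class (narrow ring/backbone modes
## 15-25 cm^-1, broad amide and phosphate envelopes 30-40 cm^-1).  The
## senescence effect is a multiplicative amplitude change on protein and
## lipid bands plus growth of the 1740 cm^-1 cholesterol-ester/fatty-acid
## carbonyl band; the per-band weights are stand-ins for fold changes no
## reference quantifies (see the methods vignette).

#' Construct an absorption band
#'
#' @param center Band centre in cm^-1.
#' @param fwhm Full width at half maximum in cm^-1 (> 0).
#' @param amplitude Peak absorbance in AU (>= 0).
#' @param shape `"gaussian"`, `"lorentzian"` or `"pseudo_voigt"`.
#' @param eta Lorentzian mixing fraction in `[0, 1]` (pseudo-Voigt only).
#' @param assignment Free-text functional-group label.
#' @return A list of class `"ftir_band"`.
#' @export
band <- function(center, fwhm, amplitude, shape = "gaussian", eta = 0.5,
                 assignment = "") {
  shape <- match.arg(shape, c("gaussian", "lorentzian", "pseudo_voigt"))
  if (fwhm <= 0) stop("band fwhm must be > 0", call. = FALSE)
  if (amplitude < 0) stop("band amplitude must be >= 0", call. = FALSE)
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape, eta = eta, assignment = assignment),
            class = "ftir_band")
}

# peak-normalized profiles: value 1 at the centre
band_profile <- function(b, nu) {
  g <- exp(-4 * log(2) * (nu - b$center)^2 / b$fwhm^2)
  if (b$shape == "gaussian") return(g)
  hw2 <- (b$fwhm / 2)^2
  l <- hw2 / ((nu - b$center)^2 + hw2)
  if (b$shape == "lorentzian") l else b$eta * l + (1 - b$eta) * g
}

#' Evaluate a band model's absorbance on a grid
#'
#' @param model An `ftir_band_model`.
#' @param grid A wavenumber grid.
#' @param amplitudes Optional replacement amplitudes (e.g. jittered).
#' @return Numeric absorbance vector.
#' @export
render_bands <- function(model, grid, amplitudes = NULL) {
  if (is.null(amplitudes)) {
    amplitudes <- vapply(model$bands, `[[`, 0, "amplitude")
  }
  a <- numeric(length(grid))
  for (k in seq_along(model$bands)) {
    a <- a + amplitudes[k] * band_profile(model$bands[[k]], grid)
  }
  a
}

#' Construct a band model
#'
#' @param bands List of [band()] objects; centres must be unique within
#'   1 cm^-1.
#' @param group_label Population label the model renders.
#' @return A list of class `"ftir_band_model"`.
#' @export
band_model <- function(bands, group_label = "control") {
  ctr <- vapply(bands, `[[`, 0, "center")
  if (any(diff(sort(ctr)) < 1)) {
    stop("band centres must be unique within 1 cm^-1", call. = FALSE)
  }
  structure(list(bands = bands, group_label = group_label),
            class = "ftir_band_model")
}

#' @export
print.ftir_band_model <- function(x, ...) {
  cat(sprintf("<ftir_band_model> group '%s', %d bands\n",
              x$group_label, length(x$bands)))
  df <- data.frame(center = vapply(x$bands, `[[`, 0, "center"),
                   fwhm = vapply(x$bands, `[[`, 0, "fwhm"),
                   amplitude = vapply(x$bands, `[[`, 0, "amplitude"),
                   assignment = vapply(x$bands, `[[`, "", "assignment"))
  print(df, row.names = FALSE)
  invisible(x)
}

# centre, fwhm, base amplitude (relative to Amide I = 1), senescence weight,
# assignment.  w > 0 bands respond to the effect size.
.BAND_TABLE <- data.frame(
  center = c(2920, 2850, 1740, 1650, 1545, 1456, 1390, 1084, 984),
  fwhm   = c(  30,   25,   25,   40,   35,   20,   20,   30,   18),
  base   = c(0.40, 0.25, 0.30, 1.00, 0.55, 0.20, 0.15, 0.30, 0.10),
  weight = c(1.0,  1.0,  1.0,  0.5,  0.5,  1.0,  0.0,  0.0,  0.0),
  assignment = c("CH2 asym stretch (lipids)", "CH2 sym stretch (lipids)",
                 "ester C=O stretch (cholesterol esters/fatty acids)",
                 "Amide I", "Amide II", "CH2 bend (lipids)",
                 "COO- sym stretch (fatty acid side chains)",
                 "PO2- stretch (phosphodiesters)",
                 "C-O stretch (RNA ribose)"),
  stringsAsFactors = FALSE)

#' Canonical two-group macrophage band model
#'
#' Returns the default band set for a control or senescent cell population.
#' Control cells carry the eight canonical bands (the 1740 cm^-1 ester
#' carbonyl is present with amplitude 0). Senescence scales the amplitude of
#' each responsive band `b` by `(1 + effect_size * w_b)` with weights
#' `w = 1` for the lipid bands (2920, 2850, 1456 cm^-1) and `w = 0.5` for
#' the protein bands (1650, 1545 cm^-1); the ester band at 1740 cm^-1 grows
#' from zero as `base_1740 * w_1740 * effect_size` (cholesterol-ester
#' enrichment), so `effect_size = 0` reproduces the control amplitudes
#' exactly.
#'
#' @param group_label `"control"` or `"senescent"`.
#' @param effect_size Non-negative scalar controlling the between-group
#'   amplitude separation (0 = identical populations).
#' @return An `ftir_band_model`.
#' @examples
#' m <- default_band_model("senescent", effect_size = 0.5)
#' @export
default_band_model <- function(group_label = c("control", "senescent"),
                               effect_size = 0.5) {
  if (!is.character(group_label) ||
      !group_label[1] %in% c("control", "senescent")) {
    stop("unknown group label '", group_label[1],
         "'; expected \"control\" or \"senescent\"", call. = FALSE)
  }
  group_label <- group_label[1]
  if (!is.numeric(effect_size) || effect_size < 0) {
    stop("effect_size must be a non-negative number", call. = FALSE)
  }
  tab <- .BAND_TABLE
  amp <- tab$base
  ester <- tab$center == 1740
  amp[ester] <- 0
  if (group_label == "senescent") {
    resp <- tab$weight > 0 & !ester
    amp[resp] <- tab$base[resp] * (1 + effect_size * tab$weight[resp])
    amp[ester] <- tab$base[ester] * tab$weight[ester] * effect_size
  }
  bands <- lapply(seq_len(nrow(tab)), function(k) {
    band(tab$center[k], tab$fwhm[k], amp[k], "gaussian",
         assignment = tab$assignment[k])
  })
  band_model(bands, group_label)
}
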