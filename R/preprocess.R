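## Spectral pretreatment chain: Savitzky-Golay smoothing, baseline
## correction (rubberband by default, polynomial fallback), Savitzky-Golay
## second derivatives, region extraction and band semi-quantification.
## RMieS-EMSC lives in emsc.R.  Stage ordering (raw -> smoothed ->
## baseline_corrected -> emsc_corrected -> second_derivative) is enforced;
## forward skips are allowed, reordering is rejected.

# apply a per-trace function to a spectrum or every row of a set
map_traces <- function(x, f, new_stage = NULL) {
  if (inherits(x, "ftir_spectrum")) {
    out <- x
    out$absorbance <- f(x$absorbance)
    if (!is.null(new_stage)) out$stage <- new_stage
    return(out)
  }
  if (inherits(x, "ftir_set")) {
    out <- x
    out$absorbance <- t(apply(x$absorbance, 1, f))
    rownames(out$absorbance) <- x$cell_id
    if (!is.null(new_stage)) out$stage <- new_stage
    return(out)
  }
  stop("expected an ftir_spectrum or ftir_set", call. = FALSE)
}

#' Savitzky-Golay smoothing
#'
#' Nine-point Savitzky-Golay smoothing (local least-squares polynomial of
#' order `poly_order`) is the standard band-shape-preserving smoother for
#' FTIR traces. Endpoints are handled by the asymmetric polynomial fits of
#' the Savitzky-Golay projection matrix, so polynomials up to `poly_order`
#' are reproduced exactly everywhere including the edges.
#'
#' @param x An `ftir_spectrum` or `ftir_set` at stage `"raw"`.
#' @param window_points Odd window length (default 9).
#' @param poly_order Polynomial order (< `window_points`).
#' @return The smoothed object, stage `"smoothed"`.
#' @export
sg_smooth <- function(x, window_points = 9, poly_order = 2) {
  check_sg_args(x, window_points, poly_order)
  check_stage(x, "smoothed")
  map_traces(x, function(a) {
    signal::sgolayfilt(a, p = poly_order, n = window_points, m = 0)
  }, new_stage = "smoothed")
}

check_sg_args <- function(x, window_points, poly_order) {
  npts <- length(if (inherits(x, "ftir_set")) x$wavenumber else x$wavenumber)
  if (window_points %% 2 != 1) {
    stop("Savitzky-Golay window must be odd, got ", window_points,
         call. = FALSE)
  }
  if (window_points > npts) {
    stop("Savitzky-Golay window (", window_points,
         ") exceeds the number of grid points (", npts, ")", call. = FALSE)
  }
  if (poly_order >= window_points) {
    stop("poly_order must be smaller than the window length", call. = FALSE)
  }
  invisible(TRUE)
}

#' Baseline correction
#'
#' Removes broad additive baseline drift. The default `"rubberband"` method
#' subtracts the lower convex hull of the trace (the standard automatic
#' baseline for absorbance spectra); `"polynomial"` fits and subtracts an
#' ordinary least-squares polynomial of degree `degree`. Both are invariant
#' to adding a constant to the input.
#'
#' @param x An `ftir_spectrum` or `ftir_set` (stage before
#'   `"baseline_corrected"`).
#' @param method `"rubberband"` or `"polynomial"`.
#' @param degree Polynomial degree (polynomial method).
#' @return The corrected object, stage `"baseline_corrected"`.
#' @export
baseline_correct <- function(x, method = c("rubberband", "polynomial"),
                             degree = 2) {
  method <- match.arg(method)
  check_stage(x, "baseline_corrected")
  grid <- x$wavenumber
  if (length(grid) < 3) stop("need at least 3 points", call. = FALSE)
  if (method == "polynomial" && length(grid) < degree + 1) {
    stop("fewer points than polynomial degree + 1", call. = FALSE)
  }
  if (method == "rubberband") {
    f <- function(a) a - rubberband_baseline(grid, a)
  } else {
    X <- cbind(1, stats::poly(as.numeric(grid), degree, raw = TRUE))
    f <- function(a) as.numeric(stats::lm.fit(X, a)$residuals)
  }
  map_traces(x, f, new_stage = "baseline_corrected")
}

# lower convex hull of (nu, a), linearly interpolated
rubberband_baseline <- function(grid, a) {
  lower <- lower_hull(as.numeric(grid), a)
  stats::approx(as.numeric(grid)[lower], a[lower],
                xout = as.numeric(grid), rule = 2)$y
}

# Andrew's monotone chain, lower envelope indices
lower_hull <- function(x, y) {
  n <- length(x)
  idx <- integer(0)
  for (i in seq_len(n)) {
    while (length(idx) >= 2) {
      j <- idx[length(idx) - 1]; k <- idx[length(idx)]
      # pop k if it lies above the segment j-i
      if ((x[k] - x[j]) * (y[i] - y[j]) - (y[k] - y[j]) * (x[i] - x[j]) <= 0) {
        idx <- idx[-length(idx)]
      } else break
    }
    idx <- c(idx, i)
  }
  idx
}

#' Savitzky-Golay second derivative
#'
#' Second derivative with respect to wavenumber (units AU cm^2), the
#' standard band-sharpening transform for overlapped FTIR bands (absorption
#' maxima appear as negative minima). Exact on polynomials up to
#' `poly_order`, including grid edges, and linear in the input.
#'
#' @param x An `ftir_spectrum` or `ftir_set` (stage before
#'   `"second_derivative"`).
#' @param window_points Odd window length (default 9).
#' @param poly_order Polynomial order, must be >= 2 (default 3).
#' @return The differentiated object, stage `"second_derivative"`.
#' @export
second_derivative <- function(x, window_points = 9, poly_order = 3) {
  if (poly_order < 2) {
    stop("second derivative requires poly_order >= 2", call. = FALSE)
  }
  check_sg_args(x, window_points, poly_order)
  check_stage(x, "second_derivative")
  sp <- grid_spacing(x$wavenumber)
  map_traces(x, function(a) {
    signal::sgolayfilt(a, p = poly_order, n = window_points, m = 2, ts = sp)
  }, new_stage = "second_derivative")
}

## ---- spectral regions -----------------------------------------------------

# canonical analysis windows (cm^-1)
.REGIONS <- list(
  lipids        = list(c(1300, 1480), c(2800, 3000)),
  proteins      = list(c(1480, 1800)),
  nucleic_carbo = list(c(900, 1300)),
  full          = list(c(900, 1800), c(2800, 3000)))

#' Spectral region definition
#'
#' Named wavenumber windows used for region-wise multivariate analysis:
#' lipids (3000--2800 with 1480--1300), proteins (1800--1480), nucleic
#' acids/carbohydrates (1300--900) and the full informative range
#' (3000--2800 with 1800--900).
#'
#' @param name One of `"lipids"`, `"proteins"`, `"nucleic_carbo"`, `"full"`,
#'   or a custom name when `windows` is supplied.
#' @param windows Optional list of `c(lo, hi)` intervals overriding the
#'   canonical table; must be non-overlapping.
#' @return A list of class `"ftir_region"` with `name` and `windows`.
#' @export
spectral_region <- function(name, windows = NULL) {
  if (is.null(windows)) {
    if (!name %in% names(.REGIONS)) {
      stop("unknown region '", name, "'; expected one of ",
           paste(names(.REGIONS), collapse = ", "), call. = FALSE)
    }
    windows <- .REGIONS[[name]]
  }
  windows <- windows[order(vapply(windows, `[`, 0, 1))]
  lo <- vapply(windows, `[`, 0, 1); hi <- vapply(windows, `[`, 0, 2)
  if (any(hi <= lo)) stop("each window needs lo < hi", call. = FALSE)
  if (any(utils::head(hi, -1) > utils::tail(lo, -1))) {
    stop("region windows overlap", call. = FALSE)
  }
  structure(list(name = name, windows = windows), class = "ftir_region")
}

#' Restrict spectra to a spectral region
#'
#' Keeps the grid points falling in the region's windows (ascending order,
#' concatenating disjoint windows). A boundary point is included when it is
#' within half a grid spacing of the window edge. The retained point count
#' is the dimension N of the cell-to-cell Euclidean distance.
#'
#' @param x An `ftir_spectrum` or `ftir_set`.
#' @param region An [spectral_region()] or region name.
#' @return The restricted object; `$region` records the region name.
#' @export
extract_region <- function(x, region) {
  if (is.character(region)) region <- spectral_region(region)
  grid <- as.numeric(x$wavenumber)
  half <- grid_spacing(x$wavenumber) / 2
  keep <- rep(FALSE, length(grid))
  for (w in region$windows) {
    keep <- keep | (grid >= w[1] - half & grid <= w[2] + half)
  }
  if (!any(keep)) {
    stop("region '", region$name, "' does not intersect the grid",
         call. = FALSE)
  }
  if (inherits(x, "ftir_spectrum")) {
    out <- ftir_spectrum(grid[keep], x$absorbance[keep], x$cell_id, x$group,
                         x$stage, region$name)
  } else {
    out <- ftir_set(grid[keep], x$absorbance[, keep, drop = FALSE],
                    x$cell_id, x$group, x$stage, region$name)
  }
  out
}

#' L2 vector normalisation
#'
#' Scales each trace to unit Euclidean norm. Off by default throughout the
#' pipeline; provided as an explicit option.
#'
#' @param x An `ftir_spectrum` or `ftir_set`.
#' @return The normalised object (stage unchanged).
#' @export
l2_normalize <- function(x) {
  map_traces(x, function(a) {
    nrm <- sqrt(sum(a^2))
    if (nrm == 0) stop("cannot normalise an all-zero trace", call. = FALSE)
    a / nrm
  })
}

#' Semi-quantitative band measurement
#'
#' Quantifies one absorption band inside a window centred on
#' `band_center`: a local linear baseline is drawn between the absorbance
#' at the two window endpoints; `peak_height` is the maximum
#' baseline-corrected absorbance and `integrated_area` its trapezoidal
#' integral over the window. Both are linear in the input spectrum.
#'
#' @param spectrum An `ftir_spectrum`.
#' @param band_center Band centre in cm^-1.
#' @param metric `"peak_height"` (AU) or `"integrated_area"` (AU cm^-1).
#' @param window_halfwidth Half width of the analysis window in cm^-1.
#' @return A list of class `"ftir_bandquant"`: `band_center`, `metric`,
#'   `window_halfwidth`, `value`.
#' @export
band_quant <- function(spectrum, band_center,
                       metric = c("peak_height", "integrated_area"),
                       window_halfwidth = 30) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  metric <- match.arg(metric)
  nu <- as.numeric(spectrum$wavenumber)
  half <- grid_spacing(spectrum$wavenumber) / 2
  lo <- band_center - window_halfwidth
  hi <- band_center + window_halfwidth
  if (lo < nu[1] - half || hi > nu[length(nu)] + half) {
    stop("band window [", lo, ", ", hi, "] extends beyond the grid",
         call. = FALSE)
  }
  in_w <- which(nu >= lo - half & nu <= hi + half)
  if (length(in_w) < 3) stop("band window covers fewer than 3 points",
                             call. = FALSE)
  a <- spectrum$absorbance[in_w]
  xs <- nu[in_w]
  base <- a[1] + (a[length(a)] - a[1]) * (xs - xs[1]) / (xs[length(xs)] - xs[1])
  corr <- a - base
  value <- if (metric == "peak_height") {
    max(corr)
  } else {
    sum(diff(xs) * (utils::head(corr, -1) + utils::tail(corr, -1)) / 2)
  }
  structure(list(band_center = band_center, metric = metric,
                 window_halfwidth = window_halfwidth, value = value),
            class = "ftir_bandquant")
}

#' @export
print.ftir_bandquant <- function(x, ...) {
  cat(sprintf("<band_quant> %g cm^-1: %s = %.5g %s\n", x$band_center,
              x$metric, x$value,
              if (x$metric == "peak_height") "AU" else "AU*cm^-1"))
  invisible(x)
}
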