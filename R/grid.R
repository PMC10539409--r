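#' Construct a uniform wavenumber grid
#'
#' Builds the strictly ascending, uniformly spaced wavenumber axis that all
#' spectra in an analysis share. The default covers the mid-IR acquisition
#' range 4000--600 cm^-1 at 4 cm^-1 spacing (851 points), matching typical
#' synchrotron FTIR microspectroscopy settings.
#'
#' @param start,stop Range endpoints in cm^-1 (order irrelevant; the grid is
#'   stored ascending).
#' @param spacing Grid spacing in cm^-1 (> 0).
#' @return A numeric vector of class `"wn_grid"`, strictly ascending.
#' @examples
#' g <- wavenumber_grid()
#' length(g)  # 851
#' @export
wavenumber_grid <- function(start = 600, stop = 4000, spacing = 4) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(spacing) ||
      spacing <= 0) {
    stop("`start`, `stop` must be numeric and `spacing` > 0", call. = FALSE)
  }
  lo <- min(start, stop)
  hi <- max(start, stop)
  v <- seq(lo, hi, by = spacing)
  validate_grid(v)
}

#' Validate a wavenumber grid
#'
#' Checks strict monotonicity, uniform spacing (relative tolerance 1e-9) and
#' minimum length, and stamps the `"wn_grid"` class.
#'
#' @param v Numeric vector of wavenumbers.
#' @return `v` with class `"wn_grid"`; errors if invalid.
#' @export
validate_grid <- function(v) {
  if (!is.numeric(v) || length(v) < 8) {
    stop("a wavenumber grid needs at least 8 numeric points", call. = FALSE)
  }
  d <- diff(v)
  if (any(d <= 0)) {
    stop("wavenumber grid must be strictly ascending", call. = FALSE)
  }
  sp <- d[1]
  if (any(abs(d - sp) > 1e-9 * abs(sp))) {
    stop("wavenumber grid must be uniformly spaced (rel. tol. 1e-9)",
         call. = FALSE)
  }
  structure(as.numeric(v), class = "wn_grid")
}

# nominal spacing; robust to the window gaps of region-restricted axes
grid_spacing <- function(grid) {
  stats::median(diff(as.numeric(grid)))
}

# relaxed axis check for region-restricted spectra: strictly ascending only
as_axis <- function(v) {
  if (!is.numeric(v) || length(v) < 2 || any(diff(v) <= 0) ||
      !all(is.finite(v))) {
    stop("wavenumber axis must be finite and strictly ascending",
         call. = FALSE)
  }
  structure(as.numeric(v), class = "wn_grid")
}

is_uniform_axis <- function(v) {
  d <- diff(as.numeric(v))
  all(abs(d - d[1]) <= 1e-9 * abs(d[1]))
}

#' @export
print.wn_grid <- function(x, ...) {
  cat(sprintf("<wavenumber grid> %g..%g cm^-1, spacing %g, %d points\n",
              x[1], x[length(x)], grid_spacing(x), length(x)))
  invisible(x)
}

# same axis up to floating noise
same_grid <- function(a, b) {
  length(a) == length(b) && all(abs(a - b) <= 1e-9 * pmax(abs(a), 1))
}
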