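## Spectrum and SpectrumSet containers.
##
## A spectrum is one cell's absorbance trace on a shared wavenumber grid,
## plus identity metadata.  A spectrum set is the aligned cells x wavenumbers
## matrix the population analyses run on.  Both carry a `stage` marker so the
## pretreatment chain (raw -> smoothed -> baseline_corrected ->
## emsc_corrected -> second_derivative) cannot be applied out of order.

.STAGES <- c(raw = 0, smoothed = 1, baseline_corrected = 2,
             emsc_corrected = 3, second_derivative = 4)

stage_rank <- function(stage) {
  r <- .STAGES[stage]
  if (is.na(r)) stop("unknown spectral stage: ", stage, call. = FALSE)
  unname(r)
}

# each op names the stage it produces; inputs must sit strictly earlier in
# the chain (forward skips allowed, reordering rejected)
check_stage <- function(x, produces) {
  if (stage_rank(x$stage) >= stage_rank(produces)) {
    stop(sprintf(
      "cannot apply a '%s' step to a spectrum already at stage '%s'",
      produces, x$stage), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a single-cell spectrum
#'
#' @param wavenumber A [wavenumber_grid()] (or numeric vector passed through
#'   [validate_grid()]).
#' @param absorbance Numeric vector of absorbance values (AU), same length as
#'   the grid, all finite.
#' @param cell_id Character identifier of the cell.
#' @param group Optional group label (e.g. `"control"`, `"senescent"`).
#' @param stage Pretreatment stage; one of `r paste(names(.STAGES), collapse=", ")`.
#' @param region Name of the spectral region the trace is restricted to
#'   (`"full_grid"` for the whole acquisition axis).
#' @return An object of class `"ftir_spectrum"`.
#' @export
ftir_spectrum <- function(wavenumber, absorbance, cell_id = "cell_1",
                          group = NA_character_, stage = "raw",
                          region = "full_grid") {
  wavenumber <- if (region == "full_grid") validate_grid(wavenumber) else
    as_axis(wavenumber)
  if (length(absorbance) != length(wavenumber)) {
    stop("absorbance and wavenumber lengths differ", call. = FALSE)
  }
  if (!all(is.finite(absorbance))) {
    stop("absorbance contains non-finite values", call. = FALSE)
  }
  stage_rank(stage)  # validates
  structure(list(wavenumber = wavenumber,
                 absorbance = as.numeric(absorbance),
                 cell_id = as.character(cell_id),
                 group = as.character(group),
                 stage = stage, region = region),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> cell '%s'%s, stage %s, region %s\n",
              x$cell_id,
              if (is.na(x$group)) "" else paste0(" (", x$group, ")"),
              x$stage, x$region))
  print(x$wavenumber)
  cat(sprintf("  absorbance: min %.4g, max %.4g\n",
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' Construct a spectrum set (aligned cell population)
#'
#' @param wavenumber Shared wavenumber grid.
#' @param absorbance Numeric matrix, one row per cell, one column per grid
#'   point; rownames are taken as cell ids if `cell_id` is missing.
#' @param cell_id Character vector of unique cell identifiers.
#' @param group Group label(s), recycled to the number of cells.
#' @param stage,region As for [ftir_spectrum()].
#' @return An object of class `"ftir_set"`.
#' @export
ftir_set <- function(wavenumber, absorbance, cell_id = rownames(absorbance),
                     group = NA_character_, stage = "raw",
                     region = "full_grid") {
  wavenumber <- if (region == "full_grid") validate_grid(wavenumber) else
    as_axis(wavenumber)
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(wavenumber)) {
    stop("absorbance matrix must have one column per wavenumber",
         call. = FALSE)
  }
  if (is.null(cell_id)) cell_id <- paste0("cell_", seq_len(nrow(absorbance)))
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) {
    stop("duplicate cell_id: ",
         paste(unique(cell_id[duplicated(cell_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(absorbance))) {
    stop("absorbance contains non-finite values", call. = FALSE)
  }
  stage_rank(stage)
  group <- rep_len(as.character(group), nrow(absorbance))
  rownames(absorbance) <- cell_id
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 cell_id = cell_id, group = group,
                 stage = stage, region = region),
            class = "ftir_set")
}

#' @export
print.ftir_set <- function(x, ...) {
  tab <- table(x$group, useNA = "ifany")
  cat(sprintf("<ftir_set> %d cells x %d wavenumbers, stage %s, region %s\n",
              nrow(x$absorbance), ncol(x$absorbance), x$stage, x$region))
  cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of cells in a spectrum set
#' @param set An `ftir_set`.
#' @return Integer cell count.
#' @export
n_cells <- function(set) nrow(set$absorbance)

#' Extract one cell from a spectrum set
#' @param set An `ftir_set`.
#' @param i Cell index or cell id.
#' @return An `ftir_spectrum`.
#' @export
get_spectrum <- function(set, i) {
  if (is.character(i)) i <- match(i, set$cell_id)
  ftir_spectrum(set$wavenumber, set$absorbance[i, ], set$cell_id[i],
                set$group[i], set$stage, set$region)
}

#' Combine spectrum sets (pooling groups)
#'
#' @param ... `ftir_set` objects on identical grids, stages and regions.
#' @return A pooled `ftir_set`.
#' @export
bind_sets <- function(...) {
  sets <- list(...)
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!same_grid(ref$wavenumber, s$wavenumber) || ref$stage != s$stage ||
        ref$region != s$region) {
      stop("sets must share grid, stage and region to be pooled",
           call. = FALSE)
    }
  }
  ftir_set(ref$wavenumber,
           do.call(rbind, lapply(sets, `[[`, "absorbance")),
           unlist(lapply(sets, `[[`, "cell_id")),
           unlist(lapply(sets, `[[`, "group")),
           ref$stage, ref$region)
}

#' Build a set from a list of spectra
#' @param spectra List of `ftir_spectrum` objects on one grid, stage, region.
#' @return An `ftir_set`.
#' @export
set_from_spectra <- function(spectra) {
  ref <- spectra[[1]]
  for (s in spectra[-1]) {
    if (!same_grid(ref$wavenumber, s$wavenumber) || ref$stage != s$stage ||
        ref$region != s$region) {
      stop("spectra must share grid, stage and region", call. = FALSE)
    }
  }
  ftir_set(ref$wavenumber,
           do.call(rbind, lapply(spectra, `[[`, "absorbance")),
           vapply(spectra, `[[`, "", "cell_id"),
           vapply(spectra, `[[`, "", "group"),
           ref$stage, ref$region)
}

#' Pointwise average spectrum of a population
#'
#' Arithmetic mean over cells at each wavenumber, as used to compare the
#' average absorbance profile of two populations. The group label is
#' propagated when uniform across the set.
#'
#' @param set An `ftir_set` (all members share one grid and stage by
#'   construction).
#' @return An `ftir_spectrum` with `cell_id = "mean"`.
#' @export
average_spectrum <- function(set) {
  stopifnot(inherits(set, "ftir_set"))
  g <- unique(set$group)
  ftir_spectrum(set$wavenumber, colMeans(set$absorbance),
                cell_id = "mean",
                group = if (length(g) == 1) g else NA_character_,
                stage = set$stage, region = set$region)
}

#' @export
as.matrix.ftir_set <- function(x, ...) x$absorbance

#' Plot spectra
#'
#' Overlays all traces of a set (coloured by group) or a single spectrum.
#' Wavenumber axis is drawn descending, the convention in IR spectroscopy.
#'
#' @param x An `ftir_set` or `ftir_spectrum`.
#' @param col Colours per group (set method).
#' @param ... Passed to [graphics::matplot()] / [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.ftir_set <- function(x, col = NULL, ...) {
  groups <- factor(x$group)
  if (is.null(col)) col <- seq_len(nlevels(groups))
  graphics::matplot(x$wavenumber, t(x$absorbance), type = "l", lty = 1,
                    col = col[as.integer(groups)],
                    xlim = rev(range(x$wavenumber)),
                    xlab = expression(Wavenumber ~ (cm^-1)),
                    ylab = "Absorbance (AU)", ...)
  graphics::legend("topleft", legend = levels(groups), lty = 1,
                   col = col[seq_len(nlevels(groups))], bty = "n")
  invisible(x)
}

#' @rdname plot.ftir_set
#' @export
plot.ftir_spectrum <- function(x, ...) {
  graphics::plot(x$wavenumber, x$absorbance, type = "l",
                 xlim = rev(range(x$wavenumber)),
                 xlab = expression(Wavenumber ~ (cm^-1)),
                 ylab = "Absorbance (AU)", ...)
  invisible(x)
}

# run a block under a private RNG stream, restoring global state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic per-cell substream seed, kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %%
               2147483647)
}
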