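## Spectrum-set readers and writers.
##
## Wide CSV: first column `wavenumber` (ascending), one column per cell,
## header row = cell ids; a sidecar CSV (`<stem>_groups.csv`) maps cell_id
## to group label.  JCAMP-DX: one ##TITLE block per cell with
## XYDATA=(X++(Y..Y)) in plain AFFN numbers; compressed ASDF forms (SQZ /
## DIF / DUP) are rejected with a clear message.  Readers re-sort
## descending axes to the package's ascending convention and record the
## original order.

sidecar_path <- function(path) {
  sub("\\.[^.]+$", "", path) |> paste0("_groups.csv")
}

#' Write a spectrum set
#'
#' @param set An `ftir_set`.
#' @param path Output file path.
#' @param format `"csv_wide"` or `"jcamp"`.
#' @param sidecar Write the cell_id-to-group sidecar CSV next to `path`?
#' @return Invisibly, the paths written.
#' @export
write_spectra <- function(set, path, format = c("csv_wide", "jcamp"),
                          sidecar = TRUE) {
  stopifnot(inherits(set, "ftir_set"))
  format <- match.arg(format)
  if (format == "csv_wide") {
    df <- data.frame(wavenumber = as.numeric(set$wavenumber),
                     t(set$absorbance), check.names = FALSE)
    colnames(df) <- c("wavenumber", set$cell_id)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    nu <- as.numeric(set$wavenumber)
    for (i in seq_len(n_cells(set))) {
      y <- set$absorbance[i, ]
      writeLines(c(
        sprintf("##TITLE=%s", set$cell_id[i]),
        "##JCAMP-DX=4.24",
        "##DATA TYPE=INFRARED SPECTRUM",
        "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
        sprintf("##FIRSTX=%.10g", nu[1]),
        sprintf("##LASTX=%.10g", nu[length(nu)]),
        sprintf("##NPOINTS=%d", length(nu)),
        "##XFACTOR=1", "##YFACTOR=1",
        "##XYDATA=(X++(Y..Y))"), con)
      idx <- split(seq_along(nu), (seq_along(nu) - 1) %/% 6)
      for (ii in idx) {
        writeLines(paste(c(sprintf("%.10g", nu[ii[1]]),
                           sprintf("%.17g", y[ii])), collapse = " "), con)
      }
      writeLines("##END=", con)
    }
  }
  paths <- path
  if (sidecar) {
    sp <- sidecar_path(path)
    utils::write.csv(data.frame(cell_id = set$cell_id, group = set$group),
                     sp, row.names = FALSE, quote = FALSE)
    paths <- c(paths, sp)
  }
  invisible(paths)
}

#' Read a spectrum set
#'
#' @param path Input file path.
#' @param format `"csv_wide"` or `"jcamp"`.
#' @param group_file Optional sidecar CSV (`cell_id,group`); defaults to
#'   `<stem>_groups.csv` when present.
#' @return An `ftir_set` at stage `"raw"`, wavenumbers ascending;
#'   `attr(, "original_order")` is `"descending"` when the file's axis was
#'   reversed on read.
#' @export
read_spectra <- function(path, format = c("csv_wide", "jcamp"),
                         group_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(group_file) && file.exists(sidecar_path(path))) {
    group_file <- sidecar_path(path)
  }
  if (format == "csv_wide") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (ncol(df) < 2) stop("wide CSV needs a wavenumber column plus at ",
                           "least one cell column", call. = FALSE)
    ids <- colnames(df)[-1]
    if (anyDuplicated(ids)) {
      stop("duplicate cell_id in CSV header: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
    }
    num <- vapply(df, is.numeric, TRUE)
    if (!all(num)) {
      stop("non-numeric values in column(s): ",
           paste(colnames(df)[!num], collapse = ", "), call. = FALSE)
    }
    nu <- df[[1]]
    Y <- t(as.matrix(df[-1]))
    desc <- is.unsorted(nu)
    if (desc) {
      o <- order(nu)
      nu <- nu[o]; Y <- Y[, o, drop = FALSE]
    }
    cells <- list(nu = nu, Y = Y, ids = ids, desc = desc)
  } else {
    cells <- read_jcamp_blocks(path)
  }
  groups <- NA_character_
  if (!is.null(group_file)) {
    gdf <- utils::read.csv(group_file, stringsAsFactors = FALSE)
    groups <- gdf$group[match(cells$ids, gdf$cell_id)]
  }
  out <- ftir_set(cells$nu, cells$Y, cells$ids, groups, stage = "raw")
  attr(out, "original_order") <- if (cells$desc) "descending" else "ascending"
  out
}

read_jcamp_blocks <- function(path) {
  lines <- readLines(path)
  starts <- grep("^##TITLE=", lines)
  if (length(starts) == 0) stop("no ##TITLE blocks found in ", path,
                                call. = FALSE)
  ends <- grep("^##END=", lines)
  if (length(ends) < length(starts)) {
    stop("unterminated JCAMP block in ", path, call. = FALSE)
  }
  ids <- character(0); traces <- list(); nu_ref <- NULL; desc <- FALSE
  for (b in seq_along(starts)) {
    blk <- lines[starts[b]:ends[b]]
    field <- function(key) {
      v <- sub(paste0("^##", key, "="), "", grep(paste0("^##", key, "="),
                                                 blk, value = TRUE))
      if (length(v)) trimws(v[1]) else NA_character_
    }
    id <- field("TITLE")
    firstx <- as.numeric(field("FIRSTX"))
    lastx <- as.numeric(field("LASTX"))
    npts <- as.integer(field("NPOINTS"))
    xf <- as.numeric(field("XFACTOR")); if (is.na(xf)) xf <- 1
    yf <- as.numeric(field("YFACTOR")); if (is.na(yf)) yf <- 1
    xy <- grep("^##XYDATA=", blk)
    if (!length(xy)) stop("block '", id, "': missing ##XYDATA", call. = FALSE)
    form <- sub("^##XYDATA=", "", blk[xy[1]])
    if (gsub("\\s", "", form) != "(X++(Y..Y))") {
      stop("block '", id, "': unsupported XYDATA form '", form,
           "' (only (X++(Y..Y)) with plain AFFN numbers is supported)",
           call. = FALSE)
    }
    dat <- blk[(xy[1] + 1):(length(blk) - 1)]
    dat <- dat[!grepl("^##", dat)]
    if (any(grepl("[A-DF-Za-df-z@%]", dat))) {
      stop("block '", id, "': compressed ASDF (SQZ/DIF/DUP) data are not ",
           "supported; re-export as plain AFFN", call. = FALSE)
    }
    ys <- unlist(lapply(strsplit(trimws(dat), "\\s+"), function(tok) {
      as.numeric(tok[-1])  # first token per line is the line's X
    }))
    if (anyNA(ys)) stop("block '", id, "': non-numeric Y data", call. = FALSE)
    if (!is.na(npts) && length(ys) != npts) {
      stop("block '", id, "': NPOINTS=", npts, " but ", length(ys),
           " Y values read", call. = FALSE)
    }
    nu <- seq(firstx, lastx, length.out = length(ys)) * xf
    y <- ys * yf
    if (nu[1] > nu[length(nu)]) {
      desc <- TRUE
      nu <- rev(nu); y <- rev(y)
    }
    if (is.null(nu_ref)) nu_ref <- nu
    else if (!same_grid(nu_ref, nu)) {
      stop("block '", id, "' is on a different grid than the first block",
           call. = FALSE)
    }
    ids <- c(ids, id)
    traces[[length(traces) + 1]] <- y
  }
  if (anyDuplicated(ids)) {
    stop("duplicate cell_id across JCAMP blocks: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  list(nu = nu_ref, Y = do.call(rbind, traces), ids = ids, desc = desc)
}
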