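## Cell-to-cell Euclidean distance heterogeneity analysis.
##
## Similarity between two cells a and b with N retained spectral points is
## d(a, b) = sqrt(sum_i (a_i - b_i)^2); smaller d means more similar
## biochemical phenotype.  One group of n cells yields n(n-1)/2 in-group
## distances; two groups of x and y cells yield x*y inter-group distances.
## Distance histograms are summarised by a least-squares Gaussian fit and
## the pooled distance matrix is clustered with Ward linkage.

#' Euclidean distance between two cell spectra
#'
#' @param a,b `ftir_spectrum` objects on identical grids, at the same stage
#'   and region.
#' @return Non-negative scalar distance.
#' @export
euclidean_distance <- function(a, b) {
  stopifnot(inherits(a, "ftir_spectrum"), inherits(b, "ftir_spectrum"))
  if (!same_grid(a$wavenumber, b$wavenumber)) {
    stop("cells '", a$cell_id, "' and '", b$cell_id,
         "' are on different wavenumber grids", call. = FALSE)
  }
  if (a$stage != b$stage || a$region != b$region) {
    stop("cells '", a$cell_id, "' and '", b$cell_id,
         "' differ in stage or region", call. = FALSE)
  }
  sqrt(sum((a$absorbance - b$absorbance)^2))
}

new_distvec <- function(values, kind, n_a, n_b, region, stage) {
  structure(list(values = as.numeric(values), kind = kind,
                 n_cells_a = n_a, n_cells_b = n_b,
                 region = region, stage = stage),
            class = "ftir_distvec")
}

#' @export
print.ftir_distvec <- function(x, ...) {
  cat(sprintf("<ftir_distvec> %s, %d distances (n_a = %d%s), %s/%s\n",
              x$kind, length(x$values), x$n_cells_a,
              if (is.na(x$n_cells_b)) "" else
                paste0(", n_b = ", x$n_cells_b),
              x$stage, x$region))
  print(summary(x$values))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' In-group pairwise distances
#'
#' All n(n-1)/2 cell-to-cell Euclidean distances within one population,
#' ordered by pair (i, j) with i < j in cell order.
#'
#' @param set An `ftir_set` with at least 2 cells.
#' @return An `ftir_distvec` of kind `"in_group"`.
#' @export
in_group_distances <- function(set) {
  stopifnot(inherits(set, "ftir_set"))
  n <- n_cells(set)
  if (n < 2) stop("in-group distances need at least 2 cells", call. = FALSE)
  d <- stats::dist(set$absorbance, method = "euclidean")
  # dist() stores the lower triangle column-wise, i.e. pairs (i, j), i < j,
  # in lexicographic order of (i, j) -- the documented ordering
  new_distvec(as.numeric(d), "in_group", n, NA_integer_,
              set$region, set$stage)
}

#' Inter-group pairwise distances
#'
#' All x * y Euclidean distances between cells of two populations.
#'
#' @param set_x,set_y `ftir_set` objects on one grid, stage and region.
#' @return An `ftir_distvec` of kind `"inter_group"` (row-major in cells of
#'   `set_x`).
#' @export
inter_group_distances <- function(set_x, set_y) {
  stopifnot(inherits(set_x, "ftir_set"), inherits(set_y, "ftir_set"))
  if (!same_grid(set_x$wavenumber, set_y$wavenumber) ||
      set_x$stage != set_y$stage || set_x$region != set_y$region) {
    stop("the two sets differ in grid, stage or region", call. = FALSE)
  }
  A <- set_x$absorbance
  B <- set_y$absorbance
  cross <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  cross[cross < 0] <- 0
  new_distvec(as.numeric(t(sqrt(cross))), "inter_group",
              nrow(A), nrow(B), set_x$region, set_x$stage)
}

#' Pooled cell-to-cell distance matrix
#'
#' Square symmetric Euclidean distance matrix over all cells of one or more
#' pooled populations, with zero diagonal.
#'
#' @param ... One or more `ftir_set` objects (pooled with [bind_sets()]).
#' @return A numeric matrix of class `"ftir_distmat"` with cell ids as
#'   dimnames and group labels in `attr(, "group")`.
#' @export
distance_matrix <- function(...) {
  pooled <- bind_sets(...)
  m <- as.matrix(stats::dist(pooled$absorbance, method = "euclidean"))
  dimnames(m) <- list(pooled$cell_id, pooled$cell_id)
  structure(m, class = c("ftir_distmat", "matrix"),
            group = pooled$group, region = pooled$region,
            stage = pooled$stage)
}

#' Gaussian fit to a distance histogram
#'
#' Bins the distances (Freedman-Diaconis width by default) and fits
#' `A * exp(-(x - mu)^2 / (2 sigma^2))` to the bin centres and counts by
#' Levenberg-Marquardt least squares, initialised at the sample mean and
#' standard deviation. Non-convergence is reported in the result, never
#' silently.
#'
#' @param d An `ftir_distvec` or numeric vector of distances (length >= 10,
#'   not all equal).
#' @param bin_width Histogram bin width, or `"auto"` for Freedman-Diaconis.
#' @return A list of class `"ftir_gaussfit"`: `histogram` (data.frame of
#'   bin centres/counts), `mean`, `sd`, `amplitude`, `rmse`, `bin_width`,
#'   `converged`.
#' @export
distance_histogram_fit <- function(d, bin_width = "auto") {
  v <- if (inherits(d, "ftir_distvec")) d$values else as.numeric(d)
  if (length(v) < 10) stop("need at least 10 distances to fit", call. = FALSE)
  if (stats::sd(v) == 0) {
    stop("degenerate distance set: all values equal; no histogram to fit",
         call. = FALSE)
  }
  if (identical(bin_width, "auto")) {
    bin_width <- 2 * stats::IQR(v) / length(v)^(1 / 3)
    if (bin_width <= 0) bin_width <- diff(range(v)) / 10
  }
  breaks <- seq(min(v) - bin_width / 2,
                max(v) + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  df <- data.frame(center = h$mids, count = h$counts)
  start <- list(A = max(df$count), mu = mean(v), sig = stats::sd(v))
  fit <- tryCatch(
    minpack.lm::nlsLM(count ~ A * exp(-(center - mu)^2 / (2 * sig^2)),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(histogram = df, mean = start$mu, sd = start$sig,
                amplitude = start$A, rmse = NA_real_,
                bin_width = bin_width, converged = FALSE)
  } else {
    co <- stats::coef(fit)
    out <- list(histogram = df, mean = unname(co["mu"]),
                sd = abs(unname(co["sig"])),
                amplitude = unname(co["A"]),
                rmse = sqrt(mean(stats::residuals(fit)^2)),
                bin_width = bin_width, converged = TRUE)
  }
  class(out) <- "ftir_gaussfit"
  out
}

#' @export
print.ftir_gaussfit <- function(x, ...) {
  cat(sprintf(
    "<gaussian fit> mu = %.4g, sigma = %.4g, A = %.4g (bin %.3g, rmse %.3g%s)\n",
    x$mean, x$sd, x$amplitude, x$bin_width, x$rmse,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @export
plot.ftir_gaussfit <- function(x, ...) {
  graphics::plot(x$histogram$center, x$histogram$count, type = "h",
                 xlab = "Euclidean distance", ylab = "Frequency", ...)
  xs <- seq(min(x$histogram$center), max(x$histogram$center), length.out = 200)
  graphics::lines(xs, x$amplitude * exp(-(xs - x$mean)^2 / (2 * x$sd^2)),
                  col = 2, lwd = 2)
  invisible(x)
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with the Ward criterion on a precomputed
#' Euclidean distance matrix (`stats::hclust`, method `"ward.D2"`). Note
#' that Ward on a precomputed distance matrix can differ subtly between
#' toolchains from Ward on raw coordinates; this implementation uses the
#' distances directly.
#'
#' @param m An `ftir_distmat` or symmetric non-negative matrix with zero
#'   diagonal.
#' @return A list of class `"ftir_hca"`: `hclust`, `leaf_order`, `labels`,
#'   `method = "ward"`, `distance = "euclidean"`.
#' @export
hca_ward <- function(m) {
  mm <- unclass(m)
  if (!is.matrix(mm) || nrow(mm) != ncol(mm) ||
      max(abs(mm - t(mm))) > 1e-8 || any(mm < 0) ||
      any(abs(diag(mm)) > 1e-12)) {
    stop("expected a symmetric non-negative distance matrix with zero ",
         "diagonal", call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(mm), method = "ward.D2")
  structure(list(hclust = hc, leaf_order = hc$order,
                 labels = hc$labels %||% as.character(seq_len(nrow(mm))),
                 method = "ward", distance = "euclidean",
                 group = attr(m, "group")),
            class = "ftir_hca")
}

#' @export
print.ftir_hca <- function(x, ...) {
  cat(sprintf("<ftir_hca> Ward linkage on Euclidean distances, %d leaves\n",
              length(x$leaf_order)))
  invisible(x)
}

#' Heatmap of a clustered distance matrix
#'
#' Renders the distance matrix with rows and columns reordered by the
#' dendrogram leaf order.
#'
#' @param x An `ftir_hca`.
#' @param m The distance matrix the clustering was computed from.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the reordered matrix.
#' @export
plot.ftir_hca <- function(x, m, ...) {
  mm <- unclass(m)[x$leaf_order, x$leaf_order]
  graphics::image(seq_len(nrow(mm)), seq_len(ncol(mm)), mm,
                  xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(mm)
}

#' Reorder a distance matrix by dendrogram leaf order
#' @param hca An `ftir_hca`.
#' @param m The distance matrix.
#' @return The reordered matrix.
#' @export
reorder_by_leaves <- function(hca, m) {
  unclass(m)[hca$leaf_order, hca$leaf_order]
}

#' Export a dendrogram as Newick
#'
#' @param hca An `ftir_hca`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_newick <- function(hca, path) {
  ape::write.tree(ape::as.phylo(hca$hclust), file = path)
  invisible(path)
}

#' Heterogeneity summary of in-group vs inter-group distances
#'
#' Summarises both distance sets (mean, median, sd), their Gaussian
#' histogram fits, and tests whether inter-group distances are located
#' above in-group distances. When the pooled distance matrix and group
#' labels are supplied the p-value comes from a label-permutation test of
#' the mean difference (calibrated despite the dependence among pairwise
#' distances that share cells); otherwise a Wilcoxon rank-sum p-value is
#' reported as a descriptive statistic.
#'
#' @param in_g,inter_g `ftir_distvec` objects (non-empty).
#' @param pooled Optional `ftir_distmat` over both groups.
#' @param labels Optional group labels matching `pooled`'s rows (defaults
#'   to `attr(pooled, "group")`).
#' @param n_perm Number of label permutations.
#' @param seed Seed for the permutation draw.
#' @return A list of class `"ftir_het_report"`.
#' @export
heterogeneity_report <- function(in_g, inter_g, pooled = NULL,
                                 labels = NULL, n_perm = 199, seed = 1L) {
  stopifnot(inherits(in_g, "ftir_distvec"), inherits(inter_g, "ftir_distvec"))
  if (length(in_g$values) == 0 || length(inter_g$values) == 0) {
    stop("distance vectors must be non-empty", call. = FALSE)
  }
  summ <- function(v) c(mean = mean(v), median = stats::median(v),
                        sd = stats::sd(v))
  s_in <- summ(in_g$values)
  s_inter <- summ(inter_g$values)
  fits <- list(
    in_group = tryCatch(distance_histogram_fit(in_g), error = function(e) NULL),
    inter_group = tryCatch(distance_histogram_fit(inter_g),
                           error = function(e) NULL))
  diff_mean <- unname(s_inter["mean"] - s_in["mean"])
  if (!is.null(pooled)) {
    labels <- labels %||% attr(pooled, "group")
    p <- permutation_pvalue(unclass(pooled), labels, n_perm, seed)
    test <- list(method = "label permutation (mean inter - mean in)",
                 p_value = p)
  } else {
    w <- stats::wilcox.test(inter_g$values, in_g$values,
                            alternative = "greater", exact = FALSE)
    test <- list(method = paste("Wilcoxon rank-sum (descriptive;",
                                "pairwise distances are dependent)"),
                 p_value = unname(w$p.value))
  }
  structure(list(in_group = s_in, inter_group = s_inter,
                 difference = diff_mean, fits = fits, test = test,
                 direction = "inter-group located above in-group"),
            class = "ftir_het_report")
}

# one-sided permutation test: observed mean(inter) - mean(in-group-of-g1)
# against the label-permutation null on a pooled distance matrix
permutation_pvalue <- function(m, labels, n_perm, seed) {
  stat <- function(lab) {
    g <- unique(lab)
    a <- lab == g[1]
    mean(m[a, !a]) - mean(m[a, a][upper.tri(m[a, a])])
  }
  obs <- stat(labels)
  with_seed(seed, {
    perm <- replicate(n_perm, stat(sample(labels)))
    (1 + sum(perm >= obs)) / (n_perm + 1)
  })
}

#' @export
print.ftir_het_report <- function(x, ...) {
  cat("<heterogeneity report>\n")
  cat(sprintf("  in-group:    mean %.4g, median %.4g, sd %.4g\n",
              x$in_group["mean"], x$in_group["median"], x$in_group["sd"]))
  cat(sprintf("  inter-group: mean %.4g, median %.4g, sd %.4g\n",
              x$inter_group["mean"], x$inter_group["median"],
              x$inter_group["sd"]))
  cat(sprintf("  mean difference (inter - in): %.4g\n", x$difference))
  cat(sprintf("  %s: p = %.4g (%s)\n", x$test$method, x$test$p_value,
              x$direction))
  invisible(x)
}
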