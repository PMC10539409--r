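## PCA of single-cell spectra, 95% confidence ellipses on the (PC1, PC2)
## score plane, ellipse-membership classification of senescence, and
## sensitivity/specificity scoring against a reference label.

#' Principal component analysis of a spectrum set
#'
#' Mean-centred PCA (no variance scaling -- standard for spectra) via the
#' singular value decomposition. Component signs are fixed so that each
#' loading's largest-magnitude coefficient is positive, making score plots
#' reproducible across runs and platforms.
#'
#' @param set An `ftir_set` with more cells than components and non-zero
#'   variance.
#' @param n_components Number of components to retain (default 2).
#' @return A list of class `"ftir_pca"`: `scores` (cells x components),
#'   `loadings` (components x wavenumbers), `explained_variance_ratio`,
#'   `center`, `wavenumber`, `stage`, `region`, `cell_id`, `group`.
#' @export
spectral_pca <- function(set, n_components = 2) {
  stopifnot(inherits(set, "ftir_set"))
  if (n_cells(set) <= n_components) {
    stop("need more cells than components", call. = FALSE)
  }
  X <- set$absorbance
  if (max(apply(X, 2, stats::var)) == 0) {
    stop("all spectra are identical; PCA is undefined", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = sco, loadings = t(rot),
                 explained_variance_ratio = evr[seq_len(k)],
                 sdev = pc$sdev,
                 center = pc$center, wavenumber = set$wavenumber,
                 stage = set$stage, region = set$region,
                 cell_id = set$cell_id, group = set$group),
            class = "ftir_pca")
}

#' @export
print.ftir_pca <- function(x, ...) {
  cat(sprintf("<ftir_pca> %d cells, %d components (%s), stage %s, region %s\n",
              nrow(x$scores), nrow(x$loadings),
              paste(sprintf("PC%d %.1f%%", seq_along(x$explained_variance_ratio),
                            100 * x$explained_variance_ratio),
                    collapse = ", "),
              x$stage, x$region))
  invisible(x)
}

#' Project new spectra onto fitted components
#' @param object An `ftir_pca`.
#' @param newdata An `ftir_set` on the same grid/stage/region.
#' @param ... Unused.
#' @return Score matrix for the new cells.
#' @export
predict.ftir_pca <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "ftir_set"))
  if (!same_grid(object$wavenumber, newdata$wavenumber)) {
    stop("newdata is on a different wavenumber grid", call. = FALSE)
  }
  sweep(newdata$absorbance, 2, object$center) %*% t(object$loadings)
}

#' Loading trace of one component
#'
#' Aligns a component's loading coefficients to the (region-restricted)
#' wavenumber axis for plotting or export.
#'
#' @param pca An `ftir_pca`.
#' @param component Component index.
#' @return A data.frame with columns `wavenumber` and `loading`.
#' @export
pca_loading_trace <- function(pca, component = 1) {
  if (component < 1 || component > nrow(pca$loadings)) {
    stop("component index ", component, " out of range 1..",
         nrow(pca$loadings), call. = FALSE)
  }
  data.frame(wavenumber = as.numeric(pca$wavenumber),
             loading = as.numeric(pca$loadings[component, ]))
}

#' Confidence ellipse of a 2-D score cloud
#'
#' Parametric Gaussian ellipse: centre = sample mean, shape = sample
#' covariance, radius scale = the square root of the chi-squared quantile
#' at `level` with 2 degrees of freedom (computed, not hard-coded). A point
#' p lies inside iff its squared Mahalanobis distance to the centre is at
#' most that quantile. An F-corrected small-sample variant
#' (`method = "f"`) scales by `2(n-1)/(n-2) * qf(level, 2, n-2)` instead.
#'
#' @param scores Two-column matrix of (PC1, PC2) scores, >= 3 rows.
#' @param level Confidence level in (0, 1), default 0.95.
#' @param fitted_on Group label the ellipse describes.
#' @param method `"chisq"` (default) or `"f"`.
#' @return A list of class `"ftir_ellipse"`: `center`, `covariance`,
#'   `confidence_level`, `scale` (= sqrt of the squared-radius quantile),
#'   `fitted_on`, `n`.
#' @export
confidence_ellipse <- function(scores, level = 0.95, fitted_on = NA_character_,
                               method = c("chisq", "f")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  if (ncol(scores) != 2 || nrow(scores) < 3) {
    stop("need >= 3 two-dimensional score points", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  ctr <- colMeans(scores)
  S <- stats::cov(scores)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    stop("singular score covariance; ellipse undefined", call. = FALSE)
  }
  n <- nrow(scores)
  q2 <- if (method == "chisq") {
    stats::qchisq(level, df = 2)
  } else {
    2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
  }
  structure(list(center = ctr, covariance = S, confidence_level = level,
                 scale = sqrt(q2), fitted_on = fitted_on, n = n,
                 method = method),
            class = "ftir_ellipse")
}

#' @export
print.ftir_ellipse <- function(x, ...) {
  cat(sprintf(
    "<ftir_ellipse> %.0f%% ellipse%s: centre (%.3g, %.3g), scale %.4f\n",
    100 * x$confidence_level,
    if (is.na(x$fitted_on)) "" else paste0(" for '", x$fitted_on, "'"),
    x$center[1], x$center[2], x$scale))
  invisible(x)
}

#' Ellipse membership
#'
#' @param ellipse An `ftir_ellipse`.
#' @param points Two-column matrix (or length-2 vector) of score points.
#' @return Logical vector: inside (or on) the ellipse.
#' @export
in_ellipse <- function(ellipse, points) {
  mahalanobis2(ellipse, points) <= ellipse$scale^2
}

# squared Mahalanobis distance of points to the ellipse centre
mahalanobis2 <- function(ellipse, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  stats::mahalanobis(p, ellipse$center, ellipse$covariance)
}

#' Boundary polygon of an ellipse (for plotting)
#' @param ellipse An `ftir_ellipse`.
#' @param n Number of boundary points.
#' @return Two-column matrix tracing the boundary.
#' @export
ellipse_path <- function(ellipse, n = 181) {
  th <- seq(0, 2 * pi, length.out = n)
  e <- eigen(ellipse$covariance, symmetric = TRUE)
  circ <- rbind(cos(th), sin(th)) * ellipse$scale
  t(e$vectors %*% (sqrt(pmax(e$values, 0)) * circ) + ellipse$center)
}

#' Classify cells by confidence-ellipse membership
#'
#' Default rule (`"membership"`): predict the group whose ellipse contains
#' the cell's (PC1, PC2) score; if both or neither contain it, assign the
#' group with the smaller Mahalanobis distance. The variant
#' `"outside_control"` calls every cell outside the control ellipse
#' senescent (and inside it, control). Memberships, Mahalanobis distances
#' and the applied rule are returned per cell.
#'
#' @param scores Two-column score matrix for all cells (rownames = ids).
#' @param ellipses Named list of two `ftir_ellipse` objects (names = group
#'   labels; for `"outside_control"` one of them must be `"control"`).
#' @param rule `"membership"` or `"outside_control"`.
#' @return A data.frame with per-cell membership flags, Mahalanobis
#'   distances, and `predicted`; the rule is in `attr(, "rule")`.
#' @export
classify_by_ellipse <- function(scores, ellipses,
                                rule = c("membership", "outside_control")) {
  rule <- match.arg(rule)
  scores <- as.matrix(scores)
  if (length(ellipses) != 2 || is.null(names(ellipses)) ||
      any(!vapply(ellipses, inherits, TRUE, "ftir_ellipse"))) {
    stop("`ellipses` must be a named list of two ftir_ellipse objects",
         call. = FALSE)
  }
  gs <- names(ellipses)
  inside <- vapply(ellipses, function(e) in_ellipse(e, scores),
                   logical(nrow(scores)))
  maha <- vapply(ellipses, function(e) mahalanobis2(e, scores),
                 numeric(nrow(scores)))
  inside <- matrix(inside, ncol = 2, dimnames = list(NULL, gs))
  maha <- matrix(maha, ncol = 2, dimnames = list(NULL, gs))
  nearest <- gs[max.col(-maha, ties.method = "first")]
  predicted <- if (rule == "membership") {
    ifelse(inside[, 1] & !inside[, 2], gs[1],
           ifelse(inside[, 2] & !inside[, 1], gs[2], nearest))
  } else {
    if (!"control" %in% gs) {
      stop("rule 'outside_control' needs an ellipse named 'control'",
           call. = FALSE)
    }
    other <- setdiff(gs, "control")
    ifelse(inside[, "control"], "control", other)
  }
  out <- data.frame(cell_id = rownames(scores) %||%
                      as.character(seq_len(nrow(scores))),
                    inside_1 = inside[, 1], inside_2 = inside[, 2],
                    maha_1 = maha[, 1], maha_2 = maha[, 2],
                    predicted = predicted, stringsAsFactors = FALSE)
  names(out)[2:5] <- c(paste0("inside_", gs), paste0("mahalanobis_", gs))
  attr(out, "rule") <- rule
  out
}

#' Confusion matrix
#'
#' @param tp,fp,fn,tn Non-negative counts (true/false positives/negatives),
#'   with "positive" meaning the senescent class.
#' @param positive_label Positive class label.
#' @return A list of class `"ftir_confusion"`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn, positive_label = "senescent") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 positive_label = positive_label),
            class = "ftir_confusion")
}

#' @export
print.ftir_confusion <- function(x, ...) {
  cat(sprintf("<confusion> positive = '%s'\n", x$positive_label))
  # rows are truth, columns prediction
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Sensitivity and specificity of a senescence call
#'
#' `sensitivity = tp / (tp + fn) * 100`, `specificity = tn / (tn + fp) *
#' 100`, in percent. Accepts either a prediction/truth label pair or an
#' existing [confusion_matrix()]. Values are exact; rounding (1 decimal)
#' happens only in the print method.
#'
#' @param x Character vector of predicted labels, or an `ftir_confusion`.
#' @param truth Character vector of reference labels (label route).
#' @param positive Positive class label present in the label universe.
#' @param ... Unused.
#' @return A list of class `"ftir_performance"`: `confusion`,
#'   `sensitivity`, `specificity` (percent).
#' @export
sensitivity_specificity <- function(x, ...) UseMethod("sensitivity_specificity")

#' @rdname sensitivity_specificity
#' @export
sensitivity_specificity.ftir_confusion <- function(x, ...) {
  structure(list(confusion = x,
                 sensitivity = 100 * x$tp / (x$tp + x$fn),
                 specificity = 100 * x$tn / (x$tn + x$fp)),
            class = "ftir_performance")
}

#' @rdname sensitivity_specificity
#' @export
sensitivity_specificity.default <- function(x, truth, positive = "senescent",
                                            ...) {
  pred <- as.character(x); truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    stop("prediction and truth label vectors differ in length", call. = FALSE)
  }
  classes <- unique(c(pred, truth))
  negative <- setdiff(classes, positive)
  if (length(negative) > 1) {
    stop("labels outside the two-class universe {", positive, ", ",
         negative[1], "}: ", paste(negative[-1], collapse = ", "),
         call. = FALSE)
  }
  is_pos_t <- truth == positive
  is_pos_p <- pred == positive
  cm <- confusion_matrix(tp = sum(is_pos_p & is_pos_t),
                         fp = sum(is_pos_p & !is_pos_t),
                         fn = sum(!is_pos_p & is_pos_t),
                         tn = sum(!is_pos_p & !is_pos_t),
                         positive_label = positive)
  sensitivity_specificity(cm)
}

#' @export
print.ftir_performance <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%%, specificity %.1f%% (positive = '%s')\n",
              x$sensitivity, x$specificity, x$confusion$positive_label))
  invisible(x)
}

#' Score plot with confidence ellipses
#'
#' @param x An `ftir_pca`.
#' @param ellipses Optional named list of `ftir_ellipse` objects to draw.
#' @param col Colours per group.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.ftir_pca <- function(x, ellipses = NULL, col = NULL, ...) {
  groups <- factor(x$group)
  if (is.null(col)) col <- seq_len(nlevels(groups))
  evr <- 100 * x$explained_variance_ratio
  graphics::plot(x$scores[, 1], x$scores[, 2],
                 col = col[as.integer(groups)], pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", evr[1]),
                 ylab = sprintf("PC2 (%.1f%%)", evr[2]), ...)
  if (!is.null(ellipses)) {
    for (k in seq_along(ellipses)) {
      graphics::lines(ellipse_path(ellipses[[k]]), lty = 2,
                      col = col[match(names(ellipses)[k], levels(groups))])
    }
  }
  graphics::legend("topright", legend = levels(groups), pch = 19,
                   col = col[seq_len(nlevels(groups))], bty = "n")
  invisible(x)
}
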