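# Probabilistic LC-space boundary: a binned smoothed-frequency estimator on
# the (mutation %, dominance %) plane, ROC/Youden threshold selection, and
# level-set extraction; plus a penalised-spline logistic surface (mgcv) as
# the smooth alternative.

#' Labelled complexity-space points for boundary estimation
#'
#' Profiles positive (low-complexity) and background region sets and emits
#' one labelled (x, y) point per region: x the mutation percentage, y the
#' dominance percentage.
#'
#' @param positive,background Region tibbles.
#' @param proteome A proteome tibble.
#' @param x_metric `"minperiod"` or `"homorepeat"`.
#' @return A tibble with `x`, `y` and `label` (`"LC"` or `"BG"`).
#' @export
region_points <- function(positive, background, proteome,
                          x_metric = c("minperiod", "homorepeat")) {
  x_metric <- match.arg(x_metric)
  one <- function(regions, label) {
    prof <- profile_regions(regions, proteome, x_metric = x_metric)
    tibble::tibble(x = prof$mutation_pct, y = prof$dominance_pct,
                   label = label)
  }
  dplyr::bind_rows(one(positive, "LC"), one(background, "BG"))
}

check_points <- function(points) {
  stopifnot(all(c("x", "y", "label") %in% names(points)))
  bad <- points$x < 0 | points$x > 100 | points$y < 0 | points$y > 100
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("point out of [0,100] range: (%g, %g)",
                 points$x[i], points$y[i]), call. = FALSE)
  }
  if (!all(points$label %in% c("LC", "BG"))) {
    stop("labels must be 'LC' or 'BG'", call. = FALSE)
  }
  invisible(points)
}

bin_index <- function(v, delta, n_bins) {
  pmin(floor(v / delta), n_bins - 1L)  # top edge 100 closed into last bin
}

#' Bin labelled points onto the LC-space grid
#'
#' Discretises \[0,100\] x \[0,100\] into square bins of width `delta`
#' percent (default 2). A coordinate v falls in bin `floor(v/delta)`; the
#' top edge (v = 100) is closed into the last bin. Per-bin positive and
#' background counts are smoothed into posterior probabilities
#' `P(LC | i,j) = (n_pos + a) / (n_pos + n_neg + 2a)` with pseudocount
#' `a` (default 1), so empty bins sit at 0.5 rather than being undefined.
#'
#' @param points A tibble with `x`, `y` in \[0,100\] and `label` in
#'   `{"LC","BG"}`.
#' @param delta Bin width in percent; must divide 100 evenly.
#' @param a Smoothing pseudocount.
#' @return An object of class `lcr_surface`: a list with the grid tibble
#'   (`xbin`, `ybin`, bin centers `x`, `y`, `n_pos`, `n_neg`, `prob`) and
#'   the parameters.
#' @export
bin_points <- function(points, delta = 2, a = 1) {
  check_points(points)
  if (abs(100 / delta - round(100 / delta)) > 1e-9) {
    stop("delta must divide 100 evenly", call. = FALSE)
  }
  n_bins <- as.integer(round(100 / delta))
  grid <- tidyr::expand_grid(xbin = seq_len(n_bins) - 1L,
                             ybin = seq_len(n_bins) - 1L)
  if (nrow(points) > 0L) {
    counts <- points |>
      dplyr::mutate(xbin = bin_index(.data$x, delta, n_bins),
                    ybin = bin_index(.data$y, delta, n_bins)) |>
      dplyr::count(.data$xbin, .data$ybin, .data$label) |>
      tidyr::pivot_wider(names_from = "label", values_from = "n",
                         values_fill = 0L)
    for (col in c("LC", "BG")) {
      if (!col %in% names(counts)) counts[[col]] <- 0L
    }
    grid <- grid |>
      dplyr::left_join(counts, by = c("xbin", "ybin")) |>
      dplyr::mutate(n_pos = dplyr::coalesce(.data$LC, 0L),
                    n_neg = dplyr::coalesce(.data$BG, 0L)) |>
      dplyr::select("xbin", "ybin", "n_pos", "n_neg")
  } else {
    grid$n_pos <- 0L
    grid$n_neg <- 0L
  }
  grid <- grid |>
    dplyr::mutate(x = (.data$xbin + 0.5) * delta,
                  y = (.data$ybin + 0.5) * delta,
                  prob = (.data$n_pos + a) / (.data$n_pos + .data$n_neg + 2 * a))
  structure(list(grid = grid, delta = delta, a = a, n_bins = n_bins),
            class = "lcr_surface")
}

#' @export
print.lcr_surface <- function(x, ...) {
  cat(sprintf("<lcr_surface> %d x %d bins (delta = %g%%, pseudocount a = %g)\n",
              x$n_bins, x$n_bins, x$delta, x$a))
  cat(sprintf("  points: %d positive, %d background\n",
              sum(x$grid$n_pos), sum(x$grid$n_neg)))
  invisible(x)
}

#' Per-bin posterior probabilities of a binned surface
#'
#' @param surface An `lcr_surface`.
#' @return The grid tibble with the smoothed `prob` column.
#' @export
posterior_probability <- function(surface) {
  stopifnot(inherits(surface, "lcr_surface"))
  surface$grid
}

#' Score points against a fitted surface
#'
#' @param surface An `lcr_surface` or `lcr_smooth`.
#' @param points A tibble with `x`, `y`.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
surface_scores <- function(surface, points) {
  if (inherits(surface, "lcr_smooth")) {
    return(as.numeric(mgcv::predict.gam(surface$fit,
                                        newdata = points[, c("x", "y")],
                                        type = "response")))
  }
  stopifnot(inherits(surface, "lcr_surface"))
  xb <- bin_index(points$x, surface$delta, surface$n_bins)
  yb <- bin_index(points$y, surface$delta, surface$n_bins)
  key <- xb * surface$n_bins + yb
  grid_key <- surface$grid$xbin * surface$n_bins + surface$grid$ybin
  surface$grid$prob[match(key, grid_key)]
}

#' ROC curve over score thresholds
#'
#' Sweeps the decision rule "predict LC when score >= t" over the sorted
#' unique scores plus 0 and 1, computing TPR and FPR at each threshold and
#' Youden's J = TPR - FPR. Requires at least one point of each class.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels `"LC"`/`"BG"` labels (or logical with TRUE = positive).
#' @param thresholds Optional threshold vector; default sorted unique
#'   scores plus `{0, 1}`.
#' @return An object of class `lcr_roc`: tibble `curve` with `threshold`,
#'   `tpr`, `fpr`, `youden_j`; plus `t_star`, `j_max`, `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_curve <- function(scores, labels, thresholds = NULL) {
  if (is.logical(labels)) labels <- ifelse(labels, "LC", "BG")
  stopifnot(length(scores) == length(labels))
  pos <- labels == "LC"
  if (!any(pos) || all(pos)) {
    stop("ROC requires at least one positive and one negative point",
         call. = FALSE)
  }
  if (is.null(thresholds)) thresholds <- sort(unique(c(0, scores, 1)))
  curve <- tibble::tibble(
    threshold = thresholds,
    tpr = vapply(thresholds, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(thresholds, function(t) mean(scores[!pos] >= t), numeric(1))
  ) |>
    dplyr::mutate(youden_j = .data$tpr - .data$fpr)
  # trapezoidal AUC over the (fpr, tpr) path, swept from high to low t
  ord <- order(curve$fpr, curve$tpr)
  auc <- sum(diff(curve$fpr[ord]) *
               (utils::head(curve$tpr[ord], -1) +
                  utils::tail(curve$tpr[ord], -1)) / 2)
  i_star <- which.max(curve$youden_j)  # ties: smallest threshold wins
  structure(list(curve = curve, t_star = curve$threshold[i_star],
                 j_max = curve$youden_j[i_star], auc = auc,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "lcr_roc")
}

#' @export
print.lcr_roc <- function(x, ...) {
  cat(sprintf("<lcr_roc> %d thresholds, %d positive / %d negative points\n",
              nrow(x$curve), x$n_pos, x$n_neg))
  cat(sprintf("  t* = %.4g (Youden J = %.4g), AUC = %.4g\n",
              x$t_star, x$j_max, x$auc))
  invisible(x)
}

#' Youden-optimal threshold of an ROC curve
#'
#' The threshold maximising J(t) = TPR(t) - FPR(t); ties are broken by the
#' smallest such threshold.
#'
#' @param roc An `lcr_roc`.
#' @return The optimal threshold t*.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "lcr_roc"))
  roc$t_star
}

#' Extract the P(LC) = t* boundary contour
#'
#' Marching-squares level set of the probability surface at threshold
#' `t_star`, computed on bin centers (binned surface) or the evaluation
#' grid (smooth surface) with linear interpolation along cell edges. May be
#' empty (surface entirely above or below the level) or consist of several
#' polylines.
#'
#' @param surface An `lcr_surface` or `lcr_smooth`.
#' @param t_star Probability level.
#' @return A tibble with `piece` (polyline id), `x`, `y` in percent.
#' @export
boundary_contour <- function(surface, t_star) {
  if (inherits(surface, "lcr_smooth")) {
    grid <- surface$grid
    xs <- sort(unique(grid$x))
    ys <- sort(unique(grid$y))
  } else {
    stopifnot(inherits(surface, "lcr_surface"))
    grid <- surface$grid
    xs <- sort(unique(grid$x))
    ys <- sort(unique(grid$y))
  }
  z <- matrix(NA_real_, nrow = length(xs), ncol = length(ys))
  z[cbind(match(grid$x, xs), match(grid$y, ys))] <- grid$prob
  cl <- grDevices::contourLines(x = xs, y = ys, z = z, levels = t_star)
  if (length(cl) == 0L) {
    return(tibble::tibble(piece = integer(), x = numeric(), y = numeric()))
  }
  purrr::imap_dfr(cl, function(pl, i) {
    tibble::tibble(piece = as.integer(i), x = pl$x, y = pl$y)
  })
}

#' Area of LC space on the permissive side of the boundary
#'
#' Fraction of grid bins (binned estimator) or grid cells (smooth surface)
#' whose probability is at least `t_star` — the operational size of the
#' LC-permissive region. Used to show that stricter positive sets contract
#' the boundary.
#'
#' @param surface An `lcr_surface` or `lcr_smooth`.
#' @param t_star Probability level.
#' @return Fraction in \[0, 1\].
#' @export
lc_permissive_area <- function(surface, t_star) {
  grid <- if (inherits(surface, "lcr_smooth")) surface$grid else {
    stopifnot(inherits(surface, "lcr_surface"))
    surface$grid
  }
  mean(grid$prob >= t_star)
}

#' Penalised-spline logistic surface over LC space
#'
#' Fits P(LC | x, y) as a smooth logistic surface — a tensor-product
#' penalised regression spline with smoothness chosen by REML — and
#' evaluates it on a regular grid over \[0,100\]^2. The logit link keeps
#' every fitted probability strictly inside (0, 1); with heavy penalisation
#' the surface degenerates towards an ordinary logistic plane.
#'
#' @param points A labelled point tibble (`x`, `y`, `label`).
#' @param k Basis dimension per margin (default 10).
#' @param grid_n Evaluation grid resolution per axis (default 50).
#' @return An object of class `lcr_smooth`: the mgcv fit plus the
#'   evaluation `grid` tibble (`x`, `y`, `prob`).
#' @export
fit_smooth_surface <- function(points, k = 10, grid_n = 50) {
  check_points(points)
  if (length(unique(points$label)) < 2L) {
    stop("smooth surface requires both LC and BG points", call. = FALSE)
  }
  if (nrow(points) < 100L) {
    stop("too few points for a stable smooth fit (need >= 100)",
         call. = FALSE)
  }
  dat <- data.frame(x = points$x, y = points$y,
                    z = as.integer(points$label == "LC"))
  fit <- mgcv::gam(z ~ te(x, y, k = c(k, k)), family = stats::binomial(),
                   data = dat, method = "REML")
  if (!fit$converged) {
    stop("smooth surface fit did not converge (deviance ",
         format(fit$deviance), ")", call. = FALSE)
  }
  centers <- (seq_len(grid_n) - 0.5) * (100 / grid_n)
  grid <- tidyr::expand_grid(x = centers, y = centers)
  grid$prob <- as.numeric(mgcv::predict.gam(fit, newdata = grid,
                                            type = "response"))
  structure(list(fit = fit, grid = grid, k = k, grid_n = grid_n),
            class = "lcr_smooth")
}

#' @export
print.lcr_smooth <- function(x, ...) {
  cat(sprintf("<lcr_smooth> tensor-product logistic surface (k = %d), %dx%d grid\n",
              x$k, x$grid_n, x$grid_n))
  invisible(x)
}

#' Estimate the probabilistic LC-space boundary
#'
#' The full boundary pipeline: split the labelled points into a training
#' and a held-out evaluation half (stratified by label), fit the surface
#' (binned smoothed-frequency estimator or penalised-spline logistic
#' surface) on the training half, score the held-out half, select the
#' Youden-optimal threshold t* from the held-out ROC, and extract the
#' P(LC) = t* contour.
#'
#' @param points A labelled point tibble (`x`, `y`, `label`).
#' @param estimator `"binned"` or `"smooth"`.
#' @param delta,a Binned-estimator parameters.
#' @param split Fraction of points used for training (default 0.5).
#' @param seed Integer seed for the stratified split.
#' @param ... Passed to [fit_smooth_surface()].
#' @return An object of class `lcr_boundary`: the fitted `surface`, the
#'   held-out `roc` (`lcr_roc`), `t_star`, the `contour` tibble, the
#'   LC-permissive `area`, and the split bookkeeping.
#' @export
estimate_lc_boundary <- function(points, estimator = c("binned", "smooth"),
                                 delta = 2, a = 1, split = 0.5, seed = 1L,
                                 ...) {
  estimator <- match.arg(estimator)
  check_points(points)
  stopifnot(split > 0, split < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx_train <- logical(nrow(points))
  for (lb in unique(points$label)) {
    which_lb <- which(points$label == lb)
    n_train <- max(1L, round(split * length(which_lb)))
    idx_train[sample(which_lb, n_train)] <- TRUE
  }
  train <- points[idx_train, , drop = FALSE]
  test <- points[!idx_train, , drop = FALSE]
  surface <- if (estimator == "binned") {
    bin_points(train, delta = delta, a = a)
  } else {
    fit_smooth_surface(train, ...)
  }
  scores <- surface_scores(surface, test)
  roc <- roc_curve(scores, test$label)
  t_star <- youden_optimal(roc)
  structure(list(surface = surface, roc = roc, t_star = t_star,
                 contour = boundary_contour(surface, t_star),
                 area = lc_permissive_area(surface, t_star),
                 estimator = estimator, seed = seed,
                 n_train = nrow(train), n_test = nrow(test)),
            class = "lcr_boundary")
}

#' @export
print.lcr_boundary <- function(x, ...) {
  cat(sprintf("<lcr_boundary> %s estimator, %d train / %d held-out points\n",
              x$estimator, x$n_train, x$n_test))
  cat(sprintf("  t* = %.4g (Youden J = %.4g), LC-permissive area = %.3f\n",
              x$t_star, x$roc$j_max, x$area))
  invisible(x)
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
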