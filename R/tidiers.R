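# broom-style accessors for the fitted boundary objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a binned LC-space surface
#'
#' @param x An `lcr_surface`.
#' @param ... Unused.
#' @return The per-bin grid tibble (`xbin`, `ybin`, centers `x`, `y`,
#'   `n_pos`, `n_neg`, `prob`).
#' @export
tidy.lcr_surface <- function(x, ...) {
  x$grid
}

#' @rdname tidy.lcr_surface
#' @export
glance.lcr_surface <- function(x, ...) {
  tibble::tibble(n_bins = x$n_bins, delta = x$delta, a = x$a,
                 n_pos = sum(x$grid$n_pos), n_neg = sum(x$grid$n_neg))
}

#' Tidy an ROC curve
#'
#' @param x An `lcr_roc`.
#' @param ... Unused.
#' @return The threshold sweep tibble (`threshold`, `tpr`, `fpr`,
#'   `youden_j`).
#' @export
tidy.lcr_roc <- function(x, ...) {
  x$curve
}

#' @rdname tidy.lcr_roc
#' @export
glance.lcr_roc <- function(x, ...) {
  tibble::tibble(t_star = x$t_star, j_max = x$j_max, auc = x$auc,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a smooth logistic surface
#'
#' @param x An `lcr_smooth`.
#' @param ... Unused.
#' @return The evaluation grid tibble (`x`, `y`, `prob`).
#' @export
tidy.lcr_smooth <- function(x, ...) {
  x$grid
}

#' @rdname tidy.lcr_smooth
#' @export
glance.lcr_smooth <- function(x, ...) {
  tibble::tibble(k = x$k, grid_n = x$grid_n,
                 deviance = x$fit$deviance, aic = x$fit$aic,
                 converged = x$fit$converged)
}

#' Tidy an estimated LC boundary
#'
#' @param x An `lcr_boundary`.
#' @param ... Unused.
#' @return The contour tibble (`piece`, `x`, `y`).
#' @export
tidy.lcr_boundary <- function(x, ...) {
  x$contour
}

#' @rdname tidy.lcr_boundary
#' @export
glance.lcr_boundary <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, t_star = x$t_star,
                 j_max = x$roc$j_max, auc = x$roc$auc, area = x$area,
                 n_train = x$n_train, n_test = x$n_test, seed = x$seed)
}
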