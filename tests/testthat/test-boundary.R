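test_that("binning follows the floor rule with a closed top edge", {
  pts <- tibble::tibble(x = 3, y = 7, label = "LC")
  s <- bin_points(pts, delta = 2)
  hit <- s$grid[s$grid$n_pos == 1, ]
  expect_equal(c(hit$xbin, hit$ybin), c(1L, 3L))

  s <- bin_points(tibble::tibble(x = 100, y = 100, label = "LC"))
  hit <- s$grid[s$grid$n_pos == 1, ]
  expect_equal(c(hit$xbin, hit$ybin), c(49L, 49L))

  s <- bin_points(tibble::tibble(x = numeric(), y = numeric(),
                                 label = character()))
  expect_true(all(s$grid$prob == 0.5))
  expect_error(bin_points(tibble::tibble(x = 101, y = 5, label = "LC")),
               "range")
  expect_error(bin_points(pts, delta = 3), "divide")
})

test_that("posterior probabilities follow the smoothed frequency ratio", {
  pts <- dplyr::bind_rows(
    tibble::tibble(x = rep(1, 3), y = rep(1, 3), label = "LC"),
    tibble::tibble(x = 1, y = 1, label = "BG"))
  s <- bin_points(pts, delta = 2, a = 1)
  grid <- posterior_probability(s)
  expect_equal(grid$prob[grid$xbin == 0 & grid$ybin == 0], 4 / 6)
  # a = 0 reduces to the empirical frequency where defined
  s0 <- bin_points(pts, delta = 2, a = 0)
  expect_equal(s0$grid$prob[s0$grid$xbin == 0 & s0$grid$ybin == 0], 3 / 4)
  # larger pseudocounts pull every bin monotonically toward 0.5
  probs <- vapply(c(0, 1, 5, 50), function(a) {
    g <- bin_points(pts, delta = 2, a = a)$grid
    g$prob[g$xbin == 0 & g$ybin == 0]
  }, numeric(1))
  expect_true(all(diff(abs(probs - 0.5)) < 0))
  # many positives, no negatives: probability increases toward 1
  probs <- vapply(c(3, 30, 300), function(n) {
    g <- bin_points(tibble::tibble(x = rep(1, n), y = 1, label = "LC"))$grid
    g$prob[g$xbin == 0 & g$ybin == 0]
  }, numeric(1))
  expect_true(all(diff(probs) > 0) && all(probs < 1))
})

test_that("ROC sweep matches brute force and the four-point worked case", {
  rc <- roc_curve(c(0.8, 0.6, 0.4, 0.2), c("LC", "BG", "LC", "BG"))
  at <- rc$curve[rc$curve$threshold == 0.4, ]
  expect_equal(at$tpr, 1)
  expect_equal(at$fpr, 0.5)
  # exhaustive-sweep optimum
  expect_equal(youden_optimal(rc), 0.4)
  expect_true(all(rc$curve$youden_j <= rc$j_max))

  # perfectly separated scores
  rc <- roc_curve(c(0.9, 0.9, 0.1, 0.1), c("LC", "LC", "BG", "BG"))
  expect_equal(rc$j_max, 1)
  at <- rc$curve[rc$curve$threshold == 0.9, ]
  expect_equal(c(at$tpr, at$fpr), c(1, 0))
  # uninformative scores: TPR = FPR everywhere, smallest threshold returned
  rc <- roc_curve(rep(0.5, 6), c("LC", "BG", "LC", "BG", "LC", "BG"))
  expect_equal(rc$curve$tpr, rc$curve$fpr)
  expect_equal(rc$t_star, 0)
  expect_error(roc_curve(c(0.1, 0.9), c("LC", "LC")), "negative")

  # random scores against a per-threshold brute force and pROC's AUC
  set.seed(61)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    sc <- round(stats::runif(n), 2)
    lb <- sample(c("LC", "BG"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lb)) < 2) next
    rc <- roc_curve(sc, lb)
    for (t in sample(rc$curve$threshold, 5)) {
      pred <- sc >= t
      expect_equal(rc$curve$tpr[rc$curve$threshold == t],
                   sum(pred & lb == "LC") / sum(lb == "LC"))
      expect_equal(rc$curve$fpr[rc$curve$threshold == t],
                   sum(pred & lb == "BG") / sum(lb == "BG"))
    }
    expect_true(all(diff(rc$curve$tpr) <= 1e-12))  # non-increasing in t
    if (requireNamespace("pROC", quietly = TRUE)) {
      auc_ref <- as.numeric(pROC::auc(pROC::roc(
        response = lb, predictor = sc, levels = c("BG", "LC"),
        direction = "<", quiet = TRUE)))
      expect_equal(rc$auc, auc_ref, tolerance = 1e-9)
    }
  }
})

test_that("contours extract the level set of simple planted surfaces", {
  # left half positive, right half negative: vertical contour at midline
  set.seed(62)
  grid4 <- function(n, xlo, xhi) {
    cx <- sample(seq(xlo, xhi - 4, by = 4), n, replace = TRUE)
    cy <- sample(seq(0, 96, by = 4), n, replace = TRUE)
    tibble::tibble(x = cx + runif(n, 0, 4), y = cy + runif(n, 0, 4))
  }
  pts <- dplyr::bind_rows(grid4(6000, 0, 48) |> dplyr::mutate(label = "LC"),
                          grid4(6000, 52, 100) |> dplyr::mutate(label = "BG"))
  s <- bin_points(pts, delta = 4)
  ct <- boundary_contour(s, 0.5)
  expect_gt(nrow(ct), 0)
  expect_true(all(abs(ct$x - 50) <= 4))
  expect_gt(diff(range(ct$y)), 80)  # spans most of the axis
  # constant surface above the level: empty contour
  hi <- bin_points(tibble::tibble(x = rep(50, 10), y = 50, label = "LC"))
  expect_equal(nrow(boundary_contour(hi, 0.05)), 0L)
})

test_that("the smooth surface recovers a planted logistic plane", {
  set.seed(63)
  n <- 5000
  x <- runif(n, 0, 100)
  y <- runif(n, 0, 100)
  p_true <- stats::plogis(-0.08 * x + 0.08 * y)  # planar log-odds
  pts <- tibble::tibble(x = x, y = y,
                        label = ifelse(runif(n) < p_true, "LC", "BG"))
  fit <- fit_smooth_surface(pts)
  expect_true(all(fit$grid$prob > 0 & fit$grid$prob < 1))
  p_grid <- stats::plogis(-0.08 * fit$grid$x + 0.08 * fit$grid$y)
  rmse <- sqrt(mean((fit$grid$prob - p_grid)^2))
  expect_lt(rmse, 0.05)
  expect_error(fit_smooth_surface(pts[pts$label == "LC", ]), "both")
  expect_error(fit_smooth_surface(pts[1:50, ]), "few")
})

test_that("the full boundary pipeline separates a margin-separated cloud", {
  pts <- separable_boundary_points(12000, grid = 4, seed = 64)
  b <- estimate_lc_boundary(pts, "binned", delta = 4, seed = 65)
  expect_equal(b$roc$j_max, 1)
  expect_gt(nrow(b$contour), 0)
  # contour stays within one bin width of the planted x + y = 100 line
  d <- abs(b$contour$x + b$contour$y - 100) / sqrt(2)
  expect_gt(mean(d <= 4), 0.95)
  # glance/tidy accessors expose the fit
  g <- generics::glance(b)
  expect_equal(g$t_star, b$t_star)
  expect_named(generics::tidy(b), c("piece", "x", "y"))
  # stricter positive sets contract the LC-permissive area
  areas <- vapply(c(0, 20, 40), function(m) {
    p <- separable_boundary_points(12000, margin = m, grid = 4, seed = 66)
    estimate_lc_boundary(p, "binned", delta = 4, seed = 67)$area
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("surface scoring is consistent between the two estimators", {
  pts <- separable_boundary_points(600, margin = 10, seed = 68)
  s <- bin_points(pts)
  sc <- surface_scores(s, pts)
  expect_true(all(sc > 0 & sc < 1))
  expect_gt(mean(sc[pts$label == "LC"]), mean(sc[pts$label == "BG"]))
})
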