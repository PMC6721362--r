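disk_mask <- function(r, center, n = 100)
  outer(1:n, 1:n, function(y, x)
    (x - center[1])^2 + (y - center[2])^2 <= r^2)

test_that("centroid detector returns the center of gravity", {
  mask <- disk_mask(20, c(50, 50))
  d <- detect_cent(mask)
  expect_equal(d$method, "CENT")
  expect_lt(sqrt(sum((d$center - c(50, 50))^2)), 0.5)
  # a far 1-px artifact biases the centroid by exactly d * 1 / (A + 1)
  A <- sum(mask)
  mask2 <- mask; mask2[90, 90] <- TRUE
  d2 <- detect_cent(mask2)
  expected <- (c(50, 50) * A + c(90, 90)) / (A + 1)
  pc <- which(mask, arr.ind = TRUE)
  exact <- c(mean(c(pc[, 2], 90)), mean(c(pc[, 1], 90)))
  expect_equal(d2$center, exact, tolerance = 1e-12)
  expect_equal(d2$center, expected, tolerance = 1e-2)
  expect_error(detect_cent(matrix(FALSE, 5, 5)), class = "no_pupil")
})

test_that("projection method reproduces the worked rectangle cases", {
  # filled rectangle: all positive column sums equal the threshold mean,
  # so the >= comparison keeps the full extent
  mask <- matrix(FALSE, 10, 10)
  mask[3:6, 4:9] <- TRUE
  d <- detect_proj(mask)
  expect_equal(d$center, c((4 + 9) / 2, (3 + 6) / 2))
  p <- projection_profile(mask)
  expect_equal(p$X_th, 4); expect_equal(p$Y_th, 6)
  expect_equal(p$m, 6); expect_equal(p$n, 4)
  # an outlier column below the mean threshold is excluded
  mask2 <- mask; mask2[3, 1] <- TRUE
  p2 <- projection_profile(mask2)
  expect_equal(p2$X_th, 25 / 7, tolerance = 1e-12)
  d2 <- detect_proj(mask2)
  expect_equal(d2$center[1], 6.5)   # x-range unchanged by the outlier
  expect_error(detect_proj(matrix(FALSE, 4, 4)), class = "no_pupil")
})

test_that("CHT recovers a clean rasterized circle", {
  edges <- matrix(FALSE, 200, 200)
  th <- seq(0, 2 * pi, length.out = 720)
  xs <- round(100 + 30 * cos(th)); ys <- round(120 + 30 * sin(th))
  edges[cbind(ys, xs)] <- TRUE
  d <- detect_cht(edges, 25:35)
  expect_equal(d$shape$radius, 30)
  expect_lt(sqrt(sum((d$center - c(100, 120))^2)), 1.01)
  expect_error(detect_cht(matrix(FALSE, 50, 50), 5:10), class = "no_pupil")
})

test_that("CHT peak ties break toward the smallest (y, x)", {
  edges <- matrix(FALSE, 120, 120)
  th <- seq(0, 2 * pi, length.out = 360)
  for (ctr in list(c(80, 85), c(30, 25))) {
    xs <- round(ctr[1] + 15 * cos(th)); ys <- round(ctr[2] + 15 * sin(th))
    edges[cbind(ys, xs)] <- TRUE
  }
  d <- detect_cht(edges, hough_config(radii = 15, tol = 0.5))
  # identical circles: the peak at the smaller (y, x) center wins
  expect_equal(d$center, c(30, 25))
})

test_that("EHT recovers axis-aligned and rotated ellipses", {
  edges <- matrix(FALSE, 200, 200)
  pts <- ellipse_points(720, c(80, 90), 30, 20, 0)
  edges[cbind(round(pts[, 2]), round(pts[, 1]))] <- TRUE
  d <- detect_eht(edges, hough_config(a = c(26, 30, 34), b = c(16, 20, 24),
                                      tau = 0, dims = 4))
  expect_equal(d$shape$a, 30); expect_equal(d$shape$b, 20)
  expect_lt(sqrt(sum((d$center - c(80, 90))^2)), 1.01)
  # rotated ellipse with a 15-degree grid: tau recovered within one step
  edges2 <- matrix(FALSE, 200, 200)
  tau_true <- pi / 6
  pts2 <- ellipse_points(720, c(100, 100), 30, 18, tau_true)
  edges2[cbind(round(pts2[, 2]), round(pts2[, 1]))] <- TRUE
  d2 <- detect_eht(edges2, hough_config(a = c(28, 30, 32),
                                        b = c(16, 18, 20),
                                        tau = seq(0, pi - pi / 12, pi / 12),
                                        dims = 5))
  expect_lte(min(abs(d2$shape$tau - tau_true),
                 pi - abs(d2$shape$tau - tau_true)), pi / 12)
  expect_lt(sqrt(sum((d2$center - c(100, 100))^2)), 1.5)
})

test_that("EHT restricted to a = b coincides with CHT", {
  set.seed(21)
  for (i in 1:20) {
    edges <- matrix(FALSE, 64, 64)
    r <- sample(8:14, 1)
    ctr <- stats::runif(2, 20, 44)
    th <- seq(0, 2 * pi, length.out = 180)
    edges[cbind(pmin(pmax(round(ctr[2] + r * sin(th)), 1), 64),
                pmin(pmax(round(ctr[1] + r * cos(th)), 1), 64))] <- TRUE
    edges[sample(64 * 64, 15)] <- TRUE   # clutter
    radii <- 8:14
    dc <- detect_cht(edges, radii)
    # the eht grid expansion of equal a and b vectors also contains mixed
    # a != b pairs; restrict to the diagonal for a true equivalence check
    de <- lapply(radii, function(r)
      detect_eht(edges, hough_config(a = r, b = r, tau = 0, dims = 4)))
    key <- t(vapply(de, function(d)
      c(-d$score, d$center[2], d$center[1]), numeric(3)))
    best <- de[[order(key[, 1], key[, 2], key[, 3])[1]]]
    expect_equal(dc$center, best$center)
    expect_equal(dc$score, best$score)
  }
})

test_that("ellipse grids with a < b are normalized by axis swap", {
  cfg <- hough_config(a = 10, b = 20, tau = 0, dims = 5)
  g <- pupiltrack:::eht_triplets(cfg)
  expect_true(all(g$a >= g$b))
  expect_equal(g$a, 20); expect_equal(g$b, 10)
  expect_equal(g$tau, pi / 2)
})

test_that("LSFE fits exact ellipse samples to machine precision", {
  pts <- ellipse_points(20, c(80, 90), 30, 20, 0)
  d <- detect_lsfe(pts)
  expect_equal(d$center, c(80, 90), tolerance = 1e-6)
  expect_equal(d$shape$a, 30, tolerance = 1e-6)
  expect_equal(d$shape$b, 20, tolerance = 1e-6)
  # rotated case
  pts2 <- ellipse_points(24, c(50, 60), 25, 12, 0.7)
  d2 <- detect_lsfe(pts2)
  expect_equal(d2$center, c(50, 60), tolerance = 1e-6)
  expect_equal(d2$shape$tau, 0.7, tolerance = 1e-6)
  # circle: a and b coincide
  pts3 <- ellipse_points(16, c(40, 40), 15, 15, 0)
  d3 <- detect_lsfe(pts3)
  expect_equal(d3$shape$a, d3$shape$b, tolerance = 1e-6)
  expect_error(detect_lsfe(pts[1:4, ]), class = "fit_error")
  collinear <- cbind(1:10, 2 * (1:10) + 3)
  expect_error(detect_lsfe(collinear), class = "fit_error")
})

test_that("RANSAC matches LSFE on clean data and rejects outliers", {
  pts <- ellipse_points(40, c(80, 90), 30, 20, 0.4)
  dl <- detect_lsfe(pts)
  dr <- detect_ransac(pts, seed = 11)
  expect_equal(dr$center, dl$center, tolerance = 1e-6)
  expect_equal(dr$score, 1)   # all points inliers
  # contaminated data: 30 % uniform outliers
  set.seed(99)
  n_out <- 18
  noisy <- rbind(ellipse_points(42, c(80, 90), 30, 20, 0.4),
                 cbind(stats::runif(n_out, 10, 150),
                       stats::runif(n_out, 10, 150)))
  hits <- 0
  for (s in 1:20) {
    d <- detect_ransac(noisy, seed = s, inlier_tol = 2)
    inl <- attr(d, "inliers")
    err <- sqrt(sum((d$center - c(80, 90))^2))
    out_kept <- sum(inl > 42)
    if (err < 1 && out_kept <= ceiling(0.05 * n_out)) hits <- hits + 1
  }
  expect_gte(hits, 19)
  # determinism under a fixed seed
  expect_identical(detect_ransac(noisy, seed = 5)$center,
                   detect_ransac(noisy, seed = 5)$center)
  expect_error(detect_ransac(cbind(1:10, 2 * (1:10))),
               class = "ransac_failure")
})

test_that("the full pipeline localizes the pupil for every method", {
  out <- make_test_eye(r = 25, center = c(320.5, 240.5), sigma = 0,
                       glint_placement = NULL)
  for (m in c("cent", "proj", "cht", "eht", "lsfe", "ransac")) {
    d <- detect(out$image, m, config = list(r_pupil = 25))
    expect_lt(sqrt(sum((d$center - out$truth$center)^2)), 2,
              label = paste("center error for", m))
  }
  expect_error(detect(matrix(128L, 100, 100), "cent"), class = "no_pupil")
  expect_error(detect(out$image, "nonsense"))
})

test_that("pipeline errors identify their stage", {
  err <- tryCatch(detect(matrix(128L, 100, 100), "cht"),
                  pupiltrack_error = function(e) conditionMessage(e))
  expect_match(err, "stage threshold")
})

test_that("CHT beats the centroid when a glint notches the pupil edge", {
  # glint on the boundary distorts the reconstructed mask asymmetrically;
  # voting on edges is less affected on average
  errs <- sapply(1:15, function(s) {
    out <- make_test_eye(r = 25, center = c(320.3, 240.7), sigma = 6,
                         glint_placement = "on_edge", seed = s)
    e_cht <- sqrt(sum((detect(out$image, "cht",
                              list(r_pupil = 25))$center -
                       out$truth$center)^2))
    e_cent <- sqrt(sum((detect(out$image, "cent",
                               list(r_pupil = 25))$center -
                        out$truth$center)^2))
    c(cht = e_cht, cent = e_cent)
  })
  expect_lte(mean(errs["cht", ]), mean(errs["cent", ]) + 0.5)
})
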