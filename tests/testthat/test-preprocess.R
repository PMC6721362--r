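test_that("median denoising restores isolated impulse noise", {
  img <- matrix(100L, 20, 20)
  expect_identical(denoise(img, 3), img)          # constant unchanged
  expect_identical(denoise(img, 1), img)          # window 1 is identity
  img[10, 10] <- 255L
  out <- denoise(img, 3)
  expect_equal(out[10, 10], 100L)
  expect_identical(out, matrix(100L, 20, 20))
  expect_error(denoise(img, 4), class = "invalid_parameter")
})

test_that("pupil percentile follows the area ratio", {
  expect_equal(percentile_from_radius(25, 640, 480),
               pi * 25^2 / (640 * 480) * 100, tolerance = 1e-12)
  expect_equal(percentile_from_radius(25, 640, 480), 0.6393, tolerance = 1e-3)
  r_full <- sqrt(100 * 100 / pi)
  expect_equal(percentile_from_radius(r_full, 100, 100), 100)
  expect_error(percentile_from_radius(0, 640, 480),
               class = "invalid_parameter")
})

test_that("quantitative threshold is the minimal level reaching t0", {
  img <- matrix(200L, 100, 100)
  img[seq_len(100)] <- 10L
  T_ <- quantitative_threshold(img, 1)
  expect_equal(as.integer(T_), 10L)
  expect_equal(sum(binarize(img, T_)), 100)
  # constant image is degenerate: threshold equals the constant
  Tc <- quantitative_threshold(matrix(42L, 10, 10), 5)
  expect_equal(as.integer(Tc), 42L)
  expect_true(attr(Tc, "degenerate"))
  expect_error(quantitative_threshold(img, 0), class = "invalid_parameter")
  expect_error(quantitative_threshold(img, 100), class = "invalid_parameter")
})

test_that("threshold agrees with a 256-level linear scan on random images", {
  set.seed(31)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 400, replace = TRUE,
                         prob = stats::runif(256)^2), 20, 20)
    t0 <- stats::runif(1, 0.5, 60)
    T_ <- as.integer(quantitative_threshold(img, t0))
    expect_identical(T_, oracle_threshold(img, t0))
    # minimality and attainment
    expect_gte(100 * mean(img <= T_), t0)
    if (T_ > 0) expect_lt(100 * mean(img <= T_ - 1L), t0)
  }
})

test_that("binarization is invariant to order-preserving intensity remaps", {
  set.seed(5)
  img <- matrix(sample(0:120, 900, replace = TRUE), 30, 30)
  t0 <- 10
  m1 <- binarize(img, as.integer(quantitative_threshold(img, t0)))
  remap <- img * 2L + 10L   # monotone, stays within 0-255
  m2 <- binarize(remap, as.integer(quantitative_threshold(remap, t0)))
  expect_identical(m1, m2)
})

test_that("binarization polarity selects dark pixels", {
  img <- matrix(c(10L, 200L), 10, 10)
  expect_true(all(binarize(img, 255)))
  expect_false(any(binarize(img, 5)))
  m <- binarize(img, 10)
  expect_identical(m, img <= 10)
})

test_that("mask area of a noiseless eye matches the pupil disk area", {
  # t0 is derived, as in the calibration stage, from the radius equivalent
  # to the measured pupil area; Eq.-style pi r^2 with the true continuous
  # radius can straddle the discrete histogram step on noiseless images
  for (r in c(15, 25, 35)) {
    sc <- eye_scene(center = c(320, 240), axes = c(r, r))
    img <- render_eye_image(sc)$image
    r_meas <- sqrt((sum(img == sc$levels["pupil"]) - 0.5) / pi)
    t0 <- percentile_from_radius(r_meas, 640, 480)
    mask <- binarize(img, as.integer(quantitative_threshold(img, t0)))
    expect_lt(abs(sum(mask) - pi * r^2) / (pi * r^2), 0.05)
  }
})

test_that("largest component selection matches a flood-fill oracle", {
  set.seed(8)
  for (i in 1:10) {
    mask <- matrix(stats::runif(30 * 30) < 0.25, 30, 30)
    if (!any(mask)) next
    keep <- largest_component(mask)
    lab <- oracle_components(mask)
    areas <- tabulate(lab[lab > 0])
    expect_equal(sum(keep), max(areas))
    # the kept pixels are one oracle component
    expect_equal(length(unique(lab[keep])), 1L)
  }
  expect_error(largest_component(matrix(FALSE, 5, 5)), class = "no_pupil")
})

test_that("largest component area ties break on row-major order", {
  mask <- matrix(FALSE, 10, 10)
  mask[6:7, 2:3] <- TRUE   # area 4, top-left pixel at row 6
  mask[2:3, 6:7] <- TRUE   # area 4, top-left pixel at row 2 -> wins
  keep <- largest_component(mask)
  expect_true(all(keep[2:3, 6:7]))
  expect_false(any(keep[6:7, 2:3]))
})

test_that("morphological reconstruction removes glint artifacts", {
  disk <- function(r, ctr = c(40, 40), n = 80)
    outer(1:n, 1:n, function(y, x) (x - ctr[1])^2 + (y - ctr[2])^2 <= r^2)
  pupil <- disk(20)
  # interior hole
  holed <- pupil & !disk(4, c(45, 40))
  rec <- reconstruct_pupil(holed, 3)
  expect_lt(abs(sum(rec) - sum(pupil)) / sum(pupil), 0.02)
  expect_false(any(rec & !pupil & disk(10, c(45, 40))))
  # boundary notch (glint on the pupil edge)
  notched <- pupil & !disk(4, c(60, 40))
  rec2 <- reconstruct_pupil(notched, 5)
  pc <- which(rec2, arr.ind = TRUE)
  expect_lt(sqrt((mean(pc[, 2]) - 40)^2 + (mean(pc[, 1]) - 40)^2), 1)
  # near-idempotence on a smooth disk
  rec3 <- reconstruct_pupil(pupil, 3)
  expect_lt(abs(sum(rec3) - sum(pupil)) / sum(pupil), 0.01)
  expect_error(reconstruct_pupil(matrix(FALSE, 5, 5), 3),
               class = "no_pupil")
})

test_that("reconstruction output has no interior holes and covers the erosion", {
  set.seed(12)
  for (i in 1:5) {
    mask <- matrix(FALSE, 60, 60)
    ctr <- stats::runif(2, 20, 40); r <- stats::runif(1, 8, 15)
    mask <- outer(1:60, 1:60, function(y, x)
      (x - ctr[1])^2 + (y - ctr[2])^2 <= r^2)
    mask[sample(which(mask), 10)] <- FALSE  # poke holes
    rec <- reconstruct_pupil(mask, 3)
    # interior holes absent: complement has a single border-connected part
    lab <- oracle_components(!rec)
    border_labels <- unique(c(lab[1, ], lab[60, ], lab[, 1], lab[, 60]))
    expect_true(all(lab[!rec] %in% border_labels))
    # superset of the erosion of the input
    kern <- EBImage::makeBrush(7, "disc")
    eroded <- EBImage::erode(mask * 1L, kern) > 0
    expect_true(all(rec[eroded]))
  }
})

test_that("LoG zero crossings trace object boundaries", {
  disk <- outer(1:100, 1:100, function(y, x)
    (x - 50)^2 + (y - 50)^2 <= 30^2)
  ed <- log_edges(disk, 2)
  pc <- which(ed, arr.ind = TRUE)
  expect_gt(nrow(pc), 50)
  d <- sqrt((pc[, 2] - 50)^2 + (pc[, 1] - 50)^2)
  expect_true(all(abs(d - 30) <= 2))
  # constant input has no edges
  expect_equal(sum(log_edges(matrix(100L, 50, 50), 2)), 0)
  # nested disks give two rings
  img <- matrix(200L, 100, 100)
  img[outer(1:100, 1:100, function(y, x)
    (x - 50)^2 + (y - 50)^2 <= 30^2)] <- 100L
  img[outer(1:100, 1:100, function(y, x)
    (x - 50)^2 + (y - 50)^2 <= 15^2)] <- 30L
  rings <- log_edges(img, 2)
  lab <- oracle_components(rings)
  expect_equal(max(lab), 2L)
  expect_error(log_edges(disk, 0), class = "invalid_parameter")
})

test_that("the preprocessing pipeline is deterministic", {
  img <- make_test_eye(seed = 3)$image
  run <- function() {
    d <- denoise(img, 3)
    T_ <- quantitative_threshold(d, percentile_from_radius(25, 640, 480))
    reconstruct_pupil(largest_component(binarize(d, as.integer(T_))), 5)
  }
  expect_identical(run(), run())
})
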