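new_detection <- function(center, method, shape = NULL, score = 0) {
  structure(list(center = as.numeric(center), shape = shape,
                 method = method, score = score),
            class = "pupil_detection")
}

#' @export
print.pupil_detection <- function(x, ...) {
  cat(sprintf("<pupil_detection %s> center = (%.2f, %.2f), score = %.3g\n",
              x$method, x$center[1], x$center[2], x$score))
  if (!is.null(x$shape))
    cat(sprintf("  shape: a = %.2f, b = %.2f, tau = %.3f rad\n",
                x$shape$a, x$shape$b, x$shape$tau))
  invisible(x)
}

#' Centroid (CENT) pupil-center detector
#'
#' Center of gravity of the reconstructed pupil mask. Fast but sensitive to
#' residual artifacts, which pull the centroid toward them.
#'
#' @param mask Reconstructed logical pupil mask.
#' @return A `pupil_detection` (`shape = NULL`, score = object area).
#' @export
detect_cent <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop_pupiltrack("empty mask: no pupil", "no_pupil")
  pc <- mask_coords(mask)
  new_detection(c(mean(pc$x), mean(pc$y)), "CENT", score = nrow(pc))
}

#' Projection profile of a binary mask
#'
#' Column and row sums of the mask with the adaptive thresholds of the
#' projection method: each threshold is the mean of the strictly positive
#' profile elements, and the above-threshold index range (comparison uses
#' `>=` so that an ideal rectangle, whose positive elements all equal the
#' mean, keeps its full extent).
#'
#' @param mask Logical mask.
#' @return List with `z_x`, `z_y`, `X_th`, `Y_th`, `m`, `n`,
#'   `x_min`, `x_max`, `y_min`, `y_max`.
#' @export
projection_profile <- function(mask) {
  assert_mask(mask)
  z_x <- colSums(mask); z_y <- rowSums(mask)
  pos_x <- z_x[z_x > 0]; pos_y <- z_y[z_y > 0]
  if (length(pos_x) == 0L)
    stop_pupiltrack("empty mask: no pupil", "no_pupil")
  X_th <- mean(pos_x); Y_th <- mean(pos_y)
  xr <- which(z_x >= X_th); yr <- which(z_y >= Y_th)
  list(z_x = z_x, z_y = z_y, X_th = X_th, Y_th = Y_th,
       m = length(pos_x), n = length(pos_y),
       x_min = min(xr), x_max = max(xr), y_min = min(yr), y_max = max(yr))
}

#' Projection (PROJ) pupil-center detector
#'
#' Projects the mask on both axes, thresholds each profile at the mean of
#' its strictly positive elements to reject sparse false detections, and
#' takes the center as the middle of the above-threshold index range.
#'
#' @param mask Reconstructed logical pupil mask.
#' @return A `pupil_detection` (`shape = NULL`).
#' @export
detect_proj <- function(mask) {
  p <- projection_profile(mask)
  new_detection(c((p$x_min + p$x_max) / 2, (p$y_min + p$y_max) / 2),
                "PROJ", score = sum(p$z_x))
}

#' Hough-transform parameter grids
#'
#' @param radii Radius grid for the circular transform (3-D accumulator).
#' @param a,b Semi-axis grids for the elliptical transform.
#' @param tau Rotation-angle grid in radians; ignored when `dims = 4`
#'   (angle neglected, as in the real-time variant).
#' @param dims Accumulator dimensionality: 3 (circle), 4 (ellipse, tau = 0)
#'   or 5 (full ellipse).
#' @param tol Vote-band half-width in pixels: an edge pixel votes for a
#'   center when its radial distance to the candidate boundary is at most
#'   `tol`. The default 1 px absorbs edge-localization and grid
#'   quantization error.
#' @return A `hough_config` list.
#' @export
hough_config <- function(radii = NULL, a = NULL, b = NULL, tau = 0,
                         dims = if (is.null(a)) 3L else
                           if (length(tau) > 1L || any(tau != 0)) 5L else 4L,
                         tol = 1) {
  if (dims == 3L && (is.null(radii) || length(radii) == 0L))
    stop_pupiltrack("radius grid must be non-empty", "invalid_parameter")
  if (dims > 3L && (is.null(a) || is.null(b) ||
                    length(a) == 0L || length(b) == 0L))
    stop_pupiltrack("axis grids must be non-empty", "invalid_parameter")
  structure(list(radii = radii, a = a, b = b,
                 tau = if (dims == 4L) 0 else tau, dims = as.integer(dims),
                 tol = tol),
            class = "hough_config")
}

# Expand (a, b, tau) triplets in ascending order; grids with a < b are
# normalized by swapping axes and rotating tau by pi/2.
eht_triplets <- function(cfg) {
  g <- expand.grid(tau = cfg$tau, b = cfg$b, a = cfg$a)
  swap <- g$a < g$b
  if (any(swap)) {
    tmp <- g$a[swap]; g$a[swap] <- g$b[swap]; g$b[swap] <- tmp
    g$tau[swap] <- (g$tau[swap] + pi / 2) %% pi
  }
  g <- unique(g[order(g$a, g$b, g$tau), c("a", "b", "tau")])
  g
}

edge_xy <- function(edges) {
  assert_mask(edges)
  pc <- mask_coords(edges)
  if (nrow(pc) == 0L)
    stop_pupiltrack("no edge pixels", "no_pupil")
  pc
}

# Run the accumulator on the edge bounding box plus one max-axis margin:
# a center can only collect votes within reach of an edge pixel, so the
# crop is lossless; returned coordinates are shifted back to the image.
vote_cropped <- function(pc, a, b, tau, width, height, tol) {
  R <- ceiling(max(a, b) + tol + 1)
  x0 <- max(1L, min(pc$x) - R); x1 <- min(width, max(pc$x) + R)
  y0 <- max(1L, min(pc$y) - R); y1 <- min(height, max(pc$y) + R)
  res <- hough_vote(as.integer(pc$x - x0 + 1L), as.integer(pc$y - y0 + 1L),
                    a, b, tau, as.integer(x1 - x0 + 1L),
                    as.integer(y1 - y0 + 1L), tol)
  res$cx <- res$cx + x0 - 1L
  res$cy <- res$cy + y0 - 1L
  res
}

#' Circular Hough transform (CHT) pupil detector
#'
#' Every edge pixel votes, for each radius in the grid, for all integer
#' centers at that radial distance; the global accumulator peak over
#' (x, y, r) gives the detected circle. Peak ties are broken by smallest
#' y, then x, then radius.
#'
#' @param edges Logical edge mask (e.g. from [log_edges()]), >= 3 pixels.
#' @param config A [hough_config()] or a plain numeric radius grid.
#' @return A `pupil_detection` with circle `shape` and score = peak votes.
#' @export
detect_cht <- function(edges, config) {
  if (is.numeric(config)) config <- hough_config(radii = config)
  radii <- sort(config$radii)
  pc <- edge_xy(edges)
  if (nrow(pc) < 3L)
    stop_pupiltrack("need at least 3 edge pixels", "no_pupil")
  res <- vote_cropped(pc, radii, radii, rep(0, length(radii)),
                      ncol(edges), nrow(edges), config$tol)
  r <- radii[res$triplet]
  new_detection(c(res$cx, res$cy), "CHT",
                shape = list(a = r, b = r, tau = 0, radius = r),
                score = res$votes)
}

#' Elliptical Hough transform (EHT) pupil detector
#'
#' Generalizes [detect_cht()] to ellipses: for each (a, b, tau) triplet in
#' the grid, edge pixels vote for the centers whose ellipse of those
#' parameters passes through them (the boundary offset is rotated by tau
#' about the edge pixel). The returned parameters are those of the maximum
#' accumulator value over all triplets. With `dims = 4` the rotation angle
#' is neglected (tau = 0), trading accuracy for running time as required
#' for real-time use; `dims = 5` searches the full 5-D parameter space.
#'
#' @param edges Logical edge mask, >= 5 pixels.
#' @param config A [hough_config()] with axis grids.
#' @return A `pupil_detection` with ellipse `shape` and score = peak votes.
#' @export
detect_eht <- function(edges, config) {
  stopifnot(inherits(config, "hough_config"))
  g <- eht_triplets(config)
  pc <- edge_xy(edges)
  if (nrow(pc) < 5L)
    stop_pupiltrack("need at least 5 edge pixels", "no_pupil")
  res <- vote_cropped(pc, g$a, g$b, g$tau,
                      ncol(edges), nrow(edges), config$tol)
  k <- res$triplet
  new_detection(c(res$cx, res$cy), "EHT",
                shape = list(a = g$a[k], b = g$b[k], tau = g$tau[k]),
                score = res$votes)
}

# Geometric ellipse parameters from conic coefficients
# A x^2 + B xy + C y^2 + D x + E y + F = 0; NULL if not an ellipse.
conic_to_ellipse <- function(v) {
  A <- v[1]; B <- v[2]; C <- v[3]; D <- v[4]; E <- v[5]; F_ <- v[6]
  if (4 * A * C - B^2 <= 0) return(NULL)
  M <- matrix(c(2 * A, B, B, 2 * C), 2, 2)
  ctr <- tryCatch(solve(M, c(-D, -E)), error = function(e) NULL)
  if (is.null(ctr)) return(NULL)
  F0 <- F_ + (D * ctr[1] + E * ctr[2]) / 2
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(Q, symmetric = TRUE)
  ax2 <- -F0 / ev$values
  if (any(ax2 <= 0) || any(!is.finite(ax2))) return(NULL)
  semi <- sqrt(ax2)
  i_major <- which.max(semi)
  tau <- atan2(ev$vectors[2, i_major], ev$vectors[1, i_major]) %% pi
  list(center = ctr, a = max(semi), b = min(semi), tau = tau)
}

# Direct least-squares ellipse fit (ellipse-constrained algebraic fit).
# Points are centered for numerical conditioning; only the center needs
# shifting back.
fit_ellipse_lsq <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  xc <- x - mx; yc <- y - my
  D1 <- cbind(xc^2, xc * yc, yc^2)
  D2 <- cbind(xc, yc, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T_ <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T_)) return(NULL)
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(eg)) return(NULL)
  V <- Re(eg$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L) return(NULL)
  a1 <- V[, ok[1]]
  conic <- c(a1, as.numeric(T_ %*% a1))
  el <- conic_to_ellipse(conic)
  if (is.null(el)) return(NULL)
  el$center <- el$center + c(mx, my)
  el
}

as_points <- function(points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  if (!is.matrix(points) || ncol(points) != 2L)
    stop_pupiltrack("points must be an n x 2 matrix or data frame with x, y",
                    "invalid_parameter")
  points
}

#' Least-squares ellipse fitting (LSFE) pupil detector
#'
#' Fits a conic to the contour points by minimizing the sum of squared
#' algebraic distances, with the constraint that the conic is an ellipse
#' (negative discriminant); non-ellipse outcomes are rejected as errors.
#'
#' @param points n x 2 matrix or data frame (`x`, `y`) of contour points,
#'   n >= 5 and not collinear.
#' @return A `pupil_detection` with ellipse `shape`; score = number of
#'   points fitted.
#' @export
detect_lsfe <- function(points) {
  points <- as_points(points)
  if (nrow(points) < 5L)
    stop_pupiltrack("need at least 5 points for an ellipse fit", "fit_error")
  el <- fit_ellipse_lsq(points[, 1], points[, 2])
  if (is.null(el))
    stop_pupiltrack("degenerate point configuration: no ellipse fit",
                    "fit_error")
  new_detection(el$center, "LSFE",
                shape = list(a = el$a, b = el$b, tau = el$tau),
                score = nrow(points))
}

# Approximate point-to-ellipse distance, measured radially from the center.
ellipse_radial_distance <- function(points, el) {
  dx <- points[, 1] - el$center[1]; dy <- points[, 2] - el$center[2]
  u <- dx * cos(el$tau) + dy * sin(el$tau)
  v <- -dx * sin(el$tau) + dy * cos(el$tau)
  d <- sqrt(dx^2 + dy^2)
  s <- sqrt((u / el$a)^2 + (v / el$b)^2)
  dist <- abs(d - d / s)
  dist[d == 0] <- el$b
  dist
}

#' RANSAC ellipse-fitting pupil detector
#'
#' Repeatedly fits an ellipse to a random 5-point sample, counts the points
#' within `inlier_tol` of it, and keeps the largest consensus set; the
#' required iteration count shrinks adaptively as the observed inlier
#' fraction grows, and the search stops early once the consensus size has
#' remained constant for `patience` iterations. The final ellipse is refit
#' on the winning consensus set. Deterministic under a fixed seed.
#'
#' @param points n x 2 matrix or data frame of candidate contour points,
#'   n >= 5.
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @param max_iter Iteration cap.
#' @param inlier_tol Inlier distance tolerance in pixels.
#' @param patience Early-stop window (iterations with unchanged consensus).
#' @param confidence Target probability of sampling one all-inlier subset.
#' @return A `pupil_detection` with ellipse `shape`; score = inlier
#'   fraction; attribute `"inliers"` gives the consensus index set.
#' @export
detect_ransac <- function(points, seed = 1L, max_iter = 500L,
                          inlier_tol = 2, patience = 20L,
                          confidence = 0.99) {
  points <- as_points(points)
  n <- nrow(points)
  if (n < 5L)
    stop_pupiltrack("need at least 5 points", "fit_error")
  best_inl <- NULL; best_cnt <- -1L; stable <- 0L
  n_adapt <- max_iter
  with_seed(seed, {
    i <- 0L
    while (i < min(max_iter, n_adapt) && stable < patience) {
      i <- i + 1L
      idx <- sample.int(n, 5L)
      el <- fit_ellipse_lsq(points[idx, 1], points[idx, 2])
      if (is.null(el)) { stable <- stable + 1L; next }
      inl <- which(ellipse_radial_distance(points, el) <= inlier_tol)
      if (length(inl) > best_cnt) {
        best_cnt <- length(inl); best_inl <- inl; stable <- 0L
        w <- best_cnt / n
        if (w > 0 && w < 1)
          n_adapt <- min(max_iter,
                         ceiling(log(1 - confidence) / log(1 - w^5)))
        else if (w >= 1) n_adapt <- i
      } else stable <- stable + 1L
    }
  })
  if (is.null(best_inl) || best_cnt < 5L)
    stop_pupiltrack("no ellipse consensus found", "ransac_failure")
  el <- fit_ellipse_lsq(points[best_inl, 1], points[best_inl, 2])
  if (is.null(el))
    stop_pupiltrack("consensus refit failed", "ransac_failure")
  out <- new_detection(el$center, "RANSAC",
                       shape = list(a = el$a, b = el$b, tau = el$tau),
                       score = best_cnt / n)
  attr(out, "inliers") <- best_inl
  out
}

#' Contour pixels of a mask
#'
#' Object pixels with at least one 4-neighbor outside the object; feeds the
#' ellipse-fitting detectors.
#'
#' @param mask Logical mask.
#' @return Data frame `x`, `y` of boundary pixel coordinates.
#' @export
mask_contour <- function(mask) {
  assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[2:(h + 1), 2:(w + 1)] &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  mask_coords(mask & !inner)
}

#' Run the full pupil-detection pipeline on an eye image
#'
#' Shared front end followed by the chosen detector: median denoising,
#' quantitative thresholding (from `t0` or from a pupil-radius estimate),
#' binarization, then (for CENT/PROJ/LSFE/RANSAC) largest-component
#' selection and morphological reconstruction, or (for CHT/EHT, which
#' tolerate residual artifacts) reconstruction plus Laplacian-of-Gaussian
#' edge extraction.
#'
#' @param img Grayscale eye image.
#' @param method One of `"cent"`, `"proj"`, `"cht"`, `"eht"`, `"lsfe"`,
#'   `"ransac"` (case-insensitive).
#' @param config Named list of pipeline parameters: `r_pupil` (radius
#'   estimate driving the percentile, structuring element and Hough grids;
#'   default 25), `t0` (explicit percentile, overriding `r_pupil`),
#'   `t0_safety` (deflation factor applied to the radius-derived
#'   percentile, default 0.95: undershooting the pupil area only thins the
#'   mask, which reconstruction refills, while overshooting floods the
#'   mask with iris pixels), `denoise_window`, `se_radius`, `log_sigma`,
#'   `radii`, `a`, `b`, `tau`, `dims`, `seed`, `max_iter`, `inlier_tol`.
#' @return A `pupil_detection`.
#' @export
#' @examples
#' img <- render_eye_image(eye_scene(center = c(320, 240)))$image
#' detect(img, "cht")
detect <- function(img, method = c("cent", "proj", "cht", "eht", "lsfe",
                                   "ransac"),
                   config = list()) {
  method <- match.arg(tolower(method[1]),
                      c("cent", "proj", "cht", "eht", "lsfe", "ransac"))
  assert_gray_image(img)
  cfg <- utils::modifyList(
    list(r_pupil = 25, t0 = NULL, t0_safety = 0.95, denoise_window = 3L,
         se_radius = NULL, log_sigma = 2, radii = NULL, a = NULL, b = NULL,
         tau = NULL, dims = NULL, seed = 1L, max_iter = 500L,
         inlier_tol = 2),
    config)
  stage <- function(name, expr) {
    tryCatch(expr, pupiltrack_error = function(e) {
      e$message <- sprintf("[stage %s] %s", name, conditionMessage(e))
      stop(e)
    })
  }
  img <- stage("denoise", denoise(img, cfg$denoise_window))
  t0 <- if (is.null(cfg$t0))
    cfg$t0_safety * percentile_from_radius(cfg$r_pupil, ncol(img),
                                           nrow(img)) else cfg$t0
  T_ <- stage("threshold", quantitative_threshold(img, t0))
  if (isTRUE(attr(T_, "degenerate")))
    stop_pupiltrack("[stage threshold] degenerate histogram: no dark pupil",
                    "no_pupil")
  mask <- binarize(img, T_)
  se <- if (is.null(cfg$se_radius)) default_se_radius(cfg$r_pupil) else
    cfg$se_radius
  if (method %in% c("cent", "proj", "lsfe", "ransac")) {
    mask <- stage("largest_component", largest_component(mask))
    mask <- stage("reconstruct", reconstruct_pupil(mask, se))
    switch(method,
      cent = detect_cent(mask),
      proj = detect_proj(mask),
      lsfe = stage("lsfe", detect_lsfe(mask_contour(mask))),
      ransac = stage("ransac",
        detect_ransac(mask_contour(mask), seed = cfg$seed,
                      max_iter = cfg$max_iter,
                      inlier_tol = cfg$inlier_tol)))
  } else {
    mask <- stage("reconstruct", reconstruct_pupil(mask, se))
    edges <- stage("log_edges", log_edges(mask, cfg$log_sigma))
    r <- cfg$r_pupil
    if (method == "cht") {
      radii <- if (is.null(cfg$radii))
        seq(round(0.6 * r), round(1.4 * r), by = 2) else cfg$radii
      stage("cht", detect_cht(edges, hough_config(radii = radii)))
    } else {
      a <- if (is.null(cfg$a)) seq(round(0.6 * r), round(1.4 * r), by = 2)
        else cfg$a
      b <- if (is.null(cfg$b)) a else cfg$b
      tau <- if (is.null(cfg$tau)) 0 else cfg$tau
      dims <- if (is.null(cfg$dims)) {
        if (length(tau) > 1L || any(tau != 0)) 5L else 4L
      } else cfg$dims
      stage("eht", detect_eht(edges,
        hough_config(a = a, b = b, tau = tau, dims = dims)))
    }
  }
}
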