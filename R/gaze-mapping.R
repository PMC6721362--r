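#' Calibration target layout
#'
#' Nine on-screen calibration targets: M1 at the screen center (the fixation
#' used to estimate the pupil radius) followed by the remaining eight
#' quadrant centers of the 3x3 screen tiling, row-major.
#'
#' @param screen_width,screen_height Screen size in pixels.
#' @return Data frame `target`, `sx`, `sy`.
#' @export
calibration_targets <- function(screen_width = 1920, screen_height = 1080) {
  qc <- quadrant_centers(screen_width, screen_height)
  ctr <- c(screen_width / 2, screen_height / 2)
  is_ctr <- qc[, 1] == ctr[1] & qc[, 2] == ctr[2]
  ord <- c(which(is_ctr), which(!is_ctr))
  data.frame(target = paste0("M", 1:9),
             sx = qc[ord, 1], sy = qc[ord, 2], row.names = NULL)
}

biquad_design <- function(x, y) cbind(1, x, y, x * y, x^2, y^2)

#' Fit the biquadratic eye-to-screen mapping
#'
#' Least-squares fit, per screen axis, of the second-order polynomial in
#' the monomials \{1, x, y, xy, x^2, y^2\} that maps raw eye-image pupil
#' coordinates to screen coordinates. The nonlinear terms compensate the
#' nonlinearity of eye rotation so that the cursor moves linearly across
#' the screen. Nine well-spread calibration pairs determine the 12
#' coefficients with 3 residual degrees of freedom per axis.
#'
#' @param cal Data frame with columns `ex`, `ey` (eye coordinates) and
#'   `sx`, `sy` (screen targets); at least 6 non-degenerate rows.
#' @return A `biquadratic_map` with per-axis coefficient vectors and the
#'   maximum absolute residual at the calibration points.
#' @export
fit_biquadratic <- function(cal) {
  cal <- as.data.frame(cal)
  stopifnot(all(c("ex", "ey", "sx", "sy") %in% names(cal)))
  if (nrow(cal) < 6L)
    stop_pupiltrack("need at least 6 calibration pairs", "calibration_error")
  X <- biquad_design(cal$ex, cal$ey)
  qrX <- qr(X)
  if (qrX$rank < 6L)
    stop_pupiltrack("degenerate calibration geometry (rank-deficient design)",
                    "calibration_error")
  cx <- qr.coef(qrX, cal$sx)
  cy <- qr.coef(qrX, cal$sy)
  fit <- cbind(X %*% cx, X %*% cy)
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy),
                 residual = max(abs(fit - cbind(cal$sx, cal$sy))),
                 eye_range = cbind(range(cal$ex), range(cal$ey))),
            class = "biquadratic_map")
}

#' @export
print.biquadratic_map <- function(x, ...) {
  cat("<biquadratic_map> terms {1, x, y, xy, x^2, y^2}\n")
  m <- rbind(screen_x = x$cx, screen_y = x$cy)
  colnames(m) <- c("1", "x", "y", "xy", "x^2", "y^2")
  print(signif(m, 5))
  cat(sprintf("max residual at calibration points: %.3g px\n", x$residual))
  invisible(x)
}

#' Apply the forward eye-to-screen mapping
#'
#' @param map A `biquadratic_map`.
#' @param eye_point Length-2 vector or n x 2 matrix of eye coordinates.
#' @return Screen coordinates, same shape as the input.
#' @export
apply_map <- function(map, eye_point) {
  stopifnot(inherits(map, "biquadratic_map"))
  p <- if (is.matrix(eye_point)) eye_point else matrix(eye_point, ncol = 2)
  X <- biquad_design(p[, 1], p[, 2])
  out <- cbind(X %*% map$cx, X %*% map$cy)
  if (!is.matrix(eye_point)) as.numeric(out) else out
}

map_jacobian <- function(map, x, y) {
  matrix(c(map$cx[2] + map$cx[4] * y + 2 * map$cx[5] * x,
           map$cy[2] + map$cy[4] * y + 2 * map$cy[5] * x,
           map$cx[3] + map$cx[4] * x + 2 * map$cx[6] * y,
           map$cy[3] + map$cy[4] * x + 2 * map$cy[6] * y), 2, 2)
}

#' Invert the mapping at a screen point
#'
#' Solves the 2-D polynomial system numerically with a damped Newton
#' iteration, seeded at the inverse of the map's affine part (or at a
#' user-supplied guess). Used to pull quadrant centers back into the raw
#' eye image when computing the mapping rate.
#'
#' @param map A `biquadratic_map`.
#' @param screen_point Length-2 screen coordinates.
#' @param guess Optional starting eye coordinates.
#' @param tol Convergence tolerance in screen pixels.
#' @param max_iter Iteration cap; non-convergence raises an
#'   `inverse_failure` error (expected far outside the calibrated region).
#' @return Length-2 eye coordinates.
#' @export
invert_map <- function(map, screen_point, guess = NULL, tol = 1e-6,
                       max_iter = 100L) {
  stopifnot(inherits(map, "biquadratic_map"))
  if (is.null(guess)) {
    Aff <- matrix(c(map$cx[2], map$cy[2], map$cx[3], map$cy[3]), 2, 2)
    guess <- tryCatch(
      solve(Aff, screen_point - c(map$cx[1], map$cy[1])),
      error = function(e) colMeans(map$eye_range))
  }
  p <- as.numeric(guess)
  res <- apply_map(map, p) - screen_point
  for (i in seq_len(max_iter)) {
    if (max(abs(res)) < tol) return(p)
    J <- map_jacobian(map, p[1], p[2])
    step <- tryCatch(solve(J, res), error = function(e) NULL)
    if (is.null(step))
      stop_pupiltrack("singular Jacobian during map inversion",
                      "inverse_failure")
    lambda <- 1
    repeat {
      cand <- p - lambda * step
      cres <- apply_map(map, cand) - screen_point
      if (sum(cres^2) < sum(res^2) || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    p <- cand; res <- cres
  }
  if (max(abs(res)) < tol) return(p)
  stop_pupiltrack("map inversion did not converge", "inverse_failure")
}

# Lower threshold of a three-class Otsu split of the intensity histogram:
# maximizes between-class variance over (t1, t2) pairs; under the
# dark-pupil intensity ordering (pupil < iris < sclera/glint) the darkest
# class is the pupil.
otsu3_lower <- function(img) {
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  lev <- 0:255
  cw <- cumsum(p)            # class weight up to g
  cm <- cumsum(p * lev)      # class first moment up to g
  mu_tot <- cm[256]
  best <- -Inf; best_t1 <- NA_integer_
  for (t1 in 0:253) {
    w0 <- cw[t1 + 1]; m0 <- cm[t1 + 1]
    if (w0 <= 0) next
    t2 <- (t1 + 1):254
    w1 <- cw[t2 + 1] - w0; m1 <- cm[t2 + 1] - m0
    w2 <- 1 - w0 - w1; m2 <- mu_tot - m0 - m1
    ok <- w1 > 0 & w2 > 0
    if (!any(ok)) next
    v <- rep(-Inf, length(t2))
    v[ok] <- m0^2 / w0 + m1[ok]^2 / w1[ok] + m2[ok]^2 / w2[ok]
    j <- which.max(v)
    if (v[j] > best) { best <- v[j]; best_t1 <- t1 }
  }
  if (!is.finite(best))
    stop_pupiltrack("degenerate histogram: no pupil class", "no_pupil")
  best_t1
}

# Two-class Otsu threshold on a vector of intensities (NA if degenerate).
otsu2 <- function(vals) {
  counts <- tabulate(as.integer(vals) + 1L, nbins = 256L)
  p <- counts / sum(counts); lev <- 0:255
  cw <- cumsum(p); cm <- cumsum(p * lev); mu <- cm[256]
  w0 <- cw[1:255]; m0 <- cm[1:255]
  ok <- w0 > 0 & w0 < 1
  if (!any(ok)) return(NA_integer_)
  v <- rep(-Inf, 255)
  v[ok] <- (mu * w0[ok] - m0[ok])^2 / (w0[ok] * (1 - w0[ok]))
  which.max(v) - 1L
}

# Threshold isolating the darkest (pupil) intensity class. Starts from the
# lower three-class Otsu threshold; if the class below it is itself
# strongly bimodal (pupil and iris merged, which happens when the pupil is
# a very small fraction of the image), it is re-split. At most three
# refinement rounds.
darkest_class_threshold <- function(img) {
  t1 <- otsu3_lower(img)
  for (round in 1:3) {
    vals <- img[img <= t1]
    ts <- otsu2(vals)
    if (is.na(ts) || ts >= t1) break
    lo <- vals[vals <= ts]; hi <- vals[vals > ts]
    if (length(lo) < 9 || length(hi) < 9) break
    pooled_sd <- sqrt((sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) /
                        length(vals))
    if (mean(hi) - mean(lo) <= max(3 * pooled_sd, 2)) break
    t1 <- ts
  }
  t1
}

#' Estimate the pupil radius from a central-fixation image
#'
#' Calibration-stage radius estimation from the eye image captured while
#' the user fixates the central target M1. The estimate feeds
#' [percentile_from_radius()] for the adaptive binarization of all
#' subsequent frames, so it must be found without knowing the percentile in
#' advance. Two stages resolve that circularity:
#'
#' 1. *Initialization.* An Otsu split of the denoised histogram isolates
#'    the darkest intensity class, which under the dark-pupil model is the
#'    pupil; the equivalent radius (`sqrt(area / pi)`) of its reconstructed
#'    largest component gives the effective radius `r0`. Because the
#'    percentile of the binarization is an *area* fraction, `r0` is the
#'    quantity it needs even when the pupil is elliptical.
#' 2. *Circular Hough refinement.* The image is re-thresholded at the
#'    quantitative percentile a pupil of radius `r0` would occupy, and the
#'    accumulator peak of the circular Hough transform over a narrow
#'    radius grid around `r0` gives the final circle radius.
#'
#' @param img Grayscale eye image at the central fixation.
#' @param config List: `refine_span` (relative half-width of the
#'   refinement grid, default 0.3), `denoise_window`, `log_sigma`.
#' @return Estimated radius in pixels (attribute `"detection"` carries the
#'   full CHT result and `"effective_radius"` the area-equivalent radius
#'   `r0`, the preferred input to [percentile_from_radius()]).
#' @export
estimate_pupil_radius <- function(img, config = list()) {
  cfg <- utils::modifyList(list(refine_span = 0.3, denoise_window = 3L,
                                log_sigma = 2), config)
  assert_gray_image(img)
  dimg <- denoise(img, cfg$denoise_window)
  w <- ncol(dimg); h <- nrow(dimg)
  lc <- largest_component(binarize(dimg, darkest_class_threshold(dimg)))
  r_coarse <- sqrt(sum(lc) / pi)
  rec <- reconstruct_pupil(lc, default_se_radius(r_coarse))
  r0 <- sqrt(sum(rec) / pi)
  # deflated percentile: overshooting the pupil area floods the mask with
  # iris pixels, undershooting is repaired by the reconstruction
  T_ <- quantitative_threshold(dimg,
                               0.95 * percentile_from_radius(r0, w, h))
  mask <- reconstruct_pupil(largest_component(binarize(dimg, T_)),
                            default_se_radius(r0))
  edges <- log_edges(mask, cfg$log_sigma)
  radii <- seq(max(3, round((1 - cfg$refine_span) * r0)),
               round((1 + cfg$refine_span) * r0))
  det <- detect_cht(edges, hough_config(radii = radii))
  structure(det$shape$radius, detection = det, effective_radius = r0)
}

#' Mapping rate: calibration-quality indicator
#'
#' For each of the nine quadrant centers of the screen, the center is pulled
#' back into the raw eye image with [invert_map()], circles of radius
#' r = 1..10 px around that pre-image are sampled (64 angles) and mapped
#' forward, and each mapped shape is approximated by a circle whose radius
#' `R_i(r)` is the mean distance of the mapped samples from their centroid.
#' The per-quadrant mapping rate is `MR_i = mean_r(R_i(r) / r)`, the overall
#' mapping rate the mean of the `MR_i`, and the linearized model
#' `R(r) = MR * r` predicts the on-screen target size reachable for a given
#' raw-image pixel accuracy. Calibrations with `MR >= 16` degrade real-time
#' accuracy and are rejected.
#'
#' @param map A `biquadratic_map`.
#' @param screen_width,screen_height Scene-image (screen) size.
#' @param radii Raw-image circle radii (default 1:10 px).
#' @param n_angles Samples per circle.
#' @param accept_threshold Acceptance bound on MR (default 16).
#' @return A `mapping_rate_report`: `MR`, `MR_i` (per quadrant), matrix `R`
#'   (9 x length(radii)), `accept`, plus any per-quadrant inversion
#'   failures (skipped with a warning).
#' @export
compute_mapping_rate <- function(map, screen_width = 1920,
                                 screen_height = 1080, radii = 1:10,
                                 n_angles = 64L, accept_threshold = 16) {
  stopifnot(inherits(map, "biquadratic_map"))
  qc <- quadrant_centers(screen_width, screen_height)
  ang <- seq(0, 2 * pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  R <- matrix(NA_real_, 9, length(radii),
              dimnames = list(rownames(qc), paste0("r", radii)))
  failed <- character(0)
  for (i in 1:9) {
    eye0 <- tryCatch(invert_map(map, qc[i, ]),
                     pupiltrack_error = function(e) NULL)
    if (is.null(eye0)) { failed <- c(failed, rownames(qc)[i]); next }
    for (j in seq_along(radii)) {
      circ <- cbind(eye0[1] + radii[j] * cos(ang),
                    eye0[2] + radii[j] * sin(ang))
      mapped <- apply_map(map, circ)
      ctr <- colMeans(mapped)
      R[i, j] <- mean(sqrt((mapped[, 1] - ctr[1])^2 +
                           (mapped[, 2] - ctr[2])^2))
    }
  }
  if (length(failed) > 0)
    warning("map inversion failed in quadrant(s) ",
            paste(failed, collapse = ", "), "; MR computed over the rest")
  MR_i <- rowMeans(sweep(R, 2, radii, `/`))
  MR <- mean(MR_i, na.rm = TRUE)
  structure(list(MR = MR, MR_i = MR_i, R = R, radii = radii,
                 accept = MR < accept_threshold,
                 accept_threshold = accept_threshold, failed = failed),
            class = "mapping_rate_report")
}

#' @export
print.mapping_rate_report <- function(x, ...) {
  cat(sprintf("<mapping_rate_report> MR = %.3f (%s; threshold %g)\n",
              x$MR, if (x$accept) "accepted" else "rejected",
              x$accept_threshold))
  print(signif(x$MR_i, 4))
  invisible(x)
}

#' Serialize / deserialize a biquadratic map as JSON
#'
#' Twelve named coefficients (`x.*`, `y.*` over the six monomials).
#'
#' @param map A `biquadratic_map`.
#' @param path JSON file path.
#' @return `write_map_json` returns `path` invisibly; `read_map_json`
#'   returns a `biquadratic_map`.
#' @export
write_map_json <- function(map, path) {
  stopifnot(inherits(map, "biquadratic_map"))
  terms <- c("c", "x", "y", "xy", "x2", "y2")
  obj <- c(setNames(as.list(map$cx), paste0("x.", terms)),
           setNames(as.list(map$cy), paste0("y.", terms)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map_json
#' @export
read_map_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- c("c", "x", "y", "xy", "x2", "y2")
  structure(list(cx = as.numeric(obj[paste0("x.", terms)]),
                 cy = as.numeric(obj[paste0("y.", terms)]),
                 residual = NA_real_,
                 eye_range = cbind(c(0, 640), c(0, 480))),
            class = "biquadratic_map")
}
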