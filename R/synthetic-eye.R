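#' Describe a synthetic infrared eye scene
#'
#' Bundles the exact ground truth of one synthetic dark-pupil eye image:
#' pupil ellipse geometry, corneal-reflection glints, eyelid occlusion,
#' intensity levels and noise parameters. [render_eye_image()] rasterizes it.
#'
#' The intensity model follows the dark-pupil assumption of infrared
#' video-oculography: the pupil is the darkest region, surrounded by a
#' brighter iris disk on a sclera-level background, with glints as the
#' brightest spots.
#'
#' @param width,height Image size in pixels.
#' @param center Pupil center `c(x, y)`; subpixel values allowed.
#' @param axes Pupil ellipse semi-axes `c(a, b)` in pixels; for a circular
#'   pupil of radius r use `c(r, r)`.
#' @param angle Ellipse rotation tau in radians, counter-clockwise from the
#'   x axis.
#' @param glints Data frame with columns `x`, `y`, `radius`, `placement`
#'   (one of `"inside"`, `"on_edge"`), or `NULL`. See [glint()].
#' @param eyelid_coverage Fraction of the pupil's vertical extent occluded
#'   from the top by a horizontal band at sclera intensity, in `[0, 1)`.
#' @param levels Named 8-bit intensity levels
#'   `c(pupil=, iris=, sclera=, glint=)`; must satisfy
#'   pupil < iris < sclera < glint.
#' @param gaussian_sigma Additive Gaussian noise standard deviation
#'   (grey levels).
#' @param salt_pepper Fraction of pixels replaced by 0 or 255 (shot/line
#'   noise surrogate).
#' @param seed Integer seed controlling noise; identical seeds and
#'   parameters yield bit-identical images.
#' @return An object of class `eye_scene`.
#' @export
#' @examples
#' sc <- eye_scene(center = c(320, 240), axes = c(25, 25))
#' img <- render_eye_image(sc)$image
#' dim(img)
eye_scene <- function(width = 640, height = 480,
                      center = c(width / 2, height / 2),
                      axes = c(25, 25), angle = 0,
                      glints = NULL, eyelid_coverage = 0,
                      levels = c(pupil = 30, iris = 100, sclera = 180,
                                 glint = 250),
                      gaussian_sigma = 0, salt_pepper = 0, seed = 1L) {
  if (width <= 0 || height <= 0)
    stop_pupiltrack("image dimensions must be positive", "invalid_parameter")
  if (any(axes <= 0))
    stop_pupiltrack("pupil semi-axes must be positive", "invalid_parameter")
  if (eyelid_coverage < 0 || eyelid_coverage >= 1)
    stop_pupiltrack("eyelid_coverage must lie in [0, 1)", "invalid_parameter")
  lv <- levels[c("pupil", "iris", "sclera", "glint")]
  if (anyNA(lv) || !all(diff(lv) > 0))
    stop_pupiltrack("intensity levels must satisfy pupil < iris < sclera < glint",
                    "invalid_parameter")
  ext <- max(axes)
  if (eyelid_coverage == 0 &&
      (center[1] - ext < 0.5 || center[1] + ext > width + 0.5 ||
       center[2] - ext < 0.5 || center[2] + ext > height + 0.5))
    stop_pupiltrack("pupil ellipse must lie fully inside the image",
                    "invalid_parameter")
  if (!is.null(glints)) {
    glints <- as.data.frame(glints)
    stopifnot(all(c("x", "y", "radius", "placement") %in% names(glints)))
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 center = as.numeric(center), axes = as.numeric(axes),
                 angle = as.numeric(angle), glints = glints,
                 eyelid_coverage = eyelid_coverage, levels = lv,
                 gaussian_sigma = gaussian_sigma,
                 salt_pepper = salt_pepper, seed = as.integer(seed)),
            class = "eye_scene")
}

#' Specify a corneal-reflection glint
#'
#' Convenience constructor for the `glints` argument of [eye_scene()]. If
#' `x`/`y` are omitted the glint is placed from its `placement` tag relative
#' to the pupil at render time: `"inside"` halfway between center and
#' boundary along the major axis, `"on_edge"` centered on the boundary.
#'
#' @param radius Glint radius in pixels.
#' @param placement `"inside"` or `"on_edge"` (relative to the pupil).
#' @param x,y Explicit glint center, or `NA` to derive from `placement`.
#' @return One-row data frame usable as `glints`.
#' @export
glint <- function(radius = 4, placement = c("inside", "on_edge"),
                  x = NA_real_, y = NA_real_) {
  placement <- match.arg(placement)
  data.frame(x = x, y = y, radius = radius, placement = placement)
}

# Logical mask of the pupil ellipse on the pixel-center grid.
rasterize_ellipse <- function(width, height, center, axes, angle) {
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), times = width), height, width)
  dx <- xs - center[1]; dy <- ys - center[2]
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

resolve_glints <- function(scene) {
  g <- scene$glints
  if (is.null(g) || nrow(g) == 0L) return(g)
  for (k in seq_len(nrow(g))) {
    if (is.na(g$x[k]) || is.na(g$y[k])) {
      d <- if (g$placement[k] == "inside") scene$axes[1] / 2 else scene$axes[1]
      g$x[k] <- scene$center[1] + d * cos(scene$angle)
      g$y[k] <- scene$center[2] + d * sin(scene$angle)
    }
  }
  g
}

#' Render a synthetic eye image
#'
#' Rasterizes an [eye_scene()] with hard (non-anti-aliased) classification of
#' each pixel by its center: sclera background, iris disk, pupil ellipse,
#' glint disks, an optional eyelid band at sclera intensity, then seeded
#' Gaussian and salt-and-pepper noise.
#'
#' @param scene An `eye_scene`.
#' @return List with `image` (integer matrix, `height x width`, values
#'   0-255) and `truth` (the input scene with resolved glint positions, for
#'   bookkeeping).
#' @export
render_eye_image <- function(scene) {
  stopifnot(inherits(scene, "eye_scene"))
  w <- scene$width; h <- scene$height; lv <- scene$levels
  img <- matrix(as.numeric(lv["sclera"]), h, w)
  iris_r <- 2.5 * max(scene$axes)
  img[rasterize_ellipse(w, h, scene$center, c(iris_r, iris_r), 0)] <-
    lv["iris"]
  pupil <- rasterize_ellipse(w, h, scene$center, scene$axes, scene$angle)
  img[pupil] <- lv["pupil"]
  g <- resolve_glints(scene)
  if (!is.null(g) && nrow(g) > 0L)
    for (k in seq_len(nrow(g)))
      img[rasterize_ellipse(w, h, c(g$x[k], g$y[k]),
                            rep(g$radius[k], 2), 0)] <- lv["glint"]
  if (scene$eyelid_coverage > 0) {
    ys <- which(apply(pupil, 1, any))
    if (length(ys) > 0) {
      lid_to <- floor(min(ys) + scene$eyelid_coverage *
                        (max(ys) - min(ys)))
      if (lid_to >= 1) img[seq_len(min(lid_to, h)), ] <- lv["sclera"]
    }
  }
  img <- with_seed(scene$seed, {
    if (scene$gaussian_sigma > 0)
      img <- img + rnorm(length(img), 0, scene$gaussian_sigma)
    if (scene$salt_pepper > 0) {
      n_sp <- round(scene$salt_pepper * length(img))
      if (n_sp > 0) {
        idx <- sample.int(length(img), n_sp)
        img[idx] <- sample(c(0, 255), n_sp, replace = TRUE)
      }
    }
    img
  })
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), h, w)
  truth <- scene; truth$glints <- g
  list(image = img, truth = truth)
}

#' Generate a dataset of synthetic eye images
#'
#' Samples `n` scenes with parameters drawn independently and uniformly from
#' the supplied ranges (a length-2 numeric gives a range, a scalar is held
#' fixed) and renders each. Optionally writes PNG images plus a ground-truth
#' CSV with header `filename,cx,cy,a,b,tau`.
#'
#' @param n Number of images (>= 1).
#' @param ranges Named list overriding defaults; recognized entries:
#'   `width`, `height`, `center_x`, `center_y`, `radius` (semi-major axis a),
#'   `axis_ratio` (b/a), `tau`, `glint` (character vector of placements drawn
#'   uniformly, possibly including `"none"`), `glint_radius`,
#'   `eyelid_coverage`, `gaussian_sigma`, `salt_pepper`.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param dir Output directory for PNGs + `truth.csv`, or `NULL` to skip
#'   writing.
#' @return Invisibly, a list of `list(image, truth)` pairs with a
#'   `"truth_table"` attribute (the ground-truth data frame).
#' @export
generate_dataset <- function(n, ranges = list(), seed = 1L, dir = NULL) {
  if (length(n) != 1L || n < 1)
    stop_pupiltrack("n must be >= 1", "invalid_parameter")
  if (!is.list(ranges))
    stop_pupiltrack("ranges must be a list", "invalid_parameter")
  if (any(lengths(ranges) == 0L))
    stop_pupiltrack("empty parameter range", "invalid_parameter")
  def <- list(width = 640, height = 480, center_x = c(280, 360),
              center_y = c(200, 280), radius = c(15, 35), axis_ratio = 1,
              tau = 0, glint = "none", glint_radius = 4,
              eyelid_coverage = 0, gaussian_sigma = 0, salt_pepper = 0)
  unknown <- setdiff(names(ranges), names(def))
  if (length(unknown))
    stop_pupiltrack(paste("unknown parameter range:",
                          paste(unknown, collapse = ", ")),
                    "invalid_parameter")
  p <- utils::modifyList(def, ranges)
  draw <- function(v) if (length(v) == 2L && is.numeric(v))
    runif(1, v[1], v[2]) else if (length(v) > 1L) sample(v, 1L) else v
  out <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      a <- draw(p$radius); b <- a * draw(p$axis_ratio)
      gl_tag <- draw(p$glint)
      gl <- if (identical(gl_tag, "none")) NULL else
        glint(radius = draw(p$glint_radius), placement = gl_tag)
      sc <- eye_scene(width = p$width, height = p$height,
                      center = c(draw(p$center_x), draw(p$center_y)),
                      axes = c(a, b), angle = draw(p$tau), glints = gl,
                      eyelid_coverage = draw(p$eyelid_coverage),
                      gaussian_sigma = draw(p$gaussian_sigma),
                      salt_pepper = draw(p$salt_pepper),
                      seed = sample.int(.Machine$integer.max, 1L))
      render_eye_image(sc)
    })
  })
  tab <- do.call(rbind, lapply(seq_along(out), function(i) {
    tr <- out[[i]]$truth
    data.frame(filename = sprintf("eye_%04d.png", i),
               cx = tr$center[1], cy = tr$center[2],
               a = tr$axes[1], b = tr$axes[2], tau = tr$angle)
  }))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(out))
      write_eye_image(out[[i]]$image, file.path(dir, tab$filename[i]))
    write.csv(tab, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  attr(out, "truth_table") <- tab
  invisible(out)
}

#' Centers of the 3x3 quadrant tiling of a screen
#'
#' @param screen_width,screen_height Screen size in pixels.
#' @return 9x2 matrix of quadrant centers (columns `x`, `y`), row-major from
#'   the top-left quadrant.
#' @export
quadrant_centers <- function(screen_width = 1920, screen_height = 1080) {
  cx <- (c(1, 3, 5) / 6) * screen_width
  cy <- (c(1, 3, 5) / 6) * screen_height
  m <- cbind(x = rep(cx, times = 3), y = rep(cy, each = 3))
  rownames(m) <- paste0("Q", 1:9)
  m
}

#' Describe a cursor-trajectory testing scenario
#'
#' The scenario emulates the real-time test protocol: the cursor dwells in
#' each of the nine quadrant centers of the screen in turn, with Gaussian
#' jitter around the target and an optional fraction of outlier frames
#' scattered uniformly over the screen.
#'
#' @param screen_width,screen_height Screen size (full-HD default).
#' @param dwell_frames Frames spent per quadrant (>= 1).
#' @param jitter_sigma Isotropic Gaussian jitter (pixels).
#' @param outlier_rate Fraction of frames replaced by uniform screen points.
#' @param seed Integer seed.
#' @return Object of class `trajectory_scenario`.
#' @export
trajectory_scenario <- function(screen_width = 1920, screen_height = 1080,
                                dwell_frames = 100, jitter_sigma = 10,
                                outlier_rate = 0, seed = 1L) {
  if (dwell_frames < 1)
    stop_pupiltrack("dwell_frames must be >= 1", "invalid_parameter")
  if (outlier_rate < 0 || outlier_rate > 1)
    stop_pupiltrack("outlier_rate must lie in [0, 1]", "invalid_parameter")
  structure(list(screen_width = screen_width, screen_height = screen_height,
                 centers = quadrant_centers(screen_width, screen_height),
                 dwell_frames = as.integer(dwell_frames),
                 jitter_sigma = jitter_sigma, outlier_rate = outlier_rate,
                 seed = as.integer(seed)),
            class = "trajectory_scenario")
}

#' Generate a labeled cursor trajectory
#'
#' @param scenario A [trajectory_scenario()].
#' @return Data frame `frame, x, y, quadrant` with
#'   `9 * dwell_frames` rows; every point keeps the label of the quadrant
#'   being dwelt on, including outlier frames.
#' @export
generate_trajectory <- function(scenario) {
  stopifnot(inherits(scenario, "trajectory_scenario"))
  nq <- nrow(scenario$centers); df <- scenario$dwell_frames
  n <- nq * df
  with_seed(scenario$seed, {
    qlab <- rep(rownames(scenario$centers), each = df)
    x <- rep(scenario$centers[, "x"], each = df) + rnorm(n, 0, scenario$jitter_sigma)
    y <- rep(scenario$centers[, "y"], each = df) + rnorm(n, 0, scenario$jitter_sigma)
    if (scenario$outlier_rate > 0) {
      out <- runif(n) < scenario$outlier_rate
      x[out] <- runif(sum(out), 0, scenario$screen_width)
      y[out] <- runif(sum(out), 0, scenario$screen_height)
    }
    data.frame(frame = seq_len(n), x = x, y = y, quadrant = qlab)
  })
}

#' Read or write an 8-bit grayscale image (PNG or PGM)
#'
#' @param img Integer matrix (`height x width`, 0-255).
#' @param path File path; format chosen by extension (`.png` or `.pgm`).
#' @return `write_eye_image` returns `path` invisibly; `read_eye_image`
#'   returns an integer matrix.
#' @export
write_eye_image <- function(img, path) {
  assert_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(ncol(img), nrow(img)), "255"), con)
    writeBin(as.raw(as.integer(t(img))), con)
  } else {
    png::writePNG(img / 255, path)
  }
  invisible(path)
}

#' @rdname write_eye_image
#' @export
read_eye_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- character(0)
    while (length(hdr) < 4) {
      tok <- scan(con, what = character(), n = 1, quiet = TRUE,
                  comment.char = "#")
      hdr <- c(hdr, tok)
    }
    w <- as.integer(hdr[2]); h <- as.integer(hdr[3])
    vals <- as.integer(readBin(con, "raw", n = w * h))
    matrix(vals, h, w, byrow = TRUE)
  } else {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1]
    matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
  }
}
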