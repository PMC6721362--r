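#' Detection-rate curve for static eye images
#'
#' The pixel error of a detection is the Euclidean distance between the
#' detected and true pupil centers. `DR(e)` is the percentage of images
#' whose pixel error is strictly below `e`; `DR(5)` (detection rate at five
#' pixels) is the standard headline figure.
#'
#' @param errors Numeric vector of pixel errors (>= 1 value), or a data
#'   frame with columns `dx`/`dy` pairs `det_x, det_y, true_x, true_y`.
#' @param thresholds Error thresholds in pixels (default 1:10).
#' @return List: `curve` (data frame `threshold`, `dr`), `mean`, `sd`,
#'   `dr5` (when 5 is among the thresholds).
#' @export
detection_rate_curve <- function(errors, thresholds = 1:10) {
  if (is.data.frame(errors))
    errors <- sqrt((errors$det_x - errors$true_x)^2 +
                   (errors$det_y - errors$true_y)^2)
  if (length(errors) == 0L)
    stop_pupiltrack("no detection records", "invalid_parameter")
  if (any(errors < 0))
    stop_pupiltrack("pixel errors must be non-negative", "invalid_parameter")
  dr <- vapply(thresholds, function(e) 100 * mean(errors < e), numeric(1))
  out <- list(curve = data.frame(threshold = thresholds, dr = dr),
              mean = mean(errors), sd = stats::sd(errors))
  if (5 %in% thresholds) out$dr5 <- dr[match(5, thresholds)]
  out
}

scene_distances <- function(points, centers) {
  stopifnot(all(c("x", "y", "quadrant") %in% names(points)))
  if (anyNA(points$quadrant) ||
      !all(points$quadrant %in% rownames(centers)))
    stop_pupiltrack("every point must carry a known quadrant label",
                    "invalid_parameter")
  idx <- match(points$quadrant, rownames(centers))
  sqrt((points$x - centers[idx, 1])^2 + (points$y - centers[idx, 2])^2)
}

#' Scene-image detection rate
#'
#' Real-time accuracy metric: percentage of cursor points whose Euclidean
#' distance to the center of their quadrant's circular target is strictly
#' below the target radius, pooled over all quadrants with equal weight per
#' point.
#'
#' @param points Data frame `x`, `y`, `quadrant` (labels matching
#'   `rownames(centers)`).
#' @param centers Quadrant-center matrix, e.g. [quadrant_centers()].
#' @param target_radius Target radius in pixels (default 50).
#' @return List: `dr` (percent), `mean`, `sd` of the distances, `n`.
#' @export
scene_detection_rate <- function(points, centers = quadrant_centers(),
                                 target_radius = 50) {
  d <- scene_distances(points, centers)
  list(dr = 100 * mean(d < target_radius), mean = mean(d),
       sd = stats::sd(d), n = length(d))
}

#' Cluster detection and dispersion rates
#'
#' Cursor-stability metric: distances are measured to the per-quadrant
#' cluster center (the mean of that quadrant's points) rather than to the
#' target, so a constant calibration bias does not penalize the score.
#' `CDR` is the percentage of points within the radius of their cluster
#' center and `CDIR = 100 - CDR` the dispersion rate.
#'
#' @param points Data frame `x`, `y`, `quadrant`.
#' @param target_radius Radius in pixels (default 50).
#' @return List: `cdr`, `cdir` (percent), `mean`, `sd` of the cluster
#'   distances, per-quadrant cluster `centers`.
#' @export
cluster_metrics <- function(points, target_radius = 50) {
  stopifnot(all(c("x", "y", "quadrant") %in% names(points)))
  if (nrow(points) == 0L)
    stop_pupiltrack("no points", "invalid_parameter")
  qs <- unique(points$quadrant)
  ctr <- do.call(rbind, lapply(qs, function(q) {
    p <- points[points$quadrant == q, ]
    c(mean(p$x), mean(p$y))
  }))
  rownames(ctr) <- qs
  idx <- match(points$quadrant, qs)
  d_c <- sqrt((points$x - ctr[idx, 1])^2 + (points$y - ctr[idx, 2])^2)
  cdr <- 100 * mean(d_c < target_radius)
  list(cdr = cdr, cdir = 100 - cdr, mean = mean(d_c), sd = stats::sd(d_c),
       centers = ctr)
}

#' Stabilize a cursor signal
#'
#' Rolling-median spike canceller for the per-frame cursor coordinates:
#' samples deviating from the local median by more than `spike_threshold`
#' are replaced by that median, removing the high-frequency spikes produced
#' by occasional pupil mis-detections while preserving genuine gaze shifts
#' (a step persisting longer than half the window survives).
#'
#' @param xy n x 2 matrix or data frame with columns `x`, `y`.
#' @param window Odd median window length (default 5).
#' @param spike_threshold Deviation threshold in pixels (default 50).
#' @param causal If `TRUE`, use the median of the trailing `window` samples
#'   only (streaming variant); default is the centered window.
#' @return Matrix (or data frame, matching the input) of stabilized
#'   coordinates.
#' @export
stabilize_signal <- function(xy, window = 5L, spike_threshold = 50,
                             causal = FALSE) {
  if (window %% 2 == 0 || window < 1)
    stop_pupiltrack("window must be odd", "invalid_parameter")
  was_df <- is.data.frame(xy)
  m <- if (was_df) cbind(xy$x, xy$y) else as.matrix(xy)
  filt <- function(v) {
    if (length(v) < 2L || window == 1L) return(v)
    med <- if (causal) {
      vapply(seq_along(v), function(i)
        median(v[max(1L, i - window + 1L):i]), numeric(1))
    } else {
      k <- min(window, length(v) - (1 - length(v) %% 2))
      as.numeric(stats::runmed(v, k, endrule = "median"))
    }
    ifelse(abs(v - med) > spike_threshold, med, v)
  }
  out <- cbind(filt(m[, 1]), filt(m[, 2]))
  if (was_df) data.frame(x = out[, 1], y = out[, 2]) else out
}

#' Dwell-time target selection
#'
#' A selection event fires when the cursor has stayed inside one target's
#' selection area for at least `ceil(dwell_ms * frame_rate / 1000)`
#' consecutive frames; the dwell counter resets whenever the cursor leaves,
#' and a selected target cannot refire until the cursor exits it (the
#' guard against the Midas-touch problem). When targets overlap, the
#' containing target with the smallest index claims the frame.
#'
#' @param xy n x 2 matrix or data frame of cursor positions per frame.
#' @param targets Data frame `x`, `y`, `radius` (one row per target).
#' @param dwell_ms Dwell time in milliseconds (> 0; 1000 ms is a typical
#'   novice setting).
#' @param frame_rate Frames per second (> 0).
#' @return Data frame `frame`, `target` of selection events.
#' @export
dwell_select <- function(xy, targets, dwell_ms = 1000, frame_rate = 30) {
  if (dwell_ms <= 0 || frame_rate <= 0)
    stop_pupiltrack("dwell_ms and frame_rate must be positive",
                    "invalid_parameter")
  m <- if (is.data.frame(xy)) cbind(xy$x, xy$y) else as.matrix(xy)
  targets <- as.data.frame(targets)
  need <- as.integer(ceiling(dwell_ms * frame_rate / 1000))
  cur <- 0L; count <- 0L; locked <- FALSE
  ev_frame <- integer(0); ev_target <- integer(0)
  for (f in seq_len(nrow(m))) {
    d <- sqrt((targets$x - m[f, 1])^2 + (targets$y - m[f, 2])^2)
    inside <- which(d <= targets$radius)
    tgt <- if (length(inside) > 0L) inside[1] else 0L
    if (tgt != cur) { cur <- tgt; count <- 0L; locked <- FALSE }
    if (cur > 0L && !locked) {
      count <- count + 1L
      if (count >= need) {
        ev_frame <- c(ev_frame, f); ev_target <- c(ev_target, cur)
        locked <- TRUE
      }
    }
  }
  data.frame(frame = ev_frame, target = ev_target)
}

#' Gaze-typing error rates
#'
#' Text-entry error taxonomy over a typing session: with `C` correct
#' inputs, `IF` errors made and corrected, and `INF` errors left
#' uncorrected,
#' \deqn{TER = 100 (INF + IF) / (C + INF + IF)}
#' \deqn{NCER = 100\, INF / (C + INF + IF)}
#' \deqn{CER = 100\, IF / (C + INF + IF)}
#' so that `TER = NCER + CER` exactly.
#'
#' @param C,IF,INF Non-negative counts with `C + IF + INF > 0`; or pass a
#'   single list/data-frame row with those fields as `C`.
#' @return Named numeric vector `c(TER, NCER, CER)` in percent.
#' @export
#' @examples
#' typing_error_rates(C = 116, IF = 14, INF = 5)
typing_error_rates <- function(C, IF = NULL, INF = NULL) {
  if (is.list(C)) { IF <- C$IF; INF <- C$INF; C <- C$C }
  counts <- c(C = C, IF = IF, INF = INF)
  if (anyNA(counts) || any(counts < 0))
    stop_pupiltrack("counts must be non-negative", "invalid_parameter")
  denom <- C + INF + IF
  if (denom <= 0)
    stop_pupiltrack("C + INF + IF must be positive", "invalid_parameter")
  c(TER = 100 * (INF + IF) / denom,
    NCER = 100 * INF / denom,
    CER = 100 * IF / denom)
}
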