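# Independent oracles used across the suite. These deliberately take the
# slow, obvious route (nested loops, linear scans, direct arithmetic) so
# they share no code path with the package implementation.

# Same boundary predicate as the accumulator, written out directly.
oracle_on_boundary <- function(dx, dy, a, b, tau, tol) {
  if (a == b) {
    dd <- dx * dx + dy * dy
    if (dd == 0) return(FALSE)
    lo <- if (a > tol) (a - tol) * (a - tol) else 0
    return(dd >= lo && dd <= (a + tol) * (a + tol))
  }
  d <- sqrt(dx * dx + dy * dy)
  if (d == 0) return(FALSE)
  u <- dx * cos(tau) + dy * sin(tau)
  v <- -dx * sin(tau) + dy * cos(tau)
  s <- sqrt((u / a)^2 + (v / b)^2)
  abs(d - d / s) <= tol
}

# Count of edge pixels on the boundary, same predicate vectorized over
# offsets.
oracle_boundary_count <- function(dx, dy, a, b, tau, tol) {
  if (a == b) {
    dd <- dx * dx + dy * dy
    lo <- if (a > tol) (a - tol) * (a - tol) else 0
    return(sum(dd != 0 & dd >= lo & dd <= (a + tol) * (a + tol)))
  }
  d <- sqrt(dx * dx + dy * dy)
  u <- dx * cos(tau) + dy * sin(tau)
  v <- -dx * sin(tau) + dy * cos(tau)
  s <- sqrt((u / a)^2 + (v / b)^2)
  sum(d > 0 & abs(d - d / s) <= tol)
}

# Brute-force nested-loop Hough accumulator: for every (a, b, tau) triplet
# and every candidate center, count the edge pixels lying on that boundary.
oracle_hough_peak <- function(edges, a, b, tau, tol = 1) {
  pc <- which(edges, arr.ind = TRUE)  # (row = y, col = x)
  ey <- pc[, 1]; ex <- pc[, 2]
  h <- nrow(edges); w <- ncol(edges)
  best <- list(votes = -1L, cx = 0L, cy = 0L, triplet = 0L)
  for (t in seq_along(a)) {
    for (cy in seq_len(h)) for (cx in seq_len(w)) {
      v <- oracle_boundary_count(ex - cx, ey - cy, a[t], b[t], tau[t], tol)
      if (v > best$votes ||
          (v == best$votes && (cy < best$cy ||
                               (cy == best$cy && cx < best$cx)))) {
        best <- list(votes = v, cx = cx, cy = cy, triplet = t)
      }
    }
  }
  best
}

# Flood-fill component labelling by breadth-first search, 8-connectivity.
oracle_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = TRUE]; queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  lab
}

# Minimal grey level whose cumulative fraction reaches t0, by scanning all
# 256 thresholds.
oracle_threshold <- function(img, t0) {
  n <- length(img)
  for (g in 0:255)
    if (100 * sum(img <= g) / n >= t0) return(g)
  NA_integer_
}

# Points sampled exactly on an ellipse.
ellipse_points <- function(n, center, a, b, tau) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  u <- a * cos(th); v <- b * sin(th)
  cbind(x = center[1] + u * cos(tau) - v * sin(tau),
        y = center[2] + u * sin(tau) + v * cos(tau))
}

# One standard noisy test eye with known truth.
make_test_eye <- function(r = 25, center = c(320, 240), sigma = 8,
                          glint_placement = "inside", seed = 1) {
  sc <- eye_scene(center = center, axes = c(r, r), gaussian_sigma = sigma,
                  glints = if (is.null(glint_placement)) NULL else
                    glint(4, glint_placement),
                  seed = seed)
  render_eye_image(sc)
}
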