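# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive results by the most literal method available
# and share no code with the package internals they check.

# even-odd point-in-polygon with an explicit on-boundary test
oracle_point_in_polygon <- function(px, py, xs, ys, eps = 1e-9) {
  n <- length(xs)
  on_edge <- FALSE
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    # on-segment check
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cross) < eps &&
        px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
        py >= min(y1, y2) - eps && py <= max(y1, y2) + eps)
      on_edge <- TRUE
    # even-odd ray crossing (ray toward +x)
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside || on_edge
}

# rasterize by testing every pixel center with the oracle
oracle_rasterize <- function(pts, height, width) {
  m <- matrix(FALSE, height, width)
  for (r in seq_len(height)) for (c in seq_len(width))
    m[r, c] <- oracle_point_in_polygon(c - 1, r - 1, pts[, 1], pts[, 2])
  m
}

# boundary pixels by literal 4-neighbor counting
oracle_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- NULL
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    nb <- c(if (r > 1) mask[r - 1, c] else FALSE,
            if (r < h) mask[r + 1, c] else FALSE,
            if (c > 1) mask[r, c - 1] else FALSE,
            if (c < w) mask[r, c + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(c - 1, r - 1))
  }
  out
}

# symmetric Hausdorff by an O(n * m) double loop over boundary pixels
oracle_hausdorff <- function(mask_a, mask_b) {
  a <- oracle_boundary(mask_a); b <- oracle_boundary(mask_b)
  directed <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- min(sqrt((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2))
      worst <- max(worst, best)
    }
    worst
  }
  max(directed(a, b), directed(b, a))
}

# long-axis angle from vertical via central second moments (sign: positive
# when the top of the shape leans toward +x)
oracle_principal_axis_angle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  phi <- 0.5 * atan2(-2 * mu11, mu20 - mu02)
  ang <- 90 - phi * 180 / pi
  ((ang + 90) %% 180) - 90
}

# random simple (convex) test polygon with area >= min_area
random_convex_polygon <- function(n_vertices, radius, center, min_area = 100) {
  repeat {
    ang <- sort(runif(n_vertices, 0, 2 * pi))
    r <- runif(n_vertices, 0.5, 1) * radius
    pts <- cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
    area <- abs(pracma::polyarea(pts[, 1], pts[, 2]))
    if (area >= min_area) return(pts)
  }
}

# random small blob mask (union of a few rectangles), never empty
random_blob_mask <- function(h, w) {
  m <- matrix(FALSE, h, w)
  for (k in seq_len(sample(1:3, 1))) {
    r0 <- sample(1:(h - 2), 1); c0 <- sample(1:(w - 2), 1)
    r1 <- min(h, r0 + sample(1:6, 1)); c1 <- min(w, c0 + sample(1:6, 1))
    m[r0:r1, c0:c1] <- TRUE
  }
  m
}
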