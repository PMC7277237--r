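#' Parametric molar silhouette
#'
#' Shape parameters of the synthetic molar phantom: a tapering trapezoid
#' crown (wider than the cervix), a rectangular cervix with near-vertical
#' parallel walls, and 0-2 tapering root prongs.  `n_roots = 0` encodes a
#' follicle without root formation (development stages A-D).
#'
#' @param crown_width,crown_height,cervix_width,cervix_height,root_length
#'   lengths in px; `crown_width > cervix_width > 0` required.
#' @param n_roots 0, 1 or 2.
#' @param root_spread horizontal distance between the two root tips (px).
#' @param asymmetry mesial/distal taper imbalance in `[-0.3, 0.3]`; 0 gives
#'   a mirror-symmetric silhouette.
#' @return list of class `molar_shape_params`.
#' @export
molar_shape_params <- function(crown_width = 44, crown_height = 18,
                               cervix_width = 30, cervix_height = 42,
                               root_length = 30, n_roots = 2,
                               root_spread = 16, asymmetry = 0) {
  lens <- c(crown_width, crown_height, cervix_width, cervix_height, root_length)
  if (any(lens <= 0)) stop("all lengths must be > 0")
  if (crown_width <= cervix_width)
    stop("crown_width must exceed cervix_width")
  if (!n_roots %in% 0:2) stop("n_roots must be 0, 1 or 2")
  if (abs(asymmetry) > 0.3) stop("asymmetry must lie in [-0.3, 0.3]")
  if (n_roots == 2 && root_spread >= cervix_width)
    stop("root_spread must be smaller than cervix_width")
  structure(list(crown_width = crown_width, crown_height = crown_height,
                 cervix_width = cervix_width, cervix_height = cervix_height,
                 root_length = root_length, n_roots = as.integer(n_roots),
                 root_spread = root_spread, asymmetry = asymmetry),
            class = "molar_shape_params")
}

#' Boundary-noise parameters for phantom generation
#'
#' @param vertex_jitter_sd Gaussian jitter of polygon vertices, px.
#' @param dropout_prob probability of dropping each vertex.
#' @param seed RNG seed; the same seed reproduces the same phantom.
#' @return list of class `noise_params`.
#' @export
noise_params <- function(vertex_jitter_sd = 0, dropout_prob = 0, seed = 1L) {
  if (vertex_jitter_sd < 0) stop("vertex_jitter_sd must be >= 0")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must lie in [0, 1)")
  structure(list(vertex_jitter_sd = vertex_jitter_sd,
                 dropout_prob = dropout_prob, seed = as.integer(seed)),
            class = "noise_params")
}

#' Upright molar polygon from shape parameters
#'
#' Builds the silhouette with the occlusal edge at the top (y = 0), roots
#' at the bottom, centered on x = 0.  With `asymmetry = 0` the polygon is
#' mirror-symmetric about its vertical centerline.  Vertices run clockwise
#' in image coordinates starting at the occlusal-left corner.  The side
#' walls are densified (several vertices per edge) so that vertex jitter
#' acts like boundary noise rather than gross shape distortion.
#'
#' @param params a [molar_shape_params()].
#' @return n x 2 matrix of `(x, y)` vertices.
#' @export
make_molar_polygon <- function(params) {
  if (!inherits(params, "molar_shape_params"))
    params <- do.call(molar_shape_params, params)
  a <- params$asymmetry
  cw2 <- params$crown_width / 2
  hw <- params$cervix_width / 2
  y_crown <- params$crown_height
  y_cervix <- y_crown + params$cervix_height
  xl_top <- -cw2 * (1 + a)
  xr_top <- cw2 * (1 - a)
  # interpolate k points along segment p->q, excluding p, including q
  seg <- function(p, q, k = 4) {
    t <- seq_len(k) / k
    cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))
  }
  top_l <- c(xl_top, 0); top_r <- c(xr_top, 0)
  cerv_tr <- c(hw, y_crown); cerv_br <- c(hw, y_cervix)
  cerv_tl <- c(-hw, y_crown); cerv_bl <- c(-hw, y_cervix)
  pts <- rbind(top_l, seg(top_l, top_r, 4))              # occlusal edge
  pts <- rbind(pts, seg(top_r, cerv_tr, 4))              # right crown taper
  pts <- rbind(pts, seg(cerv_tr, cerv_br, 5))            # right cervix wall
  y_tip <- y_cervix + params$root_length
  if (params$n_roots == 0) {
    pts <- rbind(pts, seg(cerv_br, cerv_bl, 3))          # flat follicle base
  } else if (params$n_roots == 1) {
    tip <- c(0, y_tip)
    pts <- rbind(pts, seg(cerv_br, tip, 3), seg(tip, cerv_bl, 3))
  } else {
    s2 <- params$root_spread / 2
    notch <- c(0, y_cervix + 0.25 * params$root_length)
    tip_r <- c(s2, y_tip); tip_l <- c(-s2, y_tip)
    root_hw <- min(2, (hw - s2) / 2)                     # half-width of a prong tip base
    pts <- rbind(pts,
                 seg(cerv_br, c(s2 + root_hw, y_cervix + 0.3 * params$root_length), 2),
                 seg(c(s2 + root_hw, y_cervix + 0.3 * params$root_length), tip_r, 2),
                 seg(tip_r, notch, 3),
                 seg(notch, tip_l, 3),
                 seg(tip_l, c(-s2 - root_hw, y_cervix + 0.3 * params$root_length), 2),
                 seg(c(-s2 - root_hw, y_cervix + 0.3 * params$root_length), cerv_bl, 2))
  }
  pts <- rbind(pts, seg(cerv_bl, cerv_tl, 5))            # left cervix wall
  pts <- rbind(pts, seg(cerv_tl, top_l, 4))              # left crown taper
  pts <- pts[!duplicated(round(pts, 9)), , drop = FALSE]
  colnames(pts) <- c("x", "y")
  pts
}

polygon_centroid <- function(pts) {
  n <- nrow(pts)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  cr <- x * yn - xn * y
  area <- sum(cr) / 2
  c(x = sum((x + xn) * cr) / (6 * area),
    y = sum((y + yn) * cr) / (6 * area))
}

#' Generate a single molar phantom at a known angle
#'
#' The upright polygon is translated to `center`, rotated by
#' `true_angle_deg` about its centroid (positive = occlusal end toward +x),
#' optionally jittered, and rasterized.
#'
#' @param params a [molar_shape_params()].
#' @param true_angle_deg signed ground-truth angle, `|angle| < 90`.
#' @param noise a [noise_params()].
#' @param canvas `c(height, width)` in px.
#' @param center `(x, y)` placement of the shape centroid; default canvas
#'   center.
#' @param fdi FDI code for the generated instance (default 38).
#' @param image_id id stored on the instance.
#' @return list of class `phantom_record`: `instance` ([tooth_instance()]),
#'   `true_angle_deg`, `params`, `polygon` (the rasterized, possibly
#'   jittered polygon).
#' @export
make_phantom <- function(params, true_angle_deg,
                         noise = noise_params(),
                         canvas = c(160, 160),
                         center = NULL, fdi = 38L, image_id = "phantom") {
  if (!inherits(params, "molar_shape_params"))
    params <- do.call(molar_shape_params, params)
  if (abs(true_angle_deg) >= 90) stop("|true_angle_deg| must be < 90")
  poly <- make_molar_polygon(params)
  cen <- polygon_centroid(poly)
  if (is.null(center)) center <- c((canvas[2] - 1) / 2, (canvas[1] - 1) / 2)
  # ground-truth landmarks in the upright shape frame: occlusal-edge
  # midpoint and a pulp-floor point on the cervix centerline; they travel
  # with the shape and emulate the learned landmark estimates that seed
  # the orientation on real radiographs
  lms <- rbind(
    occ = c(-params$crown_width / 2 * params$asymmetry, 0),
    pulp = c(0, params$crown_height + 0.25 * params$cervix_height))
  shift <- function(m) cbind(m[, 1] - cen["x"] + center[1],
                             m[, 2] - cen["y"] + center[2])
  poly <- shift(poly)
  lms <- shift(lms)
  poly <- rotate_points(poly, true_angle_deg, center)
  lms <- rotate_points(lms, true_angle_deg, center)
  if (noise$vertex_jitter_sd > 0 || noise$dropout_prob > 0) {
    poly <- with_seed(noise$seed, {
      keep <- runif(nrow(poly)) >= noise$dropout_prob
      if (sum(keep) < 3) keep[] <- TRUE
      p <- poly[keep, , drop = FALSE]
      p + matrix(rnorm(length(p), 0, noise$vertex_jitter_sd),
                 nrow(p), 2)
    })
  }
  if (any(poly[, 1] < 0 | poly[, 1] > canvas[2] - 1 |
          poly[, 2] < 0 | poly[, 2] > canvas[1] - 1))
    stop("canvas error: rotated shape does not fit the canvas")
  mask <- tryCatch(polygon_to_mask(poly, canvas[1], canvas[2]),
                   error = function(e) {
                     # jitter can occasionally self-intersect the outline;
                     # fall back to the convex hull of the jittered points
                     hull <- grDevices::chull(poly)
                     polygon_to_mask(poly[hull, , drop = FALSE],
                                     canvas[1], canvas[2])
                   })
  structure(list(instance = tooth_instance(fdi, mask,
                                           landmarks = landmark_pair(lms[1, ], lms[2, ]),
                                           source_image_id = image_id),
                 true_angle_deg = true_angle_deg,
                 params = params, polygon = poly),
            class = "phantom_record")
}

#' Per-position angle model (magnitude mean and SD, degrees)
#'
#' Defaults reproduce the reported per-position angulation distributions of
#' mandibular molars on panoramic radiographs: M1 16.7 +/- 5.2, M2
#' 19.4 +/- 6.8, M3 44.8 +/- 11.2 degrees.
#'
#' @return data.frame with columns `position`, `mean`, `sd`.
#' @export
default_angle_model <- function() {
  data.frame(position = c("M1", "M2", "M3"),
             mean = c(16.7, 19.4, 44.8),
             sd = c(5.2, 6.8, 11.2))
}

# magnitudes drawn per position from the angle model, truncated to [0, 90)
sample_angle_magnitudes <- function(positions, angle_model = default_angle_model()) {
  mu <- angle_model$mean[match(positions, angle_model$position)]
  s <- angle_model$sd[match(positions, angle_model$position)]
  if (anyNA(mu)) stop("angle model missing position(s): ",
                      paste(setdiff(positions, angle_model$position), collapse = ", "))
  out <- rnorm(length(mu), mu, s)
  while (any(bad <- out < 0 | out >= 90))
    out[bad] <- rnorm(sum(bad), mu[bad], s[bad])
  out
}

demirjian_letters <- LETTERS[1:8]

# morphology knobs per shortened development stage class
stage_to_morphology <- function(letter) {
  cls <- shorten_demirjian(letter)
  switch(cls,
         no_roots = list(n_roots = 0L, root_length_scale = 1),   # length unused
         bifurcation = list(n_roots = 2L, root_length_scale = 0.45),
         developed_roots = list(n_roots = 2L, root_length_scale = 1))
}

#' Sample a six-tooth phantom scene
#'
#' Places the six mandibular molars (M1-M3, both sides) along a shallow
#' arch.  Per-position angle magnitudes are drawn from `angle_model`
#' (truncated to `[0, 90)`); signs follow the side convention (left-side
#' teeth positive, i.e. occlusal end toward +x).  Third molars get a random
#' development stage which sets their root morphology; first and second
#' molars are fully developed (stage H).
#'
#' @param rng_seed integer seed; the same seed reproduces the same scene.
#' @param angle_model data.frame as [default_angle_model()].
#' @param canvas `c(height, width)`; default `c(420, 1220)`.
#' @param noise a [noise_params()] applied per tooth (its `seed` field is
#'   re-derived from `rng_seed`).
#' @param image_id scene id; default derived from the seed.
#' @param stage_probs probabilities of the M3 stage classes
#'   (A-D follicle, E bifurcation, F-H developed), in that order.
#' @param max_retries placement retries per tooth before a placement error.
#' @return list with `scene` (a [molar_scene()]) and `records` (list of
#'   `phantom_record`, one per tooth, each carrying `stage` as attribute).
#' @export
sample_scene <- function(rng_seed,
                         angle_model = default_angle_model(),
                         canvas = c(420, 1220),
                         noise = noise_params(),
                         image_id = NULL,
                         stage_probs = c(0.15, 0.25, 0.60),
                         max_retries = 10L) {
  if (is.null(image_id)) image_id <- sprintf("scene_%06d", rng_seed)
  with_seed(rng_seed, {
    fdis <- c(46L, 47L, 48L, 38L, 37L, 36L)
    # shallow arch: molars more posterior (toward image edge) sit higher
    xc <- c(170, 350, 530, 690, 870, 1050)
    yc <- c(195, 210, 220, 220, 210, 195)
    positions <- vapply(fdis, function(f) tooth_label(f)$position, "")
    sides <- vapply(fdis, function(f) tooth_label(f)$side, "")
    mags <- sample_angle_magnitudes(positions, angle_model)
    signs <- ifelse(sides == "left", 1, -1)
    stages <- vapply(positions, function(p) {
      if (p != "M3") return("H")
      cls <- sample.int(3, 1, prob = stage_probs)
      switch(cls, sample(LETTERS[1:4], 1), "E", sample(LETTERS[6:8], 1))
    }, "")
    records <- vector("list", 6)
    occupied <- list()
    for (i in seq_along(fdis)) {
      morph <- stage_to_morphology(stages[i])
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        params <- molar_shape_params(
          crown_width = runif(1, 41, 47),
          crown_height = runif(1, 16, 20),
          cervix_width = runif(1, 28, 33),
          cervix_height = runif(1, 39, 45),
          root_length = max(6, runif(1, 27, 33) * morph$root_length_scale),
          n_roots = morph$n_roots,
          root_spread = runif(1, 14, 18),
          asymmetry = runif(1, -0.15, 0.15))
        tooth_noise <- noise_params(noise$vertex_jitter_sd, noise$dropout_prob,
                                    seed = (rng_seed * 7L + i * 101L + try) %% .Machine$integer.max)
        rec <- tryCatch(
          make_phantom(params, signs[i] * mags[i], tooth_noise, canvas,
                       center = c(xc[i], yc[i]), fdi = fdis[i],
                       image_id = image_id),
          error = identity)
        if (inherits(rec, "error")) next
        bb <- apply(rec$polygon, 2, range)
        clash <- any(vapply(occupied, function(o)
          bb[1, 1] <= o[2, 1] && bb[2, 1] >= o[1, 1] &&
          bb[1, 2] <= o[2, 2] && bb[2, 2] >= o[1, 2], logical(1)))
        if (!clash) { ok <- TRUE; break }
        mags[i] <- sample_angle_magnitudes(positions[i], angle_model)
      }
      if (!ok) stop("placement error: could not place FDI ", fdis[i],
                    " without overlap")
      occupied[[length(occupied) + 1]] <- bb
      attr(rec, "stage") <- stages[i]
      records[[i]] <- rec
    }
    scene <- molar_scene(image_id, lapply(records, `[[`, "instance"),
                         canvas[1], canvas[2])
    list(scene = scene, records = records)
  })
}

#' Ground-truth table of a sampled scene
#'
#' @param sampled result of [sample_scene()].
#' @return data.frame with image_id, fdi, position, side, true_angle_deg,
#'   stage.
#' @export
phantom_truth_table <- function(sampled) {
  do.call(rbind, lapply(sampled$records, function(r) {
    lab <- r$instance$label
    data.frame(image_id = r$instance$source_image_id, fdi = lab$fdi_code,
               position = lab$position, side = lab$side,
               true_angle_deg = r$true_angle_deg,
               stage = attr(r, "stage") %||% NA_character_)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
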