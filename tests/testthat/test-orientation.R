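test_that("upright rotation matches rotation-matrix arithmetic and is invertible", {
  seg <- rbind(c(0, 0), c(10, 0))
  # identity at angle 0
  expect_equal(to_upright(seg, 0, c(0, 0)), seg, ignore_attr = TRUE)
  # frozen example: rotate by -90 about the origin maps (10,0) to (0,10)
  got <- to_upright(seg, -90, c(0, 0))
  expect_equal(unname(got[2, ]), c(0, 10), tolerance = 1e-9)
  # inverse composition
  set.seed(11)
  pts <- cbind(runif(20, -50, 50), runif(20, -50, 50))
  for (th in c(-73, -12, 31, 88)) {
    back <- to_upright(to_upright(pts, th, c(3, -4)), -th, c(3, -4))
    expect_equal(back, pts, tolerance = 1e-9, ignore_attr = TRUE)
  }
  # rigid: lengths preserved
  rot <- to_upright(pts, 37, c(0, 0))
  expect_equal(dist(rot), dist(pts), tolerance = 1e-9, ignore_attr = TRUE)
  # a shape whose axis is at theta becomes vertical
  axis_pts <- rbind(c(0, 0), c(sin(pi / 6) * 10, -cos(pi / 6) * 10))
  up <- to_upright(axis_pts, 30, c(0, 0))
  expect_equal(unname(up[2, 1]), 0, tolerance = 1e-9)
  expect_lt(up[2, 2], 0)
})

test_that("censoring keeps the stated fraction of the vertical extent", {
  set.seed(5)
  pts <- cbind(runif(300, 0, 40), runif(300, 0, 100))
  pts[1, 2] <- 0; pts[2, 2] <- 100          # pin the extent
  kept <- censor_band(pts, orientation_config())
  expect_true(all(kept[, 2] >= 15 - 1e-12 & kept[, 2] <= 55 + 1e-12))
  expect_true(any(kept[, 2] < 16) && any(kept[, 2] > 54))

  # full band is the identity
  all_kept <- censor_band(pts, orientation_config(band_top_frac = 0,
                                                  band_bottom_frac = 1))
  expect_equal(nrow(all_kept), nrow(pts))

  # too few retained rows errors
  flat <- cbind(runif(20, 0, 10), rep(c(0, 1, 2, 3, 4), each = 4))
  expect_error(censor_band(flat, orientation_config(min_band_rows = 8)),
               "censor error")
})

test_that("side splitting takes row-wise extremes", {
  # axis-aligned rectangle contour
  rect <- rbind(cbind(0, 0:20), cbind(19, 0:20), cbind(1:18, 0), cbind(1:18, 20))
  s <- split_sides(rect)
  expect_true(all(s$left[s$left[, 2] %in% 1:19, 1] == 0))
  expect_true(all(s$right[s$right[, 2] %in% 1:19, 1] == 19))

  # trapezoid walls with slope +/-0.1 are recovered by the side fits
  y <- seq(0, 40, by = 0.5)
  trap <- rbind(cbind(10 - 0.1 * y, y), cbind(30 + 0.1 * y, y))
  st <- split_sides(trap)
  expect_equal(fit_side_line(st$left)$slope_dx_dy, -0.1, tolerance = 1e-6)
  expect_equal(fit_side_line(st$right)$slope_dx_dy, 0.1, tolerance = 1e-6)

  expect_error(split_sides(cbind(1:5, rep(2, 5))), "split error")
})

test_that("side-line regression is exact least squares of x on y", {
  fit <- fit_side_line(rbind(c(5, 0), c(6, 10), c(7, 20)))
  expect_equal(fit$slope_dx_dy, 0.1, tolerance = 1e-12)
  expect_equal(fit$angle_deg, 5.7106, tolerance = 1e-4)
  expect_equal(fit$intercept_x, 5, tolerance = 1e-12)
  expect_equal(fit$n_points, 3L)

  vert <- fit_side_line(rbind(c(5, 0), c(5, 10), c(5, 20)))
  expect_equal(vert$slope_dx_dy, 0)
  expect_equal(vert$angle_deg, 0)

  expect_error(fit_side_line(rbind(c(5, 0), c(7, 0))), "fit error")

  # agrees with lm() on noisy chains
  set.seed(8)
  y <- runif(30, 0, 50); x <- 12 + 0.07 * y + rnorm(30, 0, 0.3)
  fit2 <- fit_side_line(cbind(x, y))
  ref <- unname(coef(lm(x ~ y)))
  expect_equal(c(fit2$intercept_x, fit2$slope_dx_dy), ref, tolerance = 1e-9)
})

test_that("a symmetric upright phantom refines to zero angle", {
  rec <- make_phantom(molar_shape_params(asymmetry = 0), 0,
                      canvas = c(160, 160))
  # seed deliberately off at 3 degrees
  inst <- tooth_instance(38, rec$instance$mask,
                         landmark_pair(c(79.5 + 3, 40), c(79.5, 100)))
  res <- refine_orientation(inst)
  expect_lt(abs(res$final_angle_deg), 0.1)
})

test_that("refinement recovers the generated angle and its trace is well-formed", {
  rec <- make_phantom(molar_shape_params(), 25, canvas = c(200, 200))
  res <- refine_orientation(rec$instance)
  expect_lt(abs(res$final_magnitude_deg - 25), 1)
  expect_equal(res$final_angle_deg, res$trace[length(res$trace)])
  expect_equal(res$final_magnitude_deg, abs(res$final_angle_deg))
  expect_lte(length(res$trace), 10)
  expect_equal(res$n_iterations, length(res$trace))
  expect_s3_class(res$mesial_line, "regression_line")
  expect_s3_class(res$distal_line, "regression_line")
})

test_that("refinement is equivariant under rigid pre-rotation", {
  p <- molar_shape_params(asymmetry = 0.1)
  base <- refine_orientation(make_phantom(p, 10, canvas = c(220, 220))$instance)
  for (delta in c(-30, -15, 15, 30)) {
    shifted <- refine_orientation(
      make_phantom(p, 10 + delta, canvas = c(220, 220))$instance)
    expect_lt(abs(shifted$final_angle_deg - base$final_angle_deg - delta), 0.5,
              label = paste("equivariance at delta", delta))
  }
})

test_that("horizontal mirroring negates the signed angle", {
  for (a in c(8, 22, 41)) {
    rec <- make_phantom(molar_shape_params(asymmetry = 0.12), a,
                        canvas = c(200, 200))
    m <- rec$instance$mask
    flipped <- binary_mask(m[, ncol(m):1])
    r1 <- refine_orientation(tooth_instance(38, m))        # heuristic seeds
    r2 <- refine_orientation(tooth_instance(48, flipped))
    expect_lt(abs(r2$final_angle_deg + r1$final_angle_deg), 0.2,
              label = paste("mirror at", a, "deg"))
  }
})

test_that("ten iterations converge on noise-free phantoms", {
  for (a in c(-50, -20, 5, 35, 60)) {
    rec <- make_phantom(molar_shape_params(asymmetry = 0.05), a,
                        canvas = c(200, 200))
    res <- refine_orientation(rec$instance)
    expect_equal(res$n_iterations, 10L)
    last_update <- res$trace[10] - res$trace[9]
    expect_lt(abs(last_update), 0.1, label = paste("update at", a, "deg"))
    expect_true(res$converged)
  }
})

test_that("refinement is deterministic and honors config overrides", {
  rec <- make_phantom(molar_shape_params(), 18, canvas = c(200, 200))
  r1 <- refine_orientation(rec$instance)
  r2 <- refine_orientation(rec$instance)
  expect_identical(r1$trace, r2$trace)

  r3 <- refine_orientation(rec$instance, orientation_config(n_iterations = 3))
  expect_equal(r3$n_iterations, 3L)

  r4 <- refine_orientation(rec$instance,
                           orientation_config(early_stop_tol_deg = 0.5))
  expect_true(r4$converged)
  expect_lt(r4$n_iterations, 10L)
  expect_lt(abs(r4$final_angle_deg - r1$final_angle_deg), 0.5)
})

test_that("small masks warn and scene measurement collects per-tooth errors", {
  m <- matrix(FALSE, 44, 20); m[3:36, 9:13] <- TRUE    # 170 px
  expect_warning(refine_orientation(tooth_instance(36, m)), "200")

  sam <- sample_scene(21)
  tab <- measure_scene(sam$scene)
  expect_equal(nrow(tab), 6)
  expect_true(all(is.finite(tab$angle_signed_deg)))
  expect_named(tab, c("image_id", "fdi", "position", "side",
                      "angle_signed_deg", "angle_magnitude_deg",
                      "n_iterations", "converged"))
})
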