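test_that("polygon rasterization counts pixel centers inside or on the boundary", {
  sq <- polygon_to_mask(rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5)), 6, 6)
  expect_equal(sum(sq), 36)   # centers 0..5 inclusive on both axes

  tri_pts <- rbind(c(0, 0), c(4, 0), c(0, 4))
  tri <- polygon_to_mask(tri_pts, 6, 6)
  expect_equal(unclass(matrix(tri, 6, 6)),
               oracle_rasterize(tri_pts, 6, 6))

  # random simple polygons agree with the brute-force even-odd oracle
  set.seed(42)
  for (k in 1:10) {
    pts <- random_convex_polygon(sample(3:8, 1), runif(1, 4, 9), c(10, 10),
                                 min_area = 15)
    got <- polygon_to_mask(pts, 20, 20)
    expect_equal(unclass(matrix(got, 20, 20)), oracle_rasterize(pts, 20, 20),
                 info = paste("polygon", k))
  }
})

test_that("degenerate and self-intersecting polygons are rejected", {
  expect_error(polygon_to_mask(rbind(c(0, 0), c(1, 1), c(2, 2)), 5, 5),
               "degenerate")
  bowtie <- rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 4))
  expect_error(polygon_to_mask(bowtie, 6, 6), "self-intersecting")
  expect_error(polygon_to_mask(rbind(c(0, 0), c(4, 0)), 5, 5), "at least 3")
})

test_that("mask boundary operator matches 4-neighbor counting with border as background", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(mask_to_boundary(binary_mask(one)), cbind(x = 2, y = 2))

  solid <- matrix(FALSE, 5, 5); solid[2:4, 2:4] <- TRUE
  b <- mask_to_boundary(binary_mask(solid))
  expect_equal(nrow(b), 8)            # all but the center of a 3x3 block
  expect_false(any(b[, 1] == 2 & b[, 2] == 2))

  full <- binary_mask(matrix(TRUE, 4, 6))
  bf <- mask_to_boundary(full)        # frame edges only
  expect_equal(nrow(bf), 2 * 6 + 2 * (4 - 2))

  set.seed(7)
  for (k in 1:10) {
    m <- random_blob_mask(12, 12)
    got <- mask_to_boundary(binary_mask(m))
    want <- oracle_boundary(m)
    expect_equal(got[order(got[, 2], got[, 1]), , drop = FALSE],
                 unname(want[order(want[, 2], want[, 1]), , drop = FALSE]),
                 ignore_attr = TRUE)
  }
  expect_error(mask_to_boundary(binary_mask(matrix(FALSE, 3, 3))), "empty")
})

test_that("label-map PNG round trip preserves scenes and rejects unknown indices", {
  dir <- withr::local_tempdir()
  img <- matrix(0L, 10, 10)
  img[2:4, 2:4] <- 1L          # 3x3 block -> FDI 36
  img[6:9, 5:8] <- 4L          # 4x4 block -> FDI 46
  f <- file.path(dir, "scene.png")
  png::writePNG(img / 255, f)

  scene <- read_label_map(f)
  expect_s3_class(scene, "molar_scene")
  expect_equal(length(scene$instances), 2)
  fdi <- vapply(scene$instances, function(i) i$label$fdi_code, integer(1))
  expect_setequal(fdi, c(36L, 46L))
  expect_equal(sum(scene$instances[[which(fdi == 36)]]$mask), 9)

  # write-read identity
  f2 <- file.path(dir, "scene2.png")
  write_label_map(scene, f2)
  scene2 <- read_label_map(f2)
  expect_equal(scene2$instances[[1]]$mask, scene$instances[[1]]$mask)
  expect_equal(scene2$instances[[2]]$mask, scene$instances[[2]]$mask)

  # empty map -> 0 instances
  f3 <- file.path(dir, "empty.png")
  png::writePNG(matrix(0, 10, 10), f3)
  expect_equal(length(read_label_map(f3)$instances), 0)

  # unknown index named in the error
  img9 <- matrix(0L, 5, 5); img9[2:3, 2:3] <- 9L
  f4 <- file.path(dir, "bad.png")
  png::writePNG(img9 / 255, f4)
  expect_error(read_label_map(f4), "unknown label index 9")
})

test_that("LabelMe-style JSON is parsed, rasterized, and validated", {
  dir <- withr::local_tempdir()
  js <- list(imageHeight = 10, imageWidth = 10,
             shapes = list(list(label = "46",
                                points = list(c(2, 2), c(7, 2), c(7, 7), c(2, 7)),
                                shape_type = "polygon")))
  f <- file.path(dir, "ann.json")
  jsonlite::write_json(js, f, auto_unbox = TRUE)
  scene <- read_labelme(f)
  expect_equal(length(scene$instances), 1)
  expect_equal(scene$instances[[1]]$label$fdi_code, 46L)
  expect_equal(sum(scene$instances[[1]]$mask), 36)

  # empty annotation
  js0 <- list(imageHeight = 5, imageWidth = 5, shapes = list())
  f0 <- file.path(dir, "empty.json")
  jsonlite::write_json(js0, f0, auto_unbox = TRUE)
  expect_equal(length(read_labelme(f0)$instances), 0)

  # unsupported shape type
  js$shapes[[1]]$shape_type <- "circle"
  fc <- file.path(dir, "circle.json")
  jsonlite::write_json(js, fc, auto_unbox = TRUE)
  expect_error(read_labelme(fc), "unsupported shape_type")

  # unparseable label
  js$shapes[[1]]$shape_type <- "polygon"
  js$shapes[[1]]$label <- "upper-left"
  fl <- file.path(dir, "label.json")
  jsonlite::write_json(js, fl, auto_unbox = TRUE)
  expect_error(read_labelme(fl), "FDI")
})

test_that("later LabelMe shapes win on overlap, with a warning", {
  dir <- withr::local_tempdir()
  js <- list(imageHeight = 12, imageWidth = 12,
             shapes = list(
               list(label = "36", points = list(c(1, 1), c(8, 1), c(8, 8), c(1, 8)),
                    shape_type = "polygon"),
               list(label = "37", points = list(c(6, 6), c(10, 6), c(10, 10), c(6, 10)),
                    shape_type = "polygon")))
  f <- file.path(dir, "overlap.json")
  jsonlite::write_json(js, f, auto_unbox = TRUE)
  expect_warning(scene <- read_labelme(f), "overlap")
  fdi <- vapply(scene$instances, function(i) i$label$fdi_code, integer(1))
  m36 <- scene$instances[[which(fdi == 36)]]$mask
  m37 <- scene$instances[[which(fdi == 37)]]$mask
  expect_false(any(m36 & m37))
  expect_equal(sum(m37), 25)           # 5x5 block, kept whole
})

test_that("angle CSV round trip preserves values to 1e-6", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "angles.csv")
  rec <- data.frame(image_id = c("s1", "s1"), fdi = c(38L, 48L),
                    position = "M3", side = c("left", "right"),
                    angle_signed_deg = c(44.123456, -31.654321),
                    angle_magnitude_deg = c(44.123456, 31.654321),
                    n_iterations = 10L, converged = TRUE)
  write_angle_csv(rec, f, comment = "seed=7")
  back <- read_angle_csv(f)
  expect_equal(back$angle_signed_deg, rec$angle_signed_deg, tolerance = 1e-6)
  expect_equal(back$fdi, rec$fdi)
  expect_equal(nrow(back), 2)

  # header-only file for zero records
  f0 <- file.path(dir, "empty.csv")
  write_angle_csv(rec[0, ], f0)
  expect_equal(nrow(read_angle_csv(f0)), 0)
  expect_equal(length(readLines(f0)), 1)
})

test_that("rasterize-trace round trip keeps convex shapes (IoU >= 0.95)", {
  set.seed(99)
  for (k in 1:8) {
    pts <- random_convex_polygon(sample(5:9, 1), runif(1, 11, 16), c(20, 20),
                                 min_area = 100)
    m1 <- polygon_to_mask(pts, 40, 40)
    poly <- mask_to_polygon(m1)
    m2 <- polygon_to_mask(poly, 40, 40)
    cc <- confusion_counts(m2, m1)
    expect_gte(iou(cc), 0.95)
  }
})

test_that("label tables read and write the key=value dialect", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "labels.txt")
  write_label_table(default_label_table(), f)
  back <- read_label_table(f)
  expect_equal(back, default_label_table())
  expect_equal(unname(back["1"]), 36L)
})
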