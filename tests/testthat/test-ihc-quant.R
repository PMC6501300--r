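test_that("optical-density transform obeys Beer-Lambert on key pixels", {
  img <- array(255, dim = c(2, 2, 3))
  expect_equal(rgb_to_optical_density(img), array(0, dim = c(2, 2, 3)))

  img2 <- array(255, dim = c(1, 1, 3))
  img2[1, 1, 2] <- 25.5
  od <- rgb_to_optical_density(img2)
  expect_equal(od[1, 1, 2], -log10((25.5 + 1 / 255) / 255), tolerance = 1e-12)
  expect_lt(abs(od[1, 1, 2] - 1.0), 1e-3)

  expect_error(rgb_to_optical_density(array(300, dim = c(1, 1, 3))), "8-bit")
})

test_that("OD -> intensity -> OD round trip is quantization-limited", {
  od_in <- seq(0, 2, by = 0.05)
  ivals <- round(255 * 10^(-od_in))
  img <- aperm(array(rep(ivals, each = 3), dim = c(3, length(od_in), 1)),
               c(2, 3, 1))
  od_out <- rgb_to_optical_density(img)[, 1, 1]
  # deterministic: the output is exactly the Beer-Lambert transform of the
  # rounded 8-bit intensity
  expect_equal(od_out, pmax(0, -log10((ivals + 1 / 255) / 255)),
               tolerance = 1e-12)
  # at intensities >= 13 counts (OD <= ~1.3) half-count rounding moves the
  # OD by at most 0.434 * 0.5 / I < 0.02
  lo <- od_in <= 1.3
  expect_true(all(abs(od_out[lo] - od_in[lo]) < 0.02))
  # everywhere, the error stays within the half-count quantization bound
  bound <- abs(log10((ivals + 0.5 + 1 / 255) / pmax(ivals - 0.5, 0.5)))
  expect_true(all(abs(od_out - od_in) <= bound))
})

test_that("unmixing recovers known stain concentrations exactly", {
  m <- default_stain_matrix()
  # pure hematoxylin pixel at concentration 0.8
  od <- array(0.8 * m["hematoxylin", ], dim = c(1, 1, 3))
  conc <- unmix_stains(od, m)
  expect_equal(conc$hematoxylin[1, 1], 0.8, tolerance = 1e-9)
  expect_equal(conc$dab[1, 1], 0, tolerance = 1e-9)

  # zero OD pixel
  conc0 <- unmix_stains(array(0, dim = c(1, 1, 3)), m)
  expect_true(all(vapply(conc0, function(x) x[1, 1], numeric(1)) == 0))

  # random non-negative mixtures: exact linear-algebra recovery
  set.seed(9)
  for (i in 1:20) {
    c1 <- runif(1, 0, 2); c2 <- runif(1, 0, 2)
    od <- array(c1 * m["hematoxylin", ] + c2 * m["dab", ], dim = c(1, 1, 3))
    conc <- unmix_stains(od, m)
    expect_lt(abs(conc$hematoxylin[1, 1] - c1), 1e-6)
    expect_lt(abs(conc$dab[1, 1] - c2), 1e-6)
  }

  singular <- rbind(m[1, ], m[1, ], m[1, ])
  expect_error(unmix_stains(od, singular), "condition number")
})

test_that("detection binarizes, labels 8-connected components and filters by area", {
  expect_equal(detect_positive_cells(matrix(0, 20, 20))$count, 0L)

  # two diagonal-touching blobs must merge under 8-connectivity
  m <- matrix(0, 20, 20)
  m[3:8, 3:8] <- 1
  m[9:14, 9:14] <- 1
  det <- detect_positive_cells(m, threshold = 0.5,
                               area_min_px = 5, area_max_px = 500)
  expect_equal(det$count, 1L)

  # a blob below area_min_px is dropped
  s <- matrix(0, 20, 20)
  s[5:6, 5:6] <- 1
  expect_equal(detect_positive_cells(s, threshold = 0.5,
                                     area_min_px = 20,
                                     area_max_px = 2000)$count, 0L)

  # two separated blobs, centroids where expected
  two <- matrix(0, 30, 30)
  two[3:8, 3:8] <- 1
  two[20:25, 20:25] <- 1
  det2 <- detect_positive_cells(two, threshold = 0.5,
                                area_min_px = 5, area_max_px = 500)
  expect_equal(det2$count, 2L)
  expect_equal(sort(det2$centroids[, "row"]), c(5.5, 22.5))
})

test_that("density normalizes in-mask counts by mask area", {
  det <- structure(list(
    centroids = cbind(row = c(10, 100), col = c(10, 100)),
    count = 2L, per_object_area_px = c(30L, 30L)), class = "cell_detections")
  mask <- matrix(TRUE, 500, 500)
  # 500 x 500 px at 2 um/px is exactly 1 mm2
  d <- compute_density(det, mask, microns_per_pixel = 2)
  expect_equal(d$area_mm2, 1.0)
  expect_equal(d$density, 2.0)

  # centroid outside the mask is excluded
  mask2 <- mask
  mask2[1:50, 1:50] <- FALSE
  d2 <- compute_density(det, mask2, microns_per_pixel = 2)
  expect_equal(d2$count, 1L)

  expect_error(compute_density(det, matrix(FALSE, 5, 5), 2), "empty")
})

test_that("doubling pixel pitch quadruples area and quarters density", {
  det <- structure(list(centroids = cbind(row = 50, col = 50), count = 1L,
                        per_object_area_px = 30L), class = "cell_detections")
  mask <- matrix(TRUE, 100, 100)
  d1 <- compute_density(det, mask, 1)
  d2 <- compute_density(det, mask, 2)
  expect_equal(d2$area_mm2, 4 * d1$area_mm2)
  expect_equal(d2$density, d1$density / 4)
})
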