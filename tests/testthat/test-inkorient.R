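# Edge band, HSV ink detection, centroids, orientation line.

test_that("edge band is an annulus around the mask boundary", {
  mask <- matrix(FALSE, 300, 300)
  xs <- matrix(rep(1:300, each = 300), 300, 300)
  ys <- matrix(rep(1:300, 300), 300, 300)
  mask[(xs - 150)^2 + (ys - 150)^2 <= 100^2] <- TRUE
  band <- tissue_edge_band(mask, band_px = 16L)
  # oracle: dilation minus erosion of the mask by half the band width
  br <- EBImage::makeBrush(17L, "disc")
  oracle <- (EBImage::dilate(mask * 1, br) > 0.5) & !(EBImage::erode(mask * 1, br) > 0.5)
  expect_gte(iou(band, oracle), 0.8)
  # empty mask -> empty band
  expect_equal(sum(tissue_edge_band(matrix(FALSE, 50, 50), 8L)), 0)
  # square mask: all four edges covered
  sq <- matrix(FALSE, 200, 200); sq[51:150, 51:150] <- TRUE
  b2 <- tissue_edge_band(sq, 10L)
  expect_true(any(b2[51:150, 48:53]) && any(b2[51:150, 148:153]) &&
              any(b2[48:53, 51:150]) && any(b2[148:153, 51:150]))
})

test_that("ink detection finds edge arcs and ignores interior seepage", {
  fx <- memo("ink640", std_section_fixture(seed = 9, blue_clock = 0,
                                           red_clock = 180))
  m <- compute_tissue_mask(fx$raster)
  band <- tissue_edge_band(m, 16L)
  inks <- detect_inks(fx$raster, band)
  truth <- fx$truth$sections[[1]]$inks
  for (ti in truth) {
    got <- ink_centroid(inks, ti$color)
    expect_lt(sqrt(sum((got - ti$centroid)^2)), 10)
  }
  # a 20 px spurious blue blob deep in the interior is excluded
  r2 <- fx$raster
  r2[315:319, 315:320, 1] <- 0.1; r2[315:319, 315:320, 2] <- 0.2
  r2[315:319, 315:320, 3] <- 0.9
  inks2 <- detect_inks(r2, band)
  c1 <- ink_centroid(inks, "blue"); c2 <- ink_centroid(inks2, "blue")
  expect_lt(sqrt(sum((c1 - c2)^2)), 1e-9)
  # no ink at all
  fx2 <- memo("disk400", std_section_fixture(seed = 6, canvas = 400L,
                                             patch_size = 50L, inks = list()))
  m2 <- compute_tissue_mask(fx2$raster)
  inks3 <- detect_inks(fx2$raster, tissue_edge_band(m2, 16L))
  expect_null(inks3$blue); expect_null(inks3$red)
  # output invariant to color enumeration order
  inks_rev <- detect_inks(fx$raster, band, colors = c("red", "blue"))
  expect_equal(ink_centroid(inks_rev, "blue"), ink_centroid(inks, "blue"))
})

test_that("ink centroids support mean, median and trimmed mean", {
  im <- structure(list(blue = list(pixels = cbind(x = c(0, 2), y = c(0, 0)),
                                   n_components = 1)), class = "ink_map")
  expect_equal(ink_centroid(im, "blue", "mean"), c(1, 0))
  im2 <- structure(list(red = list(pixels = cbind(x = c(0, 0, 0),
                                                  y = c(0, 2, 100)),
                                   n_components = 1)), class = "ink_map")
  expect_equal(ink_centroid(im2, "red", "median"), c(0, 2))
  # trimmed mean equals mean after discarding the sorted tail slices
  set.seed(5)
  px <- cbind(x = c(rnorm(40), 500), y = c(rnorm(40), -300))
  im3 <- structure(list(green = list(pixels = px, n_components = 1)),
                   class = "ink_map")
  tm <- ink_centroid(im3, "green", "trimmed", trim = 0.1)
  oracle <- apply(px, 2, function(v) {
    k <- floor(0.1 * length(v))
    mean(sort(v)[(k + 1):(length(v) - k)])
  })
  expect_equal(tm, unname(oracle))
  expect_error(ink_centroid(im, "purple"), "purple")
})

test_that("orientation line follows the clock convention", {
  ol <- orientation_line(c(100, 0), c(100, 200))
  expect_equal(ol$theta, 180)
  expect_equal(relative_angle(180, 180), 0)
  expect_equal(relative_angle(350, 10), -20)
  expect_equal(relative_angle(10, 350), 20)
  # full wraparound sweep against direct angle arithmetic
  for (a in seq(0, 350, 37)) for (b in seq(0, 350, 53)) {
    d <- relative_angle(a, b)
    expect_gte(d, -180); expect_lt(d, 180)
    expect_equal((b + d) %% 360, a %% 360, tolerance = 1e-9)
  }
  expect_error(orientation_line(c(5, 5), c(5, 5)), "degenerate")
})

test_that("detected orientation is equivariant to raster rotation", {
  fx <- memo("ink640", std_section_fixture(seed = 9))
  base <- section_orientation(fx$raster)
  expect_s3_class(base, "orientation_line")
  # 90 and 180 degrees: exact array rotations
  rot90 <- function(a) {
    out <- array(0, dim = c(dim(a)[2], dim(a)[1], 3))
    for (ch in 1:3) out[, , ch] <- t(a[nrow(a):1, , ch])
    out
  }
  r90 <- rot90(fx$raster)                   # clockwise 90
  r180 <- rot90(r90)
  t90 <- section_orientation(r90)$theta
  t180 <- section_orientation(r180)$theta
  expect_lt(abs(relative_angle(t90, base$theta + 90)), 1)
  expect_lt(abs(relative_angle(t180, base$theta + 180)), 1)
  # 15 degrees: render the fixture with all clock positions shifted
  fx15 <- std_section_fixture(seed = 9, blue_clock = 15, red_clock = 195)
  t15 <- section_orientation(fx15$raster)$theta
  expect_lt(abs(relative_angle(t15, base$theta + 15)), 1)
})

test_that("orientation recovers known ink placements across 20 fixtures", {
  errs <- vapply(1:20, function(s) {
    phi <- (s * 37.7) %% 360
    fx <- std_section_fixture(seed = 100 + s, blue_clock = phi,
                              red_clock = (phi + 180) %% 360,
                              canvas = 512L, patch_size = 64L)
    ol <- section_orientation(fx$raster)
    truth <- fx$truth$sections[[1]]$orientation
    abs(relative_angle(ol$theta, truth))
  }, numeric(1))
  expect_gte(mean(errs <= 5), 0.9)
  expect_true(all(errs <= 15))
})
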