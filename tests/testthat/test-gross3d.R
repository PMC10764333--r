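# Turntable frames, calibration, cloud orientation, measurement, grossing.

test_that("frame segmentation recovers the specimen with high IoU", {
  tt <- memo("frames36", make_turntable_frames(n_frames = 36, seed = 4))
  det <- segment_frames(tt$frames)
  expect_length(det, 36)
  H <- nrow(tt$frames[[1]]); W <- ncol(tt$frames[[1]])
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  ious <- vapply(seq_along(det), function(f) {
    o <- det[[f]]$objects[[1]]
    truth <- (xs - tt$truth$centers[f, 1])^2 +
             (ys - tt$truth$centers[f, 2])^2 <= tt$truth$blob_r^2
    iou(o$mask, truth)
  }, numeric(1))
  expect_true(all(ious >= 0.9))
  # blank frames error
  blank <- replicate(10, matrix(0.95, 60, 60), simplify = FALSE)
  expect_error(segment_frames(blank), "no candidate")
  # one-tenth frame subsampling is honored in the output count
  expect_length(segment_frames(tt$frames, keep_fraction = 0.1), 4)
})

test_that("trajectory filtering keeps the revolving specimen only", {
  tt <- make_turntable_frames(n_frames = 36,
                              distractors = list(list(center = c(40, 40), r = 8)),
                              seed = 4)
  det <- filter_by_trajectory(segment_frames(tt$frames))
  for (d in det) for (o in seq_along(d$objects)) {
    is_distractor <- sqrt(sum((d$objects[[o]]$centroid - c(40, 40))^2)) < 10
    expect_equal(d$kept[o], !is_distractor)
  }
  # all centroids on the ellipse: all kept
  tt2 <- memo("frames36", make_turntable_frames(n_frames = 36, seed = 4))
  det2 <- filter_by_trajectory(segment_frames(tt2$frames))
  expect_true(all(unlist(lapply(det2, function(d) d$kept))))
  # pure noise: no trajectory
  set.seed(9)
  noise <- lapply(1:12, function(f)
    list(frame = f, objects = list(list(centroid = runif(2, 0, 300),
                                        npx = 50, mask = NULL)), kept = NA))
  expect_error(filter_by_trajectory(noise), "trajectory")
})

test_that("turntable calibration reads the rim diameter", {
  tt <- memo("frames36", make_turntable_frames(n_frames = 36, seed = 4))
  sc <- calibrate_scale(tt$frames[[1]], diameter_cm = 24)
  expect_equal(as.numeric(sc), 24 / 240, tolerance = 0.02)
  # doubled resolution halves the scale
  big <- tt$frames[[1]][rep(1:240, each = 2), rep(1:320, each = 2)]
  sc2 <- calibrate_scale(big, diameter_cm = 24)
  expect_equal(as.numeric(sc2), as.numeric(sc) / 2, tolerance = 0.02 * 24 / 240)
  # major axis survives edge noise (fit within 2 percent)
  set.seed(5)
  noisy <- tt$frames[[1]] + matrix(rnorm(240 * 320, sd = 0.02), 240)
  sc3 <- calibrate_scale(noisy, diameter_cm = 24)
  expect_equal(as.numeric(sc3), 0.1, tolerance = 0.002)
})

test_that("k-NN outlier removal strips stragglers and nothing else", {
  cl <- make_cloud(cloud_spec(n = 1500, noise_sd = 0.01, suture = NULL,
                              seed = 3))
  stragglers <- matrix(runif(30, 5, 8), 10, 3)
  sc <- specimen_cloud(rbind(cl$points, stragglers))
  out <- remove_outliers(sc, k = 8, sd_factor = 2)
  expect_equal(nrow(out$points), 1500)
  expect_true(max(out$points[, 1]) < 5)
  # clean cloud untouched at a generous threshold
  clean <- remove_outliers(specimen_cloud(cl$points), k = 8, sd_factor = 6)
  expect_equal(nrow(clean$points), 1500)
  # order independence
  perm <- sample(nrow(sc$points))
  out2 <- remove_outliers(specimen_cloud(sc$points[perm, ]), k = 8, sd_factor = 2)
  expect_setequal(apply(round(out2$points, 9), 1, paste, collapse = ","),
                  apply(round(out$points, 9), 1, paste, collapse = ","))
})

test_that("orientation recovers the bottom plane and suture direction", {
  cl <- std_box_cloud(seed = 31, angle = 30, axis = c(1, 0, 0))
  oc <- orient_cloud(specimen_cloud(cl$points, cl$colors, scale = 1), seed = 2)
  rn <- as.vector(oc$rotation %*% cl$truth$bottom_normal)
  expect_lt(acos(pmin(1, -rn[3])) * 180 / pi, 2)
  # suture placed at 3 o'clock ends up at +y after orientation
  cl2 <- std_box_cloud(seed = 32, angle = 0, suture = list(clock = 90))
  oc2 <- orient_cloud(specimen_cloud(cl2$points, cl2$colors, scale = 1), seed = 2)
  expect_true(oc2$suture_found)
  sut <- marginmap:::is_suture_color(oc2$colors)
  sc <- colMeans(oc2$points[sut, , drop = FALSE])
  ang <- atan2(sc[1], sc[2]) * 180 / pi
  expect_lt(abs(ang), 5)
  # an already-oriented cloud rotates by (nearly) the identity
  oc3 <- orient_cloud(oc2, seed = 3)
  expect_lt(acos(pmin(1, (sum(diag(oc3$rotation)) - 1) / 2)) * 180 / pi, 1)
})

test_that("measurements are exact for axis boxes and scale linearly", {
  cl <- make_cloud(cloud_spec(extents = c(1, 2, 0.5), n = 3000,
                              noise_sd = 0.001, suture = NULL, seed = 2))
  oc <- specimen_cloud(cl$points, cl$colors, scale = 1)
  oc$oriented <- TRUE
  m <- measure(oc)
  expect_equal(unname(m), c(2, 1, 0.5), tolerance = 0.01)
  oc$scale <- 0.5
  expect_equal(unname(measure(oc)), c(1, 0.5, 0.25), tolerance = 0.005)
  # unoriented or uncalibrated clouds refuse to measure
  expect_error(measure(specimen_cloud(cl$points, scale = 1)), "not oriented")
  expect_error(measure(structure(list(points = cl$points, scale = NA,
                                      oriented = TRUE),
                                 class = "specimen_cloud")), "scale")
})

test_that("measure after orientation is rigid-invariant within 2 percent", {
  base <- std_box_cloud(seed = 41, angle = 0, suture = list(clock = 0))
  for (ang in c(20, 65)) {
    cl <- std_box_cloud(seed = 41, angle = ang, axis = c(0.3, 1, 0.4))
    oc <- orient_cloud(remove_outliers(
      specimen_cloud(cl$points, cl$colors, scale = 1)), seed = 5)
    m <- measure(oc)
    expect_equal(unname(m) / c(2, 1, 0.5), rep(1, 3), tolerance = 0.02)
  }
})

test_that("recovered extents stay within tolerance across 10 seeded boxes", {
  errs <- t(vapply(1:10, function(s) {
    cl <- std_box_cloud(seed = s)
    oc <- orient_cloud(remove_outliers(
      specimen_cloud(cl$points, cl$colors, scale = 1)), seed = s)
    measure(oc) - c(L = 2, W = 1, H = 0.5)
  }, numeric(3)))
  expect_lte(median(abs(errs)), 0.05)
  expect_true(all(abs(errs) / rep(c(2, 1, 0.5), each = 10) <= 0.02))
})

test_that("grossing plans encode the inking rules", {
  cl <- make_cloud(cloud_spec(extents = c(1, 1.5, 0.5), n = 3000,
                              noise_sd = 0.001, suture = NULL, seed = 2))
  oc <- specimen_cloud(cl$points, cl$colors, scale = 1); oc$oriented <- TRUE
  # Mohs, fits on one slide: single blue-red line, no bisection
  gp <- grossing_plan(oc, "mohs", slide_fit_cm = 2)
  cols <- vapply(gp$segments, `[[`, character(1), "color")
  expect_equal(sort(cols), c("blue", "red"))
  # blue segment nearer 12 o'clock (+y) than red
  ymid <- vapply(gp$segments, function(s) mean(c(s$from[2], s$to[2])), numeric(1))
  expect_gt(ymid[cols == "blue"], ymid[cols == "red"])
  # Mohs with bisection: black midline plus two blue-red pairs
  gp2 <- grossing_plan(oc, "mohs", slide_fit_cm = 1)
  cols2 <- vapply(gp2$segments, `[[`, character(1), "color")
  expect_equal(sum(cols2 == "black"), 1)
  expect_equal(sum(cols2 == "blue"), 2)
  expect_equal(sum(cols2 == "red"), 2)
  # breadloaf increment rule: y-extent 4.2, spacing 1 -> lines at 0, +-1, +-2
  cl3 <- make_cloud(cloud_spec(extents = c(1, 4.2, 0.5), n = 4000,
                               noise_sd = 0.001, suture = NULL, seed = 3))
  oc3 <- specimen_cloud(cl3$points, cl3$colors, scale = 1); oc3$oriented <- TRUE
  gp3 <- grossing_plan(oc3, "breadloaf", spacing_cm = 1)
  ys <- sort(unique(round(vapply(gp3$segments, function(s) s$from[2], numeric(1)), 3)))
  expect_equal(ys, c(-2, -1, 0, 1, 2), tolerance = 0.05)
  # left halves blue, right halves cycle the section palette
  lefts <- vapply(gp3$segments, function(s) s$role == "cut-left", logical(1))
  expect_true(all(vapply(gp3$segments[lefts], `[[`, character(1), "color") == "blue"))
  expect_warning(grossing_plan(oc3, "breadloaf", spacing_cm = 1.5), "0.5-1")
})

test_that("surface refinement averages z and color over the grid", {
  set.seed(20)
  pts <- cbind(runif(600, 0, 2), runif(600, 0, 2), 0.5 + rnorm(600, sd = 0.01))
  cols <- matrix(runif(1800, 0.4, 0.6), ncol = 3)
  sc <- specimen_cloud(pts, cols, scale = 1); sc$oriented <- TRUE
  rf <- refine_surface(sc, grid_step = 0.1)
  expect_true(all(abs(rf$points[, 3] - 0.5) < 0.02))
  expect_true(all(rf$colors >= 0.4 - 1e-9 & rf$colors <= 0.6 + 1e-9))
  # grid values match brute-force averaging
  for (i in sample(nrow(rf$points), 5)) {
    d2 <- (pts[, 1] - rf$points[i, 1])^2 + (pts[, 2] - rf$points[i, 2])^2
    nb <- d2 <= 0.15^2
    expect_equal(unname(rf$points[i, 3]), mean(pts[nb, 3]), tolerance = 1e-9)
  }
  expect_gte(nrow(rf$points), 300)
})

test_that("PLY and XYZ files round-trip point clouds", {
  cl <- make_cloud(cloud_spec(n = 300, seed = 5))
  sc <- specimen_cloud(cl$points, cl$colors, scale = 0.1)
  f1 <- tempfile(fileext = ".ply"); f2 <- tempfile(fileext = ".xyz")
  write_ply(sc, f1); write_xyz(sc, f2)
  r1 <- read_ply(f1, scale = 0.1); r2 <- read_xyz(f2, scale = 0.1)
  expect_equal(unname(r1$points), unname(sc$points), tolerance = 1e-4)
  expect_equal(unname(r2$points), unname(sc$points), tolerance = 1e-4)
  expect_equal(unname(r1$colors), unname(sc$colors), tolerance = 1 / 255)
  expect_equal(readLines(f1)[1], "ply")
})
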