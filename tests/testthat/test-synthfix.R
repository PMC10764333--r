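# Fixture generators: determinism, ground-truth conventions, and the
# spatial patch dataset.

test_that("section renders are bit-reproducible and honor conventions", {
  fx1 <- std_section_fixture(seed = 3, canvas = 400L, patch_size = 50L)
  fx2 <- std_section_fixture(seed = 3, canvas = 400L, patch_size = 50L)
  expect_identical(fx1$raster, fx2$raster)
  # blue at 12, red at 6 -> blue-to-red vector points down: 180 degrees
  expect_equal(fx1$truth$sections[[1]]$orientation, 180, tolerance = 1.5)
  # no ink -> no orientation
  fx3 <- std_section_fixture(seed = 4, canvas = 400L, patch_size = 50L,
                             inks = list())
  expect_true(is.na(fx3$truth$sections[[1]]$orientation))
  expect_length(fx3$truth$sections[[1]]$inks, 0)
})

test_that("multi-section layouts write their own labels consistently", {
  mkpieces <- function(cx) list(disk_polygon(cx, 300, 120),
                                disk_polygon(cx + 400, 300, 120))
  spec <- section_spec(canvas = c(2200, 600), patch_size = 100L,
    sections = list(list(pieces = mkpieces(200)),
                    list(pieces = mkpieces(1600))), seed = 5)
  fx <- make_section_image(spec)
  lab <- fx$truth$patch_labels
  tissue <- lab[!is.na(lab$section), ]
  expect_setequal(unique(tissue$section), c(0, 1))
  expect_setequal(unique(tissue$piece), c(0, 1))
  # sections are 1400 px apart, pieces 400 px apart, as laid out
  s0 <- tissue[tissue$section == 0, ]; s1 <- tissue[tissue$section == 1, ]
  expect_lt(max(s0$x), min(s1$x))
})

test_that("overlapping non-conjoined pieces are rejected", {
  spec <- section_spec(canvas = c(500, 500), patch_size = 50L,
    sections = list(list(pieces = list(disk_polygon(200, 250, 100),
                                       disk_polygon(260, 250, 100)))),
    seed = 1)
  expect_error(make_section_image(spec), "overlapping")
})

test_that("box clouds reproduce their stated geometry", {
  # identity transform, no noise: exact axis-aligned extents
  cl <- make_cloud(cloud_spec(extents = c(1, 2, 0.5), n = 2000,
                              noise_sd = 0, suture = NULL, seed = 2))
  ext <- apply(cl$points, 2, function(v) diff(range(v)))
  expect_equal(unname(ext), c(1, 2, 0.5), tolerance = 1e-6)
  # 30 degree tilt about x rotates the bottom normal accordingly
  cl2 <- make_cloud(cloud_spec(rotation = list(axis = c(1, 0, 0), angle = 30),
                               seed = 2))
  expect_equal(cl2$truth$bottom_normal,
               c(0, sin(30 * pi / 180), -cos(30 * pi / 180)),
               tolerance = 1e-8)
  # determinism
  cl3 <- make_cloud(cloud_spec(seed = 9)); cl4 <- make_cloud(cloud_spec(seed = 9))
  expect_identical(cl3$points, cl4$points)
  expect_identical(cl3$colors, cl4$colors)
  # invalid specs
  expect_error(cloud_spec(n = 50))
  expect_error(cloud_spec(noise_sd = -1))
})

test_that("spatial patch dataset couples labels to context as dialed", {
  # spatial_signal = 0: neighbor features carry no label information
  # (permutation test on the correlation between label and neighbor mean)
  ds0 <- make_patch_dataset(1, 250, feature_dim = 4, spatial_signal = 0,
                            seed = 3)[[1]]
  nb_mean <- vapply(seq_len(250), function(i) {
    d <- sqrt(rowSums(sweep(ds0$coords, 2, ds0$coords[i, ])^2))
    sel <- d <= ds0$radius & d > 0
    if (!any(sel)) 0 else mean(ds0$features[sel, 1])
  }, numeric(1))
  obs <- abs(cor(nb_mean, ds0$labels))
  set.seed(11)
  null <- replicate(400, abs(cor(nb_mean, sample(ds0$labels))))
  expect_gt(mean(null >= obs), 0.05)   # not significant at alpha = 0.05

  # spatial_signal = 1: a neighbor-mean classifier beats node-only features
  ds1 <- make_patch_dataset(2, 400, feature_dim = 4, spatial_signal = 1,
                            seed = 4)
  aucs <- vapply(ds1, function(g) {
    nb <- vapply(seq_len(nrow(g$coords)), function(i) {
      d <- sqrt(rowSums(sweep(g$coords, 2, g$coords[i, ])^2))
      mean(g$features[d <= g$radius, 1])
    }, numeric(1))
    c(node = oracle_auc(g$features[, 1], g$labels),
      nbr = oracle_auc(nb, g$labels))
  }, numeric(2))
  expect_gt(mean(aucs["nbr", ]), mean(aucs["node", ]))

  # seed reproducibility
  expect_identical(make_patch_dataset(1, 50, 3, 0.5, seed = 8),
                   make_patch_dataset(1, 50, 3, 0.5, seed = 8))
})

test_that("map templates encode the blue-red orientation line", {
  el <- list(center = c(250, 250), axes = c(100, 100), rotation = 0)
  tp <- make_template("scalp", el, blue_mark = c(250, 150),
                      red_mark = c(250, 350))
  expect_equal(tp$meta$template_angle, 180)
  tp2 <- make_template("scalp", el, blue_mark = c(250, 350),
                       red_mark = c(250, 150))
  expect_equal((tp2$meta$template_angle - tp$meta$template_angle) %% 360, 180)
  expect_error(make_template("x", list(center = c(0, 0), axes = c(0, 10)),
                             c(0, 10), c(0, -10)), "degenerate")
  expect_error(make_template("x", el, blue_mark = c(250, 250),
                             red_mark = c(250, 350)), "boundary")
})
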