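# Sliced Wasserstein distance, morphing, rotation, overlays, concordance.

test_that("sliced distance matches identity, symmetry and translation", {
  set.seed(22)
  A <- matrix(rnorm(300), ncol = 2)
  expect_equal(sliced_wasserstein(A, A, 64, seed = 1), 0, tolerance = 1e-12)
  B <- sweep(A, 2, c(3, 4), `+`)
  expect_identical(sliced_wasserstein(A, B, 128, seed = 5),
                   sliced_wasserstein(B, A, 128, seed = 5))
  d <- sliced_wasserstein(A, B, 512, seed = 2)
  expect_equal(d, 5 / sqrt(2), tolerance = 0.05 * 5 / sqrt(2))
  expect_error(sliced_wasserstein(matrix(numeric(0), ncol = 2), A), "empty")
})

test_that("morphing contracts into the ellipse and keeps relative layout", {
  el <- list(center = c(250, 250), axes = c(120, 80), rotation = 0)
  set.seed(1)
  pts <- cbind(runif(300, 600, 900), runif(300, 100, 250))
  probs <- matrix(runif(300), ncol = 1, dimnames = list(NULL, "tumor"))
  tr <- morph_to_ellipse(pts, el, probs = probs, seed = 4)
  expect_lte(tr$sw_final, tr$sw_initial)
  expect_lt(tr$sw_final, 0.2 * tr$sw_initial)
  expect_identical(tr$probs, probs)                       # carried unchanged
  expect_equal(nrow(tr$transported), nrow(pts))           # count conserved
  d <- sweep(tr$transported, 2, el$center)
  q <- sqrt((d[, 1] / el$axes[1])^2 + (d[, 2] / el$axes[2])^2)
  expect_gte(mean(q <= 1 + 0.02), 0.99)
  set.seed(3); i <- sample(300, 100)
  rho <- cor(as.vector(dist(pts[i, ])), as.vector(dist(tr$transported[i, ])),
             method = "spearman")
  expect_gte(rho, 0.8)
  expect_error(morph_to_ellipse(pts[1:5, ], el), "10 points")
})

test_that("points already uniform in the ellipse barely move", {
  el <- list(center = c(0, 0), axes = c(100, 60), rotation = 20)
  pu <- marginmap:::sample_ellipse_interior(el, 1500, 31)
  tr <- morph_to_ellipse(pu, el, seed = 6)
  disp <- mean(sqrt(rowSums((tr$transported - pu)^2)))
  # displacement stays at the sampling-noise scale (mean NN spacing)
  nn_spacing <- sqrt(pi * el$axes[1] * el$axes[2] / 1500)
  expect_lte(disp, nn_spacing)
})

test_that("template rotation applies the signed clock difference", {
  el <- list(center = c(100, 100), axes = c(50, 50), rotation = 0)
  pts <- marginmap:::sample_ellipse_interior(el, 200, 3)
  tr <- morph_to_ellipse(pts, el, seed = 2,
                         landmarks = rbind(c(100, 60), c(100, 140)))
  tr2 <- rotate_to_template(tr, 180, 90)
  expect_equal(tr2$rotation, -90)
  lm <- tr2$landmarks
  theta_after <- clock_angle(lm[2, 1] - lm[1, 1], lm[2, 2] - lm[1, 2])
  expect_lt(abs(relative_angle(theta_after, 90)), 1)
  # aligned lines: no rotation
  tr3 <- rotate_to_template(tr, 135, 135)
  expect_equal(tr3$rotation, 0)
  # opposite layouts rotate by half a turn
  tr4 <- rotate_to_template(tr, 0, 180)
  expect_equal(abs(tr4$rotation), 180)
  expect_error(rotate_to_template(tr, NA_real_, 90), "missing")
})

test_that("density overlays threshold monotonically", {
  el <- list(center = c(0, 0), axes = c(100, 100), rotation = 0)
  set.seed(24)
  pts <- rbind(matrix(rnorm(300, sd = 10), ncol = 2) + 40,
               matrix(rnorm(100, sd = 30), ncol = 2))
  probs <- cbind(tumor = c(rep(0.95, 150), rep(0.02, 50)))
  tr <- structure(list(transported = pts, probs = probs, ellipse = el),
                  class = "transport_result")
  ov <- density_overlay(tr, "tumor", threshold = 0.5)
  expect_gt(length(ov$contours), 0)
  # the high-probability cluster centroid falls inside a contour
  inside <- any(vapply(ov$contours, function(p)
    marginmap:::point_in_polygon(40, 40, p), logical(1)))
  expect_true(inside)
  # threshold above the max: empty
  ov2 <- density_overlay(tr, "tumor", threshold = 1.0000001)
  expect_length(ov2$contours, 0)
  # area monotone non-increasing over thresholds
  areas <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    marginmap:::overlay_area(density_overlay(tr, "tumor", threshold = th)),
    numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  # zero weights: empty overlay
  tr$probs[, 1] <- 0
  expect_length(density_overlay(tr, "tumor", threshold = 0.5)$contours, 0)
})

test_that("the Jeffreys Beta posterior reproduces exact quantiles", {
  cp <- concordance_posterior(28, 28)
  expect_equal(cp$a, 28.5); expect_equal(cp$b, 0.5)
  expect_equal(round(100 * cp$q50, 1), 99.2)
  expect_equal(round(100 * cp$`q2.5`, 1), 91.5)
  expect_gte(100 * cp$`q97.5`, 99.9)
  # empty data returns the symmetric prior
  cp0 <- concordance_posterior(0, 0)
  expect_equal(cp0$q50, 0.5)
  # quantiles agree with quadrature + bisection to 1e-6
  cp8 <- concordance_posterior(8, 10)
  for (p in c(0.025, 0.5, 0.975)) {
    want <- oracle_beta_quantile(p, 8.5, 2.5)
    got <- switch(as.character(p), "0.025" = cp8$`q2.5`, "0.5" = cp8$q50,
                  "0.975" = cp8$`q97.5`)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # quantiles increase with k at fixed n
  q50s <- vapply(0:10, function(k) concordance_posterior(k, 10)$q50, numeric(1))
  expect_true(all(diff(q50s) > 0))
  expect_error(concordance_posterior(5, 3))
})

test_that("tumor position survives the full morph-and-rotate mapping", {
  el <- list(center = c(250, 250), axes = c(110, 90), rotation = 0)
  errs <- vapply(1:10, function(s) {
    phi <- (s * 61) %% 360                       # true tumor clock position
    psi <- (s * 133) %% 360                      # template orientation
    cc <- 320; pr <- 230
    tc <- c(cc, cc) + 140 * clock_vector(phi)
    fx <- std_section_fixture(seed = 300 + s, canvas = 640L, patch_size = 64L,
                              blue_clock = 0, red_clock = 180,
                              tumors = list(disk_polygon(tc[1], tc[2], 80)))
    lab <- fx$truth$patch_labels
    keep <- !is.na(lab$section)
    coords <- cbind(lab$x[keep] + 32, lab$y[keep] + 32)
    probs <- cbind(tumor = as.numeric(lab$label[keep] == "tumor"))
    ol <- section_orientation(fx$raster)
    tpl_blue <- c(250, 250) + 110 * clock_vector(psi)
    tpl_red <- c(250, 250) + 110 * clock_vector((psi + 180) %% 360)
    tpl_angle <- clock_angle(tpl_red[1] - tpl_blue[1], tpl_red[2] - tpl_blue[2])
    tr <- morph_to_ellipse(coords, el, probs = probs,
                           landmarks = rbind(ol$blue, ol$red),
                           seed = 400 + s)
    lm <- tr$landmarks
    sect_theta <- clock_angle(lm[2, 1] - lm[1, 1], lm[2, 2] - lm[1, 2])
    tr <- rotate_to_template(tr, sect_theta, tpl_angle)
    w <- tr$probs[, "tumor"]
    ctr <- colSums(tr$transported * w) / sum(w)
    got_clock <- clock_angle(ctr[1] - el$center[1], ctr[2] - el$center[2])
    # the template's 12 o'clock points at psi; the tumor should appear at
    # phi relative to that reference
    abs(relative_angle(got_clock, (phi + psi) %% 360))
  }, numeric(1))
  expect_true(all(errs <= 15))
})
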