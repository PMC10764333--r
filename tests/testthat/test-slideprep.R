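# Tissue masking, patch extraction, section/piece assignment, hole candidates.

test_that("tissue mask handles background, tissue and gray artifacts", {
  white <- array(1, dim = c(128, 128, 3))
  expect_equal(sum(compute_tissue_mask(white)$mask), 0)
  expect_error(compute_tissue_mask(array(0, dim = c(0, 4, 3))), "empty")

  fx <- memo("disk400", std_section_fixture(seed = 6, canvas = 400L,
                                            patch_size = 50L, inks = list()))
  m <- compute_tissue_mask(fx$raster)
  truth <- marginmap:::rasterize_polygon(fx$truth$sections[[1]]$pieces[[1]],
                                         c(400L, 400L))
  expect_gte(iou(m$mask, truth), 0.95)

  # dark gray low-saturation block (scanner text) is excluded
  r2 <- fx$raster
  r2[21:140, 21:140, ] <- 0.45         # saturation ~ 0 gray block
  m2 <- compute_tissue_mask(r2)
  expect_lt(mean(m2$mask[31:130, 31:130]), 0.05)
  # tissue part still present
  expect_gte(iou(m2$mask | (truth & m$mask), truth), 0.9)
})

test_that("patch extraction matches a brute-force tissue-fraction scan", {
  full <- structure(list(mask = matrix(TRUE, 512, 512), dim = c(512L, 512L)),
                    class = "tissue_mask")
  ps <- extract_patches(full, 256L, 0.5)
  expect_equal(nrow(ps), 4)
  expect_setequal(paste(ps$x, ps$y),
                  c("0 0", "256 0", "0 256", "256 256"))
  empty <- structure(list(mask = matrix(FALSE, 512, 512), dim = c(512L, 512L)),
                     class = "tissue_mask")
  expect_equal(nrow(extract_patches(empty, 256L, 0.5)), 0)
  expect_error(extract_patches(full, 1024L, 0.5), "larger")

  # random half-covered mask vs brute force at several thresholds
  set.seed(12)
  mm <- matrix(runif(192 * 192) < 0.5, 192, 192)
  tm <- structure(list(mask = mm, dim = c(192L, 192L)), class = "tissue_mask")
  for (thr in c(0.3, 0.5, 0.52)) {
    got <- extract_patches(tm, 64L, thr)
    want <- NULL
    for (bx in 0:2) for (by in 0:2) {
      fr <- mean(mm[(by * 64 + 1):(by * 64 + 64), (bx * 64 + 1):(bx * 64 + 64)])
      if (fr >= thr) want <- rbind(want, c(bx * 64, by * 64))
    }
    expect_setequal(paste(got$x, got$y), paste(want[, 1], want[, 2]))
  }
})

test_that("sections and pieces are assigned from connectivity radii", {
  # two blobs 6000 px apart: two sections, one piece each
  xy <- rbind(blob_coords(1000, 1000, 900), blob_coords(7000, 1000, 900))
  ps <- assign_sections_pieces(coords_patchset(xy), 2, c(1, 1))
  truth <- c(rep(0L, nrow(blob_coords(1000, 1000, 900))),
             rep(1L, nrow(blob_coords(7000, 1000, 900))))
  expect_equal(ps$section, truth)
  expect_true(all(ps$piece == 0))

  # one section, two pieces 1000 px apart (joined at 4096, split at 512)
  xy2 <- rbind(blob_coords(1000, 1000, 600), blob_coords(3000, 1000, 600))
  ps2 <- assign_sections_pieces(coords_patchset(xy2), 1, 2)
  expect_true(all(ps2$section == 0))
  piece_truth <- c(rep(0L, nrow(blob_coords(1000, 1000, 600))),
                   rep(1L, nrow(blob_coords(3000, 1000, 600))))
  expect_equal(ps2$piece, piece_truth)

  # more sections than expected -> error naming the count
  expect_error(assign_sections_pieces(coords_patchset(xy), 1, 1), "2 sections")
})

test_that("conjoined pieces are split spectrally with high label agreement", {
  # twin-lobe dumbbell: two overlapping-ish blobs sharing a neck
  a <- blob_coords(1000, 1000, 700)
  b <- blob_coords(2600, 1000, 700)
  xy <- unique(rbind(a, b))
  ps <- assign_sections_pieces(coords_patchset(xy), 1, 2, seed = 2)
  truth <- as.integer(xy[, 1] + 128 > 1800)
  agree <- max(mean(ps$piece == truth), mean(ps$piece == 1 - truth))
  expect_gte(agree, 0.9)
})

test_that("assignment is invariant to patch order and translation", {
  xy <- rbind(blob_coords(1000, 1000, 600), blob_coords(3000, 1500, 500))
  ps <- assign_sections_pieces(coords_patchset(xy), 1, 2, seed = 5)
  set.seed(3); perm <- sample(nrow(xy))
  ps_p <- assign_sections_pieces(coords_patchset(xy[perm, ]), 1, 2, seed = 5)
  expect_equal(ps_p$piece[order(perm)], ps$piece)
  ps_t <- assign_sections_pieces(coords_patchset(sweep(xy, 2, c(512, 1024), `+`)),
                                 1, 2, seed = 5)
  expect_equal(ps_t$piece, ps$piece)
})

test_that("radius components agree with brute-force union-find", {
  set.seed(21)
  for (rep in 1:4) {
    xy <- cbind(runif(120, 0, 4000), runif(120, 0, 4000))
    for (r in c(300, 700)) {
      got <- marginmap:::radius_components(xy, r)
      want <- oracle_components(xy, r)
      # same partition up to relabeling
      expect_equal(length(unique(got)), length(unique(want)))
      expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
    }
  }
})

test_that("hole candidates tile interior holes and bridged tears", {
  # convex disk: no candidates
  fxc <- memo("disk400", std_section_fixture(seed = 6, canvas = 400L,
                                             patch_size = 50L, inks = list()))
  mc <- compute_tissue_mask(fxc$raster)
  pc <- assign_sections_pieces(extract_patches(mc, 50L, 0.5), 1, 1)
  mmc <- hole_candidates(pc, mc)
  expect_equal(sum(mmc$hole_candidate), 0)
  expect_identical(attr(mmc, "config"), "macro_map")

  # annulus: candidates equal the brute-force grid-in-hole count
  fx <- memo("annulus", std_section_fixture(
    seed = 7, canvas = 640L, patch_size = 64L, inks = list(),
    holes = list(disk_polygon(320, 320, 100))))
  m <- compute_tissue_mask(fx$raster)
  ps <- assign_sections_pieces(extract_patches(m, 64L, 0.5), 1, 1)
  mm <- hole_candidates(ps, m)
  hole_patches <- mm[mm$hole_candidate, ]
  want <- oracle_centers_in_polygon(seq(0, 576, 64), seq(0, 576, 64), 64,
                                    disk_polygon(320, 320, 100))
  expect_setequal(paste(hole_patches$x, hole_patches$y),
                  paste(want$x, want$y))
  # macro_map is a superset of tumor_map
  expect_true(all(paste(ps$x, ps$y) %in% paste(mm$x, mm$y)))
  # hole candidates never reach the tissue threshold
  expect_true(all(hole_patches$frac < attr(ps, "min_tissue_frac")))

  # wedge tear open to the boundary: the alpha shape bridges the mouth so
  # the tear patches are flagged
  fx2 <- memo("tear32", std_section_fixture(
    seed = 18, canvas = 640L, patch_size = 32L, inks = list(),
    tears = list(wedge_polygon(320, 320, 230.4, clock = 90, width_deg = 40,
                               depth = 0.8))))
  m2 <- compute_tissue_mask(fx2$raster)
  ps2 <- assign_sections_pieces(extract_patches(m2, 32L, 0.5), 1, 1)
  mm2 <- hole_candidates(ps2, m2, alpha = 1 / 128)
  tear_got <- mm2[mm2$hole_candidate, c("x", "y")]
  lab <- truth_patch_labels(fx2$truth, 32L)
  tear_want <- lab[lab$label == "hole", c("x", "y")]
  inter <- length(intersect(paste(tear_got$x, tear_got$y),
                            paste(tear_want$x, tear_want$y)))
  expect_gte(inter / length(union(paste(tear_got$x, tear_got$y),
                                  paste(tear_want$x, tear_want$y))), 0.8)
  expect_gt(nrow(tear_got), 0)

  # pieces with fewer than 4 patches are skipped with a warning
  tiny <- coords_patchset(rbind(c(0, 0), c(256, 0)))
  tiny$section <- 0L; tiny$piece <- 0L
  expect_warning(hole_candidates(tiny), "skipped")
})
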