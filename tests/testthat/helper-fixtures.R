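# Shared fixture builders. Expensive renders are memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A single-section disk slide with blue/red inks at given clock positions,
# optional holes/tears/tumors. Small canvas for speed.
std_section_fixture <- function(seed, blue_clock = 0, red_clock = 180,
                                canvas = 640L, patch_size = 64L,
                                holes = list(), tears = list(),
                                tumors = list(), follicles = list(),
                                inks = NULL) {
  cc <- canvas / 2; pr <- canvas * 0.36
  if (is.null(inks))
    inks <- list(list(color = "blue", clock = blue_clock),
                 list(color = "red", clock = red_clock))
  spec <- section_spec(
    canvas = c(canvas, canvas), patch_size = patch_size,
    sections = list(list(pieces = list(disk_polygon(cc, cc, pr)),
                         inks = inks, holes = holes, tears = tears,
                         tumors = tumors, follicles = follicles)),
    seed = seed)
  make_section_image(spec)
}

# Synthetic patch set directly from coordinates (no rendering) for the
# section/piece assignment tests.
coords_patchset <- function(xy, patch_size = 256L) {
  structure(data.frame(x = xy[, 1], y = xy[, 2], frac = 1,
                       section = NA_integer_, piece = NA_integer_,
                       hole_candidate = FALSE),
            patch_size = as.integer(patch_size), slide = "synth",
            config = "tumor_map", min_tissue_frac = 0.5,
            class = c("patch_set", "data.frame"))
}

# Grid-blob patch coordinates: all stride-grid points whose centers fall in
# a disk at (cx, cy) with radius r.
blob_coords <- function(cx, cy, r, patch = 256L) {
  xs <- seq(floor((cx - r) / patch) * patch, cx + r, by = patch)
  ys <- seq(floor((cy - r) / patch) * patch, cy + r, by = patch)
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x + patch / 2 - cx)^2 + (g$y + patch / 2 - cy)^2 <= r^2
  as.matrix(g[keep, , drop = FALSE])
}

std_box_cloud <- function(seed, extents = c(1, 2, 0.5), angle = 25,
                          axis = c(1, 0.3, 0.2), noise_sd = 0.02,
                          suture = list(clock = 0), n = 4000L) {
  make_cloud(cloud_spec(extents = extents,
                        rotation = list(axis = axis, angle = angle),
                        n = n, noise_sd = noise_sd, suture = suture,
                        seed = seed))
}
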