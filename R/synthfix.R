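# Synthetic fixture generators. Every generator is a pure function of its
# spec + seed and returns the synthetic input together with ground truth rich
# enough to score the downstream operation without re-deriving it from pixels.
# Rasters are numeric arrays [row = y, col = x, channel] in [0, 1]; pixel
# coordinates are 0-based with the origin at the top-left and y down.

#' Specification for a synthetic multi-piece tissue section raster
#'
#' Describes the content of one synthetic slide: tissue piece outlines, edge
#' ink arcs at clock positions, interior holes, edge tears, texture-distinct
#' tumor regions and follicle disks. Textures are low-amplitude value noise
#' plus cell-like speckle; tumor regions carry a region-level latent that
#' raises the speckle density, so classes are separable but noisy at the
#' single-patch level.
#'
#' @param canvas integer `c(width, height)` in pixels.
#' @param sections list of sections. Each section is a list with elements
#'   `pieces` (list of polygon matrices, columns x and y, pixel units),
#'   `conjoined` (logical; allow touching pieces), `inks` (list of
#'   `list(color=, clock=, span=, piece=)` arcs on the piece boundary),
#'   `holes`, `tears`, `tumors` (lists of polygons) and `follicles`
#'   (list of `list(center=, r=)` disks).
#' @param background background shade in `[0, 1]`.
#' @param noise texture value-noise amplitude.
#' @param patch_size grid used for the ground-truth per-patch class labels.
#' @param seed integer seed; the render is bit-reproducible.
#' @return an object of class `section_spec`.
#' @export
section_spec <- function(canvas = c(1024L, 1024L), sections = list(),
                         background = 0.97, noise = 0.04,
                         patch_size = 256L, seed = 1L) {
  stopifnot(length(canvas) == 2, all(canvas > 0), noise >= 0)
  defaults <- list(pieces = list(), conjoined = FALSE, inks = list(),
                   holes = list(), tears = list(), tumors = list(),
                   follicles = list())
  sections <- lapply(sections, function(s) {
    for (nm in names(defaults)) if (is.null(s[[nm]])) s[[nm]] <- defaults[[nm]]
    s
  })
  for (s in sections) for (poly in c(s$pieces, s$holes, s$tumors))
    if (any(poly[, 1] < 0 | poly[, 1] >= canvas[1] |
            poly[, 2] < 0 | poly[, 2] >= canvas[2]))
      stop("section_spec: ground-truth element outside canvas bounds")
  structure(list(canvas = as.integer(canvas), sections = sections,
                 background = background, noise = noise,
                 patch_size = as.integer(patch_size), seed = as.integer(seed)),
            class = "section_spec")
}

#' Regular-polygon approximations of common fixture shapes
#'
#' @param cx,cy center in pixels.
#' @param r radius in pixels.
#' @param n number of vertices.
#' @return polygon matrix with columns x, y.
#' @export
disk_polygon <- function(cx, cy, r, n = 72L) regular_polygon(cx, cy, r, n)

#' @rdname disk_polygon
#' @param clock clock angle (degrees) at which the wedge opens.
#' @param width_deg angular width of the wedge.
#' @param depth radial depth of the wedge, as a fraction of `r`.
#' @export
wedge_polygon <- function(cx, cy, r, clock, width_deg = 25, depth = 0.55) {
  th <- (clock + seq(-width_deg / 2, width_deg / 2, length.out = 9)) * pi / 180
  outer <- cbind(cx + 1.06 * r * sin(th), cy - 1.06 * r * cos(th))
  tip <- c(cx + (1 - depth) * r * sin(mean(th)), cy - (1 - depth) * r * cos(mean(th)))
  rbind(outer, tip)
}

ink_palette <- function() {
  list(blue   = c(0.10, 0.20, 0.90), red    = c(0.85, 0.06, 0.08),
       yellow = c(0.95, 0.85, 0.10), green  = c(0.10, 0.70, 0.15),
       orange = c(0.95, 0.55, 0.05), purple = c(0.55, 0.10, 0.75),
       black  = c(0.08, 0.08, 0.08))
}

# Rasterise a polygon into a logical [y, x] matrix over the full canvas.
rasterize_polygon <- function(poly, canvas) {
  W <- canvas[1]; H <- canvas[2]
  xr <- pmax(0L, floor(min(poly[, 1]))):pmin(W - 1L, ceiling(max(poly[, 1])))
  yr <- pmax(0L, floor(min(poly[, 2]))):pmin(H - 1L, ceiling(max(poly[, 2])))
  m <- matrix(FALSE, H, W)
  if (!length(xr) || !length(yr)) return(m)
  gx <- rep(xr, times = length(yr)); gy <- rep(yr, each = length(xr))
  inside <- point_in_polygon(gx, gy, poly)
  m[cbind(gy[inside] + 1L, gx[inside] + 1L)] <- TRUE
  m
}

# Paint speckle discs of radius `rad` at `centers` (0-based x, y) scaled by
# `dark` into raster channels.
paint_speckle <- function(raster, centers, rad, dark) {
  if (!nrow(centers)) return(raster)
  H <- dim(raster)[1]; W <- dim(raster)[2]
  off <- expand.grid(dx = -rad:rad, dy = -rad:rad)
  off <- off[off$dx^2 + off$dy^2 <= rad^2, ]
  px <- rep(centers[, 1], each = nrow(off)) + off$dx
  py <- rep(centers[, 2], each = nrow(off)) + off$dy
  ok <- px >= 0 & px < W & py >= 0 & py < H
  idx <- cbind(py[ok] + 1L, px[ok] + 1L)
  for (ch in 1:3) {
    pl <- raster[, , ch]
    pl[idx] <- pl[idx] * (1 - dark)
    raster[, , ch] <- pl
  }
  raster
}

#' Render a synthetic tissue-section raster with ground truth
#'
#' Draws each tissue piece on a near-white background with a textured
#' interior, saturated ink bands on the outer boundary at the requested clock
#' positions, interior holes and edge tears rendered as background, tumor
#' regions with distinct (denser, darker) speckle statistics and follicle
#' disks. The returned ground truth records all generating polygons, rendered
#' ink pixel centroids, the true blue-to-red orientation angle per section and
#' per-patch class labels on the spec's patch grid.
#'
#' @param spec a [section_spec()].
#' @return list with elements `raster` (H x W x 3 array) and `truth`.
#' @export
make_section_image <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  W <- spec$canvas[1]; H <- spec$canvas[2]
  with_seed(spec$seed, {
    raster <- array(spec$background, dim = c(H, W, 3)) +
      array(runif(H * W, -0.01, 0.01), dim = c(H, W, 3))
    tissue_masks <- list()
    truth_sections <- list()
    all_piece_masks <- list()
    for (si in seq_along(spec$sections)) {
      sec <- spec$sections[[si]]
      piece_masks <- lapply(sec$pieces, rasterize_polygon, canvas = spec$canvas)
      if (!isTRUE(sec$conjoined) && length(piece_masks) > 1) {
        for (i in seq_along(piece_masks)[-1]) for (j in seq_len(i - 1))
          if (any(piece_masks[[i]] & piece_masks[[j]]))
            stop("make_section_image: overlapping non-conjoined pieces in section ", si)
      }
      sec_inks <- list()
      # Texture statistics are drawn per region (latent stain/texture
      # variability): each piece gets a jittered benign tint and speckle
      # rate, each tumor region a depth factor for its darker tint and
      # denser speckle. Classes overlap at the single-patch level, so
      # patch-level evidence is noisy while patches of one region share
      # the same latent -- mirroring why spatial context helps on real
      # sections.
      benign_rate <- 0.0045
      base <- c(0.87, 0.72, 0.78) + runif(3, -0.03, 0.03)
      for (pi in seq_along(sec$pieces)) {
        m <- piece_masks[[pi]]
        idx <- which(m, arr.ind = TRUE)          # [row=y+1, col=x+1]
        if (!nrow(idx)) next
        for (ch in 1:3) {
          pl <- raster[, , ch]
          pl[idx] <- base[ch] + runif(nrow(idx), -spec$noise, spec$noise)
          raster[, , ch] <- pl
        }
        # benign cell-like speckle
        ns <- max(1L, round(nrow(idx) * benign_rate))
        cs <- idx[sample.int(nrow(idx), ns), , drop = FALSE]
        raster <- paint_speckle(raster, cbind(cs[, 2] - 1L, cs[, 1] - 1L), 2L, 0.30)
      }
      # tumor regions: darker basaloid tint + denser speckle, with a
      # region-level depth factor that overlaps the benign range
      for (tp in sec$tumors) {
        tm <- rasterize_polygon(tp, spec$canvas)
        tm <- tm & Reduce(`|`, piece_masks)
        idx <- which(tm, arr.ind = TRUE)
        if (!nrow(idx)) next
        depth <- runif(1, 0.3, 1)
        tint <- base
        for (ch in 1:3) {
          pl <- raster[, , ch]
          pl[idx] <- tint[ch] + runif(nrow(idx), -spec$noise, spec$noise)
          raster[, , ch] <- pl
        }
        ns <- max(1L, round(nrow(idx) * (benign_rate + depth * 0.005)))
        cs <- idx[sample.int(nrow(idx), ns), , drop = FALSE]
        raster <- paint_speckle(raster, cbind(cs[, 2] - 1L, cs[, 1] - 1L), 2L, 0.30)
      }
      for (fo in sec$follicles) {
        fp <- disk_polygon(fo$center[1], fo$center[2], fo$r)
        fm <- rasterize_polygon(fp, spec$canvas) & Reduce(`|`, piece_masks)
        idx <- which(fm, arr.ind = TRUE)
        if (!nrow(idx)) next
        tint <- c(0.76, 0.62, 0.72)
        for (ch in 1:3) {
          pl <- raster[, , ch]
          pl[idx] <- tint[ch] + runif(nrow(idx), -spec$noise, spec$noise)
          raster[, , ch] <- pl
        }
        ns <- max(1L, round(nrow(idx) * 0.012))
        cs <- idx[sample.int(nrow(idx), ns), , drop = FALSE]
        raster <- paint_speckle(raster, cbind(cs[, 2] - 1L, cs[, 1] - 1L), 2L, 0.40)
      }
      # holes / tears rendered as background
      for (hp in c(sec$holes, sec$tears)) {
        hm <- rasterize_polygon(hp, spec$canvas)
        idx <- which(hm, arr.ind = TRUE)
        if (!nrow(idx)) next
        for (ch in 1:3) {
          pl <- raster[, , ch]
          pl[idx] <- spec$background + runif(nrow(idx), -0.01, 0.01)
          raster[, , ch] <- pl
        }
        for (pi in seq_along(piece_masks)) piece_masks[[pi]] <- piece_masks[[pi]] & !hm
      }
      # ink bands restricted to the outer boundary
      pal <- ink_palette()
      for (ink in sec$inks) {
        pi <- ink$piece %||% 1L
        thk <- ink$thickness %||% 12L
        span <- ink$span %||% 40
        poly <- sec$pieces[[pi]]
        m <- piece_masks[[pi]]
        er <- EBImage::erode(m * 1, EBImage::makeBrush(2L * thk + 1L, "disc"))
        band <- which(m & !(er > 0.5), arr.ind = TRUE)
        if (!nrow(band)) next
        ctr <- polygon_centroid(poly)
        ang <- clock_angle(band[, 2] - 1L - ctr[1], band[, 1] - 1L - ctr[2])
        keep <- abs(relative_angle(ang, ink$clock)) <= span / 2
        idx <- band[keep, , drop = FALSE]
        if (!nrow(idx)) next
        col <- pal[[ink$color]]
        for (ch in 1:3) {
          pl <- raster[, , ch]
          pl[idx] <- col[ch]
          raster[, , ch] <- pl
        }
        sec_inks[[length(sec_inks) + 1L]] <- list(
          color = ink$color, clock = ink$clock,
          centroid = c(mean(idx[, 2] - 1L), mean(idx[, 1] - 1L)),
          n_pixels = nrow(idx))
      }
      ink_cols <- vapply(sec_inks, `[[`, character(1), "color")
      orientation <- NA_real_
      if ("blue" %in% ink_cols && "red" %in% ink_cols) {
        b <- sec_inks[[match("blue", ink_cols)]]$centroid
        r <- sec_inks[[match("red", ink_cols)]]$centroid
        orientation <- clock_angle(r[1] - b[1], r[2] - b[2])
      }
      tissue_masks <- c(tissue_masks, piece_masks)
      all_piece_masks[[si]] <- piece_masks
      truth_sections[[si]] <- list(
        pieces = sec$pieces, holes = sec$holes, tears = sec$tears,
        tumors = sec$tumors, follicles = sec$follicles,
        inks = sec_inks, orientation = orientation)
    }
    raster[raster < 0] <- 0; raster[raster > 1] <- 1
    truth <- list(canvas = spec$canvas, patch_size = spec$patch_size,
                  sections = truth_sections)
    truth$patch_labels <- truth_patch_labels(truth, spec$patch_size)
    list(raster = raster, truth = truth)
  })
}

#' Ground-truth patch labels on a regular grid
#'
#' Labels every patch of the grid by the membership of its center point:
#' `tumor`, `follicle`, `hole` (holes and tears), `benign` (other tissue) or
#' `background`, together with 0-based section and piece indices.
#'
#' @param truth ground truth from [make_section_image()].
#' @param patch_size grid pitch in pixels.
#' @return data.frame with columns x, y (top-left corner), label, section, piece.
#' @export
truth_patch_labels <- function(truth, patch_size = 256L) {
  W <- truth$canvas[1]; H <- truth$canvas[2]
  xs <- seq(0L, W - patch_size, by = patch_size)
  ys <- seq(0L, H - patch_size, by = patch_size)
  g <- expand.grid(x = xs, y = ys)
  cx <- g$x + patch_size / 2; cy <- g$y + patch_size / 2
  lab <- rep("background", nrow(g))
  sec_id <- rep(NA_integer_, nrow(g)); piece_id <- rep(NA_integer_, nrow(g))
  for (si in seq_along(truth$sections)) {
    sec <- truth$sections[[si]]
    for (pi in seq_along(sec$pieces)) {
      inside <- point_in_polygon(cx, cy, sec$pieces[[pi]])
      lab[inside] <- "benign"
      sec_id[inside] <- si - 1L; piece_id[inside] <- pi - 1L
    }
    for (fo in sec$follicles) {
      inside <- point_in_polygon(cx, cy, disk_polygon(fo$center[1], fo$center[2], fo$r))
      lab[inside & lab == "benign"] <- "follicle"
    }
    for (tp in sec$tumors) {
      inside <- point_in_polygon(cx, cy, tp)
      lab[inside & lab %in% c("benign", "follicle")] <- "tumor"
    }
    for (hp in c(sec$holes, sec$tears)) {
      inside <- point_in_polygon(cx, cy, hp)
      lab[inside & lab != "background"] <- "hole"
    }
  }
  data.frame(x = g$x, y = g$y, label = lab, section = sec_id, piece = piece_id)
}

#' Specification for a synthetic boxlike gross-specimen point cloud
#'
#' @param extents numeric `c(x, y, z)` box extents in cm (all > 0).
#' @param rotation list with `axis` (3-vector) and `angle` (degrees).
#' @param translation 3-vector, model units.
#' @param n point count (>= 100).
#' @param noise_sd isotropic Gaussian noise, cm.
#' @param suture `NULL` or `list(clock=)`: clock angle of a distinctly
#'   colored suture marker blob on the top rim (12 o'clock = +y).
#' @param scale cm per model unit.
#' @param seed integer seed.
#' @return object of class `cloud_spec`.
#' @export
cloud_spec <- function(extents = c(1, 2, 0.5),
                       rotation = list(axis = c(0, 0, 1), angle = 0),
                       translation = c(0, 0, 0), n = 4000L, noise_sd = 0.02,
                       suture = list(clock = 0), scale = 1, seed = 1L) {
  stopifnot(n >= 100, noise_sd >= 0, all(extents > 0), scale > 0)
  structure(list(extents = extents, rotation = rotation,
                 translation = translation, n = as.integer(n),
                 noise_sd = noise_sd, suture = suture, scale = scale,
                 seed = as.integer(seed)), class = "cloud_spec")
}

rotation_matrix_axis_angle <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2)); th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a boxlike specimen point cloud with ground truth
#'
#' Samples the surface of a box with the given extents (the flat bottom face
#' is sampled three times as densely, emulating the turntable contact face),
#' adds Gaussian noise, colors a suture marker blob near the top rim at the
#' requested clock angle, and applies the rigid transform.
#'
#' @param spec a [cloud_spec()].
#' @return list with `points` (n x 3, model units), `colors` (n x 3),
#'   `scale` (cm per model unit) and `truth` (true extents cm, bottom-face
#'   normal, suture direction, rotation, translation).
#' @export
make_cloud <- function(spec) {
  stopifnot(inherits(spec, "cloud_spec"))
  ex <- spec$extents / spec$scale  # model units
  with_seed(spec$seed, {
    areas <- c(bottom = 3 * ex[1] * ex[2], top = ex[1] * ex[2],
               x1 = ex[2] * ex[3], x2 = ex[2] * ex[3],
               y1 = ex[1] * ex[3], y2 = ex[1] * ex[3])
    cnt <- round(spec$n * areas / sum(areas))
    cnt[1] <- spec$n - sum(cnt[-1])
    face <- function(k, m) {
      u <- runif(m, -0.5, 0.5); v <- runif(m, -0.5, 0.5)
      switch(k,
        bottom = cbind(u * ex[1], v * ex[2], 0),
        top    = cbind(u * ex[1], v * ex[2], ex[3]),
        x1     = cbind(-ex[1] / 2, u * ex[2], (v + 0.5) * ex[3]),
        x2     = cbind(ex[1] / 2, u * ex[2], (v + 0.5) * ex[3]),
        y1     = cbind(u * ex[1], -ex[2] / 2, (v + 0.5) * ex[3]),
        y2     = cbind(u * ex[1], ex[2] / 2, (v + 0.5) * ex[3]))
    }
    pts <- do.call(rbind, lapply(names(areas), function(k) face(k, cnt[[k]])))
    cols <- matrix(rep(c(0.85, 0.70, 0.72), each = nrow(pts)), ncol = 3) +
      matrix(runif(3 * nrow(pts), -0.05, 0.05), ncol = 3)
    suture_dir <- NULL
    if (!is.null(spec$suture)) {
      d2 <- clock_vector(spec$suture$clock) * c(1, -1)  # x east, y north
      pos <- c(d2[1] * 0.42 * ex[1], d2[2] * 0.42 * ex[2], ex[3])
      ns <- max(20L, round(spec$n * 0.015))
      blob <- matrix(rnorm(3 * ns, sd = 0.02 * min(ex[1:2])), ncol = 3)
      blob <- sweep(blob, 2, pos, `+`)
      pts <- rbind(pts, blob)
      cols <- rbind(cols, matrix(rep(c(0.05, 0.05, 0.35), each = ns), ncol = 3))
      suture_dir <- c(d2, 0)
    }
    pts <- pts + matrix(rnorm(length(pts), sd = spec$noise_sd / spec$scale),
                        ncol = 3)
    R <- rotation_matrix_axis_angle(spec$rotation$axis, spec$rotation$angle)
    pts <- t(R %*% t(pts))
    pts <- sweep(pts, 2, spec$translation, `+`)
    cols[cols < 0] <- 0; cols[cols > 1] <- 1
    list(points = pts, colors = cols, scale = spec$scale,
         truth = list(extents_cm = spec$extents,
                      bottom_normal = as.vector(R %*% c(0, 0, -1)),
                      suture_dir = if (is.null(suture_dir)) NULL
                                   else as.vector(R %*% suture_dir),
                      rotation = R, translation = spec$translation))
  })
}

#' Synthetic spatially structured patch-graph datasets
#'
#' Generates `n_slides` point layouts with latent node fields; the node label
#' is a thresholded mixture of the node's own latent value and its
#' radius-neighborhood average, so that graph context carries label
#' information in proportion to `spatial_signal`. Node features are noisy
#' views of the latent value padded with pure-noise dimensions.
#'
#' @param n_slides number of independent graphs.
#' @param nodes_per_slide nodes per graph.
#' @param feature_dim feature dimensionality (first dimension informative).
#' @param spatial_signal mixing weight in `[0, 1]`: 0 = label depends only on
#'   the node's own latent value, 1 = only on the neighborhood average.
#' @param seed integer seed.
#' @param radius neighbor radius in the unit layout (default 0.18).
#' @param feature_noise sd of the feature observation noise.
#' @return list of graphs, each with `coords`, `features`, `labels`, `radius`.
#' @export
make_patch_dataset <- function(n_slides, nodes_per_slide, feature_dim = 8L,
                               spatial_signal = 1, seed = 1L, radius = 0.18,
                               feature_noise = 0.8) {
  stopifnot(spatial_signal >= 0, spatial_signal <= 1)
  with_seed(seed, {
    lapply(seq_len(n_slides), function(g) {
      coords <- cbind(runif(nodes_per_slide), runif(nodes_per_slide))
      u <- rnorm(nodes_per_slide)
      pr <- radius_pairs(coords, radius)
      nb_sum <- u; nb_n <- rep(1, nodes_per_slide)
      if (nrow(pr)) {
        for (cl in 1:2) {
          i <- pr[, cl]; j <- pr[, 3 - cl]
          acc <- tapply(u[j], i, sum); cnt <- table(i)
          ii <- as.integer(names(acc))
          nb_sum[ii] <- nb_sum[ii] + acc
          nb_n[ii] <- nb_n[ii] + as.integer(cnt)
        }
      }
      ubar <- nb_sum / nb_n
      m <- (1 - spatial_signal) * u + spatial_signal * ubar
      labels <- as.integer(m > 0)
      feats <- matrix(rnorm(nodes_per_slide * feature_dim), ncol = feature_dim)
      feats[, 1] <- u + feature_noise * rnorm(nodes_per_slide)
      list(coords = coords, features = feats, labels = labels, radius = radius)
    })
  })
}

#' Surgical-map template raster with ellipse and orientation marks
#'
#' Renders the surgeon's template: a black ellipse marking the removal site
#' with blue and red marks on its boundary defining 12 and 6 o'clock.
#'
#' @param anatomy_name label stored in the metadata.
#' @param ellipse `list(center=c(x,y), axes=c(a,b), rotation=deg)`;
#'   axes are the semi-axes in pixels.
#' @param blue_mark,red_mark `c(x, y)` points on the ellipse boundary.
#' @param canvas `c(width, height)` pixels.
#' @param tol relative tolerance for the on-boundary check.
#' @return list with `raster` and `meta` (ellipse, marks, template clock
#'   angle of the blue-to-red line).
#' @export
make_template <- function(anatomy_name, ellipse, blue_mark, red_mark,
                          canvas = c(512L, 512L), tol = 0.08) {
  if (any(ellipse$axes <= 0)) stop("make_template: degenerate ellipse axis")
  rot <- (ellipse$rotation %||% 0) * pi / 180
  eval_ellipse <- function(p) {
    d <- p - ellipse$center
    xr <- cos(rot) * d[1] + sin(rot) * d[2]
    yr <- -sin(rot) * d[1] + cos(rot) * d[2]
    (xr / ellipse$axes[1])^2 + (yr / ellipse$axes[2])^2
  }
  for (mk in list(blue_mark, red_mark))
    if (abs(sqrt(eval_ellipse(mk)) - 1) > tol)
      stop("make_template: mark not on ellipse boundary within tolerance")
  W <- canvas[1]; H <- canvas[2]
  raster <- array(1, dim = c(H, W, 3))
  th <- seq(0, 2 * pi, length.out = 720)
  bx <- ellipse$center[1] + ellipse$axes[1] * cos(th) * cos(rot) -
        ellipse$axes[2] * sin(th) * sin(rot)
  by <- ellipse$center[2] + ellipse$axes[1] * cos(th) * sin(rot) +
        ellipse$axes[2] * sin(th) * cos(rot)
  paint_disk <- function(raster, cx, cy, r, col) {
    for (xx in max(0, floor(cx - r)):min(W - 1, ceiling(cx + r)))
      for (yy in max(0, floor(cy - r)):min(H - 1, ceiling(cy + r)))
        if ((xx - cx)^2 + (yy - cy)^2 <= r^2) raster[yy + 1, xx + 1, ] <- col
    raster
  }
  for (k in seq_along(th))
    raster <- paint_disk(raster, bx[k], by[k], 1.5, c(0, 0, 0))
  raster <- paint_disk(raster, blue_mark[1], blue_mark[2], 5, c(0.1, 0.2, 0.9))
  raster <- paint_disk(raster, red_mark[1], red_mark[2], 5, c(0.85, 0.06, 0.08))
  meta <- list(anatomy = anatomy_name, ellipse = ellipse,
               blue_mark = blue_mark, red_mark = red_mark,
               template_angle = clock_angle(red_mark[1] - blue_mark[1],
                                            red_mark[2] - blue_mark[2]))
  list(raster = raster, meta = meta)
}

#' Synthetic turntable video frames of a revolving specimen
#'
#' Emulates the calibration/segmentation input: a light background, a darker
#' turntable ellipse, a dark specimen blob revolving along an elliptical
#' trajectory, and optional static distractor blobs.
#'
#' @param n_frames number of frames.
#' @param size `c(height, width)` pixels.
#' @param table_axes turntable ellipse semi-axes `c(a, b)` in pixels.
#' @param blob_r specimen blob radius in pixels.
#' @param path_scale specimen trajectory semi-axes as a fraction of the table's.
#' @param distractors list of `list(center=, r=)` static dark blobs.
#' @param seed integer seed.
#' @return list with `frames` (list of H x W grayscale matrices) and `truth`
#'   (per-frame blob centers, table ellipse parameters).
#' @export
make_turntable_frames <- function(n_frames = 36L, size = c(240L, 320L),
                                  table_axes = c(120, 80), blob_r = 14,
                                  path_scale = 0.55, distractors = list(),
                                  seed = 1L) {
  H <- size[1]; W <- size[2]
  ctr <- c(W / 2, H / 2)
  with_seed(seed, {
    ang <- seq(0, 2 * pi, length.out = n_frames + 1L)[seq_len(n_frames)]
    centers <- cbind(ctr[1] + path_scale * table_axes[1] * cos(ang),
                     ctr[2] + path_scale * table_axes[2] * sin(ang))
    xs <- matrix(rep(0:(W - 1), each = H), H, W)
    ys <- matrix(rep(0:(H - 1), W), H, W)
    table_mask <- ((xs - ctr[1]) / table_axes[1])^2 +
                  ((ys - ctr[2]) / table_axes[2])^2 <= 1
    frames <- lapply(seq_len(n_frames), function(f) {
      img <- matrix(0.92, H, W) + matrix(rnorm(H * W, sd = 0.01), H, W)
      img[table_mask] <- 0.75
      blob <- (xs - centers[f, 1])^2 + (ys - centers[f, 2])^2 <= blob_r^2
      img[blob] <- 0.15
      for (d in distractors) {
        dm <- (xs - d$center[1])^2 + (ys - d$center[2])^2 <= d$r^2
        img[dm] <- 0.18
      }
      img[img < 0] <- 0; img[img > 1] <- 1
      img
    })
    list(frames = frames,
         truth = list(centers = centers, blob_r = blob_r,
                      table_center = ctr, table_axes = table_axes))
  })
}
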