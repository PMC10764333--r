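# Gross-specimen 3D workflow: turntable-frame segmentation and trajectory
# filtering, turntable distance calibration, point-cloud refinement and
# orientation (RANSAC plane to the flat bottom face, suture to +y), L/W/H
# measurement, and Mohs/breadloaf grossing-and-inking recommendations.
# Clouds come from external photogrammetry; the package consumes their
# PLY/XYZ output (see read_ply/read_xyz).

#' Specimen point-cloud container
#'
#' @param points n x 3 matrix, model units.
#' @param colors n x 3 RGB matrix in `[0, 1]` (optional).
#' @param scale cm per model unit (NA until calibrated).
#' @param oriented has [orient_cloud()] been applied.
#' @return object of class `specimen_cloud`.
#' @export
specimen_cloud <- function(points, colors = NULL, scale = NA_real_,
                           oriented = FALSE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  structure(list(points = points, colors = colors, scale = scale,
                 oriented = oriented, suture_found = FALSE,
                 orientation_fixed = FALSE),
            class = "specimen_cloud")
}

# ---- frame segmentation and trajectory filtering --------------------------

#' Segment the specimen in turntable video frames
#'
#' Per frame: intensity thresholding (the specimen is dark against the light
#' table), connected-component labeling, and an object size filter. A
#' configurable fraction of frames is retained, emulating the frame
#' subsampling used to bound reconstruction time.
#'
#' @param frames list of grayscale matrices in `[0, 1]`.
#' @param intensity_thresh pixels below this are object candidates.
#' @param min_px,max_px component size window in pixels.
#' @param keep_fraction fraction of frames retained (evenly spaced).
#' @return list of per-frame detections: `frame`, `objects` (each with
#'   `centroid`, `npx`, `mask`), `kept` flag (set by trajectory filtering).
#' @export
segment_frames <- function(frames, intensity_thresh = 0.4, min_px = 40L,
                           max_px = Inf, keep_fraction = 1) {
  stopifnot(length(frames) >= 8)
  sel <- unique(round(seq(1, length(frames),
                          length.out = max(1, round(length(frames) * keep_fraction)))))
  dets <- lapply(sel, function(f) {
    img <- frames[[f]]
    cand <- img < intensity_thresh
    objects <- list()
    if (any(cand)) {
      lab <- EBImage::bwlabel(cand * 1)
      sizes <- tabulate(lab[lab > 0])
      for (o in which(sizes >= min_px & sizes <= max_px)) {
        idx <- which(lab == o, arr.ind = TRUE)
        objects[[length(objects) + 1L]] <- list(
          centroid = c(mean(idx[, 2] - 1L), mean(idx[, 1] - 1L)),
          npx = nrow(idx), mask = lab == o)
      }
    }
    list(frame = f, objects = objects, kept = rep(NA, length(objects)))
  })
  n_empty <- sum(vapply(dets, function(d) length(d$objects) == 0, logical(1)))
  if (n_empty > length(dets) / 2)
    stop("segment_frames: no candidate object in more than half of the frames")
  dets
}

# Residual of points to an ellipse (center cx,cy; semi-axes a,b; rotation phi):
# |sqrt(Q) - 1| * min(a, b), an approximate geometric distance.
ellipse_residual <- function(px, py, el) {
  ca <- cos(el$phi); sa <- sin(el$phi)
  xr <- ca * (px - el$cx) + sa * (py - el$cy)
  yr <- -sa * (px - el$cx) + ca * (py - el$cy)
  q <- sqrt(pmax((xr / el$a)^2 + (yr / el$b)^2, 0))
  abs(q - 1) * min(el$a, el$b)
}

# Direct least-squares conic fit (ellipse-specific, Halir-Flusser partition).
fit_ellipse_lsq <- function(px, py) {
  x <- px - mean(px); y <- py - mean(py)
  D1 <- cbind(x^2, x * y, y^2); D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) return(NULL)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) return(NULL)
  a1 <- vecs[, ok[1]]
  coef <- c(a1, Tm %*% a1)   # A B C D E F on centered coords
  A <- coef[1]; B <- coef[2] / 2; C <- coef[3]
  D <- coef[4] / 2; E <- coef[5] / 2; F <- coef[6]
  den <- A * C - B^2
  if (abs(den) < 1e-12) return(NULL)
  cx <- (B * E - C * D) / den
  cy <- (B * D - A * E) / den
  # constant term after translating to the center; semi-axes from the
  # eigenvalues of the quadratic form [[A, B], [B, C]]
  F2 <- A * cx^2 + 2 * B * cx * cy + C * cy^2 + 2 * D * cx + 2 * E * cy + F
  s <- sqrt(pmax((A - C)^2 + 4 * B^2, 0))
  lam1 <- (A + C + s) / 2; lam2 <- (A + C - s) / 2
  a2 <- -F2 / lam2; b2 <- -F2 / lam1   # along-phi axis uses lam1
  if (is.na(a2) || is.na(b2) || a2 <= 0 || b2 <= 0) return(NULL)
  phi <- 0.5 * atan2(2 * B, A - C)
  ax <- sqrt(b2); bx <- sqrt(a2)       # ax = semi-axis along phi
  if (ax < bx) { tmp <- ax; ax <- bx; bx <- tmp; phi <- phi + pi / 2 }
  list(cx = cx + mean(px), cy = cy + mean(py), a = ax, b = bx,
       phi = phi %% pi)
}

# RANSAC ellipse fit over 2D points.
ransac_ellipse <- function(px, py, n_iter = 300L, tol = 3, seed = 1L,
                           min_inliers = 5L) {
  n <- length(px)
  if (n < 6) return(NULL)
  with_seed(seed, {
    best <- NULL; best_in <- 0L
    for (it in seq_len(n_iter)) {
      s <- sample.int(n, 6L)
      el <- tryCatch(fit_ellipse_lsq(px[s], py[s]), error = function(e) NULL)
      if (is.null(el) || el$a > 10 * diff(range(px)) + 10) next
      r <- ellipse_residual(px, py, el)
      nin <- sum(r < tol)
      if (nin > best_in) { best_in <- nin; best <- el }
    }
    if (is.null(best) || best_in < min_inliers) return(NULL)
    inl <- ellipse_residual(px, py, best) < tol
    ref <- tryCatch(fit_ellipse_lsq(px[inl], py[inl]), error = function(e) NULL)
    if (!is.null(ref)) best <- ref
    best$inliers <- which(ellipse_residual(px, py, best) < tol)
    best
  })
}

#' Keep detections whose centroids follow the turntable ellipse
#'
#' The specimen is the only object whose centroid traces an elliptical
#' trajectory over one revolution; a RANSAC ellipse is fit to all candidate
#' centroids and objects off the trajectory (static distractors, noise) are
#' rejected.
#'
#' @param detections a [segment_frames()] result.
#' @param tol inlier residual threshold in pixels.
#' @param seed RANSAC seed.
#' @param min_inlier_frac minimum fraction of distinct centroid positions on
#'   the fitted ellipse for the trajectory to count as found.
#' @return detections with `kept` flags filled.
#' @export
filter_by_trajectory <- function(detections, tol = 4, seed = 1L,
                                 min_inlier_frac = 0.6) {
  cents <- do.call(rbind, lapply(detections, function(d)
    if (length(d$objects))
      cbind(do.call(rbind, lapply(d$objects, `[[`, "centroid")))))
  if (is.null(cents) || nrow(cents) < 8)
    stop("filter_by_trajectory: need at least 8 centroids")
  # fit on de-duplicated positions so a static object (many identical
  # centroids) cannot dominate the inlier count
  uq <- unique(round(cents))
  el <- ransac_ellipse(uq[, 1], uq[, 2], tol = tol, seed = seed,
                       n_iter = 1000L)
  if (is.null(el) || length(el$inliers) < 5 ||
      length(el$inliers) < min_inlier_frac * nrow(uq) ||
      el$a / el$b > 10)
    stop("filter_by_trajectory: fewer than 5 trajectory inliers ",
         "(no elliptical temporal trajectory found)")
  el$inliers <- which(ellipse_residual(cents[, 1], cents[, 2], el) < tol)
  k <- 0L
  for (f in seq_along(detections)) {
    for (o in seq_along(detections[[f]]$objects)) {
      k <- k + 1L
      detections[[f]]$kept[o] <- k %in% el$inliers
    }
  }
  attr(detections, "ellipse") <- el
  detections
}

#' Calibrate cm-per-pixel scale from the turntable rim
#'
#' Edges are detected with a Scharr filter and a RANSAC ellipse is fit to
#' the rim; a circle viewed obliquely preserves its diameter along the
#' fitted major axis, so `scale = diameter_cm / (2 * a)`.
#'
#' @param turntable_frame grayscale matrix in `[0, 1]`.
#' @param diameter_cm true turntable diameter in cm.
#' @param edge_quantile gradient-magnitude quantile kept as edge pixels.
#' @param seed RANSAC seed.
#' @return cm per pixel (attribute `ellipse` carries the fit).
#' @export
calibrate_scale <- function(turntable_frame, diameter_cm,
                            edge_quantile = 0.985, seed = 1L) {
  kx <- matrix(c(-3, 0, 3, -10, 0, 10, -3, 0, 3), 3, 3) / 16
  gx <- EBImage::filter2(turntable_frame, kx)
  gy <- EBImage::filter2(turntable_frame, t(kx))
  g <- sqrt(gx^2 + gy^2)
  thr <- quantile(g, edge_quantile)
  idx <- which(g >= thr & g > 1e-3, arr.ind = TRUE)
  if (nrow(idx) < 6) stop("calibrate_scale: no edges found")
  el <- ransac_ellipse(idx[, 2] - 1, idx[, 1] - 1, tol = 2.5, seed = seed,
                       n_iter = 500L)
  if (is.null(el)) stop("calibrate_scale: no ellipse found in frame")
  structure(diameter_cm / (2 * el$a), ellipse = el)
}

# ---- point-cloud refinement and orientation -------------------------------

# Chunked pairwise mean k-NN distance.
mean_knn_dist <- function(pts, k) {
  n <- nrow(pts)
  out <- numeric(n)
  step <- max(1L, floor(2e6 / n))
  for (s in seq(1, n, by = step)) {
    ix <- s:min(s + step - 1L, n)
    d2 <- outer(rowSums(pts[ix, , drop = FALSE]^2), rowSums(pts^2), `+`) -
      2 * pts[ix, , drop = FALSE] %*% t(pts)
    d2[cbind(seq_along(ix), ix)] <- Inf
    out[ix] <- apply(d2, 1, function(r) mean(sqrt(pmax(sort(r)[seq_len(k)], 0))))
  }
  out
}

#' Remove k-NN outlier points from a cloud
#'
#' Points whose mean distance to their k nearest neighbors exceeds
#' `mean + sd_factor * sd` of that statistic are removed.
#'
#' @param cloud a [specimen_cloud()].
#' @param k neighbor count (< point count).
#' @param sd_factor rejection threshold in standard deviations.
#' @return filtered cloud.
#' @export
remove_outliers <- function(cloud, k = 8L, sd_factor = 2) {
  stopifnot(inherits(cloud, "specimen_cloud"), k < nrow(cloud$points))
  d <- mean_knn_dist(cloud$points, k)
  keep <- d <= mean(d) + sd_factor * sd(d)
  cloud$points <- cloud$points[keep, , drop = FALSE]
  if (!is.null(cloud$colors)) cloud$colors <- cloud$colors[keep, , drop = FALSE]
  cloud
}

# Rotation matrix taking unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to u
    ax <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- ax - sum(ax * u) * u; ax <- ax / sqrt(sum(ax^2))
    return(rotation_matrix_axis_angle(ax, 180))
  }
  ax <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

# RANSAC plane over a point subset; returns unit normal and offset
# (n . x = d) plus inlier index.
ransac_plane <- function(pts, tol, n_iter = 200L, seed = 1L) {
  n <- nrow(pts)
  with_seed(seed, {
    best <- NULL; best_in <- -1L
    for (it in seq_len(n_iter)) {
      s <- sample.int(n, 3L)
      v1 <- pts[s[2], ] - pts[s[1], ]; v2 <- pts[s[3], ] - pts[s[1], ]
      nv <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
              v1[1] * v2[2] - v1[2] * v2[1])
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-12) next
      nv <- nv / nn
      r <- abs(pts %*% nv - sum(nv * pts[s[1], ]))
      nin <- sum(r < tol)
      if (nin > best_in) { best_in <- nin; best <- list(normal = nv, p0 = pts[s[1], ]) }
    }
    inl <- abs(pts %*% best$normal - sum(best$normal * best$p0)) < tol
    # least-squares refit on inliers
    sub <- pts[inl, , drop = FALSE]
    ctr <- colMeans(sub)
    ev <- eigen(crossprod(sweep(sub, 2, ctr)), symmetric = TRUE)
    nv <- ev$vectors[, 3]
    list(normal = nv, d = sum(nv * ctr), inliers = which(inl),
         inlier_frac = mean(inl))
  })
}

# Suture color rule: dark navy by default.
is_suture_color <- function(colors) {
  colors[, 3] - pmax(colors[, 1], colors[, 2]) > 0.12 &
    apply(colors, 1, max) < 0.6
}

#' Orient a specimen cloud: bottom to -z, centroid to origin, suture to +y
#'
#' Pre-aligns by PCA, fits a RANSAC plane to the lowest 20% of points (the
#' dense flat face that sat on the turntable), rotates the plane normal to
#' -z and translates the centroid to the origin. If suture-colored points
#' are found, an in-plane rotation sends their centroid direction to +y
#' (12 o'clock); otherwise the in-plane orientation is left untouched and
#' flagged.
#'
#' @param cloud a [specimen_cloud()].
#' @param inlier_tol plane inlier tolerance (model units); default is
#'   derived from the residual spread of a least-squares pre-fit.
#' @param min_inlier_frac minimum fraction of candidate points on the plane.
#' @param seed RANSAC seed.
#' @return oriented `specimen_cloud` (fields `oriented`, `suture_found`,
#'   `orientation_fixed`, `rotation`).
#' @export
orient_cloud <- function(cloud, inlier_tol = NULL, min_inlier_frac = 0.3,
                         seed = 1L) {
  stopifnot(inherits(cloud, "specimen_cloud"))
  pts <- cloud$points
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2, ctr)
  # PCA pre-alignment: smallest-variance direction to z
  ev <- eigen(crossprod(pts) / nrow(pts), symmetric = TRUE)
  R1 <- t(ev$vectors[, c(1, 2, 3)])
  if (det(R1) < 0) R1[3, ] <- -R1[3, ]
  p1 <- pts %*% t(R1)
  # dense face down: bottom face is sampled most densely, so more points sit
  # in a thin band at the low-z end than at the high-z end
  zr <- range(p1[, 3]); band <- 0.08 * diff(zr)
  if (sum(p1[, 3] < zr[1] + band) < sum(p1[, 3] > zr[2] - band)) {
    R1 <- diag(c(1, -1, -1)) %*% R1   # flip z (and y to keep det = +1)
    p1 <- pts %*% t(R1)
  }
  low <- p1[p1[, 3] <= quantile(p1[, 3], 0.2), , drop = FALSE]
  if (is.null(inlier_tol)) {
    res <- low[, 3] - median(low[, 3])
    inlier_tol <- max(2 * 1.4826 * mad(res), 1e-6)
  }
  pl <- ransac_plane(low, tol = inlier_tol, seed = child_seed(seed, 3L))
  if (pl$inlier_frac < min_inlier_frac)
    stop("orient_cloud: bottom-plane inlier fraction ",
         round(pl$inlier_frac, 3), " below threshold")
  nv <- pl$normal
  if (nv[3] > 0) nv <- -nv           # normal points down (away from body)
  R2 <- rotation_between(nv, c(0, 0, -1))
  p2 <- p1 %*% t(R2)
  R <- R2 %*% R1
  # iterative least-squares refinement of the bottom plane: re-select the
  # points near the current bottom and refit, shrinking the residual tilt
  for (ref in 1:3) {
    z0 <- quantile(p2[, 3], 0.05)
    sel <- p2[, 3] <= z0 + 3 * inlier_tol
    if (sum(sel) < 20) break
    sub <- p2[sel, , drop = FALSE]
    ctr2 <- colMeans(sub)
    evr <- eigen(crossprod(sweep(sub, 2, ctr2)), symmetric = TRUE)
    nv2 <- evr$vectors[, 3]
    if (nv2[3] > 0) nv2 <- -nv2
    R2b <- rotation_between(nv2, c(0, 0, -1))
    p2 <- p2 %*% t(R2b)
    R <- R2b %*% R
  }
  suture_found <- FALSE; fixed <- FALSE
  if (!is.null(cloud$colors)) {
    sut <- is_suture_color(cloud$colors)
    if (sum(sut) >= 10) {
      sc <- colMeans(p2[sut, , drop = FALSE])
      if (sqrt(sum(sc[1:2]^2)) > 1e-9) {
        alpha <- atan2(sc[2], sc[1])
        th <- pi / 2 - alpha
        R3 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                     3, 3, byrow = TRUE)
        p2 <- p2 %*% t(R3)
        R <- R3 %*% R
        suture_found <- TRUE; fixed <- TRUE
      }
    }
  }
  cloud$points <- sweep(p2, 2, colMeans(p2))
  cloud$oriented <- TRUE
  cloud$suture_found <- suture_found
  cloud$orientation_fixed <- fixed
  cloud$rotation <- R
  cloud
}

# Locate a sampled face position along axis values v near its lower or upper
# end: kernel-density peak of the outer region (robust to symmetric noise,
# unlike the raw extreme).
face_position <- function(v, side = c("low", "high"), bw = NULL) {
  side <- match.arg(side)
  if (length(v) < 60) return(if (side == "low") min(v) else max(v))
  rng <- diff(range(v))
  bw <- max(bw %||% (stats::bw.nrd0(v) / 2), rng * 5e-4)
  d <- density(v, bw = bw, n = 2048)
  if (side == "low") {
    ref <- quantile(v, 0.005)
    win <- d$x >= ref - 4 * bw & d$x <= ref + 0.1 * rng + 4 * bw
  } else {
    ref <- quantile(v, 0.995)
    win <- d$x <= ref + 4 * bw & d$x >= ref - 0.1 * rng - 4 * bw
  }
  if (!any(win)) return(if (side == "low") min(v) else max(v))
  d$x[win][which.max(d$y[win])]
}

#' Measure oriented specimen extents
#'
#' Length (y extent), width (x extent) and height (z extent) in cm of an
#' oriented, calibrated cloud. Face positions are estimated by density peaks
#' of the outer point bands, which is robust to surface measurement noise;
#' for sparse clouds the raw extent is used.
#'
#' @param cloud oriented `specimen_cloud` with a calibration scale.
#' @return named numeric `c(L, W, H)` in cm.
#' @export
measure <- function(cloud) {
  stopifnot(inherits(cloud, "specimen_cloud"))
  if (!isTRUE(cloud$oriented)) stop("measure: cloud is not oriented")
  if (is.na(cloud$scale)) stop("measure: cloud has no calibration scale")
  p <- cloud$points
  # measurement-noise scale from the flat bottom face (densest band)
  zlow <- p[p[, 3] <= quantile(p[, 3], 0.3), 3]
  sigma <- 1.4826 * mad(zlow)
  bw <- if (sigma > 0) sigma / 2 else NULL
  ext <- vapply(1:3, function(ax)
    face_position(p[, ax], "high", bw) - face_position(p[, ax], "low", bw),
    numeric(1))
  c(L = ext[2], W = ext[1], H = ext[3]) * cloud$scale
}

#' Grossing and inking recommendations
#'
#' Mohs mode: a blue-red line from 12 to 6 o'clock; when the length exceeds
#' what fits on one slide, a black bisection line at y = 0 plus a blue-red
#' pair per half. Breadloaf mode: cut lines across the specimen
#' (side-to-side, along x) at regular `spacing_cm` increments symmetric
#' about the centroid; the left half of each line is blue to maintain
#' orientation, right halves cycle red/yellow/green/purple/orange to denote
#' unique sections.
#'
#' @param cloud oriented, calibrated `specimen_cloud`.
#' @param mode `"mohs"` or `"breadloaf"`.
#' @param spacing_cm breadloaf cut increment (0.5 to 1 cm; values outside
#'   warn but are honored).
#' @param slide_fit_cm largest length that fits a slide without bisection.
#' @return object of class `grossing_plan`: list of segments, each
#'   `list(role=, color=, from=, to=)` with cm coordinates.
#' @export
grossing_plan <- function(cloud, mode = c("mohs", "breadloaf"),
                          spacing_cm = 1, slide_fit_cm = 2) {
  mode <- match.arg(mode)
  dims <- measure(cloud)
  L <- dims[["L"]]; W <- dims[["W"]]; H <- dims[["H"]]
  ztop <- H / 2
  segs <- list()
  add <- function(role, color, from, to)
    segs[[length(segs) + 1L]] <<- list(role = role, color = color,
                                       from = from, to = to)
  if (mode == "mohs") {
    if (L <= slide_fit_cm) {
      add("ink-12", "blue", c(0, L / 2, ztop), c(0, 0, ztop))
      add("ink-6", "red", c(0, 0, ztop), c(0, -L / 2, ztop))
    } else {
      add("cut", "black", c(-W / 2, 0, ztop), c(W / 2, 0, ztop))
      for (h in c(1, -1)) {
        yb <- h * L * 3 / 8; yr <- h * L / 8
        if (yb < yr) { tmp <- yb; yb <- yr; yr <- tmp }
        add("ink-12", "blue", c(-W / 2, yb, ztop), c(W / 2, yb, ztop))
        add("ink-6", "red", c(-W / 2, yr, ztop), c(W / 2, yr, ztop))
      }
    }
  } else {
    if (spacing_cm < 0.5 || spacing_cm > 1)
      warning("breadloaf spacing ", spacing_cm, " cm outside the usual 0.5-1 cm")
    kmax <- floor((L / 2) / spacing_cm)
    ys <- seq(-kmax, kmax) * spacing_cm
    right_cols <- c("red", "yellow", "green", "purple", "orange")
    for (i in seq_along(ys)) {
      add("cut-left", "blue", c(-W / 2, ys[i], ztop), c(0, ys[i], ztop))
      add("cut-right", right_cols[(i - 1) %% length(right_cols) + 1],
          c(0, ys[i], ztop), c(W / 2, ys[i], ztop))
    }
  }
  structure(list(mode = mode, segments = segs, dims = dims),
            class = "grossing_plan")
}

#' Refine a cloud surface on a regular x-y grid
#'
#' Radius-neighbor regression: z and RGB are predicted at each node of a
#' regular x-y grid over the footprint as the average of points within the
#' neighbor radius; grid cells with no neighbor are omitted.
#'
#' @param cloud oriented `specimen_cloud`.
#' @param grid_step grid pitch, model units.
#' @param radius neighbor radius (default `1.5 * grid_step`).
#' @return `specimen_cloud` of grid points.
#' @export
refine_surface <- function(cloud, grid_step, radius = NULL) {
  stopifnot(inherits(cloud, "specimen_cloud"))
  if (!isTRUE(cloud$oriented)) stop("refine_surface: cloud is not oriented")
  radius <- radius %||% (1.5 * grid_step)
  p <- cloud$points
  gx <- seq(min(p[, 1]), max(p[, 1]), by = grid_step)
  gy <- seq(min(p[, 2]), max(p[, 2]), by = grid_step)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  vals <- matrix(NA_real_, nrow(grid), 4)
  for (i in seq_len(nrow(grid))) {
    d2 <- (p[, 1] - grid[i, 1])^2 + (p[, 2] - grid[i, 2])^2
    nb <- d2 <= radius^2
    if (!any(nb)) next
    vals[i, 1] <- mean(p[nb, 3])
    if (!is.null(cloud$colors)) vals[i, 2:4] <- colMeans(cloud$colors[nb, , drop = FALSE])
  }
  keep <- !is.na(vals[, 1])
  out <- specimen_cloud(cbind(grid[keep, , drop = FALSE], vals[keep, 1]),
                        colors = if (is.null(cloud$colors)) NULL else
                          vals[keep, 2:4, drop = FALSE],
                        scale = cloud$scale, oriented = TRUE)
  out$suture_found <- cloud$suture_found
  out
}
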