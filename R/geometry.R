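# Computational-geometry primitives: polygon predicates, Delaunay
# triangulation (Bowyer-Watson), alpha-shape outlines, and convex clipping.
# These back the hole-candidate extraction and the follicle docking scheme.
# No triangulation package is assumed; point counts are desk-scale (<= a few
# thousand), so the O(n^2) incremental insertion is adequate.

# Signed area of polygon (matrix with columns x, y); positive if
# counter-clockwise in a y-up frame.
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  i2 <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  i2 <- c(seq_len(nrow(poly))[-1], 1L)
  cr <- x * y[i2] - x[i2] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + x[i2]) * cr), sum((y + y[i2]) * cr)) / (6 * a)
}

# Even-odd (crossing number) point-in-polygon test, vectorised over points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Circumcenter and squared circumradius of triangle (3x2 matrix).
circumcircle <- function(p) {
  ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
  cx <- p[3, 1]; cy <- p[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(list(center = c(NA, NA), r2 = Inf))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), r2 = (ux - ax)^2 + (uy - ay)^2)
}

# Bowyer-Watson Delaunay triangulation. Returns an m x 3 matrix of vertex
# indices into `pts`. A tiny deterministic jitter breaks the exact
# cocircularity of regular-grid inputs; circumradii used downstream are
# recomputed from the unjittered coordinates.
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(matrix(integer(0), ncol = 3))
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1)
  jit <- ((seq_len(n) * 2654435761) %% 9973) / 9973 - 0.5
  jit2 <- ((seq_len(n) * 40503) %% 9871) / 9871 - 0.5
  p <- pts + cbind(jit, jit2) * span * 1e-6
  # super-triangle
  cx <- mean(range(p[, 1])); cy <- mean(range(p[, 2])); s <- span * 10
  P <- rbind(p, c(cx - 2 * s, cy - s), c(cx + 2 * s, cy - s), c(cx, cy + 2 * s))
  sup <- n + 1:3
  tri <- list(list(v = sup, cc = circumcircle(P[sup, ])))
  for (ip in seq_len(n)) {
    px <- P[ip, 1]; py <- P[ip, 2]
    bad <- vapply(tri, function(t)
      (px - t$cc$center[1])^2 + (py - t$cc$center[2])^2 < t$cc$r2, logical(1))
    if (!any(bad)) { # numeric degeneracy guard: attach to nearest triangle
      bad <- rep(FALSE, length(tri))
      bad[which.min(vapply(tri, function(t)
        (px - t$cc$center[1])^2 + (py - t$cc$center[2])^2 - t$cc$r2, numeric(1)))] <- TRUE
    }
    cav <- tri[bad]
    tri <- tri[!bad]
    edges <- do.call(rbind, lapply(cav, function(t)
      rbind(t$v[c(1, 2)], t$v[c(2, 3)], t$v[c(3, 1)])))
    ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[ek %in% names(which(table(ek) == 1)), , drop = FALSE]
    for (e in seq_len(nrow(boundary))) {
      v <- c(boundary[e, ], ip)
      tri[[length(tri) + 1L]] <- list(v = v, cc = circumcircle(P[v, ]))
    }
  }
  keep <- vapply(tri, function(t) all(t$v <= n), logical(1))
  out <- do.call(rbind, lapply(tri[keep], function(t) t$v))
  if (is.null(out)) matrix(integer(0), ncol = 3) else out
}

# Alpha-shape outer outline(s) of a planar point set: keep Delaunay triangles
# with circumradius <= 1/alpha, take edges used by exactly one kept triangle,
# and assemble them into closed loops. Loops not contained in another loop are
# the outer boundaries; these outline each piece while bridging concavities
# (e.g. edge tears) narrower than ~1/alpha. Falls back to the convex hull
# (with a warning) when the alpha complex is degenerate.
alpha_shape_outline <- function(pts, alpha) {
  stopifnot(alpha > 0)
  tri <- delaunay_triangulate(pts)
  if (nrow(tri) == 0) return(list(polys = list(), fallback = TRUE))
  r2max <- (1 / alpha)^2
  r2 <- apply(tri, 1, function(v) circumcircle(pts[v, ])$r2)
  kept <- tri[r2 <= r2max, , drop = FALSE]
  if (nrow(kept) == 0) {
    h <- chull(pts)
    warning("degenerate alpha complex; falling back to convex hull")
    return(list(polys = list(pts[h, , drop = FALSE]), fallback = TRUE))
  }
  edges <- rbind(kept[, c(1, 2)], kept[, c(2, 3)], kept[, c(3, 1)])
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  bnd <- edges[ek %in% names(which(table(ek) == 1)), , drop = FALSE]
  loops <- assemble_loops(bnd)
  if (!length(loops)) {
    h <- chull(pts)
    warning("alpha-shape boundary did not close; falling back to convex hull")
    return(list(polys = list(pts[h, , drop = FALSE]), fallback = TRUE))
  }
  polys <- lapply(loops, function(ix) pts[ix, , drop = FALSE])
  outer <- rep(TRUE, length(polys))
  if (length(polys) > 1) {
    for (i in seq_along(polys)) for (j in seq_along(polys)) {
      if (i == j || !outer[i]) next
      if (abs(polygon_area(polys[[j]])) > abs(polygon_area(polys[[i]])) &&
          point_in_polygon(polys[[i]][1, 1], polys[[i]][1, 2], polys[[j]]))
        outer[i] <- FALSE
    }
  }
  list(polys = polys[outer], fallback = FALSE)
}

# Filled alpha-shape membership of grid patches: a grid cell (top-left x, y;
# center at +patch/2) is inside the filled outline when its center lies in a
# kept triangle of the alpha complex, or in a region enclosed by the complex
# (interior holes and bridged tears are filled; concavities open to the
# exterior are not). Robust to pinched boundaries, unlike loop walking.
alpha_filled_membership <- function(centers, alpha, patch, xr, yr) {
  tri <- delaunay_triangulate(centers)
  r2max <- (1 / alpha)^2
  keep <- apply(tri, 1, function(v) circumcircle(centers[v, ])$r2) <= r2max
  kept <- tri[keep, , drop = FALSE]
  xs <- seq(xr[1] - patch, xr[2] + patch, by = patch)
  ys <- seq(yr[1] - patch, yr[2] + patch, by = patch)
  grid <- expand.grid(x = xs, y = ys)
  px <- grid$x + patch / 2; py <- grid$y + patch / 2
  in_complex <- rep(FALSE, nrow(grid))
  for (t in seq_len(nrow(kept))) {
    v <- centers[kept[t, ], ]
    d1 <- (v[2, 1] - v[1, 1]) * (py - v[1, 2]) - (v[2, 2] - v[1, 2]) * (px - v[1, 1])
    d2 <- (v[3, 1] - v[2, 1]) * (py - v[2, 2]) - (v[3, 2] - v[2, 2]) * (px - v[2, 1])
    d3 <- (v[1, 1] - v[3, 1]) * (py - v[3, 2]) - (v[1, 2] - v[3, 2]) * (px - v[3, 1])
    in_complex <- in_complex |
      ((d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0))
  }
  # flood-fill: off-complex cells connected to the padded border are
  # exterior; the rest are enclosed and therefore filled
  m <- matrix(in_complex, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  lab <- EBImage::bwlabel((!m) * 1)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  enclosed <- !m & !(lab %in% setdiff(border, 0L)) & lab > 0
  filled <- m | matrix(enclosed, nrow(m), ncol(m))
  list(grid = grid, inside = as.vector(t(filled)))
}

# Assemble undirected edges into vertex-index loops.
assemble_loops <- function(edges) {
  if (!nrow(edges)) return(list())
  used <- rep(FALSE, nrow(edges))
  adj <- split(rep(seq_len(nrow(edges)), 2), c(edges[, 1], edges[, 2]))
  loops <- list()
  for (e0 in seq_len(nrow(edges))) {
    if (used[e0]) next
    used[e0] <- TRUE
    start <- edges[e0, 1]; cur <- edges[e0, 2]
    loop <- c(start, cur)
    repeat {
      nxt_e <- NULL
      for (cand in adj[[as.character(cur)]]) if (!used[cand]) { nxt_e <- cand; break }
      if (is.null(nxt_e)) break
      used[nxt_e] <- TRUE
      cur <- if (edges[nxt_e, 1] == cur) edges[nxt_e, 2] else edges[nxt_e, 1]
      if (cur == start) break
      loop <- c(loop, cur)
    }
    if (length(loop) >= 3 && cur == start) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# Sutherland-Hodgman clipping of an arbitrary subject polygon against a
# CONVEX clip polygon (vertices in counter-clockwise order w.r.t. the usual
# x-y frame). Returns the clipped polygon (possibly empty).
clip_polygon_convex <- function(subject, clip) {
  if (polygon_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (!length(out) || nrow(out) == 0) return(matrix(numeric(0), ncol = 2))
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    sdist <- function(p) ex * (p[, 2] - a[2]) - ey * (p[, 1] - a[1])
    inp <- out
    d <- sdist(inp)
    n <- nrow(inp)
    res <- vector("list", 2 * n)
    m <- 0L
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      cur_in <- d[k] >= -1e-12; nxt_in <- d[k2] >= -1e-12
      if (cur_in) { m <- m + 1L; res[[m]] <- inp[k, ] }
      if (cur_in != nxt_in) {
        t <- d[k] / (d[k] - d[k2])
        m <- m + 1L
        res[[m]] <- inp[k, ] + t * (inp[k2, ] - inp[k, ])
      }
    }
    out <- if (m) do.call(rbind, res[seq_len(m)]) else matrix(numeric(0), ncol = 2)
  }
  out
}

regular_polygon <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Fraction of the disk (cx, cy, r) covered by the union of `polys`
# (assumed mutually disjoint; the sum is capped at 1). The disk is
# approximated by a 64-gon and clipped exactly; a seeded Monte-Carlo fallback
# handles degenerate clip results.
disk_polygon_overlap <- function(cx, cy, r, polys, n_circle = 64L, mc_seed = 17L) {
  circ <- regular_polygon(cx, cy, r, n_circle)
  denom <- abs(polygon_area(circ))
  tot <- 0
  for (poly in polys) {
    inter <- tryCatch(clip_polygon_convex(poly, circ), error = function(e) NULL)
    if (is.null(inter)) {
      # Monte-Carlo fallback on degenerate geometry
      pts <- with_seed(mc_seed, {
        th <- runif(1e4, 0, 2 * pi); rr <- r * sqrt(runif(1e4))
        cbind(cx + rr * cos(th), cy + rr * sin(th))
      })
      tot <- tot + mean(point_in_polygon(pts[, 1], pts[, 2], poly))
    } else if (nrow(inter) >= 3) {
      tot <- tot + abs(polygon_area(inter)) / denom
    }
  }
  min(tot, 1)
}
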