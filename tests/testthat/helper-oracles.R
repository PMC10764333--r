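# Independent oracles used across the suite. These deliberately use naive
# O(n^2) / enumeration / quadrature implementations so they stay independent
# of the package's own code paths.

# Brute-force union-find components of the distance-<=r graph.
oracle_components <- function(coords, r) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= r) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Brute-force O(n^2) radius edge list (i < j).
oracle_radius_edges <- function(coords, r) {
  n <- nrow(coords)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= r)
      out <- rbind(out, c(i, j))
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# Beta quantile by adaptive quadrature of the density + bisection.
oracle_beta_quantile <- function(p, a, b) {
  cdf <- function(x) integrate(function(t) dbeta(t, a, b), 0, x,
                               rel.tol = 1e-10)$value
  lo <- 0; hi <- 1
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Pair-counting AUC (concordant + 0.5 * ties) / (n1 * n0).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Grid patch centers inside a polygon (brute force point-in-polygon by ray
# crossing, written independently of the package's helper).
oracle_centers_in_polygon <- function(xs, ys, patch, poly) {
  inside_one <- function(px, py) {
    n <- nrow(poly); cnt <- 0
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
      if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi) cnt <- cnt + 1
      j <- i
    }
    cnt %% 2 == 1
  }
  g <- expand.grid(x = xs, y = ys)
  keep <- mapply(function(x, y) inside_one(x + patch / 2, y + patch / 2),
                 g$x, g$y)
  g[keep, , drop = FALSE]
}

# Mask IoU.
iou <- function(a, b) sum(a & b) / max(sum(a | b), 1)
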