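# Mapping histological findings onto the surgeon-drawn tumor map: the
# section's patch point cloud is morphed into the template ellipse by
# gradient descent on the sliced Wasserstein distance, rotated to align the
# blue-red ink line with the template's, and summarized as a kernel-density
# contour overlay. Concordance with surgeon-drawn maps is modeled with a
# Jeffreys-prior Beta posterior.

#' Sliced Wasserstein distance between 2D point sets
#'
#' Order-2 sliced distance: the square root of the mean, over seeded random
#' unit directions, of the squared 1D Wasserstein distance between the
#' projected empirical distributions (quantile matching for unequal sizes).
#' For a set against a translate of itself the distance converges to
#' `|t| / sqrt(2)` as the number of projections grows.
#'
#' @param A,B n x 2 / m x 2 matrices (non-empty).
#' @param n_projections number of random directions.
#' @param seed direction seed (identical directions for both arguments, so
#'   the distance is exactly symmetric).
#' @return nonnegative distance.
#' @export
sliced_wasserstein <- function(A, B, n_projections = 512L, seed = 1L) {
  A <- matrix(A, ncol = 2); B <- matrix(B, ncol = 2)
  if (!nrow(A) || !nrow(B)) stop("sliced_wasserstein: empty point set")
  th <- with_seed(seed, runif(n_projections, 0, pi))
  dirs <- cbind(cos(th), sin(th))
  pa <- A %*% t(dirs); pb <- B %*% t(dirs)
  na <- nrow(A); nb <- nrow(B)
  tot <- 0
  for (j in seq_len(n_projections)) {
    a <- sort(pa[, j]); b <- sort(pb[, j])
    if (na == nb) {
      tot <- tot + mean((a - b)^2)
    } else {
      m <- max(na, nb)
      u <- (seq_len(m) - 0.5) / m
      qa <- a[ceiling(u * na)]; qb <- b[ceiling(u * nb)]
      tot <- tot + mean((qa - qb)^2)
    }
  }
  sqrt(tot / n_projections)
}

# Mean transport field of X toward Y under random projections: for each
# point, the average over directions of (proj residual to the rank-matched
# target quantile) times the direction. Also returns the mean squared 1D
# distance (the squared sliced distance estimate).
sw_transport_field <- function(X, Y, dirs) {
  n <- nrow(X); m <- nrow(Y)
  G <- matrix(0, n, 2)
  d2 <- 0
  for (j in seq_len(nrow(dirs))) {
    px <- X %*% dirs[j, ]
    py <- sort(Y %*% dirs[j, ])
    r <- rank(px, ties.method = "first")
    q <- py[ceiling(((r - 0.5) / n) * m)]
    res <- as.vector(px) - q
    d2 <- d2 + mean(res^2)
    G <- G + outer(res, dirs[j, ])
  }
  list(field = G / nrow(dirs), d2 = d2 / nrow(dirs))
}

sample_ellipse_interior <- function(ellipse, n, seed) {
  rot <- (ellipse$rotation %||% 0) * pi / 180
  with_seed(seed, {
    r <- sqrt(runif(n)); t <- runif(n, 0, 2 * pi)
    ex <- r * cos(t) * ellipse$axes[1]; ey <- r * sin(t) * ellipse$axes[2]
    cbind(ellipse$center[1] + ex * cos(rot) - ey * sin(rot),
          ellipse$center[2] + ex * sin(rot) + ey * cos(rot))
  })
}

#' Morph section points into the template ellipse by sliced-Wasserstein descent
#'
#' The section's patch coordinates are first rigidly recentered on the
#' ellipse (centroid to center, isotropic pre-scale), then iteratively moved
#' along the mean sliced-Wasserstein transport field toward a fixed uniform
#' sample of the ellipse interior, with a geometrically decaying step. The
#' relative positioning of the section is maintained (no reflection, no
#' anisotropic distortion beyond what transport induces) and per-point class
#' probabilities are carried unchanged.
#'
#' @param points n x 2 matrix (n >= 10) of section coordinates (pixels).
#' @param ellipse `list(center=, axes=, rotation=)` target ellipse.
#' @param probs optional per-point probability matrix carried through.
#' @param landmarks optional q x 2 matrix (e.g. ink centroids) transported
#'   with the cloud but excluded from the objective.
#' @param n_target uniform target sample size (default `max(1024, n)`).
#' @param iters gradient-descent iterations.
#' @param step initial dimensionless step along the transport field.
#' @param decay per-iteration step decay.
#' @param n_projections directions per iteration (final distances use 512).
#' @param seed seed for the target sample and projection directions.
#' @return object of class `transport_result`: `source`, `transported`,
#'   `landmarks`, `probs`, `rotation` (0 until [rotate_to_template()]),
#'   `sw_initial`, `sw_final`, `iteration_log`, `ellipse`.
#' @export
morph_to_ellipse <- function(points, ellipse, probs = NULL, landmarks = NULL,
                             n_target = NULL, iters = 300L, step = 0.5,
                             decay = 0.98, n_projections = 64L, seed = 1L) {
  X0 <- matrix(points, ncol = 2)
  if (nrow(X0) < 10) stop("morph_to_ellipse: need at least 10 points")
  n_target <- n_target %||% max(1024L, nrow(X0))
  Y <- sample_ellipse_interior(ellipse, n_target, child_seed(seed, 5L))
  # rigid pre-alignment: centroid to center, isotropic scale to a rough fit
  ctr <- colMeans(X0)
  rms <- sqrt(mean(rowSums(sweep(X0, 2, ctr)^2)))
  target_rms <- sqrt(mean(rowSums(sweep(Y, 2, ellipse$center)^2)))
  sc <- if (rms > 1e-12) target_rms / rms else 1
  if (abs(sc - 1) < 0.05) sc <- 1   # already fitting: no pre-scale
  pre <- function(P) sweep(P, 2, ctr) * sc + rep(ellipse$center, each = nrow(P))
  X <- pre(X0)
  L <- if (is.null(landmarks)) NULL else pre(matrix(landmarks, ncol = 2))
  init_d <- sliced_wasserstein(X0, Y, 512L, seed = child_seed(seed, 7L))
  # resolvable-noise floor: the sliced distance between an independent
  # source-sized uniform sample and the target sample. Once the section is
  # this close to the target it is statistically indistinguishable from a
  # uniform draw, and further descent would only chase sampling noise.
  Yref <- sample_ellipse_interior(ellipse, nrow(X), child_seed(seed, 17L))
  floor2 <- sliced_wasserstein(Yref, Y, 128L, seed = child_seed(seed, 13L))^2
  log_d2 <- numeric(0)
  th_all <- with_seed(child_seed(seed, 9L), runif(iters * n_projections, 0, pi))
  for (it in seq_len(iters)) {
    th <- th_all[((it - 1) * n_projections + 1):(it * n_projections)]
    dirs <- cbind(cos(th), sin(th))
    tf <- sw_transport_field(X, Y, dirs)
    if (it == 1 && tf$d2 <= 1.5 * floor2) {
      # already statistically indistinguishable from a uniform draw of the
      # target: leave the section untouched (fixed point up to sampling noise)
      log_d2 <- tf$d2
      break
    }
    eta <- step * decay^(it - 1)
    disp <- -eta * tf$field
    if (!is.null(L)) {
      # landmarks follow the locally averaged displacement of nearby points
      for (q in seq_len(nrow(L))) {
        d2q <- rowSums(sweep(X, 2, L[q, ])^2)
        w <- exp(-d2q / (2 * (stats::median(d2q) + 1e-12)))
        L[q, ] <- L[q, ] + colSums(disp * w) / sum(w)
      }
    }
    X <- X + disp
    log_d2 <- c(log_d2, tf$d2)
  }
  final_d <- sliced_wasserstein(X, Y, 512L, seed = child_seed(seed, 7L))
  if (!all(is.finite(X)))
    stop("morph_to_ellipse: non-finite coordinates at iteration ",
         which(!is.finite(rowSums(X)))[1])
  structure(list(source = X0, transported = X, landmarks = L,
                 probs = probs, rotation = 0,
                 sw_initial = init_d, sw_final = final_d,
                 iteration_log = sqrt(pmax(log_d2, 0)), ellipse = ellipse),
            class = "transport_result")
}

#' Final rotational alignment of a morphed section to the template
#'
#' Rotates the transported points (and landmarks) about the ellipse center
#' by the signed angle taking the morphed section's blue-red ink line onto
#' the template's line; probabilities are untouched.
#'
#' @param result a [morph_to_ellipse()] result.
#' @param section_theta clock angle (degrees) of the morphed section's
#'   blue-red line, or an `orientation_line`.
#' @param template_theta clock angle of the template's blue-red line.
#' @return the result with rotated coordinates and `rotation` set.
#' @export
rotate_to_template <- function(result, section_theta, template_theta) {
  if (inherits(section_theta, "missing_orientation") || is.null(section_theta) ||
      (is.numeric(section_theta) && anyNA(section_theta)))
    stop("rotate_to_template: section ink line missing; orient the section manually")
  if (inherits(section_theta, "orientation_line")) section_theta <- section_theta$theta
  phi <- relative_angle(template_theta, section_theta)
  rad <- phi * pi / 180
  R <- matrix(c(cos(rad), sin(rad), -sin(rad), cos(rad)), 2, 2)
  ctr <- result$ellipse$center
  rot <- function(P) sweep(sweep(P, 2, ctr) %*% t(R), 2, ctr, `+`)
  result$transported <- rot(result$transported)
  if (!is.null(result$landmarks)) result$landmarks <- rot(result$landmarks)
  result$rotation <- phi
  result
}

#' Kernel-density contour overlay of mapped prediction results
#'
#' Gaussian product-kernel density over the transported coordinates,
#' weighted by the per-point probability of `class_name`, normalized to peak
#' 1 and contoured at `threshold`. Raising the threshold never enlarges the
#' contoured area.
#'
#' @param result a `transport_result` with `probs`.
#' @param class_name probability column to overlay.
#' @param bandwidth `c(bx, by)` or NULL for Scott's rule on the transported
#'   coordinates.
#' @param threshold contour level in (0, 1] on the normalized density.
#' @param grid_n density grid resolution per axis.
#' @return object of class `density_overlay`: `bandwidth`, `threshold`,
#'   `contours` (list of polygon matrices), `grid` (x, y, z). All-zero
#'   weights yield an empty overlay.
#' @export
density_overlay <- function(result, class_name, bandwidth = NULL,
                            threshold = 0.5, grid_n = 128L) {
  P <- result$transported
  w <- if (is.null(result$probs)) rep(1, nrow(P)) else {
    pm <- as.matrix(result$probs)
    if (!class_name %in% colnames(pm))
      stop("density_overlay: no probability column '", class_name, "'")
    pm[, class_name]
  }
  empty <- structure(list(bandwidth = bandwidth, threshold = threshold,
                          contours = list(), grid = NULL),
                     class = "density_overlay")
  if (all(w <= 0)) return(empty)
  if (is.null(bandwidth)) {
    n <- nrow(P)
    bandwidth <- pmax(apply(P, 2, sd), 1e-6) * n^(-1 / 6)   # Scott, 2D
  }
  el <- result$ellipse
  pad <- 1.25 * max(el$axes)
  gx <- seq(el$center[1] - pad, el$center[1] + pad, length.out = grid_n)
  gy <- seq(el$center[2] - pad, el$center[2] + pad, length.out = grid_n)
  Kx <- dnorm(outer(gx, P[, 1], "-") / bandwidth[1])
  Ky <- dnorm(outer(gy, P[, 2], "-") / bandwidth[2])
  Z <- sweep(Kx, 2, w, `*`) %*% t(Ky)
  if (max(Z) <= 0) return(empty)
  Z <- Z / max(Z)
  cl <- contourLines(gx, gy, Z, levels = threshold)
  contours <- lapply(cl, function(c) cbind(x = c$x, y = c$y))
  structure(list(bandwidth = bandwidth, threshold = threshold,
                 contours = contours, grid = list(x = gx, y = gy, z = Z)),
            class = "density_overlay")
}

# Total area of the thresholded super-level set of an overlay (grid measure).
overlay_area <- function(overlay) {
  if (is.null(overlay$grid)) return(0)
  g <- overlay$grid
  cell <- diff(g$x[1:2]) * diff(g$y[1:2])
  sum(g$z >= overlay$threshold) * cell
}

#' Jeffreys-prior Beta posterior for map concordance
#'
#' Conjugate update of the Jeffreys prior Beta(0.5, 0.5) with `k` successes
#' in `n` binomial trials, giving the posterior Beta(0.5 + k, 0.5 + n - k);
#' exact quantiles at 2.5%, 50% and 97.5% summarize the point estimate and
#' 95% credible interval of the concordance proportion.
#'
#' @param k successes (cases judged concordant), `0 <= k <= n`.
#' @param n trials.
#' @return object of class `concordance_posterior` with fields `k`, `n`,
#'   `a`, `b`, `q2.5`, `q50`, `q97.5`.
#' @export
concordance_posterior <- function(k, n) {
  stopifnot(k >= 0, n >= 0, k <= n)
  a <- 0.5 + k; b <- 0.5 + n - k
  q <- qbeta(c(0.025, 0.5, 0.975), a, b)
  structure(list(k = k, n = n, a = a, b = b,
                 q2.5 = q[1], q50 = q[2], q97.5 = q[3]),
            class = "concordance_posterior")
}

#' @export
print.concordance_posterior <- function(x, ...) {
  cat(sprintf("Beta(%.1f, %.1f) posterior (Jeffreys prior), %d/%d concordant\n",
              x$a, x$b, x$k, x$n))
  cat(sprintf("  median %.1f%%  (95%% CrI %.1f%% - %.1f%%)\n",
              100 * x$q50, 100 * x$`q2.5`, 100 * x$`q97.5`))
  invisible(x)
}
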