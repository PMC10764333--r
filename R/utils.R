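#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
#' @importFrom grDevices rgb2hsv chull contourLines
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route their seeds through this so
# results are a pure function of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream index; stays below 2^31.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483647L)
}

#' Clock angle of a 2D image-plane vector
#'
#' Angles follow the package-wide clock convention: 0 degrees points to
#' 12 o'clock ("up", the negative-y direction in image coordinates where y
#' increases downward) and angles increase clockwise, so 90 degrees is
#' 3 o'clock (+x). A correctly laid Mohs section (blue ink at top, red at
#' bottom) has a blue-to-red line angle of 180 degrees.
#'
#' @param dx,dy vector components in image coordinates (y down).
#' @return angle in degrees in `[0, 360)`.
#' @export
clock_angle <- function(dx, dy) {
  (atan2(dx, -dy) * 180 / pi) %% 360
}

# Unit vector (image coords, y down) pointing at clock angle `theta` degrees.
clock_vector <- function(theta) {
  t <- theta * pi / 180
  c(sin(t), -cos(t))
}

#' Signed smallest angular difference
#'
#' Returns the signed rotation (degrees, in `[-180, 180)`) that takes angle
#' `b` onto angle `a` under the clock convention, i.e. `a - b` wrapped.
#'
#' @param a,b angles in degrees.
#' @return signed difference in degrees.
#' @export
relative_angle <- function(a, b) {
  ((a - b + 180) %% 360) - 180
}

# All index pairs (i, j), i < j, with euclidean distance <= r.
# Grid-bucket neighbour search; O(n) buckets, exact distances checked.
radius_pairs <- function(coords, r) {
  n <- nrow(coords)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cx <- floor(coords[, 1] / r); cy <- floor(coords[, 2] / r)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  cell_xy <- do.call(rbind, lapply(strsplit(names(cells), " "), as.numeric))
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(cells)) assign(names(cells)[k], cells[[k]], envir = lookup)
  out <- vector("list", length(cells) * 5L)
  m <- 0L
  offs <- cbind(c(0, 1, 1, 0, -1), c(0, 0, 1, 1, 1))  # half-neighbourhood
  for (k in seq_along(cells)) {
    a <- cells[[k]]
    for (o in seq_len(nrow(offs))) {
      nb_key <- paste(cell_xy[k, 1] + offs[o, 1], cell_xy[k, 2] + offs[o, 2])
      b <- if (o == 1) a else get0(nb_key, envir = lookup)
      if (is.null(b)) next
      if (o == 1) {
        if (length(a) < 2) next
        pr <- t(combn(a, 2L))
      } else {
        pr <- cbind(rep(a, each = length(b)), rep(b, times = length(a)))
      }
      d2 <- (coords[pr[, 1], 1] - coords[pr[, 2], 1])^2 +
            (coords[pr[, 1], 2] - coords[pr[, 2], 2])^2
      keep <- d2 <= r * r
      if (any(keep)) { m <- m + 1L; out[[m]] <- pr[keep, , drop = FALSE] }
    }
  }
  if (m == 0L) return(matrix(integer(0), ncol = 2))
  pr <- do.call(rbind, out[seq_len(m)])
  sw <- pr[, 1] > pr[, 2]
  pr[sw, ] <- pr[sw, c(2, 1), drop = FALSE]
  unique(pr)
}

# Connected-component labels (dense integers from 1) of the graph whose edges
# join points within distance r.
radius_components <- function(coords, r) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  pr <- radius_pairs(coords, r)
  if (nrow(pr)) for (e in seq_len(nrow(pr))) {
    ra <- find(pr[e, 1]); rb <- find(pr[e, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
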