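# Ink detection and spatial statistics for tissue orientation. Inks are
# detected in HSV space within a band around the tissue edge; the line from
# the blue centroid (12 o'clock) to the red centroid (6 o'clock) defines the
# section's orientation under the clock convention of [clock_angle()].

#' Default HSV in-range thresholds for tissue inks
#'
#' Hue is in degrees `[0, 360)`; a color may own several hue intervals
#' (red wraps around 0). Saturation/value minima gate out faded pixels;
#' black is detected by low value alone.
#'
#' @return named list of per-color threshold lists.
#' @export
default_hsv_ranges <- function() {
  list(
    blue   = list(h = list(c(200, 260)), s_min = 0.35, v_min = 0.20),
    red    = list(h = list(c(345, 360), c(0, 15)), s_min = 0.35, v_min = 0.20),
    yellow = list(h = list(c(40, 70)),  s_min = 0.35, v_min = 0.30),
    green  = list(h = list(c(80, 160)), s_min = 0.35, v_min = 0.20),
    orange = list(h = list(c(16, 40)),  s_min = 0.45, v_min = 0.30),
    purple = list(h = list(c(261, 320)), s_min = 0.35, v_min = 0.20),
    black  = list(h = list(c(0, 360)), s_min = 0, v_min = 0, v_max = 0.18)
  )
}

#' Band around the tissue-mask boundary
#'
#' Segments tissue edges with a Sobel gradient on the mask, thresholds, then
#' applies morphological dilation (to the requested band width) and opening
#' (to remove spurs).
#'
#' @param mask logical matrix `[y, x]` (or a `tissue_mask`).
#' @param band_px approximate band thickness in pixels.
#' @return logical matrix of the edge band; empty for an empty mask.
#' @export
tissue_edge_band <- function(mask, band_px = 16L) {
  if (inherits(mask, "tissue_mask")) mask <- mask$mask
  m <- mask * 1
  if (!any(m > 0)) return(mask & FALSE)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(m, kx)
  gy <- EBImage::filter2(m, t(kx))
  edge <- sqrt(gx^2 + gy^2) > 0.5
  sz <- band_px + (band_px %% 2 == 0)  # odd brush diameter ~ band thickness
  band <- EBImage::dilate(edge * 1, EBImage::makeBrush(sz, "disc"))
  band <- EBImage::opening(band, EBImage::makeBrush(3L, "disc"))
  band > 0.5
}

#' Detect edge inks in HSV color space
#'
#' Per color: pixels inside the HSV in-range thresholds intersected with the
#' edge band, grouped by connected components; components smaller than
#' `min_component_px` are removed as spurious applications. Ink away from
#' the tissue edge (seepage into the interior) is never reported.
#'
#' @param raster H x W x 3 RGB array.
#' @param edge_band logical matrix from [tissue_edge_band()].
#' @param colors colors to look for (names of `hsv_ranges`).
#' @param hsv_ranges per-color thresholds, see [default_hsv_ranges()].
#' @param min_component_px minimum connected-component size in pixels.
#' @return object of class `ink_map`: per color either `NULL` (absent) or a
#'   list with `pixels` (n x 2 matrix of 0-based x, y) and `n_components`.
#' @export
detect_inks <- function(raster, edge_band, colors = c("blue", "red"),
                        hsv_ranges = default_hsv_ranges(),
                        min_component_px = 50L) {
  stopifnot(length(dim(raster)) == 3)
  H <- dim(raster)[1]; W <- dim(raster)[2]
  out <- setNames(vector("list", length(colors)), colors)
  band_idx <- which(edge_band)
  if (length(band_idx)) {
    rgbm <- rbind(r = raster[, , 1][band_idx],
                  g = raster[, , 2][band_idx],
                  b = raster[, , 3][band_idx])
    hsv <- rgb2hsv(rgbm, maxColorValue = 1)
    hdeg <- hsv[1, ] * 360; s <- hsv[2, ]; v <- hsv[3, ]
    for (col in colors) {
      rg <- hsv_ranges[[col]]
      if (is.null(rg)) stop("detect_inks: no HSV range for color ", col)
      in_h <- Reduce(`|`, lapply(rg$h, function(iv) hdeg >= iv[1] & hdeg <= iv[2]))
      sel <- in_h & s >= rg$s_min & v >= rg$v_min
      if (!is.null(rg$v_max)) sel <- sel & v <= rg$v_max
      if (!any(sel)) next
      cm <- matrix(FALSE, H, W)
      cm[band_idx[sel]] <- TRUE
      lab <- EBImage::bwlabel(cm * 1)
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= min_component_px)
      if (!length(keep)) next
      cm <- matrix(lab %in% keep, H, W)
      idx <- which(cm, arr.ind = TRUE)
      out[[col]] <- list(pixels = cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L),
                         n_components = length(keep))
    }
  }
  structure(out, class = "ink_map")
}

#' Center of mass of a detected ink color
#'
#' @param inkmap an [detect_inks()] result.
#' @param color color name.
#' @param method `"mean"`, coordinatewise `"median"`, or `"trimmed"` mean.
#' @param trim per-coordinate trim fraction for the trimmed mean.
#' @return `c(x, y)` centroid in pixels.
#' @export
ink_centroid <- function(inkmap, color, method = c("mean", "median", "trimmed"),
                         trim = 0.1) {
  method <- match.arg(method)
  entry <- inkmap[[color]]
  if (is.null(entry)) stop("ink_centroid: ink color '", color, "' not detected")
  px <- entry$pixels
  switch(method,
    mean = c(mean(px[, 1]), mean(px[, 2])),
    median = c(median(px[, 1]), median(px[, 2])),
    trimmed = c(mean(px[, 1], trim = trim), mean(px[, 2], trim = trim)))
}

#' Blue-to-red orientation line of a section
#'
#' The clock angle of the vector from the blue (12 o'clock) to the red
#' (6 o'clock) ink centroid; a correctly laid section has theta = 180.
#'
#' @param blue_xy,red_xy `c(x, y)` centroids in pixels.
#' @return object of class `orientation_line` with `blue`, `red`, `theta`
#'   (degrees in `[0, 360)`).
#' @export
orientation_line <- function(blue_xy, red_xy) {
  d <- red_xy - blue_xy
  if (sqrt(sum(d^2)) < 1e-9)
    stop("orientation_line: coincident centroids give a degenerate line")
  structure(list(blue = blue_xy, red = red_xy,
                 theta = clock_angle(d[1], d[2])),
            class = "orientation_line")
}

#' One-call section orientation from a raster
#'
#' Convenience wrapper: tissue mask (optional, computed if missing), edge
#' band, ink detection, centroids, orientation line.
#'
#' @param raster RGB array.
#' @param mask optional `tissue_mask` or logical matrix.
#' @param band_px edge-band thickness.
#' @param method centroid method, see [ink_centroid()].
#' @param ... passed to [detect_inks()].
#' @return `orientation_line`, or `NULL` (with attribute `"reason"`) if the
#'   blue or red ink is absent.
#' @export
section_orientation <- function(raster, mask = NULL, band_px = 16L,
                                method = "mean", ...) {
  if (is.null(mask)) mask <- compute_tissue_mask(raster)
  band <- tissue_edge_band(mask, band_px)
  inks <- detect_inks(raster, band, ...)
  if (is.null(inks$blue) || is.null(inks$red)) {
    miss <- c("blue", "red")[c(is.null(inks$blue), is.null(inks$red))]
    return(structure(list(NULL), class = "missing_orientation",
                     reason = paste("missing ink:", paste(miss, collapse = ", "))))
  }
  orientation_line(ink_centroid(inks, "blue", method),
                   ink_centroid(inks, "red", method))
}
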