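# Whole-slide preprocessing: tissue masking, non-overlapping 256-px patch
# extraction, section/piece assignment over radius-neighbor graphs (with a
# spectral-clustering split for conjoined pieces), and alpha-shape hole
# candidates forming the macro_map configuration.

#' Default tissue-mask parameters
#'
#' @param white_cutoff mean-RGB intensity above which a pixel is background.
#' @param gray_sat saturation below which a non-white object is considered a
#'   gray artifact (scanner text, pen).
#' @param gray_area minimum area (pixels) for a gray object to be removed.
#' @param close_size diameter of the binary-closing brush.
#' @param blur_sigma Gaussian blur sigma applied before re-thresholding.
#' @param small_obj,small_hole area cutoffs (pixels) for small-object removal
#'   and small-hole filling at mask resolution.
#' @return parameter list.
#' @export
mask_params <- function(white_cutoff = 235 / 255, gray_sat = 0.08,
                        gray_area = 1e4, close_size = 5L, blur_sigma = 2,
                        small_obj = 64L, small_hole = 64L) {
  as.list(environment())
}

#' Tissue mask from an RGB raster
#'
#' Builds the binary tissue mask by (1) removing near-white pixels with an
#' intensity threshold, (2) removing large low-saturation gray objects such
#' as scanner text or pen, (3) smoothing with binary closing plus blur and
#' re-threshold, and (4) removing small objects and filling small holes.
#'
#' @param raster H x W x 3 array in `[0, 1]`.
#' @param params see [mask_params()].
#' @return object of class `tissue_mask`: list with `mask` (logical matrix
#'   `[y, x]`), `dim`, and `params`. A fully background raster yields an
#'   empty mask, not an error.
#' @export
compute_tissue_mask <- function(raster, params = mask_params()) {
  if (is.null(dim(raster)) || length(dim(raster)) != 3 || any(dim(raster) == 0))
    stop("compute_tissue_mask: empty or non-RGB raster")
  mean_rgb <- (raster[, , 1] + raster[, , 2] + raster[, , 3]) / 3
  mask <- mean_rgb <= params$white_cutoff
  if (any(mask)) {
    mx <- apply(raster, c(1, 2), max)
    mn <- pmin(raster[, , 1], pmin(raster[, , 2], raster[, , 3]))
    sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
    grayish <- mask & sat < params$gray_sat
    if (any(grayish)) {
      lab <- EBImage::bwlabel(grayish * 1)
      sizes <- tabulate(lab[lab > 0])
      big <- which(sizes > params$gray_area)
      if (length(big)) mask[lab %in% big] <- FALSE
    }
  }
  if (any(mask)) {
    br <- EBImage::makeBrush(params$close_size, "disc")
    sm <- EBImage::closing(mask * 1, br)
    sm <- EBImage::gblur(sm, sigma = params$blur_sigma)
    mask <- sm > 0.5
    lab <- EBImage::bwlabel(mask * 1)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < params$small_obj)
    if (length(small)) mask[lab %in% small] <- FALSE
    # fill small interior holes
    inv <- EBImage::bwlabel((!mask) * 1)
    border_labels <- unique(c(inv[1, ], inv[nrow(inv), ], inv[, 1], inv[, ncol(inv)]))
    hsizes <- tabulate(inv[inv > 0])
    fill <- setdiff(which(hsizes < params$small_hole), border_labels)
    if (length(fill)) mask[inv %in% fill] <- TRUE
  }
  structure(list(mask = mask, dim = dim(raster)[1:2], params = params),
            class = "tissue_mask")
}

# Per-grid-cell tissue fraction via indicator-matrix products.
grid_tissue_fraction <- function(mask, patch_size) {
  H <- nrow(mask); W <- ncol(mask)
  nby <- H %/% patch_size; nbx <- W %/% patch_size
  if (nby == 0 || nbx == 0) stop("patch size larger than raster")
  m <- mask[seq_len(nby * patch_size), seq_len(nbx * patch_size), drop = FALSE] * 1
  A <- matrix(0, nby, nby * patch_size)
  for (i in seq_len(nby)) A[i, ((i - 1) * patch_size + 1):(i * patch_size)] <- 1
  B <- matrix(0, nbx * patch_size, nbx)
  for (j in seq_len(nbx)) B[((j - 1) * patch_size + 1):(j * patch_size), j] <- 1
  (A %*% m %*% B) / patch_size^2   # [block_y, block_x]
}

#' Extract grid patches overlapping the tissue mask
#'
#' Non-overlapping `patch_size` grid patches (stride = patch size, 0-based
#' top-left coordinates) are kept when their tissue fraction meets
#' `min_tissue_frac`. This is the `tumor_map` configuration.
#'
#' @param tissue_mask a [compute_tissue_mask()] result.
#' @param patch_size patch edge in pixels (default 256).
#' @param min_tissue_frac minimum fraction of tissue pixels in a patch.
#' @param slide_id identifier carried in the patch records.
#' @return object of class `patch_set`: data.frame with columns `x`, `y`,
#'   `frac`, `section`, `piece`, `hole_candidate`, plus attributes
#'   `patch_size`, `slide`, `config`.
#' @export
extract_patches <- function(tissue_mask, patch_size = 256L,
                            min_tissue_frac = 0.5, slide_id = "slide") {
  stopifnot(inherits(tissue_mask, "tissue_mask"))
  fr <- grid_tissue_fraction(tissue_mask$mask, patch_size)
  keep <- which(fr >= min_tissue_frac, arr.ind = TRUE)
  n <- nrow(keep)
  ps <- data.frame(
    x = (keep[, 2] - 1L) * patch_size, y = (keep[, 1] - 1L) * patch_size,
    frac = fr[keep], section = rep(NA_integer_, n),
    piece = rep(NA_integer_, n), hole_candidate = rep(FALSE, n))
  ps <- ps[order(ps$y, ps$x), , drop = FALSE]
  rownames(ps) <- NULL
  structure(ps, patch_size = as.integer(patch_size), slide = slide_id,
            config = "tumor_map", min_tissue_frac = min_tissue_frac,
            class = c("patch_set", "data.frame"))
}

# Spectral clustering of 2D points into k groups: RBF affinity with the
# supplied bandwidth, symmetric normalized Laplacian, k smallest
# eigenvectors, row-normalized, then k-means with deterministic
# farthest-point initialization.
spectral_split <- function(coords, k, bandwidth, seed = 1L) {
  n <- nrow(coords)
  if (n <= k) return(seq_len(n))
  d2 <- as.matrix(dist(coords))^2
  W <- exp(-d2 / (2 * bandwidth^2)); diag(W) <- 0
  dg <- pmax(rowSums(W), 1e-12)
  S <- W / sqrt(outer(dg, dg))
  L <- diag(n) - S
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, n - seq_len(k) + 1L, drop = FALSE]
  U <- U / pmax(sqrt(rowSums(U^2)), 1e-12)
  ctrs <- matrix(0, k, k)
  start <- which.min(rowSums(sweep(coords, 2, colMeans(coords))^2))
  sel <- start
  for (j in seq_len(k - 1)) {
    dmin <- apply(as.matrix(dist(rbind(U[sel, , drop = FALSE], U)))[
      -seq_along(sel), seq_along(sel), drop = FALSE], 1, min)
    sel <- c(sel, setdiff(order(dmin, decreasing = TRUE), sel)[1])
  }
  km <- with_seed(seed, kmeans(U, centers = U[sel, , drop = FALSE],
                               iter.max = 50))
  km$cluster
}

#' Assign section and piece labels to a patch set
#'
#' Sections are the connected components of the radius-`r_section` graph over
#' patch centers; within each section, candidate pieces are components of the
#' radius-`r_piece` graph. While a section holds fewer pieces than expected,
#' its largest piece is split by spectral clustering on the patch coordinates
#' into deficit + 1 parts, iterating until the expectation is met. Sections
#' (and pieces within a section) are numbered 0-based in reading order of
#' their centroids.
#'
#' The default radii follow the 256-px patch convention (4096 px to join
#' pieces of a section, 512 px to separate pieces) and scale linearly with
#' the patch size.
#'
#' @param patchset a [extract_patches()] result.
#' @param n_sections expected number of sections on the slide.
#' @param pieces_per_section integer vector (length `n_sections`) of expected
#'   piece counts, in reading order.
#' @param r_section,r_piece connection radii in pixels.
#' @param max_iter maximum spectral-split iterations per section.
#' @param seed seed for the spectral split.
#' @return the patch set with `section` and `piece` columns filled.
#' @export
assign_sections_pieces <- function(patchset, n_sections, pieces_per_section,
                                   r_section = NULL, r_piece = NULL,
                                   max_iter = 10L, seed = 1L) {
  stopifnot(inherits(patchset, "patch_set"), nrow(patchset) > 0,
            n_sections >= 1, length(pieces_per_section) == n_sections)
  psz <- attr(patchset, "patch_size")
  r_section <- r_section %||% (4096 * psz / 256)
  r_piece <- r_piece %||% (512 * psz / 256)
  ctr <- cbind(patchset$x + psz / 2, patchset$y + psz / 2)
  comp <- radius_components(ctr, r_section)
  ncomp <- length(unique(comp))
  if (ncomp > n_sections)
    stop("assign_sections_pieces: found ", ncomp,
         " sections but expected ", n_sections)
  # reading order by component centroid (top-to-bottom, then left-to-right)
  cy <- tapply(ctr[, 2], comp, mean); cx <- tapply(ctr[, 1], comp, mean)
  ord <- order(round(cy / r_section), cx)
  sec_of <- match(comp, as.integer(names(cy))[ord]) - 1L
  patchset$section <- sec_of
  patchset$piece <- NA_integer_
  for (s in seq_len(ncomp) - 1L) {
    idx <- which(patchset$section == s)
    want <- pieces_per_section[s + 1L]
    sub <- ctr[idx, , drop = FALSE]
    piece <- radius_components(sub, r_piece)
    it <- 0L
    while (length(unique(piece)) < want) {
      it <- it + 1L
      if (it > max_iter)
        stop("assign_sections_pieces: piece expectation unreachable for section ", s)
      sizes <- table(piece)
      largest <- as.integer(names(sizes)[which.max(sizes)])
      deficit <- want - length(unique(piece))
      members <- which(piece == largest)
      parts <- spectral_split(sub[members, , drop = FALSE],
                              k = deficit + 1L, bandwidth = r_piece,
                              seed = child_seed(seed, s * 100L + it))
      piece[members] <- max(piece) + parts
      piece <- match(piece, unique(piece))
    }
    if (length(unique(piece)) > want)
      warning("section ", s, ": found ", length(unique(piece)),
              " pieces, expected ", want)
    pcy <- tapply(sub[, 2], piece, mean); pcx <- tapply(sub[, 1], piece, mean)
    pord <- order(round(pcy / r_piece), pcx)
    patchset$piece[idx] <- match(piece, as.integer(names(pcy))[pord]) - 1L
  }
  patchset
}

#' Hole/tear candidate patches via alpha-shape outlines (macro_map)
#'
#' For each labeled piece, the alpha shape of its tissue-patch centers is
#' computed; its outer outline follows the piece while bridging edge tears
#' connected to the exterior. Grid patches whose centers fall inside the
#' outline but which are absent from the tissue (tumor_map) set are appended
#' with the hole-candidate flag; the union is the macro_map configuration,
#' always a superset of the tumor_map set.
#'
#' @param patchset labeled patch set from [assign_sections_pieces()].
#' @param tissue_mask optional [compute_tissue_mask()] result used to record
#'   the (sub-threshold) tissue fraction of candidate patches.
#' @param alpha alpha-shape parameter; default `1 / (2 * patch_size)`.
#' @return patch set with `config = "macro_map"` and appended hole-candidate
#'   rows.
#' @export
hole_candidates <- function(patchset, tissue_mask = NULL, alpha = NULL) {
  stopifnot(inherits(patchset, "patch_set"))
  if (anyNA(patchset$section))
    stop("hole_candidates: run assign_sections_pieces first")
  psz <- attr(patchset, "patch_size")
  alpha <- alpha %||% (1 / (2 * psz))
  fr <- NULL
  if (!is.null(tissue_mask)) fr <- grid_tissue_fraction(tissue_mask$mask, psz)
  have <- paste(patchset$x, patchset$y)
  extra <- list()
  for (s in sort(unique(patchset$section))) {
    for (p in sort(unique(patchset$piece[patchset$section == s]))) {
      idx <- which(patchset$section == s & patchset$piece == p)
      if (length(idx) < 4) {
        warning("piece ", p, " of section ", s, " has < 4 patches; skipped")
        next
      }
      ctr <- cbind(patchset$x[idx] + psz / 2, patchset$y[idx] + psz / 2)
      inside <- alpha_filled_membership(ctr, alpha, psz,
                                        xr = range(patchset$x[idx]),
                                        yr = range(patchset$y[idx]))
      cand <- inside$grid
      cand <- cand[inside$inside & !(paste(cand$x, cand$y) %in% have), ,
                   drop = FALSE]
      if (!nrow(cand)) next
      cf <- if (is.null(fr)) 0 else
        fr[cbind(cand$y / psz + 1L, cand$x / psz + 1L)]
      extra[[length(extra) + 1L]] <- data.frame(
        x = cand$x, y = cand$y, frac = cf, section = s, piece = p,
        hole_candidate = TRUE)
    }
  }
  out <- rbind(as.data.frame(patchset),
               if (length(extra)) do.call(rbind, extra))
  rownames(out) <- NULL
  structure(out, patch_size = psz, slide = attr(patchset, "slide"),
            config = "macro_map",
            min_tissue_frac = attr(patchset, "min_tissue_frac"),
            class = c("patch_set", "data.frame"))
}
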