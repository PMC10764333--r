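# Prediction post-processing and evaluation statistics: follicle-confounder
# docking, pooled and macro (per-slide) AUC, and the cluster bootstrap.

#' Cut patch pixel arrays out of a slide raster
#'
#' @param raster H x W x 3 array.
#' @param patchset a `patch_set`.
#' @return list of (p x p x 3) arrays in patch-set row order.
#' @export
extract_patch_arrays <- function(raster, patchset) {
  psz <- attr(patchset, "patch_size")
  lapply(seq_len(nrow(patchset)), function(i) {
    x <- patchset$x[i]; y <- patchset$y[i]
    raster[(y + 1):(y + psz), (x + 1):(x + psz), , drop = FALSE]
  })
}

#' Dock tumor probabilities near detected follicles
#'
#' For each patch, three concentric circles (default radii 128, 256 and 512
#' pixels) are placed at the patch center and their fractional area overlap
#' with the follicle polygons computed by exact convex clipping (seeded
#' Monte-Carlo fallback on degenerate geometry). The normalized penalty is
#' the weight-decreasing convex combination of the three overlaps, and the
#' adjusted probability is `prob * (1 - penalty)` — never an increase.
#'
#' @param patch_probs numeric vector of tumor probabilities.
#' @param patch_coords n x 2 matrix of patch centers.
#' @param follicle_polygons list of polygon matrices (columns x, y).
#' @param radii circle radii in pixels, innermost first.
#' @param weights penalty weights, summing to 1 and decreasing with radius.
#' @return adjusted probability vector.
#' @export
follicle_adjust <- function(patch_probs, patch_coords, follicle_polygons,
                            radii = c(128, 256, 512),
                            weights = c(0.6, 0.3, 0.1)) {
  stopifnot(length(radii) == length(weights))
  if (abs(sum(weights) - 1) > 1e-8)
    stop("follicle_adjust: weights must sum to 1")
  if (is.unsorted(rev(weights)))
    stop("follicle_adjust: weights must decrease with radius")
  if (!length(follicle_polygons)) return(patch_probs)
  patch_coords <- matrix(patch_coords, ncol = 2)
  penalty <- vapply(seq_len(nrow(patch_coords)), function(i) {
    ov <- vapply(radii, function(r)
      disk_polygon_overlap(patch_coords[i, 1], patch_coords[i, 2], r,
                           follicle_polygons), numeric(1))
    min(sum(weights * ov), 1)
  }, numeric(1))
  patch_probs * (1 - penalty)
}

#' Pooled or macro (slide-averaged) AUC
#'
#' The pooled AUC is the Mann-Whitney concordance probability with the
#' standard tie convention (ties count 1/2). The macro AUC computes an AUC
#' per slide and averages with equal slide weight; slides lacking one of the
#' classes are skipped with a warning.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1, logical, or two-level factor).
#' @param slide_ids slide membership, required when `macro = TRUE`.
#' @param macro average per-slide AUCs instead of pooling.
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, labels, slide_ids = NULL, macro = FALSE) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels == 1)
  pooled_auc <- function(s, y) {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(s, ties.method = "average")
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (!macro) {
    a <- pooled_auc(scores, labels)
    if (is.na(a)) stop("evaluate_auc: AUC undefined, only one class present")
    return(a)
  }
  stopifnot(!is.null(slide_ids))
  per <- vapply(split(seq_along(scores), slide_ids), function(ix)
    pooled_auc(scores[ix], labels[ix]), numeric(1))
  if (anyNA(per)) {
    warning("evaluate_auc: ", sum(is.na(per)),
            " slide(s) lack a class and were skipped")
    per <- per[!is.na(per)]
  }
  if (!length(per)) stop("evaluate_auc: no slide with both classes")
  mean(per)
}

#' Cluster (slide-level) nonparametric bootstrap percentile interval
#'
#' Clusters (whole slides) are resampled with replacement and the statistic
#' recomputed on the concatenation; the percentile interval is returned. A
#' resample on which the statistic is undefined (error or NA) is redrawn, up
#' to `max_retries` times.
#'
#' @param statistic_fn function of a records subset (data.frame or vector).
#' @param records data.frame (or vector) of observations.
#' @param cluster_ids cluster membership of each record.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level interval coverage.
#' @param seed integer seed.
#' @param max_retries redraw budget for degenerate resamples.
#' @return `c(lo, hi)` percentile interval.
#' @export
bootstrap_ci <- function(statistic_fn, records, cluster_ids, n_boot = 1000L,
                         level = 0.95, seed = 1L, max_retries = 100L) {
  ids <- unique(cluster_ids)
  if (length(ids) < 2) stop("bootstrap_ci: need at least 2 clusters")
  take <- function(sel) {
    ix <- unlist(lapply(sel, function(id) which(cluster_ids == id)))
    if (is.data.frame(records)) records[ix, , drop = FALSE] else records[ix]
  }
  with_seed(seed, {
    stats <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      val <- NA_real_
      for (try in seq_len(max_retries)) {
        sel <- sample(ids, length(ids), replace = TRUE)
        val <- tryCatch(statistic_fn(take(sel)), error = function(e) NA_real_)
        if (!is.na(val)) break
      }
      if (is.na(val)) stop("bootstrap_ci: statistic undefined after retries")
      stats[b] <- val
    }
    unname(quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2), type = 7))
  })
}
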