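# Point-cloud file dialects: ASCII PLY with uchar RGB, and whitespace
# XYZ(+RGB) tables.

#' Write a specimen cloud as ASCII PLY
#'
#' @param cloud a [specimen_cloud()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path) {
  n <- nrow(cloud$points)
  has_col <- !is.null(cloud$colors)
  hdr <- c("ply", "format ascii 1.0", paste("element vertex", n),
           "property float x", "property float y", "property float z",
           if (has_col) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           "end_header")
  body <- if (has_col) {
    cbind(cloud$points, round(cloud$colors * 255))
  } else cloud$points
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(body, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY point cloud
#'
#' Parses vertex x/y/z plus optional uchar red/green/blue properties.
#'
#' @param path PLY file.
#' @param scale cm per model unit to attach.
#' @return a [specimen_cloud()].
#' @export
read_ply <- function(path, scale = NA_real_) {
  lines <- readLines(path)
  if (!identical(lines[1], "ply")) stop("read_ply: not a PLY file")
  end <- match("end_header", lines)
  if (is.na(end)) stop("read_ply: missing end_header")
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)[1]))
  props <- sub("^property \\S+ ", "", grep("^property", hdr, value = TRUE))
  tab <- read.table(text = lines[(end + 1):(end + nv)])
  colnames(tab)[seq_along(props)] <- props
  pts <- as.matrix(tab[, c("x", "y", "z")])
  cols <- if (all(c("red", "green", "blue") %in% props))
    as.matrix(tab[, c("red", "green", "blue")]) / 255 else NULL
  specimen_cloud(pts, cols, scale = scale)
}

#' Read/write whitespace XYZ(+RGB) point tables
#'
#' @param path file path.
#' @param scale cm per model unit to attach.
#' @return a [specimen_cloud()] (`read_xyz`) or `path` (`write_xyz`).
#' @export
read_xyz <- function(path, scale = NA_real_) {
  tab <- as.matrix(read.table(path))
  cols <- if (ncol(tab) >= 6) {
    cc <- tab[, 4:6]
    if (max(cc) > 1) cc / 255 else cc
  } else NULL
  specimen_cloud(tab[, 1:3], cols, scale = scale)
}

#' @rdname read_xyz
#' @param cloud a [specimen_cloud()].
#' @export
write_xyz <- function(cloud, path) {
  body <- if (is.null(cloud$colors)) cloud$points else
    cbind(cloud$points, round(cloud$colors * 255))
  write.table(body, path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
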