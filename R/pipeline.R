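# Pipeline orchestration: a serializable run configuration, the per-slide
# preprocess -> per-section fan-out (ink orientation, model prediction,
# mapping) pipeline, and Deep Zoom (DZI) tile export for the viewer.

#' Run configuration
#'
#' Collects every pipeline tunable; results are a pure function of
#' (inputs, config). The configuration survives a JSON round-trip
#' unchanged, which the test suite asserts.
#'
#' @param patch_size patch edge, pixels.
#' @param min_tissue_frac tissue-fraction threshold for patch extraction
#'   (no canonical value exists; 0.5 is the package default).
#' @param r_section,r_piece section/piece connection radii (NULL = scaled
#'   defaults, see [assign_sections_pieces()]).
#' @param band_px ink edge-band width.
#' @param min_component_px minimum ink component size.
#' @param ot list of optimal-transport settings (`iters`, `step`, `decay`,
#'   `n_projections`).
#' @param workers parallel workers for the per-section fan-out.
#' @param seed master seed; every stochastic stage derives its own stream.
#' @param profile `"desk"` or `"full"` model profile.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(patch_size = 256, min_tissue_frac = 0.5,
                       r_section = NULL, r_piece = NULL, band_px = 16,
                       min_component_px = 50,
                       ot = list(iters = 300, step = 0.5, decay = 0.98,
                                 n_projections = 64),
                       workers = 1, seed = 1, profile = "desk") {
  structure(list(patch_size = patch_size, min_tissue_frac = min_tissue_frac,
                 r_section = r_section, r_piece = r_piece, band_px = band_px,
                 min_component_px = min_component_px, ot = ot,
                 workers = workers, seed = seed, profile = profile),
            class = "run_config")
}

#' @rdname run_config
#' @param x a list (e.g. parsed from JSON).
#' @export
as_run_config <- function(x) {
  cfg <- run_config()
  cfg[names(x)] <- x
  cfg
}

section_bbox <- function(patchset, s, psz, dims) {
  ix <- which(patchset$section == s)
  list(x0 = max(0, min(patchset$x[ix]) - psz),
       x1 = min(dims[2], max(patchset$x[ix]) + 2 * psz),
       y0 = max(0, min(patchset$y[ix]) - psz),
       y1 = min(dims[1], max(patchset$y[ix]) + 2 * psz))
}

#' Run the margin-assessment pipeline over fixture slides
#'
#' Per slide: tissue mask, patch extraction and section/piece assignment run
#' in series; then every section fans out (in parallel over `workers`) to
#' ink orientation and, when models are supplied, CNN embedding + GAT
#' prediction; finally each oriented section is morphed onto the template.
#' Results are identical for 1 or N workers. Any stage failure marks the
#' bundle partial with a stage-level error record.
#'
#' @param config a [run_config()].
#' @param slides list of slides: each `list(id=, raster=, n_sections=,
#'   pieces_per_section=)`.
#' @param models optional `list(backbone=, gnn=)` from [train_patch_cnn()] /
#'   [train_gnn()].
#' @param template optional [make_template()] result for mapping.
#' @return result bundle: per-slide list of per-section records plus `log`
#'   (stage wall times) and `partial` flag.
#' @export
run_pipeline <- function(config, slides, models = NULL, template = NULL) {
  t_all <- proc.time()[3]
  bundle <- list(slides = list(), log = list(), partial = FALSE)
  for (si in seq_along(slides)) {
    sl <- slides[[si]]
    rec <- list(id = sl$id %||% paste0("slide", si), sections = list(),
                errors = list())
    t0 <- proc.time()[3]
    prep <- tryCatch({
      mask <- compute_tissue_mask(sl$raster)
      ps <- extract_patches(mask, config$patch_size, config$min_tissue_frac,
                            slide_id = rec$id)
      if (nrow(ps) == 0) NULL else {
        ps <- assign_sections_pieces(ps, sl$n_sections, sl$pieces_per_section,
                                     r_section = config$r_section,
                                     r_piece = config$r_piece,
                                     seed = child_seed(config$seed, si))
        list(mask = mask, patches = ps)
      }
    }, error = function(e) structure(list(message = conditionMessage(e)),
                                     class = "stage_error"))
    rec$t_preprocess <- proc.time()[3] - t0
    if (inherits(prep, "stage_error")) {
      rec$errors$preprocess <- prep$message
      bundle$partial <- TRUE
      bundle$slides[[rec$id]] <- rec
      next
    }
    if (is.null(prep)) {
      rec$empty <- TRUE
      warning("slide ", rec$id, ": no tissue found")
      bundle$slides[[rec$id]] <- rec
      next
    }
    ps <- prep$patches
    psz <- attr(ps, "patch_size")
    sections <- sort(unique(ps$section))
    t0 <- proc.time()[3]
    worker <- function(s) {
      out <- list(section = s)
      ix <- which(ps$section == s)
      bb <- section_bbox(ps, s, psz, dim(sl$raster))
      sub_r <- sl$raster[(bb$y0 + 1):bb$y1, (bb$x0 + 1):bb$x1, , drop = FALSE]
      sub_m <- prep$mask$mask[(bb$y0 + 1):bb$y1, (bb$x0 + 1):bb$x1]
      ol <- tryCatch(
        section_orientation(sub_r, structure(list(mask = sub_m),
                                             class = "tissue_mask"),
                            band_px = config$band_px,
                            min_component_px = config$min_component_px),
        error = function(e) structure(list(NULL), class = "missing_orientation",
                                      reason = conditionMessage(e)))
      if (inherits(ol, "missing_orientation")) {
        out$theta <- NA_real_
        out$orientation_flag <- attr(ol, "reason")
      } else {
        out$theta <- ol$theta
        out$blue <- ol$blue + c(bb$x0, bb$y0)
        out$red <- ol$red + c(bb$x0, bb$y0)
      }
      if (!is.null(models)) {
        arrs <- extract_patch_arrays(sl$raster, ps[ix, , drop = FALSE])
        emb <- embed_patches(models$backbone, arrs)
        gr <- build_patch_graph(cbind(ps$x[ix] + psz / 2, ps$y[ix] + psz / 2),
                                emb, radius = 1.5 * psz)
        pr <- gnn_predict(models$gnn, gr)
        out$probs <- pr
        out$coords <- gr$coords
      }
      out
    }
    res <- if (config$workers > 1 && .Platform$OS.type == "unix") {
      parallel::mclapply(sections, worker, mc.cores = config$workers)
    } else lapply(sections, worker)
    rec$t_sections <- proc.time()[3] - t0
    names(res) <- paste0("section", sections)
    # mapping stage (series; cheap relative to models)
    if (!is.null(template)) {
      t0 <- proc.time()[3]
      for (k in seq_along(res)) {
        r <- res[[k]]
        if (is.null(r$probs)) next
        if (is.na(r$theta)) {
          res[[k]]$mapping <- list(flag = "unoriented")
          next
        }
        tr <- morph_to_ellipse(
          r$coords, template$meta$ellipse, probs = r$probs,
          iters = config$ot$iters, step = config$ot$step,
          decay = config$ot$decay, n_projections = config$ot$n_projections,
          landmarks = rbind(r$blue, r$red),
          seed = child_seed(config$seed, 1000 + si * 10 + k))
        lm <- tr$landmarks
        sect_theta <- clock_angle(lm[2, 1] - lm[1, 1], lm[2, 2] - lm[1, 2])
        tr <- rotate_to_template(tr, sect_theta, template$meta$template_angle)
        res[[k]]$mapping <- list(rotation = tr$rotation,
                                 sw_final = tr$sw_final,
                                 transported = tr$transported)
      }
      rec$t_mapping <- proc.time()[3] - t0
    }
    rec$sections <- res
    bundle$slides[[rec$id]] <- rec
  }
  bundle$log$t_total <- proc.time()[3] - t_all
  bundle
}

#' Serialize a result bundle to per-section JSON records
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created).
#' @return paths written, invisibly.
#' @export
export_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in names(bundle$slides)) {
    rec <- bundle$slides[[id]]
    for (sn in names(rec$sections)) {
      s <- rec$sections[[sn]]
      out <- list(slide = id, section = s$section, theta = s$theta)
      if (!is.null(s$orientation_flag)) out$flag <- s$orientation_flag
      if (!is.null(s$probs)) {
        out$patches <- cbind(as.data.frame(s$coords), as.data.frame(s$probs))
        names(out$patches)[1:2] <- c("x", "y")
      }
      if (!is.null(s$mapping))
        out$mapping <- s$mapping[setdiff(names(s$mapping), "transported")]
      p <- file.path(dir, paste0(id, "_", sn, ".json"))
      write_json_file(out, p)
      paths <- c(paths, p)
    }
  }
  summary_p <- file.path(dir, "case_summary.json")
  write_json_file(list(n_slides = length(bundle$slides),
                       partial = bundle$partial), summary_p)
  invisible(c(paths, summary_p))
}

# Block-average downscale of a raster to given dims via EBImage resize.
resize_raster <- function(raster, h, w) {
  out <- array(0, dim = c(h, w, dim(raster)[3]))
  for (ch in seq_len(dim(raster)[3]))
    out[, , ch] <- EBImage::resize(raster[, , ch], w = h, h = w)
  out
}

#' Export a raster as a Deep Zoom Image (DZI) pyramid
#'
#' Writes the standard DZI XML descriptor and the `<name>_files/<level>`
#' tile folders; the deepest level holds the raster at native resolution so
#' its tiles stitch back to the input exactly.
#'
#' @param raster H x W x 3 array.
#' @param out_dir output directory.
#' @param name base name of descriptor and tile folder.
#' @param tile_size tile edge (a power of two).
#' @return path of the descriptor file.
#' @export
export_tiles <- function(raster, out_dir, name = "section", tile_size = 256L) {
  if (bitwAnd(tile_size, tile_size - 1L) != 0L || tile_size < 1L)
    stop("export_tiles: tile size must be a power of two")
  H <- dim(raster)[1]; W <- dim(raster)[2]
  L <- ceiling(log2(max(W, H, 1)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files_dir <- file.path(out_dir, paste0(name, "_files"))
  lvl_raster <- raster
  for (lvl in L:0) {
    lw <- max(1L, ceiling(W / 2^(L - lvl))); lh <- max(1L, ceiling(H / 2^(L - lvl)))
    if (lvl < L) lvl_raster <- resize_raster(lvl_raster, lh, lw)
    ld <- file.path(files_dir, lvl)
    dir.create(ld, recursive = TRUE, showWarnings = FALSE)
    for (col in 0:((lw - 1) %/% tile_size)) {
      for (row in 0:((lh - 1) %/% tile_size)) {
        xs <- (col * tile_size + 1):min((col + 1) * tile_size, lw)
        ys <- (row * tile_size + 1):min((row + 1) * tile_size, lh)
        tile <- lvl_raster[ys, xs, , drop = FALSE]
        png::writePNG(pmin(pmax(tile, 0), 1),
                      file.path(ld, paste0(col, "_", row, ".png")))
      }
    }
  }
  desc <- file.path(out_dir, paste0(name, ".dzi"))
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               sprintf('<Image TileSize="%d" Overlap="0" Format="png" xmlns="http://schemas.microsoft.com/deepzoom/2008">',
                       tile_size),
               sprintf('  <Size Width="%d" Height="%d"/>', W, H),
               '</Image>'), desc)
  desc
}

#' Reassemble the deepest DZI level into a raster
#'
#' @param out_dir,name as passed to [export_tiles()].
#' @return H x W x 3 array.
#' @export
read_dzi_level0 <- function(out_dir, name = "section") {
  desc <- readLines(file.path(out_dir, paste0(name, ".dzi")))
  sz <- regmatches(desc, regexec('Width="([0-9]+)" Height="([0-9]+)"', desc))
  sz <- sz[vapply(sz, length, integer(1)) == 3][[1]]
  W <- as.integer(sz[2]); H <- as.integer(sz[3])
  ts <- as.integer(sub('.*TileSize="([0-9]+)".*', "\\1",
                       grep("TileSize", desc, value = TRUE)[1]))
  L <- ceiling(log2(max(W, H, 1)))
  ld <- file.path(out_dir, paste0(name, "_files"), L)
  out <- array(0, dim = c(H, W, 3))
  for (f in list.files(ld, full.names = TRUE)) {
    cr <- as.integer(strsplit(sub("\\.png$", "", basename(f)), "_")[[1]])
    tile <- png::readPNG(f)
    if (length(dim(tile)) == 2) tile <- array(tile, dim = c(dim(tile), 3))
    ys <- (cr[2] * ts + 1):(cr[2] * ts + dim(tile)[1])
    xs <- (cr[1] * ts + 1):(cr[1] * ts + dim(tile)[2])
    out[ys, xs, ] <- tile[, , 1:3]
  }
  out
}
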