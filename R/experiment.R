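# Desk-scale end-to-end margin experiment: seeded synthetic slides ->
# patch CNN -> embeddings -> radius graph -> GAT, with a node-only CNN
# probe as the context-free baseline. Used by the test suite and the
# acceptance script; all sizes are chosen for a single CPU.

#' Render one desk-scale tumor slide fixture
#'
#' A disk-shaped section with two tumor regions at seeded clock positions;
#' texture latents are drawn by the renderer.
#'
#' @param seed fixture seed.
#' @param canvas canvas edge, pixels.
#' @param patch_size patch edge, pixels.
#' @return [make_section_image()] result.
#' @export
demo_tumor_slide <- function(seed, canvas = 864L, patch_size = 48L) {
  cc <- canvas / 2
  pr <- canvas * 0.37
  pos <- with_seed(child_seed(seed, 101L), {
    list(a1 = runif(1, 0, 360), a2 = runif(1, 0, 360),
         r1 = runif(1, 0.16, 0.22) * canvas, r2 = runif(1, 0.14, 0.20) * canvas)
  })
  t1 <- cc + 0.55 * pr * clock_vector(pos$a1)
  t2 <- cc + 0.55 * pr * clock_vector(pos$a2)
  spec <- section_spec(
    canvas = c(canvas, canvas), patch_size = patch_size,
    sections = list(list(
      pieces = list(disk_polygon(cc, cc, pr)),
      tumors = list(disk_polygon(t1[1], t1[2], pos$r1),
                    disk_polygon(t2[1], t2[2], pos$r2)))),
    seed = seed)
  make_section_image(spec)
}

#' Desk-scale CNN-graph-GAT tumor experiment on synthetic slides
#'
#' Renders `n_train + n_test` seeded slides, trains the patch CNN on the
#' training patches (tumor vs benign), embeds all patches, builds radius
#' patch graphs, trains the GAT on the training graphs and evaluates both
#' the GAT and the node-only CNN probe on the held-out slides.
#'
#' @param seed master seed.
#' @param n_train,n_test slide counts.
#' @param config a [model_config()]; default desk profile.
#' @param patch_size fixture patch size.
#' @return list with `auc_gnn`, `auc_cnn_probe`, `n_test_patches`, the
#'   trained `backbone` and `gnn`, and the per-slide data.
#' @export
run_desk_experiment <- function(seed = 1L, n_train = 8L, n_test = 4L,
                                config = NULL, patch_size = 48L) {
  config <- config %||% desk_config(seed = child_seed(seed, 7L),
                                    input_size = 24L, epochs_gnn = 400L)
  slides <- lapply(seq_len(n_train + n_test), function(k)
    demo_tumor_slide(child_seed(seed, k), patch_size = patch_size))
  dat <- lapply(slides, function(fx) {
    lab <- fx$truth$patch_labels
    keep <- lab$label %in% c("benign", "tumor")
    ps <- structure(data.frame(x = lab$x[keep], y = lab$y[keep],
                               frac = 1, section = 0L, piece = 0L,
                               hole_candidate = FALSE),
                    patch_size = as.integer(patch_size),
                    class = c("patch_set", "data.frame"))
    list(arrs = extract_patch_arrays(fx$raster, ps),
         labels = lab$label[keep],
         coords = cbind(lab$x[keep] + patch_size / 2,
                        lab$y[keep] + patch_size / 2))
  })
  tr <- seq_len(n_train); te <- n_train + seq_len(n_test)
  backbone <- train_patch_cnn(do.call(c, lapply(dat[tr], `[[`, "arrs")),
                              unlist(lapply(dat[tr], `[[`, "labels")), config)
  graphs <- lapply(dat, function(d)
    build_patch_graph(d$coords, embed_patches(backbone, d$arrs),
                      radius = 1.5 * patch_size))
  gnn <- train_gnn(graphs[tr], lapply(dat[tr], `[[`, "labels"), config)
  te_y <- unlist(lapply(dat[te], `[[`, "labels")) == "tumor"
  te_gnn <- do.call(rbind, lapply(te, function(k) gnn_predict(gnn, graphs[[k]])))
  te_cnn <- do.call(rbind, lapply(te, function(k)
    predict_patch_cnn(backbone, dat[[k]]$arrs)))
  slide_ids <- rep(seq_along(te), vapply(dat[te], function(d)
    length(d$labels), integer(1)))
  list(auc_gnn = evaluate_auc(te_gnn[, "tumor"], te_y),
       auc_cnn_probe = evaluate_auc(te_cnn[, "tumor"], te_y),
       macro_auc_gnn = evaluate_auc(te_gnn[, "tumor"], te_y,
                                    slide_ids = slide_ids, macro = TRUE),
       n_test_patches = length(te_y),
       backbone = backbone, gnn = gnn, data = dat, graphs = graphs,
       test_idx = te)
}
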