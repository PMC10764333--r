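# Radius patch graphs and the graph attention network (GAT). Three attention
# layers (default 32, 32, 64, one head each) with DropEdge and Dropout during
# training, a dense softmax node head, Adam + cosine annealing. Forward and
# backward passes are written out explicitly over the edge list; sparse
# aggregation uses Matrix.

#' Build a radius-neighbor patch graph
#'
#' Nodes are patch (or nucleus) centers; undirected edges join all pairs
#' within `radius` (self-loops excluded from the edge list but added
#' internally during attention).
#'
#' @param coords n x 2 matrix of node coordinates.
#' @param embeddings n x d node attribute matrix.
#' @param radius connection radius (> 0), same units as `coords`.
#' @param task optional task tag, e.g. `"tumor_map"` or `"macro_map"`.
#' @return object of class `patch_graph` with `coords`, `features`, `edges`
#'   (m x 2, i < j), `radius`, `task`.
#' @export
build_patch_graph <- function(coords, embeddings, radius, task = "tumor_map") {
  stopifnot(radius > 0, nrow(coords) == nrow(embeddings))
  edges <- radius_pairs(as.matrix(coords), radius)
  structure(list(coords = as.matrix(coords),
                 features = as.matrix(embeddings),
                 edges = edges, radius = radius, task = task),
            class = "patch_graph")
}

# Directed edge list with self-loops from an undirected edge matrix.
directed_edges <- function(edges, n) {
  src <- c(edges[, 1], edges[, 2], seq_len(n))
  dst <- c(edges[, 2], edges[, 1], seq_len(n))
  list(src = src, dst = dst)
}

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)

gat_layer_forward <- function(X, W, a_src, a_dst, b, src, dst, n) {
  Z <- X %*% W
  s <- as.vector(Z[src, , drop = FALSE] %*% a_src +
                 Z[dst, , drop = FALSE] %*% a_dst)
  e <- leaky_relu(s)
  emax <- tapply(e, dst, max)
  ex <- exp(e - emax[as.character(dst)])
  denom <- tapply(ex, dst, sum)
  alpha <- as.vector(ex / denom[as.character(dst)])
  A <- Matrix::sparseMatrix(i = dst, j = src, x = alpha, dims = c(n, n))
  U <- as.matrix(A %*% Z)
  U <- sweep(U, 2, b, `+`)
  out <- elu(U)
  list(out = out, Z = Z, s = s, alpha = alpha, A = A, U = U)
}

gat_layer_backward <- function(dOut, cache, X, W, a_src, a_dst, src, dst) {
  U <- cache$U
  dU <- dOut * ifelse(U > 0, 1, cache$out + 1)      # ELU'
  db <- colSums(dU)
  Z <- cache$Z; alpha <- cache$alpha
  dalpha <- rowSums(dU[dst, , drop = FALSE] * Z[src, , drop = FALSE])
  dZ <- as.matrix(Matrix::crossprod(cache$A, dU))   # t(A) %*% dU
  S <- tapply(alpha * dalpha, dst, sum)
  de <- alpha * (dalpha - S[as.character(dst)])
  ds <- as.vector(de * ifelse(cache$s > 0, 1, 0.2))
  da_src <- colSums(ds * Z[src, , drop = FALSE])
  da_dst <- colSums(ds * Z[dst, , drop = FALSE])
  dZ <- dZ + rowsum_into(outer(ds, a_src), src, nrow(Z)) +
             rowsum_into(outer(ds, a_dst), dst, nrow(Z))
  dW <- crossprod(X, dZ)
  dX <- dZ %*% t(W)
  list(dX = dX, dW = dW, da_src = da_src, da_dst = da_dst, db = db)
}

rowsum_into <- function(M, group, n) {
  rs <- rowsum(M, group = group)
  out <- matrix(0, n, ncol(M))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

init_gnn <- function(config, d_in, n_classes) {
  dims <- c(d_in, config$gnn_dims)
  with_seed(child_seed(config$seed, 31L), {
    params <- list()
    for (l in 1:3) {
      params[[paste0("W", l)]] <- matrix(
        rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])), dims[l], dims[l + 1])
      params[[paste0("as", l)]] <- rnorm(dims[l + 1], sd = 0.1)
      params[[paste0("ad", l)]] <- rnorm(dims[l + 1], sd = 0.1)
      params[[paste0("b", l)]] <- numeric(dims[l + 1])
    }
    # output head sees the last attention layer plus a skip connection to
    # the input embedding, so context can only add to node-level evidence
    d_out <- dims[4] + d_in
    params$Wo <- matrix(rnorm(d_out * n_classes, sd = sqrt(2 / d_out)),
                        d_out, n_classes)
    params$bo <- numeric(n_classes)
    structure(list(params = params, config = config, dims = dims,
                   classes = NULL), class = "patch_gnn")
  })
}

gnn_forward <- function(gnn, X, edges, training = FALSE, rng_active = FALSE) {
  n <- nrow(X)
  cfg <- gnn$config
  if (training && rng_active && cfg$drop_edge > 0 && nrow(edges) > 0) {
    keep <- runif(nrow(edges)) >= cfg$drop_edge
    edges <- edges[keep, , drop = FALSE]
  }
  de <- directed_edges(edges, n)
  p <- gnn$params
  caches <- list(); drops <- list()
  H <- X
  Xs <- list()
  for (l in 1:3) {
    Xs[[l]] <- H
    cc <- gat_layer_forward(H, p[[paste0("W", l)]], p[[paste0("as", l)]],
                            p[[paste0("ad", l)]], p[[paste0("b", l)]],
                            de$src, de$dst, n)
    H <- cc$out
    if (training && rng_active && cfg$dropout > 0) {
      mask <- matrix(runif(length(H)) >= cfg$dropout, nrow(H), ncol(H))
      H <- H * mask / (1 - cfg$dropout)
      drops[[l]] <- mask
    }
    caches[[l]] <- cc
  }
  Hfull <- cbind(H, X)
  logits <- sweep(Hfull %*% p$Wo, 2, p$bo, `+`)
  list(logits = logits, H = Hfull, caches = caches, drops = drops, Xs = Xs,
       de = de, d_att = ncol(H))
}

gnn_backward <- function(gnn, fw, dlogits) {
  p <- gnn$params
  g <- list()
  g$Wo <- crossprod(fw$H, dlogits)
  g$bo <- colSums(dlogits)
  dH <- dlogits %*% t(p$Wo[seq_len(fw$d_att), , drop = FALSE])
  for (l in 3:1) {
    if (length(fw$drops) >= l && !is.null(fw$drops[[l]]))
      dH <- dH * fw$drops[[l]] / (1 - gnn$config$dropout)
    bb <- gat_layer_backward(dH, fw$caches[[l]], fw$Xs[[l]],
                             p[[paste0("W", l)]], p[[paste0("as", l)]],
                             p[[paste0("ad", l)]], fw$de$src, fw$de$dst)
    g[[paste0("W", l)]] <- bb$dW
    g[[paste0("as", l)]] <- bb$da_src
    g[[paste0("ad", l)]] <- bb$da_dst
    g[[paste0("b", l)]] <- bb$db
    dH <- bb$dX
  }
  g[names(p)]
}

#' Train the graph attention network on labeled patch graphs
#'
#' Full-graph training with Adam, cosine annealing, DropEdge and Dropout
#' (active only during training). Gradients accumulate over `batch_gnn`
#' graphs per step.
#'
#' @param graphs list of [build_patch_graph()] objects.
#' @param labels list of per-node class vectors (factor/character), aligned
#'   with `graphs`.
#' @param config a [model_config()].
#' @return object of class `patch_gnn`.
#' @export
train_gnn <- function(graphs, labels, config = desk_config()) {
  stopifnot(length(graphs) == length(labels))
  all_lab <- factor(unlist(lapply(labels, as.character)))
  classes <- levels(all_lab)
  if (length(classes) < 2) stop("train_gnn: need at least 2 classes")
  y <- lapply(labels, function(l) match(as.character(l), classes))
  for (k in seq_along(graphs))
    if (length(y[[k]]) != nrow(graphs[[k]]$features))
      stop("train_gnn: label/graph size mismatch for graph ", k)
  gnn <- init_gnn(config, ncol(graphs[[1]]$features), length(classes))
  gnn$classes <- classes
  nomcl <- diag(length(classes))
  loss_log <- numeric(0)
  opt <- adam_init(gnn$params)
  with_seed(child_seed(config$seed, 37L), {
    for (ep in seq_len(config$epochs_gnn)) {
      lr <- cosine_lr(config$lr_gnn, ep, config$epochs_gnn)
      ord <- sample.int(length(graphs))
      ep_loss <- 0; ep_n <- 0
      for (bt in split(ord, ceiling(seq_along(ord) / config$batch_gnn))) {
        acc <- NULL
        for (k in bt) {
          gr <- graphs[[k]]
          fw <- gnn_forward(gnn, gr$features, gr$edges, training = TRUE,
                            rng_active = TRUE)
          pr <- softmax_rows(fw$logits)
          nk <- nrow(pr)
          ep_loss <- ep_loss - sum(log(pmax(pr[cbind(seq_len(nk), y[[k]])], 1e-12)))
          ep_n <- ep_n + nk
          dlogits <- (pr - nomcl[y[[k]], , drop = FALSE]) / (nk * length(bt))
          g <- gnn_backward(gnn, fw, dlogits)
          acc <- if (is.null(acc)) g else Map(`+`, acc, g)
        }
        st <- adam_step(gnn$params, acc, opt, lr)
        gnn$params <- st$params; opt <- st$state
      }
      loss_log <- c(loss_log, ep_loss / max(ep_n, 1))
    }
  })
  gnn$loss_log <- loss_log
  gnn
}

#' Per-node class probabilities from a trained GAT
#'
#' Evaluation mode: DropEdge and Dropout are inactive, so prediction is
#' deterministic and permutation-equivariant in the node order.
#'
#' @param gnn a [train_gnn()] result.
#' @param graph a [build_patch_graph()] object.
#' @return n x K matrix of probabilities (rows sum to 1), columns named by
#'   class, rows in node order.
#' @export
gnn_predict <- function(gnn, graph) {
  fw <- gnn_forward(gnn, graph$features, graph$edges, training = FALSE)
  pr <- softmax_rows(fw$logits)
  colnames(pr) <- gnn$classes
  pr
}

#' Interpolate node predictions at query positions
#'
#' Fixed-weight message passing: each query receives the inverse-distance
#' weighted average of the probabilities of all nodes within the graph
#' radius. A query at a node's exact position returns that node's
#' probability; queries with no node in radius are flagged missing, never
#' extrapolated.
#'
#' @param graph a [build_patch_graph()] object.
#' @param probs n x K per-node probability matrix.
#' @param query_coords q x 2 matrix.
#' @return q x K matrix with attribute `missing` (logical vector); missing
#'   rows are NA.
#' @export
propagate_predictions <- function(graph, probs, query_coords) {
  query_coords <- matrix(query_coords, ncol = 2)
  n <- nrow(graph$coords)
  out <- matrix(NA_real_, nrow(query_coords), ncol(probs))
  missing <- logical(nrow(query_coords))
  for (q in seq_len(nrow(query_coords))) {
    d <- sqrt((graph$coords[, 1] - query_coords[q, 1])^2 +
              (graph$coords[, 2] - query_coords[q, 2])^2)
    hit <- which(d < 1e-9)
    if (length(hit)) { out[q, ] <- probs[hit[1], ]; next }
    nb <- which(d <= graph$radius)
    if (!length(nb)) { missing[q] <- TRUE; next }
    w <- 1 / d[nb]
    out[q, ] <- colSums(probs[nb, , drop = FALSE] * w) / sum(w)
  }
  colnames(out) <- colnames(probs)
  attr(out, "missing") <- missing
  out
}
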