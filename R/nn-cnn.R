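# Small convolutional embedding backbone, written directly in R on top of
# BLAS matrix products (im2col convolutions, 2x2 max pooling, global average
# pooling, dense softmax head; Adam with cosine-annealed learning rate).
# The backbone is desk-scale by design: four conv blocks, 64-d embeddings,
# 32x32 inputs by default. Channel widths and input size are configurable.

#' Model configuration for the CNN backbone and the graph network
#'
#' Collects every tunable of the patch-model stack. The defaults are the
#' production-scale schedule (CNN: batch 32 patches, lr 1e-4, 100 epochs;
#' GNN: batch 16 graphs, lr 1e-2, 1500 epochs; cosine annealing; graph
#' attention layers of width 32, 32, 64 with DropEdge and Dropout); the
#' desk-scale profile used in tests and examples is expressed purely through
#' this config via [desk_config()].
#'
#' @param input_size CNN input edge (patches are average-pooled to this).
#' @param conv_channels channel widths of the four conv blocks; the last is
#'   the embedding dimension.
#' @param gnn_dims widths of the three graph attention layers.
#' @param drop_edge,dropout DropEdge / Dropout rates (training only).
#' @param lr_cnn,lr_gnn Adam learning rates.
#' @param batch_cnn patches per CNN batch; `batch_gnn` graphs per GNN batch.
#' @param batch_gnn graphs per GNN step.
#' @param epochs_cnn,epochs_gnn training epochs.
#' @param seed integer seed governing initialization, shuffling and dropout.
#' @return object of class `model_config`.
#' @export
model_config <- function(input_size = 32L, conv_channels = c(8L, 16L, 32L, 64L),
                         gnn_dims = c(32L, 32L, 64L), drop_edge = 0.2,
                         dropout = 0.2, lr_cnn = 1e-4, lr_gnn = 1e-2,
                         batch_cnn = 32L, batch_gnn = 16L,
                         epochs_cnn = 100L, epochs_gnn = 1500L, seed = 1L) {
  stopifnot(drop_edge >= 0, drop_edge <= 1, dropout >= 0, dropout <= 1)
  structure(as.list(environment()), class = "model_config")
}

#' Desk-scale profile of [model_config()]
#'
#' Shorter schedules and a slightly higher CNN learning rate suited to the
#' synthetic fixture datasets and a single CPU.
#'
#' @param ... overrides passed to [model_config()].
#' @return `model_config`.
#' @export
desk_config <- function(...) {
  args <- modifyList(list(lr_cnn = 1e-3, epochs_cnn = 20L,
                          epochs_gnn = 150L, batch_gnn = 4L), list(...))
  do.call(model_config, args)
}

# ---- tensor plumbing -------------------------------------------------------
# Images are stored per batch as a matrix (h*w*c) x N, column-major over
# (y, x, channel) within each image.

conv_index <- function(h, w, cin, k = 3L, pad = 1L) {
  oy <- rep(seq_len(h), times = w)
  ox <- rep(seq_len(w), each = h)
  I <- matrix(NA_integer_, h * w, k * k * cin)
  col <- 0L
  for (c in seq_len(cin)) for (kx in seq_len(k)) for (ky in seq_len(k)) {
    col <- col + 1L
    iy <- oy + ky - 1L - pad
    ix <- ox + kx - 1L - pad
    ok <- iy >= 1L & iy <= h & ix >= 1L & ix <= w
    I[ok, col] <- iy[ok] + (ix[ok] - 1L) * h + (c - 1L) * h * w
  }
  I
}

conv_forward <- function(A, Wm, b, I) {
  P <- nrow(I); K <- ncol(I); N <- ncol(A); cout <- ncol(Wm)
  Ipad <- I; Ipad[is.na(Ipad)] <- nrow(A) + 1L
  G <- rbind(A, 0)[as.vector(Ipad), , drop = FALSE]          # (P*K) x N
  Cm <- matrix(aperm(array(G, c(P, K, N)), c(1, 3, 2)), P * N, K)
  Y <- Cm %*% Wm
  Y <- Y + rep(b, each = P * N)
  out <- matrix(aperm(array(Y, c(P, N, cout)), c(1, 3, 2)), P * cout, N)
  list(out = out, Cm = Cm, Ipad = Ipad, P = P, K = K, cout = cout)
}

conv_backward <- function(dOut, cache, Wm, n_in) {
  P <- cache$P; K <- cache$K; cout <- cache$cout; N <- ncol(dOut)
  dY <- matrix(aperm(array(dOut, c(P, cout, N)), c(1, 3, 2)), P * N, cout)
  dW <- crossprod(cache$Cm, dY)
  db <- colSums(dY)
  dCm <- dY %*% t(Wm)
  dG <- matrix(aperm(array(dCm, c(P, N, K)), c(1, 3, 2)), P * K, N)
  rs <- rowsum(dG, group = as.vector(cache$Ipad))
  dA <- matrix(0, n_in + 1L, N)
  dA[as.integer(rownames(rs)), ] <- rs
  list(dA = dA[seq_len(n_in), , drop = FALSE], dW = dW, db = db)
}

pool_index <- function(h, w, cin) {
  oh <- h %/% 2L; ow <- w %/% 2L
  oy <- rep(seq_len(oh), times = ow * cin)
  ox <- rep(rep(seq_len(ow), each = oh), times = cin)
  oc <- rep(seq_len(cin), each = oh * ow)
  base <- function(dy, dx) (2L * oy - 1L + dy) + (2L * ox - 2L + dx) * h +
    (oc - 1L) * h * w
  cbind(base(0L, 0L), base(0L, 1L), base(1L, 0L), base(1L, 1L))
}

pool_forward <- function(A, Mp) {
  P2 <- nrow(Mp); N <- ncol(A)
  arr <- array(A[as.vector(Mp), , drop = FALSE], c(P2, 4, N))
  a1 <- arr[, 1, ]; a2 <- arr[, 2, ]; a3 <- arr[, 3, ]; a4 <- arr[, 4, ]
  mx <- pmax(a1, a2, a3, a4)
  am <- ifelse(mx == a1, 1L, ifelse(mx == a2, 2L, ifelse(mx == a3, 3L, 4L)))
  list(out = matrix(mx, P2, N), am = matrix(am, P2, N))
}

pool_backward <- function(dOut, Mp, am, n_in) {
  P2 <- nrow(Mp); N <- ncol(dOut)
  rows <- Mp[cbind(rep(seq_len(P2), N), as.vector(am))]
  dA <- matrix(0, n_in, N)
  dA[cbind(rows, rep(seq_len(N), each = P2))] <- as.vector(dOut)
  dA
}

relu <- function(x) { x[x < 0] <- 0; x }
# leaky rectifier used in the backbone (slope 0.1) -- avoids dead units in
# the small desk-scale network
lrelu <- function(x) pmax(x, 0) + 0.1 * pmin(x, 0)
lrelu_grad <- function(g, act) g * ifelse(act > 0, 1, 0.1)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

cosine_lr <- function(lr0, epoch, total, lr_min = 0) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (epoch - 1) / max(total, 1)))
}

# ---- backbone --------------------------------------------------------------

init_backbone <- function(config, n_classes) {
  s <- config$input_size
  ch <- c(3L, config$conv_channels)
  with_seed(child_seed(config$seed, 11L), {
    params <- list()
    for (l in 1:4) {
      K <- 9L * ch[l]
      params[[paste0("W", l)]] <-
        matrix(rnorm(K * ch[l + 1], sd = sqrt(2 / K)), K, ch[l + 1])
      params[[paste0("b", l)]] <- numeric(ch[l + 1])
    }
    d <- ch[5]
    params$Wd <- matrix(rnorm(d * n_classes, sd = sqrt(2 / d)), d, n_classes)
    params$bd <- numeric(n_classes)
    sizes <- s / c(1, 2, 4, 8)
    structure(list(params = params, config = config, sizes = sizes,
                   idx = list(
                     I1 = conv_index(sizes[1], sizes[1], ch[1]),
                     M1 = pool_index(sizes[1], sizes[1], ch[2]),
                     I2 = conv_index(sizes[2], sizes[2], ch[2]),
                     M2 = pool_index(sizes[2], sizes[2], ch[3]),
                     I3 = conv_index(sizes[3], sizes[3], ch[3]),
                     M3 = pool_index(sizes[3], sizes[3], ch[4]),
                     I4 = conv_index(sizes[4], sizes[4], ch[4])),
                   channels = ch, classes = NULL),
              class = "cnn_backbone")
  })
}

# Forward pass; returns embeddings (N x d), logits (N x K) and caches.
backbone_forward <- function(bk, A, want_cache = FALSE) {
  p <- bk$params; ix <- bk$idx; ch <- bk$channels; s <- bk$sizes
  cache <- list(A0 = A)
  c1 <- conv_forward(A, p$W1, p$b1, ix$I1); r1 <- lrelu(c1$out)
  p1 <- pool_forward(r1, ix$M1)
  c2 <- conv_forward(p1$out, p$W2, p$b2, ix$I2); r2 <- lrelu(c2$out)
  p2 <- pool_forward(r2, ix$M2)
  c3 <- conv_forward(p2$out, p$W3, p$b3, ix$I3); r3 <- lrelu(c3$out)
  p3 <- pool_forward(r3, ix$M3)
  c4 <- conv_forward(p3$out, p$W4, p$b4, ix$I4); r4 <- lrelu(c4$out)
  # global average pool: (s4*s4*ch5) x N -> N x ch5
  hw <- s[4]^2
  emb <- t(rowsum(r4, group = rep(seq_len(ch[5]), each = hw)) / hw)
  logits <- sweep(emb %*% p$Wd, 2, p$bd, `+`)
  if (want_cache)
    cache <- c(cache, list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2,
                           p2 = p2, c3 = c3, r3 = r3, p3 = p3, c4 = c4,
                           r4 = r4, emb = emb))
  list(emb = emb, logits = logits, cache = cache)
}

backbone_backward <- function(bk, fw, dlogits) {
  p <- bk$params; ix <- bk$idx; ch <- bk$channels; s <- bk$sizes
  ca <- fw$cache
  g <- list()
  g$Wd <- crossprod(ca$emb, dlogits)
  g$bd <- colSums(dlogits)
  demb <- dlogits %*% t(p$Wd)                      # N x ch5
  hw <- s[4]^2
  # distribute average-pool gradient: each of the hw positions gets demb/hw
  dr4 <- matrix(0, nrow(ca$r4), ncol(ca$r4))
  for (c5 in seq_len(ch[5]))
    dr4[((c5 - 1) * hw + 1):(c5 * hw), ] <- rep(demb[, c5] / hw, each = hw)
  dr4 <- lrelu_grad(dr4, ca$r4)
  b4 <- conv_backward(dr4, ca$c4, p$W4, nrow(ca$p3$out))
  g$W4 <- b4$dW; g$b4 <- b4$db
  dp3 <- b4$dA
  dr3 <- pool_backward(dp3, ix$M3, ca$p3$am, nrow(ca$r3))
  dr3 <- lrelu_grad(dr3, ca$r3)
  b3 <- conv_backward(dr3, ca$c3, p$W3, nrow(ca$p2$out))
  g$W3 <- b3$dW; g$b3 <- b3$db
  dr2 <- pool_backward(b3$dA, ix$M2, ca$p2$am, nrow(ca$r2))
  dr2 <- lrelu_grad(dr2, ca$r2)
  b2 <- conv_backward(dr2, ca$c2, p$W2, nrow(ca$p1$out))
  g$W2 <- b2$dW; g$b2 <- b2$db
  dr1 <- pool_backward(b2$dA, ix$M1, ca$p1$am, nrow(ca$r1))
  dr1 <- lrelu_grad(dr1, ca$r1)
  b1 <- conv_backward(dr1, ca$c1, p$W1, nrow(ca$A0))
  g$W1 <- b1$dW; g$b1 <- b1$db
  g[names(bk$params)]
}

# Average-pool an (hp x hp x 3) patch array down to the backbone input size
# and flatten to the column layout. `patches` is a list of arrays or an
# (hp, hp, 3, N) array.
patches_to_batch <- function(patches, input_size) {
  if (is.array(patches) && length(dim(patches)) == 4)
    patches <- lapply(seq_len(dim(patches)[4]), function(i) patches[, , , i])
  hp <- dim(patches[[1]])[1]
  if (hp %% input_size != 0)
    stop("patch size ", hp, " is not a multiple of backbone input ", input_size)
  f <- hp %/% input_size
  Ph <- matrix(0, input_size, hp)
  for (i in seq_len(input_size)) Ph[i, ((i - 1) * f + 1):(i * f)] <- 1 / f
  vapply(patches, function(a) {
    as.vector(vapply(1:3, function(ch) Ph %*% a[, , ch] %*% t(Ph),
                     matrix(0, input_size, input_size)))
  }, numeric(input_size^2 * 3))
}

#' Train the patch-embedding CNN
#'
#' Trains the small convolutional classifier on labeled patches with Adam and
#' a cosine-annealed learning rate. The penultimate (global-average-pooled)
#' layer provides the patch embeddings used by the graph network.
#'
#' @param patches list of (p x p x 3) patch arrays, or a (p, p, 3, N) array.
#' @param labels factor or character vector of patch classes (>= 2 classes).
#' @param config a [model_config()].
#' @return object of class `cnn_backbone` with a `classes` attribute and a
#'   training-loss log.
#' @export
train_patch_cnn <- function(patches, labels, config = desk_config()) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("train_patch_cnn: need at least 2 classes")
  labels <- droplevels(labels)
  A <- patches_to_batch(patches, config$input_size)
  y <- as.integer(labels)
  n <- ncol(A)
  train_once <- function(cfg) {
    bk <- init_backbone(cfg, nlevels(labels))
    bk$classes <- levels(labels)
    log <- numeric(0)
    if (cfg$epochs_cnn > 0) {
      opt <- adam_init(bk$params)
      with_seed(child_seed(cfg$seed, 23L), {
        for (ep in seq_len(cfg$epochs_cnn)) {
          lr <- cosine_lr(cfg$lr_cnn, ep, cfg$epochs_cnn)
          ord <- sample.int(n)
          ep_loss <- 0
          for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_cnn))) {
            fw <- backbone_forward(bk, A[, b, drop = FALSE], want_cache = TRUE)
            pr <- softmax_rows(fw$logits)
            onehot <- diag(nlevels(labels))[y[b], , drop = FALSE]
            ep_loss <- ep_loss - sum(log(pmax(pr[cbind(seq_along(b), y[b])], 1e-12)))
            dlogits <- (pr - onehot) / length(b)
            g <- backbone_backward(bk, fw, dlogits)
            st <- adam_step(bk$params, g, opt, lr)
            bk$params <- st$params; opt <- st$state
          }
          log <- c(log, ep_loss / n)
        }
      })
    }
    bk$loss_log <- log
    bk
  }
  bk <- train_once(config)
  # Deterministic re-initialization if optimization stalled near its
  # starting loss (rare flat-init pathology of small nets); seeds derive
  # from the config seed, so retraining with the same config reproduces
  # the same restarts.
  attempt <- 1L
  while (config$epochs_cnn >= 10 && attempt < 3 &&
         tail(bk$loss_log, 1) > 0.92 * bk$loss_log[1]) {
    cfg2 <- config
    cfg2$seed <- child_seed(config$seed, 9000L + attempt)
    bk2 <- train_once(cfg2)
    if (tail(bk2$loss_log, 1) < tail(bk$loss_log, 1)) bk <- bk2
    attempt <- attempt + 1L
  }
  bk
}

#' Embed patches with a trained (or initialized) backbone
#'
#' @param backbone a [train_patch_cnn()] result.
#' @param patches list of patch arrays or a 4-d array, same patch size used
#'   in training.
#' @param batch forward batch size.
#' @return n x d embedding matrix (penultimate layer), rows in input order.
#' @export
embed_patches <- function(backbone, patches, batch = 256L) {
  A <- patches_to_batch(patches, backbone$config$input_size)
  n <- ncol(A)
  out <- matrix(0, n, backbone$channels[5])
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch)))
    out[b, ] <- backbone_forward(backbone, A[, b, drop = FALSE])$emb
  out
}

#' Class probabilities from the CNN head
#'
#' @inheritParams embed_patches
#' @return n x K matrix of softmax probabilities, columns named by class.
#' @export
predict_patch_cnn <- function(backbone, patches, batch = 256L) {
  A <- patches_to_batch(patches, backbone$config$input_size)
  n <- ncol(A)
  out <- matrix(0, n, length(backbone$classes))
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch)))
    out[b, ] <- softmax_rows(backbone_forward(backbone, A[, b, drop = FALSE])$logits)
  colnames(out) <- backbone$classes
  out
}
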