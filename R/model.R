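#' Model configuration
#'
#' Collects every architectural and ablation switch of the classifier.
#' The per-slice encoder is a compact channel-shuffle CNN
#' (`"shuffle_micro"`, the default: 3x3 conv stem, grouped pointwise
#' convolutions with a channel shuffle and a depthwise 3x3 in between,
#' global average pooling) or a plain two-stage CNN (`"plain_micro"`);
#' both accept the full 3 x 125 x 125 fused tensor -- a parameter-free
#' 5 x 5 average-pool stem and the final global average pooling absorb
#' the spatial size -- and emit a d = 32 embedding. The slice-embedding
#' matrix M (d x n, columns in temporal order) is then modeled by a
#' standard Transformer encoder (post-norm, scaled dot-product attention
#' with `1/sqrt(d_k)` scaling, sinusoidal positions by default), and
#' classified by mean-pooling the tokens through a linear softmax head.
#'
#' @param view `"fused"`, `"tfr_only"` or `"raw_only"`: which views reach
#'   the fusion layer. The excluded branch's 1x1 convolution is frozen at
#'   zero, so `"tfr_only"` reduces the network exactly to the
#'   time-frequency-only variant.
#' @param backbone `"shuffle_micro"` or `"plain_micro"`.
#' @param pretrained Logical; `TRUE` requires `weights_file` (a saved
#'   parameter list from a previous run) -- no weights are bundled.
#' @param weights_file Optional RDS file of initial backbone parameters.
#' @param use_transformer Logical; `FALSE` mean-pools the slice embeddings
#'   directly (the "without temporal model" ablation).
#' @param n_layers,n_heads Transformer depth and head count; the embedding
#'   size d (32) must be divisible by `n_heads`.
#' @param ff_mult Feed-forward width as a multiple of d.
#' @param dropout Residual dropout probability (training only).
#' @param positional_encoding `"sinusoidal"`, `"learned"` or `"none"`.
#' @param fusion_init `"identity_zero"` or `"random"` (see
#'   [fusion_weights()]).
#' @return A `model_config` object.
#' @export
model_config <- function(view = c("fused", "tfr_only", "raw_only"),
                         backbone = "shuffle_micro",
                         pretrained = FALSE, weights_file = NULL,
                         use_transformer = TRUE,
                         n_layers = 2L, n_heads = 4L, ff_mult = 4L,
                         dropout = 0.1,
                         positional_encoding = c("sinusoidal", "learned",
                                                 "none"),
                         fusion_init = "identity_zero") {
  view <- match.arg(view)
  positional_encoding <- match.arg(positional_encoding)
  supported <- c("shuffle_micro", "plain_micro")
  if (!backbone %in% supported) {
    stop("unsupported backbone \"", backbone, "\"; available: ",
         paste(supported, collapse = ", "))
  }
  if (pretrained && is.null(weights_file)) {
    stop("`pretrained = TRUE` requires `weights_file`; no pretrained ",
         "weights are bundled with the package")
  }
  d <- 32L
  if (d %% n_heads != 0) stop("embedding size ", d,
                              " must be divisible by n_heads")
  structure(list(view = view, backbone = backbone, pretrained = pretrained,
                 weights_file = weights_file,
                 use_transformer = use_transformer,
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 ff_mult = as.integer(ff_mult), dropout = dropout,
                 positional_encoding = positional_encoding,
                 fusion_init = fusion_init,
                 d = d, stem_pool = 5L, hw = 25L, mid_pool = 5L),
            class = "model_config")
}

# He-style initialization helpers (draws from the current RNG stream).
he_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

# Build the flat parameter list for a model. n_tokens is needed only for
# learned positional encodings.
init_params <- function(cfg, n_tokens = 8L) {
  d <- cfg$d
  p <- list()
  fw <- fusion_weights(cfg$fusion_init)
  if (cfg$view == "raw_only") {
    # the raw branch is the only active view: it takes the identity-ish
    # initialization instead of the near-zero one
    p$fus_Wt <- fw$raw$W
    p$fus_bt <- fw$raw$b
    p$fus_Wr <- fw$tfr$W
    p$fus_br <- fw$tfr$b
  } else {
    p$fus_Wt <- fw$tfr$W
    p$fus_bt <- fw$tfr$b
    p$fus_Wr <- fw$raw$W
    p$fus_br <- fw$raw$b
  }
  # backbone; ReLU biases start slightly positive so that units are active
  # and the network is not positively homogeneous at initialization (a
  # homogeneous encoder followed by layer normalization would be exactly
  # invariant to input amplitude)
  b0 <- 0.1
  p$conv1_W <- he_mat(9 * 3, 8)
  p$conv1_b <- rep(b0, 8)
  if (cfg$backbone == "shuffle_micro") {
    p$g1_W1 <- he_mat(4, 8)   # grouped 1x1, 8 -> 16, g = 2
    p$g1_W2 <- he_mat(4, 8)
    p$g1_b <- rep(b0, 16)
    p$dw_W <- matrix(stats::rnorm(9 * 16, 0, sqrt(2 / 9)), 9, 16)
    p$dw_b <- numeric(16)
    p$g2_W1 <- he_mat(8, 16)  # grouped 1x1, 16 -> 32, g = 2
    p$g2_W2 <- he_mat(8, 16)
    p$g2_b <- rep(b0, 32)
  } else {
    p$conv2_W <- he_mat(9 * 8, 32)
    p$conv2_b <- rep(b0, 32)
  }
  if (cfg$use_transformer) {
    sd0 <- sqrt(1 / d)
    for (l in seq_len(cfg$n_layers)) {
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        p[[paste0("tr", l, "_", nm)]] <-
          matrix(stats::rnorm(d * d, 0, sd0), d, d)
      }
      for (nm in c("bq", "bk", "bv", "bo")) {
        p[[paste0("tr", l, "_", nm)]] <- numeric(d)
      }
      p[[paste0("tr", l, "_ln1_g")]] <- rep(1, d)
      p[[paste0("tr", l, "_ln1_b")]] <- numeric(d)
      p[[paste0("tr", l, "_ff_W1")]] <- he_mat(d, d * cfg$ff_mult)
      p[[paste0("tr", l, "_ff_b1")]] <- numeric(d * cfg$ff_mult)
      p[[paste0("tr", l, "_ff_W2")]] <-
        matrix(stats::rnorm(d * cfg$ff_mult * d, 0, sd0), d * cfg$ff_mult, d)
      p[[paste0("tr", l, "_ff_b2")]] <- numeric(d)
      p[[paste0("tr", l, "_ln2_g")]] <- rep(1, d)
      p[[paste0("tr", l, "_ln2_b")]] <- numeric(d)
    }
    if (cfg$positional_encoding == "learned") {
      p$pe <- matrix(stats::rnorm(n_tokens * d, 0, 0.02), n_tokens, d)
    }
  }
  p$head_W <- matrix(stats::rnorm(d * 2, 0, sqrt(1 / d)), d, 2)
  p$head_b <- numeric(2)
  p
}

#' Construct an untrained classifier
#'
#' Initializes all parameters from `seed`. The returned object carries the
#' configuration, the flat parameter list, and (after training) the
#' feature-preparation statistics needed to evaluate new trials.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed controlling every random initialization.
#' @param n_tokens Slices per trial (tokens per sequence).
#' @return A `mieeg_model`.
#' @export
mieeg_model <- function(cfg = model_config(), seed = 1L, n_tokens = 8L) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))
  params <- init_params(cfg, n_tokens)
  if (!is.null(cfg$weights_file)) {
    loaded <- readRDS(cfg$weights_file)
    common <- intersect(names(loaded), names(params))
    mismatch <- common[!vapply(common, function(nm) {
      identical(dim_or_len(loaded[[nm]]), dim_or_len(params[[nm]]))
    }, logical(1))]
    if (length(mismatch)) {
      stop("weights file shape mismatch for: ",
           paste(mismatch, collapse = ", "))
    }
    params[common] <- loaded[common]
  }
  structure(list(cfg = cfg, params = params, n_tokens = as.integer(n_tokens),
                 seed = as.integer(seed), prep = NULL),
            class = "mieeg_model")
}

#' @export
print.mieeg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "MI-EEG classifier: view = %s, backbone = %s (d = %d), %s, %d parameters\n",
    x$cfg$view, x$cfg$backbone, x$cfg$d,
    if (x$cfg$use_transformer)
      sprintf("transformer %dL/%dH", x$cfg$n_layers, x$cfg$n_heads)
    else "no temporal model",
    np))
  if (!is.null(x$prep)) cat("  trained (feature statistics attached)\n")
  invisible(x)
}

# Backbone forward over a batch of N pooled fused maps, x: (hw^2*N) x 3.
# Returns the N x d embedding matrix and caches for the backward pass.
backbone_forward <- function(x, p, cfg, N) {
  hw <- cfg$hw
  caches <- list()
  c1 <- conv2d_forward(x, hw, hw, N, p$conv1_W, p$conv1_b)
  caches$c1 <- c1$cache
  r1 <- relu_forward(c1$y)
  caches$r1 <- r1$cache
  p1 <- avg_pool_forward(r1$y, hw, hw, cfg$mid_pool, N)
  caches$p1 <- p1$cache
  hw2 <- hw %/% cfg$mid_pool
  if (cfg$backbone == "shuffle_micro") {
    g1 <- gconv1x1_forward(p1$y, list(p$g1_W1, p$g1_W2), p$g1_b, 2L)
    caches$g1 <- g1$cache
    rg <- relu_forward(g1$y)
    caches$rg <- rg$cache
    perm <- shuffle_perm(16L, 2L)
    xs <- rg$y[, perm, drop = FALSE]
    caches$perm <- perm
    dw <- dwconv2d_forward(xs, hw2, hw2, N, p$dw_W, p$dw_b)
    caches$dw <- dw$cache
    g2 <- gconv1x1_forward(dw$y, list(p$g2_W1, p$g2_W2), p$g2_b, 2L)
    caches$g2 <- g2$cache
    r2 <- relu_forward(g2$y)
    caches$r2 <- r2$cache
    feat <- r2$y
  } else {
    c2 <- conv2d_forward(p1$y, hw2, hw2, N, p$conv2_W, p$conv2_b)
    caches$c2 <- c2$cache
    r2 <- relu_forward(c2$y)
    caches$r2 <- r2$cache
    feat <- r2$y
  }
  gp <- global_avg_pool_forward(feat, hw2, hw2, N)
  caches$gp <- gp$cache
  caches$hw2 <- hw2
  list(M = gp$y, caches = caches)
}

backbone_backward <- function(dM, caches, cfg, grads) {
  dfeat <- global_avg_pool_backward(dM, caches$gp)
  if (cfg$backbone == "shuffle_micro") {
    dfeat <- relu_backward(dfeat, caches$r2)
    g2 <- gconv1x1_backward(dfeat, caches$g2)
    grads$g2_W1 <- g2$dWg[[1]]
    grads$g2_W2 <- g2$dWg[[2]]
    grads$g2_b <- g2$db
    dw <- dwconv2d_backward(g2$dx, caches$dw)
    grads$dw_W <- dw$dW
    grads$dw_b <- dw$db
    dxs <- dw$dx
    inv <- order(caches$perm)
    drg <- dxs[, inv, drop = FALSE]
    drg <- relu_backward(drg, caches$rg)
    g1 <- gconv1x1_backward(drg, caches$g1)
    grads$g1_W1 <- g1$dWg[[1]]
    grads$g1_W2 <- g1$dWg[[2]]
    grads$g1_b <- g1$db
    dp1 <- g1$dx
  } else {
    dfeat <- relu_backward(dfeat, caches$r2)
    c2 <- conv2d_backward(dfeat, caches$c2)
    grads$conv2_W <- c2$dW
    grads$conv2_b <- c2$db
    dp1 <- c2$dx
  }
  dr1 <- avg_pool_backward(dp1, caches$p1)
  dr1 <- relu_backward(dr1, caches$r1)
  c1 <- conv2d_backward(dr1, caches$c1)
  grads$conv1_W <- c1$dW
  grads$conv1_b <- c1$db
  list(dx = c1$dx, grads = grads)
}

# One transformer encoder layer (post-norm), token matrix (B*n) x d.
transformer_layer_forward <- function(x, p, l, cfg, n, train,
                                      collect_weights = FALSE) {
  pre <- paste0("tr", l, "_")
  att_p <- list(Wq = p[[paste0(pre, "Wq")]], bq = p[[paste0(pre, "bq")]],
                Wk = p[[paste0(pre, "Wk")]], bk = p[[paste0(pre, "bk")]],
                Wv = p[[paste0(pre, "Wv")]], bv = p[[paste0(pre, "bv")]],
                Wo = p[[paste0(pre, "Wo")]], bo = p[[paste0(pre, "bo")]])
  at <- mhsa_forward(x, att_p, n, cfg$n_heads, collect_weights)
  do1 <- dropout_forward(at$y, cfg$dropout, train)
  ln1 <- layer_norm_forward(x + do1$y, p[[paste0(pre, "ln1_g")]],
                            p[[paste0(pre, "ln1_b")]])
  h <- sweep(ln1$y %*% p[[paste0(pre, "ff_W1")]], 2,
             p[[paste0(pre, "ff_b1")]], `+`)
  rl <- relu_forward(h)
  f2 <- sweep(rl$y %*% p[[paste0(pre, "ff_W2")]], 2,
              p[[paste0(pre, "ff_b2")]], `+`)
  do2 <- dropout_forward(f2, cfg$dropout, train)
  ln2 <- layer_norm_forward(ln1$y + do2$y, p[[paste0(pre, "ln2_g")]],
                            p[[paste0(pre, "ln2_b")]])
  list(y = ln2$y,
       cache = list(at = at$cache, do1 = do1$cache, ln1 = ln1$cache,
                    rl = rl$cache, do2 = do2$cache, ln2 = ln2$cache,
                    ln1_y = ln1$y, rl_y = rl$y, pre = pre, p = p),
       weights = at$weights)
}

transformer_layer_backward <- function(dy, cache, grads) {
  pre <- cache$pre
  p <- cache$p
  l2 <- layer_norm_backward(dy, cache$ln2)
  grads[[paste0(pre, "ln2_g")]] <- l2$dgamma
  grads[[paste0(pre, "ln2_b")]] <- l2$dbeta
  dres2 <- l2$dx
  df2 <- dropout_backward(dres2, cache$do2)
  grads[[paste0(pre, "ff_b2")]] <- colSums(df2)
  grads[[paste0(pre, "ff_W2")]] <- crossprod(cache$rl_y, df2)
  drl <- tcrossprod(df2, p[[paste0(pre, "ff_W2")]])
  dh <- relu_backward(drl, cache$rl)
  grads[[paste0(pre, "ff_b1")]] <- colSums(dh)
  grads[[paste0(pre, "ff_W1")]] <- crossprod(cache$ln1_y, dh)
  dln1 <- tcrossprod(dh, p[[paste0(pre, "ff_W1")]]) + dres2
  l1 <- layer_norm_backward(dln1, cache$ln1)
  grads[[paste0(pre, "ln1_g")]] <- l1$dgamma
  grads[[paste0(pre, "ln1_b")]] <- l1$dbeta
  dres1 <- l1$dx
  dat <- dropout_backward(dres1, cache$do1)
  at <- mhsa_backward(dat, cache$at)
  grads[[paste0(pre, "Wq")]] <- at$dWq
  grads[[paste0(pre, "bq")]] <- at$dbq
  grads[[paste0(pre, "Wk")]] <- at$dWk
  grads[[paste0(pre, "bk")]] <- at$dbk
  grads[[paste0(pre, "Wv")]] <- at$dWv
  grads[[paste0(pre, "bv")]] <- at$dbv
  grads[[paste0(pre, "Wo")]] <- at$dWo
  grads[[paste0(pre, "bo")]] <- at$dbo
  list(dx = at$dx + dres1, grads = grads)
}

# Full forward pass over a prepared batch.
# batch: list(Xt, Xr) -- (hw^2 * N) x 3 pooled view matrices, N = B*n.
model_forward <- function(model, batch, n, train = FALSE,
                          collect = FALSE) {
  cfg <- model$cfg
  p <- model$params
  mask_t <- if (cfg$view == "raw_only") 0 else 1
  mask_r <- if (cfg$view == "tfr_only") 0 else 1
  N <- nrow(batch$Xt) / cfg$hw^2
  B <- N / n
  fused <- mask_t * (batch$Xt %*% t(p$fus_Wt)) +
    mask_r * (batch$Xr %*% t(p$fus_Wr))
  fused <- sweep(fused, 2, mask_t * p$fus_bt + mask_r * p$fus_br, `+`)
  bb <- backbone_forward(fused, p, cfg, N)
  M <- bb$M                                  # N x d, trial-major token rows
  tok <- M
  tr_caches <- NULL
  att_weights <- NULL
  if (cfg$use_transformer) {
    pe <- switch(cfg$positional_encoding,
                 sinusoidal = sinusoidal_pe(n, cfg$d),
                 learned = p$pe,
                 none = NULL)
    if (!is.null(pe)) {
      tok <- tok + pe[rep(seq_len(n), B), , drop = FALSE]
    }
    tr_caches <- vector("list", cfg$n_layers)
    att_weights <- list()
    for (l in seq_len(cfg$n_layers)) {
      tl <- transformer_layer_forward(tok, p, l, cfg, n, train, collect)
      tok <- tl$y
      tr_caches[[l]] <- tl$cache
      if (collect) att_weights[[l]] <- tl$weights
    }
  }
  gpool <- global_avg_pool_forward(tok, n, 1L, B)   # mean over tokens -> B x d
  logits <- sweep(gpool$y %*% p$head_W, 2, p$head_b, `+`)
  probs <- softmax_rows(logits)
  list(probs = probs, M = M, tokens = tok,
       cache = list(fused_in = batch, fused = fused, bb = bb$caches,
                    tr = tr_caches, gpool = gpool$cache,
                    pooled = gpool$y, N = N, B = B, n = n,
                    mask_t = mask_t, mask_r = mask_r),
       att_weights = att_weights)
}

# Backward pass from probabilities; returns flat gradient list.
model_backward <- function(model, fw, labels) {
  cfg <- model$cfg
  p <- model$params
  cache <- fw$cache
  B <- cache$B
  y <- label_index(labels)
  Y <- matrix(0, B, 2)
  Y[cbind(seq_len(B), y)] <- 1
  dlogits <- (fw$probs - Y) / B
  grads <- list()
  grads$head_W <- crossprod(cache$pooled, dlogits)
  grads$head_b <- colSums(dlogits)
  dpool <- tcrossprod(dlogits, p$head_W)
  dtok <- global_avg_pool_backward(dpool, cache$gpool)
  if (cfg$use_transformer) {
    for (l in rev(seq_len(cfg$n_layers))) {
      tb <- transformer_layer_backward(dtok, cache$tr[[l]], grads)
      dtok <- tb$dx
      grads <- tb$grads
    }
    if (cfg$positional_encoding == "learned") {
      idx <- rep(seq_len(cache$n), B)
      grads$pe <- rowsum(dtok, idx)
      dimnames(grads$pe) <- NULL
    }
  }
  bb <- backbone_backward(dtok, cache$bb, cfg, grads)
  grads <- bb$grads
  dfused <- bb$dx
  db_all <- colSums(dfused)
  grads$fus_Wt <- cache$mask_t * crossprod(dfused, cache$fused_in$Xt)
  grads$fus_bt <- cache$mask_t * db_all
  grads$fus_Wr <- cache$mask_r * crossprod(dfused, cache$fused_in$Xr)
  grads$fus_br <- cache$mask_r * db_all
  grads
}

#' Encode one fused slice tensor into its d-dimensional embedding
#'
#' Runs the model's per-slice CNN encoder on a full-resolution
#' `3 x 125 x 125` fused tensor (the 5 x 5 average-pool stem absorbs the
#' spatial size) and returns the globally pooled feature vector.
#' Deterministic: no dropout is active outside training.
#'
#' @param model A `mieeg_model`.
#' @param fused `3 x T x F` numeric array.
#' @return Numeric vector of length `model$cfg$d`.
#' @export
encode_slice <- function(model, fused) {
  cfg <- model$cfg
  d3 <- dim(fused)
  if (length(d3) != 3 || d3[1] != 3) stop("expected a 3 x T x F array")
  x <- pool_view_tensor(fused, cfg$stem_pool)   # (hw^2) x 3
  bb <- backbone_forward(x, model$params, cfg, 1L)
  as.numeric(bb$M)
}

# Stem pooling of a C x T x F tensor into a (T/k * F/k) x C matrix in
# (i, j) row order.
pool_view_tensor <- function(v, k) {
  C <- dim(v)[1]
  T_len <- dim(v)[2]
  F_len <- dim(v)[3]
  x <- matrix(aperm(v, c(2, 3, 1)), ncol = C)   # rows (t, f), cols channel
  pm <- pool_map(T_len, F_len, k, 1L)
  y <- rowsum(x, pm$map) / (k * k)
  dimnames(y) <- NULL
  y
}

#' Contextualize a slice-embedding matrix with the Transformer encoder
#'
#' Adds positional encodings and applies the model's Transformer layers in
#' evaluation mode. With positional encodings disabled the map is
#' permutation-equivariant, so mean-pooled outputs are invariant to slice
#' order.
#'
#' @param model A `mieeg_model` with `use_transformer = TRUE`.
#' @param M `d x n` embedding matrix (columns = slices in temporal order).
#' @param collect_weights Return the attention matrices as well?
#' @return `d x n` matrix of contextual features; if `collect_weights`,
#'   a list with `context` and `weights` (list over layers of per-head
#'   row-stochastic matrices).
#' @export
encode_sequence <- function(model, M, collect_weights = FALSE) {
  cfg <- model$cfg
  if (!cfg$use_transformer) stop("model was configured without a Transformer")
  if (nrow(M) != cfg$d) {
    stop("`M` must have d = ", cfg$d, " rows, got ", nrow(M))
  }
  n <- ncol(M)
  tok <- t(M)
  pe <- switch(cfg$positional_encoding,
               sinusoidal = sinusoidal_pe(n, cfg$d),
               learned = model$params$pe[seq_len(n), , drop = FALSE],
               none = NULL)
  if (!is.null(pe)) tok <- tok + pe
  weights <- list()
  for (l in seq_len(cfg$n_layers)) {
    tl <- transformer_layer_forward(tok, model$params, l, cfg, n,
                                    train = FALSE,
                                    collect_weights = collect_weights)
    tok <- tl$y
    if (collect_weights) weights[[l]] <- tl$weights
  }
  ctx <- t(tok)
  if (collect_weights) list(context = ctx, weights = weights) else ctx
}

#' Classify contextual features into class probabilities
#'
#' Mean-pools the token dimension and applies the linear softmax head.
#' Probabilities sum to one; with zero head weights the output is uniform.
#'
#' @param model A `mieeg_model`.
#' @param context `d x n` matrix of (contextual) slice features.
#' @return Named probability vector `c(left = , right = )`.
#' @export
classify <- function(model, context) {
  if (nrow(context) != model$cfg$d) {
    stop("`context` must have d = ", model$cfg$d, " rows")
  }
  pooled <- rowMeans(context)
  logits <- drop(pooled %*% model$params$head_W) + model$params$head_b
  pr <- drop(softmax_rows(matrix(logits, 1)))
  names(pr) <- c("left", "right")
  pr
}
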