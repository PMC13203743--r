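# Minimal dense-tensor neural-network primitives with analytic gradients.
#
# Activation maps are stored as matrices of shape (H*W*N) x C with row
# ordering r = i + H*(j-1) + H*W*(n-1): within-column index i fastest,
# then column j, then image n. This makes convolution an im2col gather
# followed by one large matrix multiply, which is where base R is fast.
# All layers are written as forward functions returning a cache and
# backward functions consuming it; gradient correctness is pinned by
# finite-difference tests.

.idx_cache <- new.env(parent = emptyenv())

# Gather/scatter indices for a k x k, stride-1 convolution with symmetric
# zero padding. Returns padded-plane embedding indices and the im2col
# index matrix ((Ho*Wo*N) x k^2) into the padded (Hp*Wp*N) space.
conv_index <- function(H, W, k, pad, N) {
  key <- paste(H, W, k, pad, N, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2 * pad
  Wp <- W + 2 * pad
  Ho <- Hp - k + 1
  Wo <- Wp - k + 1
  # embedding of an unpadded plane into the padded plane, for one image
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  embed1 <- (i + pad) + Hp * (j + pad - 1)
  embed <- rep(embed1, N) + rep((seq_len(N) - 1) * Hp * Wp, each = H * W)
  # output-position base indices for one image
  io <- rep(seq_len(Ho), times = Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  base <- io + Hp * (jo - 1)
  basefull <- rep(base, N) + rep((seq_len(N) - 1) * Hp * Wp, each = Ho * Wo)
  # kernel offsets, di fastest then dj
  di <- rep(0:(k - 1), times = k)
  dj <- rep(0:(k - 1), each = k)
  off <- di + Hp * dj
  idx <- outer(basefull, off, `+`)
  out <- list(Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, embed = embed, idx = idx)
  .idx_cache[[key]] <- out
  out
}

# Dense k x k convolution, stride 1. W: (k^2*Cin) x Cout with row order
# (offset within kernel fastest, then input channel); b: length Cout.
conv2d_forward <- function(x, H, W_sp, N, Wmat, b, k = 3L, pad = 1L) {
  Cin <- ncol(x)
  ci <- conv_index(H, W_sp, k, pad, N)
  npad <- ci$Hp * ci$Wp * N
  cols <- matrix(0, nrow = nrow(ci$idx), ncol = k * k * Cin)
  for (c in seq_len(Cin)) {
    xp <- numeric(npad)
    xp[ci$embed] <- x[, c]
    cols[, ((c - 1) * k * k + 1):(c * k * k)] <- xp[ci$idx]
  }
  y <- cols %*% Wmat
  y <- sweep(y, 2, b, `+`)
  list(y = y, cache = list(cols = cols, ci = ci, k = k, Cin = Cin, N = N,
                           Wmat = Wmat, npad = npad))
}

conv2d_backward <- function(dy, cache) {
  k <- cache$k
  ci <- cache$ci
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dcols <- tcrossprod(dy, cache$Wmat)  # dy %*% t(W)
  dx <- matrix(0, nrow = length(ci$embed), ncol = cache$Cin)
  for (c in seq_len(cache$Cin)) {
    gp <- numeric(cache$npad)
    for (o in seq_len(k * k)) {
      tgt <- ci$idx[, o]
      gp[tgt] <- gp[tgt] + dcols[, (c - 1) * k * k + o]
    }
    dx[, c] <- gp[ci$embed]
  }
  list(dx = dx, dW = dW, db = db)
}

# Depthwise k x k convolution: Wmat is k^2 x C (one kernel per channel).
dwconv2d_forward <- function(x, H, W_sp, N, Wmat, b, k = 3L, pad = 1L) {
  C <- ncol(x)
  ci <- conv_index(H, W_sp, k, pad, N)
  npad <- ci$Hp * ci$Wp * N
  y <- matrix(0, nrow = nrow(ci$idx), ncol = C)
  cols_list <- vector("list", C)
  for (c in seq_len(C)) {
    xp <- numeric(npad)
    xp[ci$embed] <- x[, c]
    cols <- xp[ci$idx]
    dim(cols) <- dim(ci$idx)
    cols_list[[c]] <- cols
    y[, c] <- cols %*% Wmat[, c]
  }
  y <- sweep(y, 2, b, `+`)
  list(y = y, cache = list(cols_list = cols_list, ci = ci, k = k, C = C,
                           Wmat = Wmat, npad = npad))
}

dwconv2d_backward <- function(dy, cache) {
  k <- cache$k
  ci <- cache$ci
  C <- cache$C
  dW <- matrix(0, nrow = k * k, ncol = C)
  db <- colSums(dy)
  dx <- matrix(0, nrow = length(ci$embed), ncol = C)
  for (c in seq_len(C)) {
    dW[, c] <- crossprod(cache$cols_list[[c]], dy[, c])
    dcols <- tcrossprod(dy[, c], cache$Wmat[, c])
    gp <- numeric(cache$npad)
    for (o in seq_len(k * k)) {
      tgt <- ci$idx[, o]
      gp[tgt] <- gp[tgt] + dcols[, o]
    }
    dx[, c] <- gp[ci$embed]
  }
  list(dx = dx, dW = dW, db = db)
}

# Grouped 1x1 convolution: per-pixel linear map within channel groups.
# Wmat: Cin x Cout (block diagonal use only); represented dense per group:
# list of (Cin/g x Cout/g) matrices. b: length Cout.
gconv1x1_forward <- function(x, Wg, b, groups) {
  Cin <- ncol(x)
  cin_g <- Cin / groups
  cout_g <- ncol(Wg[[1]])
  y <- matrix(0, nrow = nrow(x), ncol = cout_g * groups)
  for (g in seq_len(groups)) {
    xin <- x[, ((g - 1) * cin_g + 1):(g * cin_g), drop = FALSE]
    y[, ((g - 1) * cout_g + 1):(g * cout_g)] <- xin %*% Wg[[g]]
  }
  y <- sweep(y, 2, b, `+`)
  list(y = y, cache = list(x = x, Wg = Wg, groups = groups,
                           cin_g = cin_g, cout_g = cout_g))
}

gconv1x1_backward <- function(dy, cache) {
  g <- cache$groups
  cin_g <- cache$cin_g
  cout_g <- cache$cout_g
  dWg <- vector("list", g)
  dx <- matrix(0, nrow = nrow(dy), ncol = cin_g * g)
  for (gi in seq_len(g)) {
    xin <- cache$x[, ((gi - 1) * cin_g + 1):(gi * cin_g), drop = FALSE]
    dyg <- dy[, ((gi - 1) * cout_g + 1):(gi * cout_g), drop = FALSE]
    dWg[[gi]] <- crossprod(xin, dyg)
    dx[, ((gi - 1) * cin_g + 1):(gi * cin_g)] <- tcrossprod(dyg, cache$Wg[[gi]])
  }
  list(dx = dx, dWg = dWg, db = colSums(dy))
}

# Channel shuffle for `groups` groups: interleaves channels across groups.
shuffle_perm <- function(C, groups) {
  as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
}

# Non-overlapping k x k average pooling via rowsum.
pool_map <- function(H, W, k, N) {
  key <- paste("pool", H, W, k, N, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- H %/% k
  Wo <- W %/% k
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  base <- ceiling(i / k) + Ho * (ceiling(j / k) - 1)
  full <- rep(base, N) + rep((seq_len(N) - 1) * Ho * Wo, each = H * W)
  out <- list(map = full, Ho = Ho, Wo = Wo)
  .idx_cache[[key]] <- out
  out
}

avg_pool_forward <- function(x, H, W, k, N) {
  pm <- pool_map(H, W, k, N)
  y <- rowsum(x, pm$map) / (k * k)
  dimnames(y) <- NULL
  list(y = y, cache = list(map = pm$map, k = k))
}

avg_pool_backward <- function(dy, cache) {
  dy[cache$map, , drop = FALSE] / (cache$k^2)
}

global_avg_pool_forward <- function(x, H, W, N) {
  g <- rep(seq_len(N), each = H * W)
  y <- rowsum(x, g) / (H * W)
  dimnames(y) <- NULL
  list(y = y, cache = list(g = g, hw = H * W))
}

global_avg_pool_backward <- function(dy, cache) {
  dy[cache$g, , drop = FALSE] / cache$hw
}

relu_forward <- function(x) {
  list(y = pmax(x, 0), cache = x > 0)
}

relu_backward <- function(dy, cache) {
  dy * cache
}

# Layer normalization over the feature (column) dimension of a token
# matrix (tokens x d), with per-feature gain and bias.
layer_norm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = y, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

layer_norm_backward <- function(dy, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, cache$gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx,
       dgamma = colSums(dy * xhat),
       dbeta = colSums(dy))
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` with row-wise softmax; rows of
#' the weight matrix therefore sum to one, and a single-token sequence
#' receives weight exactly 1 on itself.
#'
#' @param Q,K,V Numeric matrices of shape tokens x d_k (Q) and
#'   tokens x d_k / tokens x d_v (K, V); Q and K must share `d_k`, K and V
#'   the token count.
#' @return List with `output` (tokens x d_v) and `weights` (the
#'   row-stochastic attention matrix).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  S <- tcrossprod(Q, K) / sqrt(ncol(K))
  A <- softmax_rows(S)
  list(output = A %*% V, weights = A)
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# Multi-head self-attention over a batch of equal-length token sequences.
# x: (B*n) x d with trial-major contiguous rows. p: list with Wq, Wk, Wv,
# Wo (d x d) and bq, bk, bv, bo (length d).
mhsa_forward <- function(x, p, n, n_heads, collect_weights = FALSE) {
  d <- ncol(x)
  dk <- d %/% n_heads
  B <- nrow(x) %/% n
  Q <- sweep(x %*% p$Wq, 2, p$bq, `+`)
  K <- sweep(x %*% p$Wk, 2, p$bk, `+`)
  V <- sweep(x %*% p$Wv, 2, p$bv, `+`)
  O <- matrix(0, nrow(x), d)
  att <- vector("list", B * n_heads)
  weights <- if (collect_weights) vector("list", B * n_heads) else NULL
  for (b in seq_len(B)) {
    rows <- ((b - 1) * n + 1):(b * n)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      Sa <- tcrossprod(Q[rows, cols, drop = FALSE],
                       K[rows, cols, drop = FALSE]) / sqrt(dk)
      A <- softmax_rows(Sa)
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      att[[(b - 1) * n_heads + h]] <- A
      if (collect_weights) weights[[(b - 1) * n_heads + h]] <- A
    }
  }
  y <- sweep(O %*% p$Wo, 2, p$bo, `+`)
  list(y = y,
       cache = list(x = x, Q = Q, K = K, V = V, O = O, att = att,
                    n = n, n_heads = n_heads, dk = dk, B = B, p = p),
       weights = weights)
}

mhsa_backward <- function(dy, cache) {
  p <- cache$p
  n <- cache$n
  dk <- cache$dk
  nh <- cache$n_heads
  dWo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dO <- tcrossprod(dy, p$Wo)
  dQ <- matrix(0, nrow(dy), ncol(dy))
  dK <- matrix(0, nrow(dy), ncol(dy))
  dV <- matrix(0, nrow(dy), ncol(dy))
  for (b in seq_len(cache$B)) {
    rows <- ((b - 1) * n + 1):(b * n)
    for (h in seq_len(nh)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      A <- cache$att[[(b - 1) * nh + h]]
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOb, Vb)
      dV[rows, cols] <- crossprod(A, dOb)
      dS <- A * (dA - rowSums(A * dA))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] / sqrt(dk)
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) /
        sqrt(dk)
    }
  }
  x <- cache$x
  list(dx = tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) +
         tcrossprod(dV, p$Wv),
       dWq = crossprod(x, dQ), dbq = colSums(dQ),
       dWk = crossprod(x, dK), dbk = colSums(dK),
       dWv = crossprod(x, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}

dropout_forward <- function(x, p, train) {
  if (!train || p <= 0) {
    return(list(y = x, cache = NULL))
  }
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(y = x * mask, cache = mask)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

#' Mean cross-entropy loss for two-class probability predictions
#'
#' `L = -(1/N) * sum_i log p_i(y_i)` where `p_i(y_i)` is the predicted
#' probability of the true class. Perfect one-hot predictions give 0;
#' uniform (0.5, 0.5) predictions give `log(2)`.
#'
#' @param pred N x 2 matrix of class probabilities (columns left, right),
#'   or a length-2 probability vector for a single prediction.
#' @param labels Character vector (`"left"`/`"right"`), factor, or integer
#'   column indices (1 or 2), length N.
#' @param eps Floor applied inside the logarithm.
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(pred, labels, eps = 1e-12) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1)
  y <- label_index(labels, ncol(pred))
  if (length(y) != nrow(pred)) stop("length of `labels` must match `pred` rows")
  -mean(log(pmax(pred[cbind(seq_len(nrow(pred)), y)], eps)))
}

label_index <- function(labels, n_classes = 2) {
  if (is.numeric(labels)) {
    y <- as.integer(labels)
  } else {
    y <- match(as.character(labels), c("left", "right"))
  }
  if (any(is.na(y)) || any(y < 1) || any(y > n_classes)) {
    stop("labels must be \"left\"/\"right\" or class indices 1..", n_classes)
  }
  y
}

# Sinusoidal positional encoding, tokens x d.
sinusoidal_pe <- function(n, d) {
  pos <- seq_len(n) - 1
  i <- seq_len(d)
  dim_pair <- (ceiling(i / 2) - 1) * 2
  angle <- outer(pos, 1 / 10000^(dim_pair / d))
  pe <- matrix(0, n, d)
  pe[, seq(1, d, by = 2)] <- sin(angle[, seq(1, d, by = 2), drop = FALSE])
  pe[, seq(2, d, by = 2)] <- cos(angle[, seq(2, d, by = 2), drop = FALSE])
  pe
}

# Adam optimizer over a flat named list of parameter arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim_or_len(p))),
       v = lapply(params, function(p) array(0, dim = dim_or_len(p))),
       t = 0)
}

dim_or_len <- function(p) if (is.null(dim(p))) length(p) else dim(p)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
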