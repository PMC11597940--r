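# Low-level neural-network primitives.
#
# Activation tensors are C x P matrices with P = N*H*W; pixels of each
# sample are flattened row-major (index = r*W + c). Shapes travel
# alongside as c(N, H, W). All primitives are deterministic and have
# hand-written backward passes; convolutions call the Rcpp gather-GEMM
# kernels in src/nnops.cpp.

.idx_cache <- new.env(parent = emptyenv())

# Output-position -> input-position index table for a k x k convolution.
# Returns a P x k^2 integer matrix (1-based, 0 = zero padding) plus the
# output spatial size. Offset order is row-major in (di, dj), matching
# the slice order of the weight cube.
conv_index <- function(N, H, W, k, stride, pad) {
  key <- paste(N, H, W, k, stride, pad, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  P1 <- Ho * Wo
  orow <- rep(0:(Ho - 1L), each = Wo)
  ocol <- rep(0:(Wo - 1L), times = Ho)
  IDX <- matrix(0L, nrow = N * P1, ncol = k * k)
  off <- rep((0:(N - 1L)) * H * W, each = P1)
  for (di in 0:(k - 1L)) {
    for (dj in 0:(k - 1L)) {
      ir <- orow * stride + di - pad
      ic <- ocol * stride + dj - pad
      valid <- ir >= 0L & ir < H & ic >= 0L & ic < W
      flat <- ifelse(valid, ir * W + ic + 1L, 0L)
      full <- rep(flat, times = N)
      full[full > 0L] <- full[full > 0L] + off[full > 0L]
      IDX[, di * k + dj + 1L] <- full
    }
  }
  out <- list(idx = IDX, Ho = Ho, Wo = Wo)
  .idx_cache[[key]] <- out
  out
}

# He-normal initialised convolution layer.
conv_new <- function(Cin, Cout, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  W <- array(stats::rnorm(Cout * Cin * k * k, sd = sqrt(2 / (Cin * k * k))),
             dim = c(Cout, Cin, k * k))
  list(W = W, b = numeric(Cout), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
}

conv_fw <- function(layer, X, shp) {
  ix <- conv_index(shp[1], shp[2], shp[3], layer$k, layer$stride, layer$pad)
  Y <- nn_conv_fw(X, layer$W, layer$b, ix$idx)
  list(Y = Y, shp = c(shp[1], ix$Ho, ix$Wo), cache = list(X = X, shp = shp))
}

conv_bw <- function(layer, cache, dY) {
  shp <- cache$shp
  ix <- conv_index(shp[1], shp[2], shp[3], layer$k, layer$stride, layer$pad)
  g <- nn_conv_bw(cache$X, layer$W, ix$idx, dY)
  list(dX = g$dX, grads = list(W = g$dW, b = as.numeric(g$db)))
}

bn_new <- function(C) {
  list(g = rep(1, C), b = numeric(C))
}

bn_state_new <- function(C) {
  list(rm = numeric(C), rv = rep(1, C))
}

bn_fw <- function(layer, state, X, train, eps = 1e-5, momentum = 0.1) {
  if (train) {
    mu <- rowMeans(X)
    xc <- X - mu
    v <- rowMeans(xc * xc)
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * v
  } else {
    mu <- state$rm
    v <- state$rv
    xc <- X - mu
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  Y <- layer$g * xhat + layer$b
  list(Y = Y, state = state, cache = list(xhat = xhat, inv_sd = inv_sd))
}

bn_bw <- function(layer, cache, dY) {
  m <- ncol(dY)
  xhat <- cache$xhat
  dg <- rowSums(dY * xhat)
  db <- rowSums(dY)
  dxhat <- dY * layer$g
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv_sd
  list(dX = dX, grads = list(g = dg, b = db))
}

relu_fw <- function(X) {
  mask <- X > 0
  list(Y = X * mask, cache = mask)
}

relu_bw <- function(cache, dY) dY * cache

lrelu_fw <- function(X, slope = 0.2) {
  mask <- X > 0
  list(Y = ifelse(mask, X, slope * X), cache = mask)
}

lrelu_bw <- function(cache, dY, slope = 0.2) ifelse(cache, dY, slope * dY)

# 2x2 max pooling, stride 2.
pool_fw <- function(X, shp) {
  ix <- conv_index(shp[1], shp[2], shp[3], 2L, 2L, 0L)
  G1 <- X[, ix$idx[, 1], drop = FALSE]
  A <- G1
  arg <- matrix(1L, nrow(X), ncol(G1))
  for (k in 2:4) {
    Gk <- X[, ix$idx[, k], drop = FALSE]
    sel <- Gk > A
    A[sel] <- Gk[sel]
    arg[sel] <- k
  }
  list(Y = A, shp = c(shp[1], ix$Ho, ix$Wo),
       cache = list(arg = arg, shp = shp, Pin = ncol(X)))
}

pool_bw <- function(cache, dY) {
  shp <- cache$shp
  ix <- conv_index(shp[1], shp[2], shp[3], 2L, 2L, 0L)
  dX <- matrix(0, nrow(dY), cache$Pin)
  for (k in 1:4) {
    M <- dY * (cache$arg == k)
    dX[, ix$idx[, k]] <- dX[, ix$idx[, k]] + M
  }
  dX
}

.up_cache <- new.env(parent = emptyenv())

# 1D factor-2 bilinear interpolation matrix (half-pixel centers, edges
# clamped), as used for decoder upsampling.
up_mat <- function(H) {
  key <- as.character(H)
  hit <- .up_cache[[key]]
  if (!is.null(hit)) return(hit)
  U <- matrix(0, 2L * H, H)
  for (i in 0:(2L * H - 1L)) {
    s <- (i + 0.5) / 2 - 0.5
    s <- min(max(s, 0), H - 1)
    i0 <- floor(s)
    i1 <- min(i0 + 1, H - 1)
    w1 <- s - i0
    U[i + 1L, i0 + 1L] <- U[i + 1L, i0 + 1L] + (1 - w1)
    U[i + 1L, i1 + 1L] <- U[i + 1L, i1 + 1L] + w1
  }
  .up_cache[[key]] <- U
  U
}

# Factor-2 bilinear upsampling. Each sample/channel plane (stored as a
# W x H matrix because pixels are row-major) is interpolated with the
# separable 1D matrices; the backward pass is the transposed map.
up_fw <- function(X, shp) {
  N <- shp[1]; H <- shp[2]; W <- shp[3]; C <- nrow(X)
  Uh <- up_mat(H); Uw <- up_mat(W)
  H2 <- 2L * H; W2 <- 2L * W
  Y <- matrix(0, C, N * H2 * W2)
  for (n in 1:N) {
    src <- (n - 1L) * H * W
    dst <- (n - 1L) * H2 * W2
    for (ch in 1:C) {
      Mt <- matrix(X[ch, src + 1:(H * W)], W, H)
      Y[ch, dst + 1:(H2 * W2)] <- Uw %*% Mt %*% t(Uh)
    }
  }
  list(Y = Y, shp = c(N, H2, W2), cache = list(shp = shp))
}

up_bw <- function(cache, dY) {
  shp <- cache$shp
  N <- shp[1]; H <- shp[2]; W <- shp[3]; C <- nrow(dY)
  Uh <- up_mat(H); Uw <- up_mat(W)
  H2 <- 2L * H; W2 <- 2L * W
  dX <- matrix(0, C, N * H * W)
  for (n in 1:N) {
    src <- (n - 1L) * H2 * W2
    dst <- (n - 1L) * H * W
    for (ch in 1:C) {
      Mt <- matrix(dY[ch, src + 1:(H2 * W2)], W2, H2)
      dX[ch, dst + 1:(H * W)] <- t(Uw) %*% Mt %*% Uh
    }
  }
  dX
}

softmax_fw <- function(X) {
  m <- X[1, ]
  for (i in seq_len(nrow(X))[-1]) m <- pmax(m, X[i, ])
  E <- exp(X - rep(m, each = nrow(X)))
  P <- E / rep(colSums(E), each = nrow(X))
  P
}

# Gradient wrt logits given gradient wrt softmax probabilities.
softmax_bw <- function(P, dP) {
  s <- colSums(dP * P)
  P * (dP - rep(s, each = nrow(P)))
}

# ---- parameter-tree utilities and Adam ----

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) return(mapply(tree_add, a, b, SIMPLIFY = FALSE))
  a + b
}

tree_zero <- function(a) {
  if (is.list(a)) return(lapply(a, tree_zero))
  a * 0
}

adam_new <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.99,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  t <- opt$t
  # recurse over the names present in the gradient tree only, so
  # non-trainable layer fields (kernel size, stride, pad) are untouched
  upd <- function(p, g, m, v) {
    if (is.list(g)) {
      for (nm in names(g)) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- upd(params, grads, opt$m, opt$v)
  list(params = out$p, opt = list(m = out$m, v = out$v, t = t))
}
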