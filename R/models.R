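# Segmenter (customized U-Net) and patch domain discriminators.
#
# The segmenter is a customized U-Net: four
# Double-Conv + max-pool encoder stages with widths (w, 2w, 4w, 8w), a
# Double-Conv bottom at 8w, and four Upsample-Double-Conv decoder stages
# with widths (4w, 2w, w, w/2); skip connections concatenate the pooled
# encoder features at matching resolution (the last decoder stage has no
# skip). A final 3x3 convolution maps to the three classes
# (background, rim, cup) and a softmax yields the probability map. The
# first decoder feature ("Up1", 4w channels at H/8 x W/8) is exposed as
# the encoding-space feature for domain supervision.

#' Segmenter architecture specification
#'
#' @param base_width Channel width of the first encoder stage. The
#'   reference model uses 64; tests use 8. Must be divisible by 4.
#' @param in_channels Number of input channels (RGB fundus images: 3).
#' @param n_classes Number of output classes (background, rim, cup).
#' @return An object of class `segmenter_spec`.
#' @export
segmenter_spec <- function(base_width = 64L, in_channels = 3L,
                           n_classes = 3L) {
  base_width <- as.integer(base_width)
  if (base_width %% 4L != 0L)
    stop("base_width must be divisible by 4")
  structure(list(base_width = base_width, in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes)),
            class = "segmenter_spec")
}

#' Build the U-Net segmenter
#'
#' Weights are He-initialised from the current RNG state; seed the RNG
#' before calling for reproducible builds.
#'
#' @param spec A [segmenter_spec()].
#' @return A list with elements `spec`, `params` (convolution and
#'   batch-norm parameters) and `state` (batch-norm running statistics),
#'   consumed by [segmenter_forward()].
#' @export
build_segmenter <- function(spec = segmenter_spec()) {
  w <- spec$base_width
  ci <- spec$in_channels
  dc <- function(cin, cout) list(c1 = conv_new(cin, cout, 3L),
                                 b1 = bn_new(cout),
                                 c2 = conv_new(cout, cout, 3L),
                                 b2 = bn_new(cout))
  dcs <- function(cout) list(b1 = bn_state_new(cout), b2 = bn_state_new(cout))
  params <- list(
    d1 = dc(ci, w),          d2 = dc(w, 2L * w),
    d3 = dc(2L * w, 4L * w), d4 = dc(4L * w, 8L * w),
    bt = dc(8L * w, 8L * w),
    u1 = dc(12L * w, 4L * w), u2 = dc(6L * w, 2L * w),
    u3 = dc(3L * w, w),       u4 = dc(w, w %/% 2L),
    out = conv_new(w %/% 2L, spec$n_classes, 3L)
  )
  state <- list(d1 = dcs(w), d2 = dcs(2L * w), d3 = dcs(4L * w),
                d4 = dcs(8L * w), bt = dcs(8L * w), u1 = dcs(4L * w),
                u2 = dcs(2L * w), u3 = dcs(w), u4 = dcs(w %/% 2L))
  structure(list(spec = spec, params = params, state = state),
            class = "odcseg_segmenter")
}

dc_fw <- function(params, state, X, shp, train) {
  a <- conv_fw(params$c1, X, shp)
  b <- bn_fw(params$b1, state$b1, a$Y, train)
  r1 <- relu_fw(b$Y)
  a2 <- conv_fw(params$c2, r1$Y, a$shp)
  b2 <- bn_fw(params$b2, state$b2, a2$Y, train)
  r2 <- relu_fw(b2$Y)
  list(Y = r2$Y, shp = a2$shp,
       state = list(b1 = b$state, b2 = b2$state),
       cache = list(c1 = a$cache, b1 = b$cache, r1 = r1$cache,
                    c2 = a2$cache, b2 = b2$cache, r2 = r2$cache))
}

dc_bw <- function(params, cache, dY) {
  d <- relu_bw(cache$r2, dY)
  b2 <- bn_bw(params$b2, cache$b2, d)
  c2 <- conv_bw(params$c2, cache$c2, b2$dX)
  d <- relu_bw(cache$r1, c2$dX)
  b1 <- bn_bw(params$b1, cache$b1, d)
  c1 <- conv_bw(params$c1, cache$c1, b1$dX)
  list(dX = c1$dX,
       grads = list(c1 = c1$grads, b1 = b1$grads,
                    c2 = c2$grads, b2 = b2$grads))
}

#' Segmenter forward pass
#'
#' @param model A segmenter from [build_segmenter()].
#' @param X Input activations, `in_channels x (N*H*W)` matrix (pixels
#'   row-major per sample), or an `H x W x 3` array for a single image.
#' @param shp Integer vector `c(N, H, W)`; inferred for array input.
#' @param train Logical; `TRUE` uses batch statistics and updates the
#'   running batch-norm state, `FALSE` uses the stored running state.
#' @return A list with `probs` (softmax probability map, `n_classes x P`),
#'   `encoding` (Up1 feature, `4*base_width x N*(H/8)*(W/8)`),
#'   `enc_shp`, `shp`, the (possibly updated) `model`, and a `cache` for
#'   [segmenter_backward()].
#' @export
segmenter_forward <- function(model, X, shp = NULL, train = FALSE) {
  if (is.array(X) && length(dim(X)) == 3L) {
    shp <- c(1L, dim(X)[1], dim(X)[2])
    X <- image_to_mat(X)
  }
  stopifnot(length(shp) == 3L)
  if (shp[2] %% 16L != 0L || shp[3] %% 16L != 0L)
    stop("input spatial dimensions must be divisible by 16")
  p <- model$params; s <- model$state
  d1 <- dc_fw(p$d1, s$d1, X, shp, train);    p1 <- pool_fw(d1$Y, d1$shp)
  d2 <- dc_fw(p$d2, s$d2, p1$Y, p1$shp, train); p2 <- pool_fw(d2$Y, d2$shp)
  d3 <- dc_fw(p$d3, s$d3, p2$Y, p2$shp, train); p3 <- pool_fw(d3$Y, d3$shp)
  d4 <- dc_fw(p$d4, s$d4, p3$Y, p3$shp, train); p4 <- pool_fw(d4$Y, d4$shp)
  bt <- dc_fw(p$bt, s$bt, p4$Y, p4$shp, train)
  o1 <- up_fw(bt$Y, bt$shp)
  u1 <- dc_fw(p$u1, s$u1, rbind(o1$Y, p3$Y), o1$shp, train)
  o2 <- up_fw(u1$Y, u1$shp)
  u2 <- dc_fw(p$u2, s$u2, rbind(o2$Y, p2$Y), o2$shp, train)
  o3 <- up_fw(u2$Y, u2$shp)
  u3 <- dc_fw(p$u3, s$u3, rbind(o3$Y, p1$Y), o3$shp, train)
  o4 <- up_fw(u3$Y, u3$shp)
  u4 <- dc_fw(p$u4, s$u4, o4$Y, o4$shp, train)
  fin <- conv_fw(p$out, u4$Y, u4$shp)
  probs <- softmax_fw(fin$Y)
  model$state <- list(d1 = d1$state, d2 = d2$state, d3 = d3$state,
                      d4 = d4$state, bt = bt$state, u1 = u1$state,
                      u2 = u2$state, u3 = u3$state, u4 = u4$state)
  cache <- list(d1 = d1, p1 = p1, d2 = d2, p2 = p2, d3 = d3, p3 = p3,
                d4 = d4, p4 = p4, bt = bt, o1 = o1, u1 = u1, o2 = o2,
                u2 = u2, o3 = o3, u3 = u3, o4 = o4, u4 = u4, fin = fin,
                probs = probs)
  list(probs = probs, encoding = u1$Y, enc_shp = u1$shp, shp = shp,
       model = model, cache = cache)
}

# Backward pass through the segmenter. dProbs is the loss gradient wrt
# the softmax probability map; dEnc (optional) is an extra gradient
# injected at the Up1 encoding feature (from the encoding-space
# discriminator). Returns a gradient tree matching model$params.
segmenter_backward <- function(model, cache, dProbs, dEnc = NULL) {
  p <- model$params
  nch <- function(x) nrow(x)
  dLogits <- softmax_bw(cache$probs, dProbs)
  fin <- conv_bw(p$out, cache$fin$cache, dLogits)
  u4 <- dc_bw(p$u4, cache$u4$cache, fin$dX)
  d <- up_bw(cache$o4$cache, u4$dX)
  u3 <- dc_bw(p$u3, cache$u3$cache, d)
  # split concat gradients: first rows upsampled path, rest skip
  cu <- nch(cache$o3$Y)
  d <- up_bw(cache$o3$cache, u3$dX[seq_len(cu), , drop = FALSE])
  dskip1 <- u3$dX[-seq_len(cu), , drop = FALSE]
  u2 <- dc_bw(p$u2, cache$u2$cache, d)
  cu <- nch(cache$o2$Y)
  # gradient arriving at the Up1 output = decoder path + injected dEnc
  dU1Y <- up_bw(cache$o2$cache, u2$dX[seq_len(cu), , drop = FALSE])
  dskip2 <- u2$dX[-seq_len(cu), , drop = FALSE]
  if (!is.null(dEnc)) dU1Y <- dU1Y + dEnc
  u1 <- dc_bw(p$u1, cache$u1$cache, dU1Y)
  cu <- nch(cache$o1$Y)
  d <- up_bw(cache$o1$cache, u1$dX[seq_len(cu), , drop = FALSE])
  dskip3 <- u1$dX[-seq_len(cu), , drop = FALSE]
  bt <- dc_bw(p$bt, cache$bt$cache, d)
  d <- pool_bw(cache$p4$cache, bt$dX)
  d4 <- dc_bw(p$d4, cache$d4$cache, d)
  d <- pool_bw(cache$p3$cache, d4$dX + dskip3)
  d3 <- dc_bw(p$d3, cache$d3$cache, d)
  d <- pool_bw(cache$p2$cache, d3$dX + dskip2)
  d2 <- dc_bw(p$d2, cache$d2$cache, d)
  d <- pool_bw(cache$p1$cache, d2$dX + dskip1)
  d1 <- dc_bw(p$d1, cache$d1$cache, d)
  list(d1 = d1$grads, d2 = d2$grads, d3 = d3$grads, d4 = d4$grads,
       bt = bt$grads, u1 = u1$grads, u2 = u2$grads, u3 = u3$grads,
       u4 = u4$grads, out = fin$grads)
}

#' Discriminator architecture specification
#'
#' Five convolutions with kernel sizes (4,4,4,3,3) and strides
#' (2,2,2,1,1), LeakyReLU activations, and a single-channel patch-logit
#' output at 1/8 spatial resolution. Channel widths follow the
#' (3, 6, 12, 24, 1) progression for both the output-space (3-channel)
#' and encoding-space (wider) inputs, keeping the discriminators far
#' smaller than the segmenter; `scale_widths = TRUE` instead scales the
#' progression proportionally to the input width.
#'
#' @param in_channels Input channel count: 3 for the output space,
#'   `4 * base_width` for the encoding space.
#' @param scale_widths Scale the width progression by `in_channels/3`.
#' @return An object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(in_channels = 3L, scale_widths = FALSE) {
  in_channels <- as.integer(in_channels)
  if (in_channels < 1L) stop("in_channels must be positive")
  base <- if (scale_widths) in_channels else 3L
  structure(list(in_channels = in_channels,
                 widths = c(base, 2L * base, 4L * base, 8L * base, 1L),
                 kernels = c(4L, 4L, 4L, 3L, 3L),
                 strides = c(2L, 2L, 2L, 1L, 1L)),
            class = "discriminator_spec")
}

#' Build a patch domain discriminator
#'
#' @param spec A [discriminator_spec()].
#' @return A list with `spec` and `params`, consumed by
#'   [discriminator_forward()].
#' @export
build_discriminator <- function(spec = discriminator_spec()) {
  cin <- c(spec$in_channels, spec$widths[1:4])
  params <- lapply(1:5, function(i)
    conv_new(cin[i], spec$widths[i], spec$kernels[i], spec$strides[i], 1L))
  names(params) <- paste0("c", 1:5)
  structure(list(spec = spec, params = params),
            class = "odcseg_discriminator")
}

#' Discriminator forward pass
#'
#' @param model A discriminator from [build_discriminator()].
#' @param X Input map, `in_channels x (N*H*W)` matrix.
#' @param shp Integer vector `c(N, H, W)`; `H` and `W` must be divisible
#'   by 8.
#' @return A list with `logits` (`1 x N*(H/8)*(W/8)` pre-sigmoid patch
#'   logits), `shp` of the logits, and a `cache` for the backward pass.
#' @export
discriminator_forward <- function(model, X, shp) {
  if (shp[2] %% 8L != 0L || shp[3] %% 8L != 0L)
    stop("discriminator input spatial dimensions must be divisible by 8")
  if (nrow(X) != model$spec$in_channels)
    stop(sprintf("discriminator expects %d input channels, got %d",
                 model$spec$in_channels, nrow(X)))
  caches <- vector("list", 5L)
  cur <- X; cshp <- shp
  for (i in 1:4) {
    cv <- conv_fw(model$params[[i]], cur, cshp)
    lr <- lrelu_fw(cv$Y)
    caches[[i]] <- list(conv = cv$cache, act = lr$cache)
    cur <- lr$Y; cshp <- cv$shp
  }
  cv <- conv_fw(model$params[[5]], cur, cshp)
  caches[[5]] <- list(conv = cv$cache)
  list(logits = cv$Y, shp = cv$shp, cache = caches)
}

# Backward through a discriminator: returns gradient wrt its input and
# (optionally used) parameter gradients.
discriminator_backward <- function(model, cache, dLogits) {
  g5 <- conv_bw(model$params[[5]], cache[[5]]$conv, dLogits)
  d <- g5$dX
  grads <- vector("list", 5L)
  grads[[5]] <- g5$grads
  for (i in 4:1) {
    d <- lrelu_bw(cache[[i]]$act, d)
    gi <- conv_bw(model$params[[i]], cache[[i]]$conv, d)
    grads[[i]] <- gi$grads
    d <- gi$dX
  }
  names(grads) <- paste0("c", 1:5)
  list(dX = d, grads = grads)
}

# Convert an H x W x C image array to the internal C x (H*W) row-major
# matrix, and back.
image_to_mat <- function(img) {
  d <- dim(img)
  t(matrix(aperm(img, c(2, 1, 3)), d[1] * d[2], d[3]))
}

mat_to_image <- function(X, H, W) {
  C <- nrow(X)
  aperm(array(t(X), dim = c(W, H, C)), c(2, 1, 3))
}
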