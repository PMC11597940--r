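# Preprocessing: OD-centered ROI cropping with margin, contrast-limited
# adaptive histogram equalization (CLAHE), label encoding and network
# resizing. Coordinates are 0-based with half-open [min, max) boxes.

#' Tight bounding box of a binary mask
#'
#' @param mask Binary matrix.
#' @return List with `row_min`, `row_max`, `col_min`, `col_max`
#'   (0-based, half-open).
#' @export
mask_bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  list(row_min = min(idx[, 1]) - 1L, row_max = max(idx[, 1]),
       col_min = min(idx[, 2]) - 1L, col_max = max(idx[, 2]))
}

#' Crop an ROI around the optic disc
#'
#' The crop box is the tight OD bounding box expanded by `margin` pixels
#' on all four sides and clamped to the image bounds; image and both
#' masks are cropped identically.
#'
#' @param image `H x W x 3` array.
#' @param od_mask,oc_mask Binary matrices of the same spatial size.
#' @param margin Expansion in pixels (`>= 0`).
#' @return List with cropped `image`, `od_mask`, `oc_mask` and the
#'   `box` used (0-based, half-open).
#' @export
crop_roi <- function(image, od_mask, oc_mask, margin = 200L) {
  if (margin < 0) stop("margin must be >= 0")
  if (sum(od_mask) == 0) stop("od_mask is empty")
  H <- nrow(od_mask); W <- ncol(od_mask)
  bb <- mask_bbox(od_mask)
  box <- list(row_min = max(bb$row_min - margin, 0L),
              row_max = min(bb$row_max + margin, H),
              col_min = max(bb$col_min - margin, 0L),
              col_max = min(bb$col_max + margin, W))
  rr <- (box$row_min + 1L):box$row_max
  cc <- (box$col_min + 1L):box$col_max
  list(image = image[rr, cc, , drop = FALSE],
       od_mask = od_mask[rr, cc, drop = FALSE],
       oc_mask = oc_mask[rr, cc, drop = FALSE],
       box = box)
}

#' Contrast-limited adaptive histogram equalization
#'
#' CLAHE is applied to the luma channel of a YCbCr transform (or to each
#' RGB channel with `per_channel = TRUE`); chrominance is preserved and
#' the result re-encoded as an 8-bit RGB array.
#'
#' @param image `H x W x 3` numeric array, 0-255 or 0-1 scale.
#' @param clip_limit CLAHE clip limit (default 2).
#' @param tile_grid Integer vector `(rows, cols)` of tiles (default 8x8).
#' @param per_channel Equalize each RGB channel independently instead of
#'   the luma channel.
#' @return Array of the same shape and scale as the input.
#' @export
equalize_contrast <- function(image, clip_limit = 2, tile_grid = c(8L, 8L),
                              per_channel = FALSE) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an H x W x 3 image")
  was_int <- max(image) > 1
  img <- if (was_int) image / 255 else image
  run_clahe <- function(m) {
    out <- as.matrix(EBImage::clahe(EBImage::Image(m),
                                    nx = tile_grid[2], ny = tile_grid[1],
                                    limit = clip_limit))
    pmin(pmax(out, 0), 1)
  }
  if (per_channel) {
    for (ch in 1:3) img[, , ch] <- run_clahe(img[, , ch])
  } else {
    R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
    Y <- 0.299 * R + 0.587 * G + 0.114 * B
    Cb <- B - Y; Cr <- R - Y
    Y2 <- run_clahe(Y)
    img[, , 1] <- Y2 + Cr
    img[, , 3] <- Y2 + Cb
    img[, , 2] <- (Y2 - 0.299 * img[, , 1] - 0.114 * img[, , 3]) / 0.587
    img <- pmin(pmax(img, 0), 1)
  }
  if (was_int) {
    out <- round(img * 255)
    storage.mode(out) <- "integer"
    out
  } else img
}

#' Encode nested OD/OC masks as mutually exclusive one-hot labels
#'
#' Channels: background (not OD), rim (OD and not OC), cup (OC). The OD
#' is reconstructed from a prediction as rim plus cup.
#'
#' @param od_mask,oc_mask Binary matrices with `oc_mask` contained in
#'   `od_mask`.
#' @return A `3 x H x W` array in `{0,1}` whose channels sum to 1 at
#'   every pixel.
#' @export
encode_labels <- function(od_mask, oc_mask) {
  bad <- sum(oc_mask == 1 & od_mask == 0)
  if (bad > 0)
    stop(sprintf("masks are not nested: %d cup pixels outside the disc", bad))
  H <- nrow(od_mask); W <- ncol(od_mask)
  lab <- array(0, dim = c(3L, H, W))
  lab[1, , ] <- 1 - od_mask
  lab[2, , ] <- od_mask * (1 - oc_mask)
  lab[3, , ] <- oc_mask
  lab
}

#' Decode a one-hot (or probability) label map back to masks
#'
#' @param label `3 x H x W` array; argmax over channels selects the
#'   class.
#' @return List with binary `od_mask` (rim or cup) and `oc_mask` (cup).
#' @export
decode_labels <- function(label) {
  cls <- apply(label, c(2, 3), which.max)
  list(od_mask = (cls >= 2) * 1L, oc_mask = (cls == 3) * 1L)
}

#' Resize an image and its label to the network input size
#'
#' Image channels are resized bilinearly, label masks nearest-neighbor.
#'
#' @param image `H x W x 3` array.
#' @param od_mask,oc_mask Binary matrices (optional).
#' @param size Target side length.
#' @return List with resized `image` (and masks if given).
#' @export
resize_sample <- function(image, od_mask = NULL, oc_mask = NULL, size) {
  rs_img <- function(m, filter)
    as.matrix(EBImage::resize(EBImage::Image(m), w = size, h = size,
                              filter = filter))
  out <- array(0, dim = c(size, size, 3L))
  scl <- if (max(image) > 1) 255 else 1
  for (ch in 1:3) out[, , ch] <- rs_img(image[, , ch] / scl, "bilinear")
  res <- list(image = out)
  if (!is.null(od_mask))
    res$od_mask <- (rs_img(od_mask, "none") > 0.5) * 1L
  if (!is.null(oc_mask))
    res$oc_mask <- (rs_img(oc_mask, "none") > 0.5) * 1L
  res
}

# Full preprocessing of one synthetic sample to network-ready tensors:
# optional CLAHE, scaling to [0,1], optional resize, one-hot labels.
prepare_sample <- function(sample, size = NULL, equalize = FALSE,
                           clip_limit = 2, tile_grid = c(8L, 8L)) {
  img <- sample$image
  if (equalize) img <- equalize_contrast(img, clip_limit, tile_grid)
  img <- img / 255
  od <- sample$od_mask; oc <- sample$oc_mask
  if (!is.null(size) && size != nrow(od)) {
    r <- resize_sample(img, od, oc, size)
    img <- r$image; od <- r$od_mask; oc <- r$oc_mask
    oc <- oc * od  # nearest-neighbor resize cannot break nesting, but be safe
  }
  lab <- encode_labels(od, oc)
  list(x = image_to_mat(img), shp = c(1L, nrow(od), ncol(od)),
       label = matrix(aperm(lab, c(1, 3, 2)), 3L, length(od)),
       od_mask = od, oc_mask = oc)
}
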