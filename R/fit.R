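# Model-fitting front end: fit_odcseg() wraps the training procedure in
# the classic R modelling idiom and odcseg_fit objects carry
# print/summary/predict/plot methods.

#' Fit a glaucoma-specialized disc/cup segmentation model
#'
#' Trains the pixel-supervised U-Net segmenter with Gram-matrix
#' style-contrastive refinement and two-space domain adversarial
#' refinement on a dataset of fundus ROI images, following the
#' alternating min-max schedule. This is the main entry point; it wraps
#' [run_training()].
#'
#' @param dataset An `odcseg_dataset` (see [generate_dataset()] and
#'   [read_dataset()]).
#' @param scenario Annotation scenario (1, 2 or 3); defaults to the
#'   dataset's scenario if recorded.
#' @param config A [train_config()]; `scenario` and `seed` arguments
#'   override its fields.
#' @param seed Master seed.
#' @param baseline If `TRUE`, fit the pixel-supervised baseline
#'   (style and domain weights zero) instead of the full model.
#' @param verbose Print per-epoch progress.
#' @return An `odcseg_fit` object.
#' @export
fit_odcseg <- function(dataset, scenario = NULL, config = train_config(),
                       seed = NULL, baseline = FALSE, verbose = FALSE) {
  if (is.null(scenario))
    scenario <- if (!is.null(dataset$scenario)) dataset$scenario else 1L
  config$scenario <- as.integer(scenario)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  override <- if (baseline) loss_weights(1, 0, 0, config$w_e, config$w_o)
              else NULL
  fit <- run_training(dataset, config, weights_override = override,
                      verbose = verbose)
  fit$baseline <- baseline
  fit
}

#' @export
print.odcseg_fit <- function(x, ...) {
  cat("Glaucoma-specialized OD/OC segmentation fit\n")
  cat(sprintf("  scenario %d, %d epochs, image size %d, base width %d\n",
              x$config$scenario, x$config$epochs, x$config$image_size,
              x$config$base_width))
  cat(sprintf("  %d annotated / %d target samples; %d discriminator updates\n",
              x$n_annotated, x$n_target, x$disc_updates))
  if (isTRUE(x$baseline)) cat("  pixel-supervised baseline (no style/domain)\n")
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  final epoch: l_seg %.4f, l_style %.5f, style gap %.5f\n",
              h$l_seg, h$l_style, h$style_gap))
  invisible(x)
}

#' @export
summary.odcseg_fit <- function(object, dataset = NULL, ...) {
  out <- list(fit = object)
  if (!is.null(dataset))
    out$validation <- evaluate_model(object, dataset, split = "validation")
  class(out) <- "summary.odcseg_fit"
  out
}

#' @export
print.summary.odcseg_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$validation)) {
    cat("Validation split:\n")
    print(x$validation)
  }
  invisible(x)
}

#' Predict disc/cup masks for new images
#'
#' Runs the trained segmenter (evaluation mode; no discriminator is
#' involved at inference) and argmax-decodes the probability map.
#'
#' @param object An `odcseg_fit`.
#' @param newdata A list of `synthetic_sample` objects, an
#'   `odcseg_dataset`, or a single `H x W x 3` image array.
#' @param type `"masks"` for decoded OD/OC masks, `"probs"` for the
#'   per-class probability array.
#' @param ... Unused.
#' @return A list per input image with `od_mask`/`oc_mask` (or a
#'   `3 x H x W` probability array).
#' @export
predict.odcseg_fit <- function(object, newdata, type = c("masks", "probs"),
                               ...) {
  type <- match.arg(type)
  if (is.array(newdata) && length(dim(newdata)) == 3L)
    newdata <- list(list(image = newdata, od_mask = NULL, oc_mask = NULL))
  if (inherits(newdata, "odcseg_dataset")) newdata <- newdata$samples
  lapply(newdata, function(s) {
    img <- if (max(s$image) > 1) s$image / 255 else s$image
    if (isTRUE(object$config$equalize))
      img <- equalize_contrast(img * 255, per_channel = FALSE) / 255
    sz <- object$config$image_size
    if (nrow(img) != sz) img <- resize_sample(img, size = sz)$image
    fwd <- segmenter_forward(object$segmenter, image_to_mat(img),
                             c(1L, sz, sz), train = FALSE)
    if (type == "probs")
      return(aperm(array(fwd$probs, dim = c(3L, sz, sz)), c(1, 3, 2)))
    cls <- matrix(max.col(t(fwd$probs)), sz, sz, byrow = TRUE)
    od <- (cls >= 2) * 1L
    oc <- (cls == 3) * 1L
    # largest-component cleanup keeps the prediction a single nested pair
    od <- largest_cc_mask(od)
    oc <- largest_cc_mask(oc * od)
    list(od_mask = od, oc_mask = oc)
  })
}

largest_cc_mask <- function(mask) {
  if (sum(mask) == 0) return(mask)
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  tab <- tabulate(lab[lab > 0])
  (lab == which.max(tab)) * 1L
}

#' Plot training diagnostics
#'
#' Plots the per-epoch losses and the style gap between validation
#' predictions and glaucoma ground truth (the curve used to diagnose
#' style-contrastive refinement).
#'
#' @param x An `odcseg_fit`.
#' @param which `"losses"` or `"style_gap"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.odcseg_fit <- function(x, which = c("style_gap", "losses"), ...) {
  which <- match.arg(which)
  h <- x$history
  if (which == "style_gap") {
    graphics::plot(h$epoch, h$style_gap, type = "l", xlab = "epoch",
                   ylab = "style gap to glaucoma ground truth", ...)
  } else {
    graphics::plot(h$epoch, h$l_seg, type = "l", xlab = "epoch",
                   ylab = "loss", ...)
    graphics::lines(h$epoch, h$l_style, lty = 2)
    graphics::lines(h$epoch, h$l_domain, lty = 3)
    graphics::legend("topright", c("dice", "style", "domain"), lty = 1:3,
                     bty = "n")
  }
  invisible(x)
}
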