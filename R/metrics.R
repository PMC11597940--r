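# Glaucoma-oriented evaluation suite: per-region Dice, two-direction
# cup-to-disc ratio (CDR) and its mean squared error, the G-score, and
# whole-split evaluation (M-Dice reporting).

#' Dice coefficient of two binary masks
#'
#' `2*TP / (2*TP + FP + FN)`; two empty masks score 1 (a correct
#' negative is not penalized).
#'
#' @param pred_mask,gt_mask Binary matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred_mask, gt_mask) {
  if (!all(dim(pred_mask) == dim(gt_mask))) stop("mask shapes differ")
  p <- pred_mask > 0; g <- gt_mask > 0
  tp <- sum(p & g)
  if (tp == 0 && !any(p) && !any(g)) return(1)
  2 * tp / (2 * tp + sum(p & !g) + sum(!p & g))
}

# Intersection-over-union; both-empty pairs score 1.
iou <- function(pred_mask, gt_mask) {
  p <- pred_mask > 0; g <- gt_mask > 0
  u <- sum(p | g)
  if (u == 0) return(1)
  sum(p & g) / u
}

# Bounding-box extents (height, width) of the largest connected
# component of a binary mask; c(0, 0) for an empty mask.
largest_cc_extent <- function(mask) {
  if (sum(mask) == 0) return(c(0, 0))
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- as.matrix(lab)
  tab <- tabulate(lab[lab > 0])
  big <- which.max(tab)
  idx <- which(lab == big, arr.ind = TRUE)
  c(max(idx[, 1]) - min(idx[, 1]) + 1, max(idx[, 2]) - min(idx[, 2]) + 1)
}

#' Vertical and horizontal cup-to-disc ratios
#'
#' Diameters are the bounding-box extents of the largest connected
#' component of each structure; an empty cup yields `(0, 0)`.
#'
#' @param od_mask,oc_mask Binary masks; `od_mask` must be nonempty.
#' @return List of class `cdr_pair` with `vertical` and `horizontal`
#'   ratios.
#' @export
extract_cdr <- function(od_mask, oc_mask) {
  if (sum(od_mask) == 0) stop("od_mask is empty")
  de <- largest_cc_extent(od_mask)
  ce <- largest_cc_extent(oc_mask)
  structure(list(vertical = ce[1] / de[1], horizontal = ce[2] / de[2]),
            class = "cdr_pair")
}

#' Mean squared CDR error over a sample set
#'
#' `sum((dH)^2 + (dV)^2) / n` over paired predictions and ground
#' truths.
#'
#' @param preds,gts Lists of [extract_cdr()] pairs of equal length.
#' @return Scalar mean squared error.
#' @export
cdr_mse <- function(preds, gts) {
  if (length(preds) != length(gts)) stop("pred/gt lengths differ")
  if (length(preds) < 1) stop("need at least one sample")
  s <- 0
  for (i in seq_along(preds)) {
    s <- s + (preds[[i]]$horizontal - gts[[i]]$horizontal)^2 +
      (preds[[i]]$vertical - gts[[i]]$vertical)^2
  }
  s / length(preds)
}

#' G-score of predicted versus ground-truth disc/cup masks
#'
#' Per sample: `(mean(IoU_OD, IoU_OC) * 100) / 2` minus the relative
#' vertical-CDR error `|vCDR_pred - vCDR_gt| / vCDR_gt * 100`; averaged
#' over samples. 50 is the perfect score. Overlap region and CDR
#' direction are configurable.
#'
#' @param pred_od,pred_oc,gt_od,gt_oc Binary masks or lists of masks.
#' @param region `"mean"` (mean of OD and OC IoU), `"od"` or `"oc"`.
#' @param direction `"vertical"` or `"horizontal"` CDR.
#' @return Scalar score (at most 50; not clamped below).
#' @export
g_score <- function(pred_od, pred_oc, gt_od, gt_oc,
                    region = c("mean", "od", "oc"),
                    direction = c("vertical", "horizontal")) {
  region <- match.arg(region)
  direction <- match.arg(direction)
  if (!is.list(pred_od)) {
    pred_od <- list(pred_od); pred_oc <- list(pred_oc)
    gt_od <- list(gt_od); gt_oc <- list(gt_oc)
  }
  scores <- vapply(seq_along(pred_od), function(i) {
    ov <- switch(region,
                 mean = (iou(pred_od[[i]], gt_od[[i]]) +
                           iou(pred_oc[[i]], gt_oc[[i]])) / 2,
                 od = iou(pred_od[[i]], gt_od[[i]]),
                 oc = iou(pred_oc[[i]], gt_oc[[i]]))
    cg <- extract_cdr(gt_od[[i]], gt_oc[[i]])[[direction]]
    if (cg <= 0) stop("ground-truth CDR is zero")
    cp <- if (sum(pred_od[[i]]) == 0) 0
          else extract_cdr(pred_od[[i]], pred_oc[[i]])[[direction]]
    ov * 100 / 2 - abs(cp - cg) / cg * 100
  }, numeric(1))
  mean(scores)
}

#' Evaluate a segmenter on a dataset split
#'
#' Each sample is forwarded in evaluation mode, the probability map is
#' argmax-decoded (OD = rim or cup, OC = cup, Rim = rim), and per-region
#' Dice, M-Dice (their mean), CDR mean squared error and G-score are
#' reported over the split.
#'
#' @param model A segmenter (from [build_segmenter()] or a fitted
#'   `odcseg_fit`), or a function taking a prepared sample (with
#'   elements `x`, `shp`, `label`) and returning a `3 x P` probability
#'   matrix (e.g. a reference predictor in tests).
#' @param samples List of `synthetic_sample` objects (or an
#'   `odcseg_dataset` with a `split` argument).
#' @param split Split name when `samples` is a dataset.
#' @param size Network input size (samples are resized if needed).
#' @param equalize Apply CLAHE before inference.
#' @return A list of class `metrics_report` with `dice_od`, `dice_oc`,
#'   `dice_rim`, `m_dice`, `cdr_mse`, `g_score`, `n_samples` and a
#'   `per_sample` data frame.
#' @export
evaluate_model <- function(model, samples, split = "validation",
                           size = NULL, equalize = FALSE) {
  if (inherits(model, "odcseg_fit")) {
    if (is.null(size)) size <- model$config$image_size
    equalize <- model$config$equalize
    model <- model$segmenter
  }
  if (inherits(samples, "odcseg_dataset"))
    samples <- Filter(function(s) identical(s$split, split), samples$samples)
  if (length(samples) == 0) stop("empty evaluation split")
  decoded <- lapply(samples, function(s) {
    pr <- prepare_sample(s, size = size, equalize = equalize)
    probs <- if (is.function(model)) model(pr)
             else segmenter_forward(model, pr$x, pr$shp, train = FALSE)$probs
    cls <- max.col(t(probs))  # 1 = background, 2 = rim, 3 = cup
    H <- pr$shp[2]; W <- pr$shp[3]
    cm <- matrix(cls, H, W, byrow = TRUE)
    list(pred_od = (cm >= 2) * 1L, pred_oc = (cm == 3) * 1L,
         gt_od = pr$od_mask, gt_oc = pr$oc_mask)
  })
  rows <- lapply(decoded, function(d) {
    gt_rim <- d$gt_od * (1 - d$gt_oc)
    pred_rim <- d$pred_od * (1 - d$pred_oc)
    cg <- extract_cdr(d$gt_od, d$gt_oc)
    cp <- if (sum(d$pred_od) > 0) extract_cdr(d$pred_od, d$pred_oc)
          else structure(list(vertical = 0, horizontal = 0), class = "cdr_pair")
    data.frame(dice_od = dice_coefficient(d$pred_od, d$gt_od),
               dice_oc = dice_coefficient(d$pred_oc, d$gt_oc),
               dice_rim = dice_coefficient(pred_rim, gt_rim),
               cdr_v_pred = cp$vertical, cdr_h_pred = cp$horizontal,
               cdr_v_gt = cg$vertical, cdr_h_gt = cg$horizontal,
               g = g_score(d$pred_od, d$pred_oc, d$gt_od, d$gt_oc))
  })
  per <- do.call(rbind, rows)
  per$sample_id <- vapply(samples, `[[`, "", "sample_id")
  rownames(per) <- NULL
  preds <- lapply(seq_len(nrow(per)), function(i)
    list(vertical = per$cdr_v_pred[i], horizontal = per$cdr_h_pred[i]))
  gts <- lapply(seq_len(nrow(per)), function(i)
    list(vertical = per$cdr_v_gt[i], horizontal = per$cdr_h_gt[i]))
  structure(list(dice_od = mean(per$dice_od), dice_oc = mean(per$dice_oc),
                 dice_rim = mean(per$dice_rim),
                 m_dice = mean(c(mean(per$dice_od), mean(per$dice_oc),
                                 mean(per$dice_rim))),
                 cdr_mse = cdr_mse(preds, gts), g_score = mean(per$g),
                 n_samples = nrow(per), per_sample = per),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Segmentation metrics over %d samples\n", x$n_samples))
  cat(sprintf("  Dice  OD: %.4f  OC: %.4f  Rim: %.4f  (M-Dice %.4f)\n",
              x$dice_od, x$dice_oc, x$dice_rim, x$m_dice))
  cat(sprintf("  CDR MSE: %.4f   G-score: %.2f\n", x$cdr_mse, x$g_score))
  invisible(x)
}
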