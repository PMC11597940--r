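# Loss suite: soft dice supervision, Gram-matrix style gap,
# discriminator BCE, two-space adversarial domain gap, and the combined
# objective. Every loss has a companion gradient used by the trainer.

.loss_eps <- 1e-7

as_cp <- function(x) {
  # accept C x H x W arrays or C x P matrices
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 3L) return(matrix(x, d[1], d[2] * d[3]))
  stop("expected a C x P matrix or C x H x W array")
}

#' Soft dice segmentation loss
#'
#' Per channel `1 - 2*sum(p*y) / (sum(p^2) + sum(y^2))`, averaged over
#' the channels; sums run over all pixels of a channel. Zero when the
#' prediction equals the one-hot target, one when all mass is on wrong
#' classes.
#'
#' @param probs Predicted probability map (`C x P` matrix or
#'   `C x H x W` array), values in `[0, 1]`.
#' @param target One-hot target of the same shape.
#' @return Scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(probs, target) {
  p <- as_cp(probs); y <- as_cp(target)
  if (!all(dim(p) == dim(y))) stop("probs and target shapes differ")
  num <- 2 * rowSums(p * y)
  den <- rowSums(p * p) + rowSums(y * y) + .loss_eps
  mean(1 - num / den)
}

soft_dice_grad <- function(probs, target) {
  p <- as_cp(probs); y <- as_cp(target)
  num <- 2 * rowSums(p * y)
  den <- rowSums(p * p) + rowSums(y * y) + .loss_eps
  C <- nrow(p)
  # d/dp of -num/den averaged over channels
  (-(2 * y) / den + num / den^2 * (2 * p)) / C
}

#' Channel-wise Gram matrix
#'
#' For a feature map with `C` channels, the `C x C` matrix of channel
#' inner products `R^T R`, where `R` is the `HW x C` reshape of the map.
#' No normalization is applied here.
#'
#' @param feature `C x P` matrix or `C x H x W` array.
#' @return A `C x C` matrix of class `gram_matrix` with attribute
#'   `source_shape`.
#' @export
gram_matrix <- function(feature) {
  f <- as_cp(feature)
  G <- f %*% t(f)
  structure(G, class = c("gram_matrix", class(G)),
            source_shape = if (is.matrix(feature)) dim(feature) else dim(feature))
}

#' Gram-matrix style gap loss
#'
#' Mean squared difference between the Gram matrices of two prediction
#' maps, normalized by the number of Gram entries `C^2`.
#'
#' @param pred_a,pred_b Probability maps (`C x P` or `C x H x W`) with
#'   equal channel counts.
#' @param normalize If `TRUE`, each Gram matrix is divided by its
#'   number of spatial positions before differencing, making the loss
#'   independent of image size (entries become mean per-position channel
#'   co-occurrences). The trainer uses this scale-free form so that the
#'   default style weight is commensurate with the dice loss; the
#'   default `FALSE` is the raw-Gram form.
#' @return Scalar loss, `>= 0`, zero iff the (normalized) Gram matrices
#'   coincide.
#' @export
style_gap_loss <- function(pred_a, pred_b, normalize = FALSE) {
  a <- as_cp(pred_a); b <- as_cp(pred_b)
  if (nrow(a) != nrow(b)) stop("channel counts differ")
  na <- if (normalize) ncol(a) else 1
  nb <- if (normalize) ncol(b) else 1
  Ga <- a %*% t(a) / na; Gb <- b %*% t(b) / nb
  sum((Ga - Gb)^2) / nrow(a)^2
}

# Gradients of style_gap_loss wrt both inputs.
style_gap_grad <- function(pred_a, pred_b, normalize = FALSE) {
  a <- as_cp(pred_a); b <- as_cp(pred_b)
  na <- if (normalize) ncol(a) else 1
  nb <- if (normalize) ncol(b) else 1
  Ga <- a %*% t(a) / na; Gb <- b %*% t(b) / nb
  dG <- 2 * (Ga - Gb) / nrow(a)^2
  list(dA = 2 * dG %*% a / na, dB = -2 * dG %*% b / nb)
}

#' Patch discriminator binary cross-entropy loss
#'
#' Mean over patch positions of the binary cross-entropy between the
#' sigmoid of the logits and the domain label (glaucoma = 1, normal = 0).
#'
#' @param logits Pre-sigmoid patch logits (any numeric shape).
#' @param domain_label 0 (normal) or 1 (glaucoma).
#' @return Scalar loss.
#' @export
discriminator_bce_loss <- function(logits, domain_label) {
  if (!domain_label %in% c(0, 1)) stop("domain_label must be 0 or 1")
  x <- as.numeric(logits)
  s <- stats::plogis(x)
  mean(-(domain_label * log(pmax(s, .loss_eps)) +
           (1 - domain_label) * log(pmax(1 - s, .loss_eps))))
}

discriminator_bce_grad <- function(logits, domain_label) {
  s <- stats::plogis(logits)
  (s - domain_label) / length(logits)
}

#' Adversarial two-space domain gap loss
#'
#' For normal-sample forward passes, the cost of the discriminators not
#' classifying them as glaucoma: per space, the mean of
#' `-log sigmoid(logit)`; the two spaces are combined as
#' `w_e * L_enc + w_o * L_out`.
#'
#' @param enc_logits Encoding-space patch logits of a normal sample.
#' @param out_logits Output-space patch logits of a normal sample.
#' @param weights A [loss_weights()] (only `w_e` and `w_o` are used).
#' @return Scalar loss.
#' @export
adversarial_domain_loss <- function(enc_logits, out_logits, weights) {
  if (abs(weights$w_e + weights$w_o - 1) > 1e-8)
    stop("w_e and w_o must sum to 1")
  le <- mean(-log(pmax(stats::plogis(as.numeric(enc_logits)), .loss_eps)))
  lo <- mean(-log(pmax(stats::plogis(as.numeric(out_logits)), .loss_eps)))
  weights$w_e * le + weights$w_o * lo
}

# d/dlogit of mean(-log sigmoid(logit)) is (sigmoid - 1)/n.
adversarial_grad <- function(logits) {
  (stats::plogis(logits) - 1) / length(logits)
}

#' Objective loss weights
#'
#' Scalar weights of the overall objective
#' `w_seg*L_seg + w_style*L_style + w_domain*(w_e*L_enc + w_o*L_out)`
#' and the two-phase schedule: phase 1 uses
#' `(w_seg, w_style, w_domain) = (1, 0.05, 0)`, phase 2 `(0, 0, 1)`;
#' the space weights are `w_e = 0.2`, `w_o = 0.8` throughout.
#'
#' @param w_seg,w_style,w_domain Nonnegative component weights.
#' @param w_e,w_o Nonnegative encoding/output space weights summing to 1.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(w_seg = 1, w_style = 0.05, w_domain = 0,
                         w_e = 0.2, w_o = 0.8) {
  vals <- c(w_seg, w_style, w_domain, w_e, w_o)
  if (any(vals < 0)) stop("loss weights must be nonnegative")
  if (abs(w_e + w_o - 1) > 1e-8) stop("w_e and w_o must sum to 1")
  structure(list(w_seg = w_seg, w_style = w_style, w_domain = w_domain,
                 w_e = w_e, w_o = w_o), class = "loss_weights")
}

#' Phase weights of the two-phase schedule
#'
#' @param phase 1 (pixel + style supervision) or 2 (adversarial).
#' @param w_e,w_o Space weights.
#' @return A [loss_weights()].
#' @export
phase_weights <- function(phase, w_e = 0.2, w_o = 0.8) {
  if (phase == 1) loss_weights(1, 0.05, 0, w_e, w_o)
  else loss_weights(0, 0, 1, w_e, w_o)
}

#' Combined training objective
#'
#' @param l_seg,l_style,l_domain_enc,l_domain_out Component losses.
#' @param weights A [loss_weights()].
#' @param l_disc Optional discriminator-phase loss to record.
#' @return A list of class `loss_breakdown` with all components and
#'   `l_total`.
#' @export
total_objective <- function(l_seg, l_style, l_domain_enc, l_domain_out,
                            weights, l_disc = NA_real_) {
  l_total <- weights$w_seg * l_seg + weights$w_style * l_style +
    weights$w_domain * (weights$w_e * l_domain_enc +
                          weights$w_o * l_domain_out)
  structure(list(l_seg = l_seg, l_style = l_style,
                 l_domain_enc = l_domain_enc, l_domain_out = l_domain_out,
                 l_total = l_total, l_disc = l_disc),
            class = "loss_breakdown")
}
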