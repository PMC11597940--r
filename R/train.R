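# Min-max dual-step training: alternating segmenter and discriminator
# updates with the two-phase weight schedule and the three clinical
# annotation scenarios.
#
# Phase 1 optimizes pixel supervision plus the style-contrastive loss
# with weights (w_seg, w_style, w_domain) = (1, 0.05, 0); phase 2
# engages the adversarial refinement (w_domain = 1), alternating one
# segmenter update (discriminators frozen) with one discriminator
# update (segmenter frozen) per iteration. Scenario 2 (annotated
# glaucoma only) has no normal samples to discriminate against, so it
# keeps the phase-1 weights throughout and never updates a
# discriminator, reducing the model to single-style contrastive
# learning.

#' Training configuration
#'
#' @param scenario Annotation scenario: 1 (annotated normals +
#'   unannotated glaucomas), 2 (annotated + unannotated glaucomas), 3
#'   (both classes annotated).
#' @param epochs Number of epochs.
#' @param image_size Network input size (pixels, divisible by 16).
#' @param base_width Segmenter width (reference 64, tests 8).
#' @param batch_size Samples per iteration (reference: 2 = one
#'   annotated + one target image).
#' @param lr_seg,lr_disc Initial Adam learning rates of the segmenter
#'   and discriminators.
#' @param betas Adam moment decay rates.
#' @param lr_gamma Stepwise learning-rate decay per epoch.
#' @param phase1_fraction Fraction of epochs in phase 1 (supervised +
#'   style). The default devotes the last fifth of training to the
#'   adversarial refinement: the dual-step game is a fine-tuning stage
#'   on an already-converged segmenter, and longer adversarial schedules
#'   progressively undo the pixel supervision.
#' @param w_e,w_o Encoding/output space weights of the domain loss.
#' @param w_style_phase1 Style weight in phase 1.
#' @param keep_seg_in_phase2 Keep the dice and style losses active in
#'   phase 2 alongside the adversarial loss, i.e. weights
#'   `(1, w_style_phase1, 1)` — the reading in which the dual-step
#'   algorithm computes all three losses every iteration (default).
#'   `FALSE` gives the literal pure-adversarial weight setting
#'   `(0, 0, 1)`, which removes every anchor to the annotations and
#'   drifts away from segmentation competence.
#' @param style_detach_target Treat the glaucoma prediction as a fixed
#'   style target (no gradient into the target branch) instead of the
#'   default symmetric pairing.
#' @param equalize Apply CLAHE during sample preparation.
#' @param upsample_encoding Upsample the encoding feature to full
#'   resolution before the encoding-space discriminator instead of
#'   consuming it at its native resolution (off by default).
#' @param seed Master seed for initialization and batch order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(scenario = 1L, epochs = 30L, image_size = 64L,
                         base_width = 8L, batch_size = 2L,
                         lr_seg = 1e-4, lr_disc = 1e-2,
                         betas = c(0.9, 0.99), lr_gamma = 0.95,
                         phase1_fraction = 0.8, w_e = 0.2, w_o = 0.8,
                         w_style_phase1 = 0.05,
                         keep_seg_in_phase2 = TRUE,
                         style_detach_target = FALSE, equalize = FALSE,
                         upsample_encoding = FALSE, seed = 1L) {
  stopifnot(scenario %in% 1:3, phase1_fraction > 0, phase1_fraction <= 1)
  structure(list(scenario = as.integer(scenario), epochs = as.integer(epochs),
                 image_size = as.integer(image_size),
                 base_width = as.integer(base_width),
                 batch_size = as.integer(batch_size),
                 lr_seg = lr_seg, lr_disc = lr_disc, betas = betas,
                 lr_gamma = lr_gamma, phase1_fraction = phase1_fraction,
                 w_e = w_e, w_o = w_o, w_style_phase1 = w_style_phase1,
                 keep_seg_in_phase2 = keep_seg_in_phase2,
                 style_detach_target = style_detach_target,
                 equalize = equalize,
                 upsample_encoding = upsample_encoding,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Forward the encoding feature into the encoding-space discriminator,
# optionally through the literal x8 upsampling.
enc_disc_input <- function(fwd, upsample) {
  enc <- fwd$encoding; shp <- fwd$enc_shp
  ups <- list()
  if (upsample) {
    for (i in 1:3) {
      u <- up_fw(enc, shp)
      ups[[i]] <- u$cache
      enc <- u$Y; shp <- u$shp
    }
  }
  list(X = enc, shp = shp, ups = ups)
}

enc_disc_input_bw <- function(dX, ups) {
  for (i in rev(seq_along(ups))) dX <- up_bw(ups[[i]], dX)
  dX
}

#' One segmenter optimization step (discriminators fixed)
#'
#' Forwards the annotated sample (dice loss) and the target sample
#' (style pairing), evaluates the two-space adversarial loss on the
#' normal sample's outputs against the frozen discriminators,
#' backpropagates the weighted objective and applies one Adam update to
#' the segmenter only.
#'
#' @param segmenter Segmenter model.
#' @param discs List with `enc` and `out` discriminators (may be `NULL`
#'   when `w_domain = 0`).
#' @param batch List with `ann` (prepared annotated sample: `x`, `shp`,
#'   `label`, `domain`) and optionally `tgt` (prepared target sample).
#' @param weights A [loss_weights()].
#' @param opt Adam state for the segmenter (from [adam_new()]).
#' @param lr Learning rate for this step.
#' @param config A [train_config()] (for `upsample_encoding` and betas).
#' @return List with updated `segmenter`, `opt` and a `loss_breakdown`.
#' @export
segmenter_step <- function(segmenter, discs, batch, weights, opt, lr,
                           config = train_config()) {
  if (weights$w_seg > 0 && is.null(batch$ann$label))
    stop("batch has no pixel-annotated sample but w_seg > 0")
  fwd_a <- segmenter_forward(segmenter, batch$ann$x, batch$ann$shp,
                             train = TRUE)
  segmenter <- fwd_a$model
  # Step 1 also forwards the target glaucoma image whenever class-level
  # supervision is active (the dual-path forward of the training
  # algorithm); the target prediction receives gradient only through
  # the style pairing.
  need_tgt <- (weights$w_style > 0 || weights$w_domain > 0) &&
    !is.null(batch$tgt)
  fwd_t <- NULL
  if (need_tgt) {
    fwd_t <- segmenter_forward(segmenter, batch$tgt$x, batch$tgt$shp,
                               train = TRUE)
    segmenter <- fwd_t$model
  }
  l_seg <- 0; dseg <- NULL
  if (weights$w_seg > 0) {
    l_seg <- soft_dice_loss(fwd_a$probs, batch$ann$label)
    dseg <- soft_dice_grad(fwd_a$probs, batch$ann$label)
  }
  l_style <- 0; dsty <- NULL
  if (need_tgt && weights$w_style > 0) {
    l_style <- style_gap_loss(fwd_a$probs, fwd_t$probs, normalize = TRUE)
    dsty <- style_gap_grad(fwd_a$probs, fwd_t$probs, normalize = TRUE)
  }
  l_de <- 0; l_do <- 0
  dEnc <- NULL; dOutProbs <- NULL
  adversarial <- weights$w_domain > 0 && !is.null(discs) &&
    identical(batch$ann$domain, 0L)
  if (adversarial) {
    ein <- enc_disc_input(fwd_a, config$upsample_encoding)
    de <- discriminator_forward(discs$enc, ein$X, ein$shp)
    do_ <- discriminator_forward(discs$out, fwd_a$probs, batch$ann$shp)
    l_de <- mean(-log(pmax(stats::plogis(as.numeric(de$logits)), .loss_eps)))
    l_do <- mean(-log(pmax(stats::plogis(as.numeric(do_$logits)), .loss_eps)))
    ge <- discriminator_backward(discs$enc, de$cache,
                                 weights$w_domain * weights$w_e *
                                   adversarial_grad(de$logits))
    go <- discriminator_backward(discs$out, do_$cache,
                                 weights$w_domain * weights$w_o *
                                   adversarial_grad(do_$logits))
    dEnc <- enc_disc_input_bw(ge$dX, ein$ups)
    dOutProbs <- go$dX
  }
  dprobs_a <- fwd_a$probs * 0
  if (!is.null(dseg)) dprobs_a <- dprobs_a + weights$w_seg * dseg
  if (!is.null(dsty)) dprobs_a <- dprobs_a + weights$w_style * dsty$dA
  if (!is.null(dOutProbs)) dprobs_a <- dprobs_a + dOutProbs
  grads <- segmenter_backward(segmenter, fwd_a$cache, dprobs_a, dEnc)
  if (!is.null(dsty) && !isTRUE(config$style_detach_target)) {
    grads_t <- segmenter_backward(segmenter, fwd_t$cache,
                                  weights$w_style * dsty$dB)
    grads <- tree_add(grads, grads_t)
  }
  st <- adam_step(segmenter$params, grads, opt, lr,
                  beta1 = config$betas[1], beta2 = config$betas[2])
  segmenter$params <- st$params
  breakdown <- total_objective(l_seg, l_style, l_de, l_do, weights)
  list(segmenter = segmenter, opt = st$opt, breakdown = breakdown)
}

#' One discriminator optimization step (segmenter fixed)
#'
#' Forwards one normal and one glaucoma sample through the frozen
#' segmenter (evaluation mode), then updates both discriminators by one
#' Adam step of the patch BCE with true domain labels (glaucoma = 1).
#'
#' @param segmenter Segmenter model (not modified).
#' @param discs List with `enc` and `out` discriminators.
#' @param batch List with prepared `normal` and `glaucoma` samples.
#' @param opt Adam state for the discriminators.
#' @param lr Learning rate for this step.
#' @param config A [train_config()].
#' @return List with updated `discs`, `opt` and the scalar `l_disc`.
#' @export
discriminator_step <- function(segmenter, discs, batch, opt, lr,
                               config = train_config()) {
  if (is.null(batch$normal) || is.null(batch$glaucoma) ||
      !identical(batch$normal$domain, 0L) ||
      !identical(batch$glaucoma$domain, 1L))
    stop("discriminator step needs one normal and one glaucoma sample")
  # train-mode forwards of the frozen segmenter, so the discriminators
  # see the same batch statistics the segmenter step optimizes against;
  # the returned model (updated running buffers) is discarded --
  # theta_S is untouched
  fn <- segmenter_forward(segmenter, batch$normal$x, batch$normal$shp,
                          train = TRUE)
  fg <- segmenter_forward(segmenter, batch$glaucoma$x, batch$glaucoma$shp,
                          train = TRUE)
  en <- enc_disc_input(fn, config$upsample_encoding)
  eg <- enc_disc_input(fg, config$upsample_encoding)
  losses <- numeric(0)
  grads <- list(enc = NULL, out = NULL)
  inputs <- list(
    enc = list(list(X = en$X, shp = en$shp, z = 0),
               list(X = eg$X, shp = eg$shp, z = 1)),
    out = list(list(X = fn$probs, shp = batch$normal$shp, z = 0),
               list(X = fg$probs, shp = batch$glaucoma$shp, z = 1)))
  for (space in c("enc", "out")) {
    for (inp in inputs[[space]]) {
      fw <- discriminator_forward(discs[[space]], inp$X, inp$shp)
      losses <- c(losses, discriminator_bce_loss(fw$logits, inp$z))
      # factor 1/4: l_disc is the mean of the four BCE terms
      bw <- discriminator_backward(discs[[space]], fw$cache,
                                   discriminator_bce_grad(fw$logits, inp$z) / 4)
      grads[[space]] <- tree_add(grads[[space]], bw$grads)
    }
  }
  params <- list(enc = discs$enc$params, out = discs$out$params)
  st <- adam_step(params, grads, opt, lr,
                  beta1 = config$betas[1], beta2 = config$betas[2])
  discs$enc$params <- st$params$enc
  discs$out$params <- st$params$out
  list(discs = discs, opt = st$opt, l_disc = mean(losses))
}

prepare_dataset <- function(dataset, config) {
  lapply(dataset$samples, function(s) {
    pr <- prepare_sample(s, size = config$image_size,
                         equalize = config$equalize)
    pr$domain <- s$domain_label
    pr$annotated <- isTRUE(s$has_pixel_annotation)
    pr$split <- s$split
    pr$sample_id <- s$sample_id
    pr
  })
}

#' Run the full training procedure
#'
#' @param dataset An `odcseg_dataset` from [generate_dataset()] or
#'   [read_dataset()].
#' @param config A [train_config()].
#' @param weights_override Optional [loss_weights()] fixing the
#'   objective weights for all epochs (used for ablation baselines,
#'   e.g. pixel supervision only); `NULL` uses the two-phase schedule.
#' @param verbose Print per-epoch progress.
#' @return An object of class `odcseg_fit` with the trained
#'   `segmenter`, `discs`, per-epoch `history` (losses and the style
#'   gap of validation predictions to glaucoma ground truth), the
#'   `config` and the count of discriminator updates.
#' @export
run_training <- function(dataset, config = train_config(),
                         weights_override = NULL, verbose = FALSE) {
  prepared <- prepare_dataset(dataset, config)
  ann_pool <- Filter(function(p) p$annotated, prepared)
  if (length(ann_pool) == 0) stop("no pixel-annotated samples in dataset")
  tgt_pool <- Filter(function(p)
    p$domain == 1L && p$split == "target" && !p$annotated, prepared)
  if (length(tgt_pool) == 0)
    tgt_pool <- Filter(function(p) p$domain == 1L && p$split == "target",
                       prepared)
  nrm_pool <- Filter(function(p) p$domain == 0L, prepared)
  val_pool <- Filter(function(p) p$split == "validation", prepared)
  w <- config$base_width
  set.seed(derive_seed(config$seed, "init"))
  segmenter <- build_segmenter(segmenter_spec(base_width = w))
  discs <- NULL; opt_d <- NULL
  use_disc <- config$scenario != 2L && length(nrm_pool) > 0 &&
    is.null(weights_override)
  if (use_disc && config$image_size %% 64L != 0L)
    stop("image_size must be a multiple of 64 for the encoding-space ",
         "discriminator (Up1 feature at 1/8 resolution, patch logits at ",
         "1/64)")
  if (use_disc) {
    discs <- list(enc = build_discriminator(discriminator_spec(4L * w)),
                  out = build_discriminator(discriminator_spec(3L)))
    opt_d <- adam_new(list(enc = discs$enc$params, out = discs$out$params))
  }
  opt_s <- adam_new(segmenter$params)
  n_phase1 <- ceiling(config$phase1_fraction * config$epochs)
  history <- list()
  disc_updates <- 0L
  val_labels <- lapply(val_pool, `[[`, "label")
  for (epoch in seq_len(config$epochs)) {
    phase <- if (epoch <= n_phase1) 1L else 2L
    weights <- if (!is.null(weights_override)) weights_override
      else if (config$scenario == 2L)
        loss_weights(1, config$w_style_phase1, 0, config$w_e, config$w_o)
      else if (phase == 1L)
        loss_weights(1, config$w_style_phase1, 0, config$w_e, config$w_o)
      else if (config$keep_seg_in_phase2)
        loss_weights(1, config$w_style_phase1, 1, config$w_e, config$w_o)
      else
        loss_weights(0, 0, 1, config$w_e, config$w_o)
    lr_s <- config$lr_seg * config$lr_gamma^(epoch - 1)
    lr_d <- config$lr_disc * config$lr_gamma^(epoch - 1)
    set.seed(derive_seed(config$seed, paste0("epoch", epoch)))
    ord_a <- sample(seq_along(ann_pool))
    ord_t <- rep_len(sample(seq_along(tgt_pool)), length(ord_a))
    ord_n <- if (length(nrm_pool) > 0)
      rep_len(sample(seq_along(nrm_pool)), length(ord_a)) else integer(0)
    ep <- c(l_seg = 0, l_style = 0, l_domain = 0, l_disc = 0)
    n_disc_ep <- 0L
    for (i in seq_along(ord_a)) {
      batch <- list(ann = ann_pool[[ord_a[i]]], tgt = tgt_pool[[ord_t[i]]])
      res <- segmenter_step(segmenter, discs, batch, weights, opt_s, lr_s,
                            config)
      segmenter <- res$segmenter; opt_s <- res$opt
      b <- res$breakdown
      ep["l_seg"] <- ep["l_seg"] + b$l_seg
      ep["l_style"] <- ep["l_style"] + b$l_style
      ep["l_domain"] <- ep["l_domain"] +
        weights$w_e * b$l_domain_enc + weights$w_o * b$l_domain_out
      if (phase == 2L && use_disc && is.null(weights_override)) {
        dbatch <- list(normal = nrm_pool[[ord_n[i]]],
                       glaucoma = tgt_pool[[ord_t[i]]])
        dres <- discriminator_step(segmenter, discs, dbatch, opt_d, lr_d,
                                   config)
        discs <- dres$discs; opt_d <- dres$opt
        ep["l_disc"] <- ep["l_disc"] + dres$l_disc
        disc_updates <- disc_updates + 1L
        n_disc_ep <- n_disc_ep + 1L
      }
    }
    n_it <- length(ord_a)
    style_gap_val <- NA_real_
    if (length(val_pool) > 0) {
      gaps <- vapply(seq_along(val_pool), function(j) {
        fv <- segmenter_forward(segmenter, val_pool[[j]]$x,
                                val_pool[[j]]$shp, train = FALSE)
        style_gap_loss(fv$probs, val_labels[[j]], normalize = TRUE)
      }, numeric(1))
      style_gap_val <- mean(gaps)
    }
    history[[epoch]] <- data.frame(
      epoch = epoch, phase = phase,
      l_seg = ep["l_seg"] / n_it, l_style = ep["l_style"] / n_it,
      l_domain = ep["l_domain"] / n_it,
      l_disc = if (n_disc_ep > 0) ep["l_disc"] / n_disc_ep else NA_real_,
      style_gap = style_gap_val, row.names = NULL)
    if (verbose)
      message(sprintf(
        "epoch %3d phase %d  l_seg %.4f l_style %.5f l_domain %.4f style_gap %.5f",
        epoch, phase, history[[epoch]]$l_seg, history[[epoch]]$l_style,
        history[[epoch]]$l_domain, style_gap_val))
  }
  structure(list(segmenter = segmenter, discs = discs,
                 history = do.call(rbind, history), config = config,
                 disc_updates = disc_updates,
                 n_annotated = length(ann_pool), n_target = length(tgt_pool)),
            class = "odcseg_fit")
}
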