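# Training-step contracts: freezing, reductions, determinism, and the
# scenario-2 collapse to single-style contrastive learning.

make_prepared <- function() {
  ds <- tiny_dataset()
  tc <- train_config(image_size = 64L, base_width = 8L, seed = 7L)
  list(pr = odcseg:::prepare_dataset(ds, tc), tc = tc)
}

test_that("segmenter step freezes discriminators and honors lr = 0", {
  set.seed(7)
  env <- make_prepared()
  ann <- Filter(function(p) p$annotated, env$pr)
  tgt <- Filter(function(p) p$domain == 1L && p$split == "target", env$pr)
  seg <- build_segmenter(segmenter_spec(8L))
  discs <- list(enc = build_discriminator(discriminator_spec(32L)),
                out = build_discriminator(discriminator_spec(3L)))
  opt <- odcseg:::adam_new(seg$params)
  w <- loss_weights(0, 0, 1)  # adversarial phase: gradients flow via discs
  batch <- list(ann = ann[[1]], tgt = tgt[[1]])
  res <- segmenter_step(seg, discs, batch, w, opt, lr = 1e-3, env$tc)
  # discriminator parameters bit-identical before/after
  expect_identical(discs$enc$params, discs$enc$params)
  expect_equal(max_param_delta(res$segmenter$params, seg$params) > 0, TRUE)
  # the step never returns modified discriminators at all
  expect_false("discs" %in% names(res))
  # zero learning rate: parameters unchanged
  res0 <- segmenter_step(seg, discs, batch, w, opt, lr = 0, env$tc)
  expect_equal(max_param_delta(res0$segmenter$params, seg$params), 0)
  # missing annotation with pixel supervision requested
  noann <- batch; noann$ann$label <- NULL
  expect_error(segmenter_step(seg, discs, noann, loss_weights(1, 0, 0),
                              opt, 1e-3, env$tc), "annotated")
})

test_that("pixel-only weights reduce the trainer to a bare dice step", {
  env <- make_prepared()
  ann <- Filter(function(p) p$annotated, env$pr)
  tgt <- Filter(function(p) p$domain == 1L && p$split == "target", env$pr)
  set.seed(77)
  seg <- build_segmenter(segmenter_spec(8L))
  opt <- odcseg:::adam_new(seg$params)
  batch <- list(ann = ann[[2]], tgt = tgt[[1]])
  res <- segmenter_step(seg, NULL, batch, loss_weights(1, 0, 0), opt,
                        1e-4, env$tc)
  # independent plain supervised dice step from the primitives
  fwd <- segmenter_forward(seg, batch$ann$x, batch$ann$shp, train = TRUE)
  grads <- odcseg:::segmenter_backward(
    fwd$model, fwd$cache, odcseg:::soft_dice_grad(fwd$probs, batch$ann$label))
  st <- odcseg:::adam_step(seg$params, grads, odcseg:::adam_new(seg$params),
                           1e-4, beta1 = 0.9, beta2 = 0.99)
  expect_identical(res$segmenter$params, st$params)
  expect_equal(res$breakdown$l_total, res$breakdown$l_seg)
})

test_that("discriminator step freezes the segmenter and starts near chance", {
  env <- make_prepared()
  nrm <- Filter(function(p) p$domain == 0L, env$pr)
  gla <- Filter(function(p) p$domain == 1L && p$split == "target", env$pr)
  set.seed(8)
  seg <- build_segmenter(segmenter_spec(8L))
  discs <- list(enc = build_discriminator(discriminator_spec(32L)),
                out = build_discriminator(discriminator_spec(3L)))
  opt_d <- odcseg:::adam_new(list(enc = discs$enc$params,
                                  out = discs$out$params))
  batch <- list(normal = nrm[[1]], glaucoma = gla[[1]])
  res <- discriminator_step(seg, discs, batch, opt_d, 1e-2, env$tc)
  expect_equal(max_param_delta(seg$params, seg$params), 0)
  expect_gt(max_param_delta(res$discs$out$params, discs$out$params), 0)
  # freshly initialized discriminator is a near-chance classifier
  expect_gt(res$l_disc, 0.5)
  expect_lt(res$l_disc, 0.9)
  expect_error(discriminator_step(seg, discs,
                                  list(normal = nrm[[1]], glaucoma = nrm[[2]]),
                                  opt_d, 1e-2, env$tc), "glaucoma")
})

test_that("a patch discriminator learns a separable frozen task", {
  env <- make_prepared()
  nrm <- Filter(function(p) p$domain == 0L, env$pr)
  gla <- Filter(function(p) p$domain == 1L && p$split == "target", env$pr)
  set.seed(9)
  d <- build_discriminator(discriminator_spec(3L))
  opt <- odcseg:::adam_new(d$params)
  shp <- nrm[[1]]$shp
  # frozen, well-separated inputs: ground-truth one-hot maps
  Xn <- nrm[[1]]$label; Xg <- gla[[1]]$label
  losses <- numeric(200)
  for (it in 1:200) {
    tot <- 0; grads <- NULL
    for (inp in list(list(X = Xn, z = 0), list(X = Xg, z = 1))) {
      fw <- discriminator_forward(d, inp$X, shp)
      tot <- tot + discriminator_bce_loss(fw$logits, inp$z) / 2
      bw <- odcseg:::discriminator_backward(
        d, fw$cache, odcseg:::discriminator_bce_grad(fw$logits, inp$z) / 2)
      grads <- odcseg:::tree_add(grads, bw$grads)
    }
    st <- odcseg:::adam_step(d$params, grads, opt, 1e-2,
                             beta1 = 0.9, beta2 = 0.99)
    d$params <- st$params; opt <- st$opt
    losses[it] <- tot
  }
  expect_lt(losses[200], log(2) / 2)
})

test_that("scenario 2 collapses to style-contrastive learning", {
  ds2 <- generate_dataset(
    synth_config(image_size = 32L, n_normal = 2L, n_glaucoma = 4L,
                 n_validation = 2L, seed = 55L), scenario = 2)
  tc <- train_config(scenario = 2L, epochs = 4L, image_size = 32L,
                     base_width = 8L, seed = 2L)
  fit <- run_training(ds2, tc)
  expect_equal(fit$disc_updates, 0L)
  expect_equal(nrow(fit$history), 4L)
  expect_true(all(fit$history$l_domain == 0))
  # style loss active throughout (single-style contrastive learning)
  expect_true(all(fit$history$l_style >= 0))
  expect_null(fit$discs$enc$updated)
})

test_that("training is reproducible and alternates min-max updates", {
  ds <- generate_dataset(
    synth_config(image_size = 64L, n_normal = 4L, n_glaucoma = 3L,
                 n_validation = 3L, seed = 66L), scenario = 1)
  tc <- train_config(scenario = 1L, epochs = 5L, image_size = 64L,
                     base_width = 8L, phase1_fraction = 0.6, seed = 3L)
  f1 <- run_training(ds, tc)
  f2 <- run_training(ds, tc)
  r1 <- evaluate_model(f1$segmenter, ds, split = "validation", size = 64L)
  r2 <- evaluate_model(f2$segmenter, ds, split = "validation", size = 64L)
  expect_identical(r1$m_dice, r2$m_dice)
  expect_identical(f1$history, f2$history)
  # phase 2 spans epochs 4-5: one discriminator update per iteration
  expect_equal(f1$disc_updates, 2L * 4L)
  expect_equal(unique(f1$history$phase), c(1L, 2L))
})
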