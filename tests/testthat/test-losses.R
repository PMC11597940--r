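test_that("soft dice loss matches closed forms", {
  # exact one-hot prediction
  y <- matrix(0, 3, 9); y[cbind(rep(1:3, each = 3), 1:9)] <- 1
  expect_equal(soft_dice_loss(y, y), 0, tolerance = 1e-6)
  # all mass on wrong classes: rotate the channels
  wrong <- y[c(2, 3, 1), ]
  expect_equal(soft_dice_loss(wrong, y), 1, tolerance = 1e-6)
  # uniform prediction against balanced one-hot: per-channel dice term
  # 2*(3/3) / (9/9*... ) -> 0.5, loss 0.5
  u <- matrix(1 / 3, 3, 9)
  expect_equal(soft_dice_loss(u, y), 0.5, tolerance = 1e-6)
  expect_error(soft_dice_loss(u, y[, 1:4]), "shape")
})

test_that("soft dice loss is invariant under spatial permutation", {
  set.seed(42)
  for (i in 1:5) {
    p <- matrix(runif(3 * 20), 3)
    p <- p / rep(colSums(p), each = 3)
    cls <- sample(1:3, 20, TRUE)
    y <- matrix(0, 3, 20); y[cbind(cls, 1:20)] <- 1
    perm <- sample(20)
    expect_equal(soft_dice_loss(p, y),
                 soft_dice_loss(p[, perm], y[, perm]), tolerance = 1e-12)
  }
})

test_that("gram matrix matches definition and brute force", {
  ones <- matrix(1, 2, 4)  # C=2, H=W=2
  expect_equal(unclass(gram_matrix(ones))[1:2, 1:2],
               matrix(4, 2, 2), ignore_attr = TRUE)
  # disjoint channel support -> zero off-diagonals
  f <- rbind(c(1, 2, 0, 0), c(0, 0, 3, 4))
  G <- gram_matrix(f)
  expect_equal(G[1, 2], 0)
  expect_equal(G[2, 1], 0)
  # C = 1: sum of squares
  v <- array(rnorm(12), dim = c(1, 3, 4))
  expect_equal(as.numeric(gram_matrix(v)), sum(v^2))
  # brute-force double loop over channel pairs
  set.seed(7)
  f <- array(rnorm(3 * 5 * 4), dim = c(3, 5, 4))
  G <- unclass(gram_matrix(f))
  for (r in 1:3) for (c_ in 1:3)
    expect_equal(G[r, c_], sum(f[r, , ] * f[c_, , ]), tolerance = 1e-6)
  # symmetry and positive semidefiniteness
  expect_equal(G, t(G), ignore_attr = TRUE)
  expect_true(all(eigen(G, symmetric = TRUE)$values > -1e-8))
})

test_that("style gap loss matches closed forms and is symmetric", {
  a <- matrix(runif(3 * 10), 3)
  expect_equal(style_gap_loss(a, a), 0)
  # Gram_a = I (orthonormal rows), Gram_b = 0 -> (1+0+0+1)/4 = 0.5
  pa <- rbind(c(1, 0), c(0, 1))
  pb <- matrix(0, 2, 2)
  expect_equal(style_gap_loss(pa, pb), 0.5, tolerance = 1e-6)
  b <- matrix(runif(3 * 10), 3)
  expect_equal(style_gap_loss(a, b), style_gap_loss(b, a))
  expect_error(style_gap_loss(a, matrix(0, 2, 10)), "channel")
})

test_that("style gap gradient matches central finite differences", {
  set.seed(11)
  a <- matrix(runif(3 * 16), 3)  # 3 x 4 x 4 map
  b <- matrix(runif(3 * 16), 3)
  g <- odcseg:::style_gap_grad(a, b)
  eps <- 1e-6
  for (i in c(1, 17, 48)) {
    a2 <- a; a2[i] <- a2[i] + eps
    a3 <- a; a3[i] <- a3[i] - eps
    fd <- (style_gap_loss(a2, b) - style_gap_loss(a3, b)) / (2 * eps)
    expect_equal(g$dA[i], fd, tolerance = 1e-4)
  }
})

test_that("discriminator BCE matches closed forms", {
  z <- matrix(0, 1, 16)
  expect_equal(discriminator_bce_loss(z, 0), log(2), tolerance = 1e-6)
  expect_equal(discriminator_bce_loss(z, 1), log(2), tolerance = 1e-6)
  expect_lt(discriminator_bce_loss(z + 20, 1), 1e-6)
  l <- matrix(rnorm(16), 1)
  expect_equal(discriminator_bce_loss(l, 1),
               discriminator_bce_loss(-l, 0), tolerance = 1e-12)
  expect_error(discriminator_bce_loss(l, 2), "0 or 1")
})

test_that("adversarial domain loss matches closed forms and weighting", {
  w <- loss_weights(0, 0, 1, w_e = 0.2, w_o = 0.8)
  z <- matrix(0, 1, 8)
  expect_equal(adversarial_domain_loss(z, z, w), log(2), tolerance = 1e-6)
  expect_lt(adversarial_domain_loss(z + 20, z + 20, w), 1e-6)
  w1 <- loss_weights(0, 0, 1, w_e = 1, w_o = 0)
  enc <- matrix(rnorm(8), 1)
  expect_equal(adversarial_domain_loss(enc, z, w1),
               adversarial_domain_loss(enc, z + 5, w1))
  wbad <- loss_weights(0, 0, 1)
  wbad$w_e <- 0.5  # break the invariant behind the constructor's back
  expect_error(adversarial_domain_loss(z, z, wbad), "sum to 1")
})

test_that("total objective combines components per the weight schedule", {
  w <- loss_weights(1, 0, 0)
  expect_equal(total_objective(0.37, 5, 1, 1, w)$l_total, 0.37)
  w <- loss_weights(0, 0, 1, w_e = 0.2, w_o = 0.8)
  expect_equal(total_objective(9, 9, 1.0, 0.5, w)$l_total, 0.6)
  w <- phase_weights(1)
  expect_equal(total_objective(0.4, 2.0, 0, 0, w)$l_total, 0.5)
  # breakdown invariant
  b <- total_objective(0.1, 0.2, 0.3, 0.4, loss_weights(0.5, 0.3, 0.7))
  expect_equal(b$l_total,
               0.5 * 0.1 + 0.3 * 0.2 + 0.7 * (0.2 * 0.3 + 0.8 * 0.4))
})

test_that("losses are nonnegative and vanish only at coincidence", {
  set.seed(3)
  for (i in 1:10) {
    p <- matrix(runif(3 * 12), 3); p <- p / rep(colSums(p), each = 3)
    cls <- sample(1:3, 12, TRUE)
    y <- matrix(0, 3, 12); y[cbind(cls, 1:12)] <- 1
    expect_gte(soft_dice_loss(p, y), 0)
    q <- matrix(runif(3 * 12), 3)
    expect_gte(style_gap_loss(p, q), 0)
    expect_gte(discriminator_bce_loss(matrix(rnorm(9), 1), 1), 0)
  }
  y <- matrix(0, 3, 12); y[cbind(sample(1:3, 12, TRUE), 1:12)] <- 1
  expect_lt(soft_dice_loss(y, y), 1e-6)
  p2 <- y; p2[, 1] <- c(0.5, 0.5, 0)
  expect_gt(soft_dice_loss(p2, y), 1e-4)
})
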