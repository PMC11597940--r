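test_that("dice coefficient matches hand-counted confusion toys", {
  m <- matrix(0L, 4, 4)
  gt <- m; gt[1:2, 1:4] <- 1L              # 8 positives
  pred <- m; pred[1:2, 1:3] <- 1L; pred[3, 1:2] <- 1L  # TP=6 FP=2 FN=2
  expect_equal(dice_coefficient(pred, gt), 0.75)
  expect_equal(dice_coefficient(gt, gt), 1.0)
  a <- m; a[1, 1] <- 1L
  b <- m; b[4, 4] <- 1L
  expect_equal(dice_coefficient(a, b), 0.0)
  expect_equal(dice_coefficient(m, m), 1.0)  # both empty
  expect_error(dice_coefficient(m, matrix(0L, 3, 3)), "shape")
})

test_that("dice is symmetric and translation invariant", {
  set.seed(5)
  for (i in 1:10) {
    p <- random_nested_masks(24)
    q <- random_nested_masks(24)
    expect_equal(dice_coefficient(p$od, q$od), dice_coefficient(q$od, p$od))
    shift <- function(m) {
      out <- matrix(0L, nrow(m) + 4, ncol(m) + 4)
      out[3:(nrow(m) + 2), 3:(ncol(m) + 2)] <- m
      out
    }
    expect_equal(dice_coefficient(p$od, q$od),
                 dice_coefficient(shift(p$od), shift(q$od)))
  }
})

test_that("extract_cdr measures extents in both directions", {
  n <- 120L
  od <- matrix(0L, n, n); od[11:110, 21:100] <- 1L   # 100 x 80 rectangle
  oc <- matrix(0L, n, n); oc[36:85, 51:70] <- 1L     # 50 x 20, concentric
  cdr <- extract_cdr(od, oc)
  expect_equal(cdr$vertical, 0.5)
  expect_equal(cdr$horizontal, 0.25)
  expect_equal(unlist(extract_cdr(od, od)[c("vertical", "horizontal")]),
               c(vertical = 1, horizontal = 1))
  empty <- matrix(0L, n, n)
  expect_equal(extract_cdr(od, empty)$vertical, 0)
  expect_error(extract_cdr(empty, oc), "empty")
  # padding invariance
  pad <- function(m) {
    out <- matrix(0L, n + 20, n + 20); out[11:(n + 10), 11:(n + 10)] <- m
    out
  }
  expect_equal(extract_cdr(pad(od), pad(oc)), extract_cdr(od, oc))
})

test_that("extract_cdr uses the largest connected component", {
  n <- 60L
  od <- matrix(0L, n, n); od[11:50, 11:50] <- 1L
  oc <- matrix(0L, n, n); oc[21:40, 21:40] <- 1L  # 20 px extent
  oc[1, 1] <- 1L  # stray pixel far away must be ignored
  expect_equal(extract_cdr(od, oc)$vertical, 20 / 40)
})

test_that("cdr_mse averages squared differences in both directions", {
  p1 <- list(vertical = 0.5, horizontal = 0.4)
  g1 <- list(vertical = 0.7, horizontal = 0.5)  # dV=0.2 dH=0.1 -> 0.05
  expect_equal(cdr_mse(list(p1), list(g1)), 0.05)
  expect_equal(cdr_mse(list(g1), list(g1)), 0)
  p2 <- list(vertical = 0.3, horizontal = 0.5)
  g2 <- list(vertical = 0.4, horizontal = 0.5)  # 0.01
  expect_equal(cdr_mse(list(p1, p2), list(g1, g2)), 0.03)
  expect_error(cdr_mse(list(p1), list(g1, g2)), "length")
})

test_that("g_score matches its arithmetic and caps at 50", {
  p <- random_nested_masks(48)
  expect_equal(g_score(p$od, p$oc, p$od, p$oc), 50.0)
  # engineered case: IoU_od = 1, IoU_oc = 0.5, equal vertical CDRs
  n <- 40L
  gt_od <- matrix(0L, n, n); gt_od[11:30, 6:35] <- 1L
  gt_oc <- matrix(0L, n, n); gt_oc[16:25, 11:20] <- 1L
  pr_oc <- matrix(0L, n, n); pr_oc[16:25, 11:15] <- 1L  # half width
  expect_equal(g_score(gt_od, pr_oc, gt_od, gt_oc), (1 + 0.5) / 2 * 50 - 0)
  set.seed(9)
  for (i in 1:10) {
    a <- random_nested_masks(32); b <- random_nested_masks(32)
    expect_lte(g_score(a$od, a$oc, b$od, b$oc), 50)
  }
})

test_that("metrics agree with independent set-operation oracles", {
  set.seed(13)
  for (i in 1:50) {
    a <- random_nested_masks(32)
    b <- random_nested_masks(32)
    expect_equal(dice_coefficient(a$od, b$od), oracle_dice(a$od, b$od),
                 tolerance = 1e-12)
    expect_equal(odcseg:::iou(a$oc, b$oc), oracle_iou(a$oc, b$oc),
                 tolerance = 1e-12)
    ea <- oracle_extent(a$od); ca <- oracle_extent(a$oc)
    cdr <- extract_cdr(a$od, a$oc)
    expect_equal(cdr$vertical, ca[1] / ea[1], tolerance = 1e-12)
    expect_equal(cdr$horizontal, ca[2] / ea[2], tolerance = 1e-12)
    # G-score against the formula assembled from oracles
    ov <- (oracle_iou(a$od, b$od) + oracle_iou(a$oc, b$oc)) / 2
    vg <- oracle_extent(b$oc)[1] / oracle_extent(b$od)[1]
    vp <- oracle_extent(a$oc)[1] / oracle_extent(a$od)[1]
    expect_equal(g_score(a$od, a$oc, b$od, b$oc),
                 ov * 50 - abs(vp - vg) / vg * 100, tolerance = 1e-12)
  }
})

test_that("cdr components stay in [0,1] for nested masks", {
  set.seed(17)
  for (i in 1:20) {
    m <- random_nested_masks(28)
    cdr <- extract_cdr(m$od, m$oc)
    expect_gte(cdr$vertical, 0); expect_lte(cdr$vertical, 1)
    expect_gte(cdr$horizontal, 0); expect_lte(cdr$horizontal, 1)
  }
})

test_that("evaluate_model reduces to per-sample means and honors oracles", {
  ds <- tiny_dataset()
  oracle <- function(pr) pr$label
  rep <- evaluate_model(oracle, ds, split = "validation")
  expect_equal(rep$m_dice, 1.0)
  expect_equal(rep$cdr_mse, 0.0)
  expect_equal(rep$g_score, 50.0)
  # constant all-background predictor
  bg <- function(pr) {
    p <- matrix(0, 3, ncol(pr$label)); p[1, ] <- 1; p
  }
  rep0 <- evaluate_model(bg, ds, split = "validation")
  expect_equal(rep0$dice_od, 0)
  expect_equal(rep0$dice_oc, 0)
  # summary equals the unweighted mean of per-sample metrics
  expect_equal(rep0$dice_od, mean(rep0$per_sample$dice_od))
  expect_equal(rep0$g_score, mean(rep0$per_sample$g))
  expect_error(evaluate_model(oracle, list()), "empty")
})
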