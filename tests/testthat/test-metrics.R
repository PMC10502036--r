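test_that("dice loss closed forms", {
  n <- 16
  ones <- rep(1, n)
  expect_equal(dice_loss(ones, ones, eps = 1), 1 - 2 * n / (2 * n + 1))
  expect_equal(dice_loss(ones, rep(0, n)), 1, tolerance = 1e-6)
  expect_equal(dice_loss(c(1, 0, 1, 0), c(1, 1, 0, 0), eps = 0), 0.5)
  # empty-empty with positive eps is zero loss
  expect_equal(dice_loss(rep(0, 4), rep(0, 4), eps = 1), 1)
  expect_equal(dice_loss(rep(0, 4), rep(0, 4), eps = 0), 0)
})

test_that("bce loss closed forms and clamping", {
  y <- c(1, 0, 1, 0)
  expect_equal(bce_loss(y, rep(0.5, 4)), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(y, y), 1e-6)
  expect_equal(bce_loss(1, 0.75), -log(0.75), tolerance = 1e-12)
  expect_true(is.finite(bce_loss(c(1, 0), c(0, 1))))
  # the printed variant differs on background pixels
  expect_equal(bce_loss(0, 0.5, printed_form = TRUE), -log(1 - 0.25),
               tolerance = 1e-12)
})

test_that("total loss is the sum of its parts and nonnegative", {
  set.seed(1)
  p <- rand_mask_pair()
  expect_equal(total_loss(p$y, p$y_hat),
               dice_loss(p$y, p$y_hat) + bce_loss(p$y, p$y_hat))
  expect_gte(total_loss(p$y, p$y_hat), 0)
})

test_that("thresholded overlap metrics count pixels correctly", {
  id <- matrix(c(1, 0, 0, 1), 2, 2)
  r <- dice_iou_mae(id, id)
  expect_equal(unlist(r), c(dice = 1, iou = 1, mae = 0))
  comp <- dice_iou_mae(id, 1 - id)
  expect_equal(unlist(comp), c(dice = 0, iou = 0, mae = 1))
  y <- matrix(c(1, 0, 1, 0), 2, 2)      # [[1,1],[0,0]]
  yh <- matrix(c(1, 1, 0, 0), 2, 2)     # [[1,0],[1,0]]
  r <- dice_iou_mae(y, yh)
  expect_equal(r$dice, 0.5)
  expect_equal(r$iou, 1 / 3)
  expect_equal(r$mae, 0.5)
  # empty-empty convention
  z <- matrix(0, 2, 2)
  expect_equal(dice_iou_mae(z, z)$dice, 1)
  expect_equal(dice_iou_mae(z, z)$iou, 1)
})

test_that("dice and iou satisfy their algebraic identity on random binary pairs", {
  set.seed(42)
  for (rep in 1:1000) {
    y <- matrix(rbinom(16, 1, runif(1, 0.1, 0.9)), 4, 4)
    b <- matrix(rbinom(16, 1, runif(1, 0.1, 0.9)), 4, 4)
    r <- dice_iou_mae(y, b + 0)
    expect_true(r$iou <= r$dice + 1e-12 && r$dice <= 1)
    expect_equal(r$dice, 2 * r$iou / (1 + r$iou), tolerance = 1e-12)
  }
})

test_that("dice equals one minus dice loss for binary predictions as eps -> 0", {
  set.seed(9)
  y <- matrix(rbinom(36, 1, 0.5), 6, 6)
  b <- matrix(rbinom(36, 1, 0.5), 6, 6)
  if (sum(y) + sum(b) > 0) {
    expect_equal(dice_iou_mae(y, b + 0)$dice, 1 - dice_loss(y, b, eps = 0),
                 tolerance = 1e-12)
  }
})

test_that("saliency-style metrics match their scalar-loop oracles on 8x8 pairs", {
  set.seed(77)
  for (rep in 1:4) {
    p <- rand_mask_pair(8, 8, p_fg = runif(1, 0.2, 0.6))
    expect_lt(abs(weighted_fbeta(p$y, p$y_hat) - oracle_wfb(p$y, p$y_hat)),
              1e-6)
    expect_lt(abs(s_measure(p$y, p$y_hat) - oracle_sm(p$y, p$y_hat)), 1e-6)
    expect_lt(abs(e_measure(p$y, p$y_hat) - oracle_em(p$y, p$y_hat)), 1e-6)
  }
})

test_that("perfect predictions score 1, inverted predictions score near 0", {
  y <- matrix(0, 8, 8); y[3:6, 3:6] <- 1
  expect_equal(weighted_fbeta(y, y), 1, tolerance = 1e-9)
  expect_gt(s_measure(y, y), 0.97)
  expect_equal(e_measure(y, y), 1)
  half <- matrix(0, 8, 8); half[, 1:4] <- 1
  inv <- 1 - half
  # on tiny images the Gaussian's zero padding softens the border errors,
  # so "near 0" is bounded loosely; the ordering against a perfect
  # prediction is what matters
  expect_lt(weighted_fbeta(half, inv), 0.3)
  expect_lt(s_measure(half, inv), 0.25)
  expect_lt(e_measure(half, inv), 0.3)
  expect_gt(weighted_fbeta(half, half), 0.99)
})

test_that("degenerate ground truths fall back to the inverse-prediction mean", {
  z <- matrix(0, 6, 6)
  yh <- matrix(runif(36), 6, 6)
  expect_equal(weighted_fbeta(z, yh), 1 - mean(yh))
  expect_equal(s_measure(z, yh), 1 - mean(yh))
  full <- matrix(1, 6, 6)
  expect_equal(s_measure(full, yh), mean(yh))
})

test_that("metrics are invariant to a simultaneous horizontal flip", {
  set.seed(13)
  p <- rand_mask_pair(8, 8)
  fl <- function(m) m[, rev(seq_len(ncol(m)))]
  a <- metrics_report(p$y, p$y_hat)
  b <- metrics_report(fl(p$y), fl(p$y_hat))
  for (k in c("m_dice", "m_iou", "e_measure", "mae")) {
    expect_equal(a[[k]], b[[k]], tolerance = 1e-9, label = k)
  }
  # the weighted F-measure's nearest-foreground assignment breaks distance
  # ties by pixel order, so flipping is invariant only up to tie effects
  expect_equal(a$w_fbeta, b$w_fbeta, tolerance = 2e-2)
  # MAE symmetry and report ranges
  expect_equal(mean(abs(p$y - p$y_hat)), mean(abs(p$y_hat - p$y)))
  expect_true(all(unlist(a) >= 0 & unlist(a) <= 1))
})

test_that("folder scorer matches direct metric computation", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "pred")); dir.create(file.path(root, "mask"))
  set.seed(31)
  y <- matrix(0, 16, 16); y[5:12, 4:10] <- 1
  yh <- pmin(pmax(y + matrix(rnorm(256, sd = 0.2), 16, 16), 0), 1)
  png::writePNG(yh, file.path(root, "pred", "a.png"))
  png::writePNG(y, file.path(root, "mask", "a.png"))
  got <- score_folders(file.path(root, "pred"), file.path(root, "mask"))
  # PNG storage quantizes to 8 bits; compare against the quantized pair
  yq <- png::readPNG(file.path(root, "pred", "a.png"))
  direct <- metrics_report(y, yq)
  expect_equal(got$mean$m_dice, direct$m_dice, tolerance = 1e-9)
  expect_equal(got$mean$w_fbeta, direct$w_fbeta, tolerance = 1e-9)
})
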