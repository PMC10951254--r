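probs_of <- function(p_vessel) {
  # build an (H,W,2) probability array from a vessel-probability matrix
  array(c(1 - p_vessel, p_vessel), c(nrow(p_vessel), ncol(p_vessel), 2))
}

test_that("weighted cross-entropy closed forms", {
  H <- 4; W <- 4
  y <- matrix(0, H, W); y[2, 2] <- 1
  # perfect prediction -> 0
  perfect <- probs_of(y)
  expect_equal(weighted_ce(perfect, y, c(1, 20))$mean, 0, tolerance = 1e-6)
  # uniform prediction, unit weights -> ln 2 per pixel
  half <- probs_of(matrix(0.5, H, W))
  wc <- weighted_ce(half, y, c(1, 1))
  expect_equal(wc$mean, log(2), tolerance = 1e-12)
  expect_true(all(abs(wc$per_pixel - log(2)) < 1e-12))
})

test_that("weighted cross-entropy matches hand summation on a 2x2 toy", {
  pv <- matrix(c(0.9, 0.2, 0.6, 0.3), 2, 2)
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  # hand: vessel pixels weight 20, -20*log(p_v); background -log(1 - p_v)
  hand <- c(-20 * log(0.9), -log(1 - 0.2), -20 * log(0.6), -log(1 - 0.3))
  wc <- weighted_ce(probs_of(pv), y, c(1, 20))
  expect_equal(as.vector(wc$per_pixel), hand, tolerance = 1e-12)
  expect_equal(wc$mean, mean(hand), tolerance = 1e-12)
})

test_that("focal loss closed forms", {
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(focal_loss(probs_of(y), y), 0, tolerance = 1e-5)
  # gamma = 0, alpha = 1 reduces exactly to weighted cross-entropy
  pv <- matrix(c(0.7, 0.4, 0.2, 0.8), 2, 2)
  p0 <- focal_loss_params(alpha = 1, gamma = 0, class_weights = c(1, 20))
  expect_equal(focal_loss(probs_of(pv), y, p0),
               weighted_ce(probs_of(pv), y, c(1, 20))$mean, tolerance = 1e-12)
  # single vessel pixel, p_t = 0.75, alpha .8, gamma 2, w 20:
  # 0.8 * 0.25^2 * 20 * (-ln 0.75) = 0.2876821...
  p1 <- matrix(0.75, 1, 1)
  expect_equal(focal_loss(probs_of(p1), matrix(1, 1, 1), focal_loss_params()),
               0.8 * 0.25^2 * 20 * (-log(0.75)), tolerance = 1e-12)
  expect_equal(focal_loss(probs_of(p1), matrix(1, 1, 1), focal_loss_params()),
               0.2876821, tolerance = 1e-6)
})

test_that("focal loss is monotone decreasing in p_t and bounded below by 0", {
  y <- matrix(1, 1, 1)
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, function(p) focal_loss(probs_of(matrix(p, 1, 1)), y), 0)
  expect_true(all(diff(ls) < 0))
  expect_true(all(ls >= 0))
})

test_that("literal scalar-modulated reading is available and finite", {
  pv <- matrix(c(0.7, 0.4, 0.2, 0.8), 2, 2)
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  prm <- focal_loss_params(class_weights = c(1, 1))
  wce <- weighted_ce(probs_of(pv), y, c(1, 1))$mean
  lit <- focal_loss(probs_of(pv), y, prm, literal = TRUE)
  expect_equal(lit, -prm$alpha * (1 - wce)^2 * log(wce), tolerance = 1e-12)
})

test_that("focal loss gradient matches finite differences", {
  set.seed(4)
  z <- array(rnorm(6 * 5 * 2 * 2), c(6, 5, 2, 2))
  y <- array(rbinom(60, 1, 0.3), c(6, 5, 2))
  prm <- focal_loss_params()
  ana <- angioseg:::focal_loss_grad(z, y, prm)
  f <- function(zz) focal_loss(angioseg:::softmax_channels(zz), y, prm)
  num <- fd_grad(f, z, eps = 1e-6)
  expect_lt(max(abs(ana - num)), 1e-6)
})

test_that("dice score identities and symmetry", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  expect_equal(dice_score(a, a), 1)
  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  expect_equal(dice_score(a, b), 0)
  # |X| = 4, |Y| = 4, overlap 2 -> 0.5
  c1 <- matrix(0, 4, 4); c1[1, 1:4] <- 1
  c2 <- matrix(0, 4, 4); c2[1, 3:4] <- 1; c2[2, 1:2] <- 1
  expect_equal(dice_score(c1, c2), 0.5)
  expect_equal(dice_score(c2, c1), 0.5)
  # both empty -> 1
  expect_equal(dice_score(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(dice_score(matrix(0, 3, 3), matrix(0, 4, 4)), "shape")
})

test_that("confusion metrics on a constructed 4x4 grid", {
  truth <- matrix(0, 4, 4); pred <- matrix(0, 4, 4)
  truth[1, 1:4] <- 1            # 4 vessel pixels
  pred[1, 1:2] <- 1             # TP = 2, FN = 2
  pred[2, 1] <- 1               # FP = 1 -> TN = 11
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$specificity, 11 / 12)
  expect_equal(cm$accuracy, 13 / 16)
  expect_equal(cm$precision, 2 / 3)
  # identity and total-disagreement cases
  cm1 <- confusion_metrics(truth, truth)
  expect_equal(unlist(cm1[1:4]), c(sensitivity = 1, specificity = 1,
                                   accuracy = 1, precision = 1))
  cm0 <- confusion_metrics(1 - truth, truth)
  expect_equal(cm0$sensitivity, 0)
  expect_equal(cm0$specificity, 0)
  expect_equal(cm0$accuracy, 0)
  # zero denominators are flagged NA
  cme <- confusion_metrics(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(is.na(cme$sensitivity))
  expect_true(is.na(cme$precision))
  expect_equal(cme$accuracy, 1)
})

test_that("confusion metrics agree with brute-force counting on random masks", {
  set.seed(99)
  for (trial in 1:100) {
    pred <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    truth <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    cm <- confusion_metrics(pred, truth)
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in 1:16) for (j in 1:16) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
      else if (pred[i, j] == 1) fp <- fp + 1
      else if (truth[i, j] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(cm$sensitivity, tp / (tp + fn))
    expect_equal(cm$specificity, tn / (tn + fp))
    expect_equal(cm$accuracy, (tp + tn) / 256)
    expect_equal(cm$precision, tp / (tp + fp))
    expect_equal(dice_score(pred, truth), 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("AUC: worked example, separation, ties, null, and cross-check", {
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc_score(c(0.5, 0.5, 0.5, 0.5), c(0, 1, 0, 1)), 0.5)
  set.seed(12)
  sc <- runif(4000); lb <- rbinom(4000, 1, 0.5)
  expect_equal(auc_score(sc, lb), 0.5, tolerance = 0.05)
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(5)
  sc <- c(rnorm(40), rnorm(40, 1)); lb <- rep(c(0, 1), each = 40)
  expect_equal(auc_score(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("metrics report aggregates match hand computation on a 3-image fixture", {
  set.seed(8)
  preds <- lapply(1:3, function(i) matrix(rbinom(64, 1, 0.4), 8, 8))
  truths <- lapply(1:3, function(i) matrix(rbinom(64, 1, 0.4), 8, 8))
  rep <- metrics_report(preds, truths)
  dices <- vapply(1:3, function(i) dice_score(preds[[i]], truths[[i]]), 0)
  expect_equal(rep$per_image$dice, dices)
  agg <- rep$aggregate
  expect_equal(agg$mean[agg$metric == "dice"], mean(dices))
  expect_equal(agg$sd[agg$metric == "dice"], sd(dices))
  lo <- vapply(agg$metric, function(m) min(rep$per_image[[m]], na.rm = TRUE), 0)
  hi <- vapply(agg$metric, function(m) max(rep$per_image[[m]], na.rm = TRUE), 0)
  expect_true(all(agg$mean >= lo - 1e-12 & agg$mean <= hi + 1e-12))
  # report writing round-trips
  tf <- tempfile(fileext = ".json"); tc <- tempfile(fileext = ".csv")
  write_metrics_report(rep, tf, tc)
  expect_true(file.exists(tf) && file.exists(tc))
  back <- utils::read.csv(tc)
  expect_equal(nrow(back), 4)  # 3 images + aggregate row
})
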