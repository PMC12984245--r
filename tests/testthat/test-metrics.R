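test_that("DSC handles identity, disjoint, partial overlap and empties", {
  a <- disc_mask(40, 40, 20, 20, 10)
  expect_equal(dsc(a, a), 100)
  b <- matrix(0L, 40, 40)
  expect_equal(dsc(a, b), 0)
  expect_equal(dsc(b, b), 100)
  # |A| = |B| = 100, overlap 50 -> 50%
  m1 <- matrix(0L, 20, 20); m1[1:10, 1:10] <- 1L
  m2 <- matrix(0L, 20, 20); m2[1:10, 6:15] <- 1L
  expect_equal(dsc(m1, m2), 50)
})

test_that("DSC is monotone in overlap for fixed mask sizes", {
  m1 <- matrix(0L, 20, 30); m1[5:14, 1:10] <- 1L
  prev <- -1
  for (shift in c(8, 6, 4, 2, 0)) {
    m2 <- matrix(0L, 20, 30); m2[5:14, (1 + shift):(10 + shift)] <- 1L
    cur <- dsc(m1, m2)
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("ASSD matches a brute-force all-pairs oracle", {
  sq1 <- matrix(0L, 40, 40); sq1[11:30, 11:30] <- 1L  # half-width 10
  sq2 <- matrix(0L, 40, 40); sq2[9:32, 9:32] <- 1L    # half-width 12
  expect_equal(assd(sq1, sq1), 0)
  expect_equal(assd(sq1, sq2), assd_bruteforce(sq1, sq2), tolerance = 1e-9)
  expect_equal(assd(sq1, sq2), assd(sq2, sq1))        # symmetry
  tr <- matrix(0L, 40, 40); tr[12:31, 11:30] <- 1L    # 1 px translation
  expect_equal(assd(sq1, tr), assd_bruteforce(sq1, tr), tolerance = 1e-9)
  # a 1-px shift displaces only the leading/trailing edges; the lateral
  # edges still meet boundary pixels at distance 0, so the symmetric
  # mean sits near 0.5 (confirmed by the all-pairs oracle above)
  expect_lt(assd(sq1, tr), 1)
  expect_gt(assd(sq1, tr), 0.25)
  withr::with_seed(7, {
    r1 <- cortexfuse:::mask_dilate(random_mask(30, 30, 0.02), 2)
    r2 <- cortexfuse:::mask_dilate(random_mask(30, 30, 0.02), 2)
    expect_equal(assd(r1, r2), assd_bruteforce(r1, r2), tolerance = 1e-9)
  })
  expect_error(assd(sq1, matrix(0L, 40, 40)), "empty")
})

test_that("VHR, VER, DSC and confusion matrices match set-intersection oracles", {
  withr::with_seed(42, {
    for (trial in 1:100) {
      mask <- random_mask(50, 50, runif(1, 0.05, 0.5))
      gt <- matrix(sample(0:4, 2500, replace = TRUE,
                          prob = c(0.5, 0.2, 0.1, 0.1, 0.1)), 50, 50)
      av <- gt == 3
      if (sum(av) == 0 || sum(mask) == 0) next
      expect_equal(vhr(mask, gt),
                   100 * sum(mask == 1 & av) / sum(av))
      expect_equal(ver(mask, gt),
                   100 * sum(mask == 1 & (gt == 1 | gt == 2)) / sum(mask))
      ref <- random_mask(50, 50, 0.3)
      expect_equal(dsc(mask, ref),
                   200 * sum(mask & ref) / (sum(mask) + sum(ref)))
    }
  })
})

test_that("confusion matrix rows are the true classes and sum to 100", {
  withr::with_seed(3, {
    gt <- matrix(sample(0:4, 400, replace = TRUE), 20, 20)
    pred <- matrix(sample(1:4, 400, replace = TRUE), 20, 20)
  })
  cm <- confusion_matrix(pred, gt)
  lab <- gt > 0
  expect_equal(unname(rowSums(cm)), rep(100, 4), tolerance = 1e-6)
  # hand count one cell: true healthy predicted tumor
  expect_equal(cm["H", "T"],
               100 * sum(gt == 1 & pred == 2) / sum(gt == 1))
  # perfect map -> identity x 100
  expect_equal(unname(confusion_matrix(gt, gt)), diag(4) * 100)
  # de-normalized diagonal mean equals pixel accuracy
  cmc <- confusion_matrix(pred, gt, row_normalize = FALSE)
  expect_equal(sum(diag(cmc)) / sum(cmc), mean(pred[lab] == gt[lab]))
})

test_that("F1 follows the printed formula and skips absent classes", {
  # TP = 8, FP = 4, FN = 2 -> F1 = 16 / 22 = 72.73
  gt <- matrix(0L, 10, 10)
  pred <- matrix(0L, 10, 10)
  gt[1:10] <- 1L; pred[1:8] <- 1L          # 8 TP, 2 FN
  gt[11:14] <- 2L; pred[11:14] <- 1L       # 4 FP for class 1
  r <- f1_per_class(pred, gt, classes = 1:2)
  expect_equal(unname(r$f1["1"]), 100 * 2 * 8 / (2 * 8 + 4 + 2),
               tolerance = 1e-9)
  gt2 <- matrix(c(1L, 1L, 3L, 0L), 2, 2)
  r2 <- f1_per_class(gt2, gt2)
  expect_true(is.na(r2$f1["2"]))           # absent class
  expect_equal(unname(r2$f1["1"]), 100)
})

test_that("AUC equals the rank statistic and is ~50 for random scores", {
  withr::with_seed(11, {
    gt <- matrix(sample(c(1L, 2L), 400, replace = TRUE), 20, 20)
    probs <- array(runif(400 * 4), c(20, 20, 4))
    aucs <- replicate(10, {
      p <- array(runif(400 * 4), c(20, 20, 4))
      auc_per_class(p, gt)["1"]
    })
    expect_equal(mean(aucs), 50, tolerance = 5)
    # perfect separation -> 100
    p2 <- array(0, c(20, 20, 4))
    p2[, , 1] <- (gt == 1) * 1
    expect_equal(unname(auc_per_class(p2, gt)["1"]), 100)
  })
})

test_that("per-patient aggregation averages classes then patients", {
  p1 <- c("1" = 50, "2" = 70)
  p2 <- c("1" = 80, "2" = 80)
  agg <- aggregate_metrics(list(p1, p2))
  expect_equal(agg$mean, 70)
  expect_equal(agg$sd, sd(c(60, 80)))
  # two patients with class means 60 and 80 -> 70 +/- 14.14
  expect_equal(agg$sd, 14.14, tolerance = 0.01)
  # NA class excluded from that patient only
  agg2 <- aggregate_metrics(list(c("1" = 60, "2" = NA), c("1" = 80, "2" = 80)))
  expect_equal(agg2$per_patient, c(60, 80), ignore_attr = TRUE)
  expect_equal(aggregate_metrics(list(p1))$sd, 0)
})

test_that("percentile ranking selects images nearest 5/50/95 percentiles", {
  withr::with_seed(5, {
    tab <- matrix(runif(21 * 3, 50, 100), 21, 3)
  })
  sel <- percentile_rank(tab)
  avg <- rowMeans(tab)
  qs <- quantile(avg, c(0.05, 0.5, 0.95), names = FALSE)  # sorted oracle
  for (i in 1:3)
    expect_equal(abs(avg[sel[i]] - qs[i]), min(abs(avg - qs[i])))
  expect_length(unique(sel), 3)
  expect_error(percentile_rank(tab[1:2, ]), "3 images")
})
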