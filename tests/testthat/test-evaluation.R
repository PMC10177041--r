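tax <- build_default_taxonomy()

test_that("confusion counts pixels and skips unannotated ones", {
  true <- matrix(c(0L, 1L, 2L, 255L), 2, 2)
  pred <- matrix(c(0L, 1L, 0L, 5L), 2, 2)
  cm <- confusion(true, pred, tax)
  expect_equal(sum(cm), 3)
  expect_equal(cm[1, 1], 1L)
  expect_equal(cm[2, 2], 1L)
  expect_equal(cm[3, 1], 1L)

  # perfect prediction: diagonal with trace = n annotated
  set.seed(40)
  t2 <- matrix(sample(c(0:14, 255L), 100, TRUE), 10, 10)
  cm2 <- confusion(t2, t2, tax)
  expect_equal(sum(diag(cm2)), sum(t2 != 255L))
  expect_equal(sum(cm2) - sum(diag(cm2)), 0)

  # single systematic error: one off-diagonal cell
  t3 <- matrix(2L, 4, 4)
  p3 <- matrix(7L, 4, 4)
  cm3 <- confusion(t3, p3, tax)
  expect_equal(cm3[3, 8], 16L)
  expect_equal(sum(cm3), 16)

  expect_error(confusion(t3, matrix(0L, 3, 3), tax), "shapes differ")
})

test_that("confusion equals a per-pixel tally oracle on random masks", {
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(20:80, 1)
    true <- matrix(sample(c(0:14, 255L), n, TRUE), 1, n)
    pred <- matrix(sample(0:14, n, TRUE), 1, n)
    got <- confusion(true, pred, tax)
    want <- confusion_oracle(as.vector(true), as.vector(pred), 15)
    expect_identical(unname(unclass(got)), unclass(want))
  }
})

test_that("row normalization yields recall on the diagonal", {
  cm <- matrix(0L, 15, 15)
  cm[1, 1] <- 50L
  cm[1, 2] <- 50L
  cm[2, 2] <- 10L
  fr <- row_normalize(cm)
  expect_equal(fr[1, 1:2], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(fr[2, 2], 1)
  expect_true(all(is.na(fr[3, ])))
  rs <- rowSums(fr)[1:2]
  expect_lt(max(abs(rs - 1)), 1e-9)
})

test_that("class metrics implement the TP/FP/FN definitions", {
  cm <- matrix(0L, 15, 15)
  # class 0: TP 6816, FN 284 (recall .96), FP 2784 (precision .71)
  cm[1, 1] <- 6816L
  cm[1, 2] <- 284L
  cm[2, 1] <- 2784L
  m <- class_metrics(cm, 0L)
  expect_equal(unname(m["precision"]), 0.71, tolerance = 1e-12)
  expect_equal(unname(m["recall"]), 0.96, tolerance = 1e-12)
  expect_equal(renalseg:::round_half_up(unname(m["dice"]), 2), 0.82)

  cm2 <- matrix(0L, 15, 15)
  cm2[5, 5] <- 42L
  expect_equal(unname(class_metrics(cm2, 4L)), c(1, 1, 1))
  # absent class: all three undefined, not zero
  expect_true(all(is.na(class_metrics(cm2, 7L))))

  cm3 <- matrix(0L, 15, 15)
  cm3[1, 1] <- 30L
  cm3[2, 1] <- 10L  # FP for class 0
  cm3[1, 2] <- 20L  # FN for class 0
  m3 <- class_metrics(cm3, 0L)
  expect_equal(unname(m3), c(0.75, 0.6, 2 / 3), tolerance = 1e-12)
})

test_that("pooled metrics micro-average and reduce to accuracy", {
  set.seed(42)
  cm <- matrix(sample(0:50, 225, TRUE), 15, 15)
  all_m <- pooled_metrics(cm, 0:14)
  acc <- sum(diag(cm)) / sum(cm)
  expect_equal(unname(all_m), rep(acc, 3), tolerance = 1e-15)

  one <- pooled_metrics(cm, 3L)
  expect_equal(one, class_metrics(cm, 3L))

  for (rep in 1:50) {
    ids <- sample(0:14, sample(2:8, 1))
    expect_equal(unname(pooled_metrics(cm, ids)),
                 unname(pooled_oracle(cm, ids)), tolerance = 1e-12)
  }
  expect_error(pooled_metrics(cm, integer(0)), "empty")
})

test_that("metric tables render, cross-check, and flag undefined rows", {
  set.seed(43)
  truth <- matrix(sample(0:13, 400, TRUE), 20, 20)  # class 14 absent
  pred <- truth
  flip <- sample(400, 60)
  pred[flip] <- (pred[flip] + 1L) %% 14L
  cm <- confusion(truth, pred, tax)
  dir <- withr::local_tempdir()
  tab <- report(cm, tax, dir)
  expect_equal(nrow(tab), 18)
  expect_true(all(file.exists(file.path(
    dir, c("metrics.csv", "metrics.json", "metrics_display.csv",
           "confusion.png")))))
  # cross-check every row against independent recomputation
  for (cid in 0:14) {
    m <- class_metrics(cm, cid)
    row <- tab[tab$tissue == class_name(tax, cid), ]
    expect_equal(row$dice, unname(m["dice"]))
  }
  ov <- tab[tab$tissue == "overall", ]
  expect_equal(ov$precision, sum(diag(cm)) / sum(cm))
  disp <- read.csv(file.path(dir, "metrics_display.csv"))
  expect_equal(disp$dice[disp$tissue == class_name(tax, 14L)], "undefined")

  # fully correct predictions render Dice 1.00 everywhere defined
  cm_perf <- confusion(truth, truth, tax)
  tab_perf <- report(cm_perf, tax)
  expect_true(all(tab_perf$dice[!is.na(tab_perf$dice)] == 1))
})

test_that("permuting class ids permutes the metrics consistently", {
  set.seed(44)
  cm <- matrix(sample(0:30, 225, TRUE), 15, 15)
  perm <- sample(15)
  cmp <- cm[perm, perm]
  for (cid in 0:14) {
    expect_equal(class_metrics(cmp, which(perm == cid + 1) - 1L),
                 class_metrics(cm, cid))
  }
})

test_that("display rounding is half-up at 2 decimals", {
  expect_equal(renalseg:::round_half_up(0.825, 2), 0.83)
  expect_equal(renalseg:::round_half_up(0.8649, 2), 0.86)
  expect_equal(renalseg:::round_half_up(0.365, 2), 0.37)
})
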