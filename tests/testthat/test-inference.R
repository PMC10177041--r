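test_that("tiling plans partition the image into tile interiors", {
  p1 <- plan_tiles(c(412, 412), 412, 0)
  expect_equal(nrow(p1$tiles), 1)

  p2 <- plan_tiles(c(824, 412), 412, 0)
  expect_equal(nrow(p2$tiles), 2)

  set.seed(30)
  for (rep in 1:20) {
    H <- sample(10:200, 1)
    W <- sample(10:200, 1)
    ov <- sample(0:8, 1)
    ts <- sample((2 * ov + 1):64, 1)
    plan <- plan_tiles(c(H, W), ts, ov)
    cover <- matrix(0L, H, W)
    for (i in seq_len(nrow(plan$tiles))) {
      tl <- plan$tiles[i, ]
      cover[tl$y0:tl$y1, tl$x0:tl$x1] <- cover[tl$y0:tl$y1, tl$x0:tl$x1] + 1L
    }
    expect_true(all(cover == 1L))
  }
  expect_error(plan_tiles(c(64, 64), 8, 8))
})

test_that("stitched prediction with stub models behaves per-pixel", {
  K <- 5
  # constant simplex output regardless of input
  const_fn <- function(px) {
    d <- dim(px)
    v <- c(0.5, 0.2, 0.1, 0.1, 0.1)
    array(rep(v, each = d[1] * d[2]), c(d[1], d[2], K))
  }
  m <- stub_model(const_fn)
  img <- array(runif(50 * 70 * 3), c(50, 70, 3))
  plan <- plan_tiles(c(50, 70), 16, 2)
  pm <- predict_map(m, img, plan, 0.5, "c", "stub")
  expect_equal(dim(pm$values), c(50, 70, K))
  expect_true(all(abs(pm$values[, , 1] - 0.5) < 1e-12))
  expect_true(all(decode(pm) == 0L))

  # one-hot of class 3 everywhere
  onehot_fn <- function(px) {
    d <- dim(px)
    out <- array(0, c(d[1], d[2], K))
    out[, , 4] <- 1
    out
  }
  pm2 <- predict_map(stub_model(onehot_fn), img, plan)
  expect_true(all(decode(pm2) == 3L))

  # non-simplex output violates the contract
  bad_fn <- function(px) array(0.3, c(dim(px)[1], dim(px)[2], K))
  expect_error(predict_map(stub_model(bad_fn), img, plan), "simplex")
})

test_that("overlap size does not change stitched output away from borders", {
  K <- 3
  # 3x3 box-mean per channel: a pure function of the 3x3 neighborhood
  box_fn <- function(px) {
    d <- dim(px)
    pad <- function(m) m[c(1, 1:d[1], d[1]), c(1, 1:d[2], d[2])]
    out <- array(0, c(d[1], d[2], K))
    for (k in 1:K) {
      m <- pad(px[, , k])
      s <- matrix(0, d[1], d[2])
      for (dy in 0:2) for (dx in 0:2) {
        s <- s + m[dy + 1:d[1], dx + 1:d[2]]
      }
      out[, , k] <- s / 9
    }
    sums <- out[, , 1] + out[, , 2] + out[, , 3]
    for (k in 1:K) out[, , k] <- out[, , k] / sums
    out
  }
  set.seed(31)
  img <- array(runif(40 * 40 * 3, 0.2, 0.8), c(40, 40, 3))
  m <- stub_model(box_fn)
  pm0 <- predict_map(m, img, plan_tiles(c(40, 40), 40, 0))
  pm16 <- predict_map(m, img, plan_tiles(c(40, 40), 20, 4))
  inner <- 2:39
  expect_equal(pm16$values[inner, inner, ], pm0$values[inner, inner, ],
               tolerance = 1e-10)
})

test_that("stitching is independent of tile traversal order", {
  K <- 4
  fn <- function(px) {
    d <- dim(px)
    out <- array(0, c(d[1], d[2], K))
    out[, , 1] <- px[, , 1]
    out[, , 2] <- 1 - px[, , 1]
    out
  }
  set.seed(34)
  img <- array(runif(30 * 50 * 3), c(30, 50, 3))
  plan <- plan_tiles(c(30, 50), 16, 2)
  shuffled <- plan
  shuffled$tiles <- shuffled$tiles[sample(nrow(shuffled$tiles)), ]
  m <- stub_model(fn)
  expect_equal(predict_map(m, img, plan)$values,
               predict_map(m, img, shuffled)$values)
})

test_that("ensemble averaging is the per-pixel mean on the simplex", {
  d <- c(6, 6, 4)
  set.seed(32)
  raw <- array(runif(prod(d)), d)
  s <- apply(raw, c(1, 2), sum)
  m1 <- probability_map(raw / array(rep(s, d[3]), d), 0.5, "c", "a")
  # idempotence on identical maps
  avg <- ensemble_average(list(m1, m1))
  expect_equal(avg$values, m1$values, tolerance = 1e-12)
  expect_equal(avg$source, "ensemble")
  expect_equal(decode(ensemble_average(list(m1))), decode(m1))

  # two one-hot maps -> 0.5/0.5
  a <- array(0, d); a[, , 2] <- 1
  b <- array(0, d); b[, , 4] <- 1
  avg2 <- ensemble_average(list(probability_map(a, 0.5, "c", "a"),
                                probability_map(b, 0.5, "c", "b")))
  expect_true(all(avg2$values[, , 2] == 0.5 & avg2$values[, , 4] == 0.5))

  # random maps stay on the simplex
  raws <- lapply(1:3, function(i) {
    r <- array(runif(prod(d)), d)
    s <- apply(r, c(1, 2), sum)
    probability_map(r / array(rep(s, d[3]), d), 0.5, "c", "m")
  })
  av <- ensemble_average(raws)
  expect_lt(max(abs(apply(av$values, c(1, 2), sum) - 1)), 1e-6)

  bad <- probability_map(array(0.25, c(5, 6, 4)), 0.5, "c", "x")
  expect_error(ensemble_average(list(m1, bad)), "mismatch")
})

test_that("decoding takes the arg-max with lowest-id tie-breaking", {
  v <- array(0, c(2, 2, 3))
  v[, , 2] <- 0.5
  v[, , 3] <- 0.5  # exact tie between classes 1 and 2
  expect_true(all(decode(v) == 1L))

  set.seed(33)
  for (rep in 1:100) {
    d <- c(sample(2:6, 1), sample(2:6, 1), sample(3:8, 1))
    vals <- array(runif(prod(d)), d)
    expect_identical(decode(vals), argmax_oracle(vals))
  }
})
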