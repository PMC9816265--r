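pb <- build_pyramid_filters()
fb <- build_fan_filters()

test_that("pyramid split: constant image gives constant low and zero high", {
  x <- matrix(0.37, 16, 16)
  sp <- nspfb_split(x, pb, level = 0)
  expect_lt(max(abs(sp$low - 0.37)), 1e-10)
  expect_lt(max(abs(sp$high)), 1e-10)
})

test_that("pyramid split/merge round trips at several a-trous levels", {
  x <- rand_img(32, seed = 11)
  for (lev in 0:2) {
    sp <- nspfb_split(x, pb, level = lev)
    expect_identical(dim(sp$low), dim(x))
    expect_identical(dim(sp$high), dim(x))
    back <- nspfb_merge(sp$low, sp$high, pb, level = lev)
    expect_lt(max(abs(back - x)), 1e-8)
  }
})

test_that("pyramid split commutes with circular shifts under periodic boundary", {
  x <- rand_img(32, seed = 12)
  sp <- nspfb_split(x, pb, level = 1, boundary = "periodic")
  sps <- nspfb_split(circshift(x, 5, -3), pb, level = 1, boundary = "periodic")
  expect_lt(max(abs(circshift(sp$low, 5, -3) - sps$low)), 1e-10)
  expect_lt(max(abs(circshift(sp$high, 5, -3) - sps$high)), 1e-10)
})

test_that("directional bank returns 2^n same-shape bands and inverts", {
  x <- rand_img(32, seed = 13)
  expect_identical(nsdfb_split(x, fb, 0), list(x))
  for (d in 1:3) {
    bands <- nsdfb_split(x, fb, d)
    expect_length(bands, 2^d)
    for (b in bands) expect_identical(dim(b), dim(x))
    expect_lt(max(abs(nsdfb_merge(bands, fb) - x)), 1e-6)
  }
  expect_error(nsdfb_split(x, fb, -1), class = "nsct_invalid_error")
})

test_that("full decomposition has the right band count and inverts", {
  x <- rand_img(64, seed = 14)
  p <- nsct_decompose(x, levels = 4, dirs = c(3, 3, 2, 2))
  expect_s3_class(p, "nsct_pyramid")
  expect_identical(dim(p$low), dim(x))
  expect_identical(lengths(p$highs), c(8L, 8L, 4L, 4L))
  for (lvl in p$highs) for (b in lvl) expect_identical(dim(b), dim(x))
  expect_lt(max(abs(nsct_reconstruct(p) - x)), 1e-6)
})

test_that("constant image decomposes to constant low and zero highs", {
  p <- nsct_decompose(matrix(0.6, 32, 32), levels = 3, dirs = c(2, 1, 1))
  expect_lt(max(abs(p$low - 0.6)), 1e-8)
  for (lvl in p$highs) for (b in lvl) expect_lt(max(abs(b)), 1e-8)
})

test_that("decompose and reconstruct are linear operators", {
  x <- rand_img(32, seed = 15); y <- rand_img(32, seed = 16)
  a <- 2.5; b <- -0.7
  px <- nsct_decompose(x, 2, c(2, 1)); py <- nsct_decompose(y, 2, c(2, 1))
  pz <- nsct_decompose(a * x + b * y, 2, c(2, 1))
  expect_lt(max(abs(pz$low - (a * px$low + b * py$low))), 1e-8)
  expect_lt(max(abs(pz$highs[[1]][[3]] -
                      (a * px$highs[[1]][[3]] + b * py$highs[[1]][[3]]))), 1e-8)
  # linearity of reconstruction: scale every band of px and reconstruct
  ps <- px
  ps$low <- a * px$low + b * py$low
  for (j in seq_along(ps$highs))
    for (k in seq_along(ps$highs[[j]]))
      ps$highs[[j]][[k]] <- a * px$highs[[j]][[k]] + b * py$highs[[j]][[k]]
  expect_lt(max(abs(nsct_reconstruct(ps) - (a * x + b * y))), 1e-8)
})

test_that("subbands of a circular shift are circular shifts of subbands", {
  x <- rand_img(32, seed = 17)
  p1 <- nsct_decompose(x, 2, c(2, 2), boundary = "periodic")
  p2 <- nsct_decompose(circshift(x, 7, 4), 2, c(2, 2), boundary = "periodic")
  expect_lt(max(abs(circshift(p1$low, 7, 4) - p2$low)), 1e-8)
  for (j in 1:2)
    for (k in seq_along(p1$highs[[j]]))
      expect_lt(max(abs(circshift(p1$highs[[j]][[k]], 7, 4) -
                          p2$highs[[j]][[k]])), 1e-8)
})

test_that("malformed pyramids and argument mismatches are rejected", {
  x <- rand_img(16, seed = 18)
  expect_error(nsct_decompose(x, 2, c(1, 1, 1)), class = "nsct_invalid_error")
  expect_error(nsct_decompose(x, 0), class = "nsct_invalid_error")
  p <- nsct_decompose(x, 2, c(1, 1))
  p$highs[[1]] <- p$highs[[1]][1]
  expect_error(nsct_reconstruct(p), class = "nsct_invalid_error")
  xb <- x; xb[1] <- NaN
  expect_error(nsct_decompose(xb, 2, c(1, 1)), class = "nsct_invalid_error")
})
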