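fast_cfg <- function(...) {
  fusion_config(levels = 2, dirs = c(2, 1),
                pcnn = pcnn_params(n_iter = 30), ...)
}

test_that("band fusion selects the source with the larger firing count", {
  pars <- pcnn_params(beta = 0, n_iter = 30)
  a <- rand_img(8, seed = 31)
  # identical bands: ties everywhere, the otherwise-branch returns B (== A)
  expect_identical(fuse_band_pcnn(a, a, pars), a)
  # constant 1 vs constant 0: A fires more everywhere
  one <- matrix(1, 8, 8); zero <- matrix(0, 8, 8)
  expect_identical(fuse_band_pcnn(one, zero, pars, is_highpass = TRUE), one)
  expect_error(fuse_band_pcnn(one, matrix(0, 4, 4), pars),
               class = "nsct_invalid_error")
})

test_that("per-pixel selection matches an independently computed firing mask", {
  # beta = 0 decouples neurons; stimuli already span [0,1] with max 1 so
  # normalization is the identity and the scalar oracle applies per pixel
  pars <- pcnn_params(beta = 0, n_iter = 60)
  set.seed(32)
  a <- matrix(sample(c(0.2, 0.5, 0.9, 1.0), 64, replace = TRUE), 8, 8)
  b <- matrix(sample(c(0.2, 0.5, 0.9, 1.0), 64, replace = TRUE), 8, 8)
  a[1, 1] <- 1; b[1, 2] <- 1
  ta <- matrix(vapply(a, pcnn_scalar_oracle, numeric(1), n_iter = 60), 8, 8)
  tb <- matrix(vapply(b, pcnn_scalar_oracle, numeric(1), n_iter = 60), 8, 8)
  want <- ifelse(ta > tb, a, b)
  expect_equal(fuse_band_pcnn(a, b, pars, is_highpass = TRUE), want)
})

test_that("fusing an image with itself returns the image", {
  ph <- make_phantom_pair(phantom_spec(size = 32, seed = 33))
  Fz <- fuse_images(ph$A, ph$A, fast_cfg())
  expect_lt(max(abs(Fz - ph$A)), 1e-6)
})

test_that("the average rule reproduces the pixel average by linearity", {
  a <- rand_img(32, seed = 34); b <- rand_img(32, seed = 35)
  Fz <- fuse_images(a, b, fast_cfg(rule = "average"))
  expect_lt(max(abs(Fz - (a + b) / 2)), 1e-6)
})

test_that("fused subbands are exact copies of one source (never blends)", {
  ph <- make_phantom_pair(phantom_spec(size = 32, seed = 36))
  cfg <- fast_cfg()
  pA <- nsct_decompose(ph$A, cfg$levels, cfg$dirs, boundary = cfg$boundary)
  pB <- nsct_decompose(ph$B, cfg$levels, cfg$dirs, boundary = cfg$boundary)
  pf <- fuse_subbands(pA, pB, cfg)
  expect_true(all(pf$low == pA$low | pf$low == pB$low))
  for (j in seq_along(pf$highs))
    for (k in seq_along(pf$highs[[j]])) {
      fb <- pf$highs[[j]][[k]]
      expect_true(all(fb == pA$highs[[j]][[k]] | fb == pB$highs[[j]][[k]]))
    }
})

test_that("single-modality structures survive fusion", {
  ph <- make_phantom_pair(phantom_spec(size = 64, seed = 37))
  Fz <- fuse_images(ph$A, ph$B, fast_cfg())
  bg <- mean(Fz[ph$masks$interior &
                  !Reduce(`|`, ph$masks$structures)])
  for (m in ph$masks$structures)
    expect_gt(mean(Fz[m]), bg)
})

test_that("repeated runs are bitwise identical", {
  ph <- make_phantom_pair(phantom_spec(size = 32, seed = 38))
  cfg <- fast_cfg()
  expect_identical(fuse_images(ph$A, ph$B, cfg),
                   fuse_images(ph$A, ph$B, cfg))
})

test_that("luminance-channel color fusion preserves chrominance", {
  fp <- make_functional_pair(phantom_spec(size = 32, seed = 39,
                                          noise_sigma = 0))
  cfg <- fast_cfg()
  out <- fuse_gray_color(fp$gray, fp$color, cfg)
  expect_identical(dim(out), dim(fp$color))
  expect_true(all(out >= 0 & out <= 1))

  # grayscale RGB input (zero chrominance) stays grayscale
  g2 <- make_phantom_pair(phantom_spec(size = 32, seed = 40))$A
  colg <- array(rep(g2, 3), c(32, 32, 3))
  outg <- fuse_gray_color(fp$gray, colg, cfg)
  expect_lt(max(abs(outg[, , 1] - outg[, , 2])), 1e-8)
  expect_lt(max(abs(outg[, , 2] - outg[, , 3])), 1e-8)
  # and its luminance is exactly the grayscale fusion result
  lum <- 0.299 * colg[, , 1] + 0.587 * colg[, , 2] + 0.114 * colg[, , 3]
  expect_equal(outg[, , 1], fuse_images(fp$gray, lum, cfg), tolerance = 1e-7)

  expect_error(fuse_gray_color(fp$gray, fp$color[1:16, , , drop = FALSE], cfg),
               class = "nsct_invalid_error")
  expect_error(fuse_gray_color(fp$gray, fp$gray, cfg),
               class = "nsct_invalid_error")
})

test_that("selection keeps more contrast than averaging on complementary phantoms", {
  ph <- make_phantom_pair(phantom_spec(size = 64, seed = 41))
  sd_sel <- img_sd(fuse_images(ph$A, ph$B, fast_cfg()))
  sd_avg <- img_sd(fuse_images(ph$A, ph$B, fast_cfg(rule = "average")))
  expect_gte(sd_sel, sd_avg)
})
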