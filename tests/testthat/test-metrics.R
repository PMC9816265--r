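test_that("entropy: closed-form histograms", {
  expect_equal(entropy(matrix(0.42, 8, 8)), 0)
  half <- matrix(rep(c(0, 1), each = 32), 8, 8)
  expect_equal(entropy(half), 1)
  u <- matrix(rep(0:255, each = 256) / 255, 256, 256)
  expect_equal(entropy(u), 8)
})

test_that("entropy is permutation-invariant; SD and AG are not", {
  x <- rand_img(16, seed = 51)
  set.seed(52)
  xp <- matrix(sample(x), 16, 16)
  expect_equal(entropy(xp), entropy(x))
  expect_equal(img_sd(xp), img_sd(x))          # SD is histogram-based too
  expect_false(isTRUE(all.equal(avg_gradient(xp), avg_gradient(x))))
})

test_that("mutual information: self, symmetry, independence, anti-correlation", {
  a <- rand_img(16, seed = 53)
  mi <- mutual_information(a, a, a)
  expect_equal(mi$mi_af, entropy(a))
  expect_equal(mi$mi, 2 * entropy(a))
  # symmetry of the pair measure in its two arguments
  b <- rand_img(16, seed = 54)
  expect_equal(mutual_information(a, a, b)$mi_af,
               mutual_information(b, b, a)$mi_af)
  # independent coarse-level noise: MI near zero (16 gray levels keeps the
  # plug-in estimator's bias at ~2e-3 bits for n = 65536)
  set.seed(55)
  xi <- matrix(sample(seq(0, 255, by = 17), 65536, TRUE) / 255, 256, 256)
  yi <- matrix(sample(seq(0, 255, by = 17), 65536, TRUE) / 255, 256, 256)
  expect_lt(mutual_information(xi, xi, yi)$mi_af, 0.05)
  # perfectly anti-correlated binary pair: one bit
  z <- matrix(rep(c(0, 1), 8), 4, 4)
  expect_equal(mutual_information(z, z, 1 - z)$mi_af, 1)
})

test_that("PSNR: closed forms", {
  z <- matrix(0, 16, 16); o <- matrix(1, 16, 16)
  expect_identical(psnr(z, z), Inf)
  expect_equal(psnr(z, o), 0)
  x <- matrix(100 / 255, 256, 256)
  y <- x; y[40, 200] <- 101 / 255
  expect_equal(psnr(x, y), 10 * log10(255^2 * 65536))
})

test_that("SD and AG: closed forms", {
  expect_equal(img_sd(matrix(0.3, 8, 8)), 0)
  expect_equal(img_sd(matrix(rep(c(0, 1), each = 32), 8, 8)), 127.5)
  expect_equal(avg_gradient(matrix(0.3, 8, 8)), 0)
  ramp <- matrix(rep(0:15, times = 16) / 255, 16, 16)  # unit row steps
  expect_equal(avg_gradient(ramp), 1 / sqrt(2))
})

test_that("NCC: closed forms", {
  u <- matrix(rep(0:255, each = 256) / 255, 256, 256)
  expect_equal(ncc(u, u), 1)
  # exactly uniform independent joint distribution over 256x256 cells
  xg <- matrix(rep(0:255, each = 256) / 255, 256, 256)
  yg <- matrix(rep(0:255, times = 256) / 255, 256, 256)
  expect_equal(ncc(xg, yg), 0)
  expect_equal(q_ncie(u, u, u), 1)  # all-ones matrix, eigenvalues (3,0,0)
})

test_that("Q^AB/F: perfect and destroyed transfer", {
  a <- rand_img(16, seed = 56)
  expect_lt(abs(q_abf(a, a, a) - 1), 1e-6)
  b <- rand_img(16, seed = 57)
  expect_lt(q_abf(a, b, matrix(0.5, 16, 16)), 0.05)
  expect_equal(q_abf(matrix(0.2, 8, 8), matrix(0.8, 8, 8), rand_img(8, 58)), 0)
})

test_that("every metric matches its brute-force oracle on random triples", {
  for (s in 1:50) {
    a <- rand_img(16, seed = 1000 + s)
    b <- rand_img(16, seed = 2000 + s)
    f <- rand_img(16, seed = 3000 + s)
    expect_lt(abs(entropy(f) - entropy_oracle(f)), 1e-10)
    expect_lt(abs(mutual_information(a, b, f)$mi_af - mi_oracle(a, f)), 1e-10)
    expect_lt(abs(mutual_information(a, b, f)$mi_bf - mi_oracle(b, f)), 1e-10)
    expect_lt(abs(img_sd(f) - sd_oracle(f)), 1e-10)
    expect_lt(abs(avg_gradient(f) - ag_oracle(f)), 1e-10)
    expect_lt(abs(psnr(a, f) - psnr_oracle(a, f)), 1e-10)
    expect_lt(abs(ncc(a, f) - ncc_oracle(a, f)), 1e-10)
    expect_lt(abs(q_abf(a, b, f) - qabf_oracle(a, b, f)), 1e-6)
  }
})

test_that("q_abf is bounded in [0,1] and reports go finite", {
  for (s in 1:10) {
    a <- rand_img(8, seed = 4000 + s)
    b <- rand_img(8, seed = 5000 + s)
    f <- rand_img(8, seed = 6000 + s)
    q <- q_abf(a, b, f)
    expect_gte(q, 0); expect_lte(q, 1)
  }
})

test_that("the report composes the individual metrics", {
  a <- rand_img(16, seed = 59); b <- rand_img(16, seed = 60)
  f <- (a + b) / 2
  r <- fusion_report(a, b, f)
  expect_s3_class(r, "fusion_report")
  expect_equal(r$en, entropy(f))
  expect_equal(r$mi, mutual_information(a, b, f)$mi)
  expect_equal(r$q_abf, q_abf(a, b, f))
  expect_equal(r$psnr, mean(c(psnr(a, f), psnr(b, f))))
  expect_equal(r$sd, img_sd(f))
  expect_equal(r$ag, avg_gradient(f))
  expect_equal(r$q_ncie, q_ncie(a, b, f))
  expect_true(all(vapply(unclass(r), is.finite, logical(1))))
  # (A, A, A): identity-case composition
  r2 <- fusion_report(a, a, a)
  expect_equal(r2$en, entropy(a))
  expect_equal(r2$mi, 2 * entropy(a))
  expect_equal(r2$sd, img_sd(a))
  expect_identical(r2$psnr, Inf)
  df <- as.data.frame(r)
  expect_named(df, c("EN", "MI", "QABF", "PSNR", "SD", "AG", "QNCIE"))
})
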