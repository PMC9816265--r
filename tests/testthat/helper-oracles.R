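# Independent brute-force oracles used to validate the package
# implementations. These deliberately share no code with R/: direct loops,
# table()-based histograms, scalar recurrences.

rand_img <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

circshift <- function(m, a, b) {
  m[((seq_len(nrow(m)) - 1L - a) %% nrow(m)) + 1L,
    ((seq_len(ncol(m)) - 1L - b) %% ncol(m)) + 1L]
}

# Full 2-D convolution of two kernels by direct summation over output taps.
kconv_oracle <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- matrix(0, da[1] + db[1] - 1L, da[2] + db[2] - 1L)
  for (u in seq_len(nrow(out))) {
    for (v in seq_len(ncol(out))) {
      s <- 0
      for (i in seq_len(da[1])) {
        for (j in seq_len(da[2])) {
          bi <- u - i + 1L; bj <- v - j + 1L
          if (bi >= 1L && bi <= db[1] && bj >= 1L && bj <= db[2])
            s <- s + a[i, j] * b[bi, bj]
        }
      }
      out[u, v] <- s
    }
  }
  out
}

# max |h0*g0 + h1*g1 - delta| for a filter bank, via the direct convolution.
bezout_oracle <- function(bank) {
  a <- kconv_oracle(bank$h0, bank$g0)
  b <- kconv_oracle(bank$h1, bank$g1)
  d1 <- max(nrow(a), nrow(b)); d2 <- max(ncol(a), ncol(b))
  pad <- function(k) {
    out <- matrix(0, d1, d2)
    o1 <- (d1 - nrow(k)) %/% 2L; o2 <- (d2 - ncol(k)) %/% 2L
    out[(o1 + 1):(o1 + nrow(k)), (o2 + 1):(o2 + ncol(k))] <- k
    out
  }
  s <- pad(a) + pad(b)
  dd <- matrix(0, d1, d2); dd[(d1 + 1) %/% 2, (d2 + 1) %/% 2] <- 1
  max(abs(s - dd))
}

# Scalar single-neuron trace for constant stimulus and beta = 0 (neurons
# decouple): returns the accumulated firing count.
pcnn_scalar_oracle <- function(s, n_iter = 100L, alpha_h = 0.2, v_h = 20) {
  H <- 0; cnt <- 0L
  for (n in seq_len(n_iter)) {
    H <- exp(-alpha_h) * H
    if (s > H) {
      H <- H + v_h
      cnt <- cnt + 1L
    }
  }
  cnt
}

q255 <- function(x) round(255 * x)

entropy_oracle <- function(img) {
  p <- as.numeric(table(factor(q255(img), levels = 0:255))) / length(img)
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log2(pi)
  s
}

mi_oracle <- function(X, Y) {
  jt <- table(factor(q255(X), levels = 0:255),
              factor(q255(Y), levels = 0:255)) / length(X)
  px <- rowSums(jt); py <- colSums(jt)
  s <- 0
  for (i in 1:256) {
    for (j in 1:256) {
      p <- jt[i, j]
      if (p > 0) s <- s + p * log2(p / (px[i] * py[j]))
    }
  }
  s
}

sd_oracle <- function(img) {
  v <- 255 * img
  mu <- sum(v) / length(v)
  sqrt(sum((v - mu)^2) / length(v))
}

ag_oracle <- function(img) {
  v <- 255 * img
  m <- nrow(v); n <- ncol(v)
  tot <- 0
  for (i in 1:(m - 1)) {
    for (j in 1:(n - 1)) {
      dx <- v[i, j] - v[i + 1, j]
      dy <- v[i, j] - v[i, j + 1]
      tot <- tot + sqrt((dx^2 + dy^2) / 2)
    }
  }
  tot / ((m - 1) * (n - 1))
}

psnr_oracle <- function(ref, out) {
  d <- 255 * (ref - out)
  mse <- sum(d^2) / length(d)
  if (mse == 0) Inf else 10 * log10(255^2 / mse)
}

ncc_oracle <- function(X, Y, b = 256) {
  jt <- table(factor(q255(X), levels = 0:255),
              factor(q255(Y), levels = 0:255)) / length(X)
  s <- 2
  for (p in as.numeric(jt)) if (p > 0) s <- s + p * log(p) / log(b)
  s
}

# Independent Q^AB/F: mirror-extended direct-loop Sobel correlation plus the
# normalized sigmoid preservation model evaluated pixel by pixel.
qabf_oracle <- function(A, B, F) {
  sob <- function(img) {
    sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
    m <- nrow(img); n <- ncol(img)
    refl <- function(i, nn) { # half-sample mirror
      k <- (i - 1) %% (2 * nn)
      if (k < nn) k + 1 else 2 * nn - k
    }
    gx <- matrix(0, m, n); gy <- matrix(0, m, n)
    for (i in 1:m) {
      for (j in 1:n) {
        sxx <- 0; syy <- 0
        for (p in -1:1) {
          for (q in -1:1) {
            # convolution: kernel tap (p,q) multiplies img(i-p, j-q)
            v <- img[refl(i - p, m), refl(j - q, n)]
            sxx <- sxx + sx[p + 2, q + 2] * v
            syy <- syy + t(sx)[p + 2, q + 2] * v
          }
        }
        gx[i, j] <- sxx; gy[i, j] <- syy
      }
    }
    g <- sqrt(gx^2 + gy^2)
    a <- atan(gy / gx); a[is.nan(a)] <- 0
    list(g = g, a = a)
  }
  pres <- function(s, f) {
    kg <- -15; sg <- 0.5; ka <- -22; sa <- 0.8
    G <- matrix(0, nrow(s$g), ncol(s$g))
    for (i in seq_along(G)) {
      G[i] <- if (s$g[i] == f$g[i]) 1
              else min(s$g[i], f$g[i]) / max(s$g[i], f$g[i])
    }
    Aa <- 1 - abs(s$a - f$a) / (pi / 2)
    qg <- (1 + exp(kg * (1 - sg))) / (1 + exp(kg * (G - sg)))
    qa <- (1 + exp(ka * (1 - sa))) / (1 + exp(ka * (Aa - sa)))
    qg * qa
  }
  ea <- sob(A); eb <- sob(B); ef <- sob(F)
  wa <- ea$g; wb <- eb$g
  den <- sum(wa + wb)
  if (den == 0) return(0)
  sum(pres(ea, ef) * wa + pres(eb, ef) * wb) / den
}
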