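# Centered 2-D convolution with configurable boundary extension.
#
# All analysis/synthesis kernels in this package are zero-phase (origin at the
# center tap, even-symmetric support), which makes symmetric-extension filter
# banks exactly invertible: convolution with an even kernel preserves the
# mirror symmetry of the extended signal, so analysis followed by synthesis
# telescopes into convolution with h0*g0 + h1*g1 = delta.

# Map out-of-range 1-based indices onto 1..n for the chosen extension mode.
# "symmetric" is the half-sample mirror (edge pixel repeated): x[0] = x[1].
ext_index <- function(i, n, boundary) {
  if (boundary == "periodic") return(((i - 1L) %% n) + 1L)
  m <- (i - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

# Convolve image x with centered odd-sized kernel k.
# Implemented as: extend x by the kernel radius, circular-convolve via FFT,
# crop the center. For boundary = "periodic" this equals true circular
# convolution; for "symmetric" it equals direct convolution with the
# half-sample mirrored extension.
conv2_ext <- function(x, k, boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  kd <- dim(k)
  if (any(kd %% 2L == 0L))
    stop_invalid("conv2_ext expects odd-sized centered kernels")
  r1 <- (kd[1L] - 1L) %/% 2L
  r2 <- (kd[2L] - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)

  if (r1 == 0L && r2 == 0L) return(x * k[1L, 1L])

  pi_ <- ext_index((1L - r1):(h + r1), h, boundary)
  pj_ <- ext_index((1L - r2):(w + r2), w, boundary)
  xp <- x[pi_, pj_, drop = FALSE]
  hp <- h + 2L * r1
  wp <- w + 2L * r2

  # Embed the kernel at wrapped offsets so index (0,0) sits at [1,1].
  ke <- matrix(0, hp, wp)
  ri <- ((-r1:r1) %% hp) + 1L
  rj <- ((-r2:r2) %% wp) + 1L
  ke[ri, rj] <- k

  out <- Re(stats::fft(stats::fft(xp) * stats::fft(ke), inverse = TRUE)) / (hp * wp)
  out[(r1 + 1L):(r1 + h), (r2 + 1L):(r2 + w), drop = FALSE]
}

# Full (centered) convolution of two odd-sized kernels; used for Bezout
# identity checks and for composing polynomial filter constructions.
kconv <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- matrix(0, da[1L] + db[1L] - 1L, da[2L] + db[2L] - 1L)
  for (i in seq_len(da[1L])) {
    for (j in seq_len(da[2L])) {
      if (a[i, j] != 0)
        out[i:(i + db[1L] - 1L), j:(j + db[2L] - 1L)] <-
          out[i:(i + db[1L] - 1L), j:(j + db[2L] - 1L)] + a[i, j] * b
    }
  }
  out
}

# Centered delta kernel of given odd side.
delta_kernel <- function(side = 1L) {
  k <- matrix(0, side, side)
  k[(side + 1L) %/% 2L, (side + 1L) %/% 2L] <- 1
  k
}

# Pad a centered kernel to a larger centered odd support.
embed_centered <- function(k, d1, d2) {
  out <- matrix(0, d1, d2)
  o1 <- (d1 - nrow(k)) %/% 2L
  o2 <- (d2 - ncol(k)) %/% 2L
  out[(o1 + 1L):(o1 + nrow(k)), (o2 + 1L):(o2 + ncol(k))] <- k
  out
}
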