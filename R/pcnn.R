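#' Pulse-coupled neural network parameters
#'
#' One neuron per pixel, with feeding channel `F`, linking channel `L`,
#' internal activity `U = F (1 + beta L)`, binary output `Y` and a dynamic
#' threshold `H`. The defaults are the standard fusion setting: linking
#' radius 3, `beta = 3`, `alpha_l = 1`, `v_l = 1.8`, threshold decay
#' `alpha_h = 0.2`, threshold voltage `v_h = 20`, and `n_iter = 100`
#' iterations. By default the feeding channel is the pure stimulus
#' (`F(n) = S`); supplying both `alpha_f` and `v_f` enables the full feeding
#' recurrence `F(n) = exp(-alpha_f) F(n-1) + v_f * sum(m Y) + S`.
#'
#' @param beta Linking coefficient.
#' @param alpha_l,v_l Linking decay constant and amplification voltage.
#' @param alpha_h,v_h Threshold decay constant and threshold voltage.
#' @param n_iter Number of iterations `N`.
#' @param link_arrange Odd side length of the linking neighbourhood.
#' @param alpha_f,v_f Optional feeding decay/voltage; both `NULL` (default)
#'   selects the simplified feeding `F(n) = S`.
#' @param kernel_m,kernel_w Optional weight matrices for the feeding and
#'   linking neighbourhood sums; default [linking_kernel()]`(link_arrange)`
#'   for both.
#' @return An object of class `pcnn_params`.
#' @export
pcnn_params <- function(beta = 3, alpha_l = 1, v_l = 1.8,
                        alpha_h = 0.2, v_h = 20, n_iter = 100L,
                        link_arrange = 3L,
                        alpha_f = NULL, v_f = NULL,
                        kernel_m = NULL, kernel_w = NULL) {
  if (n_iter < 1L || n_iter != round(n_iter))
    stop_invalid("n_iter must be a positive integer")
  if (link_arrange < 1L || link_arrange %% 2L == 0L)
    stop_invalid("link_arrange must be an odd positive integer")
  if (any(c(beta, alpha_l, v_l, alpha_h, v_h) < 0))
    stop_invalid("decay constants and voltages must be nonnegative")
  if (xor(is.null(alpha_f), is.null(v_f)))
    stop_invalid("alpha_f and v_f must be supplied together")
  k <- linking_kernel(link_arrange)
  if (is.null(kernel_m)) kernel_m <- k
  if (is.null(kernel_w)) kernel_w <- k
  for (nm in c("kernel_m", "kernel_w")) {
    kk <- get(nm)
    if (!is.matrix(kk) || !identical(dim(kk), c(as.integer(link_arrange),
                                                as.integer(link_arrange))))
      stop_invalid(nm, " must be a ", link_arrange, "x", link_arrange,
                   " matrix")
    if (kk[(link_arrange + 1L) %/% 2L, (link_arrange + 1L) %/% 2L] != 0)
      stop_invalid(nm, " must have zero self-weight at the center")
  }
  structure(list(beta = beta, alpha_l = alpha_l, v_l = v_l,
                 alpha_h = alpha_h, v_h = v_h,
                 n_iter = as.integer(n_iter),
                 link_arrange = as.integer(link_arrange),
                 alpha_f = alpha_f, v_f = v_f,
                 kernel_m = kernel_m, kernel_w = kernel_w),
            class = "pcnn_params")
}

#' @export
print.pcnn_params <- function(x, ...) {
  cat(sprintf(paste0("<pcnn_params: beta=%g alpha_l=%g v_l=%g alpha_h=%g ",
                     "v_h=%g N=%d link=%d feeding=%s>\n"),
              x$beta, x$alpha_l, x$v_l, x$alpha_h, x$v_h, x$n_iter,
              x$link_arrange,
              if (is.null(x$alpha_f)) "stimulus" else "recurrent"))
  invisible(x)
}

#' Inverse-distance linking kernel
#'
#' Square weight matrix of side `link_arrange` with weight `1/sqrt(p^2+q^2)`
#' at offset `(p, q)` and zero self-weight at the center.
#'
#' @param link_arrange Odd positive integer side length.
#' @return A `link_arrange` x `link_arrange` matrix.
#' @examples
#' linking_kernel(3)
#' @export
linking_kernel <- function(link_arrange) {
  if (length(link_arrange) != 1L || link_arrange < 1L ||
      link_arrange != round(link_arrange) || link_arrange %% 2L == 0L)
    stop_invalid("link_arrange must be an odd positive integer")
  r <- (link_arrange - 1L) %/% 2L
  p <- outer(-r:r, -r:r, function(a, b) sqrt(a^2 + b^2))
  w <- ifelse(p == 0, 0, 1 / p)
  w[r + 1L, r + 1L] <- 0
  w
}

# Zero-padded weighted neighbourhood sum sum_kl K(kl) Y(i+k, j+l),
# vectorized as shift-and-add over the (few) nonzero taps.
neigh_sum <- function(Y, K) {
  h <- nrow(Y); w <- ncol(Y)
  r1 <- (nrow(K) - 1L) %/% 2L
  r2 <- (ncol(K) - 1L) %/% 2L
  out <- matrix(0, h, w)
  for (p in -r1:r1) {
    ilo <- max(1L, 1L - p); ihi <- min(h, h - p)
    if (ilo > ihi) next
    si <- ilo:ihi
    ti <- si + p
    for (q in -r2:r2) {
      wgt <- K[p + r1 + 1L, q + r2 + 1L]
      if (wgt == 0) next
      jlo <- max(1L, 1L - q); jhi <- min(w, w - q)
      if (jlo > jhi) next
      sj <- jlo:jhi
      tj <- sj + q
      out[si, sj] <- out[si, sj] + wgt * Y[ti, tj]
    }
  }
  out
}

#' Run the pulse-coupled neural network and return the firing map
#'
#' Simulates the neuron lattice on a stimulus in `[0,1]` for `n_iter` steps
#' and returns the accumulated firing count `T` (number of iterations in
#' which each neuron fired). Per iteration, in order: feeding update,
#' linking update `L = exp(-alpha_l) L + v_l * sum(w Y)`, modulation
#' `U = F (1 + beta L)`, threshold decay `H <- exp(-alpha_h) H`, firing
#' `Y = (U > H)` (strict; ties do not fire), threshold recharge
#' `H <- H + v_h Y`, and `T <- T + Y`. All state starts at zero, so any
#' neuron with positive activity fires at the first step; neighbourhood
#' sums use zero padding.
#'
#' @param S Stimulus matrix, finite, expected in `[0,1]`
#'   (see [normalize_stimulus()]).
#' @param params A [pcnn_params()] object.
#' @return Integer-valued matrix `T` of firing counts in `[0, n_iter]`.
#' @examples
#' T1 <- pcnn_firing_map(matrix(1, 1, 1), pcnn_params(beta = 0))
#' T1  # 7 fires in 100 iterations at the default constants
#' @export
pcnn_firing_map <- function(S, params = pcnn_params()) {
  check_image(S, "S")
  if (!inherits(params, "pcnn_params"))
    stop_invalid("params must be a pcnn_params object")
  h <- nrow(S); w <- ncol(S)
  Fm <- matrix(0, h, w); L <- Fm; Y <- Fm; H <- Fm; Tn <- Fm
  simple_feed <- is.null(params$alpha_f)
  ef <- if (simple_feed) 0 else exp(-params$alpha_f)
  el <- exp(-params$alpha_l)
  eh <- exp(-params$alpha_h)
  for (n in seq_len(params$n_iter)) {
    Fm <- if (simple_feed) S
          else ef * Fm + params$v_f * neigh_sum(Y, params$kernel_m) + S
    L <- el * L + params$v_l * neigh_sum(Y, params$kernel_w)
    U <- Fm * (1 + params$beta * L)
    H <- eh * H
    Y <- (U > H) * 1
    H <- H + params$v_h * Y
    Tn <- Tn + Y
  }
  Tn
}

#' Map a subband to a PCNN stimulus in [0,1]
#'
#' Directional (highpass) bands carry signed detail coefficients, whose
#' salience is their magnitude: they are mapped to `|band| / max|band|`
#' (all-zero bands stay zero). The lowpass band is min-max rescaled to
#' `[0,1]`; a constant lowpass band maps to `0.5` everywhere.
#'
#' @param band Numeric matrix.
#' @param is_highpass Logical: directional band (`TRUE`) or lowpass.
#' @return Matrix in `[0,1]`, same shape.
#' @export
normalize_stimulus <- function(band, is_highpass = TRUE) {
  check_image(band, "band")
  if (is_highpass) {
    a <- abs(band)
    m <- max(a)
    if (m == 0) a else a / m
  } else {
    lo <- min(band); hi <- max(band)
    if (hi == lo) matrix(0.5, nrow(band), ncol(band))
    else (band - lo) / (hi - lo)
  }
}
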