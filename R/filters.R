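#' Filter banks for the nonsubsampled contourlet transform
#'
#' A two-channel undecimated filter bank is exactly invertible when its
#' analysis kernels `h0`, `h1` and synthesis kernels `g0`, `g1` satisfy the
#' Bezout (perfect-reconstruction) identity `h0*g0 + h1*g1 = delta`, where
#' `*` is 2-D convolution and `delta` the unit impulse. The banks shipped
#' here are zero-phase maxflat designs obtained by the McClellan transform:
#' a 1-D perfect-reconstruction polynomial identity in `cos(w)` is mapped to
#' two dimensions by substituting a 2-D transformation kernel — the diamond
#' kernel `(cos w1 + cos w2)/2` for the pyramid (multiscale) stage and the
#' fan kernel `(-cos w1 + cos w2)/2` for the directional stage. Because the
#' substitution is a polynomial identity, the Bezout identity holds to
#' machine precision, and remains true for every a-trous upsampled instance
#' used in the decomposition tree.
#'
#' @param name Filter family identifier. `"pyrexc"` is the supported pyramid
#'   pair (maxflat, lowpass DC gain 1, highpass DC gain 0); `"vk"` is the
#'   supported fan pair.
#' @return An object of class `nsct_filter_bank`: a list with 2-D kernel
#'   matrices `h0`, `h1` (analysis), `g0`, `g1` (synthesis), the `name`, and
#'   the bank `kind` (`"pyramid"` or `"fan"`).
#' @examples
#' pb <- build_pyramid_filters("pyrexc")
#' sum(pb$h0)            # DC gain 1
#' bezout_residual(pb)   # ~ 1e-16
#' @export
build_pyramid_filters <- function(name = "pyrexc") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name) ||
      !(name %in% "pyrexc"))
    stop_config("unknown pyramid filter '", name,
                "'; supported: \"pyrexc\"")
  # Diamond McClellan kernel D <-> (cos w1 + cos w2)/2
  D <- matrix(c(0, 0.25, 0,
                0.25, 0, 0.25,
                0, 0.25, 0), 3L, 3L, byrow = TRUE)
  d3 <- delta_kernel(3L)
  P <- (d3 + D) / 2            # (1 + x)/2 at x = D
  Q <- (d3 - D) / 2            # (1 - x)/2
  bank <- list(
    h0 = kconv(P, P),          # ((1+x)/2)^2 : lowpass, DC gain 1
    h1 = kconv(Q, Q),          # ((1-x)/2)^2 : highpass, DC gain 0
    g0 = 2 * d3 - D,           # 2 - x
    g1 = 2 * d3 + D,           # 2 + x
    name = name, kind = "pyramid")
  class(bank) <- "nsct_filter_bank"
  validate_filter_bank(bank)
  bank
}

#' @rdname build_pyramid_filters
#' @export
build_fan_filters <- function(name = "vk") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name) ||
      !(name %in% "vk"))
    stop_config("unknown fan filter '", name, "'; supported: \"vk\"")
  # Fan McClellan kernel F <-> (-cos w1 + cos w2)/2: rows are the first
  # image index. Modulating the diamond kernel by pi in w1 turns the
  # diamond passband into the vertical/horizontal fan pair.
  Fk <- matrix(c(0, 0.25, 0,
                 -0.25, 0, -0.25,
                 0, 0.25, 0), 3L, 3L, byrow = TRUE)
  d3 <- delta_kernel(3L)
  Qm <- (d3 - Fk) / 2
  bank <- list(
    h0 = (d3 + Fk) / 2,        # (1 + y)/2 : one fan half-plane
    h1 = kconv(Qm, Qm),        # ((1 - y)/2)^2 : complementary fan
    g0 = (3 * d3 - Fk) / 2,    # (3 - y)/2
    g1 = delta_kernel(1L),     # 1
    name = name, kind = "fan")
  class(bank) <- "nsct_filter_bank"
  validate_filter_bank(bank)
  bank
}

validate_filter_bank <- function(bank, tol = 1e-10) {
  res <- bezout_residual(bank)
  if (res > tol)
    stop_config("filter bank '", bank$name,
                "' violates the perfect-reconstruction identity (residual ",
                format(res), ")")
  invisible(bank)
}

#' Perfect-reconstruction residual of a two-channel filter bank
#'
#' Computes `max | h0*g0 + h1*g1 - delta |` over the full convolution
#' support. A value at numerical zero certifies that the undecimated bank is
#' exactly invertible.
#'
#' @param bank An `nsct_filter_bank`.
#' @param sampling Optional 2x2 integer matrix; when given, all four kernels
#'   are a-trous upsampled by it before the identity is evaluated (upsampling
#'   both sides preserves the identity; this verifies it).
#' @return Maximum absolute deviation from the unit impulse, per tap.
#' @export
bezout_residual <- function(bank, sampling = NULL) {
  h0 <- bank$h0; h1 <- bank$h1; g0 <- bank$g0; g1 <- bank$g1
  if (!is.null(sampling)) {
    h0 <- atrous_upsample(h0, sampling); h1 <- atrous_upsample(h1, sampling)
    g0 <- atrous_upsample(g0, sampling); g1 <- atrous_upsample(g1, sampling)
  }
  a <- kconv(h0, g0)
  b <- kconv(h1, g1)
  d1 <- max(nrow(a), nrow(b)); d1 <- d1 + 1L - (d1 %% 2L)
  d2 <- max(ncol(a), ncol(b)); d2 <- d2 + 1L - (d2 %% 2L)
  s <- embed_centered(a, d1, d2) + embed_centered(b, d1, d2)
  dd <- matrix(0, d1, d2)
  dd[(d1 + 1L) %/% 2L, (d2 + 1L) %/% 2L] <- 1
  max(abs(s - dd))
}

#' A-trous ("with holes") kernel upsampling
#'
#' Inserts zeros into a kernel so that the tap at offset `k` (relative to the
#' kernel origin) moves to offset `sampling %*% k`. This is how the
#' nonsubsampled transform reaches coarser scales and finer directions:
#' instead of decimating the image, the filters are upsampled — by `2^j * I`
#' for pyramid level `j`, and by the quincunx matrix `[[1,1],[1,-1]]` and its
#' parallelogram variants in the directional tree. Tap values (and hence the
#' tap sum) are unchanged.
#'
#' @param kernel 2-D numeric kernel; the origin is the center tap for
#'   odd-sized kernels and `floor(size/2)` (0-based) for even sizes.
#' @param sampling 2x2 nonsingular integer matrix.
#' @return The zero-inserted kernel, centered on an odd-sized support.
#' @examples
#' atrous_upsample(matrix(1, 3, 3), 2 * diag(2))  # 5x5, taps at even offsets
#' @export
atrous_upsample <- function(kernel, sampling) {
  if (!is.matrix(sampling) || !identical(dim(sampling), c(2L, 2L)) ||
      any(sampling != round(sampling)))
    stop_invalid("sampling must be a 2x2 integer matrix")
  if (round(det(sampling)) == 0)
    stop_invalid("sampling matrix is singular")
  if (identical(sampling, diag(2)) || all(sampling == diag(2)))
    return(kernel)
  d <- dim(kernel)
  o1 <- d[1L] %/% 2L + 1L  # 1-based origin row (floor(size/2), 0-based)
  o2 <- d[2L] %/% 2L + 1L
  idx <- which(kernel != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(0, 1L, 1L))
  off <- cbind(idx[, 1L] - o1, idx[, 2L] - o2)
  new_off <- off %*% t(sampling)
  r1 <- max(abs(new_off[, 1L]))
  r2 <- max(abs(new_off[, 2L]))
  out <- matrix(0, 2L * r1 + 1L, 2L * r2 + 1L)
  out[cbind(new_off[, 1L] + r1 + 1L, new_off[, 2L] + r2 + 1L)] <-
    kernel[idx]
  out
}

#' @export
print.nsct_filter_bank <- function(x, ...) {
  cat(sprintf("<nsct_filter_bank '%s' (%s)>\n", x$name, x$kind))
  cat(sprintf("  h0 %dx%d (sum %.4g)  h1 %dx%d (sum %.4g)\n",
              nrow(x$h0), ncol(x$h0), sum(x$h0),
              nrow(x$h1), ncol(x$h1), sum(x$h1)))
  cat(sprintf("  Bezout residual: %.3g\n", bezout_residual(x)))
  invisible(x)
}
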