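#' Nonsubsampled pyramid split and merge
#'
#' One level of the undecimated multiscale stage: the image is convolved
#' with the lowpass and highpass analysis kernels, a-trous upsampled by
#' `2^level * I`. Nothing is decimated, so both outputs keep the input's
#' shape and the split is exactly invertible by [nspfb_merge()].
#'
#' @param x Numeric matrix (intensities; the package works on `[0,1]`).
#' @param bank Pyramid `nsct_filter_bank` from [build_pyramid_filters()].
#' @param level Nonnegative integer; filters are upsampled by `2^level * I`.
#' @param boundary Extension mode. `"periodic"` (circular, the default)
#'   makes every split exactly invertible and the transform exactly
#'   shift-invariant under circular shifts; `"symmetric"` (half-sample
#'   mirror) avoids wrap-around artifacts at the borders but is only
#'   approximately invertible through the directional stage, whose
#'   quincunx-upsampled kernels are not mirror-symmetric axis by axis.
#' @return For `nspfb_split`, a list with matrices `low` and `high`; for
#'   `nspfb_merge`, the reconstructed matrix.
#' @export
nspfb_split <- function(x, bank, level = 0L,
                        boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  check_image(x)
  if (level < 0) stop_invalid("level must be >= 0")
  M <- (2^level) * diag(2)
  list(low = conv2_ext(x, atrous_upsample(bank$h0, M), boundary),
       high = conv2_ext(x, atrous_upsample(bank$h1, M), boundary))
}

#' @rdname nspfb_split
#' @param low,high Subbands produced by `nspfb_split` at the same `level`.
#' @export
nspfb_merge <- function(low, high, bank, level = 0L,
                        boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  M <- (2^level) * diag(2)
  conv2_ext(low, atrous_upsample(bank$g0, M), boundary) +
    conv2_ext(high, atrous_upsample(bank$g1, M), boundary)
}

# Sampling matrix for tree level l (1-based), parent channel k (1-based
# among 2^(l-1)). Level 1: identity; level 2: quincunx; level >= 3:
# parallelogram-type matrices in the style of the standard binary-tree
# directional filter bank. Any nonsingular choice preserves perfect
# reconstruction; these shape the directional wedges.
dfb_sampling_matrix <- function(l, k) {
  if (l == 1L) return(diag(2))
  if (l == 2L) return(matrix(c(1, 1, 1, -1), 2L, 2L))
  half <- 2L^(l - 2L)
  p <- 2L^(l - 3L)
  if (k <= half) {
    sk <- 2L * ((k - 1L) %/% 2L) - p + 1L
    2 * matrix(c(p, sk, 0, 1), 2L, 2L)
  } else {
    kk <- k - half
    sk <- 2L * ((kk - 1L) %/% 2L) - p + 1L
    2 * matrix(c(1, 0, sk, p), 2L, 2L)
  }
}

#' Nonsubsampled directional filter bank
#'
#' Splits an image (typically a bandpass subband) into `2^n_levels`
#' directional subbands through a binary tree of undecimated fan filters.
#' The first tree level applies the fan pair directly, the second applies it
#' upsampled by the quincunx matrix, deeper levels use parallelogram
#' sampling matrices. All subbands keep the source shape and
#' [nsdfb_merge()] restores the input exactly.
#'
#' @inheritParams nspfb_split
#' @param bank Fan `nsct_filter_bank` from [build_fan_filters()].
#' @param n_levels Tree depth; `0` returns the input unchanged as a single
#'   band.
#' @return For `nsdfb_split`, a list of `2^n_levels` matrices; for
#'   `nsdfb_merge`, the reconstructed matrix.
#' @export
nsdfb_split <- function(x, bank, n_levels,
                        boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  check_image(x)
  if (length(n_levels) != 1L || n_levels < 0 || n_levels != round(n_levels))
    stop_invalid("n_levels must be a nonnegative integer")
  bands <- list(x)
  if (n_levels == 0L) return(bands)
  for (l in seq_len(n_levels)) {
    nxt <- vector("list", 2L * length(bands))
    for (k in seq_along(bands)) {
      M <- dfb_sampling_matrix(l, k)
      nxt[[2L * k - 1L]] <-
        conv2_ext(bands[[k]], atrous_upsample(bank$h0, M), boundary)
      nxt[[2L * k]] <-
        conv2_ext(bands[[k]], atrous_upsample(bank$h1, M), boundary)
    }
    bands <- nxt
  }
  bands
}

#' @rdname nsdfb_split
#' @param bands List of `2^n` directional subbands from `nsdfb_split`.
#' @export
nsdfb_merge <- function(bands, bank, boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  n_levels <- as.integer(round(log2(length(bands))))
  if (2L^n_levels != length(bands))
    stop_invalid("number of bands must be a power of two")
  if (n_levels == 0L) return(bands[[1L]])
  for (l in n_levels:1L) {
    parents <- vector("list", length(bands) %/% 2L)
    for (k in seq_along(parents)) {
      M <- dfb_sampling_matrix(l, k)
      parents[[k]] <-
        conv2_ext(bands[[2L * k - 1L]], atrous_upsample(bank$g0, M), boundary) +
        conv2_ext(bands[[2L * k]], atrous_upsample(bank$g1, M), boundary)
    }
    bands <- parents
  }
  bands[[1L]]
}

#' Nonsubsampled contourlet decomposition
#'
#' Iteratively splits the running lowpass with the undecimated pyramid bank
#' (a-trous upsampled at each coarser scale), then fans each level's
#' bandpass into `2^dirs[j]` directional subbands. Every subband keeps the
#' source image's shape; the decomposition is exactly invertible by
#' [nsct_reconstruct()] and linear in the input.
#'
#' @inheritParams nspfb_split
#' @param levels Number of pyramid levels `M >= 1`.
#' @param dirs Integer vector of length `levels`: directional tree depth at
#'   each scale, finest scale first (entry `d` gives `2^d` bands; `0` keeps
#'   the bandpass undirectional). Default `c(3, 3, 2, 2)` truncated/recycled
#'   to `levels`.
#' @param pyr,fan Filter banks; defaults are built from `"pyrexc"`/`"vk"`.
#' @return An object of class `nsct_pyramid`: list with `low` (matrix),
#'   `highs` (list over levels, finest first, each a list of directional
#'   matrices), `levels`, `dirs`, `boundary`, and the filter names.
#' @examples
#' x <- matrix(runif(32 * 32), 32, 32)
#' p <- nsct_decompose(x, levels = 2, dirs = c(2, 1))
#' max(abs(nsct_reconstruct(p) - x))   # ~ 1e-12
#' @export
nsct_decompose <- function(x, levels = 4L, dirs = NULL,
                           pyr = build_pyramid_filters(),
                           fan = build_fan_filters(),
                           boundary = c("periodic", "symmetric")) {
  boundary <- match.arg(boundary)
  check_image(x)
  if (length(levels) != 1L || levels < 1L || levels != round(levels))
    stop_invalid("levels must be a positive integer")
  if (is.null(dirs)) dirs <- rep_len(c(3L, 3L, 2L, 2L), levels)
  if (length(dirs) != levels)
    stop_invalid("dirs must have one entry per level (", levels, ")")
  if (any(dirs < 0) || any(dirs != round(dirs)))
    stop_invalid("dirs entries must be nonnegative integers")

  low <- x
  highs <- vector("list", levels)
  for (j in seq_len(levels)) {
    sp <- nspfb_split(low, pyr, level = j - 1L, boundary = boundary)
    highs[[j]] <- nsdfb_split(sp$high, fan, dirs[j], boundary = boundary)
    low <- sp$low
  }
  structure(list(low = low, highs = highs, levels = as.integer(levels),
                 dirs = as.integer(dirs), boundary = boundary,
                 pyramid_filter = pyr$name, fan_filter = fan$name),
            class = "nsct_pyramid")
}

#' Inverse nonsubsampled contourlet transform
#'
#' Exact inverse of [nsct_decompose()]: each level's directional bands are
#' merged back into a bandpass image, then recombined with the running
#' lowpass through the synthesis pyramid filters, coarsest scale first.
#'
#' @param p An `nsct_pyramid`.
#' @inheritParams nsct_decompose
#' @return The reconstructed matrix (same shape as every band).
#' @export
nsct_reconstruct <- function(p, pyr = build_pyramid_filters(),
                             fan = build_fan_filters(),
                             boundary = NULL) {
  if (!inherits(p, "nsct_pyramid"))
    stop_invalid("p must be an nsct_pyramid")
  if (is.null(boundary)) boundary <- p$boundary
  if (length(p$highs) != p$levels || length(p$dirs) != p$levels)
    stop_invalid("inconsistent pyramid: highs/dirs do not match levels")
  for (j in seq_len(p$levels)) {
    if (length(p$highs[[j]]) != 2L^p$dirs[j])
      stop_invalid("inconsistent pyramid: level ", j, " has ",
                   length(p$highs[[j]]), " bands, expected ", 2L^p$dirs[j])
  }
  low <- p$low
  for (j in p$levels:1L) {
    high <- nsdfb_merge(p$highs[[j]], fan, boundary = boundary)
    low <- nspfb_merge(low, high, pyr, level = j - 1L, boundary = boundary)
  }
  low
}

#' @export
print.nsct_pyramid <- function(x, ...) {
  nb <- 1L + sum(2L^x$dirs)
  cat(sprintf("<nsct_pyramid: %d levels, dirs [%s], %d bands of %dx%d, %s boundary>\n",
              x$levels, paste(2L^x$dirs, collapse = ","), nb,
              nrow(x$low), ncol(x$low), x$boundary))
  invisible(x)
}
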