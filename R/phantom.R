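#' Specification of a synthetic complementary-modality phantom pair
#'
#' Describes a deterministic pair of co-registered "brain slice" phantoms
#' sharing an elliptical skull/anatomy but carrying structures visible in
#' only one modality each — emulating, e.g., CT bone contrast versus MR
#' soft-tissue contrast. Identical `(spec, seed)` always produces bitwise
#' identical images.
#'
#' @param size Image side in pixels (square images).
#' @param seed RNG seed for structure placement and noise.
#' @param n_structures Number of single-modality ellipse structures;
#'   odd-indexed structures are bright in A only, even-indexed in B only.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param background,interior,skull,structure Intensity levels in `[0,1]`
#'   of the shared background, shared brain interior, shared skull ring,
#'   and the modality-specific structures.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 256L, seed = 1L, n_structures = 4L,
                         noise_sigma = 0.01,
                         background = 0.05, interior = 0.3,
                         skull = 0.85, structure = 0.9) {
  if (size < 8L) stop_invalid("size must be at least 8")
  if (noise_sigma < 0) stop_invalid("noise_sigma must be nonnegative")
  if (n_structures < 0) stop_invalid("n_structures must be nonnegative")
  structure(list(size = as.integer(size), seed = as.integer(seed),
                 n_structures = as.integer(n_structures),
                 noise_sigma = noise_sigma, background = background,
                 interior = interior, skull = skull,
                 structure = structure),
            class = "phantom_spec")
}

ellipse_mask <- function(size, cx, cy, rx, ry, theta = 0) {
  x <- matrix(rep(seq_len(size), each = size), size, size)  # column index
  y <- matrix(rep(seq_len(size), times = size), size, size) # row index
  ct <- cos(theta); st <- sin(theta)
  u <- (x - cx) * ct + (y - cy) * st
  v <- -(x - cx) * st + (y - cy) * ct
  (u / rx)^2 + (v / ry)^2 <= 1
}

# Shared anatomy: skull ring + interior, identical in both modalities.
phantom_anatomy <- function(spec) {
  s <- spec$size
  c0 <- (s + 1) / 2
  outer_m <- ellipse_mask(s, c0, c0, 0.46 * s, 0.40 * s)
  inner_m <- ellipse_mask(s, c0, c0, 0.40 * s, 0.34 * s)
  img <- matrix(spec$background, s, s)
  img[outer_m] <- spec$skull
  img[inner_m] <- spec$interior
  list(img = img, interior = inner_m)
}

# Sample non-overlapping structure ellipses inside the brain interior.
sample_structures <- function(spec, interior) {
  s <- spec$size
  c0 <- (s + 1) / 2
  masks <- list()
  occupied <- matrix(FALSE, s, s)
  attempts <- 0L
  while (length(masks) < spec$n_structures && attempts < 500L) {
    attempts <- attempts + 1L
    r <- stats::runif(1, 0.05, 0.25) * 0.34 * s
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0, 0.6)
    cx <- c0 + rad * 0.40 * s * cos(ang)
    cy <- c0 + rad * 0.34 * s * sin(ang)
    m <- ellipse_mask(s, cx, cy, r * stats::runif(1, 0.8, 1.4), r,
                      stats::runif(1, 0, pi))
    grown <- ellipse_mask(s, cx, cy, 1.6 * r * 1.4, 1.6 * r,
                          0)  # clearance zone
    if (!any(m & !interior) && !any(grown & occupied)) {
      occupied <- occupied | grown
      masks[[length(masks) + 1L]] <- m
    }
  }
  masks
}

#' Generate a complementary-modality phantom pair
#'
#' Draws the shared anatomy, places `n_structures` non-overlapping ellipse
#' structures inside it (alternately bright in modality A only and in
#' modality B only), adds independent seeded Gaussian noise to each
#' modality, and clips to `[0,1]`. With `noise_sigma = 0` and
#' `n_structures = 0` the two images are identical.
#'
#' @param spec A [phantom_spec()].
#' @return List with matrices `A`, `B`, and `masks`: a list holding the
#'   `interior` anatomy mask, per-structure masks `structures`, and the
#'   `modality` ("A" or "B") each structure is visible in.
#' @examples
#' ph <- make_phantom_pair(phantom_spec(size = 64, seed = 7))
#' range(ph$A)
#' @export
make_phantom_pair <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop_invalid("spec must be a phantom_spec")
  with_seed(spec$seed, {
    an <- phantom_anatomy(spec)
    A <- an$img
    B <- an$img
    masks <- sample_structures(spec, an$interior)
    modality <- rep(c("A", "B"), length.out = length(masks))
    for (i in seq_along(masks)) {
      if (modality[i] == "A") A[masks[[i]]] <- spec$structure
      else B[masks[[i]]] <- spec$structure
    }
    if (spec$noise_sigma > 0) {
      s <- spec$size
      A <- A + matrix(stats::rnorm(s * s, 0, spec$noise_sigma), s, s)
      B <- B + matrix(stats::rnorm(s * s, 0, spec$noise_sigma), s, s)
    }
    list(A = clip01(A), B = clip01(B),
         masks = list(interior = an$interior, structures = masks,
                      modality = modality))
  })
}

#' Generate an anatomical/functional phantom pair
#'
#' Emulates an MR + SPECT/PET pairing: a grayscale anatomical phantom (with
#' its own structures) plus a pseudo-color functional image sharing the
#' anatomy outline, whose "activity" is a sum of smooth Gaussian blobs
#' mapped through a hot-body color ramp over a dim smooth baseline.
#'
#' @param spec A [phantom_spec()]; `n_structures` counts the activity blobs.
#' @return List with `gray` (matrix), `color` (`size x size x 3` array),
#'   and `masks` (anatomy `interior`, activity blob masks `structures`).
#' @export
make_functional_pair <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop_invalid("spec must be a phantom_spec")
  with_seed(spec$seed, {
    an <- phantom_anatomy(spec)
    gray <- an$img
    gmasks <- sample_structures(spec, an$interior)
    for (m in gmasks) gray[m] <- spec$structure
    s <- spec$size
    if (spec$noise_sigma > 0)
      gray <- gray + matrix(stats::rnorm(s * s, 0, spec$noise_sigma), s, s)

    # Smooth low-frequency activity field.
    c0 <- (s + 1) / 2
    xg <- matrix(rep(seq_len(s), each = s), s, s)
    yg <- matrix(rep(seq_len(s), times = s), s, s)
    act <- matrix(0, s, s)
    bmasks <- list()
    n_blobs <- spec$n_structures
    for (i in seq_len(n_blobs)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 0.55)
      cx <- c0 + rad * 0.40 * s * cos(ang)
      cy <- c0 + rad * 0.34 * s * sin(ang)
      w <- stats::runif(1, 0.05, 0.10) * s
      g <- exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * w^2))
      act <- act + g
      bmasks[[i]] <- g > exp(-0.5)  # within one sigma of the blob center
    }
    act <- pmin(act, 1) * an$interior
    base <- 0.25 * an$interior + 0.05
    color <- array(0, c(s, s, 3L))
    color[, , 1L] <- base + 0.75 * act            # hot ramp: red first,
    color[, , 2L] <- base + 0.60 * act^2          # then yellow
    color[, , 3L] <- base
    list(gray = clip01(gray), color = clip01(color),
         masks = list(interior = an$interior, structures = bmasks))
  })
}
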