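#' Fusion pipeline configuration
#'
#' Bundles every tunable of the fusion pipeline. The defaults reproduce the
#' reference setting: 4 pyramid levels, `"pyrexc"`/`"vk"` filters,
#' directional depths `c(3, 3, 2, 2)` (8, 8, 4, 4 bands, finest to
#' coarsest), the default [pcnn_params()], PCNN selection rule, periodic
#' boundary (exact reconstruction), and luminance-channel handling for
#' color functional images.
#'
#' @param levels Pyramid depth.
#' @param dirs Directional tree depth per level, finest first.
#' @param pyramid_filter,fan_filter Filter family names.
#' @param pcnn A [pcnn_params()] object.
#' @param rule Subband fusion rule: `"pcnn"` (firing-count selection),
#'   `"average"`, or `"max_abs"`.
#' @param color_mode `"luminance"` (fuse the luminance channel of a color
#'   input, keep its chrominance) or `"none"`.
#' @param boundary `"periodic"` (exactly invertible, default) or
#'   `"symmetric"` extension.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(levels = 4L, dirs = c(3L, 3L, 2L, 2L),
                          pyramid_filter = "pyrexc", fan_filter = "vk",
                          pcnn = pcnn_params(),
                          rule = c("pcnn", "average", "max_abs"),
                          color_mode = c("luminance", "none"),
                          boundary = c("periodic", "symmetric")) {
  rule <- match.arg(rule)
  color_mode <- match.arg(color_mode)
  boundary <- match.arg(boundary)
  if (length(dirs) != levels)
    stop_config("dirs must have one entry per level")
  structure(list(levels = as.integer(levels), dirs = as.integer(dirs),
                 pyramid_filter = pyramid_filter, fan_filter = fan_filter,
                 pcnn = pcnn, rule = rule, color_mode = color_mode,
                 boundary = boundary),
            class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat(sprintf("<fusion_config: levels=%d dirs=[%s] %s/%s rule=%s %s boundary>\n",
              x$levels, paste(x$dirs, collapse = ","), x$pyramid_filter,
              x$fan_filter, x$rule, x$boundary))
  invisible(x)
}

#' Fuse one pair of subbands by PCNN firing-count comparison
#'
#' Each band is mapped to a stimulus with [normalize_stimulus()] and run
#' through its own PCNN; the fused band copies, per pixel, the coefficient
#' of the source whose neuron fired strictly more often (`T_A > T_B` picks
#' A, otherwise — including ties — B). The rule selects, it never blends.
#'
#' @param bandA,bandB Same-shape numeric matrices.
#' @param params A [pcnn_params()] object.
#' @param is_highpass Passed to [normalize_stimulus()].
#' @return Fused band (matrix).
#' @export
fuse_band_pcnn <- function(bandA, bandB, params = pcnn_params(),
                           is_highpass = TRUE) {
  check_image(bandA, "bandA"); check_image(bandB, "bandB")
  check_same_shape(bandA, bandB, "bands")
  ta <- pcnn_firing_map(normalize_stimulus(bandA, is_highpass), params)
  tb <- pcnn_firing_map(normalize_stimulus(bandB, is_highpass), params)
  out <- bandB
  sel <- ta > tb
  out[sel] <- bandA[sel]
  out
}

fuse_band_rule <- function(bandA, bandB, cfg, is_highpass) {
  switch(cfg$rule,
         pcnn = fuse_band_pcnn(bandA, bandB, cfg$pcnn, is_highpass),
         average = (bandA + bandB) / 2,
         max_abs = {
           out <- bandB
           sel <- abs(bandA) > abs(bandB)
           out[sel] <- bandA[sel]
           out
         })
}

#' Fuse two decomposed pyramids band by band
#'
#' Applies the configured rule to the lowpass pair and to every directional
#' pair independently, returning a fused `nsct_pyramid` ready for
#' [nsct_reconstruct()]. Exposed so the per-band selection behaviour can be
#' inspected before reconstruction.
#'
#' @param pA,pB `nsct_pyramid` objects with identical structure.
#' @param cfg A [fusion_config()].
#' @return A fused `nsct_pyramid`.
#' @export
fuse_subbands <- function(pA, pB, cfg = fusion_config()) {
  if (!inherits(pA, "nsct_pyramid") || !inherits(pB, "nsct_pyramid"))
    stop_invalid("pA and pB must be nsct_pyramid objects")
  if (!identical(pA$dirs, pB$dirs) || !identical(pA$levels, pB$levels))
    stop_invalid("pyramids must share structure")
  out <- pA
  out$low <- fuse_band_rule(pA$low, pB$low, cfg, is_highpass = FALSE)
  for (j in seq_len(pA$levels)) {
    for (k in seq_along(pA$highs[[j]])) {
      out$highs[[j]][[k]] <- fuse_band_rule(pA$highs[[j]][[k]],
                                            pB$highs[[j]][[k]], cfg,
                                            is_highpass = TRUE)
    }
  }
  out
}

#' Fuse two co-registered grayscale images
#'
#' The full pipeline: both sources are decomposed with the nonsubsampled
#' contourlet transform, each subband pair is fused (by default by PCNN
#' firing-count selection), and the fused pyramid is inverted. The result
#' is clipped to `[0,1]`.
#'
#' @param A,B Same-shape matrices with intensities in `[0,1]`.
#' @param cfg A [fusion_config()].
#' @return Fused image matrix in `[0,1]`.
#' @examples
#' ph <- make_phantom_pair(phantom_spec(size = 64, seed = 1))
#' Fz <- fuse_images(ph$A, ph$B, fusion_config(pcnn = pcnn_params(n_iter = 20)))
#' @export
fuse_images <- function(A, B, cfg = fusion_config()) {
  check_image(A, "A"); check_image(B, "B")
  check_same_shape(A, B)
  pyr <- build_pyramid_filters(cfg$pyramid_filter)
  fan <- build_fan_filters(cfg$fan_filter)
  pA <- nsct_decompose(A, cfg$levels, cfg$dirs, pyr, fan, cfg$boundary)
  pB <- nsct_decompose(B, cfg$levels, cfg$dirs, pyr, fan, cfg$boundary)
  pf <- fuse_subbands(pA, pB, cfg)
  clip01(nsct_reconstruct(pf, pyr, fan, cfg$boundary))
}

# NTSC YIQ <-> RGB, rows are Y, I, Q.
.rgb2yiq <- matrix(c(0.299, 0.587, 0.114,
                     0.595716, -0.274453, -0.321263,
                     0.211456, -0.522591, 0.311135),
                   3L, 3L, byrow = TRUE)
.yiq2rgb <- solve(.rgb2yiq)

rgb_to_yiq <- function(rgb) {
  d <- dim(rgb)
  m <- matrix(rgb, ncol = 3L) %*% t(.rgb2yiq)
  array(m, d)
}

yiq_to_rgb <- function(yiq) {
  d <- dim(yiq)
  m <- matrix(yiq, ncol = 3L) %*% t(.yiq2rgb)
  array(m, d)
}

#' Fuse a grayscale anatomical image with a pseudo-color functional image
#'
#' The color image (e.g. a SPECT or PET pseudo-color map) is converted to
#' YIQ; its luminance channel is fused with the grayscale image by
#' [fuse_images()], the original chrominance is kept, and the result is
#' converted back to RGB and clipped. This preserves the functional color
#' coding while injecting anatomical detail into the luminance.
#'
#' @param gray Matrix in `[0,1]`.
#' @param color `h x w x 3` RGB array in `[0,1]`, same spatial shape.
#' @param cfg A [fusion_config()].
#' @return `h x w x 3` fused RGB array in `[0,1]`.
#' @export
fuse_gray_color <- function(gray, color, cfg = fusion_config()) {
  check_image(gray, "gray")
  if (length(dim(color)) != 3L || dim(color)[3L] != 3L)
    stop_invalid("color must be an h x w x 3 array")
  if (!identical(dim(gray), dim(color)[1:2]))
    stop_invalid("gray and color must share spatial dimensions")
  yiq <- rgb_to_yiq(color)
  lum <- clip01(yiq[, , 1L])
  yiq[, , 1L] <- fuse_images(gray, lum, cfg)
  clip01(yiq_to_rgb(yiq))
}
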