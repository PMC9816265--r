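# Fusion quality metrics. All functions take images with intensities in
# [0,1] and evaluate on the 8-bit scale: histogram-based measures (EN, MI,
# NCC/Q_ncie) quantize to integer gray levels round(255*x); PSNR, SD and AG
# use the un-quantized 255-scaled values.

quantize255 <- function(x) {
  q <- round(255 * x)
  storage.mode(q) <- "integer"
  q
}

#' Shannon entropy of an image (bits)
#'
#' `-sum p_l log2 p_l` over the 256-bin gray-level histogram of the image
#' quantized to 8 bits; empty bins contribute zero.
#'
#' @param img Matrix in `[0,1]`.
#' @return Entropy in bits, in `[0, 8]`.
#' @export
entropy <- function(img) {
  check_image(img, "img")
  p <- tabulate(quantize255(img) + 1L, 256L) / length(img)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between sources and fused image
#'
#' `mi_af` is the mutual information (bits) between source `A` and the fused
#' image `F`, computed from their 256 x 256 joint gray-level histogram;
#' `mi = mi_af + mi_bf` aggregates both sources.
#'
#' @param A,B,F Same-shape matrices in `[0,1]`.
#' @return List with `mi`, `mi_af`, `mi_bf`.
#' @export
mutual_information <- function(A, B, F) {
  check_image(A, "A"); check_image(B, "B"); check_image(F, "F")
  check_same_shape(A, F); check_same_shape(B, F)
  mi_af <- mi_pair(A, F)
  mi_bf <- mi_pair(B, F)
  list(mi = mi_af + mi_bf, mi_af = mi_af, mi_bf = mi_bf)
}

mi_pair <- function(X, Y) {
  qx <- quantize255(X); qy <- quantize255(Y)
  n <- length(qx)
  joint <- tabulate(qx * 256L + qy + 1L, 256L * 256L) / n
  jm <- matrix(joint, 256L, 256L)  # rows: Y levels, cols: X levels
  px <- colSums(jm); py <- rowSums(jm)
  nz <- which(jm > 0, arr.ind = TRUE)
  pj <- jm[nz]
  sum(pj * log2(pj / (px[nz[, 2L]] * py[nz[, 1L]])))
}

#' Edge-information preservation Q^AB/F
#'
#' The Xydeas-Petrovic gradient-transfer measure: Sobel edge strength and
#' orientation are extracted from each source and from the fused image;
#' per-pixel preservation factors are sigmoid functions of the relative
#' strength and of the orientation agreement, and their product is averaged
#' with the source edge strengths as weights. The sigmoid amplitudes are
#' normalized so that perfect preservation (identical gradients) scores
#' exactly 1; the score lies in `[0, 1]`.
#'
#' @param A,B,F Same-shape matrices in `[0,1]`.
#' @param k_g,sigma_g Strength-sigmoid slope and offset.
#' @param k_a,sigma_a Orientation-sigmoid slope and offset.
#' @param L Edge-strength weighting exponent.
#' @return Score in `[0, 1]`; `0` when both sources are constant.
#' @export
q_abf <- function(A, B, F, k_g = -15, sigma_g = 0.5,
                  k_a = -22, sigma_a = 0.8, L = 1) {
  check_image(A, "A"); check_image(B, "B"); check_image(F, "F")
  check_same_shape(A, F); check_same_shape(B, F)
  ga <- sobel_edges(A); gb <- sobel_edges(B); gf <- sobel_edges(F)
  qaf <- edge_preservation(ga, gf, k_g, sigma_g, k_a, sigma_a)
  qbf <- edge_preservation(gb, gf, k_g, sigma_g, k_a, sigma_a)
  wa <- ga$g^L; wb <- gb$g^L
  den <- sum(wa + wb)
  if (den == 0) return(0)
  sum(qaf * wa + qbf * wb) / den
}

# Direct (non-FFT) convolution with mirrored extension: exact zeros on
# constant regions, which the weight normalization of q_abf relies on.
conv2_direct_sym <- function(x, k) {
  r1 <- (nrow(k) - 1L) %/% 2L
  r2 <- (ncol(k) - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  xp <- x[ext_index((1L - r1):(h + r1), h, "symmetric"),
          ext_index((1L - r2):(w + r2), w, "symmetric"), drop = FALSE]
  out <- matrix(0, h, w)
  for (p in -r1:r1) {
    for (q in -r2:r2) {
      wgt <- k[p + r1 + 1L, q + r2 + 1L]
      if (wgt == 0) next
      out <- out + wgt * xp[(1L - p + r1):(h - p + r1),
                            (1L - q + r2):(w - q + r2), drop = FALSE]
    }
  }
  out
}

sobel_edges <- function(img) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L, byrow = TRUE)
  gx <- conv2_direct_sym(img, sx)
  gy <- conv2_direct_sym(img, t(sx))
  g <- sqrt(gx^2 + gy^2)
  g[g < 1e-12] <- 0            # flat regions: exact zero weight
  a <- atan(gy / gx)           # in (-pi/2, pi/2]; gx = 0 -> +-pi/2
  a[is.nan(a)] <- 0            # flat pixels (0/0)
  list(g = g, a = a)
}

edge_preservation <- function(src, fus, k_g, sigma_g, k_a, sigma_a) {
  gs <- src$g; gf <- fus$g
  G <- ifelse(gs == gf, 1, pmin(gs, gf) / pmax(gs, gf))
  G[gs == 0 & gf == 0] <- 1   # no edge to lose
  Aa <- 1 - abs(src$a - fus$a) / (pi / 2)
  qg <- (1 + exp(k_g * (1 - sigma_g))) / (1 + exp(k_g * (G - sigma_g)))
  qa <- (1 + exp(k_a * (1 - sigma_a))) / (1 + exp(k_a * (Aa - sigma_a)))
  qg * qa
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(255^2 / MSE)` with the mean squared error taken between the
#' two images on the 0-255 intensity scale. Identical images give `Inf`.
#'
#' @param ref,out Same-shape matrices in `[0,1]`.
#' @return PSNR in dB (`Inf` when MSE is zero).
#' @export
psnr <- function(ref, out) {
  check_image(ref, "ref"); check_image(out, "out")
  check_same_shape(ref, out)
  mse <- mean((255 * (ref - out))^2)
  if (mse == 0) Inf else 10 * log10(255^2 / mse)
}

#' Standard deviation of an image (0-255 scale)
#'
#' Population standard deviation of the intensities about their mean — a
#' global contrast measure.
#'
#' @param img Matrix in `[0,1]`.
#' @return Standard deviation in 8-bit intensity units.
#' @export
img_sd <- function(img) {
  check_image(img, "img")
  v <- 255 * img
  sqrt(mean((v - mean(v))^2))
}

#' Average gradient of an image (0-255 scale)
#'
#' Mean over the `(M-1) x (N-1)` valid region of
#' `sqrt((dx^2 + dy^2)/2)` with forward differences
#' `dx = F(m,n) - F(m+1,n)` and `dy = F(m,n) - F(m,n+1)`; a sharpness /
#' texture-detail measure.
#'
#' @param img Matrix in `[0,1]`, at least 2x2.
#' @return Average gradient in 8-bit intensity units.
#' @export
avg_gradient <- function(img) {
  check_image(img, "img")
  m <- nrow(img); n <- ncol(img)
  if (m < 2L || n < 2L) stop_invalid("img must be at least 2x2")
  v <- 255 * img
  dx <- v[1:(m - 1), 1:(n - 1)] - v[2:m, 1:(n - 1)]
  dy <- v[1:(m - 1), 1:(n - 1)] - v[1:(m - 1), 2:n]
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Nonlinear correlation coefficient of an image pair
#'
#' `NCC(X,Y) = 2 + sum_i (n_i/N) log_b (n_i/N)` over the `b x b` joint
#' gray-level histogram (`b = 256`); `1` for identical uniform-histogram
#' images, `0` for an exactly uniform independent joint distribution.
#'
#' @param X,Y Same-shape matrices in `[0,1]`.
#' @param b Number of gray levels (histogram side).
#' @return The nonlinear correlation coefficient.
#' @export
ncc <- function(X, Y, b = 256L) {
  check_image(X, "X"); check_image(Y, "Y")
  check_same_shape(X, Y)
  qx <- quantize255(X); qy <- quantize255(Y)
  n <- length(qx)
  p <- tabulate(qx * as.integer(b) + qy + 1L, as.integer(b)^2) / n
  p <- p[p > 0]
  2 + sum(p * log(p) / log(b))
}

#' Nonlinear correlation information entropy Q_ncie
#'
#' The pairwise nonlinear correlation coefficients of `(A, B, F)` are
#' assembled into a symmetric 3x3 matrix with unit diagonal; with
#' eigenvalues `lambda_i`, `Q_ncie = 1 + sum (lambda_i/3) log_b
#' (lambda_i/3)` (`b = 256`, zero eigenvalues contribute zero). Identical
#' uniform-histogram inputs give 1.
#'
#' @param A,B,F Same-shape matrices in `[0,1]`.
#' @param b Number of gray levels.
#' @return The Q_ncie score.
#' @export
q_ncie <- function(A, B, F, b = 256L) {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- ncc(A, B, b)
  R[1, 3] <- R[3, 1] <- ncc(A, F, b)
  R[2, 3] <- R[3, 2] <- ncc(B, F, b)
  lam <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  contrib <- vapply(lam, function(l) {
    if (l <= 0) 0 else (l / 3) * log(l / 3) / log(b)
  }, numeric(1))
  1 + sum(contrib)
}

#' Full fusion quality report
#'
#' Evaluates all seven measures for one `(A, B, F)` triple: entropy of the
#' fused image, total mutual information, Q^AB/F, PSNR (mean of
#' `psnr(A,F)` and `psnr(B,F)`), standard deviation, average gradient, and
#' Q_ncie.
#'
#' @param A,B Source images in `[0,1]`.
#' @param F Fused image in `[0,1]`.
#' @return An object of class `fusion_report` (named list of scalars, plus
#'   `mi_af`/`mi_bf` components).
#' @export
fusion_report <- function(A, B, F) {
  mi <- mutual_information(A, B, F)
  structure(list(en = entropy(F),
                 mi = mi$mi, mi_af = mi$mi_af, mi_bf = mi$mi_bf,
                 q_abf = q_abf(A, B, F),
                 psnr = mean(c(psnr(A, F), psnr(B, F))),
                 sd = img_sd(F),
                 ag = avg_gradient(F),
                 q_ncie = q_ncie(A, B, F)),
            class = "fusion_report")
}

#' @export
print.fusion_report <- function(x, ...) {
  cat("Fusion quality report\n")
  cat(sprintf("  EN     %8.4f bits\n", x$en))
  cat(sprintf("  MI     %8.4f bits (AF %.4f, BF %.4f)\n",
              x$mi, x$mi_af, x$mi_bf))
  cat(sprintf("  QABF   %8.4f\n", x$q_abf))
  cat(sprintf("  PSNR   %8.4f dB\n", x$psnr))
  cat(sprintf("  SD     %8.4f\n", x$sd))
  cat(sprintf("  AG     %8.4f\n", x$ag))
  cat(sprintf("  QNCIE  %8.4f\n", x$q_ncie))
  invisible(x)
}

#' @export
as.data.frame.fusion_report <- function(x, ...) {
  data.frame(EN = x$en, MI = x$mi, QABF = x$q_abf, PSNR = x$psnr,
             SD = x$sd, AG = x$ag, QNCIE = x$q_ncie)
}
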