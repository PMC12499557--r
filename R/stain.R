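#' H-DAB stain matrix
#'
#' Optical-density vectors for the hematoxylin and DAB stains with a
#' residual channel completing the basis. Rows are unit-L2-norm stain
#' vectors (hematoxylin, DAB, residual) in RGB order; this is the
#' Ruifrok-Johnston H-DAB basis used throughout the digital-pathology
#' ecosystem. The residual row is the normalized cross product of the two
#' stain rows, so the matrix is always invertible.
#'
#' @param h,dab length-3 optical-density vectors for hematoxylin and DAB;
#'   normalized internally.
#' @return A 3x3 matrix of class `stain_matrix`, rows
#'   `c("hematoxylin","dab","residual")`, columns `c("R","G","B")`.
#' @export
#' @examples
#' M <- stain_matrix_hdab()
#' rowSums(M^2)  # each row unit norm
stain_matrix_hdab <- function(h = c(0.650, 0.704, 0.286),
                              dab = c(0.269, 0.568, 0.778)) {
  h <- h / sqrt(sum(h^2))
  dab <- dab / sqrt(sum(dab^2))
  res <- c(h[2] * dab[3] - h[3] * dab[2],
           h[3] * dab[1] - h[1] * dab[3],
           h[1] * dab[2] - h[2] * dab[1])
  res <- res / sqrt(sum(res^2))
  M <- rbind(hematoxylin = h, dab = dab, residual = res)
  colnames(M) <- c("R", "G", "B")
  class(M) <- c("stain_matrix", class(M))
  M
}

#' Convert an RGB image to optical density
#'
#' Beer-Lambert transform `OD = -log10((I + eps) / (I0 + eps))` with
#' `I0 = 255`. The `eps` offset guards the logarithm at zero intensity; it
#' is applied to both numerator and denominator so that pure white maps to
#' exactly zero OD and the transform is exactly inverted by
#' [od_to_rgb()] / [forward_stain_render()].
#'
#' @param image numeric array (H, W, 3), values in `[0, 255]` (uint8 scale).
#' @param eps log guard, default 1.
#' @return OD array of the same shape, `>= 0` for `image <= 255`.
#' @export
rgb_to_od <- function(image, eps = 1) {
  image <- as_rgb_array(image)
  stopifnot(min(image) >= 0, max(image) <= 255)
  -log10((image + eps) / (255 + eps))
}

#' Convert optical density back to RGB intensity
#'
#' Exact inverse of [rgb_to_od()]: `I = (I0 + eps) * 10^(-OD) - eps`.
#'
#' @param od OD array (H, W, 3).
#' @inheritParams rgb_to_od
#' @return numeric array in `[0, 255]` (clamped).
#' @export
od_to_rgb <- function(od, eps = 1) {
  clamp((255 + eps) * 10^(-od) - eps, 0, 255)
}

#' Unmix an optical-density image into stain concentrations
#'
#' Solves the linear Beer-Lambert mixture `OD = c_h * H + c_dab * D +
#' c_res * R` per pixel, i.e. concentrations `C = OD %*% M^-1` where rows of
#' `M` are the stain vectors. Negative concentrations (noise outside the
#' stain simplex) are clipped to zero after unmixing, so the pre-clip
#' operation stays linear.
#'
#' @param od OD array (H, W, 3) as produced by [rgb_to_od()].
#' @param M a [stain_matrix_hdab()]-style 3x3 stain matrix.
#' @param clip clip negative concentrations to 0 (default `TRUE`); set
#'   `FALSE` to obtain the raw linear unmixing.
#' @return list with matrices `hematoxylin`, `dab`, `residual` (H x W).
#' @export
deconvolve <- function(od, M = stain_matrix_hdab(), clip = TRUE) {
  stopifnot(length(dim(od)) == 3, dim(od)[3] == 3, all(dim(M) == c(3, 3)))
  if (abs(det(M)) < 1e-12)
    stop("stain matrix is singular; cannot deconvolve")
  d <- dim(od)
  odm <- matrix(od, ncol = 3)
  conc <- odm %*% solve(M)
  if (clip) conc[conc < 0] <- 0
  out <- lapply(1:3, function(k) matrix(conc[, k], d[1], d[2]))
  names(out) <- c("hematoxylin", "dab", "residual")
  out
}

#' Nucleus-detection preprocessing chain
#'
#' Isolates the hematoxylin channel by color deconvolution, rescales it to
#' `[0, 1]`, and applies a Gaussian blur to suppress noise — the
#' single-channel input expected by the star-convex nucleus detector.
#'
#' @param image RGB array (H, W, 3) in `[0, 255]`.
#' @param M stain matrix, default H-DAB.
#' @param blur_sigma Gaussian sigma in pixels, default 1; `0` skips the blur.
#' @return numeric matrix (H x W) in `[0, 1]`.
#' @export
nuclei_preprocess <- function(image, M = stain_matrix_hdab(),
                              blur_sigma = 1.0) {
  stopifnot(blur_sigma >= 0)
  h <- deconvolve(rgb_to_od(image), M)$hematoxylin
  rng <- range(h)
  h <- if (rng[2] > rng[1]) (h - rng[1]) / (rng[2] - rng[1]) else h * 0
  if (blur_sigma > 0)
    h <- as.matrix(EBImage::gblur(h, sigma = blur_sigma))
  h
}

# Accept (H,W,3) arrays, or EBImage/other objects coercible to such.
as_rgb_array <- function(image) {
  a <- unclass(image)
  if (is.matrix(a)) stop("expected an RGB image with 3 channels")
  d <- dim(a)
  if (length(d) != 3 || d[3] != 3)
    stop("expected an (H, W, 3) RGB array, got dims ",
         paste(d, collapse = "x"))
  storage.mode(a) <- "double"
  a
}
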