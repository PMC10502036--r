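flip_h <- function(x) {
  if (length(dim(x)) == 3L) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  else x[, rev(seq_len(ncol(x))), drop = FALSE]
}

flip_v <- function(x) {
  if (length(dim(x)) == 3L) x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  else x[rev(seq_len(nrow(x))), , drop = FALSE]
}

rot90cw <- function(x) {
  if (length(dim(x)) == 3L) {
    aperm(x, c(2L, 1L, 3L))[, rev(seq_len(dim(x)[1])), , drop = FALSE]
  } else {
    t(x)[, rev(seq_len(nrow(x))), drop = FALSE]
  }
}

#' Random flip / rotation augmentation
#'
#' Horizontal flip, vertical flip, and a 90-degree rotation are each
#' applied with probability `p` (default 0.5), identically to the image and
#' the mask. Randomness comes from the R session RNG; `force` overrides the
#' draws for exact tests (`c(hflip, vflip, rot90)` logicals).
#'
#' @param sample a `seg_sample`.
#' @param p per-transform application probability.
#' @param force optional logical vector of length 3 replacing the draws.
#' @return the augmented `seg_sample`.
#' @export
augment <- function(sample, p = 0.5, force = NULL) {
  do_ops <- force %||% (stats::runif(3) < p)
  img <- sample$image; mask <- sample$mask
  if (do_ops[1]) { img <- flip_h(img); mask <- flip_h(mask) }
  if (do_ops[2]) { img <- flip_v(img); mask <- flip_v(mask) }
  if (do_ops[3]) { img <- rot90cw(img); mask <- rot90cw(mask) }
  sample$image <- img; sample$mask <- mask
  sample
}

#' Color exchange between two samples
#'
#' Transfers per-channel color statistics from a donor image to a recipient:
#' `image' = (image - mu_a) / sigma_a * sigma_b + mu_b` for each RGB
#' channel, decoupling polyp shape from color. A zero-variance recipient
#' channel is passed through unchanged. The mask is not touched.
#'
#' @param sample_a recipient `seg_sample`.
#' @param sample_b donor `seg_sample`.
#' @return `sample_a` with recolored image.
#' @export
color_exchange <- function(sample_a, sample_b) {
  img <- sample_a$image
  for (ch in 1:3) {
    a <- img[, , ch]; b <- sample_b$image[, , ch]
    sa <- stats::sd(a)
    if (sa == 0) next
    img[, , ch] <- (a - mean(a)) / sa * stats::sd(b) + mean(b)
  }
  sample_a$image <- img
  sample_a
}

#' Multi-scale training resize
#'
#' Resizes the sample to `base x base` (352 by default), then rescales to a
#' side drawn from `sizes` with probabilities `probs` — multi-scale size
#' selection for scale-robust training. Images are resized bilinearly,
#' masks with nearest neighbor so they stay binary.
#'
#' @param sample a `seg_sample`.
#' @param base canonical training size.
#' @param sizes candidate sides.
#' @param probs selection probabilities (must sum to 1).
#' @param force optional fixed side overriding the draw.
#' @return the resized `seg_sample`.
#' @export
multiscale_resize <- function(sample, base = 352L,
                              sizes = c(256L, 288L, 320L, 352L),
                              probs = c(0.1, 0.2, 0.3, 0.4), force = NULL) {
  stopifnot(length(sizes) == length(probs), abs(sum(probs) - 1) < 1e-9)
  side <- force %||% base::sample(sizes, 1L, prob = probs)
  img <- sample$image; mask <- sample$mask
  if (nrow(mask) != base || ncol(mask) != base) {
    img <- resize_image(img, base, base, "bilinear")
    mask <- resize_image(array(mask, dim = c(dim(mask), 1L)), base, base,
                         "nearest")[, , 1]
  }
  if (side != base) {
    img <- resize_image(img, side, side, "bilinear")
    mask <- resize_image(array(mask, dim = c(dim(mask), 1L)), side, side,
                         "nearest")[, , 1]
  }
  sample$image <- img; sample$mask <- mask
  sample
}
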