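check_mask_pair <- function(y, y_hat) {
  if (!identical(dim2(y), dim2(y_hat))) {
    stop("ground truth and prediction shapes differ", call. = FALSE)
  }
  invisible(NULL)
}

dim2 <- function(x) dim(x) %||% length(x)

#' Smooth Dice loss
#'
#' `1 - 2 * sum(y * yhat) / (sum(y^2) + sum(yhat^2) + eps)`, summed over all
#' pixels. For binary predictions and `eps -> 0` this is one minus the Dice
#' overlap coefficient.
#'
#' @param y binary ground-truth array (0 background, 1 polyp).
#' @param y_hat prediction array in `[0,1]`, same shape.
#' @param eps smoothing constant (> 0 keeps the empty-empty case at 0 loss;
#'   default 1, the smooth-Dice convention). `eps = 0` is allowed for exact
#'   closed-form checks on non-degenerate pairs.
#' @param boundary_weighted if `TRUE`, pixels near the mask boundary are
#'   up-weighted by `1 + 5 * |avgpool(y) - y|` (31x31 mean pool), a variant
#'   that concentrates the loss where segmentation is hardest.
#' @return a scalar loss.
#' @export
dice_loss <- function(y, y_hat, eps = 1, boundary_weighted = FALSE) {
  check_mask_pair(y, y_hat)
  if (eps < 0) stop("eps must be >= 0", call. = FALSE)
  if (boundary_weighted) {
    w <- boundary_weights(as_matrix2(y))
    y <- as_matrix2(y) * sqrt(w); y_hat <- as_matrix2(y_hat) * sqrt(w)
  }
  num <- 2 * sum(y * y_hat)
  den <- sum(y^2) + sum(y_hat^2) + eps
  if (den == 0) return(0)
  1 - num / den
}

as_matrix2 <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else x

# mean-pool based boundary emphasis used by the weighted variant
boundary_weights <- function(y, k = 31L, gain = 5) {
  p <- mean_pool2d(y, k)
  1 + gain * abs(p - y)
}

mean_pool2d <- function(y, k) {
  r <- (k - 1L) %/% 2L
  h <- nrow(y); w <- ncol(y)
  cs <- matrix(0, h + 1, w + 1)
  cs[-1, -1] <- apply(apply(y, 2, cumsum), 1, cumsum) |> t()
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    i0 <- max(1L, i - r); i1 <- min(h, i + r)
    for (j in seq_len(w)) {
      j0 <- max(1L, j - r); j1 <- min(w, j + r)
      s <- cs[i1 + 1, j1 + 1] - cs[i0, j1 + 1] - cs[i1 + 1, j0] + cs[i0, j0]
      out[i, j] <- s / ((i1 - i0 + 1) * (j1 - j0 + 1))
    }
  }
  out
}

#' Binary cross-entropy loss
#'
#' Pixel mean of `-(y log(yhat) + (1-y) log(1-yhat))` with the prediction
#' clamped to `[1e-7, 1 - 1e-7]`. `printed_form = TRUE` switches the second
#' term to `log(1 - yhat^2)` for side-by-side comparison with the
#' non-standard printed variant of this objective; the standard form is the
#' default and the one used in training.
#'
#' @inheritParams dice_loss
#' @param printed_form use `log(1 - yhat^2)` in the background term.
#' @return a scalar loss (mean over pixels).
#' @export
bce_loss <- function(y, y_hat, printed_form = FALSE) {
  check_mask_pair(y, y_hat)
  p <- clamp(y_hat, 1e-7, 1 - 1e-7)
  if (printed_form) {
    mean(-(y * log(p) + (1 - y) * log(1 - p^2)))
  } else {
    mean(-(y * log(p) + (1 - y) * log(1 - p)))
  }
}

#' Compound segmentation training loss (Dice + BCE)
#'
#' @inheritParams dice_loss
#' @return `dice_loss(y, y_hat, eps) + bce_loss(y, y_hat)`.
#' @export
total_loss <- function(y, y_hat, eps = 1, boundary_weighted = FALSE) {
  dice_loss(y, y_hat, eps = eps, boundary_weighted = boundary_weighted) +
    bce_loss(y, y_hat)
}
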