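#' Interpolation matrix for 1-D resizing
#'
#' Bilinear resizing is separable: resizing H x W to H' x W' is
#' `R_h %*% X %*% t(R_w)` with two 1-D interpolation matrices. The sampling
#' grid follows the half-pixel ("align corners = FALSE") convention:
#' output index i (0-based) samples source coordinate
#' `(i + 0.5) * n_in / n_out - 0.5`, clamped to the valid range.
#'
#' @param n_in,n_out source and target lengths.
#' @param method `"bilinear"` or `"nearest"`.
#' @return an `n_out` x `n_in` dense matrix with rows summing to 1.
#' @keywords internal
interp_matrix <- function(n_in, n_out, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  R <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5
    if (method == "nearest") {
      j <- clamp(floor(src + 0.5), 0, n_in - 1)
      R[i, j + 1] <- 1
    } else {
      src <- clamp(src, 0, n_in - 1)
      j0 <- floor(src)
      j1 <- min(j0 + 1, n_in - 1)
      w <- src - j0
      R[i, j0 + 1] <- R[i, j0 + 1] + (1 - w)
      R[i, j1 + 1] <- R[i, j1 + 1] + w
    }
  }
  R
}

# core kernel shared by the pure operator and the autodiff op:
# x is (N,H,W,C); returns (N,H',W',C). Rh: H'xH, Rw: W'xW.
resize_nhwc <- function(x, Rh, Rw) {
  d <- dim(x)
  n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  ho <- nrow(Rh); wo <- nrow(Rw)
  # contract over H: permute to (H, W, N, C)
  xp <- aperm(x, c(2L, 3L, 1L, 4L))
  y1 <- Rh %*% matrix(xp, nrow = h)              # (H', W*N*C)
  y1 <- array(y1, dim = c(ho, w, n, cc))
  yp <- aperm(y1, c(2L, 1L, 3L, 4L))             # (W, H', N, C)
  y2 <- Rw %*% matrix(yp, nrow = w)              # (W', H'*N*C)
  y2 <- array(y2, dim = c(wo, ho, n, cc))
  aperm(y2, c(3L, 2L, 1L, 4L))                   # (N, H', W', C)
}

#' Upsample a feature map
#'
#' Matches a deeper, lower-resolution feature map to a shallower level's
#' spatial resolution, as required before attention multiplication. Bilinear
#' interpolation with the half-pixel convention is the default; nearest
#' neighbor is available for exact small-integer checks.
#'
#' @param f a `(H,W,C)` or `(N,H,W,C)` numeric array.
#' @param target_rows,target_cols target spatial dimensions (must be >= the
#'   source dimensions and positive).
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return an array of the same rank with the requested spatial dimensions.
#' @examples
#' f <- array(c(0, 2, 1, 3), dim = c(2, 2, 1))  # column-major 2x2
#' dim(upsample(f, 4, 4))
#' @export
upsample <- function(f, target_rows, target_cols, method = "bilinear") {
  if (length(target_rows) != 1 || length(target_cols) != 1 ||
      !is.finite(target_rows) || !is.finite(target_cols) ||
      target_rows < 1 || target_cols < 1) {
    stop("target dimensions must be positive integers", call. = FALSE)
  }
  x <- with_batch(f)
  hb <- attr(x, "had_batch")
  d <- dim(x)
  if (target_rows < d[2] || target_cols < d[3]) {
    stop("target dimensions must be >= source dimensions", call. = FALSE)
  }
  Rh <- interp_matrix(d[2], as.integer(target_rows), method)
  Rw <- interp_matrix(d[3], as.integer(target_cols), method)
  drop_batch(resize_nhwc(x, Rh, Rw), hb)
}

# general-purpose image resize (up or down), used by the data pipeline
resize_image <- function(f, target_rows, target_cols, method = "bilinear") {
  x <- with_batch(f)
  hb <- attr(x, "had_batch")
  d <- dim(x)
  Rh <- interp_matrix(d[2], as.integer(target_rows), method)
  Rw <- interp_matrix(d[3], as.integer(target_cols), method)
  drop_batch(resize_nhwc(x, Rh, Rw), hb)
}
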