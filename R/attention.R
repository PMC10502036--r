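#' Shallow attention
#'
#' Multiplies a shallow feature map by the ReLU of the upsampled deeper
#' feature map(s): `M = relu(up(F_deep))`, `F_sa = M * F`. With a second,
#' even deeper map the two attention maps are applied in sequence,
#' `F_sa = M1 * M2 * F`, injecting additional context. High activations in
#' the deeper maps mark likely foreground, so the product suppresses
#' mucosal background in the shallow map while keeping its spatial detail.
#'
#' @param f_k shallow feature map, `(H,W,C)` or `(N,H,W,C)` array.
#' @param f_k1 deeper feature map at equal or coarser resolution, same
#'   channel count.
#' @param f_k2 optional still-deeper feature map (same channel count).
#' @return a list with `features` (the attended map, same shape as `f_k`),
#'   `map` (attention map from `f_k1`) and, when `f_k2` is given, `map2`.
#' @export
shallow_attention <- function(f_k, f_k1, f_k2 = NULL) {
  x <- with_batch(f_k); hb <- attr(x, "had_batch")
  a <- with_batch(f_k1)
  d <- dim(x)
  check_attention_pair(d, dim(a))
  m1 <- relu(resize_to(a, d))
  out <- m1 * x
  maps <- list(map = drop_batch(m1, hb))
  if (!is.null(f_k2)) {
    b <- with_batch(f_k2)
    check_attention_pair(d, dim(b))
    m2 <- relu(resize_to(b, d))
    out <- m2 * out
    maps$map2 <- drop_batch(m2, hb)
  }
  c(list(features = drop_batch(out, hb)), maps)
}

#' Reverse attention
#'
#' Builds a normalized foreground map `M = sigmoid(up(F_deep))`, reverses it
#' to `1 - M`, and multiplies the reversed map into the shallow features:
#' the network's capacity is redirected to background and boundary pixels,
#' which is where polyp/mucosa transitions are ambiguous.
#'
#' @inheritParams shallow_attention
#' @return a list with `features = (1 - sigmoid(up(f_k1))) * f_k` and
#'   `map`, the reversed attention map (elementwise in `[0,1]`).
#' @export
reverse_attention <- function(f_k, f_k1) {
  x <- with_batch(f_k); hb <- attr(x, "had_batch")
  a <- with_batch(f_k1)
  d <- dim(x)
  check_attention_pair(d, dim(a))
  m_rev <- 1 - sigmoid(resize_to(a, d))
  list(features = drop_batch(m_rev * x, hb), map = drop_batch(m_rev, hb))
}

check_attention_pair <- function(d_shallow, d_deep) {
  if (d_deep[4] != d_shallow[4]) {
    stop("channel mismatch: shallow has ", d_shallow[4],
         " channels, deep has ", d_deep[4], call. = FALSE)
  }
  if (d_deep[2] > d_shallow[2] || d_deep[3] > d_shallow[3]) {
    stop("deeper map must not exceed the shallow map's resolution",
         call. = FALSE)
  }
  invisible(NULL)
}

resize_to <- function(x4, d_target) {
  d <- dim(x4)
  if (d[2] == d_target[2] && d[3] == d_target[3]) return(x4)
  resize_nhwc(x4,
              interp_matrix(d[2], d_target[2]),
              interp_matrix(d[3], d_target[3]))
}

#' Per-channel importance logits of an attended feature map
#'
#' Squeeze-style channel descriptor: global average pooling abstracts each
#' channel to a scalar, then two bias-free fully connected layers with an
#' intermediate ReLU recalibrate it, `c = Z %*% relu(W %*% gap(f))`.
#'
#' @param f_att attended feature map, `(H,W,C)` or `(N,H,W,C)`.
#' @param w first FC weight matrix, `H_red x C` (squeeze).
#' @param z second FC weight matrix, `C x H_red` (excite).
#' @return a length-`C` numeric vector of unnormalized logits (or an
#'   `N x C` matrix for batched input).
#' @export
channel_importance <- function(f_att, w, z) {
  x <- with_batch(f_att); hb <- attr(x, "had_batch")
  d <- dim(x)
  if (ncol(w) != d[4] || nrow(z) != d[4] || nrow(w) != ncol(z)) {
    stop("gate weight shapes do not compose with ", d[4], " channels",
         call. = FALSE)
  }
  g <- apply(x, c(1L, 4L), mean)                # (N, C) spatial means
  cmat <- t(z %*% relu(w %*% t(g)))             # (N, C)
  if (hb) cmat else drop(cmat)
}

#' Make bias-free gate parameters for one dual-attention block
#'
#' One `(W, Z)` pair per attention branch; the hidden (reduction) size
#' defaults to `max(1, floor(channels / 4))`.
#'
#' @param channels number of feature channels `C`.
#' @param hidden reduction width; default `max(1, floor(channels/4))`.
#' @param init standard deviation of the normal initializer.
#' @return a list with matrices `w_sa`, `z_sa`, `w_ra`, `z_ra`.
#' @export
gate_params <- function(channels, hidden = NULL, init = 0.1) {
  hidden <- hidden %||% max(1L, channels %/% 4L)
  mk <- function(r, c) matrix(stats::rnorm(r * c, sd = init), r, c)
  list(w_sa = mk(hidden, channels), z_sa = mk(channels, hidden),
       w_ra = mk(hidden, channels), z_ra = mk(channels, hidden))
}

# numerically stable 2-way softmax along the pair (a, b); returns p(a)
softmax_pair <- function(a, b) {
  m <- pmax(a, b)
  ea <- exp(a - m); eb <- exp(b - m)
  ea / (ea + eb)
}

#' Softmax gate: convex per-channel fusion of the two attention branches
#'
#' Stacks the two channel-importance vectors and applies a two-way softmax
#' per channel, giving gate weights `v_sa + v_ra = 1`; the fused map is the
#' channel-wise convex combination `v_sa * F_sa + v_ra * F_ra`.
#'
#' @param f_sa,f_ra attended feature maps of identical shape.
#' @param c_sa,c_ra channel importance logits (length-`C` vectors, or
#'   `N x C` matrices for batched input).
#' @return a list with `features` (fused map), `v_sa`, `v_ra`.
#' @export
softmax_gate <- function(f_sa, f_ra, c_sa, c_ra) {
  xs <- with_batch(f_sa); hb <- attr(xs, "had_batch")
  xr <- with_batch(f_ra)
  if (!identical(dim(xs), dim(xr))) stop("branch shapes differ", call. = FALSE)
  d <- dim(xs)
  v_sa <- as_gate_matrix(softmax_pair(c_sa, c_ra), d)
  fused <- channel_scale(xs, v_sa) + channel_scale(xr, 1 - v_sa)
  vs <- if (hb) v_sa else drop(v_sa)
  list(features = drop_batch(fused, hb), v_sa = vs, v_ra = 1 - vs)
}

as_gate_matrix <- function(v, d) {
  if (is.matrix(v)) {
    if (nrow(v) != d[1] || ncol(v) != d[4]) stop("gate size mismatch", call. = FALSE)
    v
  } else {
    if (length(v) != d[4]) stop("gate length must equal channel count", call. = FALSE)
    matrix(v, d[1], d[4], byrow = TRUE)
  }
}

# multiply each (n, channel) slab of a (N,H,W,C) array by scalar v[n, c]
channel_scale <- function(x4, v) {
  d <- dim(x4)
  x4 * aperm(array(t(v), dim = c(d[4], d[1], d[2], d[3])), c(2L, 3L, 4L, 1L))
}

#' Fuse two attention branches
#'
#' The three aggregation variants compared in the ablation study:
#' `"sum"` adds the branches; `"sigmoid"` gates each branch independently by
#' the sigmoid of its own channel logits (no normalization across branches);
#' `"softmax"` applies the softmax gate (convex combination).
#'
#' @inheritParams softmax_gate
#' @param mode one of `"softmax"`, `"sigmoid"`, `"sum"`.
#' @param c_sa,c_ra channel logits; required for the two gated modes.
#' @return the fused feature map (same shape as the inputs).
#' @export
fuse <- function(f_sa, f_ra, mode = c("softmax", "sigmoid", "sum"),
                 c_sa = NULL, c_ra = NULL) {
  mode <- match.arg(mode)
  if (mode == "sum") {
    xs <- with_batch(f_sa); hb <- attr(xs, "had_batch")
    xr <- with_batch(f_ra)
    if (!identical(dim(xs), dim(xr))) stop("branch shapes differ", call. = FALSE)
    return(drop_batch(xs + xr, hb))
  }
  if (is.null(c_sa) || is.null(c_ra)) {
    stop("gated fusion modes need channel logits c_sa, c_ra", call. = FALSE)
  }
  if (mode == "softmax") return(softmax_gate(f_sa, f_ra, c_sa, c_ra)$features)
  xs <- with_batch(f_sa); hb <- attr(xs, "had_batch")
  xr <- with_batch(f_ra)
  if (!identical(dim(xs), dim(xr))) stop("branch shapes differ", call. = FALSE)
  d <- dim(xs)
  g_sa <- as_gate_matrix(sigmoid(c_sa), d)
  g_ra <- as_gate_matrix(sigmoid(c_ra), d)
  drop_batch(channel_scale(xs, g_sa) + channel_scale(xr, g_ra), hb)
}
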