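# Minimal reverse-mode differentiation engine.
#
# Nodes are environments carrying a value, parent links, and a backward
# closure mapping the node's output gradient to parent gradients. The
# graph is rebuilt on every forward pass; trainable parameters live in
# persistent `nn_param` environments that leaf nodes reference, so
# gradients accumulate across the tape into the parameter store.

nd_new <- function(value, parents = list(), bw = NULL, param = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$bw <- bw
  e$param <- param
  e$grad <- NULL
  class(e) <- "nd"
  e
}

nd_const <- function(x) nd_new(x)

#' Create a trainable parameter
#'
#' @param value initial numeric array.
#' @param group optimizer parameter group, `"head"` or `"backbone"`.
#' @param name identifier used in diagnostics.
#' @return a parameter environment with `value`, `grad`, `momentum` slots.
#' @keywords internal
nn_param <- function(value, group = "head", name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- value * 0
  p$momentum <- value * 0
  p$group <- group
  p$name <- name
  class(p) <- "nn_param"
  p
}

nd_param <- function(p) nd_new(p$value, param = p)

zero_grad <- function(x) x * 0

# reverse topological order by iterative depth-first post-order
nd_topo <- function(root) {
  token <- new.env()
  order <- vector("list", 0L)
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (top$stage == 1L) {
      if (!is.null(node$.seen) && identical(node$.seen, token)) next
      node$.seen <- token
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(p$.seen) || !identical(p$.seen, token)) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  order
}

nd_backward <- function(root) {
  order <- nd_topo(root)
  root$grad <- array(1, dim = dim2(root$value))
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$grad)) next
    if (!is.null(node$param)) {
      node$param$grad <- node$param$grad + node$grad
    }
    if (is.null(node$bw)) next
    gs <- node$bw(node$grad)
    for (j in seq_along(node$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- node$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# ---- elementwise ops (shape-generic) --------------------------------------

nd_add <- function(a, b) nd_new(a$value + b$value, list(a, b),
                                function(g) list(g, g))

nd_sub <- function(a, b) nd_new(a$value - b$value, list(a, b),
                                function(g) list(g, -g))

nd_mul <- function(a, b) {
  nd_new(a$value * b$value, list(a, b),
         function(g) list(g * b$value, g * a$value))
}

nd_scale <- function(a, s) nd_new(a$value * s, list(a), function(g) list(g * s))

nd_rsub1 <- function(a) nd_new(1 - a$value, list(a), function(g) list(-g))

nd_relu <- function(a) {
  mask <- a$value > 0
  nd_new(a$value * mask, list(a), function(g) list(g * mask))
}

nd_sigmoid <- function(a) {
  v <- sigmoid(a$value)
  nd_new(v, list(a), function(g) list(g * v * (1 - v)))
}

# ---- dense / channel ops ---------------------------------------------------

nd_matmul <- function(x, w) {
  nd_new(x$value %*% w$value, list(x, w),
         function(g) list(g %*% t(w$value), t(x$value) %*% g))
}

# broadcast a per-(sample, channel) matrix v (N x C) over (N,H,W,C)
bcast_nc <- function(v, d) {
  aperm(array(t(v), dim = c(d[4], d[1], d[2], d[3])), c(2L, 3L, 4L, 1L))
}

# broadcast a per-channel vector over (N,H,W,C)
bcast_c <- function(v, d) {
  aperm(array(v, dim = c(d[4], d[1], d[2], d[3])), c(2L, 3L, 4L, 1L))
}

nd_gap <- function(x) {
  d <- dim(x$value)
  v <- apply(x$value, c(1L, 4L), mean)
  dim(v) <- c(d[1], d[4])
  nd_new(v, list(x),
         function(g) list(bcast_nc(g, d) / (d[2] * d[3])))
}

nd_cmul <- function(x, v) {
  d <- dim(x$value)
  B <- bcast_nc(v$value, d)
  nd_new(x$value * B, list(x, v), function(g) {
    dv <- apply(g * x$value, c(1L, 4L), sum)
    dim(dv) <- c(d[1], d[4])
    list(g * B, dv)
  })
}

nd_concat_c <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  out <- array(0, dim = c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a$value
  out[, , , da[4] + seq_len(db[4])] <- b$value
  nd_new(out, list(a, b), function(g) {
    list(g[, , , seq_len(da[4]), drop = FALSE],
         g[, , , da[4] + seq_len(db[4]), drop = FALSE])
  })
}

nd_slice_c <- function(x, from, to) {
  idx <- from:to
  nd_new(x$value[, , , idx, drop = FALSE], list(x), function(g) {
    dx <- array(0, dim = dim(x$value))
    dx[, , , idx] <- g
    list(dx)
  })
}

nd_upsample <- function(x, out_h, out_w, method = "bilinear") {
  d <- dim(x$value)
  Rh <- interp_matrix(d[2], out_h, method)
  Rw <- interp_matrix(d[3], out_w, method)
  nd_new(resize_nhwc(x$value, Rh, Rw), list(x),
         function(g) list(resize_nhwc(g, t(Rh), t(Rw))))
}

# ---- convolution -----------------------------------------------------------

pad_nhwc <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  xp[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  xp
}

im2col <- function(xp, k, stride, ho, wo) {
  d <- dim(xp)
  n <- d[1]; cin <- d[4]
  col <- matrix(0, n * ho * wo, k * k * cin)
  for (b in seq_len(k)) {
    j0 <- b + stride * (seq_len(wo) - 1L)
    for (a in seq_len(k)) {
      i0 <- a + stride * (seq_len(ho) - 1L)
      slice <- xp[, i0, j0, , drop = FALSE]
      cols <- a + (b - 1L) * k + (seq_len(cin) - 1L) * k * k
      col[, cols] <- matrix(slice, ncol = cin)
    }
  }
  col
}

col2im <- function(dcol, d_padded, k, stride, ho, wo) {
  n <- d_padded[1]; cin <- d_padded[4]
  dxp <- array(0, dim = d_padded)
  for (b in seq_len(k)) {
    j0 <- b + stride * (seq_len(wo) - 1L)
    for (a in seq_len(k)) {
      i0 <- a + stride * (seq_len(ho) - 1L)
      cols <- a + (b - 1L) * k + (seq_len(cin) - 1L) * k * k
      patch <- array(dcol[, cols], dim = c(n, ho, wo, cin))
      dxp[, i0, j0, ] <- dxp[, i0, j0, , drop = FALSE] + patch
    }
  }
  dxp
}

nd_conv2d <- function(x, w, stride = 1L, pad = NULL) {
  dw <- dim(w$value)                    # (k, k, cin, cout)
  k <- dw[1]
  pad <- pad %||% ((k - 1L) %/% 2L)
  d <- dim(x$value)
  if (d[4] != dw[3]) stop("conv channel mismatch", call. = FALSE)
  ho <- (d[2] + 2 * pad - k) %/% stride + 1L
  wo <- (d[3] + 2 * pad - k) %/% stride + 1L
  xp <- pad_nhwc(x$value, pad)
  col <- im2col(xp, k, stride, ho, wo)
  Wmat <- matrix(w$value, nrow = k * k * dw[3])
  out <- array(col %*% Wmat, dim = c(d[1], ho, wo, dw[4]))
  d_padded <- dim(xp)
  nd_new(out, list(x, w), function(g) {
    gmat <- matrix(g, ncol = dw[4])
    dW <- array(t(col) %*% gmat, dim = dw)
    dcol <- gmat %*% t(Wmat)
    dxp <- col2im(dcol, d_padded, k, stride, ho, wo)
    dx <- if (pad > 0) {
      dxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE]
    } else dxp
    list(dx, dW)
  })
}

# ---- pooling ---------------------------------------------------------------

nd_pool <- function(x, k = 2L, stride = k, pad = 0L, type = c("avg", "max")) {
  type <- match.arg(type)
  d <- dim(x$value)
  ho <- (d[2] + 2 * pad - k) %/% stride + 1L
  wo <- (d[3] + 2 * pad - k) %/% stride + 1L
  xp <- pad_nhwc(x$value, pad)
  if (type == "max" && pad > 0) {
    # padding must not win the max
    xp_mask <- pad_nhwc(array(1, dim = d), pad) == 0
    xp[xp_mask] <- -Inf
  }
  d_padded <- dim(xp)
  if (type == "avg") {
    acc <- array(0, dim = c(d[1], ho, wo, d[4]))
    for (b in seq_len(k)) {
      j0 <- b + stride * (seq_len(wo) - 1L)
      for (a in seq_len(k)) {
        i0 <- a + stride * (seq_len(ho) - 1L)
        acc <- acc + xp[, i0, j0, , drop = FALSE]
      }
    }
    out <- acc / (k * k)
    return(nd_new(out, list(x), function(g) {
      dxp <- array(0, dim = d_padded)
      gs <- g / (k * k)
      for (b in seq_len(k)) {
        j0 <- b + stride * (seq_len(wo) - 1L)
        for (a in seq_len(k)) {
          i0 <- a + stride * (seq_len(ho) - 1L)
          dxp[, i0, j0, ] <- dxp[, i0, j0, , drop = FALSE] + gs
        }
      }
      dx <- if (pad > 0) {
        dxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE]
      } else dxp
      list(dx)
    }))
  }
  cur <- array(-Inf, dim = c(d[1], ho, wo, d[4]))
  winner <- array(0L, dim = c(d[1], ho, wo, d[4]))
  for (b in seq_len(k)) {
    j0 <- b + stride * (seq_len(wo) - 1L)
    for (a in seq_len(k)) {
      i0 <- a + stride * (seq_len(ho) - 1L)
      cand <- xp[, i0, j0, , drop = FALSE]
      better <- cand > cur
      cur[better] <- cand[better]
      winner[better] <- a + (b - 1L) * k
    }
  }
  nd_new(cur, list(x), function(g) {
    dxp <- array(0, dim = d_padded)
    for (b in seq_len(k)) {
      j0 <- b + stride * (seq_len(wo) - 1L)
      for (a in seq_len(k)) {
        i0 <- a + stride * (seq_len(ho) - 1L)
        sel <- (winner == a + (b - 1L) * k) * g
        dxp[, i0, j0, ] <- dxp[, i0, j0, , drop = FALSE] + sel
      }
    }
    dx <- if (pad > 0) {
      dxp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE]
    } else dxp
    list(dx)
  })
}

# ---- batch normalization ---------------------------------------------------

bn_state <- function(channels) {
  s <- new.env(parent = emptyenv())
  s$running_mean <- numeric(channels)
  s$running_var <- rep(1, channels)
  s$momentum <- 0.1
  s$eps <- 1e-5
  s
}

nd_bn <- function(x, gamma, beta, state, training = TRUE) {
  d <- dim(x$value)
  m <- d[1] * d[2] * d[3]
  if (training) {
    mu <- apply(x$value, 4L, mean)
    xc <- x$value - bcast_c(mu, d)
    varc <- apply(xc^2, 4L, mean)
    state$running_mean <- (1 - state$momentum) * state$running_mean + state$momentum * mu
    unb <- if (m > 1) m / (m - 1) else 1
    state$running_var <- (1 - state$momentum) * state$running_var + state$momentum * varc * unb
  } else {
    mu <- state$running_mean
    xc <- x$value - bcast_c(mu, d)
    varc <- state$running_var
  }
  invstd <- 1 / sqrt(varc + state$eps)
  xhat <- xc * bcast_c(invstd, d)
  out <- xhat * bcast_c(gamma$value, d) + bcast_c(beta$value, d)
  nd_new(out, list(x, gamma, beta), function(g) {
    dbeta <- apply(g, 4L, sum)
    dgamma <- apply(g * xhat, 4L, sum)
    gs <- g * bcast_c(gamma$value * invstd, d)
    if (training) {
      mg <- apply(gs, 4L, mean)
      mgx <- apply(gs * xhat, 4L, mean)
      dx <- gs - bcast_c(mg, d) - xhat * bcast_c(mgx, d)
    } else {
      dx <- gs
    }
    list(dx, dgamma, dbeta)
  })
}

# ---- training loss ---------------------------------------------------------

# Dice + BCE on a sigmoid probability map; per-sample Dice, batch-mean total.
nd_dice_bce <- function(pred, y, eps = 1) {
  p <- pred$value
  d <- dim(p)
  n <- d[1]; npix <- d[2] * d[3] * d[4]
  pc <- clamp(p, 1e-7, 1 - 1e-7)
  dice_vals <- numeric(n); bce_vals <- numeric(n)
  grad <- array(0, dim = d)
  for (i in seq_len(n)) {
    pi <- p[i, , , , drop = FALSE]
    pci <- pc[i, , , , drop = FALSE]
    yi <- y[i, , , , drop = FALSE]
    sxy <- sum(yi * pi); sxx <- sum(pi^2); syy <- sum(yi^2)
    den <- sxx + syy + eps
    dice_vals[i] <- 1 - 2 * sxy / den
    bce_vals[i] <- mean(-(yi * log(pci) + (1 - yi) * log(1 - pci)))
    ddice <- -(2 * yi * den - 2 * sxy * 2 * pi) / den^2
    inb <- (p[i, , , , drop = FALSE] > 1e-7) & (p[i, , , , drop = FALSE] < 1 - 1e-7)
    dbce <- ((pci - yi) / (pci * (1 - pci))) / npix * inb
    grad[i, , , ] <- (ddice + dbce) / n
  }
  out <- nd_new(mean(dice_vals) + mean(bce_vals), list(pred),
                function(g) list(as.numeric(g) * grad))
  out$dice <- mean(dice_vals)
  out$bce <- mean(bce_vals)
  out
}

# ---- optimizer -------------------------------------------------------------

#' One SGD step with momentum over two parameter groups
#'
#' Nesterov momentum (0.9) as in the released recipes of comparable
#' segmentation networks; backbone and head parameters carry separate
#' learning rates.
#'
#' @param params list of `nn_param` environments.
#' @param lr_backbone,lr_head learning rates for the two groups.
#' @param momentum momentum coefficient.
#' @param nesterov use the Nesterov update.
#' @param weight_decay L2 coefficient (0 disables).
#' @keywords internal
sgd_step <- function(params, lr_backbone, lr_head, momentum = 0.9,
                     nesterov = TRUE, weight_decay = 0) {
  for (p in params) {
    lr <- if (identical(p$group, "backbone")) lr_backbone else lr_head
    g <- p$grad
    if (weight_decay > 0) g <- g + weight_decay * p$value
    p$momentum <- momentum * p$momentum + g
    step <- if (nesterov) g + momentum * p$momentum else p$momentum
    p$value <- p$value - lr * step
    p$grad <- zero_grad(p$grad)
  }
  invisible(params)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- zero_grad(p$grad)
  invisible(params)
}
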