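# Independent scalar-loop oracles. Everything here recomputes the package's
# operators and metrics from their defining formulas with explicit loops,
# sharing no code with the implementation under test.

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

# half-pixel bilinear interpolation of a matrix, one output pixel at a time
oracle_upsample2d <- function(x, oh, ow) {
  hi <- nrow(x); wi <- ncol(x)
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) {
    for (j in seq_len(ow)) {
      si <- max((i - 0.5) * hi / oh - 0.5, 0)
      sj <- max((j - 0.5) * wi / ow - 0.5, 0)
      i0 <- floor(si); j0 <- floor(sj)
      i1 <- min(i0 + 1, hi - 1); j1 <- min(j0 + 1, wi - 1)
      wi_ <- si - i0; wj <- sj - j0
      out[i, j] <-
        (1 - wi_) * (1 - wj) * x[i0 + 1, j0 + 1] +
        (1 - wi_) * wj * x[i0 + 1, j1 + 1] +
        wi_ * (1 - wj) * x[i1 + 1, j0 + 1] +
        wi_ * wj * x[i1 + 1, j1 + 1]
    }
  }
  out
}

oracle_upsample3d <- function(f, oh, ow) {
  cc <- dim(f)[3]
  out <- array(0, dim = c(oh, ow, cc))
  for (ch in seq_len(cc)) {
    out[, , ch] <- oracle_upsample2d(matrix(f[, , ch], dim(f)[1], dim(f)[2]),
                                     oh, ow)
  }
  out
}

oracle_shallow <- function(f_k, f_k1, f_k2 = NULL) {
  d <- dim(f_k)
  m1 <- pmax(oracle_upsample3d(f_k1, d[1], d[2]), 0)
  out <- m1 * f_k
  if (!is.null(f_k2)) {
    m2 <- pmax(oracle_upsample3d(f_k2, d[1], d[2]), 0)
    out <- m2 * out
  }
  out
}

oracle_reverse <- function(f_k, f_k1) {
  d <- dim(f_k)
  m <- 1 - oracle_sigmoid(oracle_upsample3d(f_k1, d[1], d[2]))
  m * f_k
}

oracle_channel_importance <- function(f, w, z) {
  d <- dim(f)
  g <- numeric(d[3])
  for (ch in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) s <- s + f[i, j, ch]
    g[ch] <- s / (d[1] * d[2])
  }
  hid <- numeric(nrow(w))
  for (h in seq_len(nrow(w))) {
    s <- 0
    for (ch in seq_len(d[3])) s <- s + w[h, ch] * g[ch]
    hid[h] <- max(s, 0)
  }
  out <- numeric(d[3])
  for (ch in seq_len(d[3])) {
    s <- 0
    for (h in seq_len(nrow(w))) s <- s + z[ch, h] * hid[h]
    out[ch] <- s
  }
  out
}

oracle_gate <- function(f_sa, f_ra, c_sa, c_ra) {
  d <- dim(f_sa)
  out <- array(0, dim = d)
  v_sa <- numeric(d[3])
  for (ch in seq_len(d[3])) {
    ea <- exp(c_sa[ch]); eb <- exp(c_ra[ch])
    v_sa[ch] <- ea / (ea + eb)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      out[i, j, ch] <- v_sa[ch] * f_sa[i, j, ch] +
        (1 - v_sa[ch]) * f_ra[i, j, ch]
    }
  }
  list(features = out, v_sa = v_sa)
}

# --- metric oracles ---------------------------------------------------------

oracle_wfb <- function(y, y_hat, beta2 = 1) {
  h <- nrow(y); w <- ncol(y)
  if (sum(y) == 0) return(1 - mean(y_hat))
  E <- abs(y_hat - y)
  # nearest foreground pixel by brute force
  Dst <- matrix(0, h, w); Ifg <- matrix(0L, h, w); Jfg <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    best <- Inf; bi <- 0L; bj <- 0L
    # column-major scan; ties keep the first (lowest linear index)
    for (b in seq_len(w)) for (a in seq_len(h)) {
      if (y[a, b] > 0) {
        d2 <- (i - a)^2 + (j - b)^2
        if (d2 < best) { best <- d2; bi <- a; bj <- b }
      }
    }
    Dst[i, j] <- sqrt(best); Ifg[i, j] <- bi; Jfg[i, j] <- bj
  }
  Et <- E
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (y[i, j] == 0) Et[i, j] <- E[Ifg[i, j], Jfg[i, j]]
  }
  # 7x7 gaussian, sigma 5, zero-padded
  r <- 3L
  gk <- matrix(0, 7, 7)
  for (a in -r:r) for (b in -r:r) {
    gk[a + r + 1, b + r + 1] <- exp(-(a^2 + b^2) / (2 * 25))
  }
  gk <- gk / sum(gk)
  EA <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    s <- 0
    for (a in -r:r) for (b in -r:r) {
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
        s <- s + gk[a + r + 1, b + r + 1] * Et[ii, jj]
      }
    }
    EA[i, j] <- s
  }
  minEA <- E
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (y[i, j] > 0 && EA[i, j] < E[i, j]) minEA[i, j] <- EA[i, j]
  }
  B <- matrix(1, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (y[i, j] == 0) B[i, j] <- 2 - exp(log(0.5) / 5 * Dst[i, j])
  }
  Ew <- minEA * B
  eps <- .Machine$double.eps
  tpw <- sum(y[y > 0]) - sum(Ew[y > 0])
  fpw <- sum(Ew[y == 0])
  R <- 1 - mean(Ew[y > 0])
  P <- tpw / (tpw + fpw + eps)
  (1 + beta2) * R * P / (R + beta2 * P + eps)
}

oracle_sm <- function(y, y_hat, alpha = 0.5) {
  mu <- mean(y)
  if (mu == 0) return(1 - mean(y_hat))
  if (mu == 1) return(mean(y_hat))
  obj_score <- function(vals) {
    x <- mean(vals)
    sx <- if (length(vals) > 1) stats::sd(vals) else 0
    2 * x / (x^2 + 1 + sx + .Machine$double.eps)
  }
  fg <- y_hat; fg[y == 0] <- 0
  bg <- 1 - y_hat; bg[y == 1] <- 0
  so <- mu * obj_score(fg[y == 1]) + (1 - mu) * obj_score(bg[y == 0])
  # region term: quadrants at the rounded mask centroid
  h <- nrow(y); w <- ncol(y)
  idx <- which(y > 0)
  ci <- round(mean((idx - 1) %% h + 1))
  cj <- round(mean((idx - 1) %/% h + 1))
  ssim_q <- function(pp, gg) {
    n <- length(gg)
    x <- mean(pp); yb <- mean(gg)
    if (n == 1) return(if (abs(x - yb) < .Machine$double.eps) 1 else 0)
    sx <- sum((pp - x)^2) / (n - 1)
    sy <- sum((gg - yb)^2) / (n - 1)
    sxy <- sum((pp - x) * (gg - yb)) / (n - 1)
    a <- 4 * x * yb * sxy
    b <- (x^2 + yb^2) * (sx + sy)
    if (a != 0) a / (b + .Machine$double.eps) else if (b == 0) 1 else 0
  }
  sr <- 0
  quads <- list(c(1, ci, 1, cj), c(1, ci, cj + 1, w),
                c(ci + 1, h, 1, cj), c(ci + 1, h, cj + 1, w))
  for (q in quads) {
    if (q[1] > q[2] || q[3] > q[4]) next
    rows <- q[1]:q[2]; cols <- q[3]:q[4]
    wt <- (length(rows) * length(cols)) / (h * w)
    sr <- sr + wt * ssim_q(y_hat[rows, cols], y[rows, cols])
  }
  max(alpha * so + (1 - alpha) * sr, 0)
}

oracle_em <- function(y, y_hat, n_thresholds = 255L) {
  n <- length(y)
  best <- -Inf
  for (t in seq(0, 1, length.out = n_thresholds)) {
    fm <- (y_hat >= t) * 1
    if (sum(y) == 0) {
      enh <- 1 - fm
    } else if (sum(1 - y) == 0) {
      enh <- fm
    } else {
      dy <- y - mean(y); df <- fm - mean(fm)
      enh <- matrix(0, nrow(y), ncol(y))
      for (i in seq_len(nrow(y))) for (j in seq_len(ncol(y))) {
        al <- 2 * dy[i, j] * df[i, j] /
          (dy[i, j]^2 + df[i, j]^2 + .Machine$double.eps)
        enh[i, j] <- (al + 1)^2 / 4
      }
    }
    best <- max(best, sum(enh) / (n - 1 + .Machine$double.eps))
  }
  min(best, 1)
}
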