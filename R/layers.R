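# Parameterized layer constructors. Each constructor registers its
# trainable parameters and a static layer record (kernel, channels, stride,
# operating output stride) in a build context; the records drive exact
# MAC/parameter counting without re-deriving shapes at count time.

new_ctx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- list()
  ctx$layers <- list()
  ctx$bn_states <- list()
  ctx
}

add_param <- function(ctx, p) {
  ctx$params[[length(ctx$params) + 1L]] <- p
  p
}

add_layer <- function(ctx, rec) {
  ctx$layers[[length(ctx$layers) + 1L]] <- rec
  invisible(rec)
}

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

# conv -> [BN] -> [ReLU] unit
conv_bn_relu <- function(ctx, name, cin, cout, k, stride = 1L, out_stride,
                         group = "head", part = "backbone",
                         bn = TRUE, act = TRUE, pad = NULL,
                         final_zero = FALSE) {
  w <- nn_param(if (final_zero) array(0, dim = c(k, k, cin, cout))
                else he_init(k, cin, cout),
                group = group, name = paste0(name, ".w"))
  add_param(ctx, w)
  add_layer(ctx, list(type = "conv", name = name, k = k, cin = cin,
                      cout = cout, stride = stride, out_stride = out_stride,
                      part = part))
  gamma <- beta <- state <- NULL
  if (bn) {
    gamma <- add_param(ctx, nn_param(rep(1, cout), group, paste0(name, ".g")))
    beta <- add_param(ctx, nn_param(rep(0, cout), group, paste0(name, ".b")))
    state <- bn_state(cout)
    ctx$bn_states[[length(ctx$bn_states) + 1L]] <- state
    add_layer(ctx, list(type = "bn", name = paste0(name, ".bn"), cout = cout,
                        out_stride = out_stride, part = part))
  }
  list(
    fwd = function(x, training = TRUE) {
      h <- nd_conv2d(x, nd_param(w), stride = stride, pad = pad)
      if (bn) h <- nd_bn(h, nd_param(gamma), nd_param(beta), state, training)
      if (act) h <- nd_relu(h)
      h
    },
    w = w, bn_state = state
  )
}

# bias-free two-layer channel gate (squeeze C -> H -> C)
gate_fc <- function(ctx, name, channels, hidden = NULL, part = "dam_gates") {
  hidden <- hidden %||% max(1L, channels %/% 4L)
  w1 <- add_param(ctx, nn_param(
    matrix(stats::rnorm(channels * hidden, sd = sqrt(2 / channels)),
           channels, hidden), "head", paste0(name, ".w1")))
  w2 <- add_param(ctx, nn_param(
    matrix(stats::rnorm(hidden * channels, sd = sqrt(2 / hidden)),
           hidden, channels), "head", paste0(name, ".w2")))
  add_layer(ctx, list(type = "fc", name = paste0(name, ".fc1"),
                      cin = channels, cout = hidden, out_stride = NA, part = part))
  add_layer(ctx, list(type = "fc", name = paste0(name, ".fc2"),
                      cin = hidden, cout = channels, out_stride = NA, part = part))
  list(
    fwd = function(f_att) {
      nd_matmul(nd_relu(nd_matmul(nd_gap(f_att), nd_param(w1))), nd_param(w2))
    },
    w1 = w1, w2 = w2
  )
}
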