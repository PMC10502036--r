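# Backbone adapters. Every backbone exposes three pyramid taps F3/F4/F5 at
# output strides 8/16/32 with its native channel widths. `tiny_test` is a
# ~60k-parameter stack that trains on a CPU in minutes; `res2net50` and
# `resnet50` are the full 50-layer architectures (random initialization;
# loading pretrained weights is outside the scope of this package) and are
# primarily used for exact complexity accounting.

backbone_channels <- function(name) {
  switch(name,
    tiny_test = c(32L, 48L, 64L),
    res2net50 = ,
    resnet50  = c(512L, 1024L, 2048L),
    stop("unknown backbone: ", name, call. = FALSE)
  )
}

build_backbone <- function(ctx, name) {
  switch(name,
    tiny_test = build_tiny(ctx),
    resnet50 = build_resnet_like(ctx, res2net = FALSE),
    res2net50 = build_resnet_like(ctx, res2net = TRUE),
    stop("unknown backbone: ", name, call. = FALSE)
  )
}

build_tiny <- function(ctx) {
  g <- "backbone"
  stem <- conv_bn_relu(ctx, "stem", 3L, 16L, 3L, 2L, 2L, g)
  s1 <- conv_bn_relu(ctx, "stage1", 16L, 24L, 3L, 2L, 4L, g)
  s2 <- conv_bn_relu(ctx, "stage2", 24L, 32L, 3L, 2L, 8L, g)
  s3 <- conv_bn_relu(ctx, "stage3", 32L, 48L, 3L, 2L, 16L, g)
  s4 <- conv_bn_relu(ctx, "stage4", 48L, 64L, 3L, 2L, 32L, g)
  function(x, training = TRUE) {
    h <- stem$fwd(x, training)
    h <- s1$fwd(h, training)
    f3 <- s2$fwd(h, training)
    f4 <- s3$fwd(f3, training)
    f5 <- s4$fwd(f4, training)
    list(f3 = f3, f4 = f4, f5 = f5)
  }
}

# Shared builder for the two 50-layer residual backbones. The res2net
# variant replaces the bottleneck's middle 3x3 convolution with a
# hierarchical multi-scale group (base width 26, scale 4).
build_resnet_like <- function(ctx, res2net = FALSE) {
  g <- "backbone"
  stem <- conv_bn_relu(ctx, "stem", 3L, 64L, 7L, 2L, 2L, g)
  stage_cfg <- list(
    list(planes = 64L, blocks = 3L, stride = 1L, os = 4L),
    list(planes = 128L, blocks = 4L, stride = 2L, os = 8L),
    list(planes = 256L, blocks = 6L, stride = 2L, os = 16L),
    list(planes = 512L, blocks = 3L, stride = 2L, os = 32L)
  )
  inplanes <- 64L
  stages <- list()
  for (si in seq_along(stage_cfg)) {
    cfg <- stage_cfg[[si]]
    blocks <- list()
    for (bi in seq_len(cfg$blocks)) {
      stride <- if (bi == 1L) cfg$stride else 1L
      os_in <- if (bi == 1L) cfg$os %/% cfg$stride else cfg$os
      blocks[[bi]] <- if (res2net) {
        bottle2neck(ctx, sprintf("s%d.b%d", si, bi), inplanes, cfg$planes,
                    stride, os_in, first = bi == 1L)
      } else {
        bottleneck(ctx, sprintf("s%d.b%d", si, bi), inplanes, cfg$planes,
                   stride, os_in, first = bi == 1L)
      }
      inplanes <- cfg$planes * 4L
    }
    stages[[si]] <- blocks
  }
  function(x, training = TRUE) {
    h <- stem$fwd(x, training)
    h <- nd_pool(h, 3L, 2L, 1L, "max")
    taps <- list()
    for (si in seq_along(stages)) {
      for (blk in stages[[si]]) h <- blk(h, training)
      taps[[si]] <- h
    }
    list(f3 = taps[[2]], f4 = taps[[3]], f5 = taps[[4]])
  }
}

bottleneck <- function(ctx, name, inplanes, planes, stride, os_in, first) {
  g <- "backbone"
  os_out <- os_in * stride
  out <- planes * 4L
  c1 <- conv_bn_relu(ctx, paste0(name, ".c1"), inplanes, planes, 1L, 1L, os_in, g)
  c2 <- conv_bn_relu(ctx, paste0(name, ".c2"), planes, planes, 3L, stride, os_out, g)
  c3 <- conv_bn_relu(ctx, paste0(name, ".c3"), planes, out, 1L, 1L, os_out, g,
                     act = FALSE)
  ds <- if (first) {
    conv_bn_relu(ctx, paste0(name, ".ds"), inplanes, out, 1L, stride, os_out,
                 g, act = FALSE)
  } else NULL
  function(x, training = TRUE) {
    h <- c3$fwd(c2$fwd(c1$fwd(x, training), training), training)
    sc <- if (is.null(ds)) x else ds$fwd(x, training)
    nd_relu(nd_add(h, sc))
  }
}

bottle2neck <- function(ctx, name, inplanes, planes, stride, os_in, first,
                        base_width = 26L, scale = 4L) {
  g <- "backbone"
  os_out <- os_in * stride
  out <- planes * 4L
  width <- as.integer(floor(planes * base_width / 64))
  ws <- width * scale
  c1 <- conv_bn_relu(ctx, paste0(name, ".c1"), inplanes, ws, 1L, 1L, os_in, g)
  sps <- lapply(seq_len(scale - 1L), function(i) {
    conv_bn_relu(ctx, sprintf("%s.sp%d", name, i), width, width, 3L, stride,
                 os_out, g)
  })
  c3 <- conv_bn_relu(ctx, paste0(name, ".c3"), ws, out, 1L, 1L, os_out, g,
                     act = FALSE)
  ds <- if (first) {
    conv_bn_relu(ctx, paste0(name, ".ds"), inplanes, out, 1L, stride, os_out,
                 g, act = FALSE)
  } else NULL
  stage_type <- first
  function(x, training = TRUE) {
    h <- c1$fwd(x, training)
    splits <- lapply(seq_len(scale), function(i) {
      nd_slice_c(h, (i - 1L) * width + 1L, i * width)
    })
    outs <- list()
    prev <- NULL
    for (i in seq_len(scale - 1L)) {
      inp <- if (i == 1L || stage_type) splits[[i]] else nd_add(splits[[i]], prev)
      prev <- sps[[i]]$fwd(inp, training)
      outs[[i]] <- prev
    }
    last <- if (stage_type) {
      nd_pool(splits[[scale]], 3L, stride, 1L, "avg")
    } else splits[[scale]]
    outs[[scale]] <- last
    h <- Reduce(nd_concat_c, outs)
    h <- c3$fwd(h, training)
    sc <- if (is.null(ds)) x else ds$fwd(x, training)
    nd_relu(nd_add(h, sc))
  }
}
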