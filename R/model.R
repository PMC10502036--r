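#' Configuration for a dual-attention segmentation network
#'
#' @param backbone `"tiny_test"` (CPU-trainable), `"res2net50"`, or
#'   `"resnet50"`.
#' @param channels projection width `C`: all pyramid taps are reduced to
#'   this channel count by 1x1 conv + BN + ReLU before attention.
#' @param gate_mode fusion of the two attention branches: `"softmax"`
#'   (convex per-channel gate), `"sigmoid"` (independent gates), `"sum"`.
#' @param variant `"full"` (both branches), `"sam_only"`, `"ram_only"`,
#'   or `"baseline"` (no attention; decode from the deepest map alone).
#' @param pyramid `"full_fp"` (dual attention at both pyramid passes),
#'   `"single_pass"` (only between F4 and F5), `"none"`.
#' @param input_size `c(rows, cols)`, each divisible by 32.
#' @param seed seed for weight initialization.
#' @return an object of class `sranet_config`.
#' @export
sranet_config <- function(backbone = "tiny_test", channels = 64L,
                          gate_mode = c("softmax", "sigmoid", "sum"),
                          variant = c("full", "sam_only", "ram_only", "baseline"),
                          pyramid = c("full_fp", "single_pass", "none"),
                          input_size = c(352L, 352L), seed = 1L) {
  gate_mode <- match.arg(gate_mode)
  variant <- match.arg(variant)
  pyramid <- match.arg(pyramid)
  input_size <- as.integer(rep(input_size, length.out = 2L))
  if (any(input_size %% 32L != 0L) || any(input_size <= 0L)) {
    stop("input size must be positive and divisible by 32", call. = FALSE)
  }
  if (channels < 1) stop("projection width must be >= 1", call. = FALSE)
  if (variant == "baseline") pyramid <- "none"
  structure(list(backbone = backbone, channels = as.integer(channels),
                 gate_mode = gate_mode, variant = variant, pyramid = pyramid,
                 input_size = input_size, seed = as.integer(seed)),
            class = "sranet_config")
}

#' Build a dual-attention segmentation network
#'
#' Assembles backbone, 1x1 channel projections, the shallow/reverse
#' dual-attention pyramid with softmax-gated fusion, and a progressive
#' decoding head, all with freshly initialized weights.
#'
#' @param config an [sranet_config()].
#' @return an object of class `sranet_model` with elements `config`,
#'   `params` (trainable parameter list) and the forward machinery.
#' @export
sranet <- function(config = sranet_config()) {
  stopifnot(inherits(config, "sranet_config"))
  set.seed(mix_seed(config$seed, 0L))
  ctx <- new_ctx()
  bb_fwd <- build_backbone(ctx, config$backbone)
  ch <- backbone_channels(config$backbone)
  C <- config$channels
  # the baseline ablation decodes from projected F5 alone, so the unused
  # shallow projections are not built; single_pass additionally needs F4
  proj <- list(p5 = conv_bn_relu(ctx, "proj5", ch[3], C, 1L, 1L, 32L,
                                 part = "projection"))
  if (config$pyramid != "none") {
    proj$p4 <- conv_bn_relu(ctx, "proj4", ch[2], C, 1L, 1L, 16L,
                            part = "projection")
  }
  if (config$pyramid == "full_fp") {
    proj$p3 <- conv_bn_relu(ctx, "proj3", ch[1], C, 1L, 1L, 8L,
                            part = "projection")
  }
  gates <- NULL
  if (config$variant == "full" && config$gate_mode != "sum" &&
      config$pyramid != "none") {
    gates <- list(
      g4_sa = gate_fc(ctx, "g4.sa", C), g4_ra = gate_fc(ctx, "g4.ra", C)
    )
    if (config$pyramid == "full_fp") {
      gates$g3_sa <- gate_fc(ctx, "g3.sa", C)
      gates$g3_ra <- gate_fc(ctx, "g3.ra", C)
    }
  }
  dec4 <- conv_bn_relu(ctx, "dec4", 2L * C, C, 3L, 1L, 16L, part = "decoder")
  dec3 <- conv_bn_relu(ctx, "dec3", 2L * C, C, 3L, 1L, 8L, part = "decoder")
  head <- conv_bn_relu(ctx, "head", C, 1L, 1L, 1L, 8L, part = "decoder",
                       bn = FALSE, act = FALSE)
  structure(list(config = config, ctx = ctx, params = ctx$params,
                 backbone_fwd = bb_fwd, proj = proj, gates = gates,
                 dec4 = dec4, dec3 = dec3, head = head),
            class = "sranet_model")
}

# one dual-attention block on the tape; deeper maps are already projected.
# Returns the fused node plus diagnostics (numeric attention maps, gates).
sr_dam_block <- function(f_k, f_k1, f_k2 = NULL, ra_source = NULL,
                         gate_sa = NULL, gate_ra = NULL,
                         gate_mode = "softmax", variant = "full") {
  d <- dim(f_k$value)
  up1 <- nd_upsample(f_k1, d[2], d[3])
  m_sa <- nd_relu(up1)
  f_sa <- nd_mul(m_sa, f_k)
  diag <- list(sam = m_sa$value)
  if (!is.null(f_k2)) {
    m_sa2 <- nd_relu(nd_upsample(f_k2, d[2], d[3]))
    f_sa <- nd_mul(m_sa2, f_sa)
    diag$sam2 <- m_sa2$value
  }
  if (variant == "sam_only") return(list(node = f_sa, diag = diag))
  ra_src <- ra_source %||% f_k1
  m_ra <- nd_rsub1(nd_sigmoid(nd_upsample(ra_src, d[2], d[3])))
  f_ra <- nd_mul(m_ra, f_k)
  diag$ram <- m_ra$value
  if (variant == "ram_only") return(list(node = f_ra, diag = diag))
  if (gate_mode == "sum") {
    return(list(node = nd_add(f_sa, f_ra), diag = diag))
  }
  c_sa <- gate_sa$fwd(f_sa)
  c_ra <- gate_ra$fwd(f_ra)
  if (gate_mode == "softmax") {
    v_sa <- nd_sigmoid(nd_sub(c_sa, c_ra))   # 2-way softmax per channel
    v_ra <- nd_rsub1(v_sa)
  } else {
    v_sa <- nd_sigmoid(c_sa)
    v_ra <- nd_sigmoid(c_ra)
  }
  fused <- nd_add(nd_cmul(f_sa, v_sa), nd_cmul(f_ra, v_ra))
  diag$v_sa <- v_sa$value
  diag$v_ra <- v_ra$value
  list(node = fused, diag = diag)
}

#' Run the network forward
#'
#' @param model an [sranet()] model.
#' @param images `(H,W,3)` or `(N,H,W,3)` array in `[0,1]` with spatial
#'   dimensions divisible by 32.
#' @param training build batch statistics (TRUE) or use running statistics
#'   (FALSE, deterministic evaluation).
#' @param diagnostics also return per-level attention maps and gate vectors.
#' @return a list with `pred` (probability array, input resolution;
#'   `(N,H,W)` or `(H,W)`), `node` (the tape node, for training), and
#'   `diag` when requested.
#' @export
sranet_forward <- function(model, images, training = FALSE,
                           diagnostics = FALSE) {
  x <- with_batch(images)
  hb <- attr(x, "had_batch")
  d <- dim(x)
  if (any(d[2:3] %% 32L != 0L)) {
    stop("input spatial dims must be divisible by 32", call. = FALSE)
  }
  cfg <- model$config
  taps <- model$backbone_fwd(nd_const(x), training)
  F5 <- model$proj$p5$fwd(taps$f5, training)
  diag <- list()
  if (cfg$pyramid == "none" || cfg$variant == "baseline") {
    d4 <- dim(taps$f4$value); d3 <- dim(taps$f3$value)
    R4 <- nd_upsample(F5, d4[2], d4[3])
    R3 <- nd_upsample(F5, d3[2], d3[3])
  } else {
    F4 <- model$proj$p4$fwd(taps$f4, training)
    b4 <- sr_dam_block(F4, F5,
                       gate_sa = model$gates$g4_sa, gate_ra = model$gates$g4_ra,
                       gate_mode = cfg$gate_mode, variant = cfg$variant)
    R4 <- b4$node
    diag$level4 <- b4$diag
    if (cfg$pyramid == "full_fp") {
      F3 <- model$proj$p3$fwd(taps$f3, training)
      b3 <- sr_dam_block(F3, F4, f_k2 = F5, ra_source = F4,
                         gate_sa = model$gates$g3_sa,
                         gate_ra = model$gates$g3_ra,
                         gate_mode = cfg$gate_mode, variant = cfg$variant)
      R3 <- b3$node
      diag$level3 <- b3$diag
    } else {
      d3 <- dim(taps$f3$value)
      R3 <- nd_upsample(R4, d3[2], d3[3])
    }
  }
  d4 <- dim(R4$value); d3 <- dim(R3$value)
  u5 <- nd_upsample(F5, d4[2], d4[3])
  h4 <- model$dec4$fwd(nd_concat_c(u5, R4), training)
  u4 <- nd_upsample(h4, d3[2], d3[3])
  h3 <- model$dec3$fwd(nd_concat_c(u4, R3), training)
  logits <- model$head$fwd(h3, training)
  pred <- nd_sigmoid(nd_upsample(logits, d[2], d[3]))
  pv <- pred$value
  pm <- array(pv, dim = dim(pv)[1:3])
  out <- list(pred = if (hb) pm else array(pm, dim = d[2:3]), node = pred)
  if (diagnostics) out$diag <- diag
  out
}

#' Predict a segmentation probability map for one image
#'
#' @param model an [sranet()] model.
#' @param image `(H,W,3)` array in `[0,1]`, dims divisible by 32.
#' @param diagnostics return attention maps and gate vectors as well.
#' @return the `(H,W)` probability matrix, or a list with `pred` and
#'   `diag` if `diagnostics = TRUE`.
#' @export
predict_mask <- function(model, image, diagnostics = FALSE) {
  out <- sranet_forward(model, image, training = FALSE,
                        diagnostics = diagnostics)
  if (diagnostics) list(pred = out$pred, diag = out$diag) else out$pred
}

#' Count trainable parameters
#'
#' @param model an [sranet()] model.
#' @return total number of scalar trainable parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' Save / load a model checkpoint
#'
#' The weight archive is a serialized list of parameter arrays; a JSON
#' sidecar records the configuration and package version so a checkpoint is
#' reproducible from its sidecar alone.
#'
#' @param model an [sranet()] model.
#' @param path checkpoint file path (`.rds`); the sidecar is `path` +
#'   `".json"`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  weights <- lapply(model$params, function(p) p$value)
  names(weights) <- vapply(model$params, function(p) p$name, character(1))
  bn <- lapply(model$ctx$bn_states, function(s)
    list(running_mean = s$running_mean, running_var = s$running_var))
  saveRDS(list(weights = weights, bn = bn), path)
  sidecar <- list(
    config = unclass(model$config),
    package = "sranet",
    version = as.character(utils::packageVersion("sranet"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path checkpoint path written by [save_checkpoint()].
#' @param config optional [sranet_config()]; by default it is rebuilt from
#'   the JSON sidecar.
#' @export
load_checkpoint <- function(path, config = NULL) {
  blob <- readRDS(path)
  if (is.null(config)) {
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    cfg <- side$config
    config <- sranet_config(backbone = cfg$backbone, channels = cfg$channels,
                            gate_mode = cfg$gate_mode, variant = cfg$variant,
                            pyramid = cfg$pyramid, input_size = cfg$input_size,
                            seed = cfg$seed)
  }
  model <- sranet(config)
  stopifnot(length(model$params) == length(blob$weights))
  for (i in seq_along(model$params)) {
    stopifnot(identical(dim2(model$params[[i]]$value),
                        dim2(blob$weights[[i]])))
    model$params[[i]]$value <- blob$weights[[i]]
  }
  stopifnot(length(model$ctx$bn_states) == length(blob$bn))
  for (i in seq_along(blob$bn)) {
    model$ctx$bn_states[[i]]$running_mean <- blob$bn[[i]]$running_mean
    model$ctx$bn_states[[i]]$running_var <- blob$bn[[i]]$running_var
  }
  model
}
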