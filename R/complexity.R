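#' Static MAC and parameter counts for a network configuration
#'
#' Walks the architecture's layer records (convolutions, fully connected
#' layers, batch normalizations) and accumulates exact multiply-accumulate
#' counts for one forward pass at the configured input size, plus trainable
#' parameter counts. Conventions: a `k x k` convolution with `c_in` input
#' and `c_out` output channels costs `k^2 * c_in * c_out` MACs per output
#' pixel and the same number of parameters (no biases); batch normalization
#' costs 2 parameters per channel and 2 operations per output element;
#' activations, pooling and interpolation are not counted.
#'
#' @param config an [sranet_config()], or an [sranet()] model.
#' @param input_size optional `c(rows, cols)` override.
#' @return a list with `gmacs` (billions of MACs), `params_m` (parameters
#'   in millions), and `per_part`, a data.frame breaking both down by
#'   component (backbone / projection / dam_gates / decoder).
#' @export
count_complexity <- function(config, input_size = NULL) {
  model <- if (inherits(config, "sranet_model")) config else sranet(config)
  cfg <- model$config
  input_size <- as.integer(input_size %||% cfg$input_size)
  input_size <- rep(input_size, length.out = 2L)
  rows <- lapply(model$ctx$layers, function(l) {
    if (l$type == "conv") {
      np <- l$k^2 * l$cin * l$cout
      area <- (input_size[1] / l$out_stride) * (input_size[2] / l$out_stride)
      macs <- np * area
    } else if (l$type == "fc") {
      np <- l$cin * l$cout
      macs <- np
    } else {  # bn
      np <- 2 * l$cout
      area <- (input_size[1] / l$out_stride) * (input_size[2] / l$out_stride)
      macs <- 2 * l$cout * area
    }
    data.frame(name = l$name, type = l$type, part = l$part,
               params = np, macs = macs)
  })
  tab <- do.call(rbind, rows)
  per_part <- stats::aggregate(cbind(params, macs) ~ part, tab, sum)
  per_part$gmacs <- per_part$macs / 1e9
  per_part$params_m <- per_part$params / 1e6
  list(gmacs = sum(tab$macs) / 1e9,
       params_m = sum(tab$params) / 1e6,
       per_part = per_part[, c("part", "params_m", "gmacs")])
}
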