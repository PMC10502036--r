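# Small fixtures shared across test files; everything is generated in code.

rand_fmap <- function(h = 4, w = 4, c = 3, sd = 1) {
  array(stats::rnorm(h * w * c, sd = sd), dim = c(h, w, c))
}

rand_mask_pair <- function(h = 8, w = 8, p_fg = 0.4) {
  y <- matrix(stats::rbinom(h * w, 1, p_fg), h, w)
  y_hat <- matrix(stats::runif(h * w), h, w)
  list(y = y, y_hat = y_hat)
}

tiny_model <- function(seed = 3L, channels = 32L, ...) {
  sranet(sranet_config(backbone = "tiny_test", channels = channels,
                       input_size = c(64L, 64L), seed = seed, ...))
}

# the desk-scale study run: 200 synthetic samples, tiny backbone, 10 epochs.
# Trained once and shared by the training tests and the acceptance suite.
study_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- generate_dataset(synth_spec(seed = 7L), 200L)
      model <- tiny_model(seed = 3L)
      cfg <- train_config(preset = "tiny", seed = 3L)   # 10 epochs, batch 8
      res <- train(model, ds$samples[1:180], cfg)
      cache <<- list(result = res, train_samples = ds$samples[1:180],
                     held = ds$samples[181:200], config = cfg,
                     model_seed = 3L)
    }
    cache
  }
})
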