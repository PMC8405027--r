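# Shared fixtures for the test suite. Small nets (16 px, 2 base channels,
# depth 2) keep unit tests fast; the acceptance tests use the full desk
# scale (64 px, 8 base channels, depth 4).

tiny_cfg <- function() net_config(in_size = 16, base_channels = 2, depth = 2)

tiny_dataset <- function(seed = 1, n_weak = 0, n_full = 12) {
  generate_dataset(phantom_spec(image_size = 16, seed = seed),
                   n_weak = n_weak, n_full = n_full)
}

tiny_train_cfg <- function(arm = "unet", seed = 1, epochs = 2, ...) {
  train_config(epochs_max = epochs, batch_size = 4, early_stop_patience = 10,
               seed = seed, arm = arm, ...)
}

random_prob_vec <- function(n) {
  v <- runif(n)
  v / sum(v)
}

random_binary_mask <- function(nr, nc, p = 0.4) {
  matrix(rbinom(nr * nc, 1, p), nr, nc)
}

# The desk-scale benchmark is expensive; compute it once per test run and
# share it across the acceptance blocks that examine it.
benchmark_cache <- new.env(parent = emptyenv())

get_benchmark <- function() {
  if (is.null(benchmark_cache$bench)) {
    benchmark_cache$bench <- benchmark_distillation(seed = 42L)
  }
  benchmark_cache$bench
}
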