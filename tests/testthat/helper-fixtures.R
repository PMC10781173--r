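# shared fixtures and independent oracles used across test files

# brute-force K-of-N oracle: enumerate every window, union triggered spans
k_of_n_oracle <- function(dec, K, N) {
  n <- length(dec)
  out <- integer(n)
  for (s in seq_len(n - N + 1L)) {
    if (sum(dec[s:(s + N - 1L)]) >= K) out[s:(s + N - 1L)] <- 1L
  }
  out
}

# all-pairs AUC oracle with half credit for ties
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# small separable synthetic feature maps: two Gaussian classes
gaussian_maps <- function(n_per_class, n_channels = 4, shift = 3,
                          seed = 42) {
  set.seed(seed)
  maps <- c(
    lapply(seq_len(n_per_class), function(i) {
      matrix(rnorm(n_channels * 12), n_channels, 12)
    }),
    lapply(seq_len(n_per_class), function(i) {
      matrix(rnorm(n_channels * 12, mean = shift), n_channels, 12)
    }))
  list(maps = maps, labels = rep(c(0L, 1L), each = n_per_class))
}

# tiny configuration for fast training tests (higher lr: few Adam steps)
tiny_config <- function(...) {
  encoder_config(n_layers = 2L, ff_hidden = 16L, mlp_hidden = 8L,
                 max_epochs = 60L, patience = 8L, lr = 3e-3, seed = 7L, ...)
}

# one small trained model, fitted lazily and reused across tests
.fixture_env <- new.env(parent = emptyenv())
small_trained_model <- function() {
  if (is.null(.fixture_env$model)) {
    gm <- gaussian_maps(40)
    .fixture_env$gm <- gm
    .fixture_env$model <- seizure_transformer(gm$maps, gm$labels,
                                              tiny_config(),
                                              normalize = FALSE)
  }
  list(model = .fixture_env$model, data = .fixture_env$gm)
}

# hand-rolled st_tf construction for feature tests
fake_tf <- function(values, freqs, fs = 256) {
  structure(list(values = values, freqs = freqs,
                 times = (seq_len(ncol(values)) - 1) / fs, fs = fs),
            class = "st_tf")
}
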