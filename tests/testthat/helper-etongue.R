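# Small, fast study configurations shared across tests. The reduced channel
# counts and durations keep unit tests quick; full-size layouts are exercised
# in the acceptance suite.

tiny_config <- function(seed = 1, ...) {
  sim_config(n_classes = 3, n_replicates = 6, n_channels = 4,
             ref_duration_s = 20, test_duration_s = 16,
             seed = seed, ...)
}

# featurized small dataset, memoized per (task, seed, extra args)
.fixture_cache <- new.env(parent = emptyenv())

featurized_fixture <- function(task = "custom", seed = 1, resolution = 48, ...) {
  key <- paste(task, seed, resolution, rlang::hash(list(...)), sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    d <- simulate_task_data(task, tiny_config(seed = seed, ...))
    d <- encode_fingerprints(d, resolution = resolution)
    .fixture_cache[[key]] <- extract_features(d)
  }
  .fixture_cache[[key]]
}

# deterministic random image for extractor tests
random_image <- function(seed, res = 48) {
  set.seed(seed)
  g <- matrix(runif(res * res, -1, 1), res, res)
  render_image(g)
}
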