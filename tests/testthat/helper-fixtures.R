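# Shared fixtures, built lazily and cached for the whole run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache)) assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

# 40 curated synthetic molecules, deterministic
small_fixture_mols <- function() {
  cached("mols40", generate_fixtures(fixture_config(40, seed = 123)))
}

# a packaged tiny dataset (12 molecules, deepsmiles) for network/cli tests
tiny_dataset <- function() {
  cached("tinyds", {
    mols <- generate_fixtures(fixture_config(12, seed = 77))
    package_dataset(mols, "deepsmiles", file.path(tempdir(), "tinyds"),
                    base_seed = 5, test_fraction = 0.2)
  })
}

# a tiny trained network (few epochs) shared across decoding tests
tiny_network <- function() {
  cached("tinynet", {
    ds <- tiny_dataset()
    cfg <- model_config(embedding_dim = 24L, units = 32L, batch_size = 5L,
                        learning_rate = 0.002, epochs = 3L, seed = 9L)
    net <- init_network(cfg, ncol(ds$records[[1]]$features), ds$vocab)
    train_network(net, dataset_split(ds, "train"))
  })
}

expect_same_molecule <- function(a, b) {
  expect_identical(canonicalize(a), canonicalize(b))
}
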