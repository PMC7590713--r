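# Network primitives: encoder, attention, decoder step, masked loss,
# gradient correctness, seeded training and greedy decoding.

test_that("encode_features is an affine map with rectifier", {
  params <- list(Wenc = matrix(0.5, 3L, 4L), benc = rep(0, 4L))
  expect_equal(encode_features(matrix(0, 5L, 3L), params),
               matrix(0, 5L, 4L))                       # relu(0) = 0
  g <- matrix(rnorm(15), 5L, 3L)
  out <- encode_features(g, params)
  expect_true(all(out >= 0))
  # positive homogeneity on rows with non-negative preactivation
  row <- matrix(abs(rnorm(3)), 1L, 3L)
  expect_equal(encode_features(2 * row, params),
               2 * encode_features(row, params), tolerance = 1e-12)
})

test_that("attention produces a simplex and convex-hull context", {
  E <- 4L; A <- 3L; U <- 2L; L <- 6L
  set.seed(1)
  params <- list(W1a = matrix(rnorm(E * A), E, A),
                 W2a = matrix(rnorm(U * A), U, A),
                 va = rnorm(A))
  feats <- matrix(rnorm(L * E), L, E)
  att <- attend(feats, rnorm(U), params)
  expect_equal(sum(att$weights), 1, tolerance = 1e-9)
  expect_true(all(att$weights >= 0))
  expect_equal(att$context, as.vector(att$weights %*% feats), tolerance = 1e-12)

  # all scores equal (va = 0) -> uniform weights
  params0 <- params; params0$va <- rep(0, A)
  expect_equal(attend(feats, rnorm(U), params0)$weights, rep(1 / L, L),
               tolerance = 1e-12)

  # degenerate single location
  att1 <- attend(feats[1, , drop = FALSE], rnorm(U), params)
  expect_equal(att1$weights, 1)
  expect_equal(att1$context, as.vector(feats[1, ]))
})

test_that("hand-computed two-location attention example matches", {
  # features [[1,0],[0,1]]; weights chosen so scores are exactly [0, ln 3]:
  # then alpha = [1/4, 3/4] and context = [1/4, 3/4]
  feats <- rbind(c(1, 0), c(0, 1))
  params <- list(W1a = rbind(c(0, 0), c(atanh(log(3) / 2), 0)),
                 W2a = matrix(0, 1L, 2L),
                 va = c(2, 0))
  att <- attend(feats, 0, params)
  expect_equal(att$weights, c(0.25, 0.75), tolerance = 1e-9)
  expect_equal(att$context, c(0.25, 0.75), tolerance = 1e-9)
})

test_that("masked loss has its closed forms and ignores padding exactly", {
  V <- 7L
  # probability ~1 on each target -> loss ~0
  targets <- c(3L, 1L, 5L)
  logits <- matrix(0, 3L, V)
  for (i in 1:3) logits[i, targets[i] + 1L] <- 60
  expect_lt(masked_loss(logits, targets), 1e-9)

  # uniform logits -> ln V, exactly
  expect_equal(masked_loss(matrix(1, 4L, V), c(1L, 2L, 3L, 4L)), log(V),
               tolerance = 1e-9)

  # appending PAD-only rows changes nothing
  lg <- matrix(rnorm(3 * V), 3L, V)
  base <- masked_loss(lg, targets)
  padded <- masked_loss(rbind(lg, matrix(rnorm(2 * V), 2L, V)),
                        c(targets, 0L, 0L))
  expect_identical(base, padded)
  expect_equal(masked_loss(lg, c(0L, 0L, 0L)), 0)
})

test_that("decode_step is deterministic, shaped, and context-sensitive", {
  ds <- tiny_dataset()
  cfg <- model_config(embedding_dim = 8L, units = 6L, batch_size = 2L,
                      epochs = 1L, seed = 2L)
  net <- init_network(cfg, 4L, ds$vocab)
  ctx <- rnorm(8L); st <- rnorm(6L)
  a <- decode_step(3L, ctx, st, net)
  b <- decode_step(3L, ctx, st, net)
  expect_identical(a, b)
  expect_length(a$logits, ds$vocab$size)
  expect_length(a$state, 6L)
  c_ <- decode_step(3L, ctx + 0.1, st, net)
  expect_false(identical(a$logits, c_$logits))
  expect_error(decode_step(ds$vocab$size, ctx, st, net),
               class = "ocsr_contract_violation")
})

test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(99)
  V <- 6L; D <- 3L; L <- 4L; B <- 2L
  vocab <- structure(list(
    token_to_index = stats::setNames(0:5, c("<pad>", "<start>", "<end>",
                                            "<unk>", "C", "O")),
    index_to_token = c("<pad>", "<start>", "<end>", "<unk>", "C", "O"),
    max_length = 5L, size = V), class = "ocsr_vocab")
  cfg <- model_config(embedding_dim = 4L, units = 3L, attention_units = 3L,
                      fc_units = 3L, batch_size = 2L, epochs = 1L, seed = 5L)
  net <- init_network(cfg, D, vocab)
  feats <- matrix(rnorm(B * L * D), B * L, D)
  targets <- rbind(c(1L, 4L, 5L, 2L, 0L), c(1L, 5L, 2L, 0L, 0L))
  fwd <- ocsr:::.forward_batch(net$params, feats, targets, L)
  grads <- ocsr:::.backward_batch(net$params, feats, targets, L, fwd)
  eps <- 1e-5
  for (nm in names(net$params)) {
    for (trial in 1:3) {
      i <- sample(length(net$params[[nm]]), 1L)
      p2 <- net$params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      up <- ocsr:::.forward_batch(p2, feats, targets, L, keep_cache = FALSE)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      dn <- ocsr:::.forward_batch(p2, feats, targets, L, keep_cache = FALSE)$loss
      fd <- (up - dn) / (2 * eps)
      an <- grads[[nm]][i]
      if (abs(fd) > 1e-6 || abs(an) > 1e-6) {
        expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-4,
                  label = sprintf("gradient of %s[%d]", nm, i))
      }
    }
  }
})

test_that("training is seeded-reproducible and frozen at zero learning rate", {
  ds <- tiny_dataset()
  samp <- dataset_split(ds, "train")
  cfg <- model_config(embedding_dim = 12L, units = 10L, batch_size = 4L,
                      learning_rate = 0.002, epochs = 3L, seed = 4L)
  n1 <- train_network(init_network(cfg, ncol(samp[[1]]$features), ds$vocab), samp)
  n2 <- train_network(init_network(cfg, ncol(samp[[1]]$features), ds$vocab), samp)
  expect_identical(n1$loss_trace, n2$loss_trace)
  expect_identical(n1$params, n2$params)

  cfg0 <- model_config(embedding_dim = 12L, units = 10L, batch_size = 4L,
                       learning_rate = 0, epochs = 3L, seed = 4L)
  n0 <- train_network(init_network(cfg0, ncol(samp[[1]]$features), ds$vocab), samp)
  expect_equal(diff(range(n0$loss_trace)), 0, tolerance = 1e-12)
})

test_that("greedy decoding is deterministic and respects max_len", {
  net <- tiny_network()
  ds <- tiny_dataset()
  feats <- ds$records[[1]]$features
  d1 <- greedy_decode(net, feats)
  d2 <- greedy_decode(net, feats)
  expect_identical(d1, d2)
  expect_identical(d1$tokens[1], "<start>")
  d3 <- greedy_decode(net, feats, max_len = 3L)
  expect_lte(length(d3$tokens), 4L)      # start + at most 3 generated
})

test_that("featurizer is deterministic, shaped, and non-constant", {
  bb <- default_backbone()
  img <- render("CCCCC(=O)O", render_spec(299L, 0.3, 5L))
  f1 <- featurize(img, bb)
  expect_equal(dim(f1), c(64L, 64L))
  expect_identical(f1, featurize(img, bb))
  white <- array(255L, c(299L, 299L, 3L))
  expect_false(identical(featurize(white, bb), f1))
})

test_that("checkpoints embed the vocabulary hash and refuse mismatches", {
  net <- tiny_network()
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, net$params)
  corrupted <- net
  corrupted$vocab$index_to_token[5] <- "XX"
  path2 <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(corrupted, path2)
  expect_error(load_checkpoint(path2), class = "ocsr_contract_violation")
})
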