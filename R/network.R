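# The show-and-tell network: FC+ReLU encoder over spatial image features,
# additive (Bahdanau) soft attention, GRU decoder with two fully connected
# output layers. Implemented directly in base R linear algebra with manual
# backpropagation and Adam, fully seeded; a finite-difference gradient check
# in the test suite guards the derivatives.
#
# Shapes: B batch, L feature locations, D feature channels, E embedding
# width, A attention width, U decoder units, V vocabulary size. The GRU
# input at each step is [token embedding ; attention context], both width E.

#' Model configuration
#'
#' Defaults follow the reference training setup: batch size 640, embedding
#' width 600, learning rate 5e-4, Adam, 25 epochs. Desk-scale tests override
#' them downward.
#'
#' @param embedding_dim token/feature embedding width E (default 600)
#' @param units decoder GRU width U (default 512)
#' @param attention_units additive-attention width A (default = units)
#' @param fc_units width of the first output FC layer (default = units)
#' @param batch_size training batch size (default 640)
#' @param learning_rate Adam learning rate (default 0.0005)
#' @param lr_decay per-epoch multiplicative learning-rate decay (default 1,
#'   i.e. constant; overfitting sanity runs use a decay so the loss descends
#'   monotonically instead of oscillating at the optimum)
#' @param epochs training epochs (default 25)
#' @param seed master seed for parameter init and shuffling
#' @return object of class `ocsr_model_config`
#' @export
model_config <- function(embedding_dim = 600L, units = 512L,
                         attention_units = units, fc_units = units,
                         batch_size = 640L, learning_rate = 0.0005,
                         lr_decay = 1.0, epochs = 25L, seed = 1L) {
  cfg <- list(embedding_dim = as.integer(embedding_dim),
              units = as.integer(units),
              attention_units = as.integer(attention_units),
              fc_units = as.integer(fc_units),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate,
              lr_decay = lr_decay,
              epochs = as.integer(epochs),
              seed = as.integer(seed))
  stopifnot(all(vapply(cfg[1:5], function(x) x >= 1L, TRUE)),
            learning_rate >= 0, lr_decay > 0, lr_decay <= 1)
  structure(cfg, class = "ocsr_model_config")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

.mat_init <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
}

#' Initialize network parameters
#'
#' @param config an [model_config()]
#' @param feature_dim D, channels of the featurizer grid
#' @param vocab an `ocsr_vocab`
#' @return object of class `ocsr_network`
#' @export
init_network <- function(config, feature_dim, vocab) {
  E <- config$embedding_dim; U <- config$units; A <- config$attention_units
  FC <- config$fc_units; V <- vocab$size; D <- as.integer(feature_dim)
  X <- 2L * E
  params <- .with_seed(config$seed, list(
    Wenc = .mat_init(D, E), benc = rep(0, E),
    Emb = .mat_init(V, E),
    W1a = .mat_init(E, A), W2a = .mat_init(U, A), va = stats::rnorm(A, sd = 1 / sqrt(A)),
    Wz = .mat_init(X, U), Uz = .mat_init(U, U), bz = rep(0, U),
    Wr = .mat_init(X, U), Ur = .mat_init(U, U), br = rep(0, U),
    Wh = .mat_init(X, U), Uh = .mat_init(U, U), bh = rep(0, U),
    Wf1 = .mat_init(U, FC), bf1 = rep(0, FC),
    Wf2 = .mat_init(FC, V), bf2 = rep(0, V)))
  structure(list(params = params, config = config, feature_dim = D,
                 vocab = vocab, vocab_hash = .vocab_hash(vocab),
                 loss_trace = numeric(0)), class = "ocsr_network")
}

#' @export
print.ocsr_network <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<ocsr_network> V=%d D=%d E=%d U=%d | %s parameters | %d epochs trained\n",
              x$vocab$size, x$feature_dim, x$config$embedding_dim,
              x$config$units, format(np, big.mark = ","), length(x$loss_trace)))
  invisible(x)
}

# ---- primitive layers -----------------------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

#' Encode a feature grid: row-wise affine map + rectifier
#'
#' @param grid L x D feature matrix (or stacked rows for a batch)
#' @param params network parameter list (uses `Wenc`, `benc`)
#' @return matrix with `embedding_dim` columns, all entries >= 0
#' @export
encode_features <- function(grid, params) {
  pmax(sweep(grid %*% params$Wenc, 2L, params$benc, "+"), 0)
}

#' Additive soft attention over encoded feature rows
#'
#' Scores e_i = va' tanh(features_i W1a + hidden W2a); weights are the
#' softmax of the scores; the context vector is the weight-averaged feature
#' row, hence lies in their convex hull.
#'
#' @param features L x E matrix of (projected) feature rows
#' @param hidden decoder hidden state, length U
#' @param params parameter list with `W1a` (E x A), `W2a` (U x A), `va` (A)
#' @return list(weights = length-L simplex vector, context = length-E vector)
#' @export
attend <- function(features, hidden, params) {
  s <- tanh(sweep(features %*% params$W1a, 2L,
                  as.vector(hidden %*% params$W2a), "+"))
  scores <- as.vector(s %*% params$va)
  alpha <- as.vector(.softmax_rows(matrix(scores, 1L)))
  list(weights = alpha, context = as.vector(alpha %*% features))
}

#' One decoder step: GRU update then two FC layers
#'
#' @param prev_token 0-based token index
#' @param context attention context vector (length E)
#' @param state decoder hidden state (length U)
#' @param net an `ocsr_network`
#' @return list(logits = length-V, state = updated hidden state)
#' @export
decode_step <- function(prev_token, context, state, net) {
  p <- net$params
  V <- net$vocab$size
  if (prev_token < 0L || prev_token >= V) stop(ocsr_condition(
    "ocsr_contract_violation",
    sprintf("token index %d out of range [0, %d)", prev_token, V)))
  x <- matrix(c(p$Emb[prev_token + 1L, ], context), 1L)
  h <- matrix(state, 1L)
  z <- .sigmoid(x %*% p$Wz + h %*% p$Uz + rep(p$bz, each = 1L))
  r <- .sigmoid(x %*% p$Wr + h %*% p$Ur + rep(p$br, each = 1L))
  hh <- tanh(x %*% p$Wh + (r * h) %*% p$Uh + rep(p$bh, each = 1L))
  hn <- (1 - z) * h + z * hh
  o1 <- pmax(sweep(hn %*% p$Wf1, 2L, p$bf1, "+"), 0)
  logits <- as.vector(sweep(o1 %*% p$Wf2, 2L, p$bf2, "+"))
  list(logits = logits, state = as.vector(hn))
}

#' Masked sparse categorical cross-entropy
#'
#' Mean over non-PAD positions of -log softmax(logits)[target]; PAD (index
#' 0) positions contribute exactly zero and are excluded from the
#' denominator.
#'
#' @param logits N x V matrix (rows = positions) or (B, T, V) array
#' @param targets 0-based target indices, length N (or B x T matrix)
#' @return scalar loss
#' @export
masked_loss <- function(logits, targets) {
  if (length(dim(logits)) == 3L) {
    d <- dim(logits)
    logits <- matrix(logits, d[1] * d[2], d[3])
    targets <- as.vector(targets)
  }
  mask <- targets != 0L
  if (!any(mask)) return(0)
  lg <- logits[mask, , drop = FALSE]
  tg <- targets[mask]
  mx <- apply(lg, 1L, max)
  lse <- mx + log(rowSums(exp(lg - mx)))
  picked <- lg[cbind(seq_len(nrow(lg)), tg + 1L)]
  mean(lse - picked)
}

# ---- batched teacher-forced forward/backward ------------------------------

# feats: (B*L) x D matrix, rows b-major; targets: B x T 0-based index matrix
.forward_batch <- function(params, feats, targets, L, keep_cache = TRUE) {
  B <- nrow(targets); TT <- ncol(targets)
  grp <- rep(seq_len(B), each = L)
  enc <- pmax(sweep(feats %*% params$Wenc, 2L, params$benc, "+"), 0)
  encW1 <- enc %*% params$W1a
  U <- ncol(params$Uz); E <- ncol(params$Wenc)
  h <- matrix(0, B, U)
  cache <- if (keep_cache) vector("list", TT - 1L) else NULL
  total <- 0; nmask <- 0L
  for (t in seq_len(TT - 1L)) {
    tok <- targets[, t]
    gold <- targets[, t + 1L]
    mask <- gold != 0L
    hW2 <- h %*% params$W2a
    S <- tanh(encW1 + hW2[grp, , drop = FALSE])
    sc <- matrix(S %*% params$va, nrow = B, byrow = TRUE)
    alpha <- .softmax_rows(sc)
    avec <- as.vector(t(alpha))
    ctx <- rowsum(enc * avec, grp)
    x <- cbind(params$Emb[tok + 1L, , drop = FALSE], ctx)
    z <- .sigmoid(x %*% params$Wz + h %*% params$Uz +
                  matrix(params$bz, B, U, byrow = TRUE))
    r <- .sigmoid(x %*% params$Wr + h %*% params$Ur +
                  matrix(params$br, B, U, byrow = TRUE))
    hh <- tanh(x %*% params$Wh + (r * h) %*% params$Uh +
               matrix(params$bh, B, U, byrow = TRUE))
    hn <- (1 - z) * h + z * hh
    o1 <- pmax(sweep(hn %*% params$Wf1, 2L, params$bf1, "+"), 0)
    logits <- sweep(o1 %*% params$Wf2, 2L, params$bf2, "+")
    if (any(mask)) {
      lg <- logits[mask, , drop = FALSE]
      mx <- apply(lg, 1L, max)
      lse <- mx + log(rowSums(exp(lg - mx)))
      total <- total + sum(lse - lg[cbind(seq_len(nrow(lg)), gold[mask] + 1L)])
      nmask <- nmask + sum(mask)
    }
    if (keep_cache) {
      cache[[t]] <- list(tok = tok, gold = gold, mask = mask, S = S,
                         avec = avec, ctx = ctx, x = x, z = z, r = r,
                         hh = hh, h_prev = h, hn = hn, o1 = o1,
                         logits = logits)
    }
    h <- hn
  }
  list(loss = if (nmask > 0L) total / nmask else 0, nmask = nmask,
       enc = enc, cache = cache)
}

.backward_batch <- function(params, feats, targets, L, fwd) {
  B <- nrow(targets); TT <- ncol(targets)
  grp <- rep(seq_len(B), each = L)
  enc <- fwd$enc
  nmask <- max(fwd$nmask, 1L)
  g <- lapply(params, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
              else numeric(length(p)))
  denc <- matrix(0, nrow(enc), ncol(enc))
  dh_next <- matrix(0, B, ncol(params$Uz))
  for (t in rev(seq_len(TT - 1L))) {
    cc <- fwd$cache[[t]]
    probs <- .softmax_rows(cc$logits)
    dlog <- probs
    dlog[cbind(seq_len(B), cc$gold + 1L)] <- dlog[cbind(seq_len(B), cc$gold + 1L)] - 1
    dlog <- dlog * (cc$mask / nmask)
    g$Wf2 <- g$Wf2 + crossprod(cc$o1, dlog)
    g$bf2 <- g$bf2 + colSums(dlog)
    do1 <- dlog %*% t(params$Wf2)
    do1[cc$o1 <= 0] <- 0
    g$Wf1 <- g$Wf1 + crossprod(cc$hn, do1)
    g$bf1 <- g$bf1 + colSums(do1)
    dhn <- do1 %*% t(params$Wf1) + dh_next

    dz <- dhn * (cc$hh - cc$h_prev)
    dhh <- dhn * cc$z
    dh_prev <- dhn * (1 - cc$z)

    dhh_pre <- dhh * (1 - cc$hh^2)
    g$Wh <- g$Wh + crossprod(cc$x, dhh_pre)
    g$Uh <- g$Uh + crossprod(cc$r * cc$h_prev, dhh_pre)
    g$bh <- g$bh + colSums(dhh_pre)
    dx <- dhh_pre %*% t(params$Wh)
    drh <- dhh_pre %*% t(params$Uh)
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r

    dz_pre <- dz * cc$z * (1 - cc$z)
    g$Wz <- g$Wz + crossprod(cc$x, dz_pre)
    g$Uz <- g$Uz + crossprod(cc$h_prev, dz_pre)
    g$bz <- g$bz + colSums(dz_pre)
    dx <- dx + dz_pre %*% t(params$Wz)
    dh_prev <- dh_prev + dz_pre %*% t(params$Uz)

    dr_pre <- dr * cc$r * (1 - cc$r)
    g$Wr <- g$Wr + crossprod(cc$x, dr_pre)
    g$Ur <- g$Ur + crossprod(cc$h_prev, dr_pre)
    g$br <- g$br + colSums(dr_pre)
    dx <- dx + dr_pre %*% t(params$Wr)
    dh_prev <- dh_prev + dr_pre %*% t(params$Ur)

    E <- ncol(params$Wenc)
    demb <- dx[, seq_len(E), drop = FALSE]
    dctx <- dx[, E + seq_len(E), drop = FALSE]
    ids <- cc$tok + 1L
    for (b in seq_len(B)) g$Emb[ids[b], ] <- g$Emb[ids[b], ] + demb[b, ]

    # attention backward
    dctx_exp <- dctx[grp, , drop = FALSE]
    dalpha_vec <- rowSums(enc * dctx_exp)
    denc <- denc + cc$avec * dctx_exp
    dalpha <- matrix(dalpha_vec, nrow = B, byrow = TRUE)
    alpha <- matrix(cc$avec, nrow = B, byrow = TRUE)
    dsc <- alpha * (dalpha - rowSums(dalpha * alpha))
    dsc_vec <- as.vector(t(dsc))
    g$va <- g$va + as.vector(crossprod(cc$S, dsc_vec))
    dS <- dsc_vec * matrix(params$va, nrow(cc$S), length(params$va), byrow = TRUE)
    dpre <- dS * (1 - cc$S^2)
    g$W1a <- g$W1a + crossprod(enc, dpre)
    denc <- denc + dpre %*% t(params$W1a)
    dhW2 <- rowsum(dpre, grp)
    g$W2a <- g$W2a + crossprod(cc$h_prev, dhW2)
    dh_prev <- dh_prev + dhW2 %*% t(params$W2a)

    dh_next <- dh_prev
  }
  denc[enc <= 0] <- 0
  g$Wenc <- g$Wenc + crossprod(feats, denc)
  g$benc <- g$benc + colSums(denc)
  g
}

.adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# ---- training and decoding ------------------------------------------------

#' Train the network by teacher forcing
#'
#' One Adam gradient step per batch; the decoder input at step t is the gold
#' token t-1; the initial decoder state is zero. Fully seeded: parameter
#' initialization comes from `net$config$seed`, shuffling is epoch-salted
#' from `shuffle_seed`. A non-finite loss raises `ocsr_divergence` with the
#' epoch and batch index.
#'
#' @param net an `ocsr_network` from [init_network()]
#' @param samples list of samples, each `list(features = L x D matrix,
#'   target = padded 0-based index vector)`
#' @param epochs,batch_size optional overrides of the config values
#' @param shuffle_seed seed for the per-epoch shuffles (default: config seed)
#' @return the network with trained parameters and `loss_trace`: the exact
#'   full-training-set loss evaluated after each epoch's updates (so the
#'   trace measures the model state, not a running average over shifting
#'   batch compositions)
#' @export
train_network <- function(net, samples, epochs = net$config$epochs,
                          batch_size = net$config$batch_size,
                          shuffle_seed = net$config$seed) {
  stopifnot(length(samples) >= 1L)
  L <- nrow(samples[[1]]$features)
  feats_all <- do.call(rbind, lapply(samples, `[[`, "features"))
  targ_all <- do.call(rbind, lapply(samples, function(s) as.integer(s$target)))
  n <- length(samples)
  params <- net$params
  adam <- .adam_state(params)
  trace <- numeric(epochs)
  lr0 <- net$config$learning_rate
  decay <- if (is.null(net$config$lr_decay)) 1.0 else net$config$lr_decay
  for (ep in seq_len(epochs)) {
    lr_ep <- lr0 * decay^(ep - 1L)
    ord <- .with_seed(shuffle_seed + ep, sample.int(n))
    starts <- seq(1L, n, by = batch_size)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, n)]
      rows <- as.vector(t(outer(idx, seq_len(L), function(i, l) (i - 1L) * L + l)))
      feats <- feats_all[rows, , drop = FALSE]
      targets <- targ_all[idx, , drop = FALSE]
      fwd <- .forward_batch(params, feats, targets, L)
      if (!is.finite(fwd$loss)) stop(ocsr_condition("ocsr_divergence",
        sprintf("non-finite loss at epoch %d, batch %d", ep, bi),
        epoch = ep, batch = bi))
      if (lr_ep > 0) {
        grads <- .backward_batch(params, feats, targets, L, fwd)
        upd <- .adam_step(params, grads, adam, lr_ep)
        params <- upd$params
        adam <- upd$state
      }
    }
    # end-of-epoch exact training loss (token-mass weighted across batches)
    tot <- 0; cnt <- 0L
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, n)]
      rows <- as.vector(t(outer(idx, seq_len(L), function(i, l) (i - 1L) * L + l)))
      fwd <- .forward_batch(params, feats_all[rows, , drop = FALSE],
                            targ_all[idx, , drop = FALSE], L,
                            keep_cache = FALSE)
      tot <- tot + fwd$loss * fwd$nmask
      cnt <- cnt + fwd$nmask
    }
    trace[ep] <- tot / max(cnt, 1L)
  }
  net$params <- params
  net$loss_trace <- c(net$loss_trace, trace)
  net
}

#' Greedy decoding of an image (or feature grid) into a token sequence
#'
#' Starts at `<start>`, takes the argmax token at each step (ties: lowest
#' index), stops at `<end>` or `max_len`.
#'
#' @param net a trained `ocsr_network`
#' @param features L x D featurizer output (or an `ocsr_image`, which is
#'   featurized with `backbone`)
#' @param max_len decode cap, default `vocab$max_length + 2`
#' @param backbone featurizer backbone when `features` is an image
#' @return list(tokens = character vector with sentinels, text = detokenized
#'   string, truncated = logical)
#' @export
greedy_decode <- function(net, features, max_len = net$vocab$max_length + 2L,
                          backbone = NULL) {
  if (inherits(features, "ocsr_image")) {
    if (is.null(backbone)) backbone <- default_backbone()
    features <- featurize(features, backbone)
  }
  p <- net$params
  vocab <- net$vocab
  enc <- encode_features(features, p)
  start_idx <- unname(vocab$token_to_index[[.OCSR_START]])
  end_idx <- unname(vocab$token_to_index[[.OCSR_END]])
  h <- rep(0, net$config$units)
  prev <- start_idx
  out_idx <- integer(0)
  truncated <- TRUE
  for (step in seq_len(max_len)) {
    att <- attend(enc, h, p)
    ds <- decode_step(prev, att$context, h, net)
    h <- ds$state
    nxt <- which.max(ds$logits) - 1L
    out_idx <- c(out_idx, nxt)
    prev <- nxt
    if (nxt == end_idx) { truncated <- FALSE; break }
  }
  toks <- c(.OCSR_START, decode_indices(out_idx, vocab, strip_pad = FALSE))
  list(tokens = toks, text = detokenize(toks), truncated = truncated)
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the config, the vocabulary and its hash;
#' [load_checkpoint()] restores them and decoding refuses a network whose
#' vocabulary hash does not match its vocabulary.
#'
#' @param net an `ocsr_network`
#' @param path checkpoint file path
#' @return invisibly `path` / the restored `ocsr_network`
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "ocsr_network")) stop(ocsr_condition(
    "ocsr_contract_violation", "not an ocsr_network checkpoint"))
  if (!identical(net$vocab_hash, .vocab_hash(net$vocab))) {
    stop(ocsr_condition("ocsr_contract_violation",
      "checkpoint vocabulary hash mismatch"))
  }
  net
}
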