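# Conditional recurrent model core: a bidirectional LSTM feature
# extractor maps a molecule to an initial decoder state h0; a one-layer
# LSTM decoder with a dense softmax head is trained (teacher-forced) to
# reconstruct the token sequence conditioned on h0. All linear algebra
# is plain base-R matrix arithmetic; gradients are exact backprop
# through time (verified against finite differences in the test suite).

#' Training configuration
#'
#' @param encoder_dim hidden size of each direction of the bidirectional
#'   LSTM feature extractor (default 512).
#' @param decoder_dim hidden size of the LSTM generator (default 256).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param noise_sigma standard deviation of the zero-mean Gaussian
#'   state-vector regularization noise (0 disables it).
#' @param seed integer seed controlling initialization, shuffling and
#'   regularization noise; a fixed seed gives an identical loss
#'   trajectory.
#' @param tol,patience convergence rule: stop when the relative loss
#'   improvement stays below `tol` for `patience` consecutive epochs.
#' @param max_len molecules longer than this many tokens are excluded
#'   from training (with a message), not truncated.
#' @return object of class `train_config`.
#' @export
train_config <- function(encoder_dim = 512L, decoder_dim = 256L,
                         learning_rate = 1e-4, batch_size = 64L,
                         max_epochs = 200L, noise_sigma = 0,
                         seed = 1L, tol = 1e-4, patience = 10L,
                         max_len = 120L) {
  stopifnot(encoder_dim > 0, decoder_dim > 0, learning_rate >= 0,
            batch_size > 0, max_epochs >= 0, noise_sigma >= 0,
            tol >= 0, patience >= 1, max_len > 1)
  structure(list(encoder_dim = as.integer(encoder_dim),
                 decoder_dim = as.integer(decoder_dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 tol = tol, patience = as.integer(patience),
                 max_len = as.integer(max_len)),
            class = "train_config")
}

#' Gaussian state-noise specification
#'
#' @param sigma standard deviation (>= 0).
#' @param mu mean (0 for training regularization; single-point sampling
#'   may use a nonzero mean).
#' @param seed optional seed; when given, draws are reproducible and the
#'   caller's RNG stream is left untouched.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sigma, mu = 0, seed = NULL) {
  stopifnot(sigma >= 0)
  structure(list(sigma = sigma, mu = mu, seed = seed),
            class = "noise_spec")
}

#' Add Gaussian noise to a state vector
#'
#' The regularization enhancement: `h0_noise = h0 + xi` with
#' `xi_m ~ N(mu, sigma^2)` i.i.d. per coordinate. With `sigma = 0` the
#' input is returned unchanged.
#'
#' @param h0 numeric state vector.
#' @param noise a [noise_spec()].
#' @return numeric vector of the same length.
#' @export
regularize_state <- function(h0, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma == 0 && noise$mu == 0) return(h0)
  with_seed(noise$seed,
            h0 + stats::rnorm(length(h0), mean = noise$mu, sd = noise$sigma))
}

# --- parameters -----------------------------------------------------------

init_params <- function(J, enc_dim, dec_dim, seed = 1L, scale = 0.08) {
  with_seed(seed, {
    u <- function(nr, nc) matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
    list(ef_Wx = u(J, 4 * enc_dim), ef_Wh = u(enc_dim, 4 * enc_dim),
         ef_b = numeric(4 * enc_dim),
         eb_Wx = u(J, 4 * enc_dim), eb_Wh = u(enc_dim, 4 * enc_dim),
         eb_b = numeric(4 * enc_dim),
         pj_W = u(2 * enc_dim, dec_dim), pj_b = numeric(dec_dim),
         de_Wx = u(J, 4 * dec_dim), de_Wh = u(dec_dim, 4 * dec_dim),
         de_b = numeric(4 * dec_dim),
         out_W = u(dec_dim, J), out_b = numeric(J))
  })
}

zero_like <- function(params) lapply(params, function(p) p * 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# One masked LSTM step for a [B x H] state; returns new state plus the
# cache needed for the backward pass.
lstm_step <- function(x, h_prev, c_prev, Wx, Wh, b, m) {
  H <- ncol(h_prev)
  z <- x %*% Wx + h_prev %*% Wh
  z <- sweep(z, 2, b, "+")
  i <- sigmoid(z[, 1:H, drop = FALSE])
  f <- sigmoid(z[, H + 1:H, drop = FALSE])
  g <- tanh(z[, 2 * H + 1:H, drop = FALSE])
  o <- sigmoid(z[, 3 * H + 1:H, drop = FALSE])
  c_raw <- f * c_prev + i * g
  tc <- tanh(c_raw)
  h_raw <- o * tc
  h <- h_raw * m + h_prev * (1 - m)
  c <- c_raw * m + c_prev * (1 - m)
  list(h = h, c = c,
       cache = list(x = x, h_prev = h_prev, c_prev = c_prev,
                    i = i, f = f, g = g, o = o, tc = tc, m = m))
}

# Backward through one masked LSTM step. dh, dc are gradients w.r.t. the
# post-mask states. Returns gradients for the previous states, the
# input, and parameter-gradient increments.
lstm_step_back <- function(dh, dc, cache, Wx, Wh) {
  m <- cache$m
  dh_raw <- dh * m
  dh_prev0 <- dh * (1 - m)
  dc_raw <- dc * m + dh_raw * cache$o * (1 - cache$tc^2)
  dc_prev0 <- dc * (1 - m)
  d_o <- dh_raw * cache$tc
  d_i <- dc_raw * cache$g
  d_f <- dc_raw * cache$c_prev
  d_g <- dc_raw * cache$i
  dz <- cbind(d_i * cache$i * (1 - cache$i),
              d_f * cache$f * (1 - cache$f),
              d_g * (1 - cache$g^2),
              d_o * cache$o * (1 - cache$o))
  list(dh_prev = dz %*% t(Wh) + dh_prev0,
       dc_prev = dc_raw * cache$f + dc_prev0,
       dx = dz %*% t(Wx),
       dWx = crossprod(cache$x, dz),
       dWh = crossprod(cache$h_prev, dz),
       db = colSums(dz))
}

# Run a full (masked) LSTM over a list of [B x J] inputs.
lstm_run <- function(X, mask, Wx, Wh, b, h0 = NULL, c0 = NULL) {
  B <- nrow(X[[1]]); H <- nrow(Wh)
  h <- h0 %||% matrix(0, B, H)
  c <- c0 %||% matrix(0, B, H)
  states <- vector("list", length(X))
  caches <- vector("list", length(X))
  for (t in seq_along(X)) {
    st <- lstm_step(X[[t]], h, c, Wx, Wh, b, mask[, t])
    h <- st$h; c <- st$c
    states[[t]] <- h
    caches[[t]] <- st$cache
  }
  list(states = states, caches = caches, hT = h, cT = c)
}

# Backward over a full LSTM run. dstates: list of per-step gradients
# w.r.t. h_t (NULL entries allowed); dhT/dcT: extra gradient on the
# final state. Returns dWx, dWh, db, and dh0 (gradient on the initial
# hidden state).
lstm_run_back <- function(run, dstates, Wx, Wh, dhT = NULL, dcT = NULL) {
  Tn <- length(run$caches)
  B <- nrow(run$hT); H <- ncol(run$hT)
  dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4 * H)
  dh <- dhT %||% matrix(0, B, H)
  dc <- dcT %||% matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    if (!is.null(dstates[[t]])) dh <- dh + dstates[[t]]
    bk <- lstm_step_back(dh, dc, run$caches[[t]], Wx, Wh)
    dWx <- dWx + bk$dWx; dWh <- dWh + bk$dWh; db <- db + bk$db
    dh <- bk$dh_prev; dc <- bk$dc_prev
  }
  list(dWx = dWx, dWh = dWh, db = db, dh0 = dh)
}

row_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Sequence cross-entropy loss
#'
#' The training objective: softmax cross-entropy summed over sequence
#' positions and averaged over the batch. Padding positions are
#' excluded via `mask`.
#'
#' @param logits a `T x J` logit matrix or a list of them (one per
#'   batch element).
#' @param labels matching one-hot label matrix/matrices (rows one-hot).
#' @param mask optional 0/1 vector (or list of vectors) marking content
#'   positions; defaults to all ones.
#' @return non-negative scalar loss.
#' @export
crnn_loss <- function(logits, labels, mask = NULL) {
  if (is.matrix(logits)) { logits <- list(logits); labels <- list(labels)
    if (!is.null(mask) && !is.list(mask)) mask <- list(mask) }
  if (is.list(labels) && length(labels) != length(logits))
    stop2("logits/labels batch size mismatch")
  tot <- 0
  for (b in seq_along(logits)) {
    lo <- logits[[b]]; la <- labels[[b]]
    if (inherits(la, "onehot_seq")) la <- la$matrix
    if (!all(dim(lo) == dim(la))) stop2("logits/labels shape mismatch")
    p <- row_softmax(lo)
    ce <- -log(rowSums(p * la))
    w <- if (is.null(mask)) rep(1, nrow(lo)) else mask[[b]]
    tot <- tot + sum(ce * w)
  }
  tot / length(logits)
}

# --- batched teacher-forced pass ------------------------------------------

# Assemble padded one-hot tensors for a set of token-id sequences.
# Returns lists over time of [B x J] matrices plus the [B x T] mask.
pack_sequences <- function(ids_list, J, pad_id) {
  B <- length(ids_list)
  Tn <- max(lengths(ids_list))
  X <- vector("list", Tn)
  mask <- matrix(0, B, Tn)
  for (t in seq_len(Tn)) {
    m <- matrix(0, B, J)
    for (b in seq_len(B)) {
      if (t <= length(ids_list[[b]])) {
        m[b, ids_list[[b]][t]] <- 1
        mask[b, t] <- 1
      } else m[b, pad_id] <- 1
    }
    X[[t]] <- m
  }
  list(X = X, mask = mask, Tn = Tn, B = B)
}

# Encoder/decoder tensors for a corpus of SMILES under a vocabulary.
prepare_batch <- function(smiles, vocab) {
  sos <- vocab_id(vocab, "<SOS>"); eos <- vocab_id(vocab, "<EOS>")
  pad <- vocab_id(vocab, "<PAD>")
  tok_ids <- lapply(smiles, function(s) {
    toks <- tokenize_smiles(s)
    bad <- setdiff(toks, vocab$tokens)
    if (length(bad)) stop2("token(s) not in vocabulary: ",
                           paste(unique(bad), collapse = " "))
    unname(vocab$index[toks])
  })
  enc <- pack_sequences(tok_ids, vocab$J, pad)
  enc_rev <- pack_sequences(lapply(tok_ids, rev), vocab$J, pad)
  dec_in <- pack_sequences(lapply(tok_ids, function(i) c(sos, i)),
                           vocab$J, pad)
  dec_lab <- pack_sequences(lapply(tok_ids, function(i) c(i, eos)),
                            vocab$J, pad)
  list(enc = enc, enc_rev = enc_rev, dec_in = dec_in, dec_lab = dec_lab,
       smiles = smiles)
}

# Full conditional forward pass over a packed batch; optionally applies
# Gaussian regularization noise to h0 (drawn from the ambient RNG
# stream). Returns the loss and every cache needed for backprop.
cond_forward <- function(params, batch, noise_sigma = 0) {
  He <- nrow(params$ef_Wh); Hd <- nrow(params$de_Wh)
  B <- batch$enc$B
  ef <- lstm_run(batch$enc$X, batch$enc$mask,
                 params$ef_Wx, params$ef_Wh, params$ef_b)
  eb <- lstm_run(batch$enc_rev$X, batch$enc_rev$mask,
                 params$eb_Wx, params$eb_Wh, params$eb_b)
  hcat <- cbind(ef$hT, eb$hT)
  h0 <- sweep(hcat %*% params$pj_W, 2, params$pj_b, "+")
  if (noise_sigma > 0)
    h0 <- h0 + matrix(stats::rnorm(B * Hd, 0, noise_sigma), B, Hd)
  de <- lstm_run(batch$dec_in$X, batch$dec_in$mask,
                 params$de_Wx, params$de_Wh, params$de_b, h0 = h0)
  Tn <- batch$dec_in$Tn
  loss <- 0
  probs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    logit <- sweep(de$states[[t]] %*% params$out_W, 2, params$out_b, "+")
    p <- row_softmax(logit)
    probs[[t]] <- p
    y <- batch$dec_lab$X[[t]]
    ce <- -log(pmax(rowSums(p * y), 1e-300))
    loss <- loss + sum(ce * batch$dec_lab$mask[, t])
  }
  loss <- loss / B
  list(loss = loss, probs = probs, ef = ef, eb = eb, de = de,
       hcat = hcat, h0 = h0, B = B)
}

cond_backward <- function(params, batch, fwd) {
  B <- fwd$B; Tn <- batch$dec_in$Tn
  Hd <- nrow(params$de_Wh); He <- nrow(params$ef_Wh)
  g <- zero_like(params)
  dstates <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dlogit <- (fwd$probs[[t]] - batch$dec_lab$X[[t]]) *
      batch$dec_lab$mask[, t] / B
    g$out_W <- g$out_W + crossprod(fwd$de$states[[t]], dlogit)
    g$out_b <- g$out_b + colSums(dlogit)
    dstates[[t]] <- dlogit %*% t(params$out_W)
  }
  de_bk <- lstm_run_back(fwd$de, dstates, params$de_Wx, params$de_Wh)
  g$de_Wx <- de_bk$dWx; g$de_Wh <- de_bk$dWh; g$de_b <- de_bk$db
  dh0 <- de_bk$dh0   # additive noise passes gradient through unchanged
  g$pj_W <- crossprod(fwd$hcat, dh0)
  g$pj_b <- colSums(dh0)
  dhcat <- dh0 %*% t(params$pj_W)
  ef_bk <- lstm_run_back(fwd$ef, vector("list", length(fwd$ef$caches)),
                         params$ef_Wx, params$ef_Wh,
                         dhT = dhcat[, 1:He, drop = FALSE])
  eb_bk <- lstm_run_back(fwd$eb, vector("list", length(fwd$eb$caches)),
                         params$eb_Wx, params$eb_Wh,
                         dhT = dhcat[, He + 1:He, drop = FALSE])
  g$ef_Wx <- ef_bk$dWx; g$ef_Wh <- ef_bk$dWh; g$ef_b <- ef_bk$db
  g$eb_Wx <- eb_bk$dWx; g$eb_Wh <- eb_bk$dWh; g$eb_b <- eb_bk$db
  g
}

# --- user-facing forward operations ---------------------------------------

#' Encode a molecule to its conditioning state vector
#'
#' Runs the bidirectional LSTM feature extractor over the molecule's
#' one-hot sequence and projects the concatenated final states to the
#' decoder's initial hidden state h0. Deterministic given the
#' checkpoint.
#'
#' @param x a SMILES string or a `onehot_seq`.
#' @param ckpt a `crnn_checkpoint`.
#' @return numeric vector of length `decoder_dim`.
#' @export
encode_state <- function(x, ckpt) {
  stopifnot(inherits(ckpt, "crnn_checkpoint"))
  smiles <- if (inherits(x, "onehot_seq"))
    decode_tokens(x$ids, ckpt$vocab) else x
  batch <- prepare_batch(list(smiles)[[1]], ckpt$vocab)
  p <- ckpt$params
  ef <- lstm_run(batch$enc$X, batch$enc$mask, p$ef_Wx, p$ef_Wh, p$ef_b)
  eb <- lstm_run(batch$enc_rev$X, batch$enc_rev$mask,
                 p$eb_Wx, p$eb_Wh, p$eb_b)
  hcat <- cbind(ef$hT, eb$hT)
  as.numeric(sweep(hcat %*% p$pj_W, 2, p$pj_b, "+"))
}

#' Teacher-forced decoder pass
#'
#' Feeds the rows of `x` to the decoder LSTM starting from state `h0`
#' and returns the per-step hidden states, logits and softmax
#' probabilities. Step `i` depends only on steps before it, so the
#' outputs for a prefix equal the leading rows of the outputs for the
#' full sequence.
#'
#' @param h0 numeric conditioning vector (length `decoder_dim`).
#' @param x a `onehot_seq` (rows are the decoder inputs `x_1..x_n`).
#' @param ckpt a `crnn_checkpoint`.
#' @return list with `states` (`n x decoder_dim`), `logits` and `probs`
#'   (`n x J`; each probability row sums to 1).
#' @export
crnn_forward <- function(h0, x, ckpt) {
  stopifnot(inherits(ckpt, "crnn_checkpoint"), inherits(x, "onehot_seq"))
  p <- ckpt$params
  Hd <- nrow(p$de_Wh)
  if (length(h0) != Hd)
    stop2("h0 has length ", length(h0), ", expected ", Hd)
  if (ncol(x$matrix) != nrow(p$de_Wx))
    stop2("sequence vocabulary size does not match checkpoint")
  Tn <- nrow(x$matrix)
  X <- lapply(seq_len(Tn), function(t) x$matrix[t, , drop = FALSE])
  run <- lstm_run(X, matrix(1, 1, Tn), p$de_Wx, p$de_Wh, p$de_b,
                  h0 = matrix(h0, 1))
  states <- do.call(rbind, run$states)
  logits <- sweep(states %*% p$out_W, 2, p$out_b, "+")
  list(states = states, logits = logits, probs = row_softmax(logits))
}
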