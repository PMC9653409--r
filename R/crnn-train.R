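# Training: Adam on the teacher-forced reconstruction objective, with
# optional Gaussian state regularization and transfer learning
# (fine-tuning a converged checkpoint on a target corpus).

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

corpus_smiles <- function(corpus) {
  s <- if (is.data.frame(corpus)) {
    if (!is.null(corpus$status)) corpus$smiles[corpus$status == "ok"]
    else corpus$smiles
  } else corpus
  s <- s[!is.na(s) & nzchar(s)]
  if (!length(s)) stop2("corpus contains no usable molecules")
  s
}

run_training <- function(params, smiles, vocab, config, phase,
                         history = NULL) {
  keep <- vapply(smiles, function(s)
    length(tokenize_smiles(s)) + 1L <= config$max_len, logical(1))
  if (any(!keep))
    message(sum(!keep), " molecule(s) longer than max_len = ",
            config$max_len, " excluded from ", phase)
  smiles <- smiles[keep]
  if (!length(smiles)) stop2("no molecules left to train on")
  set.seed(derive_seed(config$seed, paste0("train-", phase)))
  state <- adam_init(params)
  hist <- history %||%
    data.frame(epoch = integer(0), phase = character(0),
               loss = numeric(0))
  prev <- Inf; stall <- 0L
  n <- length(smiles)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- if (n > config$batch_size) sample(n) else seq_len(n)
    split_idx <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_n <- 0
    for (idx in split_idx) {
      batch <- prepare_batch(smiles[idx], vocab)
      fwd <- cond_forward(params, batch, config$noise_sigma)
      if (!is.finite(fwd$loss))
        stop2("non-finite loss at epoch ", epoch,
              " (", phase, "); reduce the learning rate")
      grads <- cond_backward(params, batch, fwd)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + fwd$loss * length(idx)
      ep_n <- ep_n + length(idx)
    }
    loss <- ep_loss / ep_n
    hist <- rbind(hist, data.frame(epoch = epoch, phase = phase,
                                   loss = loss))
    rel <- if (is.finite(prev) && prev > 0) (prev - loss) / prev else Inf
    stall <- if (rel < config$tol) stall + 1L else 0L
    prev <- loss
    if (stall >= config$patience) break
  }
  list(params = params, history = hist)
}

#' Train the conditional recurrent generator
#'
#' Teacher-forced reconstruction training: each molecule is encoded to
#' its state vector h0 (optionally perturbed with zero-mean Gaussian
#' noise when `config$noise_sigma > 0` -- the regularization
#' enhancement) and the decoder learns to reproduce the token sequence.
#' Parameters are updated with Adam until the convergence rule or
#' `max_epochs` is reached; the loss trajectory is deterministic for a
#' fixed `config$seed`.
#'
#' @param corpus standardized molecule data frame or character vector
#'   of canonical SMILES.
#' @param config a [train_config()].
#' @param init optional `crnn_checkpoint` to continue from (its
#'   vocabulary is reused).
#' @return object of class `crnn_checkpoint`: list with `params`,
#'   `vocab`, `config` and `history` (epoch/phase/loss).
#' @export
train_crnn <- function(corpus, config = train_config(), init = NULL) {
  smiles <- corpus_smiles(corpus)
  if (is.null(init)) {
    vocab <- build_vocabulary(smiles)
    params <- init_params(vocab$J, config$encoder_dim,
                          config$decoder_dim,
                          seed = derive_seed(config$seed, "init"))
    history <- NULL
  } else {
    stopifnot(inherits(init, "crnn_checkpoint"))
    vocab <- init$vocab
    params <- init$params
    history <- init$history
  }
  res <- run_training(params, smiles, vocab, config, "train", history)
  new_checkpoint(res$params, vocab, config, res$history)
}

#' Fine-tune a pretrained checkpoint on a target corpus
#'
#' Transfer learning: all parameters of the converged pretrained model
#' are further updated on the (typically much smaller) target corpus;
#' no layers are frozen. Every token of the target corpus must already
#' be in the pretraining vocabulary.
#'
#' @param ckpt pretrained `crnn_checkpoint`.
#' @param target_corpus standardized molecule data frame or character
#'   vector.
#' @param config optional [train_config()]; defaults to the
#'   checkpoint's config. `max_epochs = 0` returns the checkpoint's
#'   parameters unchanged (with unchanged history).
#' @return a `crnn_checkpoint` whose history is extended with
#'   `phase == "finetune"` rows.
#' @export
finetune_crnn <- function(ckpt, target_corpus, config = NULL) {
  stopifnot(inherits(ckpt, "crnn_checkpoint"))
  config <- config %||% ckpt$config
  smiles <- corpus_smiles(target_corpus)
  novel <- setdiff(unique(unlist(lapply(smiles, tokenize_smiles))),
                   ckpt$vocab$tokens)
  if (length(novel))
    stop2("target corpus contains tokens absent from the pretraining ",
          "vocabulary: ", paste(novel, collapse = " "))
  if (config$max_epochs == 0L)
    return(new_checkpoint(ckpt$params, ckpt$vocab, config, ckpt$history))
  res <- run_training(ckpt$params, smiles, ckpt$vocab, config,
                      "finetune", ckpt$history)
  new_checkpoint(res$params, ckpt$vocab, config, res$history)
}

new_checkpoint <- function(params, vocab, config, history) {
  structure(list(params = params, vocab = vocab, config = config,
                 history = history),
            class = "crnn_checkpoint")
}

#' @export
print.crnn_checkpoint <- function(x, ...) {
  cat("Conditional RNN checkpoint\n")
  cat("  vocabulary:", x$vocab$J, "tokens\n")
  cat("  encoder 2 x", x$config$encoder_dim,
      "(bidirectional LSTM), decoder", x$config$decoder_dim, "(LSTM)\n")
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat("  training:", nrow(x$history), "epochs recorded; last",
        last$phase, "loss", format(last$loss, digits = 5), "\n")
  }
  invisible(x)
}

#' Save / load a checkpoint
#'
#' Checkpoints are stored as a single JSON document (format version 1)
#' holding the parameter arrays at 17 significant digits (exact for
#' IEEE doubles), the ordered vocabulary token list, the configuration
#' and the training history; a reloaded checkpoint reproduces forward
#' passes bit-identically.
#'
#' @param ckpt a `crnn_checkpoint`.
#' @param path file path (conventionally `.json`).
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "crnn_checkpoint"))
  doc <- list(format = "molcrnn-checkpoint", version = 1L,
              vocab = ckpt$vocab$tokens,
              config = unclass(ckpt$config),
              history = ckpt$history,
              params = ckpt$params)
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$format, "molcrnn-checkpoint"))
    stop2(path, " is not a molcrnn checkpoint")
  tokens <- doc$vocab
  vocab <- structure(list(tokens = tokens,
                          index = stats::setNames(seq_along(tokens), tokens),
                          J = length(tokens)),
                     class = "smiles_vocab")
  config <- structure(doc$config, class = "train_config")
  params <- lapply(doc$params, function(p)
    if (is.matrix(p)) p else as.numeric(p))
  history <- as.data.frame(doc$history)
  new_checkpoint(params, vocab, config, history)
}
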