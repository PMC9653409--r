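# Model core: analytic identities, exact gradients, training behavior,
# transfer learning and checkpoint round trips.

test_that("zero parameters give a zero state vector and uniform outputs", {
  tm <- tiny_model()
  zero <- lapply(tm$params, function(p) p * 0)
  ckpt <- molcrnn:::new_checkpoint(zero, tm$vocab,
                                   train_config(encoder_dim = 3,
                                                decoder_dim = 4),
                                   data.frame())
  h0 <- encode_state("CCO", ckpt)
  expect_equal(h0, rep(0, 4))
  fw <- crnn_forward(h0, encode_onehot("CCO", tm$vocab), ckpt)
  expect_equal(fw$probs,
               matrix(1 / tm$vocab$J, nrow(fw$probs), tm$vocab$J),
               tolerance = 1e-12)
})

test_that("loss identities: uniform = ln(J) per token, perfect = 0, J=2 = ln 2", {
  J <- 7; m <- 5
  uniform <- matrix(0, m, J)
  labels <- diag(J)[sample.int(J, m, replace = TRUE), ]
  expect_equal(crnn_loss(uniform, labels), m * log(J), tolerance = 1e-12)
  # probabilities exactly matching the one-hot labels
  perfect <- log(labels * (1 - 1e-12) + 1e-12) * 50
  expect_lt(crnn_loss(perfect, labels), 1e-6)
  # single position, two tokens, probs (0.5, 0.5)
  expect_equal(crnn_loss(matrix(c(0, 0), 1, 2), matrix(c(1, 0), 1, 2)),
               log(2), tolerance = 1e-12)
})

test_that("softmax rows of forward outputs sum to one under random parameters", {
  tm <- tiny_model()
  ckpt <- molcrnn:::new_checkpoint(tm$params, tm$vocab,
                                   train_config(encoder_dim = 3,
                                                decoder_dim = 4),
                                   data.frame())
  h0 <- encode_state("c1ccccc1", ckpt)
  fw <- crnn_forward(h0, encode_onehot("c1ccccc1", tm$vocab), ckpt)
  expect_equal(rowSums(fw$probs), rep(1, nrow(fw$probs)),
               tolerance = 1e-9)
  expect_true(all(fw$probs > 0 & fw$probs < 1))
})

test_that("forward pass is causal: prefix outputs equal leading rows", {
  tm <- tiny_model()
  ckpt <- molcrnn:::new_checkpoint(tm$params, tm$vocab,
                                   train_config(encoder_dim = 3,
                                                decoder_dim = 4),
                                   data.frame())
  h0 <- encode_state("CCNC", ckpt)
  full <- crnn_forward(h0, encode_onehot("CCNC", tm$vocab), ckpt)
  pre <- crnn_forward(h0, encode_onehot("CC", tm$vocab), ckpt)
  k <- 2
  expect_equal(pre$logits[seq_len(k), ], full$logits[seq_len(k), ],
               tolerance = 1e-12)
})

test_that("encoding is deterministic and separates different molecules", {
  ckpt <- untrained_ckpt()
  s <- fixture_corpus()$smiles
  h1 <- encode_state(s[1], ckpt)
  expect_identical(h1, encode_state(s[1], ckpt))
  states <- vapply(s, encode_state, numeric(length(h1)), ckpt = ckpt)
  dists <- as.matrix(stats::dist(t(states)))
  diag(dists) <- Inf
  expect_gt(min(dists), 0)   # no collisions on the fixture corpus
})

test_that("state regularization is exact for sigma 0 and calibrated for sigma > 0", {
  h0 <- c(0.5, -1, 2, 0)
  expect_identical(regularize_state(h0, noise_spec(0)), h0)
  sigma <- 0.3; n <- 10000
  draws <- with_seed(42, vapply(seq_len(n), function(i)
    regularize_state(h0, noise_spec(sigma)), numeric(4)))
  delta <- draws - h0
  expect_true(all(abs(rowMeans(delta)) < 4 * sigma / sqrt(n)))
  expect_equal(mean(apply(delta, 1, stats::var)), sigma^2,
               tolerance = 0.1)
  # seeded draws are reproducible
  expect_identical(regularize_state(h0, noise_spec(sigma, seed = 9)),
                   regularize_state(h0, noise_spec(sigma, seed = 9)))
})

test_that("backpropagated gradients match finite differences", {
  tm <- tiny_model()
  fwd <- molcrnn:::cond_forward(tm$params, tm$batch, 0)
  grads <- molcrnn:::cond_backward(tm$params, tm$batch, fwd)
  set.seed(4)
  for (nm in names(tm$params)) {
    idx <- sample(length(tm$params[[nm]]), min(4, length(tm$params[[nm]])))
    for (i in idx) {
      eps <- 1e-6
      p2 <- tm$params; p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- molcrnn:::cond_forward(p2, tm$batch, 0)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l2 <- molcrnn:::cond_forward(p2, tm$batch, 0)$loss
      num <- (l1 - l2) / (2 * eps)
      # absolute tolerance dominated by finite-difference noise
      expect_lt(abs(grads[[nm]][i] - num), 1e-6 + 1e-3 * abs(num))
    }
  }
})

test_that("one optimizer step with small lr decreases the batch loss", {
  tm <- tiny_model()
  fwd <- molcrnn:::cond_forward(tm$params, tm$batch, 0)
  grads <- molcrnn:::cond_backward(tm$params, tm$batch, fwd)
  st <- molcrnn:::adam_init(tm$params)
  upd <- molcrnn:::adam_step(tm$params, grads, st, lr = 1e-3)
  expect_lt(molcrnn:::cond_forward(upd$params, tm$batch, 0)$loss,
            fwd$loss)
})

test_that("zero learning rate leaves parameters and loss unchanged", {
  corpus <- fixture_corpus()
  cfg <- train_config(encoder_dim = 8, decoder_dim = 12,
                      learning_rate = 0, batch_size = 10,
                      max_epochs = 3, seed = 5, tol = 0, patience = 99)
  ck <- train_crnn(corpus, cfg)
  init <- molcrnn:::init_params(ck$vocab$J, 8, 12,
                                seed = molcrnn:::derive_seed(5, "init"))
  expect_identical(ck$params, init)
  expect_equal(length(unique(ck$history$loss)), 1L)
})

test_that("training is deterministic under a fixed seed", {
  corpus <- fixture_corpus()
  cfg <- train_config(encoder_dim = 8, decoder_dim = 12,
                      learning_rate = 0.01, batch_size = 4,
                      max_epochs = 5, seed = 21, noise_sigma = 0.1,
                      tol = 0, patience = 99)
  h1 <- train_crnn(corpus, cfg)$history
  h2 <- train_crnn(corpus, cfg)$history
  expect_identical(h1, h2)
})

test_that("checkpoints survive a save/load round trip bit-identically", {
  ckpt <- memorized_ckpt()
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(ckpt, path)
  back <- load_checkpoint(path)
  s <- fixture_corpus()$smiles[1]
  expect_identical(encode_state(s, back), encode_state(s, ckpt))
  enc <- encode_onehot(s, ckpt$vocab)
  fw1 <- crnn_forward(encode_state(s, ckpt), enc, ckpt)
  fw2 <- crnn_forward(encode_state(s, back), enc, back)
  expect_identical(fw1$logits, fw2$logits)
})

test_that("fine-tuning validates the vocabulary and honors a zero-epoch budget", {
  ckpt <- untrained_ckpt()
  cfg <- ckpt$config; cfg$max_epochs <- 0L
  same <- finetune_crnn(ckpt, fixture_corpus(), cfg)
  expect_identical(same$params, ckpt$params)
  expect_error(finetune_crnn(ckpt, "CCBr", cfg), "Br")
})

test_that("fine-tuning a pretrained model reduces target-corpus loss", {
  pair <- make_pair_corpora(seed = 3, n_source = 20, n_target = 10)
  cfg <- train_config(encoder_dim = 12, decoder_dim = 24,
                      learning_rate = 0.01, batch_size = 20,
                      max_epochs = 60, seed = 1, tol = 0, patience = 99)
  pre <- train_crnn(pair$source, cfg)
  vocab <- pre$vocab
  batch <- molcrnn:::prepare_batch(pair$target$smiles, vocab)
  loss_before <- molcrnn:::cond_forward(pre$params, batch, 0)$loss
  cfg_ft <- cfg; cfg_ft$max_epochs <- 30L
  ft <- finetune_crnn(pre, pair$target, cfg_ft)
  loss_after <- molcrnn:::cond_forward(ft$params, batch, 0)$loss
  expect_lt(loss_after, loss_before)
  expect_true(any(ft$history$phase == "finetune"))
})
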