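# Shared fixtures, built once per test run. The memorization checkpoint
# is the workhorse of the sampler/evaluation tests: a reduced model
# trained to reconstruct a 10-molecule corpus exactly.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

fixture_corpus <- function() memo("corpus", make_corpus(corpus_spec(10, seed = 7)))

fixture_corpus20 <- function() memo("corpus20",
  make_corpus(corpus_spec(20, seed = 12, complexity = "medium")))

memorize_config <- function(seed = 11)
  train_config(encoder_dim = 24, decoder_dim = 48, learning_rate = 0.01,
               batch_size = 10, max_epochs = 800, seed = seed,
               tol = 0, patience = 9999L, max_len = 80)

memorized_ckpt <- function() memo("memorized",
  train_crnn(fixture_corpus(), memorize_config()))

untrained_ckpt <- function() memo("untrained", {
  cfg <- memorize_config()
  cfg$max_epochs <- 0L
  train_crnn(fixture_corpus(), cfg)
})

tiny_model <- function(smiles = c("CCO", "c1ccccc1", "CCNC"),
                       enc = 3, dec = 4, seed = 2) {
  vocab <- build_vocabulary(smiles)
  list(vocab = vocab,
       params = init_params(vocab$J, enc, dec, seed = seed),
       batch = prepare_batch(smiles, vocab))
}
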