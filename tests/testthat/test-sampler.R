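# Interpolation sampling, autoregressive decoding and library
# post-processing.

test_that("linear interpolation is an exact convex combination", {
  h_i <- c(1, 0); h_j <- c(0, 1)
  expect_identical(linear_interp(h_i, h_j, 0), h_i)
  expect_identical(linear_interp(h_i, h_j, 1), h_j)
  expect_equal(linear_interp(h_i, h_j, 0.5), c(0.5, 0.5))
  # coordinates stay inside the segment
  a <- c(-2, 3, 0.5); b <- c(1, -1, 4)
  for (al in seq(0.1, 0.9, by = 0.2)) {
    v <- linear_interp(a, b, al)
    expect_true(all(v >= pmin(a, b) - 1e-12 & v <= pmax(a, b) + 1e-12))
  }
  expect_error(linear_interp(c(1, 2), c(1, 2, 3), 0.5), "length")
})

test_that("slerp hits its endpoints, the orthogonal midpoint, and preserves norms", {
  h_i <- c(1, 0, 0); h_j <- c(0, 1, 0)
  expect_equal(slerp_interp(h_i, h_j, 0), h_i, tolerance = 1e-12)
  expect_equal(slerp_interp(h_i, h_j, 1), h_j, tolerance = 1e-12)
  expect_equal(slerp_interp(h_i, h_j, 0.5), (h_i + h_j) * sqrt(2) / 2,
               tolerance = 1e-12)
  set.seed(8)
  u <- stats::rnorm(16); u <- u / sqrt(sum(u^2))
  v <- stats::rnorm(16); v <- v / sqrt(sum(v^2))
  for (beta in seq(0.1, 0.9, by = 0.1)) {
    out <- slerp_interp(u, v, beta)
    expect_lt(abs(sqrt(sum(out^2)) - 1), 1e-9)
  }
  expect_error(slerp_interp(c(0, 0), c(1, 0), 0.5), "zero")
})

test_that("slerp degrades gracefully to linear interpolation for collinear vectors", {
  u <- c(1, 2, 3) / sqrt(14)
  # rotate u by ~1e-4 rad within a plane
  w <- c(-2, 1, 0) / sqrt(5)
  theta <- 1e-4
  v <- cos(theta) * u + sin(theta) * w
  expect_equal(slerp_interp(u, v, 0.3), linear_interp(u, v, 0.3),
               tolerance = 1e-6)
  # exactly collinear triggers the documented linear fallback
  expect_equal(slerp_interp(u, u * 2, 0.25), linear_interp(u, u * 2, 0.25),
               tolerance = 1e-12)
})

test_that("single-point sampling is the identity at sigma 0 and centered otherwise", {
  h <- c(0.3, -0.7, 1.2)
  expect_identical(single_point_sample(h, noise_spec(0)), h)
  expect_identical(single_point_sample(h, noise_spec(0.2, seed = 4)),
                   single_point_sample(h, noise_spec(0.2, seed = 4)))
  draws <- with_seed(11, vapply(1:10000, function(i)
    single_point_sample(h, noise_spec(0.2, mu = 0.05)), numeric(3)))
  expect_equal(rowMeans(draws), h + 0.05, tolerance = 0.01)
})

test_that("greedy decoding from a memorized state reproduces the molecule", {
  ckpt <- memorized_ckpt()
  s <- fixture_corpus()$smiles
  for (m in s[1:3]) {
    out <- generate_one(ckpt, encode_state(m, ckpt), max_len = 80,
                        temperature = 0)
    expect_identical(standardize_smiles(out)$smiles, m)
  }
})

test_that("stochastic decoding is seed-reproducible and respects max_len", {
  ckpt <- memorized_ckpt()
  h0 <- encode_state(fixture_corpus()$smiles[1], ckpt)
  o1 <- generate_one(ckpt, h0, max_len = 80, temperature = 1, seed = 99)
  o2 <- generate_one(ckpt, h0, max_len = 80, temperature = 1, seed = 99)
  expect_identical(o1, o2)
  short <- generate_one(ckpt, h0, max_len = 1, temperature = 0)
  expect_true(is.na(short) || nchar(short) <= 2)
})

test_that("library generation accounts for every attempt exactly once", {
  ckpt <- memorized_ckpt()
  corpus <- fixture_corpus()
  gset <- build_library(ckpt, corpus,
                        sampling_config(n_samples = 120, seed = 3,
                                        max_len = 60),
                        training_corpora = list(corpus))
  ct <- gset$counters
  expect_identical(ct$attempts,
                   ct$kept + ct$invalid + ct$duplicate_internal +
                   ct$duplicate_vs_training + ct$alert_hits)
  expect_equal(nrow(gset$molecules), ct$kept)
  # survivors are valid, standardized, deduplicated, novel, clean
  if (nrow(gset$molecules)) {
    again <- standardize_smiles(gset$molecules$smiles)
    expect_true(all(again$status == "ok"))
    expect_identical(again$smiles, gset$molecules$smiles)
    expect_false(anyDuplicated(gset$molecules$smiles) > 0)
    expect_false(any(gset$molecules$smiles %in% corpus$smiles))
    expect_true(all(alert_counts(gset$molecules$smiles) == 0))
  }
})

test_that("a trained model emits valid molecules under stochastic sampling", {
  ckpt <- memorized_ckpt()
  g <- generation_rate(ckpt, fixture_corpus(),
                       sampling_config(seed = 5, max_len = 60),
                       attempts = 100)
  expect_gt(g, 0)   # end-to-end smoke: G% > 0
})

test_that("interpolation factors stay strictly inside (0,1) in the config", {
  expect_error(sampling_config(alpha = 0), "alpha")
  expect_error(sampling_config(alpha = 1), "alpha")
  expect_silent(sampling_config(alpha = 0.5))
})
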