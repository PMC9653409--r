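# Screening funnel: inclusive boundaries, novelty rules, conservation
# and idempotence.

fake_desc <- function(mw = 300, logp = 2, qed = 0.5, sa = 3, n = 1) {
  data.frame(id = paste0("x", seq_len(n)), smiles = rep("CCO", n),
             mw = mw, logp = logp, qed = qed, sa = sa,
             bertz_ct = 0, tpsa = 0, logs = 0, rot = 0L, hbd = 0L,
             hba = 0L, desc_status = "ok", stringsAsFactors = FALSE)
}

test_that("drug-likeness bounds are inclusive at every boundary", {
  crit <- filter_criteria()
  at_bounds <- rbind(fake_desc(mw = 200), fake_desc(mw = 700),
                     fake_desc(logp = -2), fake_desc(logp = 6),
                     fake_desc(qed = 0.15), fake_desc(sa = 5))
  res <- druglike_filter(at_bounds, crit)
  expect_equal(nrow(res$survivors), 6L)
  expect_equal(nrow(res$removed), 0L)
  outside <- rbind(fake_desc(mw = 199.999), fake_desc(mw = 700.001),
                   fake_desc(logp = -2.001), fake_desc(logp = 6.001),
                   fake_desc(qed = 0.1499), fake_desc(sa = 5.001))
  res2 <- druglike_filter(outside, crit)
  expect_equal(nrow(res2$survivors), 0L)
  expect_equal(res2$removed$reason,
               c("MW", "MW", "LogP", "LogP", "QED", "SA"))
})

test_that("removal reasons follow the fixed order MW, LogP, QED, SA", {
  multi <- fake_desc(mw = 100, logp = 10, qed = 0.01, sa = 9)
  expect_equal(druglike_filter(multi)$removed$reason, "MW")
  multi2 <- fake_desc(logp = 10, qed = 0.01)
  expect_equal(druglike_filter(multi2)$removed$reason, "LogP")
})

test_that("widened criteria make the drug-likeness stage an identity", {
  wide <- filter_criteria(mw_min = -Inf, mw_max = Inf, logp_min = -Inf,
                          logp_max = Inf, qed_min = 0, sa_max = 10)
  desc <- calc_descriptors(fixture_corpus())
  res <- druglike_filter(desc, wide)
  expect_equal(nrow(res$survivors), nrow(desc))
})

test_that("novelty filter removes shared generic scaffolds and substructures", {
  # toluene's generic scaffold is the plain six-ring, as is pyridine's
  res <- novelty_filter(c("Cc1ccccc1", "CCCCCC", "C1CCNCC1C1CCCCC1"),
                        "c1ccncc1", generic = TRUE)
  expect_false("Cc1ccccc1" %in% res$survivors$smiles)  # same skeleton
  expect_true("CCCCCC" %in% res$survivors$smiles)      # acyclic kept
  # bicyclic candidate contains the reference six-ring as substructure
  expect_false("C1CCNCC1C1CCCCC1" %in% res$survivors$smiles)
  expect_setequal(unique(res$removed$reason), c("scaffold", "substructure"))
})

test_that("an empty reference set passes the library through with a warning", {
  expect_warning(res <- novelty_filter(c("Cc1ccccc1", "CCO"),
                                       character(0)), "empty")
  expect_equal(nrow(res$survivors), 2L)
})

test_that("the funnel conserves molecules, chains stages, and is idempotent", {
  lib <- fixture_corpus20()
  ref <- make_corpus(corpus_spec(6, seed = 31))
  rep1 <- suppressWarnings(run_funnel(lib, ref))
  st <- rep1$stages
  expect_equal(st$n_out + st$n_removed, st$n_in)
  expect_equal(st$n_in[2], st$n_out[1])
  expect_equal(st$n_in[1], nrow(lib))
  # survivors are a subset of the input
  expect_true(all(rep1$survivors$smiles %in% lib$smiles))
  if (nrow(rep1$survivors)) {
    rep2 <- suppressWarnings(run_funnel(rep1$survivors, ref))
    expect_equal(sum(rep2$stages$n_removed), 0L)
    expect_setequal(rep2$survivors$smiles, rep1$survivors$smiles)
  }
})

test_that("the surviving set does not depend on stage order", {
  lib <- fixture_corpus20()
  # fused-bicycle reference: removes part of the library, not all of it
  ref <- "Cc1ccc2ccccc2c1"
  crit <- filter_criteria(mw_min = 0, qed_min = 0.3, sa_max = 6)
  a <- novelty_filter(lib, ref, generic = TRUE)
  expect_gt(nrow(a$survivors), 0L)
  expect_gt(nrow(a$removed), 0L)
  ab <- druglike_filter(calc_descriptors(a$survivors$smiles), crit)
  b <- druglike_filter(calc_descriptors(lib), crit)
  ba <- if (nrow(b$survivors))
    novelty_filter(b$survivors$smiles, ref, generic = TRUE)$survivors
  else data.frame(smiles = character(0))
  expect_setequal(ab$survivors$smiles, ba$smiles)
})

test_that("external score stages keep rows meeting their threshold", {
  surv <- fake_desc(n = 3)
  scores <- data.frame(id = c("x1", "x2", "x3"),
                       value = c(5, 3, 9), threshold = 4)
  expect_equal(apply_score_stage(surv, scores, "ge")$id, c("x1", "x3"))
  expect_equal(apply_score_stage(surv, scores, "le")$id, "x2")
  # molecules without a score row are dropped
  expect_equal(nrow(apply_score_stage(surv, scores[1, ], "ge")), 1L)
})
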