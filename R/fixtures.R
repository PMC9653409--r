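# Seeded synthetic corpora. Molecules are assembled from a hand-curated
# fragment grammar (ring cores with one substitution slot x
# substituents), which guarantees chemical validity by construction;
# randomness only shuffles and subsets the deterministic enumeration,
# so a given spec always yields a byte-identical corpus.

.fix_cores <- list(
  tiny = c("c1ccc({R})cc1", "C1CCC({R})CC1", "c1ccc({R})nc1"),
  small = c("C1CCN({R})CC1", "c1cc({R})sc1", "C1CC({R})OC1",
            "c1cc({R})oc1"),
  medium = c("c1ccc2cc({R})ccc2c1", "O=C1CCCN1{R}", "C1CN({R})CCN1C"))

.fix_subs <- list(
  tiny = c("C", "O", "N", "F", "CC", "OC"),
  small = c("Cl", "C(F)(F)F", "C#N", "N(C)C", "CO", "CCN", "C(C)C",
            "OCC"),
  medium = c("Cc2ccccc2", "Oc2ccccc2", "C(=O)Nc2ccccc2", "N2CCCCC2",
             "CN2CCOCC2", "Cc2ccc(F)cc2", "CC(N)=O", "S(C)(=O)=O"))

.fix_alert_sub <- "[N+](=O)[O-]"   # nitro group, in default_alerts()

fix_fragments <- function(complexity) {
  lvl <- match(complexity, c("tiny", "small", "medium"))
  list(cores = unlist(.fix_cores[seq_len(lvl)], use.names = FALSE),
       subs = unlist(.fix_subs[seq_len(lvl)], use.names = FALSE))
}

#' Specification for a synthetic SMILES corpus
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed controlling the shuffle/subset.
#' @param complexity `"tiny"`, `"small"` or `"medium"`; higher levels
#'   add ring cores (fused/saturated heterocycles) and substituents
#'   (including second ring systems).
#' @param alert_fraction fraction of molecules carrying the designated
#'   structural-alert substructure (a nitro group).
#' @return an object of class `corpus_spec`.
#' @export
corpus_spec <- function(n, seed = 1L,
                        complexity = c("small", "tiny", "medium"),
                        alert_fraction = 0) {
  complexity <- match.arg(complexity)
  stopifnot(n >= 1, alert_fraction >= 0, alert_fraction <= 1)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 complexity = complexity,
                 alert_fraction = alert_fraction),
            class = "corpus_spec")
}

#' Generate a synthetic corpus of standardized molecules
#'
#' @param spec a [corpus_spec()].
#' @return standardized molecule data frame (`id`, `input`, `smiles`,
#'   `status`, all `status == "ok"`), with exactly `spec$n` pairwise
#'   distinct molecules, `round(alert_fraction * n)` of which carry the
#'   alert substructure.
#' @export
make_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  frag <- fix_fragments(spec$complexity)
  combos <- as.vector(outer(frag$cores, frag$subs,
                            function(co, su) {
                              mapply(function(c1, s1)
                                sub("{R}", s1, c1, fixed = TRUE), co, su)
                            }))
  n_alert <- round(spec$alert_fraction * spec$n)
  n_plain <- spec$n - n_alert
  plain <- dedup_molecules(ok_only(standardize_smiles(combos)))
  alert_smiles <- vapply(frag$cores, function(co)
    sub("{R}", .fix_alert_sub, co, fixed = TRUE), character(1),
    USE.NAMES = FALSE)
  alert <- dedup_molecules(ok_only(standardize_smiles(alert_smiles)))
  # alert-bearing and plain sets must not overlap
  plain <- plain[!plain$smiles %in% alert$smiles, , drop = FALSE]
  if (n_plain > nrow(plain) || n_alert > nrow(alert))
    stop2("corpus_spec infeasible: n = ", spec$n, " (alert ", n_alert,
          ") exceeds the ", spec$complexity, " grammar (",
          nrow(plain), " plain / ", nrow(alert), " alert molecules)")
  with_seed(spec$seed, {
    sel_plain <- plain[sample(nrow(plain), n_plain), , drop = FALSE]
    sel_alert <- alert[sample(nrow(alert), n_alert), , drop = FALSE]
    out <- rbind(sel_plain, sel_alert)
    out <- out[sample(nrow(out)), , drop = FALSE]
    out
  }) -> out
  out$id <- paste0("fix_", seq_len(nrow(out)))
  out$input <- out$smiles
  rownames(out) <- NULL
  out
}

ok_only <- function(std) std[std$status == "ok", , drop = FALSE]

#' Source / target corpus pair for transfer-learning experiments
#'
#' Emulates the pretraining/fine-tuning setup: a structurally diverse
#' source corpus and a smaller target corpus concentrated on one
#' scaffold family (para-substituted benzyl- and phenethylpiperidines),
#' disjoint from the source as canonical-SMILES sets, with every target
#' token present in the source vocabulary.
#'
#' @param seed integer seed.
#' @param n_source,n_target corpus sizes.
#' @return list with elements `source` and `target`, each a
#'   standardized molecule data frame.
#' @export
make_pair_corpora <- function(seed = 1L, n_source = 40L, n_target = 16L) {
  source <- make_corpus(corpus_spec(n_source,
                                    seed = derive_seed(seed, "source"),
                                    complexity = "medium"))
  fams <- c("C1CCN(Cc2ccc({R})cc2)CC1", "C1CCN(CCc2ccc({R})cc2)CC1")
  subs <- c(.fix_subs$tiny, .fix_subs$small)
  cand <- as.vector(outer(fams, subs, function(fa, su)
    mapply(function(f1, s1) sub("{R}", s1, f1, fixed = TRUE), fa, su)))
  target <- dedup_molecules(ok_only(standardize_smiles(cand)))
  # enforce disjointness and vocabulary containment
  target <- target[!target$smiles %in% source$smiles, , drop = FALSE]
  src_tokens <- unique(unlist(lapply(source$smiles, tokenize_smiles)))
  covered <- vapply(target$smiles, function(s)
    all(tokenize_smiles(s) %in% src_tokens), logical(1))
  target <- target[covered, , drop = FALSE]
  if (n_target > nrow(target))
    stop2("n_target = ", n_target, " exceeds the ", nrow(target),
          " available target-family molecules")
  with_seed(derive_seed(seed, "target"), {
    target <- target[sample(nrow(target), n_target), , drop = FALSE]
  })
  target$id <- paste0("tgt_", seq_len(nrow(target)))
  target$input <- target$smiles
  rownames(target) <- NULL
  list(source = source, target = target)
}
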