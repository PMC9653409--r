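# Synthetic-accessibility estimate. Follows the fragment-contribution /
# complexity-penalty framework: an atom-environment commonness score
# (computed against a deterministic internal reference corpus) is
# rewarded, and size, ring and branching complexity are penalized; the
# raw score is mapped onto the conventional 1 (easy) .. 10 (hard)
# scale. This is an in-package estimator -- see the methods vignette
# for its definition, calibration and limitations.

.molcrnn_cache <- new.env(parent = emptyenv())

# Canonical signatures of circular atom environments, radius 0..2.
atom_environments <- function(g) {
  r0 <- paste0(g$elem, ifelse(g$arom, "a", ""), ":", g$degree,
               ":", g$charge)
  nb <- vector("list", g$n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[k]; b <- g$bonds$a2[k]; o <- g$bonds$order[k]
      nb[[a]] <- c(nb[[a]], paste0(o, "-", r0[b]))
      nb[[b]] <- c(nb[[b]], paste0(o, "-", r0[a]))
    }
  }
  r1 <- vapply(seq_len(g$n), function(a)
    paste0(r0[a], "(", paste(sort(nb[[a]]), collapse = ","), ")"),
    character(1))
  nb2 <- vector("list", g$n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[k]; b <- g$bonds$a2[k]; o <- g$bonds$order[k]
      nb2[[a]] <- c(nb2[[a]], paste0(o, "-", r1[b]))
      nb2[[b]] <- c(nb2[[b]], paste0(o, "-", r1[a]))
    }
  }
  r2 <- vapply(seq_len(g$n), function(a)
    paste0(r1[a], "{", paste(sort(nb2[[a]]), collapse = ","), "}"),
    character(1))
  list(r0 = r0, r1 = r1, r2 = r2)
}

# Environment frequency table over the internal reference corpus
# (grammar-generated, fixed seed; computed once per session).
sa_reference <- function() {
  if (!is.null(.molcrnn_cache$sa_ref)) return(.molcrnn_cache$sa_ref)
  corpus <- make_corpus(corpus_spec(n = 150, seed = 8675309,
                                    complexity = "medium"))
  tabs <- list(r0 = character(0), r1 = character(0), r2 = character(0))
  for (s in corpus$smiles) {
    env <- atom_environments(mol_graph(s))
    tabs$r0 <- c(tabs$r0, env$r0)
    tabs$r1 <- c(tabs$r1, env$r1)
    tabs$r2 <- c(tabs$r2, env$r2)
  }
  ref <- lapply(tabs, table)
  .molcrnn_cache$sa_ref <- ref
  ref
}

# Commonness score in [-1, 1] per atom: deepest environment radius with
# a reference hit wins; completely unseen environments score -1.
env_scores <- function(g, ref) {
  env <- atom_environments(g)
  score_tab <- function(sig, tab) {
    cnt <- as.numeric(tab[sig])
    mx <- max(as.numeric(tab))
    ifelse(is.na(cnt), NA_real_, 2 * log1p(cnt) / log1p(mx) - 1)
  }
  s2 <- score_tab(env$r2, ref$r2)
  s1 <- score_tab(env$r1, ref$r1)
  s0 <- score_tab(env$r0, ref$r0)
  s <- ifelse(!is.na(s2), s2, ifelse(!is.na(s1), 0.5 * s1,
                                     ifelse(!is.na(s0), 0.25 * s0, -1)))
  s
}

#' Synthetic-accessibility estimate
#'
#' @param smiles character vector of standardized SMILES.
#' @param g internal use: a precomputed molecular graph for a single
#'   molecule.
#' @return numeric vector of scores in `[1, 10]` (1 = easy to make).
#' @export
sa_score <- function(smiles, g = NULL) {
  if (!is.null(g)) return(sa_one(g))
  vapply(smiles, function(s) sa_one(mol_graph(s)), numeric(1),
         USE.NAMES = FALSE)
}

sa_one <- function(g) {
  ref <- sa_reference()
  fscore <- mean(env_scores(g, ref))
  n <- g$n
  size_pen <- 0.15 * (n^1.005 - n)
  ring_pen <- 0.5 * log1p(max(n_rings(g), 0))
  branch_pen <- 0.3 * log1p(sum(g$degree >= 4))
  raw <- 2.5 * fscore - size_pen - ring_pen - branch_pen
  # raw spans roughly [-6.5, 2.5]; map linearly onto [10, 1]
  sa <- 1 + 9 * (2.5 - raw) / 9
  min(max(sa, 1), 10)
}
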