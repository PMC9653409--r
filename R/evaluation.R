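# Evaluation metrics: reconstruction rate (R%), generation rate (G%),
# dynamic validation subsets, scaffold diversity/novelty, and
# per-property distribution reports.

#' Reconstruction rate (R%)
#'
#' Each subset molecule is encoded to its state vector and decoded
#' greedily (teacher-free, temperature 0); a molecule counts as
#' reconstructed when the decoded string standardizes to exactly the
#' same canonical SMILES. Returns `100 * M_recon / N_recon`.
#'
#' @param ckpt a `crnn_checkpoint`.
#' @param subset standardized molecule data frame or SMILES vector.
#' @param max_len decoding length cap.
#' @return percentage in `[0, 100]`.
#' @export
reconstruction_rate <- function(ckpt, subset, max_len = 120L) {
  smiles <- corpus_smiles(subset)
  hits <- vapply(smiles, function(s) {
    out <- generate_one(ckpt, encode_state(s, ckpt), max_len = max_len,
                        temperature = 0)
    if (is.na(out) || !nzchar(out)) return(FALSE)
    std <- standardize_smiles(out)
    std$status == "ok" && std$smiles == s
  }, logical(1))
  100 * sum(hits) / length(hits)
}

#' Generation rate (G%)
#'
#' Conditioning vectors are built from the subset per the sampling
#' configuration and decoded stochastically; `M_gen` counts attempts
#' that yield a chemically valid (parseable, standardizable) molecule.
#' The denominator `N_gen` is the number of decoding attempts. (Config
#' switch `count`: `"valid"` (default), `"valid_unique"`, or
#' `"valid_novel"` additionally requires distinctness within the run or
#' novelty w.r.t. the subset.)
#'
#' @param ckpt a `crnn_checkpoint`.
#' @param subset standardized molecules seeding the conditioning
#'   vectors.
#' @param s_cfg a [sampling_config()] (`n_samples` is ignored in favor
#'   of `attempts`).
#' @param attempts number of decoding attempts (>= 1).
#' @param count which numerator to use, see above.
#' @return percentage in `[0, 100]`.
#' @export
generation_rate <- function(ckpt, subset, s_cfg = sampling_config(),
                            attempts = 100L,
                            count = c("valid", "valid_unique",
                                      "valid_novel")) {
  count <- match.arg(count)
  stopifnot(attempts >= 1)
  smiles <- corpus_smiles(subset)
  if (s_cfg$mode != "single_point" && length(smiles) < 2L)
    stop2("interpolation sampling needs at least two subset molecules")
  H <- do.call(rbind, lapply(smiles, encode_state, ckpt = ckpt))
  raw <- with_seed(s_cfg$seed, {
    vapply(seq_len(attempts), function(k) {
      d <- draw_state(H, s_cfg)
      generate_one_impl(ckpt, d$h0, s_cfg$max_len, s_cfg$temperature)
    }, character(1))
  })
  ok <- rep(FALSE, attempts)
  parseable <- !is.na(raw) & nzchar(raw)
  std <- rep(NA_character_, attempts)
  if (any(parseable)) {
    sr <- standardize_smiles(raw[parseable])
    std[parseable] <- ifelse(sr$status == "ok", sr$smiles, NA_character_)
  }
  valid <- !is.na(std)
  m <- switch(count,
    valid = sum(valid),
    valid_unique = length(unique(std[valid])),
    valid_novel = length(setdiff(unique(std[valid]), smiles)))
  100 * m / attempts
}

#' Random evaluation subset
#'
#' Uniform sample without replacement, reproducible under `seed`;
#' intended to be redrawn for every evaluation call (dynamic validation
#' subsets).
#'
#' @param corpus standardized molecule data frame or SMILES vector.
#' @param n subset size (`n <= |corpus|`).
#' @param seed integer seed.
#' @return object of the same type as `corpus`, `n` molecules.
#' @export
dynamic_subset <- function(corpus, n, seed = 1L) {
  size <- if (is.data.frame(corpus)) nrow(corpus) else length(corpus)
  if (n > size)
    stop2("requested subset of ", n, " from a corpus of ", size)
  idx <- with_seed(seed, sample.int(size, n))
  if (is.data.frame(corpus)) corpus[idx, , drop = FALSE] else corpus[idx]
}

#' Relative scaffold diversity of a molecule set
#'
#' Relative diversity = (number of distinct Murcko scaffolds) /
#' (number of molecules). Acyclic molecules share the empty scaffold,
#' which counts as one scaffold value. The report also carries the
#' cumulative scaffold frequency curve (scaffolds sorted by decreasing
#' membership; cumulative fraction of molecules covered).
#'
#' @param mols standardized molecule data frame or SMILES vector.
#' @param generic use generic (all-carbon skeleton) scaffolds.
#' @return object of class `diversity_report`: `n_molecules`,
#'   `n_distinct_scaffolds`, `relative_diversity` (fraction),
#'   `percent`, `generic`, and `curve` (data frame `rank`, `count`,
#'   `cumulative_fraction`).
#' @export
scaffold_diversity <- function(mols, generic = FALSE) {
  smiles <- corpus_smiles(mols)
  scaf <- murcko_scaffold(smiles, generic = generic)
  tab <- sort(table(scaf), decreasing = TRUE)
  curve <- data.frame(rank = seq_along(tab),
                      count = as.integer(tab),
                      cumulative_fraction = cumsum(as.integer(tab)) /
                        length(smiles))
  structure(list(n_molecules = length(smiles),
                 n_distinct_scaffolds = length(tab),
                 relative_diversity = length(tab) / length(smiles),
                 percent = relative_scaffold_diversity(length(tab),
                                                       length(smiles)),
                 generic = generic, curve = curve),
            class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(
    "Scaffold diversity (%s Murcko): %d distinct / %d molecules = %.1f%%\n",
    if (x$generic) "generic" else "plain",
    x$n_distinct_scaffolds, x$n_molecules, x$percent))
  invisible(x)
}

#' Relative scaffold diversity as a percentage
#'
#' The arithmetic used by [scaffold_diversity()], exposed for
#' count-level use: `100 * n_distinct / n_molecules`.
#'
#' @param n_distinct number of distinct scaffolds.
#' @param n_molecules number of molecules (> 0).
#' @return percentage.
#' @export
relative_scaffold_diversity <- function(n_distinct, n_molecules) {
  stopifnot(n_molecules > 0, n_distinct >= 0, n_distinct <= n_molecules)
  100 * n_distinct / n_molecules
}

#' Scaffold novelty of one set against another
#'
#' Percentage of the distinct scaffolds of `set_a` that do not occur
#' among the scaffolds of `set_b`.
#'
#' @param set_a,set_b standardized molecule data frames or SMILES
#'   vectors (both non-empty).
#' @param generic use generic scaffolds.
#' @return percentage in `[0, 100]`.
#' @export
scaffold_overlap <- function(set_a, set_b, generic = FALSE) {
  a <- unique(murcko_scaffold(corpus_smiles(set_a), generic = generic))
  b <- unique(murcko_scaffold(corpus_smiles(set_b), generic = generic))
  100 * length(setdiff(a, b)) / length(a)
}

# Fixed histogram bin widths per descriptor (right-open bins anchored
# at 0), so counts are additive across disjoint molecule sets.
.hist_widths <- c(mw = 25, logp = 0.5, qed = 0.05, sa = 0.5,
                  bertz_ct = 50, tpsa = 10, logs = 0.5, rot = 1,
                  hbd = 1, hba = 1)

#' Descriptor distribution report
#'
#' Per-descriptor summary (mean, sd, quartiles) and histogram counts
#' under a fixed binning rule (fixed width per property, bins anchored
#' at zero), deterministic and additive across subsets.
#'
#' @param mols standardized molecules, or a precomputed descriptor data
#'   frame from [calc_descriptors()].
#' @return object of class `property_report`: named list per
#'   descriptor with `summary` and `hist` (data frame `bin_lo`,
#'   `bin_hi`, `count`), plus attribute `n`.
#' @export
property_report <- function(mols) {
  desc <- if (is.data.frame(mols) && all(names(.hist_widths) %in%
                                         names(mols))) mols
          else calc_descriptors(mols)
  desc <- desc[desc$desc_status == "ok", , drop = FALSE]
  if (!nrow(desc)) stop2("no molecules with computable descriptors")
  rep <- lapply(names(.hist_widths), function(pn) {
    x <- desc[[pn]]
    w <- .hist_widths[[pn]]
    bin <- floor(x / w)
    tab <- table(bin)
    lo <- as.numeric(names(tab)) * w
    list(summary = c(mean = mean(x), sd = stats::sd(x),
                     stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1))),
         hist = data.frame(bin_lo = lo, bin_hi = lo + w,
                           count = as.integer(tab)))
  })
  names(rep) <- names(.hist_widths)
  structure(rep, n = nrow(desc), class = "property_report")
}

#' @export
print.property_report <- function(x, ...) {
  cat("Descriptor report over", attr(x, "n"), "molecules\n")
  s <- t(vapply(x, function(p) p$summary, numeric(7)))
  print(round(s, 3))
  invisible(x)
}
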