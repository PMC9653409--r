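# Virtual-screening funnel: scaffold/substructure novelty filtering
# against a reference set, drug-likeness property filtering, and
# per-stage accounting. Pharmacophore and docking stages are external
# hooks consuming a per-molecule score table.

#' Drug-likeness filter criteria
#'
#' All bounds are inclusive. Defaults: `200 <= MW <= 700`,
#' `-2 <= LogP <= 6`, `QED >= 0.15`, `SA <= 5`.
#'
#' @param mw_min,mw_max molecular-weight range (g/mol).
#' @param logp_min,logp_max logP range.
#' @param qed_min minimum drug-likeness.
#' @param sa_max maximum synthetic-accessibility score.
#' @return object of class `filter_criteria`.
#' @export
filter_criteria <- function(mw_min = 200, mw_max = 700, logp_min = -2,
                            logp_max = 6, qed_min = 0.15, sa_max = 5) {
  stopifnot(mw_min <= mw_max, logp_min <= logp_max)
  structure(list(mw_min = mw_min, mw_max = mw_max,
                 logp_min = logp_min, logp_max = logp_max,
                 qed_min = qed_min, sa_max = sa_max),
            class = "filter_criteria")
}

#' Drug-likeness property filter
#'
#' Keeps molecules satisfying every criterion (inclusive bounds);
#' removed molecules are labeled with the first violated criterion in
#' the fixed order MW, LogP, QED, SA.
#'
#' @param desc descriptor data frame from [calc_descriptors()] (or
#'   standardized molecules, for which descriptors are computed).
#' @param criteria a [filter_criteria()].
#' @return list with `survivors` and `removed` (with a `reason`
#'   column), both subsets of the descriptor table.
#' @export
druglike_filter <- function(desc, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  if (!is.data.frame(desc) || !all(c("mw", "logp", "qed", "sa") %in%
                                   names(desc)))
    desc <- calc_descriptors(desc)
  reason <- rep(NA_character_, nrow(desc))
  mark <- function(cond, lab) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- lab
  }
  mark(desc$mw < criteria$mw_min | desc$mw > criteria$mw_max, "MW")
  mark(desc$logp < criteria$logp_min | desc$logp > criteria$logp_max, "LogP")
  mark(desc$qed < criteria$qed_min, "QED")
  mark(desc$sa > criteria$sa_max, "SA")
  removed <- desc[!is.na(reason), , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[!is.na(reason)]
  else removed$reason <- character(0)
  list(survivors = desc[is.na(reason), , drop = FALSE],
       removed = removed)
}

#' Scaffold / substructure novelty filter
#'
#' Removes a candidate when (a) its generic Murcko scaffold equals the
#' generic scaffold of any reference molecule, or (b) any reference
#' scaffold occurs as a substructure of the candidate (compared at the
#' same scaffold level; with `substructure = "molecule"` whole
#' reference molecules are used as the substructure queries instead).
#' Acyclic candidates (empty scaffold) never match by scaffold
#' equality. An empty reference set returns the library unchanged with
#' a warning.
#'
#' @param library,reference standardized molecule data frames or SMILES
#'   vectors.
#' @param generic compare generic (all-carbon) scaffolds.
#' @param substructure substructure-query source: reference scaffolds
#'   (default) or whole reference molecules.
#' @return list with `survivors` and `removed` (data frames with a
#'   `reason` column: `scaffold` or `substructure`).
#' @export
novelty_filter <- function(library, reference, generic = TRUE,
                           substructure = c("scaffold", "molecule")) {
  substructure <- match.arg(substructure)
  lib <- corpus_smiles(library)
  ref <- tryCatch(corpus_smiles(reference), error = function(e) character(0))
  out_df <- function(keep, reason) {
    list(survivors = data.frame(smiles = lib[keep],
                                stringsAsFactors = FALSE),
         removed = data.frame(smiles = lib[!keep],
                              reason = reason[!keep],
                              stringsAsFactors = FALSE))
  }
  if (!length(ref)) {
    warning("empty reference set; novelty filter is the identity")
    return(out_df(rep(TRUE, length(lib)), rep(NA_character_, length(lib))))
  }
  lib_scaf <- murcko_scaffold(lib, generic = generic)
  ref_scaf <- unique(murcko_scaffold(ref, generic = generic))
  ref_scaf <- ref_scaf[nzchar(ref_scaf)]
  hit_scaf <- nzchar(lib_scaf) & lib_scaf %in% ref_scaf
  # substructure test at the scaffold level (or whole molecules)
  queries <- if (substructure == "scaffold") ref_scaf
             else unique(ref)
  subjects <- if (substructure == "scaffold") lib_scaf else lib
  hit_sub <- rep(FALSE, length(lib))
  nonempty <- nzchar(subjects)
  if (any(nonempty) && length(queries)) {
    mols <- ob_mols(subjects[nonempty])
    hs <- rep(FALSE, sum(nonempty))
    for (q in queries) {
      n <- suppressWarnings(tryCatch(
        ChemmineOB::smartsSearch_OB(mols, q),
        error = function(e) rep(0, sum(nonempty))))
      hs <- hs | (n > 0)
    }
    hit_sub[nonempty] <- hs
  }
  reason <- ifelse(hit_scaf, "scaffold",
                   ifelse(hit_sub, "substructure", NA_character_))
  out_df(!hit_scaf & !hit_sub, reason)
}

#' Run the screening funnel
#'
#' Executes the computational screening stages in order: (1) scaffold /
#' substructure novelty against the reference set, (2) drug-likeness
#' property filter. Per-stage accounting satisfies
#' `n_out + n_removed == n_in` and stage `k`'s `n_in` equals stage
#' `k-1`'s `n_out`. An optional external-score stage (pharmacophore or
#' docking scores produced outside the package) can be appended with
#' [apply_score_stage()].
#'
#' @param library standardized candidate molecules.
#' @param reference standardized reference molecules (known actives).
#' @param criteria a [filter_criteria()].
#' @param generic compare scaffolds at the generic level.
#' @return object of class `funnel_report`: `stages` data frame
#'   (`stage`, `n_in`, `n_out`, `n_removed`), `removed` per-stage
#'   detail, `survivors` data frame, and `settings`.
#' @export
run_funnel <- function(library, reference,
                       criteria = filter_criteria(), generic = TRUE) {
  lib <- corpus_smiles(library)
  st1 <- novelty_filter(lib, reference, generic = generic)
  n1 <- c(length(lib), nrow(st1$survivors))
  surv1 <- st1$survivors$smiles
  if (length(surv1)) {
    desc <- calc_descriptors(surv1)
    st2 <- druglike_filter(desc, criteria)
    surv2 <- st2$survivors
    removed2 <- st2$removed
  } else {
    surv2 <- data.frame(smiles = character(0))
    removed2 <- data.frame(smiles = character(0), reason = character(0))
  }
  stages <- data.frame(
    stage = c("novelty", "druglike"),
    n_in = c(n1[1], n1[2]),
    n_out = c(n1[2], nrow(surv2)),
    n_removed = c(n1[1] - n1[2], n1[2] - nrow(surv2)))
  if (!nrow(surv2)) warning("no molecules survived the funnel")
  structure(list(stages = stages,
                 removed = list(novelty = st1$removed,
                                druglike = removed2),
                 survivors = surv2,
                 settings = list(criteria = criteria, generic = generic,
                                 substructure = "scaffold")),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Screening funnel\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' External-score screening stage
#'
#' Pass-through hook for screening stages whose scores are produced
#' outside the package (pharmacophore fit values, docking scores):
#' consumes a table with columns `id`, `value`, `threshold` and keeps
#' molecules whose value meets the threshold in the requested
#' direction.
#'
#' @param survivors data frame with an `id` column (e.g. funnel
#'   survivors).
#' @param scores data frame or CSV path with columns `id`, `value`,
#'   `threshold`.
#' @param direction `"ge"` keeps `value >= threshold` (fit values);
#'   `"le"` keeps `value <= threshold` (docking energies).
#' @return filtered `survivors`; molecules without a score row are
#'   removed.
#' @export
apply_score_stage <- function(survivors, scores,
                              direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (is.character(scores)) scores <- utils::read.csv(scores)
  stopifnot(all(c("id", "value", "threshold") %in% names(scores)))
  m <- match(survivors$id, scores$id)
  ok <- !is.na(m) & if (direction == "ge")
    scores$value[m] >= scores$threshold[m]
  else scores$value[m] <= scores$threshold[m]
  survivors[ok, , drop = FALSE]
}
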