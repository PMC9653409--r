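# Molecule standardization on top of Open Babel (via ChemmineOB).
# Open Babel is the format authority: parsing, canonicalization and
# SMILES/SDF interconversion all go through it.

# Canonicalize one SMILES string; "" when Open Babel cannot parse it.
ob_canonical <- function(smiles) {
  out <- suppressWarnings(suppressMessages(
    tryCatch(ChemmineOB::convertFormat("SMI", "CAN", smiles),
             error = function(e) "")))
  strip_title(out)
}

# Open Babel SMILES output carries a trailing "\ttitle\n"; strip it.
strip_title <- function(x) {
  x <- sub("[\t ].*$", "", sub("\n$", "", x))
  trimws(x)
}

# Batch canonicalization for inputs already known to parse (alignment
# between input and output lines is only guaranteed for valid records).
ob_canonical_batch <- function(smiles) {
  if (!length(smiles)) return(character(0))
  out <- suppressWarnings(suppressMessages(
    ChemmineOB::convertFormat("SMI", "CAN", paste(smiles, collapse = "\n"))))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- vapply(lines, strip_title, character(1), USE.NAMES = FALSE)
  if (length(lines) != length(smiles))
    stop2("batch canonicalization misaligned; standardize inputs first")
  lines
}

# Remove stereochemistry descriptors (tetrahedral @, double-bond / \)
# from a SMILES string. H counts inside bracket atoms are untouched, so
# "[C@@H]" becomes "[CH]" which Open Babel normalizes on re-reading.
strip_stereo <- function(smiles) gsub("[@/\\\\]", "", smiles)

heavy_atom_count <- function(smiles) {
  toks <- tokenize_smiles(smiles)
  at <- toks[is_atom_token(toks)]
  sum(token_element(at) != "H")
}

contains_carbon <- function(smiles) {
  toks <- tokenize_smiles(smiles)
  any(token_element(toks[is_atom_token(toks)]) == "C")
}

#' Standardize raw SMILES records
#'
#' Applies the preprocessing used for every corpus handled by the
#' package: stereochemistry descriptors are removed, salts and solvents
#' are stripped by keeping the largest organic fragment (most heavy
#' atoms; ties broken by lexicographically smallest canonical SMILES),
#' and the survivor is canonicalized with Open Babel. The operation is
#' deterministic and idempotent. Records that fail to parse are kept in
#' the output with a non-`ok` status rather than dropped, so pipeline
#' stages can account for them.
#'
#' @param text character vector of SMILES strings as read.
#' @param id optional identifiers (default `mol_1`, `mol_2`, ...).
#' @return a data frame with columns `id`, `input`, `smiles` (canonical,
#'   `NA` unless `status == "ok"`) and `status` (one of `ok`,
#'   `unparseable`, `empty_after_strip`).
#' @examples
#' \dontrun{
#' standardize_smiles(c("C[C@@H](N)C(=O)O", "CCO.Cl", "C1CC"))
#' }
#' @export
standardize_smiles <- function(text, id = NULL) {
  stopifnot(is.character(text), all(nzchar(text)))
  if (is.null(id)) id <- paste0("mol_", seq_along(text))
  stopifnot(length(id) == length(text))
  res <- lapply(text, standardize_one)
  data.frame(id = as.character(id),
             input = text,
             smiles = vapply(res, `[[`, character(1), "smiles"),
             status = vapply(res, `[[`, character(1), "status"),
             stringsAsFactors = FALSE)
}

standardize_one <- function(text) {
  text <- trimws(text)
  frags <- strsplit(strip_stereo(text), ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (!length(frags)) return(list(smiles = NA_character_, status = "unparseable"))
  can <- vapply(frags, ob_canonical, character(1), USE.NAMES = FALSE)
  if (any(!nzchar(can)))
    return(list(smiles = NA_character_, status = "unparseable"))
  organic <- vapply(can, contains_carbon, logical(1))
  if (!any(organic))
    return(list(smiles = NA_character_, status = "empty_after_strip"))
  can <- can[organic]
  sizes <- vapply(can, heavy_atom_count, integer(1))
  best <- can[sizes == max(sizes)]
  keep <- sort(best)[1]
  # canonical form of a canonical fragment is itself, but re-canonicalize
  # once more so idempotence never depends on that assumption
  final <- ob_canonical(keep)
  if (!nzchar(final)) return(list(smiles = NA_character_, status = "unparseable"))
  list(smiles = final, status = "ok")
}

#' Deduplicate standardized molecules
#'
#' Keeps the first occurrence of each canonical SMILES; ordering is
#' otherwise preserved. All inputs must have `status == "ok"`.
#'
#' @param mols standardized molecule data frame from
#'   [standardize_smiles()].
#' @return the input data frame restricted to canonical-SMILES-distinct
#'   rows.
#' @export
dedup_molecules <- function(mols) {
  stopifnot(is.data.frame(mols), "smiles" %in% names(mols))
  if (!is.null(mols$status) && any(mols$status != "ok"))
    stop2("dedup_molecules expects only records with status == 'ok'")
  mols[!duplicated(mols$smiles), , drop = FALSE]
}
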