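#' SMILES tokenization
#'
#' Splits a SMILES string into the token alphabet used by the sequence
#' model: bracket atoms (`[nH]`, `[O-]`, ...), the two-letter halogens
#' `Cl` and `Br`, two-digit ring closures (`%10`), and all remaining
#' single characters (organic-subset atoms, bonds, branches, ring digits).
#'
#' @param smiles character scalar, a SMILES string.
#' @return character vector of tokens; collapsing it with `paste0`
#'   reproduces the input exactly.
#' @examples
#' tokenize_smiles("BrCC[nH0]")
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (!nzchar(smiles)) return(character(0))
  m <- gregexpr("\\[[^]]+\\]|Br|Cl|%[0-9]{2}|.", smiles)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  if (paste0(toks, collapse = "") != smiles)
    stop2("tokenizer failed to cover input: ", smiles)
  toks
}

# Atom-token classification. Bracket atoms are always atoms; otherwise the
# organic subset plus aromatic forms. Ring digits, bonds and branches are
# not atoms.
.atom_single <- c("B", "C", "N", "O", "P", "S", "F", "I",
                  "b", "c", "n", "o", "p", "s")

is_atom_token <- function(tok) {
  startsWith(tok, "[") | tok %in% c(.atom_single, "Cl", "Br")
}

# Element symbol of an atom token ("" for non-atoms). For bracket atoms
# the optional isotope prefix is skipped; aromatic lowercase symbols are
# upcased ("c" -> "C", "[nH]" -> "N").
token_element <- function(tok) {
  vapply(tok, function(t) {
    if (startsWith(t, "[")) {
      body <- sub("^\\[[0-9]*", "", t)
      m <- regmatches(body, regexpr("[A-Za-z][a-z]?", body))
      if (!length(m)) return("")
      e <- m[1]
      # lowercase-only symbol is an aromatic organic element
      if (e %in% c("nH", "cH", "sH", "oH", "pH")) e <- substr(e, 1, 1)
      if (grepl("^[a-z]", e)) toupper(substr(e, 1, 1)) else e
    } else if (t %in% c("Cl", "Br")) t
    else if (t %in% .atom_single) toupper(t)
    else ""
  }, character(1), USE.NAMES = FALSE)
}

# TRUE for atom tokens written in aromatic (lowercase) form.
token_aromatic <- function(tok) {
  vapply(tok, function(t) {
    if (startsWith(t, "[")) grepl("^\\[[0-9]*[a-z]", t)
    else t %in% c("b", "c", "n", "o", "p", "s")
  }, logical(1), USE.NAMES = FALSE)
}

#' Build a token vocabulary from a corpus
#'
#' Collects every token occurring in the corpus, sorts them, and appends
#' the special tokens `<SOS>`, `<EOS>` and `<PAD>`. The ordering is a pure
#' function of the token set, so any permutation of the same corpus yields
#' the same vocabulary.
#'
#' @param corpus character vector of SMILES strings, or a standardized
#'   molecule data frame with a `smiles` column.
#' @return an object of class `smiles_vocab`: a list with `tokens`
#'   (ordered token vector), `index` (named integer map, 1-based) and `J`
#'   (vocabulary size).
#' @export
build_vocabulary <- function(corpus) {
  smiles <- if (is.data.frame(corpus)) corpus$smiles else corpus
  smiles <- smiles[!is.na(smiles) & nzchar(smiles)]
  if (!length(smiles)) stop2("cannot build a vocabulary from an empty corpus")
  toks <- sort(unique(unlist(lapply(smiles, tokenize_smiles))))
  tokens <- c(toks, "<SOS>", "<EOS>", "<PAD>")
  vocab <- list(tokens = tokens,
                index = stats::setNames(seq_along(tokens), tokens),
                J = length(tokens))
  class(vocab) <- "smiles_vocab"
  vocab
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat("SMILES vocabulary: J =", x$J, "tokens\n")
  cat(" ", paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

vocab_id <- function(vocab, token) unname(vocab$index[[token]])

#' One-hot encode a SMILES string
#'
#' Maps a SMILES string to the model's sequence representation: one row
#' per token plus a terminal `<EOS>` row, each row a one-hot indicator
#' over the vocabulary.
#'
#' @param smiles character scalar.
#' @param vocab a `smiles_vocab`.
#' @return an object of class `onehot_seq`: list with `matrix`
#'   (`n_tok x J` 0/1 matrix whose last row is `<EOS>`), `length`, and
#'   the integer token `ids`.
#' @export
encode_onehot <- function(smiles, vocab) {
  toks <- tokenize_smiles(smiles)
  unknown <- setdiff(toks, vocab$tokens)
  if (length(unknown))
    stop2("token(s) not in vocabulary: ", paste(unique(unknown), collapse = " "))
  ids <- c(unname(vocab$index[toks]), vocab_id(vocab, "<EOS>"))
  m <- matrix(0L, nrow = length(ids), ncol = vocab$J)
  m[cbind(seq_along(ids), ids)] <- 1L
  structure(list(matrix = m, length = length(ids), ids = ids),
            class = "onehot_seq")
}

#' Decode token ids back to a SMILES string
#'
#' Concatenates the tokens for `ids` up to (and excluding) the first
#' `<EOS>`; `<PAD>` and `<SOS>` tokens are ignored.
#'
#' @param ids integer vector of 1-based vocabulary indices.
#' @param vocab a `smiles_vocab`.
#' @return character scalar (possibly empty).
#' @export
decode_tokens <- function(ids, vocab) {
  ids <- as.integer(ids)
  if (any(is.na(ids)) || any(ids < 1L) || any(ids > vocab$J))
    stop2("token id out of range 1..", vocab$J)
  toks <- vocab$tokens[ids]
  eos <- which(toks == "<EOS>")
  if (length(eos)) toks <- toks[seq_len(eos[1] - 1L)]
  toks <- toks[!toks %in% c("<PAD>", "<SOS>")]
  paste0(toks, collapse = "")
}

#' Serialize / restore a vocabulary as JSON
#'
#' The ordered token list is the complete state, so checkpoints referring
#' to a vocabulary are portable across sessions.
#' @param vocab a `smiles_vocab`.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(list(tokens = vocab$tokens), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- jsonlite::read_json(path, simplifyVector = TRUE)$tokens
  vocab <- list(tokens = tokens,
                index = stats::setNames(seq_along(tokens), tokens),
                J = length(tokens))
  class(vocab) <- "smiles_vocab"
  vocab
}
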