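#' Murcko scaffold of a molecule
#'
#' Extracts the Murcko framework: ring systems plus the linker atoms
#' connecting them, with side chains pruned. Atoms attached to the
#' framework by a double or triple bond (exocyclic carbonyls and the
#' like) are retained. With `generic = TRUE` every retained atom is
#' mapped to carbon and every bond to a single bond, giving the pure
#' skeleton used for scaffold-novelty comparisons. Acyclic molecules
#' have an empty scaffold (`""`). The operation is idempotent:
#' `murcko_scaffold(murcko_scaffold(s)) == murcko_scaffold(s)`.
#'
#' @param smiles character vector of standardized SMILES.
#' @param generic logical; return the generic (all-carbon, all-single
#'   bond) framework.
#' @return character vector of canonical scaffold SMILES (`""` for
#'   acyclic molecules).
#' @export
murcko_scaffold <- function(smiles, generic = FALSE) {
  vapply(smiles, murcko_one, character(1), generic = generic,
         USE.NAMES = FALSE)
}

murcko_one <- function(smiles, generic = FALSE) {
  if (is.na(smiles) || !nzchar(smiles)) return("")
  g <- mol_graph(smiles)
  if (!any(g$ring_atom)) return("")
  # iterative removal of terminal atoms leaves rings plus linkers
  keep <- rep(TRUE, g$n)
  repeat {
    deg <- tabulate(c(g$bonds$a1[keep[g$bonds$a1] & keep[g$bonds$a2]],
                      g$bonds$a2[keep[g$bonds$a1] & keep[g$bonds$a2]]),
                    nbins = g$n)
    drop <- keep & deg <= 1 & !g$ring_atom
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # re-attach atoms multiply bonded to the framework (e.g. C=O)
  skel <- keep
  live <- g$bonds$order >= 2 &
    (skel[g$bonds$a1] | skel[g$bonds$a2]) &
    !(skel[g$bonds$a1] & skel[g$bonds$a2])
  keep[g$bonds$a1[live]] <- TRUE
  keep[g$bonds$a2[live]] <- TRUE
  idx <- which(keep)
  remap <- integer(g$n)
  remap[idx] <- seq_along(idx)
  kb <- g$bonds[keep[g$bonds$a1] & keep[g$bonds$a2], , drop = FALSE]
  bonds <- data.frame(a1 = remap[kb$a1], a2 = remap[kb$a2], order = kb$order)
  elem <- g$elem[idx]
  charge <- g$charge[idx]
  if (generic) {
    elem <- rep("C", length(elem))
    bonds$order <- rep(1L, nrow(bonds))
    charge <- integer(length(elem))
  }
  out <- molfile_to_smiles(write_molfile(elem, bonds, charge))
  if (!nzchar(out)) stop2("scaffold serialization failed for: ", smiles)
  out
}
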