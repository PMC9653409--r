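# Internal molecular-graph substrate. Open Babel produces a kekulized
# V2000 molfile from a canonical SMILES with the heavy-atom order of the
# SMILES preserved; the graph (elements, bonds, charges, ring
# perception, aromatic flags from the SMILES tokens) feeds scaffold
# extraction and graph-based descriptors.

mol_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  mf <- suppressWarnings(suppressMessages(
    tryCatch(ChemmineOB::convertFormat("SMI", "MOL", smiles),
             error = function(e) "")))
  if (!nzchar(mf)) stop2("cannot build molecular graph for: ", smiles)
  lines <- strsplit(mf, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[4 + seq_len(n_atoms)]
  elem <- trimws(substr(atom_lines, 32, 34))
  bonds <- if (n_bonds > 0) {
    bl <- lines[4 + n_atoms + seq_len(n_bonds)]
    data.frame(a1 = as.integer(substr(bl, 1, 3)),
               a2 = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)))
  } else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  # formal charges: old-style atom-line code (3 -> +1, 5 -> -1, ...)
  # overridden by M  CHG property lines when present
  code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  code[is.na(code)] <- 0L
  charge <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)[code + 1L]
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge <- integer(n_atoms)
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      k <- f[1]
      for (i in seq_len(k)) charge[f[2 * i]] <- f[2 * i + 1]
    }
  }
  # aromatic flags come from the SMILES tokens; verify the element
  # sequence so the token/molfile correspondence is never silently wrong
  toks <- tokenize_smiles(smiles)
  at <- toks[is_atom_token(toks)]
  tok_elem <- token_element(at)
  heavy <- tok_elem != "H"
  arom <- rep(FALSE, n_atoms)
  if (sum(heavy) == n_atoms && all(tok_elem[heavy] == elem)) {
    arom <- token_aromatic(at)[heavy]
  } else if (length(at) == n_atoms && all(tok_elem == elem)) {
    arom <- token_aromatic(at)
  } else {
    stop2("atom order mismatch between SMILES and molfile for: ", smiles)
  }
  deg <- tabulate(c(bonds$a1, bonds$a2), nbins = n_atoms)
  ring_bond <- ring_bond_flags(n_atoms, bonds)
  ring_atom <- rep(FALSE, n_atoms)
  if (any(ring_bond))
    ring_atom[unique(c(bonds$a1[ring_bond], bonds$a2[ring_bond]))] <- TRUE
  list(smiles = smiles, n = n_atoms, elem = elem, charge = charge,
       arom = arom, bonds = bonds, degree = deg,
       ring_bond = ring_bond, ring_atom = ring_atom)
}

# Ring bonds are the non-bridge edges of the molecular graph.
ring_bond_flags <- function(n_atoms, bonds) {
  if (!nrow(bonds)) return(logical(0))
  g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
  if (igraph::vcount(g) < n_atoms)
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  br <- igraph::bridges(g)
  flags <- rep(TRUE, nrow(bonds))
  flags[as.integer(br)] <- FALSE
  flags
}

# Number of smallest rings (cycle rank) of the whole graph.
n_rings <- function(g) {
  nrow(g$bonds) - g$n + n_components(g)
}

n_components <- function(g) {
  if (!nrow(g$bonds)) return(g$n)
  ig <- igraph::graph_from_edgelist(cbind(g$bonds$a1, g$bonds$a2),
                                    directed = FALSE)
  if (igraph::vcount(ig) < g$n)
    ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
  igraph::components(ig)$no
}

# Serialize a (sub)graph back to a V2000 molfile. Coordinates are zero;
# Open Babel only needs the connection table to emit canonical SMILES.
write_molfile <- function(elem, bonds, charge = NULL) {
  n_atoms <- length(elem)
  header <- c("", " molcrnn", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      n_atoms, nrow(bonds)))
  atoms <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   elem)
  bl <- if (nrow(bonds))
    sprintf("%3d%3d%3d  0", bonds$a1, bonds$a2, bonds$order) else character(0)
  chg <- character(0)
  if (!is.null(charge) && any(charge != 0)) {
    idx <- which(charge != 0)
    # at most 8 entries per M CHG line
    for (grp in split(idx, ceiling(seq_along(idx) / 8))) {
      chg <- c(chg, paste0("M  CHG", sprintf("%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp, charge[grp]),
                                  collapse = "")))
    }
  }
  paste(c(header, atoms, bl, chg, "M  END", ""), collapse = "\n")
}

molfile_to_smiles <- function(molfile) {
  out <- suppressWarnings(suppressMessages(
    tryCatch(ChemmineOB::convertFormat("MOL", "CAN", molfile),
             error = function(e) "")))
  strip_title(out)
}
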