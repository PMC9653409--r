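# Descriptor layer. MW, logP, TPSA, HBD and HBA come from Open Babel;
# rotatable bonds, aromatic ring counts and the Bertz-style complexity
# index are computed on the internal molecular graph; QED, estimated
# aqueous solubility (ESOL) and the synthetic-accessibility estimate are
# authored here (see the methods vignette for their exact definitions).

ob_mols <- function(smiles) {
  suppressWarnings(suppressMessages(
    ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                           identity)))
}

ob_props <- function(smiles) {
  mols <- ob_mols(smiles)
  do.call(rbind, lapply(mols, function(m)
    suppressWarnings(ChemmineOB::prop_OB(m))))
}

#' Structural alert patterns
#'
#' The package's curated set of reactive / toxicophoric substructure
#' patterns (SMARTS), used for post-generation filtering and as the
#' alert term of the QED estimate. Users may supply their own table of
#' the same shape (columns `name`, `smarts`) anywhere an `alerts`
#' argument is accepted.
#'
#' @return data frame with columns `name` and `smarts`.
#' @export
default_alerts <- function() {
  path <- system.file("extdata", "structural_alerts.tsv",
                      package = "molcrnn", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "",
                    quote = "")
}

#' Count structural-alert matches
#'
#' @param smiles character vector of standardized SMILES.
#' @param alerts alert table as from [default_alerts()].
#' @return integer vector: for each molecule, the number of alert
#'   patterns with at least one substructure match.
#' @export
alert_counts <- function(smiles, alerts = default_alerts()) {
  if (!length(smiles)) return(integer(0))
  mols <- ob_mols(smiles)
  if (length(mols) != length(smiles))
    stop2("alert matching: molecule parsing misaligned")
  hits <- matrix(0L, nrow = length(smiles), ncol = nrow(alerts))
  for (k in seq_len(nrow(alerts))) {
    n <- suppressWarnings(ChemmineOB::smartsSearch_OB(mols, alerts$smarts[k]))
    hits[, k] <- as.integer(n > 0)
  }
  as.integer(rowSums(hits))
}

# Rotatable bonds: acyclic single bonds between two non-terminal heavy
# atoms, excluding amide C-N bonds.
count_rotatable <- function(g) {
  b <- g$bonds
  if (!nrow(b)) return(0L)
  cand <- b$order == 1L & !g$ring_bond &
    g$degree[b$a1] >= 2L & g$degree[b$a2] >= 2L
  if (!any(cand)) return(0L)
  # amide: C(=O)-N
  carbonyl <- rep(FALSE, g$n)
  co <- b$order == 2L &
    ((g$elem[b$a1] == "C" & g$elem[b$a2] == "O") |
     (g$elem[b$a2] == "C" & g$elem[b$a1] == "O"))
  carbonyl[c(b$a1[co & g$elem[b$a1] == "C"],
             b$a2[co & g$elem[b$a2] == "C"])] <- TRUE
  amide <- (g$elem[b$a1] == "N" & carbonyl[b$a2]) |
           (g$elem[b$a2] == "N" & carbonyl[b$a1])
  sum(cand & !amide)
}

# Number of aromatic rings: cycle rank of the subgraph of aromatic ring
# bonds (both endpoints aromatic).
count_aromatic_rings <- function(g) {
  b <- g$bonds
  sel <- g$ring_bond & g$arom[b$a1] & g$arom[b$a2]
  if (!any(sel)) return(0L)
  verts <- unique(c(b$a1[sel], b$a2[sel]))
  ig <- igraph::graph_from_edgelist(
    cbind(match(b$a1[sel], verts), match(b$a2[sel], verts)),
    directed = FALSE)
  as.integer(sum(sel) - length(verts) + igraph::components(ig)$no)
}

# Bertz-style topological complexity: bond-connectivity information
# (over classes of atoms with equal element / valence-degree / aromatic
# state) plus element-distribution information. See the vignette for
# the formula; this is a documented in-package variant, not a clone of
# any particular toolkit's implementation.
bertz_ct <- function(g) {
  if (!nrow(g$bonds)) return(0)
  ki <- vapply(seq_len(g$n), function(a) {
    sum(g$bonds$order[g$bonds$a1 == a | g$bonds$a2 == a])
  }, numeric(1))
  conn <- choose(ki, 2)
  N <- sum(conn)
  cls <- paste(g$elem, ki, g$arom)
  n_i <- tapply(conn, cls, sum)
  n_i <- n_i[n_i > 0]
  c_bond <- if (N > 0) 2 * N * log2(N) - sum(n_i * log2(n_i)) else 0
  tab <- table(g$elem)
  p <- as.numeric(tab) / g$n
  c_elem <- -g$n * sum(p * log2(p))
  c_bond + c_elem
}

# ESOL estimated aqueous solubility, log10(mol/L).
esol_logs <- function(logp, mw, rotb, arom_prop) {
  0.16 - 0.63 * logp - 0.0062 * mw + 0.066 * rotb - 0.74 * arom_prop
}

# --- QED ------------------------------------------------------------------
# Quantitative estimate of drug-likeness: geometric mean of eight
# asymmetric-double-sigmoid desirability functions with the published
# parameterization; property inputs are this package's descriptor layer
# (Open Babel logP etc.), so absolute values can differ slightly from
# other toolkits.

.qed_ads <- data.frame(
  prop = c("MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM", "ALERTS"),
  a = c(2.817065973, 3.172690585, 2.948620388, 1.618662227, 1.876861559,
        0.010000000, 3.217788970, 0.010000000),
  b = c(392.5754953, 137.8624751, 160.4605972, 1010.051101, 125.2232657,
        272.4121427, 957.7374108, 1199.094025),
  c = c(290.7489764, 2.534937431, 3.615294657, 0.985094388, 62.90773554,
        2.558379970, 2.274627939, -0.09002593),
  d = c(2.419764353, 4.581497897, 4.435986202, 1e-12, 87.83366614,
        1.565547684, 1e-12, 1e-12),
  e = c(49.22325677, 0.822739154, 0.290141953, 0.713820843, 12.01999824,
        1.271567166, 1.317690384, 0.185904477),
  f = c(65.37051707, 0.576295591, 1.300669958, 0.920922555, 28.51324732,
        2.758063707, 0.375760881, 0.875193782),
  dmax = c(104.9805561, 131.3186604, 148.7763046, 258.1632616, 104.5686167,
           105.4420403, 312.3372610, 417.7253140))

.qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

qed_desirability <- function(x, p) {
  v <- p$a + p$b / (1 + exp(-(x - p$c + p$d / 2) / p$e)) *
    (1 - 1 / (1 + exp(-(x - p$c - p$d / 2) / p$f)))
  pmin(pmax(v / p$dmax, 1e-6), 1)
}

qed_score <- function(mw, alogp, hba, hbd, psa, rotb, arom, alerts,
                      weights = .qed_weights) {
  vals <- c(MW = mw, ALOGP = alogp, HBA = hba, HBD = hbd, PSA = psa,
            ROTB = rotb, AROM = arom, ALERTS = alerts)
  d <- vapply(seq_len(nrow(.qed_ads)), function(i)
    qed_desirability(vals[[.qed_ads$prop[i]]], .qed_ads[i, ]), numeric(1))
  w <- weights[.qed_ads$prop]
  exp(sum(w * log(d)) / sum(w))
}

#' Molecular descriptors for drug-likeness analysis
#'
#' Computes the ten descriptors used throughout the package:
#' molecular weight (`mw`, g/mol), octanol-water partition coefficient
#' (`logp`), drug-likeness (`qed`, 0-1), synthetic-accessibility
#' estimate (`sa`, 1 easy to 10 hard), Bertz-style complexity
#' (`bertz_ct`), topological polar surface area (`tpsa`, A^2),
#' estimated aqueous solubility (`logs`, log10 mol/L), rotatable bonds
#' (`rot`), H-bond donors (`hbd`) and acceptors (`hba`). Calculation is
#' deterministic; molecules for which a descriptor cannot be computed
#' are flagged in the `desc_status` column instead of raising.
#'
#' @param mols standardized molecule data frame (from
#'   [standardize_smiles()], `status == "ok"`) or a character vector of
#'   canonical SMILES.
#' @param alerts alert table used by the QED alert term.
#' @return data frame: `id`, `smiles`, the ten descriptor columns in
#'   the fixed order above, and `desc_status` (`ok` or a reason).
#' @export
calc_descriptors <- function(mols, alerts = default_alerts()) {
  if (is.data.frame(mols)) {
    if (!is.null(mols$status) && any(mols$status != "ok"))
      stop2("calc_descriptors expects only records with status == 'ok'")
    smiles <- mols$smiles
    id <- mols$id %||% paste0("mol_", seq_along(smiles))
  } else {
    smiles <- mols
    id <- paste0("mol_", seq_along(smiles))
  }
  stopifnot(length(smiles) >= 1L)
  props <- ob_props(smiles)
  if (nrow(props) != length(smiles))
    stop2("descriptor calculation misaligned with input")
  n_alert <- alert_counts(smiles, alerts)
  out <- lapply(seq_along(smiles), function(i) {
    tryCatch({
      g <- mol_graph(smiles[i])
      rot <- count_rotatable(g)
      arom_rings <- count_aromatic_rings(g)
      arom_prop <- if (g$n > 0) mean(g$arom) else 0
      mw <- props$MW[i]; logp <- props$logP[i]; tpsa <- props$TPSA[i]
      hbd <- props$HBD[i]; hba <- props$HBA1[i]
      data.frame(
        mw = mw, logp = logp,
        qed = qed_score(mw, logp, hba, hbd, tpsa, rot, arom_rings,
                        n_alert[i]),
        sa = sa_score(smiles[i], g = g),
        bertz_ct = bertz_ct(g), tpsa = tpsa,
        logs = esol_logs(logp, mw, rot, arom_prop),
        rot = as.integer(rot), hbd = as.integer(hbd),
        hba = as.integer(hba), desc_status = "ok",
        stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(mw = NA_real_, logp = NA_real_, qed = NA_real_,
                 sa = NA_real_, bertz_ct = NA_real_, tpsa = NA_real_,
                 logs = NA_real_, rot = NA_integer_, hbd = NA_integer_,
                 hba = NA_integer_,
                 desc_status = paste("failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  })
  cbind(data.frame(id = id, smiles = smiles, stringsAsFactors = FALSE),
        do.call(rbind, out))
}
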