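# File interfaces: .smi (one SMILES per line, optional TAB + id), SDF
# via Open Babel, descriptor tables as CSV with a fixed column order.

#' Read raw SMILES records from a .smi file
#'
#' One molecule per line; an optional TAB-separated second field is the
#' record identifier.
#'
#' @param path file path.
#' @return data frame `text`, `id`, `source_line` (raw records; pass
#'   through [standardize_smiles()] before use).
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) stop2("no records in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  text <- vapply(parts, `[[`, character(1), 1)
  id <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("mol_", i),
    character(1))
  if (anyDuplicated(id))
    stop2("duplicate record identifiers in ", path)
  data.frame(text = trimws(text), id = id,
             source_line = which(keep), stringsAsFactors = FALSE)
}

#' Write molecules to a .smi file
#'
#' @param mols standardized molecule data frame (columns `smiles`,
#'   `id`) or SMILES vector.
#' @param path file path.
#' @export
write_smi <- function(mols, path) {
  if (is.data.frame(mols)) {
    writeLines(paste(mols$smiles, mols$id, sep = "\t"), path)
  } else writeLines(mols, path)
  invisible(path)
}

#' Read molecules from an SDF file
#'
#' Converts records to SMILES via Open Babel and returns raw records
#' ready for [standardize_smiles()].
#'
#' @param path SDF file path (V2000/V3000).
#' @return data frame `text`, `id`, `source_line`.
#' @export
read_sdf <- function(path) {
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp))
  suppressWarnings(suppressMessages(
    ChemmineOB::convertFormatFile("SDF", "SMI", path, tmp)))
  read_smi(tmp)
}

#' Write molecules to an SDF file
#'
#' @param mols standardized molecule data frame or SMILES vector.
#' @param path output path.
#' @export
write_sdf <- function(mols, path) {
  smiles <- if (is.data.frame(mols)) mols$smiles else mols
  id <- if (is.data.frame(mols) && !is.null(mols$id)) mols$id
        else paste0("mol_", seq_along(smiles))
  tmp <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp))
  writeLines(paste(smiles, id, sep = "\t"), tmp)
  suppressWarnings(suppressMessages(
    ChemmineOB::convertFormatFile("SMI", "SDF", tmp, path)))
  invisible(path)
}

#' Write a generated library with its accounting sidecar
#'
#' Writes the kept molecules as SDF and `.smi`, plus a JSON sidecar
#' holding the attempt counters and the sampling configuration.
#'
#' @param gset a `generated_set` from [build_library()].
#' @param prefix output path prefix (writes `<prefix>.sdf`,
#'   `<prefix>.smi`, `<prefix>.json`).
#' @export
write_generated_set <- function(gset, prefix) {
  stopifnot(inherits(gset, "generated_set"))
  if (nrow(gset$molecules)) {
    write_sdf(gset$molecules, paste0(prefix, ".sdf"))
    write_smi(gset$molecules, paste0(prefix, ".smi"))
  }
  jsonlite::write_json(list(counters = gset$counters,
                            config = unclass(gset$config)),
                       paste0(prefix, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(prefix)
}

#' Write a descriptor table as CSV
#'
#' Fixed column order: `id`, `smiles`, `mw`, `logp`, `qed`, `sa`,
#' `bertz_ct`, `tpsa`, `logs`, `rot`, `hbd`, `hba`, `desc_status`.
#'
#' @param desc data frame from [calc_descriptors()].
#' @param path output path.
#' @export
write_descriptors <- function(desc, path) {
  cols <- c("id", "smiles", "mw", "logp", "qed", "sa", "bertz_ct",
            "tpsa", "logs", "rot", "hbd", "hba", "desc_status")
  utils::write.csv(desc[, cols], path, row.names = FALSE)
  invisible(path)
}
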