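# Parsing binding-pocket structure files (PDB ATOM/HETATM records) into
# atom tables, plus the residue-level property table that supplies the
# hydrophobicity / charge / binding-probability feature channels.

# Bondi van der Waals radii (Angstrom) used by the SASA calculation.
PG_VDW <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
            F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)
PG_VDW_DEFAULT <- 1.70

#' Parse a pocket structure (PDB text) into an atom table
#'
#' Reads ATOM/HETATM records, drops hydrogens, keeps the first alternate
#' location and renumbers residues consecutively in order of appearance.
#'
#' @param text PDB-format content: a single string or a character vector of
#'   lines. Use [read_pocket()] for a file path.
#' @return A data.frame of class `pocket_atoms` with columns `atom_index`,
#'   `element`, `atom_name`, `residue_name`, `residue_index`, `x`, `y`, `z`.
#' @export
parse_pocket <- function(text) {
  pg_assert(is.character(text) && length(text) >= 1, "text must be character")
  lines <- if (length(text) == 1 && grepl("\n", text)) strsplit(text, "\n")[[1]] else text
  rec <- grepl("^(ATOM  |HETATM)", lines)
  pg_assert(any(rec), "no ATOM/HETATM records found in pocket file")
  # pre-validate coordinate fields so malformed lines are reported by number
  for (ln in which(rec)) {
    coords <- c(substr(lines[ln], 31, 38), substr(lines[ln], 39, 46),
                substr(lines[ln], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      pg_stop("malformed coordinate field on line ", ln, ": '", lines[ln], "'")
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
  at <- pdb$atom
  # first alternate location only
  keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep_alt, , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  guess <- function(name) {
    nm <- gsub("[0-9' ]", "", name)
    two <- substr(toupper(nm), 1, 2)
    if (two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"))
      return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
    substr(toupper(nm), 1, 1)
  }
  miss <- is.na(elem) | !nzchar(elem)
  if (any(miss)) elem[miss] <- vapply(at$elety[miss], guess, character(1))
  elem <- ifelse(nchar(elem) == 2,
                 paste0(substr(elem, 1, 1), tolower(substr(elem, 2, 2))), elem)
  heavy <- !(elem %in% c("H", "D"))
  pg_assert(any(heavy), "pocket contains no non-hydrogen atoms")
  at <- at[heavy, , drop = FALSE]
  elem <- elem[heavy]
  pg_assert(all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)),
            "non-finite coordinates in pocket file")
  res_key <- paste(at$chain, at$resno, at$insert)
  res_idx <- as.integer(factor(res_key, levels = unique(res_key)))
  out <- data.frame(
    atom_index = seq_len(nrow(at)),
    element = elem,
    atom_name = trimws(at$elety),
    residue_name = toupper(trimws(at$resid)),
    residue_index = res_idx,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  class(out) <- c("pocket_atoms", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname parse_pocket
#' @param path path to a PDB file.
#' @export
read_pocket <- function(path) {
  pg_assert(file.exists(path), "pocket file not found: ", path)
  parse_pocket(readLines(path, warn = FALSE))
}

pocket_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

#' Residue-level property table
#'
#' Loads the per-residue-type scalars broadcast to all atoms of a residue
#' during featurization: Kyte-Doolittle hydrophobicity, formal side-chain
#' charge (elementary charges at physiological pH) and a binding-site
#' propensity in [0, 1]. The bundled defaults cover the 20 standard amino
#' acids plus an explicit `UNK` row (all zeros) to which unknown residue
#' types resolve; the file is a plain TSV so the scales can be swapped.
#'
#' @param path optional path to a replacement TSV with columns `residue`,
#'   `hydrophobicity`, `charge`, `binding_probability`.
#' @return data.frame keyed by 3-letter residue code.
#' @export
residue_property_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "residue_properties.tsv", package = "pocketgen")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "hydrophobicity", "charge", "binding_probability")
  pg_assert(all(need %in% names(tab)),
            "property table must have columns: ", paste(need, collapse = ", "))
  pg_assert("UNK" %in% tab$residue, "property table must contain an UNK row")
  rownames(tab) <- tab$residue
  tab
}

# Read a per-residue profile file (TSV: residue_index, entropy).
read_profile <- function(path) {
  pg_assert(file.exists(path), "profile file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pg_assert(all(c("residue_index", "entropy") %in% names(tab)),
            "profile file must have columns residue_index, entropy")
  tab
}

#' Read a pocket-to-ligand pairing file
#'
#' @param path TSV with columns `pocket_id`, `smiles`.
#' @return data.frame with those two columns.
#' @export
read_pairing <- function(path) {
  pg_assert(file.exists(path), "pairing file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pg_assert(all(c("pocket_id", "smiles") %in% names(tab)),
            "pairing file must have columns pocket_id, smiles")
  tab
}
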