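# Interface to OpenBabel for molecule canonicalization, kekulization and
# fingerprints. Everything goes through the obabel executable in batch (one
# short-lived process per call, arbitrarily many molecules), which keeps the
# R session's memory flat no matter how many molecules are processed.

obabel_path <- function() {
  p <- Sys.which("obabel")
  pg_assert(nzchar(p), "the 'obabel' executable is required but was not found on PATH")
  p
}

# Batch-convert SMILES with obabel. Returns a character vector aligned with
# `smiles`; molecules obabel drops come back as NA. `out_opts` are output
# format options (e.g. "k" for Kekule form).
obabel_convert <- function(smiles, out_format = "can", out_opts = character()) {
  if (length(smiles) == 0) return(character())
  pg_assert(!any(grepl("[[:space:]]", smiles)), "SMILES strings must not contain whitespace")
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), infile)
  args <- c("-ismi", infile, paste0("-o", out_format))
  for (o in out_opts) args <- c(args, paste0("-x", o))
  out <- suppressWarnings(system2(obabel_path(), args, stdout = TRUE, stderr = FALSE))
  res <- rep(NA_character_, length(smiles))
  if (length(out)) {
    parts <- strsplit(out, "[ \t]+")
    for (p in parts) {
      if (length(p) >= 2) {
        i <- suppressWarnings(as.integer(p[[2]]))
        if (!is.na(i) && i >= 1 && i <= length(smiles)) res[i] <- p[[1]]
      }
    }
  }
  res
}

#' Canonical SMILES form of molecules
#'
#' Returns the canonical SMILES string used as the molecule identity
#' throughout the package: generated-sample deduplication, frequency
#' ranking, label-recovery checks and round-trip tests all compare
#' molecules by this form.
#'
#' @param smiles character vector of SMILES strings (no whitespace).
#' @return Character vector of canonical SMILES, `NA` where a string could
#'   not be interpreted as a molecule.
#' @examples
#' \donttest{
#' canonical_smiles(c("OCC", "CCO"))  # same molecule, same canonical form
#' }
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character())
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (any(ok)) out[ok] <- obabel_convert(smiles[ok], "can")
  out
}

# Kekulized SMILES (aromatic rings written with alternating single/double
# bonds, uppercase atoms). The SELFIES grammar works on Kekule structures.
kekulize_smiles <- function(smiles) {
  obabel_convert(smiles, "smi", out_opts = "k")
}

# Lookup table: hex digit -> 4 bits.
HEX_BITS <- local({
  m <- matrix(FALSE, 16, 4)
  for (v in 0:15) m[v + 1, ] <- as.logical(bitwAnd(v, c(8L, 4L, 2L, 1L)))
  rownames(m) <- c(0:9, letters[1:6])
  m
})

# ECFP-family binary fingerprints through the obabel fingerprint (fpt)
# format, one batched call per request. Returns a logical matrix, one row
# per molecule. Unparseable molecules raise an error.
morgan_fingerprints <- function(smiles, fp_name = "ECFP4") {
  pg_assert(length(smiles) >= 1, "need at least one molecule")
  bad <- is.na(smiles) | !nzchar(smiles)
  pg_assert(!any(bad), "cannot fingerprint empty/NA molecule string(s): index ",
            paste(which(bad), collapse = ", "))
  for (s in unique(smiles)) check_smiles_syntax(s)
  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), infile)
  out <- suppressWarnings(system2(
    obabel_path(), c("-ismi", infile, "-ofpt", paste0("-xf", fp_name), "-xh"),
    stdout = TRUE, stderr = FALSE))
  starts <- grep("^>", out)
  pg_assert(length(starts) == length(smiles),
            "fingerprinting failed: OpenBabel returned ", length(starts),
            " of ", length(smiles), " fingerprints")
  ends <- c(starts[-1] - 1L, length(out))
  res <- NULL
  for (k in seq_along(starts)) {
    id <- as.integer(sub("^>([0-9]+).*", "\\1", out[starts[k]]))
    # fpt blocks may interleave annotation lines (e.g. Tanimoto comparisons);
    # the fingerprint itself is the sequence of 8-hex-digit words
    pg_assert(ends[k] > starts[k], "missing fingerprint data for molecule ", id)
    block <- paste(out[(starts[k] + 1L):ends[k]], collapse = " ")
    words <- regmatches(block, gregexpr("\\b[0-9a-f]{8}\\b", block))[[1]]
    hex <- paste(words, collapse = "")
    bits <- as.logical(t(HEX_BITS[strsplit(hex, "")[[1]], , drop = FALSE]))
    if (is.null(res)) res <- matrix(FALSE, length(smiles), length(bits))
    pg_assert(length(bits) == ncol(res), "inconsistent fingerprint width")
    res[id, ] <- bits
  }
  res
}
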