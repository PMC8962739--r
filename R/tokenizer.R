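# Vocabulary over SELFIES tokens plus the special tokens <pad> (index 0) and
# <eos> (index 1), and conversion between molecule strings and padded index
# batches. Indices are 0-based throughout the public interface (pad = 0,
# eos = 1); internal matrix code adds 1 where R indexing requires it.

PG_PAD <- 0L
PG_EOS <- 1L

#' Build a token vocabulary from a molecule corpus
#'
#' The vocabulary is the union of all SELFIES tokens occurring in the corpus
#' plus the specials `<pad>` (index 0) and `<eos>` (index 1). Chemical tokens
#' are indexed in sorted order, so the result depends only on the corpus as a
#' set of molecules, not on its order.
#'
#' @param corpus character vector of SMILES strings (all must be valid).
#' @return An object of class `pg_vocab`: list with `token_to_index` (named
#'   integer, 0-based), `index_to_token` (character, position = index + 1)
#'   and `size`.
#' @export
build_vocab <- function(corpus) {
  pg_assert(length(corpus) >= 1, "corpus must contain at least one molecule")
  toks <- unique(unlist(lapply(corpus, smiles_to_tokens)))
  toks <- sort(toks, method = "radix")
  all_tokens <- c("<pad>", "<eos>", toks)
  idx <- seq_along(all_tokens) - 1L
  names(idx) <- all_tokens
  structure(list(token_to_index = idx, index_to_token = all_tokens,
                 size = length(all_tokens)),
            class = "pg_vocab")
}

#' @export
print.pg_vocab <- function(x, ...) {
  cat("<pg_vocab> ", x$size, " tokens (", x$size - 2L, " chemical + 2 special)\n",
      sep = "")
  invisible(x)
}

#' Write / read a vocabulary as JSON
#'
#' The file maps each token to its 0-based index (`{"<pad>": 0, ...}`).
#'
#' @param vocab a `pg_vocab`.
#' @param path JSON file path.
#' @return `read_vocab` returns the `pg_vocab`.
#' @export
write_vocab <- function(vocab, path) {
  jsonlite::write_json(as.list(vocab$token_to_index), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  idx <- unlist(jsonlite::read_json(path))
  pg_assert(identical(sort(unname(idx)), seq_along(idx) - 1L) ||
              all(sort(unname(idx)) == seq_along(idx) - 1),
            "vocabulary file indices must be 0..V-1")
  pg_assert(idx[["<pad>"]] == 0 && idx[["<eos>"]] == 1,
            "vocabulary file must fix <pad> = 0 and <eos> = 1")
  ord <- order(idx)
  structure(list(token_to_index = stats::setNames(as.integer(idx), names(idx)),
                 index_to_token = names(idx)[ord], size = length(idx)),
            class = "pg_vocab")
}

# TokenSequence: 0-based index vector ending in <eos> when terminated.
new_token_sequence <- function(indices, terminated) {
  structure(list(indices = as.integer(indices), terminated = isTRUE(terminated)),
            class = "pg_tokenseq")
}

#' Encode a molecule into a terminated index sequence
#'
#' @param smiles a single SMILES string.
#' @param vocab a `pg_vocab`.
#' @return A `pg_tokenseq`: 0-based vocabulary indices ending with `<eos>`.
#' @export
encode_molecule <- function(smiles, vocab) {
  toks <- smiles_to_tokens(smiles)
  idx <- vocab$token_to_index[toks]
  if (anyNA(idx)) {
    missing <- unique(toks[is.na(idx)])
    pg_stop("token(s) not in vocabulary: ", paste(missing, collapse = ", "))
  }
  new_token_sequence(c(unname(idx), PG_EOS), terminated = TRUE)
}

#' Decode an index sequence back to a molecule string
#'
#' Reads tokens up to the first `<eos>` (padding ignored) and derives the
#' molecule through the SELFIES grammar; by construction this never fails on
#' in-range indices. An empty derivation returns `""` flagged with attribute
#' `empty = TRUE`.
#'
#' @param seq a `pg_tokenseq` or integer vector of 0-based indices.
#' @param vocab a `pg_vocab`.
#' @return A SMILES string (possibly empty, see above).
#' @export
decode_molecule <- function(seq, vocab) {
  idx <- if (inherits(seq, "pg_tokenseq")) seq$indices else as.integer(seq)
  pg_assert(all(idx >= 0 & idx < vocab$size), "index out of vocabulary range")
  eos_at <- which(idx == PG_EOS)
  if (length(eos_at)) idx <- idx[seq_len(eos_at[1] - 1L)]
  idx <- idx[idx != PG_PAD]
  if (!length(idx)) return(structure("", empty = TRUE))
  tokens_to_smiles(vocab$index_to_token[idx + 1L])
}

#' Pad a batch of token sequences into a rectangular index matrix
#'
#' @param seqs list of `pg_tokenseq` objects (each terminated with `<eos>`).
#' @param max_len maximum row length.
#' @param truncate if `FALSE` (training), overlong sequences are an error;
#'   if `TRUE` (inference), they are clipped and flagged.
#' @return List with `indices` (n x max_len integer matrix, 0-based,
#'   right-padded with `<pad>`), `lengths` (padding excluded, `<eos>`
#'   included) and `truncated` (logical vector).
#' @export
pad_batch <- function(seqs, max_len, truncate = FALSE) {
  pg_assert(length(seqs) >= 1, "empty batch")
  mat <- matrix(PG_PAD, nrow = length(seqs), ncol = max_len)
  lens <- integer(length(seqs))
  trunc <- logical(length(seqs))
  for (k in seq_along(seqs)) {
    idx <- if (inherits(seqs[[k]], "pg_tokenseq")) seqs[[k]]$indices
           else as.integer(seqs[[k]])
    if (length(idx) > max_len) {
      if (!truncate)
        pg_stop("sequence ", k, " has length ", length(idx),
                " > max_len = ", max_len)
      idx <- c(idx[seq_len(max_len - 1L)], PG_EOS)
      trunc[k] <- TRUE
    }
    mat[k, seq_along(idx)] <- idx
    lens[k] <- length(idx)
  }
  list(indices = mat, lengths = lens, truncated = trunc)
}

# Inverse of pad_batch for round-trip checks.
unpad_batch <- function(padded) {
  lapply(seq_len(nrow(padded$indices)), function(k) {
    idx <- padded$indices[k, seq_len(padded$lengths[k])]
    new_token_sequence(idx, terminated = idx[length(idx)] == PG_EOS)
  })
}
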