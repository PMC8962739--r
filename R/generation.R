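# Batch sampling from a trained model for a target pocket, canonical
# deduplication, frequency ranking and top-k selection. Sampling is
# vectorized across the batch: every sequence in a batch advances one GRU
# step at a time as one matrix operation.

# Vectorized multinomial draw: one category per row of a probability matrix.
row_multinomial <- function(probs) {
  cs <- probs %*% upper.tri(diag(ncol(probs)), diag = TRUE)
  u <- stats::runif(nrow(probs))
  as.integer(rowSums(cs < u) + 1L)
}

# Sample `n` token sequences in one vectorized pass. Returns a list of
# 0-based index vectors plus a terminated flag vector.
sample_sequences_batch <- function(embedding, model, n, max_len, temperature = 1) {
  cfg <- model$decoder_config
  P <- model$params
  x0 <- ad_val(decoder_step0_input(matrix(as.numeric(embedding), 1), P))
  x <- matrix(x0, nrow = n, ncol = ncol(x0), byrow = TRUE)
  hs <- decoder_init_hidden(cfg, n_rows = n)
  toks <- matrix(PG_PAD, n, max_len)
  active <- seq_len(n)            # rows still emitting; shrinks as rows finish
  lens <- integer(n)
  for (t in seq_len(max_len)) {
    st <- decoder_step(x, hs, P, cfg)
    hs <- st$hs
    probs <- masked_softmax(st$logits, temperature)
    tok <- row_multinomial(probs) - 1L
    toks[cbind(active, t)] <- tok
    lens[active] <- t
    keep <- tok != PG_EOS
    if (!any(keep)) break
    if (!all(keep)) {
      active <- active[keep]
      hs <- lapply(hs, function(h) h[keep, , drop = FALSE])
      tok <- tok[keep]
    }
    if (t == max_len) break
    x <- P[["dec.emb"]][tok + 1L, , drop = FALSE]
  }
  list(indices = lapply(seq_len(n), function(k) toks[k, seq_len(lens[k])]),
       terminated = vapply(seq_len(n), function(k) toks[k, lens[k]] == PG_EOS,
                           logical(1)))
}

#' Sample a batch of molecules for a target pocket
#'
#' Draws `n_total` sequences from the trained model in batches of
#' `batch_size`, decodes them through the SELFIES grammar and
#' canonicalizes. Non-terminated (truncated) samples are excluded from the
#' returned multiset but counted in attributes.
#'
#' @param pocket a `pocket_graph`.
#' @param model a trained `pg_model`.
#' @param n_total number of molecules to sample.
#' @param batch_size sequences per vectorized batch (default 2048).
#' @param seed RNG seed; the full multiset is reproducible under it.
#' @param temperature sampling temperature.
#' @return Character vector of `n_total - truncated` canonical SMILES with
#'   attributes `truncated_count`, `empty_count` and `n_batches`.
#' @export
sample_batch <- function(pocket, model, n_total, batch_size = 2048, seed = 1L,
                         temperature = 1) {
  pg_assert(n_total >= 1, "n_total must be >= 1")
  emb <- model_embedding(pocket, model)
  max_len <- model$decoder_config$max_len
  sizes <- rep(batch_size, n_total %/% batch_size)
  if (n_total %% batch_size) sizes <- c(sizes, n_total %% batch_size)
  out <- vector("list", length(sizes))
  n_trunc <- 0L
  with_seed(derive_seed(seed, "sample-batch"), {
    for (b in seq_along(sizes)) {
      res <- sample_sequences_batch(emb, model, sizes[b], max_len, temperature)
      keep <- res$terminated
      n_trunc <- n_trunc + sum(!keep)
      out[[b]] <- vapply(res$indices[keep], function(idx)
        as.character(decode_molecule(idx, model$vocab)), character(1))
    }
  })
  raw <- unlist(out)
  empty <- !nzchar(raw)
  raw <- raw[!empty]
  # canonicalize through the dedup table (one OpenBabel call per unique string)
  uniq <- unique(raw)
  can <- canonical_smiles(uniq)
  pg_assert(!anyNA(can), "a sampled molecule failed canonicalization")
  res <- unname(can[match(raw, uniq)])
  structure(res, truncated_count = n_trunc, empty_count = sum(empty),
            n_batches = length(sizes))
}

#' Frequency-rank a multiset of sampled molecules
#'
#' Groups canonical strings, sorts by frequency (descending) with
#' deterministic lexicographic tie-breaking, and assigns ranks 1, 2, ...
#'
#' @param samples character vector of canonical SMILES (a multiset).
#' @return data.frame with columns `rank`, `smiles`, `frequency`.
#' @export
frequency_rank <- function(samples) {
  pg_assert(length(samples) >= 1, "empty sample multiset")
  tab <- table(samples)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  data.frame(rank = seq_along(ord),
             smiles = names(tab)[ord],
             frequency = as.integer(tab)[ord],
             stringsAsFactors = FALSE)
}

#' Top-k most frequent molecules
#'
#' @param ranked output of [frequency_rank()].
#' @param k number of entries to keep (default 100).
#' @return The first `min(k, nrow)` rows.
#' @export
top_k <- function(ranked, k = 100) {
  pg_assert(k >= 0, "k must be nonnegative")
  ranked[seq_len(min(k, nrow(ranked))), , drop = FALSE]
}

#' Write / read a ranked sample table
#'
#' @param ranked data.frame from [frequency_rank()].
#' @param path TSV path.
#' @export
write_samples <- function(ranked, path) {
  utils::write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
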