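# Dataset assembly (pairing, synthetic-accessibility filter, seeded split)
# and the end-to-end optimization loop with checkpointing.

#' Filter records by synthetic-accessibility score
#'
#' Keeps records with 1 < SA < 6; low-complexity (SA <= 1) and
#' high-complexity (SA >= 6) compounds are removed, boundaries included.
#' Scoring is pluggable: pass precomputed scores or a scoring function.
#'
#' @param records data.frame with columns `id`, `smiles`, `sa_score` (or
#'   without `sa_score` if `scorer` is given).
#' @param scorer optional function `smiles -> numeric` used to fill
#'   `sa_score` (e.g. [estimate_sa_score()]).
#' @return The surviving rows of `records`.
#' @export
sa_filter <- function(records, scorer = NULL) {
  if (nrow(records) == 0) return(records)
  if (!is.null(scorer))
    records$sa_score <- vapply(records$smiles, scorer, numeric(1), USE.NAMES = FALSE)
  pg_assert("sa_score" %in% names(records), "records need an sa_score column (or a scorer)")
  pg_assert(all(is.finite(records$sa_score)), "sa_score must be finite")
  records[records$sa_score > 1 & records$sa_score < 6, , drop = FALSE]
}

#' Crude synthetic-accessibility estimate
#'
#' A bundled size/topology heuristic mapped to the conventional 1-10 scale:
#' larger molecules, more rings and more branching score as harder to make.
#' It is a stand-in scorer for pipelines that do not supply their own SA
#' scores and is not a fragment-contribution method.
#'
#' @param smiles a single SMILES string.
#' @return Numeric score, clamped to [1, 10].
#' @export
estimate_sa_score <- function(smiles) {
  mol <- parse_smiles(kekulize_smiles(smiles))
  n <- mol_n_atoms(mol)
  n_rings <- nrow(mol$bonds) - (n - 1)        # cyclomatic count (connected graph)
  deg <- tabulate(c(mol$bonds[, 1], mol$bonds[, 2]), nbins = n)
  branching <- sum(pmax(deg - 2, 0))
  hetero <- sum(mol$element != "C")
  raw <- 1 + 0.08 * n + 0.35 * n_rings + 0.15 * branching + 0.08 * hetero
  min(10, max(1, raw))
}

#' Assemble a paired pocket/ligand dataset
#'
#' @param graphs list of `pocket_graph` objects with `label_smiles` set (or
#'   labels supplied via `pairing`).
#' @param pairing optional data.frame (`pocket_id`, `smiles`) overriding the
#'   graph labels.
#' @param vocab optional `pg_vocab`; built from the labels when missing.
#' @return A `pg_dataset`: list with `pairs` (each holding `graph`, `smiles`,
#'   `seq`), `vocab` and `split` tag.
#' @export
make_paired_dataset <- function(graphs, pairing = NULL, vocab = NULL) {
  pg_assert(length(graphs) >= 1, "need at least one pocket graph")
  ids <- vapply(graphs, function(g) g$pocket_id, character(1))
  pg_assert(!anyDuplicated(ids), "pocket_ids must be unique")
  labels <- vapply(graphs, function(g) g$label_smiles %||% NA_character_, character(1))
  if (!is.null(pairing)) {
    hit <- match(ids, pairing$pocket_id)
    labels <- ifelse(is.na(hit), labels, pairing$smiles[hit])
  }
  pg_assert(!anyNA(labels), "every pocket needs a label molecule")
  if (is.null(vocab)) vocab <- build_vocab(labels)
  pairs <- lapply(seq_along(graphs), function(k) {
    list(graph = graphs[[k]], smiles = labels[k],
         seq = encode_molecule(labels[k], vocab))
  })
  structure(list(pairs = pairs, vocab = vocab, split = "all"),
            class = "pg_dataset")
}

#' @export
print.pg_dataset <- function(x, ...) {
  cat("<pg_dataset> ", length(x$pairs), " pocket/ligand pairs, vocab size ",
      x$vocab$size, ", split = ", x$split, "\n", sep = "")
  invisible(x)
}

#' Random train/test split
#'
#' Disjoint, exhaustive and reproducible under `seed`; the test set holds
#' `round(test_fraction * N)` pairs.
#'
#' @param dataset a `pg_dataset`.
#' @param test_fraction held-out fraction (default 0.10).
#' @param seed split seed.
#' @return List with `train` and `test` datasets.
#' @export
split_dataset <- function(dataset, test_fraction = 0.10, seed = 1L) {
  n <- length(dataset$pairs)
  pg_assert(n >= 10, "dataset too small to split (need >= 10 pairs)")
  n_test <- round(test_fraction * n)
  idx_test <- sort(with_seed(seed, sample.int(n, n_test)))
  mk <- function(idx, tag) {
    d <- dataset
    d$pairs <- dataset$pairs[idx]
    d$split <- tag
    d
  }
  list(train = mk(setdiff(seq_len(n), idx_test), "train"),
       test = mk(idx_test, "test"))
}

#' Fit the encoder-decoder model
#'
#' End-to-end optimization of the mean sequence NLL with Adam; encoder and
#' decoder parameters are updated jointly through backpropagation. Feature
#' columns are standardized over the training graphs (the scaler is stored
#' in the model and applied at every later encoding).
#'
#' @param dataset a `pg_dataset` (training split).
#' @param enc_cfg an `encoder_config` (its `feature_dim` must match the
#'   graphs).
#' @param dec_cfg a `decoder_config`, or `NULL` to construct one matching
#'   the dataset vocabulary and encoder.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size pairs per gradient step.
#' @param clip_norm global gradient-norm clip.
#' @param seed seed controlling initialization and epoch shuffling.
#' @param condition `"pocket"` trains the conditional model; `"constant"`
#'   replaces every graph embedding with zeros (the unconditional baseline,
#'   which can only learn the marginal distribution of ligands).
#' @param freeze_encoder zero the encoder gradients (diagnostic ablation).
#' @param target_recovery optional early-stop: after each epoch, stop once
#'   greedy decoding recovers at least this fraction of training labels.
#' @param verbose print per-epoch loss.
#' @return A `pg_model`: list with `params`, configs, `vocab`,
#'   `feature_scaler`, `history`, `seeds`.
#' @export
fit_model <- function(dataset, enc_cfg, dec_cfg = NULL, epochs = 50, lr = 1e-3,
                      batch_size = 32, clip_norm = 5, seed = 1L,
                      condition = c("pocket", "constant"),
                      freeze_encoder = FALSE, target_recovery = NULL,
                      verbose = FALSE) {
  condition <- match.arg(condition)
  pairs <- dataset$pairs
  pg_assert(length(pairs) >= 1, "empty training set")
  enc_cfg$seed <- derive_seed(seed, "enc-init")
  if (is.null(dec_cfg))
    dec_cfg <- decoder_config(vocab_size = dataset$vocab$size,
                              embedding_dim = 32, hidden_dim = 128,
                              context_dim = embedding_length(enc_cfg),
                              seed = derive_seed(seed, "dec-init"))
  pg_assert(dec_cfg$context_dim == embedding_length(enc_cfg),
            "decoder context_dim must equal the encoder embedding length")
  params <- c(init_encoder_params(enc_cfg), init_decoder_params(dec_cfg))
  feats <- do.call(rbind, lapply(pairs, function(p) p$graph$node_features))
  scaler <- list(center = colMeans(feats),
                 scale = pmax(apply(feats, 2, stats::sd), 1e-8))
  opt <- adam_init(params, lr = lr, clip_norm = clip_norm)
  enc_names <- grep("^enc\\.", names(params), value = TRUE)
  history <- data.frame(epoch = integer(), loss = numeric())
  model_of <- function(params) {
    structure(list(params = params, encoder_config = enc_cfg,
                   decoder_config = dec_cfg, vocab = dataset$vocab,
                   feature_scaler = scaler, condition = condition,
                   seeds = list(fit = seed, encoder = enc_cfg$seed,
                                decoder = dec_cfg$seed),
                   history = history), class = "pg_model")
  }
  zero_embedding <- matrix(0, 1, dec_cfg$context_dim)
  set.seed(derive_seed(seed, "shuffle"))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(pairs))
    ep_loss <- 0
    for (b0 in seq(1, length(pairs), by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1, length(pairs))]
      ad_tape_begin()
      pnodes <- lapply(params, ad_leaf)
      per_seq <- lapply(idx, function(k) {
        pair <- pairs[[k]]
        emb <- if (condition == "constant") zero_embedding
               else encoder_forward(pair$graph, pnodes, enc_cfg, scaler)
        tgt <- pair$seq$indices
        logits <- decoder_teacher_logits(emb, tgt, pnodes, dec_cfg)
        ad_nll_rows(logits, tgt + 1L, mask_cols = PG_PAD + 1L)
      })
      total <- Reduce(ad_add, per_seq)
      loss_node <- ad_affine(total, a = 1 / length(idx))
      ad_backward(loss_node)
      loss_val <- ad_val(loss_node)
      if (!is.finite(loss_val)) {
        ad_tape_clear()
        pg_stop("training diverged (non-finite loss) at epoch ", ep)
      }
      grads <- lapply(names(params), function(nm) {
        g <- pnodes[[nm]]$grad
        if (is.null(g)) array(0, dim(params[[nm]])) else g
      })
      names(grads) <- names(params)
      ad_tape_clear()
      if (freeze_encoder) for (nm in enc_names) grads[[nm]][] <- 0
      upd <- adam_step(params, grads, opt)
      params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + loss_val * length(idx)
    }
    ep_loss <- ep_loss / length(pairs)
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss))
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, ep_loss))
    if (!is.null(target_recovery) && ep %% 10 == 0) {
      m <- model_of(params)
      if (greedy_recovery(m, dataset)$rate >= target_recovery) break
    }
  }
  model_of(params)
}

#' Mean sequence NLL of a model on a dataset
#'
#' @param model a `pg_model`.
#' @param dataset a `pg_dataset`.
#' @return Scalar mean (over sequences) of the per-sequence NLL sums.
#' @export
evaluate_nll <- function(model, dataset) {
  lps <- lapply(dataset$pairs, function(pair) {
    emb <- model_embedding(pair$graph, model)
    teacher_forced_logprobs(emb, pair$seq, model)
  })
  sequence_nll(lps)
}

# Embedding honoring the model's conditioning mode.
model_embedding <- function(graph, model) {
  if (identical(model$condition, "constant"))
    return(numeric(model$decoder_config$context_dim))
  encode_pocket(graph, model)
}

#' Greedy label recovery on a dataset
#'
#' Greedy-decodes each pocket and compares the result with its label ligand
#' under canonical molecule identity.
#'
#' @param model a `pg_model`.
#' @param dataset a `pg_dataset`.
#' @return List with `rate`, logical vector `recovered` and the decoded
#'   strings.
#' @export
greedy_recovery <- function(model, dataset) {
  decoded <- vapply(dataset$pairs, function(pair) {
    emb <- model_embedding(pair$graph, model)
    seq <- sample_sequence(emb, model, mode = "greedy")
    as.character(decode_molecule(seq, model$vocab))
  }, character(1))
  labels <- vapply(dataset$pairs, function(p) p$smiles, character(1))
  can_dec <- canonical_smiles(decoded)
  can_lab <- canonical_smiles(labels)
  rec <- !is.na(can_dec) & can_dec == can_lab
  list(rate = mean(rec), recovered = rec, decoded = decoded)
}

#' Save / load a model checkpoint
#'
#' One archive holds both configs, every parameter matrix, the vocabulary,
#' the feature scaler, all seeds and the training history, so evaluation
#' after a load reproduces results bit-exactly on CPU.
#'
#' @param model a `pg_model`.
#' @param path checkpoint file path (RDS).
#' @return `load_checkpoint` returns the `pg_model`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- unclass(model)
  obj$format_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  pg_assert(identical(obj$format_version, 1L), "unsupported checkpoint version")
  obj$format_version <- NULL
  structure(obj, class = "pg_model")
}

#' @export
print.pg_model <- function(x, ...) {
  cat("<pg_model> encoder ", x$encoder_config$num_layers, "x",
      x$encoder_config$num_channels, " channels, hidden ",
      x$encoder_config$hidden_dim, "; decoder GRU hidden ",
      x$decoder_config$hidden_dim, ", vocab ", x$decoder_config$vocab_size,
      "; ", nrow(x$history), " epochs trained\n", sep = "")
  invisible(x)
}
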