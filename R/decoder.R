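# Autoregressive GRU decoder over SELFIES tokens, conditioned on the graph
# embedding. The embedding, linearly projected to the token-embedding
# dimension, occupies the input slot of step 0 (the hidden state starts at
# zero); each later step consumes the embedded previous token. The per-step
# distribution is a softmax over the vocabulary with <pad> masked to zero,
# so the model defines a proper distribution over token sequences ending in
# <eos>.

#' Decoder configuration
#'
#' @param vocab_size vocabulary size V (including `<pad>` and `<eos>`).
#' @param embedding_dim token embedding dimension E.
#' @param hidden_dim GRU hidden width.
#' @param num_layers GRU depth.
#' @param context_dim length of the conditioning graph embedding (2 * K * H
#'   of the paired encoder); the conditioning projection maps it to E.
#' @param max_len maximum sequence length (tokens incl. `<eos>`).
#' @param seed parameter-initialization seed.
#' @export
decoder_config <- function(vocab_size, embedding_dim = 128, hidden_dim = 512,
                           num_layers = 1, context_dim, max_len = 140,
                           seed = 1L) {
  pg_assert(vocab_size >= 3, "vocabulary must hold at least one chemical token")
  pg_assert(embedding_dim >= 1 && hidden_dim >= 1 && num_layers >= 1 &&
            context_dim >= 1, "all dimensions must be positive")
  structure(list(vocab_size = as.integer(vocab_size),
                 embedding_dim = as.integer(embedding_dim),
                 hidden_dim = as.integer(hidden_dim),
                 num_layers = as.integer(num_layers),
                 context_dim = as.integer(context_dim),
                 max_len = as.integer(max_len),
                 seed = as.integer(seed)), class = "decoder_config")
}

init_decoder_params <- function(cfg) {
  with_seed(cfg$seed, {
    P <- list()
    P[["dec.emb"]] <- nn_mat(cfg$vocab_size, cfg$embedding_dim)
    P[["dec.proj.W"]] <- nn_mat(cfg$context_dim, cfg$embedding_dim)
    P[["dec.proj.b"]] <- nn_zeros(1, cfg$embedding_dim)
    for (l in seq_len(cfg$num_layers)) {
      d_in <- if (l == 1) cfg$embedding_dim else cfg$hidden_dim
      P <- c(P, nn_gru_init(d_in, cfg$hidden_dim, sprintf("dec.gru%d", l)))
    }
    P[["dec.out.W"]] <- nn_mat(cfg$hidden_dim, cfg$vocab_size)
    P[["dec.out.b"]] <- nn_zeros(1, cfg$vocab_size)
    P
  })
}

# Project the graph embedding into the step-0 input slot.
decoder_step0_input <- function(embedding, params) {
  emb <- if (is_ad(embedding)) embedding
         else matrix(as.numeric(embedding), nrow = 1)
  ad_add_bias(ad_mm(emb, params[["dec.proj.W"]]), params[["dec.proj.b"]])
}

# One stacked-GRU step. `hs` is a list of per-layer hidden states; returns
# updated hidden list and output logits (1 x V, or B x V for batched rows).
decoder_step <- function(x, hs, params, cfg) {
  for (l in seq_len(cfg$num_layers)) {
    hs[[l]] <- nn_gru_step(x, hs[[l]], params, sprintf("dec.gru%d", l))
    x <- hs[[l]]
  }
  logits <- ad_add_bias(ad_mm(x, params[["dec.out.W"]]), params[["dec.out.b"]])
  list(hs = hs, logits = logits)
}

decoder_init_hidden <- function(cfg, n_rows = 1) {
  lapply(seq_len(cfg$num_layers), function(l) matrix(0, n_rows, cfg$hidden_dim))
}

# Softmax with <pad> masked out; logits: numeric matrix rows = positions.
masked_softmax <- function(logits, temperature = 1) {
  l <- logits / temperature
  l[, PG_PAD + 1L] <- -Inf
  mx <- apply(l, 1, max)
  e <- exp(l - mx)
  e / rowSums(e)
}

#' Per-step probability distribution of the next token
#'
#' Runs the decoder for a given (possibly empty) prefix of emitted tokens
#' and returns the distribution over the next token; `<pad>` carries zero
#' probability. This is the single-step reference used by enumeration
#' oracles and by sampling.
#'
#' @param embedding conditioning graph embedding (numeric vector).
#' @param prefix integer vector of already-emitted 0-based token indices.
#' @param model a `pg_model` (or list with `params` and `decoder_config`).
#' @param temperature softmax temperature.
#' @return Numeric probability vector of length V (sums to 1).
#' @export
step_distribution <- function(embedding, prefix, model, temperature = 1) {
  cfg <- model$decoder_config
  P <- model$params
  x <- decoder_step0_input(embedding, P)
  hs <- decoder_init_hidden(cfg)
  st <- decoder_step(x, hs, P, cfg)
  for (tok in prefix) {
    x <- P[["dec.emb"]][tok + 1L, , drop = FALSE]
    st <- decoder_step(x, st$hs, P, cfg)
  }
  as.numeric(masked_softmax(st$logits, temperature))
}

# Shared teacher-forcing core. `target` is the 0-based output sequence
# s_0 ... s_n with s_n = <eos>. Step-t input: projected embedding for t = 0,
# embedded s_{t-1} otherwise. Returns the T x V logits (plain or node).
decoder_teacher_logits <- function(embedding, target, params, cfg) {
  T_ <- length(target)
  pg_assert(T_ >= 1, "empty target sequence")
  pg_assert(T_ <= cfg$max_len, "target length ", T_, " exceeds max_len ", cfg$max_len)
  pg_assert(target[T_] == PG_EOS, "target must end with <eos>")
  pg_assert(all(target != PG_PAD), "targets must not contain <pad>")
  x <- decoder_step0_input(embedding, params)
  hs <- decoder_init_hidden(cfg)
  rows <- vector("list", T_)
  st <- decoder_step(x, hs, params, cfg)
  rows[[1]] <- st$logits
  if (T_ > 1) {
    for (t in 2:T_) {
      x <- ad_rows(params[["dec.emb"]], target[t - 1] + 1L)
      st <- decoder_step(x, st$hs, params, cfg)
      rows[[t]] <- st$logits
    }
  }
  ad_rbind(rows)
}

#' Teacher-forced log-probabilities of a target sequence
#'
#' @param embedding conditioning graph embedding (numeric vector).
#' @param target a `pg_tokenseq` (terminated with `<eos>`) or 0-based
#'   integer vector ending in `<eos>`.
#' @param model a `pg_model`.
#' @return Numeric vector of log P(s_t | pocket, s_0..s_{t-1}) for
#'   t = 0..n (the last entry is the `<eos>` step).
#' @export
teacher_forced_logprobs <- function(embedding, target, model) {
  tgt <- if (inherits(target, "pg_tokenseq")) target$indices else as.integer(target)
  logits <- decoder_teacher_logits(embedding, tgt, model$params,
                                   model$decoder_config)
  p <- masked_softmax(ad_val(logits))
  log(p[cbind(seq_along(tgt), tgt + 1L)])
}

#' Sequence negative log-likelihood
#'
#' The training loss: L = -sum_t log P(s_t). For a list of per-sequence
#' log-probability vectors the batch reduction is the mean over sequences
#' of the per-sequence sums.
#'
#' @param logprobs numeric vector of per-step log-probabilities, or a list
#'   of such vectors (a batch).
#' @return Scalar loss.
#' @export
sequence_nll <- function(logprobs) {
  if (is.list(logprobs))
    return(mean(vapply(logprobs, function(lp) -sum(lp), numeric(1))))
  -sum(logprobs)
}

#' Sample a token sequence from the decoder
#'
#' Autoregressive sampling conditioned on a pocket embedding. Emission stops
#' at `<eos>` or after `max_len` tokens (the latter flagged as truncated).
#' Greedy mode is deterministic; multinomial mode is reproducible under
#' `rng_seed`.
#'
#' @param embedding conditioning graph embedding.
#' @param model a `pg_model`.
#' @param max_len maximum number of emitted tokens (including `<eos>`).
#' @param mode `"multinomial"` (default) or `"greedy"`.
#' @param temperature softmax temperature (multinomial mode).
#' @param rng_seed optional seed for multinomial draws.
#' @return A `pg_tokenseq`.
#' @export
sample_sequence <- function(embedding, model, max_len = model$decoder_config$max_len,
                            mode = c("multinomial", "greedy"), temperature = 1,
                            rng_seed = NULL) {
  mode <- match.arg(mode)
  cfg <- model$decoder_config
  P <- model$params
  draw <- function(probs) {
    if (mode == "greedy") return(which.max(probs) - 1L)
    sample.int(length(probs), 1, prob = probs) - 1L
  }
  run <- function() {
    x <- decoder_step0_input(embedding, P)
    hs <- decoder_init_hidden(cfg)
    out <- integer()
    for (t in seq_len(max_len)) {
      st <- decoder_step(x, hs, P, cfg)
      hs <- st$hs
      probs <- as.numeric(masked_softmax(st$logits, temperature))
      tok <- draw(probs)
      out <- c(out, tok)
      if (tok == PG_EOS) return(new_token_sequence(out, terminated = TRUE))
      x <- P[["dec.emb"]][tok + 1L, , drop = FALSE]
    }
    new_token_sequence(out, terminated = FALSE)
  }
  if (!is.null(rng_seed)) with_seed(rng_seed, run()) else run()
}
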