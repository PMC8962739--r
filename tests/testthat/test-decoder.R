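# The GRU decoder: closed-form loss, enumeration-oracle equivalence,
# sequence-distribution normalization and sampling behavior.

# A decoder whose output layer is frozen to constant logits.
frozen_logit_model <- function(vocab, logits_row, max_len = 6) {
  m <- tiny_model(vocab = vocab, max_len = max_len)
  m$params[["dec.out.W"]][] <- 0
  m$params[["dec.out.b"]] <- matrix(logits_row, 1)
  m
}

test_that("uniform logits give the closed-form NLL 3 ln 4", {
  # four-outcome step distribution: 3 chemical tokens + <eos> (pad masked)
  vocab <- build_vocab(c("C", "O", "N"))
  expect_identical(vocab$size, 5L)
  m <- frozen_logit_model(vocab, rep(0, 5))
  emb <- rnorm(pg$embedding_length(m$encoder_config))
  target <- c(2L, 3L, 1L)  # two chemical tokens then <eos>: 3 steps
  lp <- teacher_forced_logprobs(emb, target, m)
  expect_equal(lp, rep(-log(4), 3), tolerance = 1e-9)
  expect_equal(sequence_nll(lp), 3 * log(4), tolerance = 1e-9)
  expect_equal(sequence_nll(lp), 4.158883, tolerance = 1e-6)
})

test_that("certain predictions give zero loss and batches reduce by mean", {
  # per-step log-probability 0 (probability 1) at every step
  expect_identical(sequence_nll(c(0, 0, 0)), 0)
  # a near-certain frozen decoder approaches zero loss on its favored token
  vocab <- build_vocab("C")
  m <- frozen_logit_model(vocab, c(0, 0, 40))
  lp <- teacher_forced_logprobs(rnorm(16), c(2L, 2L, 1L), m)
  expect_lt(-sum(lp[1:2]), 1e-9)
  # batch reduction: mean over sequences of per-sequence sums
  expect_equal(sequence_nll(list(c(-1, -2), c(-3))), mean(c(3, 3)))
})

test_that("teacher forcing equals the step-by-step enumeration oracle", {
  vocab <- build_vocab("C")   # V = 3: pad, eos, one chemical token
  m <- tiny_model(vocab = vocab, seed = 77, max_len = 3)
  set.seed(5)
  emb <- rnorm(pg$embedding_length(m$encoder_config), sd = 2)
  enum <- oracle_enumerate_sequences(emb, m, max_len = 3)
  for (entry in enum$terminated) {
    lp <- teacher_forced_logprobs(emb, entry$seq, m)
    expect_equal(sum(lp), entry$logp, tolerance = 1e-6)
  }
})

test_that("the sequence distribution is normalized (terminated + truncated = 1)", {
  vocab <- build_vocab("C")
  m <- tiny_model(vocab = vocab, seed = 101, max_len = 3)
  emb <- rnorm(pg$embedding_length(m$encoder_config), sd = 3)
  enum <- oracle_enumerate_sequences(emb, m, max_len = 3)
  total <- sum(exp(vapply(enum$terminated, `[[`, numeric(1), "logp"))) +
    enum$trunc_mass
  expect_equal(total, 1, tolerance = 1e-6)
  # and via the teacher-forcing route
  total_tf <- sum(vapply(enum$terminated, function(e)
    exp(sum(teacher_forced_logprobs(emb, e$seq, m))), numeric(1))) +
    enum$trunc_mass
  expect_equal(total_tf, 1, tolerance = 1e-6)
})

test_that("two targets sharing a prefix agree up to the divergence step", {
  vocab <- build_vocab(c("CCO", "CC(=O)O"))
  m <- tiny_model(vocab = vocab, seed = 13, max_len = 20)
  emb <- rnorm(pg$embedding_length(m$encoder_config))
  a <- encode_molecule("CCO", vocab)$indices
  b <- encode_molecule("CC(=O)O", vocab)$indices
  shared <- which(cumsum(seq_along(a) > length(b) |
                         a[seq_along(a)] != b[seq_along(a)]) == 0)
  lpa <- teacher_forced_logprobs(emb, a, m)
  lpb <- teacher_forced_logprobs(emb, b, m)
  expect_equal(lpa[shared], lpb[shared], tolerance = 1e-12)
  d <- length(shared) + 1L
  # at the divergence step both distributions are identical; only the
  # indexed entries differ
  pd <- step_distribution(emb, a[seq_len(d - 1L)], m)
  expect_equal(lpa[d], log(pd[a[d] + 1L]), tolerance = 1e-9)
  expect_equal(lpb[d], log(pd[b[d] + 1L]), tolerance = 1e-9)
})

test_that("sampling stops at eos, is seeded, and greedy is the T -> 0 limit", {
  vocab <- build_vocab(c("CCO", "CC(=O)O"))
  # all mass on <eos>: immediate termination
  m_eos <- frozen_logit_model(vocab, c(0, 100, rep(0, vocab$size - 2L)))
  s <- sample_sequence(rnorm(16), m_eos, rng_seed = 4)
  expect_identical(s$indices, 1L)
  expect_true(s$terminated)
  # reproducibility and the greedy limit
  m <- tiny_model(vocab = vocab, seed = 19, max_len = 25)
  emb <- rnorm(pg$embedding_length(m$encoder_config))
  s1 <- sample_sequence(emb, m, rng_seed = 7)
  s2 <- sample_sequence(emb, m, rng_seed = 7)
  expect_identical(s1, s2)
  g1 <- sample_sequence(emb, m, mode = "greedy")
  g2 <- sample_sequence(emb, m, mode = "multinomial", temperature = 1e-8,
                        rng_seed = 1)
  expect_identical(g1, g2)
  # every sampled sequence satisfies the TokenSequence invariants
  for (k in 1:25) {
    s <- sample_sequence(emb, m, rng_seed = k)
    expect_false(any(s$indices == 0L))
    if (s$terminated)
      expect_identical(s$indices[length(s$indices)], 1L)
    else
      expect_identical(length(s$indices), m$decoder_config$max_len)
  }
})

test_that("step-0 sample frequencies match the exact distribution", {
  vocab <- build_vocab(c("CCO", "CC(=O)O"))
  m <- tiny_model(vocab = vocab, seed = 23)
  emb <- rnorm(pg$embedding_length(m$encoder_config), sd = 2)
  probs <- step_distribution(emb, integer(), m)
  n <- 10000
  batch <- pg$sample_sequences_batch(emb, m, n, max_len = 5)
  first <- vapply(batch$indices, `[[`, integer(1), 1)
  for (tok in which(probs > 0) - 1L) {
    p <- probs[tok + 1L]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(first == tok) - p), 3 * se + 1e-12)
  }
  expect_identical(sum(first == 0L), 0L)  # pad never sampled
})
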