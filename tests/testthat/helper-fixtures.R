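# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are built once per test run and cached in this
# environment.

pg <- asNamespace("pocketgen")

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- small shared fixtures --------------------------------------------------

fixture_graph <- local({
  cache <- NULL
  function(n_atoms = 30, seed = 3) {
    if (is.null(cache)) {
      pdb <- make_pocket_pdb(n_atoms, seed = seed)
      cache <<- to_graph(parse_pocket(pdb), pocket_id = "fix", label_smiles = "CCO")
    }
    cache
  }
})

tiny_vocab <- function(corpus = c("CCO", "CC(=O)O")) build_vocab(corpus)

# An untrained model wrapper around fresh parameters (for decoder/encoder
# behavioral tests that do not need training).
tiny_model <- function(vocab = tiny_vocab(), enc = NULL, seed = 5,
                       emb_dim = 6, hid = 8, max_len = 40) {
  if (is.null(enc)) enc <- encoder_config(num_layers = 2, num_channels = 2,
                                          hidden_dim = 4, set2set_steps = 2,
                                          seed = seed)
  dec <- decoder_config(vocab_size = vocab$size, embedding_dim = emb_dim,
                        hidden_dim = hid, context_dim = pg$embedding_length(enc),
                        max_len = max_len, seed = seed + 1)
  params <- c(pg$init_encoder_params(enc), pg$init_decoder_params(dec))
  structure(list(params = params, encoder_config = enc, decoder_config = dec,
                 vocab = vocab, feature_scaler = NULL, condition = "pocket",
                 seeds = list(), history = data.frame()), class = "pg_model")
}

# Node permutation of a pocket graph (edges relabeled consistently).
permute_graph <- function(g, perm) {
  inv <- match(seq_along(perm), perm)
  g2 <- g
  g2$node_features <- g$node_features[perm, , drop = FALSE]
  g2$coords <- g$coords[perm, , drop = FALSE]
  g2$edges <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
  g2
}

# --- independent oracles ----------------------------------------------------

# RDKit validity oracle (python + rdkit are part of the standard toolchain).
rdkit_valid <- function(smiles) {
  f <- tempfile(fileext = ".smi")
  on.exit(unlink(f), add = TRUE)
  writeLines(smiles, f)
  script <- paste0(
    "from rdkit import Chem, RDLogger\n",
    "RDLogger.DisableLog('rdApp.*')\n",
    "for line in open('", f, "'):\n",
    "    print(int(Chem.MolFromSmiles(line.strip()) is not None))\n")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  as.logical(as.integer(out))
}

# Brute-force Shrake-Rupley with random (not lattice) surface points at
# higher density: an implementation-independent SASA reference.
oracle_sasa <- function(xyz, radii, probe = 1.4, n_points = 9600, seed = 1) {
  set.seed(seed)
  r_exp <- radii + probe
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- matrix(rnorm(n_points * 3), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    p <- sweep(v * r_exp[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 >= r_exp[j]^2)
    }
    out[i] <- 4 * pi * r_exp[i]^2 * mean(acc)
  }
  out
}

# Dense-matrix reference for one message-passing layer: materializes the
# N x N weight matrix per channel with explicit matrix algebra.
oracle_message_passing <- function(X, edges, edge_attr, P, cfg, layer) {
  n <- nrow(X)
  blocks <- list()
  for (c_ in seq_len(cfg$num_channels)) {
    pre <- sprintf("enc.l%d.c%d", layer, c_)
    W <- matrix(0, n, n)
    if (nrow(edges)) for (r in seq_len(nrow(edges))) {
      e <- matrix(edge_attr[r], 1, 1)
      w <- tanh(e %*% P[[paste0(pre, ".edge.W1")]] +
                  as.numeric(P[[paste0(pre, ".edge.b1")]])) %*%
        P[[paste0(pre, ".edge.W2")]] + as.numeric(P[[paste0(pre, ".edge.b2")]])
      W[edges[r, 2], edges[r, 1]] <- as.numeric(w)  # dst row, src col
    }
    eps <- as.numeric(P[[paste0(pre, ".eps")]])
    blocks[[c_]] <- (1 + eps) * X + W %*% X
  }
  H <- do.call(cbind, blocks)
  pre <- sprintf("enc.l%d.theta", layer)
  hid <- pmax(sweep(H %*% P[[paste0(pre, ".W1")]], 2,
                    -as.numeric(P[[paste0(pre, ".b1")]]), `-`), 0)
  sweep(hid %*% P[[paste0(pre, ".W2")]], 2, -as.numeric(P[[paste0(pre, ".b2")]]), `-`)
}

# Exhaustive sequence-tree enumeration for a tiny decoder: probability of
# every terminated sequence up to max_len, plus the truncation mass, built
# from step_distribution() alone.
oracle_enumerate_sequences <- function(embedding, model, max_len) {
  vocab_size <- model$decoder_config$vocab_size
  chem <- setdiff(seq_len(vocab_size) - 1L, c(pg$PG_PAD, pg$PG_EOS))
  terminated <- list()
  trunc_mass <- 0
  recurse <- function(prefix, logp) {
    probs <- step_distribution(embedding, prefix, model)
    for (tok in c(pg$PG_EOS, chem)) {
      p <- probs[tok + 1L]
      lp <- logp + log(p)
      seq_ <- c(prefix, tok)
      if (tok == pg$PG_EOS) {
        terminated[[length(terminated) + 1L]] <<-
          list(seq = seq_, logp = lp)
      } else if (length(seq_) == max_len) {
        trunc_mass <<- trunc_mass + exp(lp)
      } else {
        recurse(seq_, lp)
      }
    }
  }
  recurse(integer(), 0)
  list(terminated = terminated, trunc_mass = trunc_mass)
}
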