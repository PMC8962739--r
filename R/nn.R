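# Parameter containers and cells shared by the encoder and decoder. All
# parameters live in one flat named list of matrices; forward code works on
# either the plain matrices (inference) or tape nodes wrapping them
# (training), via the operators in R/autodiff.R.

# Glorot-scaled dense init.
nn_mat <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}
nn_zeros <- function(n_in, n_out) matrix(0, n_in, n_out)

# y = act(x W1 + b1) W2 + b2, parameters looked up by prefix.
nn_mlp2 <- function(x, P, prefix, act = ad_relu) {
  h <- act(ad_add_bias(ad_mm(x, P[[paste0(prefix, ".W1")]]),
                       P[[paste0(prefix, ".b1")]]))
  ad_add_bias(ad_mm(h, P[[paste0(prefix, ".W2")]]), P[[paste0(prefix, ".b2")]])
}

nn_mlp2_init <- function(n_in, n_hidden, n_out, prefix) {
  out <- list(nn_mat(n_in, n_hidden), nn_zeros(1, n_hidden),
              nn_mat(n_hidden, n_out), nn_zeros(1, n_out))
  names(out) <- paste0(prefix, c(".W1", ".b1", ".W2", ".b2"))
  out
}

# --- GRU cell ---------------------------------------------------------------
# r = sigmoid(x Wxr + bxr + h Whr + bhr)
# z = sigmoid(x Wxz + bxz + h Whz + bhz)
# n = tanh(x Wxn + bxn + r * (h Whn + bhn))
# h' = (1 - z) * n + z * h

GRU_GATES <- c("r", "z", "n")

nn_gru_init <- function(n_in, n_hidden, prefix) {
  out <- list()
  for (g in GRU_GATES) {
    out[[paste0(prefix, ".Wx", g)]] <- nn_mat(n_in, n_hidden)
    out[[paste0(prefix, ".Wh", g)]] <- nn_mat(n_hidden, n_hidden)
    out[[paste0(prefix, ".bx", g)]] <- nn_zeros(1, n_hidden)
    out[[paste0(prefix, ".bh", g)]] <- nn_zeros(1, n_hidden)
  }
  out
}

nn_gru_step <- function(x, h, P, prefix) {
  gate <- function(g) {
    ad_add(ad_add_bias(ad_mm(x, P[[paste0(prefix, ".Wx", g)]]),
                       P[[paste0(prefix, ".bx", g)]]),
           ad_add_bias(ad_mm(h, P[[paste0(prefix, ".Wh", g)]]),
                       P[[paste0(prefix, ".bh", g)]]))
  }
  r <- ad_sigmoid(gate("r"))
  z <- ad_sigmoid(gate("z"))
  hn <- ad_add_bias(ad_mm(h, P[[paste0(prefix, ".Whn")]]),
                    P[[paste0(prefix, ".bhn")]])
  n_ <- ad_tanh(ad_add(ad_add_bias(ad_mm(x, P[[paste0(prefix, ".Wxn")]]),
                                   P[[paste0(prefix, ".bxn")]]),
                       ad_mul(r, hn)))
  ad_add(ad_mul(ad_affine(z, -1, 1), n_), ad_mul(z, h))
}

# --- LSTM cell (used by the Set2Set readout) --------------------------------

LSTM_GATES <- c("i", "f", "g", "o")

nn_lstm_init <- function(n_in, n_hidden, prefix) {
  out <- list()
  for (g in LSTM_GATES) {
    out[[paste0(prefix, ".Wx", g)]] <- nn_mat(n_in, n_hidden)
    out[[paste0(prefix, ".Wh", g)]] <- nn_mat(n_hidden, n_hidden)
    out[[paste0(prefix, ".b", g)]] <- nn_zeros(1, n_hidden)
  }
  out
}

nn_lstm_step <- function(x, h, cc, P, prefix) {
  gate <- function(g, act) {
    act(ad_add_bias(ad_add(ad_mm(x, P[[paste0(prefix, ".Wx", g)]]),
                           ad_mm(h, P[[paste0(prefix, ".Wh", g)]])),
                    P[[paste0(prefix, ".b", g)]]))
  }
  i <- gate("i", ad_sigmoid)
  f <- gate("f", ad_sigmoid)
  g_ <- gate("g", ad_tanh)
  o <- gate("o", ad_sigmoid)
  cc2 <- ad_add(ad_mul(f, cc), ad_mul(i, g_))
  list(h = ad_mul(o, ad_tanh(cc2)), c = cc2)
}

# --- Adam optimizer ---------------------------------------------------------

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip_norm = 5) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, clip_norm = clip_norm,
       t = 0L,
       m = lapply(params, function(p) array(0, dim(p))),
       v = lapply(params, function(p) array(0, dim(p))))
}

adam_step <- function(params, grads, state) {
  gn2 <- sum(vapply(grads, function(g) sum(g^2), numeric(1)))
  scale <- if (is.finite(state$clip_norm) && sqrt(gn2) > state$clip_norm)
    state$clip_norm / sqrt(gn2) else 1
  state$t <- state$t + 1L
  b1t <- 1 - state$beta1^state$t
  b2t <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      state$lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + state$eps)
  }
  list(params = params, state = state)
}
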