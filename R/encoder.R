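# Graph encoder: K layers of edge-conditioned multi-channel message passing,
# jumping-knowledge concatenation over layers, and a Set2Set attention
# readout producing a fixed-size embedding of length 2 * K * hidden_dim.
#
# Per layer k and channel c the node update is
#   (1 + eps_c) * x_i + sum_{j in N(i)} h_wc(e_ij) * x_j
# where eps_c is a trainable scalar (initialized to 0) and h_wc is a
# two-layer fully connected network mapping the scalar edge attribute to a
# scalar neighbor weight. Channels are concatenated and passed through the
# update network h_theta (one hidden rectified layer).

#' Encoder configuration
#'
#' @param num_layers number of message-passing layers (K).
#' @param num_channels number of channels per layer (C).
#' @param feature_dim node feature dimension (8 for the standard pocket
#'   featurization).
#' @param hidden_dim node embedding width per layer (H). The graph embedding
#'   has length `2 * num_layers * hidden_dim` (jumping-knowledge
#'   concatenation doubled by Set2Set).
#' @param set2set_steps Set2Set processing iterations.
#' @param edge_hidden hidden width of the per-channel edge network.
#' @param seed parameter-initialization seed.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(num_layers = 4, num_channels = 8, feature_dim = 8,
                           hidden_dim = 64, set2set_steps = 3, edge_hidden = 8,
                           seed = 1L) {
  pg_assert(num_layers >= 1 && num_channels >= 1 && hidden_dim >= 1,
            "num_layers, num_channels and hidden_dim must all be >= 1")
  structure(list(num_layers = as.integer(num_layers),
                 num_channels = as.integer(num_channels),
                 feature_dim = as.integer(feature_dim),
                 hidden_dim = as.integer(hidden_dim),
                 set2set_steps = as.integer(set2set_steps),
                 edge_hidden = as.integer(edge_hidden),
                 seed = as.integer(seed)), class = "encoder_config")
}

embedding_length <- function(cfg) 2L * cfg$num_layers * cfg$hidden_dim

# Flat named parameter list; names carry the "enc." prefix so encoder and
# decoder parameters can share one container.
init_encoder_params <- function(cfg) {
  with_seed(cfg$seed, {
    P <- list()
    for (k in seq_len(cfg$num_layers)) {
      d_in <- if (k == 1) cfg$feature_dim else cfg$hidden_dim
      for (c_ in seq_len(cfg$num_channels)) {
        pre <- sprintf("enc.l%d.c%d", k, c_)
        P[[paste0(pre, ".eps")]] <- matrix(0, 1, 1)  # eps_c starts at 0
        P <- c(P, nn_mlp2_init(1, cfg$edge_hidden, 1, paste0(pre, ".edge")))
      }
      P <- c(P, nn_mlp2_init(d_in * cfg$num_channels, cfg$hidden_dim,
                             cfg$hidden_dim, sprintf("enc.l%d.theta", k)))
    }
    D <- cfg$num_layers * cfg$hidden_dim
    P <- c(P, nn_lstm_init(2L * D, D, "enc.s2s"))
    P
  })
}

#' One edge-conditioned message-passing layer
#'
#' @param node_feats N x d matrix of node features.
#' @param edges E x 2 integer matrix (both directions of each pair).
#' @param edge_attr numeric vector aligned with `edges`.
#' @param params flat parameter list (plain matrices or tape nodes).
#' @param cfg an `encoder_config`.
#' @param layer layer index k (selects the layer's parameters).
#' @return N x hidden_dim matrix (or tape node during training).
#' @export
message_passing_layer <- function(node_feats, edges, edge_attr, params, cfg, layer) {
  n <- nrow(ad_val(node_feats))
  eattr <- matrix(as.numeric(edge_attr), ncol = 1)
  chans <- vector("list", cfg$num_channels)
  for (c_ in seq_len(cfg$num_channels)) {
    pre <- sprintf("enc.l%d.c%d", layer, c_)
    w <- nn_mlp2(eattr, params, paste0(pre, ".edge"), act = ad_tanh)
    nbr <- ad_edge_scatter(node_feats, w, edges[, 1], edges[, 2], n)
    self <- ad_add(node_feats, ad_scale_by(params[[paste0(pre, ".eps")]], node_feats))
    chans[[c_]] <- ad_add(self, nbr)
  }
  nn_mlp2(ad_cbind(chans), params, sprintf("enc.l%d.theta", layer))
}

#' Jumping-knowledge aggregation
#'
#' Concatenates the per-layer node representations along the feature axis
#' (concat-mode JK), letting downstream layers weight shallow and deep
#' neighborhoods per node.
#'
#' @param per_layer list of K matrices, each N x hidden_dim.
#' @param mode `"concat"` (default), `"max"` or `"sum"`.
#' @return N x (K * hidden_dim) matrix for `"concat"`, N x hidden_dim
#'   otherwise.
#' @export
jk_aggregate <- function(per_layer, mode = c("concat", "max", "sum")) {
  mode <- match.arg(mode)
  ns <- vapply(per_layer, function(m) nrow(ad_val(m)), integer(1))
  pg_assert(length(unique(ns)) == 1, "inconsistent node counts across layers")
  if (mode == "concat") return(ad_cbind(per_layer))
  pg_assert(!any(vapply(per_layer, is_ad, logical(1))),
            "max/sum JK modes are inference-only")
  if (mode == "sum") return(Reduce(`+`, per_layer))
  Reduce(function(a, b) pmax(a, b), per_layer)
}

#' Set2Set readout
#'
#' Order-invariant attention readout: an LSTM produces a query, attention
#' over node embeddings yields a readout vector, and the concatenated
#' query/readout feeds the next iteration. Output length is twice the node
#' embedding dimension.
#'
#' @param node_embeddings N x D matrix.
#' @param params flat parameter list holding the `enc.s2s.*` LSTM weights.
#' @param steps number of processing iterations.
#' @return 1 x 2D matrix (or tape node during training).
#' @export
set2set_readout <- function(node_embeddings, params, steps = 3) {
  D <- ncol(ad_val(node_embeddings))
  q <- matrix(0, 1, D)
  cc <- matrix(0, 1, D)
  qstar <- matrix(0, 1, 2 * D)
  for (s in seq_len(steps)) {
    st <- nn_lstm_step(qstar, q, cc, params, "enc.s2s")
    q <- st$h; cc <- st$c
    e <- ad_mm(node_embeddings, ad_t(q))
    a <- ad_softmax_col(e)
    r <- ad_t(ad_mm(ad_t(node_embeddings), a))
    qstar <- ad_cbind(list(q, r))
  }
  qstar
}

# Full encoder forward; `scaler` optionally standardizes feature columns.
encoder_forward <- function(graph, params, cfg, scaler = NULL) {
  X <- graph$node_features
  if (!is.null(scaler))
    X <- sweep(sweep(X, 2, scaler$center, `-`), 2, scaler$scale, `/`)
  outs <- vector("list", cfg$num_layers)
  for (k in seq_len(cfg$num_layers)) {
    X <- message_passing_layer(X, graph$edges, graph$edge_attr, params, cfg, k)
    outs[[k]] <- X
  }
  set2set_readout(jk_aggregate(outs), params, cfg$set2set_steps)
}

#' Encode a pocket graph into a fixed-size embedding
#'
#' @param graph a `pocket_graph`.
#' @param model a trained `pg_model` (or a list with `params`,
#'   `encoder_config` and optionally `feature_scaler`).
#' @return Numeric vector of length `2 * num_layers * hidden_dim`.
#' @export
encode_pocket <- function(graph, model) {
  out <- encoder_forward(graph, model$params, model$encoder_config,
                         scaler = model$feature_scaler)
  as.numeric(ad_val(out))
}
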