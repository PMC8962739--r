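# The message-passing encoder: single-node collapse, dense-matrix oracle,
# jumping-knowledge layout, Set2Set properties and whole-encoder invariance.

test_that("an isolated node reduces to the self term", {
  # eps = 0 and identity-like update: with no edges the channel output is
  # exactly the input features, so the layer equals h_theta(concat of X)
  cfg <- encoder_config(num_layers = 1, num_channels = 1, feature_dim = 3,
                        hidden_dim = 3, seed = 1)
  P <- pg$init_encoder_params(cfg)
  # freeze h_theta to the identity on a single channel
  P[["enc.l1.theta.W1"]] <- diag(3)
  P[["enc.l1.theta.b1"]] <- matrix(10, 1, 3)   # keep relu in its linear region
  P[["enc.l1.theta.W2"]] <- diag(3)
  P[["enc.l1.theta.b2"]] <- matrix(-10, 1, 3)
  X <- matrix(c(1, 2, 3), 1, 3)
  out <- message_passing_layer(X, matrix(integer(), ncol = 2), numeric(), P, cfg, 1)
  expect_equal(out, X, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a single neighbor contributes x_i + w * x_j", {
  cfg <- encoder_config(num_layers = 1, num_channels = 1, feature_dim = 2,
                        hidden_dim = 2, seed = 2)
  P <- pg$init_encoder_params(cfg)
  P[["enc.l1.theta.W1"]] <- diag(2)
  P[["enc.l1.theta.b1"]] <- matrix(10, 1, 2)
  P[["enc.l1.theta.W2"]] <- diag(2)
  P[["enc.l1.theta.b2"]] <- matrix(-10, 1, 2)
  X <- rbind(c(1, 0), c(0, 2))
  edges <- rbind(c(1L, 2L), c(2L, 1L))
  attr_ <- c(0, 0)
  # the frozen edge network's weight at attribute 0
  w <- as.numeric(tanh(matrix(0, 1, 1) %*% P[["enc.l1.c1.edge.W1"]] +
                       as.numeric(P[["enc.l1.c1.edge.b1"]])) %*%
                  P[["enc.l1.c1.edge.W2"]] + as.numeric(P[["enc.l1.c1.edge.b2"]]))
  out <- message_passing_layer(X, edges, attr_, P, cfg, 1)
  expect_equal(out[1, ], X[1, ] + w * X[2, ], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(out[2, ], X[2, ] + w * X[1, ], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("message passing equals the dense-adjacency reference on random graphs", {
  set.seed(31)
  for (trial in 1:5) {
    n <- sample(4:8, 1)
    cfg <- encoder_config(num_layers = 2, num_channels = 3, feature_dim = 4,
                          hidden_dim = 5, seed = 30 + trial)
    P <- pg$init_encoder_params(cfg)
    # random eps (init is 0; perturb to exercise the self-weight path)
    for (nm in grep("\\.eps$", names(P), value = TRUE))
      P[[nm]] <- matrix(rnorm(1, sd = 0.3), 1, 1)
    # random symmetric edge set with attributes in {0, 1, 2}
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- pairs[runif(nrow(pairs)) < 0.5, , drop = FALSE]
    edges <- rbind(cbind(pick[, 1], pick[, 2]), cbind(pick[, 2], pick[, 1]))
    eattr <- rep(sample(0:2, nrow(pick), TRUE), 2)
    X <- matrix(rnorm(n * 4), n, 4)
    got <- message_passing_layer(X, edges, eattr, P, cfg, 1)
    want <- oracle_message_passing(X, edges, eattr, P, cfg, 1)
    expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("jumping-knowledge concatenation preserves layer blocks", {
  A <- matrix(1:6, 2, 3)
  B <- matrix(7:12, 2, 3)
  expect_identical(jk_aggregate(list(A)), A)
  out <- jk_aggregate(list(A, B))
  expect_identical(out[, 1:3], A)
  expect_identical(out[, 4:6], B)
  expect_error(jk_aggregate(list(A, matrix(0, 3, 3))), "inconsistent")
  expect_identical(jk_aggregate(list(A, B), mode = "sum"), A + B)
  expect_identical(jk_aggregate(list(A, B), mode = "max"), pmax(A, B))
})

test_that("Set2Set is permutation invariant and collapses for one node", {
  cfg <- encoder_config(num_layers = 1, num_channels = 1, feature_dim = 4,
                        hidden_dim = 4, seed = 7)
  P <- pg$init_encoder_params(cfg)
  x1 <- matrix(rnorm(4, sd = 2), 1, 4)
  out1 <- set2set_readout(x1, P, steps = 3)
  # attention over one element is that element: second half = the embedding
  expect_equal(out1[1, 5:8], x1[1, ], tolerance = 1e-9, ignore_attr = TRUE)
  # two identical nodes behave exactly like one
  out2 <- set2set_readout(rbind(x1, x1), P, steps = 3)
  expect_equal(out2, out1, tolerance = 1e-9)
  # node-order invariance
  set.seed(8)
  X <- matrix(rnorm(6 * 4), 6, 4)
  o1 <- set2set_readout(X, P, steps = 3)
  o2 <- set2set_readout(X[sample(6), ], P, steps = 3)
  expect_equal(o1, o2, tolerance = 1e-5)
})

test_that("the full encoder is deterministic and node-order invariant", {
  g <- fixture_graph()
  m <- tiny_model()
  e1 <- encode_pocket(g, m)
  e2 <- encode_pocket(g, m)
  expect_identical(e1, e2)
  set.seed(12)
  for (k in 1:20) {
    gp <- permute_graph(g, sample(g$n_atoms))
    expect_equal(encode_pocket(gp, m), e1, tolerance = 1e-5)
  }
})

test_that("encoder output composes the three stage oracles", {
  g <- fixture_graph()
  cfg <- encoder_config(num_layers = 2, num_channels = 2, feature_dim = 8,
                        hidden_dim = 4, set2set_steps = 2, seed = 44)
  P <- pg$init_encoder_params(cfg)
  X <- g$node_features
  l1 <- oracle_message_passing(X, g$edges, g$edge_attr, P, cfg, 1)
  l2 <- oracle_message_passing(l1, g$edges, g$edge_attr, P, cfg, 2)
  want <- set2set_readout(cbind(l1, l2), P, steps = 2)
  got <- pg$encoder_forward(g, P, cfg)
  expect_equal(got, want, tolerance = 1e-6)
})
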