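# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every operator accepts plain matrices and/or tape nodes and dispatches on
# the argument types: with plain inputs it computes the plain result (so the
# same forward code serves training and inference), with at least one node
# input it records the operation on the active tape. Node creation order is
# a topological order of the computation graph, so the backward pass is a
# single reverse sweep over the tape.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$n <- 0L

ad_tape_begin <- function() {
  .ad$tape <- vector("list", 1024L)
  .ad$n <- 0L
  invisible(NULL)
}

ad_tape_clear <- function() {
  .ad$tape <- NULL
  .ad$n <- 0L
  invisible(NULL)
}

ad_record <- function(node) {
  pg_assert(!is.null(.ad$tape), "no active autodiff tape (call ad_tape_begin())")
  n <- .ad$n + 1L
  if (n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  .ad$tape[[n]] <- node
  .ad$n <- n
  node
}

# value: matrix; parents: list possibly containing non-nodes (ignored by the
# backward sweep); backward: function(grad) -> list of per-parent gradients.
ad_node <- function(value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$grad <- NULL
  class(node) <- "ad_node"
  ad_record(node)
}

is_ad <- function(x) inherits(x, "ad_node")
ad_val <- function(x) if (is_ad(x)) x$value else x

# Leaf node for a trainable parameter (no backward; gradient accumulates).
ad_leaf <- function(value) ad_node(value)

# Reverse sweep from `root` (scalar-valued node).
ad_backward <- function(root, seed = 1) {
  pg_assert(is_ad(root), "root must be an ad_node")
  root$grad <- seed
  for (k in seq(.ad$n, 1L)) {
    node <- .ad$tape[[k]]
    if (is.null(node$grad) || is.null(node$backward)) next
    pgrads <- node$backward(node$grad)
    for (m in seq_along(node$parents)) {
      p <- node$parents[[m]]
      if (!is_ad(p)) next
      g <- pgrads[[m]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

# --- operators --------------------------------------------------------------

ad_mm <- function(a, b) {
  if (!is_ad(a) && !is_ad(b)) return(a %*% b)
  av <- ad_val(a); bv <- ad_val(b)
  ad_node(av %*% bv, list(a, b), function(g) list(
    if (is_ad(a)) g %*% t(bv) else NULL,
    if (is_ad(b)) t(av) %*% g else NULL))
}

ad_add <- function(a, b) {
  if (!is_ad(a) && !is_ad(b)) return(a + b)
  ad_node(ad_val(a) + ad_val(b), list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  if (!is_ad(a) && !is_ad(b)) return(a - b)
  ad_node(ad_val(a) - ad_val(b), list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  if (!is_ad(a) && !is_ad(b)) return(a * b)
  av <- ad_val(a); bv <- ad_val(b)
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# a * x + b with constant scalars a, b
ad_affine <- function(x, a = 1, b = 0) {
  if (!is_ad(x)) return(a * x + b)
  ad_node(a * ad_val(x) + b, list(x), function(g) list(a * g))
}

# add a 1 x k bias row to every row of an n x k matrix
ad_add_bias <- function(x, bias) {
  if (!is_ad(x) && !is_ad(bias)) return(sweep(x, 2, as.numeric(bias), `+`))
  xv <- ad_val(x)
  out <- sweep(xv, 2, as.numeric(ad_val(bias)), `+`)
  ad_node(out, list(x, bias), function(g) list(
    g,
    matrix(colSums(g), nrow = 1)))
}

# multiply matrix x by scalar held in a 1 x 1 node/parameter
ad_scale_by <- function(s, x) {
  if (!is_ad(s) && !is_ad(x)) return(as.numeric(s) * x)
  sv <- as.numeric(ad_val(s)); xv <- ad_val(x)
  ad_node(sv * xv, list(s, x), function(g) list(
    matrix(sum(g * xv), 1, 1),
    sv * g))
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-ad_val(x)))
  if (!is_ad(x)) return(s)
  ad_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(x) {
  tv <- tanh(ad_val(x))
  if (!is_ad(x)) return(tv)
  ad_node(tv, list(x), function(g) list(g * (1 - tv^2)))
}

ad_relu <- function(x) {
  xv <- ad_val(x)
  if (!is_ad(x)) return(pmax(xv, 0))
  ad_node(pmax(xv, 0), list(x), function(g) list(g * (xv > 0)))
}

ad_cbind <- function(xs) {
  if (!any(vapply(xs, is_ad, logical(1)))) return(do.call(cbind, xs))
  vals <- lapply(xs, ad_val)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(do.call(cbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

ad_rbind <- function(xs) {
  if (!any(vapply(xs, is_ad, logical(1)))) return(do.call(rbind, xs))
  vals <- lapply(xs, ad_val)
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  ad_node(do.call(rbind, vals), xs, function(g) {
    lapply(seq_along(xs), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

ad_t <- function(x) {
  if (!is_ad(x)) return(t(x))
  ad_node(t(ad_val(x)), list(x), function(g) list(t(g)))
}

ad_sum <- function(x) {
  if (!is_ad(x)) return(sum(x))
  xv <- ad_val(x)
  ad_node(sum(xv), list(x), function(g) list(array(g, dim(xv))))
}

# select rows (gradient scatters back into the source matrix)
ad_rows <- function(x, idx) {
  if (!is_ad(x)) return(x[idx, , drop = FALSE])
  xv <- ad_val(x)
  ad_node(xv[idx, , drop = FALSE], list(x), function(g) {
    out <- matrix(0, nrow(xv), ncol(xv))
    agg <- rowsum(g, group = idx)
    out[as.integer(rownames(agg)), ] <- agg
    list(out)
  })
}

# softmax of a column vector (n x 1)
ad_softmax_col <- function(x) {
  xv <- as.numeric(ad_val(x))
  e <- exp(xv - max(xv))
  s <- matrix(e / sum(e), ncol = 1)
  if (!is_ad(x)) return(s)
  ad_node(s, list(x), function(g) {
    gv <- as.numeric(g)
    sv <- as.numeric(s)
    matrix(sv * (gv - sum(gv * sv)), ncol = 1) |> list()
  })
}

# Edge-weighted neighbor aggregation: out[d, ] = sum over edges e with
# dst[e] = d of w[e] * x[src[e], ]. The workhorse of message passing.
ad_edge_scatter <- function(x, w, src, dst, n_nodes) {
  xv <- ad_val(x)
  wv <- as.numeric(ad_val(w))
  plain <- function() {
    out <- matrix(0, n_nodes, ncol(xv))
    if (length(src)) {
      contrib <- xv[src, , drop = FALSE] * wv
      agg <- rowsum(contrib, group = dst)
      out[as.integer(rownames(agg)), ] <- agg
    }
    out
  }
  if (!is_ad(x) && !is_ad(w)) return(plain())
  ad_node(plain(), list(x, w), function(g) {
    gx <- NULL; gw <- NULL
    if (is_ad(x)) {
      gx <- matrix(0, nrow(xv), ncol(xv))
      if (length(src)) {
        back <- g[dst, , drop = FALSE] * wv
        agg <- rowsum(back, group = src)
        gx[as.integer(rownames(agg)), ] <- agg
      }
    }
    if (is_ad(w)) {
      gw <- if (length(src))
        matrix(rowSums(xv[src, , drop = FALSE] * g[dst, , drop = FALSE]), ncol = 1)
      else matrix(numeric(), ncol = 1)
    }
    list(gx, gw)
  })
}

# Sequence NLL with masked softmax: logits is T x V; targets is a 1-based
# integer vector of length T; mask_cols (1-based) get probability zero.
# Value: -sum_t log P(target_t). Steps with target in mask_cols would be
# ill-defined and are disallowed by the decoder (pad never appears as a
# target).
ad_nll_rows <- function(logits, targets, mask_cols = integer()) {
  lv <- ad_val(logits)
  lv2 <- lv
  if (length(mask_cols)) lv2[, mask_cols] <- -Inf
  mx <- apply(lv2, 1, max)
  ex <- exp(lv2 - mx)
  p <- ex / rowSums(ex)
  picked <- p[cbind(seq_along(targets), targets)]
  value <- -sum(log(picked))
  if (!is_ad(logits)) return(value)
  ad_node(value, list(logits), function(g) {
    d <- p
    d[cbind(seq_along(targets), targets)] <-
      d[cbind(seq_along(targets), targets)] - 1
    if (length(mask_cols)) d[, mask_cols] <- 0
    list(as.numeric(g) * d)
  })
}
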