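#' Gated graph transformer configuration
#'
#' Architecture hyperparameters for the gated graph transformer (GGT).  The
#' node hidden width must equal `n_heads * head_dim`: per-head attention
#' outputs are concatenated back to the hidden width.  Defaults are sized for
#' desk-scale work: 4 layers, 8 heads of dimension 4 (hidden 32), edge hidden
#' 32, dropout 0.1, read-out stack 32-16.
#'
#' @param n_layers number of message-passing layers (>= 1).
#' @param n_heads attention heads per layer (>= 1).
#' @param head_dim per-head channel dimension.
#' @param edge_hidden edge embedding width.
#' @param dropout read-out dropout fraction (training only).
#' @param node_gate_enabled,edge_gate_enabled the two information gates.
#' @param pe_dim Laplacian positional-encoding dims (part of the 35 node
#'   features).
#' @param k neighbours used at featurisation time (recorded for provenance).
#' @param readout_hidden_dims widths of the two read-out hidden layers.
#' @param n_node_feats,n_edge_feats input feature counts.
#' @param leaky_slope negative slope of every LeakyReLU.
#' @param ffn_expand feed-forward expansion factor.
#' @param seed seed from which all parameter initialisation randomness flows.
#' @return a `ggt_config` list.
#' @export
ggt_config <- function(n_layers = 4, n_heads = 8, head_dim = 4,
                       edge_hidden = 32, dropout = 0.1,
                       node_gate_enabled = TRUE, edge_gate_enabled = TRUE,
                       pe_dim = 8, k = 10, readout_hidden_dims = c(32, 16),
                       n_node_feats = 35, n_edge_feats = 6,
                       leaky_slope = 0.01, ffn_expand = 2, seed = 1) {
  cfg <- list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
              head_dim = as.integer(head_dim),
              node_hidden = as.integer(n_heads * head_dim),
              edge_hidden = as.integer(edge_hidden), dropout = dropout,
              node_gate_enabled = isTRUE(node_gate_enabled),
              edge_gate_enabled = isTRUE(edge_gate_enabled),
              pe_dim = as.integer(pe_dim), k = as.integer(k),
              readout_hidden_dims = as.integer(readout_hidden_dims),
              n_node_feats = as.integer(n_node_feats),
              n_edge_feats = as.integer(n_edge_feats),
              leaky_slope = leaky_slope, ffn_expand = ffn_expand,
              seed = as.integer(seed))
  stopifnot(cfg$n_layers >= 1, cfg$n_heads >= 1, cfg$head_dim >= 1,
            length(cfg$readout_hidden_dims) >= 1,
            cfg$dropout >= 0, cfg$dropout < 1)
  class(cfg) <- "ggt_config"
  cfg
}

#' Gate-ablation variants of the GGT
#'
#' "GGT" enables both gates, "GT" (the plain graph transformer) neither,
#' "GTE" only the edge gate, "GTN" only the node gate.
#'
#' @param config a [ggt_config()].
#' @param name one of "GGT", "GT", "GTE", "GTN".
#' @return the config with the gate flags set accordingly.
#' @export
ggt_variant <- function(config, name = c("GGT", "GT", "GTE", "GTN")) {
  name <- match.arg(name)
  config$node_gate_enabled <- name %in% c("GGT", "GTN")
  config$edge_gate_enabled <- name %in% c("GGT", "GTE")
  config
}

new_bn <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d),
       r_mean = rep(0, d), r_var = rep(1, d))
}

uinit <- function(n_in, n_out) {
  matrix(runif(n_in * n_out, -1, 1) / sqrt(n_in), n_in, n_out)
}

#' Initialise GGT parameters
#'
#' All weights are uniform fan-in initialised; batch-norm scales start at 1
#' with zero shift and unit running variance.  Fully determined by
#' `config$seed`.
#'
#' @param config a [ggt_config()].
#' @return a nested parameter list (see source for layout).
#' @export
ggt_init_params <- function(config) {
  set.seed(config$seed)
  dh <- config$node_hidden
  de <- config$edge_hidden
  hd <- config$n_heads * config$head_dim
  layer_params <- function() {
    list(W_Q = uinit(dh, hd), W_K = uinit(dh, hd), W_V = uinit(dh, hd),
         W_E = uinit(de, hd), W_Ge = uinit(de, hd), W_Gh = uinit(dh, hd),
         O_h = uinit(hd, dh), b_Oh = rep(0, dh),
         O_e = uinit(hd, de), b_Oe = rep(0, de),
         ffn_h = list(W1 = uinit(dh, config$ffn_expand * dh),
                      b1 = rep(0, config$ffn_expand * dh),
                      W2 = uinit(config$ffn_expand * dh, dh),
                      b2 = rep(0, dh)),
         bn_h_in = new_bn(dh), bn_h_out = new_bn(dh),
         ffn_e = list(W1 = uinit(de, config$ffn_expand * de),
                      b1 = rep(0, config$ffn_expand * de),
                      W2 = uinit(config$ffn_expand * de, de),
                      b2 = rep(0, de)),
         bn_e_in = new_bn(de), bn_e_out = new_bn(de))
  }
  readout_params <- function(d_out) {
    r1 <- config$readout_hidden_dims[1]
    r2 <- config$readout_hidden_dims[2]
    list(W1 = uinit(dh, r1), b1 = rep(0, r1), bn1 = new_bn(r1),
         W2 = uinit(r1, r2), b2 = rep(0, r2), bn2 = new_bn(r2),
         W3 = uinit(r2, d_out), b3 = rep(0, d_out))
  }
  list(embed_h = list(W = uinit(config$n_node_feats, dh), b = rep(0, dh),
                      bn = new_bn(dh)),
       embed_e = list(W = uinit(config$n_edge_feats, de), b = rep(0, de),
                      bn = new_bn(de)),
       layers = replicate(config$n_layers, layer_params(),
                          simplify = FALSE),
       readout = list(reg = readout_params(1), cls = readout_params(4)))
}

sigmoid_f <- function(x) 1 / (1 + exp(-x))
lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x > 0, 1, slope)

# --- batch-norm ----------------------------------------------------------

bn_forward <- function(x, bn, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    v[v < 0] <- 0
    xhat <- sweep(sweep(x, 2, mu), 2, sqrt(v + eps), "/")
    bn$r_mean <- (1 - momentum) * bn$r_mean + momentum * mu
    bn$r_var <- (1 - momentum) * bn$r_var + momentum * v
    cache <- list(xhat = xhat, var = v, eps = eps, gamma = bn$gamma)
  } else {
    xhat <- sweep(sweep(x, 2, bn$r_mean), 2, sqrt(bn$r_var + eps), "/")
    cache <- NULL
  }
  list(out = sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+"),
       bn = bn, cache = cache)
}

bn_backward <- function(dy, cache) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, "*")
  inv_sd <- 1 / sqrt(cache$var + cache$eps)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
  dx <- sweep(t1 - t2, 2, inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- grouped softmax over incoming edges ---------------------------------

# x: E x C scores; dst: length-E group index in 1..n (edges of one group are
# contiguous by construction).  Softmax per group per column.
group_softmax <- function(x, dst, n) {
  counts <- tabulate(dst, n)
  starts <- c(1L, head(cumsum(counts), -1L) + 1L)
  w <- x
  gmax <- matrix(-Inf, n, ncol(x))
  for (s in unique(counts)) {
    if (s == 0) next
    nodes <- which(counts == s)
    M <- outer(0:(s - 1L), starts[nodes], "+")  # s x m edge rows
    for (cc in seq_len(ncol(x))) {
      vals <- matrix(x[as.vector(M), cc], s)
      mx <- vals[1, ]
      if (s > 1) for (r in 2:s) mx <- pmax(mx, vals[r, ])
      gmax[nodes, cc] <- mx
    }
  }
  ex <- exp(x - gmax[dst, , drop = FALSE])
  denom <- scatter_add(ex, dst, n)
  ex / denom[dst, , drop = FALSE]
}

group_softmax_backward <- function(dw, w, dst, n) {
  s <- scatter_add(dw * w, dst, n)
  w * (dw - s[dst, , drop = FALSE])
}

scatter_add <- function(x, idx, n) {
  r <- rowsum(x, idx)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(r)), ] <- r
  out
}

# --- graph batching ------------------------------------------------------

# Concatenate featurised graphs into one block-diagonal batch.
batch_graphs <- function(graphs) {
  if (inherits(graphs, "complex_graph")) graphs <- list(graphs)
  ns <- vapply(graphs, function(g) g$n_nodes, integer(1))
  offs <- cumsum(c(0L, head(ns, -1L)))
  list(
    node_feats = do.call(rbind, lapply(graphs, function(g) g$node_feats)),
    edge_feats = do.call(rbind, lapply(graphs, function(g) g$edge_feats)),
    src = unlist(mapply(function(g, o) g$edge_src + o, graphs, offs,
                        SIMPLIFY = FALSE)),
    dst = unlist(mapply(function(g, o) g$edge_dst + o, graphs, offs,
                        SIMPLIFY = FALSE)),
    graph_of_node = rep(seq_along(graphs), ns),
    n_nodes = sum(ns), n_graphs = length(graphs),
    ids = vapply(graphs, function(g) g$target_id %||% "g", character(1)))
}

# --- single GGT layer ----------------------------------------------------

ggt_layer_forward <- function(h, e, src, dst, lp, config, training) {
  dk <- config$head_dim
  H <- config$n_heads
  n <- nrow(h)
  QH <- h %*% lp$W_Q
  KH <- h %*% lp$W_K
  VH <- h %*% lp$W_V
  EH <- e %*% lp$W_E
  # per-head scaled dot products (E-vector each), expanded over channels
  dot <- matrix(0, length(src), H)
  for (k in seq_len(H)) {
    ck <- ((k - 1) * dk + 1):(k * dk)
    dot[, k] <- rowSums(QH[dst, ck, drop = FALSE] *
                        KH[src, ck, drop = FALSE]) / sqrt(dk)
  }
  what <- EH * dot[, rep(seq_len(H), each = dk), drop = FALSE]
  ehat <- e + sweep(what %*% lp$O_e, 2, lp$b_Oe, "+")
  if (config$edge_gate_enabled) {
    GEpre <- e %*% lp$W_Ge
    ge <- sigmoid_f(GEpre)
    wg <- what * ge
  } else {
    ge <- NULL
    wg <- what
  }
  w <- group_softmax(wg, dst, n)
  if (config$node_gate_enabled) {
    GHpre <- h %*% lp$W_Gh
    gh_src <- sigmoid_f(GHpre)[src, , drop = FALSE]
  } else {
    GHpre <- NULL
    gh_src <- NULL
  }
  msg <- w * VH[src, , drop = FALSE]
  if (!is.null(gh_src)) msg <- msg * gh_src
  agg <- scatter_add(msg, dst, n)
  hhat <- h + sweep(agg %*% lp$O_h, 2, lp$b_Oh, "+")

  ffn_block <- function(x, fp, bn_in, bn_out) {
    z <- sweep(x %*% fp$W1, 2, fp$b1, "+")
    a <- lrelu(z, config$leaky_slope)
    f <- sweep(a %*% fp$W2, 2, fp$b2, "+")
    b1 <- bn_forward(f, bn_in, training)
    v <- x + b1$out
    b2 <- bn_forward(v, bn_out, training)
    list(out = b2$out, bn_in = b1$bn, bn_out = b2$bn,
         cache = list(z = z, a = a, b1 = b1$cache, b2 = b2$cache, x = x))
  }
  fh <- ffn_block(hhat, lp$ffn_h, lp$bn_h_in, lp$bn_h_out)
  fe <- ffn_block(ehat, lp$ffn_e, lp$bn_e_in, lp$bn_e_out)
  lp$bn_h_in <- fh$bn_in; lp$bn_h_out <- fh$bn_out
  lp$bn_e_in <- fe$bn_in; lp$bn_e_out <- fe$bn_out

  cache <- list(h = h, e = e, QH = QH, KH = KH, VH = VH, EH = EH, dot = dot,
                what = what, ge = ge, wg = wg, w = w, GHpre = GHpre,
                gh_src = gh_src, msg = msg, agg = agg, hhat = hhat,
                ehat = ehat, fh = fh$cache, fe = fe$cache)
  list(h = fh$out, e = fe$out, lp = lp, cache = cache)
}

embed_forward <- function(x, ep, config, training) {
  z <- sweep(x %*% ep$W, 2, ep$b, "+")
  b <- bn_forward(z, ep$bn, training)
  out <- lrelu(b$out, config$leaky_slope)
  ep$bn <- b$bn
  list(out = out, ep = ep,
       cache = list(x = x, z = z, bn = b$cache, pre_act = b$out))
}

readout_forward <- function(p, rp, config, training, drop_mask = NULL) {
  act <- function(x) lrelu(x, config$leaky_slope)
  z1 <- sweep(p %*% rp$W1, 2, rp$b1, "+")
  b1 <- bn_forward(z1, rp$bn1, training)
  a1 <- act(b1$out)
  m1 <- NULL
  if (training && config$dropout > 0 && !is.null(drop_mask)) {
    m1 <- drop_mask$m1
    a1 <- a1 * m1
  }
  z2 <- sweep(a1 %*% rp$W2, 2, rp$b2, "+")
  b2 <- bn_forward(z2, rp$bn2, training)
  a2 <- act(b2$out)
  m2 <- NULL
  if (training && config$dropout > 0 && !is.null(drop_mask)) {
    m2 <- drop_mask$m2
    a2 <- a2 * m2
  }
  out <- sweep(a2 %*% rp$W3, 2, rp$b3, "+")
  rp$bn1 <- b1$bn; rp$bn2 <- b2$bn
  list(out = out, rp = rp,
       cache = list(p = p, z1 = z1, bn1 = b1$cache, pre1 = b1$out, m1 = m1,
                    a1 = a1, z2 = z2, bn2 = b2$cache, pre2 = b2$out, m2 = m2,
                    a2 = a2))
}

#' Forward pass of the gated graph transformer
#'
#' Embeds node and edge features, applies `n_layers` gated attention layers,
#' sum-pools node embeddings per graph, and evaluates the regression
#' (sigmoid) and classification (softmax) read-out heads.  In inference mode
#' (`training = FALSE`, the default) normalisation uses running statistics,
#' dropout is off, and the output is deterministic.
#'
#' @param graphs a featurised `complex_graph` or list of them.
#' @param params from [ggt_init_params()] or a trained checkpoint.
#' @param config the matching [ggt_config()].
#' @param training if TRUE, use batch statistics, apply dropout and keep the
#'   caches needed for the backward pass.
#' @param drop_masks pre-drawn dropout masks (internal, training only).
#' @return list with `score` (numeric per graph), `class_probs` (graphs x 4
#'   matrix, rows sum to 1), `ids`, and, when training, `cache` and updated
#'   `params` (running statistics).
#' @export
ggt_forward <- function(graphs, params, config, training = FALSE,
                        drop_masks = NULL) {
  b <- batch_graphs(graphs)
  if (!all(is.finite(b$node_feats)) || !all(is.finite(b$edge_feats))) {
    stop("non-finite input features", call. = FALSE)
  }
  emb_h <- embed_forward(b$node_feats, params$embed_h, config, training)
  emb_e <- embed_forward(b$edge_feats, params$embed_e, config, training)
  params$embed_h <- emb_h$ep
  params$embed_e <- emb_e$ep
  h <- emb_h$out
  e <- emb_e$out
  layer_caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    st <- ggt_layer_forward(h, e, b$src, b$dst, params$layers[[l]], config,
                            training)
    if (!all(is.finite(st$h)) || !all(is.finite(st$e))) {
      stop("numerical failure (non-finite embeddings) at layer ", l,
           call. = FALSE)
    }
    h <- st$h
    e <- st$e
    params$layers[[l]] <- st$lp
    layer_caches[[l]] <- st$cache
  }
  p <- scatter_add(h, b$graph_of_node, b$n_graphs)
  ro_reg <- readout_forward(p, params$readout$reg, config, training,
                            drop_masks$reg)
  ro_cls <- readout_forward(p, params$readout$cls, config, training,
                            drop_masks$cls)
  params$readout$reg <- ro_reg$rp
  params$readout$cls <- ro_cls$rp
  reg_logit <- as.numeric(ro_reg$out)
  score <- sigmoid_f(reg_logit)
  logits <- ro_cls$out
  lmax <- apply(logits, 1, max)
  ez <- exp(logits - lmax)
  class_probs <- ez / rowSums(ez)
  colnames(class_probs) <- QUALITY_CLASSES
  out <- list(score = score, class_probs = class_probs, ids = b$ids)
  if (training) {
    out$params <- params
    out$cache <- list(batch = b, emb_h = emb_h$cache, emb_e = emb_e$cache,
                      layers = layer_caches, p = p, ro_reg = ro_reg$cache,
                      ro_cls = ro_cls$cache, reg_logit = reg_logit,
                      score = score, class_probs = class_probs)
  }
  out
}

#' Score structures or graphs with a trained model
#'
#' Featurises structures if needed and returns one row per decoy with the
#' predicted DockQ-like score, the four class probabilities and the argmax
#' class.
#'
#' @param x a `complex_structure`, `complex_graph`, or list of either.
#' @param model a `ggt_fit` from [train_ggt()], or a list with elements
#'   `params` and `config`.
#' @return a tibble: `decoy_id`, `score`, `p_incorrect`, `p_acceptable`,
#'   `p_medium`, `p_high`, `class`.
#' @export
predict_quality <- function(x, model) {
  if (inherits(x, "complex_structure") || inherits(x, "complex_graph")) {
    x <- list(x)
  }
  graphs <- lapply(x, function(g) {
    if (inherits(g, "complex_structure")) {
      featurize_structure(g, k = model$config$k, pe_dim = model$config$pe_dim)
    } else g
  })
  fw <- ggt_forward(graphs, model$params, model$config, training = FALSE)
  cls <- QUALITY_CLASSES[max.col(fw$class_probs, ties.method = "first")]
  ids <- if (!is.null(names(x))) names(x) else fw$ids
  tibble::tibble(decoy_id = unname(ids), score = fw$score,
                 p_incorrect = fw$class_probs[, 1],
                 p_acceptable = fw$class_probs[, 2],
                 p_medium = fw$class_probs[, 3],
                 p_high = fw$class_probs[, 4],
                 class = factor(cls, levels = QUALITY_CLASSES))
}
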