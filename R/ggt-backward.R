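# Hand-written reverse-mode gradients for the GGT.  Mirrors the forward
# caches layer by layer; verified against central finite differences in the
# test suite (test-gradients.R).

zeros_like <- function(x) {
  if (is.list(x)) return(lapply(x, zeros_like))
  array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
}

# elementwise combine two parameter trees
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    return(mapply(tree_map2, b = b, MoreArgs = list(f = f), a,
                  SIMPLIFY = FALSE))
  }
  f(a, b)
}

# BN running stats live inside the parameter tree but carry no gradient;
# their "gradient" entries stay zero and the optimiser skips them.
bn_stat_names <- c("r_mean", "r_var")

readout_backward <- function(dout, rp, cache, config) {
  act_grad <- function(pre) lrelu_grad(pre, config$leaky_slope)
  g <- list()
  g$W3 <- t(cache$a2) %*% dout
  g$b3 <- colSums(dout)
  da2 <- dout %*% t(rp$W3)
  if (!is.null(cache$m2)) da2 <- da2 * cache$m2
  db2 <- da2 * act_grad(cache$pre2)
  bb2 <- bn_backward(db2, cache$bn2)
  g$bn2 <- list(gamma = bb2$dgamma, beta = bb2$dbeta,
                r_mean = rp$bn2$r_mean * 0, r_var = rp$bn2$r_var * 0)
  dz2 <- bb2$dx
  g$W2 <- t(cache$a1) %*% dz2
  g$b2 <- colSums(dz2)
  da1 <- dz2 %*% t(rp$W2)
  if (!is.null(cache$m1)) da1 <- da1 * cache$m1
  db1 <- da1 * act_grad(cache$pre1)
  bb1 <- bn_backward(db1, cache$bn1)
  g$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta,
                r_mean = rp$bn1$r_mean * 0, r_var = rp$bn1$r_var * 0)
  dz1 <- bb1$dx
  g$W1 <- t(cache$p) %*% dz1
  g$b1 <- colSums(dz1)
  dp <- dz1 %*% t(rp$W1)
  list(grads = g[c("W1", "b1", "bn1", "W2", "b2", "bn2", "W3", "b3")],
       dp = dp)
}

ffn_block_backward <- function(dout, fp, cache, config) {
  bb2 <- bn_backward(dout, cache$b2)
  dv <- bb2$dx
  dx <- dv                      # residual branch
  bb1 <- bn_backward(dv, cache$b1)
  df <- bb1$dx
  gW2 <- t(cache$a) %*% df
  gb2 <- colSums(df)
  da <- df %*% t(fp$W2)
  dz <- da * lrelu_grad(cache$z, config$leaky_slope)
  gW1 <- t(cache$x) %*% dz
  gb1 <- colSums(dz)
  dx <- dx + dz %*% t(fp$W1)
  list(dx = dx,
       ffn = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
       bn_in = list(gamma = bb1$dgamma, beta = bb1$dbeta,
                    r_mean = 0 * bb1$dgamma, r_var = 0 * bb1$dgamma),
       bn_out = list(gamma = bb2$dgamma, beta = bb2$dbeta,
                     r_mean = 0 * bb2$dgamma, r_var = 0 * bb2$dgamma))
}

ggt_layer_backward <- function(dh_next, de_next, src, dst, lp, cache,
                               config) {
  dk <- config$head_dim
  H <- config$n_heads
  n <- nrow(cache$h)
  g <- list()

  fb_h <- ffn_block_backward(dh_next, lp$ffn_h, cache$fh, config)
  g$ffn_h <- fb_h$ffn; g$bn_h_in <- fb_h$bn_in; g$bn_h_out <- fb_h$bn_out
  dhhat <- fb_h$dx
  fb_e <- ffn_block_backward(de_next, lp$ffn_e, cache$fe, config)
  g$ffn_e <- fb_e$ffn; g$bn_e_in <- fb_e$bn_in; g$bn_e_out <- fb_e$bn_out
  dehat <- fb_e$dx

  # node update (Eq 5)
  dh <- dhhat                                  # residual
  g$O_h <- t(cache$agg) %*% dhhat
  g$b_Oh <- colSums(dhhat)
  dagg <- dhhat %*% t(lp$O_h)
  dmsg <- dagg[dst, , drop = FALSE]
  v_src <- cache$VH[src, , drop = FALSE]
  if (!is.null(cache$gh_src)) {
    dw <- dmsg * cache$gh_src * v_src
    dv_src <- dmsg * cache$gh_src * cache$w
    dgh_src <- dmsg * cache$w * v_src
    dGHpre_src <- dgh_src * cache$gh_src * (1 - cache$gh_src)
    dGHpre <- scatter_add(dGHpre_src, src, n)
    g$W_Gh <- t(cache$h) %*% dGHpre
  } else {
    dw <- dmsg * v_src
    dv_src <- dmsg * cache$w
    dGHpre <- NULL
    g$W_Gh <- zeros_like(lp$W_Gh)
  }
  dVH <- scatter_add(dv_src, src, n)

  # softmax (Eq 4)
  dwg <- group_softmax_backward(dw, cache$w, dst, n)

  # edge gate (Eq 3)
  if (!is.null(cache$ge)) {
    dwhat <- dwg * cache$ge
    dGEpre <- dwg * cache$what * cache$ge * (1 - cache$ge)
    g$W_Ge <- t(cache$e) %*% dGEpre
  } else {
    dwhat <- dwg
    dGEpre <- NULL
    g$W_Ge <- zeros_like(lp$W_Ge)
  }

  # edge update (Eq 2)
  de <- dehat                                  # residual
  g$O_e <- t(cache$what) %*% dehat
  g$b_Oe <- colSums(dehat)
  dwhat <- dwhat + dehat %*% t(lp$O_e)

  # attention scores (Eq 1)
  dEH <- dwhat * cache$dot[, rep(seq_len(H), each = dk), drop = FALSE]
  ddot <- matrix(0, length(src), H)
  dQH <- matrix(0, n, H * dk)
  dKH <- matrix(0, n, H * dk)
  for (k in seq_len(H)) {
    ck <- ((k - 1) * dk + 1):(k * dk)
    ddot[, k] <- rowSums(dwhat[, ck, drop = FALSE] *
                         cache$EH[, ck, drop = FALSE])
    dQH_e <- (ddot[, k] / sqrt(dk)) * cache$KH[src, ck, drop = FALSE]
    dKH_e <- (ddot[, k] / sqrt(dk)) * cache$QH[dst, ck, drop = FALSE]
    dQH[, ck] <- scatter_add(dQH_e, dst, n)
    dKH[, ck] <- scatter_add(dKH_e, src, n)
  }

  # input projections
  g$W_Q <- t(cache$h) %*% dQH
  g$W_K <- t(cache$h) %*% dKH
  g$W_V <- t(cache$h) %*% dVH
  g$W_E <- t(cache$e) %*% dEH
  dh <- dh + dQH %*% t(lp$W_Q) + dKH %*% t(lp$W_K) + dVH %*% t(lp$W_V)
  if (!is.null(dGHpre)) dh <- dh + dGHpre %*% t(lp$W_Gh)
  de <- de + dEH %*% t(lp$W_E)
  if (!is.null(dGEpre)) de <- de + dGEpre %*% t(lp$W_Ge)

  grads <- g[c("W_Q", "W_K", "W_V", "W_E", "W_Ge", "W_Gh", "O_h", "b_Oh",
               "O_e", "b_Oe", "ffn_h", "bn_h_in", "bn_h_out", "ffn_e",
               "bn_e_in", "bn_e_out")]
  list(dh = dh, de = de, grads = grads)
}

embed_backward <- function(dout, ep, cache, config) {
  db <- dout * lrelu_grad(cache$pre_act, config$leaky_slope)
  bb <- bn_backward(db, cache$bn)
  dz <- bb$dx
  list(grads = list(W = t(cache$x) %*% dz, b = colSums(dz),
                    bn = list(gamma = bb$dgamma, beta = bb$dbeta,
                              r_mean = 0 * bb$dgamma,
                              r_var = 0 * bb$dgamma)),
       dx = dz %*% t(ep$W))
}

# Full backward pass: takes the training-mode forward cache plus the
# gradients of the loss w.r.t. the regression logit (per graph) and the
# classification logits (graphs x 4), returns a gradient tree shaped like
# the parameter tree.
ggt_backward <- function(params, config, cache, d_reg_logit, d_cls_logits) {
  b <- cache$batch
  ro_reg <- readout_backward(matrix(d_reg_logit, ncol = 1),
                             params$readout$reg, cache$ro_reg, config)
  ro_cls <- readout_backward(d_cls_logits, params$readout$cls, cache$ro_cls,
                             config)
  dp <- ro_reg$dp + ro_cls$dp
  dh <- dp[b$graph_of_node, , drop = FALSE]    # sum-pool backward
  de <- matrix(0, length(b$src), config$edge_hidden)
  layer_grads <- vector("list", config$n_layers)
  for (l in rev(seq_len(config$n_layers))) {
    lb <- ggt_layer_backward(dh, de, b$src, b$dst, params$layers[[l]],
                             cache$layers[[l]], config)
    dh <- lb$dh
    de <- lb$de
    layer_grads[[l]] <- lb$grads
  }
  eb_h <- embed_backward(dh, params$embed_h, cache$emb_h, config)
  eb_e <- embed_backward(de, params$embed_e, cache$emb_e, config)
  list(embed_h = eb_h$grads, embed_e = eb_e$grads, layers = layer_grads,
       readout = list(reg = ro_reg$grads, cls = ro_cls$grads))
}
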