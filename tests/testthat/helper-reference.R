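# Independent oracles, written loop-wise and kept free of the package's
# vectorised code paths.

# dihedral via the two-plane-normal formula (acos + chirality sign)
ref_dihedral <- function(p1, p2, p3, p4) {
  u1 <- p2 - p1; u2 <- p3 - p2; u3 <- p4 - p3
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                         a[1]*b[2]-a[2]*b[1])
  n1 <- cr(u1, u2); n2 <- cr(u2, u3)
  cosang <- sum(n1*n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(cr(n1, n2) * u2) < 0) ang <- -ang
  ang
}

# exhaustive k-NN neighbour sets by sorted distances (ties: lower index)
ref_knn_sets <- function(ca, k) {
  n <- nrow(ca)
  lapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(ca) - ca[i, ])^2))
    ord <- order(d, seq_len(n))
    setdiff(ord, i)[seq_len(min(k, n - 1))]
  })
}

ref_sigmoid <- function(x) 1 / (1 + exp(-x))

# Loop-based dense reference of the full GGT forward pass in inference mode.
# Structured around the per-edge/per-head/per-channel equations rather than
# the package's head-block matrix path.
ref_ggt_forward <- function(graph, params, config) {
  slope <- config$leaky_slope
  lr <- function(x) ifelse(x > 0, x, slope * x)
  bn_inf <- function(row, bn) {
    bn$gamma * (row - bn$r_mean) / sqrt(bn$r_var + 1e-5) + bn$beta
  }
  N <- graph$n_nodes
  E <- length(graph$edge_src)
  src <- graph$edge_src
  dst <- graph$edge_dst
  H <- config$n_heads
  dk <- config$head_dim
  HD <- H * dk

  embed <- function(X, ep) {
    out <- matrix(0, nrow(X), length(ep$b))
    for (i in seq_len(nrow(X))) {
      z <- as.numeric(X[i, ] %*% ep$W) + ep$b
      out[i, ] <- lr(bn_inf(z, ep$bn))
    }
    out
  }
  h <- embed(graph$node_feats, params$embed_h)
  e <- embed(graph$edge_feats, params$embed_e)

  for (l in seq_len(config$n_layers)) {
    lp <- params$layers[[l]]
    what <- matrix(0, E, HD)
    for (ei in seq_len(E)) {
      for (k in seq_len(H)) {
        dot <- 0
        for (c in seq_len(dk)) {
          col <- (k - 1) * dk + c
          dot <- dot + sum(h[dst[ei], ] * lp$W_Q[, col]) *
            sum(h[src[ei], ] * lp$W_K[, col])
        }
        dot <- dot / sqrt(dk)
        for (c in seq_len(dk)) {
          col <- (k - 1) * dk + c
          what[ei, col] <- dot * sum(e[ei, ] * lp$W_E[, col])
        }
      }
    }
    ehat <- matrix(0, E, ncol(e))
    for (ei in seq_len(E)) {
      ehat[ei, ] <- e[ei, ] + as.numeric(what[ei, ] %*% lp$O_e) + lp$b_Oe
    }
    wg <- what
    if (config$edge_gate_enabled) {
      for (ei in seq_len(E)) {
        for (col in seq_len(HD)) {
          wg[ei, col] <- what[ei, col] *
            ref_sigmoid(sum(e[ei, ] * lp$W_Ge[, col]))
        }
      }
    }
    w <- matrix(0, E, HD)
    for (i in seq_len(N)) {
      inc <- which(dst == i)
      for (col in seq_len(HD)) {
        ex <- exp(wg[inc, col] - max(wg[inc, col]))
        w[inc, col] <- ex / sum(ex)
      }
    }
    agg <- matrix(0, N, HD)
    for (ei in seq_len(E)) {
      for (col in seq_len(HD)) {
        v <- sum(h[src[ei], ] * lp$W_V[, col])
        m <- w[ei, col] * v
        if (config$node_gate_enabled) {
          m <- m * ref_sigmoid(sum(h[src[ei], ] * lp$W_Gh[, col]))
        }
        agg[dst[ei], col] <- agg[dst[ei], col] + m
      }
    }
    hhat <- matrix(0, N, ncol(h))
    for (i in seq_len(N)) {
      hhat[i, ] <- h[i, ] + as.numeric(agg[i, ] %*% lp$O_h) + lp$b_Oh
    }
    ffn_block <- function(X, fp, bn_in, bn_out) {
      out <- matrix(0, nrow(X), ncol(X))
      for (i in seq_len(nrow(X))) {
        z <- as.numeric(X[i, ] %*% fp$W1) + fp$b1
        f <- as.numeric(lr(z) %*% fp$W2) + fp$b2
        out[i, ] <- bn_inf(X[i, ] + bn_inf(f, bn_in), bn_out)
      }
      out
    }
    h <- ffn_block(hhat, lp$ffn_h, lp$bn_h_in, lp$bn_h_out)
    e <- ffn_block(ehat, lp$ffn_e, lp$bn_e_in, lp$bn_e_out)
  }

  p <- rep(0, ncol(h))
  for (i in seq_len(N)) p <- p + h[i, ]
  readout <- function(rp) {
    a1 <- lr(bn_inf(as.numeric(p %*% rp$W1) + rp$b1, rp$bn1))
    a2 <- lr(bn_inf(as.numeric(a1 %*% rp$W2) + rp$b2, rp$bn2))
    as.numeric(a2 %*% rp$W3) + rp$b3
  }
  logit <- readout(params$readout$reg)
  cl <- readout(params$readout$cls)
  probs <- exp(cl - max(cl))
  probs <- probs / sum(probs)
  list(score = ref_sigmoid(logit), class_probs = probs)
}
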