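test_that("k-NN topology has the stated edge counts and clamps small N", {
  set.seed(31)
  big <- ca_only_structure(matrix(rnorm(150, sd = 10), 50, 3))
  g <- build_knn_graph(big, k = 10)
  expect_equal(length(g$edge_src), 50 * 10 + 50)
  small <- ca_only_structure(matrix(rnorm(15, sd = 10), 5, 3))
  gs <- build_knn_graph(small, k = 10)
  expect_equal(length(gs$edge_src), 5 * 4 + 5)
  expect_error(build_knn_graph(ca_only_structure(matrix(0, 1, 3))),
               "degenerate")
})

test_that("neighbour sets equal the exhaustive sorted-distance oracle", {
  set.seed(32)
  ca <- matrix(rnorm(90, sd = 8), 30, 3)
  g <- build_knn_graph(ca_only_structure(ca), k = 6)
  ref <- ref_knn_sets(ca, 6)
  for (i in seq_len(30)) {
    mine <- sort(g$edge_src[g$edge_dst == i & g$edge_src != i])
    expect_equal(mine, sort(ref[[i]]))
  }
})

test_that("every node carries exactly one self-loop", {
  g <- featurize_structure(toy_native(seed = 33), k = 5)
  self <- g$edge_src == g$edge_dst
  expect_equal(sum(self), g$n_nodes)
  expect_equal(sort(g$edge_dst[self]), seq_len(g$n_nodes))
})

test_that("Laplacian encoding matches a dense eigendecomposition on a path", {
  # 4-node path graph, constructed via collinear points with k = 1
  ca <- cbind(c(0, 3.8, 7.6, 11.4), 0, 0)
  g <- build_knn_graph(ca_only_structure(ca), k = 1)
  # undirected union of 1-NN edges on a path: 1-2, 2-3 (tie), 3-4 ...
  pe <- laplacian_pe(g, dim = 8)
  A <- matrix(0, 4, 4)
  keep <- g$edge_src != g$edge_dst
  A[cbind(g$edge_src[keep], g$edge_dst[keep])] <- 1
  A <- pmax(A, t(A))
  D <- diag(1 / sqrt(rowSums(A)))
  L <- diag(4) - D %*% A %*% D
  eg <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- order(eg$values)
  nonzero <- ord[eg$values[ord] > 1e-8]
  for (j in seq_along(nonzero)) {
    v <- eg$vectors[, nonzero[j]]
    v <- v / sqrt(sum(v^2))
    lead <- which(abs(v) > 1e-8)[1]
    if (v[lead] < 0) v <- -v
    expect_equal(pe[, j], v, tolerance = 1e-8)
  }
  # fewer eigenvectors than dims: padding columns are exactly zero
  expect_true(all(pe[, (length(nonzero) + 1):8] == 0))
  # returned columns are unit norm
  norms <- sqrt(colSums(pe^2))
  expect_true(all(abs(norms[seq_along(nonzero)] - 1) < 1e-8))
})

test_that("node features use the documented 35-column layout", {
  st <- annotate_structure(toy_native(seed = 34))
  g <- featurize_structure(st)
  expect_equal(ncol(g$node_feats), 35)
  expect_equal(rowSums(g$node_feats[, 1:21]), rep(1, g$n_nodes))
  expect_equal(rowSums(g$node_feats[, 22:24]), rep(1, g$n_nodes))
  expect_equal(g$node_feats[, 25], clamp(st$rsa, 0, 1), ignore_attr = TRUE)
  expect_true(all(g$node_feats[, 25:27] >= 0 & g$node_feats[, 25:27] <= 1))
})

test_that("angle columns min-max map [-180,180] to [0,1] with 0.5 for NA", {
  expect_equal(ggtqa:::normalize_angle(c(-180, 0, 180, NA)),
               c(0, 0.5, 1, 0.5))
  st <- annotate_structure(toy_native(seed = 35))
  g <- featurize_structure(st)
  expect_equal(g$node_feats[is.na(st$phi), 26],
               rep(0.5, sum(is.na(st$phi))))
})

test_that("edge features match direct geometric recomputation", {
  st <- annotate_structure(toy_native(seed = 36))
  g <- featurize_structure(st)
  expect_equal(ncol(g$edge_feats), 6)
  ca <- as.matrix(st[, c("ca_x", "ca_y", "ca_z")])
  cb <- suppressMessages(virtual_cbeta(st))
  set.seed(36)
  for (ei in sample(length(g$edge_src), 40)) {
    s <- g$edge_src[ei]; d <- g$edge_dst[ei]
    if (s == d) next  # self-loops carry the fixed degenerate features
    expect_equal(g$edge_feats[ei, 1], sqrt(sum((ca[s, ] - ca[d, ])^2)),
                 tolerance = 1e-6)
    expect_equal(g$edge_feats[ei, 2], sqrt(sum((cb[s, ] - cb[d, ])^2)),
                 tolerance = 1e-6)
    no <- sqrt(sum((as.numeric(st[s, c("n_x", "n_y", "n_z")]) -
                    as.numeric(st[d, c("o_x", "o_y", "o_z")]))^2))
    expect_equal(g$edge_feats[ei, 3], no, tolerance = 1e-6)
    expect_equal(g$edge_feats[ei, 4], as.numeric(g$edge_feats[ei, 2] < 8))
  }
})

test_that("contact flag uses a strict 8 Angstrom cutoff", {
  # two isolated residues at exactly controllable CB distance
  mk <- function(d) {
    st <- toy_native(seed = 37, lengths = c(3, 3))
    ca <- as.matrix(st[, c("ca_x", "ca_y", "ca_z")])
    cb <- suppressMessages(virtual_cbeta(st))
    # translate chain B so the closest CB pair sits at exactly d
    rowsB <- which(st$chain == "B")
    d2 <- ggtqa:::cross_dist2(cb[-rowsB, , drop = FALSE],
                              cb[rowsB, , drop = FALSE])
    ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    a <- cb[ij[1], ]; b <- cb[rowsB[ij[2]], ]
    dirv <- (b - a) / sqrt(sum((b - a)^2))
    shift <- (d - sqrt(min(d2))) * dirv
    ggtqa:::transform_rows(st, rowsB, diag(3), shift)
  }
  g1 <- featurize_structure(annotate_structure(mk(7.99)))
  g2 <- featurize_structure(annotate_structure(mk(8.00)))
  pick <- function(g, d) {
    i <- which(abs(g$edge_feats[, 2] - d) < 1e-3)
    g$edge_feats[i, 4]
  }
  expect_true(all(pick(g1, 7.99) == 1))
  expect_true(all(pick(g2, 8.00) == 0))
})

test_that("chain flag and edgewise positional encoding follow the contract", {
  st <- annotate_structure(toy_native(seed = 38, lengths = c(34, 36)))
  g <- featurize_structure(st)
  src <- g$edge_src; dst <- g$edge_dst
  same <- st$chain[src] == st$chain[dst]
  sep <- st$seq_index[dst] - st$seq_index[src]
  adj <- same & abs(sep) == 1
  expect_equal(g$edge_feats[, 5], as.numeric(adj))
  expect_true(all(g$edge_feats[!same, 6] == 0))
  expect_equal(g$edge_feats[same, 6], clamp(sep[same], -32, 32) / 32)
  # self-loops: zero distances, contact 1, chain flag 0, zero encoding
  self <- src == dst
  expect_true(all(g$edge_feats[self, 1:3] == 0))
  expect_true(all(g$edge_feats[self, 4] == 1))
  expect_true(all(g$edge_feats[self, 5:6] == 0))
})

test_that("inter-chain-only contact switch masks same-chain contacts", {
  st <- annotate_structure(toy_native(seed = 39))
  g0 <- featurize_structure(st)
  g1 <- featurize_structure(st, contact_interchain_only = TRUE)
  same <- st$chain[g1$edge_src] == st$chain[g1$edge_dst]
  self <- g1$edge_src == g1$edge_dst
  expect_true(all(g1$edge_feats[same & !self, 4] == 0))
  expect_true(all(g1$edge_feats[self, 4] == 1))  # self-loop rule wins
  expect_equal(g1$edge_feats[!same, 4], g0$edge_feats[!same, 4])
})

test_that("featurisation is deterministic and rigid-motion invariant", {
  st <- annotate_structure(toy_native(seed = 40))
  g1 <- featurize_structure(st)
  g2 <- featurize_structure(st)
  expect_identical(g1$node_feats, g2$node_feats)
  expect_identical(g1$edge_feats, g2$edge_feats)

  moved <- annotate_structure(rigid_move(st, angle = 77, shift = c(-8, 4, 2)))
  gm <- featurize_structure(moved)
  expect_equal(gm$edge_src, g1$edge_src)
  expect_equal(gm$edge_dst, g1$edge_dst)
  expect_lt(max(abs(gm$node_feats - g1$node_feats)), 1e-5)
  expect_lt(max(abs(gm$edge_feats - g1$edge_feats)), 1e-5)
})

test_that("graph containers round-trip through the JSON dump", {
  g <- featurize_structure(toy_native(seed = 41), k = 4)
  path <- withr::local_tempfile(fileext = ".graph.json")
  write_graph(g, path)
  g2 <- read_graph(path)
  expect_equal(g2$edge_src, g$edge_src)
  expect_equal(g2$node_feats, g$node_feats, tolerance = 1e-12)
  expect_equal(g2$edge_feats, g$edge_feats, tolerance = 1e-12)
  expect_equal(g2$target_id, g$target_id)
})
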