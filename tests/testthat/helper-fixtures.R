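# Small shared fixtures, built once per test run.

toy_native <- function(seed = 11, lengths = c(12, 10), geometry = "helix") {
  generate_native(fixture_spec(chain_lengths = lengths, geometry = geometry,
                               seed = seed))
}

toy_graph_small <- function() {
  # 6-node complex: two 3-residue chains, dense-ish topology with k = 2
  st <- toy_native(seed = 21, lengths = c(3, 3))
  featurize_structure(st, k = 2)
}

tiny_cfg <- function(...) {
  ggt_config(n_layers = 2, n_heads = 2, head_dim = 2, edge_hidden = 4,
             readout_hidden_dims = c(6, 5), dropout = 0, k = 2, seed = 7,
             ...)
}

# a bare structure tibble from CA coordinates only (for k-NN oracles)
ca_only_structure <- function(ca, chain = rep("A", nrow(ca))) {
  n <- nrow(ca)
  df <- tibble::tibble(
    chain = chain, resno = seq_len(n), icode = "",
    seq_index = unlist(lapply(table(factor(chain, unique(chain))),
                              function(k) seq_len(k) - 1L)),
    res_type = rep_len(c("ALA", "GLY", "SER"), n),
    n_x = NA_real_, n_y = NA_real_, n_z = NA_real_,
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    c_x = NA_real_, c_y = NA_real_, c_z = NA_real_,
    o_x = NA_real_, o_y = NA_real_, o_z = NA_real_,
    cb_x = NA_real_, cb_y = NA_real_, cb_z = NA_real_,
    phi = NA_real_, psi = NA_real_, ss3 = "coil", rsa = 0.5)
  ggtqa:::new_complex_structure(df, "points")
}

# apply a rigid rotation + translation to every atom of a structure
rigid_move <- function(structure, axis = c(1, 2, 3), angle = 35,
                       shift = c(5, -3, 11)) {
  R <- ggtqa:::rotation_matrix(axis, angle)
  ggtqa:::transform_rows(structure, seq_len(nrow(structure)), R, shift)
}
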