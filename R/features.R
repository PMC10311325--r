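#' Directed k-nearest-neighbour residue graph topology
#'
#' Each residue is a node at its C-alpha position; chains are pooled, so
#' inter-chain edges arise naturally.  For every node i, a directed edge
#' j -> i is added from each of its k nearest other nodes by C-alpha distance
#' (all k clamped to N-1 when the complex is small), plus one self-loop
#' i -> i, so that each node's incoming neighbourhood includes itself.
#' Ties at the k-th distance are broken deterministically by lower node index
#' (chain-major order), making builds bit-reproducible.
#'
#' @param structure a `complex_structure` with at least 2 residues.
#' @param k number of neighbours (default 10).
#' @return a `complex_graph` list: `n_nodes`, `edge_src`, `edge_dst` (1-based
#'   integer vectors, self-loops last per node), `chain_of_node`, `target_id`;
#'   `node_feats` / `edge_feats` are NULL until [encode_node_features()] /
#'   [encode_edge_features()] run.
#' @export
build_knn_graph <- function(structure, k = 10) {
  stopifnot(inherits(structure, "complex_structure"), k >= 1)
  n <- nrow(structure)
  if (n < 2) stop("degenerate input: need at least 2 residues", call. = FALSE)
  ca <- ca_matrix(structure)
  d2 <- cross_dist2(ca, ca)
  kk <- min(k, n - 1)
  src <- integer(0)
  dst <- integer(0)
  # squared distances are quantised (1e-6 A^2) before sorting so that ties —
  # including near-ties created by floating-point noise under rigid motion —
  # break deterministically by lower node index
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(round(d2[i, others], 6), others)]
    nb <- ord[seq_len(kk)]
    src <- c(src, nb, i)  # self-loop appended after the k neighbours
    dst <- c(dst, rep(i, kk + 1L))
  }
  g <- list(n_nodes = n,
            edge_src = as.integer(src),
            edge_dst = as.integer(dst),
            node_feats = NULL,
            edge_feats = NULL,
            chain_of_node = match(structure$chain, unique(structure$chain)),
            target_id = target_id(structure))
  class(g) <- "complex_graph"
  g
}

#' @export
print.complex_graph <- function(x, ...) {
  cat(sprintf("<complex_graph> '%s': %d nodes, %d edges%s\n", x$target_id,
              x$n_nodes, length(x$edge_src),
              if (is.null(x$node_feats)) " (topology only)" else
                sprintf(", features %dx%d / %dx%d", nrow(x$node_feats),
                        ncol(x$node_feats), nrow(x$edge_feats),
                        ncol(x$edge_feats))))
  invisible(x)
}

#' Graph Laplacian positional encoding
#'
#' Eigenvectors of the symmetric normalised Laplacian of the graph viewed as
#' undirected with self-loops removed, for the `dim` smallest non-zero
#' eigenvalues.  Columns are the (unit L2 norm) eigenvectors; the trivial
#' zero-eigenvalue vector is excluded; when fewer than `dim` non-trivial
#' eigenvectors exist the remaining columns are zero-padded.  The sign of each
#' eigenvector is fixed deterministically (first entry with magnitude above
#' 1e-8 made positive) so repeated builds are identical; an optional random
#' sign flip for training-time augmentation is off by default.
#'
#' @param graph a `complex_graph`.
#' @param dim number of encoding dimensions (default 8).
#' @param random_sign if TRUE, flip each column's sign with probability 1/2.
#' @return an N x dim numeric matrix.
#' @export
laplacian_pe <- function(graph, dim = 8, random_sign = FALSE) {
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  keep <- graph$edge_src != graph$edge_dst
  A[cbind(graph$edge_src[keep], graph$edge_dst[keep])] <- 1
  A <- pmax(A, t(A))  # undirected
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(n) - (dinv * A) %*% diag(dinv)
  L <- (L + t(L)) / 2
  eig <- eigen(L, symmetric = TRUE)
  # ascending eigenvalues, excluding the (near-)zero ones
  ord <- order(eig$values)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  nonzero <- which(vals > 1e-8)
  take <- nonzero[seq_len(min(dim, length(nonzero)))]
  pe <- matrix(0, n, dim)
  for (j in seq_along(take)) {
    v <- vecs[, take[j]]
    v <- v / sqrt(sum(v^2))
    lead <- which(abs(v) > 1e-8)[1]
    if (!is.na(lead) && v[lead] < 0) v <- -v
    if (random_sign && runif(1) < 0.5) v <- -v
    pe[, j] <- v
  }
  pe
}

# [-180, 180] -> [0, 1]; undefined angles sit at the midpoint 0.5 so they do
# not alias with a real -180 degree angle.
normalize_angle <- function(a) ifelse(is.na(a), 0.5, (a + 180) / 360)

#' Encode the N x 35 node-feature matrix
#'
#' Fixed, documented column layout (1-based): 1-21 residue-type one-hot (20
#' standard amino acids alphabetically by three-letter code, then UNK); 22-24
#' secondary-structure one-hot (helix, strand, coil); 25 relative accessible
#' surface area; 26 normalised phi; 27 normalised psi (min-max map of
#' \[-180, 180\] to \[0, 1\], undefined angles encoded 0.5); 28-35 the 8-dim
#' graph Laplacian positional encoding.
#'
#' @param structure an annotated `complex_structure`.
#' @param graph the matching `complex_graph`.
#' @param pe_dim positional-encoding dimensions.
#' @param random_sign passed to [laplacian_pe()].
#' @return the graph with `node_feats` set (N x (27 + pe_dim)).
#' @export
encode_node_features <- function(structure, graph, pe_dim = 8,
                                 random_sign = FALSE) {
  stopifnot(nrow(structure) == graph$n_nodes)
  n <- graph$n_nodes
  res_onehot <- matrix(0, n, 21L)
  res_onehot[cbind(seq_len(n), match(structure$res_type, RES_TYPES))] <- 1
  ss_onehot <- matrix(0, n, 3L)
  ss_onehot[cbind(seq_len(n),
                  match(structure$ss3, c("helix", "strand", "coil")))] <- 1
  feats <- cbind(res_onehot, ss_onehot,
                 clamp(structure$rsa, 0, 1),
                 normalize_angle(structure$phi),
                 normalize_angle(structure$psi),
                 laplacian_pe(graph, dim = pe_dim, random_sign = random_sign))
  stopifnot(ncol(feats) == 27 + pe_dim, all(is.finite(feats)))
  graph$node_feats <- unname(feats)
  graph
}

#' Encode the E x 6 edge-feature matrix
#'
#' Fixed column layout (1-based): 1 C-alpha - C-alpha distance (Angstrom);
#' 2 C-beta - C-beta distance (virtual C-beta for glycine); 3 N-O distance
#' (source residue's backbone N to destination residue's O); 4 contact flag,
#' 1 iff the C-beta - C-beta distance is strictly below 8 Angstrom (optionally
#' restricted to inter-chain pairs); 5 chain flag, 1 iff the two residues are
#' consecutive in the same chain; 6 edgewise positional encoding, the signed
#' sequence separation clipped to \[-32, 32\] and divided by 32 for same-chain
#' pairs, 0 across chains.  Self-loops carry distances 0, contact 1, chain
#' flag 0 and positional encoding 0.  A missing N or O atom yields the
#' C-alpha - C-alpha distance as a stand-in for column 3.
#'
#' @param structure an annotated `complex_structure`.
#' @param graph the matching `complex_graph` with topology built.
#' @param contact_interchain_only restrict the contact flag to inter-chain
#'   edges (default FALSE: any edge with C-beta distance under 8 A counts).
#' @param distance_divisor optional divisor applied to the three distance
#'   columns (default 1: plain Angstrom).
#' @return the graph with `edge_feats` set (E x 6).
#' @export
encode_edge_features <- function(structure, graph,
                                 contact_interchain_only = FALSE,
                                 distance_divisor = 1) {
  stopifnot(nrow(structure) == graph$n_nodes)
  src <- graph$edge_src
  dst <- graph$edge_dst
  ca <- ca_matrix(structure)
  cb <- virtual_cbeta(structure)
  Nm <- as.matrix(structure[, c("n_x", "n_y", "n_z")])
  Om <- as.matrix(structure[, c("o_x", "o_y", "o_z")])
  edist <- function(a, b) sqrt(rowSums((a - b)^2))
  d_ca <- edist(ca[src, , drop = FALSE], ca[dst, , drop = FALSE])
  d_cb <- edist(cb[src, , drop = FALSE], cb[dst, , drop = FALSE])
  d_no <- edist(Nm[src, , drop = FALSE], Om[dst, , drop = FALSE])
  d_no[!is.finite(d_no)] <- d_ca[!is.finite(d_no)]
  same_chain <- structure$chain[src] == structure$chain[dst]
  contact <- as.numeric(d_cb < 8)
  if (contact_interchain_only) contact[same_chain] <- 0
  sep <- structure$seq_index[dst] - structure$seq_index[src]
  adjacent <- as.numeric(same_chain & abs(sep) == 1)
  pe <- ifelse(same_chain, clamp(sep, -32, 32) / 32, 0)
  self <- src == dst
  contact[self] <- 1  # zero distance is trivially a contact
  d_ca[self] <- 0
  d_cb[self] <- 0
  d_no[self] <- 0     # the residue's own N-O separation is not meaningful
  feats <- cbind(d_ca / distance_divisor, d_cb / distance_divisor,
                 d_no / distance_divisor, contact, adjacent, pe)
  stopifnot(ncol(feats) == 6, all(is.finite(feats)))
  graph$edge_feats <- unname(feats)
  graph
}

#' Full featurisation pipeline: structure to ready-to-score graph
#'
#' Annotates the structure (torsions, secondary structure, RSA) unless already
#' done, builds the k-NN topology, and encodes node and edge features.
#'
#' @param structure a `complex_structure` (annotated or not).
#' @param k neighbours per node.
#' @param pe_dim Laplacian positional-encoding dimensions.
#' @param ... passed to [encode_edge_features()].
#' @return a fully featurised `complex_graph`.
#' @examples
#' g <- featurize_structure(generate_native(fixture_spec(seed = 1)))
#' dim(g$node_feats)
#' @export
featurize_structure <- function(structure, k = 10, pe_dim = 8, ...) {
  if (anyNA(structure$rsa) || all(is.na(structure$ss3))) {
    structure <- annotate_structure(structure)
  }
  g <- build_knn_graph(structure, k = k)
  g <- encode_node_features(structure, g, pe_dim = pe_dim)
  encode_edge_features(structure, g, ...)
}

#' Serialise / restore a featurised graph
#'
#' Plain-JSON container for caching graphs between the featurise and
#' train/predict stages.  The column order of both feature matrices is part
#' of the format and matches [encode_node_features()] and
#' [encode_edge_features()]; a `format_version` field guards compatibility.
#'
#' @param graph a `complex_graph`.
#' @param path file path.
#' @return `write_graph` returns `path` invisibly; `read_graph` the graph.
#' @export
write_graph <- function(graph, path) {
  obj <- list(format_version = 1L,
              target_id = graph$target_id,
              n_nodes = graph$n_nodes,
              edge_src = graph$edge_src,
              edge_dst = graph$edge_dst,
              chain_of_node = graph$chain_of_node,
              node_feats = graph$node_feats,
              edge_feats = graph$edge_feats)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unrecognised graph container version", call. = FALSE)
  }
  g <- list(n_nodes = as.integer(obj$n_nodes),
            edge_src = as.integer(obj$edge_src),
            edge_dst = as.integer(obj$edge_dst),
            node_feats = unname(as.matrix(obj$node_feats)),
            edge_feats = unname(as.matrix(obj$edge_feats)),
            chain_of_node = as.integer(obj$chain_of_node),
            target_id = obj$target_id)
  class(g) <- "complex_graph"
  g
}
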