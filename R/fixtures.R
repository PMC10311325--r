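# Ideal backbone internal coordinates (Engh-Huber-like averages).
BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
           ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
           ang_ca_c_o = 120.8, omega = 180)

GEOMETRY_TORSIONS <- list(helix = c(phi = -57, psi = -47),
                          extended = c(phi = -120, psi = 130))

FIXTURE_RES_CYCLE <- c("ALA", "GLY", "LEU", "SER", "GLU", "LYS", "VAL",
                       "THR", "PHE", "ASP")

#' Specification of a synthetic toy complex and its decoy pool
#'
#' Defines the deterministic generator for a multi-chain toy complex:
#' chain counts and lengths, backbone geometry, and the graded perturbation
#' magnitudes used to produce decoys.  The default perturbation ladder spans
#' near-native to interface-destroying (ligand translations 0 to 40 Angstrom
#' with matched rotations and atomic noise), so a default pool covers all
#' four quality classes.
#'
#' @param n_chains number of chains (>= 1; decoy generation needs >= 2).
#' @param chain_lengths residues per chain (recycled to `n_chains`; each
#'   >= 3).
#' @param geometry "helix", "extended", or "mixed" (alternating blocks).
#' @param perturbations data frame with columns `rot_deg`, `trans_ang`,
#'   `noise_ang`: ligand rotation (degrees), ligand translation (Angstrom)
#'   and per-atom Gaussian noise sd (Angstrom) per decoy grade.
#' @param seed mandatory integer seed; all generator randomness derives from
#'   it.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_chains = 2, chain_lengths = c(20, 20),
                         geometry = c("helix", "extended", "mixed"),
                         perturbations = default_perturbations(),
                         seed) {
  geometry <- match.arg(geometry)
  if (missing(seed)) stop("fixture_spec requires an explicit seed",
                          call. = FALSE)
  chain_lengths <- rep_len(chain_lengths, n_chains)
  stopifnot(n_chains >= 1, all(chain_lengths >= 3),
            all(perturbations$rot_deg >= 0),
            all(perturbations$trans_ang >= 0),
            all(perturbations$noise_ang >= 0))
  structure(list(n_chains = n_chains, chain_lengths = chain_lengths,
                 geometry = geometry,
                 perturbations = tibble::as_tibble(perturbations),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @export
default_perturbations <- function() {
  tibble::tibble(rot_deg = c(0, 5, 15, 60),
                 trans_ang = c(0, 2, 8, 40),
                 noise_ang = c(0.05, 0.05, 0.2, 0.5))
}

# Build one ideal chain of n residues; returns a residue tibble fragment.
build_chain <- function(n, chain_id, geometry, first_resno = 1L) {
  torsions <- matrix(0, n, 2)
  if (geometry == "mixed") {
    half <- ceiling(n / 2)
    torsions[seq_len(half), ] <- matrix(GEOMETRY_TORSIONS$helix, half, 2,
                                        byrow = TRUE)
    if (half < n) {
      torsions[(half + 1):n, ] <- matrix(GEOMETRY_TORSIONS$extended,
                                         n - half, 2, byrow = TRUE)
    }
  } else {
    torsions[] <- matrix(GEOMETRY_TORSIONS[[geometry]], n, 2, byrow = TRUE)
  }
  N <- CA <- C <- O <- CBm <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB$n_ca, 0, 0)
  # place C1 in the xy-plane at the ideal N-CA-C angle
  a <- BB$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + BB$ca_c * c(-cos(a), sin(a), 0)
  for (i in 2:n) {
    psi_prev <- torsions[i - 1, 2]
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BB$c_n, BB$ang_ca_c_n, psi_prev)
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BB$n_ca, BB$ang_c_n_ca, BB$omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         BB$ca_c, BB$ang_n_ca_c, torsions[i, 1])
    O[i - 1, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                             BB$c_o, BB$ang_ca_c_o, psi_prev + 180)
  }
  O[n, ] <- place_atom(N[n, ], CA[n, ], C[n, ], BB$c_o, BB$ang_ca_c_o,
                       torsions[n, 2] + 180)
  res_type <- rep_len(FIXTURE_RES_CYCLE, n)
  for (i in seq_len(n)) {
    if (res_type[i] != "GLY") {
      CBm[i, ] <- place_atom(N[i, ], C[i, ], CA[i, ],
                             bond = 1.522, angle = 110.4, dihedral = 122.5)
    }
  }
  tibble::tibble(chain = chain_id, resno = first_resno + seq_len(n) - 1L,
                 icode = "", seq_index = seq_len(n) - 1L, res_type = res_type,
                 n_x = N[, 1], n_y = N[, 2], n_z = N[, 3],
                 ca_x = CA[, 1], ca_y = CA[, 2], ca_z = CA[, 3],
                 c_x = C[, 1], c_y = C[, 2], c_z = C[, 3],
                 o_x = O[, 1], o_y = O[, 2], o_z = O[, 3],
                 cb_x = CBm[, 1], cb_y = CBm[, 2], cb_z = CBm[, 3],
                 phi = NA_real_, psi = NA_real_, ss3 = NA_character_,
                 rsa = NA_real_)
}

# Apply x %*% R + t to every atom of the given rows.
transform_rows <- function(df, rows, R, t) {
  for (grp in list(c("n_x", "n_y", "n_z"), c("ca_x", "ca_y", "ca_z"),
                   c("c_x", "c_y", "c_z"), c("o_x", "o_y", "o_z"),
                   c("cb_x", "cb_y", "cb_z"))) {
    m <- as.matrix(df[rows, grp])
    ok <- !is.na(m[, 1])
    if (any(ok)) {
      m[ok, ] <- m[ok, , drop = FALSE] %*% R +
        matrix(t, sum(ok), 3, byrow = TRUE)
    }
    df[rows, grp] <- m
  }
  df
}

all_cb <- function(df) {
  s <- new_complex_structure(df, "tmp")
  suppressMessages(virtual_cbeta(s))
}

#' Generate a deterministic native toy complex
#'
#' Chains are built from ideal backbone internal coordinates (full N, CA, C,
#' O and CB, virtual CB geometry for glycine), given a seeded random rigid
#' orientation each, and packed one by one along radial directions until the
#' minimum inter-chain C-beta distance to the already-placed chains reaches
#' 5.5 Angstrom — guaranteeing a genuine interface (contacts under 8
#' Angstrom) without steric collapse.  Byte-identical output per seed.
#'
#' @param spec a [fixture_spec()].
#' @return a `complex_structure`; serialise with [write_pdb()].
#' @export
generate_native <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  chains <- LETTERS[seq_len(spec$n_chains)]
  parts <- vector("list", spec$n_chains)
  for (ci in seq_len(spec$n_chains)) {
    part <- build_chain(spec$chain_lengths[ci], chains[ci], spec$geometry)
    # seeded random orientation about the chain centroid
    axis <- rnorm(3)
    R <- rotation_matrix(axis, runif(1, 0, 360))
    ca <- as.matrix(part[, c("ca_x", "ca_y", "ca_z")])
    centroid <- colMeans(ca)
    part <- transform_rows(part, seq_len(nrow(part)), R,
                           as.numeric(centroid - centroid %*% R))
    parts[[ci]] <- part
  }
  df <- parts[[1]]
  if (spec$n_chains > 1) {
    for (ci in 2:spec$n_chains) {
      ang <- 2 * pi * (ci - 2) / max(1, spec$n_chains - 1)
      dir <- c(cos(ang), sin(ang), 0)
      placed_cb <- all_cb(df)
      part <- parts[[ci]]
      part_cb0 <- all_cb(part)
      # start the incoming chain on top of the placed assembly's centroid so
      # the outward search always begins from overlap
      shift0 <- colMeans(placed_cb) - colMeans(part_cb0)
      part <- transform_rows(part, seq_len(nrow(part)), diag(3), shift0)
      part_cb0 <- sweep(part_cb0, 2, -shift0)
      min_dist <- function(t) {
        moved <- sweep(part_cb0, 2, t * dir, "+")
        sqrt(min(cross_dist2(moved, placed_cb)))
      }
      lo <- 0; hi <- 300
      if (min_dist(hi) < 5.5) stop("unpackable fixture spec", call. = FALSE)
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (min_dist(mid) < 5.5) lo <- mid else hi <- mid
      }
      part <- transform_rows(part, seq_len(nrow(part)), diag(3), hi * dir)
      df <- dplyr::bind_rows(df, part)
    }
  }
  st <- new_complex_structure(df, sprintf("toy%04d", spec$seed %% 10000))
  cbm <- suppressMessages(virtual_cbeta(st))
  inter <- interface_pairs(st, cbm)
  if (spec$n_chains > 1 && nrow(inter) == 0) {
    stop("generated complex has no inter-chain contact", call. = FALSE)
  }
  st
}

# All inter-chain residue pairs with CB-CB distance < 8 A.
interface_pairs <- function(structure, cbm = NULL) {
  if (is.null(cbm)) cbm <- suppressMessages(virtual_cbeta(structure))
  d2 <- cross_dist2(cbm, cbm)
  diff_chain <- outer(structure$chain, structure$chain, "!=")
  idx <- which(diff_chain & d2 < 64 & upper.tri(d2), arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2])
}

receptor_chain <- function(structure) {
  sizes <- table(structure$chain)
  names(sizes)[which.max(sizes)]  # ties: first chain
}

ligand_chain <- function(structure) {
  rec <- receptor_chain(structure)
  others <- setdiff(unique(structure$chain), rec)
  sizes <- table(structure$chain)[others]
  others[order(sizes, seq_along(others))][1]  # smallest; ties: first
}

#' Perturb a native complex into a decoy
#'
#' Applies a rigid rotation (seeded random axis) and translation (seeded
#' random direction) to the ligand chain about its centroid, then optional
#' per-atom Gaussian noise to the whole ligand; the receptor (largest chain)
#' and any other chains are untouched.  The ligand is the smallest
#' non-receptor chain.
#'
#' @param native a `complex_structure` with >= 2 chains.
#' @param rot_deg rotation magnitude in degrees.
#' @param trans_ang translation magnitude in Angstrom.
#' @param noise_ang per-coordinate Gaussian noise sd in Angstrom.
#' @param seed integer seed for axis, direction and noise.
#' @return the decoy `complex_structure`.
#' @export
perturb_decoy <- function(native, rot_deg = 0, trans_ang = 0, noise_ang = 0,
                          seed = 1) {
  stopifnot(inherits(native, "complex_structure"))
  if (length(unique(native$chain)) < 2) {
    stop("decoy perturbation needs at least 2 chains", call. = FALSE)
  }
  set.seed(as.integer(seed))
  lig <- ligand_chain(native)
  rows <- which(native$chain == lig)
  ca <- ca_matrix(native)[rows, , drop = FALSE]
  centroid <- colMeans(ca)
  R <- rotation_matrix(rnorm(3), rot_deg)
  dirv <- rnorm(3)
  dirv <- dirv / sqrt(sum(dirv^2))
  t <- as.numeric(centroid - centroid %*% R) + trans_ang * dirv
  decoy <- transform_rows(native, rows, R, t)
  if (noise_ang > 0) {
    for (grp in list(c("n_x", "n_y", "n_z"), c("ca_x", "ca_y", "ca_z"),
                     c("c_x", "c_y", "c_z"), c("o_x", "o_y", "o_z"),
                     c("cb_x", "cb_y", "cb_z"))) {
      m <- as.matrix(decoy[rows, grp])
      ok <- !is.na(m[, 1])
      m[ok, ] <- m[ok, , drop = FALSE] +
        matrix(rnorm(3 * sum(ok), sd = noise_ang), sum(ok), 3)
      decoy[rows, grp] <- m
    }
  }
  # perturbing invalidates any cached annotations
  decoy$phi <- NA_real_; decoy$psi <- NA_real_
  decoy$ss3 <- NA_character_; decoy$rsa <- NA_real_
  new_complex_structure(decoy, target_id(native))
}

#' Label a decoy against its native by residue correspondence
#'
#' Computes the three DockQ components with the known one-to-one residue
#' correspondence (no sequence alignment): fnat is the fraction of native
#' inter-chain C-beta contacts (< 8 Angstrom, virtual C-beta for glycine)
#' preserved in the decoy; iRMSD is the C-alpha RMSD over native interface
#' residues after least-squares superposition of the receptor (largest
#' chain); LRMSD is the C-alpha RMSD of the non-receptor chains after the
#' same superposition.  Note the reference DockQ tool defines contacts on
#' all heavy atoms at 5 Angstrom; this labeller intentionally reuses the
#' graph module's C-beta / 8 Angstrom definition, which is internally
#' consistent for synthetic pools.
#'
#' @param native,decoy `complex_structure`s with identical residue ordering.
#' @param thresholds class thresholds, see [dockq_thresholds()].
#' @return a one-row tibble: `fnat`, `irmsd`, `lrmsd`, `dockq`, `class`.
#' @export
label_decoy <- function(native, decoy, thresholds = dockq_thresholds()) {
  stopifnot(nrow(native) == nrow(decoy),
            all(native$chain == decoy$chain),
            all(native$resno == decoy$resno))
  cb_nat <- suppressMessages(virtual_cbeta(native))
  cb_dec <- suppressMessages(virtual_cbeta(decoy))
  pairs <- interface_pairs(native, cb_nat)
  if (nrow(pairs) == 0) {
    stop("native has no inter-chain contacts; cannot label", call. = FALSE)
  }
  d_dec <- sqrt(rowSums((cb_dec[pairs$i, , drop = FALSE] -
                         cb_dec[pairs$j, , drop = FALSE])^2))
  fnat <- mean(d_dec < 8)
  rec <- receptor_chain(native)
  rec_rows <- which(native$chain == rec)
  ca_nat <- ca_matrix(native)
  ca_dec <- ca_matrix(decoy)
  fit <- kabsch_fit(ca_nat[rec_rows, , drop = FALSE],
                    ca_dec[rec_rows, , drop = FALSE])
  ca_dec_fit <- ca_dec %*% fit$R + matrix(fit$t, nrow(ca_dec), 3,
                                          byrow = TRUE)
  iface <- sort(unique(c(pairs$i, pairs$j)))
  irmsd <- rmsd_xyz(ca_nat[iface, , drop = FALSE],
                    ca_dec_fit[iface, , drop = FALSE])
  lig_rows <- which(native$chain != rec)
  lrmsd <- rmsd_xyz(ca_nat[lig_rows, , drop = FALSE],
                    ca_dec_fit[lig_rows, , drop = FALSE])
  dq <- dockq_score(fnat, irmsd, lrmsd)
  tibble::tibble(fnat = fnat, irmsd = irmsd, lrmsd = lrmsd, dockq = dq,
                 class = dockq_class(dq, thresholds))
}

#' Generate a labelled decoy pool for one target
#'
#' Produces `n_per_magnitude` decoys per perturbation grade of the spec,
#' labels each against the native, and optionally writes PDBs plus a label
#' CSV in the training module's format.
#'
#' @param spec a [fixture_spec()] (>= 2 chains).
#' @param n_per_magnitude decoys per perturbation row.
#' @param dir optional output directory for PDB files, `labels.csv` and a
#'   `spec.yml` echo of the generating parameters.
#' @return list with `native` (structure), `decoys` (named list of
#'   structures) and `labels` (tibble: `target_id`, `decoy_id`, `fnat`,
#'   `irmsd`, `lrmsd`, `dockq`, `class`, `rot_deg`, `trans_ang`,
#'   `noise_ang`).
#' @export
make_decoy_pool <- function(spec, n_per_magnitude = 5, dir = NULL) {
  native <- generate_native(spec)
  tid <- target_id(native)
  decoys <- list()
  labels <- list()
  for (mi in seq_len(nrow(spec$perturbations))) {
    p <- spec$perturbations[mi, ]
    for (di in seq_len(n_per_magnitude)) {
      dseed <- (spec$seed * 101 + mi * 1009 + di * 13) %% .Machine$integer.max
      decoy <- perturb_decoy(native, p$rot_deg, p$trans_ang, p$noise_ang,
                             seed = dseed)
      id <- sprintf("%s_m%d_d%02d", tid, mi, di)
      decoys[[id]] <- decoy
      lab <- label_decoy(native, decoy)
      lab$target_id <- tid
      lab$decoy_id <- id
      lab$rot_deg <- p$rot_deg
      lab$trans_ang <- p$trans_ang
      lab$noise_ang <- p$noise_ang
      labels[[id]] <- lab
    }
  }
  labels <- dplyr::bind_rows(labels) |>
    dplyr::relocate("target_id", "decoy_id")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_pdb(native, file.path(dir, paste0(tid, "_native.pdb")))
    for (id in names(decoys)) {
      write_pdb(decoys[[id]], file.path(dir, paste0(id, ".pdb")))
    }
    readr::write_csv(labels[, c("target_id", "decoy_id", "dockq", "class")],
                     file.path(dir, "labels.csv"))
    readr::write_csv(labels, file.path(dir, "components.csv"))
    writeLines(c(sprintf("target_id: %s", tid),
                 sprintf("n_chains: %d", spec$n_chains),
                 sprintf("chain_lengths: %s",
                         paste(spec$chain_lengths, collapse = ",")),
                 sprintf("geometry: %s", spec$geometry),
                 sprintf("seed: %d", spec$seed)),
               file.path(dir, "spec.yml"))
  }
  list(native = native, decoys = decoys, labels = labels)
}

#' A small multi-target benchmark of toy complexes
#'
#' Convenience wrapper building several single-target pools with varied chain
#' lengths and geometries, plus a random-by-target train/validation/test
#' split table (sequence-identity clustering for real data is consumed as a
#' precomputed table; toy targets are independent by construction).
#'
#' @param n_targets number of targets.
#' @param n_per_magnitude decoys per perturbation grade per target.
#' @param seed base seed; target i uses `seed + i`.
#' @param n_test targets held out entirely as the test fold.
#' @return list with `pools` (named by target), `labels` (bound tibble) and
#'   `splits` (tibble: `target_id`, `fold` in train/val/test).
#' @export
make_benchmark_set <- function(n_targets = 4, n_per_magnitude = 5, seed = 1,
                               n_test = 1) {
  geoms <- c("helix", "extended", "mixed")
  pools <- list()
  for (i in seq_len(n_targets)) {
    lens <- c(14 + 2 * (i %% 3), 10 + 3 * (i %% 2))
    spec <- fixture_spec(n_chains = 2, chain_lengths = lens,
                         geometry = geoms[1 + (i %% 3)], seed = seed + i)
    pool <- make_decoy_pool(spec, n_per_magnitude = n_per_magnitude)
    pools[[target_id(pool$native)]] <- pool
  }
  labels <- dplyr::bind_rows(lapply(pools, `[[`, "labels"))
  tids <- names(pools)
  set.seed(seed)
  test_ids <- sample(tids, n_test)
  rest <- setdiff(tids, test_ids)
  val_ids <- if (length(rest) > 1) sample(rest, max(1, round(length(rest) / 4)))
             else character(0)
  splits <- tibble::tibble(
    target_id = tids,
    fold = ifelse(tids %in% test_ids, "test",
                  ifelse(tids %in% val_ids, "val", "train")))
  list(pools = pools, labels = labels, splits = splits)
}
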