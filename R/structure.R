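AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
RES_TYPES <- c(AA3, "UNK")

# Common non-standard residue substitutions; anything else becomes UNK.
AA_SUBSTITUTIONS <- c(MSE = "MET", HSD = "HIS", HSE = "HIS", HSP = "HIS",
                      SEP = "SER", TPO = "THR", PTR = "TYR")

# Maximum accessible surface area per residue type (A^2), Tien et al. 2013
# theoretical values; used to normalise ASA into relative ASA.  UNK uses the
# median of the 20 standard values.
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174,
             UNK = 199)

normalize_res_type <- function(resid) {
  out <- ifelse(resid %in% AA3, resid,
                ifelse(resid %in% names(AA_SUBSTITUTIONS),
                       AA_SUBSTITUTIONS[resid], "UNK"))
  unname(out)
}

new_complex_structure <- function(df, target_id) {
  df <- tibble::as_tibble(df)
  attr(df, "target_id") <- target_id
  class(df) <- c("complex_structure", class(df))
  df
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure> target '%s': %d residues in %d chain(s) [%s]\n",
              target_id(x), nrow(x), length(unique(x$chain)),
              paste(unique(x$chain), collapse = ", ")))
  NextMethod()
}

#' Target identifier of a structure
#' @param x a `complex_structure`.
#' @return character scalar.
#' @export
target_id <- function(x) attr(x, "target_id") %||% "unknown"

#' Parse a PDB file into a per-residue structure table
#'
#' Reads the first MODEL of a PDB file (text or path), keeps ATOM records
#' (HETATM and waters are skipped), resolves alternate locations by highest
#' occupancy, and returns one row per residue that has a C-alpha atom.
#' Residues lacking a C-alpha are dropped with a warning: the C-alpha defines
#' the residue's node in the downstream k-NN graph.  Rows are ordered
#' chain-major, chains in order of first appearance, residues in file order
#' (insertion codes therefore preserve their author ordering).
#'
#' @param pdb path to a PDB file, or a character scalar containing PDB text
#'   (detected by embedded newlines), or a character vector of PDB lines.
#' @param target_id identifier attached to the result (defaults to the file
#'   base name, or "model" for in-memory text).
#' @return a `complex_structure`: a tibble with columns `chain`, `resno`,
#'   `icode`, `seq_index` (0-based within chain), `res_type` (three-letter,
#'   one of the 20 standard amino acids or "UNK"), coordinates `n_*`, `ca_*`,
#'   `c_*`, `o_*`, `cb_*` (NA when the atom is absent), and placeholder
#'   columns `phi`, `psi`, `ss3`, `rsa` filled by [compute_torsions()],
#'   [assign_ss3()] and [compute_rsa()].
#' @examples
#' spec <- fixture_spec(chain_lengths = c(6, 5), seed = 1)
#' pdb <- write_pdb(generate_native(spec))
#' parse_structure(pdb, "toy")
#' @export
parse_structure <- function(pdb, target_id = NULL) {
  stopifnot(is.character(pdb), length(pdb) >= 1)
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    if (is.null(target_id)) {
      target_id <- sub("\\.(pdb|ent)$", "", basename(path))
    }
  } else {
    lines <- if (length(pdb) == 1) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    if (is.null(target_id)) target_id <- "model"
  }
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, "ATOM"))) {
    stop("no ATOM records found; cannot parse '", target_id, "'", call. = FALSE)
  }
  pdb_obj <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                             verbose = FALSE)
  at <- pdb_obj$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (nrow(at) == 0) stop("no usable ATOM records", call. = FALSE)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc: keep the highest-occupancy copy of each atom (ties: first seen)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(key, -at$o, seq_len(nrow(at)))
  keep_rows <- sort(ord[!duplicated(key[ord])])  # restore file order
  at <- at[keep_rows, , drop = FALSE]
  # chain-major: chains by first appearance, residues by file order within
  res_id <- paste(at$chain, at$resno, at$insert, sep = "|")
  at <- at[order(match(at$chain, unique(at$chain)),
                 match(res_id, unique(res_id))), , drop = FALSE]

  res_key <- paste(at$chain, at$resno, at$insert, sep = "|")
  res_key <- factor(res_key, levels = unique(res_key))
  grab <- function(name, col) {
    idx <- at$elety == name
    out <- rep(NA_real_, nlevels(res_key))
    out[as.integer(res_key[idx])] <- at[[col]][idx]
    out
  }
  first_of <- function(col) at[[col]][!duplicated(res_key)]

  df <- tibble::tibble(
    chain = first_of("chain"),
    resno = first_of("resno"),
    icode = first_of("insert"),
    res_type = normalize_res_type(first_of("resid")),
    n_x = grab("N", "x"), n_y = grab("N", "y"), n_z = grab("N", "z"),
    ca_x = grab("CA", "x"), ca_y = grab("CA", "y"), ca_z = grab("CA", "z"),
    c_x = grab("C", "x"), c_y = grab("C", "y"), c_z = grab("C", "z"),
    o_x = grab("O", "x"), o_y = grab("O", "y"), o_z = grab("O", "z"),
    cb_x = grab("CB", "x"), cb_y = grab("CB", "y"), cb_z = grab("CB", "z")
  )
  dropped <- is.na(df$ca_x)
  if (any(dropped)) {
    warning(sum(dropped), " residue(s) without a C-alpha dropped from '",
            target_id, "'", call. = FALSE)
    df <- df[!dropped, , drop = FALSE]
  }
  if (nrow(df) < 2) {
    stop("degenerate input: fewer than 2 residues with a C-alpha",
         call. = FALSE)
  }
  df <- df |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(seq_index = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    dplyr::relocate("seq_index", .after = "icode")
  df$phi <- NA_real_
  df$psi <- NA_real_
  df$ss3 <- NA_character_
  df$rsa <- NA_real_
  new_complex_structure(df, target_id)
}

#' Write a structure back out as PDB text
#'
#' Emits fixed-width ATOM records for the backbone atoms present in the table
#' (N, CA, C, O, CB), a TER record after each chain and END.  Coordinates are
#' written at the PDB's native 3-decimal precision.
#'
#' @param structure a `complex_structure`.
#' @param path optional file path; when given the text is also written there.
#' @return the PDB text as a single string, invisibly when `path` is given.
#' @export
write_pdb <- function(structure, path = NULL) {
  stopifnot(inherits(structure, "complex_structure"))
  atoms <- list(N = c("n_x", "n_y", "n_z"), CA = c("ca_x", "ca_y", "ca_z"),
                C = c("c_x", "c_y", "c_z"), O = c("o_x", "o_y", "o_z"),
                CB = c("cb_x", "cb_y", "cb_z"))
  lines <- character(0)
  serial <- 0L
  for (ch in unique(structure$chain)) {
    rows <- which(structure$chain == ch)
    for (i in rows) {
      for (nm in names(atoms)) {
        xyz <- as.numeric(structure[i, atoms[[nm]]])
        if (anyNA(xyz)) next
        serial <- serial + 1L
        name_field <- sprintf(" %-3s", nm)  # short names start in column 14
        lines <- c(lines, sprintf(
          "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_field, structure$res_type[i], ch,
          structure$resno[i], structure$icode[i],
          xyz[1], xyz[2], xyz[3], 1, 0, substr(nm, 1, 1)))
      }
    }
    serial <- serial + 1L
    i <- rows[length(rows)]
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d%1s", serial,
                              structure$res_type[i], ch, structure$resno[i],
                              structure$icode[i]))
  }
  lines <- c(lines, "END")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}

ca_matrix <- function(structure) {
  as.matrix(structure[, c("ca_x", "ca_y", "ca_z")])
}

#' Backbone dihedral angles
#'
#' Computes phi and psi for every residue from N, CA, C coordinates, per
#' chain, in the IUPAC right-handed convention, degrees in \[-180, 180\].
#' phi is undefined (NA) at each chain's first residue, psi at its last;
#' any missing backbone atom also leaves the angle NA rather than erroring.
#'
#' @param structure a `complex_structure`.
#' @return the structure with `phi` and `psi` filled in.
#' @export
compute_torsions <- function(structure) {
  stopifnot(inherits(structure, "complex_structure"))
  n <- nrow(structure)
  N <- as.matrix(structure[, c("n_x", "n_y", "n_z")])
  CA <- ca_matrix(structure)
  C <- as.matrix(structure[, c("c_x", "c_y", "c_z")])
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    same_prev <- i > 1 && structure$chain[i - 1] == structure$chain[i]
    same_next <- i < n && structure$chain[i + 1] == structure$chain[i]
    if (same_prev && !anyNA(c(C[i - 1, ], N[i, ], CA[i, ], C[i, ]))) {
      phi[i] <- dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    }
    if (same_next && !anyNA(c(N[i, ], CA[i, ], C[i, ], N[i + 1, ]))) {
      psi[i] <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
    }
  }
  structure$phi <- phi
  structure$psi <- psi
  structure
}

#' Three-state secondary structure from backbone torsions
#'
#' Ramachandran-region assignment: helix for phi in \[-90, -30\] and psi in
#' \[-77, -7\]; strand for phi in \[-170, -50\] and psi in \[80, 180\] or
#' \[-180, -170\]; everything else (including residues with undefined
#' torsions, e.g. chain termini) is coil.
#'
#' @param structure a `complex_structure` with torsions computed.
#' @return the structure with `ss3` filled with "helix", "strand" or "coil".
#' @export
assign_ss3 <- function(structure) {
  stopifnot(inherits(structure, "complex_structure"))
  phi <- structure$phi
  psi <- structure$psi
  helix <- !is.na(phi) & !is.na(psi) &
    phi >= -90 & phi <= -30 & psi >= -77 & psi <= -7
  strand <- !is.na(phi) & !is.na(psi) &
    phi >= -170 & phi <= -50 &
    ((psi >= 80 & psi <= 180) | (psi >= -180 & psi <= -170))
  structure$ss3 <- ifelse(helix, "helix", ifelse(strand, "strand", "coil"))
  structure
}

# Evenly distributed unit sphere points (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

VDW_RADII <- c(N = 1.55, C = 1.70, O = 1.52, S = 1.80)

# Deterministic canonical orientation of a point cloud: principal axes with
# a cubed-sum sign convention and det +1.  Makes the sphere-point sampling
# of the surface-area estimator invariant under rigid motion of the input.
canonical_frame <- function(coords) {
  x <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)$vectors
  y <- x %*% ev
  for (j in 1:3) {
    s <- sum(y[, j]^3)
    if (abs(s) < 1e-8) s <- y[which.max(abs(y[, j])), j]
    if (s < 0) {
      ev[, j] <- -ev[, j]
      y[, j] <- -y[, j]
    }
  }
  if (det(ev) < 0) y[, 3] <- -y[, 3]
  y
}

# Shrake-Rupley accessible surface area for a set of atoms.
# coords: n x 3; radii: length n; probe in Angstrom.  Returns per-atom ASA.
# Coordinates are first put in a canonical frame so the estimate is exactly
# reproducible under rigid-body motion of the whole input.
shrake_rupley <- function(coords, radii, probe = 1.4, n_points = 92) {
  coords <- canonical_frame(coords)
  n <- nrow(coords)
  pts <- sphere_points(n_points)
  asa <- numeric(n)
  rr <- radii + probe
  d2 <- cross_dist2(coords, coords)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rr[i] + rr)^2 & seq_len(n) != i)
    sp <- sweep(pts * rr[i], 2, coords[i, ], "+")
    if (length(nb) == 0) {
      frac <- 1
    } else {
      pd2 <- cross_dist2(sp, coords[nb, , drop = FALSE])
      buried <- rowSums(pd2 < matrix(rr[nb]^2, n_points, length(nb),
                                     byrow = TRUE)) > 0
      frac <- mean(!buried)
    }
    asa[i] <- 4 * pi * rr[i]^2 * frac
  }
  asa
}

#' Relative accessible surface area per residue
#'
#' Shrake-Rupley accessible surface area (1.4 A probe, golden-spiral point
#' sampling) summed over each residue's available heavy atoms (N, CA, C, O,
#' CB), divided by the residue type's maximum ASA (Tien et al. 2013
#' theoretical values) and clamped to \[0, 1\].  For C-alpha-only models a
#' neighbour-count proxy is used instead: rsa = 1 - (number of C-alpha
#' neighbours within 10 A) / 24, clamped.
#'
#' @param structure a `complex_structure`.
#' @param probe probe radius in Angstrom.
#' @param n_points sphere sample points per atom.
#' @return the structure with `rsa` filled in.
#' @export
compute_rsa <- function(structure, probe = 1.4, n_points = 92) {
  stopifnot(inherits(structure, "complex_structure"))
  n <- nrow(structure)
  atom_cols <- list(N = c("n_x", "n_y", "n_z"), CA = c("ca_x", "ca_y", "ca_z"),
                    C = c("c_x", "c_y", "c_z"), O = c("o_x", "o_y", "o_z"),
                    CB = c("cb_x", "cb_y", "cb_z"))
  coords <- NULL
  owner <- integer(0)
  elem <- character(0)
  for (nm in names(atom_cols)) {
    xyz <- as.matrix(structure[, atom_cols[[nm]]])
    ok <- !is.na(xyz[, 1])
    coords <- rbind(coords, xyz[ok, , drop = FALSE])
    owner <- c(owner, which(ok))
    elem <- c(elem, rep(substr(nm, 1, 1), sum(ok)))
  }
  ca_only <- !any(elem != "C" & elem != "S") &&
    length(owner) == n && all(tabulate(owner, n) == 1)
  if (ca_only) {
    ca <- ca_matrix(structure)
    d2 <- cross_dist2(ca, ca)
    n_nb <- rowSums(d2 < 100) - 1
    structure$rsa <- clamp(1 - n_nb / 24, 0, 1)
    return(structure)
  }
  asa <- shrake_rupley(coords, VDW_RADII[elem], probe = probe,
                       n_points = n_points)
  res_asa <- as.numeric(tapply(asa, factor(owner, levels = seq_len(n)), sum,
                               default = 0))
  structure$rsa <- unname(clamp(res_asa / MAX_ASA[structure$res_type], 0, 1))
  structure
}

#' Effective C-beta coordinates
#'
#' Returns one C-beta position per residue: the observed C-beta where present,
#' otherwise an ideal C-beta constructed from the backbone N, CA, C geometry
#' (1.522 A bond, 110.4 degree angle, improper dihedral N-C-CA-CB of +122.5 degrees, matching L-amino-acid chirality), as
#' needed for glycine.  If a backbone atom required for the construction is
#' missing, the C-alpha coordinate is used and a message is logged.
#'
#' @param structure a `complex_structure`.
#' @return an N x 3 matrix of coordinates.
#' @export
virtual_cbeta <- function(structure) {
  stopifnot(inherits(structure, "complex_structure"))
  n <- nrow(structure)
  CB <- as.matrix(structure[, c("cb_x", "cb_y", "cb_z")])
  N <- as.matrix(structure[, c("n_x", "n_y", "n_z")])
  CA <- ca_matrix(structure)
  C <- as.matrix(structure[, c("c_x", "c_y", "c_z")])
  fell_back <- 0L
  for (i in which(is.na(CB[, 1]))) {
    if (anyNA(N[i, ]) || anyNA(C[i, ])) {
      CB[i, ] <- CA[i, ]
      fell_back <- fell_back + 1L
    } else {
      CB[i, ] <- place_atom(N[i, ], C[i, ], CA[i, ],
                            bond = 1.522, angle = 110.4, dihedral = 122.5)
    }
  }
  if (fell_back > 0) {
    message(fell_back,
            " residue(s) lacked backbone atoms for C-beta construction; ",
            "C-alpha used")
  }
  dimnames(CB) <- NULL
  CB
}

#' Run the full per-residue annotation pipeline
#'
#' Convenience wrapper: [compute_torsions()], then [assign_ss3()], then
#' [compute_rsa()].
#'
#' @inheritParams compute_torsions
#' @param ... passed to [compute_rsa()].
#' @return the fully annotated structure.
#' @export
annotate_structure <- function(structure, ...) {
  structure |> compute_torsions() |> assign_ss3() |> compute_rsa(...)
}
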