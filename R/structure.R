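# Binding-pocket structural analysis: parsing, contact census, hydrogen
# bonds, pi-stacking, Calpha superposition and porphyrin-plane rotation.
# Coordinates are in Angstrom throughout; residue numbering follows the
# author numbering of the input file (no renumbering).

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE")
WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

# Aromatic ring atom sets (protein side chains and the four pyrrole rings of
# a porphyrin, chemical-component-dictionary atom names). Porphyrin rings
# A-D correspond to rings I-IV of the classical nomenclature.
RING_ATOMS <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(pyrrole = c("CG", "CD1", "CD2", "NE1", "CE2"),
             benzene = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))
PORPHYRIN_RINGS <- list(
  I   = c("NA", "C1A", "C2A", "C3A", "C4A"),
  II  = c("NB", "C1B", "C2B", "C3B", "C4B"),
  III = c("NC", "C1C", "C2C", "C3C", "C4C"),
  IV  = c("ND", "C1D", "C2D", "C3D", "C4D"))
PORPHYRIN_CORE <- c(unlist(PORPHYRIN_RINGS, use.names = FALSE),
                    "CHA", "CHB", "CHC", "CHD")

#' Parse a structure file into an atom table
#'
#' Reads PDB or mmCIF coordinates (via bio3d) into a flat atom table.
#' Alternate locations are resolved to the highest-occupancy copy; insertion
#' codes are kept as part of the residue identity.
#'
#' @param path Path to the file.
#' @param format `"pdb"`, `"cif"`, or `NULL` to infer from the extension.
#' @return A `structure_model`: list with `atoms` (data.frame: `chain`,
#'   `resid`, `resno`, `insert`, `elety` (atom name), `elesy` (element),
#'   `x`, `y`, `z`, `o` (occupancy), `hetero`) and `path`.
#' @export
parse_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty structure file: ", path, call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = , ent = "pdb", cif = , mmcif = "cif",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format = 'pdb' or 'cif'", call. = FALSE))
  }
  format <- match.arg(format, c("pdb", "cif"))
  # rm.alt = FALSE: alternate locations are kept and resolved below by
  # occupancy rather than by label
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE,
                                         rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("no atom records in ", path, call. = FALSE)
  elesy <- at$elesy
  guess <- toupper(sub("^[0-9']*", "", at$elety))
  two <- substr(guess, 1, 2)
  guess <- ifelse(two %in% c("FE", "ZN", "MG", "NA", "CL", "MN", "CU", "CO",
                             "NI", "BR", "SE") &
                    at$resid %in% c(two, "HEM", "HEC", "HEA", "HEB") |
                    two == "FE",
                  two, substr(guess, 1, 1))
  elesy <- ifelse(is.na(elesy) | elesy == "", guess, toupper(elesy))
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resid = at$resid, resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    elety = at$elety, elesy = elesy,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in ", path, call. = FALSE)
  # resolve altlocs: keep the highest-occupancy copy of each atom
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$elety, sep = "|")
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, ][!duplicated(key[ord]), ]
  atoms <- atoms[order(as.integer(rownames(atoms))), ]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, path = path), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure model: %d atoms, chains %s (%d hetero atoms)\n",
              nrow(a), paste(sort(unique(a$chain)), collapse = ","),
              sum(a$hetero)))
  invisible(x)
}

# Parse "chain:resname:resnum" (any field may be empty) into a filter.
parse_selector <- function(selector) {
  if (is.list(selector)) return(selector)
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  length(parts) <- 3L
  list(chain = if (is.na(parts[1]) || parts[1] == "") NULL else parts[1],
       resname = if (is.na(parts[2]) || parts[2] == "") NULL else parts[2],
       resno = if (is.na(parts[3]) || parts[3] == "") NULL
               else as.integer(parts[3]))
}

#' Select atoms by a chain:resname:resnum pattern
#'
#' @param model A `structure_model`.
#' @param selector Either a string `"chain:resname:resnum"` with empty
#'   fields as wildcards (e.g. `"E:HEM:"`, `":HEM:"`) or a list with
#'   elements `chain`, `resname`, `resno` (NULL = wildcard).
#' @return Logical vector over `model$atoms` rows.
#' @export
select_atoms <- function(model, selector) {
  stopifnot(inherits(model, "structure_model"))
  sel <- parse_selector(selector)
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain == sel$chain
  if (!is.null(sel$resname)) keep <- keep & a$resid == sel$resname
  if (!is.null(sel$resno)) keep <- keep & a$resno == sel$resno
  keep
}

is_heavy <- function(atoms) !(atoms$elesy %in% c("H", "D"))

residue_key <- function(atoms)
  paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, sep = "|")

# Minimum distance from each query atom to any of the target coordinates.
min_dist_to <- function(qx, qy, qz, txyz) {
  vapply(seq_along(qx), function(i) {
    sqrt(min((txyz[, 1] - qx[i])^2 + (txyz[, 2] - qy[i])^2 +
               (txyz[, 3] - qz[i])^2))
  }, numeric(1))
}

#' Ligand contact census
#'
#' Reports every residue with at least one heavy atom within `cutoff` of any
#' heavy atom of the selected ligand. Amino-acid residues form the main
#' census; waters and other non-protein entities are listed separately
#' (never mixed into the amino-acid count). Hydrogens are excluded.
#'
#' @param model A `structure_model`.
#' @param ligand_selector Selector for the ligand (see [select_atoms()]).
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.0).
#' @return A `contact_report`: list with data.frames `residues`, `waters`,
#'   `others` (columns `chain`, `resid`, `resno`, `insert`, `min_dist`),
#'   plus `cutoff` and `n_ligand_atoms`.
#' @export
contact_residues <- function(model, ligand_selector, cutoff = 4.0) {
  stopifnot(inherits(model, "structure_model"), cutoff >= 0)
  lig <- select_atoms(model, ligand_selector) & is_heavy(model$atoms)
  if (!any(lig)) stop("ligand selection is empty", call. = FALSE)
  a <- model$atoms
  lig_keys <- unique(residue_key(a[lig, ]))
  env <- is_heavy(a) & !(residue_key(a) %in% lig_keys)
  e <- a[env, ]
  empty <- data.frame(chain = character(), resid = character(),
                      resno = integer(), insert = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE)
  out <- list(residues = empty, waters = empty, others = empty,
              cutoff = cutoff, n_ligand_atoms = sum(lig))
  class(out) <- "contact_report"
  if (nrow(e) == 0L || cutoff == 0) return(out)
  d <- min_dist_to(e$x, e$y, e$z, as.matrix(a[lig, c("x", "y", "z")]))
  hit <- d <= cutoff
  if (!any(hit)) return(out)
  e <- e[hit, ]; d <- d[hit]
  key <- residue_key(e)
  mind <- tapply(d, key, min)
  first <- e[!duplicated(key), ]
  first <- first[order(match(unique(key), names(mind))), ]
  tab <- data.frame(chain = first$chain, resid = first$resid,
                    resno = first$resno, insert = first$insert,
                    min_dist = as.numeric(mind[residue_key(first)]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$chain, tab$resno, tab$insert), ]
  rownames(tab) <- NULL
  out$residues <- tab[tab$resid %in% AMINO_ACIDS, ]
  out$waters <- tab[tab$resid %in% WATER_RESNAMES, ]
  out$others <- tab[!(tab$resid %in% c(AMINO_ACIDS, WATER_RESNAMES)), ]
  rownames(out$residues) <- rownames(out$waters) <- rownames(out$others) <- NULL
  out
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf("Contact report (cutoff %.2f A, %d ligand atoms):\n",
              x$cutoff, x$n_ligand_atoms))
  cat(sprintf("  %d amino-acid residues, %d waters, %d other entities\n",
              nrow(x$residues), nrow(x$waters), nrow(x$others)))
  if (nrow(x$residues)) print(x$residues)
  invisible(x)
}

# Heavy covalent neighbour of atom i within its residue (< 1.8 A).
covalent_neighbours <- function(atoms, i, max_bond = 1.8) {
  same <- residue_key(atoms) == residue_key(atoms[i, , drop = FALSE]) &
    seq_len(nrow(atoms)) != i & is_heavy(atoms)
  j <- which(same)
  if (!length(j)) return(integer())
  dd <- sqrt((atoms$x[j] - atoms$x[i])^2 + (atoms$y[j] - atoms$y[i])^2 +
               (atoms$z[j] - atoms$z[i])^2)
  j[dd < max_bond]
}

angle_deg <- function(v1, v2) {
  c1 <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(c1, -1), 1)) * 180 / pi
}

#' Geometric hydrogen-bond detection
#'
#' Hydrogen atoms are usually absent from crystallographic models at
#' moderate resolution, so candidate hydrogen bonds are inferred from heavy
#' atoms alone: polar-atom (N/O/S) pairs between ligand and environment with
#' distance at most `d_max`, filtered by an angle proxy — at each partner
#' that has a covalently bonded heavy neighbour, the neighbour-atom-partner
#' angle must be at least `angle_min` degrees. This is a geometric
#' inference, not an energetic assignment.
#'
#' @param model A `structure_model`.
#' @param ligand_selector Ligand selector.
#' @param d_max Maximum heavy-atom donor-acceptor distance (default 3.5 A).
#' @param angle_min Minimum angle proxy in degrees (default 90).
#' @param include_waters Include water partners (default TRUE; flagged in
#'   the output).
#' @return data.frame with one row per candidate bond: ligand atom, partner
#'   residue and atom, distance, the two angle proxies, and `is_water`.
#' @export
detect_hbonds <- function(model, ligand_selector, d_max = 3.5,
                          angle_min = 90, include_waters = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  polar <- a$elesy %in% c("N", "O", "S")
  lig <- select_atoms(model, ligand_selector) & is_heavy(a) & polar
  if (!any(select_atoms(model, ligand_selector)))
    stop("ligand selection is empty", call. = FALSE)
  lig_keys <- unique(residue_key(a[select_atoms(model, ligand_selector), ]))
  env <- polar & is_heavy(a) & !(residue_key(a) %in% lig_keys)
  if (!include_waters) env <- env & !(a$resid %in% WATER_RESNAMES)
  li <- which(lig); ei <- which(env)
  out <- data.frame(ligand_atom = character(), chain = character(),
                    resid = character(), resno = integer(),
                    atom = character(), distance = numeric(),
                    angle_ligand = numeric(), angle_partner = numeric(),
                    is_water = logical(), stringsAsFactors = FALSE)
  if (!length(li) || !length(ei)) return(out)
  for (i in li) {
    dd <- sqrt((a$x[ei] - a$x[i])^2 + (a$y[ei] - a$y[i])^2 +
                 (a$z[ei] - a$z[i])^2)
    for (k in which(dd <= d_max)) {
      j <- ei[k]
      pi_ <- c(a$x[i], a$y[i], a$z[i]); pj <- c(a$x[j], a$y[j], a$z[j])
      ang_of <- function(idx, here, there) {
        nb <- covalent_neighbours(a, idx)
        if (!length(nb)) return(NA_real_)
        min(vapply(nb, function(n) {
          angle_deg(c(a$x[n], a$y[n], a$z[n]) - here, there - here)
        }, numeric(1)))
      }
      ang_i <- ang_of(i, pi_, pj)
      ang_j <- ang_of(j, pj, pi_)
      ok <- (is.na(ang_i) || ang_i >= angle_min) &&
        (is.na(ang_j) || ang_j >= angle_min)
      if (!ok) next
      out <- rbind(out, data.frame(
        ligand_atom = a$elety[i], chain = a$chain[j], resid = a$resid[j],
        resno = a$resno[j], atom = a$elety[j], distance = dd[k],
        angle_ligand = ang_i, angle_partner = ang_j,
        is_water = a$resid[j] %in% WATER_RESNAMES,
        stringsAsFactors = FALSE))
    }
  }
  out[order(out$distance), ]
}

ring_geometry <- function(xyz) {
  centroid <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, centroid))
  list(centroid = centroid, normal = sv$v[, 3])
}

#' Pi-stacking detection against porphyrin rings
#'
#' Pairs each aromatic side-chain ring (Phe, Tyr, Trp, His) with each of the
#' four pyrrole rings of the selected porphyrin and reports pairs whose ring
#' centroids are within `centroid_max` and whose planes are within
#' `tilt_max` degrees of parallel. Porphyrin rings are named I-IV following
#' the NA-ND nitrogen atom names (ring A = I, ..., ring D = IV).
#'
#' @param model A `structure_model`.
#' @param ligand_selector Porphyrin ligand selector.
#' @param centroid_max Maximum centroid-centroid distance (default 5.5 A).
#' @param tilt_max Maximum interplanar angle in degrees (default 30).
#' @return data.frame: residue (chain, resid, resno), residue ring id,
#'   porphyrin ring id, centroid distance, interplanar angle.
#' @export
detect_pi_stacking <- function(model, ligand_selector, centroid_max = 5.5,
                               tilt_max = 30) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  lig <- select_atoms(model, ligand_selector)
  if (!any(lig)) stop("ligand selection is empty", call. = FALSE)
  la <- a[lig & is_heavy(a), ]
  # porphyrin rings
  prings <- list()
  for (rn in names(PORPHYRIN_RINGS)) {
    rows <- la[la$elety %in% PORPHYRIN_RINGS[[rn]], ]
    if (nrow(rows) < length(PORPHYRIN_RINGS[[rn]])) {
      warning("porphyrin ring ", rn, " incomplete; skipped", call. = FALSE)
      next
    }
    prings[[rn]] <- ring_geometry(as.matrix(rows[, c("x", "y", "z")]))
  }
  out <- data.frame(chain = character(), resid = character(),
                    resno = integer(), residue_ring = character(),
                    porphyrin_ring = character(),
                    centroid_dist = numeric(), angle = numeric(),
                    stringsAsFactors = FALSE)
  if (!length(prings)) return(out)
  prot <- a[a$resid %in% names(RING_ATOMS) & is_heavy(a) &
              !(residue_key(a) %in% unique(residue_key(la))), ]
  if (nrow(prot) == 0L) return(out)
  for (key in unique(residue_key(prot))) {
    res <- prot[residue_key(prot) == key, ]
    defs <- RING_ATOMS[[res$resid[1]]]
    for (ring_name in names(defs)) {
      rows <- res[res$elety %in% defs[[ring_name]], ]
      if (nrow(rows) < length(defs[[ring_name]])) {
        warning("ring ", ring_name, " of ", res$resid[1], res$resno[1],
                " incomplete; skipped", call. = FALSE)
        next
      }
      g <- ring_geometry(as.matrix(rows[, c("x", "y", "z")]))
      for (rn in names(prings)) {
        p <- prings[[rn]]
        cd <- sqrt(sum((g$centroid - p$centroid)^2))
        ang <- angle_deg(g$normal, p$normal)
        ang <- min(ang, 180 - ang)  # plane angle, normals sign-free
        if (cd <= centroid_max && ang <= tilt_max)
          out <- rbind(out, data.frame(
            chain = res$chain[1], resid = res$resid[1],
            resno = res$resno[1], residue_ring = ring_name,
            porphyrin_ring = rn, centroid_dist = cd, angle = ang,
            stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$centroid_dist), ]
}

# Kabsch: optimal rotation R and translation t so that mobile %*% t(R) + t
# approximates reference in the least-squares sense.
kabsch <- function(reference, mobile) {
  rc <- colMeans(reference); mc <- colMeans(mobile)
  P <- sweep(mobile, 2, mc); Q <- sweep(reference, 2, rc)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-30)
  list(rotation = R, translation = as.numeric(rc - R %*% mc), rmsd = rmsd,
       degenerate = degenerate)
}

ca_table <- function(model, chain = NULL) {
  a <- model$atoms
  keep <- a$elety == "CA" & a$resid %in% AMINO_ACIDS & !a$hetero
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  a[keep, ]
}

#' Calpha superposition (Kabsch)
#'
#' Pairs Calpha atoms of two models and computes the optimal least-squares
#' rigid transform of the mobile set onto the reference, returning the
#' rotation (orthonormal, det +1), translation and rmsd.
#'
#' Pairing `"by_resnum"` matches residue numbers (plus insertion codes)
#' after optional chain filtering; residue numbers must then be unique in
#' each selection. Pairing `"by_alignment"` aligns the two sequences
#' (Needleman-Wunsch via the Biostrings package, if installed) and pairs
#' aligned positions.
#'
#' @param reference,mobile `structure_model`s.
#' @param pairing `"by_resnum"` or `"by_alignment"`.
#' @param chain_ref,chain_mobile Optional chain filters (character vectors).
#' @return A `superposition`: rotation, translation, `rmsd` (A), `n_atoms`,
#'   `pairing`, `degenerate` flag.
#' @export
superpose_ca <- function(reference, mobile,
                         pairing = c("by_resnum", "by_alignment"),
                         chain_ref = NULL, chain_mobile = NULL) {
  pairing <- match.arg(pairing)
  ca_r <- ca_table(reference, chain_ref)
  ca_m <- ca_table(mobile, chain_mobile)
  if (pairing == "by_resnum") {
    kr <- paste(ca_r$resno, ca_r$insert)
    km <- paste(ca_m$resno, ca_m$insert)
    if (anyDuplicated(kr) || anyDuplicated(km))
      stop("duplicate residue numbers in selection; filter chains first",
           call. = FALSE)
    shared <- intersect(kr, km)
    ri <- match(shared, kr); mi <- match(shared, km)
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("pairing = 'by_alignment' requires the Biostrings package",
           call. = FALSE)
    sr <- paste(bio3d::aa321(ca_r$resid), collapse = "")
    sm <- paste(bio3d::aa321(ca_m$resid), collapse = "")
    al <- Biostrings::pairwiseAlignment(sr, sm, type = "global")
    ri_all <- seq_len(nchar(sr)); mi_all <- seq_len(nchar(sm))
    pr <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    sj <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
    ri <- integer(); mi <- integer(); i <- 1L; j <- 1L
    for (k in seq_along(pr)) {
      if (pr[k] != "-" && sj[k] != "-") { ri <- c(ri, i); mi <- c(mi, j) }
      if (pr[k] != "-") i <- i + 1L
      if (sj[k] != "-") j <- j + 1L
    }
  }
  if (length(ri) < 3L)
    stop("fewer than 3 paired Calpha atoms", call. = FALSE)
  K <- kabsch(as.matrix(ca_r[ri, c("x", "y", "z")]),
              as.matrix(ca_m[mi, c("x", "y", "z")]))
  if (K$degenerate)
    warning("degenerate (near-collinear) reference set; rotation ill-defined",
            call. = FALSE)
  structure(list(rotation = K$rotation, translation = K$translation,
                 rmsd = K$rmsd, n_atoms = length(ri), pairing = pairing,
                 degenerate = K$degenerate),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param sp A `superposition`.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, sp) {
  stopifnot(inherits(sp, "superposition"))
  sweep(xyz %*% t(sp$rotation), 2, sp$translation, `+`)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition (%s): rmsd %.3f A over %d Calpha pairs\n",
              x$pairing, x$rmsd, x$n_atoms))
  invisible(x)
}

porphyrin_atoms <- function(model, selector) {
  a <- model$atoms[select_atoms(model, selector), ]
  core <- a[a$elety %in% PORPHYRIN_CORE, ]
  fe <- a[a$elesy == "FE" | a$elety == "FE", ]
  if (nrow(core) < 12L)
    stop("porphyrin core atoms missing from selection", call. = FALSE)
  list(core = core, fe = fe,
       na_atom = a[a$elety == "NA", , drop = FALSE])
}

#' In-plane rotation of a porphyrin between two complexes
#'
#' Quantifies how differently two proteins hold the same porphyrin: after
#' superposing the proteins on shared Calpha atoms, a best-fit plane is put
#' through the porphyrin core atoms (4 pyrrole N, 16 pyrrole C, 4 meso C) of
#' each complex, and the rotation of complex B's Fe-to-NA reference vector
#' relative to A's is measured in A's plane. The tilt between the two ring
#' normals is reported separately.
#'
#' @param complex_a,complex_b `structure_model`s, each containing a
#'   porphyrin.
#' @param ligand_a,ligand_b Porphyrin selectors for each model.
#' @param chain_a,chain_b Optional chain filters for the protein
#'   superposition.
#' @param pairing Calpha pairing mode (see [superpose_ca()]).
#' @return List: `rotation_deg` (in-plane angle, 0-180), `tilt_deg`
#'   (normal-normal angle, 0-90), `superposition` (the protein transform).
#' @export
heme_plane_rotation <- function(complex_a, complex_b, ligand_a, ligand_b,
                                chain_a = NULL, chain_b = NULL,
                                pairing = "by_resnum") {
  pa <- porphyrin_atoms(complex_a, ligand_a)
  pb <- porphyrin_atoms(complex_b, ligand_b)
  if (nrow(pa$fe) == 0L || nrow(pa$na_atom) == 0L ||
      nrow(pb$fe) == 0L || nrow(pb$na_atom) == 0L)
    stop("need FE and NA atoms in both porphyrins for the reference vector",
         call. = FALSE)
  sp <- superpose_ca(complex_a, complex_b, pairing = pairing,
                     chain_ref = chain_a, chain_mobile = chain_b)
  core_b <- apply_transform(as.matrix(pb$core[, c("x", "y", "z")]), sp)
  fe_b <- as.numeric(apply_transform(
    as.matrix(pb$fe[1, c("x", "y", "z")]), sp))
  na_b <- as.numeric(apply_transform(
    as.matrix(pb$na_atom[1, c("x", "y", "z")]), sp))
  core_a <- as.matrix(pa$core[, c("x", "y", "z")])
  ga <- ring_geometry(core_a)
  gb <- ring_geometry(core_b)
  tilt <- angle_deg(ga$normal, gb$normal)
  tilt <- min(tilt, 180 - tilt)
  va <- c(as.matrix(pa$na_atom[1, c("x", "y", "z")])) -
    c(as.matrix(pa$fe[1, c("x", "y", "z")]))
  vb <- na_b - fe_b
  proj <- function(v, n) v - sum(v * n) * n
  va_p <- proj(va, ga$normal); vb_p <- proj(vb, ga$normal)
  if (sqrt(sum(va_p^2)) < 1e-9 || sqrt(sum(vb_p^2)) < 1e-9)
    stop("degenerate reference vector after projection", call. = FALSE)
  list(rotation_deg = angle_deg(va_p, vb_p), tilt_deg = tilt,
       superposition = sp)
}
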