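# Synthetic structure fixtures built in code: an idealized planar porphyrin
# with CCD atom names, pocket residues at controlled geometry, and a PDB
# writer. All coordinates in Angstrom; geometry is chemically plausible but
# synthetic (constructed for the tests, not taken from any deposition).

deg2rad <- function(d) d * pi / 180

atom_row <- function(elety, elesy, x, y, z, resid, chain, resno,
                     hetero = FALSE, o = 1, alt = "") {
  data.frame(elety = elety, elesy = elesy, x = x, y = y, z = z,
             resid = resid, chain = chain, resno = resno, hetero = hetero,
             o = o, alt = alt, stringsAsFactors = FALSE)
}

# Planar porphyrin centered on Fe at `center`, ring A toward +x+y (45 deg),
# lying in the z = center[3] plane. Includes the 24 core atoms, Fe, and one
# propionate (CGA carboxylate carbon with O1A/O2A) hanging off ring A.
porphyrin_atoms_df <- function(center = c(0, 0, 0), chain = "X",
                               resno = 201) {
  rings <- c(A = 45, B = 135, C = 225, D = 315)
  rows <- list(atom_row("FE", "FE", center[1], center[2], center[3],
                        "HEM", chain, resno, hetero = TRUE))
  pol <- function(r, ang) c(center[1] + r * cos(deg2rad(ang)),
                            center[2] + r * sin(deg2rad(ang)), center[3])
  for (rn in names(rings)) {
    th <- rings[[rn]]
    xyz <- rbind(pol(2.0, th),
                 pol(3.05, th - 21), pol(4.25, th - 13),
                 pol(4.25, th + 13), pol(3.05, th + 21))
    nm <- c(paste0("N", rn), paste0("C1", rn), paste0("C2", rn),
            paste0("C3", rn), paste0("C4", rn))
    el <- c("N", "C", "C", "C", "C")
    for (i in 1:5)
      rows[[length(rows) + 1]] <- atom_row(nm[i], el[i], xyz[i, 1],
                                           xyz[i, 2], xyz[i, 3], "HEM",
                                           chain, resno, hetero = TRUE)
  }
  # PDB names the ring-A nitrogen "NA"
  meso <- c(CHA = 90, CHB = 180, CHC = 270, CHD = 0)
  for (nm in names(meso)) {
    xyz <- pol(3.4, meso[[nm]])
    rows[[length(rows) + 1]] <- atom_row(nm, "C", xyz[1], xyz[2], xyz[3],
                                         "HEM", chain, resno, hetero = TRUE)
  }
  # propionate off C2A: CAA-CBA-CGA with carboxylate O1A/O2A
  base <- pol(4.25, 45 - 13)
  dirv <- (base - center) / sqrt(sum((base - center)^2))
  caa <- base + 1.5 * dirv + c(0, 0, 0.4)
  cba <- caa + 1.5 * dirv + c(0, 0, 0.6)
  cga <- cba + 1.5 * dirv
  o1a <- cga + c(0.6, 0.6, 1.0); o2a <- cga + c(0.9, -0.9, -0.3)
  prop <- rbind(caa, cba, cga, o1a, o2a)
  pn <- c("CAA", "CBA", "CGA", "O1A", "O2A")
  pe <- c("C", "C", "C", "O", "O")
  for (i in 1:5)
    rows[[length(rows) + 1]] <- atom_row(pn[i], pe[i], prop[i, 1],
                                         prop[i, 2], prop[i, 3], "HEM",
                                         chain, resno, hetero = TRUE)
  do.call(rbind, rows)
}

# A compact protein scaffold: n CA atoms on an irregular (non-collinear)
# curve, one residue each.
ca_scaffold <- function(n = 20, chain = "A", resno_start = 1,
                        offset = c(10, 0, 5)) {
  t <- seq(0, 4 * pi, length.out = n)
  data.frame(
    elety = "CA", elesy = "C",
    x = offset[1] + 5 * cos(t), y = offset[2] + 5 * sin(t),
    z = offset[3] + 1.5 * t + 0.3 * sin(3 * t),
    resid = rep(c("ALA", "GLY", "LEU", "VAL", "SER"), length.out = n),
    chain = chain, resno = seq(resno_start, length.out = n),
    hetero = FALSE, o = 1, alt = "", stringsAsFactors = FALSE)
}

# Serialize an atom data.frame to PDB text.
write_pdb <- function(atoms, path) {
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    name4 <- if (nchar(a$elety) >= 4) substr(a$elety, 1, 4)
             else if (nchar(a$elesy) == 2) sprintf("%-4s", a$elety)
             else sprintf(" %-3s", a$elety)
    lines[i] <- sprintf(
      "%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      if (a$hetero) "HETATM" else "ATOM", i, name4,
      ifelse(a$alt == "", " ", a$alt), a$resid, a$chain, a$resno, " ",
      a$x, a$y, a$z, a$o, 0, a$elesy)
  }
  writeLines(c(lines, "END"), path)
  path
}

# Apply a rigid transform to the coordinate columns of an atom data.frame.
transform_atoms <- function(atoms, R, t) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + t[1]; atoms$y <- xyz[, 2] + t[2]
  atoms$z <- xyz[, 3] + t[3]
  atoms
}

# Rotation by `ang` degrees about the z axis.
rot_z <- function(ang) {
  c_ <- cos(deg2rad(ang)); s_ <- sin(deg2rad(ang))
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

# A full synthetic pocket: porphyrin + stacking Phe + H-bonding Tyr + two
# distance-probe residues + protein scaffold; returns a parsed model.
build_pocket_model <- function(path = tempfile(fileext = ".pdb")) {
  hem <- porphyrin_atoms_df(chain = "X", resno = 201)
  ringB <- hem[hem$elety %in% c("NB", "C1B", "C2B", "C3B", "C4B"), ]
  cenB <- unname(colMeans(as.matrix(ringB[, c("x", "y", "z")])))
  phe_ring <- local({
    th <- seq(0, 300, by = 60)
    data.frame(
      elety = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), elesy = "C",
      x = cenB[1] + 1.39 * cos(deg2rad(th)),
      y = cenB[2] + 1.39 * sin(deg2rad(th)),
      z = cenB[3] + 3.8, resid = "PHE", chain = "A", resno = 53,
      hetero = FALSE, o = 1, alt = "", stringsAsFactors = FALSE)
  })
  o1a <- as.numeric(hem[hem$elety == "O1A", c("x", "y", "z")])
  cga <- as.numeric(hem[hem$elety == "CGA", c("x", "y", "z")])
  dirv <- (o1a - cga) / sqrt(sum((o1a - cga)^2))
  oh <- o1a + 2.8 * dirv
  cz <- oh + 1.4 * dirv
  tyr <- rbind(atom_row("OH", "O", oh[1], oh[2], oh[3], "TYR", "A", 137),
               atom_row("CZ", "C", cz[1], cz[2], cz[3], "TYR", "A", 137))
  # distance probes: CB at 3.9 A (contact) and 4.1 A (not) from NB
  nb <- as.numeric(hem[hem$elety == "NB", c("x", "y", "z")])
  probes <- rbind(
    atom_row("CB", "C", nb[1], nb[2], nb[3] - 3.9, "LEU", "A", 141),
    atom_row("CB", "C", nb[1], nb[2], nb[3] - 4.1, "GLU", "A", 45))
  scaffold <- ca_scaffold(20, chain = "A", resno_start = 1,
                          offset = c(14, 0, -6))
  atoms <- rbind(hem, phe_ring, tyr, probes, scaffold)
  write_pdb(atoms, path)
  parse_structure(path)
}

# Protein + porphyrin complex used by the plane-rotation tests.
build_complex_atoms <- function(porph_rot_deg = 0) {
  hem <- porphyrin_atoms_df(chain = "X", resno = 201)
  if (porph_rot_deg != 0) {
    # rotate the porphyrin about its own normal (z) around the Fe center
    hem <- transform_atoms(hem, rot_z(porph_rot_deg), c(0, 0, 0))
  }
  rbind(ca_scaffold(25, chain = "A", resno_start = 1, offset = c(12, 3, -8)),
        hem)
}

parse_atoms <- function(atoms) {
  parse_structure(write_pdb(atoms, tempfile(fileext = ".pdb")))
}

# Build a structure_model in memory, bypassing the 3-decimal PDB coordinate
# rounding; used by the machine-precision superposition tests.
model_from_atoms <- function(atoms) {
  atoms$insert <- ""
  cols <- c("chain", "resid", "resno", "insert", "elety", "elesy",
            "x", "y", "z", "o", "alt", "hetero")
  structure(list(atoms = atoms[, cols], path = NA_character_),
            class = "structure_model")
}
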