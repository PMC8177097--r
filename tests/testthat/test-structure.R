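test_that("PDB parsing preserves atoms, chains, hetero flags and altlocs", {
  atoms <- rbind(ca_scaffold(8, chain = "A"),
                 atom_row("FE", "FE", 0, 0, 0, "HEM", "B", 201,
                          hetero = TRUE),
                 atom_row("NA", "N", 2, 0, 0, "HEM", "B", 201,
                          hetero = TRUE))
  f <- tempfile(fileext = ".pdb")
  write_pdb(atoms, f)
  m <- parse_structure(f)
  expect_equal(nrow(m$atoms), 10L)
  expect_setequal(unique(m$atoms$chain), c("A", "B"))
  expect_equal(sum(m$atoms$hetero), 2L)
  expect_identical(m$atoms$elety[m$atoms$elesy == "FE"], "FE")
  # the porphyrin nitrogen named "NA" must survive as a string
  expect_true("NA" %in% m$atoms$elety)
})

test_that("alternate locations resolve to the highest occupancy", {
  atoms <- rbind(
    atom_row("CA", "C", 0, 0, 0, "ALA", "A", 1, o = 0.4, alt = "A"),
    atom_row("CA", "C", 1, 0, 0, "ALA", "A", 1, o = 0.6, alt = "B"),
    atom_row("CB", "C", 0, 1, 0, "ALA", "A", 1))
  m <- parse_atoms(atoms)
  expect_equal(nrow(m$atoms), 2L)
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(ca$x, 1)  # the 0.6-occupancy copy
})

test_that("malformed inputs fail with explicit errors", {
  empty <- tempfile(fileext = ".pdb"); file.create(empty)
  expect_error(parse_structure(empty), "empty")
  expect_error(parse_structure(tempfile(fileext = ".pdb")), "no such file")
  bad <- tempfile(fileext = ".xyz")
  writeLines("whatever", bad)
  expect_error(parse_structure(bad), "format")
})

test_that("contact census separates amino acids, waters and cutoffs exactly", {
  hem <- porphyrin_atoms_df(chain = "X", resno = 201)
  nb <- as.numeric(hem[hem$elety == "NB", c("x", "y", "z")])
  atoms <- rbind(
    hem,
    atom_row("CB", "C", nb[1], nb[2], nb[3] - 3.9, "LEU", "A", 141),
    atom_row("CB", "C", nb[1], nb[2], nb[3] - 4.1, "GLU", "A", 45),
    atom_row("O", "O", nb[1], nb[2], nb[3] + 3.0, "HOH", "W", 301,
             hetero = TRUE))
  m <- parse_atoms(atoms)
  rep4 <- contact_residues(m, "X:HEM:201", cutoff = 4.0)
  expect_equal(nrow(rep4$residues), 1L)
  expect_equal(rep4$residues$resno, 141L)
  expect_equal(rep4$residues$min_dist, 3.9, tolerance = 1e-3)
  expect_equal(nrow(rep4$waters), 1L)  # waters never join the census
  rep42 <- contact_residues(m, "X:HEM:201", cutoff = 4.2)
  expect_setequal(rep42$residues$resno, c(45L, 141L))
  expect_equal(nrow(contact_residues(m, "X:HEM:201", cutoff = 0)$residues), 0L)
  expect_error(contact_residues(m, "Z:XYZ:9"), "empty")
})

test_that("contact report is monotone in the cutoff", {
  m <- build_pocket_model()
  r35 <- contact_residues(m, "X:HEM:201", cutoff = 3.5)
  r40 <- contact_residues(m, "X:HEM:201", cutoff = 4.0)
  key35 <- paste(r35$residues$chain, r35$residues$resno)
  key40 <- paste(r40$residues$chain, r40$residues$resno)
  expect_true(all(key35 %in% key40))
  expect_true(all(r40$residues$min_dist <= 4.0))
})

test_that("hydrogen bonds are detected by distance plus angle proxy", {
  m <- build_pocket_model()
  hb <- detect_hbonds(m, "X:HEM:201", d_max = 3.5, angle_min = 90)
  tyr <- hb[hb$resid == "TYR" & hb$resno == 137, ]
  expect_gte(nrow(tyr), 1L)
  expect_equal(tyr$distance[1], 2.8, tolerance = 1e-3)
  expect_identical(tyr$atom[1], "OH")
  expect_true(all(hb$distance <= 3.5))
  # far-apart polar atoms are never reported
  hem <- porphyrin_atoms_df()
  o1a <- as.numeric(hem[hem$elety == "O1A", c("x", "y", "z")])
  far <- rbind(hem, atom_row("OG", "O", o1a[1] + 10, o1a[2], o1a[3],
                             "SER", "A", 89))
  expect_equal(nrow(detect_hbonds(parse_atoms(far), ":HEM:")), 0L)
})

test_that("pi stacking requires near-parallel rings at short centroid range", {
  m <- build_pocket_model()
  # the fixture's truncated Tyr ring triggers an incomplete-ring warning
  st <- suppressWarnings(detect_pi_stacking(m, "X:HEM:201"))
  expect_gte(nrow(st), 1L)
  phe <- st[st$resid == "PHE" & st$resno == 53, ]
  expect_equal(nrow(phe), 1L)
  expect_identical(phe$porphyrin_ring, "II")  # placed above ring B
  expect_equal(phe$centroid_dist, 3.8, tolerance = 0.05)
  expect_lt(phe$angle, 5)
  # perpendicular distant ring is rejected
  hem <- porphyrin_atoms_df()
  th <- seq(0, 300, by = 60)
  perp <- data.frame(
    elety = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), elesy = "C",
    x = 9 + 1.39 * cos(deg2rad(th)), y = 0, z = 5 + 1.39 * sin(deg2rad(th)),
    resid = "PHE", chain = "A", resno = 7, hetero = FALSE, o = 1, alt = "",
    stringsAsFactors = FALSE)
  m2 <- parse_atoms(rbind(hem, perp))
  expect_equal(nrow(detect_pi_stacking(m2, ":HEM:")), 0L)
})

test_that("self-superposition gives identity and zero rmsd", {
  m <- model_from_atoms(ca_scaffold(15))
  sp <- superpose_ca(m, m)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sp$n_atoms, 15L)
})

test_that("a known rigid transform is inverted to machine precision", {
  base <- ca_scaffold(20)
  set.seed(31)
  for (i in 1:5) {
    tr <- random_rigid()
    moved <- transform_atoms(base, tr$R, tr$t)
    sp <- superpose_ca(model_from_atoms(base), model_from_atoms(moved))
    expect_lt(sp$rmsd, 1e-8)
    # recovered rotation must invert the applied one
    expect_equal(sp$rotation %*% tr$R, diag(3), tolerance = 1e-6)
  }
})

test_that("rotations are orthonormal with det +1 and rmsd rigid-invariant", {
  set.seed(99)
  a <- ca_scaffold(18)
  b <- a
  b$x <- b$x + rnorm(18, sd = 0.7)
  b$y <- b$y + rnorm(18, sd = 0.7)
  b$z <- b$z + rnorm(18, sd = 0.7)
  sp0 <- superpose_ca(model_from_atoms(a), model_from_atoms(b))
  expect_equal(t(sp0$rotation) %*% sp0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(det(sp0$rotation), 1, tolerance = 1e-10)
  for (i in 1:4) {
    tr_a <- random_rigid(); tr_b <- random_rigid()
    sp <- superpose_ca(model_from_atoms(transform_atoms(a, tr_a$R, tr_a$t)),
                       model_from_atoms(transform_atoms(b, tr_b$R, tr_b$t)))
    expect_equal(sp$rmsd, sp0$rmsd, tolerance = 1e-8)
  }
})

test_that("superposition agrees with an independent reference implementation", {
  set.seed(12)
  a <- ca_scaffold(16)
  b <- a
  b$x <- b$x + rnorm(16, sd = 0.5); b$y <- b$y + rnorm(16, sd = 0.5)
  b$z <- b$z + rnorm(16, sd = 0.5)
  sp <- superpose_ca(model_from_atoms(a), model_from_atoms(b))
  ref_rmsd <- bio3d::rmsd(
    as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
    as.vector(t(as.matrix(b[, c("x", "y", "z")]))), fit = TRUE)
  expect_lt(abs(sp$rmsd - ref_rmsd), 5e-4)  # bio3d rounds to 3 decimals
})

test_that("too few or degenerate Calpha pairs are flagged", {
  expect_error(superpose_ca(model_from_atoms(ca_scaffold(2)),
                            model_from_atoms(ca_scaffold(2))), "3 paired")
  line <- ca_scaffold(5)
  line$x <- 1:5; line$y <- 0; line$z <- 0
  expect_warning(superpose_ca(model_from_atoms(line), model_from_atoms(line)),
                 "degenerate")
})

test_that("porphyrin plane rotation recovers constructed angles", {
  a <- parse_atoms(build_complex_atoms(0))
  same <- heme_plane_rotation(a, a, "X:HEM:201", "X:HEM:201")
  expect_equal(same$rotation_deg, 0, tolerance = 1e-6)
  expect_equal(same$tilt_deg, 0, tolerance = 1e-6)
  for (ang in c(30, 90, 120)) {
    b_atoms <- build_complex_atoms(ang)
    set.seed(ang)
    tr <- random_rigid()  # plus an arbitrary global motion of complex B
    b <- parse_atoms(transform_atoms(b_atoms, tr$R, tr$t))
    res <- heme_plane_rotation(a, b, "X:HEM:201", "X:HEM:201")
    expect_equal(res$rotation_deg, ang, tolerance = 0.1)
    expect_lt(res$tilt_deg, 0.1)
  }
})

test_that("mirroring the porphyrin through its plane yields finite angles", {
  a <- parse_atoms(build_complex_atoms(0))
  mirrored <- build_complex_atoms(0)
  is_hem <- mirrored$resid == "HEM"
  mirrored$z[is_hem] <- -mirrored$z[is_hem]
  b <- parse_atoms(mirrored)
  res <- heme_plane_rotation(a, b, "X:HEM:201", "X:HEM:201")
  expect_true(is.finite(res$rotation_deg))
  expect_true(is.finite(res$tilt_deg))
  expect_gte(res$tilt_deg, 0)
  expect_lte(res$tilt_deg, 90)
})
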