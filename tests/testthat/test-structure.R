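test_that("reader strips waters, resolves altlocs, and checks ligands", {
  pdb_lines <- c(
    "ATOM      1  N  AALA A   1      11.104   6.134  -6.504  0.60 10.00           N",
    "ATOM      2  N  BALA A   1      11.804   6.134  -6.504  0.40 10.00           N",
    "ATOM      3  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C",
    "HETATM    4  O   HOH A 101       2.000   2.000   2.000  1.00 10.00           O",
    "HETATM    5  P1  LIG A 201       5.000   5.000   5.000  1.00 10.00           P",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_lines, path)
  model <- read_structure(path, ligand_roles = c(LIG = "catalytic_substrate"))
  expect_false(any(model$atoms$resid == "HOH"))
  ns <- model$atoms[model$atoms$elety == "N", ]
  expect_equal(nrow(ns), 1L)
  expect_equal(ns$x, 11.104)  # occupancy 0.60 altloc retained
  expect_error(read_structure(path, ligand_roles = c(FBP = "catalytic_substrate")),
               "missing ligand")
})

test_that("ligand proximity uses an inclusive heavy-atom cutoff", {
  plan <- data.frame(
    residue_id = 1:3, amino_acid = c("K", "L", "A"),
    ligand_role = c("catalytic", "catalytic", "none"),
    target_distance = c(4.0, 6.05, NA),
    exposure = "exposed", stringsAsFactors = FALSE)
  model <- gen_toy_structure(toy_structure_spec(plan))
  prox <- ligand_proximal_residues(model, "catalytic_substrate")
  expect_equal(prox$resno, 1L)
  expect_equal(prox$min_dist, 4.0, tolerance = 1e-6)

  # boundary: exactly 6.00 is kept
  plan$target_distance[2] <- 6.0
  model2 <- gen_toy_structure(toy_structure_spec(plan))
  expect_setequal(ligand_proximal_residues(model2,
                                           "catalytic_substrate")$resno,
                  c(1L, 2L))

  # monotonicity: enlarging the cutoff never shrinks the set
  for (co in c(3, 5, 7, 10, 25)) {
    small <- ligand_proximal_residues(model, "catalytic_substrate",
                                      cutoff = co)$resno
    large <- ligand_proximal_residues(model, "catalytic_substrate",
                                      cutoff = co + 2)$resno
    expect_true(all(small %in% large))
  }
  expect_error(ligand_proximal_residues(model, "allosteric_effector"),
               "missing ligand")
})

test_that("SASA matches closed forms on constructed fixtures", {
  lone <- bare_model(atom_row("ATOM", "A", 1, "ALA", "CA", "C", 0, 0, 0))
  s1 <- compute_sasa(lone, n_points = 960)
  expect_equal(s1$atom_sasa, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.005)

  pair <- bare_model(rbind(
    atom_row("ATOM", "A", 1, "ALA", "CA", "C", 0, 0, 0),
    atom_row("ATOM", "A", 2, "GLY", "CA", "C", 100, 0, 0)))
  s2 <- compute_sasa(pair, n_points = 960)
  expect_equal(sum(s2$atom_sasa), 2 * 4 * pi * (1.70 + 1.4)^2,
               tolerance = 1e-6)

  # atom enclosed by a tight cage has zero accessible area
  cage <- sphere_points(80) * 3.0
  caged <- bare_model(rbind(
    atom_row("ATOM", "A", 1, "ALA", "CA", "C", 0, 0, 0),
    do.call(rbind, lapply(seq_len(nrow(cage)), function(k)
      atom_row("HETATM", "X", 900, "CAG", sprintf("C%d", k), "C",
               cage[k, 1], cage[k, 2], cage[k, 3])))))
  s3 <- compute_sasa(caged, n_points = 960, subset = 1)
  expect_equal(s3$atom_sasa, 0, tolerance = 1e-9)

  expect_error(compute_sasa(bare_model(
    atom_row("ATOM", "A", 1, "ALA", "CA", "QQ", 0, 0, 0))),
    "unknown element")
})

test_that("SASA is converged at the default point count", {
  model <- gen_toy_structure(toy_structure_spec(toy_residue_plan()))
  coarse <- compute_sasa(model, n_points = 240)$residue_sasa
  fine <- compute_sasa(model, n_points = 3840)$residue_sasa
  rel <- abs(coarse$sasa - fine$sasa) / pmax(fine$sasa, 1)
  expect_true(all(rel < 0.02))
})

test_that("classification matches planned toy geometry and is rigid-body invariant", {
  model <- gen_toy_structure(toy_structure_spec(toy_residue_plan()))
  ann <- classify_sites(model, n_points = 240)
  expect_equal(ann$class[match(1:6, ann$resno)],
               c("catalytic", "allosteric", "surface", "other", "surface",
                 "allosteric"))
  expect_true(all(ann$rsasa >= 0 & ann$rsasa < 1.3, na.rm = TRUE))

  # rotate + translate the whole model: classes unchanged
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- model
  xyz <- as.matrix(model$atoms[c("x", "y", "z")]) %*% R
  rot$atoms$x <- xyz[, 1] + 13.7
  rot$atoms$y <- xyz[, 2] - 4.2
  rot$atoms$z <- xyz[, 3] + 8.1
  ann_rot <- classify_sites(rot, n_points = 240)
  expect_equal(ann_rot$class, ann$class)
})

test_that("catalytic takes precedence on dual ligand contact", {
  # residue 1 sits 5 A from both a substrate and an effector atom
  atoms <- rbind(
    atom_row("ATOM", "A", 1, "LYS", "CA", "C", 0, 0, 0),
    atom_row("ATOM", "A", 1, "LYS", "CB", "C", 0, -1.5, 0),
    atom_row("HETATM", "L", 901, "SUB", "P1", "P", 0, -6.5, 0),
    atom_row("HETATM", "L", 951, "EFF", "P1", "P", 5, 0, 0))
  model <- bare_model(atoms, c(SUB = "catalytic_substrate",
                               EFF = "allosteric_effector"))
  ann <- classify_sites(model, n_points = 240)
  expect_equal(ann$class, "catalytic")
  expect_true(ann$dual_contact)
})

test_that("contact areas match occlusion oracles", {
  # ligand far away: no occlusion
  far <- bare_model(rbind(
    atom_row("ATOM", "A", 1, "ALA", "CA", "C", 0, 0, 0),
    atom_row("HETATM", "L", 901, "LIG", "P1", "P", 100, 0, 0)),
    c(LIG = "catalytic_substrate"))
  expect_equal(residue_ligand_contact_area(far, "A", 1, "LIG",
                                           n_points = 960), 0)

  # single-neighbor occlusion equals the analytic spherical-cap area
  d <- 4.0
  near <- bare_model(rbind(
    atom_row("ATOM", "A", 1, "ALA", "CA", "C", 0, 0, 0),
    atom_row("HETATM", "L", 901, "LIG", "P1", "P", d, 0, 0)),
    c(LIG = "catalytic_substrate"))
  r1 <- 1.70 + 1.4; r2 <- 1.80 + 1.4
  cos_theta <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
  cap <- 2 * pi * r1^2 * (1 - cos_theta)
  area <- residue_ligand_contact_area(near, "A", 1, "LIG", n_points = 3840)
  expect_gt(area, 0)
  expect_equal(area, cap, tolerance = 0.05)
})
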