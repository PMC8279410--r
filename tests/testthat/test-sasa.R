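test_that("an isolated atom's ASA equals the full solvent-expanded sphere area", {
  m <- model_from_xyz(matrix(c(0, 0, 0), 1))
  asa <- compute_atom_sasa(m, sasa_params())
  expect_equal(unname(asa), 4 * pi * (1.70 + 1.40)^2, tolerance = 1e-12)
})

test_that("two-atom ASA matches the spherical-cap closed form within 2% at 960 points", {
  set.seed(11)
  radii_pool <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  for (k in 1:20) {
    el <- sample(names(radii_pool), 1L)
    r <- radii_pool[[el]]
    R <- r + 1.4
    d <- runif(1, 0.4 * R, 1.9 * R)
    m <- model_from_xyz(rbind(c(0, 0, 0), c(d, 0, 0)), element = el)
    asa <- compute_atom_sasa(m, sasa_params(n_sphere_points = 960L))
    expected <- two_sphere_exposed_area(r, r, d)
    expect_equal(unname(asa[1]), expected[1], tolerance = 0.02)
    expect_equal(unname(asa[2]), expected[2], tolerance = 0.02)
  }
})

test_that("an atom enclosed by a cage of neighbors has zero ASA", {
  # octahedral cage of large-overlap neighbors around the origin
  cage <- rbind(
    c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0), c(0, 0, 2), c(0, 0, -2),
    c(1.3, 1.3, 1.3), c(-1.3, 1.3, 1.3), c(1.3, -1.3, 1.3), c(1.3, 1.3, -1.3),
    c(-1.3, -1.3, 1.3), c(-1.3, 1.3, -1.3), c(1.3, -1.3, -1.3),
    c(-1.3, -1.3, -1.3)
  )
  m <- model_from_xyz(rbind(c(0, 0, 0), cage))
  asa <- compute_atom_sasa(m, sasa_params())
  expect_equal(unname(asa[1]), 0)
})

test_that("occlusion is monotone: adding an atom never increases existing atoms' ASA", {
  set.seed(23)
  params <- sasa_params(n_sphere_points = 240L)
  for (k in 1:100) {
    n <- sample(2:6, 1L)
    xyz <- matrix(runif(3 * n, -3, 3), ncol = 3)
    base <- compute_atom_sasa(model_from_xyz(xyz), params)
    xyz2 <- rbind(xyz, runif(3, -3, 3))
    grown <- compute_atom_sasa(model_from_xyz(xyz2), params)
    expect_true(all(grown[seq_len(n)] <= base + 1e-9))
  }
})

test_that("ASA is bounded by the expanded-sphere area and non-negative", {
  set.seed(5)
  xyz <- matrix(runif(30, -4, 4), ncol = 3)
  asa <- compute_atom_sasa(model_from_xyz(xyz), sasa_params())
  expect_true(all(asa >= 0))
  expect_true(all(asa <= 4 * pi * (1.70 + 1.40)^2 + 1e-9))
})

test_that("doubling the lattice density changes total ASA by under 1% on the helix fixture", {
  m <- make_structure("ideal_helix")$model
  a1 <- sum(compute_atom_sasa(m, sasa_params(n_sphere_points = 960L)))
  a2 <- sum(compute_atom_sasa(m, sasa_params(n_sphere_points = 1920L)))
  expect_lt(abs(a2 - a1) / a1, 0.01)
})

test_that("translation leaves per-atom ASA unchanged and rotation perturbs the model total under 0.5%", {
  m <- make_structure("ideal_helix")$model
  params <- sasa_params()
  a0 <- compute_atom_sasa(m, params)
  mt <- m
  mt$atoms$x <- mt$atoms$x + 17.3
  mt$atoms$y <- mt$atoms$y - 5.1
  mt$atoms$z <- mt$atoms$z + 0.7
  expect_equal(unname(compute_atom_sasa(mt, params)), unname(a0),
               tolerance = 1e-12)
  set.seed(7)
  th <- runif(2, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2]), 0,
                 0, 0, 1), 3, byrow = TRUE)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(Rx %*% Rz)
  mr <- m
  mr$atoms$x <- xyz[, 1]; mr$atoms$y <- xyz[, 2]; mr$atoms$z <- xyz[, 3]
  ar <- compute_atom_sasa(mr, params)
  expect_lt(abs(sum(ar) - sum(a0)) / sum(a0), 0.005)
})

test_that("unradiused elements raise an error listing the offending atoms", {
  at <- atom_fixture(1, 0, 0, 0)
  at$element <- "XX"
  m <- structure_model(at, "fixture", "A")
  expect_error(compute_atom_sasa(m), "XX")
})

test_that("residue ASA is the sum of its atoms and incomplete residues are flagged", {
  m <- make_structure("extended_tripeptide")$model
  atom_asa <- compute_atom_sasa(m)
  res <- aggregate_residue_asa(atom_asa, m)
  expect_equal(nrow(res), 3L)
  # re-summation oracle
  for (r in res$resseq) {
    serials <- m$atoms$serial[m$atoms$resseq == r]
    expect_equal(res$asa[res$resseq == r],
                 sum(atom_asa[as.character(serials)]))
  }
  expect_true(all(res$complete_atoms))
  # drop the central CB: residue still reported, flagged incomplete
  m2 <- m
  keep <- !(m2$atoms$resseq == 2 & m2$atoms$name == "CB")
  m2$atoms <- m2$atoms[keep, ]
  res2 <- aggregate_residue_asa(compute_atom_sasa(m2), m2)
  expect_false(res2$complete_atoms[res2$resseq == 2])
  expect_gt(res2$asa[res2$resseq == 2], 0)
})

test_that("RSA conversion divides by the residue-type maximum and rejects unknown codes", {
  expect_equal(asa_to_rsa(0, "ALA"), 0)
  expect_equal(asa_to_rsa(max_asa_table()[["TRP"]], "TRP"), 1.0)
  expect_error(asa_to_rsa(10, "XYZ"), "XYZ")
  expect_error(asa_to_rsa(-5, "ALA"), "negative")
  expect_warning(asa_to_rsa(2 * max_asa_table()[["GLY"]], "GLY"), "1.5")
})

test_that("the central residue of an extended Gly-X-Gly peptide is near-maximally exposed", {
  m <- make_structure("extended_tripeptide")$model
  # oracle: high-point-count run
  ref <- accessibility_profile(m, sasa_params(n_sphere_points = 3840L))
  central <- ref$rsa[ref$resseq == 2]
  expect_gt(central, 0.7)
  expect_lt(central, 1.3)
  std <- accessibility_profile(m)
  expect_equal(std$rsa[std$resseq == 2], central, tolerance = 0.02)
})

test_that("per-residue ASA agrees with an independent reference implementation on the helix fixture", {
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  make_structure("ideal_helix", path = pdb_path)
  script <- withr::local_tempfile(fileext = ".py")
  out_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf(paste(
    "import biotite.structure.io.pdb as pdb, biotite.structure as struc",
    "import numpy as np",
    "arr = pdb.PDBFile.read('%s').get_structure(model=1)",
    "s = struc.sasa(arr, probe_radius=1.4, point_number=1920, vdw_radii='Single')",
    "with open('%s', 'w') as fh:",
    "    for rid in np.unique(arr.res_id):",
    "        fh.write('%%d,%%.6f\\n' %% (rid, np.sum(s[arr.res_id == rid])))",
    sep = "\n"), pdb_path, out_csv), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  ref <- utils::read.csv(out_csv, header = FALSE,
                         col.names = c("resseq", "asa"))
  m <- read_structure(pdb_path, chain_id = "A")
  res <- aggregate_residue_asa(compute_atom_sasa(m, sasa_params()), m)
  merged <- merge(res, ref, by = "resseq", suffixes = c("", "_ref"))
  expect_equal(nrow(merged), 18L)
  expect_equal(merged$asa, merged$asa_ref, tolerance = 0.03)
})

test_that("consensus RSA is the mean over resolved states and differential subtracts inactive from active", {
  pa <- data.frame(resseq = c(1L, 2L, 3L), resname = "ALA",
                   asa = c(10, 20, 30), rsa = c(0.2, 0.5, 0.9),
                   complete_atoms = TRUE)
  pb <- data.frame(resseq = c(1L, 2L), resname = "ALA",
                   asa = c(20, 20), rsa = c(0.4, 0.5),
                   complete_atoms = TRUE)
  cons <- consensus_rsa(list(pa, pb))
  expect_equal(unname(cons[c("1", "2", "3")]), c(0.3, 0.5, 0.9))
  # identical profiles: consensus equals the input, differential is zero
  expect_equal(unname(consensus_rsa(list(pa, pa))), pa$rsa)
  expect_equal(unname(differential_rsa(pa, pa)), c(0, 0, 0))
  d <- differential_rsa(pa, pb)
  expect_equal(unname(d), c(0.2 - 0.4, 0.5 - 0.5))
  expect_false("3" %in% names(d))  # unresolved in inactive -> absent
  expect_error(consensus_rsa(list()), "at least one")
})

test_that("accessibility export carries the -1 sentinel for unresolved residues and reads back", {
  m <- make_structure("extended_tripeptide")$model
  prof <- accessibility_profile(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_accessibility(prof, path, full_range = 1:5)
  tab <- read_rsa_table(path)
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$rsa[tab$resseq %in% 4:5], c(-1, -1))
  lk <- rsa_lookup(tab)
  expect_false(any(lk == -1))
  expect_equal(length(lk), 3L)
})
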