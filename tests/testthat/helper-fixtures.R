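# In-code fixtures and independent oracles shared across test files.

# bare atom table row for hand-built models
atom_fixture <- function(serial, x, y, z, element = "C", name = "CA",
                         resname = "GLY", resseq = serial) {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, chain_id = "A", resseq = resseq,
             x = x, y = y, z = z, occupancy = 1, altloc = "",
             is_hetero = FALSE, stringsAsFactors = FALSE)
}

model_from_xyz <- function(xyz, element = "C") {
  atoms <- do.call(rbind, lapply(seq_len(nrow(xyz)), function(i) {
    atom_fixture(i, xyz[i, 1], xyz[i, 2], xyz[i, 3], element = element)
  }))
  structure_model(atoms, structure_id = "fixture", chain_id = "A")
}

# independent Kruskal-Wallis oracle: literal rank-sum formula with midranks
# and tie correction, no call into stats::kruskal.test
kw_bruteforce <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  n <- vapply(groups, length, 0L)
  N <- length(values)
  sorted <- sort(values)
  midrank <- function(v) {
    idx <- which(sorted == v)
    mean(idx)
  }
  r <- vapply(values, midrank, 0)
  grp <- rep(seq_along(groups), n)
  rbar <- tapply(r, grp, mean)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / correction
}

# trapezoidal AUC from a threshold-sweep ROC polygon
auc_trapezoid <- function(points) {
  o <- order(points$fpr, points$tpr)
  f <- points$fpr[o]; t <- points$tpr[o]
  sum(diff(f) * (utils::head(t, -1) + utils::tail(t, -1)) / 2)
}

# gnomAD-style population export used by the curation tests
gnomad_fixture <- function() {
  data.frame(
    protein_consequence = c("p.A100V", "p.R200Q", "p.K1395R", "p.L300P",
                            "p.G400S", "p.T500M"),
    allele_count = c(7L, 1L, 12L, 2L, 1L, 25L),
    stringsAsFactors = FALSE
  )
}

# COSMIC-style cancer export; p.T500M overlaps the gnomAD fixture
cosmic_fixture <- function() {
  data.frame(
    mutation_aa = c("p.E1799K", "p.S2215F", "p.D600N", "p.T500M", "p.P700L"),
    count = c(9L, 3L, 2L, 9L, 1L),
    stringsAsFactors = FALSE
  )
}

# two-chain PDB text with an altloc pair on chain A, a water, and a ligand
write_two_chain_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.60 10.00           N",
    "ATOM      2  N  BALA A   1       0.500   0.000   0.000  0.40 10.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      5  O   ALA A   1       1.251   2.390   0.000  1.00 10.00           O",
    "ATOM      6  CB  ALA A   1       1.988  -0.773  -1.199  1.00 10.00           C",
    "ATOM      7  H   ALA A   1       0.300   0.900   0.100  1.00 10.00           H",
    "ATOM      8  N   GLY B   1      10.000   0.000   0.000  1.00 10.00           N",
    "ATOM      9  CA  GLY B   1      11.458   0.000   0.000  1.00 10.00           C",
    "HETATM   10  O   HOH A   2       5.000   5.000   5.000  1.00 10.00           O",
    "HETATM   11 MG    MG A   3       6.000   6.000   6.000  1.00 10.00          MG",
    "END")
  writeLines(lines, path)
  path
}
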