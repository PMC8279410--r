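#' Parameters for the Shrake-Rupley calculation
#'
#' @param probe_radius solvent probe radius in Angstrom (water ~ 1.4).
#' @param n_sphere_points number of deterministic lattice points per atom
#'   sphere (>= 12); error of the area estimate scales roughly as
#'   1/sqrt(n).
#' @param radius_set_name name of the van der Waals radius set, see
#'   [vdw_radii()].
#' @param include_hetero whether hetero atoms participate (they must then be
#'   present in the model).
#' @return list of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960L,
                        radius_set_name = "single", include_hetero = FALSE) {
  stopifnot(probe_radius > 0, n_sphere_points >= 12L)
  vdw_radii(radius_set_name)  # validates the name
  structure(
    list(
      probe_radius = probe_radius,
      n_sphere_points = as.integer(n_sphere_points),
      radius_set_name = radius_set_name,
      include_hetero = isTRUE(include_hetero)
    ),
    class = "sasa_params"
  )
}

#' Deterministic golden-spiral lattice on the unit sphere
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' Samples `n_sphere_points` lattice points on each atom's solvent-expanded
#' sphere (radius = vdW + probe) and counts points not occluded by any
#' neighboring expanded sphere. Deterministic for fixed parameters.
#'
#' @param model a [structure_model()].
#' @param params a [sasa_params()].
#' @return numeric vector of per-atom ASA (Angstrom^2), in atom order of
#'   `model$atoms`.
#' @export
compute_atom_sasa <- function(model, params = sasa_params()) {
  stopifnot(inherits(model, "structure_model"),
            inherits(params, "sasa_params"))
  atoms <- model$atoms
  if (!params$include_hetero && any(atoms$is_hetero)) {
    atoms <- atoms[!atoms$is_hetero, , drop = FALSE]
  }
  radii <- vdw_radii(params$radius_set_name)
  el <- toupper(atoms$element)
  unrad <- !(el %in% names(radii))
  if (any(unrad)) {
    bad <- unique(paste0(atoms$name[unrad], " (element '", el[unrad], "')"))
    stop("no van der Waals radius in set '", params$radius_set_name,
         "' for atoms: ", paste(bad, collapse = ", "))
  }
  n <- nrow(atoms)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  R <- unname(radii[el]) + params$probe_radius
  sp <- sphere_points(params$n_sphere_points)
  npts <- nrow(sp)

  asa <- numeric(n)
  # pairwise squared distances for neighbor lists; models here are small
  d2mat <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cutoff2 <- (R[i] + R)^2
    nb <- which(d2mat[i, ] < cutoff2 & seq_len(n) != i)
    if (!length(nb)) {
      asa[i] <- 4 * pi * R[i]^2
      next
    }
    pts <- sp * R[i]
    pts <- sweep(pts, 2L, xyz[i, ], "+")
    acc <- rep(TRUE, npts)
    for (j in nb) {
      if (!any(acc)) break
      dx <- pts[acc, 1L] - xyz[j, 1L]
      dy <- pts[acc, 2L] - xyz[j, 2L]
      dz <- pts[acc, 3L] - xyz[j, 3L]
      acc[acc] <- dx * dx + dy * dy + dz * dz >= R[j]^2
    }
    asa[i] <- 4 * pi * R[i]^2 * sum(acc) / npts
  }
  names(asa) <- as.character(atoms$serial)
  asa
}

# residues flagged incomplete when an expected heavy atom is absent
.expected_heavy <- function(resname) {
  bb <- c("N", "CA", "C", "O")
  if (resname == "GLY") bb else c(bb, "CB")
}

#' Aggregate atom ASA to whole-residue ASA
#'
#' Residue ASA is the sum over its atoms (backbone plus side chain), matching
#' the per-residue granularity of standard accessibility tables. Residues
#' missing expected heavy atoms are flagged `complete_atoms = FALSE` but still
#' reported.
#'
#' @param atom_asa per-atom ASA vector from [compute_atom_sasa()], named by
#'   atom serial.
#' @param model the same [structure_model()].
#' @return data.frame with columns `resseq`, `resname`, `asa`,
#'   `complete_atoms`.
#' @export
aggregate_residue_asa <- function(atom_asa, model) {
  stopifnot(inherits(model, "structure_model"))
  atoms <- model$atoms[match(names(atom_asa),
                             as.character(model$atoms$serial)), , drop = FALSE]
  if (anyNA(atoms$serial)) stop("atom_asa names do not match model serials")
  split_idx <- split(seq_len(nrow(atoms)), atoms$resseq)
  resseq <- as.integer(names(split_idx))
  resname <- vapply(split_idx, function(ix) atoms$resname[ix[1L]], "")
  asa <- vapply(split_idx, function(ix) sum(atom_asa[ix]), 0)
  complete <- vapply(split_idx, function(ix) {
    all(.expected_heavy(atoms$resname[ix[1L]]) %in% atoms$name[ix])
  }, NA)
  out <- data.frame(
    resseq = resseq, resname = unname(resname), asa = unname(asa),
    complete_atoms = unname(complete), stringsAsFactors = FALSE
  )
  out[order(out$resseq), , drop = FALSE]
}

#' Convert absolute residue ASA to relative solvent accessibility
#'
#' @param asa residue ASA values (Angstrom^2, >= 0).
#' @param resname 3-letter residue codes (recycled against `asa`).
#' @param table maximum-ASA lookup, see [max_asa_table()].
#' @return RSA values (unitless, >= 0). RSA slightly above 1 can occur for
#'   residues more exposed than the tabulated maximum conformation; values
#'   above 1.5 trigger a warning.
#' @export
asa_to_rsa <- function(asa, resname, table = max_asa_table()) {
  if (any(asa < 0)) stop("negative ASA input")
  resname <- rep_len(toupper(resname), length(asa))
  unknown <- !(resname %in% names(table))
  if (any(unknown)) {
    stop("no maximum ASA for residue code(s): ",
         paste(unique(resname[unknown]), collapse = ", "))
  }
  rsa <- asa / unname(table[resname])
  if (any(rsa > 1.5)) {
    warning(sum(rsa > 1.5), " residue(s) with RSA > 1.5; check radii/units")
  }
  rsa
}

#' Per-residue accessibility profile of one structure state
#'
#' Runs the full chain: per-atom Shrake-Rupley, residue aggregation, RSA
#' conversion.
#'
#' @inheritParams compute_atom_sasa
#' @return data.frame of class `accessibility_profile` with columns `resseq`,
#'   `resname`, `asa`, `rsa`, `complete_atoms`; attributes `structure_id`,
#'   `state_label`, `chain_id`, `params`.
#' @export
accessibility_profile <- function(model, params = sasa_params()) {
  atom_asa <- compute_atom_sasa(model, params)
  res <- aggregate_residue_asa(atom_asa, model)
  res$rsa <- asa_to_rsa(res$asa, res$resname)
  res <- res[, c("resseq", "resname", "asa", "rsa", "complete_atoms")]
  attr(res, "structure_id") <- model$structure_id
  attr(res, "state_label") <- model$state_label
  attr(res, "chain_id") <- model$chain_id
  attr(res, "params") <- params
  class(res) <- c("accessibility_profile", "data.frame")
  res
}

.profile_rsa_map <- function(profile) {
  stats::setNames(profile$rsa, as.character(profile$resseq))
}

#' Consensus RSA across structure states
#'
#' Per residue, the arithmetic mean of RSA over the states in which the
#' residue is resolved. Residues resolved in no state are absent.
#'
#' @param profiles list of `accessibility_profile` data frames (or any data
#'   frames with `resseq` and `rsa` columns).
#' @return named numeric vector, names = resseq, values = consensus RSA.
#' @export
consensus_rsa <- function(profiles) {
  if (!length(profiles)) stop("need at least one accessibility profile")
  if (is.data.frame(profiles)) profiles <- list(profiles)
  all_res <- sort(unique(unlist(lapply(profiles, `[[`, "resseq"))))
  vals <- vapply(all_res, function(r) {
    x <- unlist(lapply(profiles, function(p) p$rsa[p$resseq == r]))
    mean(x)
  }, 0)
  stats::setNames(vals, as.character(all_res))
}

#' Differential RSA between active and inactive states
#'
#' @param active,inactive `accessibility_profile` data frames over the same
#'   residue numbering.
#' @return named numeric vector of `rsa_active - rsa_inactive` for residues
#'   resolved in both states.
#' @export
differential_rsa <- function(active, inactive) {
  common <- intersect(active$resseq, inactive$resseq)
  a <- active$rsa[match(common, active$resseq)]
  b <- inactive$rsa[match(common, inactive$resseq)]
  stats::setNames(a - b, as.character(common))[order(common)]
}

#' Write a per-residue accessibility table
#'
#' Tab-delimited export with columns `structure_id`, `state`, `chain`,
#' `resseq`, `resname`, `asa`, `rsa`. Residues of `full_range` absent from the
#' profile (unresolved in the structure) are exported with the `-1` sentinel
#' in both `asa` and `rsa`, matching the dialect of precomputed accessibility
#' tables.
#'
#' @param profile an [accessibility_profile()].
#' @param path output file.
#' @param full_range optional integer vector of residue numbers that should
#'   appear in the export (unresolved ones get `-1`).
#' @return `path`, invisibly.
#' @export
write_accessibility <- function(profile, path, full_range = NULL) {
  df <- data.frame(
    structure_id = attr(profile, "structure_id"),
    state = attr(profile, "state_label"),
    chain = attr(profile, "chain_id"),
    resseq = profile$resseq,
    resname = profile$resname,
    asa = round(profile$asa, 4),
    rsa = round(profile$rsa, 6),
    stringsAsFactors = FALSE
  )
  if (!is.null(full_range)) {
    missing_res <- setdiff(as.integer(full_range), profile$resseq)
    if (length(missing_res)) {
      df <- rbind(df, data.frame(
        structure_id = attr(profile, "structure_id"),
        state = attr(profile, "state_label"),
        chain = attr(profile, "chain_id"),
        resseq = missing_res, resname = "UNK",
        asa = -1, rsa = -1, stringsAsFactors = FALSE
      ))
      df <- df[order(df$resseq), , drop = FALSE]
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a precomputed per-residue RSA table
#'
#' Accepts tab- or comma-delimited tables carrying at least a residue-number
#' column and an RSA column (residue name optional). The `-1` sentinel for
#' unresolved residues is preserved; use [rsa_lookup()] to obtain a cleaned
#' residue -> RSA map.
#'
#' @param path file path.
#' @return data.frame with columns `resseq`, `resname` (may be `NA`), `rsa`.
#' @export
read_rsa_table <- function(path) {
  if (!file.exists(path)) stop("RSA table not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  lc <- tolower(names(df))
  res_col <- which(lc %in% c("resseq", "residue", "resno", "residue_number",
                             "position", "pos"))[1L]
  rsa_col <- which(lc %in% c("rsa", "consensus_rsa", "rel_asa",
                             "relative_asa"))[1L]
  name_col <- which(lc %in% c("resname", "residue_name", "resid", "aa"))[1L]
  if (is.na(res_col) || is.na(rsa_col)) {
    stop("RSA table needs a residue-number column and an RSA column; got: ",
         paste(names(df), collapse = ", "))
  }
  out <- data.frame(
    resseq = as.integer(df[[res_col]]),
    resname = if (!is.na(name_col)) toupper(df[[name_col]]) else NA_character_,
    rsa = as.numeric(df[[rsa_col]]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$resseq))) stop("non-integer residue numbers in ", path)
  out
}

#' Residue -> RSA lookup from a profile or RSA table
#'
#' Drops `-1` sentinel and missing values (the exclusion rule for unresolved
#' residues), returning a named vector suitable for [annotate_rsa()].
#'
#' @param x an `accessibility_profile`, a data.frame from [read_rsa_table()],
#'   or a named numeric vector (returned as-is after sentinel removal).
#' @return named numeric vector, names = residue numbers.
#' @export
rsa_lookup <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    v <- x
  } else if (is.data.frame(x)) {
    v <- stats::setNames(x$rsa, as.character(x$resseq))
  } else {
    stop("cannot build an RSA lookup from class ",
         paste(class(x), collapse = "/"))
  }
  v[!is.na(v) & v != -1]
}
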