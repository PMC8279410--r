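#' @importFrom stats setNames
NULL

.water_resnames <- c("HOH", "WAT", "DOD", "H2O", "SOL", "TIP")

#' Construct a single-chain structure model
#'
#' Low-level constructor around a per-atom data frame. Most users will call
#' [read_structure()]; the synthetic generators build models directly.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `chain_id`, `resseq`, `x`, `y`, `z`, `occupancy`, `altloc`,
#'   `is_hetero`.
#' @param structure_id identifier string (e.g. a PDB code).
#' @param state_label conformational state: `"active"`, `"inactive"` or
#'   `"other"`.
#' @param chain_id single chain identifier the atoms belong to.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, structure_id, chain_id,
                            state_label = c("other", "active", "inactive")) {
  state_label <- match.arg(state_label)
  needed <- c("serial", "name", "element", "resname", "chain_id", "resseq",
              "x", "y", "z", "occupancy", "altloc", "is_hetero")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("structure model must contain at least one atom")
  if (length(unique(atoms$chain_id)) != 1L) {
    stop("structure model must hold exactly one chain, got: ",
         paste(unique(atoms$chain_id), collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  occ <- atoms$occupancy
  if (any(!is.na(occ) & (occ < 0 | occ > 1))) stop("occupancy outside [0, 1]")
  rownames(atoms) <- NULL
  structure(
    list(
      structure_id = structure_id,
      state_label = state_label,
      chain_id = chain_id,
      atoms = atoms,
      resolved_residues = sort(unique(atoms$resseq))
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "structure_model %s chain %s (%s): %d atoms, %d residues [%d..%d]\n",
    x$structure_id, x$chain_id, x$state_label, nrow(x$atoms),
    length(x$resolved_residues),
    min(x$resolved_residues), max(x$resolved_residues)
  ))
  invisible(x)
}

.element_from_atom <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  fix <- is.na(el) | el == ""
  if (any(fix)) {
    # fall back to atom-name convention: strip digits, take leading letters;
    # two-letter elements in proteins are rare (SE of MSE handled below)
    guess <- gsub("[^A-Z]", "", toupper(elety[fix]))
    el[fix] <- substr(guess, 1L, 1L)
    sel <- substr(guess, 1L, 2L) == "SE"
    el[fix][sel] <- "SE"
  }
  el
}

#' Read one chain of one model from a PDB or mmCIF file
#'
#' Parses a structure file (format chosen by extension: `.cif`/`.mmcif` read
#' as mmCIF, anything else as PDB), extracts a single chain of a single model,
#' removes waters and hydrogens, optionally removes hetero atoms, and resolves
#' alternate locations by keeping the highest-occupancy conformer (ties broken
#' by file order).
#'
#' @param path structure file path.
#' @param chain_id chain to extract (default `"A"`).
#' @param model_index model number to use for multi-model files (default 1).
#' @param state_label conformational state label carried through downstream
#'   accessibility tables.
#' @param include_hetero keep non-water HETATM records (default `FALSE`).
#' @param structure_id identifier; defaults to the file base name.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, chain_id = "A", model_index = 1L,
                           state_label = c("other", "active", "inactive"),
                           include_hetero = FALSE, structure_id = NULL) {
  state_label <- match.arg(state_label)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (is.null(structure_id)) {
    structure_id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                        ignore.case = TRUE)
  }
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) {
      suppressWarnings(bio3d::read.cif(path, maxlines = -1, multi = TRUE,
                                       rm.alt = FALSE, verbose = FALSE))
    } else {
      bio3d::read.pdb(path, maxlines = -1, multi = TRUE, rm.alt = FALSE,
                      verbose = FALSE)
    },
    error = function(e) {
      stop("failed to parse structure file '", path, "': ",
           conditionMessage(e))
    }
  )
  at <- pdb$atom
  chains <- unique(at$chain)
  if (!chain_id %in% chains) {
    stop("chain '", chain_id, "' not present in ", path,
         "; available chains: ", paste(chains, collapse = ", "))
  }
  if (model_index != 1L) {
    # bio3d stores extra models only in $xyz; swap coordinates in
    nmod <- nrow(pdb$xyz)
    if (is.null(nmod) || model_index > nmod) {
      stop("model ", model_index, " not present (file has ",
           max(1L, nmod), ")")
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  }
  at <- at[at$chain == chain_id, , drop = FALSE]
  at <- at[!(toupper(at$resid) %in% .water_resnames), , drop = FALSE]
  element <- .element_from_atom(at$elesy, at$elety)
  at <- at[element != "H" & element != "D", , drop = FALSE]
  element <- element[element != "H" & element != "D"]
  if (!include_hetero) {
    keep <- at$type == "ATOM"
    at <- at[keep, , drop = FALSE]
    element <- element[keep]
  }
  if (nrow(at) == 0L) {
    stop("chain '", chain_id, "' of ", path,
         " has no atoms after filtering")
  }
  occ <- ifelse(is.na(at$o), 1, at$o)
  alt <- ifelse(is.na(at$alt) | at$alt == "", "", at$alt)
  # altloc resolution: per residue x atom name keep highest occupancy,
  # ties -> first record in file order (stable order of `order`)
  key <- paste(at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -occ, seq_len(nrow(at)))
  first_of_key <- !duplicated(key[ord])
  keep_idx <- sort(ord[first_of_key])
  at <- at[keep_idx, , drop = FALSE]
  element <- element[keep_idx]
  occ <- occ[keep_idx]
  alt <- alt[keep_idx]

  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = element,
    resname = toupper(at$resid),
    chain_id = at$chain,
    resseq = at$resno,
    x = at$x, y = at$y, z = at$z,
    occupancy = pmin(1, pmax(0, occ)),
    altloc = alt,
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  structure_model(atoms, structure_id = structure_id, chain_id = chain_id,
                  state_label = state_label)
}
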