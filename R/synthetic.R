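#' Analytic exposed area of two intersecting solvent-expanded spheres
#'
#' Closed-form accessible area of sphere 1 (radius `r1` + probe) partially
#' occluded by sphere 2 (radius `r2` + probe) at center distance `d`:
#' `4*pi*R1^2 - 2*pi*R1*h1` with cap height `h1 = R1 - (d^2 + R1^2 - R2^2) /
#' (2d)`. Serves as the independent oracle for the numerical lattice
#' calculation.
#'
#' @param r1,r2 van der Waals radii (Angstrom).
#' @param d center distance (Angstrom).
#' @param probe probe radius.
#' @return numeric vector `c(area1, area2)` of exposed areas.
#' @export
two_sphere_exposed_area <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  if (d >= R1 + R2) return(c(4 * pi * R1^2, 4 * pi * R2^2))
  cap <- function(R, Rother) {
    a <- (d^2 + R^2 - Rother^2) / (2 * d)
    if (a <= -R) return(0)            # sphere fully inside the other
    h <- min(2 * R, R - a)
    4 * pi * R^2 - 2 * pi * R * h
  }
  c(cap(R1, R2), cap(R2, R1))
}

.atom_row <- function(serial, name, element, resname, resseq, x, y, z) {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, chain_id = "A", resseq = resseq,
             x = x, y = y, z = z, occupancy = 1, altloc = "",
             is_hetero = FALSE, stringsAsFactors = FALSE)
}

# reduced heavy-atom residue template (extended conformation), local coords
.extended_residue <- function(resname, resseq, origin_x, serial0) {
  at <- list(
    .atom_row(serial0 + 0L, "N",  "N", resname, resseq, origin_x + 0.00,  0.50, 0),
    .atom_row(serial0 + 1L, "CA", "C", resname, resseq, origin_x + 1.21, -0.45, 0),
    .atom_row(serial0 + 2L, "C",  "C", resname, resseq, origin_x + 2.42,  0.50, 0),
    .atom_row(serial0 + 3L, "O",  "O", resname, resseq, origin_x + 2.42,  1.73, 0)
  )
  if (resname != "GLY") {
    at <- c(at, list(.atom_row(serial0 + 4L, "CB", "C", resname, resseq,
                               origin_x + 1.21, -1.25, 1.30)))
  }
  do.call(rbind, at)
}

# reduced backbone + CB on ideal helical wheel (rise 1.5 A, 100 deg/residue)
.helix_atoms <- function(n_res, resname = "ALA", resseq0 = 1L, serial0 = 1L,
                         center = c(0, 0), rise = 1.5, twist = 100) {
  rows <- list()
  s <- serial0
  for (i in seq_len(n_res)) {
    th <- (i - 1L) * twist * pi / 180
    z <- (i - 1L) * rise
    rq <- resseq0 + i - 1L
    ca <- c(2.30 * cos(th), 2.30 * sin(th))
    nn <- c(1.60 * cos(th - 0.50), 1.60 * sin(th - 0.50))
    cc <- c(1.70 * cos(th + 0.45), 1.70 * sin(th + 0.45))
    oo <- c(1.95 * cos(th + 0.55), 1.95 * sin(th + 0.55))
    cb <- c(3.45 * cos(th), 3.45 * sin(th))
    rows[[i]] <- rbind(
      .atom_row(s + 0L, "N",  "N", resname, rq, center[1] + nn[1], center[2] + nn[2], z - 0.90),
      .atom_row(s + 1L, "CA", "C", resname, rq, center[1] + ca[1], center[2] + ca[2], z),
      .atom_row(s + 2L, "C",  "C", resname, rq, center[1] + cc[1], center[2] + cc[2], z + 0.90),
      .atom_row(s + 3L, "O",  "O", resname, rq, center[1] + oo[1], center[2] + oo[2], z + 2.10),
      if (resname != "GLY") {
        .atom_row(s + 4L, "CB", "C", resname, rq, center[1] + cb[1], center[2] + cb[2], z - 0.40)
      }
    )
    s <- s + nrow(rows[[i]])
  }
  do.call(rbind, rows)
}

.write_model_pdb <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(cbind(at$x, at$y, at$z))),
    type = ifelse(at$is_hetero, "HETATM", "ATOM"),
    resno = at$resseq, resid = at$resname, eleno = at$serial,
    elety = at$name, chain = rep(model$chain_id, nrow(at)),
    o = at$occupancy, b = rep(0, nrow(at)), elesy = at$element
  )
  invisible(path)
}

#' Generate a toy structure with analytically known burial
#'
#' Deterministic generator for the structure kinds used to validate the
#' accessibility engine:
#' \describe{
#'   \item{isolated_atom}{one carbon; closed-form ASA `4*pi*(r+probe)^2`.}
#'   \item{two_atom}{two carbons at distance `d`; spherical-cap closed form.}
#'   \item{extended_tripeptide}{Gly-X-Gly in an extended conformation; the
#'     central residue is near-maximally exposed.}
#'   \item{ideal_helix}{one ideal alpha helix (rise 1.5 A, 100 degrees per
#'     residue), reduced heavy-atom backbone plus C-beta.}
#'   \item{helix_bundle}{parallel helices on a square; core-facing residues
#'     are buried. The sidecar lists buried (high-precision RSA < 0.05) and
#'     surface (> 0.3) residues from a high-point-count run at generation
#'     time.}
#' }
#'
#' @param kind structure kind, see Details.
#' @param path optional output PDB path; if supplied, a well-formed PDB file
#'   is written.
#' @param d two-atom center distance (Angstrom).
#' @param center_resname central residue of the tripeptide (3-letter code).
#' @param n_res residues per helix.
#' @param n_helices number of helices in the bundle.
#' @param spacing center-to-center helix spacing in the bundle (Angstrom).
#' @param probe probe radius used for the sidecar's analytic values.
#' @return list with `model` (a [structure_model()]), `sidecar` (analytic or
#'   high-precision expectations), and `path` (or `NULL`).
#' @export
make_structure <- function(kind = c("isolated_atom", "two_atom",
                                    "extended_tripeptide", "ideal_helix",
                                    "helix_bundle"),
                           path = NULL, d = 1.5, center_resname = "ALA",
                           n_res = 18L, n_helices = 4L, spacing = 7.5,
                           probe = 1.4) {
  kind <- match.arg(kind)
  rC <- vdw_radii("single")[["C"]]
  if (kind == "isolated_atom") {
    atoms <- .atom_row(1L, "CA", "C", "GLY", 1L, 0, 0, 0)
    sidecar <- list(kind = kind,
                    atom_asa = 4 * pi * (rC + probe)^2)
  } else if (kind == "two_atom") {
    atoms <- rbind(.atom_row(1L, "CA", "C", "GLY", 1L, 0, 0, 0),
                   .atom_row(2L, "CA", "C", "GLY", 2L, d, 0, 0))
    areas <- two_sphere_exposed_area(rC, rC, d, probe)
    sidecar <- list(kind = kind, d = d, atom_asa = areas)
  } else if (kind == "extended_tripeptide") {
    atoms <- rbind(
      .extended_residue("GLY", 1L, 0.00, 1L),
      .extended_residue(toupper(center_resname), 2L, 3.63, 5L),
      .extended_residue("GLY", 3L, 7.26, 11L)
    )
    sidecar <- list(kind = kind, center_resseq = 2L,
                    center_resname = toupper(center_resname))
  } else if (kind == "ideal_helix") {
    atoms <- .helix_atoms(n_res)
    sidecar <- list(kind = kind, n_res = n_res)
  } else {
    half <- spacing / 2
    centers <- list(c(-half, -half), c(half, -half),
                    c(-half, half), c(half, half))
    if (n_helices < 1L || n_helices > 4L) {
      stop("helix_bundle supports 1 to 4 helices")
    }
    rows <- list()
    serial0 <- 1L
    for (h in seq_len(n_helices)) {
      a <- .helix_atoms(n_res, resseq0 = as.integer((h - 1L) * n_res + 1L),
                        serial0 = serial0, center = centers[[h]])
      serial0 <- serial0 + nrow(a)
      rows[[h]] <- a
    }
    atoms <- do.call(rbind, rows)
    sidecar <- list(kind = kind, n_helices = n_helices, n_res = n_res,
                    spacing = spacing)
  }
  model <- structure_model(atoms, structure_id = paste0("synthetic_", kind),
                           chain_id = "A")
  if (kind == "helix_bundle") {
    # high-point-count reference run to designate buried/surface residues
    prof <- accessibility_profile(
      model, sasa_params(probe_radius = probe, n_sphere_points = 3840L))
    sidecar$buried_resseq <- prof$resseq[prof$rsa < 0.05]
    sidecar$surface_resseq <- prof$resseq[prof$rsa > 0.30]
    sidecar$reference_rsa <- stats::setNames(prof$rsa,
                                             as.character(prof$resseq))
  }
  if (!is.null(path)) .write_model_pdb(model, path)
  list(model = model, sidecar = sidecar, path = path)
}

.dist_sampler <- function(dist) {
  switch(dist$dist,
    normal = function(n) pmax(0, stats::rnorm(n, dist$mean, dist$sd)),
    beta = function(n) {
      scale <- if (is.null(dist$scale)) 1 else dist$scale
      scale * stats::rbeta(n, dist$shape1, dist$shape2)
    },
    uniform = function(n) stats::runif(n, dist$min, dist$max),
    stop("unknown distribution '", dist$dist, "'")
  )
}

.dist_cdf <- function(dist) {
  switch(dist$dist,
    normal = function(q) stats::pnorm(q, dist$mean, dist$sd),
    beta = function(q) {
      scale <- if (is.null(dist$scale)) 1 else dist$scale
      stats::pbeta(q / scale, dist$shape1, dist$shape2)
    },
    uniform = function(q) stats::punif(q, dist$min, dist$max),
    stop("unknown distribution '", dist$dist, "'")
  )
}

.dist_pdf <- function(dist) {
  switch(dist$dist,
    normal = function(q) stats::dnorm(q, dist$mean, dist$sd),
    beta = function(q) {
      scale <- if (is.null(dist$scale)) 1 else dist$scale
      stats::dbeta(q / scale, dist$shape1, dist$shape2) / scale
    },
    uniform = function(q) stats::dunif(q, dist$min, dist$max),
    stop("unknown distribution '", dist$dist, "'")
  )
}

#' Closed-form / numeric expected AUC for a disease-vs-population pair
#'
#' Expected AUC of the low-RSA-is-positive score: `P(RSA_disease < RSA_pop)`
#' plus half the probability of ties. For two normals this is the closed form
#' `pnorm((mu_pop - mu_dis) / sqrt(sd_dis^2 + sd_pop^2))`; for other families
#' it is computed by numeric integration of `F_dis(x) f_pop(x)`.
#'
#' @param disease,population distribution descriptors, e.g.
#'   `list(dist = "normal", mean = 0.4, sd = 0.15)`.
#' @return expected AUC in `[0, 1]`.
#' @export
expected_auc <- function(disease, population) {
  if (disease$dist == "normal" && population$dist == "normal") {
    return(stats::pnorm((population$mean - disease$mean) /
                          sqrt(disease$sd^2 + population$sd^2)))
  }
  Fd <- .dist_cdf(disease)
  fp <- .dist_pdf(population)
  stats::integrate(function(x) Fd(x) * fp(x), -Inf, Inf,
                   rel.tol = 1e-9)$value
}

#' Specification of a synthetic variant study
#'
#' Defaults encode the study conditions this package models: 33 catalogued
#' NDD variants, population and cancer groups of realistic catalog magnitude,
#' and normal RSA distributions (clipped at 0) whose mean separations give
#' closed-form AUC 0.76 (NDD vs population) and 0.67 (cancer vs population) —
#' the discrimination level the RSA feature is expected to show.
#'
#' @param n_population,n_cancer,n_ndd group sizes.
#' @param auc_ndd,auc_cancer target closed-form AUCs used to place the
#'   disease-group means below the population mean.
#' @param pop_mean,sd population RSA mean and common standard deviation.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return list of class `variant_spec` with a `rsa_distributions` element
#'   (named per-group descriptors) ready for [make_variant_table()].
#' @export
variant_spec <- function(n_population = 300L, n_cancer = 60L, n_ndd = 33L,
                         auc_ndd = 0.76, auc_cancer = 0.67,
                         pop_mean = 0.55, sd = 0.15, seed = 1L) {
  stopifnot(n_population >= 0, n_cancer >= 0, n_ndd >= 0, sd > 0)
  delta <- function(auc) stats::qnorm(auc) * sd * sqrt(2)
  structure(
    list(
      n_population = as.integer(n_population),
      n_cancer = as.integer(n_cancer),
      n_ndd = as.integer(n_ndd),
      rsa_distributions = list(
        population = list(dist = "normal", mean = pop_mean, sd = sd),
        cancer = list(dist = "normal", mean = pop_mean - delta(auc_cancer),
                      sd = sd),
        NDD = list(dist = "normal", mean = pop_mean - delta(auc_ndd),
                   sd = sd)
      ),
      seed = as.integer(seed)
    ),
    class = "variant_spec"
  )
}

.synth_hgvs <- function(n, positions) {
  refs <- sample(names(.aa3), n, replace = TRUE)
  alts <- vapply(refs, function(r) sample(setdiff(names(.aa3), r), 1L), "")
  list(hgvs = paste0("p.", refs, positions, alts), ref = refs, alt = alts)
}

#' Generate an annotated variant table with controlled group separation
#'
#' Draws per-group RSA values from the spec's distributions, fabricates
#' syntactically valid missense notations at residue positions sampled over
#' the protein, assigns domains via the packaged domain map, and reports the
#' truth sidecar (spec echo plus closed-form expected AUCs). The table has
#' the exact schema emitted by [annotate_rsa()].
#'
#' @param spec a [variant_spec()].
#' @param path optional output path for the table
#'   ([write_annotated_variants()] format).
#' @param sidecar_path optional output path for the truth sidecar (JSON).
#' @param domain_map a [load_domain_map()] result; default the packaged map.
#' @return list with `table`, `sidecar`, `path`, `sidecar_path`.
#' @export
make_variant_table <- function(spec = variant_spec(), path = NULL,
                               sidecar_path = NULL,
                               domain_map = load_domain_map()) {
  stopifnot(inherits(spec, "variant_spec"))
  set.seed(spec$seed)
  n <- c(population = spec$n_population, cancer = spec$n_cancer,
         NDD = spec$n_ndd)
  max_pos <- max(domain_map$end)
  rows <- lapply(names(n), function(g) {
    ng <- n[[g]]
    if (ng == 0L) return(NULL)
    rsa <- .dist_sampler(spec$rsa_distributions[[g]])(ng)
    positions <- sample.int(max_pos, ng, replace = ng > max_pos)
    hg <- .synth_hgvs(ng, positions)
    phen <- if (g == "NDD") {
      sample(c("SKS", "FCD", "Mega"), ng, replace = TRUE,
             prob = c(0.45, 0.35, 0.20))
    } else "none"
    data.frame(
      hgvs_p = hg$hgvs, position = positions, group = g, phenotype = phen,
      domain = assign_domain(positions, domain_map), rsa = rsa,
      stringsAsFactors = FALSE
    )
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  sidecar <- list(
    spec = unclass(spec),
    expected_auc = list(
      NDD = expected_auc(spec$rsa_distributions$NDD,
                         spec$rsa_distributions$population),
      cancer = expected_auc(spec$rsa_distributions$cancer,
                            spec$rsa_distributions$population)
    )
  )
  if (!is.null(path)) write_annotated_variants(table, path)
  if (!is.null(sidecar_path)) {
    jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE,
                         digits = NA)
  }
  list(table = table, sidecar = sidecar, path = path,
       sidecar_path = sidecar_path)
}

#' Specification of a synthetic immunoblot experiment
#'
#' Defaults follow the reporter-assay design this package models: five
#' replicate blots per construct and multiplicative lognormal noise on the
#' normalized ratio.
#'
#' @param constructs named numeric vector of true fold-changes relative to
#'   wild-type (names are construct identifiers).
#' @param n_replicates number of replicate blots.
#' @param sigma lognormal noise standard deviation (log scale) on each test
#'   lane's normalized ratio; the mean-one convention
#'   `exp(N(-sigma^2/2, sigma^2))` keeps the expected relative ratio equal to
#'   the true fold-change.
#' @param readout readout label.
#' @param baseline wild-type raw phospho/total ratio.
#' @param seed integer seed.
#' @return list of class `blot_spec`.
#' @export
blot_spec <- function(constructs = c(var1 = 3.0), n_replicates = 5L,
                      sigma = 0.2, readout = "MTORC1_T389_S6K",
                      baseline = 0.5, seed = 1L) {
  stopifnot(all(constructs > 0), sigma >= 0, n_replicates >= 1)
  if (is.null(names(constructs)) || any(!nzchar(names(constructs)))) {
    stop("constructs must be a named vector of fold-changes")
  }
  structure(
    list(constructs = constructs, n_replicates = as.integer(n_replicates),
         sigma = sigma, readout = readout, baseline = baseline,
         seed = as.integer(seed)),
    class = "blot_spec"
  )
}

#' Generate a synthetic immunoblot quantification table
#'
#' Each replicate blot carries a wild-type lane (raw ratio = the per-blot
#' baseline, itself varying between blots) and one lane per construct whose
#' normalized ratio is the true fold-change times mean-one lognormal noise.
#' Total signals vary per lane; the phospho signal is derived, so every
#' relative ratio is scale invariant by construction.
#'
#' @param spec a [blot_spec()].
#' @param path optional output path (tab-delimited [read_blot_table()]
#'   schema).
#' @param sidecar_path optional truth sidecar path (JSON).
#' @return list with `measurements`, `sidecar`, `path`, `sidecar_path`.
#' @export
make_blot_table <- function(spec = blot_spec(), path = NULL,
                            sidecar_path = NULL) {
  stopifnot(inherits(spec, "blot_spec"))
  set.seed(spec$seed)
  rows <- list()
  for (r in seq_len(spec$n_replicates)) {
    rep_id <- sprintf("blot%02d", r)
    blot_baseline <- spec$baseline * exp(stats::rnorm(1L, 0, 0.15))
    wt_total <- exp(stats::rnorm(1L, log(100), 0.3))
    rows[[length(rows) + 1L]] <- data.frame(
      construct_id = "WT", replicate_id = rep_id, readout = spec$readout,
      phospho_signal = blot_baseline * wt_total, total_signal = wt_total,
      stringsAsFactors = FALSE
    )
    for (cid in names(spec$constructs)) {
      noise <- if (spec$sigma > 0) {
        exp(stats::rnorm(1L, -spec$sigma^2 / 2, spec$sigma))
      } else 1
      rel <- spec$constructs[[cid]] * noise
      total <- exp(stats::rnorm(1L, log(100), 0.3))
      rows[[length(rows) + 1L]] <- data.frame(
        construct_id = cid, replicate_id = rep_id, readout = spec$readout,
        phospho_signal = rel * blot_baseline * total, total_signal = total,
        stringsAsFactors = FALSE
      )
    }
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  sidecar <- list(spec = unclass(spec),
                  true_fold_changes = as.list(spec$constructs))
  if (!is.null(path)) {
    utils::write.table(measurements, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(sidecar_path)) {
    jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE,
                         digits = NA)
  }
  list(measurements = measurements, sidecar = sidecar, path = path,
       sidecar_path = sidecar_path)
}
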