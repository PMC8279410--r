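.config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("rsapath_config_error",
                                             "error", "condition")))
}
.input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("rsapath_input_error",
                                             "error", "condition")))
}

.check_keys <- function(config, allowed, where) {
  extra <- setdiff(names(config), allowed)
  if (length(extra)) {
    .config_error("unknown config key(s) in ", where, ": ",
                  paste(extra, collapse = ", "))
  }
}

#' Read a pipeline run configuration
#'
#' YAML configuration with one section per subcommand (`sasa`, `analyze`,
#' `assay`, `simulate`) plus optional top-level `seed` and `out_dir`.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .config_error("config file not found: ", path)
  config <- yaml::read_yaml(path)
  .check_keys(config, c("sasa", "analyze", "assay", "simulate",
                        "seed", "out_dir"), "top level")
  config
}

.write_manifest <- function(out_dir, stage, config, input_files, seed) {
  input_files <- input_files[file.exists(input_files)]
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("rsapath")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_checksums = as.list(tools::md5sum(input_files))
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Accessibility stage: structures to per-residue RSA tables
#'
#' For each configured structure state, computes the per-residue
#' accessibility profile and writes it; then writes the consensus table
#' (mean RSA over states per residue) and, when both `active` and `inactive`
#' states are present, the differential table. In `rsa_source: table` mode a
#' precomputed consensus table is passed through (sentinel rows preserved).
#'
#' @param config list with elements `structures` (list of
#'   `path`/`chain`/`state` entries), optional `sasa`
#'   (`probe_radius`, `n_sphere_points`, `radius_set_name`), optional
#'   `rsa_source` (`"compute"`, default, or `"table"`), optional `rsa_table`
#'   (path, for table mode).
#' @param out_dir output directory (created if needed).
#' @return named character vector of written files, invisibly.
#' @export
pipeline_sasa <- function(config, out_dir = ".") {
  .check_keys(config, c("structures", "sasa", "rsa_source", "rsa_table"),
              "sasa")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rsa_source <- if (is.null(config$rsa_source)) "compute" else
    config$rsa_source
  written <- character()
  if (rsa_source == "table") {
    if (is.null(config$rsa_table)) {
      .config_error("rsa_source: table requires an rsa_table path")
    }
    tab <- read_rsa_table(config$rsa_table)   # validates; sentinels kept
    out <- file.path(out_dir, "consensus_rsa.tsv")
    utils::write.table(tab, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written["consensus"] <- out
    .write_manifest(out_dir, "sasa", config, config$rsa_table, seed = NA)
    return(invisible(written))
  }
  if (is.null(config$structures) || !length(config$structures)) {
    .config_error("sasa stage needs at least one structure entry")
  }
  sp <- config$sasa
  if (!is.null(sp)) {
    .check_keys(sp, c("probe_radius", "n_sphere_points", "radius_set_name"),
                "sasa params")
  }
  params <- sasa_params(
    probe_radius = if (is.null(sp$probe_radius)) 1.4 else sp$probe_radius,
    n_sphere_points = if (is.null(sp$n_sphere_points)) 960L else
      sp$n_sphere_points,
    radius_set_name = if (is.null(sp$radius_set_name)) "single" else
      sp$radius_set_name
  )
  profiles <- list()
  for (entry in config$structures) {
    .check_keys(entry, c("path", "chain", "model", "state", "id"),
                "structure entry")
    if (is.null(entry$path)) .config_error("structure entry without a path")
    model <- read_structure(
      entry$path,
      chain_id = if (is.null(entry$chain)) "A" else entry$chain,
      model_index = if (is.null(entry$model)) 1L else entry$model,
      state_label = if (is.null(entry$state)) "other" else entry$state,
      structure_id = entry$id
    )
    prof <- accessibility_profile(model, params)
    state <- attr(prof, "state_label")
    out <- file.path(out_dir, paste0("accessibility_", model$structure_id,
                                     "_", state, ".tsv"))
    write_accessibility(prof, out)
    written[paste0(model$structure_id, "_", state)] <- out
    profiles[[length(profiles) + 1L]] <- prof
  }
  cons <- consensus_rsa(profiles)
  cons_df <- data.frame(resseq = as.integer(names(cons)), rsa = unname(cons))
  out <- file.path(out_dir, "consensus_rsa.tsv")
  utils::write.table(cons_df, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  written["consensus"] <- out
  states <- vapply(profiles, attr, "", "state_label")
  if ("active" %in% states && "inactive" %in% states) {
    diff <- differential_rsa(profiles[[which(states == "active")[1L]]],
                             profiles[[which(states == "inactive")[1L]]])
    diff_df <- data.frame(resseq = as.integer(names(diff)),
                          delta_rsa = unname(diff))
    out <- file.path(out_dir, "differential_rsa.tsv")
    utils::write.table(diff_df, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written["differential"] <- out
  }
  .write_manifest(out_dir, "sasa", config,
                  vapply(config$structures, `[[`, "", "path"), seed = NA)
  invisible(written)
}

.analyze_table <- function(config) {
  if (!is.null(config$annotated_table)) {
    return(read_annotated_variants(config$annotated_table))
  }
  dmap <- if (is.null(config$domain_map)) load_domain_map() else
    load_domain_map(config$domain_map)
  if (is.null(config$rsa_table)) {
    .config_error("analyze stage needs rsa_table (or annotated_table)")
  }
  rsa <- rsa_lookup(read_rsa_table(config$rsa_table))
  sets <- list()
  gnomad_hgvs <- character()
  if (!is.null(config$gnomad_table)) {
    gn <- utils::read.table(config$gnomad_table, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    disease <- if (is.null(config$disease_annotations)) character() else
      readLines(config$disease_annotations)
    pcol <- .find_col(gn, c("hgvs_p", "protein_consequence", "hgvsp",
                            "protein_variant", "consequence"),
                      "protein consequence")
    gnomad_hgvs <- gn[[pcol]]
    sets$population <- curate_population(gn, disease)
  }
  if (!is.null(config$cosmic_table)) {
    cs <- utils::read.table(config$cosmic_table, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    sets$cancer <- curate_cancer(cs, gnomad_hgvs)
  }
  sets$NDD <- if (is.null(config$ndd_table)) load_ndd_catalog() else
    load_ndd_catalog(config$ndd_table)
  annotate_rsa(sets, rsa, dmap)
}

#' Analysis stage: variant groups + RSA to statistics and ROC outputs
#'
#' Builds (or loads) the annotated variant table, runs the full-protein and
#' per-domain Kruskal-Wallis and pairwise Wilcoxon battery on log(x+1) RSA,
#' computes the two disease-vs-population ROC analyses, and writes JSON
#' results plus plot-ready ROC point tables.
#'
#' @param config list: either `annotated_table` (path to a table in the
#'   [write_annotated_variants()] schema — the layout of a consensus-RSA
#'   variant export) or the raw inputs `rsa_table`, `gnomad_table`,
#'   `cosmic_table`, `ndd_table`, `disease_annotations`, `domain_map`;
#'   optional `strata` (character vector), `transform` (`"log1p"`/`"none"`).
#' @param out_dir output directory.
#' @return list with `table`, `stats`, `roc` (named list of [roc_auc()]
#'   results), and `files`.
#' @export
pipeline_analyze <- function(config, out_dir = ".") {
  .check_keys(config, c("annotated_table", "rsa_table", "gnomad_table",
                        "cosmic_table", "ndd_table", "disease_annotations",
                        "domain_map", "strata", "transform"), "analyze")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- .analyze_table(config)
  transform <- if (is.null(config$transform)) "log1p" else config$transform
  strata <- if (is.null(config$strata)) NULL else config$strata
  stats_res <- stratified_compare(table, strata = strata,
                                  transform = transform)
  roc <- list()
  for (g in intersect(c("NDD", "cancer"), unique(table$group))) {
    if ("population" %in% table$group) {
      roc[[g]] <- roc_auc(table, positive_group = g)
    }
  }
  files <- character()
  tab_path <- file.path(out_dir, "annotated_variants.tsv")
  write_annotated_variants(table, tab_path)
  files["annotated_table"] <- tab_path
  stats_json <- lapply(stats_res, function(s) {
    list(
      kruskal = list(H = s$kruskal$H, df = s$kruskal$df, p = s$kruskal$p,
                     n_per_group = as.list(s$kruskal$n_per_group)),
      pairwise = s$pairwise$comparisons,
      bonferroni_m = s$pairwise$m
    )
  })
  payload <- list(
    transform = transform,
    domain_map_version = attr(table, "domain_map_version"),
    strata = stats_json,
    skipped_strata = attr(stats_res, "skipped"),
    roc = lapply(roc, function(r) {
      list(auc = r$auc, positive = r$positive_label,
           negative = r$negative_label, n_positive = r$n_positive,
           n_negative = r$n_negative,
           score_orientation = r$score_orientation)
    })
  )
  json_path <- file.path(out_dir, "statistics.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files["statistics"] <- json_path
  for (g in names(roc)) {
    p <- file.path(out_dir, paste0("roc_", g, "_vs_population.tsv"))
    write_roc_points(roc[[g]], p)
    files[paste0("roc_", g)] <- p
  }
  .write_manifest(out_dir, "analyze", config,
                  unlist(config[c("annotated_table", "rsa_table",
                                  "gnomad_table", "cosmic_table",
                                  "ndd_table")]), seed = NA)
  list(table = table, stats = stats_res, roc = roc, files = files)
}

#' Assay stage: blot quantification table to construct summaries
#'
#' @param config list: `blot_table` (path), optional `wt_id` (default
#'   `"WT"`), optional `constructs` (subset to test).
#' @param out_dir output directory.
#' @return list with `ratios`, `summary`, `files`.
#' @export
pipeline_assay <- function(config, out_dir = ".") {
  .check_keys(config, c("blot_table", "wt_id", "constructs"), "assay")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$blot_table)) .config_error("assay stage needs blot_table")
  wt_id <- if (is.null(config$wt_id)) "WT" else config$wt_id
  measurements <- read_blot_table(config$blot_table)
  ratios <- compute_ratios(measurements, wt_id = wt_id)
  summary <- test_vs_wildtype(ratios, constructs = config$constructs,
                              wt_id = wt_id)
  files <- character()
  p <- file.path(out_dir, "construct_summary.tsv")
  utils::write.table(summary, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["summary_tsv"] <- p
  pj <- file.path(out_dir, "construct_summary.json")
  jsonlite::write_json(
    list(bonferroni_m = attr(summary, "m"),
         constructs = as.data.frame(summary)),
    pj, auto_unbox = TRUE, digits = NA)
  files["summary_json"] <- pj
  .write_manifest(out_dir, "assay", config, config$blot_table, seed = NA)
  list(ratios = ratios, summary = summary, files = files)
}

#' Simulation stage: write synthetic inputs plus truth sidecars
#'
#' @param config list: `kind` (`"structure"`, `"variants"`, `"blots"`) plus
#'   the corresponding spec fields (see [make_structure()],
#'   [variant_spec()], [blot_spec()]); `seed` overrides the spec seed.
#' @param out_dir output directory.
#' @return list of generated objects and file paths.
#' @export
pipeline_simulate <- function(config, out_dir = ".") {
  .check_keys(config, c("kind", "structure_kind", "n_population", "n_cancer",
                        "n_ndd", "auc_ndd", "auc_cancer", "constructs",
                        "n_replicates", "sigma", "seed"), "simulate")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$kind)) .config_error("simulate stage needs kind")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- switch(config$kind,
    structure = {
      kind <- if (is.null(config$structure_kind)) "helix_bundle" else
        config$structure_kind
      make_structure(kind, path = file.path(out_dir,
                                            paste0(kind, ".pdb")))
    },
    variants = {
      args <- config[intersect(names(config),
                               c("n_population", "n_cancer", "n_ndd",
                                 "auc_ndd", "auc_cancer"))]
      args$seed <- seed
      spec <- do.call(variant_spec, args)
      make_variant_table(spec,
                         path = file.path(out_dir, "synthetic_variants.tsv"),
                         sidecar_path = file.path(out_dir,
                                                  "variant_truth.json"))
    },
    blots = {
      args <- list(seed = seed)
      if (!is.null(config$constructs)) {
        args$constructs <- unlist(config$constructs)
      }
      if (!is.null(config$n_replicates)) {
        args$n_replicates <- config$n_replicates
      }
      if (!is.null(config$sigma)) args$sigma <- config$sigma
      spec <- do.call(blot_spec, args)
      make_blot_table(spec,
                      path = file.path(out_dir, "synthetic_blots.tsv"),
                      sidecar_path = file.path(out_dir, "blot_truth.json"))
    },
    .config_error("unknown simulate kind '", config$kind, "'")
  )
  .write_manifest(out_dir, "simulate", config, character(), seed = seed)
  out
}
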