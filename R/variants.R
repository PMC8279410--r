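#' Parse an HGVS protein missense notation
#'
#' Accepts 1-letter (`"p.K1395R"`) and 3-letter (`"p.Lys1395Arg"`) forms and
#' normalizes to the 1-letter form. Non-missense notations (frameshift,
#' nonsense, synonymous, deletions, ...) are rejected.
#'
#' @param text character vector of HGVS p. strings.
#' @return data.frame with columns `hgvs_p` (normalized), `ref_aa`,
#'   `position`, `alt_aa`.
#' @export
#' @examples
#' parse_hgvs_p("p.Lys1395Arg")
parse_hgvs_p <- function(text) {
  text <- trimws(text)
  one <- "^p\\.\\(?([A-Z])(\\d+)([A-Z])\\)?$"
  three <- "^p\\.\\(?([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})\\)?$"
  parse_one <- function(s) {
    if (grepl(one, s)) {
      m <- regmatches(s, regexec(one, s))[[1L]]
      ref <- m[2L]; pos <- as.integer(m[3L]); alt <- m[4L]
      if (!(ref %in% names(.aa3)) || !(alt %in% names(.aa3))) {
        stop("unrecognized amino acid code in '", s, "'")
      }
    } else if (grepl(three, s)) {
      m <- regmatches(s, regexec(three, s))[[1L]]
      r3 <- toupper(m[2L]); a3 <- toupper(m[4L]); pos <- as.integer(m[3L])
      if (!(r3 %in% names(.aa1)) || !(a3 %in% names(.aa1))) {
        stop("not a missense substitution: '", s, "'")
      }
      ref <- unname(.aa1[r3]); alt <- unname(.aa1[a3])
    } else {
      stop("cannot parse HGVS protein notation: '", s, "'")
    }
    if (pos < 1L) stop("residue position must be >= 1 in '", s, "'")
    if (ref == alt) stop("not a missense substitution (ref == alt): '", s, "'")
    c(ref, pos, alt)
  }
  parsed <- vapply(text, parse_one, character(3L))
  data.frame(
    hgvs_p = paste0("p.", parsed[1L, ], parsed[2L, ], parsed[3L, ]),
    ref_aa = unname(parsed[1L, ]),
    position = as.integer(parsed[2L, ]),
    alt_aa = unname(parsed[3L, ]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Format a parsed variant back to HGVS p. notation
#'
#' @param ref_aa,position,alt_aa parsed fields (1-letter codes).
#' @return character vector `"p.<ref><pos><alt>"`.
#' @export
format_hgvs_p <- function(ref_aa, position, alt_aa) {
  paste0("p.", ref_aa, position, alt_aa)
}

.new_curated_set <- function(group_label, variants, provenance) {
  structure(
    list(group_label = group_label, variants = variants,
         provenance_log = provenance),
    class = "curated_variant_set"
  )
}

#' @export
print.curated_variant_set <- function(x, ...) {
  cat(sprintf("curated_variant_set '%s': %d variants kept, %d dropped\n",
              x$group_label, nrow(x$variants),
              sum(x$provenance_log$action == "dropped")))
  invisible(x)
}

.find_col <- function(df, candidates, what) {
  lc <- tolower(gsub("[^a-z0-9]", "_", tolower(names(df))))
  hit <- which(lc %in% candidates)[1L]
  if (is.na(hit)) {
    stop("input table lacks a ", what, " column (looked for: ",
         paste(candidates, collapse = ", "), ")")
  }
  hit
}

#' Curate population variants from a gnomAD-style export
#'
#' Keeps a missense variant iff its allele count is at least 2 (singletons
#' removed: a single carrier may be a rare pathogenic variant rather than a
#' benign one) and it carries no disease annotation in other databases.
#' Duplicate rows for the same protein change are merged first (allele counts
#' summed). Every drop is logged with its reason.
#'
#' @param gnomad_rows data.frame with a protein-consequence column (HGVS p.)
#'   and an allele-count column.
#' @param disease_annotations character vector of HGVS p. strings annotated as
#'   overgrowth- or cancer-associated elsewhere.
#' @return a `curated_variant_set` with `group_label = "population"`.
#' @export
curate_population <- function(gnomad_rows, disease_annotations = character()) {
  pcol <- .find_col(gnomad_rows,
                    c("hgvs_p", "protein_consequence", "hgvsp",
                      "protein_variant", "consequence"), "protein consequence")
  acol <- .find_col(gnomad_rows,
                    c("allele_count", "ac", "alleles"), "allele count")
  parsed <- parse_hgvs_p(gnomad_rows[[pcol]])
  ac <- as.integer(gnomad_rows[[acol]])
  if (any(is.na(ac) | ac < 1L)) stop("allele counts must be integers >= 1")
  disease_norm <- if (length(disease_annotations)) {
    parse_hgvs_p(disease_annotations)$hgvs_p
  } else character()

  log_rows <- list()
  # merge duplicate protein changes, summing allele counts
  dup <- duplicated(parsed$hgvs_p)
  if (any(dup)) {
    for (h in unique(parsed$hgvs_p[dup])) {
      idx <- which(parsed$hgvs_p == h)
      ac[idx[1L]] <- sum(ac[idx])
      for (i in idx[-1L]) {
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          variant = h, filter = "dedup-protein-change", action = "dropped",
          reason = "duplicate protein change merged (allele counts summed)",
          stringsAsFactors = FALSE)
      }
    }
    parsed <- parsed[!dup, , drop = FALSE]
    ac <- ac[!dup]
  }
  singleton <- ac < 2L
  annotated <- parsed$hgvs_p %in% disease_norm
  keep <- !singleton & !annotated
  for (i in seq_len(nrow(parsed))) {
    if (singleton[i]) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        variant = parsed$hgvs_p[i], filter = "min-allele-count",
        action = "dropped", reason = "singleton", stringsAsFactors = FALSE)
    } else if (annotated[i]) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        variant = parsed$hgvs_p[i], filter = "disease-annotation",
        action = "dropped", reason = "disease-annotated",
        stringsAsFactors = FALSE)
    } else {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        variant = parsed$hgvs_p[i], filter = "population-filters",
        action = "kept", reason = "", stringsAsFactors = FALSE)
    }
  }
  variants <- parsed[keep, , drop = FALSE]
  variants$source <- rep("gnomad", nrow(variants))
  variants$evidence_count <- ac[keep]
  variants$phenotype <- rep("none", nrow(variants))
  rownames(variants) <- NULL
  .new_curated_set("population", variants, do.call(rbind, log_rows))
}

#' Curate cancer variants from a COSMIC-style export
#'
#' Keeps a variant iff it occurs at least 3 times in the cancer catalog
#' (recurrence raises the chance it is truly oncogenic) and is absent from the
#' population catalog.
#'
#' @param cosmic_rows data.frame with a protein-change column (HGVS p.) and an
#'   occurrence-count column.
#' @param gnomad_variants character vector of HGVS p. strings present in the
#'   population catalog (before its own filtering).
#' @return a `curated_variant_set` with `group_label = "cancer"`.
#' @export
curate_cancer <- function(cosmic_rows, gnomad_variants = character()) {
  pcol <- .find_col(cosmic_rows,
                    c("hgvs_p", "mutation_aa", "protein_variant",
                      "protein_change", "hgvsp"), "protein change")
  ocol <- .find_col(cosmic_rows,
                    c("occurrence_count", "count", "occurrences", "n_samples",
                      "sample_count"), "occurrence count")
  parsed <- parse_hgvs_p(cosmic_rows[[pcol]])
  occ <- as.integer(cosmic_rows[[ocol]])
  if (any(is.na(occ))) stop("occurrence counts must be integers")
  gnomad_norm <- if (length(gnomad_variants)) {
    parse_hgvs_p(gnomad_variants)$hgvs_p
  } else character()

  rare <- occ < 3L
  in_pop <- parsed$hgvs_p %in% gnomad_norm
  keep <- !rare & !in_pop
  log_rows <- lapply(seq_len(nrow(parsed)), function(i) {
    if (rare[i]) {
      data.frame(variant = parsed$hgvs_p[i], filter = "min-recurrence",
                 action = "dropped", reason = "recurrence < 3",
                 stringsAsFactors = FALSE)
    } else if (in_pop[i]) {
      data.frame(variant = parsed$hgvs_p[i], filter = "gnomad-overlap",
                 action = "dropped", reason = "present in gnomAD",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(variant = parsed$hgvs_p[i], filter = "cancer-filters",
                 action = "kept", reason = "", stringsAsFactors = FALSE)
    }
  })
  variants <- parsed[keep, , drop = FALSE]
  variants$source <- rep("cosmic", nrow(variants))
  variants$evidence_count <- occ[keep]
  variants$phenotype <- rep("none", nrow(variants))
  rownames(variants) <- NULL
  .new_curated_set("cancer", variants, do.call(rbind, log_rows))
}

#' Load the packaged neurodevelopmental-disorder variant catalog
#'
#' Reads the literature catalog of NDD-associated MTOR missense variants
#' shipped with the package (33 variants with phenotype evidence flags for
#' Smith-Kingsmore syndrome, focal cortical dysplasia, and the
#' megalencephaly/polymicrogyria group, plus domain and interface
#' annotations). Variants reported under more than one phenotype carry all
#' applicable tags, comma-separated.
#'
#' @param path catalog file; defaults to the packaged fixture.
#' @return a `curated_variant_set` with `group_label = "NDD"`.
#' @export
load_ndd_catalog <- function(path = system.file("extdata",
                                                "ndd_variants.tsv",
                                                package = "rsapath")) {
  if (!nzchar(path) || !file.exists(path)) stop("NDD catalog not found")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  needed <- c("hgvs_c", "hgvs_p", "sks", "fcd", "mega", "domain", "interface")
  if (!all(needed %in% names(df))) {
    stop("NDD catalog schema drift; expected columns: ",
         paste(needed, collapse = ", "))
  }
  parsed <- parse_hgvs_p(df$hgvs_p)
  tags <- mapply(function(s, f, m) {
    paste(c("SKS", "FCD", "Mega")[c(s, f, m) == 1L], collapse = ",")
  }, df$sks, df$fcd, df$mega)
  if (any(tags == "")) {
    stop("NDD catalog rows without any phenotype flag: ",
         paste(df$hgvs_p[tags == ""], collapse = ", "))
  }
  variants <- parsed
  variants$source <- "literature"
  variants$evidence_count <- 1L
  variants$phenotype <- unname(tags)
  variants$hgvs_c <- df$hgvs_c       # opaque metadata, not validated
  variants$domain_reported <- df$domain
  variants$interface <- df$interface
  log_rows <- data.frame(
    variant = variants$hgvs_p, filter = "literature-catalog",
    action = "kept", reason = "", stringsAsFactors = FALSE
  )
  .new_curated_set("NDD", variants, log_rows)
}

#' Load a protein domain map
#'
#' Reads a tab-delimited domain configuration (`domain`, `start`, `end`) and
#' validates that intervals do not overlap. A `# domain_map_version:` comment
#' line, if present, is carried as the `version` attribute and echoed in
#' statistical outputs.
#'
#' @param path configuration file; defaults to the packaged MTOR map.
#' @return data.frame of class `domain_map`.
#' @export
load_domain_map <- function(path = system.file("extdata", "mtor_domains.tsv",
                                               package = "rsapath")) {
  if (!nzchar(path) || !file.exists(path)) stop("domain map not found")
  header <- readLines(path, n = 5L)
  vline <- grep("^#\\s*domain_map_version:", header, value = TRUE)
  version <- if (length(vline)) {
    trimws(sub("^#\\s*domain_map_version:", "", vline[1L]))
  } else "unversioned"
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("domain", "start", "end") %in% names(df))) {
    stop("domain map needs columns domain, start, end")
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start > df$end)) stop("domain interval with start > end")
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)])) {
    stop("overlapping domain intervals in ", path)
  }
  attr(df, "version") <- version
  class(df) <- c("domain_map", "data.frame")
  df
}

#' Assign protein domains to residue positions
#'
#' @param position integer vector of residue numbers.
#' @param map a [load_domain_map()] result.
#' @return character vector of domain names; positions outside every interval
#'   get `"unassigned"`.
#' @export
assign_domain <- function(position, map) {
  stopifnot(inherits(map, "domain_map"))
  vapply(as.integer(position), function(p) {
    hit <- which(map$start <= p & p <= map$end)
    if (length(hit)) map$domain[hit[1L]] else "unassigned"
  }, "")
}

#' Join per-residue RSA onto curated variant sets
#'
#' Produces one row per variant with its group label, domain, and the RSA of
#' its residue. Variants whose residue carries the `-1` sentinel or has no RSA
#' entry are excluded from the table (and logged in the `excluded` attribute),
#' implementing the unresolved-residue exclusion rule. Multiple substitutions
#' at one residue each receive that residue's RSA.
#'
#' @param sets list of `curated_variant_set` objects (or a single one).
#' @param rsa residue -> RSA lookup: named numeric vector or anything accepted
#'   by [rsa_lookup()].
#' @param map a [load_domain_map()] result.
#' @return data.frame with columns `hgvs_p`, `position`, `group`, `phenotype`,
#'   `domain`, `rsa`; attributes `excluded` (data.frame) and
#'   `domain_map_version`.
#' @export
annotate_rsa <- function(sets, rsa, map) {
  if (inherits(sets, "curated_variant_set")) sets <- list(sets)
  rsa <- rsa_lookup(rsa)
  rows <- lapply(sets, function(s) {
    v <- s$variants
    if (!nrow(v)) return(NULL)
    data.frame(
      hgvs_p = v$hgvs_p, position = v$position, group = s$group_label,
      phenotype = v$phenotype, stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) {
    out <- data.frame(hgvs_p = character(), position = integer(),
                      group = character(), phenotype = character(),
                      domain = character(), rsa = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- out
    attr(out, "domain_map_version") <- attr(map, "version")
    return(out)
  }
  tab$domain <- assign_domain(tab$position, map)
  tab$rsa <- unname(rsa[as.character(tab$position)])
  excluded <- tab[is.na(tab$rsa), , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "unresolved or missing RSA"
  out <- tab[!is.na(tab$rsa), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "domain_map_version") <- attr(map, "version")
  out
}

#' Write an annotated variant table
#'
#' Tab-delimited export in the schema consumed by the statistics stage
#' (`hgvs_p`, `position`, `group`, `phenotype`, `domain`, `rsa`).
#'
#' @param table result of [annotate_rsa()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotated_variants <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an annotated variant table
#'
#' @param path tab-delimited file in the [write_annotated_variants()] schema.
#' @return data.frame.
#' @export
read_annotated_variants <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("hgvs_p", "group", "domain", "rsa")
  if (!all(needed %in% names(df))) {
    stop("annotated variant table needs columns: ",
         paste(needed, collapse = ", "))
  }
  df
}
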