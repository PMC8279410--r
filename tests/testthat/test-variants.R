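test_that("HGVS parser accepts 1- and 3-letter missense forms and normalizes", {
  p <- parse_hgvs_p(c("p.K1395R", "p.Lys1395Arg", "p.Q2524K", "p.(C1390Y)"))
  expect_equal(p$hgvs_p, c("p.K1395R", "p.K1395R", "p.Q2524K", "p.C1390Y"))
  expect_equal(p$ref_aa, c("K", "K", "Q", "C"))
  expect_equal(p$position, c(1395L, 1395L, 2524L, 1390L))
  expect_equal(p$alt_aa, c("R", "R", "K", "Y"))
})

test_that("HGVS parser rejects malformed and non-missense notations", {
  expect_error(parse_hgvs_p("p.1395K"), "cannot parse")
  expect_error(parse_hgvs_p("K1395R"), "cannot parse")
  expect_error(parse_hgvs_p("p.K1395fs"), "cannot parse")
  expect_error(parse_hgvs_p("p.Lys1395Ter"), "missense")
  expect_error(parse_hgvs_p("p.K1395K"), "missense")
  expect_error(parse_hgvs_p("p.K0R"), ">= 1")
})

test_that("parse/format round-trips every catalog variant", {
  ndd <- load_ndd_catalog()
  v <- ndd$variants
  round <- parse_hgvs_p(format_hgvs_p(v$ref_aa, v$position, v$alt_aa))
  expect_equal(round$hgvs_p, v$hgvs_p)
})

test_that("population curation keeps allele count >= 2 without disease annotation and logs drops", {
  set <- curate_population(gnomad_fixture(), disease_annotations = "p.K1395R")
  expect_s3_class(set, "curated_variant_set")
  expect_setequal(set$variants$hgvs_p, c("p.A100V", "p.L300P", "p.T500M"))
  log <- set$provenance_log
  # conservation: every input row accounted for
  expect_equal(nrow(log), nrow(gnomad_fixture()))
  expect_equal(sum(log$action == "kept") + sum(log$action == "dropped"),
               nrow(gnomad_fixture()))
  expect_equal(log$reason[log$variant == "p.R200Q"], "singleton")
  expect_equal(log$reason[log$variant == "p.G400S"], "singleton")
  expect_equal(log$reason[log$variant == "p.K1395R"], "disease-annotated")
})

test_that("duplicate protein changes are merged with allele counts summed", {
  rows <- data.frame(
    protein_consequence = c("p.A100V", "p.A100V", "p.R200Q"),
    allele_count = c(1L, 1L, 5L)
  )
  set <- curate_population(rows)
  # two singleton records of the same protein change = 2 alleles -> kept
  expect_setequal(set$variants$hgvs_p, c("p.A100V", "p.R200Q"))
  expect_equal(set$variants$evidence_count[set$variants$hgvs_p == "p.A100V"],
               2L)
})

test_that("cancer curation requires recurrence >= 3 and absence from gnomAD", {
  gn <- gnomad_fixture()$protein_consequence
  set <- curate_cancer(cosmic_fixture(), gnomad_variants = gn)
  expect_setequal(set$variants$hgvs_p, c("p.E1799K", "p.S2215F"))
  log <- set$provenance_log
  expect_equal(nrow(log), nrow(cosmic_fixture()))
  expect_equal(log$reason[log$variant == "p.D600N"], "recurrence < 3")
  expect_equal(log$reason[log$variant == "p.P700L"], "recurrence < 3")
  expect_equal(log$reason[log$variant == "p.T500M"], "present in gnomAD")
})

test_that("population and cancer sets are mutually exclusive after curation", {
  pop <- curate_population(gnomad_fixture())
  can <- curate_cancer(cosmic_fixture(),
                       gnomad_variants = gnomad_fixture()$protein_consequence)
  expect_length(intersect(pop$variants$hgvs_p, can$variants$hgvs_p), 0L)
})

test_that("curation is idempotent on an already-curated set", {
  set <- curate_population(gnomad_fixture())
  again <- curate_population(
    data.frame(protein_consequence = set$variants$hgvs_p,
               allele_count = set$variants$evidence_count))
  expect_equal(again$variants$hgvs_p, set$variants$hgvs_p)
  expect_equal(again$variants$evidence_count, set$variants$evidence_count)
})

test_that("missing required columns raise schema errors", {
  expect_error(curate_population(data.frame(x = 1)), "protein consequence")
  expect_error(
    curate_population(data.frame(protein_consequence = "p.A1V")),
    "allele count")
})

test_that("the packaged NDD catalog loads with phenotype tags and 33 variants", {
  ndd <- load_ndd_catalog()
  expect_equal(ndd$group_label, "NDD")
  expect_equal(nrow(ndd$variants), 33L)
  v <- ndd$variants
  expect_equal(v$phenotype[v$hgvs_p == "p.C1390Y"], "SKS")
  expect_match(v$phenotype[v$hgvs_p == "p.S2215F"], "FCD")
  expect_equal(v$phenotype[v$hgvs_p == "p.C1483Y"], "Mega")
  # multi-phenotype variants carry all applicable tags
  expect_equal(v$phenotype[v$hgvs_p == "p.T1977K"], "FCD,Mega")
  expect_true(all(v$source == "literature"))
})

test_that("domain assignment reproduces the catalog's printed domain labels", {
  map <- load_domain_map()
  expect_equal(assign_domain(1395, map), "FAT")
  expect_equal(assign_domain(2406, map), "Kinase C-Lobe")
  expect_equal(assign_domain(2524, map), "FATC")
  expect_equal(assign_domain(624, map), "N-HEAT")
  expect_equal(assign_domain(2215, map), "Kinase N-Lobe")
  expect_equal(assign_domain(9999, map), "unassigned")
  # the whole catalog's reported domains match the configured map
  # (map naming uses N-HEAT for the catalog's N-Heat spelling)
  ndd <- load_ndd_catalog()$variants
  assigned <- assign_domain(ndd$position, map)
  expect_equal(tolower(assigned), tolower(ndd$domain_reported))
})

test_that("domain map validation rejects overlaps and bad intervals", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("domain\tstart\tend", "A\t1\t10", "B\t5\t20"), path)
  expect_error(load_domain_map(path), "overlap")
  writeLines(c("domain\tstart\tend", "A\t10\t1"), path)
  expect_error(load_domain_map(path), "start > end")
})

test_that("RSA annotation excludes sentinel/missing residues and shares RSA across substitutions at one site", {
  ndd <- load_ndd_catalog()
  map <- load_domain_map()
  rsa <- c(`1977` = 0.12, `1395` = 0.30, `2406` = -1)
  tab <- annotate_rsa(list(ndd), rsa, map)
  # all three 1977 substitutions present, sharing one RSA value
  at1977 <- tab[tab$position == 1977, ]
  expect_equal(nrow(at1977), 3L)
  expect_equal(unique(at1977$rsa), 0.12)
  # sentinel and absent residues excluded and logged
  expect_false("p.V2406M" %in% tab$hgvs_p)
  excluded <- attr(tab, "excluded")
  expect_true("p.V2406M" %in% excluded$hgvs_p)
  expect_true(all(c("p.C1390Y", "p.Q2524K") %in% excluded$hgvs_p))
  expect_equal(nrow(tab) + nrow(excluded), 33L)
  expect_equal(attr(tab, "domain_map_version"), "mtor-6bcx-lit-1.0")
})

test_that("an empty variant set annotates to an empty table", {
  empty <- curate_population(
    data.frame(protein_consequence = "p.A1V", allele_count = 1L))
  tab <- annotate_rsa(list(empty), c(`1` = 0.5), load_domain_map())
  expect_equal(nrow(tab), 0L)
})

test_that("annotated tables round-trip through the tab-delimited schema", {
  ndd <- load_ndd_catalog()
  rsa <- stats::setNames(runif(33, 0, 1), as.character(ndd$variants$position))
  tab <- annotate_rsa(list(ndd), rsa, load_domain_map())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotated_variants(tab, path)
  back <- read_annotated_variants(path)
  expect_equal(back$hgvs_p, tab$hgvs_p)
  expect_equal(back$rsa, tab$rsa, tolerance = 1e-12)
})
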