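test_that("summary parser extracts counts and enforces row invariants", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_summary_file(f, list(
    c("A", 11, 10, 2), c("B", 12, 5, 0), c("C", 13, 7, 7),
    c("nogene", -1, 4, 1),          # GeneID -1: skipped
    c("D", 14, 3, 9),               # plp > total: rejected
    c("E", "oops", 1, 1)            # unparseable GeneID: skipped
  ))
  rec <- parse_gene_specific_summary(f)
  expect_equal(nrow(rec), 3)
  expect_equal(sum(rec$total_alleles), 22)
  expect_equal(sum(rec$plp_alleles), 9)
  rep <- parse_report(rec)
  expect_equal(rep$n_no_gene_id, 1)
  expect_equal(rep$n_invariant_rejected, 1)
  expect_equal(rep$n_unparseable, 1)
})

test_that("summary parser handles gzip, column-name drift, and bad files", {
  # gzip input
  gz <- withr::local_tempfile(fileext = ".txt.gz")
  con <- gzfile(gz, "wt")
  writeLines(c("#Symbol\tGeneID\tTotal_alleles\tAlleles_reported_Pathogenic_Likely_pathogenic",
               "A\t11\t10\t2"), con)
  close(con)
  expect_equal(parse_gene_specific_summary(gz)$plp_alleles, 2L)

  # case-insensitive header match with extra whitespace
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_summary_file(f2, list(c("A", 11, 10, 2)),
    header = "# symbol\tGENEID\tTOTAL_ALLELES\tAlleles_Reported_Pathogenic_Likely_Pathogenic")
  expect_equal(nrow(parse_gene_specific_summary(f2)), 1)

  # legacy column names via the mapping option
  f3 <- withr::local_tempfile(fileext = ".txt")
  write_summary_file(f3, list(c("A", 11, 10, 2)),
    header = "#Symbol\tGeneID\tTotal_alleles\tPLP_alleles")
  expect_error(parse_gene_specific_summary(f3), "pathogenic")
  expect_equal(
    nrow(parse_gene_specific_summary(f3,
      legacy_names = c(plp_alleles = "PLP_alleles"))), 1)

  # required column absent -> error naming it; empty file -> error
  f4 <- withr::local_tempfile(fileext = ".txt")
  write_summary_file(f4, list(c("A", 10, 2)),
                     header = "#Symbol\tTotal_alleles\tAlleles_reported_Pathogenic_Likely_pathogenic")
  expect_error(parse_gene_specific_summary(f4), "geneid")
  f5 <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), f5)
  expect_error(parse_gene_specific_summary(f5), "empty")
})

test_that("assign_months maps each panel month to the nearest-dated file", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "2018-04_summary.txt")
  f2 <- file.path(d, "2018-05_summary.txt")
  file.create(c(f1, f2))
  m <- assign_months(c(f1, f2), c("2018-04", "2018-05"))
  expect_equal(unname(m), c(f1, f2))

  # candidates 16 days before vs 14 days after month end: later one wins
  d2 <- withr::local_tempdir()
  before <- file.path(d2, "2020-06-14_x.txt")   # 16 days before Jun 30
  after <- file.path(d2, "2020-07-14_x.txt")    # 14 days after
  file.create(c(before, after))
  expect_equal(unname(assign_months(c(before, after), "2020-06")), after)

  # exact tie breaks to the earlier file
  d3 <- withr::local_tempdir()
  t1 <- file.path(d3, "2020-06-20_x.txt")       # 10 days before
  t2 <- file.path(d3, "2020-07-10_x.txt")       # 10 days after
  file.create(c(t1, t2))
  expect_equal(unname(assign_months(c(t1, t2), "2020-06")), t1)

  # month with no file within tolerance -> error listing the month
  expect_error(assign_months(c(f1, f2), c("2018-04", "2019-01")), "2019-01")
})

test_that("build_matrix populates cells, keeps provenance, and dedupes GeneIDs", {
  m <- toy_matrix()
  expect_equal(m$months, c("2020-01", "2020-02", "2020-03"))
  expect_equal(nrow(m$data), 6)
  q <- query_counts(m, "2020-02", c(11L, 12L))
  expect_equal(q$plp_alleles, c(3L, 1L))

  dup <- list("2020-01" = tibble::tibble(
    ncbi_gene_id = c(11L, 11L), symbol = c("A", "A2"),
    total_alleles = c(5L, 9L), plp_alleles = c(1L, 2L)))
  expect_warning(md <- build_matrix(dup), "duplicate GeneID")
  expect_equal(md$data$total_alleles, 9L)  # larger total kept
})

test_that("a gene absent from a month is missing, never zero", {
  m <- build_matrix(list(
    "2020-01" = tibble::tibble(ncbi_gene_id = 11L, symbol = "A",
                               total_alleles = 10L, plp_alleles = 2L)
  ))
  q <- query_counts(m, "2020-01", c(11L, 999L))
  expect_equal(q$present, c(TRUE, FALSE))
  expect_true(is.na(q$plp_alleles[2]))
  t <- total_plp(m, "2020-01", c(11L, 999L))
  expect_equal(t$value, 2L)
  expect_equal(t$n_missing, 1L)
  expect_error(query_counts(m, "2021-09"), "2021-09")
})

test_that("total_plp is additive over a partition of the gene universe", {
  m <- toy_matrix()
  all_g <- total_plp(m, "2020-03")$value
  parts <- total_plp(m, "2020-03", 11L)$value + total_plp(m, "2020-03", 12L)$value
  expect_equal(all_g, parts)
  expect_equal(total_plp(m, "2020-01")$value, 2L)
  expect_equal(total_alleles_at(m, "2020-01")$value, 15L)
})

test_that("matrix round-trips through long-format TSV", {
  m <- toy_matrix()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  m2 <- read_matrix_tsv(f)
  expect_equal(m2$months, m$months)
  expect_equal(dplyr::arrange(m2$data, month, ncbi_gene_id),
               dplyr::arrange(m$data, month, ncbi_gene_id))
})

test_that("fixture summary files parse back to the generator's truth", {
  fx <- generate_fixtures(fixture_spec(n_genes = 10, n_months = 3, seed = 11),
                          withr::local_tempdir())
  files <- list.files(fx$paths$clinvar_dir, full.names = TRUE)
  months <- sort(unique(fx$truth$counts$month))
  mf <- assign_months(files, months)
  mat <- build_matrix(lapply(mf, parse_gene_specific_summary))
  got <- dplyr::arrange(mat$data[, c("month", "ncbi_gene_id", "total_alleles",
                                     "plp_alleles")], month, ncbi_gene_id)
  want <- dplyr::arrange(
    fx$truth$counts[, c("month", "ncbi_gene_id", "total_alleles", "plp_alleles")],
    month, ncbi_gene_id)
  expect_equal(got, want)
})
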