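test_that("parse_panel_version reads the PanelApp JSON subset and counts genes only", {
  doc <- list(
    id = 7, version = "1.2", version_created = "2020-03-10T04:00:00Z",
    genes = list(
      list(entity_type = "gene", confidence_level = "3",
           gene_data = list(gene_symbol = "AAA",
                            ensembl_id_or_equivalent = "ENSG1")),
      list(entity_type = "gene", confidence_level = "2",
           gene_data = list(gene_symbol = "BBB",
                            ensembl_id_or_equivalent = "ENSG2")),
      list(entity_type = "gene", confidence_level = "3",
           gene_data = list(gene_symbol = "CCC",
                            ensembl_id_or_equivalent = "ENSG3")),
      list(entity_type = "str", confidence_level = "3",
           gene_data = list(gene_symbol = "STR1"))
    )
  )
  snap <- parse_panel_version(doc)
  expect_s3_class(snap, "panel_snapshot")
  expect_equal(nrow(snap$genes), 4)            # STR retained in the snapshot
  expect_equal(diagnostic_count(snap), 2)      # but never counted
  expect_equal(snap$timestamp,
               as.POSIXct("2020-03-10 04:00:00", tz = "UTC"))

  # an absent confidence level is rating 0
  doc$genes[[2]]$confidence_level <- NULL
  expect_equal(sum(gene_entries(parse_panel_version(doc))$rating == 0), 1)
})

test_that("parse_panel_version rejects incomplete or inconsistent documents", {
  base <- list(version = "1.0", version_created = "2020-01-01T00:00:00Z",
               genes = list())
  expect_error(parse_panel_version(base[-1]), "version")
  expect_error(parse_panel_version(base[-2]), "version_created")
  dup <- base
  dup$genes <- rep(list(list(entity_type = "gene", confidence_level = "3",
                             gene_data = list(gene_symbol = "AAA"))), 2)
  expect_error(parse_panel_version(dup), "AAA")
})

test_that("fixture panel documents round-trip through the parser", {
  spec <- fixture_spec(n_genes = 12, n_months = 4, seed = 3)
  fx <- generate_fixtures(spec, withr::local_tempdir())
  snap <- parse_panel_version(fx$paths$panel_files[1])
  expect_equal(diagnostic_count(snap), spec$n_diag)
  expect_equal(sum(gene_entries(snap)$entity_type == "gene"), spec$n_panel)
  # STR entry present but flagged out of counts
  expect_true("str" %in% snap$genes$entity_type)
})

test_that("monthly snapshot selection takes the latest version before month end and carries forward", {
  mk_v <- function(v, ts) make_snapshot("A", 3, version = v, timestamp = ts)
  v1 <- mk_v("1.0", "2020-10-03 10:00:00")
  v2 <- mk_v("1.1", "2020-10-28 10:00:00")
  s <- select_monthly_snapshots(list(v1, v2), window = c("2020-10", "2020-10"))
  expect_equal(s$months[["2020-10"]]$version, "1.1")

  # carry-forward: one January version serves four months
  s2 <- select_monthly_snapshots(list(mk_v("2.0", "2021-01-20 09:00:00")),
                                 window = c("2021-01", "2021-04"))
  expect_equal(length(s2$months), 4)
  expect_true(all(vapply(s2$months, function(x) x$version, "") == "2.0"))

  # no carry-forward into the past
  expect_error(
    select_monthly_snapshots(list(v1), window = c("2020-09", "2020-10")),
    "before the first"
  )
})

test_that("snapshot selection matches a brute-force oracle and is monotone", {
  withr::local_seed(42)
  # 12 versions over 6 months at random days
  days <- sort(sample(0:180, 12))
  versions <- lapply(seq_along(days), function(i) {
    make_snapshot("A", 3, version = sprintf("1.%d", i),
                  timestamp = as.POSIXct("2020-01-01", tz = "UTC") +
                    days[i] * 86400 + 3600)
  })
  window <- c("2020-01", "2020-06")
  s <- select_monthly_snapshots(versions, window = window)
  ts <- vapply(versions, function(v) as.numeric(v$timestamp), 0)
  for (mk in month_seq(window[1], window[2])) {
    oracle <- max(which(ts <= as.numeric(month_end(mk))))
    expect_equal(s$months[[mk]]$version, versions[[oracle]]$version)
  }
  # monotone: advancing the cutoff never selects an older version
  picked <- vapply(s$months, function(v) v$version, "")
  expect_true(!is.unsorted(match(picked, sprintf("1.%d", seq_along(days)))))
})

test_that("classify_changes places every gene in the forced category", {
  prev <- make_snapshot(c("A", "B", "C"), c(3, 2, 3))
  curr <- make_snapshot(c("A", "B", "D"), c(3, 3, 3))
  cs <- classify_changes(prev, curr)
  expect_equal(cs$upgraded, "B")
  expect_equal(cs$added_diagnostic, "D")
  expect_equal(cs$removed_diagnostic, "C")
  expect_equal(cs$downgraded, character(0))
  expect_equal(change_set_net(cs), diagnostic_count(curr) - diagnostic_count(prev))

  # identity: no changes against itself
  cs0 <- classify_changes(curr, curr)
  expect_true(all(vapply(cs0[!names(cs0) %in% "month"], length, 1L) == 0))
})

test_that("a symbol rename with a stable Ensembl ID is not a change event", {
  prev <- make_snapshot("OLDNAME", 3, ensembl = "ENSG0001")
  curr <- make_snapshot("NEWNAME", 3, ensembl = "ENSG0001")
  cs <- classify_changes(prev, curr)
  expect_true(all(vapply(cs[!names(cs) %in% "month"], length, 1L) == 0))
})

test_that("conservation identity holds across random snapshot pairs", {
  withr::local_seed(99)
  for (i in 1:25) {
    prev <- random_snapshot(sample(5:25, 1))
    curr <- random_snapshot(sample(5:25, 1))
    cs <- classify_changes(prev, curr)
    expect_equal(diagnostic_count(curr) - diagnostic_count(prev),
                 change_set_net(cs))
    # the six category lists are pairwise disjoint
    all_syms <- unlist(cs[setdiff(names(cs), "month")])
    expect_equal(anyDuplicated(all_syms), 0)
  }
})

test_that("union diagnostic list unions across panels and dedupes by Ensembl ID", {
  s1 <- select_monthly_snapshots(
    list(make_snapshot(c("A", "B"), c(3, 3), ensembl = c("E1", "E2"),
                       timestamp = "2020-01-10")),
    window = c("2020-01", "2020-02"))
  s2 <- select_monthly_snapshots(
    list(make_snapshot(c("Brenamed", "C"), c(3, 3), ensembl = c("E2", "E3"),
                       timestamp = "2020-01-12")),
    window = c("2020-01", "2020-02"))
  u <- union_diagnostic_list(list(s1, s2), at = "2020-02")
  expect_equal(sort(u$ensembl_id), c("E1", "E2", "E3"))
  expect_error(union_diagnostic_list(list(s1), at = "2020-05"), "2020-05")
})

test_that("panel_overlap reports shared and unique gene counts", {
  ov <- panel_overlap(c("A", "B"), c("B", "C", "D"))
  expect_equal(ov$shared, 1)
  expect_equal(ov$unique_a, 1)
  expect_equal(ov$unique_b, 2)
})
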