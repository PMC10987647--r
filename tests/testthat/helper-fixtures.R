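# Shared builders for tiny in-code fixtures.

make_snapshot <- function(symbols, ratings, ensembl = NULL,
                          entity_type = NULL, version = "1.0",
                          timestamp = "2020-01-15 12:00:00",
                          panel_id = 1L) {
  n <- length(symbols)
  panel_snapshot(
    panel_id = panel_id,
    version = version,
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    genes = tibble::tibble(
      symbol = symbols,
      ensembl_id = ensembl %||% rep(NA_character_, n),
      entity_type = entity_type %||% rep("gene", n),
      rating = as.integer(ratings)
    )
  )
}

# random snapshot for property-style checks
random_snapshot <- function(n = 20, version = "1.0",
                            timestamp = "2020-01-15", pool = NULL) {
  pool <- pool %||% sprintf("G%03d", 1:40)
  syms <- sample(pool, n)
  make_snapshot(syms, sample(0:3, n, replace = TRUE),
                ensembl = sprintf("ENSG%08d", match(syms, pool)),
                version = version, timestamp = timestamp)
}

# 2 genes x 3 months toy matrix with known counts
toy_matrix <- function() {
  rec <- function(ids, syms, tot, plp) {
    tibble::tibble(ncbi_gene_id = ids, symbol = syms,
                   total_alleles = tot, plp_alleles = plp)
  }
  build_matrix(list(
    "2020-01" = rec(c(11L, 12L), c("A", "B"), c(10L, 5L), c(2L, 0L)),
    "2020-02" = rec(c(11L, 12L), c("A", "B"), c(12L, 6L), c(3L, 1L)),
    "2020-03" = rec(c(11L, 12L), c("A", "B"), c(15L, 6L), c(5L, 1L))
  ))
}

# write a minimal gene-specific-summary file; rows = list of c(sym, id, tot, plp)
write_summary_file <- function(path, rows,
                               header = "#Symbol\tGeneID\tTotal_alleles\tAlleles_reported_Pathogenic_Likely_pathogenic") {
  body <- vapply(rows, function(r) paste(r, collapse = "\t"), "")
  writeLines(c("#synthetic summary", header, body), path)
  path
}

# panel-event kinds -> change-set categories
event_to_category <- c(add_diag = "added_diagnostic", upgrade = "upgraded",
                       downgrade = "downgraded",
                       remove_diag = "removed_diagnostic")

# ground-truth P/LP-in-diagnostic series from a generated fixture,
# independent of the pipeline path (reads the generator's truth tables)
truth_plp_in_diag <- function(fx) {
  ratings <- fx$truth$ratings
  counts <- fx$truth$counts
  unmatched <- unique(fx$event_log$gene[fx$event_log$kind == "unmatched_gene"])
  months <- rownames(ratings)
  vapply(months, function(mk) {
    diag <- colnames(ratings)[!is.na(ratings[mk, ]) & ratings[mk, ] == 3L]
    diag <- setdiff(diag, unmatched)
    cc <- counts[counts$month == mk & counts$symbol %in% diag, ]
    sum(cc$plp_alleles)
  }, 0L)
}
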