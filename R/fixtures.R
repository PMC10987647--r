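# Synthetic, ground-truthed pipeline inputs.
#
# The generator emits the same three file families the real pipeline
# consumes — panel version JSON documents, monthly gene-summary TSVs, and a
# BioMart-style ID mapping table — together with a machine-readable log of
# every injected event, so the entire pipeline can be exercised and checked
# offline against known truth.
#
# Panel composition is fixed by the spec fractions (gene i of n is
# diagnostic / non-diagnostic / off-panel by index), so test event schedules
# can be written against a known starting state; the seed drives only the
# stochastic count series. Baseline P/LP growth is geometric with
# multiplicative noise, defaulting to ~1.8% per month — the order of growth
# real ClinVar P/LP series show — so realistic-looking series exist without
# any download.

fixture_event_kinds <- c("add_diag", "upgrade", "downgrade", "remove_diag",
                         "plp_step", "plp_decline", "unmatched_gene",
                         "id_clash")

#' Specify a synthetic fixture
#'
#' @param n_genes Number of genes in the ClinVar universe.
#' @param n_months Number of months, starting at `launch_month`.
#' @param launch_month Month key of the panel launch.
#' @param seed Integer seed; the same spec and seed reproduce files
#'   byte-for-byte.
#' @param events Tibble with columns `month` (month key, or 1-based month
#'   index into the window), `kind` (one of `r paste(fixture_event_kinds,
#'   collapse = ", ")`), `gene` (symbol), `magnitude` (count delta for
#'   `plp_step`/`plp_decline`; ignored otherwise). `NULL` for no events.
#' @param baseline_growth Mean monthly multiplicative P/LP growth (0.018 =
#'   1.8%/month).
#' @param growth_sd Standard deviation of the log growth factor.
#' @param frac_on_panel Fraction of genes on the panel at launch.
#' @param frac_diag Fraction of on-panel genes that launch at diagnostic
#'   grade.
#' @param panel_id,source Panel identity written into the JSON documents.
#' @param include_str Also write one STR (non-gene) entry per version, which
#'   every counting operation must ignore.
#' @param overrides Optional tibble `ensembl_id`, `ncbi_gene_id` written as
#'   a manual override table.
#' @return A validated `fixture_spec` list. Panel composition: genes
#'   `1..n_diag` launch diagnostic (rating 3), genes `n_diag+1..n_panel`
#'   launch non-diagnostic (rating 2), the rest are off-panel.
#' @export
fixture_spec <- function(n_genes = 50, n_months = 24,
                         launch_month = "2018-04", seed = 1,
                         events = NULL, baseline_growth = 0.018,
                         growth_sd = 0.01, frac_on_panel = 0.8,
                         frac_diag = 0.5, panel_id = 901, source = "AUS",
                         include_str = TRUE, overrides = NULL) {
  stopifnot(n_genes >= 2, n_months >= 2)
  launch_month <- as_month_key(launch_month)
  months <- month_seq(launch_month, month_shift(launch_month, n_months - 1L))
  symbols <- sprintf("GENE%03d", seq_len(n_genes))

  if (is.null(events)) {
    events <- tibble::tibble(month = character(), kind = character(),
                             gene = character(), magnitude = integer())
  } else {
    events <- tibble::as_tibble(events)
    if (!"magnitude" %in% names(events)) events$magnitude <- NA_integer_
    if (is.numeric(events$month)) {
      bad <- events$month < 1 | events$month > n_months
      if (any(bad)) {
        stop("event month index out of window: ",
             paste(events$month[bad], collapse = ", "), call. = FALSE)
      }
      events$month <- months[events$month]
    }
    events$month <- as_month_key(events$month)
    if (!all(events$month %in% months)) {
      stop("event month outside the fixture window", call. = FALSE)
    }
    if (!all(events$kind %in% fixture_event_kinds)) {
      stop("unknown event kind(s): ",
           paste(setdiff(events$kind, fixture_event_kinds), collapse = ", "),
           call. = FALSE)
    }
    unknown <- setdiff(events$gene, symbols)
    if (length(unknown) > 0) {
      stop("event references gene(s) not in the fixture universe: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    events <- events[order(match(events$month, months)), ]
  }

  n_panel <- max(2L, round(frac_on_panel * n_genes))
  n_diag <- max(1L, round(frac_diag * n_panel))

  spec <- structure(
    list(n_genes = n_genes, n_months = n_months, launch_month = launch_month,
         months = months, seed = as.integer(seed), events = events,
         baseline_growth = baseline_growth, growth_sd = growth_sd,
         n_panel = n_panel, n_diag = n_diag, panel_id = panel_id,
         source = source, include_str = include_str, overrides = overrides,
         symbols = symbols),
    class = "fixture_spec"
  )
  validate_fixture_events(spec)
  spec
}

# chronological feasibility check of the panel-event schedule
validate_fixture_events <- function(spec) {
  state <- c(rep(3L, spec$n_diag), rep(2L, spec$n_panel - spec$n_diag))
  state <- stats::setNames(state, spec$symbols[seq_len(spec$n_panel)])
  panel_kinds <- c("add_diag", "upgrade", "downgrade", "remove_diag")
  ev <- spec$events[spec$events$kind %in% panel_kinds, ]
  for (i in seq_len(nrow(ev))) {
    g <- ev$gene[i]; k <- ev$kind[i]; mk <- ev$month[i]
    on_panel <- g %in% names(state)
    fail <- switch(k,
      add_diag = on_panel,
      upgrade = !on_panel || state[[g]] == 3L,
      downgrade = !on_panel || state[[g]] != 3L,
      remove_diag = !on_panel || state[[g]] != 3L
    )
    if (fail) {
      stop("infeasible event: ", k, " of ", g, " at ", mk,
           " (gene state does not allow it)", call. = FALSE)
    }
    state <- switch(k,
      add_diag = c(state, stats::setNames(3L, g)),
      upgrade = {state[[g]] <- 3L; state},
      downgrade = {state[[g]] <- 2L; state},
      remove_diag = state[setdiff(names(state), g)]
    )
  }
  invisible(spec)
}

#' Generate fixture files and their ground-truth event log
#'
#' Writes, under `out_dir`: `panels/` (one JSON per panel version — the
#' launch version plus one per month carrying panel events), `clinvar/`
#' (one `YYYY-MM_gene_summary.txt` per month), `ensembl_ncbi_map.tsv`,
#' optionally `overrides.tsv`, and `event_log.json`. Re-running with the
#' same spec is byte-identical.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `event_log` (tibble with realised count
#'   deltas), `truth` (list with per-month `counts` and panel `ratings`
#'   tibbles), `paths` (named file/dir locations), and `spec`.
#' @export
generate_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  panel_dir <- file.path(out_dir, "panels")
  clinvar_dir <- file.path(out_dir, "clinvar")
  dir.create(panel_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(clinvar_dir, recursive = TRUE, showWarnings = FALSE)

  months <- spec$months
  n <- spec$n_genes
  symbols <- spec$symbols
  ensembl <- sprintf("ENSG%011d", seq_len(n))
  ncbi <- 1000L + seq_len(n)

  clash_genes <- unique(spec$events$gene[spec$events$kind == "id_clash"])
  unmatched_genes <- unique(spec$events$gene[spec$events$kind == "unmatched_gene"])

  # --- count series (seed-driven) -----------------------------------------
  truth <- withr::with_seed(spec$seed, {
    plp <- matrix(0L, nrow = length(months), ncol = n,
                  dimnames = list(months, symbols))
    benign <- plp
    plp[1, ] <- sample(5:80, n, replace = TRUE)
    benign[1, ] <- sample(20:200, n, replace = TRUE)
    log_mu <- log(1 + spec$baseline_growth)
    realized <- list()
    for (m in seq(2, length(months))) {
      f_plp <- exp(stats::rnorm(n, log_mu, spec$growth_sd))
      f_ben <- exp(stats::rnorm(n, log_mu, spec$growth_sd))
      plp[m, ] <- as.integer(round(plp[m - 1, ] * f_plp))
      benign[m, ] <- as.integer(round(benign[m - 1, ] * f_ben))
      ev <- spec$events[spec$events$month == months[m] &
                          spec$events$kind %in% c("plp_step", "plp_decline"), ]
      for (i in seq_len(nrow(ev))) {
        g <- ev$gene[i]
        mag <- abs(as.integer(ev$magnitude[i]))
        delta <- if (ev$kind[i] == "plp_step") mag else -min(mag, plp[m, g])
        plp[m, g] <- plp[m, g] + delta
      }
      realized[[m]] <- plp[m, ] - plp[m - 1, ]
    }
    list(plp = plp, benign = benign, realized = realized)
  })
  plp <- truth$plp
  total <- truth$plp + truth$benign

  # --- panel version history ----------------------------------------------
  panel_kinds <- c("add_diag", "upgrade", "downgrade", "remove_diag")
  rating <- stats::setNames(
    c(rep(3L, spec$n_diag), rep(2L, spec$n_panel - spec$n_diag)),
    symbols[seq_len(spec$n_panel)]
  )
  ratings_by_month <- matrix(NA_integer_, nrow = length(months), ncol = n,
                             dimnames = list(months, symbols))
  version_n <- 0L
  panel_files <- character()
  write_version <- function(month, day) {
    version_n <<- version_n + 1L
    version <- sprintf("1.%d", version_n - 1L)
    ts <- sprintf("%s-%02dT12:00:00Z", month, day)
    entries <- lapply(names(rating), function(g) {
      i <- match(g, symbols)
      list(entity_type = "gene",
           confidence_level = as.character(rating[[g]]),
           gene_data = list(gene_symbol = g,
                            ensembl_id_or_equivalent = ensembl[i]))
    })
    if (spec$include_str) {
      entries <- c(entries, list(list(
        entity_type = "str", confidence_level = "3",
        gene_data = list(gene_symbol = "STR_EXP1",
                         ensembl_id_or_equivalent = NULL)
      )))
    }
    doc <- list(id = spec$panel_id, source = spec$source, version = version,
                version_created = ts, genes = entries)
    path <- file.path(panel_dir, sprintf("panel_%d_v%s.json",
                                         spec$panel_id, version))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
    panel_files <<- c(panel_files, path)
  }
  write_version(months[1], 10L)  # launch version
  for (m in seq_along(months)) {
    ev <- spec$events[spec$events$month == months[m] &
                        spec$events$kind %in% panel_kinds, ]
    if (nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        g <- ev$gene[i]
        rating <- switch(ev$kind[i],
          add_diag = c(rating, stats::setNames(3L, g)),
          upgrade = {rating[[g]] <- 3L; rating},
          downgrade = {rating[[g]] <- 2L; rating},
          remove_diag = rating[setdiff(names(rating), g)]
        )
      }
      write_version(months[m], 15L)
    }
    ratings_by_month[m, names(rating)] <- rating
  }

  # --- monthly gene-summary files -----------------------------------------
  decoy_ncbi <- stats::setNames(9000L + seq_along(clash_genes), clash_genes)
  for (m in seq_along(months)) {
    path <- file.path(clinvar_dir, sprintf("%s_gene_summary.txt", months[m]))
    lines <- c(
      sprintf("#Synthetic gene-specific summary for %s", months[m]),
      paste("#Symbol", "GeneID", "Total_submissions", "Total_alleles",
            "Alleles_reported_Pathogenic_Likely_pathogenic",
            "Number_uncertain", sep = "\t"),
      sprintf("%s\t%d\t%d\t%d\t%d\t%d", symbols, ncbi,
              total[m, ] + 1L, total[m, ], plp[m, ],
              pmax(0L, total[m, ] - plp[m, ]) %/% 2L)
    )
    if (length(clash_genes) > 0) {
      lines <- c(lines, sprintf("%s\t%d\t1\t1\t0\t0",
                                paste0(clash_genes, "_ALT"),
                                unname(decoy_ncbi[clash_genes])))
    }
    writeLines(lines, path)
  }

  # --- mapping table -------------------------------------------------------
  map_rows <- c("NCBI gene ID\tGene stable ID")
  for (i in seq_len(n)) {
    if (symbols[i] %in% unmatched_genes) {
      map_rows <- c(map_rows, paste0("\t", ensembl[i]))  # one-sided row
    } else {
      map_rows <- c(map_rows, sprintf("%d\t%s", ncbi[i], ensembl[i]))
    }
  }
  for (g in clash_genes) {
    i <- match(g, symbols)
    map_rows <- c(map_rows, sprintf("%d\t%s", decoy_ncbi[[g]], ensembl[i]))
  }
  mapping_file <- file.path(out_dir, "ensembl_ncbi_map.tsv")
  writeLines(map_rows, mapping_file)

  overrides_file <- NULL
  if (!is.null(spec$overrides)) {
    overrides_file <- file.path(out_dir, "overrides.tsv")
    ov <- tibble::as_tibble(spec$overrides)
    if (!"evidence" %in% names(ov)) ov$evidence <- "synthetic override"
    readr::write_tsv(ov, overrides_file)
  }

  # --- event log -----------------------------------------------------------
  event_log <- spec$events
  event_log$realized_delta <- NA_integer_
  for (i in seq_len(nrow(event_log))) {
    if (event_log$kind[i] %in% c("plp_step", "plp_decline")) {
      m <- match(event_log$month[i], months)
      event_log$realized_delta[i] <- truth$realized[[m]][[event_log$gene[i]]]
    }
  }
  log_file <- file.path(out_dir, "event_log.json")
  jsonlite::write_json(event_log, log_file, pretty = TRUE, na = "null")

  counts_truth <- purrr::map_dfr(seq_along(months), function(m) {
    tibble::tibble(month = months[m], symbol = symbols,
                   ncbi_gene_id = ncbi, ensembl_id = ensembl,
                   total_alleles = unname(total[m, ]),
                   plp_alleles = unname(plp[m, ]))
  })

  invisible(list(
    event_log = event_log,
    truth = list(counts = counts_truth, ratings = ratings_by_month),
    paths = list(panel_dir = panel_dir, clinvar_dir = clinvar_dir,
                 mapping_file = mapping_file, overrides_file = overrides_file,
                 event_log = log_file, panel_files = panel_files),
    spec = spec
  ))
}
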