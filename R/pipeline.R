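# Pipeline assembly: configuration, the end-to-end run, report tables, and
# the (network-optional) fetch manifest.
#
# The run is deterministic given fixed inputs and configuration; every
# number in the report table is re-derivable from the serialised
# intermediate artefacts.

#' Build a run configuration
#'
#' @param panel_dirs Named character vector: panel label -> directory of
#'   version JSON documents (one directory per panel).
#' @param clinvar_dir Directory of monthly gene-summary files.
#' @param mapping_file BioMart-style Ensembl/NCBI mapping TSV.
#' @param overrides_file Optional manual override TSV.
#' @param out_dir Output directory for [write_bundle()].
#' @param window Optional length-2 month keys limiting the analysis window.
#' @param burst_threshold Percent threshold for burst months.
#' @param rounding Report percent rounding, `"half_away"` or `"truncate"`.
#' @param tolerance_days File-date tolerance for [assign_months()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(panel_dirs, clinvar_dir, mapping_file,
                       overrides_file = NULL, out_dir = NULL, window = NULL,
                       burst_threshold = 5, rounding = "half_away",
                       tolerance_days = 45) {
  if (is.null(names(panel_dirs))) {
    names(panel_dirs) <- basename(panel_dirs)
  }
  for (p in c(panel_dirs, clinvar_dir)) {
    if (!dir.exists(p)) stop("input directory does not exist: ", p, call. = FALSE)
  }
  for (f in c(mapping_file, overrides_file)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("input file does not exist: ", f, call. = FALSE)
    }
  }
  if (!is.null(window)) window <- as_month_key(window)
  structure(
    list(panel_dirs = panel_dirs, clinvar_dir = clinvar_dir,
         mapping_file = mapping_file, overrides_file = overrides_file,
         out_dir = out_dir, window = window,
         burst_threshold = burst_threshold, rounding = rounding,
         tolerance_days = tolerance_days),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `panel_dirs` is a named
#' mapping of panel label to directory. Relative paths are resolved against
#' the file's directory.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  run_config(
    panel_dirs = stats::setNames(rel(unlist(y$panel_dirs)),
                                 names(y$panel_dirs)),
    clinvar_dir = rel(y$clinvar_dir),
    mapping_file = rel(y$mapping_file),
    overrides_file = rel(y$overrides_file),
    out_dir = rel(y$out_dir),
    window = y$window,
    burst_threshold = y$burst_threshold %||% 5,
    rounding = y$rounding %||% "half_away",
    tolerance_days = y$tolerance_days %||% 45
  )
}

#' Run the full pipeline
#'
#' Ingests the panel version histories, selects monthly snapshots,
#' classifies gene changes, parses the monthly gene summaries into the
#' variant matrix, resolves gene IDs, joins panel and variant information
#' in both modes, and computes change summaries and burst reports.
#'
#' @param config A `run_config`.
#' @return A `run_bundle` list: `series` (per panel), `change_sets` (long
#'   tibble), `matrix`, `idmap`, `union_list` (annotated), `static_table`,
#'   `joined` (per panel), `summaries` (per panel `change_summary` of
#'   P/LP-in-diagnostic), `bursts` (per panel), `match_reports`, `config`,
#'   and `log` (one row per stage).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  stage <- function(name, detail) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = name, detail = detail)
  }

  files <- list.files(config$clinvar_dir, full.names = TRUE)
  file_months <- sort(unique(as_month_key(extract_file_dates(files))))

  series <- lapply(config$panel_dirs, function(d) {
    versions <- read_panel_versions(d)
    # default window: each panel runs from its launch month to the last
    # month with variant data, carrying the final version forward
    window <- config$window %||%
      c(as_month_key(versions[[1]]$timestamp),
        file_months[length(file_months)])
    select_monthly_snapshots(versions, window = window)
  })
  stage("panel_history", paste(length(series), "panel series ingested"))

  all_months <- sort(unique(unlist(lapply(series, function(s) names(s$months)))))
  change_sets <- purrr::map_dfr(names(series), function(lbl) {
    cs <- classify_series_changes(series[[lbl]])
    if (nrow(cs) > 0) cs$panel <- lbl
    cs
  })
  stage("change_sets", paste(nrow(change_sets), "gene-change events"))

  month_files <- assign_months(files, all_months,
                               tolerance_days = config$tolerance_days)
  records <- lapply(month_files, parse_gene_specific_summary)
  matrix <- build_matrix(records, provenance = month_files)
  stage("variant_matrix", paste(length(matrix$months), "months parsed"))

  multimap <- load_mapping_table(config$mapping_file)
  overrides <- if (!is.null(config$overrides_file)) {
    load_overrides(config$overrides_file)
  }
  last_month <- all_months[length(all_months)]
  union_list <- union_diagnostic_list(series, at = last_month)
  panel_keys <- unique(unlist(lapply(series, function(s) {
    unlist(lapply(s$months, function(snap) gene_key(gene_entries(snap))))
  })))
  idmap <- build_id_map(panel_keys, multimap, matrix, overrides)
  union_annot <- annotate_gene_list(union_list, idmap)
  stage("id_mapping", sprintf("%d/%d union diagnostic genes matched",
                              match_report(union_annot)$n_matched,
                              match_report(union_annot)$n_total))

  static_table <- static_mode(union_annot, matrix)
  joined <- lapply(series, evolving_mode, matrix = matrix, idmap = idmap)
  stage("temporal_join", paste(length(joined), "evolving joins"))

  summaries <- lapply(joined, function(j) {
    change_summary(j$plp_in_diag, months = j$month)
  })
  bursts <- lapply(joined, function(j) {
    detect_bursts(monthly_deltas(j$plp_in_diag, months = j$month),
                  threshold = config$burst_threshold)
  })
  stage("change_metrics", paste("bursts per panel:",
                                paste(vapply(bursts, nrow, 1L), collapse = ",")))

  structure(
    list(series = series, change_sets = change_sets, matrix = matrix,
         idmap = idmap, union_list = union_annot, static_table = static_table,
         joined = joined, summaries = summaries, bursts = bursts,
         match_reports = list(union = match_report(union_annot)),
         config = config, log = dplyr::bind_rows(log)),
    class = "run_bundle"
  )
}

#' Write a run bundle to disk
#'
#' Serialises the intermediate artefacts as TSV/JSON under the configured
#' (or given) output directory: `change_sets.tsv`, `variant_matrix.tsv`,
#' `id_map.tsv`, `static_table.tsv`, `joined_<panel>.tsv`,
#' `summary.json`, `bursts.tsv`, `report.tsv` and `run_log.tsv`.
#'
#' @param bundle A `run_bundle`.
#' @param out_dir Output directory; defaults to the config's.
#' @return Invisibly, the output directory.
#' @export
write_bundle <- function(bundle, out_dir = NULL) {
  out_dir <- out_dir %||% bundle$config$out_dir
  if (is.null(out_dir)) stop("no output directory configured", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(bundle$change_sets, file.path(out_dir, "change_sets.tsv"))
  write_matrix_tsv(bundle$matrix, file.path(out_dir, "variant_matrix.tsv"))
  readr::write_tsv(bundle$idmap, file.path(out_dir, "id_map.tsv"))
  readr::write_tsv(bundle$static_table, file.path(out_dir, "static_table.tsv"))
  for (lbl in names(bundle$joined)) {
    readr::write_tsv(bundle$joined[[lbl]],
                     file.path(out_dir, sprintf("joined_%s.tsv", lbl)))
  }
  jsonlite::write_json(
    lapply(bundle$summaries, unclass),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, na = "null"
  )
  burst_tbl <- purrr::map_dfr(names(bundle$bursts), function(lbl) {
    b <- bundle$bursts[[lbl]]
    if (nrow(b) == 0) return(NULL)
    tibble::tibble(panel = lbl, month = b$month, pct_change = b$pct_change)
  })
  if (nrow(burst_tbl) == 0) {
    burst_tbl <- tibble::tibble(panel = character(), month = character(),
                                pct_change = numeric())
  }
  readr::write_tsv(burst_tbl, file.path(out_dir, "bursts.tsv"))
  readr::write_tsv(report_panels(bundle), file.path(out_dir, "report.tsv"))
  readr::write_tsv(bundle$log, file.path(out_dir, "run_log.tsv"))
  invisible(out_dir)
}

#' Per-panel evolution report
#'
#' One row per panel, from the launch-window month to the final month:
#' versions compared, dual gene counts (matched and total), P/LP counts in
#' diagnostic genes, and the increases with percentages — the shape of a
#' panel-evolution summary table.
#'
#' @param bundle A `run_bundle`.
#' @return Tibble, one row per panel.
#' @export
report_panels <- function(bundle) {
  rounding <- bundle$config$rounding %||% "half_away"
  purrr::map_dfr(names(bundle$joined), function(lbl) {
    j <- bundle$joined[[lbl]]
    first <- j[1, ]
    last <- j[nrow(j), ]
    tibble::tibble(
      panel = lbl,
      window_months = nrow(j),
      launch_month = first$month,
      final_month = last$month,
      versions_compared = paste(first$panel_version, last$panel_version,
                                sep = " -> "),
      launch_genes = sprintf("%d (%d)", first$n_genes_matched,
                             first$n_genes_total),
      final_genes = sprintf("%d (%d)", last$n_genes_matched,
                            last$n_genes_total),
      launch_diag = sprintf("%d (%d)", first$n_diag_matched,
                            first$n_diag_total),
      final_diag = sprintf("%d (%d)", last$n_diag_matched, last$n_diag_total),
      launch_alleles_all = first$total_alleles_all_genes,
      final_alleles_all = last$total_alleles_all_genes,
      launch_plp_diag = first$plp_in_diag,
      final_plp_diag = last$plp_in_diag,
      diag_increase = format_increase(first$n_diag_matched,
                                      last$n_diag_matched, rounding),
      plp_increase = format_increase(first$plp_in_diag, last$plp_in_diag,
                                     rounding)
    )
  })
}

#' URL manifest for live inputs
#'
#' Builds the download manifest the offline pipeline would consume: one
#' PanelApp API URL per panel version and one ClinVar FTP archive URL per
#' month. Listing is pure; nothing is fetched.
#'
#' @param panel_ids Integer panel IDs.
#' @param source `"AUS"` (PanelApp Australia) or `"UK"` (Genomics England).
#' @param versions Optional character vector of version strings; `NULL`
#'   lists the un-versioned latest endpoint only.
#' @param months Month keys for which ClinVar monthly archives are wanted.
#' @return Tibble `kind`, `id`, `month`, `url`.
#' @export
fetch_urls <- function(panel_ids = integer(), source = "AUS",
                       versions = NULL, months = character()) {
  base <- switch(source,
                 AUS = "https://panelapp-aus.org/api/v1",
                 UK = "https://panelapp.genomicsengland.co.uk/api/v1",
                 stop("unknown source: ", source, call. = FALSE))
  panel_rows <- purrr::map_dfr(panel_ids, function(id) {
    if (is.null(versions)) {
      tibble::tibble(kind = "panel", id = as.integer(id),
                     month = NA_character_,
                     url = sprintf("%s/panels/%d/", base, id))
    } else {
      tibble::tibble(kind = "panel", id = as.integer(id),
                     month = NA_character_,
                     url = sprintf("%s/panels/%d/?version=%s", base, id,
                                   versions))
    }
  })
  clinvar_rows <- if (length(months) > 0) {
    months <- as_month_key(months)
    tibble::tibble(
      kind = "clinvar", id = NA_integer_, month = months,
      url = sprintf(
        "https://ftp.ncbi.nlm.nih.gov/pub/clinvar/tab_delimited/archive/%s/gene_specific_summary_%s.txt.gz",
        substr(months, 1, 4), months)
    )
  } else {
    tibble::tibble(kind = character(), id = integer(), month = character(),
                   url = character())
  }
  dplyr::bind_rows(panel_rows, clinvar_rows)
}

#' Fetch live inputs (network-optional)
#'
#' With `dry_run = TRUE` (the default) the manifest is returned without any
#' network access. Otherwise each URL is downloaded into `dest_dir`,
#' skipping files already present; per-file failures are reported and do
#' not abort the rest.
#'
#' @param manifest Tibble from [fetch_urls()].
#' @param dest_dir Destination directory.
#' @param dry_run List only; do not download.
#' @return The manifest with a `status` column (`"listed"`, `"downloaded"`,
#'   `"skipped"` or `"failed"`).
#' @export
cmd_fetch <- function(manifest, dest_dir = ".", dry_run = TRUE) {
  if (dry_run) {
    manifest$status <- "listed"
    return(manifest)
  }
  dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
  manifest$status <- vapply(manifest$url, function(u) {
    dest <- file.path(dest_dir, basename(sub("/$", ".json", u)))
    if (file.exists(dest)) return("skipped")
    ok <- tryCatch(utils::download.file(u, dest, quiet = TRUE) == 0,
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (ok) "downloaded" else "failed"
  }, "")
  manifest
}
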