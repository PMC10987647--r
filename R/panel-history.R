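# Versioned gene-panel ingestion, monthly snapshot selection, and gene-change
# classification.
#
# A panel snapshot is one dated, versioned state of a clinical gene panel.
# Entries whose entity type is not "gene" (short tandem repeats, CNV regions)
# are parsed and retained but excluded from every count. Confidence level 3
# ("Green") marks a gene as diagnostic grade; levels 0-2 are non-diagnostic.

#' Construct a panel snapshot
#'
#' @param panel_id Integer panel identifier.
#' @param source Panel source instance, `"AUS"` or `"UK"`.
#' @param version Dotted version string.
#' @param timestamp `POSIXct` version creation instant (UTC).
#' @param genes Tibble with columns `symbol`, `ensembl_id`, `entity_type`,
#'   `rating`.
#' @return A `panel_snapshot` object.
#' @export
panel_snapshot <- function(panel_id, source = "AUS", version, timestamp, genes) {
  genes <- tibble::as_tibble(genes)
  need <- c("symbol", "ensembl_id", "entity_type", "rating")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols) > 0) {
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(genes$symbol) | is.na(genes$symbol))) {
    stop("gene records must carry a non-empty symbol", call. = FALSE)
  }
  dup <- genes$symbol[duplicated(genes$symbol)]
  if (length(dup) > 0) {
    stop("duplicate gene symbol(s) in panel version: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!all(genes$rating %in% 0:3)) {
    stop("confidence ratings must lie in 0..3", call. = FALSE)
  }
  structure(
    list(
      panel_id = as.integer(panel_id),
      source = source,
      version = as.character(version),
      timestamp = as.POSIXct(timestamp, tz = "UTC"),
      genes = genes[need]
    ),
    class = "panel_snapshot"
  )
}

#' @export
print.panel_snapshot <- function(x, ...) {
  cat(sprintf(
    "<panel_snapshot> panel %d (%s) v%s @ %s: %d entries, %d genes, %d diagnostic\n",
    x$panel_id, x$source, x$version,
    format(x$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    nrow(x$genes), sum(x$genes$entity_type == "gene"), diagnostic_count(x)
  ))
  invisible(x)
}

# identity key used to track a gene across versions: Ensembl ID when
# available (symbols get renamed), otherwise the symbol itself
gene_key <- function(genes) {
  ens <- genes$ensembl_id
  ifelse(!is.na(ens) & nzchar(ens), ens, genes$symbol)
}

# gene-entity records only (STRs/regions never count)
gene_entries <- function(snapshot) {
  snapshot$genes[snapshot$genes$entity_type == "gene", , drop = FALSE]
}

#' Parse one PanelApp-style panel version document
#'
#' Consumes the PanelApp API v1 JSON subset: `version`, `version_created`,
#' `genes[].entity_type`, `genes[].confidence_level`,
#' `genes[].gene_data$gene_symbol` and
#' `genes[].gene_data$ensembl_id_or_equivalent`. Non-gene entities are
#' retained in the snapshot but excluded from all counting operations.
#' An absent confidence level is treated as 0.
#'
#' @param document Path to a JSON file, a JSON string, or an already-parsed
#'   list.
#' @return A [panel_snapshot()].
#' @export
parse_panel_version <- function(document) {
  doc <- if (is.character(document) && length(document) == 1) {
    jsonlite::fromJSON(document, simplifyVector = FALSE)
  } else {
    document
  }
  # [[ ]] access throughout: $ would partial-match e.g. version_created
  if (is.null(doc[["version"]]) || !nzchar(as.character(doc[["version"]])[1])) {
    stop("panel document is missing required field 'version'", call. = FALSE)
  }
  if (is.null(doc[["version_created"]])) {
    stop("panel document is missing required field 'version_created'",
         call. = FALSE)
  }
  ts <- parse_utc_time(doc[["version_created"]])
  if (is.na(ts)) {
    stop("cannot parse 'version_created' value: ", doc[["version_created"]],
         call. = FALSE)
  }
  entries <- doc[["genes"]] %||% list()
  genes <- purrr::map_dfr(entries, function(e) {
    gd <- e[["gene_data"]] %||% list()
    tibble::tibble(
      symbol = as.character(gd[["gene_symbol"]] %||% NA_character_),
      ensembl_id = as.character(gd[["ensembl_id_or_equivalent"]] %||%
                                  NA_character_),
      entity_type = as.character(e[["entity_type"]] %||% "gene"),
      rating = parse_rating(e[["confidence_level"]])
    )
  })
  if (nrow(genes) == 0) {
    genes <- tibble::tibble(symbol = character(), ensembl_id = character(),
                            entity_type = character(), rating = integer())
  }
  panel_snapshot(
    panel_id = doc$id %||% NA_integer_,
    source = doc$source %||% "AUS",
    version = doc$version,
    timestamp = ts,
    genes = genes
  )
}

parse_rating <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(as.character(x))) {
    return(0L)
  }
  r <- suppressWarnings(as.integer(x))
  if (is.na(r)) 0L else r
}

parse_utc_time <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  out
}

#' Read a directory of panel version documents
#'
#' @param dir Directory containing one JSON file per panel version.
#' @return List of [panel_snapshot()]s sorted by timestamp.
#' @export
read_panel_versions <- function(dir) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0) {
    stop("no panel version JSON files found in ", dir, call. = FALSE)
  }
  snaps <- lapply(sort(files), parse_panel_version)
  snaps[order(vapply(snaps, function(s) as.numeric(s$timestamp), 0))]
}

#' Select one representative panel snapshot per calendar month
#'
#' For each month in the window the representative version is the latest one
#' whose timestamp is on or before the last day of that month at 23:59:59
#' (UTC). Months in which no new version appeared carry the previous month's
#' snapshot forward.
#'
#' @param versions List of [panel_snapshot()]s sorted by timestamp.
#' @param window Length-2 vector of month keys `c(first, last)`; defaults to
#'   the span of the versions themselves.
#' @return A `panel_series`: list with `panel_id`, `launch_month`, and
#'   `months`, a named list mapping each month key to its snapshot.
#' @export
select_monthly_snapshots <- function(versions, window = NULL) {
  stopifnot(length(versions) >= 1)
  ts <- vapply(versions, function(s) as.numeric(s$timestamp), 0)
  if (is.unsorted(ts)) {
    stop("panel versions must be sorted by timestamp", call. = FALSE)
  }
  first_month <- as_month_key(versions[[1]]$timestamp)
  if (is.null(window)) {
    window <- c(first_month, as_month_key(versions[[length(versions)]]$timestamp))
  }
  window <- as_month_key(window)
  if (month_index(window[1]) < month_index(first_month)) {
    stop("window starts ", window[1], ", before the first panel version (",
         first_month, "); no snapshot can be carried into the past",
         call. = FALSE)
  }
  months <- month_seq(window[1], window[2])
  cutoffs <- as.numeric(month_end(months))
  # latest version at or before each month-end cutoff
  idx <- findInterval(cutoffs, ts)
  if (any(idx == 0)) {
    stop("no panel version exists on or before the end of ",
         months[which(idx == 0)[1]], call. = FALSE)
  }
  out <- stats::setNames(lapply(idx, function(i) versions[[i]]), months)
  structure(
    list(panel_id = versions[[1]]$panel_id, launch_month = months[1],
         months = out),
    class = "panel_series"
  )
}

#' @export
print.panel_series <- function(x, ...) {
  cat(sprintf("<panel_series> panel %d: %d months (%s .. %s)\n",
              x$panel_id, length(x$months), names(x$months)[1],
              names(x$months)[length(x$months)]))
  invisible(x)
}

#' Count diagnostic-grade genes in a snapshot
#'
#' Diagnostic grade means a gene-entity record at confidence level 3
#' ("Green"). STR and region entries never count.
#'
#' @param snapshot A [panel_snapshot()].
#' @return Integer count.
#' @export
diagnostic_count <- function(snapshot) {
  g <- gene_entries(snapshot)
  sum(g$rating == 3L)
}

#' Classify gene changes between two consecutive monthly snapshots
#'
#' Genes are tracked by Ensembl ID when available, falling back to symbol, so
#' a symbol rename with a stable Ensembl ID is not a change event. Every
#' changed gene lands in exactly one of six categories; the conservation
#' identity
#' `diag(curr) - diag(prev) = added_diagnostic + upgraded - downgraded - removed_diagnostic`
#' holds by construction.
#'
#' @param prev,curr [panel_snapshot()]s for consecutive months.
#' @param month Optional month key recorded on the result.
#' @return A `change_set`: list of six symbol vectors (`added_diagnostic`,
#'   `upgraded`, `downgraded`, `removed_diagnostic`, `added_nondiagnostic`,
#'   `removed_nondiagnostic`) plus `month`.
#' @export
classify_changes <- function(prev, curr, month = NULL) {
  p <- gene_entries(prev)
  q <- gene_entries(curr)
  pk <- gene_key(p)
  qk <- gene_key(q)
  p_diag <- pk[p$rating == 3L]
  q_diag <- qk[q$rating == 3L]

  added <- setdiff(qk, pk)
  removed <- setdiff(pk, qk)
  common <- intersect(pk, qk)

  sym_q <- stats::setNames(q$symbol, qk)
  sym_p <- stats::setNames(p$symbol, pk)

  cs <- list(
    month = if (is.null(month)) NA_character_ else as_month_key(month),
    added_diagnostic = unname(sym_q[intersect(added, q_diag)]),
    upgraded = unname(sym_q[setdiff(intersect(common, q_diag), p_diag)]),
    downgraded = unname(sym_q[setdiff(intersect(common, p_diag), q_diag)]),
    removed_diagnostic = unname(sym_p[intersect(removed, p_diag)]),
    added_nondiagnostic = unname(sym_q[setdiff(added, q_diag)]),
    removed_nondiagnostic = unname(sym_p[setdiff(removed, p_diag)])
  )
  structure(cs, class = "change_set")
}

#' Net change in diagnostic genes implied by a change set
#'
#' The conservation identity: additions plus upgrades minus downgrades minus
#' removals.
#'
#' @param cs A `change_set`, or any list with the four diagnostic category
#'   vectors.
#' @return Integer net change.
#' @export
change_set_net <- function(cs) {
  length(cs$added_diagnostic) + length(cs$upgraded) -
    length(cs$downgraded) - length(cs$removed_diagnostic)
}

change_categories <- c("added_diagnostic", "upgraded", "downgraded",
                       "removed_diagnostic", "added_nondiagnostic",
                       "removed_nondiagnostic")

#' @export
print.change_set <- function(x, ...) {
  cat(sprintf("<change_set> %s: +%dd +%du -%ddown -%drm (net %+d diagnostic)\n",
              x$month %||% "?",
              length(x$added_diagnostic), length(x$upgraded),
              length(x$downgraded), length(x$removed_diagnostic),
              change_set_net(x)))
  invisible(x)
}

#' Classify changes across every consecutive month pair of a series
#'
#' @param series A `panel_series` from [select_monthly_snapshots()].
#' @return Long tibble with columns `month`, `panel_id`, `category`, `symbol`
#'   (one row per change event).
#' @export
classify_series_changes <- function(series) {
  months <- names(series$months)
  if (length(months) < 2) {
    return(tibble::tibble(month = character(), panel_id = integer(),
                          category = character(), symbol = character()))
  }
  purrr::map_dfr(seq(2, length(months)), function(i) {
    cs <- classify_changes(series$months[[i - 1]], series$months[[i]],
                           month = months[i])
    change_set_tibble(cs, panel_id = series$panel_id)
  })
}

#' Change set as a long tibble
#'
#' @param cs A `change_set`.
#' @param panel_id Optional panel id column value.
#' @return Tibble `month`, `panel_id`, `category`, `symbol`.
#' @export
change_set_tibble <- function(cs, panel_id = NA_integer_) {
  purrr::map_dfr(change_categories, function(cat) {
    syms <- cs[[cat]]
    if (length(syms) == 0) return(NULL)
    tibble::tibble(month = cs$month, panel_id = as.integer(panel_id),
                   category = cat, symbol = syms)
  })
}

#' Union diagnostic gene list across panels at a month
#'
#' Takes the set union of diagnostic genes across several monthly panel
#' series at one month, deduplicated by Ensembl ID when present, else by
#' symbol.
#'
#' @param serieses List of `panel_series` objects.
#' @param at Month key at which to take the union.
#' @return Tibble with `symbol`, `ensembl_id` (one row per unique gene).
#' @export
union_diagnostic_list <- function(serieses, at) {
  at <- as_month_key(at)
  rows <- purrr::map_dfr(serieses, function(s) {
    if (!at %in% names(s$months)) {
      stop("panel ", s$panel_id, " does not cover month ", at, call. = FALSE)
    }
    snap <- s$months[[at]]
    g <- gene_entries(snap)
    g <- g[g$rating == 3L, c("symbol", "ensembl_id")]
    g$key <- gene_key(g)
    g
  })
  rows <- rows[!duplicated(rows$key), c("symbol", "ensembl_id")]
  tibble::as_tibble(rows)
}

#' Overlap of two diagnostic gene sets
#'
#' @param set_a,set_b Character vectors of gene identifiers (tracking keys).
#' @return Tibble with `n_a`, `n_b`, `shared`, `unique_a`, `unique_b`.
#' @export
panel_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  shared <- length(intersect(set_a, set_b))
  tibble::tibble(
    n_a = length(set_a), n_b = length(set_b), shared = shared,
    unique_a = length(set_a) - shared, unique_b = length(set_b) - shared
  )
}
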