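# Monthly ClinVar "gene_specific_summary" ingestion and the month x gene
# variant-count matrix.
#
# Each monthly file is a tab-delimited table whose header line(s) are
# prefixed with '#'. The two count columns consumed are Total_alleles and
# Alleles_reported_Pathogenic_Likely_pathogenic (P/LP). A gene absent from a
# month's file is *missing*, never zero: ClinVar omits genes with no
# submissions, and conflating absence with 0 would hide schema drift.

# column-name normalisation: strip '#', whitespace, case
norm_col <- function(x) tolower(gsub("[[:space:]#]+", "", x))

# dates embedded in summary filenames; a month-only date names that month's
# snapshot and is anchored to the month end
extract_file_dates <- function(files,
                               date_pattern = "^(\\d{4}-\\d{2}(-\\d{2})?)") {
  base <- basename(files)
  m <- regmatches(base, regexpr(date_pattern, base))
  if (length(m) != length(files)) {
    stop("cannot extract a date from filename(s): ",
         paste(base[!grepl(date_pattern, base)], collapse = ", "),
         call. = FALSE)
  }
  as.Date(ifelse(nchar(m) == 7, as.character(month_end_date(m)), m))
}

clinvar_required_cols <- c(
  symbol = "symbol",
  geneid = "geneid",
  total_alleles = "total_alleles",
  plp_alleles = "alleles_reported_pathogenic_likely_pathogenic"
)

#' Parse one ClinVar gene-specific-summary file
#'
#' Handles '#'-prefixed header lines (the last such line before the data
#' names the columns), matches column names case-insensitively after
#' stripping '#' and whitespace, and reads plain or gzip files. Rows with
#' GeneID -1, unparseable counts, or P/LP > total alleles are skipped and
#' tallied in the parse report (attribute `"report"`, also available via
#' [parse_report()]).
#'
#' @param file Path to a tab-delimited summary file (optionally `.gz`).
#' @param legacy_names Optional named character vector mapping canonical
#'   column roles (`symbol`, `geneid`, `total_alleles`, `plp_alleles`) to
#'   legacy header names, for old file dialects.
#' @return Tibble with `ncbi_gene_id`, `symbol`, `total_alleles`,
#'   `plp_alleles`.
#' @export
parse_gene_specific_summary <- function(file, legacy_names = NULL) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "rt") else file(file, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(lines))) {
    stop("empty gene-specific-summary file: ", file, call. = FALSE)
  }
  is_comment <- grepl("^#", lines)
  header_line <- if (any(is_comment)) {
    lines[max(which(is_comment))]
  } else {
    lines[1]
  }
  data_lines <- if (any(is_comment)) {
    lines[!is_comment & nzchar(lines)]
  } else {
    lines[-1][nzchar(lines[-1])]
  }
  cols <- norm_col(strsplit(header_line, "\t", fixed = TRUE)[[1]])

  wanted <- clinvar_required_cols
  if (!is.null(legacy_names)) {
    wanted[names(legacy_names)] <- norm_col(legacy_names)
  }
  pos <- stats::setNames(match(wanted, cols), names(wanted))
  if (anyNA(pos)) {
    stop("gene-specific-summary file lacks required column(s): ",
         paste(wanted[is.na(pos)], collapse = ", "), call. = FALSE)
  }

  if (length(data_lines) == 0) {
    stop("gene-specific-summary file has no data rows: ", file, call. = FALSE)
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[[i]] else NA_character_
  }, "")
  raw <- tibble::tibble(
    symbol = get(pos[["symbol"]]),
    ncbi_gene_id = suppressWarnings(as.integer(get(pos[["geneid"]]))),
    total_alleles = suppressWarnings(as.integer(get(pos[["total_alleles"]]))),
    plp_alleles = suppressWarnings(as.integer(get(pos[["plp_alleles"]])))
  )

  no_gene_id <- !is.na(raw$ncbi_gene_id) & raw$ncbi_gene_id == -1L
  unparseable <- is.na(raw$ncbi_gene_id) | is.na(raw$total_alleles) |
    is.na(raw$plp_alleles)
  bad_invariant <- !unparseable & !no_gene_id &
    (raw$plp_alleles > raw$total_alleles | raw$ncbi_gene_id <= 0L)
  keep <- !no_gene_id & !unparseable & !bad_invariant

  out <- raw[keep, c("ncbi_gene_id", "symbol", "total_alleles", "plp_alleles")]
  attr(out, "report") <- list(
    file = file,
    n_rows = nrow(raw),
    n_kept = sum(keep),
    n_no_gene_id = sum(no_gene_id),
    n_unparseable = sum(unparseable & !no_gene_id),
    n_invariant_rejected = sum(bad_invariant)
  )
  out
}

#' Parse report of a summary parse
#'
#' @param x Result of [parse_gene_specific_summary()].
#' @return List of row tallies.
#' @export
parse_report <- function(x) attr(x, "report")

#' Assign monthly summary files to panel months
#'
#' Each panel month maps to the file whose embedded date lies nearest that
#' month's last day; ties break to the earlier file. Filenames carry their
#' date in a configurable pattern (default a `YYYY-MM` or `YYYY-MM-DD`
#' prefix).
#'
#' @param files Character vector of file paths.
#' @param panel_months Month keys that must each receive a file.
#' @param date_pattern Regex with one capture group extracting the date from
#'   the basename.
#' @param tolerance_days Maximum allowed distance between a month's end and
#'   its nearest file date.
#' @return Named character vector: `panel_months` -> file path.
#' @export
assign_months <- function(files, panel_months,
                          date_pattern = "^(\\d{4}-\\d{2}(-\\d{2})?)",
                          tolerance_days = 45) {
  stopifnot(length(files) > 0)
  file_dates <- extract_file_dates(files, date_pattern)
  panel_months <- as_month_key(panel_months)

  picks <- vapply(panel_months, function(mk) {
    target <- month_end_date(mk)
    dist <- abs(as.numeric(file_dates - target))
    best <- min(dist)
    if (best > tolerance_days) return(NA_integer_)
    cand <- which(dist == best)
    # tie -> earlier file
    cand[order(file_dates[cand])][1]
  }, 1L)

  if (anyNA(picks)) {
    stop("no summary file within ", tolerance_days, " days of month end for: ",
         paste(panel_months[is.na(picks)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(files[picks], panel_months)
}

#' Build the month x gene variant-count matrix
#'
#' @param monthly_records Named list: month key -> tibble of per-gene counts
#'   (as returned by [parse_gene_specific_summary()]).
#' @param provenance Optional named character vector, month key -> source
#'   filename.
#' @return A `variant_matrix`: list with sorted `months`, the long `data`
#'   tibble (`month`, `ncbi_gene_id`, `symbol`, `total_alleles`,
#'   `plp_alleles`), and `provenance`. Duplicate GeneIDs within one month
#'   keep the row with the larger total-allele count (with a warning).
#' @export
build_matrix <- function(monthly_records, provenance = NULL) {
  stopifnot(length(monthly_records) >= 1, !is.null(names(monthly_records)))
  months <- sort(as_month_key(names(monthly_records)))
  data <- purrr::map_dfr(months, function(mk) {
    rec <- tibble::as_tibble(monthly_records[[mk]])
    attr(rec, "report") <- NULL
    if (anyDuplicated(rec$ncbi_gene_id)) {
      dups <- unique(rec$ncbi_gene_id[duplicated(rec$ncbi_gene_id)])
      warning("month ", mk, ": duplicate GeneID(s) ",
              paste(dups, collapse = ", "),
              "; keeping the row with the larger total_alleles", call. = FALSE)
      rec <- rec[order(rec$ncbi_gene_id, -rec$total_alleles), ]
      rec <- rec[!duplicated(rec$ncbi_gene_id), ]
    }
    dplyr::mutate(rec, month = mk, .before = 1)
  })
  structure(
    list(months = months,
         data = data,
         provenance = provenance %||%
           stats::setNames(rep(NA_character_, length(months)), months)),
    class = "variant_matrix"
  )
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("<variant_matrix> %d months (%s .. %s), %d gene-month cells\n",
              length(x$months), x$months[1], x$months[length(x$months)],
              nrow(x$data)))
  invisible(x)
}

#' Look up per-gene counts for one month
#'
#' Genes absent from that month's file come back as rows with `NA` counts
#' and `present = FALSE` — missing is distinguishable from a zero count.
#'
#' @param matrix A `variant_matrix`.
#' @param month Month key.
#' @param gene_ids Optional integer NCBI Gene IDs; default all genes seen
#'   that month.
#' @return Tibble `ncbi_gene_id`, `symbol`, `total_alleles`, `plp_alleles`,
#'   `present`.
#' @export
query_counts <- function(matrix, month, gene_ids = NULL) {
  month <- as_month_key(month)
  if (!month %in% matrix$months) {
    stop("month ", month, " is not covered by the variant matrix",
         call. = FALSE)
  }
  col <- matrix$data[matrix$data$month == month, ]
  if (is.null(gene_ids)) {
    out <- col[, c("ncbi_gene_id", "symbol", "total_alleles", "plp_alleles")]
    out$present <- TRUE
    return(tibble::as_tibble(out))
  }
  idx <- match(as.integer(gene_ids), col$ncbi_gene_id)
  tibble::tibble(
    ncbi_gene_id = as.integer(gene_ids),
    symbol = col$symbol[idx],
    total_alleles = col$total_alleles[idx],
    plp_alleles = col$plp_alleles[idx],
    present = !is.na(idx)
  )
}

#' Sum P/LP alleles over a gene set at one month
#'
#' @param matrix A `variant_matrix`.
#' @param month Month key.
#' @param genes Optional integer NCBI Gene ID set; default all genes present
#'   that month.
#' @return List with `value` (integer sum over present genes), `n_missing`
#'   (genes of the requested set absent that month) and `n_present`.
#' @export
total_plp <- function(matrix, month, genes = NULL) {
  q <- query_counts(matrix, month, genes)
  list(value = sum(q$plp_alleles[q$present]),
       n_missing = sum(!q$present),
       n_present = sum(q$present))
}

#' Sum total alleles over a gene set at one month
#'
#' Companion of [total_plp()] for the Total_alleles column.
#'
#' @inheritParams total_plp
#' @return List with `value`, `n_missing`, `n_present`.
#' @export
total_alleles_at <- function(matrix, month, genes = NULL) {
  q <- query_counts(matrix, month, genes)
  list(value = sum(q$total_alleles[q$present]),
       n_missing = sum(!q$present),
       n_present = sum(q$present))
}

#' Per-month P/LP totals as a series
#'
#' @param matrix A `variant_matrix`.
#' @param genes Optional NCBI Gene ID set (default: all genes each month).
#' @return Tibble `month`, `plp_alleles`, `total_alleles`, `n_missing`.
#' @export
matrix_monthly_totals <- function(matrix, genes = NULL) {
  purrr::map_dfr(matrix$months, function(mk) {
    p <- total_plp(matrix, mk, genes)
    t <- total_alleles_at(matrix, mk, genes)
    tibble::tibble(month = mk, plp_alleles = p$value,
                   total_alleles = t$value, n_missing = p$n_missing)
  })
}

#' Serialise a variant matrix as long-format TSV
#'
#' @param matrix A `variant_matrix`.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(matrix, path) {
  readr::write_tsv(matrix$data, path)
  invisible(path)
}

#' Read a variant matrix back from long-format TSV
#'
#' @param path File written by [write_matrix_tsv()].
#' @return A `variant_matrix`.
#' @export
read_matrix_tsv <- function(path) {
  data <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            month = readr::col_character(),
                            ncbi_gene_id = readr::col_integer(),
                            symbol = readr::col_character(),
                            total_alleles = readr::col_integer(),
                            plp_alleles = readr::col_integer()
                          ))
  split_rec <- split(data[, -1], data$month)
  build_matrix(split_rec)
}
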