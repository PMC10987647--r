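# Ensembl <-> NCBI gene identifier reconciliation.
#
# Panels describe genes with Ensembl stable IDs; ClinVar keys its counts by
# NCBI Gene ID. A BioMart-export style two-column table provides the raw
# (possibly many-to-many, possibly one-sided) correspondence; ambiguous
# cases are resolved towards the candidate carrying the most variant
# evidence, manual overrides take precedence, and genes present in only one
# world resolve to NA (a value, not an error).

#' Load a BioMart-export style ID mapping table
#'
#' Two tab-separated columns: NCBI Gene ID, then Ensembl gene stable ID. A
#' header row is detected and dropped. Rows with one blank cell are kept as
#' one-sided entries; rows that are malformed on both sides are skipped and
#' counted (attribute `"n_skipped"`).
#'
#' @param file Path to the TSV.
#' @return Tibble `ncbi_gene_id` (integer, may be `NA`), `ensembl_id`
#'   (character, may be `NA`): the raw multimap.
#' @export
load_mapping_table <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty mapping table: ", file, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  f1 <- vapply(parts, function(p) if (length(p) >= 1) trimws(p[[1]]) else "", "")
  f2 <- vapply(parts, function(p) if (length(p) >= 2) trimws(p[[2]]) else "", "")
  # header row: first line whose NCBI cell is neither numeric nor blank
  if (nzchar(f1[1]) && is.na(suppressWarnings(as.integer(f1[1])))) {
    f1 <- f1[-1]; f2 <- f2[-1]
  }
  ncbi <- suppressWarnings(as.integer(f1))
  ens <- ifelse(nzchar(f2), f2, NA_character_)
  malformed <- (is.na(ncbi) & nzchar(f1)) |        # junk in the NCBI cell
    (is.na(ncbi) & is.na(ens))                     # nothing on either side
  out <- tibble::tibble(ncbi_gene_id = ncbi, ensembl_id = ens)[!malformed, ]
  if (any(malformed)) {
    warning(sum(malformed), " malformed mapping row(s) skipped", call. = FALSE)
  }
  attr(out, "n_skipped") <- sum(malformed)
  out
}

#' Resolve one Ensembl ID to an NCBI Gene ID
#'
#' Precedence: a manual override wins; otherwise a unique mapping candidate
#' is taken as-is; otherwise, among multiple candidates, the one with the
#' largest total-allele count at the latest month all candidates appear in
#' (falling back to the latest month any appears in), ties broken towards
#' the numerically smaller NCBI ID; with no candidate and no override the
#' resolution is `NA` with method `"unmatched"`.
#'
#' @param ensembl_id One Ensembl gene stable ID.
#' @param multimap Raw mapping tibble from [load_mapping_table()].
#' @param matrix A `variant_matrix` used as the evidence base for
#'   disambiguation.
#' @param overrides Optional tibble with `ensembl_id`, `ncbi_gene_id`
#'   (manual review results).
#' @return List with `ncbi_gene_id` (integer or `NA`) and `method` (one of
#'   `"manual"`, `"unique"`, `"largest_count"`, `"unmatched"`).
#' @export
resolve_id <- function(ensembl_id, multimap, matrix, overrides = NULL) {
  if (!is.null(overrides) && nrow(overrides) > 0) {
    hit <- match(ensembl_id, overrides$ensembl_id)
    if (!is.na(hit)) {
      return(list(ncbi_gene_id = as.integer(overrides$ncbi_gene_id[hit]),
                  method = "manual"))
    }
  }
  cand <- unique(multimap$ncbi_gene_id[
    !is.na(multimap$ensembl_id) & multimap$ensembl_id == ensembl_id &
      !is.na(multimap$ncbi_gene_id)
  ])
  if (length(cand) == 0) {
    return(list(ncbi_gene_id = NA_integer_, method = "unmatched"))
  }
  if (length(cand) == 1) {
    return(list(ncbi_gene_id = as.integer(cand), method = "unique"))
  }
  # ambiguous: weigh candidates by total_alleles at the latest shared month
  d <- matrix$data[matrix$data$ncbi_gene_id %in% cand, ]
  if (nrow(d) == 0) {
    # no evidence for any candidate; deterministic fallback
    return(list(ncbi_gene_id = min(cand), method = "largest_count"))
  }
  by_month <- split(d, d$month)
  present_all <- names(by_month)[vapply(by_month, function(x) {
    all(unique(d$ncbi_gene_id) %in% x$ncbi_gene_id)
  }, TRUE)]
  use_month <- if (length(present_all) > 0) max(present_all) else max(d$month)
  col <- by_month[[use_month]]
  col <- col[order(-col$total_alleles, col$ncbi_gene_id), ]
  list(ncbi_gene_id = as.integer(col$ncbi_gene_id[1]), method = "largest_count")
}

#' Build an ID map for a set of Ensembl IDs
#'
#' Applies [resolve_id()] to every ID; the result is the fixed per-gene
#' resolution used downstream (the chosen NCBI ID never flaps month to
#' month).
#'
#' @param ensembl_ids Character vector of Ensembl gene stable IDs.
#' @inheritParams resolve_id
#' @return Tibble `ensembl_id`, `ncbi_gene_id`, `method` — one row per
#'   input ID.
#' @export
build_id_map <- function(ensembl_ids, multimap, matrix, overrides = NULL) {
  ensembl_ids <- unique(ensembl_ids)
  res <- purrr::map(ensembl_ids, resolve_id, multimap = multimap,
                    matrix = matrix, overrides = overrides)
  tibble::tibble(
    ensembl_id = ensembl_ids,
    ncbi_gene_id = vapply(res, function(r) r$ncbi_gene_id, 1L),
    method = vapply(res, function(r) r$method, "")
  )
}

#' Annotate a gene list with its ID resolutions
#'
#' @param gene_list Tibble with at least `symbol` and `ensembl_id` (e.g.
#'   from [union_diagnostic_list()]).
#' @param idmap Tibble from [build_id_map()].
#' @return The gene list with `ncbi_gene_id` and `method` columns; the match
#'   report (`n_total`, `n_matched`, `n_unmatched`, unmatched symbols) is
#'   attached as attribute `"match_report"` and via [match_report()]. Genes
#'   with no Ensembl ID at all resolve as unmatched unless an override
#'   keyed by symbol is present in the idmap.
#' @export
annotate_gene_list <- function(gene_list, idmap) {
  gene_list <- tibble::as_tibble(gene_list)
  key <- ifelse(!is.na(gene_list$ensembl_id) & nzchar(gene_list$ensembl_id),
                gene_list$ensembl_id, gene_list$symbol)
  idx <- match(key, idmap$ensembl_id)
  out <- gene_list
  out$ncbi_gene_id <- idmap$ncbi_gene_id[idx]
  out$method <- ifelse(is.na(idx), "unmatched", idmap$method[idx])
  matched <- !is.na(out$ncbi_gene_id)
  attr(out, "match_report") <- list(
    n_total = nrow(out),
    n_matched = sum(matched),
    n_unmatched = sum(!matched),
    unmatched_symbols = out$symbol[!matched]
  )
  out
}

#' Match report of an annotated gene list
#'
#' @param x Result of [annotate_gene_list()].
#' @return List with matched/unmatched tallies.
#' @export
match_report <- function(x) attr(x, "match_report")

#' Load a manual override table
#'
#' TSV with columns `ensembl_id`, `ncbi_gene_id` and an optional free-text
#' `evidence` column recording the review source (HGNC, UniProt, ...).
#'
#' @param file Path to the TSV.
#' @return Tibble `ensembl_id`, `ncbi_gene_id`, `evidence`.
#' @export
load_overrides <- function(file) {
  out <- readr::read_tsv(file, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("ensembl_id", "ncbi_gene_id")
  if (!all(need %in% names(out))) {
    stop("override table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out$ncbi_gene_id <- as.integer(out$ncbi_gene_id)
  if (!"evidence" %in% names(out)) out$evidence <- NA_character_
  out[, c("ensembl_id", "ncbi_gene_id", "evidence")]
}
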