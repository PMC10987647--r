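# Joining panel gene information with the variant matrix.
#
# Two modes mirror the two scientific questions. Static mode annotates a
# fixed gene list with each month's variant counts (how does the evidence
# behind a frozen list grow?). Evolving mode walks the monthly panel series
# and, for each month, sums P/LP alleles over the diagnostic genes of *that
# month's* snapshot — approximating the information actually available to a
# curator at that point in time.

#' Static gene list mode
#'
#' Full cross of an annotated gene list with every month of the variant
#' matrix. Genes whose ID resolution is `NA`, or which are absent from a
#' month's file, yield missing (`NA`) cells, never zeros.
#'
#' @param gene_list Annotated gene list from [annotate_gene_list()].
#' @param matrix A `variant_matrix`.
#' @return A `static_gene_table`: long tibble `symbol`, `ensembl_id`,
#'   `ncbi_gene_id`, `method`, `month`, `total_alleles`, `plp_alleles`,
#'   `present`.
#' @export
static_mode <- function(gene_list, matrix) {
  gene_list <- tibble::as_tibble(gene_list)
  if (nrow(gene_list) == 0) {
    stop("static mode needs a non-empty gene list", call. = FALSE)
  }
  out <- purrr::map_dfr(matrix$months, function(mk) {
    q <- query_counts(matrix, mk, gene_list$ncbi_gene_id)
    tibble::tibble(
      symbol = gene_list$symbol,
      ensembl_id = gene_list$ensembl_id,
      ncbi_gene_id = gene_list$ncbi_gene_id,
      method = gene_list$method,
      month = mk,
      total_alleles = q$total_alleles,
      plp_alleles = q$plp_alleles,
      present = q$present & !is.na(gene_list$ncbi_gene_id)
    )
  })
  class(out) <- c("static_gene_table", class(out))
  out
}

#' Evolving gene panel mode
#'
#' For each month of a panel series, resolves that month's panel genes
#' through the (fixed) ID map and sums variant counts from that month's
#' matrix column. Matched counts are reported alongside totals — the
#' dual-count convention `matched (total)` — because not every panel gene
#' resolves to a gene present in the ClinVar summary.
#'
#' @param series A `panel_series` from [select_monthly_snapshots()].
#' @param matrix A `variant_matrix` covering every month of the series.
#' @param idmap Tibble from [build_id_map()].
#' @return A `joined_series` tibble, one row per month: `month`,
#'   `panel_version`, `n_genes_total`, `n_genes_matched`, `n_diag_total`,
#'   `n_diag_matched`, `total_alleles_all_genes`, `plp_in_diag`.
#' @export
evolving_mode <- function(series, matrix, idmap) {
  months <- names(series$months)
  absent <- setdiff(months, matrix$months)
  if (length(absent) > 0) {
    stop("variant matrix does not cover month(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- purrr::map_dfr(months, function(mk) {
    snap <- series$months[[mk]]
    g <- gene_entries(snap)
    key <- gene_key(g)
    idx <- match(key, idmap$ensembl_id)
    ncbi <- idmap$ncbi_gene_id[idx]
    q <- query_counts(matrix, mk, ncbi)
    matched <- !is.na(ncbi) & q$present
    diag <- g$rating == 3L
    tibble::tibble(
      month = mk,
      panel_version = snap$version,
      n_genes_total = nrow(g),
      n_genes_matched = sum(matched),
      n_diag_total = sum(diag),
      n_diag_matched = sum(matched & diag),
      total_alleles_all_genes = sum(q$total_alleles[matched]),
      plp_in_diag = sum(q$plp_alleles[matched & diag])
    )
  })
  class(out) <- c("joined_series", class(out))
  out
}

#' Per-gene-month long table behind an evolving join
#'
#' The gene-level detail of [evolving_mode()]: one row per panel gene per
#' month with its rating, resolution and counts.
#'
#' @inheritParams evolving_mode
#' @return Long tibble `month`, `symbol`, `ensembl_id`, `rating`,
#'   `ncbi_gene_id`, `total_alleles`, `plp_alleles`, `present`.
#' @export
evolving_gene_table <- function(series, matrix, idmap) {
  months <- names(series$months)
  purrr::map_dfr(months, function(mk) {
    snap <- series$months[[mk]]
    g <- gene_entries(snap)
    key <- gene_key(g)
    idx <- match(key, idmap$ensembl_id)
    ncbi <- idmap$ncbi_gene_id[idx]
    q <- query_counts(matrix, mk, ncbi)
    tibble::tibble(
      month = mk, symbol = g$symbol, ensembl_id = g$ensembl_id,
      rating = g$rating, ncbi_gene_id = ncbi,
      total_alleles = q$total_alleles, plp_alleles = q$plp_alleles,
      present = !is.na(ncbi) & q$present
    )
  })
}
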