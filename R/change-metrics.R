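# Quantifying change: percentage increases, monthly deltas, burst detection,
# per-gene summaries, and series correlation.
#
# Internal values are kept unrounded; rounding (half away from zero, to
# integer percent) is a separately named formatting step so reports can
# switch display rules without touching the arithmetic.

#' Percentage increase between two counts
#'
#' `100 * (end - start) / start`. A zero start yields `NA` (undefined), not
#' a division error. Vectorised.
#'
#' @param start,end Numeric counts.
#' @return Numeric percent (unrounded).
#' @export
#' @examples
#' percentage_increase(7477, 36930)  # ~393.9
percentage_increase <- function(start, end) {
  out <- 100 * (end - start) / start
  out[start == 0] <- NA_real_
  out
}

#' Round half away from zero
#'
#' Report-formatting rounding (2.5 -> 3, -2.5 -> -3), as opposed to R's
#' banker's rounding.
#'
#' @param x Numeric.
#' @param digits Decimal places (default integer).
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a count increase as "n (p%)"
#'
#' @param start,end Counts.
#' @param rounding `"half_away"` (default) or `"truncate"`.
#' @return Character like `"29453 (394%)"`; percent is `"NA%"` when start is
#'   zero.
#' @export
format_increase <- function(start, end, rounding = c("half_away", "truncate")) {
  rounding <- match.arg(rounding)
  pct <- percentage_increase(start, end)
  pct_i <- switch(rounding,
                  half_away = round_half_away(pct),
                  truncate = trunc(pct))
  sprintf("%d (%s%%)", as.integer(end - start),
          ifelse(is.na(pct_i), "NA", format(pct_i, scientific = FALSE)))
}

#' Month-over-month percentage changes of a series
#'
#' Change at month m is the percentage increase from month m-1. A zero value
#' at m-1 marks month m undefined (`NA`) with a warning; undefined months
#' are excluded from the summary statistics.
#'
#' @param values Numeric per-month counts (length >= 2).
#' @param months Optional month keys aligned with `values`.
#' @return Tibble `month`, `value`, `pct_change` (first month `NA` by
#'   construction); the [change_summary()] is attached as attribute
#'   `"summary"`.
#' @export
monthly_deltas <- function(values, months = NULL) {
  stopifnot(length(values) >= 2)
  if (is.null(months)) {
    months <- sprintf("m%02d", seq_along(values))
  } else {
    months <- as_month_key(months)
    stopifnot(length(months) == length(values))
  }
  pct <- c(NA_real_, percentage_increase(values[-length(values)], values[-1]))
  undef <- which(is.na(pct[-1]) & values[-length(values)] == 0) + 1L
  if (length(undef) > 0) {
    warning("undefined monthly change (zero predecessor) at: ",
            paste(months[undef], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(month = months, value = values, pct_change = pct)
  attr(out, "summary") <- change_summary(values, months = months)
  out
}

#' Summary of change over a window
#'
#' Start/end values, absolute and percentage increase, and the mean, median
#' and range of the month-over-month percentage changes (arithmetic mean;
#' a geometric alternative is available since compounding the mean monthly
#' rate is sometimes wanted instead).
#'
#' @param values Numeric per-month counts.
#' @param months Optional aligned month keys.
#' @param mean_type `"arithmetic"` (default) or `"geometric"` for the mean
#'   monthly change.
#' @return A `change_summary` list.
#' @export
change_summary <- function(values, months = NULL,
                           mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  stopifnot(length(values) >= 2)
  pct <- percentage_increase(values[-length(values)], values[-1])
  ok <- !is.na(pct)
  mean_change <- if (!any(ok)) {
    NA_real_
  } else if (mean_type == "arithmetic") {
    mean(pct[ok])
  } else {
    (exp(mean(log1p(pct[ok] / 100))) - 1) * 100
  }
  structure(
    list(
      window = if (is.null(months)) c(NA_character_, NA_character_) else
        c(months[1], months[length(months)]),
      start_value = values[1],
      end_value = values[length(values)],
      absolute_increase = values[length(values)] - values[1],
      percent_increase = percentage_increase(values[1], values[length(values)]),
      monthly_percent_changes = pct,
      mean_monthly_change = mean_change,
      median_monthly_change = if (any(ok)) stats::median(pct[ok]) else NA_real_,
      min_monthly_change = if (any(ok)) min(pct[ok]) else NA_real_,
      max_monthly_change = if (any(ok)) max(pct[ok]) else NA_real_,
      n_undefined = sum(!ok)
    ),
    class = "change_summary"
  )
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf(
    "<change_summary> %s .. %s: %s -> %s (%+d, %s%%); monthly mean %.1f%%, median %.1f%%, range %.1f..%.1f%%\n",
    x$window[1], x$window[2], x$start_value, x$end_value,
    x$absolute_increase,
    ifelse(is.na(x$percent_increase), "NA",
           format(round_half_away(x$percent_increase))),
    x$mean_monthly_change, x$median_monthly_change,
    x$min_monthly_change, x$max_monthly_change
  ))
  invisible(x)
}

#' Detect burst months
#'
#' Months whose absolute month-over-month percentage change strictly exceeds
#' the threshold. Raising the threshold never adds a burst month.
#'
#' @param deltas Tibble from [monthly_deltas()] (or any tibble with `month`
#'   and `pct_change`).
#' @param threshold Percent threshold; default 5.
#' @return A `burst_report`: tibble `month`, `pct_change`, sorted by month,
#'   with the threshold as attribute `"threshold"`.
#' @export
detect_bursts <- function(deltas, threshold = 5) {
  hit <- !is.na(deltas$pct_change) & abs(deltas$pct_change) > threshold
  out <- deltas[hit, c("month", "pct_change")]
  out <- out[order(out$month), ]
  attr(out, "threshold") <- threshold
  class(out) <- c("burst_report", class(out))
  out
}

#' Per-gene P/LP change summary over a window
#'
#' For each gene of a static table, the absolute P/LP change between the
#' window endpoints; genes missing at either endpoint are excluded and
#' reported. Cohort statistics and per-month top-k rankings (the genes
#' carrying the most P/LP variants each month) accompany the table.
#'
#' @param static_table A `static_gene_table` from [static_mode()].
#' @param window Length-2 month keys `c(start, end)`; default the table's
#'   full span.
#' @param top_k Number of genes per month in the ranking (default 3).
#' @return List with `per_gene` (tibble `symbol`, `ncbi_gene_id`,
#'   `start_plp`, `end_plp`, `change`), `stats` (mean/median/range, counts
#'   of zero- and negative-change genes), `excluded` (symbols missing at an
#'   endpoint) and `top_by_month` (tibble `month`, `rank`, `symbol`,
#'   `plp_alleles`).
#' @export
per_gene_change_summary <- function(static_table, window = NULL, top_k = 3) {
  months <- sort(unique(static_table$month))
  if (is.null(window)) window <- c(months[1], months[length(months)])
  window <- as_month_key(window)
  if (!all(window %in% months)) {
    stop("window endpoints must be months of the static table", call. = FALSE)
  }
  a <- static_table[static_table$month == window[1], ]
  b <- static_table[static_table$month == window[2], ]
  idx <- match(a$symbol, b$symbol)
  per <- tibble::tibble(
    symbol = a$symbol,
    ncbi_gene_id = a$ncbi_gene_id,
    start_plp = a$plp_alleles,
    end_plp = b$plp_alleles[idx],
    start_present = a$present,
    end_present = b$present[idx]
  )
  ok <- per$start_present & per$end_present
  excluded <- per$symbol[!ok]
  per <- per[ok, ]
  per$change <- per$end_plp - per$start_plp
  per <- per[order(-per$change, per$symbol), c("symbol", "ncbi_gene_id",
                                               "start_plp", "end_plp", "change")]

  in_window <- static_table$month >= window[1] & static_table$month <= window[2]
  top_by_month <- static_table[in_window & static_table$present, ] |>
    dplyr::group_by(.data$month) |>
    dplyr::arrange(dplyr::desc(.data$plp_alleles), .data$symbol,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = top_k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("month", "rank", "symbol", "plp_alleles")

  list(
    per_gene = per,
    stats = list(
      n_genes = nrow(per),
      mean_change = mean(per$change),
      median_change = stats::median(per$change),
      min_change = min(per$change),
      max_change = max(per$change),
      n_zero = sum(per$change == 0),
      n_negative = sum(per$change < 0)
    ),
    excluded = excluded,
    top_by_month = top_by_month
  )
}

#' Pearson correlation of two aligned series
#'
#' Standard product-moment coefficient; a constant series (or length < 3)
#' yields `NA` with a warning rather than an error.
#'
#' @param series_a,series_b Equal-length numeric vectors.
#' @return Pearson r, or `NA` when undefined.
#' @export
correlate <- function(series_a, series_b) {
  stopifnot(length(series_a) == length(series_b))
  if (length(series_a) < 3) {
    warning("correlation needs at least 3 points", call. = FALSE)
    return(NA_real_)
  }
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0) {
    warning("correlation undefined for a constant series", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(series_a, series_b, method = "pearson")
}
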