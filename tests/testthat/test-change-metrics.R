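test_that("percentage_increase has the identity, sign, and zero-start contracts", {
  expect_equal(percentage_increase(100, 100), 0)
  expect_equal(percentage_increase(100, 150), 50)
  expect_equal(percentage_increase(200, 100), -50)
  expect_true(is.na(percentage_increase(0, 10)))   # undefined, not an error
  withr::local_seed(1)
  a <- sample(1:1000, 20)
  b <- sample(0:1000, 20)
  expect_equal(sign(percentage_increase(a, b)), sign(b - a))
})

test_that("rounding half away from zero differs from banker's rounding where it must", {
  expect_equal(round_half_away(2.5), 3)
  expect_equal(round_half_away(-2.5), -3)
  expect_equal(round_half_away(393.94), 394)
  expect_equal(round_half_away(44.37), 44)
  expect_equal(round_half_away(1.25, 1), 1.3)
  expect_equal(format_increase(7477, 36930), "29453 (394%)")
  expect_equal(format_increase(100, 566.55, rounding = "truncate"), "466 (466%)")
})

test_that("monthly deltas and the change summary agree with closed forms", {
  d <- monthly_deltas(c(100, 110, 121))
  expect_equal(d$pct_change, c(NA, 10, 10))
  s <- attr(d, "summary")
  expect_equal(s$mean_monthly_change, 10)
  expect_equal(s$absolute_increase, 21)

  # constant series: all zeros
  dc <- monthly_deltas(rep(7, 5))
  expect_true(all(dc$pct_change[-1] == 0))
  expect_equal(attr(dc, "summary")$mean_monthly_change, 0)

  # a zero intermediate marks the following month undefined, with a warning,
  # and it is excluded from the mean
  expect_warning(dz <- monthly_deltas(c(5, 0, 10)), "undefined")
  expect_true(is.na(dz$pct_change[3]))
  expect_equal(attr(dz, "summary")$n_undefined, 1)

  # geometric mean option compounds back to the endpoint ratio
  sg <- change_summary(c(100, 110, 121), mean_type = "geometric")
  expect_equal((1 + sg$mean_monthly_change / 100)^2 * 100, 121)
})

test_that("applying the monthly percent changes reconstructs the series", {
  withr::local_seed(21)
  values <- cumsum(sample(5:50, 12)) + 100
  d <- monthly_deltas(values)
  rebuilt <- Reduce(function(v, p) v * (1 + p / 100), d$pct_change[-1],
                    accumulate = TRUE, init = values[1])
  expect_equal(rebuilt, values)
})

test_that("burst detection flags strict threshold exceedances and is monotone", {
  d <- tibble::tibble(month = sprintf("2020-%02d", 1:4),
                      pct_change = c(1, 2, 12, 0))
  b <- detect_bursts(d, threshold = 5)
  expect_equal(b$month, "2020-03")

  # boundary is strict
  d2 <- tibble::tibble(month = "2020-01", pct_change = 5)
  expect_equal(nrow(detect_bursts(d2, threshold = 5)), 0)

  # declines count through the absolute value
  d3 <- tibble::tibble(month = "2020-01", pct_change = -8)
  expect_equal(nrow(detect_bursts(d3, threshold = 5)), 1)

  # raising the threshold never adds a burst month
  withr::local_seed(8)
  dd <- tibble::tibble(month = sprintf("m%02d", 1:30),
                       pct_change = stats::rnorm(30, 0, 6))
  for (th in c(1, 3, 5, 10)) {
    lo <- detect_bursts(dd, threshold = th)$month
    hi <- detect_bursts(dd, threshold = th + 2)$month
    expect_true(all(hi %in% lo))
  }
})

test_that("per-gene change summary computes cohort statistics and rankings", {
  genes <- tibble::tibble(symbol = c("A", "B", "C"),
                          ensembl_id = c("E1", "E2", "E3"),
                          ncbi_gene_id = c(11L, 12L, 13L),
                          method = "unique")
  mat <- build_matrix(list(
    "2020-01" = tibble::tibble(ncbi_gene_id = c(11L, 12L, 13L),
                               symbol = c("A", "B", "C"),
                               total_alleles = c(20L, 9L, 30L),
                               plp_alleles = c(10L, 4L, 8L)),
    "2020-02" = tibble::tibble(ncbi_gene_id = c(11L, 12L, 13L),
                               symbol = c("A", "B", "C"),
                               total_alleles = c(25L, 9L, 30L),
                               plp_alleles = c(15L, 4L, 6L))
  ))
  st <- static_mode(genes, mat)
  pg <- per_gene_change_summary(st)
  expect_equal(pg$per_gene$change[match(c("A", "B", "C"), pg$per_gene$symbol)],
               c(5L, 0L, -2L))
  expect_equal(pg$stats$mean_change, 1)
  expect_equal(pg$stats$median_change, 0)
  expect_equal(pg$stats$min_change, -2)
  expect_equal(pg$stats$max_change, 5)
  expect_equal(pg$stats$n_zero, 1)
  expect_equal(pg$stats$n_negative, 1)

  # top-k per month equals a brute-force sort
  for (mk in c("2020-01", "2020-02")) {
    col <- st[st$month == mk & st$present, ]
    oracle <- col$symbol[order(-col$plp_alleles, col$symbol)][1:2]
    got <- pg$top_by_month[pg$top_by_month$month == mk, ]
    expect_equal(got$symbol[got$rank <= 2], oracle)
  }
})

test_that("genes missing at a window endpoint are excluded and reported", {
  genes <- tibble::tibble(symbol = c("A", "X"), ensembl_id = c("E1", "EX"),
                          ncbi_gene_id = c(11L, NA), method = c("unique", "unmatched"))
  st <- static_mode(genes, toy_matrix())
  pg <- per_gene_change_summary(st)
  expect_equal(pg$excluded, "X")
  expect_equal(pg$per_gene$symbol, "A")
})

test_that("correlation meets its degenerate and invariance contracts", {
  x <- c(1, 3, 2, 5, 4, 8)
  expect_equal(correlate(x, x), 1.0)
  expect_equal(correlate(x, -2 * x + 7), -1.0)
  # affine invariance and symmetry
  y <- c(2, 1, 4, 3, 7, 6)
  expect_equal(correlate(x, y), correlate(y, x))
  expect_equal(correlate(x, y), correlate(3 * x - 5, 0.5 * y + 2))
  expect_warning(r <- correlate(rep(1, 6), y), "constant")
  expect_true(is.na(r))
  expect_warning(correlate(1:2, 2:3), "at least 3")
})

test_that("a planted correlation is recovered within sampling tolerance", {
  withr::local_seed(60)
  n <- 60
  rho <- 0.9
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  r <- correlate(x, y)
  # sampling sd of r at n=60, rho=.9 is ~ (1-rho^2)/sqrt(n-1) ~ 0.025
  expect_lt(abs(r - rho), 0.1)
})
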