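# Group summaries and the exact Mann-Whitney U comparison.
#
# Summaries use the population SD (n denominator): it reproduces the
# reference +/- values for three of the four molar-ratio groupings exactly
# at 4 decimals (the fourth computes to 0.0024 against a printed 0.0023
# under either denominator, a documented discrepancy in the source table).

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; display fields here use
#' conventional half-up rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summary statistics for one measurement group
#'
#' @param values Numeric vector, length >= 1.
#' @param label Group label.
#' @return An object of class `group_summary`: `label`, `n`, `mean` and
#'   `sd_population` (half-up rounded to 4 decimals for reporting),
#'   `mean_raw`, `sd_raw`, and the raw `values`.
#' @export
group_summary <- function(values, label = "") {
  if (length(values) < 1L) stop("empty group", call. = FALSE)
  stopifnot(is.numeric(values), all(is.finite(values)))
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  structure(list(label = label, n = length(values),
                 mean = round_half_up(m, 4),
                 sd_population = round_half_up(s, 4),
                 mean_raw = m, sd_raw = s, values = values),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%-22s n=%2d  %.4f +/- %.4f\n", x$label, x$n, x$mean,
              x$sd_population))
  invisible(x)
}

#' Exact Mann-Whitney U test
#'
#' U statistic with mid-rank ties and an exact two-sided p-value from the
#' full permutation null: every C(nx+ny, nx) assignment of the pooled
#' mid-ranks to group x is weighted equally (computed by dynamic
#' programming over the rank multiset, which enumerates the same
#' distribution without materializing the labelings). The two-sided p is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y Numeric vectors, each of length 1-12 (the exact-enumeration
#'   regime).
#' @return A list: `u` (U for group x), `p_two_sided`, `nx`, `ny`.
#' @examples
#' mann_whitney_u_exact(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.10
#' @export
mann_whitney_u_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("empty group", call. = FALSE)
  if (nx > 12L || ny > 12L) {
    stop("exact enumeration supported for group sizes <= 12", call. = FALSE)
  }
  z <- c(x, y)
  r2 <- as.integer(round(2 * rank(z)))    # doubled mid-ranks are integers
  w_obs2 <- sum(r2[seq_len(nx)])

  # dp[k+1, s+1] = number of size-k subsets of the doubled ranks with sum s
  smax <- sum(r2)
  dp <- matrix(0, nrow = nx + 1L, ncol = smax + 1L)
  dp[1L, 1L] <- 1
  for (r in r2) {
    for (k in nx:1) {
      nz <- which(dp[k, ] > 0)
      if (length(nz)) {
        dp[k + 1L, nz + r] <- dp[k + 1L, nz + r] + dp[k, nz]
      }
    }
  }
  counts <- dp[nx + 1L, ]
  total <- sum(counts)
  sums2 <- seq(0L, smax)
  p_le <- sum(counts[sums2 <= w_obs2]) / total
  p_ge <- sum(counts[sums2 >= w_obs2]) / total
  list(u = (w_obs2 / 2) - nx * (nx + 1) / 2,
       p_two_sided = min(1, 2 * min(p_le, p_ge)),
       nx = nx, ny = ny)
}

#' Reproduce the reference molar-ratio summaries
#'
#' Computes the four overlapping group summaries of the packaged
#' measurement table — volatile anesthetic (groups c+d), intravenous
#' anesthetic (a+b), FIO2 0.3 (a+c), FIO2 1.0 (b+d) — twice: from the dry
#' ratios as printed in the table, and from dry ratios recomputed in-package
#' from each row's own humid ratio and bag conditions. Reports both and the
#' per-row computed-minus-printed differences, plus the Mann-Whitney
#' comparisons across anesthetics and FIO2 levels.
#'
#' @param records Optional measurement table (defaults to the packaged one).
#' @return An object of class `table1_report`.
#' @export
reproduce_table1 <- function(records = table1_fixture()) {
  if (!all(c("r_dry", "r_humid") %in% names(records))) {
    stop("fixture corrupt: r_dry / r_humid columns missing", call. = FALSE)
  }
  proc <- process_table(records)
  groupings <- list(
    isoflurane = c("c", "d"), midazolam_fentanyl = c("a", "b"),
    fio2_0.3 = c("a", "c"), fio2_1.0 = c("b", "d"))
  summarize <- function(col) {
    lapply(names(groupings), function(nm) {
      sel <- proc$group %in% groupings[[nm]]
      group_summary(proc[[col]][sel], nm)
    }) |> stats::setNames(names(groupings))
  }
  printed <- summarize("r_dry")
  recomputed <- summarize("r_dry_computed")
  diffs <- proc$r_dry_computed - proc$r_dry
  tests <- list(
    anesthetic = mann_whitney_u_exact(
      proc$r_dry[proc$group %in% c("c", "d")],
      proc$r_dry[proc$group %in% c("a", "b")]),
    fio2 = mann_whitney_u_exact(
      proc$r_dry[proc$group %in% c("a", "c")],
      proc$r_dry[proc$group %in% c("b", "d")]))
  structure(list(printed = printed, recomputed = recomputed,
                 diff_computed_printed = diffs,
                 max_abs_diff_ab = max(abs(diffs[proc$group %in% c("a", "b")])),
                 max_abs_diff_cd = max(abs(diffs[proc$group %in% c("c", "d")])),
                 qc_pass = proc$qc_pass, tests = tests, table = proc),
            class = "table1_report")
}

#' @export
print.table1_report <- function(x, ...) {
  cat("Molar-ratio group summaries (printed dry column):\n")
  for (s in x$printed) print(s)
  cat("Recomputed in-package from humid ratio + bag conditions:\n")
  for (s in x$recomputed) print(s)
  cat(sprintf("max |computed - printed| dry R: %.2e (groups a/b), %.2e (c/d)\n",
              x$max_abs_diff_ab, x$max_abs_diff_cd))
  cat(sprintf("test-lung QC: %d/%d pass\n", sum(x$qc_pass), length(x$qc_pass)))
  cat(sprintf("Mann-Whitney: anesthetic p=%.3f, FIO2 p=%.3f\n",
              x$tests$anesthetic$p_two_sided, x$tests$fio2$p_two_sided))
  invisible(x)
}
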