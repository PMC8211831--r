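# The molar ratio R of inhalation to exhalation.
#
# R is measured mechanically, not estimated from gas concentrations: exhaled
# gas fills a gasbag for te seconds, then a constant-rate piston pump empties
# it in ti seconds, so VI/VE = te/ti whenever the bag's temperature and
# pressure are equilibrated to ambient during both counts. A gas-exchange-free
# test lung (true R = 1) is run alongside every experiment as QC.

#' Gasbag timing record
#'
#' @param te_s Gas-collection (exhalation) time, seconds, > 0.
#' @param ti_s Pump-out (inhalation) time, seconds, > 0.
#' @param equilibrated Logical: did bag temperature and pressure match
#'   ambient during both counts? Unequilibrated records are dismissed as
#'   technical errors.
#' @return An object of class `bag_timing`.
#' @export
bag_timing <- function(te_s, ti_s, equilibrated = TRUE) {
  stopifnot(is.numeric(te_s), is.numeric(ti_s))
  if (te_s <= 0 || ti_s <= 0) stop("timings must be positive", call. = FALSE)
  structure(list(te_s = te_s, ti_s = ti_s,
                 equilibrated = isTRUE(equilibrated)),
            class = "bag_timing")
}

#' Molar ratio from bag timing
#'
#' `R = VI/VE = te/ti`: the fixed bag volume implies
#' `VI x ti = VE x te`. Valid only if the bag was pressure- and
#' temperature-equilibrated during both counts; otherwise the record is a
#' technical error and is rejected.
#'
#' @param timing A [bag_timing()].
#' @return The dimensionless molar ratio te/ti.
#' @examples
#' ratio_from_timing(bag_timing(606, 600))
#' @export
ratio_from_timing <- function(timing) {
  stopifnot(inherits(timing, "bag_timing"))
  if (!timing$equilibrated) {
    stop("bag not equilibrated: record dismissed as a technical error",
         call. = FALSE)
  }
  timing$te_s / timing$ti_s
}

#' Convert a humid molar ratio to a dry-gas basis
#'
#' The gasbag contains water-saturated exhalation; the inspired gas is dry.
#' The dry-basis ratio is `r_humid * humid_to_dry_factor(psychro)` using the
#' bag's temperature, relative humidity and (ambient-equilibrated) pressure.
#'
#' @param r_humid Molar ratio measured on the humid bag contents.
#' @param psychro [psychro_state()] of the bag gas.
#' @return Dry-basis molar ratio, \eqn{\ge} `r_humid`.
#' @examples
#' dry_ratio(0.97981, psychro_state(22.5, 0.925, 1002)) # 1.00511
#' @export
dry_ratio <- function(r_humid, psychro) {
  r_humid * humid_to_dry_factor(psychro)
}

#' Test-lung quality control
#'
#' A rubber test lung performs no gas exchange, so its true R is 1.0. A
#' measurement passes if `|r - 1| <= tol`; the default band of 0.005 covers
#' the observed day-to-day test-lung spread (0.99643-1.00465) plus the
#' stated +/-0.003 accuracy of the method.
#'
#' @param r_test_lung Measured test-lung ratio.
#' @param tol Pass band half-width.
#' @return Logical.
#' @export
test_lung_qc <- function(r_test_lung, tol = 0.005) {
  stopifnot(r_test_lung > 0)
  abs(r_test_lung - 1) <= tol
}

#' Read a molar-ratio measurement table
#'
#' CSV schema `group,r_test_lung,r_humid,pressure_hpa,temp_c,rh_pct[,r_dry]`.
#' Group labels follow the 2x2 design: `a` midazolam/fentanyl FIO2 0.3,
#' `b` midazolam/fentanyl FIO2 1.0, `c` isoflurane FIO2 0.3, `d` isoflurane
#' FIO2 1.0.
#'
#' @param path CSV path.
#' @return A data.frame of ratio records.
#' @export
read_ratio_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "r_test_lung", "r_humid", "pressure_hpa", "temp_c",
            "rh_pct")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("ratio table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' The packaged reference measurement table
#'
#' The 24-row 2x2 (anesthetic x FIO2) table of test-lung and animal molar
#' ratios with the bag conditions under which each was taken, as printed at
#' 5 decimals.
#'
#' @return A data.frame in the [read_ratio_table()] schema with the printed
#'   dry-ratio column `r_dry`.
#' @export
table1_fixture <- function() {
  read_ratio_table(system.file("extdata", "table1.csv", package = "ventcal",
                               mustWork = TRUE))
}

#' Apply the humid-to-dry correction and QC across a measurement table
#'
#' Adds `r_dry_computed` (the humid ratio times the bag's humid-to-dry
#' factor, reported at 5 decimals like the source table) and `qc_pass` (the
#' test-lung check) to every schema-valid row. Malformed rows are reported
#' by index and skipped; processing continues.
#'
#' @param records A data.frame from [read_ratio_table()].
#' @return The input with `r_dry_computed` and `qc_pass` columns; skipped
#'   row indices in attribute `"bad_rows"`.
#' @export
process_table <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  r_dry_computed <- rep(NA_real_, n)
  qc_pass <- rep(NA, n)
  bad <- integer(0)
  for (i in seq_len(n)) {
    row <- records[i, ]
    ok <- tryCatch({
      psy <- psychro_state(row$temp_c, row$rh_pct / 100, row$pressure_hpa)
      r_dry_computed[i] <- round(dry_ratio(row$r_humid, psy), 5)
      qc_pass[i] <- test_lung_qc(row$r_test_lung)
      TRUE
    }, error = function(e) {
      warning(sprintf("row %d skipped: %s", i, conditionMessage(e)),
              call. = FALSE)
      FALSE
    })
    if (!ok) bad <- c(bad, i)
  }
  records$r_dry_computed <- r_dry_computed
  records$qc_pass <- qc_pass
  attr(records, "bad_rows") <- bad
  records
}

#' Write a processed ratio table
#'
#' Emits the input schema plus `r_dry_computed,qc_pass`.
#'
#' @param records Output of [process_table()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
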