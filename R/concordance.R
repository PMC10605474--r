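# Cross-platform concordance: pairing Southern-blot and optical-mapping
# allele sizes, OLS regression, and relative deviation against long-read
# medians.

#' Pair Southern-blot and optical-mapping allele calls for one patient
#'
#' Each platform reports one (homozygous) or two allele sizes per patient.
#' Under the default `"rankwise"` convention a homozygous single value is
#' duplicated, both sides are sorted ascending and paired rank-wise, giving
#' exactly two (SB, OGM) points per complete record.  Two alternatives are
#' offered for sensitivity analysis: `"collapse_homozygous"` (one averaged
#' point whenever either side is homozygous) and `"average"` (one point per
#' patient, the mean of each side).
#'
#' @param sb Numeric vector of 1 or 2 Southern-blot sizes (repeat units).
#' @param ogm Numeric vector of 1 or 2 optical-mapping sizes (repeat units).
#' @param pairing One of `"rankwise"`, `"collapse_homozygous"`, `"average"`.
#' @return A data.frame with columns `sb` and `ogm` (2 rows under
#'   `"rankwise"` for complete records, 1 or 2 otherwise), or `NULL` with a
#'   warning when either side is missing.
#' @export
pair_alleles <- function(sb, ogm, pairing = c("rankwise",
                                              "collapse_homozygous",
                                              "average")) {
  pairing <- match.arg(pairing)
  sb <- sb[is.finite(sb)]
  ogm <- ogm[is.finite(ogm)]
  if (length(sb) == 0L || length(ogm) == 0L) {
    warn_ogmstr("incomplete_record",
                "record lacks a value on one side; skipped")
    return(NULL)
  }
  if (length(sb) > 2L || length(ogm) > 2L) {
    stop_ogmstr("validation", "at most two alleles per platform expected")
  }
  switch(pairing,
    rankwise = {
      sb2 <- sort(rep_len(sb, 2L))
      ogm2 <- sort(rep_len(ogm, 2L))
      data.frame(sb = sb2, ogm = ogm2)
    },
    collapse_homozygous = {
      if (length(sb) == 1L || length(ogm) == 1L) {
        data.frame(sb = mean(sb), ogm = mean(ogm))
      } else {
        data.frame(sb = sort(sb), ogm = sort(ogm))
      }
    },
    average = data.frame(sb = mean(sb), ogm = mean(ogm))
  )
}

#' Ordinary least squares fit with 95% confidence intervals
#'
#' Fits `y = intercept + slope * x` by OLS (with constant) and reports the
#' coefficient of determination and t-based 95% confidence intervals.
#'
#' @param x,y Numeric vectors of equal length (at least 3 points; `x` must
#'   vary).
#' @return An object of class `regression_result`: list with `slope`,
#'   `intercept`, `slope_ci`, `intercept_ci` (95%), `r_squared`, `n_points`,
#'   and the underlying `stats::lm` fit in `$model`.
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop_ogmstr("insufficient_data",
                "need at least 3 points for regression, got %d", length(x))
  }
  if (stats::var(x) == 0) {
    stop_ogmstr("singular_design", "x is constant; slope is not identifiable")
  }
  fit <- stats::lm(y ~ x)
  # an exactly collinear input is legitimate here; muffle summary.lm's
  # "essentially perfect fit" chatter from inside confint
  ci <- withCallingHandlers(
    stats::confint(fit, level = 0.95),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  # r^2 = 1 - SSres/SStot, computed directly so a constant y gives exactly 0
  # (summary.lm returns numerical noise there)
  sstot <- sum((y - mean(y))^2)
  ssres <- sum(stats::residuals(fit)^2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         slope_ci = unname(ci[2, ]),
         intercept_ci = unname(ci[1, ]),
         r_squared = if (sstot == 0) 0 else 1 - ssres / sstot,
         n_points = length(x),
         model = fit),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d\n", x$n_points))
  cat(sprintf("  slope     %.3f  [%.3f, %.3f] 95%% CI\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %.1f  [%.1f, %.1f] 95%% CI\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  r^2       %.4f\n", x$r_squared))
  invisible(x)
}

#' Relative deviation of a long-read estimate from a method's estimate
#'
#' `|other - reference| / reference`: the deviation of the long-read size
#' from the method under evaluation, normalised by that method's estimate.
#' Returned as a fraction; present as a percentage with
#' round-half-to-even rounding (`round(100 * rd)`).
#'
#' @param reference_est The method's estimate (SB or OGM); must be > 0.
#' @param other_est The long-read estimate.
#' @return Non-negative fraction.
#' @examples
#' relative_deviation(4746, 3363)  # 0.291 -> 29%
#' @export
relative_deviation <- function(reference_est, other_est) {
  if (any(!is.finite(reference_est)) || any(reference_est <= 0)) {
    stop_ogmstr("domain", "reference estimate must be positive")
  }
  abs(other_est - reference_est) / reference_est
}

#' Median and interquartile range of read-level repeat counts
#'
#' Standard median (even counts average the two central values); quartiles
#' by linear interpolation.
#'
#' @param reads Non-empty numeric vector of per-read repeat counts.
#' @return List with `median`, `q1`, `q3`, `iqr`, `n`.
#' @examples
#' lr_median(c(1160, 1224))$median  # 1192
#' @export
lr_median <- function(reads) {
  reads <- as.numeric(reads)
  if (length(reads) == 0L) {
    stop_ogmstr("empty_input", "no reads supplied")
  }
  q <- unname(stats::quantile(reads, c(0.25, 0.5, 0.75), type = 7))
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
       n = length(reads))
}

# --- cohort tables -------------------------------------------------------

#' Read a cohort table of per-patient SB and OGM allele sizes
#'
#' CSV with columns `patient_id`, `sb_allele1`, `sb_allele2`,
#' `sb_homozygous`, `ogm_mean1`, `ogm_sd1`, `ogm_mean2`, `ogm_sd2`,
#' `ogm_homozygous`.  Homozygous calls carry a single size (second column
#' empty) and `TRUE` in the corresponding flag.  Controls without a
#' Southern-blot size leave the SB columns empty.  The packaged file
#' `system.file("extdata", "cohort_sizes.csv", package = "ogmstr")` holds
#' the 17-patient + 2-control validation cohort.
#'
#' @param path CSV path.
#' @return A data.frame, one row per patient.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_ogmstr("io", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "sb_allele1", "sb_allele2", "sb_homozygous",
                "ogm_mean1", "ogm_sd1", "ogm_mean2", "ogm_sd2",
                "ogm_homozygous")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_ogmstr("format", "%s: missing required column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  }
  df
}

cohort_sb <- function(row) {
  v <- suppressWarnings(as.numeric(c(row$sb_allele1, row$sb_allele2)))
  v[is.finite(v)]
}

cohort_ogm <- function(row) {
  v <- suppressWarnings(as.numeric(c(row$ogm_mean1, row$ogm_mean2)))
  v[is.finite(v)]
}

#' Regress optical-mapping sizes on Southern-blot sizes over a cohort
#'
#' Expands every complete record into (SB, OGM) points via [pair_alleles()]
#' and fits OLS of OGM (y) on SB (x).  Records missing either side
#' (e.g. controls without a blot) are excluded with a warning.
#'
#' @param cohort Data.frame from [read_cohort()].
#' @param pairing Pairing convention, see [pair_alleles()].
#' @return A list with `regression` ([ols_fit()] result) and `points`
#'   (the paired data.frame, with `patient_id`).
#' @export
cohort_regression <- function(cohort, pairing = "rankwise") {
  pts <- lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, , drop = FALSE]
    p <- withCallingHandlers(
      pair_alleles(cohort_sb(row), cohort_ogm(row), pairing = pairing),
      ogmstr_incomplete_record = function(w) invokeRestart("muffleWarning")
    )
    if (is.null(p)) return(NULL)
    cbind(patient_id = row$patient_id, p)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) < 3L) {
    stop_ogmstr("insufficient_data",
                "fewer than 3 usable (SB, OGM) points in the cohort")
  }
  list(regression = ols_fit(pts$sb, pts$ogm), points = pts)
}

#' Deviation table of SB and OGM estimates against long-read sizes
#'
#' For each row of a table with per-patient `sb`, `ogm` and `lr` repeat
#' counts, computes `|lr - sb|/sb` and `|lr - ogm|/ogm` as fractions and
#' as nearest-integer percentages (round-half-to-even).
#'
#' @param sizes Data.frame with columns `patient_id`, `sb`, `ogm`, `lr`.
#' @return The input with `dev_sb`, `dev_ogm`, `dev_sb_pct`, `dev_ogm_pct`
#'   appended.
#' @export
deviation_table <- function(sizes) {
  required <- c("patient_id", "sb", "ogm", "lr")
  missing_cols <- setdiff(required, names(sizes))
  if (length(missing_cols) > 0L) {
    stop_ogmstr("format", "deviation table missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  sizes$dev_sb <- relative_deviation(sizes$sb, sizes$lr)
  sizes$dev_ogm <- relative_deviation(sizes$ogm, sizes$lr)
  sizes$dev_sb_pct <- round(100 * sizes$dev_sb)
  sizes$dev_ogm_pct <- round(100 * sizes$dev_ogm)
  sizes
}
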