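# Dose-response summaries and LC50 estimation by the spreadsheet-style
# logarithmic trendline: ordinary least squares of mean survival fraction
# on ln(concentration), solved at 50% survival.

#' Per-concentration survival mean and standard error
#'
#' Vial-level survival fractions are averaged per concentration; the
#' s.e.m. is the sample SD of the unit fractions divided by the square root
#' of the number of units. With `unit = "experiment"` (and an `experiment`
#' column present) vials are first averaged within experiments and the
#' s.e.m. is taken over experiment means.
#'
#' @param data Data frame with columns concentration, survivors, total
#'   (optionally vial, experiment).
#' @param unit `"vial"` (default) or `"experiment"`.
#' @return Data frame with columns concentration, n_units, mean_survival,
#'   sd, sem.
#' @export
summarize_survival <- function(data, unit = c("vial", "experiment")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(data),
            all(c("concentration", "survivors", "total") %in% names(data)))
  if (nrow(data) == 0) stop("no dose-response observations")
  if (any(data$total < 1)) stop("every vial must contain at least 1 larva")
  if (any(data$survivors < 0 | data$survivors > data$total))
    stop("survivors must lie in [0, total]")
  frac <- data$survivors / data$total
  if (unit == "experiment") {
    if (!"experiment" %in% names(data))
      stop("unit='experiment' needs an 'experiment' column")
    by_exp <- aggregate(frac,
                        by = list(concentration = data$concentration,
                                  experiment = data$experiment),
                        FUN = mean)
    conc <- by_exp$concentration
    frac <- by_exp$x
  } else {
    conc <- data$concentration
  }
  agg <- lapply(split(frac, conc), function(f)
    c(n = length(f), mean = mean(f), sd = if (length(f) > 1) sd(f) else 0))
  out <- data.frame(concentration = as.numeric(names(agg)),
                    n_units = vapply(agg, `[[`, numeric(1), "n"),
                    mean_survival = vapply(agg, `[[`, numeric(1), "mean"),
                    sd = vapply(agg, `[[`, numeric(1), "sd"),
                    row.names = NULL)
  out$sem <- out$sd / sqrt(out$n_units)
  out[order(out$concentration), , drop = FALSE]
}

#' Fit the logarithmic trendline and estimate the LC50
#'
#' Ordinary least squares of per-concentration mean survival fraction on
#' `ln(C)`, excluding the zero concentration; the LC50 solves the fitted
#' line at 0.5: `LC50 = exp((0.5 - intercept) / slope)`. Zero-concentration
#' vials feed a quality-control gate: if their mean survival is below
#' `qc_threshold` the fit is flagged (with a warning) but still returned.
#'
#' @param data Vial-level data frame as in [summarize_survival()].
#' @param unit Aggregation unit passed to [summarize_survival()].
#' @param qc_threshold Minimum acceptable zero-concentration survival
#'   fraction (default 0.8).
#' @return An object of class `lc50_fit`: list with `slope`, `intercept`,
#'   `lc50`, `summary` (the per-concentration table) and `qc_pass`.
#' @examples
#' dr <- simulate_dose_response(2, c(0, 0.25, 0.5, 1, 2, 4, 8, 16),
#'                              seed = 1)
#' fit_log_trend(dr)
#' @export
fit_log_trend <- function(data, unit = "vial", qc_threshold = 0.8) {
  s <- summarize_survival(data, unit)
  pos <- s[s$concentration > 0, , drop = FALSE]
  if (nrow(pos) < 2)
    stop("need at least 2 distinct positive concentrations")
  fit <- lm(mean_survival ~ log(concentration), data = pos)
  b <- unname(coef(fit)[1])
  a <- unname(coef(fit)[2])
  if (!is.finite(a) || a >= 0) stop("non-monotone dose response")
  lc50 <- exp((0.5 - b) / a)
  if (lc50 < min(pos$concentration) / 10 ||
      lc50 > max(pos$concentration) * 10)
    stop("fitted LC50 falls outside the tested concentration range")
  qc_pass <- TRUE
  zero <- s$mean_survival[s$concentration == 0]
  if (length(zero) == 1 && zero < qc_threshold) {
    qc_pass <- FALSE
    warning(sprintf(
      "zero-concentration survival %.2f is below the %.2f QC gate",
      zero, qc_threshold))
  }
  structure(list(slope = a, intercept = b, lc50 = lc50, summary = s,
                 qc_pass = qc_pass),
            class = "lc50_fit")
}

#' @export
print.lc50_fit <- function(x, ...) {
  cat(sprintf("Log-trendline LC50 fit\n  survival = %.4f * ln(C) + %.4f\n",
              x$slope, x$intercept))
  cat(sprintf("  LC50 = %.4g  (QC %s)\n", x$lc50,
              if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

#' Resistance ratio between two LC50 estimates
#'
#' @param lc50_a,lc50_b Positive LC50 values; the ratio is `lc50_a /
#'   lc50_b` (resistant over sensitive), conventionally reported to one
#'   decimal place.
#' @return The ratio at full precision.
#' @examples
#' round(resistance_ratio(2.16, 0.028), 1)  # 77.1
#' @export
resistance_ratio <- function(lc50_a, lc50_b) {
  if (any(lc50_a <= 0) || any(lc50_b <= 0))
    stop("LC50 values must be > 0")
  lc50_a / lc50_b
}
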