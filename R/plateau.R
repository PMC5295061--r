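# Steady-state (plateau) identification on infusion time courses.
#
# The default rule mirrors standard primed-continuous practice: the mean of
# the last three hourly samples for the leucine/KIC phase, and the single
# sample at the end of the bicarbonate phase (2 h) for CO2. A slope-test
# detector is available as a stricter optional mode.

new_plateau_summary <- function(values, times, n_points, fallback = FALSE) {
  m <- mean(values)
  s <- if (n_points > 1) sd(values) else 0
  structure(
    list(window = times, n_points = n_points, mean = m,
         cv_percent = if (m != 0) 100 * s / abs(m) else 0,
         sd = s, fallback = fallback),
    class = "plateau_summary")
}

#' @export
print.plateau_summary <- function(x, ...) {
  cat(sprintf("plateau: mean %.6g over %d point(s) [%s h], CV %.2f%%%s\n",
              x$mean, x$n_points, paste(x$window, collapse = ", "),
              x$cv_percent, if (isTRUE(x$fallback)) " (fallback)" else ""))
  invisible(x)
}

#' Plateau summary over the final k samples
#'
#' Summarizes the last `k` points of a time-ordered series by their
#' arithmetic mean, the convention for primed-continuous infusions sampled
#' hourly (`k = 3` for the leucine/KIC phase).
#'
#' @param values Numeric series, ordered by time.
#' @param k Number of trailing points (>= 2).
#' @param times Optional sampling times (h); defaults to the series index.
#' @return A `plateau_summary`: window, `n_points`, `mean`, `cv_percent`.
#' @export
last_k_plateau <- function(values, k = 3, times = seq_along(values)) {
  if (k < 2) leuflux_abort("k must be at least 2", "format")
  keep <- !is.na(values)
  values <- values[keep]
  times <- times[keep]
  if (length(values) < k) {
    leuflux_abort(sprintf("series has %d point(s), need %d", length(values), k),
                  "insufficient_data")
  }
  idx <- seq(length(values) - k + 1, length(values))
  new_plateau_summary(values[idx], times[idx], k)
}

#' Slope-test plateau detection
#'
#' Returns the longest trailing window whose least-squares slope does not
#' differ from zero at level `alpha` and whose coefficient of variation is at
#' most `cv_max` percent. When no window qualifies (e.g. a still-rising
#' series) the last-`min_window` summary is returned with a warning and
#' `fallback = TRUE`.
#'
#' @inheritParams last_k_plateau
#' @param alpha Significance level for the zero-slope test (default 0.05).
#' @param min_window Minimum window length (default 3).
#' @param cv_max Maximum plateau CV in percent (default 15).
#' @return A `plateau_summary`.
#' @export
detect_plateau <- function(values, times = seq_along(values), alpha = 0.05,
                           min_window = 3, cv_max = 15) {
  keep <- !is.na(values)
  values <- values[keep]
  times <- times[keep]
  n <- length(values)
  if (n == 0) leuflux_abort("series is all missing", "insufficient_data")
  if (n < min_window) {
    leuflux_abort(sprintf("series has %d point(s), need %d", n, min_window),
                  "insufficient_data")
  }
  for (start in seq_len(n - min_window + 1)) {
    idx <- start:n
    v <- values[idx]
    t <- times[idx]
    m <- mean(v)
    cv <- if (m != 0) 100 * sd(v) / abs(m) else 0
    if (cv > cv_max) next
    if (sd(v) == 0) {                      # exactly flat: slope exactly 0
      return(new_plateau_summary(v, t, length(v)))
    }
    fit <- lm(v ~ t)
    # a perfectly linear (non-flat) window makes summary.lm grumble about a
    # perfect fit; its slope p-value is ~0 and the window is rightly rejected
    p_slope <- suppressWarnings(summary(fit)$coefficients[2, 4])
    if (!is.na(p_slope) && p_slope > alpha) {
      return(new_plateau_summary(v, t, length(v)))
    }
  }
  leuflux_warn("no trailing window passes the zero-slope test; falling back to the final points",
               "plateau_fallback")
  out <- last_k_plateau(values, k = min_window, times = times)
  out$fallback <- TRUE
  out
}

#' Single fixed-time-point summary
#'
#' Used for the bicarbonate phase, where the steady state is taken from the
#' sample at a designated time (2 h by default in the study design). The only
#' summary for which `n_points = 1` is permitted.
#'
#' @inheritParams last_k_plateau
#' @param time_h Sampling time (h) at which the value is taken.
#' @return A `plateau_summary` with `n_points = 1`.
#' @export
fixed_timepoint_summary <- function(values, times, time_h) {
  hit <- which(!is.na(values) & times == time_h)
  if (length(hit) == 0) {
    leuflux_abort(sprintf("no sample at time %g h", time_h), "missing_sample")
  }
  new_plateau_summary(values[hit[1]], times[hit[1]], 1L)
}

#' Steady-state summaries for a whole sample table
#'
#' Applies the plateau rule per animal, site and analyte: last-`k` mean for
#' leucine, KIC and PAH, fixed time point (`co2_time`) for CO2. Returns one
#' row per cell with the plateau mean concentration (umol/L; PAH mg/L) and
#' mean fractional enrichment. Missing intermediate samples are tolerated;
#' windows are defined over available points.
#'
#' @param samples Sample table; passed through [normalize_units()].
#' @param rule `"last_k"` (default) or `"detect"` ([detect_plateau()]).
#' @param k Trailing window length for the last-`k` rule (default 3).
#' @param co2_time Time (h) of the CO2 steady-state sample (default 2, the
#'   end of the bicarbonate infusion).
#' @param ... Passed to [detect_plateau()] when `rule = "detect"`.
#' @return data.frame with columns `animal_id`, `group` (if present),
#'   `site`, `analyte`, `mean_concentration`, `mean_enrichment` (fraction),
#'   `cv_conc_percent`, `cv_enrich_percent`, `n_points`, `window_start`,
#'   `window_end`.
#' @export
summarize_steady_state <- function(samples, rule = c("last_k", "detect"),
                                   k = 3, co2_time = 2, ...) {
  rule <- match.arg(rule)
  samples <- normalize_units(samples)
  dt <- data.table::as.data.table(samples)
  data.table::setorderv(dt, "time_h")
  has_group <- !is.null(dt$group)
  by_cols <- c("animal_id", if (has_group) "group", "site", "analyte")

  summarize_cell <- function(conc, mpe_frac, time_h, analyte) {
    pick <- function(values) {
      if (analyte[1] == "CO2") {
        fixed_timepoint_summary(values, time_h, co2_time)
      } else if (rule == "detect") {
        detect_plateau(values, times = time_h, min_window = min(k, sum(!is.na(values))), ...)
      } else {
        last_k_plateau(values, k = k, times = time_h)
      }
    }
    sc <- tryCatch(pick(conc), leuflux_error = function(e) NULL)
    if (is.null(sc)) {
      # insufficient data in this cell: emit NAs, downstream reports the gap
      return(list(mean_concentration = NA_real_, mean_enrichment = NA_real_,
                  cv_conc_percent = NA_real_, cv_enrich_percent = NA_real_,
                  n_points = 0L, window_start = NA_real_, window_end = NA_real_))
    }
    has_enrich <- any(!is.na(mpe_frac))
    se <- if (has_enrich) pick(mpe_frac) else NULL
    list(mean_concentration = sc$mean,
         mean_enrichment = if (has_enrich) se$mean else NA_real_,
         cv_conc_percent = sc$cv_percent,
         cv_enrich_percent = if (has_enrich) se$cv_percent else NA_real_,
         n_points = as.integer(sc$n_points),
         window_start = as.numeric(min(sc$window)),
         window_end = as.numeric(max(sc$window)))
  }

  out <- dt[, summarize_cell(concentration, enrichment_frac, time_h, analyte),
            by = by_cols]
  as.data.frame(out)
}
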