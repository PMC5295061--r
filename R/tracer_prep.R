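# Conversion of raw measurements to canonical units and enrichments.
#
# Isotopic enrichment arrives either as an ion-intensity ratio (M+1/M, e.g.
# m/z 303/302 for AQC-leucine, 130/129 for KIC) or directly as mole percent
# excess. Canonical internal units are umol/L for concentrations (PAH stays
# in mg/L, it never mixes with the amino-acid pools), fractional enrichment,
# and hours.

#' Background-corrected tracer-to-tracee ratio
#'
#' Subtracts the background (baseline, pre-infusion) ion ratio from a sample
#' ion ratio to give the tracer-to-tracee ratio (TTR). Measurement noise near
#' natural abundance routinely produces small negative excesses; by default
#' these are clamped to zero and flagged rather than treated as errors.
#'
#' @param ratio_sample Numeric vector of sample M+1/M ion-intensity ratios.
#' @param ratio_background Background ratio(s), recycled against
#'   `ratio_sample`.
#' @param negative_policy `"clamp"` (default) sets negative excesses to 0 and
#'   flags them; `"error"` raises an invalid-measurement error.
#' @return Numeric vector of TTRs with a logical attribute `"clamped"`
#'   marking values that were negative before clamping.
#' @examples
#' compute_ttr(0.10, 0.07)   # 0.03
#' @export
compute_ttr <- function(ratio_sample, ratio_background,
                        negative_policy = c("clamp", "error")) {
  negative_policy <- match.arg(negative_policy)
  check_numeric(ratio_sample, "ratio_sample", lower = 0)
  check_numeric(ratio_background, "ratio_background", lower = 0)
  ttr <- ratio_sample - ratio_background
  neg <- !is.na(ttr) & ttr < 0
  if (any(neg)) {
    if (negative_policy == "error") {
      leuflux_abort("background exceeds sample ion ratio", "invalid_measurement")
    }
    leuflux_warn(sprintf("%d negative excess ratio(s) clamped to 0", sum(neg)),
                 "clamped_ttr")
    ttr[neg] <- 0
  }
  structure(ttr, clamped = neg)
}

#' Mole percent excess from a tracer-to-tracee ratio
#'
#' `MPE = 100 * TTR / (1 + TTR)`: the percentage of the analyte pool carrying
#' the label above background. Strictly below 100 and monotone in TTR.
#'
#' @param ttr Numeric vector of tracer-to-tracee ratios (>= 0).
#' @return Mole percent excess, in percent.
#' @seealso [ttr_from_mpe()] for the inverse.
#' @export
mpe_from_ttr <- function(ttr) {
  check_numeric(ttr, "ttr", lower = 0, allow_na = TRUE)
  100 * ttr / (1 + ttr)
}

#' @rdname mpe_from_ttr
#' @param mpe Mole percent excess in `[0, 100)`.
#' @export
ttr_from_mpe <- function(mpe) {
  check_numeric(mpe, "mpe", lower = 0, allow_na = TRUE)
  if (any(mpe >= 100, na.rm = TRUE)) {
    leuflux_abort("MPE must be below 100", "invalid_measurement")
  }
  mpe / (100 - mpe)
}

# Recognized concentration unit spellings, canonicalized.
.conc_units <- c(
  "umol/l" = "umol/L", "µmol/l" = "umol/L", "umol/L" = "umol/L",
  "mmol/l" = "mmol/L", "mg/l" = "mg/L"
)

#' Normalize a sample table to canonical units
#'
#' Converts concentrations to umol/L (mmol/L values are scaled by 1000; PAH
#' is kept in mg/L, its only role being indicator dilution) and derives the
#' fractional enrichment column `enrichment_frac = enrichment_mpe / 100`.
#' Idempotent: applying twice equals applying once.
#'
#' @param samples Sample table (data.frame) with at least `analyte` and
#'   `concentration` columns; `conc_unit` defaults to umol/L when absent.
#' @return The table with canonical `concentration`/`conc_unit` and an
#'   `enrichment_frac` column.
#' @export
normalize_units <- function(samples) {
  samples <- validate_samples(samples)
  unit <- if (is.null(samples$conc_unit)) rep("umol/L", nrow(samples)) else as.character(samples$conc_unit)
  unit[is.na(unit) | unit == ""] <- "umol/L"
  canon <- .conc_units[tolower(unit)]
  if (anyNA(canon)) {
    leuflux_abort(sprintf("unknown concentration unit(s): %s",
                          paste(unique(unit[is.na(canon)]), collapse = ", ")),
                  "format")
  }
  is_mmol <- canon == "mmol/L"
  samples$concentration[is_mmol] <- samples$concentration[is_mmol] * 1000
  canon[is_mmol] <- "umol/L"
  if (any(canon == "mg/L" & samples$analyte != "PAH")) {
    leuflux_abort("mg/L concentrations are only accepted for PAH", "format")
  }
  samples$conc_unit <- unname(canon)
  if (!is.null(samples$enrichment_mpe)) {
    samples$enrichment_frac <- samples$enrichment_mpe / 100
  } else {
    samples$enrichment_frac <- NA_real_
  }
  samples
}

#' Validate and canonicalize a sample table
#'
#' Checks the long-format sample schema (one row per animal, site, time and
#' analyte), canonicalizes the `site`, `analyte` and `group` enums
#' case-insensitively, and enforces the basic invariants (`time_h >= 0`,
#' `concentration >= 0`, MPE in `[0, 100)`). Unknown columns are preserved.
#'
#' @param samples data.frame in the sample-table dialect.
#' @return The validated table.
#' @export
validate_samples <- function(samples) {
  required <- c("animal_id", "site", "time_h", "analyte", "concentration")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    leuflux_abort(sprintf("sample table is missing column(s): %s",
                          paste(missing, collapse = ", ")), "schema")
  }
  samples$site <- canonical_enum(as.character(samples$site), .sites, "site")
  samples$analyte <- canonical_enum(as.character(samples$analyte), .analytes, "analyte")
  if (!is.null(samples$group)) {
    samples$group <- canonical_enum(as.character(samples$group), .groups, "group")
  }
  check_numeric(samples$time_h, "time_h", lower = 0)
  check_numeric(samples$concentration, "concentration", lower = 0, allow_na = TRUE)
  if (!is.null(samples$enrichment_mpe)) {
    check_numeric(samples$enrichment_mpe, "enrichment_mpe", lower = 0, allow_na = TRUE)
    if (any(samples$enrichment_mpe >= 100, na.rm = TRUE)) {
      leuflux_abort("enrichment_mpe must be below 100", "invalid_measurement")
    }
  }
  samples
}

#' Derive enrichments from raw ion ratios
#'
#' Fills missing `enrichment_mpe` values from the `ion_ratio` column by
#' background-correcting against the baseline (default `time_h == 0`) ion
#' ratio of the same animal, site and analyte, then converting TTR to MPE.
#' Rows that already carry an MPE are left untouched.
#'
#' @param samples Validated sample table containing an `ion_ratio` column.
#' @param background_time Time (h) of the background sample; default 0
#'   (pre-infusion baseline).
#' @inheritParams compute_ttr
#' @return The table with `enrichment_mpe` completed.
#' @export
derive_enrichment <- function(samples, background_time = 0,
                              negative_policy = c("clamp", "error")) {
  negative_policy <- match.arg(negative_policy)
  samples <- validate_samples(samples)
  if (is.null(samples$ion_ratio)) {
    leuflux_abort("sample table has no ion_ratio column", "schema")
  }
  if (is.null(samples$enrichment_mpe)) samples$enrichment_mpe <- NA_real_
  dt <- data.table::as.data.table(samples)
  key_cols <- c("animal_id", "site", "analyte")
  bg <- dt[dt$time_h == background_time & !is.na(dt$ion_ratio),
           list(.bg_ratio = mean(ion_ratio)), by = key_cols]
  dt <- merge(dt, bg, by = key_cols, all.x = TRUE, sort = FALSE)
  todo <- is.na(dt$enrichment_mpe) & !is.na(dt$ion_ratio) & dt$analyte != "PAH"
  if (any(todo & is.na(dt$.bg_ratio))) {
    leuflux_abort("no baseline ion ratio available for some animal/site/analyte",
                  "incomplete_input")
  }
  if (any(todo)) {
    ttr <- compute_ttr(dt$ion_ratio[todo], dt$.bg_ratio[todo],
                       negative_policy = negative_policy)
    dt$enrichment_mpe[todo] <- mpe_from_ttr(as.numeric(ttr))
  }
  dt$.bg_ratio <- NULL
  as.data.frame(dt)
}
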