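# Internal helpers: classed conditions and enum handling.

.datatable.aware <- TRUE

leuflux_abort <- function(msg, type, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("leuflux_", type), "leuflux_error")))
}

leuflux_warn <- function(msg, type) {
  warning(warningCondition(msg, class = c(paste0("leuflux_", type), "leuflux_warning")))
}

.sites <- c("artery", "vein")
.analytes <- c("leucine", "KIC", "CO2", "PAH")
.groups <- c("control", "treatment")

# Case-insensitive canonicalization of an enum column; unknown values rejected.
canonical_enum <- function(x, levels, what) {
  idx <- match(tolower(x), tolower(levels))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    leuflux_abort(
      sprintf("unknown %s value(s): %s (expected one of %s)",
              what, paste(bad, collapse = ", "), paste(levels, collapse = ", ")),
      "format")
  }
  levels[idx]
}

check_numeric <- function(x, what, lower = -Inf, allow_na = FALSE) {
  if (!is.numeric(x)) leuflux_abort(sprintf("%s must be numeric", what), "format")
  bad <- !is.na(x) & x < lower
  if (any(bad)) {
    leuflux_abort(sprintf("%s contains values below %g", what, lower),
                  "invalid_measurement")
  }
  if (!allow_na && anyNA(x)) {
    leuflux_abort(sprintf("%s contains missing values", what), "format")
  }
  invisible(x)
}
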