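# Readers/writers for the CSV exchange dialect and the pipeline driver.

#' Read or write a long-format sample table
#'
#' CSV (RFC-4180) with header columns `animal_id, group, site, time_h,
#' analyte, concentration, conc_unit, enrichment_mpe, ion_ratio` (`group`,
#' `conc_unit`, `enrichment_mpe` and `ion_ratio` optional; unknown columns
#' preserved). Enum columns are canonicalized case-insensitively; unknown
#' enum values and non-numeric fields are rejected with the offending
#' column named.
#'
#' @param path CSV file path.
#' @return [read_samples()] returns the validated sample table.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) leuflux_abort(sprintf("no such file: %s", path), "io")
  raw <- read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("time_h", "concentration", "enrichment_mpe", "ion_ratio"),
                        names(raw))) {
    if (!is.numeric(raw[[col]])) {
      suppressWarnings(num <- as.numeric(raw[[col]]))
      bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(num))
      if (length(bad) > 0) {
        leuflux_abort(sprintf("non-numeric value in column %s (data row %s)",
                              col, paste(utils::head(bad, 5), collapse = ", ")),
                      "format")
      }
      raw[[col]] <- num
    }
  }
  validate_samples(raw)
}

#' @rdname read_samples
#' @param samples Sample table to write.
#' @export
write_samples <- function(samples, path) {
  write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' Read an animal metadata table
#'
#' CSV with columns `animal_id`, `group`, `body_weight_kg`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_animals <- function(path) {
  if (!file.exists(path)) leuflux_abort(sprintf("no such file: %s", path), "io")
  out <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("animal_id", "body_weight_kg"), names(out))
  if (length(missing) > 0) {
    leuflux_abort(sprintf("animals table is missing column(s): %s",
                          paste(missing, collapse = ", ")), "schema")
  }
  check_numeric(out$body_weight_kg, "body_weight_kg", lower = 1e-9)
  if (!is.null(out$group)) {
    out$group <- canonical_enum(as.character(out$group), .groups, "group")
  }
  out
}

#' Run the full analysis pipeline
#'
#' Binds the stages together: unit normalization and (if raw ion ratios are
#' present) enrichment derivation, plateau summarization, per-animal plasma
#' flow, the tracer-balance kinetic panel, and group statistics (comparison
#' report and correlation matrix of the tracer fluxes and protein turnover,
#' when two groups with >= 3 animals each are present). Intermediates are
#' returned and, when `out_dir` is given, persisted as CSV.
#'
#' @param samples Sample table (data.frame) or path to a sample CSV.
#' @param animals Animal metadata (data.frame) or path to a CSV with
#'   `animal_id`, `group`, `body_weight_kg`.
#' @param protocol [infusion_protocol()] or path to a protocol JSON/YAML.
#' @param out_dir Optional output directory for CSV reports.
#' @inheritParams analyze_cohort
#' @param t_variant t-test variant for the group report.
#' @return List: `kinetics` (per-animal panel), `steady_states`,
#'   `group_stats`, `correlations`, `options`.
#' @export
run_pipeline <- function(samples, animals, protocol = infusion_protocol(),
                         out_dir = NULL,
                         precursor = c("venous_kic", "arterial_leucine"),
                         recovery = 1, rule = c("last_k", "detect"), k = 3,
                         co2_time = 2, t_variant = c("pooled", "welch")) {
  precursor <- match.arg(precursor)
  rule <- match.arg(rule)
  t_variant <- match.arg(t_variant)
  if (is.character(samples)) samples <- read_samples(samples)
  if (is.character(animals)) animals <- read_animals(animals)
  if (is.character(protocol)) protocol <- read_protocol(protocol)
  samples <- validate_samples(samples)
  if (!is.null(samples$ion_ratio) && any(!is.na(samples$ion_ratio)) &&
      (is.null(samples$enrichment_mpe) || anyNA(samples$enrichment_mpe))) {
    samples <- derive_enrichment(samples)
  }
  ss <- summarize_steady_state(samples, rule = rule, k = k, co2_time = co2_time)
  kin <- analyze_cohort(samples, animals, protocol, precursor = precursor,
                        recovery = recovery, rule = rule, k = k,
                        co2_time = co2_time)
  stats_tbl <- NULL
  cors <- NULL
  if (!is.null(kin$group)) {
    tab <- table(kin$group)
    if (length(tab) == 2 && all(tab >= 2)) {
      stats_tbl <- group_report(kin, variant = t_variant)
    }
    if (nrow(kin) >= 3) {
      cor_vars <- intersect(c("leu13_uptake", "kic13_production",
                              "protein_synthesis", "protein_degradation",
                              "protein_deposition"), names(kin))
      cors <- tryCatch(pearson_matrix(kin[, cor_vars, drop = FALSE]),
                       leuflux_error = function(e) NULL)
    }
  }
  out <- list(kinetics = kin, steady_states = ss, group_stats = stats_tbl,
              correlations = cors,
              options = attr(kin, "options"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(kin, file.path(out_dir, "kinetics.csv"), row.names = FALSE)
    write.csv(ss, file.path(out_dir, "steady_states.csv"), row.names = FALSE)
    if (!is.null(stats_tbl)) {
      write.csv(stats_tbl, file.path(out_dir, "group_stats.csv"), row.names = FALSE)
    }
    if (!is.null(cors)) {
      r_annot <- matrix(paste0(format(round(cors$r, 2)), cors$stars),
                        nrow(cors$r), dimnames = dimnames(cors$r))
      write.csv(r_annot, file.path(out_dir, "correlations.csv"))
    }
    meta <- c(list(package_version = as.character(utils::packageVersion("leuflux"))),
              out$options)
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
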