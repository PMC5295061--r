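# Group statistics: two-sample t-tests, pooled SEM, Pearson correlations.
#
# "Pooled SEM" follows the animal-science table convention of the pooled
# standard error of the difference, sqrt(sp^2 (1/n_a + 1/n_b)) with sp^2 the
# pooled within-group variance: printed group means divided by it reproduce
# the tabulated t/p values. The per-group pooled SE sqrt(sp^2/n) is also
# reported.

#' Two-sample Student's t-test
#'
#' Pooled-variance Student's t by default (Welch available), two-tailed.
#' Degenerate inputs: two zero-variance samples with equal means give
#' `t = 0, p = 1`; with unequal means the comparison is flagged degenerate
#' (`p = 0`, infinite `t`).
#'
#' @param values_a,values_b Numeric samples (n >= 2 each).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A `group_comparison` list: `mean_a`, `mean_b`, `pooled_sem` (SE of
#'   the difference), `sem_per_group`, `t_stat`, `df`, `p_value`,
#'   `degenerate`.
#' @export
students_t <- function(values_a, values_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  na <- length(values_a); nb <- length(values_b)
  if (na < 2 || nb < 2) leuflux_abort("each group needs at least 2 values", "format")
  ma <- mean(values_a); mb <- mean(values_b)
  va <- var(values_a); vb <- var(values_b)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  sem_diff <- sqrt(sp2 * (1 / na + 1 / nb))
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      t_stat <- 0; df <- na + nb - 2; p <- 1
    } else {
      degenerate <- TRUE
      t_stat <- sign(mb - ma) * Inf; df <- na + nb - 2; p <- 0
      leuflux_warn("zero variance in both groups with unequal means", "degenerate_sample")
    }
  } else if (variant == "pooled") {
    t_stat <- (mb - ma) / sem_diff
    df <- na + nb - 2
    p <- 2 * pt(-abs(t_stat), df)
  } else {
    se <- sqrt(va / na + vb / nb)
    t_stat <- (mb - ma) / se
    df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * pt(-abs(t_stat), df)
  }
  structure(list(mean_a = ma, mean_b = mb, n_a = na, n_b = nb,
                 pooled_sem = sem_diff, sem_per_group = sqrt(sp2 / ((na + nb) / 2)),
                 t_stat = t_stat, df = df, p_value = p,
                 variant = variant, degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%.4g vs %.4g (pooled SEM %.4g): t = %.3f, df = %.3g, p = %.4g%s\n",
              x$mean_a, x$mean_b, x$pooled_sem, x$t_stat, x$df, x$p_value,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' t-test from published summary statistics
#'
#' For group summaries reported as mean +/- SEM with group sizes:
#' `t = (mean_b - mean_a) / sqrt(sem_a^2 + sem_b^2)`, `df = n_a + n_b - 2`,
#' two-tailed p. Equals [students_t()] exactly when the SEMs come from the
#' raw samples.
#'
#' @param mean_a,sem_a,n_a First group mean, SEM and size.
#' @param mean_b,sem_b,n_b Second group mean, SEM and size.
#' @return A `group_comparison`.
#' @export
t_from_summary <- function(mean_a, sem_a, n_a, mean_b, sem_b, n_b) {
  if (any(c(sem_a, sem_b) <= 0)) leuflux_abort("SEMs must be positive", "format")
  if (any(c(n_a, n_b) < 2)) leuflux_abort("group sizes must be at least 2", "format")
  se_diff <- sqrt(sem_a^2 + sem_b^2)
  t_stat <- (mean_b - mean_a) / se_diff
  df <- n_a + n_b - 2
  p <- 2 * pt(-abs(t_stat), df)
  sp2 <- ((n_a - 1) * sem_a^2 * n_a + (n_b - 1) * sem_b^2 * n_b) / (n_a + n_b - 2)
  structure(list(mean_a = mean_a, mean_b = mean_b, n_a = n_a, n_b = n_b,
                 pooled_sem = sqrt(sp2 * (1 / n_a + 1 / n_b)),
                 sem_per_group = sqrt(sp2 / ((n_a + n_b) / 2)),
                 t_stat = t_stat, df = df, p_value = p,
                 variant = "summary", degenerate = FALSE),
            class = "group_comparison")
}

#' Pearson correlation matrix with significance
#'
#' Pairwise Pearson r with two-tailed p-values from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`, plus significance stars
#' (`*` p < 0.05, `**` p < 0.01) as conventionally annotated in
#' correlation tables.
#'
#' @param table data.frame of per-animal variables (>= 3 rows, no constant
#'   column).
#' @return A `correlation_matrix` list: `r`, `p`, `stars`, `n`.
#' @export
pearson_matrix <- function(table) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  table <- table[, num, drop = FALSE]
  n <- nrow(table)
  if (n < 3) leuflux_abort("need at least 3 animals for correlations", "format")
  sds <- vapply(table, sd, numeric(1))
  if (any(sds == 0)) {
    leuflux_abort(sprintf("constant column(s): %s",
                          paste(names(table)[sds == 0], collapse = ", ")),
                  "undefined_correlation")
  }
  r <- stats::cor(table)
  # exact unit diagonal and symmetry regardless of float noise
  r <- (r + t(r)) / 2
  diag(r) <- 1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), n - 2)
  diag(p) <- NA
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, stars = stars, n = n, variables = colnames(r)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  shown <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
                  nrow(x$r), dimnames = dimnames(x$r))
  shown[lower.tri(shown)] <- ""
  print(shown, quote = FALSE)
  cat(sprintf("n = %d; * p < 0.05, ** p < 0.01\n", x$n))
  invisible(x)
}

#' Group comparison report for a kinetics table
#'
#' Mirrors the layout of tracer-study summary tables: one row per variable
#' with the two group means, the pooled SEM (SE of the difference) and the
#' two-tailed pooled-t p-value.
#'
#' @param kinetics Per-animal table with a `group` column (two levels).
#' @param variables Columns to compare; defaults to the flux panel plus
#'   tracer fluxes and partition fractions present in the table.
#' @param variant Passed to [students_t()].
#' @return data.frame: `variable`, `mean_<group1>`, `mean_<group2>`,
#'   `pooled_sem`, `t_stat`, `df`, `p_value`.
#' @export
group_report <- function(kinetics, variables = NULL,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (is.null(kinetics$group)) leuflux_abort("kinetics table has no group column", "schema")
  groups <- sort(unique(as.character(kinetics$group)))
  if (length(groups) != 2) {
    leuflux_abort("group report requires exactly two groups", "format")
  }
  if (is.null(variables)) {
    panel <- c("arterial_input", "net_uptake", "utilization", "net_transamination",
               "oxidation", "protein_synthesis", "protein_degradation",
               "protein_deposition", "leu13_uptake", "kic13_production",
               "utilization_of_input", "synthesis_of_utilization",
               "transamination_of_utilization", "oxidation_of_utilization")
    variables <- intersect(panel, names(kinetics))
  }
  rows <- lapply(variables, function(v) {
    a <- kinetics[[v]][kinetics$group == groups[1]]
    b <- kinetics[[v]][kinetics$group == groups[2]]
    cmp <- students_t(a, b, variant = variant)
    data.frame(variable = v, mean_a = cmp$mean_a, mean_b = cmp$mean_b,
               pooled_sem = cmp$pooled_sem, t_stat = cmp$t_stat, df = cmp$df,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", groups[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", groups[2])
  out
}
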