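# Orchestration: read -> instrument -> harmonize -> strength -> estimate ->
# scale -> concordance report, as a configured, logged, reproducible run.

#' Analysis run configuration
#'
#' Collects every setting of an end-to-end run. `exposure`, each entry of
#' `outcomes` and `ld` may be file paths (read with [read_summary_stats()]
#' / [read_ld_matrix()]) or objects already in memory.
#'
#' @param exposure exposure summary statistics (path or tibble).
#' @param outcomes named list of outcome summary statistics (path or
#'   tibble); names label the outcomes in the report.
#' @param ld signed LD matrix covering the instrument SNPs (path or
#'   matrix).
#' @param dose exposure increment for odds-ratio scaling, native units.
#' @param exposure_sd native-unit SD of the exposure; required, no default.
#' @param p_threshold genome-wide significance threshold.
#' @param replicated_only restrict the instrument to replicated SNPs.
#' @param replication_pvalues optional named replication p-values.
#' @param ld_thresholds LD-pruning thresholds for the strength range.
#' @param palindrome_policy see [harmonize()].
#' @param trial_estimates optional tibble of externally supplied trial
#'   results for side-by-side display: columns `outcome`, `label`,
#'   `estimate`, `ci_low`, `ci_high`. Display-only, never computed.
#' @param column_map passed to [read_summary_stats()].
#' @param seed seed for any stochastic subcommand (the analysis itself is
#'   deterministic).
#' @param output_dir directory for persisted intermediates; `NULL` keeps
#'   everything in memory.
#' @return a validated `run_config` list.
#' @export
run_config <- function(exposure, outcomes, ld, dose, exposure_sd,
                       p_threshold = 5e-8, replicated_only = FALSE,
                       replication_pvalues = NULL,
                       ld_thresholds = c(0.01, 0.05),
                       palindrome_policy = "drop-ambiguous",
                       trial_estimates = NULL, column_map = NULL,
                       seed = NULL, output_dir = NULL) {
  if (!is.list(outcomes) || is.data.frame(outcomes)) outcomes <- list(outcomes)
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    names(outcomes) <- paste0("outcome", seq_along(outcomes))
  }
  if (p_threshold <= 0 || p_threshold >= 1) {
    stop_config("p_threshold must be in (0, 1)")
  }
  if (any(ld_thresholds <= 0 | ld_thresholds > 1)) {
    stop_config("ld_thresholds must be in (0, 1]")
  }
  if (dose <= 0) stop_config("dose must be positive")
  if (exposure_sd <= 0) stop_config("exposure_sd must be positive")
  structure(list(
    exposure = exposure, outcomes = outcomes, ld = ld,
    dose = dose, exposure_sd = exposure_sd,
    p_threshold = p_threshold, replicated_only = replicated_only,
    replication_pvalues = replication_pvalues,
    ld_thresholds = sort(ld_thresholds),
    palindrome_policy = palindrome_policy,
    trial_estimates = trial_estimates, column_map = column_map,
    seed = seed, output_dir = output_dir
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys are [run_config()] arguments; `exposure`, `outcomes` (a named map)
#' and `ld` must be file paths, resolved relative to the YAML file's
#' directory. `trial_estimates` may be a list of records.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p))) {
      file.path(base, p)
    } else p
  }
  raw$exposure <- resolve(raw$exposure)
  raw$ld <- resolve(raw$ld)
  raw$outcomes <- lapply(raw$outcomes, resolve)
  if (!is.null(raw$trial_estimates)) {
    raw$trial_estimates <- dplyr::bind_rows(raw$trial_estimates)
  }
  if (!is.null(raw$replication_pvalues)) {
    raw$replication_pvalues <- unlist(raw$replication_pvalues)
  }
  if (!is.null(raw$column_map)) raw$column_map <- unlist(raw$column_map)
  do.call(run_config, raw)
}

read_if_path <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1) reader(x, ...) else x
}

#' Run the full two-sample MR analysis
#'
#' Executes, for each outcome: instrument selection on the exposure
#' (significance and optional replication filters), allele harmonization
#' against the outcome (availability and palindrome drops), instrument
#' strength across the configured LD thresholds, maximum-likelihood
#' estimation with the correlated-variant model (IVW cross-check
#' alongside), and dose rescaling to an odds ratio. When
#' `config$output_dir` is set, every intermediate (instrument, harmonized
#' data, strength, estimates, audit log, rendered report) is persisted as
#' delimited text, so any reported value can be recomputed from the
#' persisted files.
#'
#' @param config a [run_config()].
#' @return a `concordance_report`: list with `results` (one tidy row per
#'   outcome and method), `strength`, `instrument`, `harmonized` (per
#'   outcome), `audit` (per outcome), `trial_estimates` and the `config`.
#' @export
run_analysis <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  exposure <- read_if_path(config$exposure, read_summary_stats,
                           column_map = config$column_map,
                           trait_id = "exposure")
  ld <- read_if_path(config$ld, read_ld_matrix)
  if (!inherits(ld, "ld_matrix")) ld <- validate_ld_matrix(ld)

  instrument <- select_instrument(
    exposure,
    p_threshold = config$p_threshold,
    replicated_only = config$replicated_only,
    replication_pvalues = config$replication_pvalues
  )
  strength <- instrument_strength(instrument, ld,
                                  r2_thresholds = config$ld_thresholds)
  scaling <- dose_scaling(config$dose, config$exposure_sd)

  harmonized <- list()
  audits <- list()
  results <- list()
  for (label in names(config$outcomes)) {
    outcome <- read_if_path(config$outcomes[[label]], read_summary_stats,
                            column_map = config$column_map, trait_id = label)
    h <- harmonize(instrument, outcome,
                   palindrome_policy = config$palindrome_policy, ld = ld)
    harmonized[[label]] <- h
    audits[[label]] <- dplyr::mutate(h$audit, outcome = label,
                                     .before = 1)
    ests <- list(
      ml = scale_to_dose(mr_ml_correlated(h), scaling),
      ivw = scale_to_dose(mr_ivw_correlated(h), scaling)
    )
    results[[label]] <- dplyr::bind_rows(lapply(ests, tidy.mr_estimate)) |>
      dplyr::mutate(outcome = label, .before = 1)
  }

  report <- structure(list(
    results = dplyr::bind_rows(results),
    strength = strength,
    instrument = instrument,
    harmonized = harmonized,
    audit = dplyr::bind_rows(audits),
    trial_estimates = config$trial_estimates,
    config = config
  ), class = "concordance_report")

  if (!is.null(config$output_dir)) persist_report(report, config$output_dir)
  report
}

persist_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tibble::as_tibble(report$instrument),
                   file.path(dir, "instrument.tsv"))
  readr::write_tsv(tibble::as_tibble(report$strength),
                   file.path(dir, "strength.tsv"))
  readr::write_tsv(report$results, file.path(dir, "estimates.tsv"))
  readr::write_tsv(report$audit, file.path(dir, "audit.tsv"))
  for (label in names(report$harmonized)) {
    readr::write_tsv(report$harmonized[[label]]$snps,
                     file.path(dir, paste0("harmonized_", label, ".tsv")))
  }
  writeLines(render_report(report), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Format an estimate with its CI for display
#'
#' `"x.xx (a.aa to b.bb)"`, two decimals, half-even rounding (machine
#' outputs keep full precision; this is display-only).
#'
#' @param est,lo,hi estimate and CI bounds.
#' @return character.
#' @export
format_estimate_ci <- function(est, lo, hi) {
  fmt <- function(x) sprintf("%.2f", round(x, 2))
  sprintf("%s (%s to %s)", fmt(est), fmt(lo), fmt(hi))
}

#' Render a concordance report as text
#'
#' A Table-1-style layout: per outcome, the externally supplied trial
#' estimate (dash when absent) next to the MR odds ratio per dose
#' increment, preceded by the instrument-strength block.
#'
#' @param report a `concordance_report` from [run_analysis()].
#' @return character vector of report lines.
#' @export
render_report <- function(report) {
  cfg <- report$config
  lines <- c(
    "Two-sample Mendelian randomization concordance report",
    sprintf("Instrument: %d SNPs at p < %g%s", nrow(report$instrument),
            cfg$p_threshold,
            if (isTRUE(cfg$replicated_only)) " (replicated only)" else ""),
    sprintf("Dose: %g native units; exposure SD: %g native units (scale factor %.4g)",
            cfg$dose, cfg$exposure_sd, cfg$dose / cfg$exposure_sd),
    "",
    "Instrument strength (lead SNPs at independent loci):"
  )
  for (i in seq_len(nrow(report$strength))) {
    s <- report$strength[i, ]
    lines <- c(lines, sprintf(
      "  r2 <= %.2f: k = %d, R2 = %.4f (%.1f%%), F = %.1f",
      s$r2_threshold, s$k, s$r2, 100 * s$r2, s$f_statistic
    ))
  }
  lines <- c(lines, "", sprintf(
    "%-28s %-24s %-24s", "Outcome", "Trial (95% CI)", "MR OR (95% CI)"))

  ml <- dplyr::filter(report$results, .data$method == "ml_correlated")
  for (i in seq_len(nrow(ml))) {
    row <- ml[i, ]
    trial <- "-"
    te <- report$trial_estimates
    if (!is.null(te) && row$outcome %in% te$outcome) {
      t <- te[te$outcome == row$outcome, ][1, ]
      trial <- format_estimate_ci(t$estimate, t$ci_low, t$ci_high)
    }
    lines <- c(lines, sprintf(
      "%-28s %-24s %-24s", row$outcome, trial,
      format_estimate_ci(row$or, row$or_ci_low, row$or_ci_high)
    ))
  }
  lines
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Tidy a concordance report
#' @param x a `concordance_report`.
#' @param ... unused.
#' @return the per-outcome, per-method results tibble.
#' @exportS3Method generics::tidy
tidy.concordance_report <- function(x, ...) x$results
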