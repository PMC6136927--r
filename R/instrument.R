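# Instrument construction (significance/replication filters, greedy LD
# pruning) and instrument strength (variance explained, F-statistics).

#' Select instrument SNPs by significance and optional replication
#'
#' Retains candidates whose exposure p-value is strictly below
#' `p_threshold` (genome-wide significance, default 5e-8). With
#' `replicated_only = TRUE` a SNP must additionally have replication
#' p < .05 in an independent study; replication p-values come from a
#' `pvalue_replication` column on `candidates` or from the named
#' `replication_pvalues` vector.
#'
#' @param candidates `snp_associations` tibble for the exposure.
#' @param p_threshold significance threshold (strict `<`).
#' @param replicated_only require independent replication at p < .05.
#' @param replication_pvalues optional named numeric vector (names = rsids).
#' @return an `mr_instrument` tibble (the retained candidate rows) with a
#'   `"selection"` attribute recording the thresholds and per-SNP drop
#'   reasons.
#' @export
select_instrument <- function(candidates, p_threshold = 5e-8,
                              replicated_only = FALSE,
                              replication_pvalues = NULL) {
  if (anyDuplicated(candidates$rsid)) {
    stop_input("duplicate rsids among instrument candidates")
  }
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop_config("p_threshold must be in (0, 1)")
  }
  p_rep <- rep(NA_real_, nrow(candidates))
  if ("pvalue_replication" %in% names(candidates)) {
    p_rep <- candidates$pvalue_replication
  }
  if (!is.null(replication_pvalues)) {
    idx <- match(candidates$rsid, names(replication_pvalues))
    p_rep <- ifelse(is.na(idx), p_rep, replication_pvalues[idx])
  }
  if (replicated_only && anyNA(p_rep)) {
    stop_config(paste0(
      "replicated_only = TRUE but replication p-values missing for: ",
      paste(candidates$rsid[is.na(p_rep)], collapse = ", ")))
  }

  reason <- dplyr::case_when(
    is.na(candidates$pvalue) ~ "missing-pvalue",
    candidates$pvalue >= p_threshold ~ "not-genome-wide-significant",
    replicated_only & !(p_rep < 0.05) ~ "not-replicated",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  if (!any(keep)) {
    stop_instrument("no SNPs satisfy the instrument selection filters")
  }
  drops <- tibble::tibble(rsid = candidates$rsid[!keep],
                          reason = reason[!keep])
  out <- tibble::new_tibble(candidates[keep, , drop = FALSE],
                            class = "mr_instrument")
  attr(out, "selection") <- list(
    p_threshold = p_threshold,
    replicated_only = replicated_only,
    replicated = setNames(p_rep[keep] < 0.05, candidates$rsid[keep]),
    drops = drops
  )
  out
}

#' Greedy LD pruning of an instrument
#'
#' Repeatedly takes the SNP with the smallest exposure p-value (ties broken
#' by rsid lexicographic order) and discards all remaining SNPs whose
#' squared correlation with it exceeds `r2_threshold`, yielding a set of
#' mutually "independent" lead SNPs at that threshold. Deterministic and
#' invariant to input ordering.
#'
#' @param instrument `mr_instrument` (or any tibble with `rsid`, `pvalue`).
#' @param ld signed LD matrix covering every instrument SNP.
#' @param r2_threshold maximum allowed squared correlation, in (0, 1\].
#' @return pruned `mr_instrument`; attribute `"pruning"` records the
#'   threshold and each dropped SNP with the lead SNP that shadowed it.
#' @export
prune_ld <- function(instrument, ld, r2_threshold) {
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1) {
    stop_config("r2_threshold must be in (0, 1]")
  }
  missing <- setdiff(instrument$rsid, rownames(ld))
  if (length(missing) > 0) {
    stop_config(paste0("SNP(s) absent from the LD matrix: ",
                      paste(missing, collapse = ", ")))
  }
  r2 <- unclass(ld)[instrument$rsid, instrument$rsid, drop = FALSE]^2

  ord <- order(instrument$pvalue, instrument$rsid)
  remaining <- ord
  lead <- integer(0)
  dropped <- tibble::tibble(rsid = character(0), reason = character(0))
  while (length(remaining) > 0) {
    i <- remaining[1]
    lead <- c(lead, i)
    remaining <- remaining[-1]
    if (length(remaining) > 0) {
      shadowed <- r2[remaining, i] > r2_threshold
      if (any(shadowed)) {
        dropped <- dplyr::bind_rows(dropped, tibble::tibble(
          rsid = instrument$rsid[remaining[shadowed]],
          reason = paste0("ld-with-", instrument$rsid[i])
        ))
        remaining <- remaining[!shadowed]
      }
    }
  }
  keep <- sort(lead) # preserve original row order
  out <- tibble::new_tibble(instrument[keep, , drop = FALSE],
                            class = "mr_instrument")
  attr(out, "selection") <- attr(instrument, "selection")
  attr(out, "pruning") <- list(r2_threshold = r2_threshold, drops = dropped)
  out
}

#' Per-SNP proportion of exposure variance explained
#'
#' For a per-allele effect `beta` in phenotype-SD units with effect-allele
#' frequency `f`, the variance explained is `2 * beta^2 * f * (1 - f)`
#' (standardized-phenotype form). When the allele frequency is missing the
#' t-statistic form `t^2 / (t^2 + n - 2)` with `t = beta / se` is used
#' instead. The form applied to each SNP is returned in the `r2_form`
#' column.
#'
#' @param data tibble with columns `beta` and (`eaf`) or (`se`, `n`).
#' @param form `"auto"` (prefer the allele-frequency form), `"eaf"`, or
#'   `"tstat"`.
#' @return `data` with columns `r2` and `r2_form` appended.
#' @export
snp_variance_explained <- function(data, form = c("auto", "eaf", "tstat")) {
  form <- match.arg(form)
  eaf <- if ("eaf" %in% names(data)) data$eaf else rep(NA_real_, nrow(data))
  se <- if ("se" %in% names(data)) data$se else rep(NA_real_, nrow(data))
  n <- if ("n" %in% names(data)) data$n else rep(NA_real_, nrow(data))

  can_eaf <- !is.na(eaf)
  can_t <- !is.na(se) & !is.na(n) & n > 2
  use_eaf <- switch(form,
    auto = can_eaf,
    eaf = rep(TRUE, nrow(data)),
    tstat = rep(FALSE, nrow(data))
  )
  if (form == "eaf" && !all(can_eaf)) {
    stop_estimation("allele-frequency form requested but eaf missing")
  }
  if (any(!use_eaf & !can_t)) {
    stop_estimation("variance explained not computable (need eaf, or se and n)")
  }
  t2 <- (data$beta / se)^2
  r2 <- ifelse(use_eaf,
               2 * data$beta^2 * eaf * (1 - eaf),
               t2 / (t2 + n - 2))
  data$r2 <- r2
  data$r2_form <- ifelse(use_eaf, "eaf", "tstat")
  data
}

#' Multi-allelic instrument strength: variance explained and F-statistics
#'
#' Approximates the total variance in the exposure explained by the
#' instrument by summing per-SNP variance explained over lead SNPs at
#' independent loci, at each LD-pruning threshold (defaults r^2 <= .01 and
#' .05, reported as a conservative-to-liberal range). The F-statistic for
#' each threshold uses the multi-allelic-score form
#' `F = R^2 * (n - k - 1) / (k * (1 - R^2))` with `k` the number of lead
#' SNPs contributing to that R^2.
#'
#' @param instrument `mr_instrument` for the exposure.
#' @param ld signed LD matrix covering the instrument.
#' @param n exposure GWAS sample size; defaults to the largest per-SNP `n`.
#' @param r2_thresholds LD-pruning thresholds (ascending).
#' @param form per-SNP variance-explained form, see
#'   [snp_variance_explained()].
#' @return an `instrument_strength` tibble, one row per threshold, with
#'   columns `r2_threshold`, `k`, `n`, `r2`, `f_statistic`.
#' @export
instrument_strength <- function(instrument, ld, n = NULL,
                                r2_thresholds = c(0.01, 0.05),
                                form = "auto") {
  if (is.null(n)) {
    if (!"n" %in% names(instrument) || all(is.na(instrument$n))) {
      stop_config("exposure sample size n not supplied and not in the data")
    }
    n <- max(instrument$n, na.rm = TRUE)
  }
  r2_thresholds <- sort(r2_thresholds)
  rows <- purrr::map(r2_thresholds, function(thr) {
    pruned <- prune_ld(instrument, ld, thr)
    k <- nrow(pruned)
    if (n <= k + 1) stop_config("need n > k + 1 for the F-statistic")
    r2 <- sum(snp_variance_explained(pruned, form = form)$r2)
    if (r2 >= 1) stop_estimation("summed variance explained >= 1; inputs inconsistent")
    tibble::tibble(
      r2_threshold = thr, k = k, n = n, r2 = r2,
      f_statistic = r2 * (n - k - 1) / (k * (1 - r2))
    )
  })
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(out, class = "instrument_strength")
}
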