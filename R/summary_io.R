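# Reading, validation and allele harmonization of GWAS summary statistics.

SUMMARY_COLUMNS <- c(
  "rsid", "effect_allele", "other_allele", "eaf", "beta", "se", "pvalue", "n"
)
MANDATORY_COLUMNS <- c("rsid", "effect_allele", "other_allele", "beta", "se")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-delimited association table into a validated tibble
#' of per-SNP summary statistics. Expected columns (renameable through
#' `column_map`) are `rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `pvalue`, `n`; `eaf`, `pvalue` and `n` are optional. `beta` is the
#' per-effect-allele effect: SD units for a continuous exposure, log-odds for
#' a binary outcome. Alleles are upper-cased. Rows violating basic validity
#' (`se <= 0`, alleles outside A/C/G/T, identical alleles, `eaf` outside
#' \[0, 1\], `pvalue` outside (0, 1\]) are rejected and reported, with source
#' line numbers, in the `"rejects"` attribute. Rows whose p-value disagrees
#' with the two-sided normal p implied by `beta/se` by more than 10% relative
#' (on the z scale) are kept but trigger a consistency warning.
#'
#' @param path file to read, or a data frame already in memory.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(rsid = "SNP", beta = "Effect")`.
#' @param trait_id optional trait label stored as an attribute.
#' @param delim field delimiter; guessed (tab, then comma) when `NULL`.
#' @return A tibble of class `snp_associations` with attributes `trait_id`
#'   and `rejects` (a tibble of dropped rows with line numbers and reasons).
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_id = NULL,
                               delim = NULL) {
  if (is.data.frame(path)) {
    raw <- tibble::as_tibble(path)
  } else {
    if (is.null(delim)) {
      first <- readLines(path, n = 1L)
      delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
    }
    raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  }
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), SUMMARY_COLUMNS)
    if (length(bad) > 0) {
      stop_config(paste0("unknown canonical column(s) in column_map: ",
                         paste(bad, collapse = ", ")))
    }
    missing_src <- setdiff(unname(column_map), names(raw))
    if (length(missing_src) > 0) {
      stop_config(paste0("column_map refers to absent column(s): ",
                         paste(missing_src, collapse = ", ")))
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  missing_mand <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing_mand) > 0) {
    stop_config(paste0("missing mandatory column(s): ",
                       paste(missing_mand, collapse = ", ")))
  }

  data <- raw |>
    dplyr::mutate(
      .line = dplyr::row_number() + 1L, # header is line 1
      rsid = as.character(.data$rsid),
      effect_allele = toupper(as.character(.data$effect_allele)),
      other_allele = toupper(as.character(.data$other_allele)),
      beta = suppressWarnings(as.numeric(.data$beta)),
      se = suppressWarnings(as.numeric(.data$se))
    )
  for (opt in c("eaf", "pvalue", "n")) {
    if (!opt %in% names(data)) {
      data[[opt]] <- NA_real_
    } else {
      data[[opt]] <- suppressWarnings(as.numeric(data[[opt]]))
    }
  }

  reason <- dplyr::case_when(
    is.na(data$rsid) | data$rsid == "" ~ "missing-rsid",
    !data$effect_allele %in% c("A", "C", "G", "T") ~ "invalid-effect-allele",
    !data$other_allele %in% c("A", "C", "G", "T") ~ "invalid-other-allele",
    data$effect_allele == data$other_allele ~ "identical-alleles",
    is.na(data$beta) ~ "missing-beta",
    is.na(data$se) | data$se <= 0 ~ "invalid-se",
    !is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1) ~ "invalid-eaf",
    !is.na(data$pvalue) & (data$pvalue <= 0 | data$pvalue > 1) ~ "invalid-pvalue",
    !is.na(data$n) & data$n <= 0 ~ "invalid-n",
    TRUE ~ NA_character_
  )
  rejects <- data[!is.na(reason), c(".line", "rsid")]
  rejects$reason <- reason[!is.na(reason)]
  names(rejects)[1] <- "line"
  ok <- data[is.na(reason), ]
  if (nrow(ok) == 0) stop_input("no valid rows in summary-statistics input")

  # p-value vs beta/se consistency (warn, never reject): compare on the z
  # scale, where the 10% relative band is well defined even for tiny p.
  has_p <- !is.na(ok$pvalue) & ok$pvalue < 1
  if (any(has_p)) {
    z_obs <- abs(ok$beta[has_p] / ok$se[has_p])
    z_p <- stats::qnorm(ok$pvalue[has_p] / 2, lower.tail = FALSE)
    rel <- abs(z_obs - z_p) / pmax(z_p, .Machine$double.eps)
    bad_p <- which(rel > 0.10 & z_p > 0)
    if (length(bad_p) > 0) {
      rlang::warn(paste0(
        "p-value inconsistent with beta/se (>10% relative on z) for: ",
        paste(ok$rsid[has_p][bad_p], collapse = ", ")
      ), class = "corrmr_pvalue_inconsistency")
    }
  }

  out <- ok[, SUMMARY_COLUMNS]
  out <- tibble::new_tibble(out, class = "snp_associations")
  attr(out, "trait_id") <- trait_id
  attr(out, "rejects") <- tibble::as_tibble(rejects)
  out
}

#' Write a summary-statistics table
#'
#' Tab-delimited, full numeric precision; the written file round-trips
#' through [read_summary_stats()] without loss.
#'
#' @param data tibble of per-SNP associations.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(data, path) {
  readr::write_tsv(data[, intersect(SUMMARY_COLUMNS, names(data))], path)
  invisible(path)
}

#' Validate (and regularize) a signed LD correlation matrix
#'
#' Checks symmetry, unit diagonal, entries in \[-1, 1\] and, after an
#' eigenvalue ridge if needed, positive semi-definiteness. The matrix must
#' hold *signed* r, not r squared; a matrix known to carry unsigned entries
#' is accepted only with `assume_positive = TRUE`, which logs a warning that
#' all correlations are being taken as positive.
#'
#' @param r square numeric matrix with rsid dimnames.
#' @param rsids optional expected identifiers; the matrix is checked against
#'   and reordered to them.
#' @param assume_positive declare the matrix unsigned (entries are |r|).
#' @param tol eigenvalue floor for the regularization ridge.
#' @return the validated matrix, class `ld_matrix`, attribute `"ridge"`.
#' @export
validate_ld_matrix <- function(r, rsids = NULL, assume_positive = FALSE,
                               tol = PSD_TOL) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop_input("LD matrix must be square")
  if (is.null(rownames(r)) || is.null(colnames(r))) {
    stop_input("LD matrix must carry rsid row and column names")
  }
  if (!identical(rownames(r), colnames(r))) {
    stop_input("LD matrix row and column labels differ")
  }
  if (anyNA(r)) stop_input("LD matrix contains missing values")
  if (any(r < -1 - 1e-12 | r > 1 + 1e-12)) {
    stop_input("LD matrix entries outside [-1, 1]")
  }
  if (max(abs(r - t(r))) > 1e-8) stop_input("LD matrix is not symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stop_input("LD matrix diagonal is not 1")
  if (assume_positive) {
    if (any(r < 0)) {
      stop_input("assume_positive = TRUE but matrix has negative entries")
    }
    rlang::warn(
      "LD matrix declared unsigned: treating all correlations as positive r",
      class = "corrmr_unsigned_ld"
    )
  }
  if (!is.null(rsids)) {
    if (!setequal(rownames(r), rsids) || length(rsids) != nrow(r)) {
      stop_input("LD matrix labels do not match the expected rsids")
    }
    r <- r[rsids, rsids, drop = FALSE]
  }
  r <- (r + t(r)) / 2
  r <- regularize_psd(r, tol = tol)
  class(r) <- c("ld_matrix", class(r))
  r
}

#' Read a signed LD correlation matrix
#'
#' Delimited square matrix whose first row and first column are rsid labels.
#'
#' @inheritParams validate_ld_matrix
#' @param path file to read.
#' @param delim delimiter; guessed when `NULL`.
#' @return validated `ld_matrix` (see [validate_ld_matrix()]).
#' @export
read_ld_matrix <- function(path, rsids = NULL, assume_positive = FALSE,
                           delim = NULL) {
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  }
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  labels <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  validate_ld_matrix(m, rsids = rsids, assume_positive = assume_positive)
}

#' Write an LD matrix in the format read by [read_ld_matrix()]
#' @param r ld matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(r, path) {
  tab <- tibble::as_tibble(unclass(r), .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(rsid = rownames(r)), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome associations to the exposure's effect allele, SNP by SNP.
#' The exposure is the reference orientation: when the outcome's
#' effect/other alleles are swapped relative to the exposure, the outcome
#' beta is negated and its eaf replaced by 1 - eaf. SNPs absent from the
#' outcome are dropped with reason `"unavailable"`; allele pairs that
#' neither match nor swap are dropped with reason `"allele-mismatch"`.
#'
#' Palindromic (A/T or C/G) SNPs cannot be oriented from allele labels
#' alone. Under the default `"drop-ambiguous"` policy they are retained only
#' when both traits' effect-allele frequencies fall on the same side of 0.5
#' and outside the ambiguity window \[0.42, 0.58\] (after label alignment);
#' otherwise they are dropped with reason `"palindromic-ambiguous"`.
#' `"drop-all"` drops every palindromic SNP; `"keep-all"` trusts the allele
#' labels as-is (both strands assumed identical).
#'
#' @param exposure,outcome `snp_associations` tibbles (see
#'   [read_summary_stats()]).
#' @param palindrome_policy `"drop-ambiguous"` (default), `"drop-all"` or
#'   `"keep-all"`.
#' @param ld optional LD matrix covering the exposure SNPs; it is restricted
#'   and reordered to the retained SNPs.
#' @param ambiguity_window eaf window within which a palindromic SNP is
#'   considered unresolvable.
#' @return An `mr_harmonized` object: list with `snps` (tibble with columns
#'   `rsid`, `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf`, exposure `pvalue` and `n`), `ld` (or `NULL`), and `audit` (one
#'   row per input SNP: action `kept`/`flipped`/`dropped` and reason code).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop-ambiguous", "drop-all",
                                            "keep-all"),
                      ld = NULL, ambiguity_window = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (anyDuplicated(exposure$rsid)) stop_input("duplicate rsids in exposure")
  if (anyDuplicated(outcome$rsid)) stop_input("duplicate rsids in outcome")

  out_idx <- match(exposure$rsid, outcome$rsid)
  k <- nrow(exposure)
  action <- character(k)
  reason <- rep(NA_character_, k)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, k)

  for (i in seq_len(k)) {
    j <- out_idx[i]
    if (is.na(j)) {
      action[i] <- "dropped"; reason[i] <- "unavailable"; next
    }
    ea_x <- exposure$effect_allele[i]; oa_x <- exposure$other_allele[i]
    ea_y <- outcome$effect_allele[j]; oa_y <- outcome$other_allele[j]
    pal <- is_palindromic(ea_x, oa_x)

    if (pal && palindrome_policy == "drop-all") {
      action[i] <- "dropped"; reason[i] <- "palindromic"; next
    }

    if (ea_y == ea_x && oa_y == oa_x) {
      flip <- FALSE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      flip <- TRUE
    } else {
      action[i] <- "dropped"; reason[i] <- "allele-mismatch"; next
    }

    b <- outcome$beta[j]; s <- outcome$se[j]; f <- outcome$eaf[j]
    if (flip) {
      b <- -b
      if (!is.na(f)) f <- 1 - f
    }

    if (pal && palindrome_policy == "drop-ambiguous") {
      fx <- exposure$eaf[i]
      # resolvable only if both eafs sit strictly on the same side of 0.5
      # and outside the ambiguity window
      same_side <- !is.na(fx) && !is.na(f) &&
        ((fx < 0.5 && f < 0.5) || (fx > 0.5 && f > 0.5))
      outside <- !is.na(fx) && !is.na(f) &&
        (fx < ambiguity_window[1] || fx > ambiguity_window[2]) &&
        (f < ambiguity_window[1] || f > ambiguity_window[2])
      if (!(same_side && outside)) {
        action[i] <- "dropped"; reason[i] <- "palindromic-ambiguous"; next
      }
    }

    action[i] <- if (flip) "flipped" else "kept"
    beta_out[i] <- b; se_out[i] <- s; eaf_out[i] <- f
  }

  audit <- tibble::tibble(rsid = exposure$rsid, action = action,
                          reason = reason)
  keep <- action %in% c("kept", "flipped")
  if (!any(keep)) stop_input("no SNPs retained after harmonization")

  snps <- tibble::tibble(
    rsid = exposure$rsid[keep],
    beta_exposure = exposure$beta[keep],
    se_exposure = exposure$se[keep],
    beta_outcome = beta_out[keep],
    se_outcome = se_out[keep],
    eaf = exposure$eaf[keep],
    pvalue = exposure$pvalue[keep],
    n = exposure$n[keep]
  )

  if (!is.null(ld)) {
    if (!all(snps$rsid %in% rownames(ld))) {
      stop_input("LD matrix does not cover all retained SNPs")
    }
    ld <- unclass(ld)[snps$rsid, snps$rsid, drop = FALSE]
    ld <- validate_ld_matrix(ld)
  }

  structure(list(snps = snps, ld = ld, audit = audit),
            class = "mr_harmonized")
}

#' @export
print.mr_harmonized <- function(x, ...) {
  dropped <- sum(x$audit$action == "dropped")
  flipped <- sum(x$audit$action == "flipped")
  cat(sprintf("<mr_harmonized> %d SNPs retained (%d flipped, %d dropped)\n",
              nrow(x$snps), flipped, dropped))
  print(x$snps, n = 6)
  invisible(x)
}
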