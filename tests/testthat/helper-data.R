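# Small builders for association tables and LD matrices used across tests.

make_assoc <- function(rsid, ea = "A", oa = "G", eaf = 0.3,
                       beta = 0.1, se = 0.02, n = 5000, pvalue = NULL) {
  k <- length(rsid)
  ea <- rep_len(ea, k); oa <- rep_len(oa, k)
  eaf <- rep_len(eaf, k); beta <- rep_len(beta, k); se <- rep_len(se, k)
  pvalue <- if (is.null(pvalue)) 2 * pnorm(-abs(beta / se)) else rep_len(pvalue, k)
  tibble::tibble(rsid = rsid, effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = se, pvalue = pvalue,
                 n = rep_len(n, k))
}

make_ld <- function(rsid, r = NULL) {
  k <- length(rsid)
  m <- if (is.null(r)) diag(k) else r
  dimnames(m) <- list(rsid, rsid)
  validate_ld_matrix(m)
}

write_assoc_file <- function(data, path = withr::local_tempfile(fileext = ".tsv",
                                                                .local_envir = parent.frame())) {
  readr::write_tsv(data, path)
  path
}
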