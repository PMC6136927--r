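test_that("a well-formed table reads into one record per row, unchanged", {
  tab <- make_assoc(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05))
  path <- write_assoc_file(tab)
  expect_no_warning(got <- read_summary_stats(path, trait_id = "selenium"))
  expect_s3_class(got, "snp_associations")
  expect_equal(nrow(got), 3)
  expect_equal(got$beta, tab$beta)
  expect_equal(attr(got, "trait_id"), "selenium")
  expect_equal(nrow(attr(got, "rejects")), 0)
})

test_that("summary statistics round-trip through write/read at full precision", {
  tab <- make_assoc(paste0("rs", 1:5),
                    beta = c(0.123456789012345, -0.2, 1e-7, 3.14159, -0.5),
                    se = c(0.0123456789, 0.02, 0.03, 0.5, 1e-4),
                    pvalue = NA_real_)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(tab, path)
  got <- read_summary_stats(path)
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    expect_identical(got[[col]], tab[[col]], label = col)
  }
})

test_that("invalid rows are rejected and reported with line numbers", {
  tab <- make_assoc(c("rs1", "rs2", "rs3", "rs4"))
  tab$se[2] <- 0                  # invalid standard error
  tab$effect_allele[3] <- "N"     # bad allele
  path <- write_assoc_file(tab)
  got <- read_summary_stats(path)
  expect_equal(got$rsid, c("rs1", "rs4"))
  rejects <- attr(got, "rejects")
  expect_equal(rejects$rsid, c("rs2", "rs3"))
  expect_equal(rejects$reason, c("invalid-se", "invalid-effect-allele"))
  expect_equal(rejects$line, c(3L, 4L)) # header is line 1
})

test_that("zero valid rows is an input error; missing column a config error", {
  tab <- make_assoc("rs1")
  tab$se <- -1
  expect_error(read_summary_stats(write_assoc_file(tab)),
               class = "corrmr_input_error")
  tab2 <- make_assoc("rs1")[, -which(names(make_assoc("rs1")) == "beta")]
  expect_error(read_summary_stats(write_assoc_file(tab2)),
               class = "corrmr_config_error")
})

test_that("column_map renames file columns to the canonical schema", {
  tab <- make_assoc(c("rs1", "rs2"))
  names(tab)[names(tab) == "rsid"] <- "SNP"
  names(tab)[names(tab) == "beta"] <- "Effect"
  got <- read_summary_stats(write_assoc_file(tab),
                            column_map = c(rsid = "SNP", beta = "Effect"))
  expect_equal(got$rsid, c("rs1", "rs2"))
  expect_error(
    read_summary_stats(write_assoc_file(tab), column_map = c(rsid = "nope")),
    class = "corrmr_config_error"
  )
})

test_that("p-values disagreeing with beta/se by >10% warn but are kept", {
  # z = 0.1/0.05 = 2; the reported p implies z = qnorm(1 - p/2)
  p_ok <- 2 * pnorm(-2 * 1.05)  # within 10% on the z scale
  p_bad <- 2 * pnorm(-2 * 1.2)  # 20% off
  tab <- make_assoc(c("rs1", "rs2"), beta = 0.1, se = 0.05,
                    pvalue = c(p_ok, p_bad))
  expect_warning(got <- read_summary_stats(write_assoc_file(tab)),
                 class = "corrmr_pvalue_inconsistency")
  expect_equal(nrow(got), 2) # kept, not rejected
  tab$pvalue <- c(p_ok, p_ok)
  expect_no_warning(read_summary_stats(write_assoc_file(tab)))
})

test_that("LD matrices validate: identity passes, bad entries fail", {
  rs <- c("rs1", "rs2")
  m <- diag(2); dimnames(m) <- list(rs, rs)
  got <- validate_ld_matrix(m)
  expect_s3_class(got, "ld_matrix")
  expect_equal(attr(got, "ridge"), 0)

  m2 <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(rs, rs))
  got2 <- validate_ld_matrix(m2)
  ev <- eigen(unclass(got2), only.values = TRUE)$values
  expect_equal(sort(ev), c(0.7, 1.3))

  m3 <- matrix(c(1, 1.2, 1.2, 1), 2, dimnames = list(rs, rs))
  expect_error(validate_ld_matrix(m3), class = "corrmr_input_error")
  m4 <- matrix(c(1, 0.3, 0.1, 1), 2, dimnames = list(rs, rs))
  expect_error(validate_ld_matrix(m4), class = "corrmr_input_error")
  m5 <- m2; dimnames(m5) <- list(rs, c("rs1", "rsX"))
  expect_error(validate_ld_matrix(m5), class = "corrmr_input_error")
})

test_that("LD matrix file reading reorders to expected rsids and rejects mismatches", {
  rs <- c("rsA", "rsB", "rsC")
  m <- matrix(c(1, .2, .1, .2, 1, .3, .1, .3, 1), 3, dimnames = list(rs, rs))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(validate_ld_matrix(m), path)
  got <- read_ld_matrix(path, rsids = c("rsC", "rsA", "rsB"))
  expect_equal(rownames(got), c("rsC", "rsA", "rsB"))
  expect_equal(got["rsC", "rsB"], 0.3)
  expect_error(read_ld_matrix(path, rsids = c("rsA", "rsB", "rsZ")),
               class = "corrmr_input_error")
})

test_that("unsigned LD needs the explicit flag and contradicts negative entries", {
  rs <- c("rs1", "rs2")
  m <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(rs, rs))
  expect_warning(validate_ld_matrix(m, assume_positive = TRUE),
                 class = "corrmr_unsigned_ld")
  m[1, 2] <- m[2, 1] <- -0.3
  expect_error(validate_ld_matrix(m, assume_positive = TRUE),
               class = "corrmr_input_error")
})

test_that("rank-deficient LD gets a logged diagonal ridge", {
  rs <- c("rs1", "rs2")
  m <- matrix(c(1, 1, 1, 1), 2, dimnames = list(rs, rs)) # perfect LD
  got <- suppressMessages(validate_ld_matrix(m))
  expect_gt(attr(got, "ridge"), 0)
  ev <- eigen(unclass(got), only.values = TRUE)$values
  expect_gte(min(ev), 1e-8 * (1 - 1e-6))
})

test_that("outcome alleles swapped relative to exposure flip beta and eaf", {
  exposure <- make_assoc("rs1", ea = "A", oa = "G", beta = 0.10, eaf = 0.3)
  outcome <- make_assoc("rs1", ea = "G", oa = "A", beta = -0.05, eaf = 0.7)
  h <- harmonize(exposure, outcome)
  expect_equal(h$snps$beta_outcome, 0.05)
  expect_equal(h$audit$action, "flipped")
})

test_that("irreconcilable allele pairs are dropped with a reason, never kept", {
  exposure <- make_assoc(c("rs1", "rs2"), ea = "A", oa = "G")
  outcome <- make_assoc(c("rs1", "rs2"), ea = c("A", "A"), oa = c("G", "C"))
  h <- harmonize(exposure, outcome)
  expect_equal(h$snps$rsid, "rs1")
  expect_equal(h$audit$reason[h$audit$rsid == "rs2"], "allele-mismatch")
})

test_that("palindromic SNPs follow the ambiguity-window policy", {
  # eaf 0.50 sits inside the window: always ambiguous
  exposure <- make_assoc(c("rs1", "rs2"), ea = "A", oa = "T",
                         eaf = c(0.50, 0.20))
  outcome <- make_assoc(c("rs1", "rs2"), ea = "A", oa = "T",
                        eaf = c(0.50, 0.22), beta = 0.05)
  h <- harmonize(exposure, outcome)
  expect_equal(h$snps$rsid, "rs2") # same side, outside window: resolvable
  expect_equal(h$audit$reason[h$audit$rsid == "rs1"], "palindromic-ambiguous")

  # opposite sides of 0.5: dropped even though both are outside the window
  outcome2 <- make_assoc("rs2", ea = "A", oa = "T", eaf = 0.80, beta = 0.05)
  expect_error(harmonize(exposure[2, ], outcome2), class = "corrmr_input_error")

  # drop-all removes palindromic SNPs regardless of frequency; with every
  # SNP palindromic nothing survives
  expect_error(harmonize(exposure, outcome, palindrome_policy = "drop-all"),
               class = "corrmr_input_error")
  mixed <- dplyr::bind_rows(exposure, make_assoc("rs9", ea = "A", oa = "G"))
  mixed_out <- dplyr::bind_rows(outcome, make_assoc("rs9", ea = "A", oa = "G",
                                                    beta = 0.02))
  h3 <- harmonize(mixed, mixed_out, palindrome_policy = "drop-all")
  expect_equal(h3$snps$rsid, "rs9")
  expect_true(all(h3$audit$reason[h3$audit$action == "dropped"] == "palindromic"))

  # missing eaf disables resolution
  exposure$eaf <- NA_real_
  expect_error(harmonize(exposure, outcome), class = "corrmr_input_error")
})

test_that("SNPs absent from the outcome drop as unavailable (12 -> 11)", {
  exposure <- make_assoc(sprintf("rs%02d", 1:12))
  outcome <- make_assoc(sprintf("rs%02d", 2:12), beta = 0.01)
  h <- harmonize(exposure, outcome)
  expect_equal(nrow(h$snps), 11)
  expect_equal(h$audit$reason[h$audit$rsid == "rs01"], "unavailable")
  expect_equal(sum(h$audit$action == "dropped"), 1)
})

test_that("harmonization is idempotent", {
  exposure <- make_assoc(c("rs1", "rs2", "rs3"), ea = c("A", "C", "T"),
                         oa = c("G", "T", "C"), beta = c(0.1, 0.2, -0.1),
                         eaf = c(0.2, 0.3, 0.25))
  outcome <- make_assoc(c("rs1", "rs2", "rs3"), ea = c("G", "C", "C"),
                        oa = c("A", "T", "T"), beta = c(-0.05, 0.02, 0.04),
                        eaf = c(0.8, 0.31, 0.73))
  h1 <- harmonize(exposure, outcome)
  # express the harmonized outcome back as a table in exposure orientation
  outcome2 <- exposure
  outcome2$beta <- h1$snps$beta_outcome
  outcome2$se <- h1$snps$se_outcome
  h2 <- harmonize(exposure, outcome2)
  expect_true(all(h2$audit$action == "kept"))
  expect_equal(h2$snps$beta_outcome, h1$snps$beta_outcome)
  expect_equal(h2$snps$se_outcome, h1$snps$se_outcome)
})

test_that("double allele flip is the identity", {
  set.seed(7)
  for (i in 1:10) {
    beta <- rnorm(1)
    eaf <- runif(1)
    exposure <- make_assoc("rs1", ea = "A", oa = "G", beta = 0.1, eaf = 0.3)
    flipped <- make_assoc("rs1", ea = "G", oa = "A", beta = -beta, eaf = 1 - eaf)
    h <- harmonize(exposure, flipped)
    expect_equal(h$snps$beta_outcome, beta)
  }
})

test_that("the LD matrix is restricted and reordered to the retained SNPs", {
  rs <- c("rs1", "rs2", "rs3")
  ld <- make_ld(rs, matrix(c(1, .2, .1, .2, 1, .3, .1, .3, 1), 3))
  exposure <- make_assoc(rs)
  outcome <- make_assoc(c("rs3", "rs1"), beta = 0.01) # rs2 unavailable
  h <- harmonize(exposure, outcome, ld = ld)
  expect_equal(rownames(h$ld), c("rs1", "rs3"))
  expect_equal(h$ld["rs1", "rs3"], 0.1)
})
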