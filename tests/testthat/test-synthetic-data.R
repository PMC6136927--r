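test_that("simulation configs validate dimensions and ranges", {
  expect_error(simulation_config(k = 3, maf = c(0.1, 0.2)),
               class = "corrmr_config_error")
  expect_error(simulation_config(k = 2, maf = c(0.1, 0.6)),
               class = "corrmr_config_error")
  expect_error(simulation_config(case_fraction = 1.2),
               class = "corrmr_config_error")
  expect_error(simulation_config(k = 2, ld_r = diag(3)),
               class = "corrmr_config_error")
  cfg <- simulation_config(k = 3, seed = 2)
  expect_length(cfg$rsids, 3)
  expect_equal(cfg$pleiotropy, rep(0, 3))
})

test_that("summary-level output is a deterministic function of the seed", {
  cfg <- simulation_config(k = 5, theta = 0.1, seed = 77)
  s1 <- simulate_summary_level(cfg)
  s2 <- simulate_summary_level(cfg)
  expect_identical(s1$exposure, s2$exposure)
  expect_identical(s1$outcome, s2$outcome)
  cfg2 <- simulation_config(k = 5, theta = 0.1, seed = 78)
  s3 <- simulate_summary_level(cfg2)
  expect_false(identical(s1$exposure$beta, s3$exposure$beta))
})

test_that("the noiseless override returns the generative means exactly", {
  cfg <- simulation_config(k = 4, theta = 0.3,
                           pleiotropy = c(0.01, -0.01, 0, 0.02), seed = 5)
  s <- simulate_summary_level(cfg, se_exposure = 0, se_outcome = 0)
  expect_identical(s$exposure$beta, cfg$xi)
  expect_identical(s$outcome$beta, cfg$theta * cfg$xi + cfg$pleiotropy)
})

test_that("summary-level betas scatter with the analytic standard errors", {
  cfg <- simulation_config(k = 3, n_exposure = 4000, theta = 0, seed = 1,
                           ld_r = diag(3), maf = c(0.2, 0.3, 0.4))
  draws <- sapply(1:400, function(i) {
    cfg$seed <- i
    simulate_summary_level(cfg)$exposure$beta
  })
  emp_sd <- apply(draws, 1, sd)
  expect_equal(emp_sd, simulate_summary_level(cfg)$exposure$se,
               tolerance = 0.12)
})

test_that("simulated summary files survive the io layer unchanged", {
  cfg <- simulation_config(k = 3, theta = 0.2, seed = 4)
  s <- simulate_summary_level(cfg)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(s$exposure, p1)
  write_ld_matrix(s$ld, p2)
  expect_equal(read_summary_stats(p1)$beta, s$exposure$beta)
  got_ld <- read_ld_matrix(p2, rsids = cfg$rsids)
  expect_equal(unclass(got_ld), unclass(s$ld), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("individual-level genotypes reproduce the target LD", {
  cfg <- simulation_config(k = 4, n_exposure = 10000, n_outcome = 500,
                           maf = c(0.15, 0.25, 0.35, 0.45),
                           mode = "individual-level", seed = 42)
  s <- simulate_individual_level(cfg)
  expect_lt(max(abs(unclass(s$ld) - unclass(cfg$ld_r))), 0.05)
})

test_that("with xi = 0 the per-SNP exposure tests are null-calibrated", {
  hits <- 0; total <- 0
  for (i in 1:50) {
    cfg <- simulation_config(k = 4, n_exposure = 2000, n_outcome = 500,
                             xi = rep(0, 4), mode = "individual-level",
                             seed = 500 + i)
    s <- simulate_individual_level(cfg)
    hits <- hits + sum(s$exposure$pvalue < 0.05)
    total <- total + 4
  }
  rate <- hits / total
  band <- 3 * sqrt(0.05 * 0.95 / total)
  expect_gt(rate, 0.05 - band)
  expect_lt(rate, 0.05 + band)
})

test_that("individual-level prevalence matches the configured case fraction", {
  cfg <- simulation_config(k = 3, n_exposure = 500, n_outcome = 8000,
                           theta = 0.4, case_fraction = 0.3,
                           mode = "individual-level", seed = 9)
  s <- simulate_individual_level(cfg)
  # logistic per-SNP SEs should be near the analytic binary-trait form
  analytic <- 1 / sqrt(2 * cfg$maf * (1 - cfg$maf) * cfg$n_outcome *
                         0.3 * 0.7)
  expect_equal(s$outcome$se, analytic, tolerance = 0.15)
})

test_that("summary- and individual-level modes agree on the exposure betas", {
  k <- 3
  reps <- 120
  cfg_s <- simulation_config(k = k, n_exposure = 20000, n_outcome = 1000,
                             theta = 0.2, seed = 1)
  cfg_i <- simulation_config(k = k, n_exposure = 20000, n_outcome = 1000,
                             theta = 0.2, mode = "individual-level", seed = 1)
  bx_s <- matrix(NA_real_, reps, k)
  bx_i <- matrix(NA_real_, reps, k)
  for (i in seq_len(reps)) {
    cfg_s$seed <- i
    cfg_i$seed <- i
    bx_s[i, ] <- simulate_summary_level(cfg_s)$exposure$beta
    bx_i[i, ] <- simulate_individual_level(cfg_i)$exposure$beta
  }
  for (j in seq_len(k)) {
    mc_s <- sd(bx_s[, j]) / sqrt(reps)
    mc_i <- sd(bx_i[, j]) / sqrt(reps)
    expect_lt(abs(mean(bx_s[, j]) - cfg_s$xi[j]), 3 * mc_s)
    expect_lt(abs(mean(bx_i[, j]) - cfg_i$xi[j]), 3 * mc_i)
  }
})

test_that("balanced pleiotropy biases less as the instrument grows", {
  det_bias <- function(k) {
    pl <- 0.02 * rep_len(c(1, -1), k)
    pl <- pl - mean(pl)
    cfg <- simulation_config(k = k, theta = 0.2, pleiotropy = pl, seed = 1,
                             target_r2 = 0.0035 * k)
    s <- simulate_summary_level(cfg, se_exposure = 1e-6, se_outcome = 1e-6)
    h <- harmonize(s$exposure, s$outcome, ld = s$ld)
    abs(mr_ml_correlated(h)$theta - 0.2)
  }
  expect_lt(det_bias(20), det_bias(5))
})

test_that("individual-level mode refuses consortium-scale samples", {
  cfg <- simulation_config(k = 2, n_exposure = 40000, n_outcome = 20000,
                           mode = "individual-level")
  expect_error(simulate_individual_level(cfg), class = "corrmr_config_error")
  cfg2 <- simulation_config(k = 2, mode = "summary-level")
  expect_error(simulate_individual_level(cfg2), class = "corrmr_config_error")
})

test_that("the selenium fixture is deterministic and mirrors the published filters", {
  f1 <- selenium_fixture()
  f2 <- selenium_fixture()
  expect_identical(f1, f2)

  expect_equal(sum(f1$candidates$in_primary), 12)
  expect_equal(sum(!is.na(f1$candidates$pvalue_replication)), 5)
  expect_true(all(f1$candidates$pvalue < 5e-8))
  expect_true(all(f1$candidates$pvalue_replication < 0.05, na.rm = TRUE))
  expect_setdiff <- setdiff(f1$candidates$rsid, f1$outcome_available)
  expect_setequal(expect_setdiff, c("rs558133", "rs6859667"))
  expect_true("rs558133" %in% f1$candidates$rsid[f1$candidates$in_primary])
  expect_false(is.na(f1$candidates$pvalue_replication[
    f1$candidates$rsid == "rs6859667"]))
})
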