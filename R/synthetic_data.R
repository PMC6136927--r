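# Two-sample GWAS summary-statistic simulator with known causal effect,
# LD and optional horizontal pleiotropy, plus a deterministic fixture
# reproducing the selenium instrument's filter arithmetic.

# Markov-type correlation matrix with (possibly varying) neighbour
# correlations: r[i, j] is the product of the neighbour correlations
# between i and j, which is positive definite by construction (Gaussian
# AR process with heterogeneous coefficients). The default neighbour
# pattern cycles through 0.25 / 0.15 / 0.05 so that squared correlations
# straddle the conventional pruning thresholds .01 and .05.
default_ld <- function(k, rho = c(0.25, 0.15, 0.05)) {
  rho <- rep_len(rho, max(k - 1, 1))
  r <- diag(k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r[i, j] <- r[j, i] <- prod(rho[i:(j - 1)])
    }
  }
  r
}

#' Simulation configuration for two-sample GWAS summary data
#'
#' Defines the full generative model: `k` instrument SNPs with minor-allele
#' frequencies `maf` and signed LD correlation `ld_r`; per-allele marginal
#' effects `xi` on a continuous exposure measured in SD units; a binary
#' outcome whose log-odds depend on the exposure through the causal effect
#' `theta` (per exposure SD) plus optional per-SNP direct (horizontally
#' pleiotropic) effects; and two non-overlapping samples of size
#' `n_exposure` and `n_outcome`, the latter with case fraction
#' `case_fraction`.
#'
#' Defaults mirror the geometry of the selenium-prostate cancer setting
#' they stand in for: 11 SNPs in mild LD (|r| <= 0.3), exposure GWAS of
#' 9639, outcome sample of 72 729 with 44 825 cases, and `xi` calibrated so
#' the instrument explains about 3.5% of exposure variance.
#'
#' @param n_exposure,n_outcome sample sizes of the two disjoint samples.
#' @param k number of instrument SNPs.
#' @param maf minor-allele frequencies, each in (0, 0.5].
#' @param xi per-allele marginal effects on the exposure (SD units). The
#'   default spreads `target_r2` evenly across SNPs.
#' @param ld_r signed LD correlation matrix (k x k); default AR(1) with
#'   correlation 0.25 between neighbours.
#' @param theta true causal log-odds effect per exposure SD.
#' @param pleiotropy per-SNP direct log-odds effects on the outcome
#'   (recycled; default 0).
#' @param case_fraction outcome prevalence in the outcome sample.
#' @param mode `"summary-level"` (sampling-distribution draw) or
#'   `"individual-level"` (genotypes, phenotypes and per-SNP regressions).
#' @param seed integer seed; every simulation output is a deterministic
#'   function of the config including this seed.
#' @param target_r2 total instrument variance explained used to derive the
#'   default `xi`.
#' @return a validated `simulation_config` list, including generated
#'   `rsids`.
#' @export
simulation_config <- function(n_exposure = 9639, n_outcome = 72729, k = 11,
                              maf = NULL, xi = NULL, ld_r = NULL,
                              theta = 0, pleiotropy = 0,
                              case_fraction = 44825 / 72729,
                              mode = c("summary-level", "individual-level"),
                              seed = 1L, target_r2 = 0.035) {
  mode <- match.arg(mode)
  if (k < 1) stop_config("k must be at least 1")
  maf <- maf %||% seq(0.10, 0.50, length.out = k)
  ld_r <- ld_r %||% default_ld(k)
  xi <- xi %||% sqrt((target_r2 / k) / (2 * maf * (1 - maf)))
  pleiotropy <- rep_len(pleiotropy, k)
  if (length(maf) != k || length(xi) != k) {
    stop_config("maf and xi must have length k")
  }
  if (any(maf <= 0 | maf > 0.5)) stop_config("maf must be in (0, 0.5]")
  if (case_fraction <= 0 || case_fraction >= 1) {
    stop_config("case_fraction must be in (0, 1)")
  }
  if (!all(dim(ld_r) == c(k, k))) stop_config("ld_r must be k x k")
  rsids <- sprintf("rs%07d", 1000001 + 7 * (seq_len(k) - 1))
  dimnames(ld_r) <- list(rsids, rsids)
  ld_r <- validate_ld_matrix(ld_r)
  structure(list(
    n_exposure = n_exposure, n_outcome = n_outcome, k = k, maf = maf,
    xi = xi, ld_r = ld_r, theta = theta, pleiotropy = pleiotropy,
    case_fraction = case_fraction, mode = mode, seed = as.integer(seed),
    rsids = rsids
  ), class = "simulation_config")
}

#' Read a simulation configuration from a YAML file
#' @param path YAML file whose keys are [simulation_config()] arguments
#'   (`ld_r` may be a nested list of rows).
#' @return a `simulation_config`.
#' @export
simulation_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$ld_r)) {
    raw$ld_r <- do.call(rbind, lapply(raw$ld_r, as.numeric))
  }
  do.call(simulation_config, raw)
}

assoc_tibble <- function(rsids, beta, se, n, eaf, trait_id) {
  z <- ifelse(se > 0, beta / se, NA_real_)
  out <- tibble::tibble(
    rsid = rsids,
    effect_allele = "A", other_allele = "G",
    eaf = eaf, beta = beta, se = se,
    pvalue = ifelse(is.na(z), NA_real_, 2 * stats::pnorm(-abs(z))),
    n = n
  )
  out <- tibble::new_tibble(out, class = "snp_associations")
  attr(out, "trait_id") <- trait_id
  out
}

#' Summary-level simulation of two-sample GWAS statistics
#'
#' Draws exposure betas from MVN(`xi`, Sigma_X) and outcome betas from
#' MVN(`theta * xi + pleiotropy`, Sigma_Y), where the covariances combine
#' analytic per-SNP standard errors with the LD correlation:
#' `se_X = 1 / sqrt(2 maf (1 - maf) n_exposure)` for the SD-unit exposure
#' and `se_Y = 1 / sqrt(2 maf (1 - maf) n_outcome cf (1 - cf))` for the
#' binary outcome on the log-odds scale (`cf` = case fraction). Fast and
#' exact with respect to the model the estimators assume.
#'
#' @param config a [simulation_config()] with mode `"summary-level"`.
#' @param se_exposure,se_outcome optional overrides of the analytic
#'   standard errors (recycled; 0 gives the noiseless degenerate case).
#' @return list with `exposure` and `outcome` association tibbles, `ld`
#'   (the true LD matrix) and the `config`; deterministic given
#'   `config$seed`.
#' @export
simulate_summary_level <- function(config, se_exposure = NULL,
                                   se_outcome = NULL) {
  if (config$mode != "summary-level") {
    stop_config("config mode is not summary-level")
  }
  cf <- config$case_fraction
  het <- 2 * config$maf * (1 - config$maf)
  sx <- se_exposure %||% (1 / sqrt(het * config$n_exposure))
  sy <- se_outcome %||% (1 / sqrt(het * config$n_outcome * cf * (1 - cf)))
  sx <- rep_len(sx, config$k)
  sy <- rep_len(sy, config$k)

  rho <- unclass(config$ld_r)
  mu_y <- config$theta * config$xi + config$pleiotropy

  set.seed(config$seed)
  bx <- if (all(sx == 0)) config$xi else
    as.numeric(MASS::mvrnorm(1, mu = config$xi, Sigma = outer(sx, sx) * rho))
  by <- if (all(sy == 0)) mu_y else
    as.numeric(MASS::mvrnorm(1, mu = mu_y, Sigma = outer(sy, sy) * rho))

  list(
    exposure = assoc_tibble(config$rsids, bx, sx, config$n_exposure,
                            config$maf, "exposure"),
    outcome = assoc_tibble(config$rsids, by, sy, config$n_outcome,
                           config$maf, "outcome"),
    ld = config$ld_r,
    config = config
  )
}

# P(Z1 < t1, Z2 < t2) for bivariate standard normal with correlation r.
binorm_cdf <- function(t1, t2, r) {
  if (abs(r) < 1e-12) return(stats::pnorm(t1) * stats::pnorm(t2))
  stats::integrate(
    function(z) stats::dnorm(z) * stats::pnorm((t2 - r * z) / sqrt(1 - r^2)),
    lower = -Inf, upper = t1, rel.tol = 1e-10
  )$value
}

# Latent normal correlation that makes thresholded Bernoulli(f1), Bernoulli(f2)
# alleles correlate at r_target (inverse of the threshold-model attenuation).
latent_allele_corr <- function(r_target, f1, f2) {
  if (abs(r_target) < 1e-12) return(0)
  t1 <- stats::qnorm(f1); t2 <- stats::qnorm(f2)
  target_joint <- f1 * f2 + r_target * sqrt(f1 * (1 - f1) * f2 * (1 - f2))
  stats::uniroot(
    function(r) binorm_cdf(t1, t2, r) - target_joint,
    interval = c(-0.999, 0.999), tol = 1e-8
  )$root
}

# Latent correlation matrix inducing (approximately) the target allele-level
# LD after thresholding at the maf quantiles.
latent_ld <- function(ld_r, maf) {
  k <- length(maf)
  m <- diag(k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- latent_allele_corr(ld_r[i, j], maf[i], maf[j])
    }
  }
  reg <- regularize_psd(m, tol = 1e-6, quiet = TRUE)
  # restore the unit diagonal after any ridge
  stats::cov2cor(unclass(reg))
}

# Genotypes for n individuals at k SNPs: two haplotypes per individual,
# each from thresholding MVN(0, latent) correlated latents at the maf
# quantile (Hardy-Weinberg and haplotype independence assumed). The induced
# genotype correlation approximates the target LD rather than matching it
# exactly.
draw_genotypes <- function(n, maf, ld_r) {
  k <- length(maf)
  thr <- stats::qnorm(maf)
  h1 <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = ld_r) < rep(thr, each = n)
  h2 <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = ld_r) < rep(thr, each = n)
  g <- h1 + h2
  storage.mode(g) <- "double"
  g
}

# Conditional per-genotype effects that make the *marginal* per-allele
# regression slopes equal xi, given genotype covariance C = D R D with
# D = diag(sqrt(2 f (1-f))).
conditional_effects <- function(xi, maf, ld_r) {
  sdg <- sqrt(2 * maf * (1 - maf))
  cc <- outer(sdg, sdg) * unclass(ld_r)
  alpha <- chol_solve(cc, xi * sdg^2)
  var_g <- sum(alpha * (cc %*% alpha))
  if (var_g >= 1) {
    stop_config("xi imply genetic exposure variance >= 1 SD^2; reduce xi")
  }
  list(alpha = alpha, resid_sd = sqrt(1 - var_g))
}

#' Individual-level simulation of two-sample GWAS statistics
#'
#' Generates genotypes by thresholding correlated normal latents at the
#' minor-allele-frequency quantile (two haplotypes per individual), a
#' continuous exposure `X` in SD units whose marginal per-allele effects
#' equal `xi`, and, in a disjoint outcome sample, a binary outcome
#' `Y ~ Bernoulli(logistic(alpha + theta X + G %*% pleiotropy))` with the
#' intercept solved numerically so the sample prevalence matches
#' `case_fraction`. Per-SNP summary statistics come from per-variant linear
#' regressions (exposure sample) and logistic regressions (outcome sample);
#' the reported LD matrix is the empirical genotype correlation in the
#' exposure sample.
#'
#' @param config a [simulation_config()] with mode `"individual-level"`
#'   and `n_exposure + n_outcome` at most 50 000 (the generator is meant
#'   for desk-scale checks, not consortium-scale data).
#' @return as [simulate_summary_level()], with `ld` the empirical LD.
#' @export
simulate_individual_level <- function(config) {
  if (config$mode != "individual-level") {
    stop_config("config mode is not individual-level")
  }
  if (config$n_exposure + config$n_outcome > 50000) {
    stop_config("individual-level mode supports at most 50 000 individuals total")
  }
  k <- config$k
  ce <- conditional_effects(config$xi, config$maf, config$ld_r)
  lat <- latent_ld(unclass(config$ld_r), config$maf)

  set.seed(config$seed)

  # exposure sample: genotypes, X, per-SNP linear regressions
  gx <- draw_genotypes(config$n_exposure, config$maf, lat)
  gx_c <- sweep(gx, 2, 2 * config$maf)
  x <- as.numeric(gx_c %*% ce$alpha) + stats::rnorm(config$n_exposure, 0, ce$resid_sd)
  exp_fit <- purrr::map(seq_len(k), function(j) {
    f <- stats::lm(x ~ gx[, j])
    s <- summary(f)$coefficients
    c(beta = s[2, 1], se = s[2, 2])
  })
  bx <- purrr::map_dbl(exp_fit, "beta")
  sx <- purrr::map_dbl(exp_fit, "se")

  ld_emp <- stats::cor(gx)
  dimnames(ld_emp) <- list(config$rsids, config$rsids)
  ld_emp <- validate_ld_matrix(ld_emp)

  # outcome sample: disjoint genotypes, latent X, binary Y, logistic fits
  gy <- draw_genotypes(config$n_outcome, config$maf, lat)
  gy_c <- sweep(gy, 2, 2 * config$maf)
  xo <- as.numeric(gy_c %*% ce$alpha) + stats::rnorm(config$n_outcome, 0, ce$resid_sd)
  eta <- config$theta * xo + as.numeric(gy %*% config$pleiotropy)
  root <- tryCatch(
    stats::uniroot(function(a) mean(stats::plogis(a + eta)) - config$case_fraction,
                   interval = c(-25, 25), tol = 1e-10),
    error = function(e) stop_simulation(
      "prevalence intercept solver failed to converge")
  )
  y <- stats::rbinom(config$n_outcome, 1, stats::plogis(root$root + eta))
  out_fit <- purrr::map(seq_len(k), function(j) {
    f <- stats::glm(y ~ gy[, j], family = stats::binomial())
    s <- summary(f)$coefficients
    c(beta = s[2, 1], se = s[2, 2])
  })
  by <- purrr::map_dbl(out_fit, "beta")
  sy <- purrr::map_dbl(out_fit, "se")

  list(
    exposure = assoc_tibble(config$rsids, bx, sx, config$n_exposure,
                            config$maf, "exposure"),
    outcome = assoc_tibble(config$rsids, by, sy, config$n_outcome,
                           config$maf, "outcome"),
    ld = ld_emp,
    config = config
  )
}

#' Simulate two-sample GWAS summary statistics
#'
#' Dispatches on `config$mode` to [simulate_summary_level()] or
#' [simulate_individual_level()].
#'
#' @param config a [simulation_config()].
#' @param ... passed to the mode-specific generator.
#' @return see the mode-specific generators.
#' @export
simulate_gwas <- function(config, ...) {
  switch(config$mode,
    "summary-level" = simulate_summary_level(config, ...),
    "individual-level" = simulate_individual_level(config, ...)
  )
}

#' Deterministic selenium-instrument candidate fixture
#'
#' A fixed, randomness-free stand-in for the published selenium instrument
#' selection arithmetic: 12 primary candidate SNPs, all genome-wide
#' significant (p < 5e-8) for circulating selenium in a discovery
#' meta-analysis, plus a restricted candidate list of 5 blood-selenium SNPs
#' carrying replication p-values < .05. The outcome-availability mask lacks
#' exactly rs558133 (a primary candidate) and rs6859667 (a restricted
#' candidate), so the primary instrument retains 11 of 12 SNPs and the
#' restricted instrument 4 of 5. Only those two rsids are real; all other
#' identifiers and every numeric value are synthetic.
#'
#' @return list with `candidates` (association tibble with
#'   `pvalue_replication` and `in_primary` columns), `outcome_available`
#'   (rsids present in the outcome GWAS) and `ld` (a mild-LD matrix over
#'   all candidates).
#' @export
selenium_fixture <- function() {
  rsids <- c("rs558133", sprintf("rs9100%03d", 1:11), "rs6859667")
  k <- length(rsids) # 13: 12 primary candidates + 1 restricted-only
  in_primary <- c(rep(TRUE, 12), FALSE)
  # replicated set: 4 primary SNPs + rs6859667
  replicated <- rsids %in% c(rsids[3], rsids[5], rsids[8], rsids[11], "rs6859667")

  maf <- round(seq(0.12, 0.48, length.out = k), 3)
  z <- seq(6.0, 11.5, length.out = k) # all beyond genome-wide significance
  n <- 9639
  se <- 1 / sqrt(2 * maf * (1 - maf) * n)
  beta <- z * se
  candidates <- tibble::tibble(
    rsid = rsids,
    effect_allele = "A", other_allele = "G",
    eaf = maf, beta = beta, se = se,
    pvalue = 2 * stats::pnorm(-z),
    n = n,
    pvalue_replication = ifelse(replicated, round(seq(0.001, 0.04,
                                                      length.out = k), 4), NA),
    in_primary = in_primary
  )
  ld <- default_ld(k, rho = 0.2)
  dimnames(ld) <- list(rsids, rsids)
  list(
    candidates = candidates,
    outcome_available = setdiff(rsids, c("rs558133", "rs6859667")),
    ld = validate_ld_matrix(ld)
  )
}
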