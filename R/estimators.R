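# Causal-effect estimators for harmonized two-sample summary data:
# single-SNP Wald ratio, correlated-variant IVW (closed form), and the
# profile maximum-likelihood model for correlated variants; plus dose
# rescaling of log-odds effects.

new_mr_estimate <- function(theta, se, method, k, ...) {
  structure(
    list(
      theta = theta,
      se = se,
      ci_low = theta - Z_CI * se,
      ci_high = theta + Z_CI * se,
      pvalue = two_sided_p(theta, se),
      method = method,
      k = k,
      ...
    ),
    class = "mr_estimate"
  )
}

# Accept either an mr_harmonized object or a tibble + explicit LD matrix;
# returns list(bx, sx, by, sy, rho, rsid).
unpack_harmonized <- function(data, ld = NULL) {
  if (inherits(data, "mr_harmonized")) {
    ld <- ld %||% data$ld
    data <- data$snps
  }
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop_input(paste0("harmonized data lacks column(s): ",
                      paste(missing, collapse = ", ")))
  }
  k <- nrow(data)
  if (k < 1) stop_input("no SNPs in harmonized data")
  if (is.null(ld)) {
    rho <- diag(k)
    rownames(rho) <- colnames(rho) <- data$rsid
  } else {
    rho <- unclass(ld)[data$rsid, data$rsid, drop = FALSE]
  }
  list(bx = data$beta_exposure, sx = data$se_exposure,
       by = data$beta_outcome, sy = data$se_outcome,
       rho = rho, rsid = data$rsid, k = k)
}

#' Single-SNP Wald ratio estimate
#'
#' The ratio `beta_outcome / beta_exposure` with a first-order delta-method
#' standard error `se_outcome / |beta_exposure|` (exposure-side uncertainty
#' ignored at first order).
#'
#' @param beta_exposure,se_exposure per-allele association with the exposure.
#' @param beta_outcome,se_outcome per-allele association with the outcome.
#' @return an [mr_estimate][tidy.mr_estimate] object, method `"wald"`.
#' @export
wald_ratio <- function(beta_exposure, se_exposure, beta_outcome, se_outcome) {
  if (beta_exposure == 0) {
    stop_estimation("Wald ratio undefined for beta_exposure = 0")
  }
  new_mr_estimate(
    theta = beta_outcome / beta_exposure,
    se = se_outcome / abs(beta_exposure),
    method = "wald", k = 1L
  )
}

#' Inverse-variance weighted estimate for correlated variants
#'
#' Generalized weighted regression of outcome betas on exposure betas
#' through the origin, with weight matrix the inverse of
#' `Omega_jk = se_outcome_j * se_outcome_k * rho_jk` where `rho` is the
#' signed LD correlation:
#' `theta = (bx' Omega^-1 by) / (bx' Omega^-1 bx)`,
#' `se = (bx' Omega^-1 bx)^(-1/2)`. With a single SNP this reduces to the
#' Wald ratio. Exposure betas are treated as fixed.
#'
#' @param data an `mr_harmonized` object from [harmonize()], or a tibble
#'   with columns `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome` (and `rsid` when `ld` is supplied).
#' @param ld signed LD matrix; identity assumed when absent.
#' @return an `mr_estimate`, method `"ivw_correlated"`.
#' @export
mr_ivw_correlated <- function(data, ld = NULL) {
  d <- unpack_harmonized(data, ld)
  omega <- outer(d$sy, d$sy) * d$rho
  omega <- regularize_psd(omega, quiet = TRUE)
  wbx <- tryCatch(chol_solve(omega, d$bx),
                  error = function(e) stop_estimation(
                    "outcome covariance singular beyond regularization"))
  denom <- sum(d$bx * wbx)
  if (denom <= 0) stop_estimation("degenerate exposure betas (bx' Omega^-1 bx <= 0)")
  new_mr_estimate(
    theta = sum(d$by * wbx) / denom,
    se = 1 / sqrt(denom),
    method = "ivw_correlated", k = d$k
  )
}

# Profile log-likelihood machinery for the correlated-variant ML model.
# Observed bx ~ MVN(xi, Sigma_X), by ~ MVN(theta * xi, Sigma_Y) with
# Sigma built from per-trait SEs and the shared LD correlation; the two
# samples are independent (two-sample design, no cross-trait covariance).
# For fixed theta the nuisance xi has the closed-form GLS solution
#   (Sigma_X^-1 + theta^2 Sigma_Y^-1) xi = Sigma_X^-1 bx + theta Sigma_Y^-1 by
# leaving a 1-D profile likelihood in theta.
make_profile_loglik <- function(bx, sx, by, sy, rho) {
  sigma_x <- regularize_psd(outer(sx, sx) * rho, quiet = TRUE)
  sigma_y <- regularize_psd(outer(sy, sy) * rho, quiet = TRUE)
  xi_inv <- tryCatch(chol2inv(chol(sigma_x)),
                     error = function(e) stop_estimation(
                       "exposure covariance singular beyond regularization"))
  yi_inv <- tryCatch(chol2inv(chol(sigma_y)),
                     error = function(e) stop_estimation(
                       "outcome covariance singular beyond regularization"))
  xb <- xi_inv %*% bx
  yb <- yi_inv %*% by
  function(theta) {
    a <- xi_inv + theta^2 * yi_inv
    xi_hat <- tryCatch(chol_solve(a, xb + theta * yb),
                       error = function(e) rep(NA_real_, length(bx)))
    if (anyNA(xi_hat)) return(-Inf)
    rx <- bx - xi_hat
    ry <- by - theta * xi_hat
    -0.5 * (sum(rx * (xi_inv %*% rx)) + sum(ry * (yi_inv %*% ry)))
  }
}

#' Maximum-likelihood estimate for correlated variants
#'
#' Fits the joint model in which the observed exposure betas are
#' multivariate normal about unknown true effects `xi` and the outcome
#' betas are multivariate normal about `theta * xi`, with per-trait
#' covariances built from the reported standard errors and the signed LD
#' correlation, and the two samples independent. `xi` is profiled out in
#' closed form (generalized least squares), leaving a one-dimensional
#' profile likelihood that is maximized over `theta` by golden-section /
#' Brent search on a bracket around the correlated-IVW estimate (expanded
#' if the maximum lands on an edge). The standard error comes from the
#' observed-information curvature of the profile log-likelihood, via a
#' central finite-difference second derivative.
#'
#' @inheritParams mr_ivw_correlated
#' @param tol convergence tolerance for the 1-D search on `theta`.
#' @param max_expand bracket-expansion attempts before declaring
#'   non-convergence.
#' @return an `mr_estimate`, method `"ml_correlated"`, with elements
#'   `loglik` (profile log-likelihood at the maximum, up to a constant)
#'   and `profile` (the profile log-likelihood function itself).
#' @export
mr_ml_correlated <- function(data, ld = NULL, tol = 1e-8, max_expand = 6L) {
  d <- unpack_harmonized(data, ld)
  ivw <- mr_ivw_correlated(data, ld)
  ll <- make_profile_loglik(d$bx, d$sx, d$by, d$sy, d$rho)

  half <- 10 * ivw$se
  lower <- ivw$theta - half
  upper <- ivw$theta + half
  opt <- NULL
  for (i in seq_len(max_expand)) {
    opt <- stats::optimize(ll, c(lower, upper), maximum = TRUE, tol = tol)
    edge <- 1e-4 * (upper - lower)
    if (opt$maximum - lower > edge && upper - opt$maximum > edge) break
    mid <- opt$maximum
    lower <- mid - 2 * (mid - lower + half)
    upper <- mid + 2 * (upper - mid + half)
    opt <- NULL
  }
  if (is.null(opt)) {
    stop_estimation(sprintf(
      "profile-likelihood search did not converge in [%g, %g]", lower, upper))
  }
  theta_hat <- opt$maximum

  h <- 1e-4 * max(abs(theta_hat), 1)
  d2 <- (ll(theta_hat + h) - 2 * ll(theta_hat) + ll(theta_hat - h)) / h^2
  if (!is.finite(d2) || d2 >= 0) {
    stop_estimation("profile log-likelihood curvature non-negative at optimum")
  }
  new_mr_estimate(
    theta = theta_hat,
    se = 1 / sqrt(-d2),
    method = "ml_correlated", k = d$k,
    loglik = opt$objective,
    profile = ll
  )
}

#' Dose scaling for a trial-equivalent exposure increment
#'
#' Packages the exposure increment of interest (in native units, e.g.
#' 114 ug/L of circulating selenium) together with the native-unit SD that
#' corresponds to one unit of the genetic exposure betas; the ratio is the
#' factor applied to a per-SD log-odds estimate.
#'
#' @param dose exposure increment in native units (> 0).
#' @param exposure_sd native-unit SD of the exposure (> 0). No default: it
#'   must come from the exposure GWAS's measurement scale.
#' @return a `dose_scaling` list with `dose`, `exposure_sd`, `scale_factor`.
#' @export
dose_scaling <- function(dose, exposure_sd) {
  if (!is.numeric(dose) || length(dose) != 1 || dose <= 0) {
    stop_config("dose must be a positive scalar")
  }
  if (!is.numeric(exposure_sd) || length(exposure_sd) != 1 || exposure_sd <= 0) {
    stop_config("exposure_sd must be a positive scalar")
  }
  structure(list(dose = dose, exposure_sd = exposure_sd,
                 scale_factor = dose / exposure_sd),
            class = "dose_scaling")
}

#' Rescale a per-SD log-odds estimate to a dose increment
#'
#' Multiplies the effect, its standard error and confidence bounds by
#' `dose / exposure_sd` and reports the corresponding odds ratio with an
#' exp-transformed CI. The z statistic, hence the p-value, is invariant to
#' this linear rescaling.
#'
#' @param estimate an `mr_estimate` on the log-odds-per-SD scale.
#' @param scaling a [dose_scaling()] object, or a dose when `exposure_sd`
#'   is given.
#' @param exposure_sd native-unit exposure SD (used when `scaling` is a
#'   bare dose).
#' @return an `mr_estimate` (subclass `mr_estimate_scaled`) on the
#'   log-odds-per-dose scale, with elements `or`, `or_ci_low`,
#'   `or_ci_high`, `dose`, `exposure_sd`, `scale_factor`.
#' @export
scale_to_dose <- function(estimate, scaling, exposure_sd = NULL) {
  if (!inherits(scaling, "dose_scaling")) {
    scaling <- dose_scaling(scaling, exposure_sd)
  }
  s <- scaling$scale_factor
  out <- new_mr_estimate(
    theta = estimate$theta * s,
    se = estimate$se * s,
    method = estimate$method,
    k = estimate$k,
    or = exp(estimate$theta * s),
    or_ci_low = exp((estimate$theta - Z_CI * estimate$se) * s),
    or_ci_high = exp((estimate$theta + Z_CI * estimate$se) * s),
    dose = scaling$dose,
    exposure_sd = scaling$exposure_sd,
    scale_factor = s
  )
  out$pvalue <- estimate$pvalue # z is scale-invariant
  class(out) <- c("mr_estimate_scaled", class(out))
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate: %s, k = %d>\n", x$method, x$k))
  cat(sprintf("  theta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$theta, x$se, x$ci_low, x$ci_high, x$pvalue))
  if (!is.null(x$or)) {
    cat(sprintf("  OR per %.4g native units = %.3f (%.3f to %.3f)\n",
                x$dose, x$or, x$or_ci_low, x$or_ci_high))
  }
  invisible(x)
}

#' Tidy an MR estimate into a one-row tibble
#'
#' @param x an `mr_estimate`.
#' @param ... unused.
#' @return one-row tibble with `method`, `k`, `theta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue` and, when dose-scaled, `or`, `or_ci_low`,
#'   `or_ci_high`, `dose`, `exposure_sd`.
#' @exportS3Method generics::tidy
tidy.mr_estimate <- function(x, ...) {
  out <- tibble::tibble(
    method = x$method, k = x$k, theta = x$theta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue
  )
  if (!is.null(x$or)) {
    out$or <- x$or
    out$or_ci_low <- x$or_ci_low
    out$or_ci_high <- x$or_ci_high
    out$dose <- x$dose
    out$exposure_sd <- x$exposure_sd
  }
  out
}

#' One-row model summary of an MR estimate
#' @param x an `mr_estimate`.
#' @param ... unused.
#' @return tibble with `method`, `k`, `statistic` (z), `pvalue` and
#'   `loglik` when available.
#' @exportS3Method generics::glance
glance.mr_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method, k = x$k,
    statistic = x$theta / x$se, pvalue = x$pvalue,
    loglik = if (!is.null(x$loglik)) x$loglik else NA_real_
  )
}
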