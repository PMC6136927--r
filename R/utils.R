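# Internal helpers shared across modules.

stop_input <- function(msg, ...) rlang::abort(msg, class = "corrmr_input_error", ...)
stop_config <- function(msg, ...) rlang::abort(msg, class = "corrmr_config_error", ...)
stop_estimation <- function(msg, ...) rlang::abort(msg, class = "corrmr_estimation_error", ...)
stop_instrument <- function(msg, ...) rlang::abort(msg, class = "corrmr_instrument_error", ...)
stop_simulation <- function(msg, ...) rlang::abort(msg, class = "corrmr_simulation_error", ...)

#' Ridge-regularize a symmetric matrix to positive semi-definiteness
#'
#' If the smallest eigenvalue of `m` falls below `tol`, a diagonal ridge of
#' `tol - lambda_min` is added so the result has smallest eigenvalue `tol`.
#' The ridge actually applied is recorded in the `"ridge"` attribute
#' (0 when no regularization was needed).
#'
#' @param m symmetric numeric matrix.
#' @param tol eigenvalue floor (default `1e-8`).
#' @param quiet suppress the log message when a ridge is applied.
#' @return `m`, possibly with a diagonal ridge added; attribute `"ridge"`.
#' @keywords internal
regularize_psd <- function(m, tol = PSD_TOL, quiet = FALSE) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  lambda_min <- min(ev)
  ridge <- 0
  if (lambda_min < tol) {
    ridge <- tol - lambda_min
    m <- m + diag(ridge, nrow(m))
    if (!quiet) {
      rlang::inform(sprintf(
        "regularized matrix: smallest eigenvalue %.3e, ridge %.3e applied",
        lambda_min, ridge
      ))
    }
  }
  attr(m, "ridge") <- ridge
  m
}

# Two-sided normal p-value from an estimate and its standard error.
two_sided_p <- function(theta, se) 2 * stats::pnorm(-abs(theta / se))

# Solve A x = b for symmetric positive-definite A via Cholesky.
chol_solve <- function(a, b) {
  ch <- chol(a)
  backsolve(ch, backsolve(ch, b, transpose = TRUE))
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}
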