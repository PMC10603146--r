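# Partial-likelihood machinery shared by all fitting modules.
# Ties are handled with the Breslow approximation throughout, and the risk
# set at an event time t is {i : T_i >= t} (the failing subject included).

#' Cox partial log-likelihood
#'
#' Evaluates the Breslow partial log-likelihood
#' `pl(beta) = sum_i delta_i [beta'x_i - log sum_{i' in R(t_i)} exp(beta'x_i')]`
#' with log-sum-exp stabilisation.
#'
#' @param beta Coefficient vector of length `p`.
#' @param data A [survival_dataset()].
#' @return The scalar partial log-likelihood.
#' @export
partial_log_likelihood <- function(beta, data) {
  stopifnot(inherits(data, "survival_dataset"))
  if (length(beta) != data$p) stop("beta does not conform with data")
  if (data$n == 0) stop("empty dataset")
  eta <- as.vector(data$X %*% beta)
  pl <- cpp_cox_pl(eta, data$time, as.numeric(data$event))
  if (!is.finite(pl)) stop("partial log-likelihood overflowed")
  pl
}

#' Gradient of the Cox partial log-likelihood
#'
#' @inheritParams partial_log_likelihood
#' @return The length-`p` score vector at `beta`.
#' @export
partial_ll_gradient <- function(beta, data) {
  stopifnot(inherits(data, "survival_dataset"))
  if (length(beta) != data$p) stop("beta does not conform with data")
  eta <- as.vector(data$X %*% beta)
  d <- cpp_cox_eta_derivs(eta, data$time, as.numeric(data$event))
  as.vector(crossprod(data$X, d$u))
}

# Internal: observed information (negative Hessian) at beta.
cox_information <- function(beta, data) {
  eta <- as.vector(data$X %*% beta)
  cpp_cox_info(data$X, eta, data$time, as.numeric(data$event))
}

new_model_fit <- function(method, beta, names = NULL, se = NULL,
                          loglik = NA_real_, lambda = NULL, alpha = NULL,
                          converged = TRUE, details = list()) {
  beta <- as.vector(beta)
  if (!is.null(names)) names(beta) <- names
  if (!is.null(se) && !is.null(names)) names(se) <- names
  structure(
    list(method = method, beta = beta, se = se, loglik = loglik,
         lambda = lambda, alpha = alpha, converged = converged,
         details = details),
    class = "survsel_fit"
  )
}

#' @export
print.survsel_fit <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat("survsel_fit:", x$method, "|", length(x$beta), "coefficients,",
      nz, "non-zero")
  if (!is.null(x$lambda)) cat(" | lambda =", signif(x$lambda, 4))
  if (!is.null(x$alpha)) cat(", alpha =", x$alpha)
  cat("\n")
  invisible(x)
}

#' Maximum partial-likelihood Cox fit (low-dimensional)
#'
#' Newton optimisation with step-halving of the Breslow partial
#' log-likelihood, for use where `p < n` and the design has full rank:
#' BIC-rule refits, adaptive-lasso sanity checks, oracle comparisons.
#' Standard errors come from the inverse observed information.
#'
#' @param data A [survival_dataset()].
#' @param ridge Optional non-negative ridge penalty (scalar or length-`p`)
#'   added as `0.5 * sum d_j beta_j^2`; the default 0 gives the MLE.
#' @param beta_init Optional starting value (default 0).
#' @param tol Convergence tolerance on the relative change in the
#'   objective.
#' @param maxit Iteration bound.
#' @return A `survsel_fit` with coefficients, standard errors, and the
#'   maximised partial log-likelihood in `$loglik`.
#' @export
fit_cox_mle <- function(data, ridge = 0, beta_init = NULL, tol = 1e-9,
                        maxit = 100) {
  stopifnot(inherits(data, "survival_dataset"))
  p <- data$p
  d <- rep_len(as.numeric(ridge), p)
  init <- beta_init %||% numeric(p)
  res <- cpp_cox_newton(data$X, data$time, as.numeric(data$event), d,
                        init, tol, maxit)
  if (res$singular)
    stop(structure(
      class = c("survsel_rank_error", "error", "condition"),
      list(message = paste("Cox information is singular (rank-deficient",
                           "design or p too large); use a penalized fit"),
           call = sys.call())))
  if (!res$converged)
    warning("fit_cox_mle did not converge in ", maxit, " iterations")
  info <- res$info
  diag(info) <- diag(info) + d
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) NULL)
  new_model_fit("cox_mle", res$beta, names = data$feature_names, se = se,
                loglik = res$pl, converged = res$converged,
                details = list(iter = res$iter, ridge = ridge))
}
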