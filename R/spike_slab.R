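# Posterior-mode spike-and-slab Cox models, fitted by EM.
#
# Three prior families on each coefficient beta_j with latent inclusion
# indicator gamma_j:
#   * SSVS:      (1-gamma) N(0, tau^2)   + gamma N(0, c^2 tau^2), c = 1/tau
#   * sslasso:   (1-gamma) DE(0, s0)     + gamma DE(0, s1)
#   * gsslasso:  as sslasso with gamma_{kj} | p_k ~ Bernoulli(p_k) shared
#                within covariate group k, p_k ~ Beta(a, b)
# The E-step computes the inclusion responsibilities gamma_j at the current
# mode; the M-step maximises the resulting penalised partial likelihood
# (a weighted ridge for SSVS, a weighted lasso for the DE families) by
# coordinate descent.  p_k is updated to its conditional beta-posterior
# mean, which for a = b = 1 is the within-group mean of gamma.
# All fitting happens on standardized covariates; coefficients and
# standard errors are returned on the original scale.

dde <- function(x, scale) exp(-abs(x) / scale) / (2 * scale)

# Shared EM engine.  family "de": spike/slab are double-exponential with
# scales s0 < s1; family "gauss": spike sd tau, slab sd ctau.
em_spike_slab <- function(Xs, time, event, family, groups_idx,
                          s0 = NULL, s1 = NULL, tau = NULL, ctau = NULL,
                          a = 1, b = 1, tol = 1e-6, maxit = 500,
                          beta_init = NULL) {
  n <- length(time)
  p <- ncol(Xs)
  ev <- as.numeric(event)
  beta <- beta_init %||% numeric(p)
  gamma <- rep(0.5, p)
  p_k <- rep(0.5, length(groups_idx))
  p_var <- numeric(p)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  spike_dens <- function(bta) {
    if (family == "de") dde(bta, s0) else stats::dnorm(bta, 0, tau)
  }
  slab_dens <- function(bta) {
    if (family == "de") dde(bta, s1) else stats::dnorm(bta, 0, ctau)
  }
  for (it in seq_len(maxit)) {
    for (k in seq_along(groups_idx)) p_var[groups_idx[[k]]] <- p_k[k]
    f0 <- spike_dens(beta)
    f1 <- slab_dens(beta)
    gamma <- p_var * f1 / (p_var * f1 + (1 - p_var) * f0)
    # group inclusion probabilities: beta-posterior mean
    p_k <- vapply(groups_idx, function(idx) {
      (a - 1 + sum(gamma[idx])) / (a + b - 2 + length(idx))
    }, numeric(1))
    p_k <- pmin(pmax(p_k, 1e-10), 1 - 1e-10)
    if (family == "de") {
      w <- gamma / s1 + (1 - gamma) / s0   # per-variable lasso weight 1/S_j
      d <- rep(0, p)
    } else {
      w <- rep(0, p)
      d <- gamma / ctau^2 + (1 - gamma) / tau^2
    }
    # M-step: the subproblem need only be solved a notch tighter than the
    # outer EM tolerance (generalized EM; the ascent check still runs)
    res <- cpp_cox_cd(Xs, time, ev, w, d, beta, tol / 10, 50, 100)
    beta_new <- as.vector(res$beta)
    # marginal log posterior (gamma integrated out), for the ascent check
    for (k in seq_along(groups_idx)) p_var[groups_idx[[k]]] <- p_k[k]
    lp <- res$pl +
      sum(log((1 - p_var) * spike_dens(beta_new) +
                p_var * slab_dens(beta_new))) +
      sum(stats::dbeta(p_k, a, b, log = TRUE))
    trace <- c(trace, lp)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  f0 <- spike_dens(beta)
  f1 <- slab_dens(beta)
  for (k in seq_along(groups_idx)) p_var[groups_idx[[k]]] <- p_k[k]
  gamma <- p_var * f1 / (p_var * f1 + (1 - p_var) * f0)
  prior_curv <- if (family == "de") {
    (gamma / s1 + (1 - gamma) / s0) / pmax(abs(beta), 1e-3)
  } else {
    gamma / ctau^2 + (1 - gamma) / tau^2
  }
  list(beta = beta, gamma = gamma, p_k = p_k, prior_curv = prior_curv,
       iter = it, converged = converged, trace = trace)
}

# CV over a scale grid using the Verweij - van Houwelingen deviance.
# Fold fits only rank the scale: they use a looser EM tolerance and are
# warm-started along the (increasing-scale) grid within each fold.
cv_spike_slab <- function(Xs, time, event, family, groups_idx, grid,
                          fixed, foldid, a = 1, b = 1) {
  k <- max(foldid)
  ev <- as.numeric(event)
  ord <- order(grid)
  loss <- numeric(length(grid))
  for (f in seq_len(k)) {
    train <- which(foldid != f)
    warm <- NULL
    for (i in ord) {
      g <- grid[i]
      em <- if (family == "de") {
        em_spike_slab(Xs[train, , drop = FALSE], time[train], ev[train],
                      "de", groups_idx, s0 = g, s1 = fixed$s1,
                      a = a, b = b, tol = 1e-4, maxit = 100,
                      beta_init = warm)
      } else {
        em_spike_slab(Xs[train, , drop = FALSE], time[train], ev[train],
                      "gauss", groups_idx, tau = g,
                      ctau = fixed$ctau_fun(g), a = a, b = b,
                      tol = 1e-4, maxit = 100, beta_init = warm)
      }
      warm <- em$beta
      eta_full <- as.vector(Xs %*% em$beta)
      loss[i] <- loss[i] - 2 * (cpp_cox_pl(eta_full, time, ev) -
                                  cpp_cox_pl(eta_full[train], time[train],
                                             ev[train]))
    }
  }
  # ties broken toward the stronger-shrinkage (smaller) scale
  best <- which(loss == min(loss))
  best <- best[which.min(grid[best])]
  list(grid = grid, cv_loss = loss, chosen = grid[best])
}

finalize_spike_slab <- function(method, em, std, data, chosen_scale,
                                cv, extra = list()) {
  beta <- em$beta / std$scale
  D <- diag(em$prior_curv, length(em$beta))
  H <- cpp_cox_info(std$X, as.vector(std$X %*% em$beta), data$time,
                    as.numeric(data$event))
  se_flag <- FALSE
  se_std <- tryCatch(sqrt(diag(solve(H + D))), error = function(e) NULL)
  if (is.null(se_std) || any(!is.finite(se_std))) {
    se_std <- 1 / sqrt(diag(H) + em$prior_curv)
    se_flag <- TRUE
  }
  fit <- new_model_fit(method, beta, names = data$feature_names,
                       se = se_std / std$scale,
                       loglik = cpp_cox_pl(as.vector(std$X %*% em$beta),
                                           data$time,
                                           as.numeric(data$event)),
                       converged = em$converged,
                       details = c(list(
                         beta_std = em$beta, prior_curv = em$prior_curv,
                         se_diag_fallback = se_flag,
                         standardize = std[c("center", "scale")],
                         trace = em$trace, iter = em$iter, cv = cv),
                         extra))
  fit$gamma_post <- em$gamma
  fit$p_post <- em$p_k
  fit$chosen_scale <- chosen_scale
  fit
}

groups_to_idx <- function(groups, p) {
  if (is.null(groups)) {
    as.list(seq_len(p))          # singleton groups: per-variable p_j
  } else {
    split(seq_len(p), factor(groups, levels = unique(groups)))
  }
}

#' Spike-and-slab Cox model with Gaussian mixture prior (SSVS)
#'
#' Each coefficient has prior
#' `(1 - gamma) N(0, tau^2) + gamma N(0, c^2 tau^2)` with `c = 1/tau`, so
#' the slab has unit standard deviation.  The posterior mode is found by
#' EM (ridge-type M-step); the spike scale `tau` is tuned by
#' cross-validated grid search.
#'
#' @param data A [survival_dataset()].
#' @param tau_grid Positive spike scales to search.
#' @param folds Number of CV folds.
#' @param seed Optional seed for the fold draw.
#' @param foldid Optional shared fold assignment.
#' @param slab_c Optional fixed slab multiplier (test hook); the default
#'   `NULL` uses the `c = 1/tau` convention.
#' @return A `survsel_fit` with posterior-mode coefficients, mode-curvature
#'   standard errors, posterior inclusion probabilities `$gamma_post`, and
#'   the CV-chosen `$chosen_scale`.
#' @export
fit_ssvs_cox <- function(data, tau_grid = c(0.001, 0.005, 0.01, 0.05, 0.1),
                         folds = 10, seed = NULL, foldid = NULL,
                         slab_c = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  if (any(tau_grid <= 0)) stop("tau_grid must be positive")
  std <- standardize_design(data$X)
  if (is.null(foldid)) foldid <- make_folds(data$event, folds, seed)
  gi <- groups_to_idx(NULL, data$p)
  ctau_fun <- function(tau) if (is.null(slab_c)) 1 else slab_c * tau
  cv <- if (length(tau_grid) > 1) {
    cv_spike_slab(std$X, data$time, data$event, "gauss", gi, tau_grid,
                  list(ctau_fun = ctau_fun), foldid)
  } else list(grid = tau_grid, cv_loss = NA_real_, chosen = tau_grid[1])
  tau <- cv$chosen
  em <- em_spike_slab(std$X, data$time, data$event, "gauss", gi,
                      tau = tau, ctau = ctau_fun(tau))
  if (!em$converged)
    warning("SSVS EM did not converge; returning best iterate")
  finalize_spike_slab("ssvs", em, std, data, tau, cv,
                      extra = list(tau = tau, c = ctau_fun(tau) / tau))
}

#' Spike-and-slab lasso Cox model (double-exponential mixture)
#'
#' Prior `(1 - gamma) DE(0, s0) + gamma DE(0, s1)` on each coefficient.
#' The slab scale `s1` is fixed at a relatively large value (default 1)
#' and the spike scale `s0` is tuned by cross-validated grid search; the
#' posterior mode is found by EM with a weighted Cox-lasso M-step.
#'
#' @param data A [survival_dataset()].
#' @param s0_grid Spike scales to search (each `< s1`).
#' @param s1 Slab scale.
#' @param folds,seed,foldid As in [fit_ssvs_cox()].
#' @return A `survsel_fit`; see [fit_ssvs_cox()] for the extra fields.
#' @export
fit_sslasso_cox <- function(data,
                            s0_grid = c(0.005, 0.01, 0.02, 0.03, 0.05, 0.1),
                            s1 = 1, folds = 10, seed = NULL,
                            foldid = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  if (any(s0_grid <= 0) || any(s0_grid > s1))
    stop("s0_grid must be positive and no larger than s1")
  std <- standardize_design(data$X)
  if (is.null(foldid)) foldid <- make_folds(data$event, folds, seed)
  gi <- groups_to_idx(NULL, data$p)
  cv <- if (length(s0_grid) > 1) {
    cv_spike_slab(std$X, data$time, data$event, "de", gi, s0_grid,
                  list(s1 = s1), foldid)
  } else list(grid = s0_grid, cv_loss = NA_real_, chosen = s0_grid[1])
  em <- em_spike_slab(std$X, data$time, data$event, "de", gi,
                      s0 = cv$chosen, s1 = s1)
  if (!em$converged)
    warning("sslasso EM did not converge; returning best iterate")
  finalize_spike_slab("sslasso", em, std, data, cv$chosen, cv,
                      extra = list(s0 = cv$chosen, s1 = s1))
}

#' Group spike-and-slab lasso Cox model
#'
#' As [fit_sslasso_cox()], but the latent inclusion indicators share a
#' group-specific probability `p_k ~ Beta(a, b)`; if a group holds
#' important predictors its estimated `p_k` grows, borrowing strength
#' across the group.  With every variable in its own group and
#' `a = b = 1` the model reduces exactly to the sslasso fit.
#'
#' @param data A [survival_dataset()]; `groups` defaults to
#'   `data$groups`.
#' @param groups Length-`p` group labels.
#' @param s0_grid,s1,folds,seed,foldid As in [fit_sslasso_cox()].
#' @param a,b Beta-prior hyperparameters for the group inclusion
#'   probabilities (`a = b = 1` is the uniform prior).
#' @return A `survsel_fit`; `$p_post` holds the per-group inclusion
#'   probability estimates.
#' @export
fit_gsslasso_cox <- function(data, groups = data$groups,
                             s0_grid = c(0.005, 0.01, 0.02, 0.03, 0.05,
                                         0.1),
                             s1 = 1, a = 1, b = 1, folds = 10, seed = NULL,
                             foldid = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  if (is.null(groups)) stop("gsslasso requires group labels")
  if (length(groups) != data$p) stop("groups must have one label per column")
  if (any(s0_grid <= 0) || any(s0_grid > s1))
    stop("s0_grid must be positive and no larger than s1")
  gi <- groups_to_idx(groups, data$p)
  if (any(lengths(gi) == 0)) stop("empty covariate group")
  std <- standardize_design(data$X)
  if (is.null(foldid)) foldid <- make_folds(data$event, folds, seed)
  cv <- if (length(s0_grid) > 1) {
    cv_spike_slab(std$X, data$time, data$event, "de", gi, s0_grid,
                  list(s1 = s1), foldid, a = a, b = b)
  } else list(grid = s0_grid, cv_loss = NA_real_, chosen = s0_grid[1])
  em <- em_spike_slab(std$X, data$time, data$event, "de", gi,
                      s0 = cv$chosen, s1 = s1, a = a, b = b)
  if (!em$converged)
    warning("gsslasso EM did not converge; returning best iterate")
  fit <- finalize_spike_slab("gsslasso", em, std, data, cv$chosen, cv,
                             extra = list(s0 = cv$chosen, s1 = s1,
                                          a = a, b = b, groups = groups))
  names(fit$p_post) <- names(gi)
  fit
}

#' Standard errors at a spike-and-slab posterior mode
#'
#' Recomputes the mode-curvature standard errors for a fitted
#' spike-and-slab model: the inverse of the penalised observed information
#' (partial-likelihood curvature plus prior curvature) at the posterior
#' mode.  For the double-exponential families the prior curvature uses a
#' local quadratic approximation `(1/S_j) / max(|beta_j|, 1e-3)`, which
#' diverges for spiked-out coefficients so their intervals collapse onto
#' zero.  If the penalised information cannot be inverted, a diagonal
#' approximation is used and flagged.
#'
#' @param fit A converged spike-and-slab `survsel_fit`.
#' @param data The dataset it was fitted on.
#' @return Length-`p` vector of standard errors on the original covariate
#'   scale; attribute `"diag_fallback"` records whether the diagonal
#'   approximation was used.
#' @export
posterior_se <- function(fit, data) {
  stopifnot(inherits(fit, "survsel_fit"),
            inherits(data, "survival_dataset"))
  det <- fit$details
  if (is.null(det$beta_std) || is.null(det$prior_curv))
    stop("fit does not carry spike-and-slab state")
  Xs <- sweep(sweep(data$X, 2L, det$standardize$center, "-"), 2L,
              det$standardize$scale, "/")
  H <- cpp_cox_info(Xs, as.vector(Xs %*% det$beta_std), data$time,
                    as.numeric(data$event))
  D <- diag(det$prior_curv, length(det$beta_std))
  flag <- FALSE
  se_std <- tryCatch(sqrt(diag(solve(H + D))), error = function(e) NULL)
  if (is.null(se_std) || any(!is.finite(se_std))) {
    se_std <- 1 / sqrt(diag(H) + det$prior_curv)
    flag <- TRUE
  }
  out <- se_std / det$standardize$scale
  names(out) <- data$feature_names
  attr(out, "diag_fallback") <- flag
  out
}
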