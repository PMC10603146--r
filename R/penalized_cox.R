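# Penalized Cox regression: lasso, elastic net, ridge, adaptive lasso.
#
# The penalised objective is written on the unscaled partial likelihood,
#   Q(beta) = -pl(beta) + lambda * sum_j w_j |beta_j|   (+ L2 part),
# and solved with glmnet, whose Cox objective is -(1/n) pl + lambda_g * P.
# Covariates are standardised internally to unit (population) variance and
# coefficients are returned on the original scale.  The elastic-net L2
# term uses the standard (1 - alpha)/2 * sum beta^2 parameterisation.

#' Specify a Cox penalty
#'
#' @param kind One of `"lasso"`, `"elastic_net"`, `"ridge"`,
#'   `"adaptive_lasso"`.
#' @param lambda Non-negative regularisation parameter, on the scale of
#'   the unscaled objective `-pl(beta) + lambda * penalty`.
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (`alpha = 1` is
#'   the lasso, `alpha = 0` the ridge); required for `"elastic_net"`.
#' @param weights Length-`p` positive weights for `"adaptive_lasso"`;
#'   entries may be `Inf` to exclude a variable entirely.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(kind = c("lasso", "elastic_net", "ridge",
                                  "adaptive_lasso"),
                         lambda, alpha = NULL, weights = NULL) {
  kind <- match.arg(kind)
  if (lambda < 0) stop("lambda must be non-negative")
  if (kind == "elastic_net") {
    if (is.null(alpha) || alpha < 0 || alpha > 1)
      stop("elastic_net requires alpha in [0, 1]")
  }
  if (kind == "adaptive_lasso") {
    if (is.null(weights) || any(weights <= 0, na.rm = TRUE))
      stop("adaptive_lasso requires strictly positive weights (Inf allowed)")
  }
  structure(list(kind = kind, lambda = lambda, alpha = alpha,
                 weights = weights),
            class = "penalty_spec")
}

# Effective glmnet alpha for each penalty kind.
penalty_alpha <- function(kind, alpha) {
  switch(kind,
         lasso = 1, adaptive_lasso = 1, ridge = 0,
         elastic_net = alpha)
}

# Largest lambda (on the unscaled objective) with an all-zero solution:
# max_j |score_j(0)| / w_j, divided by max(alpha, 1e-3) as in glmnet.
lambda_max_unscaled <- function(Xs, time, event, alpha = 1, weights = NULL) {
  d <- cpp_cox_eta_derivs(numeric(length(time)), time, as.numeric(event))
  g <- abs(as.vector(crossprod(Xs, d$u)))
  if (!is.null(weights)) {
    g <- g / weights          # Inf weight -> 0, excluded from the max
    g[!is.finite(weights)] <- 0
  }
  max(g) / max(alpha, 1e-3)
}

default_lambda_grid <- function(lmax, nlambda = 100,
                                lambda_min_ratio = 0.01) {
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# glmnet call on pre-standardised X for a decreasing unscaled-lambda
# sequence; returns the glmnet fit plus the conversion factor.
glmnet_cox <- function(Xs, time, event, alpha, lambda_seq, weights = NULL,
                       thresh = 1e-11) {
  n <- length(time)
  p <- ncol(Xs)
  pf <- weights %||% rep(1, p)
  excl <- which(!is.finite(pf))
  pf_fit <- pf
  pf_fit[excl] <- 1           # excluded via `exclude`, keep pf finite
  # glmnet rescales penalty factors to sum to p; compensate in lambda so
  # that lambda_g * pf_rescaled_j = lambda * w_j / n.
  conv <- sum(pf_fit) / (p * n)
  fit <- withCallingHandlers(
    glmnet::glmnet(
      Xs, survival::Surv(time, event), family = "cox",
      alpha = alpha, lambda = lambda_seq * conv,
      standardize = FALSE, penalty.factor = pf_fit,
      exclude = if (length(excl)) excl else NULL,
      thresh = thresh, maxit = 1e6
    ),
    warning = function(w) {
      # short user-supplied lambda sequences are intentional here
      if (grepl("1 or less", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  list(fit = fit, conv = conv)
}

#' Fit a penalized Cox model at a fixed penalty
#'
#' Minimises `-pl(beta) + lambda * sum_j w_j |beta_j|` (plus the ridge part
#' for the elastic net) by coordinate descent, warm-started along a
#' decreasing lambda path down to the requested value.  Coefficients shrunk
#' out are exactly zero.
#'
#' @param data A [survival_dataset()].
#' @param spec A [penalty_spec()].
#' @return A `survsel_fit` with coefficients on the original covariate
#'   scale.
#' @export
fit_penalized_cox <- function(data, spec) {
  stopifnot(inherits(data, "survival_dataset"),
            inherits(spec, "penalty_spec"))
  std <- standardize_design(data$X)
  alpha <- penalty_alpha(spec$kind, spec$alpha)
  w <- if (spec$kind == "adaptive_lasso") spec$weights else NULL
  lmax <- lambda_max_unscaled(std$X, data$time, data$event, alpha, w)
  lam <- spec$lambda
  if (lam >= lmax && alpha > 0) {
    path <- c(lam * 1.001, lam)
  } else if (lam == 0) {
    path <- c(default_lambda_grid(lmax, 25, 0.005), 0)
  } else {
    path <- c(exp(seq(log(lmax), log(max(lam, 1e-12)), length.out = 25)))
    path[length(path)] <- lam
  }
  g <- glmnet_cox(std$X, data$time, data$event, alpha, path, w)
  beta_std <- as.vector(coef(g$fit, s = lam * g$conv, exact = FALSE))
  beta <- beta_std / std$scale
  beta[beta_std == 0] <- 0
  new_model_fit(spec$kind, beta, names = data$feature_names,
                lambda = lam, alpha = spec$alpha,
                details = list(weights = w, standardize = std[c("center",
                                                                "scale")],
                               beta_std = beta_std))
}

#' Indices of non-zero coefficients
#'
#' The selection rule for penalized methods: a variable is selected iff its
#' fitted coefficient is exactly non-zero.
#'
#' @param fit A `survsel_fit`.
#' @return Sorted integer vector of 1-based selected indices.
#' @export
select_nonzero <- function(fit) {
  stopifnot(inherits(fit, "survsel_fit"))
  unname(which(fit$beta != 0))
}

#' Seeded cross-validation folds with events in every fold
#'
#' @param event Event indicator vector (defines `n`).
#' @param k Number of folds.
#' @param seed Optional integer seed.
#' @param max_tries Redraw bound when a fold has no events.
#' @return Integer fold labels of length `n`.
#' @export
make_folds <- function(event, k = 10, seed = NULL, max_tries = 100) {
  if (k < 2) stop("folds must be >= 2")
  n <- length(event)
  for (try in seq_len(max_tries)) {
    foldid <- with_seed(if (is.null(seed)) NULL else sub_seed(seed, try),
                        sample(rep_len(seq_len(k), n)))
    ok <- all(vapply(seq_len(k), function(f) sum(event[foldid == f]) > 0,
                     numeric(1)) > 0)
    if (ok) return(foldid)
  }
  stop("could not build ", k, " folds each containing an event; ",
       "data has too few events")
}

# Verweij - van Houwelingen cross-validated partial-likelihood deviance
# for a matrix of standardized-scale coefficients (p x nlambda) fitted on
# the training rows of one fold:  -2 * [ pl_full(b) - pl_train(b) ].
cv_fold_deviance <- function(beta_mat, Xs, time, event, train) {
  ev <- as.numeric(event)
  eta_full <- Xs %*% beta_mat
  eta_train <- eta_full[train, , drop = FALSE]
  vapply(seq_len(ncol(beta_mat)), function(j) {
    -2 * (cpp_cox_pl(eta_full[, j], time, ev) -
            cpp_cox_pl(eta_train[, j], time[train], ev[train]))
  }, numeric(1))
}

#' Cross-validated grid search for penalized Cox models
#'
#' 10-fold (by default) cross-validation using the Verweij-van Houwelingen
#' partial-likelihood deviance.  For the elastic net the search is a
#' two-stage sweep: for each alpha on its grid, lambda is chosen by CV,
#' and the best (alpha, lambda) pair overall is returned.  Ties are broken
#' toward the larger (sparser) lambda.
#'
#' @param data A [survival_dataset()].
#' @param kind Penalty kind as in [penalty_spec()].
#' @param lambda_grid Optional decreasing lambda grid (unscaled objective);
#'   default 100 log-spaced values from `lambda_max` down to
#'   `0.01 * lambda_max`.
#' @param alpha_grid Elastic-net alpha grid; default `seq(0.1, 1, 0.1)`.
#' @param folds Number of folds (>= 2).
#' @param seed Optional seed controlling the fold draw.
#' @param foldid Optional explicit fold labels (shared-fold comparisons).
#' @param weights Adaptive-lasso weights.
#' @return An object of class `survsel_cv`: grid with mean CV deviance,
#'   `chosen` hyperparameters, and the fold assignment.
#' @export
cross_validate <- function(data, kind = "lasso", lambda_grid = NULL,
                           alpha_grid = NULL, folds = 10, seed = NULL,
                           foldid = NULL, weights = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  std <- standardize_design(data$X)
  if (is.null(foldid)) foldid <- make_folds(data$event, folds, seed)
  k <- max(foldid)
  alphas <- if (kind == "elastic_net") {
    alpha_grid %||% seq(0.1, 1, by = 0.1)
  } else penalty_alpha(kind, NULL)
  grid_rows <- list()
  for (a in alphas) {
    lam_grid <- lambda_grid %||% default_lambda_grid(
      lambda_max_unscaled(std$X, data$time, data$event, a, weights))
    lam_grid <- sort(lam_grid, decreasing = TRUE)
    dev <- matrix(0, length(lam_grid), k)
    for (f in seq_len(k)) {
      train <- which(foldid != f)
      # fold fits only rank hyperparameters: glmnet's default-level
      # tolerance is ample and much faster than the final-fit tolerance
      lam_u <- unique(lam_grid)   # duplicated grid points: fit once
      g <- glmnet_cox(std$X[train, , drop = FALSE], data$time[train],
                      data$event[train], a, lam_u, weights,
                      thresh = 1e-7)
      bm_u <- as.matrix(coef(g$fit, s = lam_u * g$conv, exact = FALSE))
      bm <- bm_u[, match(lam_grid, lam_u), drop = FALSE]
      dev[, f] <- cv_fold_deviance(bm, std$X, data$time, data$event, train)
    }
    grid_rows[[length(grid_rows) + 1L]] <-
      data.frame(alpha = a, lambda = lam_grid, cv_loss = rowSums(dev))
  }
  grid <- do.call(rbind, grid_rows)
  # minimise; ties toward larger lambda (grid is decreasing within alpha)
  best <- which(grid$cv_loss == min(grid$cv_loss))
  best <- best[which.max(grid$lambda[best])]
  structure(
    list(kind = kind, grid = grid,
         chosen = list(alpha = grid$alpha[best],
                       lambda = grid$lambda[best]),
         foldid = foldid),
    class = "survsel_cv"
  )
}

#' Cross-validate and fit a penalized Cox model
#'
#' Convenience wrapper: run [cross_validate()] and refit on the full data
#' at the chosen hyperparameters.
#'
#' @inheritParams cross_validate
#' @return A `survsel_fit` with the `survsel_cv` object in
#'   `$details$cv`.
#' @export
fit_cv_penalized <- function(data, kind = "lasso", folds = 10, seed = NULL,
                             foldid = NULL, weights = NULL,
                             lambda_grid = NULL, alpha_grid = NULL) {
  cv <- cross_validate(data, kind, lambda_grid = lambda_grid,
                       alpha_grid = alpha_grid, folds = folds, seed = seed,
                       foldid = foldid, weights = weights)
  spec <- if (kind == "adaptive_lasso") {
    penalty_spec(kind, lambda = cv$chosen$lambda, weights = weights)
  } else if (kind == "elastic_net") {
    penalty_spec(kind, lambda = cv$chosen$lambda, alpha = cv$chosen$alpha)
  } else {
    penalty_spec(kind, lambda = cv$chosen$lambda)
  }
  fit <- fit_penalized_cox(data, spec)
  fit$details$cv <- cv
  fit
}

#' Adaptive lasso for the Cox model
#'
#' Two-stage procedure: stage 1 fits a cross-validated ridge Cox model to
#' obtain initial estimates `beta_tilde`; stage 2 runs a cross-validated
#' lasso with variable-specific weights `w_j = 1 / |beta_tilde_j|`
#' (computed on the standardized scale).  Variables whose ridge estimate
#' falls below `eps` in absolute value receive infinite weight and are
#' excluded.
#'
#' @param data A [survival_dataset()].
#' @param folds Number of CV folds.
#' @param seed Optional seed.
#' @param foldid Optional shared fold assignment.
#' @param eps Threshold on `|beta_tilde_j|` below which a variable is
#'   excluded.
#' @return A `survsel_fit`; stage-1 results are in `$details$stage1`.
#' @export
fit_adaptive_lasso <- function(data, folds = 10, seed = NULL,
                               foldid = NULL, eps = 1e-8) {
  stopifnot(inherits(data, "survival_dataset"))
  if (is.null(foldid)) foldid <- make_folds(data$event, folds, seed)
  ridge <- fit_cv_penalized(data, "ridge", foldid = foldid)
  beta_tilde <- ridge$details$beta_std
  w <- 1 / abs(beta_tilde)
  w[abs(beta_tilde) < eps] <- Inf
  if (all(!is.finite(w)))
    stop("all ridge initial estimates are below eps; no variables remain")
  fit <- fit_cv_penalized(data, "adaptive_lasso", foldid = foldid,
                          weights = w)
  fit$method <- "adaptive_lasso"
  fit$details$stage1 <- list(lambda_ridge = ridge$lambda,
                             beta_tilde_std = beta_tilde,
                             n_excluded = sum(!is.finite(w)))
  fit
}
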