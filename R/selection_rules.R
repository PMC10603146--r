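# Rules converting continuous posterior estimates into selected sets.

#' Confidence-interval selection rule
#'
#' Selects variable j iff the (1 - alpha) Wald interval
#' `[beta_j - z * se_j, beta_j + z * se_j]` with `z = qnorm(1 - alpha/2)`
#' does not contain 0, i.e. `|beta_j| > z * se_j`.
#'
#' @param beta_hat Coefficient estimates.
#' @param se Standard errors (strictly positive, same length).
#' @param alpha Significance level (typical values 0.25, 0.1, 0.05).
#' @return Sorted integer vector of selected (1-based) indices.
#' @export
ci_rule <- function(beta_hat, se, alpha = 0.05) {
  if (length(beta_hat) != length(se))
    stop("beta_hat and se must have equal length")
  if (any(se <= 0) || anyNA(se)) stop("standard errors must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  z <- qnorm(1 - alpha / 2)
  unname(which(abs(beta_hat) > z * se))
}

# Refit a Cox model on a candidate subset, returning the maximised partial
# log-likelihood; falls back to a tiny ridge on rank deficiency or
# non-convergence.  `counter` (an environment) tracks refit counts.
refit_pl <- function(data, idx, counter = NULL, init = NULL) {
  if (!is.null(counter)) counter$n <- counter$n + 1L
  sub <- survival_dataset(data$time, data$event,
                          data$X[, idx, drop = FALSE])
  fit <- tryCatch(
    suppressWarnings(fit_cox_mle(sub, beta_init = init)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    fit <- suppressWarnings(fit_cox_mle(sub, ridge = 1e-4,
                                        beta_init = init))
  }
  list(pl = fit$loglik, beta = fit$beta)
}

bic_candidates <- function(beta_hat, j_max) {
  nz <- which(beta_hat != 0)
  if (length(nz) == 0) return(integer(0))
  nz[order(-abs(beta_hat[nz]))][seq_len(min(j_max, length(nz)))]
}

#' BIC thresholding rule
#'
#' Candidates are the (at most `j_max`) variables with largest non-zero
#' `|beta_hat|`, in descending order.  For each prefix of length j, a Cox
#' model on those j variables is refitted by maximum partial likelihood
#' and scored with `BIC_j = -2 (l(1:j) - l(0)) + j log(n)`; the prefix
#' minimising BIC (including the empty model with `BIC_0 = 0`) is
#' returned.  Ties go to the smaller model.
#'
#' @param beta_hat Posterior (or other continuous) coefficient estimates.
#' @param data The [survival_dataset()] used for refitting.
#' @param j_max Prefilter size (default 50).
#' @return Sorted integer vector of selected indices, with attributes
#'   `"trace"` (the BIC sequence) and `"refits"` (number of Cox refits).
#' @export
bic_threshold <- function(beta_hat, data, j_max = 50) {
  stopifnot(inherits(data, "survival_dataset"))
  if (j_max < 1) stop("j_max must be >= 1")
  cand <- bic_candidates(beta_hat, j_max)
  counter <- new.env()
  counter$n <- 0L
  n <- data$n
  bics <- numeric(length(cand))
  init <- NULL
  for (j in seq_along(cand)) {
    r <- refit_pl(data, cand[seq_len(j)], counter,
                  init = if (is.null(init)) NULL else c(init, 0))
    init <- r$beta
    bics[j] <- -2 * r$pl + j * log(n)   # l(0) enters via BIC_0 = 0 below
  }
  l0 <- cpp_cox_pl(numeric(n), data$time, as.numeric(data$event))
  bics <- bics + 2 * l0
  trace <- data.frame(j = c(0L, seq_along(cand)), bic = c(0, bics))
  j_best <- trace$j[which.min(trace$bic)]   # which.min: first = smaller j
  out <- sort(cand[seq_len(j_best)])
  attr(out, "trace") <- trace
  attr(out, "refits") <- counter$n
  out
}

#' Modified (greedy) BIC thresholding rule
#'
#' A greedy forward search over the same candidate set as
#' [bic_threshold()]: the variable with the largest `|beta_hat|` is
#' force-included first; at each later step the remaining candidate whose
#' inclusion minimises BIC is added, until candidates are exhausted; the
#' step with minimum BIC (the empty model included, `BIC_0 = 0`) gives the
#' final set.  Less conservative than the prefix rule, at the price of
#' `O(j_max^2)` refits.
#'
#' @inheritParams bic_threshold
#' @return As [bic_threshold()]; the `"trace"` attribute records the
#'   variable added at every step.
#' @export
modified_bic_threshold <- function(beta_hat, data, j_max = 50) {
  stopifnot(inherits(data, "survival_dataset"))
  if (j_max < 1) stop("j_max must be >= 1")
  cand <- bic_candidates(beta_hat, j_max)
  counter <- new.env()
  counter$n <- 0L
  n <- data$n
  l0 <- cpp_cox_pl(numeric(n), data$time, as.numeric(data$event))
  model <- integer(0)
  remaining <- cand
  bics <- numeric(0)
  added <- integer(0)
  beta_prev <- numeric(0)
  while (length(remaining) > 0) {
    step <- length(model) + 1L
    if (step == 1L) {
      pick_idx <- 1L   # candidates are sorted by |beta_hat|: force largest
      r <- refit_pl(data, remaining[1L], counter)
      best <- list(pl = r$pl, beta = r$beta)
    } else {
      pls <- vapply(remaining, function(v) {
        refit_pl(data, c(model, v), counter,
                 init = c(beta_prev, 0))$pl
      }, numeric(1))
      pick_idx <- which.max(pls)
      r <- refit_pl(data, c(model, remaining[pick_idx]), counter,
                    init = c(beta_prev, 0))
      best <- list(pl = r$pl, beta = r$beta)
    }
    model <- c(model, remaining[pick_idx])
    added <- c(added, remaining[pick_idx])
    remaining <- remaining[-pick_idx]
    beta_prev <- best$beta
    bics <- c(bics, -2 * (best$pl - l0) + step * log(n))
  }
  trace <- data.frame(step = c(0L, seq_along(bics)),
                      added = c(NA_integer_, added),
                      bic = c(0, bics))
  k_best <- trace$step[which.min(trace$bic)]
  out <- sort(added[seq_len(k_best)])
  attr(out, "trace") <- trace
  attr(out, "refits") <- counter$n
  out
}
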