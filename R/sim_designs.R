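# Synthetic survival data with block-autoregressive collinearity, sparse
# protective effects, exponential event times, and exponential censoring
# calibrated to a target rate.

#' The four benchmark simulation designs
#'
#' Each design uses n = 450 subjects and p = 200 standard-normal covariates
#' in 4 blocks of 50 with within-block AR(1) correlation rho = 0.9, a
#' baseline median survival of 4 years, and censoring targeted at 50%.
#' Designs differ in the number of true biomarkers (q = 5 or 10) and the
#' magnitude of their (all negative, i.e. protective) coefficients:
#' LOW = \[-0.4, -0.1\], HIGH = \[-1.0, -0.5\].
#'
#' @return A data.frame with one row per design.
#' @export
design_table <- function() {
  data.frame(
    design_id = 1:4,
    n = 450L, p = 200L,
    q = c(5L, 5L, 10L, 10L),
    beta_low = c(-0.4, -1.0, -0.4, -1.0),
    beta_high = c(-0.1, -0.5, -0.1, -0.5),
    rho = 0.9, block_size = 50L,
    median_survival = 4, target_censoring = 0.5
  )
}

#' Specify a simulation design
#'
#' Either pick one of the four built-in designs by `design_id`, or supply a
#' full custom parameter set.
#'
#' @param design_id Integer in 1..4 selecting a built-in design, or `NULL`.
#' @param n,p Subject and covariate counts.
#' @param q Number of true biomarkers (non-zero coefficients).
#' @param beta_range Length-2 numeric interval the true coefficients are
#'   drawn from (uniformly).
#' @param rho Within-block AR(1) correlation in `[0, 1)`.
#' @param block_size Covariates per correlated block; must divide `p`.
#' @param median_survival Baseline (x = 0) median event time, in years.
#' @param target_censoring Target censoring proportion in (0, 1).
#' @param censor_rate_c Exponential censoring rate; `NA` until calibrated
#'   (see [calibrate_censoring()]).
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(design_id = NULL, n = 450, p = 200, q = 5,
                              beta_range = c(-0.4, -0.1), rho = 0.9,
                              block_size = 50, median_survival = 4,
                              target_censoring = 0.5, censor_rate_c = NA) {
  if (!is.null(design_id)) {
    tab <- design_table()
    if (!design_id %in% tab$design_id)
      stop("design_id must be one of ", paste(tab$design_id, collapse = ", "))
    row <- tab[tab$design_id == design_id, ]
    n <- row$n; p <- row$p; q <- row$q
    beta_range <- c(row$beta_low, row$beta_high)
    rho <- row$rho; block_size <- row$block_size
    median_survival <- row$median_survival
    target_censoring <- row$target_censoring
  }
  if (p %% block_size != 0)
    stop("p must be an integer multiple of block_size")
  if (q > p) stop("q must not exceed p")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (target_censoring <= 0 || target_censoring >= 1)
    stop("target_censoring must lie in (0, 1)")
  if (median_survival <= 0) stop("median_survival must be positive")
  structure(
    list(design_id = design_id, n = as.integer(n), p = as.integer(p),
         q = as.integer(q), beta_range = as.numeric(beta_range), rho = rho,
         block_size = as.integer(block_size),
         median_survival = median_survival,
         target_censoring = target_censoring,
         censor_rate_c = censor_rate_c),
    class = "simulation_design"
  )
}

#' Generate block-autoregressive standard-normal covariates
#'
#' Rows are independent subjects.  Within a block of `block_size` columns,
#' columns i and j have correlation `rho^|i-j|` with unit variances
#' (stationary AR(1)); distinct blocks are independent.
#'
#' @param n,p Row and column counts; `p` must be divisible by `block_size`.
#' @param rho AR(1) correlation in `[0, 1)`.
#' @param block_size Columns per block.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return An `n x p` numeric matrix.
#' @export
make_covariates <- function(n, p, rho, block_size, seed = NULL) {
  if (p %% block_size != 0)
    stop("p must be an integer multiple of block_size")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  with_seed(seed, {
    n_blocks <- p %/% block_size
    X <- matrix(0, n, p)
    innov_sd <- sqrt(1 - rho^2)
    for (b in seq_len(n_blocks)) {
      off <- (b - 1L) * block_size
      X[, off + 1L] <- rnorm(n)
      if (block_size > 1) {
        for (j in 2:block_size) {
          X[, off + j] <- rho * X[, off + j - 1L] + innov_sd * rnorm(n)
        }
      }
    }
    X
  })
}

#' Draw a sparse true coefficient vector
#'
#' Exactly `q` coefficients are non-zero, drawn independently and uniformly
#' from `beta_range`.  Support positions are drawn without replacement,
#' either uniformly over all `p` positions (default) or forced inside a
#' single correlated block (a stress test for within-block confounding).
#'
#' @param p Total number of covariates.
#' @param q Number of non-zero coefficients; `q <= p`.
#' @param beta_range Length-2 interval for the non-zero values.
#' @param seed Optional integer seed.
#' @param placement `"random"` (anywhere) or `"block"` (all inside one
#'   randomly chosen block; requires `block_size`).
#' @param block_size Block size when `placement = "block"`.
#' @return A list of class `true_model` with `beta` (length-`p`) and
#'   `support` (1-based indices of the non-zero entries).
#' @export
make_true_model <- function(p, q, beta_range = c(-0.4, -0.1), seed = NULL,
                            placement = c("random", "block"),
                            block_size = NULL) {
  placement <- match.arg(placement)
  if (q > p) stop("q must not exceed p")
  if (length(beta_range) != 2 || anyNA(beta_range) ||
      beta_range[1] > beta_range[2])
    stop("beta_range must be a non-empty interval c(low, high)")
  with_seed(seed, {
    beta <- numeric(p)
    if (q > 0) {
      if (placement == "block") {
        if (is.null(block_size)) stop("placement='block' needs block_size")
        if (q > block_size) stop("q exceeds block_size for block placement")
        b <- sample.int(p %/% block_size, 1L)
        support <- sort((b - 1L) * block_size + sample.int(block_size, q))
      } else {
        support <- sort(sample.int(p, q))
      }
      beta[support] <- runif(q, beta_range[1], beta_range[2])
    } else {
      support <- integer(0)
    }
    structure(list(beta = beta, support = support), class = "true_model")
  })
}

#' Simulate exponential event times under a Cox model
#'
#' Subject i's event time is exponential with rate
#' `lambda0 * exp(beta' x_i)` where `lambda0 = log(2) / median_survival`,
#' so the baseline (x = 0) median event time equals `median_survival`.
#'
#' @param X Covariate matrix.
#' @param beta Coefficient vector conforming with `ncol(X)`.
#' @param median_survival Baseline median event time (> 0).
#' @param seed Optional integer seed.
#' @return A vector of event times.
#' @export
simulate_event_times <- function(X, beta, median_survival = 4, seed = NULL) {
  if (median_survival <= 0) stop("median_survival must be positive")
  X <- as.matrix(X)
  if (length(beta) != ncol(X)) stop("beta does not conform with X")
  lambda0 <- log(2) / median_survival
  rate <- lambda0 * exp(as.vector(X %*% beta))
  with_seed(seed, rexp(nrow(X), rate = rate))
}

#' Calibrate the exponential censoring rate to a target proportion
#'
#' Finds the rate `c` of an independent exponential censoring time C such
#' that P(C < T) equals `target`, by bisection on a large Monte-Carlo
#' sample of event times T drawn from the design.  Given the sampled event
#' times, P(C < T) is evaluated analytically as `mean(1 - exp(-c * T))`,
#' so the bisection solves a smooth monotone equation with no extra
#' censoring noise.
#'
#' By default a fresh true coefficient vector is drawn for each simulation
#' chunk, matching a study that redraws coefficients per replicate; pass
#' `true_model` to calibrate under one fixed model.
#'
#' @param design A [simulation_design()].
#' @param true_model Optional fixed [make_true_model()] output.
#' @param target Target censoring proportion in (0, 1); defaults to the
#'   design's `target_censoring`.
#' @param seed Optional integer seed.
#' @param nsim Number of Monte-Carlo subjects (default 1e5).
#' @param max_iter Bisection iteration bound.
#' @return The calibrated censoring rate `c` (events per year).
#' @export
calibrate_censoring <- function(design, true_model = NULL,
                                target = design$target_censoring,
                                seed = NULL, nsim = 1e5, max_iter = 200) {
  stopifnot(inherits(design, "simulation_design"))
  if (target <= 0 || target >= 1) stop("target must lie in (0, 1)")
  Tev <- with_seed(seed, {
    chunk <- 10000L
    out <- numeric(0)
    while (length(out) < nsim) {
      m <- min(chunk, nsim - length(out))
      X <- make_covariates(m, design$p, design$rho, design$block_size)
      tm <- if (is.null(true_model)) {
        make_true_model(design$p, design$q, design$beta_range)
      } else true_model
      out <- c(out, simulate_event_times(X, tm$beta,
                                         design$median_survival))
    }
    out
  })
  cens_prop <- function(c) mean(1 - exp(-c * Tev))
  lo <- 1e-10
  hi <- log(2) / design$median_survival
  tries <- 0
  while (cens_prop(hi) < target) {
    hi <- hi * 2
    tries <- tries + 1
    if (tries > 60) stop("censoring calibration failed to bracket target")
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (cens_prop(mid) < target) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-12 * max(1, hi)) break
  }
  c_hat <- (lo + hi) / 2
  if (abs(cens_prop(c_hat) - target) > 0.02)
    stop("censoring calibration did not converge to within 0.02 of target")
  c_hat
}

#' Generate one simulated replicate of a design
#'
#' Draws covariates, a true coefficient vector, exponential event times and
#' independent exponential censoring times, and returns the observed data
#' `T = min(event, censoring)`, `delta = 1{event <= censoring}` together
#' with the generating truth.  Covariates are labelled with their block as
#' group labels.
#'
#' @param design A [simulation_design()]; if its `censor_rate_c` is `NA`
#'   it is calibrated on the fly (calibrate once and reuse across
#'   replicates for speed).
#' @param seed Optional integer seed; identical (design, seed) pairs yield
#'   bit-identical replicates.
#' @param true_model Optional fixed true model reused across replicates
#'   (default: redrawn every replicate).
#' @param placement Passed to [make_true_model()].
#' @return A list of class `sim_replicate` with elements `data`
#'   (a [survival_dataset()]), `truth` (a `true_model`) and `design`.
#' @export
generate_replicate <- function(design, seed = NULL, true_model = NULL,
                               placement = "random") {
  stopifnot(inherits(design, "simulation_design"))
  c_rate <- design$censor_rate_c
  if (is.na(c_rate)) {
    c_rate <- calibrate_censoring(design, seed = sub_seed(seed %||% 0, 777))
    design$censor_rate_c <- c_rate
  }
  with_seed(seed, {
    X <- make_covariates(design$n, design$p, design$rho, design$block_size)
    tm <- if (is.null(true_model)) {
      make_true_model(design$p, design$q, design$beta_range,
                      placement = placement,
                      block_size = design$block_size)
    } else true_model
    t_event <- simulate_event_times(X, tm$beta, design$median_survival)
    t_cens <- rexp(design$n, rate = c_rate)
    obs <- pmin(t_event, t_cens)
    delta <- as.integer(t_event <= t_cens)
    groups <- rep(paste0("block", seq_len(design$p %/% design$block_size)),
                  each = design$block_size)
    data <- survival_dataset(obs, delta, X,
                             feature_names = paste0("x", seq_len(design$p)),
                             groups = groups)
    structure(list(data = data, truth = tm, design = design),
              class = "sim_replicate")
  })
}

#' Write a simulated replicate to disk
#'
#' The dataset goes to `<path>.csv` (columns `time, event, x1..xp`) and the
#' generating truth plus design parameters to a JSON sidecar
#' `<path>.json`; support indices in the sidecar are 0-based.
#'
#' @param rep A `sim_replicate` from [generate_replicate()].
#' @param path Output path stem (without extension).
#' @return The two file paths, invisibly.
#' @export
write_replicate <- function(rep, path) {
  stopifnot(inherits(rep, "sim_replicate"))
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  write_dataset(rep$data, csv)
  side <- list(
    support_0based = as.integer(rep$truth$support - 1L),
    beta_nonzero = rep$truth$beta[rep$truth$support],
    design = rep$design[c("design_id", "n", "p", "q", "beta_range", "rho",
                          "block_size", "median_survival",
                          "target_censoring", "censor_rate_c")]
  )
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(csv, js))
}
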