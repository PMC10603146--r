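# Shared fixture builders: everything is generated in code, seeded.

# Small independent-covariate survival dataset with known coefficients.
toy_cox_data <- function(n = 150, p = 5, beta = NULL, rate0 = 0.2,
                         cens_rate = 0.2, seed = 1) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    if (is.null(beta)) beta <- c(1, -0.8, rep(0, p - 2))
    X <- matrix(rnorm(n * p), n, p)
    t_ev <- rexp(n, rate0 * exp(as.vector(X %*% beta)))
    t_ce <- rexp(n, cens_rate)
    list(
      data = survival_dataset(pmin(t_ev, t_ce), as.integer(t_ev <= t_ce),
                              X),
      beta = beta
    )
  })
}

# All-event dataset with distinct times (for the -log(n!) identity).
all_event_data <- function(n = 8, p = 2, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  survival_dataset(sample(seq_len(n)) + 0.5, rep(1L, n), X)
}

# A small design for fast simulation tests.
tiny_design <- function(...) {
  simulation_design(n = 120, p = 40, q = 3, beta_range = c(-1, -0.5),
                    rho = 0.9, block_size = 20, median_survival = 4,
                    target_censoring = 0.5, ...)
}
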