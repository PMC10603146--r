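test_that("CI rule worked examples at standard normal quantiles", {
  # beta 0.5, SE 0.1, alpha 0.05: CI [0.304, 0.696] excludes 0
  expect_equal(ci_rule(0.5, 0.1, 0.05), 1L)
  # beta 0.1, SE 0.1, alpha 0.1: CI [-0.0645, 0.2645] contains 0
  expect_equal(ci_rule(0.1, 0.1, 0.10), integer(0))
  # an estimate of exactly 0 is never selected
  expect_equal(ci_rule(0, 5, 0.25), integer(0))
  # vectorised case with the explicit z value
  z <- qnorm(1 - 0.05 / 2)
  expect_equal(z, 1.95996, tolerance = 1e-5)
  b <- c(0.5, 0.1, -0.3)
  s <- c(0.1, 0.1, 0.2)
  expect_equal(ci_rule(b, s, 0.05), which(abs(b) > z * s))
  expect_error(ci_rule(c(1, 2), c(1, 0), 0.05), "positive")
})

test_that("CI rule is monotone in alpha", {
  set.seed(61)
  b <- rnorm(50)
  s <- rexp(50, 3) + 0.05
  s05 <- ci_rule(b, s, 0.05)
  s25 <- ci_rule(b, s, 0.25)
  expect_true(all(s05 %in% s25))
})

test_that("BIC arithmetic on a constructed likelihood sequence", {
  # toy n = 100: 2*(l(A)-l(0)) = 20, 2*(l(A,B)-l(0)) = 21
  #   BIC1 = -20 + log(100) = -15.39; BIC2 = -21 + 2 log(100) = -11.79
  n <- 100
  bic1 <- -20 + 1 * log(n)
  bic2 <- -21 + 2 * log(n)
  expect_equal(bic1, -15.39483, tolerance = 1e-5)
  expect_equal(bic2, -11.78966, tolerance = 1e-5)
  expect_lt(bic1, bic2)  # {A} preferred over {A, B}
})

test_that("bic_threshold selects the supported prefix on real refits", {
  toy <- toy_cox_data(n = 200, p = 6, beta = c(1.2, -1, 0, 0, 0, 0),
                      seed = 67)
  d <- toy$data
  beta_hat <- c(1.0, -0.9, 0.05, -0.02, 0.01, 0)
  sel <- bic_threshold(beta_hat, d)
  expect_true(all(c(1, 2) %in% sel))
  expect_lt(length(sel), 6)
  tr <- attr(sel, "trace")
  # reported minimum equals the minimum of the recorded trace
  expect_equal(min(tr$bic), tr$bic[tr$j == length(sel)])
  # all-zero estimates: no candidates
  expect_equal(bic_threshold(numeric(6), d), integer(0),
               ignore_attr = TRUE)
  # prefilter: at most j_max candidates are considered
  sel2 <- bic_threshold(seq(0.9, 0.1, length.out = 6), d, j_max = 3)
  expect_lte(length(sel2), 3)
})

test_that("brute-force oracle: both BIC rules find the best model on a
           3-candidate instance with a collinear decoy", {
  # x1 strong; x2 a noisy copy of x1 (collinear decoy with the
  # 2nd-largest posterior estimate); x3 smaller estimate but independent
  # signal
  set.seed(71)
  n <- 300
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n, sd = 0.4)
  x3 <- rnorm(n)
  eta <- 1.2 * x1 + 0.8 * x3
  tt <- rexp(n, 0.2 * exp(eta))
  cc <- rexp(n, 0.2)
  d <- survival_dataset(pmin(tt, cc), as.integer(tt <= cc),
                        cbind(x1, x2, x3))
  beta_hat <- c(1.1, 0.9, 0.5)
  n_obs <- d$n
  l0 <- partial_log_likelihood(c(0, 0, 0), d)
  # exhaustive enumeration of all non-empty subsets (independent oracle)
  subsets <- unlist(lapply(1:3, function(k)
    combn(3, k, simplify = FALSE)), recursive = FALSE)
  bic_of <- function(idx) {
    sub <- survival_dataset(d$time, d$event, d$X[, idx, drop = FALSE])
    -2 * (fit_cox_mle(sub)$loglik - l0) + length(idx) * log(n_obs)
  }
  bics <- vapply(subsets, bic_of, numeric(1))
  best_subset <- sort(subsets[[which.min(bics)]])
  expect_equal(best_subset, c(1, 3))  # sanity: decoy not in best model

  msel <- modified_bic_threshold(beta_hat, d)
  expect_equal(sort(msel), best_subset)
  # original rule is constrained to prefixes of the |beta_hat| order and
  # must evaluate the collinear decoy before x3
  psel <- bic_threshold(beta_hat, d)
  expect_true(1 %in% psel)
  # modified rule adds the independent variable at step 2
  tr <- attr(msel, "trace")
  expect_equal(tr$added[tr$step == 2], 3L)
})

test_that("single candidate: both rules coincide; sizes are bounded", {
  toy <- toy_cox_data(n = 120, p = 4, beta = c(1, 0, 0, 0), seed = 73)
  d <- toy$data
  bh <- c(0.8, 0, 0, 0)
  expect_equal(bic_threshold(bh, d), modified_bic_threshold(bh, d),
               ignore_attr = TRUE)
  bh2 <- c(0.8, 0.3, -0.2, 0.1)
  expect_lte(length(modified_bic_threshold(bh2, d, j_max = 2)), 2)
})

test_that("refit counters reflect O(j_max) vs O(j_max^2) behaviour", {
  toy <- toy_cox_data(n = 150, p = 8, seed = 79)
  d <- toy$data
  bh <- seq(1, 0.3, length.out = 8)
  s1 <- bic_threshold(bh, d)
  s2 <- modified_bic_threshold(bh, d)
  expect_equal(attr(s1, "refits"), 8L)
  # greedy: 8 + (7 + 1) + (6 + 1) + ... evaluations plus re-fits of picks
  expect_gt(attr(s2, "refits"), attr(s1, "refits"))
  expect_lte(attr(s2, "refits"), 8 * 9)
})

test_that("pure noise may select the empty model (BIC_0 = 0 included)", {
  set.seed(83)
  n <- 120
  X <- matrix(rnorm(n * 5), n, 5)
  d <- survival_dataset(rexp(n, 0.3), rbinom(n, 1, 0.7), X)
  bh <- rnorm(5, sd = 0.01)
  sel <- bic_threshold(bh, d)
  tr <- attr(sel, "trace")
  expect_equal(tr$bic[tr$j == 0], 0)
  expect_equal(length(sel), tr$j[which.min(tr$bic)])
})
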