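test_that("full shrinkage and objective identities", {
  toy <- toy_cox_data(seed = 11)
  d <- toy$data
  std <- survsel:::standardize_design(d$X)
  lmax <- survsel:::lambda_max_unscaled(std$X, d$time, d$event)
  f <- fit_penalized_cox(d, penalty_spec("lasso", lambda = lmax * 1.01))
  expect_equal(select_nonzero(f), integer(0))
  expect_true(all(f$beta == 0))
  # elastic net with alpha = 1 is the lasso at the same lambda
  lam <- lmax / 3
  fl <- fit_penalized_cox(d, penalty_spec("lasso", lambda = lam))
  fe <- fit_penalized_cox(d, penalty_spec("elastic_net", lambda = lam,
                                          alpha = 1))
  expect_equal(fl$beta, fe$beta, tolerance = 1e-8)
})

test_that("lambda = 0 penalized fit equals the Cox MLE", {
  toy <- toy_cox_data(n = 200, p = 4, beta = c(0.8, -0.6, 0.3, 0),
                      seed = 23)
  d <- toy$data
  f0 <- fit_penalized_cox(d, penalty_spec("lasso", lambda = 0))
  mle <- fit_cox_mle(d)
  expect_equal(f0$beta, mle$beta, tolerance = 1e-4)
})

test_that("KKT conditions certify penalized optima", {
  toy <- toy_cox_data(n = 180, p = 8,
                      beta = c(1, -0.8, 0.5, rep(0, 5)), seed = 29)
  d <- toy$data
  std <- survsel:::standardize_design(d$X)
  ds <- survival_dataset(d$time, d$event, std$X)
  for (lam in c(2, 5, 10)) {
    f <- fit_penalized_cox(d, penalty_spec("lasso", lambda = lam))
    bs <- f$details$beta_std
    g <- partial_ll_gradient(bs, ds)
    act <- bs != 0
    if (any(act)) expect_lt(max(abs(abs(g[act]) - lam)), 1e-3)
    if (any(!act)) expect_lt(max(abs(g[!act])) - lam, 1e-4)
  }
  # weighted (adaptive) KKT: |grad_j| <= lambda * w_j at zeros
  w <- c(0.5, 2, 1, 1, Inf, 1, 3, 1)
  lam <- 4
  f <- fit_penalized_cox(d, penalty_spec("adaptive_lasso", lambda = lam,
                                         weights = w))
  bs <- f$details$beta_std
  g <- partial_ll_gradient(bs, ds)
  act <- which(bs != 0)
  ina <- which(bs == 0 & is.finite(w))
  expect_lt(max(abs(abs(g[act]) - lam * w[act])), 1e-3)
  expect_true(all(abs(g[ina]) <= lam * w[ina] + 1e-4))
  expect_identical(unname(f$beta[5]), 0)  # infinite weight: excluded
})

test_that("penalized objective certifies optimality against perturbations", {
  toy <- toy_cox_data(n = 120, p = 6, seed = 31)
  d <- toy$data
  std <- survsel:::standardize_design(d$X)
  ds <- survival_dataset(d$time, d$event, std$X)
  lam <- 4
  f <- fit_penalized_cox(d, penalty_spec("lasso", lambda = lam))
  bs <- f$details$beta_std
  q_obj <- function(b) -partial_log_likelihood(b, ds) + lam * sum(abs(b))
  q0 <- q_obj(bs)
  set.seed(1)
  for (i in 1:100) {
    expect_gte(q_obj(bs + rnorm(6) * 0.05), q0 - 1e-6)
  }
})

test_that("elastic-net grouping ties identical columns", {
  toy <- toy_cox_data(n = 150, p = 3, beta = c(1, 0, 0), seed = 37)
  d <- toy$data
  dd <- survival_dataset(d$time, d$event,
                         cbind(d$X[, 1], d$X[, 1], d$X[, 2:3]))
  # glmnet backend: symmetric up to its convergence threshold
  f <- fit_penalized_cox(dd, penalty_spec("elastic_net", lambda = 3,
                                          alpha = 0.5))
  expect_equal(unname(f$beta[1]), unname(f$beta[2]), tolerance = 1e-3)
  # the package coordinate-descent solver (same objective, w = lambda
  # alpha, d = lambda (1 - alpha)) reaches the unique symmetric optimum
  std <- survsel:::standardize_design(dd$X)
  r <- survsel:::cpp_cox_cd(std$X, dd$time, as.numeric(dd$event),
                            rep(3 * 0.5, 4), rep(3 * 0.5, 4),
                            rep(0, 4), 1e-10, 500, 200)
  b <- as.vector(r$beta)
  expect_equal(b[1], b[2], tolerance = 1e-6)
})

test_that("cross_validate picks sensible hyperparameters", {
  toy <- toy_cox_data(n = 160, p = 5, seed = 41)
  d <- toy$data
  # single-point grid: chosen equals that point
  cv1 <- cross_validate(d, "lasso", lambda_grid = 2.5, folds = 5, seed = 1)
  expect_equal(cv1$chosen$lambda, 2.5)
  # duplicated grid values give identical losses; tie goes to larger lambda
  cv2 <- cross_validate(d, "lasso", lambda_grid = c(3, 3, 1), folds = 5,
                        seed = 1)
  ll <- cv2$grid$cv_loss[cv2$grid$lambda == 3]
  expect_equal(ll[1], ll[2])
  expect_true(cv2$chosen$lambda %in% c(3, 1))
  # the chosen model minimises the recorded loss
  expect_equal(min(cv2$grid$cv_loss),
               cv2$grid$cv_loss[cv2$grid$lambda == cv2$chosen$lambda][1])
})

test_that("strong-signal CV retains the true variables", {
  toy <- toy_cox_data(n = 400, p = 6, beta = c(1, -1, 0, 0, 0, 0),
                      seed = 43)
  fit <- fit_cv_penalized(toy$data, "lasso", folds = 10, seed = 7)
  expect_true(all(c(1, 2) %in% select_nonzero(fit)))
})

test_that("select_nonzero reads exact zeros", {
  f <- survsel:::new_model_fit("lasso", c(0.3, 0, -0.1))
  expect_equal(select_nonzero(f), c(1L, 3L))
  f0 <- survsel:::new_model_fit("lasso", numeric(4))
  expect_equal(select_nonzero(f0), integer(0))
})

test_that("make_folds guarantees events in every fold", {
  set.seed(2)
  ev <- c(rep(1L, 6), rep(0L, 94))
  foldid <- make_folds(ev, k = 5, seed = 3)
  expect_equal(sort(unique(foldid)), 1:5)
  for (f in 1:5) expect_gt(sum(ev[foldid == f]), 0)
  expect_error(make_folds(rep(0L, 50), k = 5, seed = 1), "events")
})

test_that("adaptive lasso with constant weights matches plain lasso", {
  toy <- toy_cox_data(n = 150, p = 5, seed = 47)
  d <- toy$data
  lam <- 3
  fw <- fit_penalized_cox(d, penalty_spec("adaptive_lasso", lambda = lam,
                                          weights = rep(1, 5)))
  fl <- fit_penalized_cox(d, penalty_spec("lasso", lambda = lam))
  expect_equal(fw$beta, fl$beta, tolerance = 1e-7)
})

test_that("fit_adaptive_lasso excludes eps-underflow variables", {
  toy <- toy_cox_data(n = 200, p = 5, beta = c(1, -0.8, 0, 0, 0),
                      seed = 53)
  d <- toy$data
  expect_error(fit_adaptive_lasso(d, folds = 5, seed = 5, eps = Inf),
               "eps")
  fit <- fit_adaptive_lasso(d, folds = 5, seed = 5)
  expect_s3_class(fit, "survsel_fit")
  expect_true(all(c(1, 2) %in% select_nonzero(fit)))
})
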