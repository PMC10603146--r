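test_that("minimal depth reads hand-built trees correctly", {
  # root split on v1 (depth 0), one child split on v2 (depth 1), three
  # leaves at depths 1 and 2
  tree <- cbind(var = c(1, 2, NA, NA, NA),
                cut = c(0, 0, NA, NA, NA),
                left = c(2, 3, NA, NA, NA),
                right = c(5, 4, NA, NA, NA),
                depth = c(0, 1, 2, 2, 1),
                mortality = c(NA, NA, 1, 2, 3))
  forest <- list(trees = list(tree), p = 3)
  prof <- minimal_depth(forest)
  expect_equal(unname(prof$minimal_depth[1]), 0)
  expect_equal(unname(prof$minimal_depth[2]), 1)
  # v3 never splits: sentinel = max terminal depth + 1 = 3
  expect_equal(unname(prof$minimal_depth[3]), 3)

  # v splitting both the root and a grandchild still has depth 0
  tree2 <- cbind(var = c(1, 1, NA, NA, NA),
                 cut = c(0, 0, NA, NA, NA),
                 left = c(2, 3, NA, NA, NA),
                 right = c(5, 4, NA, NA, NA),
                 depth = c(0, 1, 2, 2, 1),
                 mortality = c(NA, NA, 1, 2, 3))
  prof2 <- minimal_depth(list(trees = list(tree2), p = 2))
  expect_equal(unname(prof2$minimal_depth[1]), 0)

  # averaging across the two trees
  prof12 <- minimal_depth(list(trees = list(tree, tree2), p = 3))
  expect_equal(unname(prof12$minimal_depth[1]), 0)
  expect_equal(unname(prof12$minimal_depth[2]), 2)   # (1 + 3) / 2
})

test_that("select_by_minimal_depth honours threshold and top-k variants", {
  prof <- structure(list(minimal_depth = c(a = 1, b = 3, c = 3, d = 5),
                         threshold = 3, ntree = 10),
                    class = "depth_profile")
  # strict inequality: ties at the threshold are not selected
  expect_equal(select_by_minimal_depth(prof), 1L)
  expect_equal(select_by_minimal_depth(prof, threshold = 10), 1:4)
  expect_equal(select_by_minimal_depth(prof, top_k = 2), c(1L, 2L))
  expect_length(select_by_minimal_depth(prof, top_k = 4), 4)
  # all depths equal: nothing selected under the null threshold
  prof_eq <- structure(list(minimal_depth = rep(2, 4), threshold = 2,
                            ntree = 10),
                       class = "depth_profile")
  expect_equal(select_by_minimal_depth(prof_eq), integer(0))
})

test_that("forest fitting is deterministic given the seed", {
  toy <- toy_cox_data(n = 80, p = 4, seed = 131)
  f1 <- fit_rsf(toy$data, ntree = 25, seed = 17)
  f2 <- fit_rsf(toy$data, ntree = 25, seed = 17)
  expect_identical(f1$trees, f2$trees)
  expect_identical(f1$oob_error, f2$oob_error)
  f3 <- fit_rsf(toy$data, ntree = 25, seed = 18)
  expect_false(identical(f1$trees, f3$trees))
})

test_that("OOB error: null concordance on pure noise, informative on a
           strong binary covariate", {
  set.seed(137)
  n <- 250
  Xn <- matrix(rnorm(n * 5), n, 5)
  dn <- survival_dataset(rexp(n, 0.3), rbinom(n, 1, 0.75), Xn)
  fn <- fit_rsf(dn, ntree = 120, seed = 3)
  expect_lt(abs(fn$oob_error - 0.5), 0.06)

  xb <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.2 * exp(1.8 * xb))
  cc <- rexp(n, 0.15)
  ds <- survival_dataset(pmin(tt, cc), as.integer(tt <= cc),
                         cbind(xb, matrix(rnorm(n * 3), n, 3)))
  fs <- fit_rsf(ds, ntree = 120, seed = 4)
  expect_lt(fs$oob_error, 0.4)
  # the informative variable is shallowest and always selected
  prof <- minimal_depth(fs)
  expect_equal(unname(which.min(prof$minimal_depth)), 1L)
  expect_true(1 %in% select_by_minimal_depth(prof))
})

test_that("minimal depth never exceeds a variable's mean split depth", {
  toy <- toy_cox_data(n = 100, p = 4, seed = 139)
  f <- fit_rsf(toy$data, ntree = 30, seed = 7)
  for (tm in f$trees[1:5]) {
    internal <- !is.na(tm[, "var"])
    if (!any(internal)) next
    mins <- tapply(tm[internal, "depth"], tm[internal, "var"], min)
    means <- tapply(tm[internal, "depth"], tm[internal, "var"], mean)
    expect_true(all(mins <= means + 1e-12))
  }
})

test_that("more trees stabilise the average minimal depth", {
  toy <- toy_cox_data(n = 90, p = 5, seed = 149)
  md_at <- function(ntree, seed) {
    # small forests may leave some subjects never out-of-bag; that
    # warning is expected and irrelevant to the depth profile
    f <- suppressWarnings(fit_rsf(toy$data, ntree = ntree, seed = seed))
    minimal_depth(f)$minimal_depth
  }
  seeds <- 1:6
  v_small <- apply(vapply(seeds, function(s) md_at(15, s), numeric(5)),
                   1, var)
  v_large <- apply(vapply(seeds, function(s) md_at(150, s), numeric(5)),
                   1, var)
  expect_lt(mean(v_large), mean(v_small))
})

test_that("degenerate forests are rejected", {
  set.seed(151)
  X <- matrix(rnorm(40), 20, 2)
  d <- survival_dataset(rexp(20) + 0.1, rep(0L, 20), X)
  expect_error(fit_rsf(d, ntree = 5), "events")
  toy <- toy_cox_data(n = 50, p = 3, seed = 5)
  expect_error(fit_rsf(toy$data, ntree = 0), "ntree")
  expect_error(fit_rsf(toy$data, ntree = 5, mtry = 10), "mtry")
})
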