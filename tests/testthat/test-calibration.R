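# calibration: standardization, separable kernels, SVM training, boundary
# inversion, cross-validation, bootstrap, ranking, learning curve

test_that("standardization centers, scales and inverts", {
  tab <- observation_table(v = cbind(c(1, 2, 3), c(10, 20, 40)),
                           delta = c(0.2, 0.5, 0.9),
                           outcome = c(1, -1, 1))
  s <- standardize_table(tab)
  for (cn in c("v_1", "v_2", "delta")) {
    expect_lt(abs(mean(s$table[[cn]])), 1e-10)
    expect_lt(abs(sd(s$table[[cn]]) - 1), 1e-10)
  }
  expect_identical(s$table$outcome, tab$outcome)
  # round trip is the identity
  back <- std_apply_v(s$standardization, table_v(tab))
  again <- sweep(sweep(back, 2, s$standardization$sd[1:2], "*"), 2,
                 -s$standardization$mean[1:2])
  expect_lt(max(abs(again - table_v(tab))), 1e-12)
  bad <- observation_table(v = cbind(c(5, 5, 5), c(1, 2, 3)),
                           delta = c(0.2, 0.5, 0.9), outcome = c(1, -1, 1))
  expect_error(standardize_table(bad), "v_1")
})

test_that("observation table validates its inputs", {
  expect_error(observation_table(cbind(1:3), c(1, NA, 3), c(1, -1, 1)),
               "missing")
  expect_error(observation_table(cbind(1:3), 1:3, c(1, 2, -1)), "labels")
  expect_error(observation_table(cbind(1), 1, 1), "two observations")
})

test_that("separable kernel evaluates, is symmetric, and the linear Gram is PSD", {
  k <- kernel_spec("linear", k_delta = 2)
  expect_equal(kernel_value(k, c(1, 2, 0.5), c(3, 4, 0.2)), 11.2)
  set.seed(4)
  for (fam in c("linear", "quadratic", "cubic", "sigmoid")) {
    kk <- kernel_spec(fam, k_delta = 0.7, scale = 1.3, offset = -0.2)
    for (r in 1:5) {
      a <- rnorm(4)
      b <- rnorm(4)
      expect_equal(kernel_value(kk, a, b), kernel_value(kk, b, a))
    }
  }
  expect_error(kernel_value(k, c(1, 2, 0.5), c(3, 4)), "dimension")
  V <- matrix(rnorm(60), 20, 3)
  d <- rnorm(20)
  G <- bdrule:::gram_matrix(kernel_spec("linear", k_delta = 1.5), V, d)
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("training separates a separable toy set and satisfies the margin conditions", {
  tab <- toy_four_point()
  s <- standardize_table(tab)
  clf <- train_classifier(s$table, kernel_spec("linear", k_delta = 1, C = 10),
                          s$standardization)
  f <- decision_function(clf, table_v(s$table), s$table$delta)
  expect_equal(sign(f), as.numeric(s$table$outcome)) # 100% training accuracy
  # free support vectors sit on the margin: y * f = 1
  big <- toy_separable(60)
  s2 <- standardize_table(big)
  clf2 <- train_classifier(s2$table, kernel_spec("quadratic", C = 1),
                           s2$standardization)
  G <- bdrule:::gram_matrix(clf2$kernel, table_v(s2$table), s2$table$delta)
  fit <- smo_train(G, as.numeric(s2$table$outcome), 1)
  free <- which(fit$alpha > 1e-6 & fit$alpha < 1 - 1e-6)
  f2 <- decision_function(clf2, table_v(s2$table), s2$table$delta)
  expect_true(all(abs(s2$table$outcome[free] * f2[free] - 1) < 1e-3))
  # single-class input errors
  ones <- observation_table(cbind(1:4, 4:1), c(0.1, 0.2, 0.3, 0.4),
                            rep(1, 4))
  expect_error(train_classifier(standardize_table(ones)$table,
                                kernel_spec("linear")),
               "both")
})

test_that("the decision function is affine in delta (kernel separability)", {
  cb <- calibrate(toy_separable(50), kernel_spec("cubic", k_delta = 2))
  clf <- cb$classifier
  set.seed(9)
  for (r in 1:20) {
    v <- matrix(rnorm(2), 1)
    d <- rnorm(3)
    f <- decision_function(clf, v[rep(1, 3), ], d)
    second_diff <- f[1] - 2 * f[2] + f[3]
    h <- d[1] - 2 * d[2] + d[3]
    expect_lt(abs(second_diff - clf$kernel$k_delta * clf$S_delta * h), 1e-8)
  }
})

test_that("benefit extraction inverts the boundary exactly", {
  # hand-built classifier: single SV, weight 1, K_v = 2 at the probe,
  # bias -1, k_delta 1, S_delta -0.5 => B0 = (-2 + 1)/(-0.5) = 2
  clf <- structure(list(
    V_sv = matrix(c(2, 0), 1), d_sv = 0.3, weights = 1, bias = -1,
    kernel = kernel_spec("linear", k_delta = 1), S_delta = -0.5),
    class = "svm_classifier")
  expect_equal(bdrule:::benefit0_std(clf, matrix(c(1, 0), 1)), 2)
  # boundary identity on a trained model: B0(v) solves f(v, delta) = 0
  for (fam in c("linear", "quadratic", "sigmoid")) {
    cb <- calibrate(toy_separable(60), kernel_spec(fam, k_delta = 1.5))
    clf <- cb$classifier
    set.seed(21)
    vs <- matrix(rnorm(40), 20, 2)
    b0 <- bdrule:::benefit0_std(clf, vs)
    for (i in 1:20) {
      root <- uniroot(function(d)
        decision_function(clf, vs[i, , drop = FALSE], d),
        c(-100, 100), tol = 1e-12)$root
      expect_lt(abs(b0[i] - root), 1e-6)
    }
  }
  # S_delta = 0 is rejected
  clf0 <- structure(list(S_delta = 0), class = "svm_classifier")
  expect_error(extract_benefit(clf0), "S_delta")
})

test_that("extracted surface recovers a known benefit within R^2 >= 0.9", {
  ds <- suppressMessages(generate_scenario(
    scenario_config("model21_truth", seed = 1)))
  cb <- calibrate(ds$train, kernel_spec("linear", k_delta = 4, C = 10))
  B <- benefit_at(cb, table_v(ds$test))
  expect_gte(r_squared(B, ds$test$b_truth), 0.9)
  # prediction consistency: sign(B - delta) matches sign(f) everywhere
  clf <- cb$classifier
  v_s <- bdrule:::std_apply_v(clf$standardization, table_v(ds$test))
  d_s <- bdrule:::std_apply_delta(clf$standardization, ds$test$delta)
  f <- decision_function(clf, v_s, d_s)
  expect_true(all(sign(cb$direction * (B - ds$test$delta)) == sign(f)))
})

test_that("cross-validation behaves on separable, null and edge cases", {
  tab <- toy_separable(60, margin = 0.3)
  acc <- cross_validation_accuracy(tab, default_kernel(), folds = 10,
                                   seed = 2)
  expect_equal(as.numeric(acc), 100)
  expect_length(attr(acc, "fold_accuracy"), 10)
  # permuted labels: accuracy near chance
  set.seed(31)
  null_tab <- observation_table(matrix(runif(400), 200, 2),
                                runif(200, 0.5, 1.5),
                                sample(c(-1, 1), 200, replace = TRUE))
  acc0 <- as.numeric(cross_validation_accuracy(null_tab, default_kernel(),
                                               folds = 10, seed = 3))
  expect_gte(acc0, 40)
  expect_lte(acc0, 60)
  expect_error(cross_validation_accuracy(toy_four_point(), default_kernel(),
                                         folds = 10, seed = 1),
               "folds")
})

test_that("bootstrap variability is zero for the degenerate resample and non-negative", {
  tab <- toy_separable(40)
  one <- bootstrap_variability(tab, default_kernel(), n_boot = 1, seed = 5)
  expect_true(all(one$rel_sd == 0))
  bv <- bootstrap_variability(tab, default_kernel(), n_boot = 15, seed = 5)
  expect_true(all(bv$rel_sd >= 0))
  expect_equal(bv$mean_rel_sd, mean(bv$rel_sd))
})

test_that("bootstrap variability shrinks with sample size", {
  shrink <- vapply(1:6, function(s) {
    small <- toy_separable(50, seed = 100 + s, noise = 0.15)
    large <- toy_separable(200, seed = 100 + s, noise = 0.15)
    kern <- kernel_spec("linear", C = 1)
    bootstrap_variability(small, kern, n_boot = 25, seed = s)$mean_rel_sd -
      bootstrap_variability(large, kern, n_boot = 25, seed = s)$mean_rel_sd
  }, numeric(1))
  expect_gt(mean(shrink), 0)
})

test_that("candidate ranking is complete, deterministic and truth-seeking", {
  ds <- suppressMessages(generate_scenario(
    scenario_config("model21_truth", seed = 2, test_n = c(15, 15))))
  grid <- rbind(
    data.frame(family = c("linear", "linear", "quadratic", "cubic"),
               scale = 1, offset = 0, k_delta = c(1, 4, 1, 1),
               C = c(1, 10, 1, 1)),
    data.frame(family = "sigmoid", scale = 2, offset = -1, k_delta = 0.25,
               C = 0.1))
  rk <- rank_candidates(ds$train, grid, folds = 10, n_boot = 20, seed = 7)
  expect_equal(nrow(rk$report), nrow(grid))
  expect_length(rk$top_five, 5)
  expect_equal(rk$report$rank, seq_len(nrow(grid)))
  # identical specs receive identical scores
  grid2 <- rbind(grid[1, ], grid[1, ])
  rk2 <- rank_candidates(ds$train, grid2, folds = 10, n_boot = 10, seed = 7)
  expect_equal(rk2$report$cv_loss[1], rk2$report$cv_loss[2])
  expect_equal(rk2$report$boot_rel_sd[1], rk2$report$boot_rel_sd[2])
  # top-ranked surface is at least as close to truth as the median candidate
  r2s <- vapply(seq_len(nrow(grid)), function(i) {
    cb <- calibrate(ds$train, bdrule:::grid_row_kernel(grid, i))
    r_squared(benefit_at(cb, table_v(ds$test)), ds$test$b_truth)
  }, numeric(1))
  top <- r_squared(benefit_at(rk$best, table_v(ds$test)), ds$test$b_truth)
  expect_gte(top, median(r2s))
})

test_that("learning curve decreases and fits an exponential decay", {
  tab <- toy_separable(160, noise = 0.25)
  lc <- learning_curve(tab, sizes = c(40, 80, 160), folds = 5, seed = 9)
  expect_lte(lc$loss[3], lc$loss[1] + 0.05)
  expect_true(lc$fitted)
  expect_gte(lc$fit[["b"]], 0)
  one <- learning_curve(tab, sizes = 160, folds = 5, seed = 9)
  expect_false(one$fitted)
  expect_null(one$fit)
  expect_error(learning_curve(tab, sizes = c(3, 160), seed = 1), "small")
})
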