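# model family: enumeration, dynamics, outcomes, stress, critical stress

test_that("enumeration is canonical: 52 structures, duplicate-free, id 21 pinned", {
  fam <- enumerate_models()
  expect_equal(nrow(fam), 52)
  expect_equal(fam$id, sort(fam$id))
  expect_equal(anyDuplicated(fam$id), 0)
  key <- with(fam, paste(benefit_target, cost_form, stress_form,
                         benefit_saturating, complexity))
  expect_equal(anyDuplicated(key), 0)
  expect_equal(length(unique(fam$base)), 13)
  expect_setequal(unique(fam$complexity),
                  c("none", "competition", "asymmetry", "turnover"))
  s21 <- model_structure(21)
  expect_equal(s21$benefit_target, "stress_denominator")
  expect_equal(s21$cost_form, "constant")
  expect_equal(s21$stress_form, "divisive")
  expect_true(s21$benefit_saturating)
  expect_equal(s21$complexity, "none")
  expect_error(model_structure(53), "1..52")
})

test_that("every structure passes the four-assumption audit", {
  expect_true(all(audit_family()))
})

test_that("rate function reproduces the canonical pair and its fixed points", {
  s <- model_structure(21)
  f <- rate_function(s, model_params(beta = 3, eps = 1, delta = 1))
  # root of (1 - X)(beta X + 1) = eps delta, verified by substitution
  expect_equal(f(c(2 / 3, 2 / 3)), c(0, 0), tolerance = 1e-12)
  for (beta in c(1, 2.5, 7)) {
    f0 <- rate_function(s, model_params(beta = beta, eps = 1.3, delta = 0))
    expect_equal(f0(c(1, 1)), c(0, 0), tolerance = 1e-12)
  }
  # extinction is absorbing across structures
  for (id in c(1, 9, 21, 30, 44, 52)) {
    st <- model_structure(id)
    p <- model_params(beta = 2, eps = 1, delta = 0.4,
                      a = if (st$complexity == "competition") 0.2 else 0,
                      d = if (st$complexity == "turnover") 0.1 else 0)
    expect_identical(rate_function(st, p)(c(0, 0.7))[1], 0)
  }
})

test_that("parameter/structure mismatches raise configuration errors", {
  expect_error(rate_function(model_structure(21),
                             model_params(beta = 3, a = 0.5)),
               "configuration error")
  expect_error(rate_function(model_structure(21),
                             model_params(beta = 3, d = 0.1)),
               "configuration error")
  expect_error(rate_function(model_structure(21),
                             model_params(beta = 3, beta2 = 4)),
               "configuration error")
  expect_error(model_params(beta = -1), "non-negative")
  expect_error(model_params(eps = 0), "positive")
})

test_that("simulation finds the analytic attractors of the canonical pair", {
  s <- model_structure(21)
  tr <- simulate_model(s, model_params(beta = 3, eps = 1, delta = 1))
  expect_true(tr$steady)
  expect_equal(tr$final_state, c(2 / 3, 2 / 3), tolerance = 1e-3)
  # delta = 2 exceeds the critical 4/3: collapse
  tr2 <- simulate_model(s, model_params(beta = 3, eps = 1, delta = 2))
  expect_equal(tr2$final_state, c(0, 0))
  # uncoupled logistic at delta = 0
  tr3 <- simulate_model(s, model_params(beta = 5, eps = 1, delta = 0),
                        x0 = c(0.02, 1.4))
  expect_equal(tr3$final_state, c(1, 1), tolerance = 1e-3)
  expect_error(simulate_model(s, model_params(beta = 3), x0 = c(-0.1, 0.1)),
               "non-negative")
  expect_error(simulate_model(s, model_params(beta = 3), horizon = -1),
               "positive")
})

test_that("trajectories conserve non-negativity across the family", {
  set.seed(7)
  ids <- sample(1:52, 12)
  for (id in ids) {
    st <- model_structure(id)
    beta <- if (st$benefit_target == "carrying_capacity" &&
                !st$benefit_saturating) runif(1, 0.2, 0.8) else
      runif(1, 0.5, 6)
    p <- model_params(beta = beta, eps = runif(1, 0.5, 2),
                      delta = runif(1, 0, 2),
                      a = if (st$complexity == "competition") 0.2 else 0,
                      d = if (st$complexity == "turnover") 0.1 else 0)
    tr <- simulate_model(st, p, x0 = runif(2, 0.01, 1.2), horizon = 100)
    expect_true(all(tr$states >= 0), label = paste("structure", id))
  }
})

test_that("outcome classification separates coexistence from collapse", {
  s <- model_structure(21)
  expect_equal(classify_outcome(s, model_params(beta = 3, eps = 1,
                                                delta = 1))$code, 1L)
  out <- classify_outcome(s, model_params(beta = 3, eps = 1, delta = 2))
  expect_equal(out$code, -1L)
  expect_equal(out$label, "collapse")
  # asymmetry layer: the weaker partner is lost; the survivor settles at its
  # monoculture reference, which the tie rule reports as collapse
  s_asym <- model_structure(23)
  out2 <- classify_outcome(s_asym, model_params(beta = 1.2, eps = 1,
                                                delta = 0.9))
  if (out2$code != 1L) {
    expect_equal(out2$code, -1L)
    expect_lte(out2$survivor_fitness_change, 1e-3)
  }
})

test_that("stress measurement matches its definition 1 - r_m", {
  s <- model_structure(21)
  expect_lt(abs(measure_delta(s, model_params(beta = 3, eps = 1,
                                              delta = 0.4)) - 0.4), 2e-3)
  expect_equal(measure_delta(s, model_params(beta = 3, eps = 1, delta = 0)),
               0, tolerance = 1e-9)
  # negative monoculture growth (obligate mutualism) gives delta-hat > 1
  expect_gt(measure_delta(s, model_params(beta = 3, eps = 1, delta = 1.5)),
            1)
  # constant cost scales the measured stress: delta-hat = eps * delta
  expect_lt(abs(measure_delta(s, model_params(beta = 3, eps = 2,
                                              delta = 0.4)) - 0.8), 3e-3)
  # turnover can push the reference growth rate to zero: degenerate
  expect_error(measure_delta(model_structure(24),
                             model_params(beta = 3, eps = 1, delta = 0.4,
                                          d = 2)),
               "degenerate")
})

test_that("closed-form benefit and fixed point of the canonical pair", {
  expect_equal(closed_form_B_model21(3, 1), 4 / 3)
  expect_equal(closed_form_B_model21(1, 1), 1)
  expect_equal(closed_form_B_model21(1, 0.25), 4)
  expect_error(closed_form_B_model21(0.9, 1), "beta >= 1")
  expect_equal(fixed_point_model21(3, 1, 1), c(2 / 3, 2 / 3))
  expect_equal(fixed_point_model21(1, 1, 1), c(0, 0))
  expect_equal(fixed_point_model21(4, 1, 0), c(1, 1))
  expect_error(fixed_point_model21(3, 1, 2), "discriminant")
  # self-consistency: the rate function vanishes at the fixed point
  s <- model_structure(21)
  for (beta in c(1.5, 3, 8)) for (delta in c(0.3, 0.6)) {
    xs <- fixed_point_model21(beta, 1.2, delta)
    f <- rate_function(s, model_params(beta = beta, eps = 1.2,
                                       delta = delta))
    expect_equal(f(xs), c(0, 0), tolerance = 1e-10)
  }
})

test_that("bisection recovers the closed-form critical stress", {
  s <- model_structure(21)
  expect_lt(abs(critical_delta(s, model_params(beta = 3, eps = 1)) - 4 / 3),
            1e-3)
  expect_lt(abs(critical_delta(s, model_params(beta = 1, eps = 2)) - 0.5),
            1e-3)
  # increasing in beta at fixed eps
  dc <- vapply(c(1, 2, 5, 10), function(b)
    critical_delta(s, model_params(beta = b, eps = 1)), numeric(1))
  expect_true(all(diff(dc) > 0))
  expect_error(critical_delta(s, model_params(beta = 3, eps = 1),
                              delta_max = 0.5),
               "monotonicity")
})

test_that("coexistence is monotone in stress across the family", {
  fam <- enumerate_models()
  set.seed(3)
  for (id in fam$id) {
    st <- model_structure(id)
    beta <- if (st$benefit_target == "carrying_capacity" &&
                !st$benefit_saturating) 0.7 else 3
    codes <- vapply(seq(0, 2.5, length.out = 6), function(delta) {
      p <- model_params(beta = beta, eps = 1, delta = delta,
                        a = if (st$complexity == "competition") 0.2 else 0,
                        d = if (st$complexity == "turnover") 0.1 else 0)
      classify_outcome(st, p, x0 = c(1, 1))$code
    }, integer(1))
    coexist <- codes == 1L
    expect_lte(sum(abs(diff(coexist))), 1)
    if (any(diff(coexist) != 0)) expect_true(coexist[1])
  }
})

test_that("the noise-free criterion classifies noisy simulations", {
  s <- model_structure(21)
  set.seed(5)
  n <- 60
  sigma <- 0.03
  agree <- vapply(seq_len(n), function(i) {
    beta <- runif(1, 1.5, 6)
    eps <- runif(1, 0.5, 2)
    B <- closed_form_B_model21(beta, eps)
    delta <- B * runif(1, 0.5, 1.5)
    z <- exp(rnorm(3, 0, sigma))
    p <- model_params(beta = beta * z[1], eps = eps * z[2],
                      delta = delta * z[3])
    sim <- classify_outcome(s, p, x0 = c(1, 1))$code == 1L
    (B > delta) == sim
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})
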