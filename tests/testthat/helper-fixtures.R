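# shared fixtures, all generated in code

# linearly separable toy set: coexistence at low delta, collapse at high;
# margin > 0 keeps a delta gap around the boundary
toy_separable <- function(n = 40, seed = 11, noise = 0, margin = 0) {
  set.seed(seed)
  v <- cbind(runif(n), runif(n))
  b_true <- 1.0 + 0.5 * v[, 1]
  if (margin > 0) {
    y <- sample(c(-1, 1), n, replace = TRUE)
    delta <- b_true - y * runif(n, margin, margin + 0.5)
    delta <- pmax(delta, 0.01)
  } else {
    delta <- runif(n, 0.1, 1.9)
    y <- ifelse(b_true + rnorm(n, 0, noise) > delta, 1, -1)
  }
  if (length(unique(y)) < 2) stop("degenerate toy draw; change seed")
  observation_table(v, delta, y)
}

# four-point set, two per class, separated in delta at fixed v
toy_four_point <- function() {
  observation_table(v = cbind(c(0, 1, 0, 1), c(1, 0, 1, 0)),
                    delta = c(0.1, 0.2, 0.8, 0.9),
                    outcome = c(1, 1, -1, -1))
}

# small scenario (reduced grids) for fast unit tests
small_scenario <- function(name, seed = 1, ...) {
  suppressMessages(generate_scenario(
    scenario_config(name, seed = seed, train_n = c(5, 5), test_n = c(7, 7),
                    ...)))
}

r_squared <- function(pred, truth) {
  1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)
}

default_kernel <- function() kernel_spec("linear", k_delta = 1, C = 10)
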