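# Seeded synthetic scenario generators. Each generator simulates a grid of
# (v1, v2) conditions, measures the stress of a reference population from
# partner-free monocultures, classifies the simulated outcome, and returns
# train/test observation tables plus ground truth. Surrogate model forms
# stand in for experiment-specific supplementary models; their structure is
# documented in the methods vignette.

# shared parameter-to-context maps: stress rises with v1, benefit with v2
map_delta <- function(v1) 0.1 + 1.8 * v1
map_beta1 <- function(v2) 10 * v2
map_beta2 <- function(v2) 8 * v2

SCENARIO_NAMES <- c("complex_pair", "n_mutualist", "oscillatory",
                    "bystander", "model21_truth")

#' Scenario configuration
#'
#' @param scenario One of `"complex_pair"`, `"n_mutualist"`,
#'   `"oscillatory"`, `"bystander"`, `"model21_truth"`.
#' @param seed Integer seed (mandatory; all generator randomness flows from
#'   it).
#' @param train_n,test_n Points per axis of the uniform train / test grids
#'   (defaults 10 x 10 = 100 and 50 x 50 = 2500).
#' @param n_members Number of mutualists (`n_mutualist`, `>= 3`).
#' @param n_bystanders Number of bystander populations (`bystander`,
#'   `>= 1`).
#' @param asym Member-specific parameter spread of the N-mutualist
#'   scenario (0 gives fully symmetric members).
#' @param signal Oscillatory-signal settings: `period`, and the static
#'   baseline `beta0`, `eps`, `delta0`.
#' @param ranges Optional list of two axis ranges overriding the scenario
#'   defaults.
#' @return A `scenario_config`.
#' @export
scenario_config <- function(scenario = SCENARIO_NAMES, seed,
                            train_n = c(10, 10), test_n = c(50, 50),
                            n_members = 5, n_bystanders = 5, asym = 0.1,
                            signal = list(period = 5, beta0 = 3, eps = 1,
                                          delta0 = 1),
                            ranges = NULL) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("a seed is mandatory for scenario generation")
  if (scenario == "n_mutualist" && n_members < 3)
    stop("n_mutualist requires n_members >= 3")
  if (scenario == "bystander" && n_bystanders < 1)
    stop("bystander requires n_bystanders >= 1")
  if (is.null(ranges))
    ranges <- if (scenario == "oscillatory")
      list(c(0, 1), c(0.5, 4.5)) else list(c(0, 1), c(0, 1))
  sig <- utils::modifyList(list(period = 5, beta0 = 3, eps = 1, delta0 = 1),
                           signal)
  if (sig$period <= 0) stop("signal period must be positive")
  structure(list(scenario = scenario, seed = as.integer(seed),
                 train_n = train_n, test_n = test_n, n_members = n_members,
                 n_bystanders = n_bystanders, asym = asym, signal = sig,
                 ranges = ranges),
            class = "scenario_config")
}

uniform_grid <- function(n, ranges) {
  axes <- lapply(seq_along(n), function(j)
    seq(ranges[[j]][1], ranges[[j]][2], length.out = n[j]))
  g <- expand.grid(v1 = axes[[1]], v2 = axes[[2]], KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

# steady final state for a raw dynamics kind, doubling the horizon on
# non-convergence (up to 3 times)
scen_steady <- function(kind, par, x0, horizon = DEFAULT_HORIZON,
                        max_extensions = 3) {
  sol <- ode_solve(kind, par, x0, horizon, DEFAULT_RTOL, DEFAULT_ATOL,
                   STEADY_TOL, FALSE)
  ext <- 0
  while (!sol$steady && ext < max_extensions) {
    ext <- ext + 1
    horizon <- horizon * 2
    sol <- ode_solve(kind, par, sol$final_state, horizon, DEFAULT_RTOL,
                     DEFAULT_ATOL, STEADY_TOL, FALSE)
  }
  if (!sol$steady)
    stop("scenario grid point failed to reach steady state")
  sol$final_state
}

clamp_extinct <- function(x) ifelse(x < EXTINCTION_THRESHOLD, 0, x)

# stress of the reference population from its partner-free monoculture:
# per-capita rate at density 1e-3 normalized by the stress-free rate
scen_measure_delta <- function(kind, par, par_nostress, m, ref_index) {
  x <- numeric(m)
  x[ref_index] <- 1e-3
  r_m <- ode_rhs(kind, par, x)[ref_index] / x[ref_index]
  r_max <- ode_rhs(kind, par_nostress, x)[ref_index] / x[ref_index]
  if (r_max <= 0) stop("degenerate scenario: maximum growth rate <= 0")
  1 - r_m / r_max
}

# classify a focal pair: +1 coexistence, -1 collapse, 0 exclusion
# (survivor steady density above its monoculture reference)
classify_pair <- function(fin, mono_ref) {
  alive <- fin > 0
  if (all(alive)) return(1L)
  if (!any(alive)) return(-1L)
  i <- which(alive)[1]
  if (fin[i] > mono_ref(i) + STEADY_TOL) 0L else -1L
}

# ---- per-scenario row evaluation -------------------------------------------

row_complex_pair <- function(v1, v2) {
  par <- c(map_delta(v1), map_delta(v1), map_beta1(v2), map_beta2(v2))
  fin <- clamp_extinct(scen_steady(1L, par, c(0.1, 0.1)))
  mono_ref <- function(i) {
    x0 <- c(0, 0)
    x0[i] <- 0.1
    clamp_extinct(scen_steady(1L, par, x0))[i]
  }
  par0 <- par
  par0[2] <- 0
  list(outcome = classify_pair(fin, mono_ref),
       delta = scen_measure_delta(1L, par, par0, 2L, 2L),
       total_density = sum(fin))
}

n_mut_par <- function(v1, v2, n, asym) {
  mult <- 1 + asym * seq(-1, 1, length.out = n)
  c(n, 1, 2, 0.3, mult * map_delta(v1), rev(mult) * map_beta1(v2))
}

row_n_mutualist <- function(v1, v2, n, asym) {
  par <- n_mut_par(v1, v2, n, asym)
  fin <- clamp_extinct(scen_steady(2L, par, rep(0.1, n)))
  # mutualism-only community: competitive exclusion cannot arise without
  # competition, so any member loss is collapse
  outcome <- if (all(fin > 0)) 1L else -1L
  par0 <- par
  par0[5] <- 0 # member 1 stress off
  list(outcome = outcome,
       delta = scen_measure_delta(2L, par, par0, n, 1L),
       total_density = sum(fin))
}

row_oscillatory <- function(I, L, sig) {
  par <- c(sig$beta0, sig$eps, sig$delta0, I, L, sig$period)
  horizon <- 50 * sig$period
  sol <- ode_solve(3L, par, c(0.1, 0.1), horizon, DEFAULT_RTOL, DEFAULT_ATOL,
                   STEADY_TOL, FALSE, window_start = 40 * sig$period)
  coexist <- all(sol$window_min > EXTINCTION_THRESHOLD)
  # period-averaged stress from the partner-free monoculture
  tg <- seq(0, sig$period, length.out = 65)[-65] + sig$period / 128
  x <- c(0, 1e-3)
  par0 <- par
  par0[3] <- 0
  r_m <- mean(vapply(tg, function(t) ode_rhs(3L, par, x, t)[2], numeric(1))) / 1e-3
  r_max <- mean(vapply(tg, function(t) ode_rhs(3L, par0, x, t)[2],
                       numeric(1))) / 1e-3
  list(outcome = if (coexist) 1L else -1L,
       delta = 1 - r_m / r_max,
       total_density = if (coexist) sum(sol$window_mean) else
         sum(clamp_extinct(sol$window_mean)))
}

bystander_par <- function(v1, v2, nb, W) {
  c(nb, map_delta(v1), map_delta(v1), map_beta1(v2), map_beta2(v2), 1, 0.2,
    as.vector(t(W)))
}

row_bystander <- function(v1, v2, nb, W) {
  m <- 2L + nb
  par <- bystander_par(v1, v2, nb, W)
  fin_all <- scen_steady(4L, par, rep(0.1, m))
  fin <- clamp_extinct(fin_all[1:2])
  cp_par <- par[2:5]
  mono_ref <- function(i) { # focal monoculture, bystander-free
    x0 <- c(0, 0)
    x0[i] <- 0.1
    clamp_extinct(scen_steady(1L, cp_par, x0))[i]
  }
  cp0 <- cp_par
  cp0[2] <- 0
  list(outcome = classify_pair(fin, mono_ref),
       delta = scen_measure_delta(1L, cp_par, cp0, 2L, 2L),
       total_density = sum(fin))
}

# ---- generators ------------------------------------------------------------

scen_rows_static <- function(grid, row_fun) {
  out <- lapply(seq_len(nrow(grid)),
                function(i) row_fun(grid[i, 1], grid[i, 2]))
  data.frame(v1 = grid[, 1], v2 = grid[, 2],
             delta = vapply(out, `[[`, numeric(1), "delta"),
             outcome = vapply(out, `[[`, integer(1), "outcome"),
             total_density = vapply(out, `[[`, numeric(1), "total_density"))
}

rows_to_table <- function(rows, extra = NULL) {
  keep <- rows$outcome != 0L
  rows <- rows[keep, , drop = FALSE]
  q <- data.frame(total_density = rows$total_density)
  if (!is.null(extra)) q <- cbind(q, extra[keep, , drop = FALSE])
  list(table = observation_table(cbind(rows$v1, rows$v2), rows$delta,
                                 rows$outcome, quantitative = q),
       dropped = sum(!keep))
}

#' Generate a synthetic scenario dataset
#'
#' Dispatches on `config$scenario`. All scenarios share the layout:
#' a 10 x 10 training grid (100 observations) and a 50 x 50 test grid
#' (2500 points) over two context variables, outcome labels from
#' simulation, and a stress column measured from partner-free monocultures
#' by the same rule for train and test. Exclusion-labeled rows are dropped
#' with a logged count.
#'
#' @param config A `scenario_config`.
#' @return A `scenario_dataset`: `train` and `test` observation tables
#'   (with a `total_density` quantitative column; `model21_truth` adds
#'   `b_truth`), and `meta` (config echo, dropped-row counts, generator
#'   version).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  gen <- switch(config$scenario,
                complex_pair = generate_complex_pair,
                n_mutualist = generate_n_mutualist,
                oscillatory = generate_oscillatory,
                bystander = generate_bystander,
                model21_truth = generate_model21_truth)
  gen(config)
}

finish_dataset <- function(config, train, test) {
  if (train$dropped + test$dropped > 0)
    message(sprintf("dropped exclusion rows: %d train, %d test",
                    train$dropped, test$dropped))
  structure(list(train = train$table, test = test$table,
                 meta = list(config = config,
                             dropped_train = train$dropped,
                             dropped_test = test$dropped,
                             generator_version = 1L)),
            class = "scenario_dataset")
}

#' @export
print.scenario_dataset <- function(x, ...) {
  cat(sprintf("<scenario dataset> %s (seed %d): %d train / %d test rows, %d coexistence in test\n",
              x$meta$config$scenario, x$meta$config$seed, nrow(x$train),
              nrow(x$test), sum(x$test$outcome == 1)))
  invisible(x)
}

#' @rdname generate_scenario
#' @export
generate_complex_pair <- function(config) {
  finish_dataset(config,
    rows_to_table(scen_rows_static(
      uniform_grid(config$train_n, config$ranges), row_complex_pair)),
    rows_to_table(scen_rows_static(
      uniform_grid(config$test_n, config$ranges), row_complex_pair)))
}

#' @rdname generate_scenario
#' @export
generate_n_mutualist <- function(config) {
  f <- function(v1, v2) row_n_mutualist(v1, v2, config$n_members,
                                        config$asym)
  finish_dataset(config,
    rows_to_table(scen_rows_static(uniform_grid(config$train_n,
                                                config$ranges), f)),
    rows_to_table(scen_rows_static(uniform_grid(config$test_n,
                                                config$ranges), f)))
}

#' @rdname generate_scenario
#' @export
generate_oscillatory <- function(config) {
  f <- function(I, L) row_oscillatory(I, L, config$signal)
  finish_dataset(config,
    rows_to_table(scen_rows_static(uniform_grid(config$train_n,
                                                config$ranges), f)),
    rows_to_table(scen_rows_static(uniform_grid(config$test_n,
                                                config$ranges), f)))
}

#' @rdname generate_scenario
#' @export
generate_bystander <- function(config) {
  nb <- config$n_bystanders
  m <- 2L + nb
  # cross-interaction coefficients, drawn once per seed; focal-focal zero
  W <- with_seed(config$seed, {
    W <- matrix(runif(m * m, -0.15, 0.15), m, m)
    W[1:2, 1:2] <- 0
    diag(W) <- 0
    W
  })
  f <- function(v1, v2) row_bystander(v1, v2, nb, W)
  ds <- finish_dataset(config,
    rows_to_table(scen_rows_static(uniform_grid(config$train_n,
                                                config$ranges), f)),
    rows_to_table(scen_rows_static(uniform_grid(config$test_n,
                                                config$ranges), f)))
  ds$meta$interaction_matrix <- W
  ds
}

# model-21 context maps for the known-truth scenario
truth_beta <- function(v1) 1 + 4 * v1
truth_eps <- function(v2) 0.6 + 0.9 * v2

#' @rdname generate_scenario
#' @export
generate_model21_truth <- function(config) {
  s21 <- model_structure(21)
  build <- function(grid, seed) {
    b <- truth_beta(grid[, 1])
    e <- truth_eps(grid[, 2])
    if (any(b < 1)) stop("beta map must stay >= 1 for the closed form")
    dpar <- with_seed(seed, runif(nrow(grid), 0.3, 2.5))
    B_raw <- closed_form_B_model21(b, e)
    outcome <- ifelse(B_raw > dpar, 1L, -1L)
    dhat <- vapply(seq_len(nrow(grid)), function(i)
      measure_delta(s21, model_params(beta = b[i], eps = e[i],
                                      delta = dpar[i])), numeric(1))
    total <- vapply(seq_len(nrow(grid)), function(i) {
      if (outcome[i] == 1L)
        sum(fixed_point_model21(b[i], e[i], dpar[i])) else 0
    }, numeric(1))
    # effective benefit in measured-stress units: B > delta_raw is
    # algebraically identical to (beta+1)^2/(4 beta) > eps * delta_raw
    rows <- data.frame(v1 = grid[, 1], v2 = grid[, 2], delta = dhat,
                       outcome = outcome, total_density = total)
    rows_to_table(rows, extra = data.frame(b_truth = (b + 1)^2 / (4 * b)))
  }
  finish_dataset(config,
    build(uniform_grid(config$train_n, config$ranges), config$seed),
    build(uniform_grid(config$test_n, config$ranges), config$seed + 1L))
}
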