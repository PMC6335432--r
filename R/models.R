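# Model family: enumeration, simulation, outcome classification, stress
# measurement, critical stress.

# the 13 base structures; bases 6, 8, 9 place the benefit in the stress
# denominator (relief is divisively saturating), as in the canonical pair
#   dX1/dtau = (1/eps) X1 (1 - X1) - delta X1 / (beta X2 + 1)
# which is base 6 (ids 21-24); id 21 is the complexity-free member.
family_bases <- function() {
  b <- data.frame(
    base = 1:13,
    benefit_target = c(
      "growth_rate", "growth_rate", "growth_rate", "growth_rate",
      "growth_rate", "stress_denominator", "growth_rate",
      "stress_denominator", "stress_denominator",
      "carrying_capacity", "carrying_capacity", "carrying_capacity",
      "carrying_capacity"),
    cost_form = c(
      "constant", "constant", "linear_in_self", "linear_in_self",
      "saturating", "constant", "saturating", "linear_in_self",
      "saturating", "constant", "constant", "linear_in_self", "saturating"),
    benefit_saturating = c(
      FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
      FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  b$stress_form <- ifelse(b$benefit_target == "stress_denominator",
                          "divisive", "additive_death")
  b
}

COMPLEXITY_LEVELS <- c("none", "competition", "asymmetry", "turnover")

#' Enumerate the mutualism model family
#'
#' Returns the canonical ordered list of the 52 model structures: 13 base
#' structures (placement of benefit, form of the cooperation cost, and
#' whether the raw benefit function saturates) crossed with 4 complexity
#' layers (none, interspecific competition, structural asymmetry, turnover).
#' Structure id 21 is the symmetric constant-cost model with benefit in the
#' stress denominator, `dX1/dtau = (1/eps) X1 (1-X1) - delta X1/(beta X2+1)`.
#'
#' @return A data frame with one row per structure: `id`, `base`,
#'   `benefit_target`, `cost_form`, `stress_form`, `benefit_saturating`,
#'   `complexity`.
#' @examples
#' fam <- enumerate_models()
#' nrow(fam) # 52
#' @export
enumerate_models <- function() {
  b <- family_bases()
  out <- do.call(rbind, lapply(1:13, function(i) {
    data.frame(
      id = (i - 1L) * 4L + 1:4,
      base = i,
      benefit_target = b$benefit_target[i],
      cost_form = b$cost_form[i],
      stress_form = b$stress_form[i],
      benefit_saturating = b$benefit_saturating[i],
      complexity = COMPLEXITY_LEVELS,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Retrieve one model structure by id
#'
#' @param id Integer in 1..52.
#' @return A `model_structure` object (a named list of structural flags).
#' @export
model_structure <- function(id) {
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L || id > 52L)
    stop("model id must be a single integer in 1..52")
  fam <- enumerate_models()
  s <- as.list(fam[fam$id == id, , drop = FALSE])
  s <- lapply(s, `[[`, 1L)
  structure(s, class = "model_structure")
}

#' @export
print.model_structure <- function(x, ...) {
  cat(sprintf("<model structure %d> benefit on %s, %s cost, %s stress%s, %s\n",
              x$id, x$benefit_target, x$cost_form, x$stress_form,
              if (x$benefit_saturating) ", saturating benefit" else "",
              x$complexity))
  invisible(x)
}

#' Construct model parameters
#'
#' Parameters for the two-population model family. All quantities are
#' dimensionless (time in units of the maximal growth rate, densities
#' relative to carrying capacity). Index-2 fields default to the index-1
#' values (symmetric parameterization); the asymmetry complexity layer adds
#' fixed structural multipliers on top (`beta2 * 0.8`, `eps2 * 1.25`), so
#' user-supplied fields stay equal for symmetric use.
#'
#' @param beta,beta2 Benefit strength, `>= 0`.
#' @param eps,eps2 Cooperation cost, `> 0`.
#' @param delta,delta2 Stress, `>= 0`.
#' @param a Interspecific competition coefficient (competition layer only).
#' @param d Turnover/dilution rate (turnover layer only).
#' @param hill Hill coefficient of the saturating benefit (`>= 1`).
#' @param K_b Benefit half-saturation density (`> 0`).
#' @param K_c Cost half-saturation density (`> 0`).
#' @return A `model_params` object.
#' @export
model_params <- function(beta = 1, eps = 1, delta = 0, a = 0, d = 0,
                         hill = 1, K_b = 0.3, K_c = 0.3,
                         beta2 = beta, eps2 = eps, delta2 = delta) {
  p <- list(beta = beta, beta2 = beta2, eps = eps, eps2 = eps2,
            delta = delta, delta2 = delta2, a = a, d = d, hill = hill,
            K_b = K_b, K_c = K_c)
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("all model parameters must be finite")
  if (any(c(p$beta, p$beta2, p$delta, p$delta2, p$a, p$d) < 0))
    stop("beta, delta, a and d must be non-negative")
  if (any(c(p$eps, p$eps2, p$K_b, p$K_c) <= 0))
    stop("eps, K_b and K_c must be positive")
  if (p$hill < 1) stop("hill coefficient must be >= 1")
  structure(p, class = "model_params")
}

# configuration-consistency check between a structure and parameters
validate_params <- function(structure, params) {
  stopifnot(inherits(structure, "model_structure"),
            inherits(params, "model_params"))
  if (structure$complexity != "competition" && params$a != 0)
    stop(sprintf(
      "configuration error: competition coefficient a supplied to the %s '%s' structure (id %d)",
      "no-competition", structure$complexity, structure$id))
  if (structure$complexity != "turnover" && params$d != 0)
    stop(sprintf(
      "configuration error: turnover rate d supplied to structure id %d (complexity '%s')",
      structure$id, structure$complexity))
  if (structure$complexity != "asymmetry" &&
      (params$beta != params$beta2 || params$eps != params$eps2 ||
       params$delta != params$delta2))
    stop("configuration error: symmetric structures require equal index-1 and index-2 parameters")
  invisible(TRUE)
}

pack_family_params <- function(structure, params) {
  bt <- match(structure$benefit_target,
              c("growth_rate", "carrying_capacity", "stress_denominator")) - 1L
  cf <- match(structure$cost_form,
              c("constant", "linear_in_self", "saturating")) - 1L
  layer <- match(structure$complexity, COMPLEXITY_LEVELS) - 1L
  c(bt, cf, as.integer(structure$benefit_saturating), layer,
    params$beta, params$beta2, params$eps, params$eps2,
    params$delta, params$delta2, params$a, params$d,
    params$hill, params$K_b, params$K_c)
}

#' Rate function of a model structure
#'
#' @param structure A `model_structure`.
#' @param params A `model_params` consistent with the structure.
#' @return A function mapping a state vector `c(X1, X2)` to the derivative
#'   vector `dX/dtau`.
#' @examples
#' f <- rate_function(model_structure(21),
#'                    model_params(beta = 3, eps = 1, delta = 1))
#' f(c(2 / 3, 2 / 3)) # ~ c(0, 0)
#' @export
rate_function <- function(structure, params) {
  validate_params(structure, params)
  p <- pack_family_params(structure, params)
  function(x) {
    if (length(x) != 2L) stop("state must have length 2")
    ode_rhs(0L, p, as.numeric(x))
  }
}

#' Simulate a model trajectory
#'
#' Integrates the model from `x0` until `horizon` or until a steady state
#' (derivative max-norm below `steady_tol`). Densities below the extinction
#' threshold are clamped to zero in `final_state` at readout.
#'
#' @inheritParams rate_function
#' @param x0 Non-negative initial state, default `c(0.1, 0.1)` (equal
#'   low-density seeding, the standard co-culture protocol).
#' @param horizon Integration horizon in dimensionless time.
#' @param rtol,atol Integration tolerances.
#' @param steady_tol Steady-state tolerance on the derivative max-norm.
#' @param record Keep the full trajectory (times x states)?
#' @param extinction_threshold Densities below this are read out as zero.
#' @return A `trajectory` object: `times`, `states` (when recorded),
#'   `steady`, `final_state` (clamped), `final_raw`.
#' @export
simulate_model <- function(structure, params, x0 = c(0.1, 0.1),
                           horizon = DEFAULT_HORIZON, rtol = DEFAULT_RTOL,
                           atol = DEFAULT_ATOL, steady_tol = STEADY_TOL,
                           record = TRUE,
                           extinction_threshold = EXTINCTION_THRESHOLD) {
  validate_params(structure, params)
  if (any(x0 < 0)) stop("initial densities must be non-negative")
  if (horizon <= 0) stop("horizon must be positive")
  p <- pack_family_params(structure, params)
  sol <- ode_solve(0L, p, as.numeric(x0), horizon, rtol, atol, steady_tol,
                   record)
  fin <- sol$final_state
  out <- list(times = sol$times, states = sol$states, steady = sol$steady,
              final_state = ifelse(fin < extinction_threshold, 0, fin),
              final_raw = fin, t_final = sol$t_final)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> t_final = %.4g, steady = %s, final = (%s)\n",
              x$t_final, x$steady,
              paste(signif(x$final_state, 4), collapse = ", ")))
  invisible(x)
}

# steady final state with horizon-doubling on non-convergence
steady_final <- function(structure, params, x0, horizon = DEFAULT_HORIZON,
                         max_extensions = 3, ...) {
  tr <- simulate_model(structure, params, x0, horizon, record = FALSE, ...)
  ext <- 0
  while (!tr$steady && ext < max_extensions) {
    ext <- ext + 1
    horizon <- horizon * 2
    tr <- simulate_model(structure, params, tr$final_raw, horizon,
                         record = FALSE, ...)
  }
  if (!tr$steady)
    stop("no steady state within extended horizon; increase `horizon`")
  tr
}

#' Classify the outcome of a co-culture
#'
#' Coexistence means every population persists above the extinction
#' threshold at steady state. When one population is lost, the outcome is
#' collapse if the survivor's steady density is at or below its partner-free
#' monoculture density, and competitive exclusion (label 0) if it exceeds it
#' -- exclusion cannot be generated by the mutualistic interaction alone and
#' is excluded from calibration.
#'
#' @inheritParams simulate_model
#' @param max_extensions Number of horizon doublings tried before a
#'   non-convergence error is raised.
#' @return An `outcome_label`: `label` (`"coexistence"`, `"collapse"` or
#'   `"exclusion"`), `code` (+1 / -1 / 0), `survivor_fitness_change`
#'   (survivor steady density minus the monoculture reference), and
#'   `final_state`.
#' @export
classify_outcome <- function(structure, params, x0 = c(0.1, 0.1),
                             horizon = DEFAULT_HORIZON, max_extensions = 3,
                             extinction_threshold = EXTINCTION_THRESHOLD,
                             ...) {
  tr <- steady_final(structure, params, x0, horizon, max_extensions,
                     extinction_threshold = extinction_threshold, ...)
  fin <- tr$final_state
  alive <- fin > 0
  if (all(alive)) {
    out <- list(label = "coexistence", code = 1L,
                survivor_fitness_change = NA_real_, final_state = fin)
  } else if (!any(alive)) {
    out <- list(label = "collapse", code = -1L,
                survivor_fitness_change = NA_real_, final_state = fin)
  } else {
    i <- which(alive)[1]
    mono_x0 <- c(0, 0)
    mono_x0[i] <- if (x0[i] > 0) x0[i] else 0.1
    ref <- steady_final(structure, params, mono_x0, horizon, max_extensions,
                        extinction_threshold = extinction_threshold,
                        ...)$final_state[i]
    change <- fin[i] - ref
    # the tie band must exceed the steady-state integration residual
    if (change > EXCLUSION_MARGIN) {
      out <- list(label = "exclusion", code = 0L,
                  survivor_fitness_change = change, final_state = fin)
    } else {
      out <- list(label = "collapse", code = -1L,
                  survivor_fitness_change = change, final_state = fin)
    }
  }
  class(out) <- "outcome_label"
  out
}

#' @export
print.outcome_label <- function(x, ...) {
  cat(sprintf("<outcome> %s (%+d)\n", x$label, x$code))
  invisible(x)
}

#' Measure stress from partner-free growth
#'
#' Stress is defined as `1 - r_m`, where `r_m` is the population's partner-
#' free per-capita growth rate normalized by its maximum growth rate (the
#' rate with stress fully relieved). Rates are evaluated at low density
#' (1e-3) through the model rate function so the same rule applies to every
#' structure. The estimate can exceed 1 when monoculture growth is negative
#' (obligate mutualism).
#'
#' @inheritParams rate_function
#' @param population Index (1 or 2) of the population measured.
#' @return The stress estimate, a non-negative scalar.
#' @export
measure_delta <- function(structure, params, population = 1) {
  validate_params(structure, params)
  stopifnot(population %in% c(1, 2))
  x <- c(0, 0)
  x[population] <- 1e-3
  p_mono <- pack_family_params(structure, params)
  rate_m <- ode_rhs(0L, p_mono, x)[population] / x[population]
  params0 <- params
  params0$delta <- 0
  params0$delta2 <- 0
  p_max <- pack_family_params(structure, params0)
  rate_max <- ode_rhs(0L, p_max, x)[population] / x[population]
  if (rate_max <= 0)
    stop("degenerate model: maximum growth rate is not positive")
  1 - rate_m / rate_max
}

#' Closed-form effective benefit of model 21
#'
#' For the canonical pair (structure 21) the coexistence criterion is
#' `(beta + 1)^2 / (4 beta eps) > delta` for `beta >= 1`; the left-hand side
#' is the effective benefit `B`.
#'
#' @param beta Benefit strength, `>= 1` (the closed form is restricted to
#'   this domain).
#' @param eps Cooperation cost, `> 0`.
#' @return The effective benefit `B = (beta + 1)^2 / (4 beta eps)`.
#' @export
closed_form_B_model21 <- function(beta, eps) {
  if (any(beta < 1)) stop("closed form requires beta >= 1")
  if (any(eps <= 0)) stop("eps must be positive")
  (beta + 1)^2 / (4 * beta * eps)
}

#' Coexistence fixed point of model 21
#'
#' The symmetric coexistence state solves
#' `beta X^2 - (beta - 1) X + (eps delta - 1) = 0`; the larger root is
#' `X* = (beta - 1 + sqrt((beta + 1)^2 - 4 beta eps delta)) / (2 beta)`.
#' (The denominator follows from self-consistency with the rate function,
#' which evaluates to zero there.)
#'
#' @param beta,eps Model parameters (`beta > 0`, `eps > 0`).
#' @param delta Stress.
#' @return The coexistence state `c(X1, X2)`.
#' @export
fixed_point_model21 <- function(beta, eps, delta) {
  disc <- (beta + 1)^2 - 4 * beta * eps * delta
  if (disc < 0)
    stop("no coexistence fixed point: discriminant is negative")
  xs <- (beta - 1 + sqrt(disc)) / (2 * beta)
  c(xs, xs)
}

#' Critical stress by bisection
#'
#' Finds the stress level at which the coexistence attractor is lost, by
#' bisection on the simulated outcome. The probe starts from the
#' high-density state `x0 = c(1, 1)`: the model family is bistable near the
#' transition, and probing from high density tracks the disappearance of
#' the coexistence state itself (the quantity the closed-form criteria
#' describe) rather than a basin boundary.
#'
#' @inheritParams rate_function
#' @param params Parameters; the `delta`/`delta2` fields are scanned and
#'   need not be set.
#' @param tol Absolute tolerance on the returned critical stress.
#' @param delta_max Upper limit of the bracket search.
#' @param x0 Initial state used by the outcome probe.
#' @return The critical stress `delta_c`.
#' @export
critical_delta <- function(structure, params, tol = 1e-3, delta_max = 64,
                           x0 = c(1, 1)) {
  coexists <- function(delta) {
    p <- params
    p$delta <- delta
    p$delta2 <- delta
    tr <- steady_final(structure, p, x0)
    # Newton-polish the simulated endpoint onto the nearest equilibrium:
    # near a fold the flow is algebraically slow and a pure derivative
    # threshold would misread the transient; the criterion concerns the
    # existence of a real positive fixed point
    eq <- polish_equilibrium(rate_function(structure, p), tr$final_raw)
    fin <- if (is.null(eq)) tr$final_state else eq
    all(fin > EXTINCTION_THRESHOLD)
  }
  if (!coexists(0))
    stop("no transition to find: outcome is not coexistence at delta = 0")
  lo <- 0
  hi <- 1
  while (coexists(hi)) {
    lo <- hi
    hi <- hi * 2
    if (hi > delta_max)
      stop("monotonicity violation: no collapse found below delta_max")
  }
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    if (coexists(mid)) lo <- mid else hi <- mid
  }
  (hi + lo) / 2
}

# damped Newton onto a root of the rate function; NULL when it wanders or
# stalls (caller falls back to the simulated endpoint)
polish_equilibrium <- function(f, x, tol = 1e-12, maxit = 60) {
  n <- length(x)
  for (it in seq_len(maxit)) {
    Fx <- f(x)
    if (max(abs(Fx)) < tol) return(pmax(x, 0))
    J <- matrix(0, n, n)
    h <- pmax(1e-7, abs(x) * 1e-7)
    for (j in seq_len(n)) {
      xp <- x
      xp[j] <- xp[j] + h[j]
      J[, j] <- (f(xp) - Fx) / h[j]
    }
    step <- tryCatch(solve(J, Fx), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    xn <- x - step
    if (any(!is.finite(xn)) || any(xn < -0.05) || any(xn > 5)) return(NULL)
    x <- xn
  }
  NULL
}

# ---- four-assumption audit -------------------------------------------------

# per-capita rate at a state, for audits
percapita <- function(structure, params, x, i) {
  p <- pack_family_params(structure, params)
  ode_rhs(0L, p, x)[i] / x[i]
}

audit_beta_grid <- function(structure) {
  # unsaturated carrying-capacity benefit needs beta < 1 for bounded growth
  if (structure$benefit_target == "carrying_capacity" &&
      !structure$benefit_saturating) c(0.4, 0.8) else c(0.8, 2, 4, 8)
}

audit_params <- function(structure, beta, eps = 1, delta = 0,
                         strip_competition = FALSE) {
  a <- if (structure$complexity == "competition" && !strip_competition)
    0.2 else 0
  model_params(beta = beta, eps = eps, delta = delta, a = a,
               d = if (structure$complexity == "turnover") 0.1 else 0,
               hill = 2)
}

#' Audit a structure against the four model-development assumptions
#'
#' Numerically checks that (1) the benefit term is non-decreasing in partner
#' density, (2) the cost term is non-increasing on growth, (3) some
#' parameter combination produces negative per-capita growth, and (4) that
#' negative growth can be reversed by sufficiently large partner benefit.
#'
#' @inheritParams rate_function
#' @return A named logical vector of length 4.
#' @export
audit_structure <- function(structure) {
  betas <- audit_beta_grid(structure)
  xj_grid <- seq(0, 2, by = 0.25)

  # (1) benefit effect phi(beta) - phi(beta = 0) non-negative and
  #     non-decreasing in partner density; the benefit and cost terms are
  #     layer-independent, so (1) and (2) are probed with the competition
  #     crowding term switched off to avoid conflating the two
  pb <- audit_params(structure, betas[length(betas)], delta = 0.5,
                     strip_competition = TRUE)
  p0 <- audit_params(structure, 0, delta = 0.5, strip_competition = TRUE)
  eff <- vapply(xj_grid, function(xj) {
    percapita(structure, pb, c(0.5, xj), 1) -
      percapita(structure, p0, c(0.5, xj), 1)
  }, numeric(1))
  a1 <- all(eff >= -1e-12) && all(diff(eff) >= -1e-9)

  # (2) cost non-increasing: raising eps never raises per-capita growth
  states <- expand.grid(xi = c(0.1, 0.5, 0.9), xj = c(0.1, 0.5, 0.9))
  a2 <- all(vapply(seq_len(nrow(states)), function(r) {
    x <- c(states$xi[r], states$xj[r])
    p1 <- audit_params(structure, betas[1], eps = 1, delta = 0.3,
                       strip_competition = TRUE)
    p2 <- audit_params(structure, betas[1], eps = 2, delta = 0.3,
                       strip_competition = TRUE)
    percapita(structure, p2, x, 1) <= percapita(structure, p1, x, 1) + 1e-12
  }, logical(1)))

  # (3) some parameter combination yields negative per-capita growth and
  # (4) a witness where the negative growth is reversed by partner benefit
  a3 <- FALSE
  a4 <- FALSE
  for (beta in betas) {
    for (delta in c(0.3, 0.6, 1, 2)) {
      for (xi in c(0.05, 0.5, 0.9)) {
        p <- audit_params(structure, beta, delta = delta)
        low <- percapita(structure, p, c(xi, 1e-9), 1)
        if (low < -1e-6) {
          a3 <- TRUE
          for (xj in c(1, 2, 5)) {
            if (percapita(structure, p, c(xi, xj), 1) > 1e-6) a4 <- TRUE
          }
        }
      }
    }
  }
  c(benefit_monotone = a1, cost_monotone = a2, stress_negative_growth = a3,
    benefit_reverses = a4)
}

#' Audit the whole enumerated family
#'
#' @return Logical vector of length 52: does each structure pass all four
#'   assumptions?
#' @export
audit_family <- function() {
  fam <- enumerate_models()
  vapply(fam$id, function(id) all(audit_structure(model_structure(id))),
         logical(1))
}
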