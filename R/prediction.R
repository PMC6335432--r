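# Prediction: qualitative outcomes from B(v)/delta, quantitative-trend
# assessment, coexistence probability under parameter noise, and composed
# multi-member metrics.

#' Predict outcomes from a calibrated benefit surface
#'
#' Applies the rule: coexistence is predicted when the effective benefit
#' exceeds stress, i.e. `ratio = B(v)/delta > 1` (a boundary tie
#' `ratio = 1` predicts collapse, matching the strict inequality of the
#' criterion). The classifier's directionality adjustment is respected, so
#' the prediction always agrees with the sign of the underlying decision
#' function.
#'
#' @param object A `calibrated_benefit`.
#' @param v Raw context matrix (one row per prediction) or vector.
#' @param delta Positive stress values (stress-free systems trivially
#'   coexist and are rejected rather than predicted).
#' @param ... Unused.
#' @return A data frame with columns `B`, `ratio`, `label` (+1/-1),
#'   `outcome` (`"coexistence"`/`"collapse"`) and `margin = |ratio - 1|`.
#' @export
predict.calibrated_benefit <- function(object, v, delta, ...) {
  B <- benefit_at(object, v)
  if (length(delta) != length(B))
    stop("delta must have one value per row of v")
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop("delta must be positive: stress-free systems trivially coexist and are flagged, not predicted")
  ratio <- B / delta
  coexist <- object$direction * (ratio - 1) > 0
  data.frame(B = B, ratio = ratio,
             label = ifelse(coexist, 1L, -1L),
             outcome = ifelse(coexist, "coexistence", "collapse"),
             margin = abs(ratio - 1))
}

#' Trend of a quantitative outcome against B/delta
#'
#' Within the predicted-coexistence region (`ratio > 1`) the ratio is
#' expected to be positively related to quantitative outcomes such as total
#' steady-state density. The association is summarized by a Spearman rank
#' correlation (the rule claims a positive trend, not linearity) together
#' with equal-count binned means.
#'
#' @param results Prediction data frame from [predict.calibrated_benefit()]
#'   (or any data frame with a `ratio` column), or a numeric ratio vector.
#' @param outcome Numeric outcome vector, same length.
#' @param n_bins Number of equal-count bins.
#' @return A `trend_report`: `correlation`, `positive` flag, `bins`
#'   (data frame of bin centers, outcome means, counts), `n`.
#' @export
quantitative_trend <- function(results, outcome, n_bins = 10) {
  ratio <- if (is.numeric(results)) results else results$ratio
  if (length(outcome) != length(ratio))
    stop("outcome must match the predictions in length")
  keep <- ratio > 1
  if (sum(keep) < 10)
    stop("insufficient data: fewer than 10 rows with ratio > 1")
  r <- ratio[keep]
  o <- outcome[keep]
  rho <- suppressWarnings(cor(r, o, method = "spearman"))
  if (is.na(rho)) rho <- 0 # constant outcome carries no trend
  brk <- unique(quantile(r, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(r, brk, include.lowest = TRUE)
  bins <- data.frame(
    ratio_mid = as.numeric(tapply(r, bin, mean)),
    outcome_mean = as.numeric(tapply(o, bin, mean)),
    count = as.integer(table(bin)))
  structure(list(correlation = rho, positive = rho > 0, bins = bins,
                 n = sum(keep)), class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat(sprintf("<trend> Spearman rho = %.3f (%s) on %d rows with B/delta > 1\n",
              x$correlation, if (x$positive) "positive" else "not positive",
              x$n))
  invisible(x)
}

#' Probability of coexistence under parameter noise
#'
#' Fraction of replicate simulations that coexist when `beta`, `eps`,
#' `delta` and the initial densities are perturbed by independent
#' multiplicative lognormal noise (`sdlog = noise_sigma`).
#'
#' @inheritParams simulate_model
#' @param noise_sigma Lognormal noise scale (`>= 0`).
#' @param n_rep Number of replicates (`>= 1`).
#' @param seed Integer seed.
#' @return Fraction in `[0, 1]`.
#' @export
coexistence_probability <- function(structure, params, noise_sigma, n_rep,
                                    seed, x0 = c(0.1, 0.1)) {
  if (n_rep < 1) stop("n_rep must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  with_seed(seed, {
    hits <- 0L
    for (r in seq_len(n_rep)) {
      z <- function() exp(rnorm(1, 0, noise_sigma))
      p <- params
      p$beta <- params$beta * z()
      p$beta2 <- if (structure$complexity == "asymmetry")
        params$beta2 * z() else p$beta
      p$eps <- params$eps * z()
      p$eps2 <- if (structure$complexity == "asymmetry")
        params$eps2 * z() else p$eps
      p$delta <- params$delta * z()
      p$delta2 <- if (structure$complexity == "asymmetry")
        params$delta2 * z() else p$delta
      x <- x0 * exp(rnorm(length(x0), 0, noise_sigma))
      out <- classify_outcome(structure, p, x0 = x)
      if (out$code == 1L) hits <- hits + 1L
    }
    hits / n_rep
  })
}

#' Compose a three-member metric from pairwise calibrations
#'
#' The effective benefit of a three-member system is approximated by the
#' average of the three pairwise benefits, and likewise for stress; the
#' prediction ratio is the ratio of the two averages.
#'
#' @param pair_B Three pairwise benefit values.
#' @param pair_delta Three pairwise stress values.
#' @return List with `B`, `delta`, `ratio`.
#' @export
compose_triplet <- function(pair_B, pair_delta) {
  if (length(pair_B) != 3 || length(pair_delta) != 3)
    stop("exactly three pairwise B and three pairwise delta values are required")
  B <- mean(pair_B)
  d <- mean(pair_delta)
  if (d <= 0) stop("mean pairwise delta must be positive")
  list(B = B, delta = d, ratio = B / d)
}
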