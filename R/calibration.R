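# Calibration: delta-separable kernel SVMs on (v, delta, Y) observations and
# inversion of the decision boundary into an empirical benefit surface B(v).

#' Construct an observation table
#'
#' The calibration input: context variables `v` (one row per observation),
#' the stress `delta` of the chosen reference population (the same proxy for
#' every row), and the qualitative outcome `outcome` coded +1 (coexistence),
#' -1 (collapse) or 0 (competitive exclusion; dropped before training).
#'
#' @param v Numeric matrix or data frame, n x k, `k >= 1`.
#' @param delta Numeric vector of length n.
#' @param outcome Vector of labels in `{-1, 0, 1}`.
#' @param quantitative Optional named list/data frame of additional numeric
#'   outcome columns (total density, fold change, ...), each of length n.
#' @return An `observation_table` (a data frame with columns `v_1..v_k`,
#'   `delta`, `outcome`, then any quantitative columns).
#' @export
observation_table <- function(v, delta, outcome, quantitative = NULL) {
  v <- as.matrix(v)
  storage.mode(v) <- "double"
  n <- nrow(v)
  k <- ncol(v)
  if (k < 1) stop("at least one context variable is required")
  if (n < 2) stop("at least two observations are required")
  if (length(delta) != n || length(outcome) != n)
    stop("v, delta and outcome must have matching lengths")
  if (any(is.na(v)) || any(is.na(delta)) || any(is.na(outcome)))
    stop("missing values are not allowed in v, delta or outcome")
  if (!all(outcome %in% c(-1, 0, 1)))
    stop("outcome labels must be +1 (coexistence), -1 (collapse) or 0 (exclusion)")
  tab <- as.data.frame(v)
  names(tab) <- paste0("v_", seq_len(k))
  tab$delta <- as.numeric(delta)
  tab$outcome <- as.integer(outcome)
  if (!is.null(quantitative)) {
    quantitative <- as.data.frame(quantitative)
    if (nrow(quantitative) != n)
      stop("quantitative columns must have length n")
    tab <- cbind(tab, quantitative)
  }
  attr(tab, "k") <- k
  class(tab) <- c("observation_table", "data.frame")
  tab
}

table_k <- function(table) {
  attr(table, "k") %||% sum(grepl("^v_[0-9]+$", names(table)))
}

table_v <- function(table) {
  as.matrix(table[, paste0("v_", seq_len(table_k(table))), drop = FALSE])
}

# drop exclusion-labeled rows (label 0); count retained as attribute
drop_exclusion <- function(table, quiet = FALSE) {
  n0 <- sum(table$outcome == 0L)
  if (n0 > 0) {
    if (!quiet)
      message(sprintf("dropping %d exclusion-labeled row(s) before training",
                      n0))
    table <- table[table$outcome != 0L, , drop = FALSE]
  }
  attr(table, "dropped_exclusion") <- n0
  table
}

#' Standardize an observation table
#'
#' Centers and scales every `v` column and `delta` to mean 0 and (sample)
#' standard deviation 1; labels are untouched.
#'
#' @param table An `observation_table`.
#' @return A list with `table` (the standardized table) and
#'   `standardization` (per-column means and SDs, class `standardization`).
#' @export
standardize_table <- function(table) {
  k <- table_k(table)
  cols <- c(paste0("v_", seq_len(k)), "delta")
  mu <- vapply(cols, function(cn) mean(table[[cn]]), numeric(1))
  sg <- vapply(cols, function(cn) sd(table[[cn]]), numeric(1))
  bad <- cols[!is.finite(sg) | sg <= 0]
  if (length(bad))
    stop("degenerate input: constant column(s) ", paste(bad, collapse = ", "))
  out <- table
  for (cn in cols) out[[cn]] <- (table[[cn]] - mu[[cn]]) / sg[[cn]]
  std <- structure(list(columns = cols, mean = mu, sd = sg),
                   class = "standardization")
  list(table = out, standardization = std)
}

# apply / invert a standardization to a v matrix and delta vector
std_apply_v <- function(std, v) {
  v <- as.matrix(v)
  k <- length(std$columns) - 1L
  if (ncol(v) != k)
    stop(sprintf("dimension error: model expects %d context variable(s), got %d",
                 k, ncol(v)))
  sweep(sweep(v, 2, std$mean[seq_len(k)]), 2, std$sd[seq_len(k)], "/")
}

std_apply_delta <- function(std, delta) {
  i <- length(std$columns)
  (delta - std$mean[[i]]) / std$sd[[i]]
}

#' Kernel specification
#'
#' Kernels are additively separable between the context variables and the
#' stress coordinate: `K([v_i, d_i], [v_j, d_j]) = K_v(v_i, v_j) +
#' k_delta * d_i * d_j`. `K_v` dictates the shape of the calibrated benefit
#' surface; because delta enters only bilinearly, the decision boundary can
#' be solved for delta in closed form.
#'
#' @param family One of `"linear"`, `"quadratic"`, `"cubic"`, `"sigmoid"`.
#' @param k_delta Positive weight on the delta component.
#' @param C Soft-margin penalty, `> 0`.
#' @param scale,offset Sigmoid parameters (`tanh(scale * <v, v'> + offset)`).
#' @return A `kernel_spec`.
#' @export
kernel_spec <- function(family = c("linear", "quadratic", "cubic", "sigmoid"),
                        k_delta = 1, C = 1, scale = 1, offset = 0) {
  family <- match.arg(family)
  if (k_delta <= 0) stop("k_delta must be positive")
  if (C <= 0) stop("C must be positive")
  structure(list(family = family, k_delta = k_delta, C = C, scale = scale,
                 offset = offset),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- if (x$family == "sigmoid")
    sprintf(", scale=%g, offset=%g", x$scale, x$offset) else ""
  cat(sprintf("<kernel> %s, k_delta=%g, C=%g%s\n", x$family, x$k_delta, x$C,
              extra))
  invisible(x)
}

# v-part kernel matrix between row sets V1 (m x k) and V2 (n x k)
kv_matrix <- function(kernel, V1, V2) {
  lin <- V1 %*% t(V2)
  switch(kernel$family,
         linear = lin,
         quadratic = (lin + 1)^2,
         cubic = (lin + 1)^3,
         sigmoid = tanh(kernel$scale * lin + kernel$offset))
}

#' Evaluate the separable kernel on two (v, delta) points
#'
#' @param kernel A `kernel_spec`.
#' @param a,b Numeric vectors `c(v_1, ..., v_k, delta)` (the stress
#'   coordinate last), assumed standardized.
#' @return The kernel value, symmetric in `a` and `b`.
#' @export
kernel_value <- function(kernel, a, b) {
  if (length(a) != length(b)) stop("dimension mismatch between a and b")
  k <- length(a) - 1L
  if (k < 1) stop("points must contain at least one context variable")
  va <- matrix(a[seq_len(k)], 1)
  vb <- matrix(b[seq_len(k)], 1)
  drop(kv_matrix(kernel, va, vb)) + kernel$k_delta * a[k + 1] * b[k + 1]
}

gram_matrix <- function(kernel, V, delta) {
  kv_matrix(kernel, V, V) + kernel$k_delta * tcrossprod(delta)
}

#' Train the soft-margin SVM classifier
#'
#' Trains on a standardized observation table using the precomputed Gram
#' matrix of the separable kernel. The stored decision function is
#' `f(v, d) = sum_i alpha_i y_i K_v(v_i, v) + k_delta * d * S_delta +
#' lambda_0` with `S_delta = sum_i alpha_i y_i delta_i`; the sign convention
#' is `f > 0` for coexistence.
#'
#' @param table_s A standardized `observation_table` (see
#'   [standardize_table()]); exclusion rows are dropped.
#' @param kernel A `kernel_spec`.
#' @param standardization The `standardization` used to produce `table_s`
#'   (kept so the classifier can be applied to raw inputs later).
#' @return An `svm_classifier`.
#' @export
train_classifier <- function(table_s, kernel, standardization = NULL) {
  table_s <- drop_exclusion(table_s, quiet = TRUE)
  y <- table_s$outcome
  if (length(unique(y)) < 2)
    stop("training requires both coexistence and collapse labels")
  V <- table_v(table_s)
  d <- table_s$delta
  G <- gram_matrix(kernel, V, d)
  fit <- smo_train(G, as.numeric(y), kernel$C)
  alpha <- fit$alpha
  sv <- which(alpha > 1e-8)
  w <- alpha[sv] * y[sv]
  S_delta <- sum(alpha * y * d)
  gram_min_eig <- if (kernel$family == "sigmoid")
    min(eigen(kv_matrix(kernel, V, V), symmetric = TRUE,
              only.values = TRUE)$values) else NA_real_
  structure(list(
    V_sv = V[sv, , drop = FALSE], d_sv = d[sv], weights = w,
    bias = fit$bias, kernel = kernel, S_delta = S_delta,
    standardization = standardization,
    train_V = V, train_d = d, train_y = y,
    n = length(y), converged = fit$converged,
    gram_min_eig = gram_min_eig), class = "svm_classifier")
}

#' Decision function of a trained classifier
#'
#' @param clf An `svm_classifier`.
#' @param v_s Standardized context matrix (n x k).
#' @param d_s Standardized stress vector.
#' @return `f(v, delta)`; positive predicts coexistence.
#' @export
decision_function <- function(clf, v_s, d_s) {
  v_s <- as.matrix(v_s)
  drop(kv_matrix(clf$kernel, v_s, clf$V_sv) %*% clf$weights) +
    clf$kernel$k_delta * d_s * clf$S_delta + clf$bias
}

# primitive benefit surface in standardized delta units
benefit0_std <- function(clf, v_s) {
  v_s <- as.matrix(v_s)
  fv <- drop(kv_matrix(clf$kernel, v_s, clf$V_sv) %*% clf$weights)
  (-fv - clf$bias) / (clf$kernel$k_delta * clf$S_delta)
}

#' Invert the decision boundary into a benefit surface
#'
#' On the decision boundary `f(v, delta) = 0` the rule gives `B = delta`,
#' so solving `f` for the (linear) delta coordinate yields the primitive
#' surface `B_0(v) = (-sum_i alpha_i y_i K_v(v_i, v) - lambda_0) /
#' (k_delta S_delta)`. `B_0` is then adjusted for directionality (the sign
#' of the `B - delta` comparison is flipped when fewer than half of the
#' training rows sign-match their labels) and rescaled to the original
#' delta units.
#'
#' @param clf An `svm_classifier` with `S_delta != 0` and a stored
#'   standardization.
#' @return A `calibrated_benefit`.
#' @export
extract_benefit <- function(clf) {
  if (!is.finite(clf$S_delta) || abs(clf$S_delta) < 1e-12)
    stop("benefit extraction undefined: S_delta is zero")
  if (is.null(clf$standardization))
    stop("classifier carries no standardization; train via calibrate() or pass one")
  b0 <- benefit0_std(clf, clf$train_V)
  match_frac <- mean(sign(b0 - clf$train_d) == clf$train_y)
  direction <- if (match_frac >= 0.5) 1L else -1L
  i <- length(clf$standardization$columns)
  structure(list(
    classifier = clf, direction = direction,
    rescale = list(mean = clf$standardization$mean[[i]],
                   sd = clf$standardization$sd[[i]]),
    train_match_fraction = match_frac,
    diagnostics = list()), class = "calibrated_benefit")
}

#' Evaluate a calibrated benefit surface
#'
#' @param calibrated A `calibrated_benefit`.
#' @param v Raw (unstandardized) context matrix or vector.
#' @return `B(v)` in the original delta units.
#' @export
benefit_at <- function(calibrated, v) {
  clf <- calibrated$classifier
  if (is.null(dim(v))) v <- matrix(v, ncol = length(clf$standardization$columns) - 1L)
  v_s <- std_apply_v(clf$standardization, v)
  benefit0_std(clf, v_s) * calibrated$rescale$sd + calibrated$rescale$mean
}

#' @export
print.calibrated_benefit <- function(x, ...) {
  cat(sprintf(
    "<calibrated benefit surface> %s kernel, k_delta=%g, C=%g, %d SVs, direction %+d\n",
    x$classifier$kernel$family, x$classifier$kernel$k_delta,
    x$classifier$kernel$C, length(x$classifier$weights), x$direction))
  invisible(x)
}

#' One-call calibration
#'
#' Standardize, train and extract in one step.
#'
#' @param table An `observation_table` (raw units).
#' @param kernel A `kernel_spec`.
#' @return A `calibrated_benefit`.
#' @export
calibrate <- function(table, kernel) {
  table <- drop_exclusion(table, quiet = TRUE)
  s <- standardize_table(table)
  clf <- train_classifier(s$table, kernel, s$standardization)
  extract_benefit(clf)
}

# stratified fold assignment; deterministic given the current RNG state
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated classification accuracy
#'
#' Stratified k-fold cross-validation (leave-one-out when `n < 30`);
#' each fold is standardized on its training part only.
#'
#' @param table An `observation_table` (raw units).
#' @param kernel A `kernel_spec`.
#' @param folds Number of folds (`>= 2`); `NULL` (default) selects 10-fold,
#'   or leave-one-out when `n < 30`.
#' @param seed Integer seed (mandatory; fold assignment is stochastic).
#' @return Mean held-out accuracy in percent. The per-fold accuracies are
#'   attached as attribute `"fold_accuracy"`.
#' @export
cross_validation_accuracy <- function(table, kernel, folds = NULL, seed) {
  table <- drop_exclusion(table, quiet = TRUE)
  n <- nrow(table)
  if (is.null(folds)) folds <- if (n < 30) n else 10
  if (folds < 2) stop("folds must be >= 2")
  if (n < folds) stop("more folds than observations")
  fold <- with_seed(seed, stratified_folds(table$outcome, folds))
  correct <- logical(n)
  for (f in sort(unique(fold))) {
    tr <- table[fold != f, , drop = FALSE]
    te <- table[fold == f, , drop = FALSE]
    if (length(unique(tr$outcome)) < 2)
      stop("a fold's training part lost a class; use fewer folds")
    s <- standardize_table(tr)
    clf <- train_classifier(s$table, kernel, s$standardization)
    fte <- decision_function(clf, std_apply_v(s$standardization, table_v(te)),
                             std_apply_delta(s$standardization, te$delta))
    correct[fold == f] <- (fte > 0) == (te$outcome > 0)
  }
  acc <- 100 * mean(correct)
  fold_acc <- vapply(sort(unique(fold)),
                     function(f) 100 * mean(correct[fold == f]), numeric(1))
  attr(acc, "fold_accuracy") <- fold_acc
  acc
}

default_benefit_grid <- function(table, points_per_axis = 8) {
  V <- table_v(table)
  axes <- lapply(seq_len(ncol(V)), function(j)
    seq(min(V[, j]), max(V[, j]), length.out = points_per_axis))
  as.matrix(expand.grid(axes))
}

#' Bootstrap variability of the benefit surface
#'
#' Refits the calibration on class-stratified resamples (with replacement)
#' and reports the pointwise relative standard deviation `SD/|mean|` of
#' `B(v)` over a grid. Resamples on which the fit fails (single class after
#' resampling, or `S_delta = 0`) are redrawn and counted.
#'
#' @param table An `observation_table` (raw units).
#' @param kernel A `kernel_spec`.
#' @param n_boot Number of bootstrap resamples (`>= 1`; `n_boot = 1` uses
#'   the full table once and reports zero variability).
#' @param v_grid Evaluation grid (matrix, one point per row); default: an
#'   8-per-axis grid spanning the observed ranges.
#' @param seed Integer seed.
#' @return List with `grid`, `rel_sd` (pointwise), `mean_rel_sd`,
#'   `n_redrawn`.
#' @export
bootstrap_variability <- function(table, kernel, n_boot = 100, v_grid = NULL,
                                  seed) {
  table <- drop_exclusion(table, quiet = TRUE)
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (is.null(v_grid)) v_grid <- default_benefit_grid(table)
  v_grid <- as.matrix(v_grid)
  with_seed(seed, {
    idx_by_class <- split(seq_len(nrow(table)), table$outcome)
    B <- matrix(NA_real_, n_boot, nrow(v_grid))
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      ok <- FALSE
      tries <- 0L
      while (!ok) {
        tries <- tries + 1L
        if (tries > 50L) stop("bootstrap failed: no usable resample found")
        idx <- if (n_boot == 1L) seq_len(nrow(table)) else
          unlist(lapply(idx_by_class, function(ii)
            ii[sample.int(length(ii), length(ii), replace = TRUE)]))
        res <- tryCatch(calibrate(table[idx, , drop = FALSE], kernel),
                        error = function(e) NULL)
        if (!is.null(res)) {
          B[b, ] <- benefit_at(res, v_grid)
          ok <- TRUE
        } else n_redrawn <- n_redrawn + 1L
      }
    }
    mu <- colMeans(B)
    sdv <- if (n_boot == 1L) rep(0, ncol(B)) else apply(B, 2, sd)
    rel <- sdv / pmax(abs(mu), 1e-12)
    list(grid = v_grid, rel_sd = rel, mean_rel_sd = mean(rel),
         n_redrawn = n_redrawn)
  })
}

#' Default kernel candidate grid
#'
#' Linear, quadratic and cubic kernels plus sigmoid variants
#' (`scale` in 0.5/1/2, `offset` in -1/0), crossed with
#' `k_delta` in \{0.25, 0.5, 1, 2, 4\} and `C` in \{0.1, 1, 10\}.
#'
#' @return A data frame of kernel candidates (135 rows).
#' @export
default_kernel_grid <- function() {
  fams <- rbind(
    data.frame(family = c("linear", "quadratic", "cubic"), scale = 1,
               offset = 0, stringsAsFactors = FALSE),
    expand.grid(family = "sigmoid", scale = c(0.5, 1, 2), offset = c(-1, 0),
                stringsAsFactors = FALSE))
  grid <- merge(merge(fams, data.frame(k_delta = c(0.25, 0.5, 1, 2, 4))),
                data.frame(C = c(0.1, 1, 10)))
  grid <- grid[order(match(grid$family, c("linear", "quadratic", "cubic",
                                          "sigmoid")),
                     grid$scale, grid$offset, grid$k_delta, grid$C), ]
  rownames(grid) <- NULL
  grid
}

grid_row_kernel <- function(grid, i) {
  kernel_spec(family = grid$family[i], k_delta = grid$k_delta[i],
              C = grid$C[i], scale = grid$scale[i], offset = grid$offset[i])
}

#' Rank kernel candidates
#'
#' Every candidate is scored by stratified cross-validation loss (the same
#' fold assignment for all candidates). Candidates within one standard
#' error of the minimum loss are additionally scored by mean bootstrap
#' relative SD of their benefit surface, and the final ordering is: the
#' one-SE set ordered by bootstrap variability, then the remaining
#' candidates by loss. Deterministic given `seed`.
#'
#' @param table An `observation_table` (raw units).
#' @param kernel_grid Data frame of candidates (see
#'   [default_kernel_grid()]).
#' @param folds CV folds.
#' @param n_boot Bootstrap resamples for the one-SE set.
#' @param seed Integer seed.
#' @return A `ranking_report`: `report` (data frame with `cv_loss`,
#'   `cv_se`, `boot_rel_sd`, `gram_min_eig`, `indefinite`, `rank`),
#'   `top_five` (up to five `calibrated_benefit` surfaces, best first) and
#'   `best`.
#' @export
rank_candidates <- function(table, kernel_grid = default_kernel_grid(),
                            folds = NULL, n_boot = 100, seed) {
  if (nrow(kernel_grid) < 1) stop("kernel grid is empty")
  table <- drop_exclusion(table)
  m <- nrow(kernel_grid)
  cv_loss <- cv_se <- boot <- gme <- rep(NA_real_, m)
  usable <- logical(m)
  for (i in seq_len(m)) {
    kern <- grid_row_kernel(kernel_grid, i)
    res <- tryCatch({
      acc <- cross_validation_accuracy(table, kern, folds, seed)
      fit <- calibrate(table, kern)
      list(acc = acc, fit = fit)
    }, error = function(e) NULL)
    if (is.null(res)) next
    usable[i] <- TRUE
    cv_loss[i] <- 1 - as.numeric(res$acc) / 100
    fa <- attr(res$acc, "fold_accuracy") / 100
    cv_se[i] <- sd(1 - fa) / sqrt(length(fa))
    gme[i] <- res$fit$classifier$gram_min_eig
  }
  if (!any(usable)) stop("no usable kernel candidate")
  min_loss <- min(cv_loss[usable])
  se_min <- cv_se[usable][which.min(cv_loss[usable])]
  in_ose <- usable & (cv_loss <= min_loss + se_min)
  for (i in which(in_ose)) {
    kern <- grid_row_kernel(kernel_grid, i)
    boot[i] <- tryCatch(
      bootstrap_variability(table, kern, n_boot, seed = seed + 7919L)$mean_rel_sd,
      error = function(e) NA_real_)
  }
  ord <- order(!in_ose,                       # one-SE set first
               ifelse(in_ose, boot, Inf),     # then by bootstrap variability
               cv_loss, seq_len(m))
  report <- cbind(kernel_grid,
                  data.frame(cv_loss = cv_loss, cv_se = cv_se,
                             boot_rel_sd = boot, gram_min_eig = gme,
                             indefinite = !is.na(gme) & gme < -1e-6,
                             in_one_se_set = in_ose))
  report <- report[ord, ]
  report$rank <- seq_len(m)
  rownames(report) <- NULL
  top_idx <- ord[seq_len(min(5L, sum(usable)))]
  top_five <- lapply(top_idx, function(i) {
    cb <- calibrate(table, grid_row_kernel(kernel_grid, i))
    cb$diagnostics <- list(cv_accuracy = 100 * (1 - cv_loss[i]),
                           cv_loss = cv_loss[i], boot_rel_sd = boot[i],
                           rank = match(i, ord))
    cb
  })
  structure(list(report = report, top_five = top_five, best = top_five[[1]],
                 seed = seed), class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  cat(sprintf("<ranking report> %d candidates; best: %s (k_delta=%g, C=%g), CV accuracy %.1f%%\n",
              nrow(x$report), x$best$classifier$kernel$family,
              x$best$classifier$kernel$k_delta, x$best$classifier$kernel$C,
              x$best$diagnostics$cv_accuracy))
  print(head(x$report[, c("family", "scale", "offset", "k_delta", "C",
                          "cv_loss", "boot_rel_sd", "rank")], 5))
  invisible(x)
}

#' Learning curve of the calibration
#'
#' Computes the cross-validation loss on stratified subsamples of
#' increasing size and fits an exponential decay
#' `loss ~ a * exp(-b * n) + c`.
#'
#' @param table An `observation_table`.
#' @param sizes Increasing subsample sizes (`max(sizes) <= n`, each
#'   `>= 2 * folds`).
#' @param folds CV folds per size.
#' @param seed Integer seed.
#' @return List with `sizes`, `loss`, `fit` (`a`, `b`, `c`, or `NULL`) and
#'   `fitted` flag (FALSE when fewer than three sizes are given).
#' @export
learning_curve <- function(table, sizes, folds = NULL, seed) {
  table <- drop_exclusion(table, quiet = TRUE)
  n <- nrow(table)
  if (max(sizes) > n) stop("sizes cannot exceed the number of observations")
  if (any(sizes < 4)) stop("subsample sizes too small for cross-validation")
  loss <- vapply(seq_along(sizes), function(si) {
    sz <- sizes[si]
    idx <- with_seed(seed + si, {
      by_cls <- split(seq_len(n), table$outcome)
      prop <- sz / n
      unlist(lapply(by_cls, function(ii)
        ii[sample.int(length(ii), max(1L, round(prop * length(ii))))]))
    })
    sub <- table[idx, , drop = FALSE]
    acc <- cross_validation_accuracy(sub, kernel_spec("quadratic"),
                                     folds, seed + 100L + si)
    1 - as.numeric(acc) / 100
  }, numeric(1))
  fit <- NULL
  fitted <- FALSE
  if (length(sizes) >= 3) {
    obj <- function(p) {
      pred <- p[1] * exp(-exp(p[2]) * sizes) + p[3]
      sum((pred - loss)^2)
    }
    start <- c(max(loss[1] - loss[length(loss)], 1e-3),
               log(1 / mean(sizes)), loss[length(loss)])
    start[2] <- log(max(exp(start[2]), 1e-8))
    opt <- tryCatch(optim(c(start[1], start[2], start[3]), obj,
                          method = "Nelder-Mead"),
                    error = function(e) NULL)
    if (!is.null(opt)) {
      fit <- c(a = opt$par[1], b = exp(opt$par[2]), c = opt$par[3])
      fitted <- TRUE
    }
  }
  list(sizes = sizes, loss = loss, fit = fit, fitted = fitted)
}
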