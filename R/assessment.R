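#' Pearson chi-square statistic for an occupancy model fit
#'
#' Compares observed detection-history frequencies with their expected
#' frequencies under the fitted model. Sites are grouped into cohorts
#' sharing the same missingness pattern (hence the same surveyed occasions);
#' within a cohort the fitted occupancy and detection probabilities are
#' averaged, under which the probability of a history depends only on its
#' number of detections. The statistic sums `(O_h - E_h)^2 / E_h` over all
#' possible histories; histories never observed contribute their expected
#' count, which is accumulated in closed form (total expected mass equals
#' the cohort size), so no explicit enumeration of the `2^J` histories is
#' required.
#'
#' @param fit An `occu_fit`.
#' @param dm The `detection_matrix` the model was fitted to.
#' @param cov The covariate table used in fitting.
#' @return Scalar Pearson chi-square.
#' @export
pearson_chi2 <- function(fit, dm, cov) {
  pr <- fitted_probs(fit, dm, cov)
  y <- dm$y
  pattern <- apply((!is.na(y)) * 1L, 1, paste, collapse = "")
  x2 <- 0
  for (pat in unique(pattern)) {
    rows <- which(pattern == pat)
    obs_cols <- which(strsplit(pat, "")[[1]] == "1")
    n_c <- length(rows)
    psi_bar <- mean(pr$psi[rows])
    p_bar <- mean(pr$p[rows])
    J_c <- length(obs_cols)
    hist_key <- apply(y[rows, obs_cols, drop = FALSE], 1, paste,
                      collapse = "")
    counts <- table(hist_key)
    ones <- vapply(names(counts), function(h) {
      sum(strsplit(h, "")[[1]] == "1")
    }, numeric(1))
    prh <- psi_bar * p_bar^ones * (1 - p_bar)^(J_c - ones) +
      (ones == 0) * (1 - psi_bar)
    E <- n_c * prh
    O <- as.numeric(counts)
    # unobserved histories contribute E_h each; their total is n_c - sum(E)
    x2 <- x2 + sum((O - E)^2 / E) + (n_c - sum(E))
  }
  x2
}

# Simulate a dataset from the fitted model, preserving the design and
# missingness pattern of the original matrix.
simulate_from_fit <- function(fit, dm, cov) {
  pr <- fitted_probs(fit, dm, cov)
  y <- dm$y
  n <- nrow(y)
  J <- ncol(y)
  z <- rbinom(n, 1, pr$psi)
  ynew <- matrix(rbinom(n * J, 1, rep(z * pr$p, J)), n, J,
                 dimnames = dimnames(y))
  ynew[is.na(y)] <- NA_integer_
  # guarantee the all-NA-free invariant holds (it does: pattern preserved)
  dm2 <- dm
  dm2$y <- ynew
  dm2
}

#' Parametric-bootstrap goodness of fit and overdispersion
#'
#' Simulates `B` datasets from the fitted model (same design and
#' missingness), refits the same model specification to each, and recomputes
#' the Pearson chi-square. The overdispersion factor is
#' `c_hat = observed chi-square / mean(bootstrap chi-square)` and the
#' goodness-of-fit p-value is the share of bootstrap statistics at least as
#' large as the observed one.
#'
#' @inheritParams pearson_chi2
#' @param B Number of bootstrap replicates (>= 100 recommended for
#'   inference; smaller values are accepted for quick checks).
#' @param seed Integer seed; required for reproducibility.
#' @return An `occu_gof` object: `observed_chi2`, `bootstrap_chi2`,
#'   `c_hat`, `p_value`, `B`, `seed`, `n_failed`.
#' @export
bootstrap_gof <- function(fit, dm, cov, B = 500, seed = 1) {
  if (B < 1) abort("`B` must be at least 1.")
  set.seed(seed)
  obs <- pearson_chi2(fit, dm, cov)
  boot <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    dm_b <- simulate_from_fit(fit, dm, cov)
    fit_b <- tryCatch(
      occu_fit(dm_b, cov, psi_terms = fit$psi_terms, p_terms = fit$p_terms),
      error = function(e) NULL
    )
    if (!is.null(fit_b) && fit_b$converged) {
      boot[b] <- pearson_chi2(fit_b, dm_b, cov)
    }
  }
  n_failed <- sum(is.na(boot))
  if (n_failed > 0.1 * B) {
    abort(paste0("Bootstrap refits failed for ", n_failed, " of ", B,
                 " replicates."))
  }
  boot <- boot[!is.na(boot)]
  structure(list(
    observed_chi2 = obs, bootstrap_chi2 = boot,
    c_hat = obs / mean(boot),
    p_value = mean(boot >= obs),
    B = B, seed = seed, n_failed = n_failed
  ), class = "occu_gof")
}

#' @export
print.occu_gof <- function(x, ...) {
  cat("<occu_gof> parametric bootstrap, B = ", x$B, "\n", sep = "")
  cat("  observed X2 = ", format(x$observed_chi2, digits = 5),
      ", c-hat = ", format(x$c_hat, digits = 4),
      ", p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
glance.occu_gof <- function(x, ...) {
  tibble::tibble(observed_chi2 = x$observed_chi2, c_hat = x$c_hat,
                 p_value = x$p_value, B = x$B, n_failed = x$n_failed,
                 seed = x$seed)
}

#' Inflate standard errors for overdispersion
#'
#' When the overdispersion factor exceeds 1, multiplies the coefficient
#' covariance by `c_hat` (standard errors by `sqrt(c_hat)`); point estimates
#' are never altered. A `c_hat <= 1` leaves the fit unchanged. The applied
#' factor is recorded in the fit's `c_hat` field.
#'
#' @param fit An `occu_fit`.
#' @param c_hat Overdispersion factor (> 0), e.g. from [bootstrap_gof()].
#' @return The adjusted `occu_fit`.
#' @export
adjust_se <- function(fit, c_hat) {
  stopifnot(inherits(fit, "occu_fit"))
  if (!is.numeric(c_hat) || length(c_hat) != 1 || c_hat <= 0) {
    abort("`c_hat` must be a positive scalar.")
  }
  if (c_hat > 1) {
    fit$vcov <- fit$vcov * c_hat
    fit$c_hat <- c_hat
  }
  fit
}

#' Site-level k-fold cross-validation of an occupancy model
#'
#' Randomly partitions sites into `k` folds; for each fold, the model is
#' refitted on the remaining sites and the held-out site-by-occasion cells
#' are predicted. The default prediction is the unconditional per-occasion
#' detection probability `psi_hat * p_hat` (the marginal probability of a 1
#' in any cell); `prediction = "conditional"` uses `p_hat` alone, the
#' probability given occupancy. The mean squared error is computed over
#' non-missing held-out cells and averaged across folds.
#'
#' @param dm A `detection_matrix`.
#' @param cov Standardized covariate table.
#' @param psi_terms,p_terms Model specification to validate.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @param prediction `"unconditional"` (default) or `"conditional"`.
#' @return An `occu_cv` object: `k`, `fold_mse`, `mean_mse`, `seed`,
#'   `skipped` (folds whose training data had no detections or whose refit
#'   failed).
#' @export
cross_validate <- function(dm, cov, psi_terms = character(),
                           p_terms = character(), k = 5, seed = 1,
                           prediction = c("unconditional", "conditional")) {
  prediction <- match.arg(prediction)
  if (k < 2) abort("`k` must be at least 2.")
  n <- nrow(dm$y)
  if (k > n) abort("More folds than sites.")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  fold_mse <- rep(NA_real_, k)
  skipped <- integer(0)
  for (f in seq_len(k)) {
    test <- fold == f
    dm_tr <- subset_dm(dm, !test)
    cov_tr <- cov[match(dm_tr$site_ids, cov$site_id), ]
    if (sum(dm_tr$y == 1, na.rm = TRUE) == 0) {
      warn(paste0("Fold ", f, ": no detections in training data; skipped."))
      skipped <- c(skipped, f)
      next
    }
    fit <- tryCatch(
      occu_fit(dm_tr, cov_tr, psi_terms = psi_terms, p_terms = p_terms),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      warn(paste0("Fold ", f, ": refit failed; skipped."))
      skipped <- c(skipped, f)
      next
    }
    dm_te <- subset_dm(dm, test)
    pr <- fitted_probs(fit, dm_te, cov)
    pred <- if (prediction == "unconditional") pr$psi * pr$p else pr$p
    yhat <- matrix(pred, nrow(dm_te$y), ncol(dm_te$y))
    err <- (dm_te$y - yhat)^2
    fold_mse[f] <- mean(err[!is.na(dm_te$y)])
  }
  if (all(is.na(fold_mse))) abort("All cross-validation folds failed.")
  structure(list(
    k = k, fold_mse = fold_mse, mean_mse = mean(fold_mse, na.rm = TRUE),
    seed = seed, skipped = skipped, prediction = prediction
  ), class = "occu_cv")
}

subset_dm <- function(dm, keep) {
  y <- dm$y[keep, , drop = FALSE]
  surveyed <- colSums(!is.na(y)) > 0
  dm2 <- new_detection_matrix(y[, surveyed, drop = FALSE],
                              dm$occasion_length)
  if (!is.null(dm$anchors)) {
    dm2$anchors <- dm$anchors[keep, ]
  }
  dm2
}

#' @export
print.occu_cv <- function(x, ...) {
  cat("<occu_cv> ", x$k, "-fold, mean MSE = ",
      format(x$mean_mse, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
glance.occu_cv <- function(x, ...) {
  tibble::tibble(k = x$k, mean_mse = x$mean_mse,
                 n_skipped = length(x$skipped), seed = x$seed)
}

#' @export
tidy.occu_cv <- function(x, ...) {
  tibble::tibble(fold = seq_len(x$k), mse = x$fold_mse,
                 skipped = seq_len(x$k) %in% x$skipped)
}
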