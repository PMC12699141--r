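#' Single-site occupancy likelihood
#'
#' Probability of one site's detection history under the closed
#' single-season occupancy model: with occupancy probability `psi` and
#' per-occasion detection probabilities `p`, the likelihood is
#' `psi * prod(p^y * (1-p)^(1-y))` over surveyed occasions, plus
#' `(1 - psi)` when no occasion recorded a detection (the site may be
#' unoccupied). `NA` occasions contribute nothing.
#'
#' @param history 0/1/`NA` vector of detections for one site.
#' @param psi Occupancy probability.
#' @param p Per-occasion detection probabilities, same length as `history`
#'   (a scalar is recycled).
#' @return Likelihood in \[0, 1\].
#' @examples
#' site_likelihood(c(1, 0, 1), 0.5, 0.5)    # 0.0625
#' site_likelihood(c(0, 0, 0), 0.5, 0.5)    # 0.5625
#' @export
site_likelihood <- function(history, psi, p) {
  if (length(p) == 1) p <- rep(p, length(history))
  if (length(p) != length(history)) {
    abort("`p` must match the history length.")
  }
  if (psi < 0 || psi > 1 || any(p < 0 | p > 1)) {
    abort("`psi` and `p` must be probabilities.")
  }
  obs <- !is.na(history)
  y <- history[obs]
  pj <- p[obs]
  cond <- prod(pj^y * (1 - pj)^(1 - y))
  psi * cond + (1 - psi) * as.numeric(all(y == 0))
}

#' Negative log-likelihood of an occupancy model
#'
#' Objective minimized by [occu_fit()]. Coefficients are on the logit scale,
#' occupancy block first (intercept then `psi_terms`), detection block
#' second (intercept then `p_terms`). Detection covariates are site-level,
#' so detection probability is constant across a site's occasions and the
#' per-site likelihood reduces to a function of the detection count and the
#' number of surveyed occasions.
#'
#' @param params Coefficient vector, length `length(psi_terms) +
#'   length(p_terms) + 2`.
#' @param dm A `detection_matrix`.
#' @param cov Standardized covariate table.
#' @param psi_terms,p_terms Covariate names for occupancy and detection
#'   (intercepts are implicit).
#' @return Scalar negative log-likelihood.
#' @export
occu_nll <- function(params, dm, cov, psi_terms = character(),
                     p_terms = character()) {
  X <- cov_matrix(cov, psi_terms, dm$site_ids)
  W <- cov_matrix(cov, p_terms, dm$site_ids)
  d <- rowSums(dm$y == 1, na.rm = TRUE)
  m <- rowSums(!is.na(dm$y))
  make_occu_nll(X, W, d, m)(params)
}

# Closure over the sufficient statistics (detections d, surveyed occasions m)
make_occu_nll <- function(X, W, d, m) {
  k1 <- ncol(X)
  k2 <- ncol(W)
  zero <- d == 0
  function(par) {
    if (any(!is.finite(par))) return(.Machine$double.xmax)
    eta_psi <- drop(X %*% par[seq_len(k1)])
    eta_p <- drop(W %*% par[k1 + seq_len(k2)])
    log_psi <- plogis(eta_psi, log.p = TRUE)
    log_1mpsi <- plogis(-eta_psi, log.p = TRUE)
    log_p <- plogis(eta_p, log.p = TRUE)
    log_1mp <- plogis(-eta_p, log.p = TRUE)
    ll <- log_psi + d * log_p + (m - d) * log_1mp
    if (any(zero)) {
      a <- ll[zero]
      b <- log_1mpsi[zero]
      hi <- pmax(a, b)
      ll[zero] <- hi + log(exp(a - hi) + exp(b - hi))
    }
    nll <- -sum(ll)
    if (!is.finite(nll)) .Machine$double.xmax else nll
  }
}

#' Fit a single-season occupancy model by maximum likelihood
#'
#' Fits the closed single-season occupancy model with logit-linked linear
#' predictors on occupancy (`psi_terms`) and detection (`p_terms`), both with
#' intercepts, by quasi-Newton (BFGS) minimization of the negative
#' log-likelihood. The covariance matrix is the inverse of the observed
#' information (numerical Hessian at the optimum); AICc uses the number of
#' sites as the effective sample size.
#'
#' Covariates should be standardized (see [standardize_covariates()]) so
#' that starting all coefficients at zero corresponds to psi = p = 0.5 at
#' the average site; a restart from the naive-occupancy and naive-detection
#' logits is attempted if the first run fails to converge. Fits whose
#' estimated occupancy or detection reaches the 0/1 boundary, or whose
#' Hessian is singular, are flagged.
#'
#' @inheritParams occu_nll
#' @param control Passed to [stats::optim()] (defaults: BFGS,
#'   `maxit = 500`, `reltol = 1e-12`).
#' @return An `occu_fit` object with elements `coef`, `vcov`, `loglik`,
#'   `K`, `n_sites`, `aicc`, `converged`, `boundary`, `psi_terms`,
#'   `p_terms`, `label`, `c_hat`.
#' @examples
#' set.seed(1)
#' sim <- simulate_camtrap(sim_design(n_sites = 150, J = 8,
#'   beta_psi = c(forest_d = 0.5), psi_intercept = 0, p_intercept = 0))
#' occu_fit(sim$matrix, sim$covariates, psi_terms = "forest_d")
#' @export
occu_fit <- function(dm, cov, psi_terms = character(),
                     p_terms = character(), control = list()) {
  stopifnot(inherits(dm, "detection_matrix"))
  if (anyDuplicated(psi_terms) || anyDuplicated(p_terms)) {
    abort("Duplicate covariate terms in the model formula.")
  }
  X <- cov_matrix(cov, psi_terms, dm$site_ids)
  W <- cov_matrix(cov, p_terms, dm$site_ids)
  d <- rowSums(dm$y == 1, na.rm = TRUE)
  m <- rowSums(!is.na(dm$y))
  K <- ncol(X) + ncol(W)
  n <- nrow(X)
  if (n <= K + 1) {
    abort("Too few sites for this model (need n_sites > K + 1).")
  }
  nll <- make_occu_nll(X, W, d, m)
  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)

  run <- function(start) {
    optim(start, nll, method = "BFGS", control = ctrl)
  }
  opt <- run(rep(0, K))
  grad_tol <- 1e-4 * max(1, abs(opt$value))
  gnorm <- sqrt(sum(num_grad(nll, opt$par)^2))
  if (opt$convergence != 0 || gnorm > grad_tol) {
    naive <- min(max(mean(d > 0), 0.02), 0.98)
    rate <- min(max(sum(d) / sum(m), 0.02), 0.98)
    start2 <- rep(0, K)
    start2[1] <- qlogis(naive)
    start2[ncol(X) + 1] <- qlogis(rate)
    opt2 <- run(start2)
    if (opt2$value < opt$value) opt <- opt2
    gnorm <- sqrt(sum(num_grad(nll, opt$par)^2))
  }
  converged <- opt$convergence == 0 && gnorm <= grad_tol

  coefs <- opt$par
  names(coefs) <- c(paste0("psi_", colnames(X)), paste0("p_", colnames(W)))
  eta_psi <- drop(X %*% coefs[seq_len(ncol(X))])
  eta_p <- drop(W %*% coefs[ncol(X) + seq_len(ncol(W))])
  boundary <- max(abs(c(eta_psi, eta_p))) > 12

  H <- tryCatch(optimHess(opt$par, nll), error = function(e) NULL)
  V <- NULL
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && any(diag(V) <= 0)) V <- NULL
  }
  singular <- is.null(V)
  if (singular) {
    V <- matrix(NA_real_, K, K)
    boundary <- TRUE
  }
  dimnames(V) <- list(names(coefs), names(coefs))

  loglik <- -opt$value
  structure(list(
    coef = coefs, vcov = V, loglik = loglik, K = K, n_sites = n,
    aicc = aicc(loglik, K, n),
    converged = converged, boundary = boundary, singular = singular,
    psi_terms = psi_terms, p_terms = p_terms,
    label = model_label(psi_terms, p_terms),
    c_hat = 1, n_psi = ncol(X), n_p = ncol(W)
  ), class = "occu_fit")
}

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x))
    e[i] <- h * max(1, abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, numeric(1))
}

model_label <- function(psi_terms, p_terms) {
  fmt <- function(v) if (length(v) == 0) "." else paste(v, collapse = "+")
  paste0("p(", fmt(p_terms), ")Psi(", fmt(psi_terms), ")")
}

#' @export
print.occu_fit <- function(x, ...) {
  cat("<occu_fit> ", x$label, "\n", sep = "")
  cat("  logLik ", format(x$loglik, digits = 6), ", K = ", x$K,
      ", n_sites = ", x$n_sites, ", AICc = ",
      format(x$aicc, digits = 6), "\n", sep = "")
  if (!x$converged) cat("  ** not converged **\n")
  if (x$boundary) cat("  ** boundary / singular information **\n")
  print(tidy(x), n = x$K)
  invisible(x)
}

#' @export
coef.occu_fit <- function(object, ...) object$coef

#' @export
vcov.occu_fit <- function(object, ...) object$vcov

#' @export
logLik.occu_fit <- function(object, ...) {
  structure(object$loglik, df = object$K, nobs = object$n_sites,
            class = "logLik")
}

#' Tidy an occupancy model fit
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `submodel`
#'   (`"occupancy"`/`"detection"`), `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` (Wald z on the logit scale). Standard errors
#'   reflect any overdispersion adjustment applied via [adjust_se()].
#' @export
tidy.occu_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  term <- sub("^(psi|p)_", "", names(x$coef))
  z <- x$coef / se
  tibble::tibble(
    submodel = rep(c("occupancy", "detection"), c(x$n_psi, x$n_p)),
    term = term,
    estimate = unname(x$coef),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
}

#' One-row summary of an occupancy model fit
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `AICc`, `K`, `n_sites`, `converged`,
#'   `boundary`, `c_hat`.
#' @export
glance.occu_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AICc = x$aicc, K = x$K,
                 n_sites = x$n_sites, converged = x$converged,
                 boundary = x$boundary, c_hat = x$c_hat)
}

#' Predict occupancy or detection probability from a fit
#'
#' Evaluates the fitted logit-linear predictor at supplied covariate values
#' and transforms to the probability scale. Wald confidence intervals are
#' computed on the logit scale from the joint coefficient covariance and
#' then back-transformed, guaranteeing bounds inside \[0, 1\]. Covariates are
#' on the standardized scale; any term not supplied is held at 0 (its
#' standardized mean).
#'
#' @param object An `occu_fit`.
#' @param newdata Data frame (or named list) of standardized covariate
#'   values, one row per prediction; `NULL` predicts at the average site.
#' @param quantity `"psi"` (occupancy) or `"p"` (detection).
#' @param level Confidence level, default 0.95.
#' @param ... Unused.
#' @return Tibble with `quantity`, `estimate`, `lower`, `upper` (plus the
#'   supplied covariate columns).
#' @export
predict.occu_fit <- function(object, newdata = NULL,
                             quantity = c("psi", "p"), level = 0.95, ...) {
  quantity <- match.arg(quantity)
  terms <- if (quantity == "psi") object$psi_terms else object$p_terms
  block <- if (quantity == "psi") seq_len(object$n_psi) else
    object$n_psi + seq_len(object$n_p)
  newdata <- if (is.null(newdata)) tibble::tibble(.rows = 1) else
    tibble::as_tibble(newdata)
  extra <- setdiff(names(newdata), c(terms, "site_id"))
  if (length(extra) > 0) {
    abort(paste0("Covariate(s) not in the ", quantity, " submodel: ",
                 paste(extra, collapse = ", ")))
  }
  X <- matrix(0, nrow(newdata), length(terms) + 1,
              dimnames = list(NULL, c("(Intercept)", terms)))
  X[, 1] <- 1
  for (nm in intersect(terms, names(newdata))) X[, nm] <- newdata[[nm]]

  beta <- object$coef[block]
  V <- object$vcov[block, block, drop = FALSE]
  eta <- drop(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  zq <- qnorm(1 - (1 - level) / 2)
  dplyr::bind_cols(
    newdata,
    tibble::tibble(
      quantity = quantity,
      estimate = plogis(eta),
      lower = plogis(eta - zq * se),
      upper = plogis(eta + zq * se)
    )
  )
}

#' Coefficient plot for an occupancy model fit
#'
#' Dot-and-whisker plot of logit-scale coefficient estimates with Wald
#' intervals, faceted by submodel.
#'
#' @param object An `occu_fit`.
#' @param level Confidence level for the whiskers.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occu_fit <- function(object, level = 0.95, ...) {
  zq <- qnorm(1 - (1 - level) / 2)
  td <- tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - zq * .data$std.error,
      xmax = .data$estimate + zq * .data$std.error)) +
    ggplot2::facet_wrap(~submodel, scales = "free_y") +
    ggplot2::labs(x = "Coefficient (logit scale)", y = NULL,
                  title = object$label)
}

# Fitted per-site probabilities on the probability scale
fitted_probs <- function(fit, dm, cov) {
  X <- cov_matrix(cov, fit$psi_terms, dm$site_ids)
  W <- cov_matrix(cov, fit$p_terms, dm$site_ids)
  list(
    psi = plogis(drop(X %*% fit$coef[seq_len(fit$n_psi)])),
    p = plogis(drop(W %*% fit$coef[fit$n_psi + seq_len(fit$n_p)]))
  )
}
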