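#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K + 1) / (n - K - 1)`. The correction is
#' undefined for `n <= K + 1`. The effective sample size `n` is the number
#' of sites (each site contributes one detection history).
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of estimated parameters.
#' @param n Effective sample size (sites).
#' @return Scalar AICc.
#' @examples
#' aicc(-100, 5, 40)  # 211.7647
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1) abort("AICc undefined: need n > K + 1.")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Enumerate all covariate combinations for occupancy and detection
#'
#' Builds the exhaustive model set: every subset of `psi_candidates` crossed
#' with every subset of `p_candidates` (both including the intercept-only
#' submodel), giving `2^|psi| * 2^|p|` specifications when uncapped.
#' Candidate lists should already be pruned for collinearity.
#'
#' @param psi_candidates,p_candidates Covariate names eligible for the
#'   occupancy and detection submodels.
#' @param max_terms Optional cap on the number of covariates per submodel.
#' @param budget Maximum allowed model count (default 20000); exceeded
#'   without `max_terms` set, the function errors rather than enumerate.
#' @return Tibble with list-columns `psi_terms`, `p_terms` and a `label`
#'   column.
#' @examples
#' nrow(enumerate_model_specs(c("a", "b"), "c"))  # 8
#' @export
enumerate_model_specs <- function(psi_candidates = character(),
                                  p_candidates = character(),
                                  max_terms = NULL, budget = 20000) {
  subsets <- function(v) {
    out <- list(character(0))
    for (k in seq_along(v)) {
      if (!is.null(max_terms) && k > max_terms) break
      out <- c(out, combn(v, k, simplify = FALSE))
    }
    out
  }
  n_total <- length(subsets(psi_candidates)) * length(subsets(p_candidates))
  if (n_total > budget) {
    abort(paste0("Model set would contain ", n_total, " models (> budget ",
                 budget, "); set `max_terms` or raise `budget`."))
  }
  grid <- tidyr::expand_grid(psi_terms = subsets(psi_candidates),
                             p_terms = subsets(p_candidates))
  grid$label <- purrr::map2_chr(grid$psi_terms, grid$p_terms, model_label)
  grid
}

#' Fit a set of occupancy model specifications
#'
#' Fits each specification with [occu_fit()] and ranks the results
#' (see [rank_models()]). Fits are independent of one another, so the
#' resulting table does not depend on evaluation order.
#'
#' @param specs Tibble from [enumerate_model_specs()] (columns `psi_terms`,
#'   `p_terms` as list-columns).
#' @inheritParams occu_nll
#' @return An `occu_model_set`.
#' @export
fit_models <- function(specs, dm, cov) {
  fits <- purrr::map2(specs$psi_terms, specs$p_terms, function(ps, pp) {
    occu_fit(dm, cov, psi_terms = ps, p_terms = pp)
  })
  rank_models(fits)
}

#' Rank fitted occupancy models by AICc
#'
#' Sorts fits ascending by AICc (ties broken by fewer parameters, then model
#' label), computes `delta` (AICc difference from the best model) and Akaike
#' weights `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`. Fits that
#' failed to converge are excluded with a warning before ranking.
#'
#' @param fits List of `occu_fit` objects.
#' @return An `occu_model_set`: a tibble with columns `label`, `K`,
#'   `logLik`, `AICc`, `delta`, `weight` and a `fit` list-column, plus
#'   attribute `n_excluded`.
#' @export
rank_models <- function(fits) {
  if (inherits(fits, "occu_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) abort("No converged fits to rank.")
  if (any(!ok)) {
    warn(paste0(sum(!ok), " non-converged fit(s) excluded from ranking."))
  }
  fits <- fits[ok]
  tbl <- tibble::tibble(
    label = vapply(fits, `[[`, character(1), "label"),
    K = vapply(fits, `[[`, integer(1), "K"),
    logLik = vapply(fits, `[[`, numeric(1), "loglik"),
    AICc = vapply(fits, `[[`, numeric(1), "aicc"),
    fit = fits
  )
  tbl <- tbl[order(tbl$AICc, tbl$K, tbl$label), ]
  tbl$delta <- tbl$AICc - tbl$AICc[1]
  w <- exp(-tbl$delta / 2)
  tbl$weight <- w / sum(w)
  tbl <- tbl[c("label", "K", "logLik", "AICc", "delta", "weight", "fit")]
  structure(tbl, n_excluded = sum(!ok), renormalized = FALSE,
            class = c("occu_model_set", class(tibble::tibble())))
}

#' Confidence set of top-ranked models
#'
#' Retains models with `delta < threshold` (strict inequality; the default
#' threshold 2 keeps models commonly considered comparable to the best one)
#' and renormalizes Akaike weights over the retained members. Weights
#' normalized over the full model set are kept in `weight_all`.
#'
#' @param set An `occu_model_set`.
#' @param threshold Strict upper bound on delta-AICc, default 2.
#' @return An `occu_model_set` restricted to the confidence set.
#' @export
confidence_set <- function(set, threshold = 2) {
  stopifnot(inherits(set, "occu_model_set"))
  if (threshold <= 0) abort("`threshold` must be positive.")
  keep <- set$delta < threshold
  out <- set[keep, ]
  out$weight_all <- out$weight
  out$weight <- out$weight / sum(out$weight)
  structure(out, n_excluded = attr(set, "n_excluded"), renormalized = TRUE,
            class = class(set))
}

#' Model-averaged coefficient estimates
#'
#' Averages logit-scale coefficients across a (typically renormalized
#' confidence) model set with Akaike weights. The default `"shrinkage"`
#' estimator substitutes 0 for models omitting a term, shrinking weak
#' effects toward zero; `"conditional"` averages only over models containing
#' the term, renormalizing their weights. The unconditional standard error
#' incorporates between-model spread:
#' `SE = sum_i w_i * sqrt(var_i + (b_i - b_bar)^2)`.
#'
#' @param set An `occu_model_set`.
#' @param terms Coefficient names as `submodel:term` pairs; default all
#'   non-intercept terms appearing in any member. A term present in no
#'   member is an error.
#' @param method `"shrinkage"` (default) or `"conditional"`.
#' @return Tibble: `submodel`, `term`, `estimate`, `std.error`,
#'   `n_models`, `weight_sum`.
#' @export
model_average <- function(set, terms = NULL,
                          method = c("shrinkage", "conditional")) {
  stopifnot(inherits(set, "occu_model_set"))
  method <- match.arg(method)
  coef_tbl <- purrr::map2_dfr(set$fit, set$weight, function(f, w) {
    td <- tidy(f)
    td$weight <- w
    td$model <- f$label
    td
  })
  all_terms <- coef_tbl |>
    dplyr::distinct(.data$submodel, .data$term) |>
    dplyr::mutate(id = paste(.data$submodel, .data$term, sep = ":"))
  if (is.null(terms)) {
    terms <- all_terms$id[all_terms$term != "(Intercept)"]
    if (length(terms) == 0) terms <- all_terms$id
  }
  bad <- setdiff(terms, all_terms$id)
  if (length(bad) > 0) {
    abort(paste0("Term(s) in no model-set member: ",
                 paste(bad, collapse = ", ")))
  }
  purrr::map_dfr(terms, function(id) {
    sub <- all_terms$submodel[all_terms$id == id]
    trm <- all_terms$term[all_terms$id == id]
    rows <- coef_tbl[coef_tbl$submodel == sub & coef_tbl$term == trm, ]
    w_present <- sum(rows$weight)
    if (method == "conditional") {
      w <- rows$weight / w_present
      est <- sum(w * rows$estimate)
      se <- sum(w * sqrt(rows$std.error^2 + (rows$estimate - est)^2))
    } else {
      # absent models contribute estimate 0 with variance 0
      est <- sum(rows$weight * rows$estimate)
      se <- sum(rows$weight * sqrt(rows$std.error^2 +
                                     (rows$estimate - est)^2)) +
        (1 - w_present) * abs(0 - est)
    }
    tibble::tibble(submodel = sub, term = trm, estimate = est,
                   std.error = se, n_models = nrow(rows),
                   weight_sum = w_present)
  })
}

#' Model-averaged occupancy or detection predictions
#'
#' Weighted average of per-model probability-scale predictions at the given
#' covariate values. The confidence interval is formed on the logit scale
#' around the logit of the averaged point estimate, using the unconditional
#' standard error of the per-model linear predictors (within-model Wald
#' variance plus between-model spread), then back-transformed so bounds stay
#' in \[0, 1\]. With a single-member set this reproduces
#' [predict.occu_fit()] exactly.
#'
#' @inheritParams predict.occu_fit
#' @param set An `occu_model_set` (typically a renormalized confidence set).
#' @return Tibble with `quantity`, `estimate`, `lower`, `upper`.
#' @export
average_predictions <- function(set, newdata = NULL,
                                quantity = c("psi", "p"), level = 0.95) {
  stopifnot(inherits(set, "occu_model_set"))
  quantity <- match.arg(quantity)
  newdata <- if (is.null(newdata)) tibble::tibble(.rows = 1) else
    tibble::as_tibble(newdata)

  per_model <- purrr::map(set$fit, function(f) {
    terms <- if (quantity == "psi") f$psi_terms else f$p_terms
    use <- newdata[intersect(names(newdata), terms)]
    pr <- predict(f, newdata = use, quantity = quantity, level = level)
    eta <- qlogis(pr$estimate)
    zq <- qnorm(1 - (1 - level) / 2)
    se_eta <- (qlogis(pr$upper) - qlogis(pr$lower)) / (2 * zq)
    list(p = pr$estimate, eta = eta, se_eta = se_eta)
  })
  w <- set$weight
  p_mat <- do.call(cbind, purrr::map(per_model, "p"))
  eta_mat <- do.call(cbind, purrr::map(per_model, "eta"))
  se_mat <- do.call(cbind, purrr::map(per_model, "se_eta"))
  point <- drop(p_mat %*% w)
  eta_bar <- drop(eta_mat %*% w)
  se_unc <- drop(sqrt(se_mat^2 + (eta_mat - eta_bar)^2) %*% w)
  zq <- qnorm(1 - (1 - level) / 2)
  eta_pt <- qlogis(point)
  dplyr::bind_cols(newdata, tibble::tibble(
    quantity = quantity,
    estimate = point,
    lower = plogis(eta_pt - zq * se_unc),
    upper = plogis(eta_pt + zq * se_unc)
  ))
}

#' Tidy a ranked model set into a model-selection table
#'
#' @param x An `occu_model_set`.
#' @param ... Unused.
#' @return Tibble `model`, `K`, `logLik`, `AICc`, `delta_AICc`, `w_AICc`
#'   (plus `w_AICc_all` for a renormalized confidence set).
#' @export
tidy.occu_model_set <- function(x, ...) {
  out <- tibble::tibble(model = x$label, K = x$K, logLik = x$logLik,
                        AICc = x$AICc, delta_AICc = x$delta,
                        w_AICc = x$weight)
  if (!is.null(x[["weight_all"]])) out$w_AICc_all <- x$weight_all
  out
}

#' @export
glance.occu_model_set <- function(x, ...) {
  tibble::tibble(n_models = nrow(x), n_excluded = attr(x, "n_excluded") %||% 0L,
                 best_model = x$label[1], best_AICc = x$AICc[1],
                 renormalized = isTRUE(attr(x, "renormalized")))
}

#' @export
print.occu_model_set <- function(x, ...) {
  cat("<occu_model_set> ", nrow(x), " models",
      if (isTRUE(attr(x, "renormalized"))) " (confidence set)", "\n",
      sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Write / read a model-selection table as CSV
#'
#' @param set An `occu_model_set` (or its [tidy()] table).
#' @param path CSV file path.
#' @return `write_model_table()` returns `path` invisibly;
#'   `read_model_table()` returns the table as a tibble.
#' @export
write_model_table <- function(set, path) {
  tbl <- if (inherits(set, "occu_model_set")) tidy(set) else set
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_model_table
#' @export
read_model_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
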