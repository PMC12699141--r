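#' Cumulative detection probability over repeated surveys
#'
#' Probability of detecting the species at least once in `K` surveys when
#' each survey independently detects with probability `p`:
#' `p* = 1 - (1 - p)^K`. Vectorized over `K`.
#'
#' @param p Per-survey detection probability.
#' @param K Number of surveys (>= 1).
#' @return `p*` in \[0, 1\].
#' @examples
#' p_star(0.46, 5)
#' p_star(0.2, 15)  # 0.96482
#' @export
p_star <- function(p, K) {
  if (any(p < 0 | p > 1)) abort("`p` must be a probability.")
  if (any(K < 1)) abort("`K` must be >= 1.")
  1 - (1 - p)^K
}

#' Cumulative detection probability with occasion-varying detection
#'
#' Product form for unequal per-occasion probabilities:
#' `p* = 1 - prod(1 - p_j)`.
#'
#' @param p Vector of per-occasion detection probabilities.
#' @return Scalar `p*`.
#' @export
p_star_occasions <- function(p) {
  if (any(p < 0 | p > 1)) abort("`p` must be probabilities.")
  1 - prod(1 - p)
}

#' Cumulative detection curve with delta-method confidence bounds
#'
#' Evaluates `p* = 1 - (1 - p)^K` for `K = 1..k_max` and propagates the
#' uncertainty of the baseline detection estimate by the delta method:
#' `SE(p*) = K (1 - p)^(K - 1) SE(p)`. Intervals are truncated to \[0, 1\],
#' matching the symmetric error bars conventionally drawn on survey-effort
#' curves. At `K = 1` the interval equals the Wald interval of `p` itself.
#'
#' @param p Baseline per-survey detection probability.
#' @param se Standard error of `p` (0 gives zero-width intervals).
#' @param k_max Largest survey count to evaluate.
#' @param level Confidence level, default 0.95.
#' @return A `p_star_curve` tibble: `n_surveys`, `p_star`, `se`, `lower`,
#'   `upper`, with attributes `baseline_p`, `baseline_se`.
#' @export
p_star_curve <- function(p, se = 0, k_max = 15, level = 0.95) {
  if (se < 0) abort("`se` must be non-negative.")
  if (k_max < 1) abort("`k_max` must be >= 1.")
  K <- seq_len(k_max)
  pt <- p_star(p, K)
  se_k <- K * (1 - p)^(K - 1) * se
  zq <- qnorm(1 - (1 - level) / 2)
  out <- tibble::tibble(
    n_surveys = K, p_star = pt, se = se_k,
    lower = pmax(0, pt - zq * se_k),
    upper = pmin(1, pt + zq * se_k)
  )
  structure(out, baseline_p = p, baseline_se = se,
            class = c("p_star_curve", class(out)))
}

#' Surveys required to reach a target cumulative detection probability
#'
#' Smallest integer `K` with `1 - (1 - p)^K >= target`, i.e.
#' `ceiling(log(1 - target) / log(1 - p))`. Non-increasing in `p`: better
#' per-survey detectability needs fewer repeat surveys.
#'
#' @param p Per-survey detection probability in (0, 1\].
#' @param target Target cumulative probability in (0, 1).
#' @return Integer number of surveys.
#' @examples
#' required_surveys(0.46, 0.95)  # 5
#' @export
required_surveys <- function(p, target) {
  if (target <= 0 || target >= 1) abort("`target` must be in (0, 1).")
  if (p <= 0) abort("`p` = 0 cannot reach a positive target.")
  if (p >= 1) return(1L)
  K <- ceiling(log(1 - target) / log(1 - p))
  # guard against floating-point overshoot at the boundary
  while (K > 1 && p_star(p, K - 1) >= target) K <- K - 1
  as.integer(K)
}

#' Plot a cumulative detection curve
#'
#' @param object A `p_star_curve` from [p_star_curve()].
#' @param ... Unused.
#' @return A ggplot object: `p*` against the number of surveys with the
#'   confidence ribbon.
#' @export
autoplot.p_star_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_surveys,
                                       y = .data$p_star)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Number of surveys",
      y = "P(detected at least once)",
      title = paste0("Cumulative detection, per-survey p = ",
                     format(attr(object, "baseline_p"), digits = 3))
    )
}

#' Write a cumulative detection curve as CSV
#'
#' @param curve A `p_star_curve`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_p_star_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
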