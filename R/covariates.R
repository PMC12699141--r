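#' Standardize site covariates to z-scores
#'
#' Centers and scales every numeric covariate column to mean 0 and sample
#' standard deviation 1 (n - 1 denominator), so coefficient magnitudes are
#' comparable across covariates. The centers and scales are stored as
#' attributes `"center"` and `"scale"` for back-transforming effect plots to
#' the original units.
#'
#' @param cov Data frame with a `site_id` column followed by numeric
#'   covariate columns.
#' @return A tibble of the same shape with standardized columns and
#'   attributes `center`, `scale`, `standardized = TRUE`.
#' @examples
#' standardize_covariates(data.frame(site_id = 1:3, forest_d = c(1, 2, 3)))
#' @export
standardize_covariates <- function(cov) {
  cov <- as_site_covariates(cov)
  num <- setdiff(names(cov), "site_id")
  ctr <- vapply(cov[num], mean, numeric(1))
  scl <- vapply(cov[num], sd, numeric(1))
  zero <- num[scl == 0 | !is.finite(scl)]
  if (length(zero) > 0) {
    abort(paste0("Cannot standardize constant covariate(s): ",
                 paste(zero, collapse = ", ")))
  }
  out <- cov
  out[num] <- purrr::map2(cov[num], num, function(x, nm) {
    (x - ctr[nm]) / scl[nm]
  })
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "standardized") <- TRUE
  out
}

#' Drop collinear covariates by pairwise Pearson correlation
#'
#' Repeatedly removes one member of the most-correlated covariate pair until
#' all pairwise absolute Pearson correlations are at or below `threshold`
#' (strictly-greater rule: a pair at exactly the threshold is retained).
#' Within an offending pair, the column later in `priority` is dropped.
#' Correlations use complete cases; missing values are never imputed.
#'
#' @param cov Covariate data frame (`site_id` + numeric columns).
#' @param threshold Maximum allowed absolute pairwise correlation,
#'   default 0.7.
#' @param priority Character vector ordering covariates from most to least
#'   important; defaults to column order. Columns absent from `priority`
#'   rank below all listed ones.
#' @return The pruned tibble, with attribute `"dropped"`: a tibble logging
#'   each removal (`dropped`, `kept`, `r`).
#' @export
prune_correlated <- function(cov, threshold = 0.7, priority = NULL) {
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  cov <- as_site_covariates(cov)
  num <- setdiff(names(cov), "site_id")
  drop_log <- tibble::tibble(dropped = character(), kept = character(),
                             r = numeric())
  if (length(num) < 2) {
    attr(cov, "dropped") <- drop_log
    return(cov)
  }
  priority <- c(intersect(priority %||% num, num),
                setdiff(num, priority %||% num))
  rank_of <- setNames(seq_along(priority), priority)

  keep <- num
  repeat {
    cc <- cor(as.data.frame(cov[keep]), use = "pairwise.complete.obs")
    cc[!upper.tri(cc)] <- 0
    if (max(abs(cc), na.rm = TRUE) <= threshold) break
    worst <- which(abs(cc) == max(abs(cc), na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    loser <- pair[which.max(rank_of[pair])]
    winner <- setdiff(pair, loser)
    drop_log <- dplyr::bind_rows(drop_log, tibble::tibble(
      dropped = loser, kept = winner,
      r = cc[worst["row"], worst["col"]]
    ))
    keep <- setdiff(keep, loser)
  }
  out <- cov[c("site_id", keep)]
  attr(out, "center") <- attr(cov, "center")[keep]
  attr(out, "scale") <- attr(cov, "scale")[keep]
  attr(out, "standardized") <- attr(cov, "standardized")
  attr(out, "dropped") <- drop_log
  out
}

#' Convert per-site land-cover class areas to buffer proportions
#'
#' Divides each class area by the buffer area, yielding the percent-cover
#' covariates used in occupancy modeling (e.g. fraction of dense forest
#' within a 1-km buffer around each camera station, ~314.16 ha).
#'
#' @param areas Data frame: `site_id` plus per-class area columns, same
#'   units as `buffer_area`.
#' @param buffer_area Total buffer area (e.g. hectares); scalar.
#' @param exhaustive If TRUE, require per-site class areas to sum to the
#'   buffer area (fractions sum to 1 within `1e-6`).
#' @return Tibble of per-site class fractions.
#' @export
landcover_proportions <- function(areas, buffer_area, exhaustive = FALSE) {
  if (buffer_area <= 0) abort("`buffer_area` must be positive.")
  areas <- as_site_covariates(areas)
  num <- setdiff(names(areas), "site_id")
  vals <- as.matrix(areas[num])
  if (any(vals < 0, na.rm = TRUE)) abort("Class areas must be non-negative.")
  tot <- rowSums(vals, na.rm = TRUE)
  if (any(tot > buffer_area * (1 + 1e-6))) {
    abort("Per-site class areas exceed the buffer area.")
  }
  if (exhaustive && any(abs(tot - buffer_area) > buffer_area * 1e-6)) {
    abort("Class areas do not tile the buffer (exhaustive = TRUE).")
  }
  out <- areas
  out[num] <- lapply(areas[num], function(x) x / buffer_area)
  out
}

as_site_covariates <- function(cov) {
  cov <- tibble::as_tibble(cov)
  if (!"site_id" %in% names(cov)) {
    abort("Covariate table needs a `site_id` column.")
  }
  cov <- dplyr::relocate(cov, "site_id")
  num <- setdiff(names(cov), "site_id")
  not_num <- num[!vapply(cov[num], is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(paste0("Non-numeric covariate column(s): ",
                 paste(not_num, collapse = ", ")))
  }
  if (any(vapply(cov[num], function(x) any(!is.finite(x) & !is.na(x)),
                 logical(1)))) {
    abort("Covariates must be finite or NA.")
  }
  cov
}

cov_matrix <- function(cov, terms, site_ids = NULL) {
  cov <- as_site_covariates(cov)
  if (!is.null(site_ids)) {
    idx <- match(site_ids, cov$site_id)
    if (anyNA(idx)) abort("Covariate table lacks some detection-matrix sites.")
    cov <- cov[idx, ]
  }
  bad <- setdiff(terms, names(cov))
  if (length(bad) > 0) {
    abort(paste0("Unknown covariate(s): ", paste(bad, collapse = ", ")))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(cov[terms]))
  if (anyNA(X)) abort("Model covariates contain missing values.")
  X
}
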