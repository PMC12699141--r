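#' Validate a pipeline run configuration
#'
#' Schema and cross-field checks for [run_occupancy_pipeline()]. Issues are
#' returned, not thrown, so a caller can display all problems at once; an
#' empty character vector means the configuration is clean.
#'
#' @param config Run configuration list (see [run_occupancy_pipeline()]).
#' @return Character vector of issues (empty when valid).
#' @export
validate_run_config <- function(config) {
  issues <- character(0)
  note <- function(msg) issues <<- c(issues, msg)

  has_files <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (!has_files && !has_sim) {
    note("Provide either `input` file paths or a `simulation` block.")
  }
  if (has_files) {
    for (f in c("photos", "deployments", "covariates")) {
      path <- config$input[[f]]
      if (is.null(path)) {
        note(paste0("`input$", f, "` is missing."))
      } else if (!file.exists(path)) {
        note(paste0("`input$", f, "` does not exist: ", path))
      }
    }
  }
  if (is.null(config$seed)) note("`seed` is required (stochastic stages).")
  occ_len <- config$occasion_length %||% 4
  if (occ_len < 1) note("`occasion_length` must be >= 1.")
  thr <- config$cor_threshold %||% 0.7
  if (thr <= 0 || thr > 1) note("`cor_threshold` must be in (0, 1].")
  if ((config$delta_threshold %||% 2) <= 0) {
    note("`delta_threshold` must be positive.")
  }
  if ((config$gof_B %||% 200) < 1) note("`gof_B` must be >= 1.")
  if ((config$cv_k %||% 5) < 2) note("`cv_k` must be >= 2.")

  cov_names <- NULL
  if (has_files && !is.null(config$input$covariates) &&
      file.exists(config$input$covariates)) {
    cov_names <- setdiff(names(utils::read.csv(config$input$covariates,
                                               nrows = 1)), "site_id")
  } else if (has_sim) {
    cov_names <- config$simulation$design$covariates
  }
  cands <- union(config$psi_candidates %||% character(0),
                 config$p_candidates %||% character(0))
  if (!is.null(cov_names)) {
    bad <- setdiff(cands, cov_names)
    if (length(bad) > 0) {
      note(paste0("Candidate covariate(s) not in the covariate table: ",
                  paste(bad, collapse = ", ")))
    }
  }
  n_sites <- if (has_sim) config$simulation$design$n_sites else NULL
  if (!is.null(n_sites)) {
    k_max <- length(config$psi_candidates %||% character(0)) +
      length(config$p_candidates %||% character(0)) + 2
    if (n_sites <= k_max + 1) {
      note(paste0("Largest candidate model has K = ", k_max,
                  " parameters but only ", n_sites,
                  " sites; AICc requires n_sites > K + 1."))
    }
  }
  issues
}

#' Run the full occupancy analysis pipeline
#'
#' Executes, in order: data loading or simulation, detection-history
#' construction, covariate standardization and collinearity pruning,
#' exhaustive model enumeration and fitting, AICc ranking with confidence
#' set and model averaging, goodness of fit with overdispersion adjustment,
#' site-level cross-validation of the best model, and the cumulative
#' detection (survey-effort) curve from the averaged detection estimate.
#' Given identical configuration and seeds, reruns produce byte-identical
#' report files; the run manifest (which includes wall-clock timings) is
#' the only non-deterministic output.
#'
#' The configuration is a named list:
#' \describe{
#'   \item{input}{List of CSV paths `photos`, `deployments`, `covariates`
#'     (photo schema `site_id,timestamp,species`), or}
#'   \item{simulation}{List with a `design` ([sim_design()]) to simulate
#'     instead of reading files.}
#'   \item{seed}{Integer master seed (required); stage seeds derive from it.}
#'   \item{occasion_length, cor_threshold, delta_threshold}{Defaults 4 days,
#'     0.7, 2.}
#'   \item{psi_candidates, p_candidates}{Candidate covariate names.}
#'   \item{max_terms, budget}{Passed to [enumerate_model_specs()].}
#'   \item{gof_B, cv_k}{Bootstrap replicates (default 200) and folds (5).}
#'   \item{k_max}{Survey counts for the detection curve (default 15).}
#' }
#'
#' @param config Configuration list.
#' @param out_dir Output directory; created if needed.
#' @return Invisibly, a list with the in-memory results (`matrix`,
#'   `covariates`, `models`, `top`, `averaged`, `estimates`, `gof`, `cv`,
#'   `curve`) and `paths` to the written reports.
#' @export
run_occupancy_pipeline <- function(config, out_dir) {
  issues <- validate_run_config(config)
  if (length(issues) > 0) {
    abort(paste0("Invalid configuration:\n- ",
                 paste(issues, collapse = "\n- ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  manifest <- list(seed = config$seed, stages = list())
  t_all <- Sys.time()

  stage <- function(name, expr) {
    t0 <- Sys.time()
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", name, "] start\n",
        sep = "", file = log_path, append = TRUE)
    res <- tryCatch(expr, error = function(e) {
      cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", name,
          "] FAILED: ", conditionMessage(e), "\n",
          sep = "", file = log_path, append = TRUE)
      abort(paste0("Pipeline stage `", name, "` failed: ",
                   conditionMessage(e)))
    })
    dur <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[name]] <<- list(seconds = round(dur, 3))
    cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", name, "] done (",
        round(dur, 2), "s)\n", sep = "", file = log_path, append = TRUE)
    res
  }
  seed <- as.integer(config$seed)

  data <- stage("load_data", {
    if (!is.null(config$simulation)) {
      sim <- simulate_camtrap(config$simulation$design, seed = seed)
      list(dm = sim$matrix, cov = sim$covariates, photos = sim$photos,
           deployments = sim$deployments)
    } else {
      photos <- utils::read.csv(config$input$photos)
      photos$timestamp <- as.POSIXct(photos$timestamp, tz = "UTC",
                                     tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                    "%Y-%m-%d %H:%M:%S",
                                                    "%Y-%m-%d"))
      if (!is.null(config$species) && "species" %in% names(photos)) {
        photos$is_target <- photos$species == config$species
      }
      deployments <- utils::read.csv(config$input$deployments)
      cov <- utils::read.csv(config$input$covariates)
      dm <- build_detection_matrix(photos, deployments,
                                   config$occasion_length %||% 4)
      list(dm = dm, cov = tibble::as_tibble(cov), photos = photos,
           deployments = deployments)
    }
  })

  cov_std <- stage("covariates", {
    cov <- standardize_covariates(data$cov)
    prune_correlated(cov, threshold = config$cor_threshold %||% 0.7,
                     priority = config$covariate_priority)
  })
  dropped <- attr(cov_std, "dropped")
  if (nrow(dropped) > 0) {
    writeLines(paste0("dropped ", dropped$dropped, " (|r| = ",
                      round(abs(dropped$r), 3), " with ", dropped$kept, ")"),
               file.path(out_dir, "covariate_drop_log.txt"))
  }

  kept <- setdiff(names(cov_std), "site_id")
  psi_cand <- intersect(config$psi_candidates %||% kept, kept)
  p_cand <- intersect(config$p_candidates %||% kept, kept)

  models <- stage("fit_models", {
    specs <- enumerate_model_specs(psi_cand, p_cand,
                                   max_terms = config$max_terms,
                                   budget = config$budget %||% 20000)
    fit_models(specs, data$dm, cov_std)
  })

  top <- stage("model_selection",
               confidence_set(models, config$delta_threshold %||% 2))
  averaged <- stage("model_average", model_average(top))

  gof <- stage("goodness_of_fit", {
    bootstrap_gof(top$fit[[1]], data$dm, cov_std,
                  B = config$gof_B %||% 200, seed = seed + 1L)
  })
  best_adj <- adjust_se(top$fit[[1]], gof$c_hat)

  cv <- stage("cross_validation", {
    best <- top$fit[[1]]
    cross_validate(data$dm, cov_std, psi_terms = best$psi_terms,
                   p_terms = best$p_terms, k = config$cv_k %||% 5,
                   seed = seed + 2L)
  })

  estimates <- stage("estimates", {
    psi_hat <- average_predictions(top, quantity = "psi")
    p_hat <- average_predictions(top, quantity = "p")
    dplyr::bind_rows(psi_hat, p_hat)
  })

  curve <- stage("survey_design", {
    p_row <- estimates[estimates$quantity == "p", ]
    se_p <- (qlogis(p_row$upper) - qlogis(p_row$lower)) / (2 * qnorm(0.975))
    se_prob <- se_p * p_row$estimate * (1 - p_row$estimate)
    p_star_curve(p_row$estimate, se = se_prob,
                 k_max = config$k_max %||% 15)
  })

  paths <- stage("reports", {
    p <- c(model_table = file.path(out_dir, "model_table.csv"),
           confidence_set = file.path(out_dir, "confidence_set.csv"),
           estimates = file.path(out_dir, "estimates.json"),
           assessment = file.path(out_dir, "assessment.json"),
           p_star = file.path(out_dir, "p_star_curve.csv"))
    write_model_table(models, p["model_table"])
    write_model_table(top, p["confidence_set"])
    jsonlite::write_json(list(
      naive_occupancy = naive_occupancy(data$dm),
      naive_detection_rate = naive_detection_rate(data$dm),
      n_models = nrow(models),
      n_confidence_set = nrow(top),
      averaged_coefficients = averaged,
      averaged_probabilities = estimates,
      best_model = top$label[1],
      best_model_coefficients = tidy(best_adj)
    ), p["estimates"], auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(
      gof = list(observed_chi2 = gof$observed_chi2, c_hat = gof$c_hat,
                 p_value = gof$p_value, B = gof$B, seed = gof$seed,
                 se_adjusted = gof$c_hat > 1),
      cv = list(k = cv$k, fold_mse = cv$fold_mse, mean_mse = cv$mean_mse,
                seed = cv$seed, skipped = cv$skipped)
    ), p["assessment"], auto_unbox = TRUE, digits = NA)
    write_p_star_curve(curve, p["p_star"])
    p
  })

  manifest$total_seconds <- round(as.numeric(
    difftime(Sys.time(), t_all, units = "secs")), 3)
  manifest$n_models <- nrow(models)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(matrix = data$dm, covariates = cov_std, models = models,
                 top = top, averaged = averaged, estimates = estimates,
                 gof = gof, cv = cv, curve = curve, paths = paths))
}
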