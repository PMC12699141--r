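#' Build a binary detection matrix from photo records and deployments
#'
#' Converts timestamped camera-trap photo records into site-by-occasion
#' detection histories. Each site's deployment period is partitioned into
#' consecutive occasions of `occasion_length` days, anchored at that site's
#' deployment start (sites need not share calendar windows). A cell is 1 if
#' at least one target-species photo falls inside the occasion window, 0 if
#' the camera was active for at least one day of the window but recorded no
#' target photo, and `NA` for occasions wholly outside the deployment
#' (deployments of unequal length produce trailing `NA`s up to the longest
#' site's occasion count).
#'
#' A deployment whose length is not a multiple of `occasion_length` keeps its
#' final, shorter occasion rather than dropping those days; such sites are
#' flagged in the `anchors` metadata.
#'
#' @param photos Data frame of photo records with columns `site_id`,
#'   `timestamp` (`POSIXct`, `Date`, or parseable character), and optionally
#'   `is_target` (logical; all photos are treated as target-species records
#'   when absent).
#' @param deployments Data frame with columns `site_id`, `start`, `end`
#'   (dates); one row per site, `end >= start`, both days inclusive.
#' @param occasion_length Occasion length in days (default 4).
#' @param outside How to treat photos falling outside their site's
#'   deployment: `"warn"` drops them with a warning, `"error"` aborts.
#' @return A `detection_matrix` object: a list with the binary matrix `y`
#'   (sites x occasions, `NA` = not surveyed), `site_ids`,
#'   `occasion_length`, and per-site `anchors` metadata.
#' @examples
#' dep <- data.frame(site_id = "s1", start = as.Date("2020-01-01"),
#'                   end = as.Date("2020-01-12"))
#' ph <- data.frame(site_id = "s1",
#'                  timestamp = as.Date("2020-01-01") + c(0, 1, 8))
#' build_detection_matrix(ph, dep, occasion_length = 4)
#' @export
build_detection_matrix <- function(photos, deployments, occasion_length = 4,
                                   outside = c("warn", "error")) {
  outside <- match.arg(outside)
  if (occasion_length < 1) abort("`occasion_length` must be >= 1 day.")
  deployments <- as_deployments(deployments)
  if (anyDuplicated(deployments$site_id)) {
    abort("`deployments` must have one row per site.")
  }
  photos <- as_photos(photos)
  unknown <- setdiff(photos$site_id, deployments$site_id)
  if (length(unknown) > 0) {
    abort(paste0("Photo records reference unknown site(s): ",
                 paste(unknown, collapse = ", ")))
  }

  days <- as.integer(deployments$end - deployments$start) + 1L
  n_occ <- as.integer(ceiling(days / occasion_length))
  J <- max(n_occ)
  n <- nrow(deployments)
  y <- matrix(NA_integer_, n, J,
              dimnames = list(deployments$site_id,
                              paste0("occ", seq_len(J))))
  for (i in seq_len(n)) y[i, seq_len(n_occ[i])] <- 0L

  ph <- photos[photos$is_target, , drop = FALSE]
  if (nrow(ph) > 0) {
    idx <- match(ph$site_id, deployments$site_id)
    day0 <- as.integer(as.Date(ph$timestamp) - deployments$start[idx])
    bad <- day0 < 0L | day0 >= days[idx]
    if (any(bad)) {
      msg <- paste0(sum(bad), " photo record(s) fall outside their site's ",
                    "deployment period")
      if (outside == "error") abort(msg)
      warn(paste0(msg, "; dropped."))
      ph <- ph[!bad, , drop = FALSE]
      idx <- idx[!bad]
      day0 <- day0[!bad]
    }
    occ <- day0 %/% occasion_length + 1L
    y[cbind(idx, occ)] <- 1L
  }

  anchors <- tibble::tibble(
    site_id = deployments$site_id,
    start = deployments$start,
    end = deployments$end,
    days = days,
    n_occasions = n_occ,
    short_final = days %% occasion_length != 0L
  )
  new_detection_matrix(y, occasion_length, anchors)
}

new_detection_matrix <- function(y, occasion_length, anchors = NULL) {
  structure(
    list(y = y, site_ids = rownames(y),
         occasion_length = occasion_length, anchors = anchors),
    class = "detection_matrix"
  )
}

#' Construct a detection matrix from an existing site-by-occasion matrix
#'
#' Wraps an already-built 0/1/`NA` matrix (rows = sites, columns = survey
#' occasions) as a `detection_matrix`, for data prepared outside the package.
#'
#' @param y Numeric or integer matrix of 0/1 with `NA` for unsurveyed cells.
#' @param occasion_length Occasion length in days (metadata only here).
#' @param site_ids Site identifiers; default row names or `site_<i>`.
#' @return A `detection_matrix` object.
#' @export
detection_matrix <- function(y, occasion_length = 4, site_ids = NULL) {
  y <- as.matrix(y)
  if (!all(y %in% c(0, 1, NA))) abort("Cells must be 0, 1 or NA.")
  if (nrow(y) < 1) abort("Detection matrix needs at least one site.")
  if (any(rowSums(!is.na(y)) == 0)) {
    abort("Every site must have at least one surveyed occasion.")
  }
  storage.mode(y) <- "integer"
  if (is.null(site_ids)) {
    site_ids <- rownames(y) %||% paste0("site_", seq_len(nrow(y)))
  }
  rownames(y) <- site_ids
  colnames(y) <- paste0("occ", seq_len(ncol(y)))
  new_detection_matrix(y, occasion_length)
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("<detection_matrix> ", nrow(x$y), " sites x ", ncol(x$y),
      " occasions (", x$occasion_length, "-day)\n", sep = "")
  cat("  naive occupancy: ", round(naive_occupancy(x), 3),
      "; surveyed cells: ", sum(!is.na(x$y)), "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.detection_matrix <- function(x, ...) x$y

#' @export
dim.detection_matrix <- function(x) dim(x$y)

#' Long-format view of a detection matrix
#'
#' @param x A `detection_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `site_id`, `occasion`, `detected`
#'   (surveyed cells only).
#' @export
as_tibble.detection_matrix <- function(x, ...) {
  tibble::tibble(
    site_id = rep(x$site_ids, ncol(x$y)),
    occasion = rep(seq_len(ncol(x$y)), each = nrow(x$y)),
    detected = as.integer(x$y)
  ) |>
    dplyr::filter(!is.na(.data$detected)) |>
    dplyr::arrange(.data$site_id, .data$occasion)
}

#' Naive occupancy: fraction of sites with at least one detection
#'
#' The proportion of sites where the species was photographed at least once,
#' uncorrected for imperfect detection. Always less than or equal to the
#' model-based occupancy estimate in expectation.
#'
#' @param x A `detection_matrix` or a plain site-by-occasion 0/1/`NA` matrix.
#' @return A proportion in \[0, 1\].
#' @examples
#' y <- rbind(c(1, 0, 0), c(0, 0, 0))
#' naive_occupancy(y)  # 0.5
#' @export
naive_occupancy <- function(x) {
  y <- if (inherits(x, "detection_matrix")) x$y else as.matrix(x)
  if (nrow(y) < 1) abort("Detection matrix has zero sites.")
  mean(rowSums(y == 1, na.rm = TRUE) > 0)
}

#' Naive per-occasion detection rate
#'
#' Detections divided by surveyed occasions, by default restricted to sites
#' with at least one detection (the sites known to be occupied), giving an
#' empirical analogue of per-occasion detection probability.
#'
#' @param x A `detection_matrix` or matrix.
#' @param occupied_only Restrict to sites with >= 1 detection (default TRUE).
#' @return A proportion in \[0, 1\].
#' @export
naive_detection_rate <- function(x, occupied_only = TRUE) {
  y <- if (inherits(x, "detection_matrix")) x$y else as.matrix(x)
  if (occupied_only) {
    keep <- rowSums(y == 1, na.rm = TRUE) > 0
    y <- y[keep, , drop = FALSE]
  }
  if (nrow(y) == 0) return(NA_real_)
  sum(y == 1, na.rm = TRUE) / sum(!is.na(y))
}

#' Count independent detection events
#'
#' Collapses runs of same-site target photos separated by less than `window`
#' minutes into single events, the usual deduplication applied before
#' reporting camera-trap detection totals. The occupancy pipeline itself uses
#' only occasion-level 0/1 records, so the window affects reporting only.
#'
#' @param photos Photo-record data frame (see [build_detection_matrix()]).
#' @param window Independence window in minutes (default 60).
#' @return Integer count of independent events.
#' @export
independent_detections <- function(photos, window = 60) {
  if (window <= 0) abort("`window` must be positive (minutes).")
  photos <- as_photos(photos)
  photos <- photos[photos$is_target, , drop = FALSE]
  if (nrow(photos) == 0) return(0L)
  photos |>
    dplyr::mutate(timestamp = as.POSIXct(.data$timestamp, tz = "UTC")) |>
    dplyr::arrange(.data$site_id, .data$timestamp) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::mutate(
      gap = c(Inf, diff(as.numeric(.data$timestamp)) / 60),
      new_event = .data$gap >= window
    ) |>
    dplyr::ungroup() |>
    dplyr::summarise(n = sum(.data$new_event)) |>
    dplyr::pull(.data$n) |>
    as.integer()
}

#' Write / read a detection matrix as CSV plus JSON sidecar
#'
#' The CSV holds one row per site (`site_id` then 0/1/`NA` occasion columns);
#' the sidecar `<path>.meta.json` stores the occasion length and per-site
#' deployment anchors so the object round-trips.
#'
#' @param x A `detection_matrix`.
#' @param path CSV file path.
#' @return `write_detection_matrix()` returns `path` invisibly;
#'   `read_detection_matrix()` returns a `detection_matrix`.
#' @export
write_detection_matrix <- function(x, path) {
  df <- data.frame(site_id = x$site_ids, x$y, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  meta <- list(occasion_length = x$occasion_length)
  if (!is.null(x$anchors)) {
    a <- x$anchors
    meta$anchors <- lapply(seq_len(nrow(a)), function(i) {
      list(site_id = a$site_id[i], start = as.character(a$start[i]),
           end = as.character(a$end[i]))
    })
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_detection_matrix
#' @export
read_detection_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  y <- as.matrix(df[, -1, drop = FALSE])
  rownames(y) <- df$site_id
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  dm <- detection_matrix(y, occasion_length = meta$occasion_length,
                         site_ids = df$site_id)
  if (!is.null(meta$anchors)) {
    dm$anchors <- purrr::map_dfr(meta$anchors, function(a) {
      tibble::tibble(site_id = a$site_id, start = as.Date(a$start),
                     end = as.Date(a$end))
    })
  }
  dm
}

as_photos <- function(photos) {
  photos <- tibble::as_tibble(photos)
  need <- c("site_id", "timestamp")
  missing_cols <- setdiff(need, names(photos))
  if (length(missing_cols) > 0) {
    abort(paste0("`photos` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"is_target" %in% names(photos)) photos$is_target <- TRUE
  if (any(!nzchar(photos$site_id)) || anyNA(photos$site_id)) {
    abort("`photos$site_id` must be non-empty.")
  }
  photos
}

as_deployments <- function(deployments) {
  deployments <- tibble::as_tibble(deployments)
  need <- c("site_id", "start", "end")
  missing_cols <- setdiff(need, names(deployments))
  if (length(missing_cols) > 0) {
    abort(paste0("`deployments` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  deployments$start <- as.Date(deployments$start)
  deployments$end <- as.Date(deployments$end)
  if (any(deployments$end < deployments$start)) {
    abort("Deployment `end` must not precede `start`.")
  }
  deployments
}
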