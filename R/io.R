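trials_cols <- c("observer_id", "experiment", "condition", "size_mode",
                 "target_distance_m", "matched_distance_m", "trial_index")
locs_cols <- c("observer_id", "condition", "localized_distance_m",
               "trial_index")

#' Read and write trial and localization tables
#'
#' CSV round-trip for the two trial-level tables. Files are comma-separated
#' UTF-8 with a header row; all distances are in meters (column names carry
#' the `_m` suffix to make the unit explicit).
#'
#' @param trials,localizations Tibbles as produced by [simulate_trials()] /
#'   [simulate_surface_localizations()].
#' @param path File path.
#' @return The readers return tibbles; the writers return `path` invisibly.
#' @name trials_io
NULL

#' @rdname trials_io
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(trials_cols %in% names(trials)))
  readr::write_csv(trials[trials_cols], path)
  invisible(path)
}

#' @rdname trials_io
#' @export
read_trials <- function(path) {
  tr <- readr::read_csv(path, col_types = readr::cols(
    observer_id = readr::col_character(),
    experiment = readr::col_character(),
    condition = readr::col_character(),
    size_mode = readr::col_character(),
    target_distance_m = readr::col_double(),
    matched_distance_m = readr::col_double(),
    trial_index = readr::col_integer()
  ))
  missing <- setdiff(trials_cols, names(tr))
  if (length(missing) > 0) {
    stop("Trials file lacks column(s): ", paste(missing, collapse = ", "))
  }
  tr
}

#' @rdname trials_io
#' @export
write_localizations <- function(localizations, path) {
  stopifnot(all(locs_cols %in% names(localizations)))
  readr::write_csv(localizations[locs_cols], path)
  invisible(path)
}

#' @rdname trials_io
#' @export
read_localizations <- function(path) {
  loc <- readr::read_csv(path, col_types = readr::cols(
    observer_id = readr::col_character(),
    condition = readr::col_character(),
    localized_distance_m = readr::col_double(),
    trial_index = readr::col_integer()
  ))
  missing <- setdiff(locs_cols, names(loc))
  if (length(missing) > 0) {
    stop("Localizations file lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  loc
}

#' Serialize observer parameters to JSON
#'
#' Writes a list of observer parameter sets (true generating parameters or
#' fitted values) as pretty-printed JSON with stable key order, one entry
#' per observer.
#'
#' @param params A list of `observer_params` objects (e.g.
#'   `simulate_panel()$params`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observer_params <- function(params, path) {
  payload <- purrr::map(params, function(p) {
    list(
      observer_id = p$observer_id,
      sigma_resp = p$sigma_resp,
      disparity = p$disparity,
      surface = p$surface,
      sigma_opacity = p$sigma_opacity
    )
  })
  names(payload) <- purrr::map_chr(params, "observer_id")
  jsonlite::write_json(payload, path, dataframe = "rows", pretty = TRUE,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate a trial-level dataset
#'
#' Schema and consistency checks for a trials CSV and a localizations CSV:
#' required columns; distances within the grid bounds; known condition
#' labels; non-positive or non-integer trial indices; duplicated
#' (observer, condition, distance, trial) keys; and the referential rule
#' that every surface-present condition with matching trials also has
#' localization records for that observer. Problems are collected, not
#' thrown, so a report always comes back.
#'
#' @param trials_path,localizations_path CSV paths.
#' @param grid A [distance_grid()] giving the admissible distance range.
#'
#' @return An object of class `"dataset_validation"`: a list with `valid`
#'   (logical), `issues` (tibble: `check`, `detail`), and `cell_counts`
#'   (trials per observer x condition x distance).
#' @export
validate_dataset <- function(trials_path, localizations_path,
                             grid = distance_grid()) {
  g <- as_grid_values(grid)
  issues <- list()
  note <- function(check, detail) {
    issues[[length(issues) + 1]] <<- tibble::tibble(check = check,
                                                    detail = detail)
  }
  trials <- tryCatch(read_trials(trials_path), error = function(e) {
    note("trials_schema", conditionMessage(e))
    NULL
  })
  locs <- tryCatch(read_localizations(localizations_path), error = function(e) {
    note("localizations_schema", conditionMessage(e))
    NULL
  })
  cell_counts <- tibble::tibble()
  if (!is.null(trials)) {
    bad_t <- trials$target_distance_m < min(g) | trials$target_distance_m > max(g)
    bad_m <- trials$matched_distance_m < min(g) | trials$matched_distance_m > max(g)
    if (any(bad_t)) {
      note("trials_range", sprintf(
        "%d trial(s) with target distance outside [%g, %g] m",
        sum(bad_t), min(g), max(g)))
    }
    if (any(bad_m)) {
      note("trials_range", sprintf(
        "%d trial(s) with matched distance outside [%g, %g] m",
        sum(bad_m), min(g), max(g)))
    }
    bad_cond <- setdiff(unique(trials$condition), condition_levels)
    if (length(bad_cond) > 0) {
      note("trials_condition",
           paste("unknown condition label(s):",
                 paste(bad_cond, collapse = ", ")))
    }
    if (any(is.na(trials$trial_index)) || any(trials$trial_index < 1,
                                              na.rm = TRUE)) {
      note("trials_index", "trial_index must be a positive integer")
    }
    dup <- duplicated(trials[c("observer_id", "condition",
                               "target_distance_m", "trial_index")])
    if (any(dup)) {
      note("trials_duplicate", sprintf(
        "%d duplicated (observer, condition, distance, trial_index) key(s)",
        sum(dup)))
    }
    cell_counts <- trials |>
      dplyr::count(.data$observer_id, .data$condition,
                   .data$target_distance_m, name = "n_trials")
  }
  if (!is.null(locs)) {
    bad_l <- locs$localized_distance_m < min(g) |
      locs$localized_distance_m > max(g)
    if (any(bad_l)) {
      note("localizations_range", sprintf(
        "%d localization(s) outside [%g, %g] m", sum(bad_l), min(g), max(g)))
    }
    if (any(locs$condition == "absent")) {
      note("localizations_condition",
           "localization records exist for the surface-absent condition")
    }
  }
  if (!is.null(trials) && !is.null(locs)) {
    need <- trials |>
      dplyr::filter(.data$condition != "absent") |>
      dplyr::distinct(.data$observer_id, .data$condition)
    have <- dplyr::distinct(locs, .data$observer_id, .data$condition)
    orphan <- dplyr::anti_join(need, have, by = c("observer_id", "condition"))
    if (nrow(orphan) > 0) {
      note("referential", paste(
        "surface-present trials without localization records:",
        paste(sprintf("%s/%s", orphan$observer_id, orphan$condition),
              collapse = ", ")))
    }
  }
  issues <- if (length(issues) == 0) {
    tibble::tibble(check = character(), detail = character())
  } else {
    dplyr::bind_rows(issues)
  }
  structure(list(
    valid = nrow(issues) == 0,
    issues = issues,
    cell_counts = cell_counts
  ), class = "dataset_validation")
}

#' @export
print.dataset_validation <- function(x, ...) {
  if (x$valid) {
    cat("<dataset_validation> OK:", nrow(x$cell_counts), "cells checked\n")
  } else {
    cat("<dataset_validation>", nrow(x$issues), "issue(s):\n")
    for (i in seq_len(nrow(x$issues))) {
      cat(sprintf("  [%s] %s\n", x$issues$check[i], x$issues$detail[i]))
    }
  }
  invisible(x)
}
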