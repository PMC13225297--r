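#' Condition-by-distance summary of depth matches
#'
#' For every surface condition and target distance: the across-observer mean
#' of per-observer mean matches, the pooled within-observer SD (root mean of
#' per-observer variances), trial and observer counts, and — when every
#' observer contributes to every cell and there are at least two observers —
#' a within-subject 95% CI half-width computed over the condition-by-distance
#' cells via [within_subject_ci()].
#'
#' @param trials Trial tibble with columns `observer_id`, `condition`,
#'   `target_distance_m`, `matched_distance_m`.
#' @param ci_level Confidence level for the within-subject interval.
#'
#' @return A tibble with columns `condition`, `target_distance_m`,
#'   `mean_matched_m`, `sd_matched_m`, `n_trials`, `n_observers`,
#'   `ci_halfwidth_m` (NA when not computable).
#' @export
summarize_matches <- function(trials, ci_level = 0.95) {
  stopifnot(all(c("observer_id", "condition", "target_distance_m",
                  "matched_distance_m") %in% names(trials)),
            nrow(trials) > 0)
  per_obs <- trials |>
    dplyr::group_by(.data$observer_id, .data$condition,
                    .data$target_distance_m) |>
    dplyr::summarise(
      obs_mean = mean(.data$matched_distance_m),
      obs_var = stats::var(.data$matched_distance_m),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  out <- per_obs |>
    dplyr::group_by(.data$condition, .data$target_distance_m) |>
    dplyr::summarise(
      mean_matched_m = mean(.data$obs_mean),
      sd_matched_m = sqrt(mean(.data$obs_var)),
      n_trials = sum(.data$n_trials),
      n_observers = dplyr::n(),
      .groups = "drop"
    )
  # within-subject CI across condition x distance cells, if the table is
  # complete and there are >= 2 observers
  cell_tbl <- per_obs |>
    dplyr::mutate(cell = paste(.data$condition, .data$target_distance_m,
                               sep = "@"))
  n_obs <- length(unique(cell_tbl$observer_id))
  n_cells <- length(unique(cell_tbl$cell))
  complete <- nrow(cell_tbl) == n_obs * n_cells
  if (n_obs >= 2 && n_cells >= 2 && complete) {
    ci <- within_subject_ci(cell_tbl, subject = "observer_id", cell = "cell",
                            value = "obs_mean", level = ci_level)
    out <- out |>
      dplyr::mutate(cell = paste(.data$condition, .data$target_distance_m,
                                 sep = "@")) |>
      dplyr::left_join(dplyr::select(ci, "cell", "ci_halfwidth_m"),
                       by = "cell") |>
      dplyr::select(-"cell")
  } else {
    out$ci_halfwidth_m <- NA_real_
  }
  dplyr::arrange(out, order_conditions(.data$condition),
                 .data$target_distance_m)
}

#' Within-subject confidence intervals (Cousineau-Morey)
#'
#' Repeated-measures CIs that remove between-subject variance: each
#' subject's values are normalized by subtracting the subject's own mean
#' across cells and adding the grand mean; per-cell SDs of the normalized
#' values are inflated by the Morey factor `sqrt(C / (C - 1))` for `C` cells;
#' half-widths are `t`-based with `n - 1` degrees of freedom for `n`
#' subjects. Adding a subject-specific constant to all of a subject's values
#' leaves the intervals unchanged — the method's defining property.
#'
#' @param data A tibble with one row per subject-by-cell combination.
#' @param subject,cell,value Names (strings) of the subject identifier,
#'   cell identifier, and value columns.
#' @param level Confidence level (default 0.95).
#'
#' @return A tibble with columns `cell`, `mean`, `ci_halfwidth_m`, `n`
#'   (subjects per cell).
#' @export
within_subject_ci <- function(data, subject = "observer_id", cell = "cell",
                              value = "value", level = 0.95) {
  stopifnot(all(c(subject, cell, value) %in% names(data)),
            level > 0, level < 1)
  d <- tibble::tibble(
    subject = as.character(data[[subject]]),
    cell = as.character(data[[cell]]),
    value = as.numeric(data[[value]])
  )
  n_subj <- length(unique(d$subject))
  n_cells <- length(unique(d$cell))
  if (n_subj < 2) stop("At least 2 subjects are required.")
  if (n_cells < 2) stop("At least 2 cells are required.")
  if (nrow(d) != n_subj * n_cells ||
      anyDuplicated(d[c("subject", "cell")]) > 0) {
    stop("The subject-by-cell table must be complete, with exactly one ",
         "value per subject and cell (no imputation is performed).")
  }
  grand <- mean(d$value)
  d <- d |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(norm = .data$value - mean(.data$value) + grand) |>
    dplyr::ungroup()
  morey <- sqrt(n_cells / (n_cells - 1))
  tcrit <- stats::qt((1 + level) / 2, df = n_subj - 1)
  d |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(
      mean = mean(.data$value),
      ci_halfwidth_m = tcrit * stats::sd(.data$norm) * morey / sqrt(n_subj),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Segmented in-front versus behind regression slopes
#'
#' Ordinary least-squares slopes of matched distance against target distance,
#' fit separately to distances at or in front of the surface
#' (`<= split_at`) and behind it (`> split_at`), per surface condition.
#' Accurate metric matching gives slopes near 1; occlusion-induced
#' compression behind the surface shows up as `slope_behind < slope_front`.
#' By default regressions are fit to per-distance mean matches pooled over
#' observers; `per_observer = TRUE` fits each observer separately.
#'
#' @param trials Trial tibble (or a [summarize_matches()] result, in which
#'   case its `mean_matched_m` values are used directly).
#' @param split_at Surface distance in meters; distances `<= split_at` form
#'   the front segment (default 1.2, the surface position).
#' @param per_observer Fit per observer instead of pooling.
#'
#' @return A tibble with columns `condition` (and `observer_id` if
#'   `per_observer`), `slope_front`, `intercept_front_m`, `slope_behind`,
#'   `intercept_behind_m`.
#' @export
segmented_slopes <- function(trials, split_at = 1.2, per_observer = FALSE) {
  if ("mean_matched_m" %in% names(trials)) {
    d <- trials |>
      dplyr::transmute(.data$condition, .data$target_distance_m,
                       y = .data$mean_matched_m)
    groups <- "condition"
  } else {
    stopifnot(all(c("condition", "target_distance_m", "matched_distance_m")
                  %in% names(trials)))
    groups <- if (per_observer) c("observer_id", "condition") else "condition"
    d <- trials |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(groups,
                                                    "target_distance_m")))) |>
      dplyr::summarise(y = mean(.data$matched_distance_m), .groups = "drop")
  }
  fit_segment <- function(dd, seg_name, cond) {
    if (length(unique(dd$target_distance_m)) < 2) {
      stop(sprintf(
        "Condition '%s': fewer than 2 distinct distances in the '%s' segment.",
        cond, seg_name))
    }
    co <- coef(lm(y ~ target_distance_m, data = dd))
    c(slope = unname(co[2]), intercept = unname(co[1]))
  }
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(function(dd, key) {
      cond <- as.character(key$condition)
      front <- fit_segment(dd[dd$target_distance_m <= split_at, ],
                           "front", cond)
      behind <- fit_segment(dd[dd$target_distance_m > split_at, ],
                            "behind", cond)
      tibble::tibble(
        slope_front = front[["slope"]],
        intercept_front_m = front[["intercept"]],
        slope_behind = behind[["slope"]],
        intercept_behind_m = behind[["intercept"]]
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(order_conditions(.data$condition))
}

#' Signed difference from the surface-absent baseline
#'
#' Per condition and distance, the reference (surface-absent) mean match
#' minus the condition's mean match: positive values indicate that the
#' surface pulled matches closer than the baseline (underestimation relative
#' to no-conflict viewing).
#'
#' @param summaries A [summarize_matches()] result (columns `condition`,
#'   `target_distance_m`, `mean_matched_m`).
#' @param reference Reference condition label (default `"absent"`).
#'
#' @return A tibble with columns `condition`, `target_distance_m`,
#'   `difference_m` for every non-reference condition.
#' @export
signed_difference <- function(summaries, reference = "absent") {
  stopifnot(all(c("condition", "target_distance_m", "mean_matched_m")
                %in% names(summaries)))
  ref <- summaries |>
    dplyr::filter(.data$condition == reference) |>
    dplyr::select("target_distance_m", ref_mean = "mean_matched_m")
  if (nrow(ref) == 0) {
    stop("Reference condition '", reference, "' not found in the summaries.")
  }
  others <- dplyr::filter(summaries, .data$condition != reference)
  missing_cells <- dplyr::anti_join(others, ref, by = "target_distance_m")
  if (nrow(missing_cells) > 0) {
    stop("Reference condition '", reference, "' is missing at distance(s): ",
         paste(format(sort(unique(missing_cells$target_distance_m))),
               collapse = ", "), " m")
  }
  others |>
    dplyr::inner_join(ref, by = "target_distance_m") |>
    dplyr::transmute(
      .data$condition, .data$target_distance_m,
      difference_m = .data$ref_mean - .data$mean_matched_m
    ) |>
    dplyr::arrange(order_conditions(.data$condition),
                   .data$target_distance_m)
}
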