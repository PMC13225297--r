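#' Tidy an occlusion-prior model fit
#'
#' @param x An [fit_panel()] result.
#' @param type `"observers"` (one row per observer and condition) or
#'   `"conditions"` (per-condition mean and SEM of the fitted fall-off
#'   parameter).
#' @param ... Unused.
#'
#' @return A tibble.
#' @export
tidy.occlusion_fit <- function(x, type = c("observers", "conditions"), ...) {
  type <- match.arg(type)
  if (type == "observers") {
    x$sigma_opacity
  } else {
    x$condition_means
  }
}

#' Glance at an occlusion-prior model fit
#'
#' @param x An [fit_panel()] result.
#' @param ... Unused.
#'
#' @return A one-row tibble: `n_observers`, `n_conditions`,
#'   `total_objective` (summed optimum objective values), `n_at_bound`
#'   (fits pinned at a search bound), `objective` (criterion name).
#' @export
glance.occlusion_fit <- function(x, ...) {
  tibble::tibble(
    n_observers = length(unique(x$sigma_opacity$observer_id)),
    n_conditions = length(unique(x$sigma_opacity$condition)),
    total_objective = sum(x$sigma_opacity$objective),
    n_at_bound = sum(x$sigma_opacity$at_bound),
    objective = x$objective
  )
}

#' Tidy a parameter-recovery report
#'
#' @param x A [recover_parameters()] result.
#' @param ... Unused.
#' @return The per-condition recovery tibble (`condition`, `true_mean`,
#'   `fitted_mean`, `bias`, `rmse`, `n`).
#' @export
tidy.recovery_report <- function(x, ...) {
  x$by_condition
}

#' Glance at a parameter-recovery report
#'
#' @param x A [recover_parameters()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_reps`, `rank_agreement`, `max_abs_bias`,
#'   `max_rmse`.
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(
    n_reps = x$n_reps,
    rank_agreement = x$rank_agreement,
    max_abs_bias = max(abs(x$by_condition$bias)),
    max_rmse = max(x$by_condition$rmse)
  )
}
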