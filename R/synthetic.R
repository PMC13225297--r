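#' Experimental design for a depth-matching study
#'
#' Returns the design of the two depth-matching experiments the simulator
#' emulates. Experiment 1: target distances 0.9–1.6 m in 0.1 m steps, 10
#' trials per distance, four surface conditions (opaque, semi-transparent,
#' highly transparent, absent), surface at 1.2 m, stimulus scaled to hold a
#' constant 2.7 degree visual angle. Experiment 2: same distances and trial
#' counts, but only opaque / highly transparent / absent conditions and a
#' constant 5.65 cm physical stimulus size. Every field can be overridden.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param ... Named overrides for any design field (e.g.
#'   `trials_per_distance = 20`).
#'
#' @return An object of class `"experiment_design"`: a list with fields
#'   `experiment`, `target_distances_m`, `trials_per_distance`,
#'   `surface_conditions`, `size_mode`, `surface_distance_m`,
#'   `angular_size_deg`, `physical_size_m`.
#' @examples
#' make_design("exp1")
#' make_design("exp2", trials_per_distance = 5)
#' @export
make_design <- function(experiment = c("exp1", "exp2"), ...) {
  experiment <- match.arg(experiment)
  design <- list(
    experiment = experiment,
    target_distances_m = seq(0.9, 1.6, by = 0.1),
    trials_per_distance = 10L,
    surface_conditions = c("opaque", "semi_transparent",
                           "highly_transparent", "absent"),
    size_mode = "constant_angle",
    surface_distance_m = 1.2,
    angular_size_deg = 2.7,
    physical_size_m = 0.0565
  )
  if (experiment == "exp2") {
    design$surface_conditions <- c("opaque", "highly_transparent", "absent")
    design$size_mode <- "constant_physical"
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(design))
  if (length(unknown) > 0) {
    stop("Unknown design field(s): ", paste(unknown, collapse = ", "))
  }
  design[names(overrides)] <- overrides
  validate_design(design)
  structure(design, class = "experiment_design")
}

validate_design <- function(design) {
  d <- design$target_distances_m
  if (length(d) < 2 || any(diff(d) <= 0)) {
    stop("`target_distances_m` must be strictly increasing and unique.")
  }
  if (design$trials_per_distance < 1) stop("`trials_per_distance` must be >= 1.")
  if (!design$size_mode %in% c("constant_angle", "constant_physical")) {
    stop("`size_mode` must be 'constant_angle' or 'constant_physical'.")
  }
  if (length(design$surface_conditions) < 1) {
    stop("At least one surface condition is required.")
  }
  invisible(design)
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> %s: %d distances (%.1f-%.1f m), %d trials/distance\n",
    x$experiment, length(x$target_distances_m),
    min(x$target_distances_m), max(x$target_distances_m),
    x$trials_per_distance
  ))
  cat("  conditions:", paste(x$surface_conditions, collapse = ", "), "\n")
  cat(sprintf("  surface at %.2f m, size mode: %s\n",
              x$surface_distance_m, x$size_mode))
  invisible(x)
}

#' Generative parameters for one synthetic observer
#'
#' Samples a plausible parameter set for a synthetic observer performing the
#' depth-matching task. Disparity likelihood means are veridical
#' (`mu_disp` = target distance, matching the accurate surface-absent
#' baseline); per-distance likelihood SDs are drawn log-uniformly from
#' `sigma_disp_range` and sorted so uncertainty grows with distance.
#' Perceived-surface means equal the physical surface distance with
#' localization SDs drawn uniformly from `sigma_surf_range`. The prior
#' fall-off defaults encode the opacity ordering (opaque steepest, highly
#' transparent shallowest). `sigma_resp` is trial-level response/motor noise
#' added to the model's deterministic prediction; it is a simulator
#' construct, not part of the perceptual model.
#'
#' @param observer_id Identifier string.
#' @param seed Integer seed; the same seed reproduces the same parameters.
#' @param design An [make_design()] object.
#' @param sigma_opacity Named numeric: fall-off SD (m) per present-surface
#'   condition.
#' @param sigma_resp Response noise SD in meters (>= 0).
#' @param sigma_disp_range Length-2 range (m) for the log-uniform draw of
#'   per-distance likelihood SDs.
#' @param sigma_surf_range Length-2 range (m) for the uniform draw of
#'   surface-localization SDs.
#'
#' @return An object of class `"observer_params"`: a list with
#'   `observer_id`, `disparity` (tibble: `target_distance_m`, `mu_disp`,
#'   `sigma_disp`), `surface` (tibble: `condition`, `mu_surf`, `sigma_surf`,
#'   `contrast`), `sigma_opacity` (tibble: `condition`, `sigma_opacity`),
#'   and `sigma_resp`.
#' @export
default_observer <- function(observer_id, seed,
                             design = make_design("exp1"),
                             sigma_opacity = c(opaque = 0.08,
                                               semi_transparent = 0.10,
                                               highly_transparent = 0.25),
                             sigma_resp = 0.03,
                             sigma_disp_range = c(0.02, 0.10),
                             sigma_surf_range = c(0.01, 0.05)) {
  stopifnot(sigma_resp >= 0, all(sigma_opacity > 0),
            all(sigma_disp_range > 0), all(sigma_surf_range > 0))
  present <- setdiff(design$surface_conditions, "absent")
  missing_op <- setdiff(present, names(sigma_opacity))
  if (length(missing_op) > 0) {
    stop("`sigma_opacity` lacks entries for: ", paste(missing_op, collapse = ", "))
  }
  d <- design$target_distances_m
  params <- withr::with_seed(as.integer(seed), {
    sdisp <- sort(exp(runif(length(d), log(sigma_disp_range[1]),
                            log(sigma_disp_range[2]))))
    ssurf <- runif(length(present), sigma_surf_range[1], sigma_surf_range[2])
    list(sdisp = sdisp, ssurf = ssurf)
  })
  contrasts <- surface_contrast_defaults[present]
  structure(list(
    observer_id = as.character(observer_id),
    disparity = tibble::tibble(
      target_distance_m = d,
      mu_disp = d,
      sigma_disp = params$sdisp
    ),
    surface = tibble::tibble(
      condition = present,
      mu_surf = design$surface_distance_m,
      sigma_surf = params$ssurf,
      contrast = unname(contrasts)
    ),
    sigma_opacity = tibble::tibble(
      condition = present,
      sigma_opacity = unname(sigma_opacity[present])
    ),
    sigma_resp = sigma_resp
  ), class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("<observer_params> %s: %d distances, %d surface conditions, sigma_resp = %.3f m\n",
              x$observer_id, nrow(x$disparity), nrow(x$surface), x$sigma_resp))
  invisible(x)
}

#' Simulate depth-matching trials for one observer
#'
#' Generates trial-level matched distances under the observer model: for each
#' condition and target distance the deterministic posterior-mode prediction
#' ([predict_match()]) plus Gaussian response noise `sigma_resp`, clipped to
#' the grid bounds. Surface-absent trials use the flat-prior prediction (the
#' grid point nearest `mu_disp`). With `sigma_resp = 0` every match equals
#' the model prediction exactly.
#'
#' @param params An [default_observer()] parameter set.
#' @param design An [make_design()] object; `params` must cover all of its
#'   distances and conditions.
#' @param grid A [distance_grid()].
#' @param seed Integer seed for the response noise.
#'
#' @return A tibble with columns `observer_id`, `experiment`, `condition`,
#'   `size_mode`, `target_distance_m`, `matched_distance_m`, `trial_index`.
#' @export
simulate_trials <- function(params, design = make_design("exp1"),
                            grid = distance_grid(), seed = 1L) {
  stopifnot(inherits(params, "observer_params"),
            inherits(design, "experiment_design"))
  g <- as_grid_values(grid)
  missing_d <- setdiff(design$target_distances_m,
                       params$disparity$target_distance_m)
  if (length(missing_d) > 0) {
    stop("`params` lacks disparity entries for distance(s): ",
         paste(format(missing_d), collapse = ", "), " m")
  }
  present <- setdiff(design$surface_conditions, "absent")
  missing_c <- union(setdiff(present, params$surface$condition),
                     setdiff(present, params$sigma_opacity$condition))
  if (length(missing_c) > 0) {
    stop("`params` lacks surface parameters for condition(s): ",
         paste(missing_c, collapse = ", "))
  }
  disp <- dplyr::filter(params$disparity,
                        .data$target_distance_m %in% design$target_distances_m)

  # deterministic per-cell predictions; one prior per present condition
  preds <- purrr::map_dfr(design$surface_conditions, function(cond) {
    if (cond == "absent") {
      pred <- disp$mu_disp
    } else {
      sc <- params$surface[params$surface$condition == cond, ]
      so <- params$sigma_opacity$sigma_opacity[
        params$sigma_opacity$condition == cond]
      pv <- prior_values(g, sc$mu_surf, sc$sigma_surf, so)
      pred <- vapply(seq_len(nrow(disp)), function(i) {
        predict_with_prior(g, pv, disp$mu_disp[i], disp$sigma_disp[i])
      }, numeric(1))
    }
    tibble::tibble(condition = cond,
                   target_distance_m = disp$target_distance_m,
                   predicted_m = pred)
  })

  trials <- tidyr::expand_grid(
    preds,
    trial_index = seq_len(design$trials_per_distance)
  )
  noise <- withr::with_seed(as.integer(seed), {
    rnorm(nrow(trials), mean = 0, sd = params$sigma_resp)
  })
  trials$matched_distance_m <- pmin(pmax(trials$predicted_m + noise,
                                         min(g)), max(g))
  tibble::tibble(
    observer_id = params$observer_id,
    experiment = design$experiment,
    condition = trials$condition,
    size_mode = design$size_mode,
    target_distance_m = trials$target_distance_m,
    matched_distance_m = trials$matched_distance_m,
    trial_index = trials$trial_index
  )
}

#' Simulate surface-localization trials for one observer
#'
#' For each present-surface condition, draws `n_trials` localized distances
#' from the observer's perceived-surface distribution
#' `N(mu_surf, sigma_surf)`, clipped to the grid. The surface-absent
#' condition produces no records (there is no surface to localize).
#'
#' @inheritParams simulate_trials
#' @param n_trials Localization trials per condition (>= 2).
#'
#' @return A tibble with columns `observer_id`, `condition`,
#'   `localized_distance_m`, `trial_index`.
#' @export
simulate_surface_localizations <- function(params, n_trials = 10L,
                                           grid = distance_grid(), seed = 1L) {
  stopifnot(inherits(params, "observer_params"), n_trials >= 2)
  g <- as_grid_values(grid)
  surf <- params$surface
  draws <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(nrow(surf)), function(i) {
      rnorm(n_trials, surf$mu_surf[i], surf$sigma_surf[i])
    })
  })
  purrr::map_dfr(seq_len(nrow(surf)), function(i) {
    tibble::tibble(
      observer_id = params$observer_id,
      condition = surf$condition[i],
      localized_distance_m = pmin(pmax(draws[[i]], min(g)), max(g)),
      trial_index = seq_len(n_trials)
    )
  })
}

#' Simulate a full panel of observers
#'
#' Generates a complete synthetic dataset emulating one experiment: one
#' parameter set per observer (via [default_observer()]), matching trials and
#' surface localizations for each, with per-observer child seeds derived
#' deterministically from the master seed. True generating parameters are
#' returned alongside the data so fitting can be validated by parameter
#' recovery.
#'
#' @param n_observers Number of observers (default 12, the Experiment 1
#'   sample size).
#' @param design An [make_design()] object.
#' @param seed Master integer seed.
#' @param grid A [distance_grid()].
#' @param n_localizations Surface-localization trials per condition.
#' @param ... Passed on to [default_observer()] (e.g. `sigma_resp`,
#'   `sigma_opacity`).
#'
#' @return An object of class `"simulated_panel"`: a list with `trials`
#'   (tibble), `localizations` (tibble), `params` (list of
#'   `observer_params`), `design`, and `seed`.
#' @examples
#' panel <- simulate_panel(n_observers = 2, seed = 1)
#' dplyr::count(panel$trials, condition)
#' @export
simulate_panel <- function(n_observers = 12L, design = make_design("exp1"),
                           seed = 1L, grid = distance_grid(),
                           n_localizations = 10L, ...) {
  stopifnot(n_observers >= 1)
  seed <- as.integer(seed)
  ids <- sprintf("obs%02d", seq_len(n_observers))
  params <- purrr::map(seq_len(n_observers), function(i) {
    obs_seed <- child_seed(seed, i)
    default_observer(ids[i], seed = obs_seed, design = design, ...)
  })
  trials <- purrr::map_dfr(seq_len(n_observers), function(i) {
    simulate_trials(params[[i]], design, grid, seed = child_seed(seed, i) + 1L)
  })
  locs <- purrr::map_dfr(seq_len(n_observers), function(i) {
    simulate_surface_localizations(params[[i]], n_localizations, grid,
                                   seed = child_seed(seed, i) + 2L)
  })
  structure(list(
    trials = trials,
    localizations = locs,
    params = params,
    design = design,
    seed = seed
  ), class = "simulated_panel")
}

# Deterministic per-observer seed stream; stays within 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 131 + as.double(i) * 7919) %% 2147483629)
}

#' @export
print.simulated_panel <- function(x, ...) {
  cat(sprintf(
    "<simulated_panel> %d observers, %d trials, %d localizations (seed %d)\n",
    length(x$params), nrow(x$trials), nrow(x$localizations), x$seed
  ))
  invisible(x)
}
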