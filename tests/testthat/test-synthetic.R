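test_that("designs encode the two experiments and accept overrides", {
  e1 <- make_design("exp1")
  expect_equal(e1$target_distances_m, seq(0.9, 1.6, by = 0.1))
  expect_equal(e1$trials_per_distance, 10L)
  expect_equal(length(e1$surface_conditions), 4)
  expect_equal(e1$size_mode, "constant_angle")
  expect_equal(e1$surface_distance_m, 1.2)
  e2 <- make_design("exp2")
  expect_setequal(e2$surface_conditions,
                  c("opaque", "highly_transparent", "absent"))
  expect_equal(e2$size_mode, "constant_physical")
  expect_true(all(diff(e1$target_distances_m) > 0))
  e3 <- make_design("exp1", trials_per_distance = 5L)
  expect_equal(e3$trials_per_distance, 5L)
  expect_error(make_design("exp1", bogus_field = 1), "Unknown design field")
  expect_error(make_design("exp3"))
})

test_that("observer parameters are reproducible, ordered, and in range", {
  p1 <- default_observer("o1", seed = 42)
  p2 <- default_observer("o1", seed = 42)
  expect_equal(p1, p2)
  p3 <- default_observer("o1", seed = 43)
  expect_false(identical(p1$disparity$sigma_disp, p3$disparity$sigma_disp))
  # default fall-off ordering: opaque steepest, highly transparent shallowest
  so <- p1$sigma_opacity
  expect_lt(so$sigma_opacity[so$condition == "opaque"],
            so$sigma_opacity[so$condition == "semi_transparent"])
  expect_lt(so$sigma_opacity[so$condition == "semi_transparent"],
            so$sigma_opacity[so$condition == "highly_transparent"])
  # declared sampling ranges, and sigma_disp grows with distance
  expect_true(all(p1$disparity$sigma_disp >= 0.02 &
                    p1$disparity$sigma_disp <= 0.10))
  expect_true(all(diff(p1$disparity$sigma_disp) >= 0))
  expect_true(all(p1$surface$sigma_surf >= 0.01 & p1$surface$sigma_surf <= 0.05))
  expect_equal(p1$disparity$mu_disp, p1$disparity$target_distance_m)
  expect_equal(unique(p1$surface$mu_surf), 1.2)
})

test_that("simulated trials are the model predictions plus response noise", {
  g <- distance_grid()
  design <- make_design("exp1")
  p0 <- default_observer("o1", seed = 5, sigma_resp = 0)
  tr0 <- simulate_trials(p0, design, g, seed = 9)
  expect_equal(nrow(tr0), 8 * 10 * 4)
  # noise-free limit: every match equals the posterior-mode prediction
  opaque <- tr0[tr0$condition == "opaque", ]
  sc <- p0$surface[p0$surface$condition == "opaque", ]
  so <- p0$sigma_opacity$sigma_opacity[p0$sigma_opacity$condition == "opaque"]
  for (d in c(0.9, 1.2, 1.6)) {
    i <- which(abs(p0$disparity$target_distance_m - d) < 1e-9)
    pred <- predict_match(p0$disparity$mu_disp[i], p0$disparity$sigma_disp[i],
                          sc$mu_surf, sc$sigma_surf, so, grid = g)
    expect_true(all(opaque$matched_distance_m[
      abs(opaque$target_distance_m - d) < 1e-9] == pred))
  }
  # absent condition collapses to the disparity mean
  ab <- tr0[tr0$condition == "absent" & abs(tr0$target_distance_m - 1.1) < 1e-9, ]
  expect_true(all(abs(ab$matched_distance_m - 1.1) < 1e-9))
  # same seed reproduces; different seed does not
  p <- default_observer("o1", seed = 5)
  expect_equal(simulate_trials(p, design, g, seed = 9),
               simulate_trials(p, design, g, seed = 9))
  expect_false(identical(simulate_trials(p, design, g, seed = 9),
                         simulate_trials(p, design, g, seed = 10)))
  # missing parameter cells are named
  p_missing <- p
  p_missing$surface <- p_missing$surface[p_missing$surface$condition != "opaque", ]
  expect_error(simulate_trials(p_missing, design, g), "opaque")
})

test_that("trial noise averages out at the CLT rate", {
  g <- distance_grid()
  design <- make_design("exp1", target_distances_m = c(1.0, 1.6),
                        trials_per_distance = 10000L,
                        surface_conditions = c("opaque", "absent"))
  p <- default_observer("o1", seed = 3, design = design, sigma_resp = 0.03)
  tr <- simulate_trials(p, design, g, seed = 21)
  cell <- tr[tr$condition == "opaque" & abs(tr$target_distance_m - 1.6) < 1e-9, ]
  sc <- p$surface[p$surface$condition == "opaque", ]
  i <- which(abs(p$disparity$target_distance_m - 1.6) < 1e-9)
  pred <- predict_match(p$disparity$mu_disp[i], p$disparity$sigma_disp[i],
                        sc$mu_surf, sc$sigma_surf,
                        p$sigma_opacity$sigma_opacity[
                          p$sigma_opacity$condition == "opaque"], grid = g)
  expect_lt(abs(mean(cell$matched_distance_m) - pred), 3 * 0.03 / 100)
})

test_that("the equal-sigma conflict cell reproduces the 1.4 m signature", {
  g <- distance_grid()
  design <- make_design("exp1", surface_conditions = c("opaque", "absent"))
  p <- default_observer("o1", seed = 2, design = design, sigma_resp = 0)
  # force the textbook configuration: near-delta surface, matched sigmas
  p$surface$sigma_surf <- 0.001
  p$sigma_opacity$sigma_opacity <- p$disparity$sigma_disp[
    abs(p$disparity$target_distance_m - 1.6) < 1e-9]
  tr <- simulate_trials(p, design, g, seed = 4)
  cell <- tr[tr$condition == "opaque" & abs(tr$target_distance_m - 1.6) < 1e-9, ]
  expect_equal(mean(cell$matched_distance_m), 1.4, tolerance = 0.002)
})

test_that("surface localizations are Gaussian draws per present condition", {
  p <- default_observer("o1", seed = 8)
  loc <- simulate_surface_localizations(p, n_trials = 10000, seed = 13)
  expect_setequal(unique(loc$condition),
                  c("opaque", "semi_transparent", "highly_transparent"))
  for (cond in unique(loc$condition)) {
    mu <- p$surface$mu_surf[p$surface$condition == cond]
    s <- p$surface$sigma_surf[p$surface$condition == cond]
    m <- mean(loc$localized_distance_m[loc$condition == cond])
    expect_lt(abs(m - mu), 3 * s / 100)
  }
  expect_equal(simulate_surface_localizations(p, 10, seed = 13),
               simulate_surface_localizations(p, 10, seed = 13))
  expect_error(simulate_surface_localizations(p, n_trials = 1), "n_trials")
})

test_that("panels have disjoint observers and seed-stable content", {
  panel <- simulate_panel(n_observers = 4, seed = 3)
  expect_equal(length(unique(panel$trials$observer_id)), 4)
  expect_equal(length(panel$params), 4)
  expect_false(any(duplicated(vapply(panel$params, `[[`, "", "observer_id"))))
  panel2 <- simulate_panel(n_observers = 4, seed = 3)
  expect_equal(panel$trials, panel2$trials)
  expect_equal(panel$localizations, panel2$localizations)
  panel3 <- simulate_panel(n_observers = 4, seed = 4)
  expect_false(identical(panel$trials$matched_distance_m,
                         panel3$trials$matched_distance_m))
  expect_equal(panel3$design$target_distances_m, panel$design$target_distances_m)
})

test_that("simulated panels carry the qualitative occlusion signature", {
  panel <- simulate_panel(n_observers = 6, seed = 19)
  sm <- summarize_matches(panel$trials)
  sigma_resp <- 0.03
  front <- sm[sm$target_distance_m <= 1.2, ]
  expect_true(all(abs(front$mean_matched_m - front$target_distance_m) <=
                    2 * sigma_resp))
  far <- sm[abs(sm$target_distance_m - 1.6) < 1e-9, ]
  under <- function(cond) {
    1.6 - far$mean_matched_m[far$condition == cond]
  }
  expect_gt(under("opaque"), under("semi_transparent"))
  expect_gt(under("semi_transparent"), under("highly_transparent"))
  expect_gt(under("highly_transparent"), 0)
})
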