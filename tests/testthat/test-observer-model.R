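test_that("distance grid is validated and carries its step", {
  g <- distance_grid()
  expect_equal(range(g), c(0.5, 2.5))
  expect_equal(grid_step(g), 0.001)
  expect_true(all(abs(diff(as.numeric(g)) - 0.001) < 1e-12))
  expect_error(distance_grid(min_m = 0), "positive")
  expect_error(distance_grid(1, 0.8), "exceed")
  expect_error(distance_grid(step_m = 5), "span")
})

test_that("gaussian_density matches the normal density closed forms", {
  expect_equal(gaussian_density(0, 0, 1), 1 / sqrt(2 * pi))
  # one-sigma ratio is exp(-1/2) for any mu, sigma
  for (p in list(c(0, 1), c(1.2, 0.05), c(-3, 2.5))) {
    r <- gaussian_density(p[1] + p[2], p[1], p[2]) /
      gaussian_density(p[1], p[1], p[2])
    expect_equal(r, exp(-0.5))
  }
  expect_equal(gaussian_density(1.7, 1.2, 0.3), gaussian_density(0.7, 1.2, 0.3))
  expect_error(gaussian_density(0, 0, 0), "positive")
})

test_that("perceived surface density is a normalized unimodal Gaussian on the grid", {
  g <- distance_grid()
  d <- perceived_surface_density(g, mu_surf = 1.2, sigma_surf = 0.03)
  expect_equal(sum(d$density), 1, tolerance = 1e-9)
  expect_equal(d$distance_m[which.max(d$density)], 1.2)
  # halving sigma_surf increases the peak density
  d2 <- perceived_surface_density(g, 1.2, 0.015)
  expect_gt(max(d2$density), max(d$density))
  expect_error(perceived_surface_density(g, 5, 0.03), "grid bounds")
})

test_that("visibility function is flat in front and Gaussian behind", {
  expect_equal(visibility_function(1.2, 1.2, 0.1), 1)
  expect_equal(visibility_function(1.2 + 0.1, 1.2, 0.1), exp(-0.5))
  x_front <- seq(0.5, 1.2, by = 0.01)
  expect_true(all(visibility_function(x_front, 1.2, 0.05) == 1))
  # steeper fall-off for smaller sigma_opacity
  expect_lt(visibility_function(1.4, 1.2, 0.05),
            visibility_function(1.4, 1.2, 0.25))
  expect_error(visibility_function(1, 1.2, 0), "positive")
})

test_that("occlusion prior reduces to the visibility curve for a near-delta surface", {
  g <- distance_grid()
  pr <- occlusion_prior(g, mu_surf = 1.2, sigma_surf = 0.001,
                        sigma_opacity = 0.1)
  vis <- visibility_function(as.numeric(g), 1.2, 0.1)
  expect_lt(max(abs(pr$prior - vis)), 1e-3)
})

test_that("occlusion prior is ~1 far in front and non-increasing behind the surface", {
  g <- distance_grid()
  pr <- occlusion_prior(g, 1.2, 0.03, 0.08)
  expect_equal(pr$prior[1], 1, tolerance = 1e-6)
  behind <- pr$prior[pr$distance_m >= 1.2 + 3 * 0.03]
  expect_true(all(diff(behind) <= 1e-12))
  expect_true(all(pr$prior > 0 | pr$prior == 0))
  expect_true(all(pr$prior <= 1 + 1e-12))
})

test_that("disparity likelihood peaks at mu_disp with Gaussian shape", {
  g <- distance_grid()
  lik <- disparity_likelihood(g, 1.3, 0.05)
  expect_equal(lik$distance_m[which.max(lik$likelihood)], 1.3)
  peak <- max(lik$likelihood)
  at_sigma <- lik$likelihood[abs(lik$distance_m - 1.35) < 1e-9]
  expect_equal(at_sigma / peak, exp(-0.5), tolerance = 1e-9)
  # symmetric about a grid-point mean
  left <- lik$likelihood[abs(lik$distance_m - 1.25) < 1e-9]
  expect_equal(at_sigma, left)
})

test_that("posterior is the normalized product, with identity and point-mass limits", {
  g <- distance_grid()
  lik <- disparity_likelihood(g, 1.4, 0.1)
  post_flat <- posterior_density(lik, flat_prior(g))
  expect_equal(post_flat$posterior, lik$likelihood / sum(lik$likelihood),
               tolerance = 1e-12)
  expect_equal(sum(post_flat$posterior), 1, tolerance = 1e-9)
  # prior concentrated on one grid point -> point-mass posterior
  spike <- flat_prior(g)
  spike$prior <- as.numeric(abs(spike$distance_m - 1.0) < 1e-9)
  post_spike <- posterior_density(lik, spike)
  expect_equal(sum(post_spike$posterior), 1)
  expect_equal(post_spike$distance_m[post_spike$posterior > 0], 1.0)
  # mismatched grids are refused
  g2 <- distance_grid(0.5, 2.5, 0.002)
  expect_error(posterior_density(disparity_likelihood(g2, 1.4, 0.1),
                                 flat_prior(g)), "same grid")
  # all-zero product is degenerate
  zero <- flat_prior(g)
  zero$prior <- rep(0, nrow(zero))
  expect_error(posterior_density(lik, zero), "[Dd]egenerate")
})

test_that("predict_match handles absent, conflict, and no-conflict configurations", {
  g <- distance_grid()
  # surface absent: flat prior, prediction at the likelihood mean
  expect_equal(predict_match(1.0, 0.05, grid = g), 1.0)
  # equal-sigma conflict at 1.6 m behind a surface at 1.2 m: midway, 1.4 m
  p <- predict_match(1.6, 0.15, mu_surf = 1.2, sigma_surf = 0.001,
                     sigma_opacity = 0.15, grid = g)
  expect_equal(p, 1.4, tolerance = 0.001)
  # target in front of the surface: prior flat at the peak, prediction exact
  expect_equal(predict_match(1.0, 0.05, mu_surf = 1.2, sigma_surf = 0.001,
                             sigma_opacity = 0.08, grid = g), 1.0)
  expect_error(predict_match(1.6, 0.1, mu_surf = 1.2, grid = g), "required")
})

test_that("grid posterior mode agrees with the closed-form precision-weighted mean", {
  g <- distance_grid()
  step <- grid_step(g)
  cases <- expand.grid(
    sigma_opacity = c(0.03, 0.08, 0.2),
    sigma_disp = c(0.04, 0.15),
    mu_disp = c(1.0, 1.3, 1.5, 1.8)
  )
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    pred <- predict_match(cs$mu_disp, cs$sigma_disp, mu_surf = 1.2,
                          sigma_surf = step, sigma_opacity = cs$sigma_opacity,
                          grid = g)
    oracle <- closed_form_match(cs$mu_disp, cs$sigma_disp, 1.2,
                                cs$sigma_opacity)
    expect_lte(abs(pred - oracle), step + 1e-9)
  }
})

test_that("predictions never overshoot and respond monotonically to the prior", {
  g <- distance_grid()
  step <- grid_step(g)
  # no overestimation for targets behind the surface
  for (mu in c(1.3, 1.45, 1.6)) {
    for (so in c(0.03, 0.1, 0.3)) {
      p <- predict_match(mu, 0.08, 1.2, 0.02, so, grid = g)
      expect_lte(p, mu + 1e-9)
    }
  }
  # weaker occlusion constraint (larger sigma_opacity) -> prediction moves
  # toward the disparity-specified distance
  sigmas <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  preds <- vapply(sigmas, function(so) {
    predict_match(1.6, 0.08, 1.2, 0.02, so, grid = g)
  }, numeric(1))
  expect_true(all(diff(preds) >= -1e-9))
  expect_lt(preds[1], preds[length(preds)])
  # underestimation grows with distance behind the surface
  mus <- seq(1.25, 1.6, by = 0.05)
  under <- vapply(mus, function(mu) {
    mu - predict_match(mu, 0.08, 1.2, step, 0.08, grid = g)
  }, numeric(1))
  expect_true(all(diff(under) >= -step))
  expect_gt(under[length(under)], under[1])
})
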