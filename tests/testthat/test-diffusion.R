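test_that("a single step has radius exactly the step length in 2D and 3D", {
  for (dim in c(2, 3)) {
    ens <- simulate_walks(
      n_particles = 200, step_length_nm = 1, stop_radius_nm = 0.5,
      dimension = dim, seed = 11
    )
    expect_equal(ens$realized_steps, 1L)
    expect_true(ens$stopped_by_first_passage)
    expect_equal(tidy(ens)$radius_nm, rep(1, 200), tolerance = 1e-9)
  }
})

test_that("an unreachable stop radius runs to the step cap and is flagged", {
  ens <- simulate_walks(
    n_particles = 100, step_length_nm = 1, stop_radius_nm = 1e6,
    max_steps = 500, seed = 3
  )
  expect_equal(ens$realized_steps, 500L)
  expect_false(ens$stopped_by_first_passage)
})

test_that("at the stopping step at least one walker has crossed the radius", {
  ens <- simulate_walks(n_particles = 300, stop_radius_nm = 15, seed = 5)
  expect_true(ens$stopped_by_first_passage)
  expect_gte(max(tidy(ens)$radius_nm), 15)
  # one step earlier no walker can have been past the radius: a single step
  # moves at most L, so the maximum radius is below 15 + L but was below 15
  expect_lt(max(tidy(ens)$radius_nm), 15 + ens$params$step_length_nm)
})

test_that("identical seed gives bit-identical positions; different seeds differ", {
  a <- simulate_walks(n_particles = 50, stop_radius_nm = 10, seed = 42)
  b <- simulate_walks(n_particles = 50, stop_radius_nm = 10, seed = 42)
  c <- simulate_walks(n_particles = 50, stop_radius_nm = 10, seed = 43)
  expect_identical(a$positions, b$positions)
  expect_false(identical(a$positions, c$positions))
})

test_that("invalid walk parameters are rejected", {
  expect_error(simulate_walks(step_length_nm = 0), class = "behkit_parameter_error")
  expect_error(simulate_walks(stop_radius_nm = -1), class = "behkit_parameter_error")
  expect_error(simulate_walks(n_particles = 0), class = "behkit_parameter_error")
  expect_error(simulate_walks(dimension = 4), class = "behkit_parameter_error")
})

test_that("mean squared displacement follows n * L^2 in 2D and 3D", {
  n_steps <- 400
  for (dim in c(2, 3)) {
    ens <- simulate_walks(
      n_particles = 4000, step_length_nm = 1, stop_radius_nm = Inf,
      max_steps = n_steps, dimension = dim, seed = 8
    )
    r2 <- tidy(ens)$radius_nm^2
    se <- sd(r2) / sqrt(length(r2))
    expect_lt(abs(mean(r2) - n_steps), 4 * se)
  }
})

test_that("a point mass at the origin fills only the innermost bin", {
  pts <- tibble::tibble(x_nm = rep(0, 10), y_nm = rep(0, 10))
  prof <- radial_density_profile(pts, 1:70)
  expect_equal(prof$N_r, rep(10L, 70))
  expect_equal(prof$rho_r[1], 10 / pi)
  expect_equal(prof$rho_r[-1], rep(0, 69))
})

test_that("annulus density follows the cumulative-count arithmetic", {
  # 4 points inside r = 1, then 6 more between r = 1 and r = 2
  pts <- tibble::tibble(
    x_nm = c(rep(0.5, 4), rep(1.5, 6)),
    y_nm = rep(0, 10)
  )
  prof <- radial_density_profile(pts, c(1, 2))
  expect_equal(prof$N_r, c(4L, 10L))
  expect_equal(prof$rho_r[2], 6 / (3 * pi), tolerance = 1e-12)
})

test_that("uniform disc points give a flat density profile", {
  set.seed(21)
  n <- 10000
  radius <- 70
  pts <- uniform_disc(n, radius)
  prof <- radial_density_profile(pts, 1:70)
  target <- n / (pi * radius^2)
  inner <- c(0, prof$r_nm[-70])
  area <- pi * (prof$r_nm^2 - inner^2)
  p_bin <- area / (pi * radius^2)
  se_rho <- sqrt(n * p_bin * (1 - p_bin)) / area
  expect_true(all(abs(prof$rho_r - target) <= 3 * se_rho))
})

test_that("profile counts are conserved and bins validated", {
  ens <- simulate_walks(n_particles = 500, stop_radius_nm = 30, seed = 2)
  prof <- radial_density_profile(ens, 1:20)
  annulus <- diff(c(0L, prof$N_r))
  expect_equal(sum(annulus) + attr(prof, "n_beyond"), 500L)
  expect_true(all(diff(prof$N_r) >= 0))
  expect_error(radial_density_profile(ens, c(2, 1)), class = "behkit_parameter_error")
  expect_error(radial_density_profile(ens, c(0, 1)), class = "behkit_parameter_error")
  expect_error(
    radial_density_profile(tibble::tibble(x_nm = numeric(), y_nm = numeric())),
    class = "behkit_parameter_error"
  )
})

test_that("localization fractions are monotone, reach 1, and reject non-edges", {
  ens <- simulate_walks(n_particles = 2000, stop_radius_nm = 40, seed = 9)
  prof <- radial_density_profile(ens, 1:40)
  frac <- localization_fraction(prof, 1:40)
  expect_true(all(diff(frac$count_based) >= 0))
  expect_true(all(diff(frac$density_based) >= 0))
  expect_equal(frac$count_based[40], 1)
  expect_equal(frac$density_based[40], 1)
  expect_error(localization_fraction(prof, 20.5), class = "behkit_parameter_error")
})

test_that("count fraction at fixed step count matches the Rayleigh closed form", {
  # the Rayleigh law is the large-step-count limit; 1000 steps puts the
  # O(1/n) finite-n deviation well inside the binomial noise
  n_steps <- 1000
  ens <- simulate_walks(
    n_particles = 10000, step_length_nm = 1, stop_radius_nm = Inf,
    max_steps = n_steps, seed = 14
  )
  # outermost bin at 150 nm holds all but ~exp(-22.5) of the Rayleigh mass,
  # so the count fraction approximates the unconditional CDF
  prof <- radial_density_profile(ens, 1:150)
  for (radius in c(10, 20, 30)) {
    p <- rayleigh_fraction(n_steps, 1, radius)
    se <- sqrt(p * (1 - p) / 10000)
    observed <- localization_fraction(prof, radius)$count_based
    expect_lt(abs(observed - p), 3 * se)
  }
})

test_that("rayleigh_fraction matches its closed form and limits", {
  # frozen by independent arithmetic: 1 - exp(-400 / (12670 * 0.287^2))
  expect_equal(rayleigh_fraction(12670, 0.287, 20), 0.31838004200874237,
    tolerance = 1e-12
  )
  expect_equal(rayleigh_fraction(100, 1, 0), 0)
  expect_equal(rayleigh_fraction(100, 1, Inf), 1)
  expect_error(rayleigh_fraction(0, 1, 1), class = "behkit_parameter_error")
  expect_error(rayleigh_fraction(10, -1, 1), class = "behkit_parameter_error")
})
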