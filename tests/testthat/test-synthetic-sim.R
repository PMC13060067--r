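# synthetic-data generator and simulation drivers

test_that("null surfaces are exact members of the monotone-additive class", {
  for (seed in 1:5) {
    s <- generate_null_surface(6, 7, seed = seed)
    expect_identical(s$u[1], 0)
    expect_identical(s$v[1], 0)
    expect_true(all(diff(s$u) <= 0))
    expect_true(all(diff(s$v) <= 0))
    expect_equal(s$theta, s$alpha + outer(s$u, s$v, "+"))
    add <- fit_monotone_additive(transformed_grid(s$theta))
    expect_lt(add$objective, 1e-12)
    expect_equal(add$u, s$u, tolerance = 1e-8)
  }
  expect_identical(generate_null_surface(5, 5, seed = 3),
                   generate_null_surface(5, 5, seed = 3))
})

test_that("bump injection is a no-op at strength 0 and lands in the cone", {
  surf <- generate_null_surface(8, 8, seed = 3)$theta
  expect_equal(inject_interaction(surf, 0), surf, tolerance = 1e-10)
  alt <- inject_interaction(surf, 6)
  expect_true(all(diff(alt) <= 1e-8))
  expect_true(all(t(diff(t(alt))) <= 1e-8))
  expect_false(isTRUE(all.equal(alt, surf)))
})

test_that("departure from additivity is non-decreasing in bump strength", {
  surf <- generate_null_surface(8, 8, seed = 3)$theta
  Ts <- vapply(c(0, 2, 4, 6, 8, 10), function(s) {
    th <- inject_interaction(surf, s)
    tg <- transformed_grid(th)
    add <- fit_monotone_additive(tg)
    iso <- fit_isotonic_2d(tg)
    interaction_energy(iso$theta_iso - add$theta_add, tg$W)$T
  }, numeric(1))
  expect_true(all(diff(Ts) >= -1e-9))
  expect_gt(Ts[6], Ts[1])
})

test_that("added noise has the requested scale and is seed-reproducible", {
  surf <- matrix(0, 100, 100)
  N <- add_noise(surf, 0.1, seed = 1)
  expect_equal(sd(c(N)), 0.1, tolerance = 0.03)
  expect_identical(add_noise(surf, 0.1, seed = 1), N)
})

test_that("pseudo-null data carries no interaction by construction", {
  Z <- add_noise(generate_null_surface(6, 6, seed = 8)$theta, 0.1, seed = 4)
  tg <- transformed_grid(Z)
  add <- fit_monotone_additive(tg)
  # zero residuals: the pseudo-null is the fitted null itself
  tg0 <- transformed_grid(add$theta_add)
  expect_equal(pseudo_null_from_fit(tg0, seed = 1)$Z, add$theta_add,
               tolerance = 1e-9)
  # Rademacher symmetry: pseudo-null datasets average to the fitted null
  mats <- vapply(1:300, function(k) c(pseudo_null_from_fit(tg, seed = k)$Z),
                 numeric(36))
  expect_lt(max(abs(rowMeans(mats) - c(add$theta_add))), 0.05)
  expect_identical(pseudo_null_from_fit(tg, seed = 5)$Z,
                   pseudo_null_from_fit(tg, seed = 5)$Z)
})

test_that("simulated viability grids are valid and reproducible", {
  g <- simulate_grid(6, 5, strength = 4, sigma = 0.1, seed = 21)
  expect_s3_class(g, "dose_grid")
  expect_identical(dim(g), c(6L, 5L))
  expect_true(all(g$Y >= 0 & g$Y <= 1))
  expect_identical(simulate_grid(6, 5, strength = 4, sigma = 0.1, seed = 21)$Y,
                   g$Y)
})

test_that("power grows with interaction strength at reduced replication", {
  cfg <- simulation_config(I = 6, J = 6, B = 60, n_power_sims = 8,
                           strengths = c(0, 4, 10), seed = 2)
  pw <- run_power_study(cfg)
  expect_identical(nrow(pw), 3L)
  expect_true(all(pw$power >= 0 & pw$power <= 1))
  # Monte-Carlo jitter allowance at n = 8 per strength
  expect_gte(pw$power[3], pw$power[1])
  expect_gte(pw$power[3], pw$power[2] - 0.25)
  # the test is conservative under the null: strength 0 stays near or below alpha
  expect_lte(pw$power[1], 0.25)
})

test_that("simulation drivers are deterministic in the master seed", {
  cfg <- simulation_config(I = 5, J = 5, B = 40, n_null_sims = 6, seed = 13)
  c1 <- run_calibration_study(cfg)
  c2 <- run_calibration_study(cfg)
  expect_identical(c1$p_values, c2$p_values)
  expect_true(all(c1$p_values >= 1 / 41))
})
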