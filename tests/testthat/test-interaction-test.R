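# interaction surface, energies, residual inflation, bootstrap, FDR

test_that("interaction surface is the elementwise fit difference", {
  iso <- structure(list(theta_iso = matrix(c(0, -2, -2, -2), 2, 2,
                                           byrow = TRUE)),
                   class = "monotone_fit")
  add <- structure(list(theta_add = matrix(c(0, -1, -1, -2), 2, 2,
                                           byrow = TRUE)),
                   class = "additive_fit")
  expect_equal(interaction_surface(iso, add),
               matrix(c(0, -1, -1, 0), 2, 2, byrow = TRUE))
  bad <- structure(list(theta_add = matrix(0, 3, 3)), class = "additive_fit")
  expect_error(interaction_surface(iso, bad), "shape")
})

test_that("viability-scale effect sizes back-transform both fits", {
  iso <- structure(list(theta_iso = matrix(log(1 / 9))),  # viability 0.1
                   class = "monotone_fit")
  add <- structure(list(theta_add = matrix(0)),           # viability 0.5
                   class = "additive_fit")
  expect_equal(effect_size_viability(iso, add)[1, 1], 0.4, tolerance = 1e-12)
  # swapped fits flip the sign (antagonism)
  iso2 <- structure(list(theta_iso = matrix(0)), class = "monotone_fit")
  add2 <- structure(list(theta_add = matrix(log(1 / 9))), class = "additive_fit")
  expect_equal(effect_size_viability(iso2, add2)[1, 1], -0.4,
               tolerance = 1e-12)
  # effect-size sign is opposite to the logit-scale delta sign
  set.seed(2)
  sr <- sir_surfaces(simulate_grid(5, 5, strength = 6, sigma = 0.1, seed = 2))
  nz <- abs(sr$delta) > 1e-12
  expect_true(all(sign(sr$s_sir[nz]) == -sign(sr$delta[nz])))
})

test_that("interaction energy and its normalization behave as defined", {
  expect_equal(interaction_energy(matrix(0, 2, 2), matrix(1, 2, 2)),
               list(S2 = 0, T = 0))
  en <- interaction_energy(matrix(1), matrix(2))
  expect_equal(en$S2, 2)
  expect_equal(en$T, 1)
  # constant delta: normalization cancels the weights entirely
  W <- matrix(runif(12, 0.1, 5), 3, 4)
  expect_equal(interaction_energy(matrix(0.7, 3, 4), W)$T, 0.49)
  # uniform weight rescaling leaves T unchanged
  d <- matrix(rnorm(12), 3, 4)
  expect_equal(interaction_energy(d, W)$T, interaction_energy(d, 37 * W)$T,
               tolerance = 1e-12)
  expect_error(interaction_energy(matrix(1), matrix(0)), "zero")
})

test_that("directional energies partition the total energy", {
  set.seed(8)
  d <- matrix(rnorm(20), 4, 5)
  W <- matrix(runif(20, 0.1, 2), 4, 5)
  dir <- directional_energy(d, W)
  expect_equal(dir$S2_syn + dir$S2_ant, interaction_energy(d, W)$S2)
  neg <- -abs(d)
  expect_equal(directional_energy(neg, W)$S2_ant, 0)
  expect_equal(directional_energy(matrix(c(-1, 1), 1, 2),
                                  matrix(1, 1, 2)),
               list(S2_syn = 1, S2_ant = 1))
})

test_that("residual inflation applies the variance-ratio correction", {
  out <- inflate_residuals(matrix(1), n_eff = 25, df_null = 9)
  expect_equal(out$inflation_ratio, 25 / 16)   # = 1.5625, ~1.56
  expect_equal(out$r_tilde[1, 1], sqrt(25 / 16))  # = 1.25
  expect_equal(inflate_residuals(matrix(0), 25, 9)$r_tilde[1, 1], 0)
  expect_error(inflate_residuals(matrix(1), 9, 9), "exceed")
  expect_error(inflate_residuals(matrix(1), 8, 9), "exceed")
})

test_that("noiseless additive data gives p = 1", {
  Z <- 1 + outer(c(0, -0.4, -0.9), c(0, -0.3, -0.8), "+")
  bt <- wild_bootstrap_test(transformed_grid(Z), B = 50, seed = 1)
  expect_lt(bt$T_obs, 1e-15)
  expect_equal(bt$p_value, 1)
})

test_that("the bootstrap is reproducible bit-for-bit under a fixed seed", {
  g <- simulate_grid(5, 5, strength = 3, sigma = 0.1, seed = 14)
  tg <- transform_responses(g)
  b1 <- wild_bootstrap_test(tg, B = 60, seed = 99)
  b2 <- wild_bootstrap_test(tg, B = 60, seed = 99)
  expect_identical(b1$T_star, b2$T_star)
  expect_identical(b1$p_value, b2$p_value)
  expect_identical(length(b1$T_star), 60L)
})

test_that("p-values respect the 1/(B+1) floor and attain it under strong signal", {
  g <- simulate_grid(8, 8, strength = 10, sigma = 0.1, seed = 5)
  res <- sir_test(g, B = 99, seed = 11)
  expect_equal(res$p_value, 1 / 100)
  expect_gte(res$p_value, 1 / (res$B + 1))
})

test_that("the null rejection rate never exceeds the nominal level", {
  # the df-corrected bootstrap errs on the conservative side; the binomial
  # upper bound at alpha = 0.05 must hold on null data
  nsim <- 25
  rej <- logical(nsim)
  for (k in 1:25) {
    set.seed(3000 + k)
    Z <- add_noise(generate_null_surface(6, 6)$theta, 0.1)
    rej[k] <- wild_bootstrap_test(transformed_grid(Z), B = 60)$p_value <= 0.05
  }
  expect_lte(mean(rej), qbinom(0.975, nsim, 0.05) / nsim)
})

test_that("Benjamini-Hochberg screening matches the step-up rule", {
  out <- bh_fdr(c(0.001, 0.5, 0.9), q = 0.05)
  expect_identical(out$reject, c(TRUE, FALSE, FALSE))
  expect_equal(out$p_adj, p.adjust(c(0.001, 0.5, 0.9), "BH"))
  expect_false(any(bh_fdr(rep(1, 5), q = 0.05)$reject))
  expect_true(bh_fdr(0.04, q = 0.05)$reject)
  # stratified correction operates within strata
  strat <- bh_fdr(c(0.01, 0.9, 0.01, 0.9), q = 0.05,
                  strata = c("a", "a", "b", "b"))
  expect_equal(strat$p_adj, c(0.02, 0.9, 0.02, 0.9))
  expect_warning(bh_fdr(rep(0.5, 100), q = 0.05, B = 200), "resolution")
})
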