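# monotone cone and monotone-additive projections

test_that("a monotone surface is its own projection", {
  Z <- outer(c(0, -0.5, -1.2), c(0, -0.3, -0.9), "+") + 2
  tg <- transformed_grid(Z, matrix(runif(9, 0.5, 2), 3, 3))
  fit <- fit_isotonic_2d(tg)
  expect_equal(fit$theta_iso, Z, tolerance = 1e-8)
  expect_lt(fit$objective, 1e-12)
})

test_that("2x2 checkerboard matches the hand-solved projection", {
  tg <- transformed_grid(matrix(c(1, 0, 0, 1), 2, 2), matrix(1, 2, 2))
  fit <- fit_isotonic_2d(tg)
  expect_equal(fit$theta_iso,
               matrix(c(1, 1 / 3, 1 / 3, 1 / 3), 2, 2), tolerance = 1e-7)
  expect_equal(fit$objective, 2 / 3, tolerance = 1e-7)
  add <- fit_monotone_additive(tg)
  expect_equal(add$alpha, 0.5, tolerance = 1e-7)
  expect_equal(add$u, c(0, 0), tolerance = 1e-7)
  expect_equal(add$v, c(0, 0), tolerance = 1e-7)
  expect_equal(add$objective, 1.0, tolerance = 1e-7)
})

test_that("weighted PAVA matches the max-min oracle on random 1D problems", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:9, 1)
    y <- rnorm(n)
    w <- runif(n, 0.1, 3)
    expect_equal(sirsynergy:::cpp_pava_decreasing(y, w),
                 oracle_pava_dec(y, w), tolerance = 1e-9)
  }
})

test_that("2D projection reduces to per-column PAVA when columns decouple", {
  # second column far below the first: cross-column constraints slack
  set.seed(7)
  z1 <- rnorm(6); z2 <- rnorm(6) - 50
  w <- matrix(runif(12, 0.2, 2), 6, 2)
  tg <- transformed_grid(cbind(z1, z2, deparse.level = 0), w)
  fit <- fit_isotonic_2d(tg)
  expect_equal(fit$theta_iso[, 1], oracle_pava_dec(z1, w[, 1]),
               tolerance = 1e-6)
  expect_equal(fit$theta_iso[, 2], oracle_pava_dec(z2, w[, 2]),
               tolerance = 1e-6)
})

test_that("2D projection matches exhaustive KKT enumeration on random 3x3 grids", {
  set.seed(11)
  for (rep in 1:4) {
    tg <- random_tgrid(3, 3, weights = if (rep %% 2) "unit" else "random")
    fit <- fit_isotonic_2d(tg)
    oracle <- oracle_iso2d(tg$Z, tg$W)
    expect_equal(fit$theta_iso, oracle$theta, tolerance = 1e-6)
    expect_equal(fit$objective, oracle$objective, tolerance = 1e-6)
  }
})

test_that("additive fit recovers an exactly additive surface", {
  u <- c(0, -0.5, -1); v <- c(0, -0.3, -0.6)
  Z <- 2 + outer(u, v, "+")
  add <- fit_monotone_additive(transformed_grid(Z, matrix(1, 3, 3)))
  expect_equal(add$alpha, 2, tolerance = 1e-8)
  expect_equal(add$u, u, tolerance = 1e-8)
  expect_equal(add$v, v, tolerance = 1e-8)
  expect_lt(add$objective, 1e-12)
  expect_true(all(diff(add$u) <= 1e-10))
  expect_true(all(diff(add$v) <= 1e-10))
  expect_identical(add$u[1], 0)
  expect_identical(add$v[1], 0)
})

test_that("additive fit of a constant surface is the intercept alone", {
  add <- fit_monotone_additive(transformed_grid(matrix(1.7, 4, 5)))
  expect_equal(add$alpha, 1.7, tolerance = 1e-10)
  expect_equal(add$u, rep(0, 4), tolerance = 1e-10)
  expect_equal(add$v, rep(0, 5), tolerance = 1e-10)
})

test_that("additive fit equals the unconstrained two-way fit when monotone", {
  # steep monotone signal: constraints slack, so the projection must agree
  # with ordinary least squares on row/column indicators
  set.seed(3)
  Z <- generate_null_surface(5, 6, seed = 10)$theta +
    matrix(rnorm(30, 0, 0.05), 5, 6)
  add <- fit_monotone_additive(transformed_grid(Z, matrix(1, 5, 6)))
  lmfit <- lm(z ~ r + c, data.frame(z = c(Z), r = factor(row(Z)),
                                    c = factor(col(Z))))
  expect_equal(add$objective, sum(resid(lmfit)^2), tolerance = 1e-9)
})

test_that("the additive class is nested in the monotone cone", {
  set.seed(5)
  for (rep in 1:60) {
    tg <- random_tgrid(sample(3:5, 1), sample(3:5, 1),
                       weights = if (rep %% 2) "unit" else "random")
    iso <- fit_isotonic_2d(tg)
    add <- suppressWarnings(fit_monotone_additive(tg))
    expect_gte(add$objective, iso$objective - 1e-8)
    # additive surface is itself monotone in both directions
    expect_true(all(diff(add$theta_add) <= 1e-10))
    expect_true(all(t(diff(t(add$theta_add))) <= 1e-10))
  }
})

test_that("projections are positively scale-equivariant and idempotent", {
  set.seed(9)
  tg <- random_tgrid(4, 4, "random")
  fit <- fit_isotonic_2d(tg)
  fit3 <- fit_isotonic_2d(transformed_grid(3 * tg$Z, tg$W))
  expect_equal(fit3$theta_iso, 3 * fit$theta_iso, tolerance = 1e-7)
  refit <- fit_isotonic_2d(transformed_grid(fit$theta_iso, tg$W))
  expect_equal(refit$theta_iso, fit$theta_iso, tolerance = 1e-8)
  expect_lt(refit$objective, 1e-12)
})

test_that("effective df counts distinct monotone levels minus the shared intercept", {
  fake <- function(u, v) structure(list(u = u, v = v), class = "additive_fit")
  expect_identical(effective_df(fake(c(0, -1, -2, -3, -4),
                                     c(0, -.5, -1, -1.5, -2))), 9L)
  expect_identical(effective_df(fake(rep(0, 5), rep(0, 5))), 1L)
  expect_identical(effective_df(fake(c(0, -0.2, -0.2, -0.5),
                                     c(0, 0, -0.1, -0.3))), 5L)
  # near-ties merge at the level tolerance: u has 2 levels, v has 2
  expect_identical(effective_df(fake(c(0, -1e-9, -1), c(0, -1))), 3L)
})

test_that("missing interior wells on a uniform-step additive surface are recovered exactly", {
  a <- 0.4; b <- 0.25
  theta <- 2 + outer(-a * (0:4), -b * (0:4), "+")
  Y <- inverse_transform(theta)
  Y[3, 3] <- NA; Y[2, 4] <- NA
  g <- dose_grid(Y, 1:5, 1:5)
  pred <- predict_missing(g)
  truth <- inverse_transform(theta)
  expect_equal(pred$Y_hat[3, 3], truth[3, 3], tolerance = 1e-6)
  expect_equal(pred$Y_hat[2, 4], truth[2, 4], tolerance = 1e-6)
  expect_identical(nrow(pred$predicted), 2L)
})

test_that("a missing corner uses its one-sided envelope and stays within bounds", {
  theta <- 1 + outer(-0.5 * (0:3), -0.4 * (0:3), "+")
  Y <- inverse_transform(theta)
  Y[4, 4] <- NA
  g <- dose_grid(Y, 1:4, 1:4)
  expect_warning(pred <- predict_missing(g), "one-sided")
  expect_lte(pred$Y_hat[4, 4], min(Y[3, 4], Y[4, 3]) + 1e-9)
  expect_gt(pred$Y_hat[4, 4], 0)
})
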