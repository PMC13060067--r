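#' Simulation configuration
#'
#' Collects the settings of the synthetic calibration and power studies:
#' 8 x 8 grids, Gaussian noise with sd 0.1 on the logit scale, B = 200
#' bootstrap resamples, 200 null simulations for calibration and 30 per
#' strength for power, at test level 0.05. The five equally spaced bump
#' strengths \{2, 4, 6, 8, 10\} logit units were fixed once by the design
#' requirement that the power curve span near-null to saturated (> 95%)
#' rejection at this noise level: the cone projection smears most of a
#' localized bump's nominal amplitude, so effective departures are much
#' smaller than the amplitudes suggest.
#'
#' @param I,J grid dimensions.
#' @param sigma noise sd on the transform (logit) scale.
#' @param B bootstrap resamples per test.
#' @param n_null_sims simulations for the calibration study.
#' @param n_power_sims simulations per strength for the power study.
#' @param strengths ascending bump amplitudes (logit units); may start
#'   at 0.
#' @param alpha test level used when reporting rejection rates.
#' @param seed master seed; every simulation derives its own substream
#'   seed from it, so results are independent of execution order.
#' @param tau variance floor used to build uniform weights.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(I = 8L, J = 8L, sigma = 0.1, B = 200L,
                              n_null_sims = 200L, n_power_sims = 30L,
                              strengths = c(2, 4, 6, 8, 10),
                              alpha = 0.05, seed = 1L, tau = 1e-6) {
  stopifnot(I >= 2L, J >= 2L, sigma > 0, B >= 1L, alpha > 0, alpha < 1,
            !is.unsorted(strengths), all(strengths >= 0))
  structure(list(I = as.integer(I), J = as.integer(J), sigma = sigma,
                 B = as.integer(B), n_null_sims = as.integer(n_null_sims),
                 n_power_sims = as.integer(n_power_sims),
                 strengths = strengths, alpha = alpha,
                 seed = as.integer(seed), tau = tau),
            class = "simulation_config")
}

#' Random monotone-additive null surface
#'
#' Draws an exact member of the monotone-additive class on the logit
#' scale: intercept `alpha ~ Uniform(0.5, 2)` and row/column effects
#' built as cumulative sums of non-positive increments
#' `-|N(0.4, 0.2^2)|`, so `u[1] = v[1] = 0` and both effects are
#' non-increasing by construction. The ranges are chosen so the
#' back-transformed surfaces span realistic viability (near 1 at the
#' lowest doses, dropping towards 0 at the highest).
#'
#' @param I,J grid dimensions.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (as the study drivers do after seeding their substream).
#' @return List with `alpha`, `u`, `v` and the `I x J` matrix `theta`.
#' @export
generate_null_surface <- function(I, J, seed = NULL) {
  stopifnot(I >= 2L, J >= 2L)
  if (!is.null(seed)) set.seed(seed)
  alpha <- stats::runif(1, 0.5, 2)
  u <- c(0, cumsum(-abs(stats::rnorm(I - 1L, 0.4, 0.2))))
  v <- c(0, cumsum(-abs(stats::rnorm(J - 1L, 0.4, 0.2))))
  list(alpha = alpha, u = u, v = v,
       theta = alpha + outer(u, v, "+"))
}

#' Inject a cone-projected interaction bump
#'
#' Adds a localized Gaussian bump of the given amplitude, oriented
#' towards synergy (lower viability), to a surface and projects the
#' result back onto the monotone cone so the alternative remains a
#' model-consistent monotone surface. Strength 0 returns the input
#' surface (a cone member projects to itself).
#'
#' @param null_surface `I x J` matrix on the transform scale (typically
#'   `generate_null_surface()$theta`).
#' @param strength bump amplitude (logit units), `>= 0`.
#' @param center bump center `c(ci, cj)`; defaults to the grid midpoint.
#' @param width kernel sd in grid units; defaults to `I / 4`.
#' @return `I x J` matrix lying in the monotone cone.
#' @export
inject_interaction <- function(null_surface, strength, center = NULL,
                               width = NULL) {
  stopifnot(is.matrix(null_surface), strength >= 0)
  I <- nrow(null_surface); J <- ncol(null_surface)
  if (is.null(center)) center <- c((I + 1) / 2, (J + 1) / 2)
  if (is.null(width)) width <- I / 4
  G <- outer(seq_len(I), seq_len(J), function(i, j)
    exp(-((i - center[1L])^2 + (j - center[2L])^2) / (2 * width^2)))
  bumped <- null_surface - strength * G
  tg <- transformed_grid(bumped, W = matrix(1, I, J))
  fit_isotonic_2d(tg)$theta_iso
}

#' Add Gaussian noise on the transform scale
#'
#' @param surface matrix on the transform scale.
#' @param sigma noise sd, `> 0`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return Matrix of noisy responses.
#' @export
add_noise <- function(surface, sigma, seed = NULL) {
  stopifnot(is.matrix(surface), sigma > 0)
  if (!is.null(seed)) set.seed(seed)
  surface + matrix(stats::rnorm(length(surface), 0, sigma),
                   nrow(surface), ncol(surface))
}

#' Simulate one dose-response grid as viability data
#'
#' Convenience wrapper tying the generator together: a random
#' monotone-additive null surface, an optional cone-projected
#' interaction bump, Gaussian logit-scale noise, and back-transformation
#' to viability on a geometric dose ladder.
#'
#' @param I,J grid dimensions.
#' @param strength bump amplitude (0 = null data).
#' @param sigma noise sd on the logit scale.
#' @param seed optional seed.
#' @param spec response transform used for the back-transformation.
#' @return A [dose_grid].
#' @export
simulate_grid <- function(I = 8L, J = 8L, strength = 0, sigma = 0.1,
                          seed = NULL, spec = transform_spec()) {
  if (!is.null(seed)) set.seed(seed)
  surf <- generate_null_surface(I, J)$theta
  if (strength > 0) surf <- inject_interaction(surf, strength)
  Z <- add_noise(surf, sigma)
  Y <- inverse_transform(Z, spec)
  Y <- pmin(pmax(Y, 0), 1)
  dose_grid(Y, conc_row = 2^(seq_len(I) - 1L), conc_col = 2^(seq_len(J) - 1L),
            drug_row = "sim_drug_A", drug_col = "sim_drug_B")
}

#' Pseudo-null data from a fitted null
#'
#' Builds a dataset with no true interaction by construction: fit the
#' monotone-additive null, inflate its residuals by the df correction,
#' flip their signs with independent Rademacher variables, and add them
#' back to the fitted null surface. Running the full test on many
#' pseudo-null datasets checks p-value calibration on data with the
#' original noise structure.
#'
#' @param tg a [transformed_grid].
#' @param seed optional seed.
#' @return A [transformed_grid] carrying the pseudo-null responses, with
#'   the same weights and missingness pattern as the input.
#' @export
pseudo_null_from_fit <- function(tg, seed = NULL) {
  stopifnot(is_transformed_grid(tg))
  if (!is.null(seed)) set.seed(seed)
  add <- fit_monotone_additive(tg)
  obs <- tg$W > 0
  r <- matrix(0, nrow(tg$Z), ncol(tg$Z))
  r[obs] <- tg$Z[obs] - add$theta_add[obs]
  infl <- inflate_residuals(r, n_eff = tg$n_eff, df_null = add$df_null)
  xi <- matrix(sample(c(-1, 1), length(r), replace = TRUE), nrow(r), ncol(r))
  Zp <- tg$Z
  Zp[obs] <- add$theta_add[obs] + xi[obs] * infl$r_tilde[obs]
  transformed_grid(Zp, tg$W, spec = tg$spec, tau = tg$tau)
}

#' Type I error calibration study
#'
#' Generates `n_null_sims` independent monotone-additive null grids with
#' Gaussian noise, runs the full df-corrected wild bootstrap test on
#' each, and summarizes the p-value distribution: empirical rejection
#' rate at `alpha`, and whether the p-value ECDF stays inside the 95%
#' Dvoretzky-Kiefer-Wolfowitz band around Uniform(0, 1), the signature
#' of a calibrated test.
#'
#' @param cfg a [simulation_config].
#' @return List: `p_values`, `rejection_rate`, `alpha`, `dkw_eps` (band
#'   half-width), `sup_deviation` (worst ECDF departure from uniform),
#'   `within_band`, `config`.
#' @export
run_calibration_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  p <- numeric(cfg$n_null_sims)
  for (k in seq_len(cfg$n_null_sims)) {
    set.seed(substream_seed(cfg$seed, k))
    surf <- generate_null_surface(cfg$I, cfg$J)$theta
    Z <- add_noise(surf, cfg$sigma)
    tg <- transformed_grid(Z, tau = cfg$tau)
    p[k] <- wild_bootstrap_test(tg, B = cfg$B)$p_value
  }
  n <- length(p)
  sp <- sort(p)
  sup_dev <- max(pmax(abs(seq_len(n) / n - sp), abs((seq_len(n) - 1) / n - sp)))
  dkw <- sqrt(log(2 / 0.05) / (2 * n))
  list(p_values = p, rejection_rate = mean(p <= cfg$alpha),
       alpha = cfg$alpha, dkw_eps = dkw, sup_deviation = sup_dev,
       within_band = sup_dev <= dkw, config = cfg)
}

#' Power study over increasing interaction strengths
#'
#' For each bump strength, generates `n_power_sims` grids (null surface
#' plus cone-projected bump plus noise), tests each, and reports the
#' rejection rate at `alpha`.
#'
#' @param cfg a [simulation_config].
#' @return Data frame with `strength`, `power`, `n_sims`, `alpha`.
#' @export
run_power_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  out <- data.frame(strength = cfg$strengths,
                    power = NA_real_,
                    n_sims = cfg$n_power_sims,
                    alpha = cfg$alpha)
  for (s in seq_along(cfg$strengths)) {
    rej <- logical(cfg$n_power_sims)
    for (k in seq_len(cfg$n_power_sims)) {
      set.seed(substream_seed(cfg$seed, 100000L * s + k))
      surf <- generate_null_surface(cfg$I, cfg$J)$theta
      if (cfg$strengths[s] > 0)
        surf <- inject_interaction(surf, cfg$strengths[s])
      Z <- add_noise(surf, cfg$sigma)
      tg <- transformed_grid(Z, tau = cfg$tau)
      rej[k] <- wild_bootstrap_test(tg, B = cfg$B)$p_value <= cfg$alpha
    }
    out$power[s] <- mean(rej)
  }
  out
}
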