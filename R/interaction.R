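#' Interaction surface
#'
#' The difference between the unconstrained monotone fit and the
#' monotone-additive null fit on the transform scale,
#' `delta = theta_iso - theta_add`. Negative values mean the combination
#' lowers viability below the additive expectation (synergy); positive
#' values mean antagonism. No monotonicity constraint applies to delta:
#' synergy and antagonism may coexist across the grid.
#'
#' @param iso a `monotone_fit`.
#' @param add an `additive_fit` on the same grid.
#' @return `I x J` matrix of interaction values on the transform scale.
#' @export
interaction_surface <- function(iso, add) {
  stopifnot(inherits(iso, "monotone_fit"), inherits(add, "additive_fit"))
  if (!identical(dim(iso$theta_iso), dim(add$theta_add)))
    stop("fits are on different grid shapes", call. = FALSE)
  iso$theta_iso - add$theta_add
}

#' Viability-scale effect sizes
#'
#' Back-transforms both fitted surfaces and takes the difference
#' `inverse(theta_add) - inverse(theta_iso)`, so positive values mean
#' the combination kills more cells than the additive prediction
#' (synergy), in directly interpretable viability units.
#'
#' @inheritParams interaction_surface
#' @param spec the [transform_spec] both surfaces were fitted under.
#' @return `I x J` matrix of effect sizes on the viability scale.
#' @export
effect_size_viability <- function(iso, add, spec = transform_spec()) {
  stopifnot(inherits(iso, "monotone_fit"), inherits(add, "additive_fit"))
  inverse_transform(add$theta_add, spec) - inverse_transform(iso$theta_iso, spec)
}

#' Global interaction energy
#'
#' `S2 = sum w_ij delta_ij^2` measures the weighted squared departure
#' from additivity over the whole grid; `T = S2 / sum w_ij` is its
#' grid-size- and weight-normalised version used as the test statistic.
#' Wells with zero weight contribute nothing.
#'
#' @param delta interaction matrix, see [interaction_surface].
#' @param W nonnegative weight matrix of the same shape.
#' @return A list with `S2` and `T`.
#' @export
interaction_energy <- function(delta, W) {
  if (!identical(dim(delta), dim(W)))
    stop("delta and W shapes differ", call. = FALSE)
  if (sum(W) <= 0) stop("all weights are zero", call. = FALSE)
  d <- ifelse(W > 0, delta, 0)
  S2 <- sum(W * d^2)
  list(S2 = S2, T = S2 / sum(W))
}

#' Directional interaction energies
#'
#' Splits the interaction energy by sign of delta: `S2_syn` accumulates
#' the synergistic cells (`delta < 0`, viability below additive) and
#' `S2_ant` the antagonistic cells (`delta > 0`). They always sum to the
#' total energy.
#'
#' @inheritParams interaction_energy
#' @return A list with `S2_syn` and `S2_ant`.
#' @export
directional_energy <- function(delta, W) {
  if (!identical(dim(delta), dim(W)))
    stop("delta and W shapes differ", call. = FALSE)
  d <- ifelse(W > 0, delta, 0)
  list(S2_syn = sum(W * d^2 * (d < 0)),
       S2_ant = sum(W * d^2 * (d > 0)))
}

#' Degrees-of-freedom residual inflation
#'
#' Residuals from the fitted null underestimate the true noise because
#' the fit passes closer to the data than the true surface would.
#' Resampling them unchanged would make the bootstrap world too quiet
#' and the test anti-conservative. Analogous to the `n / (n - p)`
#' variance correction in linear regression, residuals are scaled by
#' `sqrt(n_eff / (n_eff - df_null))` so that the resampled error
#' *variance* is inflated by `n_eff / (n_eff - df_null)`.
#'
#' @param r residual matrix (or vector) on the transform scale.
#' @param n_eff number of positively weighted wells.
#' @param df_null effective df of the null fit, see [effective_df].
#' @return List with `r_tilde` (corrected residuals) and
#'   `inflation_ratio` (the variance ratio `n_eff / (n_eff - df_null)`).
#' @examples
#' inflate_residuals(matrix(1), n_eff = 25, df_null = 9)$inflation_ratio # 1.5625
#' @export
inflate_residuals <- function(r, n_eff, df_null) {
  if (!(n_eff > df_null))
    stop(sprintf(paste0("cannot inflate residuals: n_eff (%d) must exceed ",
                        "df_null (%d); the grid is too small or too sparse ",
                        "for the bootstrap test"), n_eff, df_null),
         call. = FALSE)
  if (df_null < 1) stop("df_null must be >= 1", call. = FALSE)
  ratio <- n_eff / (n_eff - df_null)
  list(r_tilde = r * sqrt(ratio), inflation_ratio = ratio)
}

#' Wild bootstrap test for interaction
#'
#' Tests the null of monotone additivity with a Rademacher wild
#' bootstrap. The null model is fitted, its residuals are inflated by
#' the df correction ([inflate_residuals]), and `B` pseudo-datasets
#' `Z* = theta_add + xi * r_tilde` are generated with independent random
#' signs `xi` in {-1, +1} per well per resample. Both models are refitted
#' on every `Z*` with the original weights and the normalised interaction
#' energy `T` is recomputed; the p-value is
#' `(1 + #\{T*_b >= T_obs\}) / (B + 1)`, so its smallest achievable value
#' is `1 / (B + 1)`.
#'
#' A solver failure inside a resample is retried once and then counted as
#' `T* = +Inf` (which can only increase the p-value) with a warning.
#'
#' @param tg a [transformed_grid].
#' @param B number of bootstrap resamples (default 200, adequate for
#'   exploratory screens; use 1000-5000 for confirmatory analyses).
#' @param seed optional integer seed making the draw reproducible.
#' @param tol solver tolerance passed to both fits.
#' @return An object of class `bootstrap_test`: `T_obs`, `T_star`
#'   (length `B`), `p_value`, `B`, `seed`, `inflation` (variance ratio),
#'   `df_null`, `n_eff`, plus the observed `iso` and `add` fits.
#' @export
wild_bootstrap_test <- function(tg, B = 200L, seed = NULL, tol = 1e-8) {
  stopifnot(is_transformed_grid(tg), B >= 1L)
  if (!is.null(seed)) set.seed(seed)
  add <- fit_monotone_additive(tg, tol = tol)
  iso <- fit_isotonic_2d(tg, tol = tol)
  delta <- interaction_surface(iso, add)
  en <- interaction_energy(delta, tg$W)
  T_obs <- en$T

  obs <- tg$W > 0
  r <- matrix(0, nrow(tg$Z), ncol(tg$Z))
  r[obs] <- tg$Z[obs] - add$theta_add[obs]
  infl <- inflate_residuals(r, n_eff = tg$n_eff, df_null = add$df_null)
  r_tilde <- infl$r_tilde

  n_obs <- sum(obs)
  T_star <- numeric(B)
  failed <- 0L
  for (b in seq_len(B)) {
    xi <- sample(c(-1, 1), n_obs, replace = TRUE)
    Zb <- tg$Z
    Zb[obs] <- add$theta_add[obs] + xi * r_tilde[obs]
    tgb <- transformed_grid(Zb, tg$W, spec = tg$spec, tau = tg$tau)
    Tb <- tryCatch(bootstrap_statistic(tgb, tol),
                   error = function(e) tryCatch(bootstrap_statistic(tgb, tol),
                                                error = function(e2) Inf))
    if (!is.finite(Tb)) failed <- failed + 1L
    T_star[b] <- Tb
  }
  if (failed > 0L)
    warning(sprintf("%d of %d bootstrap resamples failed to converge and ",
                    failed, B),
            "were counted as T* = Inf (conservative)", call. = FALSE)
  # ties at T_obs count as exceedances; the tolerance keeps exact-null
  # data (all residuals zero) from splitting ties on rounding noise
  p <- (1 + sum(T_star >= T_obs - 1e-12)) / (B + 1)
  structure(list(T_obs = T_obs, T_star = T_star, p_value = p, B = B,
                 seed = seed, inflation = infl$inflation_ratio,
                 df_null = add$df_null, n_eff = tg$n_eff, S2 = en$S2,
                 iso = iso, add = add, delta = delta),
            class = "bootstrap_test")
}

bootstrap_statistic <- function(tgb, tol) {
  addb <- suppressWarnings(fit_monotone_additive(tgb, tol = tol))
  isob <- fit_isotonic_2d(tgb, tol = tol)
  interaction_energy(isob$theta_iso - addb$theta_add, tgb$W)$T
}

#' @export
print.bootstrap_test <- function(x, ...) {
  cat(sprintf("wild bootstrap interaction test (B = %d)\n", x$B))
  cat(sprintf("  T_obs = %.5g, S2 = %.5g\n", x$T_obs, x$S2))
  cat(sprintf("  df_null = %d, n_eff = %d, variance inflation = %.4g\n",
              x$df_null, x$n_eff, x$inflation))
  cat(sprintf("  p-value = %.4g (floor %.4g)\n", x$p_value, 1 / (x$B + 1)))
  invisible(x)
}

#' Benjamini-Hochberg FDR over a screen of p-values
#'
#' Step-up FDR control applied to per-matrix bootstrap p-values, either
#' globally or within strata (e.g. cell line or plate, whose matrices
#' share noise levels and hence a more homogeneous p-value
#' distribution). Warns when the requested level is finer than the
#' bootstrap p-value resolution `1 / (B + 1)` can support.
#'
#' @param pvalues vector of p-values in `(0, 1]`.
#' @param q target FDR level (default 0.05).
#' @param strata optional factor of the same length; correction is
#'   applied within each stratum.
#' @param B optional bootstrap resample count used to produce the
#'   p-values, enabling the resolution warning.
#' @return Data frame with `p`, `p_adj`, `reject` (and `stratum` when
#'   stratified), in input order.
#' @export
bh_fdr <- function(pvalues, q = 0.05, strata = NULL, B = NULL) {
  stopifnot(is.numeric(pvalues), all(pvalues > 0 & pvalues <= 1),
            q > 0, q < 1)
  n <- length(pvalues)
  if (!is.null(B) && q / n < 1 / (B + 1))
    warning(sprintf("FDR level q/M = %.3g is below the bootstrap p-value ",
                    q / n),
            sprintf("resolution 1/(B+1) = %.3g; increase B", 1 / (B + 1)),
            call. = FALSE)
  if (is.null(strata)) {
    p_adj <- stats::p.adjust(pvalues, method = "BH")
    out <- data.frame(p = pvalues, p_adj = p_adj, reject = p_adj <= q)
  } else {
    stopifnot(length(strata) == n)
    p_adj <- numeric(n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      p_adj[idx] <- stats::p.adjust(pvalues[idx], method = "BH")
    }
    out <- data.frame(p = pvalues, p_adj = p_adj, reject = p_adj <= q,
                      stratum = strata)
  }
  out
}
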