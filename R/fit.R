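#' Weighted 2D isotonic regression
#'
#' Projects the transformed responses onto the monotone cone: surfaces
#' non-increasing along every row and every column of the dose grid
#' (viability cannot rise with more drug). The weighted least-squares
#' projection is computed by Dykstra's alternating-projection algorithm,
#' where each half-projection (row-monotone, column-monotone) is an exact
#' weighted pool-adjacent-violators step; the iterates converge to the
#' unique projection onto the intersection.
#'
#' Missing wells enter as (numerically) free variables: they receive a
#' vanishing weight during the projection and are afterwards resolved
#' deterministically to the midpoint of their tightest monotone envelope
#' (max of fitted values that must lie below, min of those that must lie
#' above), computed by two monotone sweeps.
#'
#' @param tg a [transformed_grid].
#' @param tol convergence tolerance on the fitted surface (sup-norm
#'   between successive Dykstra cycles is driven two orders below this).
#' @param max_iter iteration cap for the solver.
#' @return An object of class `monotone_fit`: `theta_iso` (fitted matrix,
#'   all cells resolved), `objective` (weighted SSE over observed wells),
#'   `solver_status`, `iterations`, `tol`.
#' @examples
#' tg <- transformed_grid(matrix(c(1, 0, 0, 1), 2, 2))
#' fit_isotonic_2d(tg)$theta_iso
#' @export
fit_isotonic_2d <- function(tg, tol = 1e-8, max_iter = 20000L) {
  stopifnot(is_transformed_grid(tg), tol > 0)
  if (tg$n_eff < 1L) stop("no positively weighted wells", call. = FALSE)
  Z <- tg$Z; W <- tg$W
  obs <- W > 0
  Zfill <- Z
  Wfit <- W
  if (any(!obs)) {
    mu <- sum(W[obs] * Z[obs]) / sum(W[obs])
    Zfill[!obs] <- mu
    # vanishing weight keeps the projection strictly convex while leaving
    # the observed-cell solution unchanged to well below tol
    Wfit[!obs] <- 1e-10 * mean(W[obs])
  }
  res <- cpp_iso2d(Zfill, Wfit, tol = tol * 1e-2, max_iter = max_iter)
  if (!res$converged)
    stop(sprintf(paste0("2D isotonic projection did not converge ",
                        "(%d iterations, last change above %g)"),
                 res$iterations, tol * 1e-2), call. = FALSE)
  theta <- res$theta
  if (any(!obs)) theta <- resolve_free_cells(theta, obs)
  objective <- sum(W[obs] * (Z[obs] - theta[obs])^2)
  structure(list(theta_iso = theta, objective = objective,
                 solver_status = "converged", iterations = res$iterations,
                 max_violation = res$max_violation, tol = tol),
            class = "monotone_fit")
}

# Midpoint-of-envelope resolution for free (unobserved) cells of a
# monotone non-increasing surface. Cells north-west of (i, j) bound it
# from above, cells south-east bound it from below; two sweeps propagate
# the tightest bounds. One-sided envelopes (fully missing row/column
# beyond the cell) fall back to the available bound with a warning.
resolve_free_cells <- function(theta, obs) {
  I <- nrow(theta); J <- ncol(theta)
  UB <- matrix(Inf, I, J); LB <- matrix(-Inf, I, J)
  for (i in seq_len(I)) for (j in seq_len(J)) {
    ub <- if (obs[i, j]) theta[i, j] else Inf
    if (i > 1L) ub <- min(ub, UB[i - 1L, j])
    if (j > 1L) ub <- min(ub, UB[i, j - 1L])
    UB[i, j] <- ub
  }
  for (i in rev(seq_len(I))) for (j in rev(seq_len(J))) {
    lb <- if (obs[i, j]) theta[i, j] else -Inf
    if (i < I) lb <- max(lb, LB[i + 1L, j])
    if (j < J) lb <- max(lb, LB[i, j + 1L])
    LB[i, j] <- lb
  }
  one_sided <- FALSE
  for (i in seq_len(I)) for (j in seq_len(J)) {
    if (obs[i, j]) next
    lo <- LB[i, j]; hi <- UB[i, j]
    if (is.finite(lo) && is.finite(hi)) theta[i, j] <- (lo + hi) / 2
    else if (is.finite(hi)) { theta[i, j] <- hi; one_sided <- TRUE }
    else if (is.finite(lo)) { theta[i, j] <- lo; one_sided <- TRUE }
    else { theta[i, j] <- mean(theta[obs]); one_sided <- TRUE }
  }
  if (one_sided)
    warning("some missing wells have a one-sided monotone envelope; ",
            "their predictions use the available bound", call. = FALSE)
  theta
}

#' Monotone-additive null fit
#'
#' Projects the transformed responses onto the monotone-additive class:
#' surfaces of the form `theta_ij = alpha + u_i + v_j` with row effects
#' `u` and column effects `v` monotone non-increasing and pinned by
#' `u[1] = v[1] = 0`. This nested subclass of the monotone cone encodes
#' "no interaction": each drug contributes its own monotone effect. The
#' weighted least-squares projection is computed by block coordinate
#' descent with exact weighted pool-adjacent-violators block updates.
#'
#' @inheritParams fit_isotonic_2d
#' @param level_tol tolerance used to merge near-tied fitted levels when
#'   counting effective degrees of freedom (see [effective_df]).
#' @return An object of class `additive_fit`: `alpha`, `u`, `v`,
#'   `theta_add`, `objective`, `df_null`, `solver_status`, `iterations`.
#' @export
fit_monotone_additive <- function(tg, tol = 1e-8, max_iter = 5000L,
                                  level_tol = 1e-6) {
  stopifnot(is_transformed_grid(tg), tol > 0)
  Z <- tg$Z; W <- tg$W
  I <- nrow(Z); J <- ncol(Z)
  if (tg$n_eff < I + J - 1L)
    warning(sprintf("only %d observed wells for %d additive parameters; ",
                    tg$n_eff, I + J - 1L),
            "the null fit may be poorly determined", call. = FALSE)
  Zfill <- Z
  Zfill[W == 0] <- 0          # zero weight: value irrelevant, keep finite
  res <- cpp_additive(Zfill, W, tol = 1e-13, max_iter = max_iter)
  if (!res$converged)
    stop("monotone-additive fit did not converge", call. = FALSE)
  u <- res$u; v <- res$v
  alpha <- u[1L] + v[1L]
  u <- u - u[1L]; v <- v - v[1L]
  theta_add <- alpha + outer(u, rep(0, J), "+") + outer(rep(0, I), v, "+")
  fit <- structure(list(alpha = alpha, u = u, v = v, theta_add = theta_add,
                        objective = res$objective, df_null = NA_integer_,
                        solver_status = "converged",
                        iterations = res$iterations, tol = tol),
                   class = "additive_fit")
  fit$df_null <- effective_df(fit, level_tol = level_tol)
  fit
}

#' Effective degrees of freedom of the monotone-additive fit
#'
#' Monotone regression pools adjacent dose levels that violate
#' monotonicity into tied groups, so the number of parameters it
#' effectively spends is data-dependent. The effective df of the
#' additive null is approximated by counting distinct fitted levels in
#' the monotone main effects: `(#levels in u) + (#levels in v) - 1`, the
#' minus one removing the shared intercept level so that a 5x5 grid with
#' fully distinct marginals gives df 9. Levels within `level_tol` of
#' each other are merged (numerical solvers return near-ties rather than
#' exact ties). Lower-bounded by 1.
#'
#' @param fit an `additive_fit`.
#' @param level_tol absolute merge tolerance on the transform scale.
#' @return Integer df, at least 1.
#' @export
effective_df <- function(fit, level_tol = 1e-6) {
  stopifnot(inherits(fit, "additive_fit"), level_tol >= 0)
  nlev <- function(x) {
    if (length(x) <= 1L) return(1L)
    1L + sum(abs(diff(x)) > level_tol)
  }
  max(1L, nlev(fit$u) + nlev(fit$v) - 1L)
}

#' Predict missing wells from the fitted monotone surface
#'
#' Fits the 2D isotonic surface to the observed wells, resolves each
#' missing well to the midpoint of its tightest monotone envelope, and
#' back-transforms to viability. Pointwise synergy scores cannot do
#' this; an explicit surface model can.
#'
#' @param grid a [dose_grid] with at least one missing well.
#' @param spec response transform, logit by default.
#' @param tau,winsor_pct weight parameters, see [compute_weights].
#' @param tol solver tolerance.
#' @return A list: `Y_hat` (full fitted viability matrix), `predicted`
#'   (data frame of missing wells: `i`, `j`, concentrations, predicted
#'   viability) and `fit` (the underlying `monotone_fit`).
#' @export
predict_missing <- function(grid, spec = transform_spec(), tau = 1e-6,
                            winsor_pct = 99, tol = 1e-8) {
  stopifnot(is_dose_grid(grid))
  tg <- transform_responses(grid, spec = spec, tau = tau,
                            winsor_pct = winsor_pct)
  fit <- fit_isotonic_2d(tg, tol = tol)
  Y_hat <- inverse_transform(fit$theta_iso, spec)
  miss <- which(is.na(grid$Y), arr.ind = TRUE)
  predicted <- data.frame(
    i = miss[, 1L], j = miss[, 2L],
    conc_row = grid$conc_row[miss[, 1L]],
    conc_col = grid$conc_col[miss[, 2L]],
    viability = Y_hat[miss])
  list(Y_hat = Y_hat, predicted = predicted, fit = fit)
}
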