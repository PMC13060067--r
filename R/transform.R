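#' Response transform specification
#'
#' Viability lives in `[0, 1]`; model fitting happens on an unconstrained
#' scale. The logit link is the default: it maps the unit interval to the
#' whole real line, stabilises variance near the boundaries, and makes
#' additivity mean equal log-odds increments of cell survival. Identity,
#' asinh and log are available as sensitivity checks. Values are clamped
#' to `[eps, 1 - eps]` before the forward map so the transform is finite.
#'
#' @param name one of `"logit"`, `"identity"`, `"asinh"`, `"log"`.
#' @param eps clamp bound (default `1e-6`).
#' @return An object of class `transform_spec` with `forward` and
#'   `inverse` functions that are mutual inverses on the clamped range.
#' @examples
#' sp <- transform_spec()
#' sp$forward(0.9)   # log(9)
#' sp$inverse(0)     # 0.5
#' @export
transform_spec <- function(name = c("logit", "identity", "asinh", "log"),
                           eps = 1e-6) {
  name <- match.arg(name)
  stopifnot(is.numeric(eps), eps > 0, eps < 0.5)
  clamp <- function(y) pmin(pmax(y, eps), 1 - eps)
  maps <- switch(name,
    logit = list(
      forward = function(y) { y <- clamp(y); log(y / (1 - y)) },
      inverse = function(z) 1 / (1 + exp(-z))),
    identity = list(
      forward = function(y) clamp(y),
      inverse = function(z) z),
    asinh = list(
      forward = function(y) asinh(clamp(y)),
      inverse = function(z) sinh(z)),
    log = list(
      forward = function(y) log(clamp(y)),
      inverse = function(z) exp(z)))
  structure(c(list(name = name, eps = eps, clamp = clamp), maps),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("transform_spec: %s (eps = %g)\n", x$name, x$eps))
  invisible(x)
}

#' Inverse-variance well weights
#'
#' Wells with two or more replicates get `w = m / max(s2, tau)`, the
#' inverse-variance weight with a variance floor `tau` guarding against
#' degenerate (zero) sample variances. Wells with a single replicate, or
#' every well when the matrix carries no replicate variance at all, get
#' the floor weight `1 / tau` (uniform weighting). Positive weights are
#' then Winsorized (capped) at the `winsor_pct` percentile within the
#' matrix so that a few ultra-low-variance wells cannot dominate the fit.
#' Missing wells get weight 0.
#'
#' @param grid a [dose_grid].
#' @param tau variance floor, default `1e-6`.
#' @param winsor_pct Winsorization percentile in `(50, 100]`, default 99.
#' @return Nonnegative `I x J` weight matrix, 0 exactly at missing wells.
#' @export
compute_weights <- function(grid, tau = 1e-6, winsor_pct = 99) {
  stopifnot(is_dose_grid(grid), tau > 0,
            winsor_pct > 50, winsor_pct <= 100)
  obs <- !is.na(grid$Y)
  W <- matrix(0, nrow(grid$Y), ncol(grid$Y))
  has_var <- obs & grid$m >= 2L & !is.na(grid$s2)
  W[obs] <- 1 / tau                         # no variance information
  W[has_var] <- grid$m[has_var] / pmax(grid$s2[has_var], tau)
  pos <- W > 0
  if (any(pos)) {
    cap <- stats::quantile(W[pos], winsor_pct / 100, names = FALSE)
    W[pos] <- pmin(W[pos], cap)
  }
  W
}

#' Transform a dose grid to the modelling scale
#'
#' Applies the forward response transform to the (clamped) viability
#' matrix and attaches inverse-variance weights, producing the
#' transformed grid that all model fits consume.
#'
#' @inheritParams compute_weights
#' @param spec a [transform_spec]; logit by default.
#' @return An object of class `transformed_grid` with fields `Z`
#'   (transformed responses, `NA` at missing wells), `W` (weights, 0 at
#'   missing wells), `n_eff` (number of positively weighted wells),
#'   `spec`, `tau`, and the originating `grid`.
#' @examples
#' Y <- outer(c(0.95, 0.7, 0.4), c(0.9, 0.6, 0.3), pmin)
#' g <- dose_grid(Y, c(0.1, 1, 10), c(0.1, 1, 10))
#' tg <- transform_responses(g)
#' tg$n_eff
#' @export
transform_responses <- function(grid, spec = transform_spec(),
                                tau = 1e-6, winsor_pct = 99) {
  stopifnot(is_dose_grid(grid), inherits(spec, "transform_spec"))
  obs <- !is.na(grid$Y)
  if (!any(obs)) stop("degenerate input: all wells missing", call. = FALSE)
  Z <- matrix(NA_real_, nrow(grid$Y), ncol(grid$Y))
  Z[obs] <- spec$forward(grid$Y[obs])
  W <- compute_weights(grid, tau = tau, winsor_pct = winsor_pct)
  transformed_grid(Z, W, spec = spec, tau = tau, grid = grid)
}

#' Low-level transformed-grid constructor
#'
#' Assembles a `transformed_grid` directly from responses already on the
#' modelling scale (as the simulation drivers do). `Z` must be finite
#' wherever `W > 0`; `W` must be 0 exactly where `Z` is missing.
#'
#' @param Z matrix of transformed responses (`NA` at missing wells).
#' @param W nonnegative weight matrix; defaults to uniform `1/tau` at
#'   observed wells.
#' @param spec the [transform_spec] whose scale `Z` lives on.
#' @param tau variance floor used for the default weights.
#' @param grid optional originating [dose_grid].
#' @return An object of class `transformed_grid`.
#' @export
transformed_grid <- function(Z, W = NULL, spec = transform_spec(),
                             tau = 1e-6, grid = NULL) {
  Z <- as.matrix(Z); storage.mode(Z) <- "double"
  obs <- is.finite(Z)
  if (is.null(W)) W <- matrix(ifelse(obs, 1 / tau, 0), nrow(Z), ncol(Z))
  W <- as.matrix(W); storage.mode(W) <- "double"
  if (!identical(dim(W), dim(Z))) stop("Z and W dimensions differ")
  if (any(W < 0)) stop("weights must be nonnegative")
  if (any(W > 0 & !obs)) stop("Z must be finite wherever W > 0")
  Z[W == 0] <- NA_real_
  structure(list(Z = Z, W = W, n_eff = sum(W > 0), spec = spec,
                 eps = spec$eps, tau = tau, grid = grid),
            class = "transformed_grid")
}

#' @export
print.transformed_grid <- function(x, ...) {
  cat(sprintf("transformed_grid: %d x %d, n_eff = %d, transform = %s\n",
              nrow(x$Z), ncol(x$Z), x$n_eff, x$spec$name))
  invisible(x)
}

is_transformed_grid <- function(x) inherits(x, "transformed_grid")

#' Back-transform from the modelling scale to viability
#'
#' @param values numeric vector or matrix on the transform scale.
#' @param spec a [transform_spec].
#' @return Values mapped through the inverse transform; in `(0, 1)` for
#'   the logit link.
#' @export
inverse_transform <- function(values, spec = transform_spec()) {
  stopifnot(inherits(spec, "transform_spec"))
  spec$inverse(values)
}
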