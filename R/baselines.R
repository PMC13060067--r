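#' Bliss independence excess surface
#'
#' Bliss assumes the two drugs act on survival independently, so the
#' expected combination viability is the product of the monotherapy
#' viabilities, `E_ij = yA_i * yB_j`. The excess `E_ij - Y_ij` is
#' positive where the combination kills more than independence predicts
#' (synergy on the viability scale, matching the orientation of the
#' SIR effect sizes).
#'
#' Monotherapy responses are taken from the first row and first column
#' of the grid: when the design has explicit zero-dose anchors these are
#' the first entries after sorting, otherwise the lowest dose serves as
#' the monotherapy approximation (common screening convention).
#'
#' @param grid a [dose_grid] with fully observed first row and column.
#' @return `I x J` excess matrix (`NA` at missing wells).
#' @export
bliss_surface <- function(grid) {
  stopifnot(is_dose_grid(grid))
  yA <- grid$Y[, 1L]; yB <- grid$Y[1L, ]
  if (anyNA(yA) || anyNA(yB))
    stop("missing monotherapy anchors: the first row and column must be ",
         "observed to compute a Bliss surface", call. = FALSE)
  outer(yA, yB) - grid$Y
}

#' Highest-single-agent (HSA) excess surface
#'
#' Compares the combination to the more active single agent at each dose
#' pair: excess `min(yA_i, yB_j) - Y_ij`, positive when the combination
#' outperforms the best monotherapy (synergy on the viability scale).
#'
#' @inheritParams bliss_surface
#' @return `I x J` excess matrix (`NA` at missing wells).
#' @export
hsa_surface <- function(grid) {
  stopifnot(is_dose_grid(grid))
  yA <- grid$Y[, 1L]; yB <- grid$Y[1L, ]
  if (anyNA(yA) || anyNA(yB))
    stop("missing monotherapy anchors: the first row and column must be ",
         "observed to compute an HSA surface", call. = FALSE)
  outer(yA, yB, pmin) - grid$Y
}

#' Both pointwise baseline surfaces with matrix-level summaries
#'
#' @inheritParams bliss_surface
#' @return List: `bliss_excess`, `hsa_excess`, `summary_bliss`,
#'   `summary_hsa` (means over non-missing wells).
#' @export
baseline_surfaces <- function(grid) {
  be <- bliss_surface(grid)
  he <- hsa_surface(grid)
  list(bliss_excess = be, hsa_excess = he,
       summary_bliss = mean(be, na.rm = TRUE),
       summary_hsa = mean(he, na.rm = TRUE))
}

#' Replicate concordance of two surfaces
#'
#' Pearson correlation between two surfaces (e.g. interaction surfaces
#' from independent experiments on the same drug pair and cell line)
#' over their jointly non-missing cells. A reproducible method should
#' give highly correlated surfaces across replicates.
#'
#' @param surfA,surfB matrices of the same shape.
#' @return Pearson r, or `NA` (with a warning) when either surface is
#'   constant over the joint support.
#' @export
replicate_concordance <- function(surfA, surfB) {
  if (!identical(dim(surfA), dim(surfB)))
    stop("surfaces have different shapes", call. = FALSE)
  ok <- is.finite(surfA) & is.finite(surfB)
  if (sum(ok) < 3L)
    stop("need at least 3 jointly observed cells", call. = FALSE)
  a <- surfA[ok]; b <- surfB[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant surface: replicate correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Disagreement statistics between two score vectors
#'
#' Quantifies how much two matrix-level synergy scorings of the same
#' screen disagree: Pearson correlation, sign-disagreement rate (the
#' fraction of matrices where exactly one score calls synergy, i.e. is
#' positive), and the Jaccard overlap of the top `top_frac` most
#' synergistic calls of each ranking.
#'
#' @param scoresA,scoresB numeric vectors of equal length.
#' @param top_frac fraction defining the top-hit sets (default 0.05).
#' @return List: `pearson`, `sign_disagreement`, `jaccard_top`.
#' @export
score_disagreement <- function(scoresA, scoresB, top_frac = 0.05) {
  if (length(scoresA) != length(scoresB))
    stop("score vectors have different lengths", call. = FALSE)
  stopifnot(top_frac > 0, top_frac <= 1)
  n <- length(scoresA)
  k <- ceiling(top_frac * n)
  topA <- order(scoresA, decreasing = TRUE)[seq_len(k)]
  topB <- order(scoresB, decreasing = TRUE)[seq_len(k)]
  list(pearson = stats::cor(scoresA, scoresB),
       sign_disagreement = mean((scoresA > 0) != (scoresB > 0)),
       jaccard_top = length(intersect(topA, topB)) /
         length(union(topA, topB)))
}

#' Holdout prediction benchmark on one grid
#'
#' Masks a random fraction of interior wells (cells outside the first
#' and last row and column, which have two-sided monotone envelopes),
#' predicts them from the remaining data with [predict_missing], and
#' reports the RMSE of the predicted viabilities against the held-out
#' truth. Also reports how stable the viability-scale effect sizes are:
#' the RMSE between the cellwise effect-size surfaces computed on the
#' full and on the masked data.
#'
#' @param grid a fully usable [dose_grid].
#' @param frac fraction of observed interior wells to hold out.
#' @param seed optional seed for the mask draw.
#' @param spec response transform.
#' @return List: `rmse_viability`, `rmse_s_sir`, `n_holdout`, `cells`
#'   (matrix of held-out array indices). With `frac = 0`, an empty
#'   result (`n_holdout = 0`, RMSEs `NA`).
#' @export
holdout_benchmark <- function(grid, frac = 0.2, seed = NULL,
                              spec = transform_spec()) {
  stopifnot(is_dose_grid(grid), frac >= 0, frac < 1)
  I <- nrow(grid$Y); J <- ncol(grid$Y)
  if (I < 3L || J < 3L)
    stop("grid has no interior wells to hold out", call. = FALSE)
  if (frac == 0)
    return(list(rmse_viability = NA_real_, rmse_s_sir = NA_real_,
                n_holdout = 0L, cells = NULL))
  if (!is.null(seed)) set.seed(seed)
  interior <- which(row(grid$Y) > 1L & row(grid$Y) < I &
                    col(grid$Y) > 1L & col(grid$Y) < J & !is.na(grid$Y))
  if (length(interior) < 1L)
    stop("no observed interior wells to hold out", call. = FALSE)
  k <- max(1L, ceiling(frac * length(interior)))
  held <- sample(interior, k)

  Ym <- grid$Y; Ym[held] <- NA
  mm <- grid$m; mm[held] <- 0L
  s2m <- grid$s2; s2m[held] <- NA
  masked <- dose_grid(Ym, grid$conc_row, grid$conc_col, m = mm, s2 = s2m,
                      drug_row = grid$drug_row, drug_col = grid$drug_col)

  pm <- predict_missing(masked, spec = spec)
  rmse_v <- sqrt(mean((pm$Y_hat[held] - grid$Y[held])^2))

  s_full <- sir_surfaces(grid, spec)$s_sir
  s_mask <- sir_surfaces(masked, spec)$s_sir
  list(rmse_viability = rmse_v,
       rmse_s_sir = sqrt(mean((s_full - s_mask)^2)),
       n_holdout = k,
       cells = which(matrix(seq_along(Ym), I, J) %in% held, arr.ind = TRUE))
}

#' Fitted surfaces and effect sizes without the bootstrap
#'
#' Runs the estimation half of the pipeline only: both projections, the
#' interaction surface and the viability-scale effect sizes, skipping the
#' bootstrap test. Useful for visualization and for benchmarks that only
#' need the surfaces.
#'
#' @inheritParams sir_test
#' @return List: `iso`, `add` (the two fits), `delta`, `s_sir`.
#' @export
sir_surfaces <- function(grid, spec = transform_spec(), tau = 1e-6,
                         winsor_pct = 99) {
  tg <- transform_responses(grid, spec = spec, tau = tau,
                            winsor_pct = winsor_pct)
  add <- suppressWarnings(fit_monotone_additive(tg))
  iso <- fit_isotonic_2d(tg)
  list(iso = iso, add = add,
       delta = interaction_surface(iso, add),
       s_sir = effect_size_viability(iso, add, spec))
}
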