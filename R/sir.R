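#' Full interaction test on one dose-response matrix
#'
#' Runs the complete pipeline on a single [dose_grid]: transform and
#' weight the responses, project onto the monotone cone and the
#' monotone-additive null, form the interaction surface and its
#' viability-scale effect sizes, and compute a calibrated p-value by the
#' df-corrected wild bootstrap.
#'
#' @param grid a [dose_grid].
#' @param spec response transform, logit by default.
#' @param B bootstrap resamples (default 200).
#' @param seed optional integer seed for the bootstrap draws.
#' @param tau variance floor for the weights.
#' @param winsor_pct weight Winsorization percentile.
#' @param tol solver tolerance.
#' @return An object of class `sir_result` collecting the p-value, the
#'   statistics (`T_obs`, `S2`, `S2_syn`, `S2_ant`), bookkeeping
#'   (`df_null`, `n_eff`, `B`, `seed`, `inflation_ratio`) and the
#'   surfaces (`delta`, `s_sir`, `theta_iso`, `theta_add`).
#' @examples
#' g <- simulate_grid(I = 5, J = 5, strength = 2, sigma = 0.1, seed = 1)
#' res <- sir_test(g, B = 50, seed = 1)
#' res
#' @export
sir_test <- function(grid, spec = transform_spec(), B = 200L, seed = NULL,
                     tau = 1e-6, winsor_pct = 99, tol = 1e-8) {
  stopifnot(is_dose_grid(grid))
  tg <- transform_responses(grid, spec = spec, tau = tau,
                            winsor_pct = winsor_pct)
  sir_test_transformed(tg, B = B, seed = seed, tol = tol)
}

#' Interaction test on an already-transformed grid
#'
#' Same as [sir_test] but starting from a [transformed_grid]; used by
#' the simulation drivers, which generate data directly on the
#' transform scale.
#'
#' @inheritParams sir_test
#' @param tg a [transformed_grid].
#' @return A `sir_result`, see [sir_test].
#' @export
sir_test_transformed <- function(tg, B = 200L, seed = NULL, tol = 1e-8) {
  stopifnot(is_transformed_grid(tg))
  bt <- wild_bootstrap_test(tg, B = B, seed = seed, tol = tol)
  s_sir <- effect_size_viability(bt$iso, bt$add, tg$spec)
  dir <- directional_energy(bt$delta, tg$W)
  structure(list(
    p_value = bt$p_value, T_obs = bt$T_obs, S2 = bt$S2,
    S2_syn = dir$S2_syn, S2_ant = dir$S2_ant,
    df_null = bt$df_null, n_eff = bt$n_eff, B = bt$B, seed = bt$seed,
    inflation_ratio = bt$inflation,
    delta = bt$delta, s_sir = s_sir,
    theta_iso = bt$iso$theta_iso, theta_add = bt$add$theta_add,
    transform = tg$spec$name, bootstrap = bt),
    class = "sir_result")
}

#' @export
print.sir_result <- function(x, ...) {
  cat("SIR interaction test\n")
  cat(sprintf("  transform: %s, B = %d, n_eff = %d, df_null = %d\n",
              x$transform, x$B, x$n_eff, x$df_null))
  cat(sprintf("  T = %.5g  (S2 = %.5g; synergy %.3g / antagonism %.3g)\n",
              x$T_obs, x$S2, x$S2_syn, x$S2_ant))
  cat(sprintf("  p-value = %.4g\n", x$p_value))
  dir <- if (x$S2_syn >= x$S2_ant) "synergy" else "antagonism"
  cat(sprintf("  dominant direction: %s (mean effect size %.3g viability units)\n",
              dir, mean(x$s_sir)))
  invisible(x)
}

#' Batch interaction screen with FDR control
#'
#' Runs the full test on every grid of a screen, derives a per-matrix
#' seed from the master seed and the block index (so results do not
#' depend on processing order), applies Benjamini-Hochberg FDR
#' (optionally within strata), and never aborts the batch on a
#' single-matrix failure: failures are recorded in the `status` column.
#'
#' @param grids named list of [dose_grid] objects (names are block ids;
#'   unnamed lists get `block_1 ...`), or a character path accepted by
#'   [read_dose_grids].
#' @param q FDR level.
#' @param strata optional vector of stratum labels, one per grid.
#' @param seed master seed; per-matrix seeds are derived from it.
#' @inheritParams sir_test
#' @return A data frame with one row per input matrix: `block_id`,
#'   `drug_row`, `drug_col`, `p_value`, `p_adj`, `reject`, `T_obs`,
#'   `S2`, `S2_syn`, `S2_ant`, `df_null`, `n_eff`, `status`; the full
#'   `sir_result` objects are attached as attribute `"results"`.
#' @export
run_screen <- function(grids, q = 0.05, strata = NULL, spec = transform_spec(),
                       B = 200L, seed = 1L, tau = 1e-6, winsor_pct = 99,
                       tol = 1e-8) {
  if (is.character(grids)) grids <- read_dose_grids(grids)
  stopifnot(is.list(grids), length(grids) >= 1L)
  if (is.null(names(grids)) || anyDuplicated(names(grids)))
    if (is.null(names(grids)))
      names(grids) <- paste0("block_", seq_along(grids))
  if (anyDuplicated(names(grids)))
    stop("duplicate block ids in the screen", call. = FALSE)

  rows <- vector("list", length(grids))
  results <- vector("list", length(grids))
  for (k in seq_along(grids)) {
    g <- grids[[k]]
    sub_seed <- substream_seed(seed, k)
    status <- "ok"
    res <- withCallingHandlers(
      tryCatch(sir_test(g, spec = spec, B = B, seed = sub_seed, tau = tau,
                        winsor_pct = winsor_pct, tol = tol),
               error = function(e) {
                 status <<- paste0("error:", conditionMessage(e)); NULL
               }),
      warning = function(w) {
        if (status == "ok") status <<- "warned"
        invokeRestart("muffleWarning")
      })
    results[[k]] <- res
    rows[[k]] <- data.frame(
      block_id = names(grids)[k],
      drug_row = if (is_dose_grid(g)) g$drug_row else NA_character_,
      drug_col = if (is_dose_grid(g)) g$drug_col else NA_character_,
      p_value = if (is.null(res)) NA_real_ else res$p_value,
      T_obs = if (is.null(res)) NA_real_ else res$T_obs,
      S2 = if (is.null(res)) NA_real_ else res$S2,
      S2_syn = if (is.null(res)) NA_real_ else res$S2_syn,
      S2_ant = if (is.null(res)) NA_real_ else res$S2_ant,
      df_null = if (is.null(res)) NA_integer_ else res$df_null,
      n_eff = if (is.null(res)) NA_integer_ else res$n_eff,
      status = status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_value)
  out$p_adj <- NA_real_; out$reject <- NA
  if (any(ok)) {
    adj <- bh_fdr(out$p_value[ok], q = q,
                  strata = if (is.null(strata)) NULL else strata[ok], B = B)
    out$p_adj[ok] <- adj$p_adj
    out$reject[ok] <- adj$reject
  }
  out <- out[, c("block_id", "drug_row", "drug_col", "p_value", "p_adj",
                 "reject", "T_obs", "S2", "S2_syn", "S2_ant", "df_null",
                 "n_eff", "status")]
  attr(out, "results") <- stats::setNames(results, names(grids))
  attr(out, "seed") <- seed
  out
}

# deterministic per-matrix substream seed, kept inside 32-bit range
substream_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% .Machine$integer.max)
}
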