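#' Read dose-response grids from CSV
#'
#' Two layouts are accepted. Long format has one row per well with
#' columns `block_id, drug_row, drug_col, conc_r, conc_c, response` and
#' an optional `replicate` column; multiple rows per `(conc_r, conc_c)`
#' are aggregated into the replicate mean, count and unbiased sample
#' variance. Wide format is a single matrix: first column holds the row
#' concentrations, the header row the column concentrations, and the
#' body the viabilities. Missing wells are empty fields or `NA`.
#'
#' Doses are sorted ascending on ingest. Responses must be viability in
#' `[0, 1]` (up to tolerance 1e-9); with
#' `response_scale = "inhibition"` values are flipped as `Y = 1 - x`
#' first. A malformed block is skipped with a warning rather than
#' aborting the whole file.
#'
#' @param path CSV file path.
#' @param format `"long"`, `"wide"`, or `"auto"` (default: long when a
#'   `response` column is present).
#' @param response_scale `"viability"` (default) or `"inhibition"`.
#' @return Named list of [dose_grid] objects, one per block.
#' @export
read_dose_grids <- function(path, format = c("auto", "long", "wide"),
                            response_scale = c("viability", "inhibition")) {
  format <- match.arg(format)
  response_scale <- match.arg(response_scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "auto")
    format <- if ("response" %in% names(df)) "long" else "wide"
  if (format == "long") read_long(df, response_scale, path)
  else read_wide(df, response_scale, path)
}

fix_response <- function(x, scale, where) {
  x <- as.numeric(x)
  if (scale == "inhibition") x <- 1 - x
  bad <- is.finite(x) & (x < -1e-9 | x > 1 + 1e-9)
  if (any(bad))
    stop(sprintf("%d response value(s) outside [0, 1] in %s", sum(bad), where),
         call. = FALSE)
  pmin(pmax(x, 0), 1)
}

read_long <- function(df, response_scale, path) {
  req <- c("block_id", "drug_row", "drug_col", "conc_r", "conc_c", "response")
  if (!all(req %in% names(df)))
    stop("long CSV must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  grids <- list()
  for (blk in unique(df$block_id)) {
    d <- df[df$block_id == blk, , drop = FALSE]
    g <- tryCatch({
      cr <- as.numeric(d$conc_r); cc <- as.numeric(d$conc_c)
      if (anyNA(cr) || anyNA(cc)) stop("non-numeric doses")
      y <- fix_response(d$response, response_scale, paste0("block ", blk))
      rlev <- sort(unique(cr)); clev <- sort(unique(cc))
      I <- length(rlev); J <- length(clev)
      Y <- matrix(NA_real_, I, J); M <- matrix(0L, I, J)
      S2 <- matrix(NA_real_, I, J)
      ri <- match(cr, rlev); ci <- match(cc, clev)
      for (cell in split(seq_len(nrow(d)), paste(ri, ci))) {
        i <- ri[cell[1L]]; j <- ci[cell[1L]]
        vals <- y[cell][is.finite(y[cell])]
        if (length(vals) == 0L) next
        Y[i, j] <- mean(vals)
        M[i, j] <- length(vals)
        if (length(vals) >= 2L) S2[i, j] <- stats::var(vals)
      }
      dose_grid(Y, rlev, clev, m = M, s2 = S2,
                drug_row = as.character(d$drug_row[1L]),
                drug_col = as.character(d$drug_col[1L]))
    }, error = function(e) {
      warning(sprintf("skipping block %s in %s: %s", blk, path,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(g)) grids[[as.character(blk)]] <- g
  }
  if (length(grids) == 0L)
    stop("no usable blocks in ", path, call. = FALSE)
  grids
}

read_wide <- function(df, response_scale, path) {
  cr <- as.numeric(df[[1L]])
  cc <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (anyNA(cr) || anyNA(cc))
    stop("wide CSV needs numeric row concentrations in the first column ",
         "and numeric column concentrations in the header", call. = FALSE)
  Y <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(Y) <- "double"
  Y[] <- fix_response(Y, response_scale, path)
  ord_r <- order(cr); ord_c <- order(cc)
  g <- dose_grid(Y[ord_r, ord_c, drop = FALSE], cr[ord_r], cc[ord_c])
  stats::setNames(list(g), tools::file_path_sans_ext(basename(path)))
}

#' Write screen results
#'
#' Serializes the table returned by [run_screen]. JSON output includes
#' the full per-matrix surfaces (`delta`, `s_sir`, `theta_iso`,
#' `theta_add`) plus the test summaries; TSV output is the flat result
#' table with a fixed, documented column order (`block_id, drug_row,
#' drug_col, p_value, p_adj, reject, T_obs, S2, S2_syn, S2_ant,
#' df_null, n_eff, status`) and no surfaces.
#'
#' @param results a data frame from [run_screen] (surfaces are pulled
#'   from its `"results"` attribute when present).
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(path))
  }
  full <- attr(results, "results")
  recs <- lapply(seq_len(nrow(results)), function(k) {
    rec <- as.list(results[k, , drop = FALSE])
    rec <- lapply(rec, function(x) if (is.factor(x)) as.character(x) else x)
    r <- if (!is.null(full)) full[[results$block_id[k]]] else NULL
    if (!is.null(r)) {
      rec$B <- r$B
      rec$seed <- r$seed
      rec$inflation_ratio <- r$inflation_ratio
      rec$transform <- r$transform
      rec$delta <- r$delta
      rec$s_sir <- r$s_sir
      rec$theta_iso <- r$theta_iso
      rec$theta_add <- r$theta_add
    }
    rec
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
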