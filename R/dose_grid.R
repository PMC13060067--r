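#' Dose-response grid container
#'
#' Bundles a single drug-combination matrix: mean viability `Y` on an
#' `I x J` grid of strictly increasing concentrations, together with
#' per-cell replicate counts `m` and within-cell sample variances `s2`.
#' Missing wells are `NA` in `Y` with `m = 0`.
#'
#' @param Y numeric `I x J` matrix of mean viability in `[0, 1]`; `NA`
#'   marks a missing well.
#' @param conc_row,conc_col strictly increasing concentration vectors for
#'   the row drug (length `I`) and column drug (length `J`). Units are
#'   arbitrary but must be consistent within a vector.
#' @param m integer matrix of replicate counts per well; defaults to 1 at
#'   observed wells and 0 at missing wells.
#' @param s2 matrix of unbiased within-well sample variances; `NA` where
#'   fewer than two replicates are available.
#' @param drug_row,drug_col drug names (metadata only).
#'
#' @return An object of class `dose_grid`.
#' @examples
#' Y <- outer(c(0.95, 0.7, 0.4), c(0.9, 0.6, 0.3), pmin)
#' g <- dose_grid(Y, conc_row = c(0.1, 1, 10), conc_col = c(0.1, 1, 10))
#' g
#' @export
dose_grid <- function(Y, conc_row, conc_col, m = NULL, s2 = NULL,
                      drug_row = "drug_row", drug_col = "drug_col") {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  dimnames(Y) <- NULL
  I <- nrow(Y); J <- ncol(Y)
  if (I < 2L || J < 2L)
    stop("dose grid must be at least 2 x 2: interaction is undefined ",
         "without two varying doses on each axis", call. = FALSE)
  conc_row <- as.numeric(conc_row); conc_col <- as.numeric(conc_col)
  if (length(conc_row) != I || length(conc_col) != J)
    stop("concentration vectors do not match the matrix dimensions",
         call. = FALSE)
  if (anyNA(conc_row) || anyNA(conc_col) ||
      any(diff(conc_row) <= 0) || any(diff(conc_col) <= 0))
    stop("concentrations must be strictly increasing", call. = FALSE)
  obs <- !is.na(Y)
  if (!any(obs)) stop("all wells are missing", call. = FALSE)
  if (any(Y[obs] < 0 | Y[obs] > 1))
    stop("viability values must lie in [0, 1]", call. = FALSE)
  if (is.null(m)) m <- matrix(as.integer(obs), I, J)
  m <- as.matrix(m); storage.mode(m) <- "integer"
  if (!identical(dim(m), dim(Y))) stop("m has wrong dimensions", call. = FALSE)
  if (any(m < 0L, na.rm = TRUE) || any((m == 0L) != !obs))
    stop("replicate counts m must be 0 exactly at missing wells and ",
         ">= 1 elsewhere", call. = FALSE)
  if (is.null(s2)) s2 <- matrix(NA_real_, I, J)
  s2 <- as.matrix(s2); storage.mode(s2) <- "double"
  if (!identical(dim(s2), dim(Y))) stop("s2 has wrong dimensions", call. = FALSE)
  if (any(s2 < 0, na.rm = TRUE)) stop("variances must be >= 0", call. = FALSE)
  structure(
    list(Y = Y, conc_row = conc_row, conc_col = conc_col, m = m, s2 = s2,
         drug_row = as.character(drug_row), drug_col = as.character(drug_col)),
    class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %s x %s, %d x %d wells (%d observed)\n",
              x$drug_row, x$drug_col, nrow(x$Y), ncol(x$Y),
              sum(!is.na(x$Y))))
  cat("row doses:", format(x$conc_row, trim = TRUE), "\n")
  cat("col doses:", format(x$conc_col, trim = TRUE), "\n")
  print(round(x$Y, 3))
  invisible(x)
}

#' @export
dim.dose_grid <- function(x) dim(x$Y)

is_dose_grid <- function(x) inherits(x, "dose_grid")
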