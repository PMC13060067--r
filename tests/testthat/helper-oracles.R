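# Independent oracles used to verify the package's solvers. Both are
# deliberately naive (O(n^3) formula / exhaustive enumeration) and share no
# code with the implementation under test.

# weighted NON-INCREASING least-squares fit via the max-min representation
# of isotonic regression applied to the negated sequence
oracle_pava_dec <- function(y, w) {
  yy <- -y
  n <- length(y)
  wmean <- function(s, t) sum(w[s:t] * yy[s:t]) / sum(w[s:t])
  fit <- numeric(n)
  for (i in seq_len(n)) {
    best <- -Inf
    for (s in 1:i) {
      m <- Inf
      for (t in i:n) m <- min(m, wmean(s, t))
      best <- max(best, m)
    }
    fit[i] <- best
  }
  -fit
}

# exhaustive brute-force solution of the 2D monotone projection QP:
# enumerate every subset of the adjacent-difference constraints as a
# candidate active set, solve the equality-constrained KKT system, keep
# the feasible candidate with the smallest objective. Valid because the
# global optimum appears at its own active set and no feasible point can
# beat it.
oracle_iso2d <- function(Z, W, feas_tol = 1e-8) {
  I <- nrow(Z); J <- ncol(Z); n <- I * J
  idx <- function(i, j) (j - 1L) * I + i
  pairs <- list()
  for (i in 1:I) for (j in 1:(J - 1))
    pairs[[length(pairs) + 1L]] <- c(idx(i, j + 1), idx(i, j))
  for (j in 1:J) for (i in 1:(I - 1))
    pairs[[length(pairs) + 1L]] <- c(idx(i + 1, j), idx(i, j))
  m <- length(pairs)
  A <- matrix(0, m, n)
  for (k in seq_len(m)) {
    A[k, pairs[[k]][1L]] <- 1
    A[k, pairs[[k]][2L]] <- -1
  }
  D <- diag(c(W), n)
  z <- c(Z)
  bits <- 2^(0:(m - 1))
  best_obj <- Inf
  best_theta <- NULL
  for (code in 0:(2^m - 1)) {
    S <- which(bitwAnd(code, bits) > 0)
    theta <- if (length(S) == 0L) z else {
      As <- A[S, , drop = FALSE]
      K <- rbind(cbind(2 * D, t(As)),
                 cbind(As, matrix(0, length(S), length(S))))
      sol <- tryCatch(solve(K, c(2 * D %*% z, rep(0, length(S)))),
                      error = function(e) NULL)
      if (is.null(sol)) next
      sol[seq_len(n)]
    }
    if (max(A %*% theta) > feas_tol) next
    obj <- sum(c(W) * (z - theta)^2)
    if (obj < best_obj) {
      best_obj <- obj
      best_theta <- theta
    }
  }
  list(theta = matrix(best_theta, I, J), objective = best_obj)
}

# small random grid on the transform scale, with optional random weights
random_tgrid <- function(I, J, weights = c("unit", "random")) {
  weights <- match.arg(weights)
  Z <- matrix(stats::rnorm(I * J), I, J)
  W <- if (weights == "unit") matrix(1, I, J)
       else matrix(stats::runif(I * J, 0.2, 3), I, J)
  transformed_grid(Z, W)
}
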