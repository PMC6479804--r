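#' Savitzky-Golay design matrix
#'
#' Vandermonde matrix of the local polynomial fit over a symmetric window of
#' `2M + 1` samples: row for offset `n` (`-M <= n <= M`) and column for power
#' `k` (`0 <= k <= N`) holds `n^k`, with `0^0 := 1` so the constant column is
#' all ones.
#'
#' @param M Half-window in samples (window length `2M + 1`), `M >= 1`.
#' @param N Polynomial order, `0 <= N <= 2M` (full-rank least squares).
#' @return A `(2M + 1) x (N + 1)` numeric matrix.
#' @examples
#' sg_design_matrix(2, 2)
#' @export
sg_design_matrix <- function(M, N) {
  check_sg_params(M, N)
  outer(seq.int(-M, M), 0:N, `^`)   # 0^0 == 1 in R, as required
}

check_sg_params <- function(M, N) {
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M))
    stop("half-window 'M' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(N) || length(N) != 1L || N < 0 || N != round(N))
    stop("order 'N' must be a non-negative integer", call. = FALSE)
  if (N > 2 * M)
    stop(sprintf("order N = %d exceeds 2M = %d: least squares would be rank-deficient",
                 N, 2 * M), call. = FALSE)
  invisible(TRUE)
}

#' Central Savitzky-Golay convolution weights
#'
#' The weight row that evaluates the least-squares order-`N` polynomial fit
#' of a `2M + 1` window at the window centre.  Computed from the thin-QR
#' factorisation of the design matrix: the centre row of the hat matrix
#' `A (A'A)^{-1} A' = Q Q'`, which is numerically stable for high orders.
#' Weights always sum to 1 (constant preservation) and are symmetric, and
#' consecutive even/odd orders share identical central weights.
#'
#' @inheritParams sg_design_matrix
#' @return Numeric vector of length `2M + 1`; element `m + M + 1` multiplies
#'   the sample at offset `m` from the centre.
#' @examples
#' sg_weights(2, 0)  # order-0 fit: the 5-point mean
#' sg_weights(2, 2)  # classic 5-point quadratic smoother
#' @export
sg_weights <- function(M, N) {
  A <- sg_design_matrix(M, N)
  Q <- qr.Q(qr(A))
  h <- drop(Q %*% Q[M + 1L, ])
  if (any(!is.finite(h)))
    stop("Savitzky-Golay normal equations are numerically singular", call. = FALSE)
  h
}

#' Brute-force polynomial fit at the window centre
#'
#' Explicitly solves the windowed least-squares problem by the textbook
#' normal-equation formula `alpha = (A'A)^{-1} A' x` and returns the fitted
#' value at the centre, `f(0) = alpha_0`.  This is the slow reference route
#' against which the convolution weights of [sg_weights()] are validated; it
#' deliberately shares no code with them.
#'
#' @param window Odd-length numeric vector of samples.
#' @param N Polynomial order, `N <= length(window) - 1`.
#' @return The least-squares fit evaluated at the window centre.
#' @export
sg_fit_oracle <- function(window, N) {
  L <- length(window)
  if (L %% 2L != 1L)
    stop("'window' must have odd length", call. = FALSE)
  M <- (L - 1L) %/% 2L
  check_sg_params(max(M, 1L), N)
  if (N + 1L > L)
    stop("order too high for window length", call. = FALSE)
  A <- outer(seq.int(-M, M), 0:N, `^`)
  alpha <- solve(crossprod(A), crossprod(A, as.numeric(window)))
  alpha[1L]
}

#' Fixed-order Savitzky-Golay filter
#'
#' Smooths a signal by discrete convolution with the central weights of
#' [sg_weights()]; interior samples (`M` away from either end) get the
#' convolution, and the `M` samples at each edge are replaced by the local
#' polynomial fit over the first/last full window ([edge_polyfit()]).
#'
#' @param x A `signal_series` or numeric vector, length >= `2M + 1`.
#' @param M Half-window in samples.
#' @param N Polynomial order.
#' @param edge_order Order used for the boundary polynomial fits; defaults
#'   to `N`.
#' @return A `signal_series` of the same length as `x`.
#' @examples
#' x <- signal_series(sin(seq(0, 4 * pi, length.out = 200)) +
#'                      rnorm(200, sd = 0.1), fs = 100)
#' y <- sg_filter(x, M = 8, N = 3)
#' @export
sg_filter <- function(x, M, N, edge_order = N) {
  x <- as_signal_series(x)
  check_sg_params(M, N)
  n <- length(x)
  if (n < 2 * M + 1)
    stop(sprintf("signal length %d is shorter than the window 2M+1 = %d",
                 n, 2 * M + 1), call. = FALSE)
  h <- sg_weights(M, N)
  y <- as.numeric(stats::filter(as.numeric(x), h, method = "convolution",
                                sides = 2))
  y[seq_len(M)] <- edge_polyfit(x, M, edge_order, side = "head")
  y[(n - M + 1L):n] <- edge_polyfit(x, M, edge_order, side = "tail")
  signal_series(y, sampling_rate(x))
}

#' Boundary values by local polynomial fit
#'
#' Samples within half a window of either end have no complete symmetric
#' window, so they are replaced by the value of a single least-squares
#' order-`N` polynomial fitted over the first (or last) full window and
#' evaluated at the edge positions.
#'
#' @param x Signal of length >= `2M + 1`.
#' @param M Half-window.
#' @param N Order of the boundary fit.
#' @param side `"head"` for the first `M` samples, `"tail"` for the last.
#' @return Numeric vector of `M` replacement values, in signal order.
#' @export
edge_polyfit <- function(x, M, N, side = c("head", "tail")) {
  side <- match.arg(side)
  x <- as.numeric(x)
  check_sg_params(M, N)
  n <- length(x)
  if (n < 2 * M + 1)
    stop("signal shorter than one full window", call. = FALSE)
  A <- outer(seq.int(-M, M), 0:N, `^`)
  win <- if (side == "head") x[1:(2 * M + 1)] else x[(n - 2 * M):n]
  alpha <- qr.coef(qr(A), win)
  # head positions are offsets -M..-1 from the first window's centre;
  # tail positions are offsets 1..M from the last window's centre
  at <- if (side == "head") seq.int(-M, -1L) else seq.int(1L, M)
  drop(outer(at, 0:N, `^`) %*% alpha)
}
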