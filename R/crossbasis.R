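#' Exposure-lag cross-basis matrix
#'
#' Builds the bidimensional design block of a distributed lag non-linear
#' model. Row `t`, column `(j, k)` holds
#' \deqn{\sum_{l=0}^{L} b_j(x_{t-l})\, c_k(l)}
#' where `b_j` are the exposure-dimension natural spline basis functions
#' (knots from the full exposure series) and `c_k` the lag-dimension basis
#' functions. Dotted with the corresponding coefficient block, a row gives
#' the total log-rate contribution of the past `L + 1` days of exposure.
#'
#' The first `L` rows have lagged exposures that precede the series; they
#' are flagged as incomplete (returned as `NA` rows) and must be excluded
#' from any likelihood, as are rows whose lag window contains a missing
#' exposure.
#'
#' @param x numeric exposure series (daily mean temperature, deg C).
#' @param max_lag maximum lag `L` in days (`0` gives a pure
#'   exposure-response basis with a constant lag dimension).
#' @param exposure_df,lag_df basis dimensions used when the corresponding
#'   spec is not supplied (defaults 6 and 4).
#' @param exposure_spec,lag_spec optional [basis_spec()] overrides; the
#'   exposure spec is completed from `x`, the lag spec defaults to
#'   [lag_knots()]`(max_lag, lag_df)`.
#' @return an object of class `"crossbasis"`: a list with elements
#'   `matrix` (`n x (vx*vl)`), `exposure_spec`, `lag_spec`, `max_lag`,
#'   `lag_basis` (`(L+1) x vl` lag basis evaluations),
#'   `incomplete_rows`, and `exposure_range`.
#' @examples
#' x <- 10 + 8 * sin(seq_len(120) / 20)
#' cb <- crossbasis(x, max_lag = 7, exposure_df = 4, lag_df = 3)
#' dim(cb$matrix)
#' @export
crossbasis <- function(x, max_lag, exposure_df = 6L, lag_df = 4L,
                       exposure_spec = NULL, lag_spec = NULL) {
  n <- length(x)
  stopifnot(max_lag >= 0, max_lag == round(max_lag))
  L <- as.integer(max_lag)
  if (n <= L) stop("series length (", n, ") must exceed max_lag (", L, ")")
  if (is.null(exposure_spec)) exposure_spec <- basis_spec(exposure_df)
  exposure_spec <- complete_spec(exposure_spec, x)
  if (L == 0L) {
    lag_spec <- NULL
    C <- matrix(1, 1L, 1L)
  } else {
    if (is.null(lag_spec)) lag_spec <- lag_knots(L, lag_df)
    C <- eval_basis(lag_spec, 0:L)
  }
  vx <- exposure_spec$df
  vl <- ncol(C)

  M <- matrix(0, n, vx * vl)
  jj <- rep(seq_len(vx), each = vl)
  for (l in 0:L) {
    xl <- if (l == 0L) x else c(rep(NA_real_, l), x[seq_len(n - l)])
    Bl <- eval_basis(exposure_spec, xl)
    w <- rep(C[l + 1L, ], times = vx)
    M <- M + Bl[, jj, drop = FALSE] *
      matrix(w, n, vx * vl, byrow = TRUE)
  }
  incomplete <- which(apply(is.na(M), 1L, any))
  colnames(M) <- paste0("cb", rep(seq_len(vx), each = vl), ".",
                        rep(seq_len(vl), times = vx))
  structure(list(matrix = M, exposure_spec = exposure_spec,
                 lag_spec = lag_spec, max_lag = L, lag_basis = C,
                 incomplete_rows = incomplete,
                 exposure_range = range(x, na.rm = TRUE)),
            class = "crossbasis")
}

## exposure basis row(s) for prediction values, with extrapolation warning
exposure_basis_at <- function(cb, x, warn = TRUE) {
  r <- cb$exposure_range
  out_of_range <- x < r[1L] | x > r[2L]
  if (warn && any(out_of_range, na.rm = TRUE))
    warning("predicting at temperature(s) outside the observed range [",
            signif(r[1L], 4L), ", ", signif(r[2L], 4L),
            "]; natural splines extrapolate linearly there")
  eval_basis(cb$exposure_spec, x)
}

#' Lag-specific prediction contrast
#'
#' The vector `c` such that `c %*% beta` is the log relative risk at
#' temperature `x` versus reference `ref` on lag day `lag`, for the
#' cross-basis coefficient block `beta`:
#' `(B(x) - B(ref)) %x% C(lag)`.
#'
#' @param cb a [crossbasis()].
#' @param x,ref temperatures (deg C); values outside the observed exposure
#'   range are allowed but trigger a warning.
#' @param lag integer lag in `0..max_lag`.
#' @return numeric vector of length `ncol(cb$matrix)`.
#' @export
contrast_vector <- function(cb, x, ref, lag) {
  stopifnot(inherits(cb, "crossbasis"), length(lag) == 1L)
  if (lag < 0 || lag > cb$max_lag || lag != round(lag))
    stop("lag must be an integer in [0, ", cb$max_lag, "]")
  dB <- exposure_basis_at(cb, x) - exposure_basis_at(cb, ref)
  as.vector(kronecker(as.vector(dB), cb$lag_basis[lag + 1L, ]))
}

#' Cumulative prediction contrast over a lag window
#'
#' Sum of [contrast_vector()] over `lag = window[1] .. window[2]`; dotted
#' with the cross-basis coefficients it gives the cumulative log relative
#' risk of `x` versus `ref` over that window.
#'
#' @inheritParams contrast_vector
#' @param window integer pair `(l0, l1)` with
#'   `0 <= l0 <= l1 <= max_lag`.
#' @return numeric vector of length `ncol(cb$matrix)`.
#' @export
cumulative_contrast <- function(cb, x, ref, window) {
  stopifnot(inherits(cb, "crossbasis"), length(window) == 2L)
  l0 <- window[1L]; l1 <- window[2L]
  if (l0 > l1 || l0 < 0 || l1 > cb$max_lag ||
      any(window != round(window)))
    stop("window must satisfy 0 <= l0 <= l1 <= ", cb$max_lag)
  dB <- exposure_basis_at(cb, x) - exposure_basis_at(cb, ref)
  Csum <- colSums(cb$lag_basis[(l0 + 1L):(l1 + 1L), , drop = FALSE])
  as.vector(kronecker(as.vector(dB), Csum))
}

#' @export
print.crossbasis <- function(x, ...) {
  cat("Cross-basis: ", nrow(x$matrix), " days x ", ncol(x$matrix),
      " columns (exposure df ", x$exposure_spec$df, " x lag df ",
      if (is.null(x$lag_spec)) 1L else x$lag_spec$df,
      "), max lag ", x$max_lag, "\n", sep = "")
  cat("  exposure range: [", signif(x$exposure_range[1L], 4L), ", ",
      signif(x$exposure_range[2L], 4L), "]; ",
      length(x$incomplete_rows), " incomplete row(s)\n", sep = "")
  invisible(x)
}
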