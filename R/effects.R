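#' Percentile temperature cutpoints
#'
#' The contrast temperatures used throughout the analysis: extreme cold
#' (P1), moderate cold (P10), the median (default reference), moderate hot
#' (P90) and extreme hot (P99).
#'
#' @param x temperature series (deg C).
#' @param probs probabilities of the five cutpoints.
#' @return a named numeric vector of class `"temp_cutpoints"` with entries
#'   `p1`, `p10`, `median`, `p90`, `p99`.
#' @export
temp_cutpoints <- function(x, probs = c(0.01, 0.10, 0.50, 0.90, 0.99)) {
  stopifnot(length(probs) == 5L, !is.unsorted(probs))
  q <- quantile_cutpoints(x, probs)
  structure(setNames(q, c("p1", "p10", "median", "p90", "p99")),
            class = "temp_cutpoints")
}

## cross-basis coefficient block and covariance of a fit
cb_slice <- function(fit) {
  idx <- fit$term_index$crossbasis
  list(beta = fit$coefficients[idx],
       V = fit$vcov[idx, idx, drop = FALSE])
}

## coefficient block reshaped vx x vl (column index is j-outer, k-inner)
cb_coef_matrix <- function(fit) {
  vx <- fit$crossbasis$exposure_spec$df
  s <- cb_slice(fit)
  matrix(s$beta, vx, length(s$beta) / vx, byrow = TRUE)
}

#' Predicted exposure-lag effect surface
#'
#' Centered log relative risks and delta-method standard errors on a
#' temperature-by-lag grid, plus cumulative summaries over lag windows.
#' For each grid point the contrast `c = (B(x) - B(ref)) %x% C(l)` gives
#' `log RR = c' beta` and `se = sqrt(c' V c)`; the relative risk and its
#' confidence limits are the exponentials.
#'
#' @param object a [dlnm_fit()].
#' @param temps prediction temperatures; default a 0.1 deg C grid over the
#'   observed range.
#' @param ref reference temperature (default the fit's reference, i.e. the
#'   observed median).
#' @param windows list of cumulative lag windows, each an integer pair.
#' @param level confidence level (default 0.95, z = 1.959964).
#' @param ... unused.
#' @return an object of class `"dlnm_surface"`: list with `temps`, `lags`,
#'   `ref`, matrices `log_rr`, `se`, `rr`, `lo`, `hi` (temps x lags), and
#'   `cumulative`, a `data.frame` with one row per (temp, window).
#' @export
predict.dlnm_fit <- function(object, temps = NULL, ref = object$ref,
                             windows = list(c(0, 3), c(0, 7), c(0, 10),
                                            c(0, 14)),
                             level = 0.95, ...) {
  cb <- object$crossbasis
  L <- cb$max_lag
  windows <- Filter(function(w) w[2L] <= L, windows)
  if (is.null(temps)) {
    r <- cb$exposure_range
    temps <- seq(r[1L], r[2L], by = 0.1)
  }
  z <- qnorm(1 - (1 - level) / 2)
  s <- cb_slice(object)
  vx <- cb$exposure_spec$df
  vl <- ncol(cb$lag_basis)

  dB <- exposure_basis_at(cb, temps) -
    matrix(exposure_basis_at(cb, ref), length(temps), vx, byrow = TRUE)
  Bm <- matrix(s$beta, vx, vl, byrow = TRUE)
  log_rr <- dB %*% Bm %*% t(cb$lag_basis)

  ## contrast rows for all (temp, lag) pairs: kron(dB[i, ], C[l, ])
  se <- matrix(0, length(temps), L + 1L)
  for (l in 0:L) {
    K <- dB[, rep(seq_len(vx), each = vl), drop = FALSE] *
      matrix(rep(cb$lag_basis[l + 1L, ], vx), length(temps), vx * vl,
             byrow = TRUE)
    se[, l + 1L] <- sqrt(pmax(rowSums((K %*% s$V) * K), 0))
  }

  cum <- do.call(rbind, lapply(windows, function(w) {
    Csum <- colSums(cb$lag_basis[(w[1L] + 1L):(w[2L] + 1L), ,
                                 drop = FALSE])
    lr <- as.vector(dB %*% Bm %*% Csum)
    K <- dB[, rep(seq_len(vx), each = vl), drop = FALSE] *
      matrix(rep(Csum, vx), length(temps), vx * vl, byrow = TRUE)
    sec <- sqrt(pmax(rowSums((K %*% s$V) * K), 0))
    data.frame(temp = temps, l0 = w[1L], l1 = w[2L], log_rr = lr, se = sec)
  }))
  if (!is.null(cum)) {
    cum$rr <- exp(cum$log_rr)
    cum$lo <- exp(cum$log_rr - z * cum$se)
    cum$hi <- exp(cum$log_rr + z * cum$se)
  }

  dimnames(log_rr) <- dimnames(se) <-
    list(format(temps, trim = TRUE), paste0("lag", 0:L))
  structure(list(temps = temps, lags = 0:L, ref = ref, level = level,
                 log_rr = log_rr, se = se, rr = exp(log_rr),
                 lo = exp(log_rr - z * se), hi = exp(log_rr + z * se),
                 cumulative = cum),
            class = "dlnm_surface")
}

#' Cumulative relative risk over a lag window
#'
#' Relative risk of sustained exposure at temperature `x` versus `ref`
#' accumulated over lags `window[1]..window[2]`, with a delta-method
#' confidence interval on the log scale.
#'
#' @param fit a [dlnm_fit()].
#' @param x temperature(s) of interest (deg C).
#' @param ref reference temperature (default the fit's reference).
#' @param window integer pair `(l0, l1)`.
#' @param level confidence level.
#' @return a `data.frame` with one row per element of `x`: `temp`, `l0`,
#'   `l1`, `log_rr`, `se`, `rr`, `lo`, `hi`.
#' @export
cumulative_rr <- function(fit, x, ref = fit$ref, window = c(0, 14),
                          level = 0.95) {
  stopifnot(inherits(fit, "dlnm_fit"))
  z <- qnorm(1 - (1 - level) / 2)
  s <- cb_slice(fit)
  rows <- lapply(x, function(xi) {
    cc <- cumulative_contrast(fit$crossbasis, xi, ref, window)
    lr <- sum(cc * s$beta)
    se <- sqrt(max(drop(cc %*% s$V %*% cc), 0))
    data.frame(temp = xi, l0 = window[1L], l1 = window[2L],
               log_rr = lr, se = se, rr = exp(lr),
               lo = exp(lr - z * se), hi = exp(lr + z * se))
  })
  do.call(rbind, rows)
}

#' Lag-specific relative risk
#'
#' Single-lag analogue of [cumulative_rr()].
#'
#' @inheritParams cumulative_rr
#' @param lag integer lag day.
#' @return a `data.frame` with one row per element of `x`.
#' @export
lag_rr <- function(fit, x, ref = fit$ref, lag = 0L, level = 0.95) {
  cumulative_rr(fit, x, ref = ref, window = c(lag, lag), level = level)
}

#' Minimum-morbidity temperature
#'
#' Grid search for the temperature minimising the overall cumulative
#' (lag 0..max_lag) log relative risk curve. The location is invariant to
#' the reference temperature, which only shifts the curve by a constant.
#'
#' @param fit a [dlnm_fit()].
#' @param grid search temperatures; default a 0.1 deg C grid between the
#'   5th and 95th percentiles of the observed series.
#' @param ref reference used to build the curve (irrelevant to the argmin).
#' @return the minimising temperature (deg C). A minimum on the grid
#'   boundary (monotone curve) is returned with a warning.
#' @export
find_mmt <- function(fit, grid = NULL, ref = fit$ref) {
  stopifnot(inherits(fit, "dlnm_fit"))
  cb <- fit$crossbasis
  if (is.null(grid)) {
    q <- quantile_cutpoints(fit$temp, c(0.05, 0.95))
    grid <- seq(q[1L], q[2L], by = 0.1)
  }
  vx <- cb$exposure_spec$df
  dB <- exposure_basis_at(cb, grid, warn = FALSE) -
    matrix(exposure_basis_at(cb, ref, warn = FALSE), length(grid), vx,
           byrow = TRUE)
  Csum <- colSums(cb$lag_basis)
  curve <- as.vector(dB %*% cb_coef_matrix(fit) %*% Csum)
  i <- which.min(curve)
  if (i == 1L || i == length(grid))
    warning("cumulative risk curve is monotone over the search grid; ",
            "returning the boundary")
  grid[i]
}

#' Relative-risk tables at the percentile temperatures
#'
#' The standard reporting layout: lag-specific RRs (95% CI) for each single
#' lag day and cumulative RRs over the requested windows, at the four
#' percentile contrast temperatures (P1, P10, P90, P99) versus the
#' reference. A cell is flagged significant when its CI excludes 1.
#'
#' @param fit a [dlnm_fit()].
#' @param cutpoints a [temp_cutpoints()] (default the fit's, computed from
#'   the modelled series).
#' @param windows list of cumulative lag windows.
#' @param ref reference temperature.
#' @param level confidence level.
#' @return list of two `data.frame`s, `lag_specific` (4 temps x
#'   `max_lag + 1` lags) and `cumulative` (4 temps x windows), each with
#'   `label`, `temp`, lag columns, `rr`, `lo`, `hi`, `significant`.
#' @export
effect_tables <- function(fit, cutpoints = fit$cutpoints,
                          windows = list(c(0, 3), c(0, 7), c(0, 10),
                                         c(0, 14)),
                          ref = fit$ref, level = 0.95) {
  stopifnot(inherits(cutpoints, "temp_cutpoints"))
  temps <- cutpoints[c("p1", "p10", "p90", "p99")]
  labels <- c("extreme_cold", "moderate_cold", "moderate_hot",
              "extreme_hot")
  L <- fit$crossbasis$max_lag

  lag_specific <- do.call(rbind, lapply(seq_along(temps), function(i) {
    do.call(rbind, lapply(0:L, function(l) {
      r <- lag_rr(fit, unname(temps[i]), ref = ref, lag = l, level = level)
      data.frame(label = labels[i], temp = r$temp, lag = l, rr = r$rr,
                 lo = r$lo, hi = r$hi)
    }))
  }))
  cumulative <- do.call(rbind, lapply(seq_along(temps), function(i) {
    do.call(rbind, lapply(windows, function(w) {
      r <- cumulative_rr(fit, unname(temps[i]), ref = ref, window = w,
                         level = level)
      data.frame(label = labels[i], temp = r$temp, l0 = w[1L], l1 = w[2L],
                 rr = r$rr, lo = r$lo, hi = r$hi)
    }))
  }))
  lag_specific$significant <- lag_specific$lo > 1 | lag_specific$hi < 1
  cumulative$significant <- cumulative$lo > 1 | cumulative$hi < 1
  rownames(lag_specific) <- rownames(cumulative) <- NULL
  list(lag_specific = lag_specific, cumulative = cumulative)
}

#' @export
print.dlnm_surface <- function(x, digits = 3L, ...) {
  cat("DLNM effect surface: ", length(x$temps), " temperatures x ",
      length(x$lags), " lags, reference ", format(x$ref, digits = 4L),
      " degC\n", sep = "")
  if (!is.null(x$cumulative)) {
    cat("Cumulative RR ranges per window:\n")
    for (w in split(x$cumulative,
                    paste0("lag ", x$cumulative$l0, "-", x$cumulative$l1))) {
      cat("  lag ", w$l0[1L], "-", w$l1[1L], ": RR in [",
          format(min(w$rr), digits = digits), ", ",
          format(max(w$rr), digits = digits), "]\n", sep = "")
    }
  }
  invisible(x)
}

#' Plot a fitted effect surface
#'
#' `type = "overall"` draws the cumulative exposure-response curve with its
#' confidence band; `"lag"` the lag-response curves at given temperatures;
#' `"contour"` a filled contour of the RR surface.
#'
#' @param x a `"dlnm_surface"` from [predict.dlnm_fit()].
#' @param type plot type.
#' @param at temperatures for `type = "lag"` (default the coldest and
#'   hottest grid values).
#' @param ... passed to the underlying plotting function.
#' @return `x`, invisibly.
#' @export
plot.dlnm_surface <- function(x, type = c("overall", "lag", "contour"),
                              at = NULL, ...) {
  type <- match.arg(type)
  if (type == "overall") {
    cum <- x$cumulative
    if (is.null(cum)) stop("surface has no cumulative component")
    w <- cum[cum$l1 == max(cum$l1), ]
    plot(w$temp, w$rr, type = "n", xlab = "Temperature (degC)",
         ylab = "Cumulative RR",
         ylim = range(w$lo, w$hi), ...)
    polygon(c(w$temp, rev(w$temp)), c(w$lo, rev(w$hi)),
            col = "grey85", border = NA)
    lines(w$temp, w$rr, lwd = 2)
    abline(h = 1, lty = 2)
    abline(v = x$ref, lty = 3)
  } else if (type == "lag") {
    if (is.null(at)) at <- range(x$temps)
    idx <- vapply(at, function(a) which.min(abs(x$temps - a)), integer(1L))
    matplot(x$lags, t(x$rr[idx, , drop = FALSE]), type = "l", lty = 1,
            lwd = 2, xlab = "Lag (days)", ylab = "RR", ...)
    abline(h = 1, lty = 2)
    legend("topleft", legend = paste0(signif(x$temps[idx], 3L), " degC"),
           lty = 1, lwd = 2, col = seq_along(idx), bty = "n")
  } else {
    filled.contour(x$temps, x$lags, x$rr,
                   color.palette = function(n) hcl.colors(n, "RdBu",
                                                          rev = TRUE),
                   xlab = "Temperature (degC)", ylab = "Lag (days)", ...)
  }
  invisible(x)
}

#' @export
plot.dlnm_fit <- function(x, ...) {
  plot(predict(x), type = "overall", ...)
}
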