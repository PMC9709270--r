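#' Percentile cutpoints
#'
#' Quantiles by linear interpolation of order statistics with plotting
#' position (k-1)/(n-1) (R's default, type 7). Used for the percentile
#' temperature contrasts (P1/P10/P90/P99), knot placement, and the
#' descriptive summaries, so every percentile in the package follows the
#' same rule.
#'
#' @param x numeric vector; missing values are dropped.
#' @param probs probabilities in \[0, 1\].
#' @return unnamed numeric vector, monotone in `probs`.
#' @export
quantile_cutpoints <- function(x, probs) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no non-missing values in 'x'")
  stopifnot(all(probs >= 0 & probs <= 1))
  unname(quantile(x, probs = probs, type = 7, names = FALSE))
}

#' Natural cubic spline basis specification
#'
#' Describes a natural cubic spline basis with `df` columns (intercept
#' excluded). When `internal_knots` is `NULL` they are derived from the
#' data at evaluation time: `df - 1` knots at equally spaced quantiles,
#' with boundary knots at the data range. For the lag dimension of a
#' cross-basis the input is transformed to `log(1 + lag)` before knot
#' placement and evaluation (`transform = "log1p-lag"`), the standard
#' choice that concentrates flexibility at short lags.
#'
#' @param df number of basis columns (>= 1). With `intercept = FALSE`
#'   (default) the constant function is excluded (it is absorbed by the
#'   model intercept) and a derived basis has `df - 1` internal knots;
#'   with `intercept = TRUE` the basis spans the constant as well and has
#'   `df - 2` internal knots, the convention used for the lag dimension of
#'   a cross-basis, where no separate intercept is available to absorb
#'   uniform-over-lag effects.
#' @param internal_knots optional sorted knot values, on the transformed
#'   scale, strictly inside the boundary.
#' @param boundary_knots optional pair, on the original (untransformed)
#'   scale.
#' @param transform `"identity"` or `"log1p-lag"`.
#' @param intercept whether the basis spans the constant function.
#' @return an object of class `"basis_spec"`.
#' @seealso [natural_spline_basis()], [lag_knots()]
#' @export
basis_spec <- function(df, internal_knots = NULL, boundary_knots = NULL,
                       transform = c("identity", "log1p-lag"),
                       intercept = FALSE) {
  transform <- match.arg(transform)
  stopifnot(length(df) == 1L, df >= 1, df == round(df),
            is.logical(intercept))
  n_internal <- max(0L, df - 1L - as.integer(intercept))
  if (!is.null(boundary_knots))
    stopifnot(length(boundary_knots) == 2L,
              boundary_knots[1L] < boundary_knots[2L])
  if (!is.null(internal_knots)) {
    internal_knots <- sort(internal_knots)
    if (!is.null(boundary_knots)) {
      b <- transform_input(boundary_knots, transform)
      if (any(internal_knots <= b[1L] | internal_knots >= b[2L]))
        stop("internal knots must lie strictly inside the boundary knots")
    }
    if (length(internal_knots) != n_internal)
      stop("need exactly ", n_internal, " internal knots, got ",
           length(internal_knots))
  }
  structure(list(df = as.integer(df), internal_knots = internal_knots,
                 boundary_knots = boundary_knots, transform = transform,
                 intercept = intercept),
            class = "basis_spec")
}

transform_input <- function(x, transform) {
  switch(transform, identity = x, `log1p-lag` = log1p(x))
}

#' Complete a basis specification from data
#'
#' Fills in missing internal and boundary knots from the observed values:
#' boundary at the data range, internal knots at `df - 1` equally spaced
#' quantiles of the (transformed) data.
#'
#' @param spec a [basis_spec()].
#' @param x numeric data the basis will be evaluated on.
#' @return the completed `basis_spec`.
#' @export
complete_spec <- function(spec, x) {
  stopifnot(inherits(spec, "basis_spec"))
  x <- x[!is.na(x)]
  if (!length(x)) stop("no data to derive knots from")
  if (is.null(spec$boundary_knots)) spec$boundary_knots <- range(x)
  n_internal <- spec$df - 1L - as.integer(isTRUE(spec$intercept))
  if (is.null(spec$internal_knots) && n_internal > 0L) {
    tx <- transform_input(x, spec$transform)
    spec$internal_knots <-
      quantile_cutpoints(tx, seq_len(n_internal) / (n_internal + 1L))
  }
  spec
}

#' Evaluate a natural cubic spline basis
#'
#' Returns the `n x df` design block of the natural cubic spline described
#' by `spec`, evaluated at `x`. Each represented function is cubic between
#' adjacent knots, twice continuously differentiable everywhere, and linear
#' beyond the boundary knots; evaluation outside the boundary therefore
#' extrapolates linearly. Missing input values give missing rows.
#'
#' @param x numeric vector.
#' @param spec a [basis_spec()]; incomplete specs are completed from `x`.
#' @return an `n x df` matrix with the completed spec attached as attribute
#'   `"spec"`.
#' @export
natural_spline_basis <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  spec <- complete_spec(spec, x)
  if (length(unique(x[!is.na(x)])) <
        spec$df + 1L - as.integer(isTRUE(spec$intercept)))
    stop("need more than df distinct values (df = ", spec$df,
         ") to span the basis")
  out <- eval_basis(spec, x)
  attr(out, "spec") <- spec
  out
}

## core evaluator: spec must be complete; NA rows propagate
eval_basis <- function(spec, x) {
  tx <- transform_input(x, spec$transform)
  tb <- transform_input(spec$boundary_knots, spec$transform)
  out <- matrix(NA_real_, length(x), spec$df)
  ok <- !is.na(tx)
  icpt <- isTRUE(spec$intercept)
  if (any(ok)) {
    if (icpt && spec$df == 1L) {
      out[ok, 1L] <- 1
    } else if (is.null(spec$internal_knots)) {
      out[ok, ] <- ns(tx[ok], Boundary.knots = tb, intercept = icpt)
    } else {
      out[ok, ] <- ns(tx[ok], knots = spec$internal_knots,
                      Boundary.knots = tb, intercept = icpt)
    }
  }
  out
}

#' Lag-dimension basis specification
#'
#' Natural cubic spline basis for the lag dimension of a cross-basis,
#' with boundary knots at lags 0 and `max_lag` and `df - 2` internal
#' knots at equally spaced quantiles of the integer lags `0..max_lag` —
#' the default knot rule of the software family this analysis descends
#' from when only a lag df is specified. `scale = "log"` instead places
#' the knots (and evaluates the basis) on the `log(1 + l)` scale, which
#' concentrates flexibility at short lags.
#'
#' The basis spans the constant function (`intercept = TRUE`): the lag
#' dimension has no separate model intercept to absorb uniform-over-lag
#' effects, and excluding the constant would force the same-day (lag 0)
#' effect to zero. `df` counts the constant, matching the convention in
#' which "lag df 4" means four cross-basis columns per exposure basis
#' function.
#'
#' @param max_lag maximum lag in days (>= 1).
#' @param df lag-basis dimension; must not exceed `max_lag`.
#' @param scale `"identity"` (default) or `"log"` knot placement.
#' @return a completed [basis_spec()].
#' @export
lag_knots <- function(max_lag, df, scale = c("identity", "log")) {
  scale <- match.arg(scale)
  stopifnot(max_lag >= 1, max_lag == round(max_lag), df >= 1)
  if (df > max_lag)
    stop("lag df (", df, ") must not exceed max_lag (", max_lag, ")")
  transform <- if (scale == "log") "log1p-lag" else "identity"
  lags <- transform_input(0:max_lag, transform)
  knots <- if (df > 2L)
    quantile_cutpoints(lags, seq_len(df - 2L) / (df - 1L))
  basis_spec(df, internal_knots = knots,
             boundary_knots = c(0, max_lag), transform = transform,
             intercept = TRUE)
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("Natural cubic spline basis: df ", x$df,
      if (x$transform != "identity") paste0(" on ", x$transform, " scale"),
      "\n", sep = "")
  if (!is.null(x$internal_knots))
    cat("  internal knots: ",
        paste(signif(x$internal_knots, 4L), collapse = ", "), "\n", sep = "")
  if (!is.null(x$boundary_knots))
    cat("  boundary: [", x$boundary_knots[1L], ", ", x$boundary_knots[2L],
        "]\n", sep = "")
  invisible(x)
}
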