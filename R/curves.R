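#' Causal exposure-outcome curves
#'
#' Constructors for the causal dose-response curves the cohort simulator can
#' impose between log-alcohol exposure and a lipid outcome (on that lipid's
#' analysis scale, i.e. the natural-log scale for log-transformed lipids and
#' mg/dL otherwise).
#'
#' * `causal_null()` — no causal effect.
#' * `causal_linear(beta)` — mean outcome shifts by `beta` per unit of
#'   log-alcohol, i.e. per unit of ln(g/wk + 1).
#' * `causal_peaked(rise, peak, decline)` — a piecewise-linear "tent": the
#'   mean outcome rises with slope `rise` up to `peak` (log-alcohol units)
#'   and falls with slope `decline` beyond it.  A beneficial effect that is
#'   strongest at moderate intake and attenuates at heavy intake is encoded
#'   with `rise < 0` and `decline < 0` reversed accordingly; sign conventions
#'   are the caller's.
#'
#' @param beta slope per unit log-alcohol.
#' @param rise slope below the peak, per unit log-alcohol.
#' @param peak peak location on the ln(g/wk + 1) scale.
#' @param decline slope magnitude above the peak (the curve changes by
#'   `-decline` per unit log-alcohol beyond `peak`).
#' @return An object of class `mr_curve`.
#' @examples
#' curve_value(causal_linear(-0.13), c(0, 1, 2))
#' curve_value(causal_peaked(0.5, 2.5, 1.0), c(0, 2.5, 4))
#' @export
causal_null <- function() {
  structure(list(kind = "null"), class = "mr_curve")
}

#' @rdname causal_null
#' @export
causal_linear <- function(beta) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  structure(list(kind = "linear", beta = beta), class = "mr_curve")
}

#' @rdname causal_null
#' @export
causal_peaked <- function(rise, peak, decline) {
  stopifnot(is.numeric(rise), is.numeric(peak), is.numeric(decline),
            is.finite(rise), is.finite(peak), is.finite(decline))
  structure(list(kind = "peaked", rise = rise, peak = peak,
                 decline = decline), class = "mr_curve")
}

#' Evaluate a causal curve
#'
#' @param curve an `mr_curve` object.
#' @param x log-alcohol values, ln(g/wk + 1).
#' @return numeric vector of causal mean shifts, same length as `x`.
#' @export
curve_value <- function(curve, x) {
  if (!inherits(curve, "mr_curve")) {
    stop("`curve` must be an mr_curve object (see causal_null()).",
         call. = FALSE)
  }
  switch(curve$kind,
    null   = rep(0, length(x)),
    linear = curve$beta * x,
    peaked = curve$rise * pmin(x, curve$peak) -
             curve$decline * pmax(x - curve$peak, 0),
    stop("unknown causal curve kind: ", curve$kind, call. = FALSE)
  )
}

#' @export
print.mr_curve <- function(x, ...) {
  desc <- switch(x$kind,
    null   = "null (no causal effect)",
    linear = sprintf("linear, beta = %g per ln(g/wk + 1)", x$beta),
    peaked = sprintf("peaked, rise %g up to %g, decline %g beyond",
                     x$rise, x$peak, x$decline))
  cat("<mr_curve> ", desc, "\n", sep = "")
  invisible(x)
}

# serializable form used for the true-parameter JSON round trip
curve_to_list <- function(curve) unclass(curve)

curve_from_list <- function(x) {
  switch(x$kind,
    null   = causal_null(),
    linear = causal_linear(x$beta),
    peaked = causal_peaked(x$rise, x$peak, x$decline),
    stop("unknown causal curve kind: ", x$kind, call. = FALSE))
}
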