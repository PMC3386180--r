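#' Hill promoter response
#'
#' Saturating promoter occupancy used throughout the gene regulatory
#' network. The activating form is \code{x^h / (K^h + x^h)}, the inhibiting
#' form \code{K^h / (K^h + x^h)}; for equal \code{(K, h)} the two are exact
#' complements.
#'
#' @param x concentration (arbitrary units), non-negative; vectorised.
#' @param spec a \code{\link{hill_spec}}.
#' @return fraction in \code{[0, 1]}, same length as \code{x}.
#' @export
hill <- function(x, spec) {
  stopifnot(inherits(spec, "hill_spec"))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("hill(): input concentration must be finite and >= 0")
  }
  if (spec$mode == "activating") {
    hill_act(x, spec$threshold, spec$coefficient)
  } else {
    hill_inh(x, spec$threshold, spec$coefficient)
  }
}

#' @rdname hill
#' @param threshold half-saturation concentration K (a.u.), > 0.
#' @param coefficient Hill coefficient h (cooperativity), >= 1.
#' @param mode \code{"activating"} or \code{"inhibiting"}.
#' @export
hill_spec <- function(threshold, coefficient, mode = c("activating", "inhibiting")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0,
            is.numeric(coefficient), length(coefficient) == 1L, coefficient >= 1)
  structure(list(threshold = threshold, coefficient = coefficient, mode = mode),
            class = "hill_spec")
}

# Internal fast forms (no spec object); used by the RHS where the promoter
# wiring is fixed. Written as (x/K)^h to stay stable for large x.
hill_act <- function(x, K, h) {
  r <- (x / K)^h
  r / (1 + r)
}

hill_inh <- function(x, K, h) {
  1 / (1 + (x / K)^h)
}
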