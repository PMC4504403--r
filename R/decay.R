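#' Distance-decay (impedance) specifications
#'
#' A decay spec encodes the willingness to travel as a weight `w(d)` in
#' `[0, 1]`, non-increasing in distance `d` (miles), with a hard cutoff
#' beyond which `w(d) = 0` and a facility is considered unreachable.
#' Five families are available:
#'
#' * `decay_exponential()`: `w(d) = exp(-lambda * d)`. The default `lambda`
#'   is chosen so that `w(cutoff) = 0.01`, i.e. willingness has essentially
#'   vanished at the cutoff. Suited to rare-disease specialty care where
#'   patients travel far.
#' * `decay_gaussian()`: `w(d) = exp(-d^2 / (2 * sigma^2))`; default `sigma`
#'   again puts `w(cutoff) = 0.01`.
#' * `decay_inverse_power()`: `w(d) = (1 + d / scale)^(-power)`, a
#'   heavy-tailed impedance bounded by 1 at the origin.
#' * `decay_step_zones()`: the classic zoned weights of the enhanced
#'   two-step floating catchment method: zone `r` covers distances in the
#'   half-open interval `[bounds[r-1], bounds[r])` and carries weight
#'   `weights[r]`; beyond the last bound the weight is 0.
#' * `decay_constant()`: a single catchment zone of constant weight up to
#'   the cutoff (the original 2SFCA).
#'
#' @param lambda,sigma,power,scale Family parameters; see Details.
#' @param weight Constant weight for `decay_constant()`, in `(0, 1]`.
#' @param bounds Strictly increasing zone upper bounds (miles).
#' @param weights Non-increasing zone weights in `[0, 1]`.
#' @param cutoff Hard cutoff distance in miles; `w(d) = 0` for `d > cutoff`.
#'
#' @return An object of class `decay_spec`.
#' @examples
#' dec <- decay_exponential(cutoff = 150)
#' decay_weight(dec, c(0, 75, 150, 151))
#'
#' zones <- decay_step_zones(bounds = c(10, 20, 30), weights = c(1, 0.6, 0.2))
#' decay_weight(zones, 15)
#' @export
decay_exponential <- function(lambda = NULL, cutoff = 150) {
  if (is.null(lambda)) lambda <- -log(0.01) / cutoff
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  new_decay_spec("exponential", list(lambda = lambda), cutoff)
}

#' @rdname decay_exponential
#' @export
decay_gaussian <- function(sigma = NULL, cutoff = 150) {
  if (is.null(sigma)) sigma <- cutoff / sqrt(-2 * log(0.01))
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  new_decay_spec("gaussian", list(sigma = sigma), cutoff)
}

#' @rdname decay_exponential
#' @export
decay_inverse_power <- function(power = 2, scale = 10, cutoff = 150) {
  stopifnot(power > 0, scale > 0)
  new_decay_spec("inverse_power", list(power = power, scale = scale), cutoff)
}

#' @rdname decay_exponential
#' @export
decay_step_zones <- function(bounds, weights, cutoff = max(bounds)) {
  if (length(bounds) != length(weights)) {
    stop("`bounds` and `weights` must have equal length", call. = FALSE)
  }
  if (any(diff(bounds) <= 0)) {
    stop("zone `bounds` must be strictly increasing", call. = FALSE)
  }
  if (any(diff(weights) > 0)) {
    stop("zone `weights` must be non-increasing", call. = FALSE)
  }
  if (any(weights < 0 | weights > 1)) {
    stop("zone `weights` must lie in [0, 1]", call. = FALSE)
  }
  new_decay_spec("step_zones", list(bounds = bounds, weights = weights),
                 min(cutoff, max(bounds)))
}

#' @rdname decay_exponential
#' @export
decay_constant <- function(weight = 1, cutoff = 150) {
  stopifnot(weight > 0, weight <= 1)
  new_decay_spec("constant", list(weight = weight), cutoff)
}

new_decay_spec <- function(family, params, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  structure(list(family = family, params = params, cutoff = cutoff),
            class = "decay_spec")
}

#' Evaluate a decay spec at given distances
#'
#' @param decay A [`decay_spec`][decay_exponential] object.
#' @param d Vector of non-negative distances in miles.
#' @return Numeric vector of weights in `[0, 1]`; 0 beyond the cutoff.
#' @export
decay_weight <- function(decay, d) {
  stopifnot(inherits(decay, "decay_spec"))
  if (!is.numeric(d) || anyNA(d)) stop("distances must be numeric and non-missing", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  p <- decay$params
  w <- switch(decay$family,
    exponential   = exp(-p$lambda * d),
    gaussian      = exp(-d^2 / (2 * p$sigma^2)),
    inverse_power = (1 + d / p$scale)^(-p$power),
    constant      = rep(p$weight, length(d)),
    step_zones    = {
      # half-open zones [D_{r-1}, D_r); beyond the last bound -> 0
      idx <- findInterval(d, c(-Inf, p$bounds))
      c(p$weights, 0)[pmin(idx, length(p$weights) + 1L)]
    },
    stop("unknown decay family: ", decay$family, call. = FALSE)
  )
  w[d > decay$cutoff] <- 0
  w
}

#' Invert a decay spec (distance at which a given weight is attained)
#'
#' Only defined for strictly decreasing families (exponential, gaussian,
#' inverse power). Used by the toy-system generator to place locations so
#' that stated distance weights and distances are mutually consistent.
#'
#' @param decay A decay spec.
#' @param w Weights in `(0, 1]`.
#' @return Distances `d` such that `decay_weight(decay, d) == w`; weights of
#'   0 map to twice the cutoff (unreachable).
#' @keywords internal
decay_inverse <- function(decay, w) {
  stopifnot(inherits(decay, "decay_spec"), all(w >= 0), all(w <= 1))
  p <- decay$params
  d <- switch(decay$family,
    exponential   = -log(w) / p$lambda,
    gaussian      = sqrt(-2 * p$sigma^2 * log(w)),
    inverse_power = p$scale * (w^(-1 / p$power) - 1),
    stop("decay_inverse is only defined for strictly decreasing families",
         call. = FALSE)
  )
  d[w == 0] <- 2 * decay$cutoff
  d
}

#' @export
print.decay_spec <- function(x, ...) {
  pars <- paste(names(x$params), vapply(x$params, function(p)
    paste(signif(p, 4), collapse = ","), ""), sep = "=", collapse = ", ")
  cat(sprintf("<decay_spec> family=%s (%s), cutoff=%g miles\n",
              x$family, pars, x$cutoff))
  invisible(x)
}

#' Plot a decay spec
#'
#' @param object A decay spec.
#' @param max_d Largest distance to draw, default slightly past the cutoff.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.decay_spec <- function(object, max_d = 1.1 * object$cutoff, ...) {
  d <- seq(0, max_d, length.out = 512)
  df <- tibble::tibble(distance = d, weight = decay_weight(object, d))
  ggplot2::ggplot(df, ggplot2::aes(.data$distance, .data$weight)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "distance (miles)", y = "w(d)",
                  title = sprintf("%s decay, cutoff %g miles",
                                  object$family, object$cutoff)) +
    ggplot2::ylim(0, 1)
}
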