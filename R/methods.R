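#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a centralized assignment
#'
#' @param x An `access_assignment` from [solve_access()] or
#'   [brute_force_small()].
#' @param ... Ignored.
#' @return Long tibble of nonzero assignments: `community_id`,
#'   `facility_id`, `fraction`, `realized_visits`.
#' @export
tidy.access_assignment <- function(x, ...) {
  idx <- which(x$assignment > 1e-12, arr.ind = TRUE)
  out <- tibble::tibble(
    community_id = x$community_id[idx[, 1]],
    facility_id = x$facility_id[idx[, 2]],
    fraction = x$assignment[idx],
    realized_visits = x$realized[idx])
  dplyr::arrange(out, .data$community_id, .data$facility_id)
}

#' @rdname tidy.access_assignment
#' @export
glance.access_assignment <- function(x, ...) {
  tibble::tibble(
    model = x$model, status = x$status, objective = x$objective,
    distance_term = x$distance_term, congestion_term = x$congestion_term,
    total_realized = sum(x$realized), total_unmet = sum(x$unmet),
    sweeps = x$sweeps, max_kkt_residual = x$max_kkt_residual,
    n_binding_capacity = length(x$binding_capacity))
}

#' @export
print.access_assignment <- function(x, ...) {
  cat(sprintf("<access_assignment> %s, status %s\n", x$model, x$status))
  cat(sprintf("  objective %.6g = distance %.6g + congestion %.6g\n",
              x$objective, x$distance_term, x$congestion_term))
  cat(sprintf("  realized visits %.6g (unmet %.6g) over %d facilities\n",
              sum(x$realized), sum(x$unmet), length(x$loads)))
  invisible(x)
}

#' Tidy a decentralized (equilibrium) assignment
#'
#' @param x A `visit_assignment` from [solve_equilibrium()].
#' @param ... Ignored.
#' @return The visit-level choice tibble.
#' @export
tidy.visit_assignment <- function(x, ...) x$choices

#' @rdname tidy.visit_assignment
#' @export
glance.visit_assignment <- function(x, ...) {
  tibble::tibble(
    model = x$model, converged = x$converged, sweeps = x$sweeps,
    total_visits = nrow(x$choices), epsilon = x$epsilon,
    potential = if (nrow(x$log)) x$log$potential[nrow(x$log)] else 0,
    n_unassigned_communities = length(x$unassigned))
}

#' @export
print.visit_assignment <- function(x, ...) {
  cat(sprintf("<visit_assignment> decentralized, %s after %d sweeps\n",
              if (x$converged) "equilibrium" else "NOT converged", x$sweeps))
  cat(sprintf("  %d visits over %d facilities, epsilon %.3g\n",
              nrow(x$choices), length(x$loads), x$epsilon))
  invisible(x)
}

#' Plot facility loads of an assignment
#'
#' @param object An `access_assignment` or `visit_assignment`.
#' @param ... Ignored.
#' @return A ggplot bar chart of realized load per facility.
#' @export
autoplot.access_assignment <- function(object, ...) {
  df <- tibble::enframe(object$loads, "facility_id", "load")
  ggplot2::ggplot(df, ggplot2::aes(.data$facility_id, .data$load)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "realized visits",
                  title = sprintf("Facility loads (%s)", object$model)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname autoplot.access_assignment
#' @export
autoplot.visit_assignment <- autoplot.access_assignment

#' Plot an access profile
#'
#' Draws a map of communities colored by a measure when coordinates are
#' available, otherwise a histogram of the measure.
#'
#' @param object An [access_profile()] tibble.
#' @param measure Column to display (default `"AE"`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.access_profile <- function(object, measure = "AE", ...) {
  if (all(c("x", "y") %in% names(object))) {
    ggplot2::ggplot(object,
                    ggplot2::aes(.data$x, .data$y, colour = .data[[measure]],
                                 size = .data$needed)) +
      ggplot2::geom_point() +
      ggplot2::scale_colour_viridis_c() +
      ggplot2::coord_equal() +
      ggplot2::labs(title = sprintf("Community %s", measure),
                    x = "miles", y = "miles")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data[[measure]])) +
      ggplot2::geom_histogram(bins = 30) +
      ggplot2::labs(title = sprintf("Distribution of %s", measure))
  }
}

#' Plot per-community access gains
#'
#' @param gain An [access_gain()] result.
#' @param measure Delta column to display (without the `delta_` prefix).
#' @return A ggplot histogram of deltas.
#' @export
plot_access_gain <- function(gain, measure = "AE") {
  col <- paste0("delta_", measure)
  ggplot2::ggplot(gain, ggplot2::aes(.data[[col]])) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("change in %s (after - before)", measure))
}
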