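#' Facility supply-to-visits ratios
#'
#' Step 1 of the floating-catchment family: for each facility `j`, the
#' ratio of its supply to the decay-weighted visit demand it captures,
#' `R_j = S_j / sum_i V_i w(d_ij)`. Zoned weights are obtained by choosing
#' a `decay_step_zones()` spec for the network; a continuous decay is the
#' limiting many-zone form. For the three-step method the demand captured
#' is additionally multiplied by the distance-based selection weight
#' `G_ij = w(d_ij) / sum_k w(d_ik)`, so each community's demand is split
#' across facilities instead of fully counted by every overlapping
#' catchment.
#'
#' A facility capturing no weighted demand is unused: its ratio is reported
#' as `Inf` with a warning, and it is excluded from accessibility sums.
#'
#' @param network An [access_network()].
#' @param method One of `"e2sfca"`, `"m2sfca"`, `"3sfca"` (E2SFCA and
#'   M2SFCA share the same ratio).
#' @return A tibble with columns `facility_id`, `method`, `ratio`.
#' @export
facility_ratio <- function(network, method = c("e2sfca", "m2sfca", "3sfca")) {
  method <- match.arg(method)
  W <- net_weights(network)
  V <- net_demand(network)
  capture <- if (method == "3sfca") selection_weights(network) * W else W
  denom <- colSums(capture * V)
  ratio <- ifelse(denom > 0, network$facilities$supply / denom, Inf)
  if (any(denom == 0)) {
    warning("facilities capturing no weighted demand (ratio = Inf): ",
            paste(network$facilities$id[denom == 0], collapse = ", "),
            call. = FALSE)
  }
  tibble::tibble(facility_id = network$facilities$id, method = method,
                 ratio = ratio)
}

# G_ij = w_ij / sum_k w_ik over eligible facilities; rows with no
# reachable facility are all zero.
selection_weights <- function(network) {
  W <- net_weights(network)
  tot <- rowSums(W)
  G <- W / ifelse(tot > 0, tot, 1)
  G[tot == 0, ] <- 0
  G
}

#' Catchment-family accessibility measures
#'
#' Per-community potential accessibility under the gravity model and the
#' floating catchment area family:
#'
#' * `gravity`: `A_i^G = sum_j S_j w(d_ij) / sum_k P_k w(d_kj)` (population
#'   in the denominator).
#' * `e2sfca`: `A_i^E = sum_j R_j w(d_ij)` with the supply-to-visits ratio
#'   `R_j` of [facility_ratio()].
#' * `m2sfca`: `A_i^M = sum_j R_j w(d_ij)^2` — the distance weight applied
#'   twice, discounting the value of supply that is merely reachable.
#' * `3sfca`: `A_i^3 = sum_j G_ij R_j w(d_ij)` with distance-based
#'   selection weights `G_ij` applied in both steps, so overlapping
#'   catchments do not double-count demand.
#'
#' Facilities with infinite ratio (unused) contribute nothing; communities
#' with no facility inside the cutoff score 0.
#'
#' @param network An [access_network()].
#' @param method Character vector of methods among `"gravity"`, `"e2sfca"`,
#'   `"m2sfca"`, `"3sfca"`; results are stacked.
#' @return A tibble with columns `community_id`, `method`, `accessibility`.
#' @examples
#' net <- toy_system(6)
#' catchment_accessibility(net, c("e2sfca", "m2sfca"))
#' @export
catchment_accessibility <- function(network, method = "e2sfca") {
  method <- match.arg(method, c("gravity", "e2sfca", "m2sfca", "3sfca"),
                      several.ok = TRUE)
  purrr::map_dfr(method, function(m) {
    a <- switch(m,
      gravity = gravity_values(network),
      e2sfca  = fca_values(network, square = FALSE),
      m2sfca  = fca_values(network, square = TRUE),
      `3sfca` = three_step_values(network)
    )
    tibble::tibble(community_id = network$communities$id, method = m,
                   accessibility = a)
  })
}

gravity_values <- function(network) {
  W <- net_weights(network)
  P <- network$communities$population
  denom <- colSums(W * P)
  share <- ifelse(denom > 0, network$facilities$supply / denom, 0)
  as.numeric(W %*% share)
}

fca_values <- function(network, square) {
  W <- net_weights(network)
  R <- facility_ratio(network, if (square) "m2sfca" else "e2sfca")$ratio
  Wuse <- if (square) W^2 else W
  Ruse <- ifelse(is.finite(R), R, 0)
  as.numeric(Wuse %*% Ruse)
}

three_step_values <- function(network) {
  W <- net_weights(network)
  G <- selection_weights(network)
  R <- suppressWarnings(facility_ratio(network, "3sfca")$ratio)
  Ruse <- ifelse(is.finite(R), R, 0)
  as.numeric((G * W) %*% Ruse)
}

#' Visit mass implied by a catchment method
#'
#' The demand each facility's denominator counts: `sum_i V_i w(d_ij)` for
#' E2SFCA/M2SFCA (every overlapping catchment counts the community in
#' full), `sum_i G_ij V_i w(d_ij)` for 3SFCA, and `sum_i P_i w(d_ij)` for
#' the gravity model. With overlapping catchments the E2SFCA total exceeds
#' the assignment-based realized total and can exceed the total demand
#' itself; under 3SFCA the selection weights sum to at most one per
#' community, so the implied total never exceeds total demand.
#'
#' @param network An [access_network()].
#' @param method One of `"e2sfca"`, `"m2sfca"`, `"3sfca"`, `"gravity"`.
#' @return A tibble with columns `facility_id`, `method`, `implied_visits`;
#'   sum the column for the network total.
#' @export
implied_visits <- function(network, method = c("e2sfca", "m2sfca", "3sfca", "gravity")) {
  method <- match.arg(method)
  W <- net_weights(network)
  mass <- switch(method,
    e2sfca  = ,
    m2sfca  = colSums(W * net_demand(network)),
    `3sfca` = colSums(selection_weights(network) * W * net_demand(network)),
    gravity = colSums(W * network$communities$population)
  )
  tibble::tibble(facility_id = network$facilities$id, method = method,
                 implied_visits = mass)
}
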