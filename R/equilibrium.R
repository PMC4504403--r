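#' Decentralized user-choice (equilibrium) model
#'
#' Each annual visit is a unit player that picks the facility minimizing
#' its own cost, distance plus linear congestion `d_ij + alpha_j * L_j`
#' where `L_j` is the facility's total assigned visits. A profile is an
#' epsilon-equilibrium when no visit can lower its cost by more than
#' `epsilon` by switching: for its current facility `j` and every
#' alternative `q`,
#' `d_ij + alpha_j L_j <= d_iq + alpha_q (L_q + 1) + epsilon`
#' (the deviating visit's current load includes itself; the destination
#' load counts the arrival).
#'
#' Because willingness to travel decays with distance, each community
#' enters with `round(v_i * w(d_i, nearest eligible))` visits to place;
#' unreachable communities contribute no visits and are flagged.
#'
#' The solver runs best-response dynamics: sweeping visits in a fixed
#' deterministic order (community id, then visit index), each visit moves
#' to its best response whenever that improves its cost by more than
#' `epsilon`. This is a congestion game; with equal congestion weights
#' every improving move strictly decreases the Rosenthal potential
#' `sum d + sum_j alpha_j L_j (L_j + 1) / 2`, so the dynamics terminate at
#' a pure Nash equilibrium. The potential is logged per sweep.
#'
#' @param network An [access_network()].
#' @param init `"nearest"` starts every visit at its nearest eligible
#'   facility; `"random"` draws initial facilities (requires `seed`).
#' @param seed Integer seed for random initialization.
#' @param max_sweeps Sweep limit; if reached without convergence the result
#'   carries `converged = FALSE` and the largest remaining deviation gain.
#' @param epsilon Equilibrium slack; default `1e-9 * max(d)`.
#' @param alpha Optional override of facility congestion weights.
#' @return An object of class `visit_assignment` with elements `choices`
#'   (tibble: `community_id`, `visit_index`, `facility_id`), `loads`,
#'   `epsilon`, `converged`, `sweeps`, `log` (per-sweep potential and move
#'   count), and `unassigned` (flagged communities with no eligible
#'   facility).
#' @examples
#' net <- toy_system(6)
#' eq <- solve_equilibrium(net)
#' glance(eq)
#' @export
solve_equilibrium <- function(network, init = c("nearest", "random"),
                              seed = NULL, max_sweeps = 1000L,
                              epsilon = NULL, alpha = NULL) {
  init <- match.arg(init)
  D <- unname(network$distances)
  W <- net_weights(network)
  alpha <- resolve_alpha(network, alpha)
  if (is.null(epsilon)) epsilon <- 1e-9 * max(D, 1)
  n <- nrow(D); m <- ncol(D)
  elig <- network$eligible

  # visits to place per community: demand thinned by decay at the nearest
  # eligible facility
  n_visits <- integer(n)
  for (i in seq_len(n)) {
    js <- which(elig[i, ])
    if (length(js)) {
      jn <- js[which.min(D[i, js])]
      n_visits[i] <- round(net_demand(network)[i] * W[i, jn])
    }
  }
  unassigned <- network$communities$id[rowSums(elig) == 0L &
                                         net_demand(network) > 0]

  ord <- order(network$communities$id)
  choice <- vector("list", n)
  loads <- numeric(m)
  if (init == "random" && is.null(seed)) {
    stop("random initialization requires an explicit seed", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(n)) {
    if (n_visits[i] == 0L) { choice[[i]] <- integer(0); next }
    js <- which(elig[i, ])
    ini <- if (init == "nearest") rep(js[which.min(D[i, js])], n_visits[i])
           else sample(js, n_visits[i], replace = TRUE)
    choice[[i]] <- ini
    loads <- loads + tabulate(ini, m)
  }

  log_rows <- vector("list", max_sweeps)
  sweeps <- 0L; converged <- FALSE; largest_gain <- 0
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    moves <- 0L
    for (i in ord) {
      ch <- choice[[i]]
      if (!length(ch)) next
      js <- which(elig[i, ])
      di <- D[i, js]; aj <- alpha[js]
      for (k in seq_along(ch)) {
        j0 <- ch[k]
        pos0 <- match(j0, js)
        cost_cur <- D[i, j0] + alpha[j0] * loads[j0]
        cost_alt <- di + aj * (loads[js] + 1)
        cost_alt[pos0] <- cost_cur  # incumbent keeps its seat on ties
        best <- which.min(cost_alt)
        if (cost_cur - cost_alt[best] > epsilon) {
          q <- js[best]
          loads[j0] <- loads[j0] - 1
          loads[q] <- loads[q] + 1
          ch[k] <- q
          moves <- moves + 1L
        }
      }
      choice[[i]] <- ch
    }
    log_rows[[sweeps]] <- tibble::tibble(
      sweep = sweeps, moves = moves,
      potential = potential_from(D, alpha, choice, loads))
    if (moves == 0L) { converged <- TRUE; break }
  }

  choices <- purrr::map_dfr(seq_len(n), function(i) {
    if (!length(choice[[i]])) return(NULL)
    tibble::tibble(community_id = network$communities$id[i],
                   visit_index = seq_along(choice[[i]]),
                   facility_id = network$facilities$id[choice[[i]]])
  })
  out <- structure(list(
    choices = choices,
    loads = stats::setNames(loads, network$facilities$id),
    epsilon = epsilon, converged = converged, sweeps = sweeps,
    log = dplyr::bind_rows(log_rows[seq_len(sweeps)]),
    unassigned = unassigned, alpha = stats::setNames(alpha, network$facilities$id),
    n_visits = stats::setNames(n_visits, network$communities$id),
    model = "decentralized"
  ), class = "visit_assignment")
  if (!converged) {
    out$largest_gain <- max(verify_equilibrium(network, out, epsilon)$gain, 0)
    warning("best-response dynamics hit max_sweeps without converging",
            call. = FALSE)
  }
  out
}

potential_from <- function(D, alpha, choice, loads) {
  d_sum <- 0
  for (i in seq_along(choice)) {
    if (length(choice[[i]])) d_sum <- d_sum + sum(D[i, choice[[i]]])
  }
  d_sum + sum(alpha * loads * (loads + 1) / 2)
}

#' Rosenthal potential of a visit assignment
#'
#' `sum of assigned distances + sum_j alpha_j L_j (L_j + 1) / 2`. Every
#' improving move under equal congestion weights strictly decreases it,
#' which is what guarantees best-response dynamics terminate.
#'
#' @param network An [access_network()].
#' @param assignment A [solve_equilibrium()] result.
#' @return A scalar.
#' @export
potential_value <- function(network, assignment) {
  stopifnot(inherits(assignment, "visit_assignment"))
  ch <- assignment$choices
  if (nrow(ch) == 0) return(0)
  ci <- match(ch$community_id, network$communities$id)
  fi <- match(ch$facility_id, network$facilities$id)
  loads <- tabulate(fi, nrow(network$facilities))
  alpha <- assignment$alpha[network$facilities$id]
  sum(network$distances[cbind(ci, fi)]) +
    sum(alpha * loads * (loads + 1) / 2)
}

#' Check the equilibrium condition of a visit assignment
#'
#' Recomputes facility loads from the choices (verifying self-consistency
#' with the stored loads) and tests, for every assigned visit and every
#' eligible alternative facility, whether switching would reduce the
#' visit's cost by more than `epsilon`. An empty result certifies an
#' epsilon-equilibrium.
#'
#' @param network An [access_network()].
#' @param assignment A `visit_assignment`.
#' @param epsilon Slack; defaults to the assignment's own.
#' @return A tibble of violations: `community_id`, `visit_index`,
#'   `facility_id` (current), `alternative_id`, `gain` (> epsilon).
#' @export
verify_equilibrium <- function(network, assignment, epsilon = assignment$epsilon) {
  stopifnot(inherits(assignment, "visit_assignment"))
  ch <- assignment$choices
  m <- nrow(network$facilities)
  fi_all <- match(ch$facility_id, network$facilities$id)
  loads <- tabulate(fi_all, m)
  if (!isTRUE(all.equal(unname(assignment$loads[network$facilities$id]),
                        as.numeric(loads)))) {
    stop("assignment loads are not consistent with its choices", call. = FALSE)
  }
  alpha <- unname(assignment$alpha[network$facilities$id])
  D <- network$distances
  out <- list()
  # all visits of a community at the same facility face the same test
  groups <- dplyr::summarise(
    dplyr::group_by(ch, .data$community_id, .data$facility_id),
    visit_index = list(.data$visit_index), .groups = "drop")
  for (g in seq_len(nrow(groups))) {
    i <- match(groups$community_id[g], network$communities$id)
    j <- match(groups$facility_id[g], network$facilities$id)
    js <- which(network$eligible[i, ])
    cost_cur <- D[i, j] + alpha[j] * loads[j]
    alts <- setdiff(js, j)
    if (!length(alts)) next
    gains <- cost_cur - (D[i, alts] + alpha[alts] * (loads[alts] + 1))
    bad <- gains > epsilon
    if (any(bad)) {
      out[[length(out) + 1L]] <- tidyr::crossing(
        tibble::tibble(community_id = groups$community_id[g],
                       facility_id = groups$facility_id[g],
                       visit_index = groups$visit_index[[g]]),
        tibble::tibble(alternative_id = network$facilities$id[alts[bad]],
                       gain = gains[bad]))
    }
  }
  if (!length(out)) {
    return(tibble::tibble(community_id = character(), visit_index = integer(),
                          facility_id = character(),
                          alternative_id = character(), gain = numeric()))
  }
  dplyr::bind_rows(out)[, c("community_id", "visit_index", "facility_id",
                            "alternative_id", "gain")]
}
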