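#' Centralized optimization model of spatial access
#'
#' A planner assigns each community's annual visits across eligible
#' facilities to minimize total travel plus congestion,
#' \deqn{\min \sum_{ij} d_{ij} r_{ij} + \sum_j \alpha_j \Big(\sum_i r_{ij}\Big)^2}
#' subject to each community's assignment fractions summing to one. The
#' congestion term is quadratic in facility load: if a facility serves `L`
#' visits, each of them experiences congestion proportional to `L`, for a
#' total of `L^2`, scaled by the facility's congestion weight `alpha_j`.
#' With `alpha = 0` the model reduces to nearest-facility assignment; as
#' `alpha` grows with equal weights it equalizes facility loads.
#'
#' When `decay_scaled = TRUE` (default) the realized visits are
#' `r_ij = v_i w(d_ij) x_ij`: willingness to travel decays with distance,
#' so the visits actually made — and the congestion they cause — shrink for
#' far assignments, and network coverage can fall below 100%. With
#' `decay_scaled = FALSE` the raw `r_ij = v_i x_ij` is used.
#'
#' The problem is a convex QP. It is solved by exact block coordinate
#' descent: each community's subproblem (a quadratic over its simplex) is
#' solved to machine precision by bisection on the KKT multiplier, and
#' sweeps repeat until the maximum complementarity residual falls below
#' `tol` (relative to the largest marginal cost). Capacity constraints are
#' enforced by projected dual ascent on per-facility prices.
#'
#' @param network An [access_network()].
#' @param alpha Optional scalar or per-facility vector overriding the
#'   facilities' `congestion_weight`.
#' @param capacity If `TRUE`, enforce `load_j <= capacity_j` (visits/year)
#'   for facilities with finite capacity.
#' @param dummy_unmet If `TRUE`, add a dummy facility (distance twice the
#'   network maximum, `alpha = 0`) that absorbs demand that cannot or
#'   should not be met; required when some community has no eligible
#'   facility.
#' @param decay_scaled Scale visits by the decay weight (see Details).
#' @param tol Relative KKT (stationarity) tolerance.
#' @param max_sweeps Maximum coordinate-descent sweeps per solve.
#' @return An object of class `access_assignment`: assignment fractions,
#'   realized visit matrix, facility loads, objective terms, and solver
#'   diagnostics. Use [tidy()] for the long assignment table, [glance()]
#'   for a one-row summary, and [access_profile()] for per-community
#'   access measures.
#' @examples
#' net <- toy_system(6)
#' fit <- solve_access(net)
#' glance(fit)
#' @export
solve_access <- function(network, alpha = NULL, capacity = FALSE,
                         dummy_unmet = FALSE, decay_scaled = TRUE,
                         tol = 1e-8, max_sweeps = 10000L) {
  prob <- build_problem(network, alpha, dummy_unmet, decay_scaled,
                        dummy_for_all = capacity)
  n <- nrow(prob$D); m <- ncol(prob$D)

  no_choice <- prob$active[vapply(prob$jsets[prob$active], length, 1L) == 0L]
  if (length(no_choice)) {
    stop("communities with no eligible facility (enable dummy_unmet or fix the network): ",
         paste(network$communities$id[no_choice], collapse = ", "), call. = FALSE)
  }

  cap <- if (capacity) prob$cap else rep(NA_real_, m)
  use_cap <- any(is.finite(cap))
  beta <- rep(0, m)
  alpha_solve <- prob$alpha
  if (use_cap && min(prob$alpha[is.finite(cap)]) <= 0) {
    # strict convexity needed for dual ascent on capacity prices
    alpha_solve <- pmax(prob$alpha, 1e-6 * max(prob$D) / max(1, sum(prob$M)))
  }

  x <- init_nearest(prob)
  outer_max <- if (use_cap) 120L else 1L
  step <- if (use_cap) 2 * min(alpha_solve[is.finite(cap)]) else 0
  res <- NULL
  cap_ok <- !use_cap
  for (outer in seq_len(outer_max)) {
    # loose inner solves while the capacity prices are still moving
    tol_inner <- if (use_cap && outer < outer_max) max(tol, 1e-4 * 0.7^outer) else tol
    res <- cd_solve(x, prob, beta, alpha_solve, tol_inner, max_sweeps)
    x <- res$x
    if (!use_cap) break
    excess <- ifelse(is.finite(cap), res$loads - cap, 0)
    cap_scale <- max(1, cap[is.finite(cap)])
    if (max(excess) <= 1e-6 * cap_scale) {
      res <- cd_solve(x, prob, beta, alpha_solve, tol, max_sweeps)
      x <- res$x
      excess <- ifelse(is.finite(cap), res$loads - cap, 0)
      if (max(excess) <= 1e-5 * cap_scale) { cap_ok <- TRUE; break }
    }
    beta <- pmax(0, beta + step * excess)
  }
  if (use_cap && !cap_ok) {
    warning("capacity dual ascent did not converge; largest violation ",
            signif(max(ifelse(is.finite(cap), res$loads - cap, 0)), 3),
            " visits", call. = FALSE)
  }

  r <- prob$M * x
  loads <- colSums(r)
  dist_term <- sum(prob$LIN * x)
  cong_term <- sum(prob$alpha * loads^2)
  real_j <- seq_len(m) <= prob$m_real
  binding <- network$facilities$id[is.finite(cap[real_j]) &
                                     (beta[real_j] > 1e-10 * max(1, max(beta)) |
                                        loads[real_j] >= cap[real_j] * (1 - 1e-3))]

  structure(list(
    assignment = x[, real_j, drop = FALSE],
    realized = r[, real_j, drop = FALSE],
    unmet = if (prob$has_dummy) r[, m] else rep(0, n),
    loads = stats::setNames(loads[real_j], network$facilities$id),
    objective = dist_term + cong_term,
    distance_term = dist_term, congestion_term = cong_term,
    alpha = stats::setNames(prob$alpha[real_j], network$facilities$id),
    decay_scaled = decay_scaled,
    status = if (!res$converged) "max_sweeps"
             else if (!cap_ok) "capacity_not_converged" else "optimal",
    sweeps = res$sweeps, max_kkt_residual = res$residual,
    binding_capacity = binding, capacity_price = beta[real_j],
    community_id = network$communities$id,
    facility_id = network$facilities$id,
    model = "centralized"
  ), class = "access_assignment")
}

# Common problem setup: distance matrix D, visit multipliers M (r_ij =
# M_ij x_ij), congestion weights, eligible facility sets, optional dummy.
build_problem <- function(network, alpha, dummy_unmet, decay_scaled,
                          dummy_for_all = FALSE) {
  D <- network$distances
  n <- nrow(D); m_real <- ncol(D)
  v <- net_demand(network)
  W <- net_weights(network)
  alpha <- resolve_alpha(network, alpha)
  M <- if (decay_scaled) v * W else v * network$eligible
  elig_mat <- network$eligible
  cap <- network$facilities$capacity
  if (dummy_unmet) {
    # the dummy absorbs demand only where it must: isolated communities,
    # or anyone when binding capacities may push demand out
    open_dummy <- if (dummy_for_all) rep(TRUE, n) else rowSums(elig_mat) == 0L
    d_dummy <- 2 * max(D)
    D <- cbind(D, d_dummy)
    M <- cbind(M, v * open_dummy)
    elig_mat <- cbind(elig_mat, open_dummy)
    alpha <- c(alpha, 0)
    cap <- c(cap, NA_real_)
  }
  # distance cost is linear in the raw assigned visits v_i x_ij; the decay
  # scaling enters the congestion load and the realized (covered) visits
  LIN <- v * unname(D) * elig_mat
  elig <- elig_mat & (M > 0 | !decay_scaled)
  jsets <- lapply(seq_len(n), function(i) which(elig[i, ]))
  active <- which(v > 0)
  list(D = unname(D), LIN = LIN, M = unname(M), alpha = alpha, cap = cap,
       jsets = jsets, active = active, has_dummy = dummy_unmet,
       m_real = m_real)
}

resolve_alpha <- function(network, alpha) {
  a <- if (is.null(alpha)) network$facilities$congestion_weight
       else rep_len(alpha, nrow(network$facilities))
  if (any(a < 0)) stop("congestion weights must be non-negative", call. = FALSE)
  a
}

sweep_cols_add <- function(mat, add) mat + rep(add, each = nrow(mat))

init_nearest <- function(prob) {
  n <- nrow(prob$D)
  x <- matrix(0, n, ncol(prob$D))
  for (i in prob$active) {
    js <- prob$jsets[[i]]
    x[i, js[which.min(prob$D[i, js])]] <- 1
  }
  x
}

# Exact cyclic block coordinate descent. Each community's subproblem
# min sum_j c_j m_j x_j + sum_j alpha_j (a_j + m_j x_j)^2, sum x = 1,
# x >= 0 is solved by bisection on the equalized marginal cost mu.
cd_solve <- function(x, prob, beta, alpha, tol, max_sweeps) {
  loads <- colSums(prob$M * x)
  residual <- Inf; sweep <- 0L
  while (sweep < max_sweeps) {
    sweep <- sweep + 1L
    for (i in prob$active) {
      js <- prob$jsets[[i]]
      mi <- prob$M[i, js]
      a <- loads[js] - mi * x[i, js]
      lin <- prob$LIN[i, js] + beta[js] * mi
      xi <- simplex_qp(lin, mi, alpha[js], a)
      loads[js] <- a + mi * xi
      x[i, js] <- xi
    }
    residual <- kkt_residual(x, prob, beta, alpha, loads)
    if (residual <= tol) break
  }
  list(x = x, loads = loads, converged = residual <= tol,
       sweeps = sweep, residual = residual)
}

# max over communities of the complementarity gap x_ij (marg_ij - mu_i),
# relative to the magnitude of the marginal costs.
kkt_residual <- function(x, prob, beta, alpha, loads) {
  marg <- prob$LIN + prob$M * rep(beta + 2 * alpha * loads, each = nrow(prob$LIN))
  worst <- 0; scale <- 1
  for (i in prob$active) {
    js <- prob$jsets[[i]]
    mg <- marg[i, js]
    mu <- min(mg)
    worst <- max(worst, max(x[i, js] * (mg - mu)))
    scale <- max(scale, max(abs(mg)))
  }
  worst / scale
}

# Exact solve of one community's simplex-constrained quadratic.
# Marginal cost of facility j at fraction x_j:
#   g_j(x_j) = m_j c_j + 2 alpha_j m_j (a_j + m_j x_j)
# At the optimum all facilities with x_j > 0 share a common marginal mu and
# no facility has a smaller marginal at x = 0. Facilities with alpha = 0
# have constant marginal t_j and act as sinks at level t_j.
simplex_qp <- function(lin, m, alpha, a) {
  k <- length(lin)
  if (k == 1L) return(1)
  base <- lin + 2 * alpha * m * a
  slope <- 2 * alpha * m^2
  pos <- slope > 0
  x <- numeric(k)
  if (!any(pos)) {
    t0 <- min(base)
    sel <- base <= t0 * (1 + 1e-12) + 1e-300
    x[sel] <- 1 / sum(sel)
    return(x)
  }
  base_p <- base[pos]; slope_p <- slope[pos]
  clamp01 <- function(z) { z[z < 0] <- 0; z[z > 1] <- 1; z }
  s_at <- function(mu) sum(clamp01((mu - base_p) / slope_p))
  t0 <- if (any(!pos)) min(base[!pos]) else Inf
  hi_pos <- max(base_p + slope_p)
  if (is.finite(t0) && s_at(t0) < 1) {
    # water level reaches the cheapest zero-alpha sink(s)
    x[pos] <- clamp01((t0 - base_p) / slope_p)
    rem <- 1 - sum(x[pos])
    zb <- base; zb[pos] <- Inf
    sel <- !pos & zb <= t0 * (1 + 1e-12) + 1e-300
    x[sel] <- rem / sum(sel)
    return(x)
  }
  lo <- min(base_p); hi <- min(hi_pos, t0)
  if (s_at(hi) < 1) hi <- hi_pos  # t0 barely binding; fall back
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (s_at(mid) < 1) lo <- mid else hi <- mid
  }
  x[pos] <- clamp01((hi - base_p) / slope_p)
  # absorb residual bisection error into interior coordinates
  rem <- 1 - sum(x)
  if (rem != 0) {
    interior <- pos & x > 0 & x < 1
    if (any(interior)) {
      wts <- 1 / slope[interior]
      x[interior] <- x[interior] + rem * wts / sum(wts)
    } else {
      x[which.max(x)] <- x[which.max(x)] + rem
    }
    x[x < 0] <- 0; x[x > 1] <- 1
    x <- x / sum(x)
  }
  x
}

objective_value <- function(prob, x) {
  sum(prob$LIN * x) + sum(prob$alpha * colSums(prob$M * x)^2)
}

#' Exact brute-force solution for tiny instances
#'
#' Independent oracle for [solve_access()] on instances with at most three
#' communities and three facilities. The default `"enumeration"` method
#' solves the KKT equality system of every joint active-set pattern in
#' closed form and keeps the best feasible solution — exact for this convex
#' QP. `"grid"` performs the simpler exhaustive search over each
#' community's simplex at resolution `grid_step`, refined once around the
#' incumbent at a tenth of the step.
#'
#' @inheritParams solve_access
#' @param method `"enumeration"` (exact) or `"grid"`.
#' @param grid_step Simplex grid resolution for the grid method.
#' @return An `access_assignment` (status `"enumerated"` or `"grid"`).
#' @export
brute_force_small <- function(network, method = c("enumeration", "grid"),
                              grid_step = 0.1, alpha = NULL,
                              decay_scaled = TRUE) {
  method <- match.arg(method)
  prob <- build_problem(network, alpha, dummy_unmet = FALSE,
                        decay_scaled = decay_scaled)
  if (length(prob$active) > 3L || prob$m_real > 3L) {
    stop("brute_force_small handles at most 3 communities x 3 facilities",
         call. = FALSE)
  }
  if (any(vapply(prob$jsets[prob$active], length, 1L) == 0L)) {
    stop("brute_force_small requires every community to have an eligible facility",
         call. = FALSE)
  }
  best <- if (method == "enumeration") bf_enumerate(prob) else bf_grid(prob, grid_step)
  x <- best$x
  r <- prob$M * x
  loads <- colSums(r)
  structure(list(
    assignment = x, realized = r, unmet = rep(0, nrow(x)),
    loads = stats::setNames(loads, network$facilities$id),
    objective = best$obj,
    distance_term = sum(prob$LIN * x),
    congestion_term = sum(prob$alpha * loads^2),
    alpha = stats::setNames(prob$alpha, network$facilities$id),
    decay_scaled = decay_scaled, status = method,
    sweeps = NA_integer_, max_kkt_residual = NA_real_,
    binding_capacity = character(),
    community_id = network$communities$id,
    facility_id = network$facilities$id,
    model = "brute_force"
  ), class = "access_assignment")
}

bf_enumerate <- function(prob) {
  act <- prob$active
  supports <- lapply(act, function(i) {
    js <- prob$jsets[[i]]
    unlist(lapply(seq_along(js), function(k)
      utils::combn(js, k, simplify = FALSE)), recursive = FALSE)
  })
  combos <- expand.grid(lapply(supports, seq_along))
  best_obj <- Inf; best_x <- NULL
  n <- nrow(prob$D); m <- ncol(prob$D)
  for (row in seq_len(nrow(combos))) {
    supp <- lapply(seq_along(act), function(q) supports[[q]][[combos[row, q]]])
    sol <- bf_solve_support(prob, act, supp, n, m)
    if (!is.null(sol) && sol$obj < best_obj - 1e-15) {
      best_obj <- sol$obj; best_x <- sol$x
    }
  }
  list(obj = best_obj, x = best_x)
}

# Solve the equality-constrained KKT system for one joint support pattern:
# unknowns are the supported x_ij and one multiplier mu_i per community.
bf_solve_support <- function(prob, act, supp, n, m) {
  nv <- sum(lengths(supp))
  nc <- length(act)
  idx <- vector("list", nc)
  pos <- 0L
  for (q in seq_len(nc)) { idx[[q]] <- pos + seq_along(supp[[q]]); pos <- pos + length(supp[[q]]) }
  A <- matrix(0, nv + nc, nv + nc)
  b <- numeric(nv + nc)
  for (q in seq_len(nc)) {
    i <- act[q]
    for (t in seq_along(supp[[q]])) {
      j <- supp[[q]][t]; rr <- idx[[q]][t]
      b[rr] <- -prob$LIN[i, j]
      for (p in seq_len(nc)) {
        tt <- match(j, supp[[p]])
        if (!is.na(tt)) {
          A[rr, idx[[p]][tt]] <- A[rr, idx[[p]][tt]] +
            2 * prob$alpha[j] * prob$M[i, j] * prob$M[act[p], j]
        }
      }
      A[rr, nv + q] <- -1
      A[nv + q, rr] <- 1
    }
    b[nv + q] <- 1
  }
  z <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(z)) return(NULL)
  xv <- z[seq_len(nv)]
  if (any(xv < -1e-9) || any(xv > 1 + 1e-9)) return(NULL)
  x <- matrix(0, n, m)
  for (q in seq_len(nc)) x[act[q], supp[[q]]] <- pmin(pmax(xv[idx[[q]]], 0), 1)
  for (q in seq_len(nc)) x[act[q], ] <- x[act[q], ] / sum(x[act[q], ])
  list(obj = objective_value(prob, x), x = x)
}

bf_grid <- function(prob, grid_step) {
  act <- prob$active
  grids <- lapply(act, function(i) simplex_grid(prob$jsets[[i]], ncol(prob$D), grid_step))
  best <- bf_grid_search(prob, act, grids)
  # refine once around the incumbent at a tenth of the step
  fine <- lapply(seq_along(act), function(q) {
    g <- simplex_grid(prob$jsets[[act[q]]], ncol(prob$D), grid_step / 10)
    keep <- apply(abs(g - matrix(best$x[act[q], ], nrow(g), ncol(g), byrow = TRUE)) <=
                    grid_step + 1e-12, 1, all)
    g[keep, , drop = FALSE]
  })
  bf_grid_search(prob, act, fine)
}

simplex_grid <- function(js, m, step) {
  k <- length(js)
  n_units <- round(1 / step)
  parts <- compositions(n_units, k) / n_units
  g <- matrix(0, nrow(parts), m)
  g[, js] <- parts
  g
}

compositions <- function(n_units, k) {
  if (k == 1L) return(matrix(n_units, 1, 1))
  out <- NULL
  for (first in 0:n_units) {
    rest <- compositions(n_units - first, k - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

bf_grid_search <- function(prob, act, grids) {
  best_obj <- Inf; best_x <- NULL
  n <- nrow(prob$D); m <- ncol(prob$D)
  counts <- vapply(grids, nrow, 1L)
  iter <- expand.grid(lapply(counts, seq_len))
  for (row in seq_len(nrow(iter))) {
    x <- matrix(0, n, m)
    for (q in seq_along(act)) x[act[q], ] <- grids[[q]][iter[row, q], ]
    obj <- objective_value(prob, x)
    if (obj < best_obj) { best_obj <- obj; best_x <- x }
  }
  list(obj = best_obj, x = best_x)
}

#' Calibrate the congestion weight
#'
#' Selects a uniform congestion weight `alpha` so that the solved model's
#' ratio of total distance cost to total congestion cost matches a target.
#' The ratio decreases monotonically in `alpha` (more weight shifts cost
#' into the congestion term), so the calibration is a bisection on
#' `log(alpha)` over the bracket.
#'
#' @param network An [access_network()].
#' @param target_ratio Desired `distance_term / congestion_term` (> 0).
#' @param bracket Positive search interval for `alpha`; a lower endpoint of
#'   0 returns the pure-distance solution with a warning when the target
#'   cannot be bracketed.
#' @param tol Relative tolerance on the achieved ratio (default 5%).
#' @param ... Passed to [solve_access()].
#' @return A list with `alpha`, `achieved_ratio`, and a `report` tibble of
#'   bisection iterates.
#' @export
calibrate_congestion_weight <- function(network, target_ratio,
                                        bracket = c(1e-3, 1e3), tol = 0.05,
                                        ...) {
  stopifnot(target_ratio > 0, length(bracket) == 2L, bracket[1] < bracket[2])
  ratio_at <- function(a) {
    fit <- solve_access(network, alpha = a, ...)
    if (fit$congestion_term <= 0) Inf else fit$distance_term / fit$congestion_term
  }
  log_rows <- list()
  note <- function(it, a, r) log_rows[[length(log_rows) + 1L]] <<-
    tibble::tibble(iteration = it, alpha = a, ratio = r)

  lo <- max(bracket[1], .Machine$double.eps)
  hi <- bracket[2]
  r_lo <- ratio_at(lo); r_hi <- ratio_at(hi)
  note(0L, lo, r_lo); note(0L, hi, r_hi)
  if (target_ratio > r_lo) {
    if (bracket[1] <= 0) {
      warning("target ratio exceeds the bracket; returning the pure-distance solution (alpha = 0)",
              call. = FALSE)
      return(list(alpha = 0, achieved_ratio = Inf,
                  report = dplyr::bind_rows(log_rows)))
    }
    stop("target ratio not bracketed: ratio at lower endpoint is ",
         signif(r_lo, 4), call. = FALSE)
  }
  if (target_ratio < r_hi) {
    stop("target ratio not bracketed: ratio at upper endpoint is ",
         signif(r_hi, 4), call. = FALSE)
  }
  a <- NA_real_; r <- NA_real_
  for (it in seq_len(60L)) {
    a <- sqrt(lo * hi)
    r <- ratio_at(a)
    note(it, a, r)
    if (abs(r / target_ratio - 1) <= tol) break
    if (r > target_ratio) lo <- a else hi <- a
  }
  list(alpha = a, achieved_ratio = r, report = dplyr::bind_rows(log_rows))
}
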