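test_that("solver matches the exact enumeration oracle on tiny instances", {
  for (s in 1:20) {
    net <- rand_net(sample(2:3, 1), sample(2:3, 1), seed = 400 + s)
    ds <- s %% 2 == 0
    fit <- solve_access(net, decay_scaled = ds)
    bf <- brute_force_small(net, decay_scaled = ds)
    expect_equal(fit$objective, bf$objective, tolerance = 1e-6)
    expect_equal(fit$status, "optimal")
  }
})

test_that("enumeration and grid brute force agree to grid resolution", {
  net <- rand_net(2, 2, seed = 17)
  ex <- brute_force_small(net, "enumeration")
  gr <- brute_force_small(net, "grid", grid_step = 0.1)
  expect_gte(gr$objective, ex$objective - 1e-9)
  expect_lt((gr$objective - ex$objective) / abs(ex$objective), 0.01)
  expect_error(brute_force_small(rand_net(4, 2, seed = 1)), "at most 3")
})

test_that("an installed QP solver confirms the objective on a small instance", {
  skip_if_not_installed("pracma")
  net <- rand_net(3, 3, seed = 55)
  fit <- solve_access(net, decay_scaled = FALSE)
  # dense QP: z = vec(x), min 0.5 z' H z + f'z with per-community sum-to-1
  prob_M <- net$communities$visit_demand * net$eligible
  n <- 3L; m <- 3L
  H <- matrix(0, 9, 9); f <- numeric(9)
  for (i in 1:n) for (j in 1:m) {
    k <- (j - 1L) * n + i
    f[k] <- net$communities$visit_demand[i] * net$distances[i, j]
    for (p in 1:n) {
      H[k, (j - 1L) * n + p] <- 2 * net$facilities$congestion_weight[j] *
        prob_M[i, j] * prob_M[p, j]
    }
  }
  Aeq <- matrix(0, n, 9)
  for (i in 1:n) Aeq[i, (1:m - 1L) * n + i] <- 1
  # H is PSD but rank-deficient (one rank-1 block per facility); a tiny
  # ridge makes it strictly convex for the reference active-set solver
  ridge <- 1e-7 * max(diag(H))
  Hr <- (H + t(H)) / 2 + ridge * diag(9)
  qp <- pracma::quadprog(Hr, f, Aeq = Aeq, beq = rep(1, n),
                         lb = rep(0, 9), ub = rep(1, 9))
  expect_equal(fit$objective, qp$fval, tolerance = 1e-4)
})

test_that("alpha = 0 assigns every community fully to its nearest facility", {
  for (s in 1:25) {
    net <- rand_net(sample(4:10, 1), sample(2:5, 1), seed = 500 + s)
    fit <- solve_access(net, alpha = 0)
    for (i in seq_len(nrow(net$communities))) {
      js <- which(net$eligible[i, ])
      jn <- js[which.min(net$distances[i, js])]
      expect_equal(unname(fit$assignment[i, jn]), 1, tolerance = 1e-9)
    }
  }
  # equidistant tie at alpha = 0: split equally (the alpha -> 0+ limit)
  tie <- line_net(c(40, 40), alpha = 0)
  ft <- solve_access(tie)
  expect_equal(unname(ft$assignment[1, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("a dominant equal congestion weight equalizes facility loads", {
  for (s in 1:10) {
    net <- rand_net(6, 3, seed = 600 + s,
                    decay = accessopt::decay_constant(1, cutoff = 1e4))
    fit <- solve_access(net, alpha = 1e9 * max(net$distances),
                        decay_scaled = FALSE)
    expect_lt((max(fit$loads) - min(fit$loads)) / mean(fit$loads), 1e-3)
  }
})

test_that("assignment conserves demand and is feasible", {
  net <- rand_net(8, 4, seed = 77)
  fit <- solve_access(net)
  expect_true(all(fit$assignment >= 0 & fit$assignment <= 1))
  expect_equal(unname(rowSums(fit$assignment)), rep(1, 8), tolerance = 1e-8)
  expect_true(all(fit$assignment[!net$eligible] == 0))
  # books balance: realized summed by community = realized summed by facility
  expect_equal(sum(rowSums(fit$realized)), sum(fit$loads), tolerance = 1e-9)
})

test_that("the optimum dominates catchment-style nearest-zone heuristics", {
  for (s in 1:100) {
    net <- rand_net(sample(2:4, 1), sample(2:3, 1), seed = 700 + s)
    fit <- solve_access(net, tol = 1e-7)
    prob <- build_problem(net, NULL, FALSE, TRUE)
    x_near <- init_nearest(prob)
    expect_lte(fit$objective, objective_value(prob, x_near) + 1e-6)
    # and any random feasible assignment
    xr <- t(apply(net$eligible, 1, function(e) {
      z <- runif(length(e)) * e; z / sum(z)
    }))
    expect_lte(fit$objective, objective_value(prob, xr) + 1e-6)
  }
})

test_that("facility congestion under optimization stays below the E2SFCA books", {
  # the catchment denominator counts every overlapping community in full,
  # so its implied facility load is never below the optimized load
  for (s in 6:8) {
    net <- toy_system(s)
    fit <- solve_access(net)
    implied <- implied_visits(net, "e2sfca")$implied_visits
    expect_lte(sum(fit$loads), sum(implied) + 1e-9)
  }
})

test_that("capacity constraints bind, are reported, and removing them helps", {
  net <- rand_net(5, 3, seed = 42, alpha = c(0.2, 1))
  free <- solve_access(net)
  cap <- unname(pmax(free$loads, 5)); cap[1] <- cap[1] * 0.6
  net$facilities$capacity <- cap
  capped <- solve_access(net, capacity = TRUE)
  expect_true(all(capped$loads <= cap * (1 + 1e-4)))
  expect_true(net$facilities$id[1] %in% capped$binding_capacity)
  # removing a binding capacity never increases the objective
  expect_lte(free$objective, capped$objective + 1e-6)

  # isolated community without a dummy is an error naming the community
  iso <- suppressMessages(accessopt::access_network(
    tibble::tibble(id = c("ok", "far"), population = 10, visit_demand = 10),
    tibble::tibble(id = "A", supply = 5, congestion_weight = 1),
    distances = matrix(c(10, 400), 2), decay = decay_exponential(cutoff = 150)))
  expect_error(solve_access(iso), "far")
  fit_d <- solve_access(iso, dummy_unmet = TRUE)
  expect_equal(unname(fit_d$unmet), c(0, 10))
  expect_error(solve_access(net, alpha = -1), "non-negative")
})

test_that("congestion weight calibration brackets and recovers a target ratio", {
  net <- rand_net(6, 3, seed = 99, alpha = c(0.5, 0.5))
  ref <- solve_access(net, alpha = 2)
  target <- ref$distance_term / ref$congestion_term
  cal <- calibrate_congestion_weight(net, target, bracket = c(1e-3, 1e3))
  expect_lt(abs(cal$achieved_ratio / target - 1), 0.05)
  expect_lt(abs(log(cal$alpha / 2)), log(1.5))
  expect_error(calibrate_congestion_weight(net, 1e12, bracket = c(1, 2)),
               "not bracketed")
  expect_warning(
    z <- calibrate_congestion_weight(net, 1e30, bracket = c(0, 2)),
    "pure-distance")
  expect_equal(z$alpha, 0)
})

test_that("increasing a uniform congestion weight reduces load imbalance", {
  for (s in 1:8) {
    net <- rand_net(6, 3, seed = 800 + s,
                    decay = accessopt::decay_constant(1, cutoff = 1e4))
    vars <- vapply(c(0.01, 1, 100), function(a)
      stats::var(solve_access(net, alpha = a, decay_scaled = FALSE)$loads), 1)
    expect_true(all(diff(vars) <= 1e-6 * max(1, vars[1])))
  }
})
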