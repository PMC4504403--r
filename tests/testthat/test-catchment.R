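test_that("facility ratios and accessibility match hand arithmetic", {
  # S = 10, one community with V = 100 at weight 0.1 -> R = 10/(100*0.1) = 1
  net <- line_net(decay_inverse(decay_exponential(cutoff = 300), 0.1), v = 100)
  expect_equal(unname(facility_ratio(net)$ratio), 1, tolerance = 1e-12)
  # S = 5, V = 100, w = 0.2 -> R = 0.25
  net2 <- line_net(decay_inverse(decay_exponential(cutoff = 300), 0.2),
                   supply = 5, v = 100)
  expect_equal(unname(facility_ratio(net2)$ratio), 0.25, tolerance = 1e-12)
  # gravity: S = 10, P = 100, w = 0.1 -> 10*0.1/(100*0.1) = 0.1
  expect_equal(catchment_accessibility(net, "gravity")$accessibility, 0.1,
               tolerance = 1e-12)
  # community outside cutoff only -> ratio is an Inf sentinel with warning
  far <- suppressMessages(accessopt::access_network(
    tibble::tibble(id = "X", population = 10, visit_demand = 10),
    tibble::tibble(id = "A", supply = 5),
    distances = matrix(500, 1), decay = decay_exponential(cutoff = 150)))
  expect_warning(r <- facility_ratio(far), "no weighted demand")
  expect_identical(unname(r$ratio), Inf)
  expect_equal(suppressWarnings(
    catchment_accessibility(far, "e2sfca")$accessibility), 0)
})

test_that("toy systems 6-8 reproduce the analytic catchment values", {
  # E2SFCA is blind to the 6 vs 7 change; M2SFCA to the 6 vs 8 change
  e <- vapply(6:8, function(s)
    catchment_accessibility(toy_system(s), "e2sfca")$accessibility, 1)
  m <- vapply(6:8, function(s)
    catchment_accessibility(toy_system(s), "m2sfca")$accessibility, 1)
  expect_equal(e, c(0.1, 0.1, 0.05), tolerance = 1e-12)
  expect_equal(m[c(1, 3)], c(0.01, 0.01), tolerance = 1e-12)
  # the stated formulas give R * w^2 = (10/20) * 0.04 = 0.02 for system 7
  # (a printed table elsewhere lists 0.04, which is inconsistent with the
  # formula R_j = S_j / sum V_i w and A^M = sum R_j w^2)
  expect_equal(m[2], 0.02, tolerance = 1e-12)
})

test_that("symmetry and degenerate weights behave as expected", {
  # two identical communities symmetric about one facility
  net <- suppressMessages(accessopt::access_network(
    tibble::tibble(id = c("L", "R"), x = c(-30, 30), y = 0,
                   population = 50, visit_demand = 50),
    tibble::tibble(id = "A", x = 0, y = 0, supply = 10)))
  g <- catchment_accessibility(net, c("gravity", "e2sfca"))
  expect_equal(g$accessibility[1], g$accessibility[2])
  expect_equal(g$accessibility[3], g$accessibility[4])
  # w = 1 everywhere degenerates M2SFCA to E2SFCA
  net1 <- rand_net(5, 3, seed = 2, decay = accessopt::decay_constant(1, 1e6))
  acc <- catchment_accessibility(net1, c("e2sfca", "m2sfca"))
  expect_equal(acc$accessibility[acc$method == "m2sfca"],
               acc$accessibility[acc$method == "e2sfca"])
})

test_that("3SFCA selection weights split demand instead of double counting", {
  # single facility: no competition, A^3 = A^E
  net <- toy_system(6)
  expect_equal(catchment_accessibility(net, "3sfca")$accessibility,
               catchment_accessibility(net, "e2sfca")$accessibility)
  # one community (V = 1000) at weight 0.1 to two equidistant facilities:
  # E2SFCA counts the 100 decayed visits at both (total 200); 3SFCA splits
  # them with G = 0.5 (total 100)
  d <- decay_inverse(decay_exponential(cutoff = 300), 0.1)
  net2 <- line_net(c(d, d), v = 1000)
  expect_equal(sum(implied_visits(net2, "e2sfca")$implied_visits), 200,
               tolerance = 1e-9)
  expect_equal(sum(implied_visits(net2, "3sfca")$implied_visits), 100,
               tolerance = 1e-9)
  G <- selection_weights(net2)
  expect_equal(unname(G[1, ]), c(0.5, 0.5))
  # single facility: implied total is the decayed demand, below total demand
  expect_lte(sum(implied_visits(net, "e2sfca")$implied_visits),
             sum(net$communities$visit_demand))
})

test_that("overlapping catchments overestimate demand under E2SFCA but not 3SFCA", {
  for (s in 1:10) {
    net <- rand_net(8, 4, seed = 100 + s)
    if (!any(rowSums(net$weights > 0) >= 2)) next
    tot_e <- sum(implied_visits(net, "e2sfca")$implied_visits)
    tot_3 <- sum(implied_visits(net, "3sfca")$implied_visits)
    expect_gt(tot_e, tot_3)
    expect_lte(tot_3, sum(net$communities$visit_demand) + 1e-9)
  }
})

test_that("M2SFCA is dominated by E2SFCA and extra facilities never hurt E2SFCA", {
  for (s in 1:10) {
    net <- rand_net(6, 3, seed = 200 + s)
    acc <- tidyr::pivot_wider(
      catchment_accessibility(net, c("e2sfca", "m2sfca")),
      names_from = "method", values_from = "accessibility")
    expect_true(all(acc$m2sfca <= acc$e2sfca + 1e-12))
    # add a facility: every community's E2SFCA is monotone non-decreasing
    net_plus <- apply_intervention(
      net, add_facility("new", x = 50, y = 50, supply = 8))
    before <- catchment_accessibility(net, "e2sfca")$accessibility
    after <- catchment_accessibility(net_plus, "e2sfca")$accessibility
    expect_true(all(after >= before - 1e-12))
  }
})

test_that("all methods coincide on single-zone unit-weight networks", {
  # one zone of weight 1: gravity (with V = P), E2SFCA, M2SFCA and 3SFCA
  # all reduce to the same supply/demand ratio sums
  for (s in 1:50) {
    set.seed(300 + s)
    n <- sample(2:6, 1); m <- sample(1:3, 1)
    comms <- tibble::tibble(id = sprintf("c%d", 1:n),
                            x = runif(n, 0, 50), y = runif(n, 0, 50),
                            population = sample(1:100, n),
                            visit_demand = NA)
    comms$visit_demand <- comms$population
    facs <- tibble::tibble(id = sprintf("f%d", 1:m),
                           x = runif(m, 0, 50), y = runif(m, 0, 50),
                           supply = runif(m, 1, 10))
    net <- suppressMessages(accessopt::access_network(
      comms, facs, decay = accessopt::decay_constant(1, cutoff = 1e4)))
    acc <- tidyr::pivot_wider(
      catchment_accessibility(net, c("gravity", "e2sfca", "m2sfca", "3sfca")),
      names_from = "method", values_from = "accessibility")
    expect_equal(acc$e2sfca, acc$gravity, tolerance = 1e-12)
    expect_equal(acc$m2sfca, acc$e2sfca, tolerance = 1e-12)
    expect_equal(acc$`3sfca`, acc$e2sfca, tolerance = 1e-12)
  }
})

test_that("a barrier that only rewires selection leaves 3SFCA access unchanged", {
  # three-community system: Y equidistant from A and B; splitting Y in half
  # with a barrier (each half reaching one side only) leaves every facility's
  # captured demand unchanged, so X, Z, and the Y-average are unchanged
  w3 <- sys2_weights()
  net3 <- toy_system(3, weights = w3)
  w5 <- rbind(X = c(0.5, 0), Y1 = c(0.25, 0), Y2 = c(0, 0.25), Z = c(0, 0.5))
  net5 <- toy_system(5, weights = w5)
  a3 <- catchment_accessibility(net3, "3sfca")
  a5 <- catchment_accessibility(net5, "3sfca")
  expect_equal(a5$accessibility[a5$community_id == "X"],
               a3$accessibility[a3$community_id == "X"], tolerance = 1e-12)
  expect_equal(a5$accessibility[a5$community_id == "Z"],
               a3$accessibility[a3$community_id == "Z"], tolerance = 1e-12)
  expect_equal(mean(a5$accessibility[a5$community_id %in% c("Y1", "Y2")]),
               a3$accessibility[a3$community_id == "Y"], tolerance = 1e-12)
})
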