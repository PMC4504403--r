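test_that("profiles reproduce the closed-form coverage and congestion of toys", {
  vals <- t(vapply(6:8, function(s) {
    net <- toy_system(s)
    p <- access_profile(net, solve_access(net))
    c(p$coverage, p$congestion, p$AE, p$AM)
  }, numeric(4)))
  expect_equal(vals[, 1], c(0.1, 0.2, 0.2), tolerance = 1e-12)  # coverage
  expect_equal(vals[, 2], c(1, 2, 4), tolerance = 1e-12)        # congestion
  expect_equal(vals[, 3], c(0.1, 0.1, 0.05), tolerance = 1e-12) # A^E
  expect_equal(vals[, 4], c(0.01, 0.02, 0.01), tolerance = 1e-12)
})

test_that("composite measures follow the coverage/congestion closed forms", {
  df <- tibble::tibble(coverage = c(0.1, 0.2, 0, NA),
                       congestion = c(1, 4, 2, 1))
  out <- composite_measures(df)
  expect_equal(out$AE, c(0.1, 0.05, 0, NA))
  expect_equal(out$AM, c(0.01, 0.01, 0, NA))
  zero_con <- composite_measures(tibble::tibble(coverage = 0.5, congestion = 0))
  expect_true(is.na(zero_con$AE))
})

test_that("single-facility pipelines equal the catchment scores exactly", {
  # circular-system identity: A^E = w(d) R and A^M = w(d)^2 R, matching
  # e2sfca/m2sfca on the same network, across a grid of (S, P, w)
  dec <- accessopt::decay_exponential(cutoff = 300)
  grid <- tidyr::expand_grid(S = c(1, 5, 10, 25, 80),
                             P = c(10, 50, 100, 400),
                             w = c(0.05, 0.1, 0.3, 0.7, 1))
  for (k in seq_len(nrow(grid))) {
    S <- grid$S[k]; P <- grid$P[k]; w <- grid$w[k]
    d <- if (w == 1) 0 else decay_inverse(dec, w)
    net <- line_net(d, supply = S, v = P, decay = dec)
    p <- access_profile(net, solve_access(net))
    R <- S / (P * w)
    expect_equal(p$AE, w * R, tolerance = 1e-12)
    expect_equal(p$AM, w^2 * R, tolerance = 1e-12)
    expect_equal(p$AE,
                 catchment_accessibility(net, "e2sfca")$accessibility,
                 tolerance = 1e-12)
    expect_equal(p$AM,
                 catchment_accessibility(net, "m2sfca")$accessibility,
                 tolerance = 1e-12)
  }
})

test_that("profiles from the two solvers are internally consistent", {
  net <- rand_net(6, 3, seed = 12)
  fit <- solve_access(net)
  p <- access_profile(net, fit)
  expect_true(all(p$coverage >= 0 & p$coverage <= 1 + 1e-9, na.rm = TRUE))
  expect_true(all(p$distance >= 0, na.rm = TRUE))
  expect_equal(sum(p$realized), sum(fit$loads), tolerance = 1e-9)
  eq <- solve_equilibrium(net)
  pe <- access_profile(net, eq)
  expect_equal(sum(pe$realized), sum(eq$loads))
  # zero-demand community gets NA markers
  net$communities$visit_demand[1] <- 0
  p0 <- access_profile(net, solve_access(net))
  expect_true(is.na(p0$coverage[1]))
})

test_that("paired comparisons handle identical, shifted, and null data correctly", {
  set.seed(3)
  a <- tibble::tibble(community_id = sprintf("c%d", 1:30),
                      AE = runif(30, 0.1, 1))
  res_id <- compare_access(a, a)
  expect_equal(res_id$p_value[res_id$test == "paired_t"], 1)
  expect_equal(res_id$statistic[res_id$test == "var_ratio_F"], 1)
  # constant positive shift: one-tailed detection
  b <- dplyr::mutate(a, AE = AE - 0.05)
  res_shift <- compare_access(a, b)
  expect_lt(res_shift$p_value[res_shift$test == "paired_t"], 0.05)
  # noisy shift: closed-form one-sample t on the differences agrees
  b2 <- dplyr::mutate(a, AE = AE - 0.05 + rnorm(30, 0, 0.02))
  res2 <- compare_access(a, b2)
  d <- a$AE - b2$AE
  t_manual <- mean(d) / (sd(d) / sqrt(30))
  expect_equal(res2$statistic[res2$test == "paired_t"], t_manual,
               tolerance = 1e-10)
  expect_equal(res2$p_value[res2$test == "paired_t"],
               pt(t_manual, 29, lower.tail = FALSE), tolerance = 1e-10)
  # permutation sanity: shuffling pair labels destroys significance
  set.seed(9)
  null_a <- rnorm(30); null_b <- rnorm(30)
  hits <- 0L; n_shuffle <- 400L
  for (k in seq_len(n_shuffle)) {
    flip <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    aa <- ifelse(flip, null_a, null_b)
    bb <- ifelse(flip, null_b, null_a)
    p <- tryCatch(t.test(aa, bb, paired = TRUE,
                         alternative = "greater")$p.value, error = function(e) 1)
    if (p < 0.05) hits <- hits + 1L
  }
  expect_lt(hits / n_shuffle, 0.1)
})

test_that("stratified comparison respects strata and degenerate cases", {
  comm <- tibble::tibble(id = sprintf("c%d", 1:40),
                         population = c(rep(100, 10), rep(20, 15), rep(2, 15)))
  strata <- size_strata(comm)
  expect_equal(sort(unique(strata$stratum)), c("large", "medium", "small"))
  set.seed(4)
  a <- tibble::tibble(community_id = comm$id, AE = runif(40))
  b <- dplyr::mutate(a, AE = AE * 0.9)
  res <- compare_access(a, b, strata = strata)
  expect_setequal(unique(res$stratum), c("large", "medium", "small"))
  expect_true(all(res$n >= 10))
  # fewer than 3 pairs in a stratum is reported, not tested
  tiny <- compare_access(a[1:2, ], b[1:2, ])
  expect_match(tiny$note, "fewer than 3")
})

test_that("interventions return modified copies and validate inputs", {
  net <- toy_system(6)
  doubled <- apply_intervention(net, scale_capacity("A", 2))
  expect_identical(net$facilities$capacity, NA_real_)
  expect_true(is.na(doubled$facilities$capacity))  # NA capacity stays NA
  net$facilities$capacity <- 100
  net2 <- apply_intervention(net, scale_capacity("A", 2))
  expect_equal(net2$facilities$capacity, 200)
  expect_equal(net$facilities$capacity, 100)  # original untouched
  expect_equal(net2$facilities$supply, net$facilities$supply)
  up <- apply_intervention(net, scale_supply("A", 2))
  expect_equal(up$facilities$supply, 20)
  expect_error(apply_intervention(net, scale_capacity("nope", 2)), "unknown")
  expect_error(scale_capacity("A", 0), "factor > 0")
  # adding a facility by explicit distances covers an uncovered community
  iso <- suppressMessages(accessopt::access_network(
    tibble::tibble(id = c("a", "b"), population = 10, visit_demand = 10),
    tibble::tibble(id = "A", supply = 5),
    distances = matrix(c(10, 400), 2), decay = decay_exponential(cutoff = 150)))
  expect_equal(iso$isolated, "b")
  fixed <- apply_intervention(iso, add_facility(
    "B", supply = 5, distances = c(a = 300, b = 20)))
  expect_length(fixed$isolated, 0)
})

test_that("access gains are elementwise deltas with a correct summary", {
  net <- rand_net(6, 3, seed = 21)
  p <- access_profile(net, solve_access(net))
  zero <- access_gain(p, p)
  expect_true(all(abs(zero$delta_AE) < 1e-15, na.rm = TRUE))
  expect_equal(attr(zero, "summary")$unchanged, 6)
  net_plus <- apply_intervention(net, add_facility("new", x = 50, y = 50,
                                                   supply = 10,
                                                   congestion_weight = 1))
  p2 <- access_profile(net_plus, solve_access(net_plus))
  g <- access_gain(p, p2)
  expect_named(g, c("community_id", "delta_realized", "delta_distance",
                    "delta_congestion", "delta_coverage", "delta_AE",
                    "delta_AM"), ignore.order = TRUE)
  expect_error(access_gain(p, p2[-1, ]), "different community sets")
})
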