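# Shared fixture builders. Everything is generated in code at test time.

# random planar network with full coordinates
rand_net <- function(n, m, seed = NULL, alpha = c(0.05, 2), side = 100,
                     decay = accessopt::decay_exponential(cutoff = 300),
                     demand = 10:200) {
  if (!is.null(seed)) set.seed(seed)
  comms <- tibble::tibble(
    id = sprintf("c%02d", seq_len(n)),
    x = stats::runif(n, 0, side), y = stats::runif(n, 0, side),
    population = sample(10:200, n, replace = TRUE),
    visit_demand = sample(demand, n, replace = TRUE))
  facs <- tibble::tibble(
    id = sprintf("f%02d", seq_len(m)),
    x = stats::runif(m, 0, side), y = stats::runif(m, 0, side),
    supply = stats::runif(m, 5, 20),
    congestion_weight = stats::runif(m, alpha[1], alpha[2]))
  suppressMessages(accessopt::access_network(comms, facs, decay = decay))
}

# 1-community / k-facility line network with explicit distances
line_net <- function(d, supply = 10, v = 100, alpha = 1,
                     decay = accessopt::decay_exponential(cutoff = 300)) {
  m <- length(d)
  suppressMessages(accessopt::access_network(
    tibble::tibble(id = "X", population = v, visit_demand = v),
    tibble::tibble(id = LETTERS[seq_len(m)], supply = supply,
                   congestion_weight = alpha),
    distances = matrix(d, 1), decay = decay))
}

# weight template for the three-community / two-facility systems:
# X only reaches A, Z only reaches B, Y reaches both equally.
sys2_weights <- function(wx = 0.5, wy = 0.25, wz = 0.5) {
  rbind(X = c(wx, 0), Y = c(wy, wy), Z = c(0, wz))
}

# exhaustive pure-Nash enumeration for tiny unit-visit congestion games;
# visits within a community are identical so profiles are per-community
# counts over eligible facilities
enumerate_nash <- function(network, alpha = NULL) {
  D <- unname(network$distances)
  m <- ncol(D)
  alpha <- if (is.null(alpha)) network$facilities$congestion_weight
           else rep_len(alpha, m)
  W <- network$weights
  elig <- network$eligible
  v <- network$communities$visit_demand
  n_visits <- vapply(seq_len(nrow(D)), function(i) {
    js <- which(elig[i, ])
    if (!length(js)) return(0L)
    jn <- js[which.min(D[i, js])]
    as.integer(round(v[i] * W[i, jn]))
  }, 1L)
  comp <- function(total, k) {
    if (k == 1L) return(matrix(total, 1, 1))
    out <- NULL
    for (f in 0:total) out <- rbind(out, cbind(f, comp(total - f, k - 1L)))
    unname(out)
  }
  per_comm <- lapply(seq_along(n_visits), function(i) {
    js <- which(elig[i, ])
    cc <- comp(n_visits[i], length(js))
    full <- matrix(0L, nrow(cc), m)
    full[, js] <- cc
    full
  })
  combos <- expand.grid(lapply(per_comm, function(g) seq_len(nrow(g))))
  nash <- list()
  for (rr in seq_len(nrow(combos))) {
    counts <- t(vapply(seq_along(per_comm), function(i)
      per_comm[[i]][combos[rr, i], ], numeric(m)))
    loads <- colSums(counts)
    ok <- TRUE
    for (i in seq_len(nrow(counts))) {
      for (j in which(counts[i, ] > 0)) {
        cost <- D[i, j] + alpha[j] * loads[j]
        alts <- setdiff(which(elig[i, ]), j)
        if (length(alts) &&
            any(cost > D[i, alts] + alpha[alts] * (loads[alts] + 1) + 1e-9)) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) nash[[length(nash) + 1L]] <- loads
  }
  nash
}
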