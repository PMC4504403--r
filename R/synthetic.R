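#' Toy analytic comparison systems
#'
#' Small networks built for analytic comparison of the access measures.
#' Systems 6-8 are fully specified single-community, single-facility
#' systems: 100 people at `X` demanding one visit each, facility `A` with
#' 10, 10, and 5 beds and distance weight 0.1, 0.2, and 0.2 respectively.
#' Systems 1-5 are structural templates — two facilities `A`, `B` of 10
#' beds each with populations `X`, `Y` (and `Z`; System 5 splits `Y` into
#' `Y1`/`Y2` by an unbreakable barrier) — whose pairwise distance weights
#' are not fixed numerically, so a `weights` override matrix is required:
#'
#' * System 1: rows `X`, `Y` (populations 100, 1), columns `A`, `B`.
#' * Systems 2-4: rows `X`, `Y`, `Z` (populations 100, 100, 100; System 3
#'   defaults `Z` to 150), columns `A`, `B`.
#' * System 5: rows `X`, `Y1`, `Y2`, `Z` (100, 50, 50, 150); a barrier is
#'   encoded as a weight of 0 (unreachable).
#'
#' Distances are derived from the weights by inverting the decay function
#' (`d = w^{-1}(weight)`), so stated weights and distances are mutually
#' consistent; a weight of 0 maps beyond the cutoff.
#'
#' @param system Integer 1-8.
#' @param weights Distance-weight override matrix (locations x facilities),
#'   required for systems 1-5. Values in `[0, 1]`.
#' @param populations Optional named vector overriding location populations.
#' @param supplies Optional named vector overriding facility supplies.
#' @param alpha Congestion weight given to every facility (default 1).
#' @param decay Strictly decreasing decay spec used to invert weights into
#'   distances; default exponential with 150-mile cutoff.
#' @return An [access_network()]. Demand is one visit per person
#'   (`visit_demand = population`).
#' @examples
#' toy_system(6)
#' toy_system(2, weights = rbind(X = c(0.5, 0), Y = c(0.25, 0.25), Z = c(0, 0.5)))
#' @export
toy_system <- function(system, weights = NULL, populations = NULL,
                       supplies = NULL, alpha = 1,
                       decay = decay_exponential()) {
  stopifnot(system %in% 1:8)
  tmpl <- toy_template(system)
  if (system <= 5 && is.null(weights)) {
    stop(sprintf(paste0("System %d is a structural template: supply a `weights` ",
                        "matrix with rows (%s) and columns (%s)"),
                 system, paste(tmpl$locations, collapse = ", "),
                 paste(tmpl$facilities, collapse = ", ")), call. = FALSE)
  }
  if (is.null(weights)) weights <- tmpl$weights
  weights <- as.matrix(weights)
  if (!identical(dim(weights), c(length(tmpl$locations), length(tmpl$facilities)))) {
    stop(sprintf("weights must be %d x %d (locations x facilities)",
                 length(tmpl$locations), length(tmpl$facilities)), call. = FALSE)
  }
  if (any(weights < 0 | weights > 1)) {
    stop("distance weights must lie in [0, 1]", call. = FALSE)
  }
  pops <- stats::setNames(tmpl$populations, tmpl$locations)
  if (!is.null(populations)) pops[names(populations)] <- populations
  sup <- stats::setNames(tmpl$supplies, tmpl$facilities)
  if (!is.null(supplies)) sup[names(supplies)] <- supplies

  d <- decay_inverse(decay, weights)
  dim(d) <- dim(weights)
  communities <- tibble::tibble(id = tmpl$locations, population = unname(pops),
                                visit_demand = unname(pops))
  facilities <- tibble::tibble(id = tmpl$facilities, supply = unname(sup),
                               congestion_weight = alpha)
  access_network(communities, facilities, distances = d, decay = decay)
}

toy_template <- function(system) {
  two_fac <- c("A", "B")
  switch(as.character(system),
    "1" = list(locations = c("X", "Y"), populations = c(100, 1),
               facilities = two_fac, supplies = c(10, 10), weights = NULL),
    "2" = list(locations = c("X", "Y", "Z"), populations = c(100, 100, 100),
               facilities = two_fac, supplies = c(10, 10), weights = NULL),
    "3" = list(locations = c("X", "Y", "Z"), populations = c(100, 100, 150),
               facilities = two_fac, supplies = c(10, 10), weights = NULL),
    "4" = list(locations = c("X", "Y", "Z"), populations = c(100, 100, 100),
               facilities = two_fac, supplies = c(10, 10), weights = NULL),
    "5" = list(locations = c("X", "Y1", "Y2", "Z"),
               populations = c(100, 50, 50, 150),
               facilities = two_fac, supplies = c(10, 10), weights = NULL),
    "6" = list(locations = "X", populations = 100, facilities = "A",
               supplies = 10, weights = matrix(0.1)),
    "7" = list(locations = "X", populations = 100, facilities = "A",
               supplies = 10, weights = matrix(0.2)),
    "8" = list(locations = "X", populations = 100, facilities = "A",
               supplies = 5, weights = matrix(0.2))
  )
}

#' Cystic-fibrosis-like synthetic national network
#'
#' Generates a seeded random network emulating a sparse specialty-care
#' system for a rare disease: a rectangular grid of "counties" with
#' heavy-tailed (lognormal) populations, patients drawn binomially per
#' county at a prevalence rate chosen so the expected national patient
#' count matches `expected_patients`, a fixed annual visit demand per
#' patient, a hard travel cutoff, a Medicaid-like subpopulation restricted
#' to facilities in its own "state" (vertical bands of the grid), and
#' identical facilities placed uniformly at random over populated
#' counties.
#'
#' Each county contributes up to two demand communities: unrestricted
#' patients (`<county>_U`) and Medicaid patients (`<county>_M`, eligibility
#' class = state). Community `population` is its patient count and
#' `visit_demand` is `visits_per_patient` times that.
#'
#' @param seed Integer seed; the generator is fully reproducible for a
#'   fixed seed.
#' @param expected_patients Expected national patient count (default 3000,
#'   a tenth of the real-world prevalence, for desk-speed analysis).
#' @param n_facilities Facilities to place (default 20).
#' @param grid_dim Grid of counties, columns x rows (default 16 x 12).
#' @param cell_miles Side of a county cell in miles (default 50).
#' @param n_states Number of vertical state bands (default 4).
#' @param visits_per_patient Annual visit demand per patient (default 10).
#' @param medicaid_share Probability a patient is Medicaid-restricted
#'   (default 0.3).
#' @param supply Facility supply in visits/year terms (default 1500).
#' @param capacity Optional facility visit capacity (default unbounded).
#' @param congestion_weight Facility congestion weight (default 10, the
#'   specialty-care calibration).
#' @param decay Decay spec (default exponential, 150-mile cutoff).
#' @param pop_meanlog,pop_sdlog Lognormal county population parameters.
#' @return An [access_network()] with two extra fields: `patients` (county
#'   roster tibble) and `seed`.
#' @examples
#' net <- cf_network(seed = 1, expected_patients = 300, n_facilities = 5)
#' net
#' @export
cf_network <- function(seed, expected_patients = 3000, n_facilities = 20,
                       grid_dim = c(16, 12), cell_miles = 50, n_states = 4,
                       visits_per_patient = 10, medicaid_share = 0.3,
                       supply = 1500, capacity = NA_real_,
                       congestion_weight = 10,
                       decay = decay_exponential(),
                       pop_meanlog = 10, pop_sdlog = 1.1) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (n_facilities < 1) stop("at least one facility is required", call. = FALSE)
  set.seed(seed)
  gw <- grid_dim[1]; gh <- grid_dim[2]
  county <- tidyr::expand_grid(gx = seq_len(gw), gy = seq_len(gh))
  county$county_id <- sprintf("c%02d_%02d", county$gx, county$gy)
  county$x <- (county$gx - 0.5) * cell_miles
  county$y <- (county$gy - 0.5) * cell_miles
  county$state <- paste0("S", ceiling(county$gx * n_states / gw))
  county$population <- round(stats::rlnorm(nrow(county), pop_meanlog, pop_sdlog))

  prevalence <- expected_patients / sum(county$population)
  county$patients <- stats::rbinom(nrow(county), county$population, prevalence)
  county$medicaid <- stats::rbinom(nrow(county), county$patients, medicaid_share)

  rosters <- dplyr::bind_rows(
    dplyr::transmute(county, county_id = .data$county_id, x = .data$x, y = .data$y,
                     state = .data$state, group = "unrestricted",
                     n_patients = .data$patients - .data$medicaid,
                     eligibility_class = NA_character_),
    dplyr::transmute(county, county_id = .data$county_id, x = .data$x, y = .data$y,
                     state = .data$state, group = "medicaid",
                     n_patients = .data$medicaid,
                     eligibility_class = .data$state))
  rosters <- rosters[rosters$n_patients > 0, ]
  communities <- tibble::tibble(
    id = paste0(rosters$county_id, ifelse(rosters$group == "medicaid", "_M", "_U")),
    x = rosters$x, y = rosters$y,
    population = rosters$n_patients,
    visit_demand = rosters$n_patients * visits_per_patient,
    eligibility_class = rosters$eligibility_class,
    county_id = rosters$county_id, state = rosters$state)

  populated <- which(county$population > 0)
  sites <- county[sample(populated, min(n_facilities, length(populated))), ]
  facilities <- tibble::tibble(
    id = sprintf("F%02d", seq_len(nrow(sites))),
    x = sites$x, y = sites$y, supply = supply, capacity = capacity,
    congestion_weight = congestion_weight, state = sites$state)

  net <- suppressMessages(
    access_network(communities, facilities, decay = decay))
  net$patients <- dplyr::select(county, "county_id", "state", "population",
                                "patients", "medicaid")
  net$seed <- seed
  net
}
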