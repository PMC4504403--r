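#' Compute a community-by-facility distance matrix
#'
#' @param communities Data frame with columns `id`, `x`, `y`.
#' @param facilities Data frame with columns `id`, `x`, `y`.
#' @param metric `"euclidean"` treats `x`, `y` as planar coordinates in
#'   miles; `"haversine"` treats them as lon/lat degrees and uses great
#'   circle distance with Earth radius 3958.8 miles.
#' @return Numeric matrix (miles) with community ids as rownames and
#'   facility ids as colnames.
#' @examples
#' compute_distances(
#'   data.frame(id = "c1", x = 0, y = 0),
#'   data.frame(id = "f1", x = 3, y = 4)
#' )
#' @export
compute_distances <- function(communities, facilities,
                              metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  for (tab in list(communities, facilities)) {
    bad <- tab$id[!is.finite(tab$x) | !is.finite(tab$y)]
    if (length(bad)) {
      stop("missing or non-finite coordinates for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (metric == "euclidean") {
    dx <- outer(communities$x, facilities$x, "-")
    dy <- outer(communities$y, facilities$y, "-")
    d <- sqrt(dx^2 + dy^2)
  } else {
    d <- geosphere::distm(cbind(communities$x, communities$y),
                          cbind(facilities$x, facilities$y),
                          fun = function(p1, p2)
                            geosphere::distHaversine(p1, p2, r = 3958.8))
  }
  dimnames(d) <- list(communities$id, facilities$id)
  d
}

#' Build an access network
#'
#' Assembles validated community and facility tables, a distance matrix and
#' a decay spec into a single network object used by all accessibility
#' methods. Eligibility of a (community, facility) pair requires the
#' distance to be within the decay cutoff, and, when the community carries
#' an `eligibility_class` (e.g. a state code for a Medicaid-restricted
#' population) and the facility a `state`, that the two match.
#'
#' @param communities Data frame with columns `id`, `population`,
#'   `visit_demand` and either coordinates (`x`, `y`) or a supplied
#'   `distances` matrix; optional `eligibility_class` (NA = unrestricted).
#' @param facilities Data frame with columns `id`, `supply` and optionally
#'   `capacity` (visits/year, NA = unbounded), `congestion_weight`
#'   (default 0), `state`, and coordinates.
#' @param distances Either `NULL` (computed from coordinates), a numeric
#'   matrix `|communities| x |facilities|`, or a long data frame with
#'   columns `community_id`, `facility_id`, `miles`.
#' @param decay A [`decay_spec`][decay_exponential]; default exponential
#'   with 150-mile cutoff.
#' @param metric Distance metric when computing from coordinates; see
#'   [compute_distances()].
#' @return An object of class `access_network`: a list with elements
#'   `communities`, `facilities` (tibbles), `distances` (matrix, miles),
#'   `eligible` (logical matrix), `weights` (decay weights, zero where
#'   ineligible), `decay`, and `metric`. Communities with no eligible
#'   facility are permitted but recorded in `$isolated`.
#' @examples
#' net <- access_network(
#'   data.frame(id = "X", x = 0, y = 0, population = 100, visit_demand = 100),
#'   data.frame(id = "A", x = 30, y = 0, supply = 10)
#' )
#' net
#' @export
access_network <- function(communities, facilities, distances = NULL,
                           decay = decay_exponential(),
                           metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  stopifnot(inherits(decay, "decay_spec"))
  communities <- normalize_communities(communities)
  facilities <- normalize_facilities(facilities)
  if (nrow(facilities) == 0L) stop("at least one facility is required", call. = FALSE)

  if (is.null(distances)) {
    distances <- compute_distances(communities, facilities, metric)
  } else if (is.data.frame(distances)) {
    distances <- distances_from_long(distances, communities$id, facilities$id)
  } else {
    distances <- as.matrix(distances)
    if (!identical(dim(distances), c(nrow(communities), nrow(facilities)))) {
      stop(sprintf("distance matrix is %d x %d but tables have %d communities and %d facilities",
                   nrow(distances), ncol(distances),
                   nrow(communities), nrow(facilities)), call. = FALSE)
    }
    dimnames(distances) <- list(communities$id, facilities$id)
  }
  if (anyNA(distances) || any(distances < 0)) {
    stop("distances must be non-negative and non-missing", call. = FALSE)
  }

  eligible <- distances <= decay$cutoff
  if ("state" %in% names(facilities)) {
    cls <- communities$eligibility_class
    restricted <- !is.na(cls) & cls != ""
    if (any(restricted)) {
      same_state <- outer(cls, facilities$state,
                          function(a, b) !is.na(b) & a == b)
      eligible[restricted, ] <- eligible[restricted, , drop = FALSE] &
        same_state[restricted, , drop = FALSE]
    }
  }
  weights <- decay_weight(decay, distances)
  dim(weights) <- dim(distances)
  weights[!eligible] <- 0
  dimnames(weights) <- dimnames(distances)

  isolated <- communities$id[rowSums(eligible) == 0L]
  if (length(isolated)) {
    message("communities with no eligible facility within the cutoff: ",
            paste(isolated, collapse = ", "))
  }
  structure(list(communities = communities, facilities = facilities,
                 distances = distances, eligible = eligible,
                 weights = weights, decay = decay, metric = metric,
                 isolated = isolated),
            class = "access_network")
}

normalize_communities <- function(communities) {
  communities <- tibble::as_tibble(communities)
  req <- c("id", "population", "visit_demand")
  miss <- setdiff(req, names(communities))
  if (length(miss)) stop("communities table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  communities$id <- as.character(communities$id)
  if (anyDuplicated(communities$id)) {
    stop("duplicate community ids: ",
         paste(unique(communities$id[duplicated(communities$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(communities$population < 0) || any(communities$visit_demand < 0)) {
    bad <- communities$id[communities$population < 0 | communities$visit_demand < 0]
    stop("negative population or visit_demand for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"eligibility_class" %in% names(communities)) communities$eligibility_class <- NA_character_
  communities
}

normalize_facilities <- function(facilities) {
  facilities <- tibble::as_tibble(facilities)
  miss <- setdiff(c("id", "supply"), names(facilities))
  if (length(miss)) stop("facilities table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  facilities$id <- as.character(facilities$id)
  if (anyDuplicated(facilities$id)) {
    stop("duplicate facility ids: ",
         paste(unique(facilities$id[duplicated(facilities$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(facilities$supply <= 0)) {
    stop("facility supply must be positive: ",
         paste(facilities$id[facilities$supply <= 0], collapse = ", "),
         call. = FALSE)
  }
  if (!"capacity" %in% names(facilities)) facilities$capacity <- NA_real_
  if (any(!is.na(facilities$capacity) & facilities$capacity <= 0)) {
    stop("facility capacity, when given, must be positive", call. = FALSE)
  }
  if (!"congestion_weight" %in% names(facilities)) facilities$congestion_weight <- 0
  if (any(facilities$congestion_weight < 0)) {
    stop("congestion_weight must be non-negative", call. = FALSE)
  }
  facilities
}

distances_from_long <- function(df, community_ids, facility_ids) {
  req <- c("community_id", "facility_id", "miles")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("long distance table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d <- matrix(NA_real_, length(community_ids), length(facility_ids),
              dimnames = list(community_ids, facility_ids))
  ci <- match(as.character(df$community_id), community_ids)
  fi <- match(as.character(df$facility_id), facility_ids)
  if (anyNA(ci) || anyNA(fi)) {
    stop("distance table references unknown ids", call. = FALSE)
  }
  d[cbind(ci, fi)] <- df$miles
  if (anyNA(d)) {
    stop("distance table does not cover all community-facility pairs", call. = FALSE)
  }
  d
}

#' @export
print.access_network <- function(x, ...) {
  cat(sprintf("<access_network> %d communities, %d facilities\n",
              nrow(x$communities), nrow(x$facilities)))
  cat(sprintf("  total population %g, total visit demand %g\n",
              sum(x$communities$population), sum(x$communities$visit_demand)))
  cat(sprintf("  decay: %s, cutoff %g miles; %d eligible pairs (%.0f%%)\n",
              x$decay$family, x$decay$cutoff, sum(x$eligible),
              100 * mean(x$eligible)))
  if (length(x$isolated)) {
    cat("  isolated communities: ", paste(x$isolated, collapse = ", "), "\n")
  }
  invisible(x)
}

# demand vector (visits/year) and decay weight matrix shorthand
net_demand <- function(network) network$communities$visit_demand
net_weights <- function(network) network$weights
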