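#' Per-community access profile of an assignment
#'
#' Converts an assignment (centralized [solve_access()] or decentralized
#' [solve_equilibrium()]) into the three individual measures of access and
#' the two composite measures:
#'
#' * `distance`: visit-weighted mean miles traveled;
#' * `congestion`: visit-weighted mean facility congestion, where a
#'   facility's congestion is its realized load per unit supply
#'   (`F_j = L_j / S_j`, so a single-facility system gives `F = 1/R`);
#' * `coverage`: realized visits / needed visits, in `[0, 1]`;
#' * `AE = coverage / congestion` and `AM = coverage^2 / congestion`, the
#'   composites comparable to the E2SFCA and M2SFCA accessibility scores.
#'
#' Communities with zero demand get `NA` measures; composites are `NA`
#' where congestion is 0 with positive coverage, and 0 where coverage is 0.
#'
#' @param network The [access_network()] the assignment was solved on.
#' @param assignment An `access_assignment` or `visit_assignment`.
#' @return A tibble (class `access_profile`) with columns `community_id`,
#'   `needed`, `realized`, `distance`, `congestion`, `coverage`, `AE`,
#'   `AM`, plus `x`, `y` when the network has community coordinates.
#' @examples
#' net <- toy_system(7)
#' access_profile(net, solve_access(net))
#' @export
access_profile <- function(network, assignment) {
  r <- realized_matrix(network, assignment)
  v <- net_demand(network)
  loads <- colSums(r)
  Fj <- loads / network$facilities$supply
  tot <- rowSums(r)
  distance <- ifelse(tot > 0, rowSums(r * network$distances) / tot, NA_real_)
  congestion <- ifelse(tot > 0, as.numeric(r %*% Fj) / tot, NA_real_)
  coverage <- ifelse(v > 0, tot / v, NA_real_)
  out <- tibble::tibble(
    community_id = network$communities$id,
    needed = v, realized = tot,
    distance = distance, congestion = congestion, coverage = coverage
  )
  out <- composite_measures(out)
  if ("x" %in% names(network$communities)) {
    out$x <- network$communities$x
    out$y <- network$communities$y
  }
  class(out) <- c("access_profile", class(out))
  attr(out, "model") <- assignment$model
  out
}

realized_matrix <- function(network, assignment) {
  if (inherits(assignment, "access_assignment")) {
    return(assignment$realized)
  }
  if (inherits(assignment, "visit_assignment")) {
    ch <- assignment$choices
    r <- matrix(0, nrow(network$communities), nrow(network$facilities),
                dimnames = list(network$communities$id, network$facilities$id))
    if (nrow(ch)) {
      tab <- dplyr::count(ch, .data$community_id, .data$facility_id)
      r[cbind(match(tab$community_id, network$communities$id),
              match(tab$facility_id, network$facilities$id))] <- tab$n
    }
    return(r)
  }
  stop("assignment must come from solve_access() or solve_equilibrium()",
       call. = FALSE)
}

#' Composite access measures from coverage and congestion
#'
#' Adds `AE = coverage / congestion` and `AM = coverage^2 / congestion` to
#' a data frame holding `coverage` and `congestion` columns. Zero coverage
#' gives 0; zero congestion with positive coverage is not applicable
#' (`NA`).
#'
#' @param profile Data frame with `coverage` and `congestion` columns.
#' @return The input tibble with `AE` and `AM` columns added/replaced.
#' @export
composite_measures <- function(profile) {
  stopifnot(all(c("coverage", "congestion") %in% names(profile)))
  profile <- tibble::as_tibble(profile)
  cov <- profile$coverage
  con <- profile$congestion
  ae <- ifelse(!is.na(cov) & cov == 0, 0,
               ifelse(!is.na(con) & con > 0, cov / con, NA_real_))
  profile$AE <- ae
  profile$AM <- ifelse(!is.na(cov) & cov == 0, 0,
                       ifelse(!is.na(con) & con > 0, cov^2 / con, NA_real_))
  profile
}

#' Compare an access measure between two methods
#'
#' Paired one-tailed comparison of a measure (default the composite `AE`)
#' between two per-community results, optionally stratified (e.g. by the
#' number of patients in the community's county). Three tests are run per
#' stratum: a paired one-tailed t-test, a variance-ratio F-test, and a
#' paired one-tailed Mann-Whitney-Wilcoxon (signed-rank) test. The default
#' direction tests whether the first argument's measure exceeds the
#' second's (catchment > optimization in the motivating comparison).
#'
#' @param a,b Data frames with `community_id` and the measure column
#'   (typically [access_profile()] outputs or pivoted
#'   [catchment_accessibility()] results).
#' @param measure Column name to compare.
#' @param strata Optional data frame `community_id`, `stratum`; when `NULL`
#'   a single stratum `"all"` is used. See [size_strata()].
#' @param alternative Direction of the alternative hypothesis for `a`
#'   relative to `b`.
#' @return A tibble: `stratum`, `n`, `test`, `statistic`, `p_value`,
#'   `note`. Degenerate strata (fewer than 3 complete pairs, or constant
#'   data where a test is undefined) are reported with an explanatory note
#'   instead of a p-value.
#' @export
compare_access <- function(a, b, measure = "AE", strata = NULL,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(measure %in% names(a), measure %in% names(b))
  df <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(a), "community_id", va = dplyr::all_of(measure)),
    dplyr::select(tibble::as_tibble(b), "community_id", vb = dplyr::all_of(measure)),
    by = "community_id")
  if (is.null(strata)) {
    df$stratum <- "all"
  } else {
    df <- dplyr::inner_join(df, strata, by = "community_id")
  }
  df <- df[stats::complete.cases(df$va, df$vb), ]
  purrr::map_dfr(split(df, df$stratum), function(s) {
    stratum <- s$stratum[1]
    n <- nrow(s)
    if (n < 3L) {
      return(tibble::tibble(stratum = stratum, n = n, test = "all",
                            statistic = NA_real_, p_value = NA_real_,
                            note = "fewer than 3 complete pairs"))
    }
    dplyr::bind_rows(
      paired_t_row(s$va, s$vb, alternative),
      var_ratio_row(s$va, s$vb, alternative),
      wilcoxon_row(s$va, s$vb, alternative)
    ) |> dplyr::mutate(stratum = stratum, n = n, .before = 1)
  })
}

paired_t_row <- function(va, vb, alternative) {
  d <- va - vb
  # same degeneracy criterion as t.test: the standard error is negligible
  # relative to the mean difference
  stderr_neg <- stats::sd(d) / sqrt(length(d)) <=
    10 * .Machine$double.eps * max(abs(mean(d)), .Machine$double.xmin)
  if (stats::sd(d) == 0 || stderr_neg) {
    if (all(d == 0)) {
      return(tibble::tibble(test = "paired_t", statistic = 0, p_value = 1,
                            note = "identical vectors; no difference"))
    }
    p <- if ((alternative == "greater" && mean(d) > 0) ||
             (alternative == "less" && mean(d) < 0)) 0 else 1
    return(tibble::tibble(test = "paired_t", statistic = sign(mean(d)) * Inf,
                          p_value = p, note = "constant nonzero difference"))
  }
  tt <- stats::t.test(va, vb, paired = TRUE, alternative = alternative)
  tibble::tibble(test = "paired_t", statistic = unname(tt$statistic),
                 p_value = tt$p.value, note = NA_character_)
}

var_ratio_row <- function(va, vb, alternative) {
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    return(tibble::tibble(test = "var_ratio_F", statistic = 1, p_value = NA_real_,
                          note = "both vectors constant; F-test undefined"))
  }
  if (stats::sd(vb) == 0 || stats::sd(va) == 0) {
    return(tibble::tibble(test = "var_ratio_F",
                          statistic = ifelse(stats::sd(vb) == 0, Inf, 0),
                          p_value = NA_real_, note = "a vector is constant"))
  }
  ft <- stats::var.test(va, vb, alternative = alternative)
  tibble::tibble(test = "var_ratio_F", statistic = unname(ft$statistic),
                 p_value = ft$p.value, note = NA_character_)
}

wilcoxon_row <- function(va, vb, alternative) {
  d <- va - vb
  if (all(d == 0)) {
    return(tibble::tibble(test = "wilcoxon", statistic = NA_real_, p_value = 1,
                          note = "identical vectors; no difference"))
  }
  wt <- suppressWarnings(stats::wilcox.test(va, vb, paired = TRUE,
                                            alternative = alternative))
  tibble::tibble(test = "wilcoxon", statistic = unname(wt$statistic),
                 p_value = wt$p.value, note = NA_character_)
}

#' Stratify communities by patient count
#'
#' The case-study stratification: communities with more than `large`
#' patients are "large", fewer than `small` are "small", the rest
#' "medium".
#'
#' @param communities Data frame with `id` and a count column.
#' @param count Column holding the patient count (default `population`).
#' @param small,large Cutoffs (defaults 5 and 50).
#' @return Tibble `community_id`, `stratum`.
#' @export
size_strata <- function(communities, count = "population", small = 5, large = 50) {
  n <- communities[[count]]
  tibble::tibble(
    community_id = as.character(communities$id),
    stratum = dplyr::case_when(n > large ~ "large", n < small ~ "small",
                               TRUE ~ "medium"))
}

#' Network interventions
#'
#' `apply_intervention()` returns a modified copy of the network (the
#' original is untouched) after applying actions built with:
#'
#' * `add_facility(id, x, y, supply, ...)` — a new facility; distances to
#'   it are computed from coordinates with the network's metric, or may be
#'   given explicitly as a named `distances` vector (community id ->
#'   miles).
#' * `scale_capacity(id, factor)` — multiply a facility's visit capacity.
#' * `scale_supply(id, factor)` — multiply a facility's supply (this is
#'   what reduces congestion `F = L/S`, e.g. "doubling" a facility).
#'
#' @param network An [access_network()].
#' @param ... Actions.
#' @return A new `access_network`.
#' @examples
#' net <- toy_system(6)
#' bigger <- apply_intervention(net, scale_supply("A", 2))
#' @export
apply_intervention <- function(network, ...) {
  actions <- list(...)
  fac <- network$facilities
  D <- network$distances
  for (act in actions) {
    stopifnot(inherits(act, "access_action"))
    if (act$type == "add_facility") {
      if (act$spec$id %in% fac$id) {
        stop("facility id already exists: ", act$spec$id, call. = FALSE)
      }
      newcol <- new_facility_distances(network, act)
      fac <- dplyr::bind_rows(fac, act$spec)
      D <- cbind(D, newcol)
      colnames(D)[ncol(D)] <- act$spec$id
    } else {
      k <- match(act$id, fac$id)
      if (is.na(k)) stop("unknown facility id: ", act$id, call. = FALSE)
      if (act$type == "scale_capacity") {
        fac$capacity[k] <- fac$capacity[k] * act$factor
      } else {
        fac$supply[k] <- fac$supply[k] * act$factor
      }
    }
  }
  access_network(network$communities, fac, distances = unname(D),
                 decay = network$decay, metric = network$metric)
}

new_facility_distances <- function(network, act) {
  if (!is.null(act$distances)) {
    d <- act$distances[network$communities$id]
    if (anyNA(d)) stop("add_facility distances must cover every community",
                       call. = FALSE)
    return(unname(d))
  }
  if (!"x" %in% names(network$communities) || is.na(act$spec$x)) {
    stop("add_facility needs coordinates (or an explicit distances vector)",
         call. = FALSE)
  }
  as.numeric(compute_distances(network$communities, act$spec, network$metric))
}

#' @rdname apply_intervention
#' @param id Facility id.
#' @param x,y Coordinates of the new facility.
#' @param supply Supply units of the new facility.
#' @param capacity Optional visit capacity.
#' @param congestion_weight Congestion weight of the new facility.
#' @param state Optional state code (for eligibility restrictions).
#' @param distances Optional named vector of miles to every community.
#' @export
add_facility <- function(id, x = NA_real_, y = NA_real_, supply,
                         capacity = NA_real_, congestion_weight = 0,
                         state = NA_character_, distances = NULL) {
  stopifnot(supply > 0)
  structure(list(
    type = "add_facility",
    spec = tibble::tibble(id = as.character(id), x = x, y = y,
                          supply = supply, capacity = capacity,
                          congestion_weight = congestion_weight,
                          state = state),
    distances = distances), class = "access_action")
}

#' @rdname apply_intervention
#' @param factor Positive multiplier.
#' @export
scale_capacity <- function(id, factor) {
  stopifnot(factor > 0)
  structure(list(type = "scale_capacity", id = as.character(id),
                 factor = factor), class = "access_action")
}

#' @rdname apply_intervention
#' @export
scale_supply <- function(id, factor) {
  stopifnot(factor > 0)
  structure(list(type = "scale_supply", id = as.character(id),
                 factor = factor), class = "access_action")
}

#' Per-community change in access after an intervention
#'
#' Elementwise `after - before` for each measure of two access profiles (or
#' any data frames sharing `community_id` and measure columns), with a
#' summary count of communities improved / worsened / unchanged on a chosen
#' measure.
#'
#' @param before,after Profiles over the same community set.
#' @param measure Measure used for the improved/worsened summary.
#' @return A tibble of `delta_*` columns keyed by `community_id`, with a
#'   `summary` attribute.
#' @export
access_gain <- function(before, after, measure = "AE") {
  before <- tibble::as_tibble(before); after <- tibble::as_tibble(after)
  if (!setequal(before$community_id, after$community_id)) {
    stop("profiles cover different community sets", call. = FALSE)
  }
  cols <- intersect(intersect(names(before), names(after)),
                    c("distance", "congestion", "coverage", "AE", "AM",
                      "realized", "accessibility"))
  joined <- dplyr::inner_join(before, after, by = "community_id",
                              suffix = c("_before", "_after"))
  out <- tibble::tibble(community_id = joined$community_id)
  for (cl in cols) {
    out[[paste0("delta_", cl)]] <-
      joined[[paste0(cl, "_after")]] - joined[[paste0(cl, "_before")]]
  }
  dcol <- out[[paste0("delta_", measure)]]
  attr(out, "summary") <- tibble::tibble(
    measure = measure,
    improved = sum(dcol > 1e-12, na.rm = TRUE),
    worsened = sum(dcol < -1e-12, na.rm = TRUE),
    unchanged = sum(abs(dcol) <= 1e-12, na.rm = TRUE))
  out
}
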