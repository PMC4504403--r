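#' Read and write the standard network tables
#'
#' All files are UTF-8, comma-delimited CSV with a required header.
#' Schemas:
#'
#' * communities: `id,x,y,population,visit_demand,eligibility_class`
#'   (coordinates and class optional);
#' * facilities: `id,x,y,supply,capacity,congestion_weight,state`
#'   (blank capacity = unbounded);
#' * distances (long): `community_id,facility_id,miles`.
#'
#' Malformed rows are reported with their line numbers; schema violations
#' name the missing columns.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_communities <- function(path) {
  df <- read_checked(path, required = c("id", "population", "visit_demand"))
  df$id <- as.character(df$id)
  df
}

#' @rdname read_communities
#' @export
read_facilities <- function(path) {
  df <- read_checked(path, required = c("id", "supply"))
  df$id <- as.character(df$id)
  df
}

#' @rdname read_communities
#' @export
read_distances <- function(path) {
  df <- read_checked(path, required = c("community_id", "facility_id", "miles"))
  neg <- which(df$miles < 0)
  if (length(neg)) {
    stop(sprintf("negative distance for pair (%s, %s) at data row %d of %s",
                 df$community_id[neg[1]], df$facility_id[neg[1]], neg[1],
                 basename(path)), call. = FALSE)
  }
  df
}

read_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # base read.csv parses doubles exactly (strtod), which keeps the
  # export -> import round trip bit-identical
  df <- tryCatch(
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)),
    error = function(e) stop(sprintf("malformed CSV %s: %s", basename(path),
                                     conditionMessage(e)), call. = FALSE))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s lacks required columns: %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @rdname read_communities
#' @param df Data frame to write.
#' @export
write_communities <- function(df, path) readr::write_csv(df, path)

#' @rdname read_communities
#' @export
write_facilities <- function(df, path) readr::write_csv(df, path)

#' @rdname read_communities
#' @export
write_distances <- function(df, path) readr::write_csv(df, path)

#' Read/write a decay configuration block
#'
#' Key-value (YAML) representation of a decay spec: `family`,
#' `cutoff_miles`, family parameters, and `zone_bounds`/`zone_weights` for
#' the step-zone family.
#'
#' @param path File path.
#' @return `read_decay_config()` returns a [`decay_spec`][decay_exponential].
#' @export
read_decay_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  decay_from_config(cfg)
}

decay_from_config <- function(cfg) {
  if (is.null(cfg$family)) stop("decay config lacks `family`", call. = FALSE)
  num <- setdiff(names(cfg), "family")
  cfg[num] <- lapply(cfg[num], function(v) as.numeric(unlist(v)))
  cutoff <- cfg$cutoff_miles %||% 150
  switch(cfg$family,
    exponential = decay_exponential(cfg$lambda, cutoff),
    gaussian = decay_gaussian(cfg$sigma, cutoff),
    inverse_power = decay_inverse_power(cfg$power %||% 2, cfg$scale %||% 10, cutoff),
    constant = decay_constant(cfg$weight %||% 1, cutoff),
    step_zones = decay_step_zones(unlist(cfg$zone_bounds),
                                  unlist(cfg$zone_weights), cutoff),
    stop("unknown decay family in config: ", cfg$family, call. = FALSE)
  )
}

#' @rdname read_decay_config
#' @param decay A decay spec.
#' @export
write_decay_config <- function(decay, path) {
  stopifnot(inherits(decay, "decay_spec"))
  cfg <- c(list(family = decay$family, cutoff_miles = decay$cutoff),
           if (decay$family == "step_zones")
             list(zone_bounds = decay$params$bounds,
                  zone_weights = decay$params$weights)
           else decay$params)
  # numeric parameters are serialized at full double precision (yaml
  # otherwise truncates and the round trip would drift)
  num <- setdiff(names(cfg), "family")
  cfg[num] <- lapply(cfg[num], function(v) sprintf("%.17g", v))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Export / import a whole network as CSV + YAML
#'
#' Writes `communities.csv`, `facilities.csv`, `distances.csv` (long
#' format) and `decay.yml` into a directory; `import_network()` rebuilds
#' the identical network from them (the round trip is exact).
#'
#' @param network An [access_network()].
#' @param dir Directory (created if needed).
#' @return `export_network()` returns `dir` invisibly; `import_network()`
#'   an `access_network`.
#' @export
export_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_communities(network$communities, file.path(dir, "communities.csv"))
  write_facilities(network$facilities, file.path(dir, "facilities.csv"))
  long <- tibble::as_tibble(as.data.frame.table(network$distances,
                                                stringsAsFactors = FALSE))
  names(long) <- c("community_id", "facility_id", "miles")
  write_distances(long, file.path(dir, "distances.csv"))
  write_decay_config(network$decay, file.path(dir, "decay.yml"))
  invisible(dir)
}

#' @rdname export_network
#' @export
import_network <- function(dir) {
  suppressMessages(access_network(
    read_communities(file.path(dir, "communities.csv")),
    read_facilities(file.path(dir, "facilities.csv")),
    distances = read_distances(file.path(dir, "distances.csv")),
    decay = read_decay_config(file.path(dir, "decay.yml"))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
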