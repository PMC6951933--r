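# Config and table I/O, plus deterministic fixture generators.
#
# All tabular interchange is CSV: header row, comma delimiter, "." decimal,
# UTF-8. The config file is YAML. Dates are simulation-day integers.

config_table_fields <- c("culling_age_cdf", "lactation")

#' Write / read a simulation configuration (YAML)
#'
#' `write_config()` serializes a `herd_config` to a YAML file (tables are
#' stored column-wise); `read_config()` loads it back, rejecting unknown
#' keys by name and raising the full list of schema violations if the
#' result is invalid. Write-then-read round-trips to an equal config.
#'
#' @param cfg a `herd_config`.
#' @param path file path.
#' @return `read_config()` returns a validated `herd_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  for (f in config_table_fields) x[[f]] <- as.list(x[[f]])
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- yaml::read_yaml(path)
  known <- names(default_config())
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(known, names(x))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  for (f in config_table_fields)
    x[[f]] <- as.data.frame(x[[f]], stringsAsFactors = FALSE)
  for (f in c("diagnosis_days", "daily_loss_rates"))
    x[[f]] <- as.numeric(unlist(x[[f]]))
  x$seed <- as.integer(x$seed)
  cfg <- structure(x[known], class = "herd_config")
  v <- validate_config(cfg)
  if (length(v))
    stop("invalid config '", path, "':\n  ", paste(v, collapse = "\n  "))
  cfg
}

#' Read / write the empirical culling-age CDF (CSV)
#'
#' Two columns: `age_days`, `cumulative_probability`; the CDF must be
#' nondecreasing over strictly increasing ages and end at exactly 1.
#'
#' @param path CSV file path.
#' @param cdf a CDF data.frame.
#' @export
read_culling_cdf <- function(path) {
  cdf <- utils::read.csv(path)
  bad <- validate_cdf(cdf)
  if (length(bad)) stop("malformed culling-age CDF in ", path, ": ", bad)
  cdf
}

#' @rdname read_culling_cdf
#' @export
write_culling_cdf <- function(cdf, path) {
  bad <- validate_cdf(cdf)
  if (length(bad)) stop("refusing to write malformed CDF: ", bad)
  utils::write.csv(cdf, path, row.names = FALSE)
  invisible(path)
}

#' Read a lactation-curve parameter table (CSV)
#'
#' Columns: breed, parity_class, form (WOOD | MILKBOT), a, b, c, d.
#'
#' @param path CSV file path.
#' @export
read_lactation_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("breed", "parity_class", "form", "a", "b", "c")
  miss <- setdiff(need, names(lt))
  if (length(miss))
    stop("lactation table missing column(s): ", paste(miss, collapse = ", "))
  if (!"d" %in% names(lt)) lt$d <- NA_real_
  lt$d <- as.numeric(lt$d)
  lt$parity_class <- as.character(lt$parity_class)
  lt
}

#' Read a feed library / requirement table (CSV)
#'
#' The feed library has columns name, cost, one column per nutrient, and
#' optional min_inclusion, max_inclusion, available. The requirement table
#' has columns nutrient, maintenance_coefficient, per_kg_milk, and
#' optional max_optional.
#'
#' @param path CSV file path.
#' @export
read_feed_library <- function(path) {
  fl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "cost") %in% names(fl)))
    stop("feed library must have 'name' and 'cost' columns")
  for (col in intersect(c("min_inclusion", "max_inclusion", "available"),
                        names(fl)))
    fl[[col]] <- as.numeric(fl[[col]])
  fl
}

#' @rdname read_feed_library
#' @export
read_requirement_table <- function(path) {
  rt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nutrient", "maintenance_coefficient", "per_kg_milk")
  miss <- setdiff(need, names(rt))
  if (length(miss))
    stop("requirement table missing column(s): ", paste(miss, collapse = ", "))
  rt
}

#' Write / read an event log (CSV)
#'
#' One row per [event_columns()] event, written in canonical column order.
#'
#' @param events event-log data.table.
#' @param path CSV file path.
#' @export
write_event_log <- function(events, path) {
  events <- data.table::as.data.table(events)
  data.table::setcolorder(events, event_columns())
  data.table::fwrite(events, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  ev <- data.table::fread(path, na.strings = "", colClasses = list(
    integer = c("sim_day", "animal_id", "age", "dim", "parity",
                "service", "diagnosis"),
    character = c("event", "reason"), numeric = "value"))
  miss <- setdiff(event_columns(), names(ev))
  if (length(miss))
    stop("malformed event log: missing column(s) ", paste(miss, collapse = ", "))
  ev
}

#' Generate a synthetic empirical culling-age CDF
#'
#' Deterministic function of (spec, seed): `steps` jump ages drawn (sorted,
#' distinct) within `[age_min, age_max]` (default support within
#' 400-4000 d) with uniform-normalized masses; the terminal cumulative
#' probability is exactly 1. A 1-step spec yields a point mass. Synthetic,
#' non-normative: stands in for a herd-specific empirical CDF.
#'
#' @param steps number of jumps.
#' @param age_min,age_max support bounds, d.
#' @param seed integer seed.
#' @return a CDF data.frame passing [read_culling_cdf()] checks.
#' @export
make_synthetic_culling_cdf <- function(steps = 5L, age_min = 400,
                                       age_max = 4000, seed = 1L) {
  stopifnot(steps >= 1, age_min >= 400, age_max <= 4000, age_min < age_max)
  s <- rng_stream(seed)
  with_stream(s, {
    ages <- sort(sample(seq(age_min, age_max), steps))
    mass <- stats::runif(steps)
    p <- cumsum(mass / sum(mass))
    p[steps] <- 1
    data.frame(age_days = ages, cumulative_probability = p)
  })
}

#' Generate a toy feed library and requirement table
#'
#' Deterministic function of (spec, seed). The first feed is a "complete"
#' feed positive in every nutrient with unlimited availability, so the
#' least-cost ration LP assembled from the pair is feasible by
#' construction; the remaining feeds have sparse compositions and finite
#' availability. Intended for tests and examples only.
#'
#' @param n_feeds 2-5 feeds.
#' @param n_nutrients 2-4 nutrients.
#' @param seed integer seed.
#' @return list with `feeds` and `requirement_table` data.frames.
#' @export
make_toy_feed_library <- function(n_feeds = 3L, n_nutrients = 2L, seed = 1L) {
  stopifnot(n_feeds >= 2, n_feeds <= 5, n_nutrients >= 2, n_nutrients <= 4)
  s <- rng_stream(seed)
  with_stream(s, {
    nutr <- paste0("nutrient_", seq_len(n_nutrients))
    comp <- matrix(stats::runif(n_feeds * n_nutrients, 0, 0.25),
                   nrow = n_feeds, dimnames = list(NULL, nutr))
    comp[1, ] <- stats::runif(n_nutrients, 0.1, 0.3)   # complete feed
    if (n_feeds > 2) {
      drop <- cbind(3:n_feeds, sample(n_nutrients, n_feeds - 2, replace = TRUE))
      comp[drop] <- 0
    }
    feeds <- data.frame(name = c("complete_feed",
                                 paste0("feed_", seq_len(n_feeds - 1L))),
                        cost = stats::runif(n_feeds, 0.1, 0.5))
    feeds <- cbind(feeds, as.data.frame(comp))
    feeds$min_inclusion <- 0
    feeds$max_inclusion <- NA_real_
    feeds$available <- c(NA_real_, stats::runif(n_feeds - 1L, 1, 10))
    req <- data.frame(nutrient = nutr,
                      maintenance_coefficient = stats::runif(n_nutrients,
                                                             5e-4, 2e-3),
                      per_kg_milk = stats::runif(n_nutrients, 0.01, 0.05))
    list(feeds = feeds, requirement_table = req)
  })
}
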