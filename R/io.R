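#' Write a settlement dataset to CSV
#'
#' Fixed dialect: comma-separated, UTF-8, '.' decimal, LF line endings,
#' header `time_min,density_label,initial_od,replicate,od600`. Rows are
#' ordered deterministically (density-major by initial OD then label, then
#' replicate, then time) and numbers are rendered with 15 significant
#' digits so a write-read round trip is lossless. Two writes of the same
#' dataset are byte-identical.
#'
#' @param dataset a [settlement_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_settlement_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "settlement_dataset"))
  d <- dataset[order(dataset$initial_od, dataset$density_label,
                     dataset$replicate, dataset$time_min), ]
  num <- function(x) vapply(x, function(v) format(v, digits = 15), "")
  lines <- c(
    "time_min,density_label,initial_od,replicate,od600",
    if (nrow(d)) sprintf("%s,%s,%s,%d,%s",
                         num(d$time_min), d$density_label,
                         num(d$initial_od), as.integer(d$replicate),
                         num(d$od600))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a settlement dataset from CSV
#'
#' Expects exactly the header names written by [write_settlement_csv()]
#' (`time_min`, `density_label`, `initial_od`, `replicate`, `od600`); any
#' extra columns are preserved in the dataset's `meta` attribute. All
#' [settlement_dataset()] invariants are validated, naming the offending
#' curve on failure. An empty file with just the header yields an empty
#' dataset with a warning.
#'
#' @param path CSV file path.
#' @return a [settlement_dataset()].
#' @export
read_settlement_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "density_label", "initial_od", "replicate", "od600")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("settlement CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), need)
  if (!nrow(df)) {
    warning("settlement CSV ", path, " contains no data rows", call. = FALSE)
  }
  settlement_dataset(df[need],
                     meta = c(list(source = path),
                              if (length(extra)) list(extra = df[extra])))
}

#' Read or write a run configuration
#'
#' A run configuration bundles everything needed to regenerate an output:
#' kinetic parameters, observable mapping, synthetic design, solver
#' settings, and the seed. Serialized as JSON or YAML by file extension;
#' the round trip is lossless.
#'
#' @param config named list; `config$model`, if present, may be a
#'   [kinetic_params()] and is restored as one on read.
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  }
  plain <- strip(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(plain, path, precision = 15)
  } else {
    stop("config path must end in .json, .yaml or .yml", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("config path must end in .json, .yaml or .yml", call. = FALSE)
  }
  if (!is.null(cfg$model)) {
    m <- cfg$model
    cfg$model <- kinetic_params(
      kp1 = m$kp1, kn1 = m$kn1,
      kernel = kernel_spec(m$kernel$family, m$kernel$kp_scale,
                           m$kernel$kn_scale),
      N = m$N, S0 = m$S0
    )
  }
  cfg
}

#' Write an observable series (or list of them) as tidy CSV
#'
#' Columns `density_label`, `time_min`, `suspended_fraction`; deterministic
#' row order.
#'
#' @param series an `observable_series` or a list of them (e.g. from
#'   [density_sweep()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observable_csv <- function(series, path) {
  if (inherits(series, "observable_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(density_label = attr(s, "density_label"),
               time_min = s$time_min,
               suspended_fraction = s$suspended_fraction)
  })
  d <- do.call(rbind, rows)
  num <- function(x) vapply(x, function(v) format(v, digits = 15), "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("density_label,time_min,suspended_fraction",
               sprintf("%s,%s,%s", d$density_label, num(d$time_min),
                       num(d$suspended_fraction))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
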