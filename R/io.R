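#' Read a long-format concentration time series
#'
#' Expects CSV (or TSV) with columns `temperature`, `time`, `species`,
#' `replicate`, `value`; an optional `below_detection` logical column is
#' honoured. Values written as "<x" (censored at a detection limit) are
#' parsed as the limit x with `below_detection = TRUE`. Lines starting with
#' `#` are ignored.
#'
#' @param path File path; tab-separated when the extension is `.tsv`.
#' @return Validated long data frame.
#' @export
read_timeseries <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("temperature", "time", "species", "replicate", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("read_timeseries: missing column(s): ", paste(miss, collapse = ", "))
  censored <- grepl("^\\s*<", raw$value)
  raw$value <- sub("^\\s*<\\s*", "", raw$value)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad))
      stop("read_timeseries: non-numeric '", col, "' at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    v
  }
  out <- data.frame(temperature = num("temperature"), time = num("time"),
                    species = raw$species, replicate = num("replicate"),
                    value = num("value"),
                    below_detection = censored, stringsAsFactors = FALSE)
  if ("below_detection" %in% names(raw))
    out$below_detection <- out$below_detection |
      as.logical(raw$below_detection)
  key <- out[c("temperature", "time", "species", "replicate")]
  dup <- which(duplicated(key))
  if (length(dup))
    stop("read_timeseries: duplicate key at row ", dup[1], ": ",
         paste(sprintf("%s=%s", names(key), key[dup[1], ]), collapse = ", "))
  out
}

#' Write a stage output table
#'
#' All pipeline writers emit a header-comment block carrying the package
#' version, the configuration hash and the column schema, followed by plain
#' CSV. Files round-trip through [utils::read.csv()] with
#' `comment.char = "#"`.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param config_hash Provenance hash of the run configuration.
#' @export
write_stage_csv <- function(df, path, config_hash = "unconfigured") {
  ver <- as.character(utils::packageVersion("thermoslurry"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# thermoslurry %s", ver),
    sprintf("# config_hash: %s", config_hash),
    sprintf("# columns: %s", paste(names(df), collapse = ","))), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' `default_config()` returns the shipped run configuration;
#' `read_config()` loads a YAML file and overlays it on the defaults,
#' rejecting unknown keys and checking that referenced input files exist.
#' `config_hash()` gives a stable md5 provenance hash of a configuration.
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    scenario = "unamended",
    temperatures = as.numeric(0:80),
    time_points = c(15, 40, 70, 100),
    replicates = 3L,
    noise_cv = 0.05,
    dt = 0.1,
    tracer_schedule = c(1, 2, 3),
    stages = c("simulate", "rates", "kinetics", "gibbs", "balance",
               "partition", "cells"),
    split_temp = 43,
    q10_t1 = 283.15,
    q10_t2 = 293.15,
    divisors = c(Bacteria = 4.19, Archaea = 1.71),
    break_grid = seq(30, 60, by = 1),
    pairing = "max",
    ph = 7.5,
    gibbs_threshold = -10,
    concentrations_file = NULL
  )
}

#' @rdname default_config
#' @param path YAML configuration file.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("read_config: unknown key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) cfg[[k]] <- user[[k]]
  if (!is.null(cfg$divisors)) cfg$divisors <- unlist(cfg$divisors)
  if (!is.null(cfg$concentrations_file) &&
      !file.exists(cfg$concentrations_file))
    stop("read_config: concentrations_file does not exist: ",
         cfg$concentrations_file)
  cfg
}

#' @rdname default_config
#' @param config Configuration list.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}
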