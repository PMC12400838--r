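# Configuration and tidy-CSV interchange plus run manifests.

#' Load / save a combined configuration file
#'
#' JSON with two blocks: `parameters` (flat, keyed by the published symbol
#' names, table units; see [load_params()]) and `protocol` (fields of
#' [protocol_config()], including an optional `resting` sub-block of
#' metabolite concentrations and grid bounds `s_min`/`s_max`/`n_nodes`).
#' Omitted keys take the package defaults; unknown keys are rejected by name.
#'
#' @param path JSON file path
#' @return list with `params` (an `xb_params`) and `config`
#'   (a `protocol_config`)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), c("parameters", "protocol"))
  if (length(unknown)) {
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  }
  params <- if (is.null(raw$parameters)) xb_params() else {
    bad <- setdiff(names(raw$parameters), c(.param_fields, "mechanism"))
    if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
    do.call(xb_params, raw$parameters)
  }
  prot <- raw$protocol
  cfg_args <- list()
  if (!is.null(prot)) {
    known <- c("T_cyc", "n_cycles", "dLdt", "duty", "velocity_waveform",
               "dt", "power_scale", "target_power", "cycles_per_10s",
               "F_pee", "resting", "grid")
    bad <- setdiff(names(prot), known)
    if (length(bad)) stop("unknown protocol key(s): ", paste(bad, collapse = ", "))
    cfg_args <- prot[setdiff(names(prot), c("resting", "grid"))]
    if (!is.null(prot$resting)) {
      cfg_args$resting <- do.call(metabolite_state, as.list(prot$resting))
    }
    if (!is.null(prot$grid)) {
      cfg_args$grid <- do.call(strain_grid, as.list(prot$grid))
    }
  }
  list(params = params, config = do.call(protocol_config, cfg_args))
}

#' @rdname load_config
#' @param params an `xb_params` to save
#' @param config a `protocol_config` to save
#' @export
save_config <- function(params, config, path) {
  blocks <- list(
    parameters = params_as_table_units(params),
    protocol = list(
      T_cyc = config$T_cyc, n_cycles = config$n_cycles, dLdt = config$dLdt,
      duty = config$duty, velocity_waveform = config$velocity_waveform,
      dt = config$dt, power_scale = config$power_scale,
      target_power = config$target_power,
      cycles_per_10s = config$cycles_per_10s, F_pee = config$F_pee,
      resting = list(ATP = config$resting$ATP, ADP = config$resting$ADP,
                     Pi = config$resting$Pi, PCr = config$resting$PCr,
                     Hp = config$resting$Hp, PCr_0 = config$resting$PCr_0),
      grid = list(s_min = config$grid$s_min, s_max = config$grid$s_max,
                  n_nodes = config$grid$n_nodes)
    ))
  jsonlite::write_json(blocks, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a tidy time-series CSV
#'
#' Plain CSV with a single `# units: ...` comment header declaring the column
#' units; round-trips losslessly at 12 significant digits. Reading validates
#' that mandatory columns are present and, when `expect_units` is given, that
#' the declared units match.
#'
#' @param df data frame to write
#' @param path file path
#' @param units named character vector of units per column (optional columns
#'   may be omitted)
#' @return `write_timeseries` the path invisibly; `read_timeseries` a data
#'   frame with a `units` attribute
#' @export
write_timeseries <- function(df, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units)) {
    writeLines(paste0("# units: ", paste(names(units), units, sep = "=",
                                         collapse = ";")), con)
  }
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = NA),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param required character vector of mandatory column names
#' @param expect_units named character vector; declared units must match
#' @export
read_timeseries <- function(path, required = NULL, expect_units = NULL) {
  first <- readLines(path, n = 1)
  units <- NULL
  if (startsWith(first, "# units:")) {
    spec <- strsplit(sub("^# units: *", "", first), ";")[[1]]
    kv <- strsplit(spec, "=")
    units <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  }
  df <- utils::read.csv(path, comment.char = "#")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path)
  }
  if (!is.null(expect_units)) {
    for (cn in names(expect_units)) {
      if (!is.null(units) && cn %in% names(units) &&
          !identical(units[[cn]], expect_units[[cn]])) {
        stop("unit mismatch for column '", cn, "': file declares '",
             units[[cn]], "', expected '", expect_units[[cn]], "'")
      }
    }
  }
  attr(df, "units") <- units
  df
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: content hashes of the parameter
#' and protocol configuration, the seeds used, package version, per-stage
#' wall time and the output file inventory. Identical hashes across runs
#' identify exact reproductions.
#'
#' @param path manifest path (JSON)
#' @param params,config the run's configuration
#' @param seeds named list/vector of seeds used
#' @param files character vector of produced files
#' @param timings named numeric vector of per-stage wall times (s)
#' @return the manifest list, invisibly
#' @export
write_manifest <- function(path, params, config, seeds = NULL, files = NULL,
                           timings = NULL) {
  hash <- function(obj) {
    # dependency-free content hash: sum of a rolling polynomial over the
    # serialized object, printed as hex
    raw <- serialize(obj, NULL, version = 2)
    v <- as.integer(raw)
    h <- 0
    for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
      h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2^31
    }
    sprintf("%08x", as.integer(h))
  }
  manifest <- list(
    package = "musclexb",
    version = as.character(utils::packageVersion("musclexb")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameter_hash = hash(params_as_table_units(params)),
    config_hash = hash(config[setdiff(names(config), "resting")]),
    seeds = seeds, files = files, timings = timings
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Export / import a cross-bridge state snapshot
#'
#' CSV with columns (s, p1, p2, p3) and a comment header carrying the
#' scalar fractions N and P, so a strain-resolved state can be inspected or
#' round-tripped.
#'
#' @param state an [xb_state()]
#' @param path CSV path
#' @return `write_state_snapshot` the path invisibly; `read_state_snapshot`
#'   an `xb_state`
#' @export
write_state_snapshot <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N=%.15g;P=%.15g", state$N, state$P), con)
  writeLines("# units: s=um;p1=1/um;p2=1/um;p3=1/um", con)
  utils::write.table(
    data.frame(s = state$grid$s, p1 = state$p1, p2 = state$p2, p3 = state$p3),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_state_snapshot
#' @export
read_state_snapshot <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- strsplit(sub("^# ", "", hdr), ";")[[1]]
  vals <- stats::setNames(
    as.numeric(sub("^[NP]=", "", kv)),
    sub("=.*$", "", kv))
  df <- utils::read.csv(path, comment.char = "#")
  n <- nrow(df)
  grid <- strain_grid(df$s[1], df$s[n], n)
  xb_state(grid, N = vals[["N"]], P = vals[["P"]],
           p1 = df$p1, p2 = df$p2, p3 = df$p3)
}
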