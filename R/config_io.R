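# Structured run configuration and deterministic result writing.

.config_defaults <- function() {
  list(
    array = list(n_units = 250L, inter_unit_angle = 3.3),
    stimulus = list(
      type = "loom",
      side = 75, speed = 10, start_distance = 500, travel = 400,
      lateral_offset = 100,
      width = 70, height = 20, distance = 100, translation_speed = 0.8,
      duration = 90
    ),
    network = as.list(unclass(network_params())),
    sweep = list(param = "S_persistence_ms", values = 3:12),
    connectome = list(records = NULL, segments = NULL),
    out_dir = ".",
    seed = 1L,
    log_level = "info"
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration file and fills every unset key with the model's
#' reference defaults (250 units at 3.3 degrees, lateral gain 200 x 1/6 % over
#' six neighbours, 7 ms self-inhibition persistence, the reference loom and
#' translation geometries). Unknown keys are rejected. The returned object
#' records, per top-level key, whether its values came from the file or from
#' the defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list merged on top of the file (same schema).
#' @return A `run_config` list with attribute `provenance`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- .config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("config file not found: %s", path), call. = FALSE)
    user <- tryCatch(
      yaml::read_yaml(path),
      error = function(e) stop(sprintf("cannot parse config %s: %s",
                                       path, conditionMessage(e)),
                               call. = FALSE)
    )
    if (is.null(user)) user <- list()
    if (!is.list(user))
      stop(sprintf("config %s must be a mapping of sections", path),
           call. = FALSE)
  }
  user <- utils::modifyList(user, overrides)

  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  cfg <- defaults
  prov <- stats::setNames(rep("default", length(defaults)), names(defaults))
  for (key in names(user)) {
    section <- user[[key]]
    if (is.list(defaults[[key]]) && !is.list(section) && !is.null(section))
      stop(sprintf("config key `%s` must be a mapping", key), call. = FALSE)
    if (is.list(section)) {
      bad <- setdiff(names(section), names(defaults[[key]]))
      if (length(bad))
        stop(sprintf("unknown config key(s) under `%s`: %s", key,
                     paste(bad, collapse = ", ")), call. = FALSE)
      for (sub in names(section)) {
        tmpl <- defaults[[key]][[sub]]
        if (!is.null(tmpl) && is.numeric(tmpl) && !is.numeric(section[[sub]]))
          stop(sprintf("config key `%s.%s` must be numeric", key, sub),
               call. = FALSE)
      }
      cfg[[key]] <- utils::modifyList(defaults[[key]], section)
    } else {
      cfg[[key]] <- section
    }
    prov[key] <- "user"
  }
  structure(cfg, provenance = prov, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<run_config>\n")
  for (key in names(prov))
    cat(sprintf("  %-10s (%s)\n", key, prov[key]))
  invisible(x)
}

#' Write a result bundle to disk with a manifest
#'
#' Writes each element of `bundle` under `dir`: data frames as CSV, other
#' objects as JSON. A `run_config` element is written as a resolved YAML copy.
#' The returned manifest lists every file with its MD5 hash, so identical
#' inputs reproduce identical manifests.
#'
#' @param bundle named list of data frames / lists / `run_config`.
#' @param dir output directory (created if needed).
#' @return Manifest data frame (`file`, `md5`, `bytes`), also written to
#'   `manifest.csv` in `dir`.
#' @export
write_outputs <- function(bundle, dir) {
  if (is.null(names(bundle)) && length(bundle))
    stop("`bundle` must be a named list", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0)
    stop(sprintf("output directory not writable: %s", dir), call. = FALSE)
  files <- character(0)
  for (name in names(bundle)) {
    x <- bundle[[name]]
    if (inherits(x, "run_config")) {
      f <- file.path(dir, paste0(name, ".yaml"))
      yaml::write_yaml(unclass(x), f)
    } else if (is.data.frame(x)) {
      f <- file.path(dir, paste0(name, ".csv"))
      utils::write.csv(x, f, row.names = FALSE, quote = FALSE)
    } else {
      f <- file.path(dir, paste0(name, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
    }
    files <- c(files, f)
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = unname(file.size(files))
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest
}

#' Export a condition battery as CSV time series and a JSON summary
#'
#' Convenience bundle used by the command-line entry point: per-condition time
#' series, a summary of divergence times and suppression indices, and the
#' final activation snapshot of the fully inhibited run.
#'
#' @param battery output of [condition_battery()].
#' @return Named list suitable for [write_outputs()].
#' @export
battery_bundle <- function(battery) {
  stopifnot(all(c("none", "L", "S", "LS") %in% names(battery)))
  series <- lapply(battery, function(r)
    data.frame(time_ms = r$time_ms, output_instant = r$output_instant,
               output_integrated = r$output_integrated))
  names(series) <- paste0("series_", names(battery))
  int_none <- battery$none$output_integrated
  summary <- list(
    stimulus = battery$none$stimulus_type,
    divergence_ms = list(
      L_vs_none = divergence_time(int_none, battery$L$output_integrated),
      S_vs_none = divergence_time(int_none, battery$S$output_integrated),
      LS_vs_none = divergence_time(int_none, battery$LS$output_integrated)
    ),
    suppression = list(
      L = suppression_index(battery$none, battery$L),
      S = suppression_index(battery$none, battery$S),
      LS = suppression_index(battery$none, battery$LS)
    ),
    params = unclass(battery$LS$params)
  )
  c(series, list(summary = summary, lgmd_input = battery$LS$activation_map))
}
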