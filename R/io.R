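#' Write an event log (and its profile sidecar) to CSV
#'
#' Times are written with fixed 3-digit decimals so that write/read
#' round-trips are byte-stable.
#'
#' @param log a [event_log()].
#' @param events_path output CSV path for the milestone records.
#' @param profiles_path output CSV path for the per-patient profile
#'   sidecar; default replaces `.csv` with `_profiles.csv`.
#' @return Invisibly, the two paths.
#' @export
write_event_log <- function(log, events_path,
                            profiles_path = sub("\\.csv$", "_profiles.csv", events_path)) {
  ev <- as.data.frame(log)
  ev$t_minutes <- sprintf("%.3f", ev$t_minutes)
  utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
  pf <- attr(log, "profiles")
  if (!is.null(pf)) {
    pf$arrival_time <- sprintf("%.3f", pf$arrival_time)
    pf$age_months <- sprintf("%.3f", pf$age_months)
    utils::write.csv(pf, profiles_path, row.names = FALSE, quote = FALSE)
  }
  invisible(c(events = events_path, profiles = profiles_path))
}

#' Read an event log from CSV
#'
#' Parses, validates and lints a milestone CSV written by
#' [write_event_log()] (or produced externally in the same schema).
#' Events shuffled within a patient are re-sorted; schema violations and
#' stage-graph violations are rejected with the offending line.
#'
#' @param events_path events CSV (columns `patient_id`, `day`, `arm`,
#'   `event`, `t_minutes`).
#' @param profiles_path optional profile sidecar CSV.
#' @return A [event_log()].
#' @export
read_event_log <- function(events_path,
                           profiles_path = sub("\\.csv$", "_profiles.csv", events_path)) {
  if (!file.exists(events_path)) stop("no such file: ", events_path)
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "arm", "event", "t_minutes")
  missing <- setdiff(need, names(ev))
  if (length(missing))
    stop("event CSV lacks column(s): ", paste(missing, collapse = ", "))
  bad <- which(!ev$event %in% EVENT_NAMES)
  if (length(bad))
    stop(sprintf("unknown event name '%s' at line %d of %s",
                 ev$event[bad[1]], bad[1] + 1L, events_path))
  if (any(!is.finite(ev$t_minutes)))
    stop(sprintf("non-numeric t_minutes at line %d of %s",
                 which(!is.finite(ev$t_minutes))[1] + 1L, events_path))
  profiles <- if (file.exists(profiles_path))
    utils::read.csv(profiles_path, stringsAsFactors = FALSE) else NULL
  event_log(ev, profiles)
}

CONFIG_KEYS <- c("arm", "n_days", "arrivals_per_day", "overnight_fraction",
                 "mode", "policy", "task_fraction", "lwbs_patience", "seed",
                 "nurse", "junior", "senior", "specialist", "start_dow")

#' Load a simulation configuration from a key-value text file
#'
#' The file holds `key: value` lines (`#` comments allowed).  An empty or
#' absent key set yields the full default configuration (78 arrivals/day,
#' 23% overnight, published stage and case-mix calibration).  Unknown keys
#' and invariant violations are rejected, all at once.
#'
#' @param path config file path.
#' @param seed default seed when the file does not set one.
#' @return A [sim_config()].
#' @export
load_config <- function(path, seed = 20210315) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  errors <- character(0)
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) {
      errors <- c(errors, sprintf("malformed line (expected 'key: value'): '%s'", ln))
      next
    }
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    if (!key %in% CONFIG_KEYS) {
      errors <- c(errors, sprintf("unknown config key '%s'", key))
      next
    }
    kv[[key]] <- val
  }
  if (length(errors)) stop(paste(errors, collapse = "\n"))
  num <- function(k, d) if (k %in% names(kv)) as.numeric(kv[[k]]) else d
  chr <- function(k, d) if (k %in% names(kv)) kv[[k]] else d
  resources <- c(nurse = as.integer(num("nurse", 2)),
                 junior = as.integer(num("junior", 2)),
                 senior = as.integer(num("senior", 2)),
                 specialist = as.integer(num("specialist", 1)))
  sim_config(arm = chr("arm", "control"),
             n_days = num("n_days", 30),
             arrivals_per_day = num("arrivals_per_day", 78),
             overnight_fraction = num("overnight_fraction", 0.23),
             resources = resources,
             mode = chr("mode", "passthrough"),
             policy = if ("policy" %in% names(kv)) kv[["policy"]] else NULL,
             task_fraction = num("task_fraction", 0.3),
             lwbs_patience = num("lwbs_patience", 120),
             seed = num("seed", seed))
}

#' Seeded-run manifest
#'
#' Records what produced a set of outputs: the configuration hash, seed,
#' package version, timestamp and output file list.  Re-running with the
#' same configuration and seed reproduces identical outputs.
#'
#' @param config a [sim_config()] (or any serializable list).
#' @param seed the seed used.
#' @param outputs character vector of output paths.
#' @param path where to write the manifest JSON; `NULL` to skip writing.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(config, seed, outputs, path = NULL) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(config[sort(names(config))], file = tf)
  manifest <- list(config_hash = unname(tools::md5sum(tf)),
                   seed = seed,
                   tool_version = as.character(utils::packageVersion("pedflow")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = outputs)
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
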