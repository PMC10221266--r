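## Readers/writers for the toolkit's plain-text dialects: sensor logs,
## calibration datasets and coefficient histories as CSV (comma
## separated, UTF-8, dot decimal; units encoded in column names),
## fits/reports/protocols as JSON. Write -> read round-trips are
## lossless at full double precision.

VALID_SENSOR_IDS <- c("pressure", "o2", "co2", "t_head", "t_soil")

#' Read a sensor signal log
#'
#' Parses the standard log dialect (`timestamp`, `sensor_id`,
#' `signal_v`). Malformed rows — unparseable timestamps, unknown sensor
#' ids, non-numeric or non-finite signals — are never silently dropped:
#' they are collected into a rejects table with their line numbers.
#'
#' @param path Path to the CSV file.
#'
#' @return A list of class `sensor_log` with `log` (tibble of parsed
#'   rows) and `rejects` (tibble with `line`, `reason` and the raw
#'   fields). An empty file yields an empty log with a warning.
#' @export
read_sensor_log <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  empty <- tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                  sensor_id = character(), signal_v = numeric())
  rejects0 <- tibble(line = integer(), timestamp = character(),
                     sensor_id = character(), signal_v = character(),
                     reason = character())
  raw <- tryCatch(
    read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0) {
    if (is.null(raw)) warn(sprintf("empty sensor log: %s", path))
    out <- list(log = empty, rejects = rejects0)
    class(out) <- "sensor_log"
    return(out)
  }
  need <- c("timestamp", "sensor_id", "signal_v")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop_data(paste0("sensor log lacks required column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  ts <- as.POSIXct(strptime(raw$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  ts2 <- as.POSIXct(strptime(raw$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  ts[is.na(ts)] <- ts2[is.na(ts)]
  sig <- suppressWarnings(as.numeric(raw$signal_v))
  ok_ts <- !is.na(ts)
  ok_id <- raw$sensor_id %in% VALID_SENSOR_IDS
  ok_sig <- !is.na(sig) & is.finite(sig)
  ok <- ok_ts & ok_id & ok_sig
  reason <- dplyr::case_when(
    !ok_ts ~ "unparseable timestamp",
    !ok_id ~ "unknown sensor_id",
    !ok_sig ~ "non-numeric signal",
    TRUE ~ NA_character_
  )
  rejects <- tibble(line = which(!ok) + 1L, # header is line 1
                    timestamp = raw$timestamp[!ok],
                    sensor_id = raw$sensor_id[!ok],
                    signal_v = raw$signal_v[!ok],
                    reason = reason[!ok])
  out <- list(
    log = tibble(timestamp = ts[ok], sensor_id = raw$sensor_id[ok],
                 signal_v = sig[ok]),
    rejects = rejects
  )
  class(out) <- "sensor_log"
  out
}

#' @export
print.sensor_log <- function(x, ...) {
  cat(sprintf("<sensor_log> %d rows, %d rejected\n", nrow(x$log),
              nrow(x$rejects)))
  invisible(x)
}

#' Read and write calibration datasets
#'
#' CSV dialect: columns `point_id`, `replicate_id`, `signal_v`,
#' `measurand`, `me_y`.
#'
#' @param path File path.
#' @param sensor_kind Sensor the dataset belongs to.
#' @return `read_calibration_data()` returns a [calibration_data()]
#'   tibble; `write_calibration_data()` returns `path` invisibly.
#' @export
read_calibration_data <- function(path, sensor_kind = c("pressure", "o2", "co2")) {
  sensor_kind <- match.arg(sensor_kind)
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  d <- read.csv(path)
  need <- c("point_id", "replicate_id", "signal_v", "measurand", "me_y")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop_data(paste0("calibration CSV lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  calibration_data(point_id = d$point_id, signal_v = d$signal_v,
                   measurand = d$measurand, me_y = d$me_y,
                   replicate_id = d$replicate_id, sensor_kind = sensor_kind)
}

#' @rdname read_calibration_data
#' @param data A [calibration_data()] tibble.
#' @export
write_calibration_data <- function(data, path) {
  need <- c("point_id", "replicate_id", "signal_v", "measurand", "me_y")
  stopifnot(all(need %in% names(data)))
  write.csv(as.data.frame(data)[need], path, row.names = FALSE)
  invisible(path)
}

#' Read and write calibration-fit records
#'
#' JSON record dialect: `{sensor, date, a, b, se_a, se_b, ci_a, ci_b,
#' r2, sigma2, dw, df}`, written at full double precision.
#'
#' @param fit A fitted `baps_ols`.
#' @param path File path.
#' @param sensor,date Provenance fields stored in the record.
#' @return `write_fit_json()` returns `path` invisibly;
#'   `read_fit_json()` returns the record as a list with class
#'   `baps_fit_record` (usable wherever `b`, `se_b`, `df` are needed).
#' @export
write_fit_json <- function(fit, path, sensor = fit$sensor_kind,
                           date = Sys.Date()) {
  stopifnot(inherits(fit, "baps_ols"))
  rec <- list(sensor = sensor, date = as.character(date),
              a = fit$a, b = fit$b, se_a = fit$se_a, se_b = fit$se_b,
              ci_a = fit$ci_a, ci_b = fit$ci_b, r2 = fit$r_squared,
              sigma2 = fit$sigma2, dw = fit$dw, df = fit$df, k = fit$k)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(rec) <- "baps_fit_record"
  rec
}

#' Read and write coefficient histories
#'
#' CSV dialect: `date`, `sensor`, `a`, `b`, and optionally `se_a`,
#' `se_b`.
#'
#' @param path File path.
#' @param history Data frame with the columns above.
#' @return A tibble (reader) or `path` invisibly (writer).
#' @export
read_history <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  d <- read.csv(path)
  need <- c("date", "sensor", "a", "b")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop_data(paste0("history CSV lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  d$date <- as.Date(d$date)
  as_tibble(d)
}

#' @rdname read_history
#' @export
write_history <- function(history, path) {
  stopifnot(all(c("date", "sensor", "a", "b") %in% names(history)))
  write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}

#' Read and write exchange protocols
#'
#' JSON dialect: `{initial_gas, injected_gas, n_steps, dp_pa,
#' chamber: {p_pa, t_k, v_head_ml}}`, all numeric fields SI with
#' unit-suffixed names.
#'
#' @param path File path.
#' @param protocol A [baps_protocol()].
#' @return A [baps_protocol()] (reader) or `path` invisibly (writer).
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("initial_gas", "injected_gas", "n_steps", "dp_pa", "chamber")
  missing_fields <- setdiff(need, names(p))
  if (length(missing_fields)) {
    stop_data(paste0("protocol JSON lacks field(s): ",
                     paste(missing_fields, collapse = ", ")))
  }
  mix <- function(g) gas_mixture(g$frac_o2, g$frac_co2, g$frac_n2,
                                 rel_accuracy = g$rel_accuracy %||% 0.02)
  baps_protocol(initial = mix(p$initial_gas), injected = mix(p$injected_gas),
                n_steps = p$n_steps, dp_pa = p$dp_pa,
                p_pa = p$chamber$p_pa, t_k = p$chamber$t_k,
                v_head_ml = p$chamber$v_head_ml)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "baps_protocol"))
  mix <- function(g) list(frac_o2 = g$frac_o2, frac_co2 = g$frac_co2,
                          frac_n2 = g$frac_n2, rel_accuracy = g$rel_accuracy)
  jsonlite::write_json(
    list(initial_gas = mix(protocol$initial),
         injected_gas = mix(protocol$injected),
         n_steps = protocol$n_steps, dp_pa = protocol$dp_pa,
         chamber = protocol$chamber),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read and write incubation series
#'
#' CSV dialect: `timestamp_h`, `t_head_k`, `t_soil_k`, plus either the
#' calibrated columns (`p_hpa`, `o2_volpct`, `co2_umol_ml`) or the raw
#' signal columns (`signal_p_v`, `signal_o2_v`, `signal_co2_v`), or
#' both. The headspace volume travels in a `v_head_ml` column (constant)
#' and is re-attached as an attribute on read.
#'
#' @param path File path.
#' @param series Incubation tibble (e.g. from [simulate_incubation()]).
#' @return A tibble with attribute `v_head_ml` (reader) or `path`
#'   invisibly (writer).
#' @export
read_incubation <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  d <- read.csv(path)
  if (!"timestamp_h" %in% names(d)) {
    stop_data("incubation CSV lacks column: timestamp_h")
  }
  out <- as_tibble(d)
  if ("v_head_ml" %in% names(out)) {
    attr(out, "v_head_ml") <- out$v_head_ml[1]
    out$v_head_ml <- NULL
  }
  out
}

#' @rdname read_incubation
#' @export
write_incubation <- function(series, path) {
  d <- as.data.frame(series)
  v <- attr(series, "v_head_ml", exact = TRUE)
  if (!is.null(v)) d$v_head_ml <- v
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
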