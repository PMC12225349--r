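#' @keywords internal
test_levels <- function() c("T0", "T1", "T2")

# canonical column order of the event CSV dialect
event_columns <- function() {
  c("pair_id", "participant_id", "test_id", "event_type", "t_start_ms",
    "insufflation_ms", "volume_ml", "effective", "depth_mm", "rate_cpm",
    "correct_depth", "correct_recoil", "correct_rate")
}

#' Validate an event data frame
#'
#' Checks the long-format event table used throughout the package: one
#' row per ventilation or compression, with millisecond integer times,
#' exposure labels restricted to T0/T1/T2, and non-negative volumes,
#' durations, depths and rates. Booleans are stored as 0/1 integers.
#'
#' @param events a data frame with the columns of the event dialect (see
#'   [read_events()]).
#' @return The validated data frame, invisibly classed `cpr_events`.
#' @export
validate_events <- function(events) {
  if (!is.data.frame(events)) stop("events must be a data frame", call. = FALSE)
  missing <- setdiff(event_columns(), names(events))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_test <- unique(events$test_id[!events$test_id %in% test_levels()])
  if (length(bad_test)) {
    stop(sprintf("unknown test_id label(s) %s; allowed labels: %s",
                 paste(sQuote(bad_test), collapse = ", "),
                 paste(test_levels(), collapse = ", ")), call. = FALSE)
  }
  bad_type <- unique(events$event_type[!events$event_type %in%
                                         c("ventilation", "compression")])
  if (length(bad_type)) {
    stop("unknown event_type: ", paste(sQuote(bad_type), collapse = ", "),
         call. = FALSE)
  }
  num_nonneg <- c("t_start_ms", "insufflation_ms", "volume_ml", "depth_mm",
                  "rate_cpm")
  for (col in num_nonneg) {
    if (any(events[[col]] < 0, na.rm = TRUE)) {
      stop("negative values in column ", col, call. = FALSE)
    }
  }
  vent <- events$event_type == "ventilation"
  if (any(is.na(events$t_start_ms))) {
    stop("t_start_ms must not be missing", call. = FALSE)
  }
  if (any(vent & events$effective %in% 1L & (is.na(events$insufflation_ms) |
                                             is.na(events$volume_ml)))) {
    stop("effective ventilations must carry insufflation_ms and volume_ml",
         call. = FALSE)
  }
  if (!inherits(events, "cpr_events")) {
    class(events) <- c("cpr_events", class(events))
  }
  invisible(events)
}

#' Read and write per-event CPR session records
#'
#' The package stores CPR sessions as a single long-format CSV (UTF-8,
#' comma-separated) with header
#' `pair_id,participant_id,test_id,event_type,t_start_ms,insufflation_ms,volume_ml,effective,depth_mm,rate_cpm,correct_depth,correct_recoil,correct_rate`.
#' Each row is one ventilation or one compression; cells not applicable
#' to the event type are left empty. Times are integer milliseconds from
#' the start of the two-minute test, volumes are mL, depths mm, rates
#' compressions/min, and booleans are serialised as 0/1. A session is
#' the group of rows sharing `(pair_id, test_id)`.
#'
#' Malformed rows are reported with their file line numbers. With
#' `on_error = "stop"` (default) any malformed row aborts the read; with
#' `on_error = "report"` malformed rows are dropped with a warning and
#' returned in the `row_errors` attribute, so that row counts always
#' reconcile: parsed events + reported errors = data rows in the file.
#'
#' @param path CSV file path.
#' @param on_error `"stop"` or `"report"`.
#' @return A `cpr_events` data frame (possibly zero rows).
#' @export
read_events <- function(path, on_error = c("stop", "report")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing <- setdiff(event_columns(), names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[, event_columns(), drop = FALSE]
  n <- nrow(raw)
  errors <- character(0)
  err_lines <- integer(0)
  note <- function(i, msg) {
    # +1 for the header line
    errors <<- c(errors, sprintf("line %d: %s", i + 1L, msg))
    err_lines <<- c(err_lines, i)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  parsed <- data.frame(
    pair_id = raw$pair_id,
    participant_id = raw$participant_id,
    test_id = raw$test_id,
    event_type = raw$event_type,
    t_start_ms = num(raw$t_start_ms),
    insufflation_ms = num(raw$insufflation_ms),
    volume_ml = num(raw$volume_ml),
    effective = as.integer(num(raw$effective)),
    depth_mm = num(raw$depth_mm),
    rate_cpm = num(raw$rate_cpm),
    correct_depth = as.integer(num(raw$correct_depth)),
    correct_recoil = as.integer(num(raw$correct_recoil)),
    correct_rate = as.integer(num(raw$correct_rate)),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    if (!parsed$test_id[i] %in% test_levels()) {
      note(i, sprintf("unknown test_id %s; allowed labels: %s",
                      sQuote(parsed$test_id[i]),
                      paste(test_levels(), collapse = ", ")))
      next
    }
    if (!parsed$event_type[i] %in% c("ventilation", "compression")) {
      note(i, sprintf("unknown event_type %s", sQuote(parsed$event_type[i])))
      next
    }
    if (is.na(parsed$t_start_ms[i]) || parsed$t_start_ms[i] < 0) {
      note(i, "t_start_ms missing, non-numeric or negative")
      next
    }
    if (parsed$event_type[i] == "ventilation") {
      if (nzchar(raw$volume_ml[i]) && is.na(parsed$volume_ml[i])) {
        note(i, "non-numeric volume_ml")
        next
      }
      if (nzchar(raw$insufflation_ms[i]) && is.na(parsed$insufflation_ms[i])) {
        note(i, "non-numeric insufflation_ms")
        next
      }
      if (isTRUE(parsed$volume_ml[i] < 0) ||
          isTRUE(parsed$insufflation_ms[i] < 0)) {
        note(i, "negative volume_ml or insufflation_ms")
        next
      }
      if (is.na(parsed$effective[i])) {
        note(i, "missing effective flag on ventilation")
        next
      }
    } else {
      if (is.na(parsed$depth_mm[i]) || is.na(parsed$rate_cpm[i])) {
        note(i, "compression missing depth_mm or rate_cpm")
        next
      }
      if (parsed$depth_mm[i] < 0 || parsed$rate_cpm[i] <= 0) {
        note(i, "compression depth must be >= 0 and rate > 0")
        next
      }
    }
  }
  if (length(errors)) {
    if (on_error == "stop") {
      stop("malformed event rows:\n", paste(errors, collapse = "\n"),
           call. = FALSE)
    }
    warning(length(errors), " malformed row(s) dropped; see attr(x, 'row_errors')",
            call. = FALSE)
    parsed <- parsed[-err_lines, , drop = FALSE]
    rownames(parsed) <- NULL
  }
  class(parsed) <- c("cpr_events", class(parsed))
  attr(parsed, "row_errors") <- errors
  parsed
}

#' @rdname read_events
#' @param events a validated event data frame.
#' @details `write_events()` and `read_events()` round-trip: reading a
#'   written file reproduces the event fields exactly, including integer
#'   millisecond times.
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  out <- as.data.frame(events)[, event_columns(), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Split an event table into per-session groups
#'
#' @param events a `cpr_events` data frame.
#' @return A named list of data frames, one per `(pair_id, test_id)`
#'   session, ordered by test then pair.
#' @export
split_sessions <- function(events) {
  events <- validate_events(events)
  key <- interaction(events$test_id, events$pair_id, drop = TRUE, sep = ":")
  out <- split(as.data.frame(events), key)
  out[order(names(out))]
}

#' Read a labelled contingency table
#'
#' Reads exposure-by-category count tables, either as JSON
#' (`{"rows": ["T0","T1","T2"], "cols": ["green","red"], "counts": [[...], ...]}`)
#' or as CSV with row labels in the first column and category labels in
#' the header. Counts must be non-negative integers. This allows the
#' case-control analysis to run directly on published count tables
#' without raw per-event data.
#'
#' @param path file path ending in `.json` or `.csv`.
#' @return An integer matrix with row/column dimnames.
#' @export
read_contingency_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("rows", "cols", "counts")
    missing <- setdiff(need, names(obj))
    if (length(missing)) {
      stop("contingency JSON missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    counts <- obj$counts
    if (is.list(counts)) counts <- do.call(rbind, counts)
    counts <- as.matrix(counts)
    dimnames(counts) <- list(obj$rows, obj$cols)
  } else {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    counts <- as.matrix(df)
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' @rdname read_contingency_table
#' @param counts labelled count matrix.
#' @export
write_contingency_table <- function(counts, path) {
  stopifnot(is.matrix(counts))
  jsonlite::write_json(
    list(rows = rownames(counts), cols = colnames(counts),
         counts = apply(counts, 1L, as.integer, simplify = FALSE)),
    path, digits = NA
  )
  invisible(path)
}
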