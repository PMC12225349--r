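#' Ventilation classification thresholds
#'
#' Builds the set of volume and insufflation-time bands that define the
#' green/amber/red ventilation categories. The defaults follow the
#' guideline-derived study bands: a target ("green") box of 500--600 mL
#' and 0.85--1.15 s, inside an acceptable ("amber") box of 400--700 mL
#' and 0.55--1.45 s. Everything outside the amber box is "red".
#'
#' All interval bounds are closed (inclusive): the red rules are strict
#' inequalities (e.g. volume < 400 mL), so values sitting exactly on a
#' band edge are never red.
#'
#' @param green_vol numeric length-2, target volume band in mL.
#' @param green_time numeric length-2, target insufflation-time band in
#'   seconds.
#' @param amber_vol numeric length-2, acceptable volume band in mL; must
#'   contain `green_vol`.
#' @param amber_time numeric length-2, acceptable time band in seconds;
#'   must contain `green_time`.
#'
#' @return An object of class `vent_thresholds`: a list with the four
#'   intervals, each sorted as `c(lower, upper)`.
#'
#' @examples
#' th <- vent_thresholds()
#' classify_ventilation(550, 1.0, th)
#'
#' @export
vent_thresholds <- function(green_vol = c(500, 600),
                            green_time = c(0.85, 1.15),
                            amber_vol = c(400, 700),
                            amber_time = c(0.55, 1.45)) {
  chk <- function(x, what) {
    if (!is.numeric(x) || length(x) != 2L || anyNA(x)) {
      stop(sprintf("'%s' must be a numeric interval c(lower, upper)", what),
           call. = FALSE)
    }
    if (x[1L] > x[2L]) {
      stop(sprintf("'%s': lower bound exceeds upper bound", what),
           call. = FALSE)
    }
    as.numeric(x)
  }
  green_vol <- chk(green_vol, "green_vol")
  green_time <- chk(green_time, "green_time")
  amber_vol <- chk(amber_vol, "amber_vol")
  amber_time <- chk(amber_time, "amber_time")
  if (green_vol[1L] < amber_vol[1L] || green_vol[2L] > amber_vol[2L]) {
    stop("green volume band must lie within the amber volume band",
         call. = FALSE)
  }
  if (green_time[1L] < amber_time[1L] || green_time[2L] > amber_time[2L]) {
    stop("green time band must lie within the amber time band",
         call. = FALSE)
  }
  structure(
    list(green_vol = green_vol, green_time = green_time,
         amber_vol = amber_vol, amber_time = amber_time),
    class = "vent_thresholds"
  )
}

#' Read or write classification thresholds as JSON
#'
#' The JSON layout mirrors [vent_thresholds()]: an object with keys
#' `green_vol`, `green_time`, `amber_vol`, `amber_time`, each a
#' two-element array `[lower, upper]` (volumes in mL, times in seconds).
#'
#' @param path file path of the JSON threshold configuration.
#' @return `read_thresholds()` returns a validated `vent_thresholds`
#'   object; `write_thresholds()` returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("thresholds file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("green_vol", "green_time", "amber_vol", "amber_time")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("thresholds file missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vent_thresholds(cfg$green_vol, cfg$green_time, cfg$amber_vol, cfg$amber_time)
}

#' @rdname read_thresholds
#' @param thresholds a `vent_thresholds` object.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "vent_thresholds"))
  jsonlite::write_json(unclass(thresholds), path, digits = NA)
  invisible(path)
}

#' @export
print.vent_thresholds <- function(x, ...) {
  cat("Ventilation classification thresholds\n")
  cat(sprintf("  green: volume %g-%g mL, time %g-%g s\n",
              x$green_vol[1], x$green_vol[2], x$green_time[1], x$green_time[2]))
  cat(sprintf("  amber: volume %g-%g mL, time %g-%g s\n",
              x$amber_vol[1], x$amber_vol[2], x$amber_time[1], x$amber_time[2]))
  cat("  red:   outside the amber bands\n")
  invisible(x)
}
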