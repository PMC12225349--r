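#' Classify ventilations into green/amber/red quality bands
#'
#' Applies the three-tier rule set to each (volume, insufflation time)
#' pair. A ventilation is **green** when both the volume and the time
#' fall inside the target bands; **red** when the volume or the time
#' falls outside the acceptable bands (strict inequalities: volume below
#' 400 mL or above 700 mL, time below 0.55 s or above 1.45 s at the
#' defaults); **amber** otherwise. The three outcomes partition the
#' (volume, time) plane: every event receives exactly one label.
#'
#' @param volume_ml numeric vector of insufflated volumes, mL.
#' @param time_s numeric vector of insufflation times, seconds. Recycled
#'   against `volume_ml` if of length 1.
#' @param thresholds a [vent_thresholds()] object.
#' @param reasons logical; if `TRUE` return a data frame with a `reason`
#'   column stating which rule fired.
#'
#' @return A factor with levels `green`, `amber`, `red` (or a data frame
#'   with columns `category` and `reason` when `reasons = TRUE`).
#'
#' @examples
#' classify_ventilation(c(550, 550, 650), c(1.0, 0.48, 1.0))
#'
#' @export
classify_ventilation <- function(volume_ml, time_s,
                                 thresholds = vent_thresholds(),
                                 reasons = FALSE) {
  stopifnot(inherits(thresholds, "vent_thresholds"))
  n <- max(length(volume_ml), length(time_s))
  volume_ml <- rep_len(as.numeric(volume_ml), n)
  time_s <- rep_len(as.numeric(time_s), n)
  if (any(volume_ml < 0, na.rm = TRUE)) {
    stop("negative volume_ml", call. = FALSE)
  }
  if (any(time_s < 0, na.rm = TRUE)) {
    stop("negative time_s", call. = FALSE)
  }
  th <- thresholds
  in_band <- function(x, b) x >= b[1L] & x <= b[2L]

  green <- in_band(volume_ml, th$green_vol) & in_band(time_s, th$green_time)
  red <- volume_ml < th$amber_vol[1L] | volume_ml > th$amber_vol[2L] |
    time_s < th$amber_time[1L] | time_s > th$amber_time[2L]

  cat_chr <- ifelse(green, "green", ifelse(red, "red", "amber"))
  category <- factor(cat_chr, levels = c("green", "amber", "red"))
  if (!reasons) return(category)

  reason <- character(n)
  reason[green] <- "volume and insufflation time within target bands"
  amber <- !green & !red
  reason[amber] <- "within acceptable bands, outside target bands"
  # first red rule that fires, in the stated order
  idx <- which(!green & red)
  for (i in idx) {
    reason[i] <- if (volume_ml[i] < th$amber_vol[1L]) {
      sprintf("volume < %g mL", th$amber_vol[1L])
    } else if (volume_ml[i] > th$amber_vol[2L]) {
      sprintf("volume > %g mL", th$amber_vol[2L])
    } else if (time_s[i] < th$amber_time[1L]) {
      sprintf("insufflation time < %g s", th$amber_time[1L])
    } else {
      sprintf("insufflation time > %g s", th$amber_time[2L])
    }
  }
  data.frame(category = category, reason = reason)
}

#' Classify every ventilation in an event set and tabulate by test
#'
#' Runs [classify_ventilation()] over all ventilation events, keeping
#' only effective ventilations (the device-captured inclusion rule used
#' for the case-control sample), and tabulates category counts per
#' exposure level.
#'
#' @param events an event data frame as returned by [read_events()] or
#'   [simulate_study()].
#' @param thresholds a [vent_thresholds()] object.
#'
#' @return An object of class `vent_classification`: a list with
#'   \describe{
#'     \item{events}{the effective ventilation rows with `category` and
#'       `reason` columns appended;}
#'     \item{counts}{integer matrix, tests in rows and the three
#'       categories in columns;}
#'     \item{excluded}{named integer vector of ineffective ventilations
#'       excluded per test;}
#'     \item{thresholds}{the thresholds used.}
#'   }
#' @export
classify_events <- function(events, thresholds = vent_thresholds()) {
  events <- validate_events(events)
  vent <- events[events$event_type == "ventilation", , drop = FALSE]
  eff <- vent[vent$effective %in% 1L, , drop = FALSE]
  excluded <- table(factor(vent$test_id[!vent$effective %in% 1L],
                           levels = test_levels()))
  cls <- classify_ventilation(eff$volume_ml, eff$insufflation_ms / 1000,
                              thresholds, reasons = TRUE)
  eff$category <- cls$category
  eff$reason <- cls$reason
  counts <- table(factor(eff$test_id, levels = test_levels()), cls$category)
  counts <- matrix(as.integer(counts), nrow = length(test_levels()),
                   dimnames = list(test_levels(), levels(cls$category)))
  structure(
    list(events = eff, counts = counts,
         excluded = as.integer(excluded), thresholds = thresholds),
    class = "vent_classification"
  )
}

#' @export
print.vent_classification <- function(x, ...) {
  cat("Ventilation classification (effective ventilations only)\n")
  tot <- sum(x$counts)
  print(x$counts)
  cat(sprintf("Total classified: %d; excluded as ineffective: %d\n",
              tot, sum(x$excluded)))
  invisible(x)
}
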