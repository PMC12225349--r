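#' Composite CPR quality scores
#'
#' Three composite percentages summarise a session:
#' \describe{
#'   \item{compression quality}{the arithmetic mean of the percentages
#'     of compressions with correct depth, correct recoil and correct
#'     rate;}
#'   \item{ventilation quality}{the percentage of effective ventilations
#'     falling in the green band (volume 500--600 mL and insufflation
#'     time 0.85--1.15 s at the default thresholds);}
#'   \item{CPR quality}{the arithmetic mean of compression quality and
#'     ventilation quality.}
#' }
#'
#' @param pct_correct_depth,pct_correct_recoil,pct_correct_rate
#'   percentages in \[0, 100\].
#' @return A percentage in \[0, 100\].
#' @examples
#' cc_quality(60, 70, 80)   # 70
#' cpr_quality(48, 0)       # 24
#' @export
cc_quality <- function(pct_correct_depth, pct_correct_recoil,
                       pct_correct_rate) {
  x <- c(pct_correct_depth, pct_correct_recoil, pct_correct_rate)
  if (anyNA(x) || any(x < 0) || any(x > 100)) {
    stop("component percentages must lie in [0, 100]", call. = FALSE)
  }
  (pct_correct_depth + pct_correct_recoil + pct_correct_rate) / 3
}

#' @rdname cc_quality
#' @param cc,v compression and ventilation quality percentages.
#' @export
cpr_quality <- function(cc, v) {
  x <- c(cc, v)
  if (anyNA(x) || any(x < 0) || any(x > 100)) {
    stop("quality percentages must lie in [0, 100]", call. = FALSE)
  }
  (cc + v) / 2
}

#' Ventilation quality of a set of ventilations
#'
#' Percentage of ventilations classified green. The denominator is the
#' number of (effective) ventilations supplied; sessions with no
#' ventilations score 0 with a message.
#'
#' @param volume_ml,time_s paired vectors of effective-ventilation
#'   volumes (mL) and insufflation times (s).
#' @param thresholds a [vent_thresholds()] object.
#' @return Percentage in \[0, 100\].
#' @examples
#' v_quality(c(550, 639), c(1.0, 0.48))  # 50: second breath is red by time
#' @export
v_quality <- function(volume_ml, time_s, thresholds = vent_thresholds()) {
  if (length(volume_ml) != length(time_s)) {
    stop("volume_ml and time_s must have equal length", call. = FALSE)
  }
  if (length(volume_ml) == 0L) {
    message("v_quality: no ventilations; returning 0")
    return(0)
  }
  cat <- classify_ventilation(volume_ml, time_s, thresholds)
  100 * sum(cat == "green") / length(cat)
}

#' Summarise one CPR session
#'
#' Computes the per-test session metrics: mean compression depth and
#' rate, no-flow time (session duration minus the time occupied by
#' compressions, where a compression at instantaneous rate r occupies
#' 60/r seconds), ventilation counts and means, and the three composite
#' quality scores.
#'
#' The compression-rate component of compression quality has two modes:
#' `"per-compression"` scores the percentage of compressions whose
#' instantaneous rate lies in `rate_band`; `"all-or-nothing"` scores 100
#' when the session mean rate lies in the band and 0 otherwise.
#'
#' @param session event rows of a single `(pair_id, test_id)` session.
#' @param duration_ms session length in integer milliseconds (default
#'   two minutes).
#' @param thresholds a [vent_thresholds()] object.
#' @param rate_mode `"per-compression"` or `"all-or-nothing"`.
#' @param rate_band guideline compression-rate band, compressions/min.
#' @return One-row data frame with columns `pair_id`, `test_id`,
#'   `mean_depth`, `mean_rate`, `no_flow_s`, `no_flow_pct`,
#'   `n_ventilations`, `pct_effective`, `mean_volume`,
#'   `mean_insufflation_time`, `cc_quality`, `v_quality`, `cpr_quality`.
#'   Compression-derived fields are `NA` when the session has no
#'   compressions.
#' @export
summarize_session <- function(session, duration_ms = 120000L,
                              thresholds = vent_thresholds(),
                              rate_mode = c("per-compression",
                                            "all-or-nothing"),
                              rate_band = c(100, 120)) {
  rate_mode <- match.arg(rate_mode)
  session <- as.data.frame(validate_events(session))
  key <- unique(session[, c("pair_id", "test_id")])
  if (nrow(key) != 1L) {
    stop("summarize_session expects events from exactly one session",
         call. = FALSE)
  }
  comp <- session[session$event_type == "compression", , drop = FALSE]
  vent <- session[session$event_type == "ventilation", , drop = FALSE]
  eff <- vent[vent$effective %in% 1L, , drop = FALSE]

  has_comp <- nrow(comp) > 0L
  mean_depth <- if (has_comp) mean(comp$depth_mm) else NA_real_
  mean_rate <- if (has_comp) mean(comp$rate_cpm) else NA_real_
  comp_time_s <- if (has_comp) sum(60 / comp$rate_cpm) else 0
  no_flow_s <- duration_ms / 1000 - comp_time_s
  no_flow_pct <- 100 * no_flow_s / (duration_ms / 1000)

  ccq <- if (!has_comp) NA_real_ else {
    pd <- 100 * mean(comp$correct_depth %in% 1L)
    pr <- 100 * mean(comp$correct_recoil %in% 1L)
    pq <- if (rate_mode == "per-compression") {
      100 * mean(comp$rate_cpm >= rate_band[1L] & comp$rate_cpm <= rate_band[2L])
    } else {
      if (mean_rate >= rate_band[1L] && mean_rate <= rate_band[2L]) 100 else 0
    }
    cc_quality(pd, pr, pq)
  }
  vq <- if (nrow(eff)) {
    v_quality(eff$volume_ml, eff$insufflation_ms / 1000, thresholds)
  } else 0
  data.frame(
    pair_id = key$pair_id, test_id = key$test_id,
    mean_depth = mean_depth, mean_rate = mean_rate,
    no_flow_s = no_flow_s, no_flow_pct = no_flow_pct,
    n_ventilations = nrow(eff),
    pct_effective = if (nrow(vent)) 100 * nrow(eff) / nrow(vent) else NA_real_,
    mean_volume = if (nrow(eff)) mean(eff$volume_ml) else NA_real_,
    mean_insufflation_time = if (nrow(eff)) mean(eff$insufflation_ms) / 1000
                             else NA_real_,
    cc_quality = ccq, v_quality = vq,
    cpr_quality = if (is.na(ccq)) NA_real_ else cpr_quality(ccq, vq),
    stringsAsFactors = FALSE
  )
}

#' @rdname summarize_session
#' @param events an event data frame covering one or more sessions.
#' @param ... passed on to `summarize_session()`.
#' @return `summarize_sessions()` returns one row per session.
#' @export
summarize_sessions <- function(events, duration_ms = 120000L, ...) {
  parts <- split_sessions(events)
  out <- do.call(rbind, lapply(parts, summarize_session,
                               duration_ms = duration_ms, ...))
  rownames(out) <- NULL
  out[order(out$test_id, out$pair_id), , drop = FALSE]
}

#' Median and interquartile range per variable per test
#'
#' Summarises session metrics the way repeated-measures CPR tables are
#' reported: median and Q1--Q3 per variable per exposure level.
#' Quartiles use the linear-interpolation convention of
#' `stats::quantile(type = 7)`, so e.g. values 1..5 give median 3 and
#' IQR 2--4.
#'
#' @param metrics output of [summarize_sessions()].
#' @return Long data frame with columns `variable`, `test_id`, `median`,
#'   `q1`, `q3`, `n`.
#' @export
summarize_group <- function(metrics) {
  stopifnot(is.data.frame(metrics), "test_id" %in% names(metrics))
  vars <- setdiff(names(metrics), c("pair_id", "test_id"))
  tests <- intersect(test_levels(), unique(metrics$test_id))
  if (!length(tests)) stop("no test groups present", call. = FALSE)
  rows <- list()
  for (v in vars) {
    for (t in tests) {
      x <- metrics[[v]][metrics$test_id == t]
      x <- x[!is.na(x)]
      if (!length(x)) {
        stop(sprintf("no sessions with non-missing '%s' in test %s", v, t),
             call. = FALSE)
      }
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, test_id = t, median = q[2L], q1 = q[1L], q3 = q[3L],
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
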