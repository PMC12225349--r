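#' Fit a lognormal distribution from a median and interquartile range
#'
#' Published session tables report medians and IQRs only; to emulate
#' their event-level distributions the simulator uses lognormals with
#' location `log(median)` and scale `log(q3/q1) / (2 z_0.75)`
#' (z_0.75 ~ 0.6745). The fitted distribution has the target median
#' exactly and its Q3/Q1 ratio equals the target ratio; with
#' `q1 = median = q3` it degenerates to a point mass.
#'
#' @param median,q1,q3 positive numbers with `q1 <= median <= q3`.
#' @return List with `meanlog` and `sdlog`, usable with
#'   [stats::rlnorm()].
#' @export
lognormal_from_median_iqr <- function(median, q1, q3) {
  if (any(c(median, q1, q3) <= 0)) {
    stop("median and quartiles must be positive", call. = FALSE)
  }
  if (q1 > median || median > q3) {
    stop("need q1 <= median <= q3", call. = FALSE)
  }
  list(meanlog = log(median),
       sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

#' Distributional profile of one test (exposure level)
#'
#' Holds the per-event sampling targets of one two-minute test:
#' lognormal medians/IQRs for ventilation volume (mL) and insufflation
#' time (s) and for compression rate (compressions/min) and depth (mm),
#' the probability that a ventilation is effective, and the fixed
#' timeline gaps (seconds after each breath, and the hand-off pause
#' between the last compression of a cycle and the first breath).
#'
#' @param test_id exposure label, one of T0/T1/T2.
#' @param volume_median,volume_iqr ventilation volume target, mL.
#' @param time_median,time_iqr insufflation-time target, s.
#' @param rate_median,rate_iqr compression-rate target, per min.
#' @param depth_median,depth_iqr compression-depth target, mm.
#' @param p_effective probability a ventilation is effective.
#' @param p_correct_recoil probability a compression has correct recoil.
#' @param inter_breath_gap seconds between breaths (mask reseal etc.).
#' @param compression_pause seconds of hand-off between compressions
#'   and ventilations in each 30:2 cycle.
#' @return A `test_profile` object.
#' @export
test_profile <- function(test_id,
                         volume_median, volume_iqr,
                         time_median, time_iqr,
                         rate_median, rate_iqr,
                         depth_median, depth_iqr,
                         p_effective = 1,
                         p_correct_recoil = 0.85,
                         inter_breath_gap = 1.5,
                         compression_pause = 2.5) {
  if (!test_id %in% test_levels()) {
    stop("test_id must be one of ", paste(test_levels(), collapse = ", "),
         call. = FALSE)
  }
  chk_iqr <- function(med, iqr, what) {
    if (length(iqr) != 2L || iqr[1L] > med || med > iqr[2L]) {
      stop(sprintf("'%s': need q1 <= median <= q3", what), call. = FALSE)
    }
  }
  chk_iqr(volume_median, volume_iqr, "volume")
  chk_iqr(time_median, time_iqr, "time")
  chk_iqr(rate_median, rate_iqr, "rate")
  chk_iqr(depth_median, depth_iqr, "depth")
  if (p_effective < 0 || p_effective > 1 ||
      p_correct_recoil < 0 || p_correct_recoil > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(test_id = test_id,
         volume = lognormal_from_median_iqr(volume_median, volume_iqr[1L],
                                            volume_iqr[2L]),
         time = lognormal_from_median_iqr(time_median, time_iqr[1L],
                                          time_iqr[2L]),
         rate = lognormal_from_median_iqr(rate_median, rate_iqr[1L],
                                          rate_iqr[2L]),
         depth = lognormal_from_median_iqr(depth_median, depth_iqr[1L],
                                           depth_iqr[2L]),
         volume_median = volume_median, time_median = time_median,
         rate_median = rate_median, depth_median = depth_median,
         p_effective = p_effective, p_correct_recoil = p_correct_recoil,
         inter_breath_gap = inter_breath_gap,
         compression_pause = compression_pause),
    class = "test_profile"
  )
}

#' Default test profiles emulating a two-session training study
#'
#' Profiles fitted to the published per-test medians and IQRs of a
#' ten-lifeguard pilot: volumes fall and insufflation times lengthen
#' towards ~1 s with training, while compression rate slows slightly.
#' T0 = before training, T1 = after one session, T2 = after two.
#'
#' @return Named list of three [test_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    T0 = test_profile("T0",
                      volume_median = 639, volume_iqr = c(593, 717),
                      time_median = 0.48, time_iqr = c(0.41, 0.59),
                      rate_median = 122, rate_iqr = c(116, 127),
                      depth_median = 56, depth_iqr = c(52, 61)),
    T1 = test_profile("T1",
                      volume_median = 452, volume_iqr = c(317, 519),
                      time_median = 0.91, time_iqr = c(0.73, 1.21),
                      rate_median = 115, rate_iqr = c(106, 120),
                      depth_median = 53, depth_iqr = c(50, 55)),
    T2 = test_profile("T2",
                      volume_median = 531, volume_iqr = c(488, 618),
                      time_median = 0.94, time_iqr = c(0.82, 1.03),
                      rate_median = 113, rate_iqr = c(108, 120),
                      depth_median = 54, depth_iqr = c(50, 56))
  )
}

#' Study design of a 30:2 simulated CPR test battery
#'
#' @param n_pairs number of rescuer pairs.
#' @param duration_s test length, seconds.
#' @param initial_breaths rescue breaths opening each test (drowning
#'   protocol).
#' @param compressions_per_cycle,breaths_per_cycle the 30:2 cycle.
#' @return A `study_design` object.
#' @export
study_design <- function(n_pairs = 5L, duration_s = 120,
                         initial_breaths = 5L,
                         compressions_per_cycle = 30L,
                         breaths_per_cycle = 2L) {
  vals <- c(n_pairs, duration_s, initial_breaths, compressions_per_cycle,
            breaths_per_cycle)
  if (any(vals <= 0)) stop("all design counts must be positive", call. = FALSE)
  structure(list(n_pairs = as.integer(n_pairs), duration_s = duration_s,
                 initial_breaths = as.integer(initial_breaths),
                 compressions_per_cycle = as.integer(compressions_per_cycle),
                 breaths_per_cycle = as.integer(breaths_per_cycle)),
            class = "study_design")
}

# deterministic per-session substream seed from the global seed and the
# session key, independent of generation order
session_seed <- function(seed, pair_id, test_id) {
  key <- paste0(pair_id, "|", test_id)
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) * 131L)
  (as.integer(seed) %% 1000003L) * 2039L + (h %% 1000003L)
}

# sample one ventilation (volume mL, time s, effective flag)
sample_ventilations <- function(profile, n) {
  if (n == 0L) {
    return(data.frame(volume_ml = numeric(0), time_s = numeric(0),
                      effective = integer(0)))
  }
  data.frame(
    volume_ml = stats::rlnorm(n, profile$volume$meanlog, profile$volume$sdlog),
    time_s = stats::rlnorm(n, profile$time$meanlog, profile$time$sdlog),
    effective = stats::rbinom(n, 1L, profile$p_effective)
  )
}

#' Simulate one two-minute 30:2 CPR session
#'
#' Builds the event timeline of a single test: `initial_breaths` rescue
#' breaths (each occupying its sampled insufflation time plus
#' `inter_breath_gap`), then repeated cycles of
#' `compressions_per_cycle` compressions (each occupying 60/rate
#' seconds at its sampled instantaneous rate) followed by the hand-off
#' pause and `breaths_per_cycle` breaths, truncated at the session
#' duration: an event is emitted only if it finishes within the
#' session. Volumes, insufflation times, rates and depths are sampled
#' independently per event from the profile's lognormals; correctness
#' flags are derived (depth in 50--60 mm, rate in 100--120/min, recoil
#' Bernoulli).
#'
#' @param profile a [test_profile()].
#' @param design a [study_design()].
#' @param pair_id session identifier.
#' @param seed integer seed for this session's substream.
#' @return A `cpr_events` data frame for one session, time-ordered.
#' @export
simulate_test <- function(profile, design = study_design(), pair_id = "P1",
                          seed = 1L) {
  stopifnot(inherits(profile, "test_profile"),
            inherits(design, "study_design"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  dur <- design$duration_s
  # columnar accumulators (a session holds a few hundred events at most)
  ev_type <- character(0)
  ev_t <- ev_ins <- ev_vol <- ev_depth <- ev_rate <- numeric(0)
  ev_eff <- ev_cd <- ev_cr <- ev_cq <- integer(0)
  t <- 0
  breathe <- function(n) {
    for (i in seq_len(n)) {
      v <- sample_ventilations(profile, 1L)
      if (t + v$time_s > dur) return(FALSE)
      ev_type <<- c(ev_type, "ventilation")
      ev_t <<- c(ev_t, round(t * 1000))
      ev_ins <<- c(ev_ins, round(v$time_s * 1000))
      ev_vol <<- c(ev_vol, round(v$volume_ml))
      ev_eff <<- c(ev_eff, v$effective)
      ev_depth <<- c(ev_depth, NA_real_)
      ev_rate <<- c(ev_rate, NA_real_)
      ev_cd <<- c(ev_cd, NA_integer_)
      ev_cr <<- c(ev_cr, NA_integer_)
      ev_cq <<- c(ev_cq, NA_integer_)
      t <<- t + v$time_s + profile$inter_breath_gap
    }
    TRUE
  }
  # initial rescue breaths
  going <- breathe(design$initial_breaths)
  # 30:2 cycles until the clock runs out
  while (going) {
    for (j in seq_len(design$compressions_per_cycle)) {
      rate <- stats::rlnorm(1L, profile$rate$meanlog, profile$rate$sdlog)
      depth <- stats::rlnorm(1L, profile$depth$meanlog, profile$depth$sdlog)
      cdur <- 60 / rate
      if (t + cdur > dur) { going <- FALSE; break }
      ev_type <- c(ev_type, "compression")
      ev_t <- c(ev_t, round(t * 1000))
      ev_ins <- c(ev_ins, NA_real_)
      ev_vol <- c(ev_vol, NA_real_)
      ev_eff <- c(ev_eff, NA_integer_)
      ev_depth <- c(ev_depth, depth)
      ev_rate <- c(ev_rate, rate)
      ev_cd <- c(ev_cd, as.integer(depth >= 50 & depth <= 60))
      ev_cr <- c(ev_cr, stats::rbinom(1L, 1L, profile$p_correct_recoil))
      ev_cq <- c(ev_cq, as.integer(rate >= 100 & rate <= 120))
      t <- t + cdur
    }
    if (!going) break
    t <- t + profile$compression_pause
    going <- breathe(design$breaths_per_cycle)
  }
  n <- length(ev_type)
  out <- data.frame(
    pair_id = rep(pair_id, n),
    participant_id = rep(paste0(pair_id, "a"), n),
    test_id = rep(profile$test_id, n),
    event_type = ev_type, t_start_ms = ev_t, insufflation_ms = ev_ins,
    volume_ml = ev_vol, effective = ev_eff, depth_mm = ev_depth,
    rate_cpm = ev_rate, correct_depth = ev_cd, correct_recoil = ev_cr,
    correct_rate = ev_cq, stringsAsFactors = FALSE)
  class(out) <- c("cpr_events", class(out))
  out
}

#' Simulate a full multi-pair, three-test study
#'
#' Simulates `n_pairs` sessions for each exposure level. The global
#' seed fans out to per-session substreams by a stable hash of
#' `(pair_id, test_id)`, so any one session is reproducible regardless
#' of generation order.
#'
#' @param profiles named list of [test_profile()] objects, one per
#'   exposure label (default [default_profiles()]).
#' @param design a [study_design()].
#' @param seed integer global seed.
#' @return A `cpr_events` data frame covering all sessions, with a
#'   `truth` attribute recording the generating parameters.
#' @export
simulate_study <- function(profiles = default_profiles(),
                           design = study_design(), seed = 1L) {
  missing <- setdiff(test_levels(), names(profiles))
  if (length(missing)) {
    stop("missing profile(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pairs <- paste0("P", seq_len(design$n_pairs))
  out <- list()
  for (tid in test_levels()) {
    for (p in pairs) {
      out[[length(out) + 1L]] <-
        simulate_test(profiles[[tid]], design, pair_id = p,
                      seed = session_seed(seed, p, tid))
    }
  }
  events <- do.call(rbind, out)
  rownames(events) <- NULL
  class(events) <- c("cpr_events", class(events))
  attr(events, "truth") <- list(
    seed = seed, design = unclass(design),
    profiles = lapply(profiles, function(pr) {
      pr[c("test_id", "volume_median", "time_median", "rate_median",
           "depth_median", "p_effective", "p_correct_recoil",
           "inter_breath_gap", "compression_pause")]
    })
  )
  events
}
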