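#' Simulate a study and write its event table
#'
#' Convenience wrapper around [simulate_study()] that optionally writes
#' the event CSV plus a `truth.json` manifest (generating parameters,
#' seed) to an output directory.
#'
#' @param profiles,design,seed passed to [simulate_study()].
#' @param out_dir output directory, created if needed; `NULL` to skip
#'   writing.
#' @return The simulated `cpr_events` data frame, invisibly when
#'   writing.
#' @export
run_simulate <- function(profiles = default_profiles(),
                         design = study_design(), seed = 1L,
                         out_dir = NULL) {
  events <- simulate_study(profiles, design, seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events(events, file.path(out_dir, "events.csv"))
    jsonlite::write_json(attr(events, "truth"),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(events))
  }
  events
}

#' Run the full analysis pipeline on an event table
#'
#' Chains classification, per-session metrics, group summaries,
#' repeated-measures comparisons of every session metric across the
#' three tests, and the case-control contingency analysis of
#' ventilation categories by exposure. Also emits the per-event scatter
#' data (volume vs insufflation time with category colouring) that a
#' quality-band figure plots.
#'
#' @param events a `cpr_events` data frame (from [read_events()] or
#'   [simulate_study()]).
#' @param thresholds a [vent_thresholds()] object.
#' @param duration_ms session length in ms.
#' @param rate_mode,rosenthal_n analysis switches, see
#'   [summarize_session()] and [rosenthal_r()].
#' @param alpha_normality normality-screen level for test routing.
#' @param out_dir optional directory; when given, every table is also
#'   written as CSV with a JSON metadata sidecar.
#' @return A `cpr_analysis` bundle: list with `classification`,
#'   `session_metrics`, `group_summary`, `comparisons`, `case_control`,
#'   `scatter`, `meta`.
#' @export
run_analyze <- function(events, thresholds = vent_thresholds(),
                        duration_ms = 120000L,
                        rate_mode = c("per-compression", "all-or-nothing"),
                        rosenthal_n = c("2n", "n"),
                        alpha_normality = 0.05,
                        out_dir = NULL) {
  rate_mode <- match.arg(rate_mode)
  rosenthal_n <- match.arg(rosenthal_n)
  events <- validate_events(events)
  if (nrow(events) == 0L) stop("empty event set", call. = FALSE)

  cls <- classify_events(events, thresholds)
  metrics <- summarize_sessions(events, duration_ms = duration_ms,
                                thresholds = thresholds,
                                rate_mode = rate_mode)
  group <- summarize_group(metrics)

  vars <- setdiff(names(metrics), c("pair_id", "test_id"))
  tests <- intersect(test_levels(), unique(metrics$test_id))
  comparisons <- list()
  if (length(tests) == 3L) {
    for (v in vars) {
      wide <- stats::reshape(
        metrics[, c("pair_id", "test_id", v)],
        idvar = "pair_id", timevar = "test_id", direction = "wide")
      m <- as.matrix(wide[, paste(v, tests, sep = "."), drop = FALSE])
      colnames(m) <- tests
      if (anyNA(m)) next  # unbalanced or undefined metric: skip
      comparisons[[v]] <- compare_tests(m, alpha = alpha_normality,
                                        n_convention = rosenthal_n,
                                        variable = v)
    }
  }
  cc <- case_control(cls$counts)
  scatter <- cls$events[, c("test_id", "pair_id", "volume_ml",
                            "insufflation_ms", "category")]
  scatter$time_s <- scatter$insufflation_ms / 1000
  meta <- list(thresholds = unclass(thresholds), duration_ms = duration_ms,
               rate_mode = rate_mode, rosenthal_n = rosenthal_n,
               alpha_normality = alpha_normality,
               n_events = nrow(events))
  bundle <- structure(
    list(classification = cls, session_metrics = metrics,
         group_summary = group, comparisons = comparisons,
         case_control = cc, scatter = scatter, meta = meta),
    class = "cpr_analysis"
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
  }
  w(bundle$classification$events, "classification.csv")
  w(bundle$session_metrics, "session_metrics.csv")
  w(bundle$group_summary, "group_summary.csv")
  w(bundle$scatter, "scatter.csv")
  comp <- do.call(rbind, lapply(bundle$comparisons, function(cm) {
    cbind(variable = cm$variable, family = cm$family,
          omnibus_p = cm$omnibus$p, cm$pairwise)
  }))
  if (!is.null(comp)) w(comp, "comparisons.csv")
  pw <- do.call(rbind, lapply(
    c("green_vs_amber", "green_vs_red", "amber_vs_red"),
    function(nm) {
      blk <- bundle$case_control[[nm]]
      cbind(pair = nm,
            overall_p = if (is.null(blk$chi_square)) NA else blk$chi_square$p,
            overall_v = if (is.null(blk$cramers_v)) NA else blk$cramers_v$v,
            blk$pairwise)
    }))
  w(pw, "case_control.csv")
  utils::write.csv(
    data.frame(test_id = rownames(bundle$case_control$counts),
               bundle$case_control$counts),
    file.path(out_dir, "category_counts.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$meta, file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

fmt_mq <- function(med, q1, q3, digits = 2) {
  sprintf("%s (%s-%s)", format(round(med, digits)),
          format(round(q1, digits)), format(round(q3, digits)))
}

#' Render an analysis bundle as aligned markdown tables
#'
#' Produces the study-style report: a session-variables table (median
#' and Q1--Q3 per test with pairwise p-values and effect-size labels)
#' and the three case-control blocks with "N (%)" cells, Cramer's V
#' values to 2 d.p. and odds ratios. Percentages are rendered to 0 d.p.
#' and effect sizes to 2 d.p.; full precision stays in the CSV/JSON
#' outputs of [run_analyze()].
#'
#' @param bundle a `cpr_analysis` object.
#' @return Character vector of report lines, invisibly; also printed.
#' @export
run_report <- function(bundle) {
  stopifnot(inherits(bundle, "cpr_analysis"))
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  add("# CPR session variables")
  add("")
  add("| Variable | T0 | T1 | T2 | Pairwise |")
  add("|---|---|---|---|---|")
  gs <- bundle$group_summary
  for (v in unique(gs$variable)) {
    cells <- vapply(test_levels(), function(t) {
      row <- gs[gs$variable == v & gs$test_id == t, ]
      if (!nrow(row)) return("-")
      fmt_mq(row$median, row$q1, row$q3)
    }, character(1))
    cm <- bundle$comparisons[[v]]
    pwtxt <- if (is.null(cm)) "-" else {
      paste(vapply(seq_len(nrow(cm$pairwise)), function(i) {
        sprintf("%s = %.3f (%s)", cm$pairwise$comparison[i],
                cm$pairwise$p_adjusted[i],
                ifelse(is.na(cm$pairwise$effect_label[i]), "n/a",
                       cm$pairwise$effect_label[i]))
      }, character(1)), collapse = "; ")
    }
    add("| %s | %s | %s | %s | %s |", v, cells[1], cells[2], cells[3], pwtxt)
  }
  add("")
  add("# Case-control analysis of ventilation categories")
  for (nm in c("green_vs_amber", "green_vs_red", "amber_vs_red")) {
    blk <- bundle$case_control[[nm]]
    if (is.null(blk)) {
      add("")
      add("## %s: section unavailable", gsub("_", " ", nm))
      next
    }
    tab <- blk$table
    add("")
    add("## %s", gsub("_", " ", nm))
    add("")
    add("| Exposure | %s | %s | |", colnames(tab)[1], colnames(tab)[2])
    add("|---|---|---|---|")
    csum <- colSums(tab)
    for (i in seq_len(nrow(tab))) {
      pcts <- ifelse(csum > 0, 100 * tab[i, ] / csum, 0)
      stat <- if (i == 1L && !is.null(blk$cramers_v)) {
        sprintf("overall p = %s, V = %.2f (%s)",
                format.pval(blk$chi_square$p, digits = 2),
                blk$cramers_v$v, blk$cramers_v$label)
      } else if (i <= nrow(blk$pairwise) + 1L && i > 1L) {
        pwr <- blk$pairwise[i - 1L, ]
        sprintf("%s p = %s%s, V = %.2f, OR %.2f (%.2f-%.2f)",
                pwr$comparison, format.pval(pwr$p, digits = 2),
                ifelse(isTRUE(pwr$significant), " *", ""),
                pwr$cramers_v, pwr$odds_ratio, pwr$or_low, pwr$or_high)
      } else ""
      add("| %s | %d (%.0f%%) | %d (%.0f%%) | %s |",
          rownames(tab)[i], tab[i, 1], pcts[1], tab[i, 2], pcts[2], stat)
    }
    if (nrow(blk$pairwise) >= nrow(tab)) {
      for (i in seq(nrow(tab), nrow(blk$pairwise))) {
        pwr <- blk$pairwise[i, ]
        add("| | | | %s p = %s%s, V = %.2f, OR %.2f (%.2f-%.2f) |",
            pwr$comparison, format.pval(pwr$p, digits = 2),
            ifelse(isTRUE(pwr$significant), " *", ""),
            pwr$cramers_v, pwr$odds_ratio, pwr$or_low, pwr$or_high)
      }
    }
  }
  add("")
  add("Bonferroni-adjusted pairwise threshold: p < %.4f (*)",
      bundle$case_control$alpha_pairwise)
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.cpr_analysis <- function(x, ...) {
  cat("CPR ventilation-quality analysis bundle\n")
  cat(sprintf("  events analysed: %d (%d sessions)\n", x$meta$n_events,
              nrow(x$session_metrics)))
  print(x$classification$counts)
  cat("  components: classification, session_metrics, group_summary,\n",
      "    comparisons, case_control, scatter; see run_report()\n", sep = "")
  invisible(x)
}
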