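#' Build category-pair contingency tables across exposure levels
#'
#' From a tests-by-categories count matrix (rows T0, T1, T2; columns
#' green, amber, red) builds the three 3x2 tables the case-control
#' analysis compares: green-vs-amber, green-vs-red and amber-vs-red.
#'
#' @param counts integer matrix, 3 exposure rows x 3 category columns
#'   (e.g. the `counts` element of [classify_events()]).
#' @return Named list of three 3x2 integer matrices.
#' @export
build_tables <- function(counts) {
  counts <- as.matrix(counts)
  need <- c("green", "amber", "red")
  if (!all(need %in% colnames(counts))) {
    stop("counts must have columns green, amber, red", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  list(
    green_vs_amber = counts[, c("green", "amber"), drop = FALSE],
    green_vs_red = counts[, c("green", "red"), drop = FALSE],
    amber_vs_red = counts[, c("amber", "red"), drop = FALSE]
  )
}

#' Pearson chi-square test of a contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction), the
#' form whose effect sizes match published manikin-study tables. A
#' warning is attached when any expected count is below 5; a zero
#' marginal row or column makes the statistic undefined and is an
#' error.
#'
#' @param tab count matrix.
#' @return List with `statistic`, `df`, `p`, `expected`,
#'   `low_expected` (logical).
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0) stop("empty table (N = 0)", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal row/column: chi-square undefined", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected,
       low_expected = any(res$expected < 5))
}

#' Cramer's V effect size
#'
#' V = sqrt(chi^2 / (N (min(r, c) - 1))), with the magnitude label of
#' the Cramer's V scale (0.1--0.3 Small, 0.3--0.5 Medium, >=0.5 Large;
#' below 0.1 reported as Negligible).
#'
#' @param tab count matrix.
#' @return List with `v`, `label`, `chi_square` (the underlying test).
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  cs <- chi_square(tab)
  v <- sqrt(cs$statistic / (sum(tab) * (min(dim(tab)) - 1)))
  list(v = unname(v), label = effect_size_label(v, "v"), chi_square = cs)
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' Cross-product odds ratio `(a d)/(b c)` for a table laid out as
#' rows = exposure levels (reference level second) and columns =
#' (case, control). The 95% CI is Woolf's logit interval,
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero the Haldane-Anscombe correction (+0.5 to every cell) is applied
#' and flagged; if both cells of a line are zero the OR is undefined.
#'
#' @param tab 2x2 count matrix: `rbind(c(a, b), c(c, d))` with a = cases
#'   at the index exposure, b = controls at the index exposure, c/d the
#'   reference exposure.
#' @param conf_level confidence level.
#' @return List with `or`, `ci` (length 2), `corrected` (logical),
#'   `defined` (logical).
#' @export
odds_ratio <- function(tab, conf_level = 0.95) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(or = NA_real_, ci = c(NA_real_, NA_real_),
                corrected = FALSE, defined = FALSE))
  }
  corrected <- any(tab == 0)
  t2 <- tab + if (corrected) 0.5 else 0
  or <- (t2[1L, 1L] * t2[2L, 2L]) / (t2[1L, 2L] * t2[2L, 1L])
  se <- sqrt(sum(1 / t2))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * zq * se)
  list(or = unname(or), ci = unname(ci), corrected = corrected,
       defined = TRUE)
}

#' Case-control analysis of ventilation categories by training exposure
#'
#' For each category pair (green-vs-amber, green-vs-red, amber-vs-red)
#' computes the overall 3x2 Pearson chi-square with Cramer's V, then
#' decomposes it into the three pairwise 2x2 exposure comparisons
#' (T0 vs T1, T0 vs T2, T1 vs T2). Pairwise Bonferroni correction
#' follows the threshold-adjustment form: a pair is significant iff its
#' raw p is below `alpha_pairwise` (0.05/3 by default); the raw p is
#' reported alongside the verdict. Each pairwise table also carries a
#' cross-product odds ratio with Woolf 95% CI, oriented so the odds of
#' the first-listed ("case") category at the higher exposure level are
#' compared against the lower exposure level.
#'
#' @param counts tests-by-categories count matrix (rows T0, T1, T2;
#'   columns green, amber, red), e.g. from [classify_events()] or
#'   [read_contingency_table()].
#' @param alpha_pairwise Bonferroni-adjusted pairwise significance
#'   threshold.
#' @return A `cpr_case_control` object: a list of per-pair results, each
#'   with the overall table, chi-square, Cramer's V and a pairwise data
#'   frame.
#' @examples
#' counts <- matrix(c(0, 6, 24, 22, 53, 74, 125, 49, 28), nrow = 3,
#'                  dimnames = list(c("T0", "T1", "T2"),
#'                                  c("green", "amber", "red")))
#' cc <- case_control(counts)
#' cc$green_vs_red$cramers_v$v  # 0.55 to 2 d.p.
#' @export
case_control <- function(counts, alpha_pairwise = 0.05 / 3) {
  tabs <- build_tables(counts)
  out <- lapply(names(tabs), function(nm) {
    tab <- tabs[[nm]]
    overall <- tryCatch(cramers_v(tab), error = function(e) NULL)
    pairs <- utils::combn(rownames(tab), 2L)
    pw <- lapply(seq_len(ncol(pairs)), function(j) {
      lo <- pairs[1L, j]; hi <- pairs[2L, j]
      sub <- tab[c(lo, hi), , drop = FALSE]
      row <- data.frame(comparison = paste(lo, "vs", hi),
                        p = NA_real_, significant = NA,
                        cramers_v = NA_real_, v_label = NA_character_,
                        odds_ratio = NA_real_, or_low = NA_real_,
                        or_high = NA_real_, or_corrected = NA,
                        stringsAsFactors = FALSE)
      cv <- tryCatch(cramers_v(sub), error = function(e) NULL)
      if (!is.null(cv)) {
        row$p <- cv$chi_square$p
        row$significant <- cv$chi_square$p < alpha_pairwise
        row$cramers_v <- cv$v
        row$v_label <- cv$label
      }
      # odds of the case category at the higher exposure vs the lower
      orr <- odds_ratio(sub[c(hi, lo), , drop = FALSE])
      row$odds_ratio <- orr$or
      row$or_low <- orr$ci[1L]
      row$or_high <- orr$ci[2L]
      row$or_corrected <- orr$corrected
      row
    })
    list(name = nm, table = tab,
         chi_square = if (is.null(overall)) NULL else overall$chi_square,
         cramers_v = if (is.null(overall)) NULL else
           overall[c("v", "label")],
         pairwise = do.call(rbind, pw))
  })
  names(out) <- names(tabs)
  structure(list(green_vs_amber = out$green_vs_amber,
                 green_vs_red = out$green_vs_red,
                 amber_vs_red = out$amber_vs_red,
                 counts = as.matrix(counts),
                 alpha_pairwise = alpha_pairwise),
            class = "cpr_case_control")
}

#' Pairwise decomposition of a 3x2 exposure table
#'
#' Standalone access to the pairwise 2x2 comparisons of one category
#' pair: chi-square p, significance at the Bonferroni-adjusted
#' threshold, Cramer's V and odds ratio per exposure pair.
#'
#' @param tab 3x2 count matrix (rows T0, T1, T2).
#' @param alpha_pairwise significance threshold (0.05/3 by default).
#' @return Data frame with one row per exposure pair.
#' @export
pairwise_decomposition <- function(tab, alpha_pairwise = 0.05 / 3) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 3L || ncol(tab) != 2L) {
    stop("expected a 3x2 exposure-by-category table", call. = FALSE)
  }
  counts <- matrix(0L, 3L, 3L,
                   dimnames = list(rownames(tab), c("green", "amber", "red")))
  counts[, 1:2] <- tab
  colnames(counts)[1:2] <- c("green", "amber")
  cc <- case_control(counts, alpha_pairwise)
  cc$green_vs_amber$pairwise
}

#' @export
print.cpr_case_control <- function(x, digits = 2, ...) {
  cat("Case-control analysis of ventilation categories by exposure\n")
  for (nm in c("green_vs_amber", "green_vs_red", "amber_vs_red")) {
    blk <- x[[nm]]
    cat("\n", gsub("_", " ", nm), "\n", sep = "")
    tab <- blk$table
    pct <- sweep(tab, 2L, colSums(tab), function(a, b) ifelse(b > 0, a / b, 0))
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-3s %s\n", rownames(tab)[i],
                  paste(sprintf("%d (%.0f%%)", tab[i, ], 100 * pct[i, ]),
                        collapse = "  ")))
    }
    if (!is.null(blk$cramers_v)) {
      cat(sprintf("  overall p = %s, Cramer's V = %.2f (%s)\n",
                  format.pval(blk$chi_square$p, digits = 3),
                  blk$cramers_v$v, blk$cramers_v$label))
    }
    pw <- blk$pairwise
    for (i in seq_len(nrow(pw))) {
      cat(sprintf("  %s: p = %s%s, V = %.2f, OR = %.2f (%.2f-%.2f)\n",
                  pw$comparison[i], format.pval(pw$p[i], digits = 3),
                  ifelse(isTRUE(pw$significant[i]), " *", ""),
                  pw$cramers_v[i], pw$odds_ratio[i], pw$or_low[i],
                  pw$or_high[i]))
    }
  }
  cat(sprintf("\n* significant at the Bonferroni-adjusted threshold p < %.4f\n",
              x$alpha_pairwise))
  invisible(x)
}
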