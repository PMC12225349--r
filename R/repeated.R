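#' Effect-size magnitude labels
#'
#' Maps an effect-size value onto the verbal magnitude scales used for
#' repeated-measures effect sizes (Cohen's d / Rosenthal's r: <0.2
#' Trivial, 0.2--0.5 Small, 0.5--0.8 Moderate, 0.8--1.3 Large, >=1.3
#' Very large) and for Cramer's V (<0.1 Negligible, 0.1--0.3 Small,
#' 0.3--0.5 Medium, >=0.5 Large). Band lower bounds are inclusive.
#'
#' @param value non-negative effect-size value.
#' @param scale `"d"` for Cohen's d / Rosenthal's r, `"v"` for
#'   Cramer's V.
#' @return Character label.
#' @export
effect_size_label <- function(value, scale = c("d", "v")) {
  scale <- match.arg(scale)
  if (is.na(value)) return(NA_character_)
  value <- abs(value)
  if (scale == "d") {
    cuts <- c(0.2, 0.5, 0.8, 1.3)
    labels <- c("Trivial", "Small", "Moderate", "Large", "Very large")
  } else {
    cuts <- c(0.1, 0.3, 0.5)
    labels <- c("Negligible", "Small", "Medium", "Large")
  }
  labels[findInterval(value, cuts) + 1L]
}

#' Paired Cohen's d
#'
#' Effect size for a paired comparison: the absolute mean of the
#' within-pair differences divided by their sample standard deviation
#' (n - 1 denominator). Undefined (NA, with a warning) when the
#' differences have zero variance.
#'
#' @param x,y paired numeric vectors.
#' @return List with `d` (value, NA if undefined) and `label`.
#' @export
cohens_d_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  d <- x - y
  s <- stats::sd(d)
  if (is.na(s) || s == 0) {
    warning("zero variance of paired differences; Cohen's d undefined",
            call. = FALSE)
    return(list(d = NA_real_, label = NA_character_))
  }
  val <- abs(mean(d)) / s
  list(d = val, label = effect_size_label(val, "d"))
}

#' Rosenthal's r for a rank-based pairwise test
#'
#' r = |z| / sqrt(N), where z is the standardised signed-rank statistic
#' and N counts observations. The default convention takes N as the
#' total number of observations across both related samples (twice the
#' number of pairs); `n_convention = "n"` uses the number of pairs.
#'
#' @param z standardised test statistic.
#' @param n_pairs number of subject pairs in the comparison.
#' @param n_convention `"2n"` (default) or `"n"`.
#' @return List with `r` and `label`.
#' @export
rosenthal_r <- function(z, n_pairs, n_convention = c("2n", "n")) {
  n_convention <- match.arg(n_convention)
  if (!is.finite(z)) stop("z must be finite", call. = FALSE)
  if (n_pairs < 2) stop("need at least 2 pairs", call. = FALSE)
  N <- if (n_convention == "2n") 2 * n_pairs else n_pairs
  val <- abs(z) / sqrt(N)
  list(r = val, label = effect_size_label(val, "d"))
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Normal-approximation signed-rank test for paired samples. Zero
#' differences are handled by the Pratt rule: they take part in the
#' ranking of absolute differences and are then discarded from the rank
#' sum, with the null mean and variance adjusted accordingly; tied
#' ranks use the usual variance correction. The standardised statistic
#' z feeds Rosenthal's r. With `exact = TRUE` (small n) the two-sided
#' p-value is instead taken from the exhaustive distribution of the
#' positive-rank sum over all sign assignments of the non-zero
#' differences.
#'
#' @param x,y paired numeric vectors.
#' @param exact logical; enumerate all 2^m sign assignments of the
#'   non-zero differences (m <= 20).
#' @return List with `z`, `p`, `statistic` (positive-rank sum),
#'   `n_pairs`, `n_nonzero`.
#' @export
wilcoxon_pratt <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  d <- x - y
  n <- length(d)
  r <- rank(abs(d))            # zeros included in the ranking (Pratt)
  pos <- sum(r[d > 0])
  nz <- sum(d == 0)
  if (all(d == 0)) {
    return(list(z = 0, p = 1, statistic = 0, n_pairs = n, n_nonzero = 0L))
  }
  # null moments of the positive-rank sum after discarding zero ranks
  mu <- n * (n + 1) / 4 - nz * (nz + 1) / 4
  ties <- table(r[d != 0])
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    nz * (nz + 1) * (2 * nz + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (pos - mu) / sqrt(sigma2) else 0
  if (exact) {
    m <- sum(d != 0)
    if (m > 20) stop("exact enumeration limited to 20 non-zero pairs",
                     call. = FALSE)
    rnz <- r[d != 0]
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    dist <- as.vector(signs %*% rnz)
    p <- 2 * min(mean(dist <= pos + 1e-9), mean(dist >= pos - 1e-9))
    p <- min(1, p)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(z = z, p = p, statistic = pos, n_pairs = n, n_nonzero = n - nz)
}

# Friedman chi-square from a subjects x treatments matrix of
# within-subject ranks (average ranks for ties).
friedman_statistic <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  r <- t(apply(m, 1L, rank))
  cs <- colSums(r)
  # tie-corrected form (reduces to the classical formula without ties)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  if (A == C) return(0)  # all columns identical within every subject
  (k - 1) * sum((cs - n * (k + 1) / 2)^2) / (A - C)
}

# exhaustive permutation p-value of the Friedman statistic: permute the
# values within each subject independently (all k!^n arrangements)
friedman_permutation_p <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  perms <- all_permutations(k)
  if (nrow(perms)^n > 2e6) {
    stop("permutation enumeration too large; use asymptotic p", call. = FALSE)
  }
  obs <- friedman_statistic(m)
  idx <- rep(1L, n)
  total <- 0L
  geq <- 0L
  repeat {
    mm <- m
    for (i in seq_len(n)) mm[i, ] <- m[i, perms[idx[i], ]]
    total <- total + 1L
    if (friedman_statistic(mm) >= obs - 1e-9) geq <- geq + 1L
    j <- 1L
    while (j <= n) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= nrow(perms)) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > n) break
  }
  geq / total
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- NULL
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                            sub[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  storage.mode(out) <- "integer"
  unname(out)
}

#' Friedman test with Bonferroni-corrected pairwise Wilcoxon tests
#'
#' Omnibus Friedman test across the k = 3 related samples, followed by
#' pairwise Wilcoxon signed-rank tests (Pratt zero handling, normal
#' approximation) with Bonferroni correction (raw p multiplied by the
#' number of comparisons, capped at 1) and Rosenthal's r effect sizes.
#'
#' @param m numeric matrix, subjects in rows, the three tests (T0, T1,
#'   T2) in columns.
#' @param n_convention passed to [rosenthal_r()].
#' @param p_method `"asymptotic"` (chi-square) or `"permutation"`
#'   (exhaustive within-subject enumeration; small n only) for the
#'   omnibus p-value.
#' @param variable optional variable name carried into the result.
#' @return A `cpr_comparison` object.
#' @export
friedman_bonferroni <- function(m, n_convention = c("2n", "n"),
                                p_method = c("asymptotic", "permutation"),
                                variable = NULL) {
  n_convention <- match.arg(n_convention)
  p_method <- match.arg(p_method)
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (anyNA(m)) stop("unequal pairing: missing values in sample matrix",
                     call. = FALSE)
  stat <- friedman_statistic(m)
  df <- ncol(m) - 1L
  p <- if (p_method == "permutation") friedman_permutation_p(m)
       else stats::pchisq(stat, df, lower.tail = FALSE)
  cols <- colnames(m)
  if (is.null(cols)) cols <- paste0("T", seq_len(ncol(m)) - 1L)
  pairs <- utils::combn(seq_len(ncol(m)), 2L)
  mcomp <- ncol(pairs)
  pw <- lapply(seq_len(mcomp), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    w <- wilcoxon_pratt(m[, i1], m[, i2])
    es <- rosenthal_r(w$z, w$n_pairs, n_convention)
    data.frame(comparison = paste(cols[i1], "vs", cols[i2]),
               p_raw = w$p, p_adjusted = min(1, w$p * mcomp),
               effect_size = es$r, effect_kind = "Rosenthal r",
               effect_label = es$label, z = w$z,
               stringsAsFactors = FALSE)
  })
  structure(
    list(variable = variable, family = "friedman",
         omnibus = list(statistic = stat, df = df, p = p,
                        method = "Friedman chi-square"),
         pairwise = do.call(rbind, pw), n = nrow(m)),
    class = "cpr_comparison"
  )
}

#' Repeated-measures ANOVA with Bonferroni-corrected paired t tests
#'
#' One-way repeated-measures ANOVA (subjects as the error stratum)
#' across the three tests, followed by pairwise paired t tests with
#' Bonferroni correction (p x 3, capped at 1) and paired Cohen's d.
#' Data with zero within-subject variance are flagged degenerate
#' (F = 0, p = 1).
#'
#' @inheritParams friedman_bonferroni
#' @return A `cpr_comparison` object.
#' @export
rm_anova_bonferroni <- function(m, variable = NULL) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (anyNA(m)) stop("unequal pairing: missing values in sample matrix",
                     call. = FALSE)
  cols <- colnames(m)
  if (is.null(cols)) cols <- paste0("T", seq_len(ncol(m)) - 1L)
  f <- rm_anova_F(m)
  pairs <- utils::combn(seq_len(ncol(m)), 2L)
  mcomp <- ncol(pairs)
  pw <- lapply(seq_len(mcomp), function(j) {
    x <- m[, pairs[1L, j]]; y <- m[, pairs[2L, j]]
    dvar <- stats::sd(x - y)
    if (is.na(dvar) || dvar == 0) {
      p_raw <- if (all(x == y)) 1 else NA_real_
      es <- list(d = NA_real_, label = NA_character_)
    } else {
      p_raw <- stats::t.test(x, y, paired = TRUE)$p.value
      es <- cohens_d_paired(x, y)
    }
    data.frame(comparison = paste(cols[pairs[1L, j]], "vs", cols[pairs[2L, j]]),
               p_raw = p_raw, p_adjusted = min(1, p_raw * mcomp),
               effect_size = es$d, effect_kind = "Cohen d",
               effect_label = es$label, z = NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(
    list(variable = variable, family = "rm_anova",
         omnibus = f, pairwise = do.call(rbind, pw), n = nrow(m)),
    class = "cpr_comparison"
  )
}

# one-way repeated-measures F via aov with subject error strata
rm_anova_F <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  if (all(m == m[, 1L])) {
    return(list(statistic = 0, df = c(k - 1L, (n - 1L) * (k - 1L)), p = 1,
                method = "RM-ANOVA F", degenerate = TRUE))
  }
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   test = factor(rep(seq_len(k), each = n)))
  fit <- summary(stats::aov(y ~ test + Error(subject / test), data = df))
  tab <- fit[["Error: subject:test"]][[1L]]
  list(statistic = tab[["F value"]][1L],
       df = c(tab[["Df"]][1L], tab[["Df"]][2L]),
       p = tab[["Pr(>F)"]][1L], method = "RM-ANOVA F", degenerate = FALSE)
}

#' Choose the repeated-measures test family by normality
#'
#' Shapiro-Wilk on each test's values at level `alpha`; the parametric
#' family (repeated-measures ANOVA) is chosen only when normality is
#' not rejected in any column. Degenerate columns (fewer than 3 values
#' or zero variance, where Shapiro-Wilk is undefined) route to the
#' nonparametric family.
#'
#' @param m numeric matrix, subjects x tests.
#' @param alpha significance level of the normality screen.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
route_test <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("unequal pairing: missing values", call. = FALSE)
  if (nrow(m) < 3L) return("nonparametric")
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (stats::sd(x) == 0) return("nonparametric")
    if (stats::shapiro.test(x)$p.value < alpha) return("nonparametric")
  }
  "parametric"
}

#' Compare one variable across the three tests
#'
#' Routes by [route_test()] and dispatches to [rm_anova_bonferroni()]
#' or [friedman_bonferroni()].
#'
#' @inheritParams friedman_bonferroni
#' @param alpha normality-screen level.
#' @export
compare_tests <- function(m, alpha = 0.05, n_convention = c("2n", "n"),
                          variable = NULL) {
  n_convention <- match.arg(n_convention)
  if (route_test(m, alpha) == "parametric") {
    rm_anova_bonferroni(m, variable = variable)
  } else {
    friedman_bonferroni(m, n_convention = n_convention, variable = variable)
  }
}

#' @export
print.cpr_comparison <- function(x, digits = 3, ...) {
  hdr <- if (x$family == "friedman") "Friedman test" else
    "Repeated-measures ANOVA"
  if (!is.null(x$variable)) cat(x$variable, ": ", sep = "")
  cat(sprintf("%s (n = %d)\n", hdr, x$n))
  om <- x$omnibus
  cat(sprintf("  omnibus %s = %s, p = %s\n", om$method,
              format(om$statistic, digits = digits),
              format.pval(om$p, digits = digits)))
  pw <- x$pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("  %s: adj p = %s, %s = %s (%s)\n", pw$comparison[i],
                format.pval(pw$p_adjusted[i], digits = digits),
                pw$effect_kind[i],
                format(pw$effect_size[i], digits = digits),
                ifelse(is.na(pw$effect_label[i]), "undefined",
                       pw$effect_label[i])))
  }
  invisible(x)
}
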