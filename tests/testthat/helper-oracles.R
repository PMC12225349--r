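# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from first principles rather
# than calling the package's own code paths.

# direct evaluation of the six classification conditions, one event at a
# time, in the literal rule order: green's two conditions, red's four
# conditions, amber otherwise
oracle_classify <- function(vol, t) {
  green <- (vol >= 500 && vol <= 600) && (t >= 0.85 && t <= 1.15)
  if (green) return("green")
  if (vol < 400 || vol > 700 || t < 0.55 || t > 1.45) return("red")
  "amber"
}

# Pearson chi-square from observed counts via explicit expected counts
oracle_chisq <- function(tab) {
  N <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / N
  sum((tab - E)^2 / E)
}

# Friedman chi-square from within-subject average ranks, tie-corrected,
# written out independently of the package's vectorised form
oracle_friedman_stat <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- matrix(0, n, k)
  for (i in 1:n) R[i, ] <- rank(m[i, ])
  Rj <- colSums(R)
  A <- sum(R^2)
  C <- n * k * (k + 1)^2 / 4
  if (abs(A - C) < 1e-12) return(0)
  (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
}

# exhaustive permutation distribution of the Friedman statistic over all
# k!^n within-subject orderings, enumerated with expand.grid (a code path
# disjoint from the package's odometer recursion)
oracle_friedman_perm_p <- function(m) {
  n <- nrow(m); k <- ncol(m)
  perms <- asplit(as.matrix(expand.grid(rep(list(1:k), k))), 1)
  perms <- Filter(function(p) length(unique(p)) == k, perms)
  grid <- expand.grid(rep(list(seq_along(perms)), n))
  obs <- oracle_friedman_stat(m)
  stats <- apply(grid, 1, function(sel) {
    mm <- m
    for (i in 1:n) mm[i, ] <- m[i, perms[[sel[i]]]]
    oracle_friedman_stat(mm)
  })
  mean(stats >= obs - 1e-9)
}

# exact two-sided sign-flip p for the Pratt signed-rank statistic:
# zeros keep their ranks but never flip; enumerate sign vectors of the
# non-zero differences
oracle_wilcoxon_exact_p <- function(x, y) {
  d <- x - y
  r <- rank(abs(d))
  rnz <- r[d != 0]
  obs <- sum(r[d > 0])
  m <- length(rnz)
  if (m == 0) return(1)
  tplus <- numeric(2^m)
  for (s in 0:(2^m - 1)) {
    bits <- as.integer(intToBits(s))[1:m]
    tplus[s + 1] <- sum(rnz[bits == 1])
  }
  min(1, 2 * min(mean(tplus <= obs + 1e-9), mean(tplus >= obs - 1e-9)))
}

# printed case-control count table of the three-test study
table3_counts <- function() {
  matrix(c(0, 6, 24, 22, 53, 74, 125, 49, 28), nrow = 3,
         dimnames = list(c("T0", "T1", "T2"), c("green", "amber", "red")))
}

# minimal valid event data frame builders
make_vent_rows <- function(pair_id = "P1", test_id = "T0", volume, time_s,
                           effective = 1L, t_start_ms = NULL) {
  n <- max(length(volume), length(time_s))
  volume <- rep_len(volume, n); time_s <- rep_len(time_s, n)
  if (is.null(t_start_ms)) t_start_ms <- seq(0, by = 4000, length.out = n)
  data.frame(pair_id = pair_id, participant_id = paste0(pair_id, "a"),
             test_id = test_id, event_type = "ventilation",
             t_start_ms = t_start_ms,
             insufflation_ms = round(time_s * 1000),
             volume_ml = volume, effective = rep_len(effective, n),
             depth_mm = NA_real_, rate_cpm = NA_real_,
             correct_depth = NA_integer_, correct_recoil = NA_integer_,
             correct_rate = NA_integer_, stringsAsFactors = FALSE)
}

make_comp_rows <- function(pair_id = "P1", test_id = "T0", depth, rate,
                           correct_recoil = 1L, t_start_ms = NULL) {
  n <- max(length(depth), length(rate))
  depth <- rep_len(depth, n); rate <- rep_len(rate, n)
  if (is.null(t_start_ms)) t_start_ms <- seq(20000, by = 600, length.out = n)
  data.frame(pair_id = pair_id, participant_id = paste0(pair_id, "a"),
             test_id = test_id, event_type = "compression",
             t_start_ms = t_start_ms,
             insufflation_ms = NA_real_, volume_ml = NA_real_,
             effective = NA_integer_, depth_mm = depth, rate_cpm = rate,
             correct_depth = as.integer(depth >= 50 & depth <= 60),
             correct_recoil = rep_len(correct_recoil, n),
             correct_rate = as.integer(rate >= 100 & rate <= 120),
             stringsAsFactors = FALSE)
}
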