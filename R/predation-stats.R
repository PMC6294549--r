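# Predation-rate statistics for paired incubations of wildtype and
# startle-deficient mutant larvae with a copepod predator. Rates follow
# the clearance-type formula I = (Ci - Cf) / (N * T); genotype
# differences are tested with an exact one-sided Wilcoxon signed-rank
# test with Pratt's treatment of zero differences.

#' Predation rate per predator per day
#'
#' `I = (Ci - Cf) / (N * T)` with `Ci`, `Cf` the initial and final prey
#' concentrations (prey/L), `N` the number of predators alive at the end
#' of the incubation and `T` the incubation time in days.
#'
#' @param Ci,Cf Initial and final prey concentrations (prey/L).
#' @param N Predators alive at the end (trials with `N = 0` yield `NA`
#'   with a warning: the rate is undefined when all predators died).
#' @param T_days Incubation time (days), > 0.
#' @return Rate(s) in prey * predator^-1 * day^-1.
#' @examples
#' predation_rate(125, 75, N = 10, T_days = 1)  # 5 prey/predator/day
#' @export
predation_rate <- function(Ci, Cf, N, T_days) {
  if (any(T_days <= 0)) stopf("incubation time must be > 0")
  out <- (Ci - Cf) / (N * T_days)
  dead <- N == 0
  if (any(dead)) {
    warnf("%d trial(s) with no surviving predators; rate undefined (NA)",
          sum(dead))
    out[dead] <- NA_real_
  }
  out
}

#' Classify paired rate differences
#'
#' @param d Differences `rate_mutant - rate_wildtype`.
#' @return Factor with levels `higher`, `equal`, `lower` (mutant rate
#'   relative to wildtype), the colour classes of paired-line plots.
#' @export
classify_pairs <- function(d) {
  factor(ifelse(d > 0, "higher", ifelse(d < 0, "lower", "equal")),
         levels = c("higher", "equal", "lower"))
}

#' Exact Wilcoxon signed-rank test with Pratt zero handling
#'
#' Zero differences are included when ranking the absolute values and
#' their ranks are then discarded (Pratt's method); ties receive average
#' ranks. The statistic is `W+`, the sum of ranks of the positive
#' differences. The p-value is exact and conditional on the realized
#' (possibly tied) rank vector: the null distribution assigns each
#' nonzero rank an independent random sign. Up to `enumerate_limit`
#' nonzero differences the distribution is obtained by full enumeration
#' of the 2^m sign assignments; beyond that a count-convolution (shift
#' algorithm on doubled ranks) gives the identical exact distribution,
#' so no normal approximation is used at any sample size.
#'
#' @param d Numeric vector of paired differences.
#' @param alternative `"greater"` (default; mutant rates higher),
#'   `"less"` or `"two.sided"`.
#' @param enumerate_limit Largest m handled by direct enumeration.
#' @return An object of class `htest` with `statistic` (`W+`), `p.value`,
#'   `parameter` (`m`, nonzero differences) and `method`.
#' @examples
#' wilcoxon_pratt_exact(c(1, 2, 3))$p.value  # 1/8
#' @export
wilcoxon_pratt_exact <- function(d, alternative = c("greater", "less", "two.sided"),
                                 enumerate_limit = 20) {
  alternative <- match.arg(alternative)
  d <- d[!is.na(d)]
  if (!length(d)) stopf("no non-missing differences")
  r <- rank(abs(d), ties.method = "average")
  nz <- d != 0
  m <- sum(nz)
  W <- sum(r[nz & d > 0])

  if (m == 0) {
    warnf("all differences are zero; p = 1")
    p_greater <- 1; p_less <- 1
  } else {
    r2 <- as.integer(round(2 * r[nz]))  # doubled ranks are integers
    if (m <= enumerate_limit) {
      # full enumeration over sign assignments
      sums <- 0L
      for (rk in r2) sums <- c(sums, sums + rk)
      w2 <- round(2 * W)
      p_greater <- sum(sums >= w2 - 1e-9) / length(sums)
      p_less <- sum(sums <= w2 + 1e-9) / length(sums)
    } else {
      # shift algorithm: counts of subset-sums of the doubled ranks
      total <- sum(r2)
      counts <- numeric(total + 1L); counts[1] <- 1
      for (rk in r2) {
        shifted <- c(numeric(rk), counts[seq_len(total + 1L - rk)])
        counts <- counts + shifted
      }
      w2 <- round(2 * W)
      p_greater <- sum(counts[(w2 + 1L):(total + 1L)]) / 2^m
      p_less <- sum(counts[seq_len(w2 + 1L)]) / 2^m
    }
  }
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  structure(list(
    statistic = c(`W+` = W),
    parameter = c(m = m),
    p.value = p,
    alternative = alternative,
    method = "Exact Wilcoxon-Pratt signed-rank test",
    data.name = deparse(substitute(d))
  ), class = "htest")
}

#' Survival summaries per condition
#'
#' @param trials Tidy predation table as produced by [gen_predation()]
#'   (columns `condition`, `survivors`, `initial_prey`).
#' @return Data frame with `condition`, `n`, `min`, `max`, `mean`
#'   survival rates (fractions in \[0, 1\]).
#' @export
survival_summary <- function(trials) {
  if (!nrow(trials)) stopf("no trials")
  rate <- trials$survivors / trials$initial_prey
  out <- lapply(split(rate, trials$condition), function(v)
    data.frame(n = length(v), min = min(v), max = max(v), mean = mean(v)))
  res <- cbind(condition = names(out), do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Paired predation analysis
#'
#' Computes per-trial predation rates for each genotype in the
#' copepod-condition trials, forms the paired differences
#' (mutant - wildtype), classifies the pairs and runs the exact
#' one-sided Wilcoxon-Pratt signed-rank test against the alternative of
#' a higher predation rate on mutants. Trials in which all predators
#' died are excluded from pairing with a warning.
#'
#' @param trials Tidy predation table (see [gen_predation()]).
#' @param alternative Passed to [wilcoxon_pratt_exact()].
#' @return A list of class `predation_analysis`: `paired` (data frame
#'   with per-trial rates, difference and category), `pair_counts`
#'   (higher/equal/lower table), `test` (the `htest`) and `survival`
#'   (per-condition summary).
#' @export
analyze_predation <- function(trials, alternative = "greater") {
  cop <- trials[trials$condition == "copepods", ]
  wide <- merge(
    cop[cop$genotype == "wildtype",
        c("batch_id", "trial_id", "Ci", "Cf", "n_predators_final", "duration_days")],
    cop[cop$genotype == "mutant", c("trial_id", "Ci", "Cf")],
    by = "trial_id", suffixes = c("_wt", "_mut"))
  rate_wt <- suppressWarnings(predation_rate(wide$Ci_wt, wide$Cf_wt,
                                             wide$n_predators_final,
                                             wide$duration_days))
  rate_mut <- suppressWarnings(predation_rate(wide$Ci_mut, wide$Cf_mut,
                                              wide$n_predators_final,
                                              wide$duration_days))
  dead <- wide$n_predators_final == 0
  if (any(dead))
    warnf("excluding %d trial(s) with no surviving predators", sum(dead))
  paired <- data.frame(batch_id = wide$batch_id, trial_id = wide$trial_id,
                       rate_wildtype = rate_wt, rate_mutant = rate_mut,
                       difference = rate_mut - rate_wt)[!dead, ]
  paired$category <- classify_pairs(paired$difference)
  test <- wilcoxon_pratt_exact(paired$difference, alternative = alternative)
  structure(list(paired = paired,
                 pair_counts = table(paired$category),
                 test = test,
                 survival = survival_summary(trials)),
            class = "predation_analysis")
}

#' @export
print.predation_analysis <- function(x, ...) {
  cat(sprintf("<predation_analysis> %d pairs (higher/equal/lower: %s)\n",
              nrow(x$paired), paste(x$pair_counts, collapse = "/")))
  cat(sprintf("  W+ = %.1f, one-sided exact Wilcoxon-Pratt p = %.3g\n",
              x$test$statistic, x$test$p.value))
  invisible(x)
}
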