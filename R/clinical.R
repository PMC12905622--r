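#' TWSTRS percentage improvement
#'
#' Percentage improvement of the TWSTRS motor score under stimulation,
#' `100 * (off - on) / off`: larger scores are expected with stimulation
#' OFF, so positive values mean benefit and negative values deterioration.
#'
#' @param off baseline score (stimulation OFF, or pre-operative); must be
#'   positive.
#' @param on score under stimulation.
#' @return Percentage improvement (vectorized).
#' @export
percent_improvement_twstrs <- function(off, on) {
  if (any(off == 0)) stop("baseline (OFF) score of 0: percent improvement undefined")
  100 * (off - on) / off
}

#' UPDRS bradykinesia percentage change
#'
#' Percentage change of the bradykinesia subscore, `100 * (on - off) / on`:
#' larger scores may occur with stimulation ON (stimulation-induced
#' slowness), so the ON score is the reference.
#'
#' @param off score with stimulation OFF.
#' @param on score with stimulation ON; must be positive.
#' @return Percentage change (vectorized).
#' @export
percent_change_updrs <- function(off, on) {
  if (any(on == 0)) stop("ON score of 0: percent change undefined")
  100 * (on - off) / on
}

#' Sum of UPDRS-III bradykinesia subitems
#'
#' Bradykinesia score used to quantify stimulation-induced slowness: the
#' sum of items 3.4, 3.5, 3.7 and 3.8 over both body sides.
#'
#' @param items numeric matrix or data frame of per-item scores (columns
#'   are the subitems, possibly one per side).
#' @return Per-subject sums.
#' @export
updrs_bradykinesia_score <- function(items) {
  items <- as.matrix(items)
  if (any(items < 0, na.rm = TRUE)) stop("UPDRS item scores must be >= 0")
  rowSums(items)
}

#' Paired t-test with Cohen's d
#'
#' Two-tailed paired t-test (`t = mean(d) / (sd(d)/sqrt(n))`, df = n - 1)
#' with the paired-data effect size `d = mean(diff) / sd(diff)`. Normality
#' of the differences is checked with Shapiro-Wilk as a precondition; a
#' violation (p <= 0.05) raises a warning, not an error.
#'
#' @param off,on equal-length score vectors (n >= 3).
#' @return List of class `ephys_test` with `statistic`, `df`, `p`,
#'   `effect_size`, `tail`, `test_name`, `shapiro_p`.
#' @export
paired_t_test <- function(off, on) {
  stopifnot(length(off) == length(on), length(off) >= 3)
  d <- off - on
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences: t and d undefined")
  sw <- stats::shapiro.test(d)
  if (sw$p.value <= 0.05)
    warning(sprintf(
      "Shapiro-Wilk on the paired differences gives p = %.3g: normality precondition violated",
      sw$p.value))
  tt <- stats::t.test(off, on, paired = TRUE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, effect_size = mean(d) / stats::sd(d),
                 tail = "two-sided", test_name = "paired t-test",
                 shapiro_p = sw$p.value),
            class = "ephys_test")
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric vector, 3 <= n <= 50, non-constant.
#' @return List of class `ephys_test` with the W statistic and p.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 50) stop("Shapiro-Wilk supported for 3 <= n <= 50 here")
  if (stats::sd(x) == 0) stop("constant vector: Shapiro-Wilk undefined")
  sw <- stats::shapiro.test(x)
  structure(list(statistic = unname(sw$statistic), df = NA_real_,
                 p = sw$p.value, effect_size = NA_real_, tail = "one-sided",
                 test_name = "Shapiro-Wilk"),
            class = "ephys_test")
}

#' @export
print.ephys_test <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g%s, p = %.4g%s>\n", x$test_name,
              x$statistic,
              if (is.finite(x$df[1])) paste0(", df = ", paste(x$df, collapse = ",")) else "",
              x$p,
              if (is.finite(x$effect_size)) sprintf(", effect size = %.3g", x$effect_size) else ""))
  invisible(x)
}

#' Responder classification
#'
#' Classifies each patient by two printed criteria: percentage TWSTRS
#' improvement of at least `pct_threshold` (non-response is "less than
#' 20%", so exactly 20% counts as response), and the minimal clinically
#' important difference of at least `mcid_points` raw points. Both
#' partitions are reported.
#'
#' @param table a cohort table from [load_cohort_table()] (needs columns
#'   `twstrs_off`, `twstrs_bipolar_on`, `pct_improvement_bipolar`).
#' @param pct_threshold percent-improvement cutoff (default 20).
#' @param mcid_points raw-change cutoff (default 3).
#' @return List with logical `responder` (percent rule), logical
#'   `mcid` (raw-points rule), counts `n_responders` /
#'   `n_non_responders`, and `rules_agree`.
#' @export
classify_responders <- function(table, pct_threshold = 20, mcid_points = 3) {
  stopifnot(all(c("twstrs_off", "twstrs_bipolar_on",
                  "pct_improvement_bipolar") %in% names(table)))
  responder <- table$pct_improvement_bipolar >= pct_threshold
  mcid <- (table$twstrs_off - table$twstrs_bipolar_on) >= mcid_points
  list(responder = responder, mcid = mcid,
       n_responders = sum(responder), n_non_responders = sum(!responder),
       rules_agree = identical(responder, mcid))
}

#' Fisher-z power for a correlation, and the minimal detectable rho
#'
#' Sensitivity power analysis for a correlation test via the Fisher
#' transform: `z = atanh(rho)` is approximately normal with SE
#' `1/sqrt(n-3)`. `fisher_z_power()` gives the power to detect `rho` at
#' level `alpha`; `minimal_detectable_rho()` inverts it, giving the
#' smallest detectable effect at a target power. The two are mutual
#' inverses.
#'
#' @param n sample size (> 3).
#' @param rho true correlation (0 < rho < 1).
#' @param alpha significance level.
#' @param tail `"one-sided"` or `"two-sided"`.
#' @param power target power.
#' @return Power (or minimal detectable rho), a single number.
#' @export
fisher_z_power <- function(n, rho, alpha = 0.05,
                           tail = c("one-sided", "two-sided")) {
  tail <- match.arg(tail)
  if (n <= 3) stop("need n > 3")
  stopifnot(rho > 0, rho < 1)
  zcrit <- stats::qnorm(1 - if (tail == "one-sided") alpha else alpha / 2)
  stats::pnorm(atanh(rho) * sqrt(n - 3) - zcrit)
}

#' @rdname fisher_z_power
#' @export
minimal_detectable_rho <- function(n, power = 0.80, alpha = 0.05,
                                   tail = c("one-sided", "two-sided")) {
  tail <- match.arg(tail)
  if (n <= 3) stop("need n > 3")
  zcrit <- stats::qnorm(1 - if (tail == "one-sided") alpha else alpha / 2)
  tanh((zcrit + stats::qnorm(power)) / sqrt(n - 3))
}

#' Linear covariate model with standardized coefficients
#'
#' Ordinary least squares of the outcome on standardized predictors
#' (all variables scaled to unit SD), e.g. TWSTRS improvement on R-map
#' similarity, age, disease duration and baseline severity. With a single
#' predictor the standardized coefficient equals its Pearson correlation
#' with the outcome.
#'
#' @param outcome numeric response.
#' @param predictors data frame or matrix of predictors.
#' @param kappa_max condition-number guard for the standardized design
#'   (default 1e6).
#' @return Data frame with one row per predictor: `beta_std`, `se`, `t`,
#'   `p` (two-tailed); attribute `"model"` carries the `lm` fit.
#' @export
covariate_model <- function(outcome, predictors, kappa_max = 1e6) {
  predictors <- as.data.frame(predictors)
  n <- length(outcome)
  if (n <= ncol(predictors) + 1)
    stop("need n > number of predictors + 1")
  xs <- as.data.frame(lapply(predictors, function(v) as.numeric(scale(v))))
  ys <- as.numeric(scale(outcome))
  mm <- cbind(1, as.matrix(xs))
  if (kappa(mm, exact = TRUE) > kappa_max)
    stop("predictors are (near-)collinear: condition number exceeds ", kappa_max)
  fit <- stats::lm(ys ~ ., data = xs)
  cf <- summary(fit)$coefficients[-1, , drop = FALSE]
  out <- data.frame(predictor = names(xs), beta_std = cf[, 1], se = cf[, 2],
                    t = cf[, 3], p = cf[, 4], row.names = NULL)
  attr(out, "model") <- fit
  out
}

#' One-way ANOVA of outcome by disease type
#'
#' @param outcome numeric response (e.g. TWSTRS improvement).
#' @param type_labels factor-like group labels (e.g. CD vs SD); at least
#'   two groups with at least two members each.
#' @return List of class `ephys_test` with the F statistic, df =
#'   (groups - 1, n - groups) and p.
#' @export
anova_by_type <- function(outcome, type_labels) {
  g <- factor(type_labels)
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("every group needs at least two members")
  if (stats::sd(outcome) == 0) stop("outcome has zero variance")
  fit <- stats::aov(outcome ~ g)
  s <- summary(fit)[[1]]
  if (!is.finite(s[["F value"]][1]))
    stop("degenerate ANOVA: no residual variance")
  structure(list(statistic = s[["F value"]][1],
                 df = c(s[["Df"]][1], s[["Df"]][2]),
                 p = s[["Pr(>F)"]][1], effect_size = NA_real_,
                 tail = "two-sided", test_name = "one-way ANOVA"),
            class = "ephys_test")
}

#' Cohort summary: per-column means and SDs
#'
#' Mean and sample SD for each numeric column of the cohort table,
#' rounded half-up to a chosen precision (matching how summary rows are
#' printed in clinical tables).
#'
#' @param table a cohort table ([load_cohort_table()]).
#' @param digits decimal places for the rounded columns (default 2).
#' @return Data frame with `column`, `mean`, `sd` (unrounded) and
#'   `mean_rounded`, `sd_rounded`.
#' @export
cohort_summary <- function(table, digits = 2) {
  num <- table[vapply(table, is.numeric, TRUE)]
  if (!ncol(num) || !nrow(num)) stop("no numeric data to summarize")
  data.frame(column = names(num),
             mean = vapply(num, mean, 1),
             sd = vapply(num, stats::sd, 1),
             mean_rounded = round_half_up(vapply(num, mean, 1), digits),
             sd_rounded = round_half_up(vapply(num, stats::sd, 1), digits),
             row.names = NULL)
}
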