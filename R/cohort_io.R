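# Integrity checksums of the bundled cohort table: column sums of the
# raw score columns over the 15 patients.
.cohort_checksums <- c(disease_duration_years = 263, dbs_duration_months = 1583,
                       aims_item7 = 19, twstrs_pre = 265, twstrs_off = 221,
                       twstrs_bipolar_on = 151, twstrs_monopolar_on = 149)

#' Load the clinical cohort table
#'
#' Reads the bundled 15-patient GPi-DBS cervical dystonia cohort (or a
#' user CSV with the same column set): TWSTRS motor scores pre-DBS,
#' stimulation OFF, bipolar ON and chronic monopolar ON, plus AIMS item 7,
#' disease type/side and durations. Percentage-change columns are always
#' derived, never stored: bipolar improvement is referenced to the
#' same-day OFF score, monopolar improvement to the pre-operative score
#' (monopolar scores were rated from archival videos, for which the
#' pre-operative assessment is the matching baseline).
#'
#' @param path CSV path; default the bundled table.
#' @param check verify the bundled table's column-sum checksums.
#' @return A `data.frame` of class `cohort_table` with the raw columns
#'   plus derived `pct_improvement_bipolar`, `pct_improvement_monopolar`
#'   and `twstrs_change_bipolar`.
#' @export
load_cohort_table <- function(path = NULL, check = is.null(path)) {
  if (is.null(path))
    path <- system.file("extdata", "dystonia_cohort.csv",
                        package = "ephysmap", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "dystonia_type", "side",
                "disease_duration_years", "dbs_duration_months", "aims_item7",
                "twstrs_pre", "twstrs_off", "twstrs_bipolar_on",
                "twstrs_monopolar_on")
  miss <- setdiff(required, names(tab))
  if (length(miss)) stop("cohort table misses columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$patient_id)) stop("patient ids must be unique")
  if (!all(tab$dystonia_type %in% c("CD", "SD")))
    stop("dystonia_type must be CD or SD")
  score_cols <- names(.cohort_checksums)
  if (any(as.matrix(tab[score_cols]) < 0)) stop("scores must be >= 0")
  if (check) {
    sums <- vapply(tab[score_cols], sum, 1)
    if (nrow(tab) != 15 || !all(sums == .cohort_checksums))
      stop("bundled cohort table failed its checksum")
  }
  tab$pct_improvement_bipolar <-
    percent_improvement_twstrs(tab$twstrs_off, tab$twstrs_bipolar_on)
  tab$pct_improvement_monopolar <-
    percent_improvement_twstrs(tab$twstrs_pre, tab$twstrs_monopolar_on)
  tab$twstrs_change_bipolar <- tab$twstrs_off - tab$twstrs_bipolar_on
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Read a run configuration file
#'
#' YAML key-value configuration for [run_recipe()]; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "n_seeds", "alpha", "m_comparisons", "k", "noise_sd",
             "effect_gain", "icosphere_level", "pct_threshold", "mcid_points",
             "table_path", "out")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Run a canonical analysis recipe
#'
#' Two end-to-end recipes: `"replicate_clinical"` computes every statistic
#' derivable from the bundled clinical table (cohort summary, paired
#' OFF-vs-bipolar t-test with Cohen's d, responder classification, outcome
#' range, minimal detectable correlation); `"synthetic_demo"` simulates a
#' default synthetic cohort and runs the mapping chain (R-map, ROI,
#' leave-one-out and 4-fold cross-validation), reporting recovery metrics
#' against the planted ground truth.
#'
#' @param name `"replicate_clinical"` or `"synthetic_demo"`.
#' @param config named list of options (see [read_run_config()]); for the
#'   synthetic demo a `seed` entry is mandatory.
#' @param out optional path for a JSON report (written with the seed
#'   recorded in the report itself).
#' @return The report, a named list (invisibly when written to `out`).
#' @export
run_recipe <- function(name = c("replicate_clinical", "synthetic_demo"),
                       config = list(), out = NULL) {
  name <- match.arg(name)
  report <- if (name == "replicate_clinical") {
    recipe_replicate_clinical(config)
  } else {
    recipe_synthetic_demo(config)
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

recipe_replicate_clinical <- function(config = list()) {
  tab <- load_cohort_table(path = config$table_path)
  tt <- suppressWarnings(paired_t_test(tab$twstrs_off, tab$twstrs_bipolar_on))
  resp <- classify_responders(tab,
                              pct_threshold = config$pct_threshold %||% 20,
                              mcid_points = config$mcid_points %||% 3)
  summ <- cohort_summary(tab)
  getm <- function(col) summ$mean[summ$column == col]
  list(recipe = "replicate_clinical", n = nrow(tab),
       paired_t = list(t = tt$statistic, df = tt$df, p = tt$p,
                       cohens_d = abs(tt$effect_size),
                       shapiro_p = tt$shapiro_p),
       mean_twstrs_off = getm("twstrs_off"),
       mean_twstrs_bipolar_on = getm("twstrs_bipolar_on"),
       mean_pct_improvement_bipolar = getm("pct_improvement_bipolar"),
       sd_pct_improvement_bipolar =
         summ$sd[summ$column == "pct_improvement_bipolar"],
       outcome_range = range(tab$pct_improvement_bipolar),
       n_responders = resp$n_responders,
       n_non_responders = resp$n_non_responders,
       responder_rules_agree = resp$rules_agree,
       minimal_detectable_rho = minimal_detectable_rho(nrow(tab)),
       anova_disease_type = {
         a <- anova_by_type(tab$pct_improvement_bipolar, tab$dystonia_type)
         list(F = a$statistic, df = a$df, p = a$p)
       })
}

recipe_synthetic_demo <- function(config = list()) {
  if (is.null(config$seed)) stop("synthetic_demo requires config$seed")
  cfg <- cohort_sim_config(seed = config$seed,
                           noise_sd = config$noise_sd %||% 0.5,
                           effect_gain = config$effect_gain %||% 1,
                           icosphere_level = config$icosphere_level %||% 3)
  space <- icosphere_space(cfg$icosphere_level, cfg$radius_mm)
  pattern <- make_pattern(space, sigma_mm = cfg$pattern_sigma_mm)
  sim <- simulate_cohort_maps(space, pattern, cfg)
  rm_full <- r_map(sim$deltas, sim$outcomes)
  recov <- stats::cor(rm_full$map$values[rm_full$map$mask],
                      pattern$map$values[rm_full$map$mask])
  tm <- group_t_map(sim$deltas)
  roi <- tryCatch(select_roi(tm$t, tm$p, space),
                  warning = function(w) select_roi_quiet(tm, space))
  roi_stat <- if (length(roi$roi_vertices))
    roi_outcome_correlation(sim$deltas, roi, sim$outcomes, m_comparisons = 4)
  loo <- cross_validate(sim$deltas, sim$outcomes, scheme = "loo")
  # fold shuffle seeded independently of the simulation stream
  k4 <- cross_validate(sim$deltas, sim$outcomes, scheme = "kfold", k = 4,
                       seed = cfg$seed + 70001L)
  list(recipe = "synthetic_demo", seed = cfg$seed, n = cfg$n_subjects,
       n_vertices = space$n_vertices,
       rmap_pattern_recovery = recov,
       roi = list(size = roi$size, sign = roi$sign,
                  rho = if (!is.null(roi_stat)) roi_stat$rho else NA,
                  p_bonferroni = if (!is.null(roi_stat)) roi_stat$p_bonferroni else NA),
       loo = list(rho = loo$rho, p_one_sided = loo$p_one_sided),
       kfold4 = list(rho = k4$rho, p_one_sided = k4$p_one_sided,
                     fold_assignment = k4$fold_assignment),
       significant = k4$p_one_sided < 0.05)
}

select_roi_quiet <- function(tm, space)
  suppressWarnings(select_roi(tm$t, tm$p, space))
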