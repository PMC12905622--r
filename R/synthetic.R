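#' Synthetic cohort configuration
#'
#' Parameters of the synthetic cohort generator. The generator emulates
#' the statistical structure the effect-mapping analysis assumes: a
#' spatially smooth ground-truth response pattern, per-subject
#' power-change maps whose expression of that pattern scales linearly
#' with clinical improvement, and exchangeable spatially correlated
#' noise. Optionally it also produces raw source time series with a 1/f
#' background, a band-limited low-frequency oscillator and narrow-band
#' stimulation artifact lines.
#'
#' @param n_subjects cohort size (default 15; must be >= 5).
#' @param icosphere_level,radius_mm synthetic source-space geometry
#'   (default level 3 = 642 vertices on an 80 mm sphere).
#' @param outcomes `"cohort"` (the bundled cohort's bipolar
#'   percent-improvement column), a numeric vector, or
#'   `list(mu =, sd =)` for normal draws.
#' @param effect_gain multiplier g of the planted pattern expression.
#' @param noise_sd noise SD relative to the SD of the planted effect at
#'   the pattern's peak vertices (default 0.5).
#' @param noise_fwhm_mm spatial correlation length of the noise field
#'   (FWHM of the smoothing kernel, default 20 mm).
#' @param subgroup_effect if `TRUE`, only responders (outcome >= 20%)
#'   express the pattern.
#' @param pattern_sigma_mm Gaussian blob width of the ground-truth
#'   pattern (default 30 mm; lobe-scale regions).
#' @param timeseries generate raw time series (`TRUE`/`FALSE`).
#' @param fs_hz,duration_sec time-series sampling rate (contract 250 Hz)
#'   and length.
#' @param osc_band_hz oscillator band (default 6-12 Hz).
#' @param ts_delta_gain oscillator ON-vs-OFF power contrast per unit of
#'   (peak-normalized) target delta; must keep ON power nonnegative.
#' @param artifact_freqs_hz stimulation artifact line frequencies added
#'   to the ON condition (default 65 and 120 Hz: a subharmonic-like line
#'   inside the 55-95 Hz reference band, and an alias-like line).
#' @param artifact_amp artifact line amplitude (0 disables lines).
#' @param seed integer seed; mandatory.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 15, icosphere_level = 3,
                              radius_mm = 80, outcomes = "cohort",
                              effect_gain = 1, noise_sd = 0.5,
                              noise_fwhm_mm = 20, subgroup_effect = FALSE,
                              pattern_sigma_mm = 30, timeseries = FALSE,
                              fs_hz = 250, duration_sec = 120,
                              osc_band_hz = c(6, 12), ts_delta_gain = 0.5,
                              artifact_freqs_hz = c(65, 120),
                              artifact_amp = 1, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_subjects >= 5, noise_sd >= 0, effect_gain >= 0,
            is.finite(seed))
  vals <- c(radius_mm, noise_fwhm_mm, pattern_sigma_mm, fs_hz, duration_sec,
            osc_band_hz, ts_delta_gain, artifact_amp)
  if (!all(is.finite(vals))) stop("non-finite configuration value")
  structure(list(n_subjects = n_subjects, icosphere_level = icosphere_level,
                 radius_mm = radius_mm, outcomes = outcomes,
                 effect_gain = effect_gain, noise_sd = noise_sd,
                 noise_fwhm_mm = noise_fwhm_mm,
                 subgroup_effect = subgroup_effect,
                 pattern_sigma_mm = pattern_sigma_mm,
                 timeseries = timeseries, fs_hz = fs_hz,
                 duration_sec = duration_sec, osc_band_hz = osc_band_hz,
                 ts_delta_gain = ts_delta_gain,
                 artifact_freqs_hz = artifact_freqs_hz,
                 artifact_amp = artifact_amp, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

resolve_outcomes <- function(cfg) {
  oc <- cfg$outcomes
  if (identical(oc, "cohort")) {
    tab <- load_cohort_table()
    oc <- tab$pct_improvement_bipolar
  } else if (is.list(oc)) {
    oc <- with_seed(cfg$seed + 1000L,
                    stats::rnorm(cfg$n_subjects, oc$mu, oc$sd))
  }
  oc <- as.numeric(oc)
  if (length(oc) < cfg$n_subjects)
    stop("outcome source provides ", length(oc), " values; need ",
         cfg$n_subjects)
  oc[seq_len(cfg$n_subjects)]
}

#' Ground-truth response pattern
#'
#' Sum of signed Gaussian blobs on Euclidean distance, normalized to unit
#' Euclidean norm. The default layout emulates the shape of an optimal
#' response signature: two negative blobs (motor/SMA-like suppression)
#' and two positive blobs (prefrontal- and cerebellar-like
#' synchronization).
#'
#' @param space a [source_space()].
#' @param centers integer vertex indices of the blob centres; default
#'   picks the vertices nearest to four canonical directions.
#' @param signs +1/-1 per blob.
#' @param sigma_mm Gaussian width per blob (recycled).
#' @param amplitudes relative blob amplitudes (recycled).
#' @return List of class `ground_truth_pattern`: unit-norm [scalar_map()]
#'   (`map`), `centers`, `signs`, `sigma_mm`, `amplitudes`.
#' @export
make_pattern <- function(space, centers = NULL, signs = c(-1, -1, 1, 1),
                         sigma_mm = 30, amplitudes = 1) {
  stopifnot(inherits(space, "source_space"))
  if (is.null(centers)) {
    dirs <- rbind(c(0, 0.35, 0.95),   # SMA-like: superior, slightly posterior
                  c(0.55, 0, 0.84),   # motor-like: superior-lateral
                  c(0.3, 0.95, -0.1), # prefrontal-like: anterior
                  c(0, -0.75, -0.66)) # cerebellar-like: posterior-inferior
    centers <- apply(dirs, 1, function(d) {
      d <- d / sqrt(sum(d^2))
      which.max(space$coords %*% d)
    })
  }
  nb <- length(centers)
  if (!(any(signs < 0) && any(signs > 0)))
    stop("pattern needs at least one negative and one positive blob")
  if (any(centers < 1 | centers > space$n_vertices))
    stop("blob centre out of range")
  sigma_mm <- rep_len(sigma_mm, nb)
  amplitudes <- rep_len(amplitudes, nb)
  signs <- rep_len(signs, nb)
  vals <- rep(0, space$n_vertices)
  for (b in seq_len(nb)) {
    d2 <- rowSums((space$coords -
                     rep(space$coords[centers[b], ], each = space$n_vertices))^2)
    vals <- vals + signs[b] * amplitudes[b] * exp(-d2 / (2 * sigma_mm[b]^2))
  }
  nrm <- sqrt(sum(vals^2))
  if (nrm == 0) stop("pattern is identically zero")
  structure(list(map = scalar_map(vals / nrm, space_label = space$label,
                                  kind = "pattern"),
                 centers = centers, signs = signs, sigma_mm = sigma_mm,
                 amplitudes = amplitudes, unit_norm = TRUE),
            class = "ground_truth_pattern")
}

#' Simulate a cohort of power-change maps
#'
#' Draws outcomes, then builds per-subject delta maps as
#' `delta_i = g * (outcome_i - mean(outcome)) * pattern + eps_i`, where
#' `eps_i` is a spatially smoothed Gaussian field rescaled so that its SD
#' equals `noise_sd` times the across-subject SD of the planted effect at
#' the pattern's peak vertex. OFF maps are smooth positive baseline
#' fields; ON = OFF + delta, so the delta maps can be recomputed with
#' [delta_maps()].
#'
#' @param space a [source_space()] (defaults to the config's icosphere).
#' @param pattern a [make_pattern()] result (default built on `space`
#'   with the config's blob width).
#' @param cfg a [cohort_sim_config()].
#' @return List with `deltas` (a [delta_map_set()]), `on`, `off`
#'   (subject x vertex matrices), `outcomes`, `pattern`, and `truth`
#'   (gain, absolute noise SD, responder flags, seed).
#' @export
simulate_cohort_maps <- function(space = NULL, pattern = NULL, cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  if (is.null(space))
    space <- icosphere_space(cfg$icosphere_level, cfg$radius_mm)
  if (is.null(pattern))
    pattern <- make_pattern(space, sigma_mm = cfg$pattern_sigma_mm)
  outcomes <- resolve_outcomes(cfg)
  n <- cfg$n_subjects
  pv <- pattern$map$values
  responder <- outcomes >= 20
  expresses <- if (cfg$subgroup_effect) responder else rep(TRUE, n)
  centred <- outcomes - mean(outcomes)
  g <- cfg$effect_gain
  # noise scale is relative to the planted effect; under the null (g = 0)
  # fall back to the unit-gain reference scale (all correlations computed
  # downstream are scale-invariant, so only degeneracy is at stake)
  peak_effect_sd <- max(g, if (g > 0) 0 else 1) *
    stats::sd(outcomes) * max(abs(pv))
  noise_sd_abs <- cfg$noise_sd * peak_effect_sd
  w <- smoothing_weights(space, cfg$noise_fwhm_mm)
  sim <- with_seed(cfg$seed, {
    deltas <- matrix(0, n, space$n_vertices)
    off <- matrix(0, n, space$n_vertices)
    for (i in seq_len(n)) {
      eps <- as.numeric(w %*% stats::rnorm(space$n_vertices))
      if (noise_sd_abs > 0 && stats::sd(eps) > 0)
        eps <- eps / stats::sd(eps) * noise_sd_abs
      else eps <- eps * 0
      deltas[i, ] <- g * centred[i] * pv * expresses[i] + eps
      base <- as.numeric(w %*% stats::rnorm(space$n_vertices))
      off[i, ] <- 1 + 0.2 * base / max(stats::sd(base), 1e-12)
    }
    list(deltas = deltas, off = off)
  })
  subjects <- sprintf("sim%02d", seq_len(n))
  rownames(sim$deltas) <- rownames(sim$off) <- subjects
  list(deltas = delta_map_set(sim$deltas, subjects = subjects,
                              band_hz = c(6, 12), space_label = space$label),
       on = sim$off + sim$deltas, off = sim$off, outcomes = outcomes,
       pattern = pattern,
       truth = list(gain = g, noise_sd_abs = noise_sd_abs,
                    responder = responder, expresses = expresses,
                    seed = cfg$seed))
}

# 1/f-shaped or band-limited Gaussian noise via FFT shaping (unit SD).
shaped_noise <- function(nsamp, fs, shape = c("one_over_f", "band"),
                         band = NULL, exponent = 1) {
  shape <- match.arg(shape)
  x <- stats::rnorm(nsamp)
  X <- stats::fft(x)
  f <- (seq_len(nsamp) - 1) * fs / nsamp
  f <- pmin(f, fs - f)  # symmetric two-sided frequency magnitudes
  amp <- if (shape == "one_over_f") {
    ifelse(f < 1, 1, f^(-exponent / 2))
  } else {
    as.numeric(f >= band[1] & f <= band[2])
  }
  y <- Re(stats::fft(X * amp, inverse = TRUE)) / nsamp
  s <- stats::sd(y)
  if (s == 0) stop("degenerate shaped noise")
  y / s
}

#' Simulate ON/OFF source time series for one subject
#'
#' Per vertex: a 1/f background plus a band-limited low-frequency
#' oscillator whose ON-vs-OFF power contrast realizes the requested
#' target delta. The ON condition additionally carries pure sinusoid
#' stimulation artifact lines. An artifact-free copy of the ON series
#' (same noise realization) is returned alongside, so the effect of the
#' spectral Hampel step can be evaluated against a line-free ground
#' truth.
#'
#' @param space a [source_space()].
#' @param delta_target numeric per-vertex target delta (any scale; it is
#'   normalized by its peak magnitude internally).
#' @param cfg a [cohort_sim_config()] with `timeseries = TRUE` (supplies
#'   fs, duration, oscillator band, contrast gain and artifact lines).
#' @param subject_id label for the generated series.
#' @param seed overrides the config seed.
#' @return List with [source_timeseries()] elements `on`, `off`,
#'   `on_clean` (ON without artifact lines) and the peak-normalized
#'   `delta_rel` used.
#' @export
simulate_timeseries <- function(space, delta_target, cfg,
                                subject_id = "sim01", seed = NULL) {
  stopifnot(inherits(space, "source_space"),
            inherits(cfg, "cohort_sim_config"))
  if (!cfg$timeseries) stop("config has timeseries mode off")
  if (cfg$fs_hz != 250) stop("time-series contract requires fs = 250 Hz")
  nv <- space$n_vertices
  if (length(delta_target) != nv)
    stop("delta_target must have one value per vertex")
  peak <- max(abs(delta_target))
  delta_rel <- if (peak > 0) delta_target / peak else delta_target
  a_off2 <- 1
  a_on2 <- a_off2 + cfg$ts_delta_gain * delta_rel
  if (any(a_on2 < 0))
    stop("requested band-power change unreachable (negative ON oscillator power) at vertex ",
         which(a_on2 < 0)[1])
  nsamp <- round(cfg$duration_sec * cfg$fs_hz)
  tgrid <- seq_len(nsamp) / cfg$fs_hz
  seed <- seed %||% cfg$seed
  out <- with_seed(seed, {
    off <- on <- matrix(0, nv, nsamp)
    for (v in seq_len(nv)) {
      bg_off <- shaped_noise(nsamp, cfg$fs_hz, "one_over_f")
      bg_on <- shaped_noise(nsamp, cfg$fs_hz, "one_over_f")
      osc_off <- shaped_noise(nsamp, cfg$fs_hz, "band", band = cfg$osc_band_hz)
      osc_on <- shaped_noise(nsamp, cfg$fs_hz, "band", band = cfg$osc_band_hz)
      off[v, ] <- bg_off + sqrt(a_off2) * osc_off
      on[v, ] <- bg_on + sqrt(a_on2[v]) * osc_on
    }
    phases <- stats::runif(length(cfg$artifact_freqs_hz) * nv, 0, 2 * pi)
    list(off = off, on = on, phases = phases)
  })
  on_clean <- out$on
  on_lines <- out$on
  if (cfg$artifact_amp > 0 && length(cfg$artifact_freqs_hz)) {
    ph <- matrix(out$phases, nrow = nv)
    for (j in seq_along(cfg$artifact_freqs_hz)) {
      f0 <- cfg$artifact_freqs_hz[j]
      for (v in seq_len(nv))
        on_lines[v, ] <- on_lines[v, ] +
          cfg$artifact_amp * sin(2 * pi * f0 * tgrid + ph[v, j])
    }
  }
  list(on = source_timeseries(on_lines, cfg$fs_hz, subject_id, "ON"),
       off = source_timeseries(out$off, cfg$fs_hz, subject_id, "OFF"),
       on_clean = source_timeseries(on_clean, cfg$fs_hz, subject_id, "ON"),
       delta_rel = delta_rel)
}
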