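#' Spectral analysis configuration
#'
#' Parameters of the spectral chain: Welch estimation, the spectral Hampel
#' filter for narrow-band stimulation artifacts, the high-frequency
#' reference band used for normalization, and the analysis bands.
#'
#' @param window_sec Welch window length in seconds (default 4, giving a
#'   0.25 Hz grid at 250 Hz sampling).
#' @param overlap_frac fractional window overlap (default 0.5).
#' @param taper window function; only `"hann"` is provided.
#' @param ref_band_hz normalization reference band (default 55-95 Hz).
#' @param band_low_hz low-frequency analysis band (default 6-12 Hz).
#' @param band_beta_hz beta band (default 13-30 Hz).
#' @param band_low_alt_hz sensitivity variant of the low band (4-12 Hz).
#' @param hampel_halfwidth_hz half-width of the sliding frequency window
#'   (default 2 Hz).
#' @param hampel_nsigma outlier threshold in scaled-MAD units (default 3).
#' @param artifact_freqs_hz optional frequencies (Hz) to which Hampel
#'   replacement is restricted (e.g. known stimulation subharmonics).
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(window_sec = 4, overlap_frac = 0.5, taper = "hann",
                            ref_band_hz = c(55, 95), band_low_hz = c(6, 12),
                            band_beta_hz = c(13, 30), band_low_alt_hz = c(4, 12),
                            hampel_halfwidth_hz = 2, hampel_nsigma = 3,
                            artifact_freqs_hz = NULL) {
  stopifnot(window_sec > 0, overlap_frac >= 0, overlap_frac < 1,
            hampel_halfwidth_hz > 0, hampel_nsigma > 0)
  taper <- match.arg(taper, "hann")
  for (b in list(ref_band_hz, band_low_hz, band_beta_hz, band_low_alt_hz))
    if (length(b) != 2L || b[1] >= b[2]) stop("bands must be increasing length-2")
  for (b in list(band_low_hz, band_beta_hz, band_low_alt_hz))
    if (b[2] >= ref_band_hz[1] && b[1] <= ref_band_hz[2])
      stop("reference band must be disjoint from analysis bands")
  structure(list(window_sec = window_sec, overlap_frac = overlap_frac,
                 taper = taper, ref_band_hz = ref_band_hz,
                 band_low_hz = band_low_hz, band_beta_hz = band_beta_hz,
                 band_low_alt_hz = band_low_alt_hz,
                 hampel_halfwidth_hz = hampel_halfwidth_hz,
                 hampel_nsigma = hampel_nsigma,
                 artifact_freqs_hz = artifact_freqs_hz),
            class = "spectral_config")
}

#' Source-space time series
#'
#' Vertex-by-sample matrix of reconstructed source activity for one
#' subject and stimulation condition. The data contract upstream of this
#' package is 250 Hz sampling with a 3 Hz high-pass already applied.
#'
#' @param data numeric matrix, vertices in rows, samples in columns.
#' @param fs_hz sampling rate (contract: 250).
#' @param subject_id subject identifier.
#' @param condition `"ON"` or `"OFF"` stimulation.
#' @param highpass_hz applied high-pass (contract: 3).
#' @return An object of class `source_timeseries`.
#' @export
source_timeseries <- function(data, fs_hz = 250, subject_id = "subj",
                              condition = c("ON", "OFF"), highpass_hz = 3) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("time series contains non-finite samples")
  structure(list(data = data, fs_hz = fs_hz, subject_id = subject_id,
                 condition = condition, highpass_hz = highpass_hz,
                 mask = rep(TRUE, nrow(data))),
            class = "source_timeseries")
}

#' Z-score source time series
#'
#' Standardizes every vertex's time course to mean 0 and sample SD 1.
#' Vertices with zero temporal variance cannot be standardized: they are
#' masked for all downstream analysis and a warning is raised.
#'
#' @param ts a [source_timeseries()].
#' @return The standardized [source_timeseries()] (with updated mask).
#' @export
zscore_timeseries <- function(ts) {
  stopifnot(inherits(ts, "source_timeseries"))
  m <- rowMeans(ts$data)
  s <- apply(ts$data, 1, stats::sd)
  bad <- s == 0 | !is.finite(s)
  if (any(bad)) {
    warning(sum(bad), " zero-variance vertex/vertices masked during z-scoring")
    s[bad] <- 1
  }
  ts$data <- (ts$data - m) / s
  ts$mask <- ts$mask & !bad
  ts
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Welch power spectral density
#'
#' Averaged Hann-tapered periodograms over 50%-overlapping windows
#' (defaults: 4 s windows, so the frequency grid step is 0.25 Hz at
#' 250 Hz sampling). One-sided density over (0, Nyquist]; partial trailing
#' windows are dropped.
#'
#' @param ts a [source_timeseries()].
#' @param cfg a [spectral_config()].
#' @return An object of class `spectrum_set` with fields `freqs_hz`
#'   (ascending grid), `power` (vertex x frequency, nonnegative),
#'   `df_hz`, `normalized`, plus the subject/condition labels and mask.
#' @export
welch_psd <- function(ts, cfg = spectral_config()) {
  stopifnot(inherits(ts, "source_timeseries"), inherits(cfg, "spectral_config"))
  fs <- ts$fs_hz
  nper <- round(cfg$window_sec * fs)
  nsamp <- ncol(ts$data)
  step <- max(1L, round(nper * (1 - cfg$overlap_frac)))
  nwin <- if (nsamp >= nper) ((nsamp - nper) %/% step) + 1L else 0L
  if (nwin < 2L)
    stop(sprintf("record too short for Welch estimation: need >= %.1f s (2 windows of %g s at %g%% overlap), got %.1f s",
                 (nper + step) / fs, cfg$window_sec, 100 * cfg$overlap_frac,
                 nsamp / fs))
  w <- hann_window(nper)
  nf <- nper %/% 2L
  freqs <- seq_len(nf) * fs / nper
  scale <- 2 / (fs * sum(w^2))
  acc <- matrix(0, nrow(ts$data), nf)
  for (k in seq_len(nwin)) {
    idx <- ((k - 1L) * step + 1L):((k - 1L) * step + nper)
    seg <- t(ts$data[, idx, drop = FALSE]) * w
    ft <- stats::mvfft(seg)
    acc <- acc + t(Mod(ft[2:(nf + 1L), , drop = FALSE])^2)
  }
  power <- acc / nwin * scale
  # Nyquist bin is not mirrored in the two-sided spectrum
  power[, nf] <- power[, nf] / 2
  structure(list(subject_id = ts$subject_id, condition = ts$condition,
                 freqs_hz = freqs, power = power, normalized = FALSE,
                 df_hz = fs / nper, mask = ts$mask),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set %s/%s: %d vertices x %d freqs (%.3g-%.3g Hz, df %.3g), %s>\n",
              x$subject_id, x$condition, nrow(x$power), length(x$freqs_hz),
              min(x$freqs_hz), max(x$freqs_hz), x$df_hz,
              if (x$normalized) "normalized" else "unnormalized"))
  invisible(x)
}

#' Spectral Hampel filter
#'
#' Robust removal of narrow-band artifact lines (stimulation subharmonics
#' and aliases) from power spectra. A window of half-width
#' `hampel_halfwidth_hz` slides along the frequency axis of each vertex's
#' spectrum; a bin whose power exceeds the local median plus
#' `hampel_nsigma` scaled MADs (1.4826 x MAD) is replaced by the local
#' median. If `artifact_freqs_hz` is set in the config, replacement is
#' restricted to bins within one half-width of those frequencies.
#'
#' @param spec an unnormalized `spectrum_set` from [welch_psd()].
#' @param cfg a [spectral_config()].
#' @return The filtered `spectrum_set`.
#' @export
hampel_filter_spectrum <- function(spec, cfg = spectral_config()) {
  stopifnot(inherits(spec, "spectrum_set"), inherits(cfg, "spectral_config"))
  if (spec$normalized)
    stop("Hampel filtering must precede reference-band normalization")
  k <- round(cfg$hampel_halfwidth_hz / spec$df_hz)
  if (k < 1L)
    stop("hampel_halfwidth_hz smaller than the frequency resolution (",
         spec$df_hz, " Hz)")
  p <- spec$power
  nf <- ncol(p)
  eligible <- rep(TRUE, nf)
  if (!is.null(cfg$artifact_freqs_hz)) {
    eligible <- rep(FALSE, nf)
    for (f0 in cfg$artifact_freqs_hz)
      eligible <- eligible |
        (abs(spec$freqs_hz - f0) <= cfg$hampel_halfwidth_hz)
  }
  out <- p
  for (j in which(eligible)) {
    win <- max(1L, j - k):min(nf, j + k)
    slab <- p[, win, drop = FALSE]
    med <- apply(slab, 1, stats::median)
    mad <- 1.4826 * apply(abs(slab - med), 1, stats::median)
    hit <- p[, j] > med + cfg$hampel_nsigma * mad
    out[hit, j] <- med[hit]
  }
  spec$power <- out
  spec
}

#' Normalize a spectrum by high-frequency reference power
#'
#' Divides each vertex's full spectrum by its mean power across the
#' reference band (default 55-95 Hz, both edges inclusive). Removes
#' scale differences between recordings and subjects; after
#' normalization the per-vertex mean over the reference band is exactly 1.
#' Vertices with zero reference power are masked with a warning.
#'
#' @param spec a `spectrum_set`.
#' @param cfg a [spectral_config()].
#' @return The normalized `spectrum_set` (`normalized = TRUE`).
#' @export
normalize_spectrum <- function(spec, cfg = spectral_config()) {
  stopifnot(inherits(spec, "spectrum_set"), inherits(cfg, "spectral_config"))
  sel <- spec$freqs_hz >= cfg$ref_band_hz[1] & spec$freqs_hz <= cfg$ref_band_hz[2]
  if (!any(sel)) stop("no frequency bins in the reference band")
  ref <- rowMeans(spec$power[, sel, drop = FALSE])
  bad <- ref <= 0 | !is.finite(ref)
  if (any(bad)) {
    warning(sum(bad), " vertex/vertices with zero reference-band power masked")
    ref[bad] <- 1
  }
  spec$power <- spec$power / ref
  spec$mask <- spec$mask & !bad
  spec$normalized <- TRUE
  spec
}

#' Band-averaged power map
#'
#' Per-vertex mean power over the bins inside a frequency band (both band
#' edges inclusive).
#'
#' @param spec a `spectrum_set`.
#' @param band_hz length-2 increasing band limits in Hz.
#' @return A [scalar_map()] of kind `"power"`.
#' @export
band_power_map <- function(spec, band_hz) {
  stopifnot(inherits(spec, "spectrum_set"), length(band_hz) == 2L,
            band_hz[1] < band_hz[2])
  sel <- spec$freqs_hz >= band_hz[1] & spec$freqs_hz <= band_hz[2]
  if (!any(sel)) stop("no frequency bins inside the band ",
                      band_hz[1], "-", band_hz[2], " Hz")
  scalar_map(rowMeans(spec$power[, sel, drop = FALSE]),
             mask = spec$mask, space_label = "source-space", kind = "power")
}

#' Spatially smooth a spectrum per frequency bin
#'
#' Applies the Gaussian surface kernel of [smooth_map()] independently at
#' every frequency bin, the order used for source power maps (smoothing
#' precedes reference normalization; band averaging and smoothing commute,
#' division does not).
#'
#' @param spec a `spectrum_set`.
#' @param space the [source_space()] the spectra live on.
#' @param fwhm_mm kernel FWHM in mm (default 6).
#' @return The smoothed `spectrum_set`.
#' @export
smooth_spectra <- function(spec, space, fwhm_mm = 6) {
  stopifnot(inherits(spec, "spectrum_set"))
  if (nrow(spec$power) != space$n_vertices)
    stop("spectrum vertex count does not match the space")
  w <- smoothing_weights(space, fwhm_mm, mask = spec$mask)
  spec$power <- w %*% spec$power
  spec$mask <- spec$mask & rowSums(w) > 0
  spec
}

#' Canonical spectral chain: time series to normalized band-power map
#'
#' Fixed pipeline order: z-score, Welch PSD, spatial smoothing per
#' frequency bin, spectral Hampel filter, reference-band normalization,
#' band averaging. Reordering normalization before the Hampel step changes
#' the result whenever artifact lines fall inside the reference band.
#'
#' @param ts a [source_timeseries()].
#' @param space the [source_space()] of its vertices.
#' @param band_hz analysis band (default the config's low band).
#' @param cfg a [spectral_config()].
#' @param fwhm_mm spatial smoothing FWHM in mm (default 6).
#' @param hampel apply the spectral Hampel step (default `TRUE`).
#' @return A normalized band-power [scalar_map()].
#' @export
band_power_pipeline <- function(ts, space, band_hz = NULL,
                                cfg = spectral_config(), fwhm_mm = 6,
                                hampel = TRUE) {
  if (is.null(band_hz)) band_hz <- cfg$band_low_hz
  ts <- zscore_timeseries(ts)
  spec <- welch_psd(ts, cfg)
  spec <- smooth_spectra(spec, space, fwhm_mm)
  if (hampel) spec <- hampel_filter_spectrum(spec, cfg)
  spec <- normalize_spectrum(spec, cfg)
  map <- band_power_map(spec, band_hz)
  map$space_label <- space$label
  map
}
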