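#' Per-subject power-change (delta) map set
#'
#' Vertex-wise difference of normalized band power, stimulation ON minus
#' OFF, for every subject of a cohort. Positive values mean DBS-induced
#' synchronization, negative values suppression.
#'
#' @param deltas numeric matrix, subjects in rows, vertices in columns.
#' @param subjects character vector of unique subject ids (defaults to
#'   row names or `s1..sn`).
#' @param band_hz the analysis band the maps were averaged over.
#' @param space_label label of the shared source space.
#' @param mask logical per-vertex validity (vertices masked in any
#'   subject's map are excluded cohort-wide).
#' @return An object of class `delta_map_set`.
#' @export
delta_map_set <- function(deltas, subjects = NULL, band_hz = c(6, 12),
                          space_label = "source-space", mask = NULL) {
  deltas <- as.matrix(deltas)
  if (is.null(subjects))
    subjects <- rownames(deltas) %||% paste0("s", seq_len(nrow(deltas)))
  if (anyDuplicated(subjects)) stop("subject ids must be unique")
  if (is.null(mask)) mask <- apply(is.finite(deltas), 2, all)
  rownames(deltas) <- subjects
  structure(list(deltas = deltas, subjects = subjects, band_hz = band_hz,
                 space_label = space_label, mask = mask),
            class = "delta_map_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.delta_map_set <- function(x, ...) {
  cat(sprintf("<delta_map_set: %d subjects x %d vertices, band %g-%g Hz on '%s'>\n",
              nrow(x$deltas), ncol(x$deltas), x$band_hz[1], x$band_hz[2],
              x$space_label))
  invisible(x)
}

#' Build delta maps from matched ON and OFF band-power maps
#'
#' Subtracts each subject's OFF-stimulation band-power map from the
#' matching ON map, vertex-wise.
#'
#' @param on,off named lists of [scalar_map()]s (names are subject ids),
#'   or numeric matrices (subjects x vertices with rownames).
#' @param band_hz the band the maps carry.
#' @return A [delta_map_set()].
#' @export
delta_maps <- function(on, off, band_hz = c(6, 12)) {
  as_mat <- function(x) {
    if (is.matrix(x)) return(list(m = x, mask = rep(TRUE, ncol(x)),
                                  label = "source-space"))
    stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "scalar_map")))
    list(m = do.call(rbind, lapply(x, `[[`, "values")),
         mask = apply(do.call(rbind, lapply(x, `[[`, "mask")), 2, all),
         label = x[[1]]$space_label)
  }
  a <- as_mat(on); b <- as_mat(off)
  ids_on <- rownames(a$m) %||% names(on)
  ids_off <- rownames(b$m) %||% names(off)
  if (!identical(sort(ids_on), sort(ids_off)) || is.null(ids_on)) {
    miss <- c(setdiff(ids_on, ids_off), setdiff(ids_off, ids_on))
    stop("ON/OFF subject sets do not match; unmatched: ",
         paste(miss, collapse = ", "))
  }
  rownames(a$m) <- ids_on; rownames(b$m) <- ids_off
  b$m <- b$m[ids_on, , drop = FALSE]
  if (ncol(a$m) != ncol(b$m)) stop("ON/OFF maps live on different spaces")
  delta_map_set(a$m - b$m, subjects = ids_on, band_hz = band_hz,
                space_label = a$label, mask = a$mask & b$mask)
}

#' Group t-map of DBS-induced power changes
#'
#' Per-vertex one-sample t-test of the subject deltas against zero
#' (algebraically the paired ON-vs-OFF t-test), df = n - 1, two-tailed
#' uncorrected p. Vertices with zero delta variance are masked.
#'
#' @param deltas a [delta_map_set()].
#' @return List with `t` and `p` [scalar_map()]s and `df`.
#' @export
group_t_map <- function(deltas) {
  stopifnot(inherits(deltas, "delta_map_set"))
  d <- deltas$deltas
  n <- nrow(d)
  if (n < 3) stop("need at least 3 subjects for a group t-map")
  m <- colMeans(d)
  s <- sqrt(colSums((d - rep(m, each = n))^2) / (n - 1))
  ok <- deltas$mask & s > 0
  tval <- ifelse(ok, m / (s / sqrt(n)), NA_real_)
  pval <- 2 * stats::pt(-abs(tval), df = n - 1)
  list(t = scalar_map(tval, mask = ok, space_label = deltas$space_label, kind = "t"),
       p = scalar_map(pval, mask = ok, space_label = deltas$space_label, kind = "p"),
       df = n - 1)
}

#' Responder / non-responder subgroup t-maps
#'
#' Applies [group_t_map()] separately to the subjects flagged as
#' responders and to the rest.
#'
#' @param deltas a [delta_map_set()].
#' @param labels logical vector, `TRUE` for responders, aligned with the
#'   subject order.
#' @return List with elements `responders` and `non_responders`, each a
#'   [group_t_map()] result (the non-responder element is `NULL` when all
#'   subjects are responders).
#' @export
subgroup_t_maps <- function(deltas, labels) {
  stopifnot(inherits(deltas, "delta_map_set"),
            length(labels) == nrow(deltas$deltas))
  labels <- as.logical(labels)
  sub <- function(keep) {
    if (!any(keep)) return(NULL)
    if (sum(keep) < 3) stop("subgroup has fewer than 3 subjects")
    group_t_map(delta_map_set(deltas$deltas[keep, , drop = FALSE],
                              subjects = deltas$subjects[keep],
                              band_hz = deltas$band_hz,
                              space_label = deltas$space_label,
                              mask = deltas$mask))
  }
  list(responders = sub(labels), non_responders = sub(!labels))
}

#' Select the region of interest from a thresholded t-map
#'
#' Thresholds the map at uncorrected two-tailed `p < alpha`, splits the
#' surviving vertices by the sign of t, extracts adjacency-connected
#' components within each sign, and returns the component with the
#' largest vertex count (ties broken by larger peak |t|), across both
#' signs.
#'
#' @param t_map,p_map [scalar_map()]s from [group_t_map()].
#' @param space the [source_space()] the maps live on.
#' @param alpha uncorrected threshold (default 0.05).
#' @return List of class `roi_result` with `roi_vertices`, `sign`
#'   (`"suppression"` or `"synchronisation"`), `size`, `peak_t`,
#'   `alpha`; `roi_vertices` is empty (with a warning) when no vertex
#'   survives.
#' @export
select_roi <- function(t_map, p_map, space, alpha = 0.05) {
  check_map_on_space(t_map, space)
  check_map_on_space(p_map, space)
  ok <- t_map$mask & p_map$mask & p_map$values < alpha
  empty <- structure(list(roi_vertices = integer(0), sign = NA_character_,
                          size = 0L, peak_t = NA_real_, alpha = alpha),
                     class = "roi_result")
  if (!any(ok)) {
    warning("no vertices survive p < ", alpha)
    return(empty)
  }
  best <- NULL
  for (sgn in c(-1, 1)) {
    sel <- which(ok & sign(t_map$values) == sgn)
    if (!length(sel)) next
    comps <- connected_components(sel, space)
    for (comp in comps) {
      peak <- max(abs(t_map$values[comp]))
      cand <- list(roi_vertices = comp,
                   sign = if (sgn < 0) "suppression" else "synchronisation",
                   size = length(comp), peak_t = peak, alpha = alpha)
      if (is.null(best) || cand$size > best$size ||
          (cand$size == best$size && cand$peak_t > best$peak_t))
        best <- cand
    }
  }
  structure(best, class = "roi_result")
}

#' Correlate ROI mean power change with clinical outcome
#'
#' Averages each subject's delta over the ROI vertices, computes the
#' two-tailed Spearman correlation with the outcomes, and applies a
#' Bonferroni correction with an explicit comparison count
#' (`p_bonferroni = min(1, m * p_raw)`).
#'
#' @param deltas a [delta_map_set()].
#' @param roi integer vector of ROI vertex indices (or a `roi_result`).
#' @param outcomes per-subject clinical outcome (e.g. % improvement).
#' @param m_comparisons number of tests entering the correction; in the
#'   replication recipe this is ROIs x outcome scores = 4.
#' @return List of class `roi_result` with `mean_delta`, `rho`, `p_raw`,
#'   `p_bonferroni`, `m_comparisons`, plus the ROI fields if supplied.
#' @export
roi_outcome_correlation <- function(deltas, roi, outcomes, m_comparisons = 4) {
  stopifnot(inherits(deltas, "delta_map_set"))
  base <- list()
  if (inherits(roi, "roi_result")) {
    base <- unclass(roi)
    roi <- roi$roi_vertices
  }
  roi <- as.integer(roi)
  if (!length(roi)) stop("ROI is empty")
  if (length(outcomes) != nrow(deltas$deltas))
    stop("outcomes must match the subject count")
  md <- rowMeans(deltas$deltas[, roi, drop = FALSE])
  if (stats::sd(md) == 0) stop("ROI mean delta is constant across subjects")
  rho <- stats::cor(md, outcomes, method = "spearman")
  p_raw <- spearman_p_two_sided(rho, length(md))
  structure(c(base, list(mean_delta = md, rho = rho, p_raw = p_raw,
                         p_bonferroni = min(1, m_comparisons * p_raw),
                         m_comparisons = m_comparisons)),
            class = "roi_result")
}

spearman_p_two_sided <- function(rho, n) {
  if (abs(rho) >= 1) return(2 / factorial(min(n, 170)))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Outcome-weighted correlation map (R-map)
#'
#' Correlates, at every vertex, the per-subject power changes with the
#' per-subject clinical improvements. The resulting map of correlation
#' coefficients is the cohort's "optimal" response signature: vertices
#' with strongly negative values are where suppression tracks benefit,
#' strongly positive values where synchronization does.
#'
#' @param deltas a [delta_map_set()].
#' @param outcomes per-subject improvement (non-constant).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List of class `rmap` with the correlation [scalar_map()]
#'   (`map`), `corr_method` and `n_subjects`. Vertices with degenerate
#'   delta variance are masked.
#' @export
r_map <- function(deltas, outcomes, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(deltas, "delta_map_set"))
  d <- deltas$deltas
  n <- nrow(d)
  if (n < 4) stop("need at least 4 subjects for an R-map")
  if (length(outcomes) != n) stop("outcomes must match the subject count")
  if (stats::sd(outcomes) == 0) stop("outcome vector has zero variance")
  x <- if (method == "spearman") rank(outcomes) else outcomes
  dm <- if (method == "spearman") apply(d, 2, rank) else d
  sds <- apply(dm, 2, stats::sd)
  ok <- deltas$mask & sds > 0
  r <- rep(NA_real_, ncol(d))
  r[ok] <- as.numeric(stats::cor(x, dm[, ok, drop = FALSE]))
  r <- pmin(1, pmax(-1, r))
  structure(list(map = scalar_map(r, mask = ok,
                                  space_label = deltas$space_label, kind = "r"),
                 corr_method = method, n_subjects = n),
            class = "rmap")
}

#' Spatial similarity of an individual map to an R-map
#'
#' Correlation across jointly unmasked vertices between one subject's
#' delta values and the R-map values. Serves as that subject's estimated
#' DBS outcome: the more the individual pattern of change resembles the
#' optimal signature, the larger the similarity.
#'
#' @param delta a [scalar_map()] or numeric vector of one subject's
#'   vertex deltas.
#' @param rmap an [r_map()] result (or a [scalar_map()] of kind `"r"`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A single correlation coefficient.
#' @export
spatial_similarity <- function(delta, rmap, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  rm_map <- if (inherits(rmap, "rmap")) rmap$map else rmap
  dvals <- if (inherits(delta, "scalar_map")) delta$values else as.numeric(delta)
  dmask <- if (inherits(delta, "scalar_map")) delta$mask else is.finite(dvals)
  ok <- dmask & rm_map$mask & is.finite(rm_map$values)
  if (sum(ok) < 10)
    stop("fewer than 10 jointly unmasked vertices for spatial similarity")
  stats::cor(dvals[ok], rm_map$values[ok], method = method)
}

#' One-sided (right-tailed) Spearman correlation test
#'
#' Rank correlation with average ranks for ties; the right-tailed p comes
#' from the t-approximation (df = n - 2) or, for n <= 10, optionally from
#' permutations (full enumeration up to n = 8, seeded Monte-Carlo with
#' 2e5 draws for n = 9, 10).
#'
#' @param x,y numeric vectors (n >= 4, both non-constant).
#' @param p_method `"t"` (default) or `"exact"`.
#' @param mc_seed seed for the Monte-Carlo fallback at n = 9, 10.
#' @return List with `rho` and `p_one_sided`.
#' @export
spearman_one_sided <- function(x, y, p_method = c("t", "exact"),
                               mc_seed = 1L) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input has no defined rank correlation")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (p_method == "exact") {
    if (n > 10) stop("exact permutation p only available for n <= 10")
    if (n <= 8) {
      perms <- permutations_all(n)
      rhos <- apply(perms, 1, function(ix) stats::cor(rx, ry[ix]))
      p <- mean(rhos >= rho - 1e-12)
    } else {
      nrep <- 2e5
      rng <- with_seed(mc_seed, replicate(nrep, stats::cor(rx, sample(ry))))
      p <- (sum(rng >= rho - 1e-12) + 1) / (nrep + 1)
    }
  } else {
    if (abs(rho) >= 1) {
      p <- if (rho > 0) 1 / factorial(min(n, 170)) else 1
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
    }
  }
  list(rho = rho, p_one_sided = max(min(p, 1), .Machine$double.xmin))
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[r:(r + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    r <- r + nrow(sub)
  }
  out
}

#' Cross-validated outcome estimation from R-maps
#'
#' Leave-one-out or k-fold validation of the R-map model: for every fold,
#' an R-map is built from the training subjects only; each held-out
#' subject's spatial similarity to that map is the estimate of their
#' outcome. The pooled estimates are then correlated with the empirical
#' improvements (one-sided right-tailed Spearman, since only positive
#' estimate-outcome correlations are meaningful).
#'
#' @param deltas a [delta_map_set()].
#' @param outcomes per-subject empirical improvements.
#' @param scheme `"loo"` or `"kfold"`.
#' @param k number of folds (kfold only; n >= 2k).
#' @param seed integer seed for the fold shuffle (required for kfold).
#' @param rmap_method vertex-wise correlation for the training R-maps.
#' @param sim_method spatial-similarity correlation.
#' @param store_rmaps keep each fold's training R-map in the result (used
#'   e.g. to audit that held-out data never leak into training).
#' @param max_retries re-randomizations allowed when a fold leaves a
#'   degenerate (constant-outcome) training set.
#' @return List of class `crossval_result`: `scheme`, `k`, `seed`,
#'   `fold_assignment`, `similarity` (one estimate per subject), `rho`,
#'   `p_one_sided`, `corr_method`, and optionally `train_rmaps`.
#' @export
cross_validate <- function(deltas, outcomes, scheme = c("loo", "kfold"),
                           k = 4, seed = NULL,
                           rmap_method = c("spearman", "pearson"),
                           sim_method = c("pearson", "spearman"),
                           store_rmaps = FALSE, max_retries = 20) {
  scheme <- match.arg(scheme)
  rmap_method <- match.arg(rmap_method)
  sim_method <- match.arg(sim_method)
  stopifnot(inherits(deltas, "delta_map_set"))
  n <- nrow(deltas$deltas)
  if (length(outcomes) != n) stop("outcomes must match the subject count")
  if (scheme == "loo") {
    if (n < 5) stop("leave-one-out requires n >= 5")
    folds <- seq_len(n)
    k <- n
  } else {
    if (n < 2 * k) stop("k-fold requires n >= 2k")
    if (is.null(seed)) stop("k-fold cross-validation requires a seed")
    folds <- NULL
    for (try in seq_len(max_retries)) {
      cand <- with_seed(seed + try - 1L, sample(rep(seq_len(k), length.out = n)))
      degenerate <- any(vapply(seq_len(k), function(f)
        stats::sd(outcomes[cand != f]) == 0, TRUE))
      if (!degenerate) { folds <- cand; break }
    }
    if (is.null(folds))
      stop("could not find a fold assignment with non-constant training outcomes")
  }
  sims <- rep(NA_real_, n)
  rmaps <- if (store_rmaps) vector("list", k) else NULL
  sub_dset <- function(keep) delta_map_set(
    deltas$deltas[keep, , drop = FALSE], subjects = deltas$subjects[keep],
    band_hz = deltas$band_hz, space_label = deltas$space_label,
    mask = deltas$mask)
  for (f in sort(unique(folds))) {
    train <- folds != f
    rm_f <- r_map(sub_dset(train), outcomes[train], method = rmap_method)
    if (store_rmaps) rmaps[[f]] <- rm_f
    for (i in which(!train))
      sims[i] <- spatial_similarity(deltas$deltas[i, ], rm_f,
                                    method = sim_method)
  }
  ct <- spearman_one_sided(sims, outcomes)
  structure(list(scheme = scheme, k = if (scheme == "kfold") k else NA_integer_,
                 seed = seed, fold_assignment = folds, similarity = sims,
                 rho = ct$rho, p_one_sided = ct$p_one_sided,
                 corr_method = list(rmap = rmap_method, similarity = sim_method),
                 train_rmaps = rmaps),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval %s%s: rho = %.3f, one-sided p = %.4g>\n",
              x$scheme, if (x$scheme == "kfold") paste0(" (k=", x$k, ")") else "",
              x$rho, x$p_one_sided))
  invisible(x)
}
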