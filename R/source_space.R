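#' Source-space geometry
#'
#' A source space is the set of locations carrying reconstructed neural
#' activity: the vertices of a triangulated cortical surface, or the points
#' of a volumetric grid. All map-level operations (smoothing, cluster
#' extraction, group statistics) live on a source space and use its
#' adjacency structure.
#'
#' @param coords numeric matrix, one row per vertex, three columns
#'   (x, y, z positions in millimetres).
#' @param faces optional integer matrix of triangle vertex indices
#'   (one triangle per row, 1-based).
#' @param adjacency optional list of integer vectors, one per vertex,
#'   giving neighbour indices. Usually derived via [build_adjacency()].
#' @param label free-text tag identifying the space (e.g.
#'   `"template-surface"`, `"volumetric-grid"`).
#' @return An object of class `source_space`: a list with elements
#'   `coords`, `faces`, `adjacency`, `label`, `n_vertices`.
#' @seealso [build_adjacency()], [icosphere_space()], [smooth_map()],
#'   [connected_components()]
#' @export
source_space <- function(coords, faces = NULL, adjacency = NULL,
                         label = "source-space") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("`coords` must have three columns (x, y, z in mm)")
  if (!all(is.finite(coords))) stop("vertex coordinates must be finite")
  n <- nrow(coords)
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    if (ncol(faces) != 3L) stop("`faces` must have three columns")
    if (any(faces < 1L) || any(faces > n))
      stop("face indices must lie in 1..", n)
  }
  sp <- structure(
    list(coords = coords, faces = faces, adjacency = adjacency,
         label = label, n_vertices = n),
    class = "source_space")
  if (!is.null(adjacency)) validate_adjacency(sp)
  sp
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space '%s': %d vertices, %s faces, adjacency %s>\n",
              x$label, x$n_vertices,
              if (is.null(x$faces)) "no" else nrow(x$faces),
              if (is.null(x$adjacency)) "absent" else "present"))
  invisible(x)
}

validate_adjacency <- function(space) {
  adj <- space$adjacency
  n <- space$n_vertices
  if (length(adj) != n) stop("adjacency must have one entry per vertex")
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (any(nb == i)) stop("self-neighbour at vertex ", i)
    if (any(nb < 1L | nb > n)) stop("neighbour index out of range at vertex ", i)
    for (j in nb) if (!(i %in% adj[[j]]))
      stop("adjacency not symmetric: ", i, " -> ", j)
  }
  invisible(TRUE)
}

#' Derive vertex adjacency
#'
#' For a surface, two vertices are neighbours when they share a triangle
#' edge. For a volumetric grid (no faces), neighbours are all vertices
#' within `neighbour_radius_mm` Euclidean distance.
#'
#' @param space a [source_space()].
#' @param neighbour_radius_mm positive radius in mm; required when the
#'   space has no faces, ignored otherwise.
#' @return The space with its `adjacency` field filled in (symmetric,
#'   no self-neighbours).
#' @export
build_adjacency <- function(space, neighbour_radius_mm = NULL) {
  stopifnot(inherits(space, "source_space"))
  n <- space$n_vertices
  if (!is.null(space$faces)) {
    f <- space$faces
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    adj <- vector("list", n)
    both <- rbind(e, e[, c(2, 1)])
    sp <- split(both[, 2], both[, 1])
    for (k in names(sp)) adj[[as.integer(k)]] <- sort(unique(sp[[k]]))
    for (i in seq_len(n)) if (is.null(adj[[i]])) adj[[i]] <- integer(0)
  } else {
    if (is.null(neighbour_radius_mm) || neighbour_radius_mm <= 0)
      stop("space has no faces: a positive `neighbour_radius_mm` is required")
    d <- as.matrix(stats::dist(space$coords))
    adj <- lapply(seq_len(n), function(i) {
      nb <- unname(which(d[i, ] <= neighbour_radius_mm))
      nb[nb != i]
    })
    iso <- which(vapply(adj, length, 1L) == 0L)
    if (length(iso))
      warning(length(iso), " isolated vertex/vertices at radius ",
              neighbour_radius_mm, " mm (kept with empty neighbourhood)")
  }
  space$adjacency <- adj
  validate_adjacency(space)
  space
}

#' Connected components of a vertex selection
#'
#' Partitions a set of selected vertices into maximal adjacency-connected
#' subsets. Used to define regions of interest as the largest cluster of
#' suprathreshold vertices in a statistical map.
#'
#' @param selected integer vector of vertex indices (subset of the space).
#' @param space a [source_space()] with adjacency present.
#' @return List of integer vectors (sorted ascending within each
#'   component), ordered by decreasing component size. Empty selection
#'   gives an empty list.
#' @export
connected_components <- function(selected, space) {
  stopifnot(inherits(space, "source_space"))
  if (is.null(space$adjacency)) stop("space has no adjacency; run build_adjacency()")
  selected <- sort(unique(as.integer(selected)))
  if (length(selected) == 0L) return(list())
  if (any(selected < 1L | selected > space$n_vertices))
    stop("selected vertices out of range")
  in_sel <- logical(space$n_vertices)
  in_sel[selected] <- TRUE
  visited <- logical(space$n_vertices)
  comps <- list()
  for (s in selected) {
    if (visited[s]) next
    queue <- s
    visited[s] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, v)
      nb <- space$adjacency[[v]]
      nb <- nb[in_sel[nb] & !visited[nb]]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, length, 1L), decreasing = TRUE)]
}

#' Triangulated icosphere source space
#'
#' A subdivided icosahedron projected onto a sphere; the default synthetic
#' stand-in for a cortical surface (level 3 gives 642 vertices). Adjacency
#' is derived from the triangulation.
#'
#' @param level subdivision level (0 = icosahedron with 12 vertices; each
#'   level quadruples the face count).
#' @param radius_mm sphere radius in mm (default 80, head-sized).
#' @return A [source_space()] with faces and adjacency.
#' @export
icosphere_space <- function(level = 3, radius_mm = 80) {
  stopifnot(level >= 0, radius_mm > 0)
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    vl <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    midcache <- new.env(parent = emptyenv())
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      got <- midcache[[k]]
      if (!is.null(got)) return(got)
      m <- (vl[[a]] + vl[[b]]) / 2
      m <- m / sqrt(sum(m^2))
      vl[[length(vl) + 1L]] <<- m
      midcache[[k]] <- length(vl)
      length(vl)
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    r <- 1L
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, cc); ca <- getmid(cc, a)
      nf[r, ] <- c(a, ab, ca); nf[r + 1L, ] <- c(b, bc, ab)
      nf[r + 2L, ] <- c(cc, ca, bc); nf[r + 3L, ] <- c(ab, bc, ca)
      r <- r + 4L
    }
    v <- do.call(rbind, vl)
    f <- nf
  }
  build_adjacency(source_space(v * radius_mm, faces = f,
                               label = sprintf("icosphere-%d", level)))
}

#' Per-vertex scalar map
#'
#' One real value per vertex of a source space, with a validity mask.
#' Carries band power, power change (delta), t/p statistics, or
#' correlation coefficients.
#'
#' @param values numeric vector, one value per vertex.
#' @param mask logical vector; `FALSE` marks vertices excluded from every
#'   statistic. Defaults to finite values.
#' @param space_label identifier of the space the map lives on.
#' @param kind one of `"power"`, `"delta"`, `"t"`, `"p"`, `"r"`,
#'   `"pattern"`.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, mask = NULL, space_label = "source-space",
                       kind = c("power", "delta", "t", "p", "r", "pattern")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (is.null(mask)) mask <- is.finite(values)
  mask <- as.logical(mask)
  if (length(mask) != length(values)) stop("mask length must match values")
  if (kind == "r" && any(abs(values[mask]) > 1 + 1e-12, na.rm = TRUE))
    stop("correlation map values must lie in [-1, 1]")
  structure(list(values = values, mask = mask,
                 space_label = space_label, kind = kind),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map [%s] on '%s': %d vertices, %d masked>\n",
              x$kind, x$space_label, length(x$values), sum(!x$mask)))
  invisible(x)
}

check_map_on_space <- function(map, space) {
  stopifnot(inherits(map, "scalar_map"), inherits(space, "source_space"))
  if (length(map$values) != space$n_vertices)
    stop("map length (", length(map$values),
         ") does not match space vertex count (", space$n_vertices, ")")
  invisible(TRUE)
}

#' Gaussian smoothing weights on a source space
#'
#' Dense row-stochastic weight matrix for Gaussian smoothing on Euclidean
#' inter-vertex distance, sigma = fwhm / 2.3548, truncated at 3 sigma.
#' Rows are normalized over unmasked vertices.
#'
#' @param space a [source_space()].
#' @param fwhm_mm kernel full width at half maximum in mm.
#' @param mask optional logical vector of valid vertices.
#' @return n x n numeric matrix; row i gives the weights of vertex i's
#'   smoothed value. Rows with no unmasked vertex in range are all zero.
#' @export
smoothing_weights <- function(space, fwhm_mm, mask = NULL) {
  stopifnot(inherits(space, "source_space"), fwhm_mm > 0)
  n <- space$n_vertices
  if (is.null(mask)) mask <- rep(TRUE, n)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- as.matrix(stats::dist(space$coords))
  w <- exp(-d^2 / (2 * sigma^2))
  w[d > 3 * sigma] <- 0
  w[, !mask] <- 0
  rs <- rowSums(w)
  ok <- rs > 0
  w[ok, ] <- w[ok, , drop = FALSE] / rs[ok]
  w
}

#' Smooth a scalar map
#'
#' Gaussian-weighted averaging of vertex values (see
#' [smoothing_weights()]); the default 6 mm FWHM matches the kernel used
#' for source-space power maps. Masked vertices contribute no weight; a
#' vertex whose whole neighbourhood is masked comes back masked.
#'
#' @param map a [scalar_map()].
#' @param space the [source_space()] the map lives on.
#' @param fwhm_mm kernel FWHM in mm (default 6).
#' @return A smoothed [scalar_map()].
#' @export
smooth_map <- function(map, space, fwhm_mm = 6) {
  check_map_on_space(map, space)
  w <- smoothing_weights(space, fwhm_mm, mask = map$mask)
  vals <- map$values
  vals[!map$mask] <- 0
  out <- as.numeric(w %*% vals)
  reachable <- rowSums(w) > 0
  newmask <- map$mask & reachable
  out[!newmask] <- NA_real_
  scalar_map(out, mask = newmask, space_label = map$space_label, kind = map$kind)
}
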