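#' Read a triangle mesh or point grid as a source space
#'
#' Supports ASCII OFF and ASCII PLY triangle meshes, and CSV point clouds
#' with columns `x,y,z` (mm) for volumetric grids. Adjacency is built from
#' faces when present; for point clouds pass `neighbour_radius_mm`.
#'
#' @param path file path (`.off`, `.ply`, or `.csv`).
#' @param neighbour_radius_mm radius for point-cloud adjacency (mm).
#' @param label space label; defaults to the file name.
#' @return A [source_space()] with adjacency.
#' @export
read_source_space <- function(path, neighbour_radius_mm = NULL, label = NULL) {
  if (is.null(label)) label <- basename(path)
  ext <- tolower(tools::file_ext(path))
  sp <- switch(ext,
    off = read_off(path, label),
    ply = read_ply(path, label),
    csv = {
      df <- utils::read.csv(path)
      if (!all(c("x", "y", "z") %in% names(df)))
        stop("volumetric grid CSV needs columns x, y, z")
      source_space(as.matrix(df[, c("x", "y", "z")]), label = label)
    },
    stop("unsupported mesh format: .", ext)
  )
  build_adjacency(sp, neighbour_radius_mm = neighbour_radius_mm)
}

read_off <- function(path, label) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[[1]]) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = lines[[2]], what = integer(), quiet = TRUE)
  nv <- counts[[1]]; nf <- counts[[2]]
  vtx <- matrix(scan(text = lines[3:(2 + nv)], what = double(), quiet = TRUE),
                ncol = 3, byrow = TRUE)
  faces <- NULL
  if (nf > 0) {
    fl <- lines[(3 + nv):(2 + nv + nf)]
    faces <- t(vapply(fl, function(s) {
      xs <- scan(text = s, what = integer(), quiet = TRUE)
      if (xs[[1]] != 3L) stop("only triangle faces supported")
      xs[2:4] + 1L
    }, integer(3)))
    dimnames(faces) <- NULL
  }
  source_space(vtx, faces = faces, label = label)
}

read_ply <- function(path, label) {
  lines <- readLines(path)
  if (trimws(lines[[1]]) != "ply") stop("not a PLY file: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[[1]]
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format ascii", trimws(hdr))))
    stop("only ASCII PLY supported")
  nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1",
                       grep("element vertex", hdr, value = TRUE)[[1]]))
  fline <- grep("element face", hdr, value = TRUE)
  nf <- if (length(fline)) as.integer(sub(".*element face (\\d+).*", "\\1",
                                          fline[[1]])) else 0L
  body <- lines[(hdr_end + 1):length(lines)]
  vtx <- t(vapply(body[seq_len(nv)], function(s)
    scan(text = s, what = double(), quiet = TRUE)[1:3], double(3)))
  dimnames(vtx) <- NULL
  faces <- NULL
  if (nf > 0) {
    faces <- t(vapply(body[(nv + 1):(nv + nf)], function(s) {
      xs <- scan(text = s, what = double(), quiet = TRUE)
      if (xs[[1]] != 3) stop("only triangle faces supported")
      as.integer(xs[2:4]) + 1L
    }, integer(3)))
    dimnames(faces) <- NULL
  }
  source_space(vtx, faces = faces, label = label)
}

#' Write / read scalar maps as CSV
#'
#' Two-column CSV (`vertex_index,value`) plus a `mask` column; a comment
#' header line carries the space label and map kind (and optional
#' provenance fields).
#'
#' @param map a [scalar_map()].
#' @param path output CSV path.
#' @param extra named character vector of extra header fields (e.g. seed,
#'   config hash) written into the comment line.
#' @return `path`, invisibly.
#' @export
write_scalar_map <- function(map, path, extra = NULL) {
  stopifnot(inherits(map, "scalar_map"))
  hdr <- sprintf("# space_label=%s kind=%s", map$space_label, map$kind)
  if (!is.null(extra))
    hdr <- paste(hdr, paste(sprintf("%s=%s", names(extra), extra), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(
    data.frame(vertex_index = seq_along(map$values),
               value = map$values, mask = map$mask),
    con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scalar_map
#' @export
read_scalar_map <- function(path) {
  first <- readLines(path, n = 1)
  label <- sub(".*space_label=(\\S+).*", "\\1", first)
  kind <- sub(".*kind=(\\S+).*", "\\1", first)
  df <- utils::read.csv(path, comment.char = "#")
  scalar_map(df$value, mask = as.logical(df$mask),
             space_label = label, kind = kind)
}
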