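# Small geometries shared across test files (built once per file load).
ico1 <- icosphere_space(1)   # 42 vertices
ico2 <- icosphere_space(2)   # 162 vertices

# Two disjoint triangles in one mesh.
two_triangles <- build_adjacency(source_space(
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
        c(10, 0, 0), c(11, 0, 0), c(10, 1, 0)),
  faces = rbind(c(1, 2, 3), c(4, 5, 6)), label = "two-triangles"))

# Independent flood-fill oracle for connected components.
flood_fill_components <- function(selected, space) {
  selected <- sort(unique(selected))
  remaining <- selected
  comps <- list()
  while (length(remaining)) {
    comp <- remaining[1]
    repeat {
      grown <- unique(c(comp, unlist(space$adjacency[comp])))
      grown <- grown[grown %in% selected]
      if (length(grown) == length(comp)) break
      comp <- grown
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps[order(vapply(comps, length, 1L), decreasing = TRUE)]
}
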