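# Graph-statistic helpers: fabricate a rin from an edge list, and an
# exhaustive shortest-path-enumeration betweenness oracle (igraph).

# fabricate a rin directly from an edge list (for graph-statistic tests)
rin_from_edges <- function(n, edges) {
  ids <- if (n > 0) sprintf("A:%d:_:ALA", seq_len(n)) else character(0)
  deg <- rep(0L, n)
  for (e in edges) { deg[e[1]] <- deg[e[1]] + 1L; deg[e[2]] <- deg[e[2]] + 1L }
  nodes <- data.frame(id = ids, chain = rep("A", n), seq_num = seq_len(n),
                      icode = rep("", n), residue = rep("ALA", n),
                      degree = deg, stringsAsFactors = FALSE)
  m <- length(edges)
  ed <- data.frame(
    bond_type = rep("CA_CONTACT", m),
    res_a = ids[vapply(edges, `[[`, 0L, 1L)],
    res_b = ids[vapply(edges, `[[`, 0L, 2L)],
    atoms_a = rep("CA", m), atoms_b = rep("CA", m),
    distance = rep(5, m), angle = rep(NA_real_, m),
    energy = rep(0, m), role_a = rep("ca", m), role_b = rep("ca", m),
    res_a_idx = vapply(edges, `[[`, 0L, 1L),
    res_b_idx = vapply(edges, `[[`, 0L, 2L),
    sigma = rep(NA_real_, m), stringsAsFactors = FALSE
  )
  ed$source <- ed$res_a; ed$target <- ed$res_b
  structure(list(nodes = nodes, edges = ed,
                 meta = list(structure_id = "synthetic", model_index = 1L,
                             param_fingerprint = "")), class = "rin")
}

# exhaustive shortest-path enumeration (igraph) for the ratio definition
enumeration_betweenness <- function(rin) {
  g <- igraph::graph_from_data_frame(
    unique(rin$edges[, c("source", "target")]), directed = FALSE,
    vertices = rin$nodes$id)
  n <- igraph::vcount(g)
  through <- stats::setNames(rep(0, n), rin$nodes$id)
  total <- 0
  if (n >= 2) for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- suppressWarnings(
      igraph::all_shortest_paths(g, from = s, to = t)$res)
    if (length(paths) == 0) next
    total <- total + length(paths)
    for (pth in paths) {
      v <- names(pth)
      if (length(v) > 2) {
        interior <- v[-c(1, length(v))]
        through[interior] <- through[interior] + 1
      }
    }
  }
  if (total == 0) through else through / total
}
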