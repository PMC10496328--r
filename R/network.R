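# Assembling the attributed residue interaction network, serializing it
# to GraphML / CSV, per-model batch output, and the shortest-path
# betweenness statistic used for trajectory analysis.

#' Build a residue interaction network
#'
#' One node per residue of the prepared model (isolated residues are
#' kept), one undirected edge per contact, with node degrees computed from
#' the incident edges.
#'
#' @param prep A `rin_prepared` model.
#' @param contacts A contact data frame from [detect_contacts()] or an
#'   individual detector.
#' @param structure_id Identifier stored in the network metadata.
#' @param model_index Model number stored in the metadata.
#' @param params The `bond_params` used, fingerprinted into the metadata.
#' @return An object of class `rin`: list with `nodes` (data frame: `id`,
#'   `chain`, `seq_num`, `icode`, `residue`, `degree`), `edges` (the
#'   contact data frame with `source`/`target` columns) and `meta`.
#' @export
build_rin <- function(prep, contacts, structure_id = "structure",
                      model_index = 1L, params = NULL) {
  res <- prep$residues
  if (nrow(contacts) > 0L) {
    unknown <- setdiff(c(contacts$res_a, contacts$res_b), res$key)
    if (length(unknown) > 0L)
      stop("build_rin: contact references unknown residue(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  nodes <- data.frame(
    id = res$key, chain = res$chain, seq_num = res$resseq,
    icode = res$icode, residue = res$resname,
    degree = 0L, stringsAsFactors = FALSE
  )
  if (nrow(contacts) > 0L) {
    deg <- table(c(contacts$res_a, contacts$res_b))
    nodes$degree <- as.integer(deg[nodes$id])
    nodes$degree[is.na(nodes$degree)] <- 0L
  }
  edges <- contacts
  if (nrow(edges) > 0L) {
    edges$source <- edges$res_a
    edges$target <- edges$res_b
  } else {
    edges$source <- character(0)
    edges$target <- character(0)
  }
  fingerprint <- if (is.null(params)) "" else
    paste(flatten_params(unclass(params)), collapse = ";")
  structure(list(
    nodes = nodes, edges = edges,
    meta = list(structure_id = structure_id, model_index = model_index,
                param_fingerprint = fingerprint)
  ), class = "rin")
}

#' @export
print.rin <- function(x, ...) {
  cat(sprintf("<rin '%s' model %d: %d nodes, %d edges>\n",
              x$meta$structure_id, x$meta$model_index,
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    tb <- table(x$edges$bond_type)
    cat(paste(sprintf("  %s: %d", names(tb), as.integer(tb)), collapse = "\n"), "\n")
  }
  invisible(x)
}

NODE_KEYS <- c(chain = "string", seq_num = "int", icode = "string",
               residue = "string", degree = "int")
EDGE_KEYS <- c(bond_type = "string", atoms_a = "string", atoms_b = "string",
               distance = "double", angle = "double", energy = "double",
               role_a = "string", role_b = "string")

#' Write a RIN as GraphML
#'
#' Emits a well-formed undirected GraphML document with a declared
#' `<key>` for every node and edge attribute (numeric attributes typed
#' `double`/`int`, the rest `string`) and stable node ids, re-readable by
#' any generic GraphML parser.
#'
#' @param rin A `rin` object.
#' @param path Output path.
#' @export
write_graphml <- function(rin, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  for (k in names(NODE_KEYS))
    xml2::xml_add_child(doc, "key", id = paste0("n_", k), `for` = "node",
                        attr.name = k, attr.type = NODE_KEYS[[k]])
  for (k in names(EDGE_KEYS))
    xml2::xml_add_child(doc, "key", id = paste0("e_", k), `for` = "edge",
                        attr.name = k, attr.type = EDGE_KEYS[[k]])
  g <- xml2::xml_add_child(doc, "graph", id = rin$meta$structure_id,
                           edgedefault = "undirected")
  fmt <- function(v) {
    if (is.numeric(v) && !is.integer(v)) sprintf("%.10g", v) else as.character(v)
  }
  for (i in seq_len(nrow(rin$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = rin$nodes$id[i])
    for (k in names(NODE_KEYS)) {
      d <- xml2::xml_add_child(nd, "data", key = paste0("n_", k))
      xml2::xml_set_text(d, fmt(rin$nodes[[k]][i]))
    }
  }
  for (i in seq_len(nrow(rin$edges))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = rin$edges$source[i],
                              target = rin$edges$target[i])
    for (k in names(EDGE_KEYS)) {
      v <- rin$edges[[k]][i]
      if (is.na(v)) next  # absent angle: omit the data element
      d <- xml2::xml_add_child(ed, "data", key = paste0("e_", k))
      xml2::xml_set_text(d, fmt(v))
    }
  }
  tryCatch(xml2::write_xml(doc, path),
           error = function(e) stop(sprintf("write_graphml: cannot write '%s': %s",
                                            path, conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' Read a GraphML file written by [write_graphml()]
#'
#' Light reader used by the `stats` command; restores nodes, edges and
#' attribute typing from the declared keys.
#'
#' @param path Path to a GraphML file.
#' @return A `rin` object (metadata limited to the graph id).
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  ktype <- stats::setNames(xml2::xml_attr(keys, "attr.type"),
                           xml2::xml_attr(keys, "id"))
  kname <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                           xml2::xml_attr(keys, "id"))
  cast <- function(v, ty) switch(ty, double = as.numeric(v),
                                 int = , long = as.integer(v), v)
  read_elems <- function(xpath, id_attrs) {
    elems <- xml2::xml_find_all(doc, xpath)
    rows <- lapply(elems, function(e) {
      out <- as.list(xml2::xml_attrs(e)[id_attrs])
      names(out) <- id_attrs
      for (d in xml2::xml_find_all(e, "./data")) {
        kid <- xml2::xml_attr(d, "key")
        out[[kname[[kid]]]] <- cast(xml2::xml_text(d), ktype[[kid]])
      }
      out
    })
    rows
  }
  nodes <- read_elems(".//graph/node", "id")
  edges <- read_elems(".//graph/edge", c("source", "target"))
  to_df <- function(rows, proto) {
    if (length(rows) == 0L) return(proto)
    cols <- unique(unlist(lapply(rows, names)))
    df <- as.data.frame(
      lapply(cols, function(cn) {
        v <- lapply(rows, function(r) if (is.null(r[[cn]])) NA else r[[cn]])
        unlist(v)
      }), col.names = cols, stringsAsFactors = FALSE, optional = TRUE)
    names(df) <- cols
    df
  }
  nodes_df <- to_df(nodes, data.frame(id = character(0)))
  edges_df <- to_df(edges, data.frame(source = character(0), target = character(0)))
  gid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//graph"), "id")
  structure(list(nodes = nodes_df, edges = edges_df,
                 meta = list(structure_id = gid, model_index = NA_integer_,
                             param_fingerprint = "")),
            class = "rin")
}

#' Write a RIN as node and edge CSV files
#'
#' Nodes file header: `node_id, chain, seq, icode, residue, degree`; edges
#' file header: `source, target, bond_type, atom_a, atom_b, distance,
#' angle, energy`. RFC 4180 quoting; rows ordered deterministically
#' (nodes by id, edges by source, target, type).
#'
#' @param rin A `rin` object.
#' @param nodes_path,edges_path Output paths.
#' @export
write_rin_csv <- function(rin, nodes_path, edges_path) {
  nodes <- rin$nodes
  nodes <- nodes[order(nodes$id, method = "radix"), , drop = FALSE]
  out_n <- data.frame(node_id = nodes$id, chain = nodes$chain,
                      seq = nodes$seq_num, icode = nodes$icode,
                      residue = nodes$residue, degree = nodes$degree)
  edges <- rin$edges
  if (nrow(edges) > 0L)
    edges <- edges[order(edges$source, edges$target, edges$bond_type,
                         edges$atoms_a, edges$atoms_b, method = "radix"),
                   , drop = FALSE]
  out_e <- data.frame(source = edges$source, target = edges$target,
                      bond_type = edges$bond_type,
                      atom_a = edges$atoms_a, atom_b = edges$atoms_b,
                      distance = edges$distance, angle = edges$angle,
                      energy = edges$energy)
  tryCatch({
    utils::write.csv(out_n, nodes_path, row.names = FALSE, quote = TRUE)
    utils::write.csv(out_e, edges_path, row.names = FALSE, quote = TRUE)
  }, error = function(e) stop(sprintf("write_rin_csv: %s", conditionMessage(e)),
                              call. = FALSE))
  invisible(c(nodes_path, edges_path))
}

#' Run the full pipeline for every model of a structure
#'
#' Prepares, annotates and detects per model, writing one output (or CSV
#' pair) per model into `out_dir`, named `<id>_model<k>.<ext>`. A model
#' that fails is skipped with a warning; the remaining models still run.
#'
#' @param structure A `rin_structure`.
#' @param prep_opts A `prep_options` object.
#' @param params A `bond_params` object.
#' @param out_dir Output directory (created if needed).
#' @param format `"graphml"` or `"csv"`.
#' @param types Detector selection, as in [detect_contacts()].
#' @return Invisibly, the vector of files written.
#' @export
run_all_models <- function(structure, prep_opts = prep_options(),
                           params = bond_params(), out_dir,
                           format = c("graphml", "csv"), types = BOND_TYPES) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (k in seq_along(structure$models)) {
    res <- tryCatch({
      prep <- prepare_model(structure$models[[k]], prep_opts)
      contacts <- detect_contacts(prep, params, types)
      rin <- build_rin(prep, contacts, structure$id, k, params)
      base <- file.path(out_dir, sprintf("%s_model%d", structure$id, k))
      if (format == "graphml") {
        write_graphml(rin, paste0(base, ".graphml"))
        paste0(base, ".graphml")
      } else {
        write_rin_csv(rin, paste0(base, "_nodes.csv"), paste0(base, "_edges.csv"))
        c(paste0(base, "_nodes.csv"), paste0(base, "_edges.csv"))
      }
    }, error = function(e) {
      warning(sprintf("model %d failed: %s", k, conditionMessage(e)), call. = FALSE)
      character(0)
    })
    files <- c(files, res)
  }
  invisible(files)
}

# adjacency list of the simple graph underlying a rin (typed multi-edges
# collapsed; path multiplicity must reflect topology, not bond multiplicity)
rin_adjacency <- function(rin) {
  n <- nrow(rin$nodes)
  adj <- vector("list", n)
  if (nrow(rin$edges) > 0L) {
    a <- match(rin$edges$source, rin$nodes$id)
    b <- match(rin$edges$target, rin$nodes$id)
    key <- paste(pmin(a, b), pmax(a, b))
    keep <- !duplicated(key) & a != b
    a <- a[keep]; b <- b[keep]
    for (k in seq_along(a)) {
      adj[[a[k]]] <- c(adj[[a[k]]], b[k])
      adj[[b[k]]] <- c(adj[[b[k]]], a[k])
    }
  }
  adj
}

# BFS from s: distances and shortest-path counts to every node
bfs_paths <- function(adj, s) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  sigma <- numeric(n)
  dist[s] <- 0L
  sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

#' Betweenness centrality (shortest-path ratio form)
#'
#' For `method = "ratio"` (the default), each node's value is the number
#' of shortest paths that pass through it as an interior vertex, summed
#' over unordered pairs of distinct other nodes, divided by the total
#' number of shortest paths over all connected unordered pairs in the
#' graph. Values lie in `[0, 1]`; disconnected pairs contribute no paths.
#' `method = "brandes"` gives the standard pair-normalized betweenness
#' (sum over pairs of the fraction of that pair's shortest paths through
#' the node) for comparability with common graph libraries.
#'
#' Paths are counted on the unweighted simple graph obtained by collapsing
#' typed multi-edges.
#'
#' @param rin A `rin` object.
#' @param method `"ratio"` or `"brandes"`.
#' @return Named numeric vector, one value per node.
#' @export
betweenness <- function(rin, method = c("ratio", "brandes")) {
  method <- match.arg(method)
  n <- nrow(rin$nodes)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  adj <- rin_adjacency(rin)
  bfs <- lapply(seq_len(n), function(s) bfs_paths(adj, s))
  through <- numeric(n)   # interior-path incidences per node
  frac <- numeric(n)      # Brandes-style summed fractions
  total <- 0              # total shortest paths over connected unordered pairs
  for (s in seq_len(n - 1L)) {
    ds <- bfs[[s]]$dist; ss <- bfs[[s]]$sigma
    for (t in (s + 1L):n) {
      if (is.na(ds[t])) next
      st <- ss[t]
      total <- total + st
      dt <- bfs[[t]]$dist; stg <- bfs[[t]]$sigma
      for (v in seq_len(n)) {
        if (v == s || v == t || is.na(ds[v]) || is.na(dt[v])) next
        if (ds[v] + dt[v] == ds[t]) {
          paths_through <- ss[v] * stg[v]
          through[v] <- through[v] + paths_through
          frac[v] <- frac[v] + paths_through / st
        }
      }
    }
  }
  vals <- if (method == "ratio") {
    if (total == 0) numeric(n) else through / total
  } else frac
  stats::setNames(vals, rin$nodes$id)
}
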