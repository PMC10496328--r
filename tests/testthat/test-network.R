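test_that("build_rin keeps isolated nodes and computes degrees", {
  st <- make_fixture("HBOND_PAIR", d = 2.9, angle = 180)
  prep <- prepare_model(st$models[[1]], prep_options())
  contacts <- detect_contacts(prep, bond_params(), types = "hbond")
  rin <- build_rin(prep, contacts, "hb", 1L, bond_params())
  expect_equal(nrow(rin$nodes), 2)
  expect_equal(nrow(rin$edges), 1)
  expect_equal(rin$nodes$degree, c(1L, 1L))

  none <- build_rin(prep, rinet:::empty_contacts(), "hb")
  expect_equal(nrow(none$nodes), 2)
  expect_equal(none$nodes$degree, c(0L, 0L))

  bad <- contacts
  bad$res_a <- "Z:9:_:GLY"
  expect_error(build_rin(prep, bad), "unknown residue")
})

test_that("GraphML output is well-formed and round-trips via igraph", {
  st <- make_fixture("HBOND_PAIR", d = 2.9, angle = 170)
  prep <- prepare_model(st$models[[1]], prep_options())
  contacts <- detect_contacts(prep, bond_params(), types = c("hbond", "vdw"))
  rin <- build_rin(prep, contacts, "hb", 1L, bond_params())
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(rin, f)

  doc <- xml2::read_xml(f)                 # well-formed XML
  xml2::xml_ns_strip(doc)
  expect_equal(length(xml2::xml_find_all(doc, ".//graph/node")), nrow(rin$nodes))
  expect_equal(xml2::xml_attr(xml2::xml_find_first(doc, ".//graph"),
                              "edgedefault"), "undirected")

  g <- igraph::read_graph(f, format = "graphml")   # independent reader
  expect_equal(igraph::vcount(g), nrow(rin$nodes))
  expect_equal(igraph::ecount(g), nrow(rin$edges))
  expect_false(igraph::is_directed(g))
  expect_setequal(igraph::V(g)$id, rin$nodes$id)
  ord <- match(igraph::V(g)$id, rin$nodes$id)
  expect_equal(igraph::V(g)$degree, rin$nodes$degree[ord])
  expect_equal(sort(igraph::E(g)$energy), sort(rin$edges$energy), tolerance = 1e-9)
  expect_equal(sort(igraph::E(g)$distance), sort(rin$edges$distance), tolerance = 1e-9)
  expect_setequal(igraph::E(g)$bond_type, rin$edges$bond_type)
})

test_that("empty RIN writes valid GraphML and header-only CSVs", {
  st <- make_fixture("CHAIN", n = 3, conformation = "extended")
  prep <- prepare_model(st$models[[1]], prep_options())
  rin <- build_rin(prep, rinet:::empty_contacts(), "empty")
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(rin, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 0)

  fn <- withr::local_tempfile(fileext = ".csv")
  fe <- withr::local_tempfile(fileext = ".csv")
  none <- build_rin(prep, rinet:::empty_contacts(), "none")
  write_rin_csv(structure(list(nodes = none$nodes[0, ], edges = none$edges,
                               meta = none$meta), class = "rin"), fn, fe)
  expect_length(readLines(fn), 1)
  expect_length(readLines(fe), 1)
})

test_that("CSV and GraphML encode the same graph", {
  prep <- random_model(n_res = 15, seed = 800)
  contacts <- detect_contacts(prep, bond_params())
  rin <- build_rin(prep, contacts, "rand", 1L, bond_params())

  fg <- withr::local_tempfile(fileext = ".graphml")
  fn <- withr::local_tempfile(fileext = ".csv")
  fe <- withr::local_tempfile(fileext = ".csv")
  write_graphml(rin, fg)
  write_rin_csv(rin, fn, fe)

  nodes_csv <- utils::read.csv(fn, stringsAsFactors = FALSE,
                               colClasses = c(icode = "character"))
  edges_csv <- utils::read.csv(fe, stringsAsFactors = FALSE)
  rin_g <- read_graphml(fg)
  expect_setequal(nodes_csv$node_id, rin_g$nodes$id)
  key_csv <- sort(paste(edges_csv$source, edges_csv$target, edges_csv$bond_type,
                        edges_csv$atom_a, edges_csv$atom_b,
                        sprintf("%.6f", edges_csv$distance)))
  key_gml <- sort(paste(rin_g$edges$source, rin_g$edges$target,
                        rin_g$edges$bond_type, rin_g$edges$atoms_a,
                        rin_g$edges$atoms_b, sprintf("%.6f", rin_g$edges$distance)))
  expect_equal(key_csv, key_gml)
  # edges file is deterministically ordered with a fixed header
  expect_equal(names(edges_csv), c("source", "target", "bond_type", "atom_a",
                                   "atom_b", "distance", "angle", "energy"))
  expect_equal(nrow(edges_csv), nrow(rin$edges))
  expect_length(readLines(fe), nrow(rin$edges) + 1L)
})

test_that("run_all_models writes one output per model and skips broken models", {
  st <- make_fixture("CHAIN", n = 5, conformation = "helix", model_count = 3)
  out <- withr::local_tempdir()
  files <- run_all_models(st, prep_options(), bond_params(), out,
                          format = "graphml", types = "ca_contact")
  expect_length(files, 3)
  expect_true(all(file.exists(files)))
  expect_equal(basename(files),
               sprintf("chain_model%d.graphml", 1:3))

  # 5 identical models of a rigid molecule -> identical edge sets
  st5 <- make_fixture("IONIC_PAIR", d = 3.5, model_count = 5)
  out5 <- withr::local_tempdir()
  f5 <- run_all_models(st5, prep_options(), bond_params(), out5,
                       format = "graphml", types = "ionic")
  expect_length(f5, 5)
  sigs <- vapply(f5, function(f) {
    r <- read_graphml(f)
    paste(r$edges$source, r$edges$target, r$edges$bond_type, collapse = "|")
  }, "")
  expect_length(unique(sigs), 1)

  # a model that empties out under preparation is skipped with a warning
  water <- st$models[[1]]
  water$resname <- "HOH"; water$is_hetero <- TRUE
  broken <- rinet:::new_structure("mix", list(st$models[[1]], water), "pdb")
  outb <- withr::local_tempdir()
  expect_warning(
    fb <- run_all_models(broken, prep_options(), bond_params(), outb,
                         format = "graphml", types = "ca_contact"),
    "model 2 failed")
  expect_length(fb, 1)
})

test_that("ratio betweenness matches hand-enumerated small graphs", {
  path3 <- rin_from_edges(3, list(c(1L, 2L), c(2L, 3L)))
  bw <- betweenness(path3)
  expect_equal(unname(bw), c(0, 1 / 3, 0))

  tri <- rin_from_edges(3, list(c(1L, 2L), c(2L, 3L), c(1L, 3L)))
  expect_equal(unname(betweenness(tri)), c(0, 0, 0))

  star <- rin_from_edges(4, list(c(1L, 2L), c(1L, 3L), c(1L, 4L)))
  expect_equal(unname(betweenness(star)), c(0.5, 0, 0, 0))

  expect_length(betweenness(rin_from_edges(0, list())), 0)
})

test_that("ratio betweenness equals exhaustive path enumeration on random graphs", {
  set.seed(42)
  for (k in 1:12) {
    n <- sample(4:12, 1)
    m <- sample(3:(n * (n - 1) / 2), 1)
    all_pairs <- utils::combn(n, 2)
    pick <- sample(ncol(all_pairs), m)
    edges <- lapply(pick, function(j) as.integer(all_pairs[, j]))
    rin <- rin_from_edges(n, edges)
    got <- betweenness(rin)
    ref <- enumeration_betweenness(rin)
    expect_equal(unname(got), unname(ref[names(got)]), tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("brandes variant matches igraph's betweenness", {
  set.seed(43)
  for (k in 1:6) {
    n <- sample(5:12, 1)
    all_pairs <- utils::combn(n, 2)
    pick <- sample(ncol(all_pairs), sample(4:(ncol(all_pairs)), 1))
    edges <- lapply(pick, function(j) as.integer(all_pairs[, j]))
    rin <- rin_from_edges(n, edges)
    got <- betweenness(rin, method = "brandes")
    g <- igraph::graph_from_data_frame(
      unique(rin$edges[, c("source", "target")]), directed = FALSE,
      vertices = rin$nodes$id)
    ref <- igraph::betweenness(g, directed = FALSE)
    expect_equal(unname(got), unname(ref[names(got)]), tolerance = 1e-9)
  }
})

test_that("multi-edges collapse before path counting", {
  # duplicate edge between 1-2 must not double path counts
  rin <- rin_from_edges(3, list(c(1L, 2L), c(1L, 2L), c(2L, 3L)))
  expect_equal(unname(betweenness(rin)), c(0, 1 / 3, 0))
})
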