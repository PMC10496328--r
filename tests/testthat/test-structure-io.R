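pdb_two_atoms <- paste(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  sep = "\n"
)

test_that("minimal PDB text parses into one model / residue / two atoms", {
  st <- parse_structure(pdb_two_atoms, format = "pdb")
  expect_s3_class(st, "rin_structure")
  expect_length(st$models, 1)
  m <- st$models[[1]]
  expect_equal(nrow(m), 2)
  expect_equal(m$name, c("N", "CA"))
  expect_equal(m$element, c("N", "C"))
  expect_equal(m$x, c(11.104, 11.639))
  expect_equal(unique(paste(m$chain, m$resseq)), "A 1")
})

test_that("malformed records are skipped with a warning, not fatal", {
  txt <- paste(pdb_two_atoms,
               "ATOM      3  C   ALA A   1      garbage  here   nope  1.00  0.00",
               sep = "\n")
  expect_warning(st <- parse_structure(txt, format = "pdb"), "malformed")
  expect_equal(nrow(st$models[[1]]), 2)

  allbad <- "ATOM      1  N   ALA A   x      bad     bad     bad"
  expect_error(parse_structure(allbad, format = "pdb"), "malformed")
  expect_error(parse_structure("REMARK nothing here\nEND", format = "pdb"), "empty")
})

test_that("occupancy outside [0, 1] is clamped with a warning", {
  txt <- "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.50  0.00           N"
  expect_warning(st <- parse_structure(txt, format = "pdb"), "clamped")
  expect_equal(st$models[[1]]$occupancy, 1)
})

test_that("fixtures round-trip through write_pdb / parse_structure", {
  kinds <- list(
    make_fixture("HBOND_PAIR", d = 2.9, angle = 150),
    make_fixture("IONIC_PAIR", d = 3.5),
    make_fixture("PIPI_PAIR", d = 4.4, gamma = 20),
    make_fixture("PICATION_PAIR", d = 4.2, alpha = 30),
    make_fixture("CHAIN", n = 6, conformation = "helix"),
    make_fixture("CHAIN", n = 4, conformation = "extended", model_count = 3)
  )
  for (st in kinds) {
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(st, f)
    st2 <- parse_structure(f)
    expect_length(st2$models, length(st$models))
    for (k in seq_along(st$models)) {
      a <- st$models[[k]]; b <- st2$models[[k]]
      expect_equal(nrow(b), nrow(a))
      expect_equal(b$name, a$name)
      expect_equal(paste(b$chain, b$resseq, b$resname),
                   paste(a$chain, a$resseq, a$resname))
      expect_lt(max(abs(cbind(b$x, b$y, b$z) - cbind(a$x, a$y, a$z))), 1e-3)
    }
  }
})

test_that("500-atom random-coordinate structure round-trips to 1e-3 A", {
  set.seed(31)
  n <- 500
  atoms <- data.frame(
    serial = 1:n, name = "CA", altloc = "", resname = "ALA", chain = "A",
    resseq = 1:n, icode = "", x = runif(n, -99, 99), y = runif(n, -99, 99),
    z = runif(n, -99, 99), occupancy = 1, element = "C", is_hetero = FALSE,
    stringsAsFactors = FALSE
  )
  st <- rinet:::new_structure("rand", list(atoms), "pdb")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st, f)
  st2 <- parse_structure(f)
  m <- st2$models[[1]]
  expect_equal(nrow(m), n)
  expect_lt(max(abs(cbind(m$x, m$y, m$z) - cbind(atoms$x, atoms$y, atoms$z))), 1e-3)
})

test_that("write_pdb emits MODEL records for multi-model and END always", {
  st3 <- make_fixture("CHAIN", n = 3, conformation = "extended", model_count = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st3, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "MODEL")), 3)
  expect_equal(sum(startsWith(lines, "ENDMDL")), 3)
  expect_equal(sum(lines == "END"), 1)

  one <- make_fixture("CHAIN", conformation = "dimer", d = 5)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(rinet:::new_structure("x", list(one$models[[1]][1, ]), "pdb"), f1)
  l1 <- readLines(f1)
  expect_equal(sum(startsWith(l1, "ATOM")), 1)
  expect_equal(sum(l1 == "END"), 1)
})

mmcif_text <- function(model_nums = 1L) {
  rows <- unlist(lapply(model_nums, function(mn) c(
    sprintf("ATOM 1 N N . ALA A 1 ? 11.104 6.134 -6.504 1.00 %d", mn),
    sprintf("ATOM 2 C CA . ALA A 1 ? 11.639 6.071 -5.147 1.00 %d", mn),
    sprintf("HETATM 3 O O . HOH A 99 ? 0.000 0.000 0.000 0.50 %d", mn)
  )))
  paste(c(
    "data_test",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.auth_atom_id", "_atom_site.label_alt_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.pdbx_PDB_model_num",
    rows, "#"
  ), collapse = "\n")
}

test_that("mmCIF _atom_site loop parses, including multi-model and auto-sniff", {
  st <- parse_structure(mmcif_text(), format = "mmcif")
  m <- st$models[[1]]
  expect_equal(nrow(m), 3)
  expect_equal(m$name[1:2], c("N", "CA"))
  expect_equal(m$x[1], 11.104)
  expect_true(m$is_hetero[3])
  expect_equal(m$resname[3], "HOH")

  auto <- parse_structure(mmcif_text())
  expect_equal(auto$source_format, "mmcif")

  multi <- parse_structure(mmcif_text(model_nums = 1:3))
  expect_length(multi$models, 3)
  expect_error(parse_structure("data_x\nloop_\n_cell.length_a\n10\n",
                               format = "mmcif"), "_atom_site")
})

test_that("prepare_model applies altloc, water, hetero and hydrogen policies", {
  mk <- function(name, altloc, occ, resname = "ALA", resseq = 1L, het = FALSE,
                 elem = "C") {
    data.frame(serial = 1L, name = name, altloc = altloc, resname = resname,
               chain = "A", resseq = resseq, icode = "", x = occ, y = 0, z = 0,
               occupancy = occ, element = elem, is_hetero = het,
               stringsAsFactors = FALSE)
  }
  m <- rbind(mk("CA", "A", 0.6), mk("CA", "B", 0.4),
             mk("O", "", 1.0, "HOH", 2L, TRUE, "O"),
             mk("O", "", 1.0, "HOH", 3L, TRUE, "O"),
             mk("FE", "", 1.0, "HEM", 4L, TRUE, "FE"),
             mk("H", "", 1.0, elem = "H"))
  prep <- prepare_model(m, prep_options())
  expect_equal(nrow(prep$atoms[prep$atoms$name == "CA", ]), 1)
  expect_equal(prep$atoms$x[prep$atoms$name == "CA"], 0.6)  # altloc A kept
  expect_false(any(prep$atoms$resname %in% c("HOH", "HEM")))
  expect_true("H" %in% prep$atoms$name)

  prep_first <- prepare_model(m, prep_options(altloc_policy = "first"))
  expect_equal(prep_first$atoms$x[prep_first$atoms$name == "CA"], 0.6)

  prep_het <- prepare_model(m, prep_options(include_hetero = TRUE))
  expect_true("HEM" %in% prep_het$atoms$resname)
  expect_false("HOH" %in% prep_het$atoms$resname)  # waters removed regardless

  prep_noh <- prepare_model(m, prep_options(strip_hydrogens = TRUE))
  expect_false("H" %in% prep_noh$atoms$name)

  # altloc collapse never increases atoms; names unique per residue
  expect_lte(nrow(prep$atoms), nrow(m))
  key <- paste(prep$atoms$res_idx, prep$atoms$name)
  expect_false(any(duplicated(key)))
})

test_that("backbone amide H synthesis places H at 1.01 A on residues 2..n", {
  st <- make_fixture("CHAIN", n = 3, conformation = "extended")
  opts <- prep_options(synthesize_backbone_h = TRUE)
  prep <- prepare_model(st$models[[1]], opts)
  h <- prep$atoms[prep$atoms$name == "H", ]
  expect_equal(nrow(h), 2)                    # residues 2 and 3 only
  expect_setequal(h$res_idx, c(2L, 3L))
  for (i in h$res_idx) {
    N <- prep$atoms[prep$atoms$res_idx == i & prep$atoms$name == "N", ]
    Hi <- h[h$res_idx == i, ]
    d <- sqrt((N$x - Hi$x)^2 + (N$y - Hi$y)^2 + (N$z - Hi$z)^2)
    expect_equal(d, 1.01, tolerance = 0.02)
  }
  # idempotent: preparing the prepared model changes nothing
  prep2 <- prepare_model(prep, opts)
  expect_equal(prep2$atoms[order(prep2$atoms$serial), ],
               prep$atoms[order(prep$atoms$serial), ], ignore_attr = TRUE)
})

test_that("count_residues supports model and per-chain conventions", {
  st <- make_fixture("CHAIN", conformation = "dimer", d = 6)
  expect_equal(count_residues(st), 2L)
  expect_equal(count_residues(st, by = "chain"), c(A = 1L, B = 1L))
})
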