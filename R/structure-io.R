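# Reading PDB / mmCIF structure files into a uniform atom table, applying
# preparation policies (altloc collapse, hetero/water removal, hydrogen
# handling, backbone amide-H synthesis) and writing PDB back out for
# fixture round-trips.
#
# Internal representation: a model is a data.frame of atoms with columns
#   serial, name, altloc, resname, chain, resseq, icode, x, y, z,
#   occupancy, element, is_hetero
# and a structure is a list of such models plus an id. Residue identity is
# the triple (chain, resseq, icode) with author numbering kept verbatim.

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

atom_columns <- function() {
  data.frame(
    serial = integer(0), name = character(0), altloc = character(0),
    resname = character(0), chain = character(0), resseq = integer(0),
    icode = character(0), x = numeric(0), y = numeric(0), z = numeric(0),
    occupancy = numeric(0), element = character(0), is_hetero = logical(0),
    stringsAsFactors = FALSE
  )
}

new_structure <- function(id, models, source_format) {
  structure(list(id = id, models = models, source_format = source_format),
            class = "rin_structure")
}

#' @export
print.rin_structure <- function(x, ...) {
  natoms <- vapply(x$models, nrow, 0L)
  cat(sprintf("<rin_structure '%s': %d model(s), %s atoms, source %s>\n",
              x$id, length(x$models),
              paste(unique(natoms), collapse = "/"), x$source_format))
  invisible(x)
}

#' Parse a PDB or mmCIF structure file
#'
#' Reads a structure file (or literal text) into a multi-model atom table.
#' `format = "auto"` sniffs mmCIF by the presence of a `data_` block or an
#' `_atom_site` loop and falls back to fixed-width PDB. ATOM and HETATM
#' records are parsed; `MODEL`/`ENDMDL` delimit models. Coordinates are
#' kept at full file precision.
#'
#' @param source Path to a file, or a character string containing the file
#'   text (anything with an embedded newline is treated as text).
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`.
#' @param id Structure identifier; defaults to the file stem (or
#'   `"structure"` for literal text).
#' @return An object of class `rin_structure`.
#' @export
parse_structure <- function(source, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  looks_like_text <- grepl("\n", source[1L]) ||
    grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK|data_|loop_|_atom_site)", source[1L])
  if (length(source) == 1L && !looks_like_text) {
    if (!file.exists(source))
      stop(sprintf("parse_structure: cannot read '%s'", source), call. = FALSE)
    lines <- readLines(source, warn = FALSE)
    if (is.null(id)) id <- tools::file_path_sans_ext(basename(source))
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(id)) id <- "structure"
  }
  if (format == "auto") {
    format <- if (any(grepl("^data_", lines)) || any(grepl("_atom_site\\.", lines)))
      "mmcif" else "pdb"
  }
  st <- if (format == "pdb") parse_pdb_lines(lines, id) else parse_mmcif_lines(lines, id)
  if (sum(vapply(st$models, nrow, 0L)) == 0L)
    stop("parse_structure: no atoms found (empty structure)", call. = FALSE)
  check_topology(st)
  st
}

# warn (don't fail) if models of a multi-model file disagree on residues
check_topology <- function(st) {
  if (length(st$models) < 2L) return(invisible(st))
  keys <- lapply(st$models, function(m)
    unique(paste(m$chain, m$resseq, m$icode, m$resname, sep = ":")))
  if (!all(vapply(keys[-1L], identical, TRUE, y = keys[[1L]])))
    warning("models differ in residue topology; treating each model independently",
            call. = FALSE)
  invisible(st)
}

guess_element <- function(name) {
  stripped <- sub("^[0-9']+", "", trimws(name))
  ifelse(nchar(stripped) == 0L, "X", toupper(substr(stripped, 1L, 1L)))
}

parse_pdb_lines <- function(lines, id) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  # model number for every line: MODEL records open a new model
  model_open <- cumsum(startsWith(lines, "MODEL"))
  model_no <- pmax(model_open, 1L)

  al <- lines[is_atom]
  if (length(al) == 0L) return(new_structure(id, list(atom_columns()), "pdb"))
  ml <- model_no[is_atom]

  num <- function(from, to) suppressWarnings(as.numeric(trimws(substr(al, from, to))))
  chr <- function(from, to) trimws(substr(al, from, to))

  df <- data.frame(
    serial = suppressWarnings(as.integer(trimws(substr(al, 7, 11)))),
    name = chr(13, 16),
    altloc = chr(17, 17),
    resname = chr(18, 20),
    chain = chr(22, 22),
    resseq = suppressWarnings(as.integer(trimws(substr(al, 23, 26)))),
    icode = chr(27, 27),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    occupancy = num(55, 60),
    element = chr(77, 78),
    is_hetero = substr(al, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z) | is.na(df$resseq)
  if (all(bad))
    stop("parse_structure: all ATOM/HETATM records are malformed", call. = FALSE)
  if (any(bad)) {
    warning(sprintf("skipping %d malformed ATOM/HETATM record(s)", sum(bad)),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    ml <- ml[!bad]
  }
  df$occupancy[is.na(df$occupancy)] <- 1
  if (any(df$occupancy < 0 | df$occupancy > 1)) {
    warning("occupancy outside [0, 1] clamped", call. = FALSE)
    df$occupancy <- pmin(1, pmax(0, df$occupancy))
  }
  noelem <- df$element == ""
  df$element[noelem] <- guess_element(df$name[noelem])
  df$serial[is.na(df$serial)] <- seq_len(nrow(df))[is.na(df$serial)]

  models <- lapply(split(seq_len(nrow(df)), ml), function(i) {
    m <- df[i, , drop = FALSE]
    rownames(m) <- NULL
    m
  })
  names(models) <- NULL
  new_structure(id, models, "pdb")
}

# --- mmCIF: only the _atom_site loop is consumed ------------------------

cif_tokens <- function(line) {
  # whitespace-separated tokens; '...' and "..." quoting
  out <- character(0)
  n <- nchar(line)
  i <- 1L
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch == "'" || ch == '"') {
      j <- i + 1L
      while (j <= n && substr(line, j, j) != ch) j <- j + 1L
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

parse_mmcif_lines <- function(lines, id) {
  # locate the _atom_site loop
  site_hdr <- grep("^\\s*_atom_site\\.", lines)
  if (length(site_hdr) == 0L)
    stop("parse_structure: mmCIF file has no _atom_site loop", call. = FALSE)
  fields <- sub("^\\s*_atom_site\\.", "", trimws(lines[site_hdr]))
  body_start <- max(site_hdr) + 1L
  body_end <- body_start - 1L
  for (i in body_start:length(lines)) {
    t <- trimws(lines[i])
    if (t == "" || startsWith(t, "_") || startsWith(t, "loop_") ||
        startsWith(t, "#") || startsWith(t, "data_")) break
    body_end <- i
  }
  if (body_end < body_start)
    stop("parse_structure: empty _atom_site loop", call. = FALSE)
  toks <- unlist(lapply(lines[body_start:body_end], cif_tokens), use.names = FALSE)
  nf <- length(fields)
  if (length(toks) %% nf != 0L)
    stop("parse_structure: ragged _atom_site loop", call. = FALSE)
  m <- matrix(toks, ncol = nf, byrow = TRUE)
  colnames(m) <- fields
  col <- function(...) {
    for (nm in c(...)) if (nm %in% fields) return(m[, nm])
    rep("", nrow(m))
  }
  blank <- function(v) ifelse(v %in% c(".", "?"), "", v)
  num <- function(v) suppressWarnings(as.numeric(v))

  occ <- num(col("occupancy"))
  occ[is.na(occ)] <- 1
  if (any(occ < 0 | occ > 1)) {
    warning("occupancy outside [0, 1] clamped", call. = FALSE)
    occ <- pmin(1, pmax(0, occ))
  }
  df <- data.frame(
    serial = suppressWarnings(as.integer(col("id"))),
    name = blank(col("auth_atom_id", "label_atom_id")),
    altloc = blank(col("label_alt_id")),
    resname = blank(col("auth_comp_id", "label_comp_id")),
    chain = blank(col("auth_asym_id", "label_asym_id")),
    resseq = suppressWarnings(as.integer(col("auth_seq_id", "label_seq_id"))),
    icode = blank(col("pdbx_PDB_ins_code")),
    x = num(col("Cartn_x")), y = num(col("Cartn_y")), z = num(col("Cartn_z")),
    occupancy = occ,
    element = blank(col("type_symbol")),
    is_hetero = col("group_PDB") == "HETATM",
    stringsAsFactors = FALSE
  )
  noelem <- df$element == ""
  df$element[noelem] <- guess_element(df$name[noelem])
  df$serial[is.na(df$serial)] <- seq_len(nrow(df))[is.na(df$serial)]
  bad <- !is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z) | is.na(df$resseq)
  if (all(bad)) stop("parse_structure: all _atom_site rows malformed", call. = FALSE)
  if (any(bad)) {
    warning(sprintf("skipping %d malformed _atom_site row(s)", sum(bad)), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  mnum <- col("pdbx_PDB_model_num")[if (any(bad)) !bad else TRUE]
  mnum <- suppressWarnings(as.integer(mnum))
  mnum[is.na(mnum)] <- 1L
  models <- lapply(split(seq_len(nrow(df)), mnum), function(i) {
    mm <- df[i, , drop = FALSE]; rownames(mm) <- NULL; mm
  })
  names(models) <- NULL
  new_structure(id, models, "mmcif")
}

#' Write a structure as fixed-width PDB
#'
#' Emits standard ATOM/HETATM records with coordinates at 3 decimals;
#' multi-model structures get `MODEL`/`ENDMDL` delimiters. Used for
#' fixture round-trips and golden files.
#'
#' @param structure A `rin_structure`.
#' @param path Output file path.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "rin_structure"))
  for (m in structure$models)
    if (!all(is.finite(c(m$x, m$y, m$z))))
      stop("write_pdb: non-finite coordinates", call. = FALSE)
  multi <- length(structure$models) > 1L
  out <- character(0)
  for (k in seq_along(structure$models)) {
    m <- structure$models[[k]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", k))
    rec <- ifelse(m$is_hetero, "HETATM", "ATOM  ")
    # atom-name column convention: names of <4 chars start at column 14
    nm <- ifelse(nchar(m$name) >= 4L, substr(m$name, 1, 4),
                 sprintf(" %-3s", m$name))
    out <- c(out, sprintf(
      "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, m$serial %% 100000L, nm, m$altloc, m$resname, m$chain,
      m$resseq, m$icode, m$x, m$y, m$z, m$occupancy, 0, m$element))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  tryCatch(writeLines(out, path),
           error = function(e) stop(sprintf("write_pdb: cannot write '%s': %s",
                                            path, conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' Preparation options
#'
#' @param altloc_policy How alternate locations are collapsed:
#'   `"highest-occupancy"` keeps, per (residue, atom name), the location
#'   with the largest occupancy (file order breaks ties); `"first"` keeps
#'   the first in file order.
#' @param include_hetero Keep HETATM residues (waters are always removed).
#' @param strip_hydrogens Remove all hydrogen (and deuterium) atoms.
#' @param synthesize_backbone_h Place an amide hydrogen on each non-proline
#'   backbone nitrogen that follows a bonded predecessor (N-H = 1.01 A, in
#'   the peptide plane along the bisector opposite the preceding carbonyl).
#' @return A list of class `prep_options`.
#' @export
prep_options <- function(altloc_policy = c("highest-occupancy", "first"),
                         include_hetero = FALSE,
                         strip_hydrogens = FALSE,
                         synthesize_backbone_h = FALSE) {
  structure(list(
    altloc_policy = match.arg(altloc_policy),
    include_hetero = isTRUE(include_hetero),
    strip_hydrogens = isTRUE(strip_hydrogens),
    synthesize_backbone_h = isTRUE(synthesize_backbone_h)
  ), class = "prep_options")
}

#' Prepare a model for interaction detection
#'
#' Applies the preparation policies and produces a flat residue table plus
#' a flat atom table with residue back-references, ready for spatial
#' indexing. Waters are always removed; residues left without atoms are
#' dropped with a warning. Preparing an already-prepared model is a no-op.
#'
#' @param model One atom data.frame from a `rin_structure` (i.e.
#'   `structure$models[[k]]`), or a `rin_prepared` object.
#' @param options A `prep_options` object.
#' @return An object of class `rin_prepared`: list with `atoms` (atom table
#'   with `res_idx`), `residues` (one row per residue: `idx`, `key`,
#'   `chain`, `resseq`, `icode`, `resname`) and `options`.
#' @export
prepare_model <- function(model, options = prep_options()) {
  df <- if (inherits(model, "rin_prepared")) model$atoms else model
  stopifnot(is.data.frame(df))
  df <- df[, intersect(names(df), names(atom_columns())), drop = FALSE]

  df <- df[!(df$resname %in% WATER_NAMES), , drop = FALSE]
  if (!options$include_hetero) df <- df[!df$is_hetero, , drop = FALSE]
  if (options$strip_hydrogens) df <- df[!(df$element %in% c("H", "D")), , drop = FALSE]

  # altloc collapse: at most one atom per (residue, atom name) afterwards
  akey <- paste(df$chain, df$resseq, df$icode, df$name, sep = "\r")
  ord <- if (options$altloc_policy == "highest-occupancy")
    order(akey, -df$occupancy, seq_len(nrow(df))) else
    order(akey, seq_len(nrow(df)))
  keep_rows <- ord[!duplicated(akey[ord])]
  df <- df[sort(keep_rows), , drop = FALSE]

  if (nrow(df) == 0L)
    stop("prepare_model: no atoms left after preparation", call. = FALSE)

  # residue table: chains in order of appearance, residues by (resseq, icode)
  rkey <- paste(df$chain, df$resseq, df$icode, sep = "\r")
  first_of <- !duplicated(rkey)
  res <- df[first_of, c("chain", "resseq", "icode", "resname"), drop = FALSE]
  chain_order <- match(res$chain, unique(df$chain))
  res <- res[order(chain_order, res$resseq, res$icode), , drop = FALSE]
  res$idx <- seq_len(nrow(res))
  res$key <- paste(res$chain, res$resseq, ifelse(res$icode == "", "_", res$icode),
                   res$resname, sep = ":")
  rownames(res) <- NULL
  res <- res[, c("idx", "key", "chain", "resseq", "icode", "resname")]

  df$res_idx <- match(paste(df$chain, df$resseq, df$icode, sep = "\r"),
                      paste(res$chain, res$resseq, res$icode, sep = "\r"))
  df <- df[order(df$res_idx, seq_len(nrow(df))), , drop = FALSE]
  rownames(df) <- NULL

  prep <- structure(list(atoms = df, residues = res, options = options),
                    class = "rin_prepared")
  if (options$synthesize_backbone_h) prep <- add_backbone_h(prep)
  prep
}

#' @export
print.rin_prepared <- function(x, ...) {
  cat(sprintf("<rin_prepared: %d residues, %d atoms>\n",
              nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

# Amide-H synthesis: H = N + 1.01 * unit(unit(N - C_prev) + unit(N - CA)).
# Prolines, chain starts and residues that already carry an amide H are
# skipped, which also makes preparation idempotent.
add_backbone_h <- function(prep) {
  atoms <- prep$atoms
  res <- prep$residues
  new_rows <- list()
  next_serial <- max(atoms$serial, 0L) + 1L
  for (i in seq_len(nrow(res))) {
    if (res$resname[i] == "PRO") next
    ai <- atoms[atoms$res_idx == i, , drop = FALSE]
    if (any(ai$name == "H")) next
    nrow_N <- which(ai$name == "N")
    nrow_CA <- which(ai$name == "CA")
    if (length(nrow_N) != 1L || length(nrow_CA) != 1L) next
    # bonded predecessor: same chain, previous residue index, resseq - 1
    if (i == 1L || res$chain[i - 1L] != res$chain[i] ||
        res$resseq[i - 1L] != res$resseq[i] - 1L) next
    ap <- atoms[atoms$res_idx == i - 1L, , drop = FALSE]
    crow <- which(ap$name == "C")
    if (length(crow) != 1L) next
    N <- c(ai$x[nrow_N], ai$y[nrow_N], ai$z[nrow_N])
    CA <- c(ai$x[nrow_CA], ai$y[nrow_CA], ai$z[nrow_CA])
    Cp <- c(ap$x[crow], ap$y[crow], ap$z[crow])
    dir <- unit_vec(unit_vec(N - Cp) + unit_vec(N - CA))
    H <- N + 1.01 * dir
    row <- ai[nrow_N, , drop = FALSE]
    row$serial <- next_serial; next_serial <- next_serial + 1L
    row$name <- "H"; row$element <- "H"; row$altloc <- ""
    row$x <- H[1]; row$y <- H[2]; row$z <- H[3]
    row$occupancy <- 1
    new_rows[[length(new_rows) + 1L]] <- row
  }
  if (length(new_rows) > 0L) {
    atoms <- rbind(atoms, do.call(rbind, new_rows))
    atoms <- atoms[order(atoms$res_idx), , drop = FALSE]
    rownames(atoms) <- NULL
    prep$atoms <- atoms
  }
  prep
}

#' Count amino-acid residues
#'
#' Counts residues of the polymer (non-hetero, non-water) part of a model,
#' either for the whole model or per chain. Both conventions are exposed
#' because published per-entry residue counts do not always state which
#' one they use.
#'
#' @param structure A `rin_structure`.
#' @param model Model number (default 1).
#' @param by `"model"` for a single total, `"chain"` for a named per-chain
#'   vector.
#' @return Integer count, or named integer vector for `by = "chain"`.
#' @export
count_residues <- function(structure, model = 1L, by = c("model", "chain")) {
  by <- match.arg(by)
  m <- structure$models[[model]]
  m <- m[!m$is_hetero & !(m$resname %in% WATER_NAMES), , drop = FALSE]
  key <- paste(m$chain, m$resseq, m$icode, sep = "\r")
  if (by == "model") return(length(unique(key)))
  vapply(split(key, m$chain), function(k) length(unique(k)), 0L)
}
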