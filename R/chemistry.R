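# Per-residue chemistry tables: hydrogen-bond donors/acceptors, charged
# groups, aromatic rings, hydrophobic side-chain atoms and van der Waals
# radii. Tables are data (overridable); unknown residue names simply get
# no annotation, so they can only form C-alpha or van der Waals contacts.

# Bondi radii (A); elements not listed fall back to 1.70
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.10, P = 1.80)

#' Built-in chemistry tables
#'
#' Returns the default per-residue annotation tables used by
#' [annotate_chemistry()]. Each component maps a 3-letter residue code to
#' atom-name sets. Exposed so callers can inspect or substitute them.
#'
#' @return A list with components `donors`, `acceptors`, `cations`,
#'   `anions`, `rings`, `hydrophobic`.
#' @export
chemistry_tables <- function() {
  list(
    # side-chain donor atoms (backbone N added programmatically, PRO excluded)
    donors = list(
      ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
      HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH",
      TRP = "NE1", CYS = "SG"
    ),
    # side-chain acceptor atoms (backbone O/OXT added programmatically)
    acceptors = list(
      ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
      HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH",
      MET = "SD", CYS = "SG"
    ),
    cations = list(
      LYS = list("NZ"),
      ARG = list(c("CZ", "NH1", "NH2", "NE")),
      HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))  # used only if enabled
    ),
    anions = list(
      ASP = list(c("CG", "OD1", "OD2")),
      GLU = list(c("CD", "OE1", "OE2"))
      # C-terminal carboxylate {C, O, OXT} added programmatically when OXT present
    ),
    rings = list(
      PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
      TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
      HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
      TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
                 c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
    ),
    # side-chain C/S atoms counted as hydrophobic; polar-terminal side
    # chains (LYS, ARG) contribute only their aliphatic stem
    hydrophobic = list(
      ALA = "CB", VAL = c("CB", "CG1", "CG2"),
      LEU = c("CB", "CG", "CD1", "CD2"), ILE = c("CB", "CG1", "CG2", "CD1"),
      PRO = c("CB", "CG", "CD"),
      PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
      MET = c("CB", "CG", "SD", "CE"),
      TRP = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
      CYS = c("CB", "SG"),
      LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG")
    )
  )
}

#' Annotate a prepared model with interaction chemistry
#'
#' Applies the built-in tables to the residues actually present. Atoms
#' named in a table but absent from the structure are skipped; charged
#' groups and rings missing any member atom are dropped. Hydrogens are
#' attached to donors by proximity (within 1.3 A), which covers both file
#' hydrogens and synthesized backbone amide H.
#'
#' @param prep A `rin_prepared` model.
#' @param params A `bond_params` object (controls whether protonated
#'   histidine counts as a cation).
#' @param tables Chemistry tables, defaulting to [chemistry_tables()].
#' @return An object of class `rin_chemistry`: list with `donors` (data
#'   frame `res_idx`, `atom` (row index into `prep$atoms`), and list column
#'   `h_atoms`), `acceptors` (data frame `res_idx`, `atom`), `cations` /
#'   `anions` (lists of `res_idx` + atom row sets), `rings` (list of
#'   `res_idx` + atom rows), `hydrophobic` (data frame), `vdw_radius`
#'   (numeric per atom row).
#' @export
annotate_chemistry <- function(prep, params = bond_params(),
                               tables = chemistry_tables()) {
  atoms <- prep$atoms
  res <- prep$residues
  n_res <- nrow(res)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  atom_rows_of <- split(seq_len(nrow(atoms)), factor(atoms$res_idx, levels = seq_len(n_res)))

  don_res <- integer(0); don_atom <- integer(0); don_h <- list()
  acc_res <- integer(0); acc_atom <- integer(0)
  cations <- list(); anions <- list(); rings <- list()
  hyd_res <- integer(0); hyd_atom <- integer(0)

  for (i in seq_len(n_res)) {
    rows <- atom_rows_of[[i]]
    if (length(rows) == 0L) next
    nm <- atoms$name[rows]
    rn <- res$resname[i]
    find <- function(wanted) rows[match(wanted, nm, nomatch = 0L)][
      match(wanted, nm, nomatch = 0L) > 0L]

    h_rows <- rows[atoms$element[rows] %in% c("H", "D")]

    # donors: backbone N (not PRO) + side-chain table
    dset <- character(0)
    if (rn != "PRO" && "N" %in% nm) dset <- "N"
    dset <- c(dset, intersect(tables$donors[[rn]], nm))
    for (d in dset) {
      drow <- rows[match(d, nm)]
      if (length(h_rows) > 0L) {
        dd <- sqrt(colSums((t(coords[h_rows, , drop = FALSE]) - coords[drow, ])^2))
        hh <- h_rows[dd <= 1.3]
      } else hh <- integer(0)
      don_res <- c(don_res, i); don_atom <- c(don_atom, drow)
      don_h[[length(don_h) + 1L]] <- hh
    }

    # acceptors: backbone O/OXT + side-chain table
    aset <- c(intersect(c("O", "OXT"), nm), intersect(tables$acceptors[[rn]], nm))
    for (a in aset) {
      acc_res <- c(acc_res, i); acc_atom <- c(acc_atom, rows[match(a, nm)])
    }

    # charged groups: all member atoms must be present
    cat_groups <- tables$cations[[rn]]
    if (rn == "HIS" && !isTRUE(params$include_his_cation)) cat_groups <- NULL
    for (g in cat_groups) {
      gr <- find(g)
      if (length(gr) == length(g))
        cations[[length(cations) + 1L]] <- list(res_idx = i, atoms = gr)
    }
    for (g in tables$anions[[rn]]) {
      gr <- find(g)
      if (length(gr) == length(g))
        anions[[length(anions) + 1L]] <- list(res_idx = i, atoms = gr)
    }
    # C-terminal carboxylate
    if (all(c("C", "O", "OXT") %in% nm))
      anions[[length(anions) + 1L]] <- list(res_idx = i,
                                            atoms = find(c("C", "O", "OXT")))

    for (g in tables$rings[[rn]]) {
      gr <- find(g)
      if (length(gr) == length(g))
        rings[[length(rings) + 1L]] <- list(res_idx = i, atoms = gr)
    }

    hset <- intersect(tables$hydrophobic[[rn]], nm)
    if (length(hset) > 0L) {
      hyd_res <- c(hyd_res, rep(i, length(hset)))
      hyd_atom <- c(hyd_atom, rows[match(hset, nm)])
    }
  }

  vdw_radius <- unname(VDW_RADII[atoms$element])
  vdw_radius[is.na(vdw_radius)] <- 1.70

  donors <- data.frame(res_idx = don_res, atom = don_atom)
  donors$h_atoms <- if (length(don_h) > 0L) don_h else vector("list", 0L)

  structure(list(
    donors = donors,
    acceptors = data.frame(res_idx = acc_res, atom = acc_atom),
    cations = cations, anions = anions, rings = rings,
    hydrophobic = data.frame(res_idx = hyd_res, atom = hyd_atom),
    vdw_radius = vdw_radius
  ), class = "rin_chemistry")
}
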