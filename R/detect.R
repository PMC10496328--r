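# The seven interaction detectors. Each maps its geometric criterion onto
# closed-ball radius queries against a kd-tree built over the relevant
# atom subset (acceptors, heavy atoms, hydrophobic atoms, CA atoms, ring
# and charged-group centroids as pseudo-points), so detection scales with
# neighbourhood size rather than all atom pairs.
#
# Conventions shared by all detectors:
#   * contacts are undirected and canonical: res_a precedes res_b in the
#     prepared model's residue ordering;
#   * same-residue pairs are never contacts;
#   * sequence-separation gating applies only to CA contacts, so e.g.
#     helical i -> i+4 backbone hydrogen bonds survive;
#   * all threshold comparisons are closed (boundary contacts count);
#   * bond types are independent layers -- the same atom pair may appear
#     under several types before policy filtering.

empty_contacts <- function() {
  data.frame(
    bond_type = character(0), res_a = character(0), res_b = character(0),
    atoms_a = character(0), atoms_b = character(0),
    distance = numeric(0), angle = numeric(0), energy = numeric(0),
    role_a = character(0), role_b = character(0),
    res_a_idx = integer(0), res_b_idx = integer(0), sigma = numeric(0),
    stringsAsFactors = FALSE
  )
}

# assemble + canonicalize (res_a_idx < res_b_idx; swap atom/role columns)
make_contacts <- function(type, prep, ia, ib, atoms_a, atoms_b, distance,
                          angle, role_a, role_b, sigma = NA_real_, params) {
  if (length(ia) == 0L) return(empty_contacts())
  swap <- ia > ib
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
  tmpc <- atoms_a[swap]; atoms_a[swap] <- atoms_b[swap]; atoms_b[swap] <- tmpc
  tmpc <- role_a[swap]; role_a[swap] <- role_b[swap]; role_b[swap] <- tmpc
  if (length(sigma) == 1L) sigma <- rep(sigma, length(ia))
  df <- data.frame(
    bond_type = rep(type, length(ia)),
    res_a = prep$residues$key[ia], res_b = prep$residues$key[ib],
    atoms_a = atoms_a, atoms_b = atoms_b,
    distance = distance, angle = angle,
    energy = energy_for(type, distance, angle, sigma, params),
    role_a = role_a, role_b = role_b,
    res_a_idx = ia, res_b_idx = ib, sigma = sigma,
    stringsAsFactors = FALSE
  )
  df[order(df$res_a_idx, df$res_b_idx, df$atoms_a, df$atoms_b), , drop = FALSE]
}

finish_contacts <- function(df) {
  df <- df[order(df$res_a_idx, df$res_b_idx, df$bond_type,
                 df$atoms_a, df$atoms_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

atom_xyz <- function(prep, rows) {
  as.matrix(prep$atoms[rows, c("x", "y", "z"), drop = FALSE])
}

#' Detect hydrogen bonds
#'
#' A donor D and acceptor A of distinct residues form a hydrogen bond when
#' `|D - A| <= d_max` and -- if the donor carries hydrogens and
#' `require_h` is on -- the best D-H...A angle (the angle at H, maximized
#' over the donor's hydrogens) is `>= angle_min_deg`. With `require_h`
#' off, detection is distance-only and no angle is recorded.
#'
#' @param prep A `rin_prepared` model.
#' @param chem A `rin_chemistry` annotation.
#' @param params A `bond_params` object.
#' @return A contact data frame (one row per donor/acceptor atom pair).
#' @export
detect_hydrogen_bonds <- function(prep, chem, params = bond_params()) {
  don <- chem$donors; acc <- chem$acceptors
  if (nrow(don) == 0L || nrow(acc) == 0L) return(empty_contacts())
  p <- params$hbond
  acc_xyz <- atom_xyz(prep, acc$atom)
  idx <- build_index(acc_xyz, seq_len(nrow(acc)))
  out <- list()
  for (k in seq_len(nrow(don))) {
    if (isTRUE(p$require_h) && length(don$h_atoms[[k]]) == 0L) next
    D <- atom_xyz(prep, don$atom[k])[1, ]
    hits <- query_radius(idx, D, p$d_max)
    hits <- hits[acc$res_idx[hits] != don$res_idx[k]]
    if (length(hits) == 0L) next
    for (h in hits) {
      A <- acc_xyz[h, ]
      d <- vec_norm(A - D)
      ang <- NA_real_
      if (isTRUE(p$require_h)) {
        hs <- don$h_atoms[[k]]
        angs <- vapply(hs, function(hr) {
          H <- atom_xyz(prep, hr)[1, ]
          angle_deg(D, H, A)
        }, 0)
        ang <- max(angs)
        if (ang < p$angle_min_deg) next
      }
      out[[length(out) + 1L]] <- list(
        ia = don$res_idx[k], ib = acc$res_idx[h],
        aa = prep$atoms$name[don$atom[k]], ab = acc$atom[h],
        d = d, ang = ang)
    }
  }
  if (length(out) == 0L) return(empty_contacts())
  make_contacts(
    "HBOND", prep,
    ia = vapply(out, `[[`, 0L, "ia"), ib = vapply(out, `[[`, 0L, "ib"),
    atoms_a = vapply(out, `[[`, "", "aa"),
    atoms_b = prep$atoms$name[vapply(out, `[[`, 0L, "ab")],
    distance = vapply(out, `[[`, 0, "d"), angle = vapply(out, `[[`, 0, "ang"),
    role_a = rep("donor", length(out)), role_b = rep("acceptor", length(out)),
    params = params
  ) |> finish_contacts()
}

#' Detect van der Waals contacts
#'
#' Heavy-atom pairs (backbone and side chain) of distinct residues whose
#' surface distance `d - (r_i + r_j)` is at most `surface_tol`, with Bondi
#' radii per element. Pairs already reported as hydrogen bonds are still
#' reported here: bond types are independent layers.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return A contact data frame (one row per atom pair).
#' @export
detect_vdw <- function(prep, chem, params = bond_params()) {
  heavy <- which(!(prep$atoms$element %in% c("H", "D")))
  if (length(heavy) < 2L) return(empty_contacts())
  rad <- chem$vdw_radius[heavy]
  xyz <- atom_xyz(prep, heavy)
  rmax <- max(rad)
  search_r <- 2 * rmax + params$vdw$surface_tol
  idx <- build_index(xyz, seq_along(heavy))
  res_of <- prep$atoms$res_idx[heavy]
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (k in seq_along(heavy)) {
    hits <- query_radius(idx, xyz[k, ], search_r)
    hits <- hits[hits > k & res_of[hits] != res_of[k]]
    if (length(hits) == 0L) next
    dd <- sqrt(colSums((t(xyz[hits, , drop = FALSE]) - xyz[k, ])^2))
    # summed form (d <= r_i + r_j + tol) keeps the closed boundary exact
    ok <- dd <= rad[k] + rad[hits] + params$vdw$surface_tol
    out_i <- c(out_i, rep(k, sum(ok)))
    out_j <- c(out_j, hits[ok])
    out_d <- c(out_d, dd[ok])
  }
  if (length(out_i) == 0L) return(empty_contacts())
  rows_i <- heavy[out_i]; rows_j <- heavy[out_j]
  make_contacts(
    "VDW", prep,
    ia = res_of[out_i], ib = res_of[out_j],
    atoms_a = prep$atoms$name[rows_i], atoms_b = prep$atoms$name[rows_j],
    distance = out_d, angle = rep(NA_real_, length(out_d)),
    role_a = rep("vdw", length(out_d)), role_b = rep("vdw", length(out_d)),
    sigma = rad[out_i] + rad[out_j], params = params
  ) |> finish_contacts()
}

group_centroid <- function(prep, rows) colMeans(atom_xyz(prep, rows))

#' Detect ionic bridges
#'
#' A positively charged group (Lys NZ, Arg guanidinium, optionally
#' protonated His) and a negatively charged group (Asp/Glu carboxylate,
#' C-terminal carboxylate) of distinct residues form an ionic bridge when
#' their group centroids lie within `d_max`.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return A contact data frame (one row per group pair).
#' @export
detect_ionic <- function(prep, chem, params = bond_params()) {
  if (length(chem$cations) == 0L || length(chem$anions) == 0L)
    return(empty_contacts())
  ani_c <- t(vapply(chem$anions, function(g) group_centroid(prep, g$atoms), numeric(3)))
  idx <- build_index(ani_c, seq_along(chem$anions))
  out <- list()
  for (k in seq_along(chem$cations)) {
    cg <- chem$cations[[k]]
    cc <- group_centroid(prep, cg$atoms)
    hits <- query_radius(idx, cc, params$ionic$d_max)
    for (h in hits) {
      ag <- chem$anions[[h]]
      if (ag$res_idx == cg$res_idx) next
      out[[length(out) + 1L]] <- list(
        ia = cg$res_idx, ib = ag$res_idx,
        aa = paste(prep$atoms$name[cg$atoms], collapse = ","),
        ab = paste(prep$atoms$name[ag$atoms], collapse = ","),
        d = vec_norm(ani_c[h, ] - cc))
    }
  }
  if (length(out) == 0L) return(empty_contacts())
  make_contacts(
    "IONIC", prep,
    ia = vapply(out, `[[`, 0L, "ia"), ib = vapply(out, `[[`, 0L, "ib"),
    atoms_a = vapply(out, `[[`, "", "aa"), atoms_b = vapply(out, `[[`, "", "ab"),
    distance = vapply(out, `[[`, 0, "d"),
    angle = rep(NA_real_, length(out)),
    role_a = rep("cation", length(out)), role_b = rep("anion", length(out)),
    params = params
  ) |> finish_contacts()
}

model_rings <- function(prep, chem) {
  lapply(chem$rings, function(g) {
    fr <- ring_frame(atom_xyz(prep, g$atoms), g$atoms)
    list(res_idx = g$res_idx, atoms = g$atoms,
         centroid = fr$centroid, normal = fr$normal)
  })
}

#' Detect pi-pi stacks
#'
#' Aromatic ring pairs of distinct residues with centroid distance within
#' `d_max` whose interplanar angle is either small (parallel stack,
#' `<= parallel_max_deg`) or large (T-shaped, `>= tshape_min_deg`).
#' Tryptophan contributes both of its rings independently.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return A contact data frame (one row per ring pair).
#' @export
detect_pipi <- function(prep, chem, params = bond_params()) {
  rings <- model_rings(prep, chem)
  if (length(rings) < 2L) return(empty_contacts())
  p <- params$pipi
  cen <- t(vapply(rings, `[[`, numeric(3), "centroid"))
  idx <- build_index(cen, seq_along(rings))
  out <- list()
  for (k in seq_along(rings)) {
    hits <- query_radius(idx, cen[k, ], p$d_max)
    for (h in hits[hits > k]) {
      if (rings[[h]]$res_idx == rings[[k]]$res_idx) next
      gamma <- plane_angle_deg(rings[[k]]$normal, rings[[h]]$normal)
      if (!(gamma <= p$parallel_max_deg || gamma >= p$tshape_min_deg)) next
      out[[length(out) + 1L]] <- list(
        ia = rings[[k]]$res_idx, ib = rings[[h]]$res_idx,
        aa = paste(prep$atoms$name[rings[[k]]$atoms], collapse = ","),
        ab = paste(prep$atoms$name[rings[[h]]$atoms], collapse = ","),
        d = vec_norm(cen[h, ] - cen[k, ]), ang = gamma)
    }
  }
  if (length(out) == 0L) return(empty_contacts())
  make_contacts(
    "PIPI", prep,
    ia = vapply(out, `[[`, 0L, "ia"), ib = vapply(out, `[[`, 0L, "ib"),
    atoms_a = vapply(out, `[[`, "", "aa"), atoms_b = vapply(out, `[[`, "", "ab"),
    distance = vapply(out, `[[`, 0, "d"), angle = vapply(out, `[[`, 0, "ang"),
    role_a = rep("ring", length(out)), role_b = rep("ring", length(out)),
    params = params
  ) |> finish_contacts()
}

#' Detect pi-cation interactions
#'
#' A ring and a cationic group of distinct residues interact when the
#' group centroid lies within `d_max` of the ring centroid and the angle
#' between the ring normal and the centroid-to-cation direction (folded to
#' `[0, 90]`) is at most `alpha_max_deg`.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return A contact data frame (one row per ring/cation-group pair).
#' @export
detect_pication <- function(prep, chem, params = bond_params()) {
  rings <- model_rings(prep, chem)
  if (length(rings) == 0L || length(chem$cations) == 0L) return(empty_contacts())
  p <- params$pication
  cen <- t(vapply(rings, `[[`, numeric(3), "centroid"))
  idx <- build_index(cen, seq_along(rings))
  out <- list()
  for (k in seq_along(chem$cations)) {
    cg <- chem$cations[[k]]
    cc <- group_centroid(prep, cg$atoms)
    hits <- query_radius(idx, cc, p$d_max)
    for (h in hits) {
      rg <- rings[[h]]
      if (rg$res_idx == cg$res_idx) next
      v <- cc - rg$centroid
      d <- vec_norm(v)
      if (d < 1e-9) next
      alpha <- acos(min(1, abs(sum(rg$normal * (v / d))))) * 180 / pi
      if (alpha > p$alpha_max_deg) next
      out[[length(out) + 1L]] <- list(
        ia = rg$res_idx, ib = cg$res_idx,
        aa = paste(prep$atoms$name[rg$atoms], collapse = ","),
        ab = paste(prep$atoms$name[cg$atoms], collapse = ","),
        d = d, ang = alpha)
    }
  }
  if (length(out) == 0L) return(empty_contacts())
  make_contacts(
    "PICATION", prep,
    ia = vapply(out, `[[`, 0L, "ia"), ib = vapply(out, `[[`, 0L, "ib"),
    atoms_a = vapply(out, `[[`, "", "aa"), atoms_b = vapply(out, `[[`, "", "ab"),
    distance = vapply(out, `[[`, 0, "d"), angle = vapply(out, `[[`, 0, "ang"),
    role_a = rep("ring", length(out)), role_b = rep("cation", length(out)),
    params = params
  ) |> finish_contacts()
}

#' Detect hydrophobic interactions
#'
#' Pairs of hydrophobic side-chain atoms (C or S) of distinct residues
#' within `d_max`; one contact per residue pair, reporting the
#' minimal-distance atom pair.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return A contact data frame (one row per residue pair).
#' @export
detect_hydrophobic <- function(prep, chem, params = bond_params()) {
  hyd <- chem$hydrophobic
  if (nrow(hyd) < 2L) return(empty_contacts())
  xyz <- atom_xyz(prep, hyd$atom)
  idx <- build_index(xyz, seq_len(nrow(hyd)))
  cand <- list()
  for (k in seq_len(nrow(hyd))) {
    hits <- query_radius(idx, xyz[k, ], params$hydrophobic$d_max)
    hits <- hits[hits > k & hyd$res_idx[hits] != hyd$res_idx[k]]
    for (h in hits) {
      cand[[length(cand) + 1L]] <- c(k, h, vec_norm(xyz[h, ] - xyz[k, ]))
    }
  }
  if (length(cand) == 0L) return(empty_contacts())
  cm <- do.call(rbind, cand)
  ra <- hyd$res_idx[cm[, 1]]; rb <- hyd$res_idx[cm[, 2]]
  lo <- pmin(ra, rb); hi <- pmax(ra, rb)
  pair <- paste(lo, hi)
  na <- prep$atoms$name[hyd$atom[cm[, 1]]]
  nb <- prep$atoms$name[hyd$atom[cm[, 2]]]
  keep <- order(pair, cm[, 3], pmin(na, nb), pmax(na, nb))
  keep <- keep[!duplicated(pair[keep])]
  make_contacts(
    "HYDROPHOBIC", prep,
    ia = ra[keep], ib = rb[keep],
    atoms_a = na[keep], atoms_b = nb[keep],
    distance = cm[keep, 3], angle = rep(NA_real_, length(keep)),
    role_a = rep("hydrophobic", length(keep)),
    role_b = rep("hydrophobic", length(keep)),
    params = params
  ) |> finish_contacts()
}

#' Detect C-alpha contacts
#'
#' CA atom pairs within `d_max`, gated by sequence separation for pairs on
#' the same chain (`|resseq difference| >= seq_sep_generic`); inter-chain
#' pairs are always eligible. CA contacts are topological edges with
#' energy 0 by convention.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return A contact data frame (one row per residue pair).
#' @export
detect_calpha_contacts <- function(prep, chem, params = bond_params()) {
  ca_rows <- which(prep$atoms$name == "CA")
  missing <- setdiff(prep$residues$idx, prep$atoms$res_idx[ca_rows])
  if (length(missing) > 0L)
    warning(sprintf("%d residue(s) lack a CA atom and are skipped", length(missing)),
            call. = FALSE)
  if (length(ca_rows) < 2L) return(empty_contacts())
  xyz <- atom_xyz(prep, ca_rows)
  res_i <- prep$atoms$res_idx[ca_rows]
  chain <- prep$residues$chain[res_i]
  seqn <- prep$residues$resseq[res_i]
  idx <- build_index(xyz, seq_along(ca_rows))
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (k in seq_along(ca_rows)) {
    hits <- query_radius(idx, xyz[k, ], params$ca_contact$d_max)
    hits <- hits[hits > k & res_i[hits] != res_i[k]]
    ok <- chain[hits] != chain[k] |
      abs(seqn[hits] - seqn[k]) >= params$seq_sep_generic
    hits <- hits[ok]
    if (length(hits) == 0L) next
    dd <- sqrt(colSums((t(xyz[hits, , drop = FALSE]) - xyz[k, ])^2))
    out_i <- c(out_i, rep(k, length(hits)))
    out_j <- c(out_j, hits)
    out_d <- c(out_d, dd)
  }
  if (length(out_i) == 0L) return(empty_contacts())
  make_contacts(
    "CA_CONTACT", prep,
    ia = res_i[out_i], ib = res_i[out_j],
    atoms_a = rep("CA", length(out_i)), atoms_b = rep("CA", length(out_i)),
    distance = out_d, angle = rep(NA_real_, length(out_i)),
    role_a = rep("ca", length(out_i)), role_b = rep("ca", length(out_i)),
    params = params
  ) |> finish_contacts()
}

#' Keep the strongest contacts per residue pair
#'
#' `"all"` keeps everything; `"best-per-type"` keeps, for each (residue
#' pair, bond type), the lowest-energy contact; `"best-overall"` keeps a
#' single lowest-energy contact per residue pair across all types. Ties
#' break on smaller distance, then lexicographic atom names.
#'
#' @param contacts A contact data frame.
#' @param policy One of `"all"`, `"best-per-type"`, `"best-overall"`.
#' @return The filtered contact data frame.
#' @export
apply_policy <- function(contacts, policy = c("all", "best-per-type", "best-overall")) {
  policy <- match.arg(policy)
  if (policy == "all" || nrow(contacts) == 0L) return(contacts)
  key <- if (policy == "best-per-type")
    paste(contacts$res_a_idx, contacts$res_b_idx, contacts$bond_type)
  else paste(contacts$res_a_idx, contacts$res_b_idx)
  ord <- order(key, contacts$energy, contacts$distance,
               contacts$atoms_a, contacts$atoms_b)
  keep <- ord[!duplicated(key[ord])]
  finish_contacts(contacts[sort(keep), , drop = FALSE])
}

BOND_TYPES <- c("hbond", "vdw", "ionic", "pipi", "pication", "hydrophobic")

#' Run a set of detectors over a prepared model
#'
#' @param prep A `rin_prepared` model.
#' @param params A `bond_params` object; its `policy` field selects the
#'   contact filtering applied after detection.
#' @param types Character vector of detectors to run: any of `"hbond"`,
#'   `"vdw"`, `"ionic"`, `"pipi"`, `"pication"`, `"hydrophobic"`,
#'   `"ca_contact"`. Default: all specific bonds (no CA contact map).
#' @param chem Optional pre-computed `rin_chemistry`.
#' @return A contact data frame combining all requested detectors, after
#'   the policy filter.
#' @export
detect_contacts <- function(prep, params = bond_params(), types = BOND_TYPES,
                            chem = NULL) {
  bad <- setdiff(types, c(BOND_TYPES, "ca_contact"))
  if (length(bad) > 0L)
    stop(sprintf("detect_contacts: unknown bond type(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (is.null(chem)) chem <- annotate_chemistry(prep, params)
  fns <- list(
    hbond = detect_hydrogen_bonds, vdw = detect_vdw, ionic = detect_ionic,
    pipi = detect_pipi, pication = detect_pication,
    hydrophobic = detect_hydrophobic, ca_contact = detect_calpha_contacts
  )
  parts <- lapply(types, function(t) fns[[t]](prep, chem, params))
  contacts <- finish_contacts(do.call(rbind, c(list(empty_contacts()), parts)))
  apply_policy(contacts, params$policy)
}
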