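# Independent brute-force reference implementations used to cross-check
# the kd-tree-backed detectors, plus a random-model generator. These
# deliberately use exhaustive all-pairs scans and their own geometry so
# that agreement with the package is a two-route check.

oracle_radius <- function(coords, center, r) {
  d <- sqrt(colSums((t(coords) - center)^2))
  which(d <= r)
}

oracle_nearest <- function(coords, center) {
  d <- sqrt(colSums((t(coords) - center)^2))
  which(d == min(d))[1L]  # rows generated with ids = row numbers
}

xyz_of <- function(prep, rows) as.matrix(prep$atoms[rows, c("x", "y", "z"), drop = FALSE])

o_angle <- function(a, b, c) {
  u <- a - b; w <- c - b
  acos(min(1, max(-1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
}

# contact "signature" set for comparing detector output with an oracle
contact_sig <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$bond_type, df$res_a, df$res_b, df$atoms_a, df$atoms_b,
             sprintf("%.6f", df$distance)))
}

sig <- function(type, prep, ia, ib, aa, ab, d) {
  if (length(ia) == 0L) return(character(0))
  swap <- ia > ib
  tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
  tmp <- aa[swap]; aa[swap] <- ab[swap]; ab[swap] <- tmp
  sort(paste(type, prep$residues$key[ia], prep$residues$key[ib], aa, ab,
             sprintf("%.6f", d)))
}

oracle_hbond <- function(prep, chem, params) {
  don <- chem$donors; acc <- chem$acceptors
  p <- params$hbond
  ia <- integer(0); ib <- integer(0); aa <- character(0); ab <- character(0)
  dd <- numeric(0)
  for (k in seq_len(nrow(don))) {
    if (isTRUE(p$require_h) && length(don$h_atoms[[k]]) == 0L) next
    D <- xyz_of(prep, don$atom[k])[1, ]
    for (h in seq_len(nrow(acc))) {
      if (acc$res_idx[h] == don$res_idx[k]) next
      A <- xyz_of(prep, acc$atom[h])[1, ]
      d <- sqrt(sum((A - D)^2))
      if (d > p$d_max) next
      if (isTRUE(p$require_h)) {
        best <- max(vapply(don$h_atoms[[k]], function(hr)
          o_angle(D, xyz_of(prep, hr)[1, ], A), 0))
        if (best < p$angle_min_deg) next
      }
      ia <- c(ia, don$res_idx[k]); ib <- c(ib, acc$res_idx[h])
      aa <- c(aa, prep$atoms$name[don$atom[k]])
      ab <- c(ab, prep$atoms$name[acc$atom[h]])
      dd <- c(dd, d)
    }
  }
  sig("HBOND", prep, ia, ib, aa, ab, dd)
}

oracle_vdw <- function(prep, chem, params) {
  heavy <- which(!(prep$atoms$element %in% c("H", "D")))
  rad <- chem$vdw_radius[heavy]
  xyz <- xyz_of(prep, heavy)
  res <- prep$atoms$res_idx[heavy]
  ia <- integer(0); ib <- integer(0); aa <- character(0); ab <- character(0)
  dd <- numeric(0)
  n <- length(heavy)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (res[i] == res[j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= rad[i] + rad[j] + params$vdw$surface_tol) {
      ia <- c(ia, res[i]); ib <- c(ib, res[j])
      aa <- c(aa, prep$atoms$name[heavy[i]]); ab <- c(ab, prep$atoms$name[heavy[j]])
      dd <- c(dd, d)
    }
  }
  sig("VDW", prep, ia, ib, aa, ab, dd)
}

oracle_ionic <- function(prep, chem, params) {
  ia <- integer(0); ib <- integer(0); aa <- character(0); ab <- character(0)
  dd <- numeric(0)
  for (cg in chem$cations) for (ag in chem$anions) {
    if (cg$res_idx == ag$res_idx) next
    cc <- colMeans(xyz_of(prep, cg$atoms))
    ac <- colMeans(xyz_of(prep, ag$atoms))
    d <- sqrt(sum((cc - ac)^2))
    if (d > params$ionic$d_max) next
    ia <- c(ia, cg$res_idx); ib <- c(ib, ag$res_idx)
    aa <- c(aa, paste(prep$atoms$name[cg$atoms], collapse = ","))
    ab <- c(ab, paste(prep$atoms$name[ag$atoms], collapse = ","))
    dd <- c(dd, d)
  }
  sig("IONIC", prep, ia, ib, aa, ab, dd)
}

# plane fit via smallest-variance eigenvector (independent of ring_frame)
o_plane_normal <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(c0), symmetric = TRUE)
  ev$vectors[, 3L]
}

oracle_rings <- function(prep, chem) {
  lapply(chem$rings, function(g) {
    xyz <- xyz_of(prep, g$atoms)
    list(res_idx = g$res_idx, atoms = g$atoms,
         centroid = colMeans(xyz), normal = o_plane_normal(xyz))
  })
}

oracle_pipi <- function(prep, chem, params) {
  rings <- oracle_rings(prep, chem)
  p <- params$pipi
  ia <- integer(0); ib <- integer(0); aa <- character(0); ab <- character(0)
  dd <- numeric(0)
  if (length(rings) >= 2L)
    for (i in seq_len(length(rings) - 1L)) for (j in (i + 1L):length(rings)) {
      if (rings[[i]]$res_idx == rings[[j]]$res_idx) next
      d <- sqrt(sum((rings[[i]]$centroid - rings[[j]]$centroid)^2))
      if (d > p$d_max) next
      g <- acos(min(1, abs(sum(rings[[i]]$normal * rings[[j]]$normal)))) * 180 / pi
      if (!(g <= p$parallel_max_deg || g >= p$tshape_min_deg)) next
      ia <- c(ia, rings[[i]]$res_idx); ib <- c(ib, rings[[j]]$res_idx)
      aa <- c(aa, paste(prep$atoms$name[rings[[i]]$atoms], collapse = ","))
      ab <- c(ab, paste(prep$atoms$name[rings[[j]]$atoms], collapse = ","))
      dd <- c(dd, d)
    }
  sig("PIPI", prep, ia, ib, aa, ab, dd)
}

oracle_pication <- function(prep, chem, params) {
  rings <- oracle_rings(prep, chem)
  p <- params$pication
  ia <- integer(0); ib <- integer(0); aa <- character(0); ab <- character(0)
  dd <- numeric(0)
  for (rg in rings) for (cg in chem$cations) {
    if (rg$res_idx == cg$res_idx) next
    cc <- colMeans(xyz_of(prep, cg$atoms))
    v <- cc - rg$centroid
    d <- sqrt(sum(v^2))
    if (d > p$d_max || d < 1e-9) next
    alpha <- acos(min(1, abs(sum(rg$normal * v / d)))) * 180 / pi
    if (alpha > p$alpha_max_deg) next
    ia <- c(ia, rg$res_idx); ib <- c(ib, cg$res_idx)
    aa <- c(aa, paste(prep$atoms$name[rg$atoms], collapse = ","))
    ab <- c(ab, paste(prep$atoms$name[cg$atoms], collapse = ","))
    dd <- c(dd, d)
  }
  sig("PICATION", prep, ia, ib, aa, ab, dd)
}

oracle_hydrophobic <- function(prep, chem, params) {
  hyd <- chem$hydrophobic
  n <- nrow(hyd)
  best <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (hyd$res_idx[i] == hyd$res_idx[j]) next
    d <- sqrt(sum((xyz_of(prep, hyd$atom[i])[1, ] - xyz_of(prep, hyd$atom[j])[1, ])^2))
    if (d > params$hydrophobic$d_max) next
    key <- paste(min(hyd$res_idx[i], hyd$res_idx[j]),
                 max(hyd$res_idx[i], hyd$res_idx[j]))
    if (is.null(best[[key]]) || d < best[[key]]$d)
      best[[key]] <- list(i = i, j = j, d = d)
  }
  if (length(best) == 0L) return(character(0))
  ia <- vapply(best, function(b) hyd$res_idx[b$i], 0L)
  ib <- vapply(best, function(b) hyd$res_idx[b$j], 0L)
  aa <- vapply(best, function(b) prep$atoms$name[hyd$atom[b$i]], "")
  ab <- vapply(best, function(b) prep$atoms$name[hyd$atom[b$j]], "")
  dd <- vapply(best, function(b) b$d, 0)
  sig("HYDROPHOBIC", prep, ia, ib, aa, ab, dd)
}

oracle_ca <- function(prep, chem, params) {
  ca <- which(prep$atoms$name == "CA")
  res <- prep$atoms$res_idx[ca]
  chain <- prep$residues$chain[res]
  seqn <- prep$residues$resseq[res]
  xyz <- xyz_of(prep, ca)
  ia <- integer(0); ib <- integer(0); dd <- numeric(0)
  n <- length(ca)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (res[i] == res[j]) next
    if (chain[i] == chain[j] && abs(seqn[i] - seqn[j]) < params$seq_sep_generic) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > params$ca_contact$d_max) next
    ia <- c(ia, res[i]); ib <- c(ib, res[j]); dd <- c(dd, d)
  }
  sig("CA_CONTACT", prep, ia, ib, rep("CA", length(ia)), rep("CA", length(ia)), dd)
}

ORACLES <- list(
  hbond = oracle_hbond, vdw = oracle_vdw, ionic = oracle_ionic,
  pipi = oracle_pipi, pication = oracle_pication,
  hydrophobic = oracle_hydrophobic, ca_contact = oracle_ca
)

DETECTORS <- list(
  hbond = detect_hydrogen_bonds, vdw = detect_vdw, ionic = detect_ionic,
  pipi = detect_pipi, pication = detect_pication,
  hydrophobic = detect_hydrophobic, ca_contact = detect_calpha_contacts
)

# ---- random model generator -------------------------------------------

# rough local residue templates (CA at origin); geometry is plausible, not
# idealized -- the detectors only consume distances and angles
res_templates <- local({
  bb <- list(N = c(-1.46, 0, 0), H = c(-1.8, 0.94, 0), CA = c(0, 0, 0),
             C = c(0.9, 1.1, 0), O = c(2.1, 1.0, 0.3))
  list(
    GLY = bb[c("N", "H", "CA", "C", "O")],
    ALA = c(bb, list(CB = c(0.2, -1.1, 1.0))),
    LEU = c(bb, list(CB = c(0.2, -1.1, 1.0), CG = c(0.1, -2.5, 1.2),
                     CD1 = c(1.2, -3.2, 0.6), CD2 = c(-1.0, -3.0, 2.0))),
    SER = c(bb, list(CB = c(0.2, -1.1, 1.0), OG = c(0.3, -2.4, 1.4))),
    LYS = c(bb, list(CB = c(0.2, -1.1, 1.0), CG = c(0.1, -2.5, 1.2),
                     CD = c(0.9, -3.4, 2.1), CE = c(0.8, -4.8, 1.8),
                     NZ = c(1.5, -5.7, 2.7))),
    ARG = c(bb, list(CB = c(0.2, -1.1, 1.0), CG = c(0.1, -2.5, 1.2),
                     NE = c(0.9, -3.4, 2.1), CZ = c(0.8, -4.7, 2.2),
                     NH1 = c(-0.1, -5.4, 1.5), NH2 = c(1.6, -5.4, 3.0))),
    ASP = c(bb, list(CB = c(0.2, -1.1, 1.0), CG = c(0.1, -2.5, 1.2),
                     OD1 = c(1.0, -3.2, 1.7), OD2 = c(-0.9, -3.0, 0.6))),
    GLU = c(bb, list(CB = c(0.2, -1.1, 1.0), CG = c(0.1, -2.5, 1.2),
                     CD = c(0.9, -3.4, 2.1), OE1 = c(1.9, -3.1, 2.7),
                     OE2 = c(0.5, -4.6, 1.9))),
    PHE = c(bb, list(CB = c(0.2, -1.1, 1.0), CG = c(0.1, -2.5, 1.2),
                     CD1 = c(1.2, -3.3, 1.3), CD2 = c(-1.1, -3.1, 1.3),
                     CE1 = c(1.1, -4.7, 1.5), CE2 = c(-1.2, -4.5, 1.5),
                     CZ = c(-0.05, -5.3, 1.6))),
    HIS = c(bb, list(CB = c(0.2, -1.1, 1.0), CG = c(0.1, -2.5, 1.2),
                     ND1 = c(1.1, -3.3, 1.4), CD2 = c(-1.0, -3.2, 1.3),
                     CE1 = c(0.7, -4.6, 1.5), NE2 = c(-0.6, -4.5, 1.5)))
  )
})

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# n_res residues of random type, randomly oriented, CA positions uniform
# in a box scaled for protein-like density
random_model <- function(n_res, seed) {
  set.seed(seed)
  types <- sample(names(res_templates), n_res, replace = TRUE)
  side <- max(8, round(5 * n_res^(1 / 3)))
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_res)) {
    tpl <- res_templates[[types[i]]]
    R <- random_rotation()
    ca <- stats::runif(3, 0, side)
    atoms <- lapply(tpl, function(v) as.numeric(R %*% v + ca))
    nm <- names(atoms)
    xyz <- do.call(rbind, atoms)
    rows[[i]] <- data.frame(
      serial = serial + seq_along(nm), name = nm, altloc = "",
      resname = types[i], chain = "A", resseq = i, icode = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
      element = substr(nm, 1, 1), is_hetero = FALSE, stringsAsFactors = FALSE
    )
    serial <- serial + length(nm)
  }
  atoms <- do.call(rbind, rows)
  prepare_model(atoms, prep_options())
}

# rigid-body transform of a prepared model
transform_prep <- function(prep, R, t) {
  xyz <- as.matrix(prep$atoms[, c("x", "y", "z")]) %*% t(R)
  prep$atoms$x <- xyz[, 1] + t[1]
  prep$atoms$y <- xyz[, 2] + t[2]
  prep$atoms$z <- xyz[, 3] + t[3]
  prep
}
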