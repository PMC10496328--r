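# Synthetic test molecules at controlled geometry. Each fixture is a
# minimal residue fragment set (only the atoms the target detector
# consults, plus a CA anchor placed well clear of the interaction) whose
# named geometric parameters are realized exactly by construction, so the
# expected detector output is analytically forced.

fixture_res <- function(chain, seq, resname, atoms, serial0 = 0L) {
  nm <- names(atoms)
  xyz <- do.call(rbind, atoms)
  data.frame(
    serial = serial0 + seq_along(nm), name = nm, altloc = "",
    resname = resname, chain = chain, resseq = seq, icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, element = guess_element(nm), is_hetero = FALSE,
    stringsAsFactors = FALSE
  )
}

hexagon <- function(radius = 1.39) {
  th <- (0:5) * pi / 3
  cbind(radius * cos(th), radius * sin(th), 0)
}

# H position realizing a requested D-H...A angle: H at 1.0 A from the
# donor, rotated off the donor->acceptor axis until the interior angle at
# H matches. Solved numerically to machine precision.
place_h <- function(N, O, angle) {
  if (angle >= 180 - 1e-9) return(N + unit_vec(O - N) * 1.0)
  f <- function(phi) {
    dir <- c(-cos(phi), sin(phi), 0)  # phi = 0 points from N toward O
    H <- N + 1.0 * dir
    angle_deg(N, H, O) - angle
  }
  # assumes O at origin, N on the +x axis (as constructed below)
  phi <- stats::uniroot(f, c(1e-9, pi - 1e-6), tol = 1e-12)$root
  N + 1.0 * c(-cos(phi), sin(phi), 0)
}

#' Generate a synthetic fixture structure
#'
#' Builds a minimal structure realizing the requested geometry exactly:
#' \describe{
#'   \item{HBOND_PAIR}{donor fragment (ALA: N, H, CA) and acceptor
#'     fragment (ALA: C, O, CA) with `|N - O| = d` and D-H...A angle
#'     `angle`.}
#'   \item{VDW_PAIR / HYDROPHOBIC_PAIR}{two LEU fragments (CA + CD1) with
#'     closest-atom (CD1-CD1) distance `d`.}
#'   \item{IONIC_PAIR}{ARG guanidinium and ASP carboxylate fragments with
#'     group-centroid distance `d`.}
#'   \item{PIPI_PAIR}{two PHE rings with centroid distance `d` and plane
#'     angle `gamma` (second ring rotated about x).}
#'   \item{PICATION_PAIR}{a PHE ring and a LYS NZ at distance `d` from the
#'     ring centroid, `alpha` degrees off the ring normal.}
#'   \item{CHAIN}{an `n`-residue poly-ALA chain: `"helix"` (CA rise 1.5 A,
#'     twist 100 deg, radius 2.3 A), `"extended"` (collinear CA spacing
#'     3.8 A), `"globule"` (compact serpentine CA walk on a 3.8 A lattice,
#'     the globular-aspect-ratio input used for scaling measurements), or
#'     `"dimer"` (two single-CA chains `d` apart).}
#' }
#' `model_count > 1` replicates the coordinates into that many identical
#' models. Generation is fully deterministic.
#'
#' @param kind Fixture kind (see above).
#' @param d Characteristic distance in Angstroms (pair fixtures).
#' @param angle,gamma,alpha Angles in degrees where applicable.
#' @param n Residue count for `CHAIN`.
#' @param conformation `"helix"`, `"extended"` or `"dimer"` for `CHAIN`.
#' @param model_count Number of identical models to emit.
#' @return A `rin_structure`.
#' @export
make_fixture <- function(kind = c("HBOND_PAIR", "VDW_PAIR", "IONIC_PAIR",
                                  "PIPI_PAIR", "PICATION_PAIR",
                                  "HYDROPHOBIC_PAIR", "CHAIN"),
                         d = NULL, angle = 180, gamma = 0, alpha = 0,
                         n = 10L,
                         conformation = c("helix", "extended", "globule", "dimer"),
                         model_count = 1L) {
  kind <- match.arg(kind)
  conformation <- match.arg(conformation)
  if (!is.null(d) && (d <= 0 || d >= 100))
    stop("make_fixture: distance parameter out of range (0, 100)", call. = FALSE)
  if (model_count < 1L) stop("make_fixture: model_count must be >= 1", call. = FALSE)

  atoms <- switch(kind,
    HBOND_PAIR = {
      if (is.null(d)) d <- 2.9
      O <- c(0, 0, 0); N <- c(d, 0, 0)
      H <- place_h(N, O, angle)
      rbind(
        fixture_res("A", 1L, "ALA", list(N = N, H = H, CA = N + c(0, -5, 0))),
        fixture_res("A", 2L, "ALA",
                    list(C = O + c(-1.0, -0.7, 0), O = O, CA = O + c(0, 5, 0)),
                    serial0 = 3L)
      )
    },
    VDW_PAIR = ,
    HYDROPHOBIC_PAIR = {
      if (is.null(d)) d <- 4.0
      rbind(
        fixture_res("A", 1L, "LEU", list(CA = c(0, 6, 0), CD1 = c(0, 0, 0))),
        fixture_res("A", 2L, "LEU", list(CA = c(d, -6, 0), CD1 = c(d, 0, 0)),
                    serial0 = 2L)
      )
    },
    IONIC_PAIR = {
      if (is.null(d)) d <- 3.5
      # coordinates chosen so both group centroids are exact in floating
      # point: (0,0,0) and (d,0,0), making boundary cases exactly at d
      guan <- rbind(CZ = c(0, 0, 0), NE = c(0, 1.32, 0),
                    NH1 = c(1.15, -0.66, 0), NH2 = c(-1.15, -0.66, 0))
      carb <- rbind(CG = c(d, 0, 0), OD1 = c(d, 0.8, 0), OD2 = c(d, -0.8, 0))
      rbind(
        fixture_res("A", 1L, "ARG", c(
          list(CA = c(0, 6, 0)),
          stats::setNames(lapply(seq_len(4), function(i) guan[i, ]), rownames(guan)))),
        fixture_res("A", 2L, "ASP", c(
          list(CA = c(d, -6, 0)),
          stats::setNames(lapply(seq_len(3), function(i) carb[i, ]), rownames(carb))),
          serial0 = 5L)
      )
    },
    PIPI_PAIR = {
      if (is.null(d)) d <- 4.0
      ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      r1 <- hexagon()
      r2 <- hexagon() %*% t(rotation_about(c(1, 0, 0), gamma))
      r2 <- sweep(r2, 2, c(0, 0, d), `+`)
      mk <- function(r) stats::setNames(lapply(seq_len(6), function(i) r[i, ]), ring_names)
      rbind(
        fixture_res("A", 1L, "PHE", c(list(CA = c(8, 0, 0)), mk(r1))),
        fixture_res("A", 2L, "PHE", c(list(CA = c(-8, 0, d)), mk(r2)), serial0 = 7L)
      )
    },
    PICATION_PAIR = {
      if (is.null(d)) d <- 4.0
      ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      r1 <- hexagon()
      a <- alpha * pi / 180
      NZ <- d * c(sin(a), 0, cos(a))
      rbind(
        fixture_res("A", 1L, "PHE", c(
          list(CA = c(8, 0, 0)),
          stats::setNames(lapply(seq_len(6), function(i) r1[i, ]), ring_names))),
        fixture_res("A", 2L, "LYS", list(CA = NZ + c(0, 8, 0), NZ = NZ),
                    serial0 = 7L)
      )
    },
    CHAIN = {
      if (conformation == "dimer") {
        if (is.null(d)) d <- 8.0
        rbind(
          fixture_res("A", 1L, "ALA", list(CA = c(0, 0, 0))),
          fixture_res("B", 1L, "ALA", list(CA = c(d, 0, 0)), serial0 = 1L)
        )
      } else {
        ca <- if (conformation == "helix") {
          th <- (seq_len(n) - 1L) * 100 * pi / 180
          cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (seq_len(n) - 1L))
        } else if (conformation == "globule") {
          # boustrophedon walk on a cubic lattice: consecutive CA stay
          # 3.8 A apart while the chain fills a compact cube
          m <- ceiling(n^(1 / 3))
          i <- seq_len(n) - 1L
          iz <- i %/% (m * m)
          j <- i %% (m * m)
          j <- ifelse(iz %% 2L == 1L, m * m - 1L - j, j)  # reverse odd layers
          iy <- j %/% m
          ix <- j %% m
          ix <- ifelse(iy %% 2L == 1L, m - 1L - ix, ix)   # reverse odd rows
          cbind(3.8 * ix, 3.8 * iy, 3.8 * iz)
        } else {
          cbind(3.8 * (seq_len(n) - 1L), 0, 0)
        }
        do.call(rbind, lapply(seq_len(n), function(i) {
          CA <- ca[i, ]
          fixture_res("A", i, "ALA", list(
            N = CA + c(-0.95, 0.95, 0), CA = CA, C = CA + c(1.05, 0.85, 0),
            O = CA + c(1.15, 2.05, 0), CB = CA + c(0, -1.3, 0.9)),
            serial0 = (i - 1L) * 5L)
        }))
      }
    }
  )
  rownames(atoms) <- NULL
  models <- rep(list(atoms), model_count)
  new_structure(tolower(kind), models, "pdb")
}

#' Curated fixture catalog
#'
#' For every bond type: a positive case inside all thresholds, a negative
#' case outside the distance gate, a negative case outside the angle gate
#' (for the angular types), and an exact-boundary case at the default
#' distance threshold. Each entry states the detector to run and the
#' exact expected contact count under default parameters.
#'
#' @return A data frame with columns `label`, `kind`, `detector`,
#'   `expected`, plus a list column `args` of [make_fixture()] arguments.
#' @export
fixture_catalog <- function() {
  e <- function(label, kind, detector, expected, args = list()) {
    list(label = label, kind = kind, detector = detector,
         expected = expected, args = args)
  }
  entries <- list(
    e("hbond positive", "HBOND_PAIR", "hbond", 1L, list(d = 2.9, angle = 180)),
    e("hbond distance negative", "HBOND_PAIR", "hbond", 0L, list(d = 4.2, angle = 180)),
    e("hbond angle negative", "HBOND_PAIR", "hbond", 0L, list(d = 2.9, angle = 100)),
    e("hbond boundary", "HBOND_PAIR", "hbond", 1L, list(d = 3.5, angle = 180)),

    e("vdw positive", "VDW_PAIR", "vdw", 1L, list(d = 3.6)),
    e("vdw negative", "VDW_PAIR", "vdw", 0L, list(d = 4.2)),
    e("vdw boundary", "VDW_PAIR", "vdw", 1L, list(d = 3.9)),

    e("ionic positive", "IONIC_PAIR", "ionic", 1L, list(d = 3.5)),
    e("ionic negative", "IONIC_PAIR", "ionic", 0L, list(d = 6.0)),
    e("ionic boundary", "IONIC_PAIR", "ionic", 1L, list(d = 4.5)),

    e("pipi parallel positive", "PIPI_PAIR", "pipi", 1L, list(d = 4.0, gamma = 0)),
    e("pipi tshape positive", "PIPI_PAIR", "pipi", 1L, list(d = 5.0, gamma = 90)),
    e("pipi distance negative", "PIPI_PAIR", "pipi", 0L, list(d = 8.5, gamma = 0)),
    e("pipi angle negative", "PIPI_PAIR", "pipi", 0L, list(d = 4.0, gamma = 45)),
    e("pipi boundary", "PIPI_PAIR", "pipi", 1L, list(d = 6.5, gamma = 0)),

    e("pication positive", "PICATION_PAIR", "pication", 1L, list(d = 4.0, alpha = 0)),
    e("pication distance negative", "PICATION_PAIR", "pication", 0L, list(d = 6.0, alpha = 0)),
    e("pication angle negative", "PICATION_PAIR", "pication", 0L, list(d = 4.0, alpha = 90)),
    e("pication boundary", "PICATION_PAIR", "pication", 1L, list(d = 5.0, alpha = 0)),

    e("hydrophobic positive", "HYDROPHOBIC_PAIR", "hydrophobic", 1L, list(d = 4.0)),
    e("hydrophobic negative", "HYDROPHOBIC_PAIR", "hydrophobic", 0L, list(d = 6.0)),
    e("hydrophobic boundary", "HYDROPHOBIC_PAIR", "hydrophobic", 1L, list(d = 4.5)),

    # helix: CA pairs at |i-j| = 3 (5.05 A) and 4 (6.20 A) are inside the
    # 8 A / seq-sep-3 gate, |i-j| >= 5 (8.66 A+) are not: 7 + 6 contacts
    e("ca helix positive", "CHAIN", "ca_contact", 13L, list(n = 10L,
      conformation = "helix")),
    e("ca extended negative", "CHAIN", "ca_contact", 0L, list(n = 10L,
      conformation = "extended")),
    e("ca interchain boundary", "CHAIN", "ca_contact", 1L,
      list(conformation = "dimer", d = 8.0)),
    e("ca interchain negative", "CHAIN", "ca_contact", 0L,
      list(conformation = "dimer", d = 8.5))
  )
  df <- data.frame(
    label = vapply(entries, `[[`, "", "label"),
    kind = vapply(entries, `[[`, "", "kind"),
    detector = vapply(entries, `[[`, "", "detector"),
    expected = vapply(entries, `[[`, 0L, "expected"),
    stringsAsFactors = FALSE
  )
  df$args <- lapply(entries, `[[`, "args")
  df
}

#' Run one catalog entry through its matching detector
#'
#' @param entry One row of [fixture_catalog()] (a single-row data frame).
#' @param params A `bond_params` object.
#' @return The contact data frame produced by the entry's detector.
#' @export
run_catalog_entry <- function(entry, params = bond_params()) {
  st <- do.call(make_fixture, c(list(kind = entry$kind), entry$args[[1L]]))
  prep <- prepare_model(st$models[[1L]], prep_options())
  detect_contacts(prep, params, types = entry$detector)
}
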