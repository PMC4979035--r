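# Deterministic synthetic fixtures: Born ions, a diatomic, ideal peptides
# with backbone hydrogen-bond networks, and a receptor-ligand toy complex
# with three designed hydrogen bonds plus paired base/polarized charge sets.

# AMBER-like nonbonded parameters by atom class
.nbParams <- list(
  N  = c(rmin_half = 1.8240, epsilon = 0.1700, mass = 14.007, pb = 1.55),
  H  = c(rmin_half = 0.6000, epsilon = 0.0157, mass = 1.008,  pb = 1.20),
  C  = c(rmin_half = 1.9080, epsilon = 0.0860, mass = 12.011, pb = 1.70),
  CT = c(rmin_half = 1.9080, epsilon = 0.1094, mass = 12.011, pb = 1.70),
  O  = c(rmin_half = 1.6612, epsilon = 0.2100, mass = 15.999, pb = 1.50)
)

# amide backbone charges; CA balances each residue to zero net charge, and
# the C,O / N,H,CA groups each sum to zero so conjugate-cap fragments keep
# integer totals at chain termini too
.bbCharge <- c(N = -0.4157, H = 0.2719, CA = 0.1438, C = 0.5973, O = -0.5973)

.geomIdeal <- list(b_NH = 1.010, b_NCA = 1.458, b_CAC = 1.525, b_CO = 1.231,
                   b_CN = 1.329, a_NCAC = 111.2, a_CACN = 116.2,
                   a_CNCA = 121.7, a_CACO = 120.4, a_CNH = 119.5)

# Build an ideal glycine-like backbone (atoms N, H, CA, C, O per residue)
# at fixed phi/psi (degrees). Returns coords plus atom bookkeeping.
.buildPeptide <- function(nres, phi, psi) {
  g <- .geomIdeal
  rad <- pi / 180
  N <- matrix(NA_real_, nres, 3); CA <- N; C <- N; O <- N; H <- N
  N[1, ]  <- c(0, 0, 0)
  CA[1, ] <- c(g$b_NCA, 0, 0)
  th <- (180 - g$a_NCAC) * rad
  C[1, ] <- CA[1, ] + g$b_CAC * c(cos(th), sin(th), 0)
  for (i in seq_len(nres)[-1]) {
    N[i, ]  <- .placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          g$b_CN, g$a_CACN * rad, psi * rad)
    CA[i, ] <- .placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_NCA, g$a_CNCA * rad, pi)
    C[i, ]  <- .placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                          g$b_CAC, g$a_NCAC * rad, phi * rad)
  }
  for (i in seq_len(nres)) {
    O[i, ] <- .placeAtom(N[i, ], CA[i, ], C[i, ], g$b_CO, g$a_CACO * rad,
                         psi * rad + pi)
    if (i == 1) {
      H[i, ] <- .placeAtom(C[i, ], CA[i, ], N[i, ], g$b_NH,
                           (180 - g$a_CNH) * rad, pi)
    } else {
      H[i, ] <- .placeAtom(O[i - 1, ], C[i - 1, ], N[i, ], g$b_NH,
                           g$a_CNH * rad, pi)
    }
  }
  atoms <- NULL
  coords <- NULL
  for (i in seq_len(nres)) {
    nm <- c("N", "H", "CA", "C", "O")
    coords <- rbind(coords, N[i, ], H[i, ], CA[i, ], C[i, ], O[i, ])
    atoms <- rbind(atoms, data.frame(name = nm, resid = i))
  }
  dimnames(coords) <- NULL
  list(atoms = atoms, coords = coords, nres = nres)
}

.peptideAtomRows <- function(pep, resname, segment, serial0 = 0L) {
  cls <- ifelse(pep$atoms$name == "CA", "CT", substr(pep$atoms$name, 1, 1))
  p <- do.call(rbind, .nbParams[cls])
  data.frame(serial = serial0 + seq_len(nrow(pep$atoms)),
             name = pep$atoms$name,
             element = substr(pep$atoms$name, 1, 1),
             resname = resname, resid = pep$atoms$resid, segment = segment,
             x = pep$coords[, 1], y = pep$coords[, 2], z = pep$coords[, 3],
             charge = unname(.bbCharge[pep$atoms$name]),
             rmin_half = p[, "rmin_half"], epsilon = p[, "epsilon"],
             mass = p[, "mass"], pb_radius = p[, "pb"])
}

# bonds within one peptide segment, indices relative to its first atom
.peptideBonds <- function(nres, offset = 0L) {
  idx <- function(i, nm) offset + (i - 1L) * 5L + match(nm, c("N", "H", "CA", "C", "O"))
  out <- NULL
  for (i in seq_len(nres)) {
    out <- rbind(out,
                 cbind(idx(i, "N"), idx(i, "H")),
                 cbind(idx(i, "N"), idx(i, "CA")),
                 cbind(idx(i, "CA"), idx(i, "C")),
                 cbind(idx(i, "C"), idx(i, "O")))
    if (i < nres) out <- rbind(out, cbind(idx(i, "C"), idx(i + 1L, "N")))
  }
  out
}

# Harmonic bond/angle tables with equilibrium values measured from the
# native geometry, so the native structure is a stationary point of the
# bonded energy. Angle terms are derived from bond connectivity.
.parameterizeBonded <- function(atoms, bondPairs, coords) {
  isH <- atoms$element == "H"
  r0 <- sqrt(rowSums((coords[bondPairs[, 1], , drop = FALSE] -
                      coords[bondPairs[, 2], , drop = FALSE])^2))
  bonds <- data.frame(i = bondPairs[, 1], j = bondPairs[, 2],
                      k = ifelse(isH[bondPairs[, 1]] | isH[bondPairs[, 2]],
                                 400, 330),
                      r0 = r0)
  nb <- split(c(bondPairs[, 2], bondPairs[, 1]),
              c(bondPairs[, 1], bondPairs[, 2]))
  ang <- NULL
  for (ctr in as.integer(names(nb))) {
    nbrs <- sort(unique(nb[[as.character(ctr)]]))
    if (length(nbrs) < 2L) next
    cmb <- utils::combn(nbrs, 2L)
    ang <- rbind(ang, cbind(cmb[1, ], ctr, cmb[2, ]))
  }
  if (is.null(ang)) {
    angles <- data.frame(i = integer(), j = integer(), k = integer(),
                         kth = numeric(), th0 = numeric())
  } else {
    th0 <- apply(ang, 1L, function(r)
      .angle3(coords[r[1], ], coords[r[2], ], coords[r[3], ]))
    angles <- data.frame(i = ang[, 1], j = ang[, 2], k = ang[, 3],
                         kth = ifelse(isH[ang[, 1]] | isH[ang[, 3]], 35, 55),
                         th0 = th0)
  }
  list(bonds = bonds, angles = angles)
}

#' Build a deterministic synthetic fixture
#'
#' Generators for every structure the pipeline is tested on:
#' \describe{
#'   \item{`born_ion`}{a single ion, charge +1 e, Poisson-Boltzmann radius
#'     2 Angstrom — the analytic Born reference case.}
#'   \item{`dimer`}{a harmonically bonded diatomic (+0.5/-0.5 e, CO-like
#'     masses) for bonded-energy and normal-mode closed forms.}
#'   \item{`mini_helix`}{an ideal alpha-helical backbone (phi = -57, psi =
#'     -47 degrees, N/H/CA/C/O per residue) whose i -> i+4 amide hydrogen
#'     bonds form the intra-protein backbone network.}
#'   \item{`toy_complex`}{an extended receptor peptide plus a small ligand
#'     placed so that exactly three receptor-ligand hydrogen bonds satisfy
#'     the 3.5 Angstrom / 120 degree criteria in the native frame — one
#'     receptor amide donating to a ligand carbonyl and two ligand amides
#'     donating to receptor carbonyls, mirroring the serine/glycine-to-ligand
#'     motif of a thrombin active site.}
#' }
#'
#' Each fixture carries a full toy force field (charges integer per residue,
#' AMBER-style Lennard-Jones, harmonic bonds/angles with equilibrium values
#' measured from the native geometry) and a pair of charge sets: `base`, and
#' `polarized` in which the partial charges of the designed hydrogen-bonding
#' atoms are scaled by `polarization` and each fragment is renormalized to
#' its integer net charge over its remaining atoms. The four-atom
#' hydrogen-bond Coulomb energies therefore scale by exactly
#' `polarization^2`, strengthening every designed bond.
#'
#' @param kind fixture kind (see above)
#' @param nres residue count (mini_helix default 10, toy_complex receptor
#'   default 12)
#' @param polarization charge scale factor for hydrogen-bonding atoms in the
#'   `polarized` set (default 1.2, a realistic 20 percent polarization of
#'   amide charges)
#' @return a list with elements `topology` ([Topology-class] including native
#'   coordinates), `native` (`N x 3` matrix), `chargeSets` (list `base`,
#'   `polarized`), and `hbonds` (data.frame of designed bonds: indices
#'   `donor`, `hydrogen`, `acceptor`, `antecedent`, and `class`)
#' @export
makeFixture <- function(kind = c("toy_complex", "mini_helix", "born_ion", "dimer"),
                        nres = NULL, polarization = 1.2) {
  kind <- match.arg(kind)
  switch(kind,
         born_ion   = .fixtureBornIon(),
         dimer      = .fixtureDimer(),
         mini_helix = .fixtureHelix(if (is.null(nres)) 10L else nres, polarization),
         toy_complex = .fixtureComplex(if (is.null(nres)) 12L else nres, polarization))
}

.fixtureBornIon <- function() {
  atoms <- data.frame(serial = 1L, name = "ION", element = "NA",
                      resname = "ION", resid = 1L, segment = "ligand",
                      x = 0, y = 0, z = 0, charge = 1, rmin_half = 1.8,
                      epsilon = 0.1, mass = 22.99, pb_radius = 2.0)
  topo <- Topology(atoms)
  list(topology = topo, native = refCoords(topo),
       chargeSets = list(base = ChargeSet("base", 1),
                         polarized = ChargeSet("polarized", 1)),
       hbonds = .emptyHBonds())
}

.fixtureDimer <- function() {
  atoms <- data.frame(serial = 1:2, name = c("C1", "O2"),
                      element = c("C", "O"), resname = "DIA", resid = 1L,
                      segment = "ligand", x = c(0, 1.1), y = 0, z = 0,
                      charge = c(0.5, -0.5),
                      rmin_half = c(1.908, 1.6612), epsilon = c(0.086, 0.21),
                      mass = c(12.011, 15.999), pb_radius = c(1.7, 1.5))
  bonds <- data.frame(i = 1L, j = 2L, k = 350, r0 = 1.1)
  topo <- Topology(atoms, bonds)
  list(topology = topo, native = refCoords(topo),
       chargeSets = list(base = ChargeSet("base", atoms$charge),
                         polarized = ChargeSet("polarized", atoms$charge)),
       hbonds = .emptyHBonds())
}

.emptyHBonds <- function() {
  data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
             antecedent = integer(), class = character())
}

.fixtureHelix <- function(nres, polarization) {
  pep <- .buildPeptide(nres, -57, -47)
  atoms <- .peptideAtomRows(pep, "ALA", "protein")
  bp <- .peptideBonds(nres)
  bonded <- .parameterizeBonded(atoms, bp, pep$coords)
  topo <- Topology(atoms, bonded$bonds, bonded$angles)
  base <- ChargeSet("base", atoms$charge)
  # polarize every backbone amide atom, rebalance on CA per residue
  f <- polarization
  q <- atoms$charge
  amide <- atoms$name %in% c("N", "H", "C", "O")
  qp <- ifelse(amide, q * f, q)
  for (i in seq_len(nres)) {
    res <- which(atoms$resid == i)
    excess <- sum(qp[res]) - round(sum(q[res]))
    ca <- res[atoms$name[res] == "CA"]
    qp[ca] <- qp[ca] - excess
  }
  idx <- function(i, nm) (i - 1L) * 5L + match(nm, c("N", "H", "CA", "C", "O"))
  hb <- if (nres > 4L) {
    don <- 5:nres
    data.frame(donor = idx(don, "N"), hydrogen = idx(don, "H"),
               acceptor = idx(don - 4L, "O"), antecedent = idx(don - 4L, "C"),
               class = "backbone")
  } else .emptyHBonds()
  list(topology = topo, native = pep$coords,
       chargeSets = list(base = base, polarized = ChargeSet("polarized", qp)),
       hbonds = hb)
}

.ligCharge <- c(O1 = -0.55, C1 = 0.55, C2 = 0, C5 = 0, N1 = -0.52,
                H9 = 0.31, C3 = 0.21, C6 = 0, N4 = -0.52, H13 = 0.31,
                C4 = 0.21)

.fixtureComplex <- function(nres, polarization) {
  if (nres < 10L) stop("toy complex receptor needs >= 10 residues")
  pep <- .buildPeptide(nres, -139, 135)
  rec <- .peptideAtomRows(pep, "GLY", "protein")
  X <- pep$coords
  idx <- function(i, nm) (i - 1L) * 5L + match(nm, c("N", "H", "CA", "C", "O"))

  # choose a donor residue and two acceptor residues whose amide H / carbonyl
  # O point to the same face of the strand (spacing >= 2 residues)
  cand <- 3:(nres - 2L)
  uNH <- t(vapply(cand, function(i) .unit(X[idx(i, "H"), ] - X[idx(i, "N"), ]),
                  numeric(3)))
  uCO <- t(vapply(cand, function(i) .unit(X[idx(i, "O"), ] - X[idx(i, "C"), ]),
                  numeric(3)))
  best <- NULL; bestScore <- -Inf
  for (di in seq_along(cand)) for (bi in seq_along(cand)) for (ci in seq_along(cand)) {
    d <- cand[di]; b <- cand[bi]; cc <- cand[ci]
    if (length(unique(c(d, b, cc))) < 3L) next
    if (min(abs(c(d - b, d - cc, b - cc))) < 2L) next
    sc <- min(sum(uNH[di, ] * uCO[bi, ]), sum(uNH[di, ] * uCO[ci, ]),
              sum(uCO[bi, ] * uCO[ci, ]))
    if (sc > bestScore) { bestScore <- sc; best <- c(d, b, cc) }
  }
  if (bestScore < 0.5) stop("toy complex generation error: no aligned face found")
  d <- best[1]; b <- best[2]; cc <- best[3]
  u <- .unit(X[idx(d, "H"), ] - X[idx(d, "N"), ])
  vb <- .unit(X[idx(b, "O"), ] - X[idx(b, "C"), ])
  vc <- .unit(X[idx(cc, "O"), ] - X[idx(cc, "C"), ])

  O1 <- X[idx(d, "N"), ] + 2.91 * u
  N1 <- X[idx(b, "O"), ] + 2.90 * vb
  H9 <- N1 - 1.01 * vb
  N4 <- X[idx(cc, "O"), ] + 2.90 * vc
  H13 <- N4 - 1.01 * vc
  w <- .unit(u + vb + vc)
  C1 <- O1 + 1.23 * .unit(u + 0.8 * w)
  C2 <- (O1 + N1) / 2 + 1.2 * w
  C5 <- C2 + 1.45 * w
  C3 <- (N1 + N4) / 2 + 1.2 * w
  C6 <- C3 + 1.45 * w
  C4 <- N4 + 1.5 * w + c(0, 0, 0)
  ligNames <- c("O1", "C1", "C2", "C5", "N1", "H9", "C3", "C6", "N4", "H13", "C4")
  ligXYZ <- rbind(O1, C1, C2, C5, N1, H9, C3, C6, N4, H13, C4)
  ligElem <- substr(ligNames, 1, 1)
  p <- do.call(rbind, .nbParams[ligElem])
  n0 <- nrow(rec)
  lig <- data.frame(serial = n0 + seq_along(ligNames), name = ligNames,
                    element = ligElem, resname = "LIG", resid = 1L,
                    segment = "ligand",
                    x = ligXYZ[, 1], y = ligXYZ[, 2], z = ligXYZ[, 3],
                    charge = unname(.ligCharge[ligNames]),
                    rmin_half = p[, "rmin_half"], epsilon = p[, "epsilon"],
                    mass = p[, "mass"], pb_radius = p[, "pb"])
  atomsAll <- rbind(rec, lig)
  coords <- rbind(X, ligXYZ)

  # designed-bond clash check (everything except the designed contacts)
  cd <- .crossDist(X, ligXYZ)
  designed <- rbind(c(idx(d, "H"), 1L), c(idx(d, "N"), 1L),
                    c(idx(b, "O"), 6L), c(idx(b, "O"), 5L),
                    c(idx(cc, "O"), 10L), c(idx(cc, "O"), 9L))
  cd[designed] <- Inf
  if (min(cd) < 1.7)
    stop("toy complex generation error: receptor-ligand clash at ",
         signif(min(cd), 3), " Angstrom")

  ligPairs <- function(a, b2) cbind(n0 + match(a, ligNames), n0 + match(b2, ligNames))
  bp <- rbind(.peptideBonds(nres),
              ligPairs(c("O1", "C1", "C2", "C2", "N1", "N1", "C3", "C3", "N4", "N4"),
                       c("C1", "C2", "C5", "N1", "H9", "C3", "C6", "N4", "H13", "C4")))
  bonded <- .parameterizeBonded(atomsAll, bp, coords)
  topo <- Topology(atomsAll, bonded$bonds, bonded$angles)

  dimnames(coords) <- NULL
  hb <- data.frame(donor = c(idx(d, "N"), n0 + match("N1", ligNames),
                             n0 + match("N4", ligNames)),
                   hydrogen = c(idx(d, "H"), n0 + match("H9", ligNames),
                                n0 + match("H13", ligNames)),
                   acceptor = c(n0 + match("O1", ligNames), idx(b, "O"),
                                idx(cc, "O")),
                   antecedent = c(n0 + match("C1", ligNames), idx(b, "C"),
                                  idx(cc, "C")),
                   class = "protein-ligand")

  q <- atomsAll$charge
  f <- polarization
  hbAtoms <- unique(unlist(hb[, c("donor", "hydrogen", "acceptor", "antecedent")]))
  qp <- q
  qp[hbAtoms] <- qp[hbAtoms] * f
  fragKey <- paste(atomsAll$segment, atomsAll$resid)
  for (kf in unique(fragKey)) {
    res <- which(fragKey == kf)
    excess <- sum(qp[res]) - round(sum(q[res]))
    if (abs(excess) < 1e-12) next
    others <- setdiff(res, hbAtoms)
    if (!length(others)) others <- res
    qp[others] <- qp[others] - excess / length(others)
  }
  list(topology = topo, native = coords,
       chargeSets = list(base = ChargeSet("base", q),
                         polarized = ChargeSet("polarized", qp)),
       hbonds = hb,
       anchors = c(donor_res = d, acceptor_res1 = b, acceptor_res2 = cc))
}

#' Generate a jittered trajectory with scripted hydrogen-bond rupture
#'
#' Each frame is the fixture's native structure plus iid Gaussian
#' displacement of standard deviation `sigma` per coordinate (harmonic
#' thermal jitter). From a scheduled rupture frame onward, the moving group
#' of that hydrogen bond — its ligand-side atoms for a receptor-ligand bond,
#' its acceptor-side `C`/`O` atoms for an intra-protein bond — is displaced
#' 3 Angstrom along the native donor-acceptor axis away from the partner, so
#' the bond is guaranteed absent under the 3.5 Angstrom cutoff.
#'
#' The generator is a pure function of its arguments: the same seed yields
#' byte-identical trajectories.
#'
#' @param fixture a list from [makeFixture()]
#' @param nFrames number of frames
#' @param sigma per-coordinate jitter, Angstrom (default 0.1)
#' @param rupture `NULL`, or data.frame with columns `bond` (row index into
#'   `fixture$hbonds`) and `frame` (first broken frame, 1-based)
#' @param seed integer RNG seed
#' @param dt frame spacing in ns (default 0.1)
#' @return a [Trajectory-class]
#' @export
makeTrajectory <- function(fixture, nFrames, sigma = 0.1, rupture = NULL,
                           seed = 1L, dt = 0.1) {
  native <- fixture$native
  n <- nrow(native)
  hb <- fixture$hbonds
  moves <- list()
  if (!is.null(rupture) && nrow(rupture)) {
    if (any(rupture$bond < 1L | rupture$bond > nrow(hb)))
      stop("rupture schedule references unknown hydrogen bond")
    if (any(rupture$frame < 1L | rupture$frame > nFrames))
      stop("rupture frame outside trajectory")
    seg <- atoms(fixture$topology)$segment
    for (r in seq_len(nrow(rupture))) {
      row <- hb[rupture$bond[r], ]
      four <- c(row$donor, row$hydrogen, row$acceptor, row$antecedent)
      ligSide <- four[seg[four] == "ligand"]
      if (length(ligSide)) {
        group <- ligSide
        partner <- four[seg[four] != "ligand"][1]
      } else {
        group <- c(row$acceptor, row$antecedent)
        partner <- row$donor
      }
      dir <- .unit(colMeans(native[group, , drop = FALSE]) - native[partner, ])
      moves[[r]] <- list(frame = rupture$frame[r], group = group,
                         shift = 3 * dir)
    }
  }
  coords <- withr::with_seed(as.integer(seed), {
    arr <- array(NA_real_, dim = c(n, 3L, nFrames))
    for (f in seq_len(nFrames)) {
      fr <- native
      if (sigma > 0) fr <- fr + matrix(stats::rnorm(3L * n, sd = sigma), n, 3L)
      for (mv in moves) if (f >= mv$frame)
        fr[mv$group, ] <- fr[mv$group, ] + rep(mv$shift, each = length(mv$group))
      arr[, , f] <- fr
    }
    arr
  })
  Trajectory(fixture$topology, coords, frameIndex = seq_len(nFrames),
             time = (seq_len(nFrames) - 1L) * dt)
}
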