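# Gas-phase molecular-mechanics energies: intergroup Coulomb and
# Lennard-Jones, per-residue interaction spectra, and the toy bonded force
# field (with analytic gradients) behind minimization and normal modes.

#' Molecular-mechanics parameters
#'
#' The Coulomb constant is fixed at 332.0636 kcal*Angstrom/(mol*e^2);
#' Lennard-Jones pairs combine AMBER-style (Lorentz-Berthelot:
#' `rmin_ij = rmin_half_i + rmin_half_j`, `eps_ij = sqrt(eps_i*eps_j)`), and
#' no cutoff is applied (end-state MM/PBSA convention). Conversion from the
#' sigma/epsilon convention: `rmin = 2^(1/6) * sigma`.
#'
#' @param cutoff pair cutoff in Angstrom, or `Inf` for none (default)
#' @return list of class `mmParams`
#' @export
mmParams <- function(cutoff = Inf) {
  structure(list(coulomb = .kCoulomb, combining = "lorentz_berthelot",
                 cutoff = cutoff), class = "mmParams")
}

# ele/vdw between index sets A and B (no intra-group terms)
.pairEnergy <- function(coords, q, rminHalf, eps, A, B, params, clashCheck = TRUE) {
  XA <- coords[A, , drop = FALSE]; XB <- coords[B, , drop = FALSE]
  r <- .crossDist(XA, XB)
  if (clashCheck && any(r < 0.1))
    stop(sprintf("atom clash: minimum intergroup distance %.3f Angstrom", min(r)))
  mask <- if (is.finite(params$cutoff)) r <= params$cutoff else TRUE
  ele <- params$coulomb * sum((outer(q[A], q[B]) / r) * mask)
  rmin <- outer(rminHalf[A], rminHalf[B], "+")
  epsij <- sqrt(outer(eps[A], eps[B]))
  sr6 <- (rmin / r)^6
  vdw <- sum(epsij * (sr6 * sr6 - 2 * sr6) * mask)
  c(ele = ele, vdw = vdw)
}

#' Intergroup Coulomb and Lennard-Jones energy
#'
#' Sums `k*q_i*q_j/r_ij` and `eps_ij*((rmin_ij/r)^12 - 2*(rmin_ij/r)^6)` over
#' all pairs with atom i in `groupA` and j in `groupB`. Only intergroup terms
#' are ever computed: in the single-trajectory binding protocol the
#' intramolecular terms cancel exactly, so they are never needed.
#'
#' @param coords `N x 3` frame coordinates
#' @param topology a [Topology-class] (Lennard-Jones parameters)
#' @param chargeSource [ChargeSet-class], [Topology-class] or numeric vector
#' @param groupA,groupB disjoint [AtomSelection-class]s or index vectors
#' @param params an [mmParams()]
#' @return named numeric: `ele`, `vdw` (kcal/mol)
#' @export
groupInteraction <- function(coords, topology, chargeSource = topology,
                             groupA, groupB, params = mmParams()) {
  A <- selectionIndices(groupA); B <- selectionIndices(groupB)
  if (length(intersect(A, B))) stop("groups overlap: interaction undefined")
  if (!length(A) || !length(B)) return(c(ele = 0, vdw = 0))
  q <- if (is(chargeSource, "ChargeSet")) charges(chargeSource)
       else if (is(chargeSource, "Topology")) charges(chargeSource)
       else as.numeric(chargeSource)
  a <- topology@atoms
  .pairEnergy(coords, q, a$rmin_half, a$epsilon, A, B, params)
}

#' Per-residue ligand interaction spectrum
#'
#' Splits the protein-ligand gas-phase interaction over protein residues:
#' entry r is `groupInteraction(atoms of residue r, ligand)`. The residue
#' sums reproduce the whole-protein interaction exactly (additivity of the
#' pair sums).
#'
#' @inheritParams groupInteraction
#' @param ligand ligand selection (disjoint from the protein)
#' @return data.frame with `resid`, `resname`, `ele`, `vdw`
#' @export
perResidueSpectrum <- function(coords, topology, chargeSource = topology,
                               ligand, params = mmParams()) {
  lig <- selectionIndices(ligand)
  rt <- residueTable(topology)
  rt <- rt[rt$segment == "protein", , drop = FALSE]
  q <- if (is(chargeSource, "ChargeSet")) charges(chargeSource)
       else if (is(chargeSource, "Topology")) charges(chargeSource)
       else as.numeric(chargeSource)
  a <- topology@atoms
  res <- t(vapply(seq_len(nrow(rt)), function(r) {
    ridx <- setdiff(rt$first[r]:rt$last[r], lig)
    .pairEnergy(coords, q, a$rmin_half, a$epsilon, ridx, lig, params)
  }, numeric(2)))
  data.frame(resid = rt$resid, resname = rt$resname,
             ele = res[, 1], vdw = res[, 2])
}

#' Toy bonded energy (harmonic bonds and angles) with analytic gradient
#'
#' `E = sum k_b (r - r0)^2 + sum k_theta (theta - theta0)^2` over the
#' topology's bond and angle tables.
#'
#' @param coords `N x 3` coordinates
#' @param topology a [Topology-class] with parameterized `bonds`/`angles`
#' @param gradient if `TRUE`, return the analytic gradient too
#' @return energy (kcal/mol), with attribute `gradient` (`N x 3`,
#'   kcal/mol/Angstrom) when requested
#' @export
toyBondedEnergy <- function(coords, topology, gradient = FALSE) {
  b <- topology@bonds; an <- topology@angles
  if (nrow(b) && (any(is.na(b$k)) || any(is.na(b$r0))))
    stop("missing bond parameters")
  E <- 0
  G <- if (gradient) matrix(0, nrow(coords), 3) else NULL
  if (nrow(b)) {
    d <- coords[b$i, , drop = FALSE] - coords[b$j, , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    E <- E + sum(b$k * (r - b$r0)^2)
    if (gradient) {
      gmag <- 2 * b$k * (r - b$r0) / r
      gv <- d * gmag
      for (c3 in 1:3) {
        acc <- rowsum(c(gv[, c3], -gv[, c3]), c(b$i, b$j))
        G[as.integer(rownames(acc)), c3] <- G[as.integer(rownames(acc)), c3] + acc
      }
    }
  }
  if (nrow(an)) {
    i <- an$i; j <- an$j; k <- an$k
    u <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    v <- coords[k, , drop = FALSE] - coords[j, , drop = FALSE]
    ru <- sqrt(rowSums(u * u)); rv <- sqrt(rowSums(v * v))
    cth <- pmax(-1, pmin(1, rowSums(u * v) / (ru * rv)))
    th <- acos(cth)
    E <- E + sum(an$kth * (th - an$th0)^2)
    if (gradient) {
      sth <- sqrt(pmax(1e-12, 1 - cth * cth))
      dEdth <- 2 * an$kth * (th - an$th0)
      gi <- (-dEdth / sth) * (v / (ru * rv) - (cth / (ru * ru)) * u)
      gk <- (-dEdth / sth) * (u / (ru * rv) - (cth / (rv * rv)) * v)
      for (c3 in 1:3) {
        acc <- rowsum(c(gi[, c3], gk[, c3], -gi[, c3] - gk[, c3]), c(i, k, j))
        G[as.integer(rownames(acc)), c3] <- G[as.integer(rownames(acc)), c3] + acc
      }
    }
  }
  if (gradient) attr(E, "gradient") <- G
  E
}

# Precompiled toy force-field model: bonded tables restricted to a subset
# plus the nonbonded pair list (all pairs minus 1-2/1-3 exclusions).
# Built once, evaluated many times by the minimizer and Hessian.
.toyModel <- function(topology, q, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(topology@atoms))
  map <- integer(nrow(topology@atoms)); map[subset] <- seq_along(subset)
  b <- topology@bonds; b <- b[b$i %in% subset & b$j %in% subset, , drop = FALSE]
  an <- topology@angles
  an <- an[an$i %in% subset & an$j %in% subset & an$k %in% subset, , drop = FALSE]
  b$i <- map[b$i]; b$j <- map[b$j]
  an$i <- map[an$i]; an$j <- map[an$j]; an$k <- map[an$k]
  a <- topology@atoms[subset, , drop = FALSE]
  if (length(q) != length(subset)) q <- q[subset]
  n <- length(subset)
  excl <- rbind(cbind(b$i, b$j), if (nrow(an)) cbind(an$i, an$k))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (!is.null(excl) && nrow(excl)) {
    key <- pmin(excl[, 1], excl[, 2]) + n * pmax(excl[, 1], excl[, 2])
    pairs <- pairs[!(pairs[, 1] + n * pairs[, 2]) %in% key, , drop = FALSE]
  }
  i <- pairs[, 1]; j <- pairs[, 2]
  list(n = n, bonds = b, angles = an, pi = i, pj = j,
       qq = .kCoulomb * q[i] * q[j],
       rmin = a$rmin_half[i] + a$rmin_half[j],
       epsij = sqrt(a$epsilon[i] * a$epsilon[j]),
       topo = new("Topology", atoms = a, bonds = b, angles = an))
}

.toyEval <- function(model, coords, gradient = FALSE) {
  n <- model$n
  E <- toyBondedEnergy(coords, model$topo, gradient = gradient)
  G <- if (gradient) attr(E, "gradient") else NULL
  E <- as.numeric(E)
  if (length(model$pi)) {
    i <- model$pi; j <- model$pj
    d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    r2 <- rowSums(d * d); r <- sqrt(r2)
    sr6 <- (model$rmin / r)^6
    E <- E + sum(model$qq / r) + sum(model$epsij * (sr6 * sr6 - 2 * sr6))
    if (gradient) {
      dEdr <- -model$qq / r2 + model$epsij * (-12 * sr6 * sr6 + 12 * sr6) / r
      gv <- d * (dEdr / r)
      for (c3 in 1:3) {
        gc <- numeric(n)
        acc <- rowsum(c(gv[, c3], -gv[, c3]), c(i, j))
        gc[as.integer(rownames(acc))] <- acc
        G[, c3] <- G[, c3] + gc
      }
    }
  }
  if (gradient) attr(E, "gradient") <- G
  E
}

# Convenience wrapper kept for one-shot evaluations
.toyTotalEnergy <- function(coords, topology, q, gradient = FALSE,
                            subset = NULL) {
  model <- .toyModel(topology, q, subset)
  if (!is.null(subset) && nrow(coords) != model$n)
    coords <- coords[subset, , drop = FALSE]
  .toyEval(model, coords, gradient)
}
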