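# Hydrogen-bond detection, occupancy/native-fraction statistics, and the
# four-atom (C,O)x(N,H) Coulomb hydrogen-bond energy.

#' Geometric hydrogen-bond criteria
#'
#' Detection uses the donor-acceptor heavy-atom distance together with the
#' donor-hydrogen-acceptor angle, both cutoffs inclusive (a pair at exactly
#' 3.5 Angstrom and exactly 120 degrees counts as bonded).
#'
#' @param distance donor-acceptor heavy-atom cutoff, Angstrom (default 3.5)
#' @param angle donor-H-acceptor cutoff, degrees (default 120)
#' @return a list of class `hbondCriteria`
#' @export
hbondCriteria <- function(distance = 3.5, angle = 120) {
  if (distance <= 0) stop("distance cutoff must be > 0")
  if (angle <= 0 || angle > 180) stop("angle cutoff must be in (0, 180]")
  structure(list(distance = distance, angle = angle), class = "hbondCriteria")
}

#' Enumerate candidate hydrogen bonds from topology connectivity
#'
#' Donors are N-H pairs read from the bond list; acceptors are carbonyl-type
#' O atoms with their bonded antecedent C. The `backbone` scope keeps amide
#' N-H donors against carbonyl C=O acceptors within the protein segment,
#' separated by at least 2 residues; `protein_ligand` keeps pairs crossing
#' the protein/ligand boundary; `all` keeps every donor/acceptor combination
#' outside the donor's own residue. The list is deterministic (ordered by
#' donor then acceptor index) and duplicate-free. A backbone nitrogen with no
#' bonded hydrogen raises a warning and is skipped.
#'
#' @param topology a [Topology-class] with hydrogens and bond records
#' @param scope `"backbone"`, `"protein_ligand"` or `"all"`
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `antecedent` (atom indices) and `class`
#' @export
hbondCandidates <- function(topology, scope = c("backbone", "protein_ligand", "all")) {
  scope <- match.arg(scope)
  a <- topology@atoms
  b <- topology@bonds
  if (!nrow(b)) stop("topology has no bond records; cannot pair donors")
  pairs <- rbind(cbind(b$i, b$j), cbind(b$j, b$i))  # directed
  isN <- a$element == "N"; isH <- a$element == "H"
  isO <- a$element == "O"; isC <- a$element == "C"
  donors <- pairs[isN[pairs[, 1]] & isH[pairs[, 2]], , drop = FALSE]
  accept <- pairs[isO[pairs[, 1]] & isC[pairs[, 2]], , drop = FALSE]
  orphan <- which(isN & a$name == "N" & !(seq_len(nrow(a)) %in% donors[, 1]))
  if (length(orphan))
    warning(sprintf("%d backbone nitrogen(s) without a bonded hydrogen skipped (e.g. atom %d)",
                    length(orphan), orphan[1]))
  if (!nrow(donors) || !nrow(accept))
    return(.emptyHBonds())
  grid <- expand.grid(d = seq_len(nrow(donors)), ac = seq_len(nrow(accept)))
  D <- donors[grid$d, 1]; H <- donors[grid$d, 2]
  A <- accept[grid$ac, 1]; C <- accept[grid$ac, 2]
  segD <- a$segment[D]; segA <- a$segment[A]
  keep <- D != A & C != D &
    !(a$resid[D] == a$resid[A] & segD == segA)
  if (scope == "backbone") {
    keep <- keep & segD == "protein" & segA == "protein" &
      a$name[D] == "N" & a$name[H] == "H" &
      a$name[A] == "O" & a$name[C] == "C" &
      abs(a$resid[D] - a$resid[A]) >= 2L
  } else if (scope == "protein_ligand") {
    keep <- keep & segD != "other" & segA != "other" & segD != segA
  } else {
    keep <- keep & segD != "other" & segA != "other"
  }
  out <- data.frame(donor = D[keep], hydrogen = H[keep], acceptor = A[keep],
                    antecedent = C[keep])
  out <- out[order(out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  cls <- ifelse(a$segment[out$donor] != a$segment[out$acceptor], "protein-ligand",
                ifelse(a$name[out$donor] == "N" & a$name[out$acceptor] == "O" &
                         a$segment[out$donor] == "protein",
                       "backbone", "other"))
  out$class <- cls
  out
}

#' Detect hydrogen bonds in one coordinate frame
#'
#' A candidate is present iff its donor-acceptor heavy-atom distance is at
#' most the distance cutoff AND its donor-hydrogen-acceptor angle is at least
#' the angle cutoff (both inclusive).
#'
#' @param coords `N x 3` frame coordinates
#' @param candidates data.frame from [hbondCandidates()] (or with the same
#'   index columns)
#' @param criteria a [hbondCriteria()]
#' @return logical presence flags, one per candidate
#' @export
hbondDetect <- function(coords, candidates, criteria = hbondCriteria()) {
  if (!nrow(candidates)) return(logical(0))
  D <- coords[candidates$donor, , drop = FALSE]
  H <- coords[candidates$hydrogen, , drop = FALSE]
  A <- coords[candidates$acceptor, , drop = FALSE]
  dDA <- sqrt(rowSums((D - A)^2))
  u <- D - H; v <- A - H
  cosang <- rowSums(u * v) /
    (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  # inclusive cutoffs, robust to last-digit rounding at the boundary
  dDA <= criteria$distance + 1e-9 & ang >= criteria$angle - 1e-9
}

#' Block-averaged native hydrogen-bond fraction series
#'
#' The native bond list is the set of candidates detected in the native
#' frame. Per trajectory frame, the fraction is the count of native bonds
#' still present divided by the native total; frames are then averaged in
#' consecutive blocks (the "every 100 snapshots" running fraction).
#'
#' @param traj a [Trajectory-class]
#' @param native `N x 3` native/crystal coordinates
#' @param criteria a [hbondCriteria()]
#' @param block frames per block (default 100; a final partial block is kept)
#' @param scope candidate scope passed to [hbondCandidates()]
#' @param candidates optional explicit candidate data.frame (overrides scope)
#' @return data.frame with `block`, `frameStart`, `frameEnd`, `fraction`;
#'   the per-frame fractions are in `attr(, "perFrame")`
#' @export
nativeFractionSeries <- function(traj, native, criteria = hbondCriteria(),
                                 block = 100L, scope = "backbone",
                                 candidates = NULL) {
  if (is.null(candidates))
    candidates <- hbondCandidates(traj@topology, scope)
  nat <- candidates[hbondDetect(native, candidates, criteria), , drop = FALSE]
  if (!nrow(nat)) stop("zero native hydrogen bonds under the criteria")
  nf <- nFrames(traj)
  frac <- vapply(seq_len(nf), function(f)
    mean(hbondDetect(frameCoords(traj, f), nat, criteria)), numeric(1))
  grp <- (seq_len(nf) - 1L) %/% as.integer(block)
  agg <- tapply(frac, grp, mean)
  starts <- tapply(seq_len(nf), grp, min)
  ends <- tapply(seq_len(nf), grp, max)
  out <- data.frame(block = as.integer(names(agg)) + 1L,
                    frameStart = as.integer(starts),
                    frameEnd = as.integer(ends),
                    fraction = as.numeric(agg))
  attr(out, "perFrame") <- frac
  attr(out, "nativeBonds") <- nat
  out
}

#' Four-atom Coulomb hydrogen-bond energy
#'
#' The energy statistic of an amide hydrogen bond: the vacuum Coulomb energy
#' over the four C,O (acceptor side) by N,H (donor side) pairs,
#' `E = k * sum q_i q_j / r_ij` with `k = 332.0636` kcal*Angstrom/(mol*e^2),
#' dielectric 1 and no cutoff. Even in the charges: `E(q) == E(-q)`.
#'
#' @param coords `N x 3` frame coordinates
#' @param hbonds one or more bond rows (data.frame as from
#'   [hbondCandidates()])
#' @param chargeSource a [ChargeSet-class], a [Topology-class] (its charges),
#'   or a numeric per-atom charge vector
#' @return numeric vector, kcal/mol per bond
#' @export
hbondCoulombEnergy <- function(coords, hbonds, chargeSource) {
  q <- if (is(chargeSource, "ChargeSet")) charges(chargeSource)
       else if (is(chargeSource, "Topology")) charges(chargeSource)
       else as.numeric(chargeSource)
  if (!nrow(hbonds)) return(numeric(0))
  E <- numeric(nrow(hbonds))
  for (side1 in c("antecedent", "acceptor")) for (side2 in c("donor", "hydrogen")) {
    i <- hbonds[[side1]]; j <- hbonds[[side2]]
    r <- sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
    if (any(r < 0.1))
      stop(sprintf("atom clash: r = %.3f Angstrom between atoms %d and %d",
                   min(r), i[which.min(r)], j[which.min(r)]))
    E <- E + .kCoulomb * q[i] * q[j] / r
  }
  unname(E)
}

#' Per-bond time series: presence, distance, energy, occupancy
#'
#' @param traj a [Trajectory-class]
#' @param hbond a single bond row (data.frame)
#' @param criteria a [hbondCriteria()]
#' @param chargeSource optional charge source for the per-frame Coulomb
#'   energy (omitted if `NULL`)
#' @return data.frame with columns `frame`, `present`, `distance` and
#'   optionally `energy`; occupancy (mean presence) in `attr(, "occupancy")`
#' @export
hbondSeries <- function(traj, hbond, criteria = hbondCriteria(),
                        chargeSource = NULL) {
  nf <- nFrames(traj)
  present <- logical(nf); dist <- numeric(nf)
  energy <- if (is.null(chargeSource)) NULL else numeric(nf)
  for (f in seq_len(nf)) {
    m <- frameCoords(traj, f)
    present[f] <- hbondDetect(m, hbond, criteria)
    dist[f] <- sqrt(sum((m[hbond$donor, ] - m[hbond$acceptor, ])^2))
    if (!is.null(energy)) energy[f] <- hbondCoulombEnergy(m, hbond, chargeSource)
  }
  out <- data.frame(frame = traj@frameIndex, present = present, distance = dist)
  if (!is.null(energy)) out$energy <- energy
  attr(out, "occupancy") <- mean(present)
  out
}

#' Occupancy: fraction of frames in which a bond is present
#' @param series logical flags, or a data.frame from [hbondSeries()]
#' @return fraction in `[0, 1]`
#' @export
occupancy <- function(series) {
  if (is.data.frame(series)) series <- series$present
  if (!length(series)) stop("occupancy of an empty series")
  mean(series)
}

#' Mean hydrogen-bond energy over a trajectory
#'
#' Averages the four-atom Coulomb statistic over all frames, whether or not
#' the bond satisfies the geometric criteria in a given frame (full-
#' trajectory mean).
#'
#' @inheritParams hbondSeries
#' @param hbonds bond rows (data.frame)
#' @return numeric vector, mean kcal/mol per bond
#' @export
meanHBondEnergy <- function(traj, hbonds, chargeSource) {
  nf <- nFrames(traj)
  acc <- numeric(nrow(hbonds))
  for (f in seq_len(nf))
    acc <- acc + hbondCoulombEnergy(frameCoords(traj, f), hbonds, chargeSource)
  acc / nf
}
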