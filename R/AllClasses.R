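#' @import methods
NULL

.atomColumns <- c("serial", "name", "element", "resname", "resid", "segment",
                  "x", "y", "z", "charge", "rmin_half", "epsilon", "mass",
                  "pb_radius")

.segmentLevels <- c("protein", "ligand", "other")

#' Topology: atoms, parameters and bonded terms of a molecular system
#'
#' A `Topology` holds the ordered atom table (names, residues, segment
#' assignment, reference coordinates, partial charges, Lennard-Jones
#' `rmin/2`-`epsilon` parameters, masses and Poisson-Boltzmann radii) together
#' with harmonic bond and angle terms of the toy force field used for
#' minimization and normal-mode entropy. Nonbonded parameters follow the
#' AMBER convention: the pair minimum distance is `rmin_half[i] + rmin_half[j]`
#' and the well depth `sqrt(epsilon[i]*epsilon[j])` (Lorentz-Berthelot).
#'
#' @slot atoms data.frame with one row per atom; columns `serial`, `name`,
#'   `element`, `resname`, `resid`, `segment` (`protein`/`ligand`/`other`),
#'   `x`,`y`,`z` (reference coordinates, Angstrom), `charge` (e),
#'   `rmin_half` (Angstrom), `epsilon` (kcal/mol), `mass` (amu),
#'   `pb_radius` (Angstrom).
#' @slot bonds data.frame with columns `i`, `j` (1-based atom indices, each
#'   pair stored once), `k` (kcal/mol/A^2) and `r0` (Angstrom); the bond
#'   energy is `k*(r - r0)^2`.
#' @slot angles data.frame with columns `i`, `j`, `k`, `kth`
#'   (kcal/mol/rad^2) and `th0` (radians); the angle energy is
#'   `kth*(theta - th0)^2`.
#'
#' @seealso [readTopology()], [readStructure()], [residueTable()]
#' @export
setClass("Topology", representation(
  atoms  = "data.frame",
  bonds  = "data.frame",
  angles = "data.frame"
))

setValidity("Topology", function(object) {
  a <- object@atoms
  msgs <- character()
  missing <- setdiff(.atomColumns, names(a))
  if (length(missing))
    return(paste("atom table lacks columns:", paste(missing, collapse = ", ")))
  if (nrow(a) == 0L) msgs <- c(msgs, "topology has zero atoms")
  if (!all(a$segment %in% .segmentLevels))
    msgs <- c(msgs, "segment must be one of protein/ligand/other")
  if (any(!is.na(a$pb_radius) & a$pb_radius <= 0))
    msgs <- c(msgs, "pb_radius must be > 0")
  if (any(!is.na(a$epsilon) & a$epsilon < 0))
    msgs <- c(msgs, "lj epsilon must be >= 0")
  if (any(!is.na(a$mass) & a$mass <= 0))
    msgs <- c(msgs, "mass must be > 0")
  for (seg in unique(a$segment)) {
    r <- a$resid[a$segment == seg]
    if (any(diff(r) < 0))
      msgs <- c(msgs, sprintf("residue_index not non-decreasing in segment %s", seg))
  }
  bondIdx <- unlist(object@bonds[, intersect(c("i", "j"), names(object@bonds))],
                    use.names = FALSE)
  angIdx <- unlist(object@angles[, intersect(c("i", "j", "k"), names(object@angles))],
                   use.names = FALSE)
  idx <- c(bondIdx, angIdx)
  if (length(idx) && any(idx < 1L | idx > nrow(a)))
    msgs <- c(msgs, "bonded term index out of range")
  b <- object@bonds
  if (nrow(b)) {
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate bond pair")
    if (any(b$i == b$j)) msgs <- c(msgs, "bond with i == j")
  }
  if (!any(is.na(a$charge)) && nrow(a)) {
    tot <- sum(a$charge)
    if (abs(tot - round(tot)) > 1e-3)
      msgs <- c(msgs, sprintf("total charge %.4f e is not within 1e-3 of an integer", tot))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Trajectory: ordered coordinate frames over a fixed Topology
#'
#' @slot topology the [Topology-class] the frames refer to.
#' @slot coords numeric array `N x 3 x F` (Angstrom).
#' @slot frameIndex strictly increasing integer frame labels.
#' @slot time frame times in ns (0 when unknown).
#' @export
setClass("Trajectory", representation(
  topology   = "Topology",
  coords     = "array",
  frameIndex = "integer",
  time       = "numeric"
))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  n <- nrow(object@topology@atoms)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an N x 3 x F array")
  if (d[1] != n)
    return(sprintf("coords hold %d atoms but topology has %d", d[1], n))
  if (d[3] != length(object@frameIndex) || d[3] != length(object@time))
    return("frameIndex/time length must equal frame count")
  if (length(object@frameIndex) > 1L && any(diff(object@frameIndex) <= 0L))
    return("frame_index must be strictly increasing")
  if (any(!is.finite(object@coords)))
    return("non-finite coordinates")
  TRUE
})

#' ChargeSet: a named per-atom partial-charge vector
#'
#' Charge sets are the swappable axis of the mixed charge-by-trajectory
#' design: the same Topology can be evaluated under its force-field charges
#' or under a polarized set while every other parameter stays fixed.
#'
#' @slot label character label, e.g. `"base"` or `"polarized"`.
#' @slot charges numeric vector of per-atom charges (e), in topology atom
#'   order; the total must be within 1e-3 e of an integer.
#' @export
setClass("ChargeSet", representation(label = "character", charges = "numeric"))

setValidity("ChargeSet", function(object) {
  if (length(object@label) != 1L) return("label must be a single string")
  tot <- sum(object@charges)
  if (length(object@charges) && abs(tot - round(tot)) > 1e-3)
    return(sprintf("total charge %.4f e is not within 1e-3 of an integer", tot))
  if (any(!is.finite(object@charges))) return("non-finite charge")
  TRUE
})

#' AtomSelection: a deterministic set of atom indices
#'
#' @slot indices unique, sorted 1-based atom indices.
#' @slot expr the selection expression the indices came from (provenance).
#' @export
setClass("AtomSelection", representation(indices = "integer", expr = "character"))

setValidity("AtomSelection", function(object) {
  if (anyDuplicated(object@indices)) return("duplicate indices in selection")
  if (length(object@indices) && any(object@indices < 1L))
    return("selection index out of range")
  TRUE
})

#' @describeIn Topology-class constructor
#' @param atoms,bonds,angles see slots.
#' @export
Topology <- function(atoms,
                     bonds = data.frame(i = integer(), j = integer(),
                                        k = numeric(), r0 = numeric()),
                     angles = data.frame(i = integer(), j = integer(),
                                         k = integer(), kth = numeric(),
                                         th0 = numeric())) {
  atoms$segment <- as.character(atoms$segment)
  new("Topology", atoms = atoms, bonds = bonds, angles = angles)
}

#' @describeIn Trajectory-class constructor
#' @param topology,coords,frameIndex,time see slots; `coords` may also be a
#'   list of `N x 3` matrices.
#' @export
Trajectory <- function(topology, coords, frameIndex = NULL, time = NULL) {
  if (is.list(coords)) {
    n <- nrow(topology@atoms)
    coords <- array(unlist(lapply(coords, function(m) as.numeric(m)),
                           use.names = FALSE),
                    dim = c(n, 3L, length(coords)))
  }
  if (length(dim(coords)) == 2L) coords <- array(coords, dim = c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (is.null(frameIndex)) frameIndex <- seq_len(nf)
  if (is.null(time)) time <- rep(0, nf)
  new("Trajectory", topology = topology, coords = coords,
      frameIndex = as.integer(frameIndex), time = as.numeric(time))
}

#' @describeIn ChargeSet-class constructor
#' @param label,charges see slots.
#' @export
ChargeSet <- function(label, charges) {
  new("ChargeSet", label = as.character(label), charges = as.numeric(charges))
}
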