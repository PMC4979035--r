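#' @include AllClasses.R
NULL

#' Number of atoms
#' @param x a [Topology-class] or [Trajectory-class]
#' @return integer
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])

#' Number of trajectory frames
#' @param x a [Trajectory-class]
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' Atom table of a Topology
#' @param x a [Topology-class] or [Trajectory-class]
#' @return data.frame, one row per atom
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "Topology", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' Per-atom partial charges
#' @param x a [Topology-class] or [ChargeSet-class]
#' @return numeric vector (e)
#' @export
setGeneric("charges", function(x) standardGeneric("charges"))

#' @rdname charges
#' @export
setMethod("charges", "Topology", function(x) x@atoms$charge)

#' @rdname charges
#' @export
setMethod("charges", "ChargeSet", function(x) x@charges)

#' Coordinates of one trajectory frame
#' @param x a [Trajectory-class]
#' @param i frame position (1-based, by storage order)
#' @return `N x 3` matrix (Angstrom)
#' @export
setGeneric("frameCoords", function(x, i = 1L) standardGeneric("frameCoords"))

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "Trajectory", function(x, i = 1L) {
  m <- x@coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
})

#' Reference coordinates stored on a Topology
#' @param x a [Topology-class]
#' @return `N x 3` matrix (Angstrom)
#' @export
setGeneric("refCoords", function(x) standardGeneric("refCoords"))

#' @rdname refCoords
#' @export
setMethod("refCoords", "Topology", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' Derived residue table
#'
#' One row per residue in atom order: residue name, residue index, segment
#' and the atom span (first/last atom row).
#' @param topology a [Topology-class]
#' @return data.frame with columns `resname`, `resid`, `segment`, `first`,
#'   `last`, `natoms`
#' @export
residueTable <- function(topology) {
  a <- topology@atoms
  key <- paste(a$segment, a$resid, sep = "\r")
  grp <- match(key, unique(key))
  first <- match(seq_along(unique(key)), grp)
  last  <- length(grp) - match(seq_along(unique(key)), rev(grp)) + 1L
  data.frame(resname = a$resname[first], resid = a$resid[first],
             segment = a$segment[first], first = first, last = last,
             natoms = last - first + 1L)
}

#' Indices of a selection
#' @param x an [AtomSelection-class] or plain integer vector
#' @return integer vector
#' @export
selectionIndices <- function(x) {
  if (is(x, "AtomSelection")) x@indices else as.integer(x)
}

#' Replace the charges of a topology with a ChargeSet
#'
#' Only the `charge` column changes; every other parameter (Lennard-Jones,
#' masses, radii, bonded terms) is untouched, mirroring the way a polarized
#' charge set is swapped onto an otherwise fixed force field. Applying a set
#' twice is idempotent; applying a second set overwrites, never accumulates.
#'
#' @param topology a [Topology-class]
#' @param chargeSet a [ChargeSet-class] with one charge per atom
#' @return a [Topology-class]
#' @export
applyChargeSet <- function(topology, chargeSet) {
  q <- charges(chargeSet)
  if (length(q) != nAtoms(topology))
    stop(sprintf("charge set '%s' has %d charges but topology has %d atoms",
                 chargeSet@label, length(q), nAtoms(topology)))
  topology@atoms$charge <- q
  validObject(topology)
  topology
}

setMethod("show", "Topology", function(object) {
  rt <- residueTable(object)
  cat(sprintf("Topology: %d atoms, %d residues (%s), %d bonds, %d angles\n",
              nAtoms(object), nrow(rt),
              paste(sprintf("%d %s", tabulate(factor(rt$segment, .segmentLevels)),
                            .segmentLevels)[tabulate(factor(rt$segment, .segmentLevels)) > 0],
                    collapse = ", "),
              nrow(object@bonds), nrow(object@angles)))
  if (!any(is.na(object@atoms$charge)))
    cat(sprintf("  total charge %+.3f e\n", sum(object@atoms$charge)))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames x %d atoms", nFrames(object), nAtoms(object)))
  if (any(object@time != 0))
    cat(sprintf(", %.3f-%.3f ns", min(object@time), max(object@time)))
  cat("\n")
})

setMethod("show", "ChargeSet", function(object) {
  cat(sprintf("ChargeSet '%s': %d charges, total %+.3f e\n",
              object@label, length(object@charges), sum(object@charges)))
})

setMethod("show", "AtomSelection", function(object) {
  cat(sprintf("AtomSelection (%s): %d atoms\n", object@expr,
              length(object@indices)))
})
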