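.waterIonNames <- c("HOH", "WAT", "TIP3", "TP3", "SOL", "NA", "NA+", "SOD",
                    "CL", "CL-", "CLA", "K", "K+", "MG", "ZN", "MN", "CS",
                    "LI", "RB", "IOD", "BR")

.inferElement <- function(name) {
  s <- sub("^[0-9]+", "", trimws(name))
  two <- toupper(substr(s, 1, 2))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN"), two,
         toupper(substr(s, 1, 1)))
}

#' Read a structure (and trajectory frames) from PDB or XYZ
#'
#' Parses `ATOM`/`HETATM`/`MODEL`/`ENDMDL`/`TER` records. Every `MODEL` block
#' becomes one trajectory frame (a file without `MODEL` records yields a
#' single frame); atom order is preserved verbatim, as is residue numbering.
#' `HETATM` atoms are assigned `segment = "ligand"` unless their residue name
#' marks water or a monatomic ion, which become `segment = "other"` and are
#' excluded from all energy terms downstream. The returned topology is a
#' skeleton: coordinates, names and residues are filled, force-field
#' parameters are `NA` until supplied by [readTopology()] or a generator.
#'
#' The `xyz` dialect accepts plain whitespace XYZ (count line, comment line,
#' `element x y z` rows, frames concatenated); it carries no residue
#' information, so all atoms land in residue 1 of segment `other`.
#'
#' @param path file path
#' @param dialect `"pdb"` (default) or `"xyz"`
#' @return list with elements `topology` ([Topology-class] skeleton) and
#'   `trajectory` ([Trajectory-class], one frame per model)
#' @export
readStructure <- function(path, dialect = c("pdb", "xyz")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "xyz") return(.readXYZ(lines, path))

  isAtom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  nModelStarts <- sum(startsWith(lines, "MODEL"))
  frameOf <- cumsum(startsWith(lines, "MODEL"))
  if (nModelStarts == 0L) frameOf <- rep(1L, length(lines))
  atomLines <- lines[isAtom]
  if (length(atomLines) == 0L) stop("no ATOM/HETATM records in ", path)
  atomFrame <- frameOf[isAtom]
  atomFrame[atomFrame == 0L] <- 1L
  lineNo <- which(isAtom)

  fx <- function(from, to) substr(atomLines, from, to)
  xyz <- suppressWarnings(cbind(as.numeric(fx(31, 38)),
                                as.numeric(fx(39, 46)),
                                as.numeric(fx(47, 54))))
  bad <- which(!is.finite(xyz[, 1]) | !is.finite(xyz[, 2]) | !is.finite(xyz[, 3]))
  if (length(bad))
    stop(sprintf("malformed coordinate field at line %d of %s", lineNo[bad[1]], path))

  firstFrame <- atomFrame == atomFrame[1]
  n <- sum(firstFrame)
  nf <- length(unique(atomFrame))
  if (length(atomLines) != n * nf)
    stop(sprintf("models differ in atom count in %s", path))

  rec <- fx(1, 6)[firstFrame]
  name <- trimws(fx(13, 16)[firstFrame])
  resname <- trimws(fx(18, 20)[firstFrame])
  resid <- suppressWarnings(as.integer(trimws(fx(23, 26)[firstFrame])))
  if (any(is.na(resid)))
    stop(sprintf("malformed residue number at line %d of %s",
                 lineNo[firstFrame][which(is.na(resid))[1]], path))
  elem <- trimws(fx(77, 78)[firstFrame])
  elem[elem == ""] <- .inferElement(name[elem == ""])
  segment <- ifelse(startsWith(rec, "HETATM"),
                    ifelse(toupper(resname) %in% .waterIonNames, "other", "ligand"),
                    "protein")

  atoms <- data.frame(serial = seq_len(n), name = name, element = elem,
                      resname = resname, resid = resid, segment = segment,
                      x = xyz[firstFrame, 1], y = xyz[firstFrame, 2],
                      z = xyz[firstFrame, 3],
                      charge = NA_real_, rmin_half = NA_real_,
                      epsilon = NA_real_, mass = NA_real_,
                      pb_radius = NA_real_)
  topo <- Topology(atoms)
  coords <- array(NA_real_, dim = c(n, 3L, nf))
  for (f in seq_len(nf)) coords[, , f] <- xyz[atomFrame == unique(atomFrame)[f], ]
  list(topology = topo,
       trajectory = Trajectory(topo, coords, frameIndex = seq_len(nf)))
}

.readXYZ <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no atoms in ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) stop("malformed XYZ count line in ", path)
  per <- n + 2L
  nf <- length(lines) %/% per
  if (nf * per != length(lines)) stop("truncated XYZ frame in ", path)
  coords <- array(NA_real_, dim = c(n, 3L, nf))
  elem <- character(n)
  for (f in seq_len(nf)) {
    rows <- strsplit(trimws(lines[(f - 1L) * per + 2L + seq_len(n)]), "\\s+")
    m <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    if (any(!is.finite(m))) stop("malformed XYZ coordinate in ", path)
    coords[, , f] <- m
    if (f == 1L) elem <- vapply(rows, `[`, "", 1L)
  }
  atoms <- data.frame(serial = seq_len(n), name = elem, element = toupper(elem),
                      resname = "UNK", resid = 1L, segment = "other",
                      x = coords[, 1, 1], y = coords[, 2, 1], z = coords[, 3, 1],
                      charge = NA_real_, rmin_half = NA_real_,
                      epsilon = NA_real_, mass = NA_real_, pb_radius = NA_real_)
  topo <- Topology(atoms)
  list(topology = topo, trajectory = Trajectory(topo, coords))
}

#' Write a structure or trajectory as (multi-model) PDB
#'
#' Coordinates are written fixed-width at 3 decimals (PDB precision); a
#' multi-frame trajectory becomes `MODEL`/`ENDMDL` blocks, with `TER` records
#' between segments.
#'
#' @param x a [Trajectory-class], or a [Topology-class] (reference
#'   coordinates, single model)
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeStructure <- function(x, path) {
  if (is(x, "Topology")) x <- Trajectory(x, refCoords(x))
  a <- atoms(x)
  rec <- ifelse(a$segment == "protein", "ATOM  ", "HETATM")
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  out <- character()
  nf <- nFrames(x)
  for (f in seq_len(nf)) {
    m <- frameCoords(x, f)
    body <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    rec, a$serial %% 100000L, name4, substr(a$resname, 1, 3),
                    "A", a$resid %% 10000L, m[, 1], m[, 2], m[, 3], 1, 0,
                    substr(a$element, 1, 2))
    segBreak <- which(a$segment[-1] != a$segment[-nrow(a)])
    for (s in rev(segBreak)) body <- append(body, "TER", after = s)
    if (nf > 1L) body <- c(sprintf("MODEL     %4d", x@frameIndex[f]), body, "ENDMDL")
    out <- c(out, body)
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a full topology from JSON or CSV
#'
#' The JSON dialect holds objects `atoms`, `bonds`, `angles` whose fields
#' mirror the [Topology-class] slots. The CSV dialect is the atom table only
#' (no bonded terms). All class invariants are validated on load, including
#' the integer-total-charge rule.
#'
#' @param path file path ending in `.json` or `.csv`
#' @return a [Topology-class]
#' @export
readTopology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    if (is.null(obj$atoms)) stop("topology schema error: missing 'atoms' in ", path)
    atoms <- as.data.frame(obj$atoms)
    bonds <- if (!is.null(obj$bonds) && length(obj$bonds))
      as.data.frame(obj$bonds) else
      data.frame(i = integer(), j = integer(), k = numeric(), r0 = numeric())
    angles <- if (!is.null(obj$angles) && length(obj$angles))
      as.data.frame(obj$angles) else
      data.frame(i = integer(), j = integer(), k = integer(),
                 kth = numeric(), th0 = numeric())
  } else {
    atoms <- utils::read.csv(path, stringsAsFactors = FALSE)
    bonds <- data.frame(i = integer(), j = integer(), k = numeric(), r0 = numeric())
    angles <- data.frame(i = integer(), j = integer(), k = integer(),
                         kth = numeric(), th0 = numeric())
  }
  missing <- setdiff(.atomColumns, names(atoms))
  if (length(missing))
    stop("topology schema error: missing column(s) ", paste(missing, collapse = ", "),
         " in ", path)
  topo <- Topology(atoms[, .atomColumns], bonds, angles)
  validObject(topo)
  topo
}

#' Write a topology as JSON
#' @param topology a [Topology-class]
#' @param path output path (`.json`)
#' @return `path`, invisibly
#' @export
writeTopology <- function(topology, path) {
  jsonlite::write_json(list(atoms = topology@atoms, bonds = topology@bonds,
                            angles = topology@angles),
                       path, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read/write a charge set as two-column CSV (serial, charge)
#' @param path CSV path
#' @param label label for the returned set (default: file name sans extension)
#' @return a [ChargeSet-class]
#' @export
readChargeSet <- function(path, label = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("serial", "charge") %in% names(df)))
    stop("charge set CSV needs columns 'serial' and 'charge': ", path)
  ChargeSet(label, df$charge[order(df$serial)])
}

#' @rdname readChargeSet
#' @param chargeSet a [ChargeSet-class]
#' @export
writeChargeSet <- function(chargeSet, path) {
  utils::write.csv(data.frame(serial = seq_along(chargeSet@charges),
                              charge = chargeSet@charges),
                   path, row.names = FALSE)
  invisible(path)
}
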