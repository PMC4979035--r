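# Polar solvation via a finite-difference linear Poisson-Boltzmann solver
# (solvent-excluded dielectric boundary, Dirichlet Coulomb boundary
# conditions, red-black SOR relaxation) plus Shrake-Rupley SASA and the
# empirical nonpolar term gamma*SASA + beta.

#' Poisson-Boltzmann solver parameters
#'
#' Defaults follow standard implicit-solvent practice for protein-ligand
#' end-state calculations: interior dielectric 1, solvent dielectric 80,
#' solvent probe 1.4 Angstrom, 4 grid points per Angstrom, zero ionic
#' strength (linear PB).
#'
#' @param epsIn interior (solute) dielectric (default 1)
#' @param epsOut exterior (solvent) dielectric (default 80)
#' @param probe solvent probe radius, Angstrom (default 1.4)
#' @param gridDensity grid points per Angstrom (default 4)
#' @param padding grid padding beyond the solute, Angstrom (default 10)
#' @param maxIter relaxation iteration cap
#' @param tol convergence threshold on the relative residual
#' @return list of class `pbParams`
#' @export
pbParams <- function(epsIn = 1, epsOut = 80, probe = 1.4, gridDensity = 4,
                     padding = 10, maxIter = 20000L, tol = 1e-6) {
  if (!(epsOut > epsIn) || epsIn < 1) stop("need epsOut > epsIn >= 1")
  if (gridDensity <= 0) stop("grid density must be > 0")
  structure(list(epsIn = epsIn, epsOut = epsOut, probe = probe,
                 gridDensity = gridDensity, padding = padding,
                 maxIter = as.integer(maxIter), tol = tol),
            class = "pbParams")
}

#' Construct the finite-difference grid for a set of atoms
#'
#' Spacing is exactly `1/gridDensity`; the box spans the atom spheres plus
#' `padding` on every side. Pass the same grid to several solves (complex,
#' receptor, ligand) so grid self-energies cancel in differences.
#'
#' @param coords `N x 3` coordinates
#' @param radii per-atom radii, Angstrom
#' @param params a [pbParams()]
#' @return list with `origin`, `h`, `dims`
#' @export
pbGrid <- function(coords, radii, params = pbParams()) {
  h <- 1 / params$gridDensity
  lo <- apply(coords - radii, 2, min) - params$padding
  hi <- apply(coords + radii, 2, max) + params$padding
  dims <- as.integer(ceiling((hi - lo) / h)) + 1L
  center <- (lo + hi) / 2
  origin <- center - (dims - 1L) * h / 2
  list(origin = origin, h = h, dims = dims)
}

#' Dielectric map on the grid faces
#'
#' Marks grid-edge midpoints inside the solvent-excluded region with `epsIn`
#' and the rest with `epsOut`. The solvent-excluded region is the
#' probe-inflated union of atom spheres, eroded by rolling the probe on the
#' grid (two-pass inflate/deflate), which approximates the re-entrant
#' molecular surface without analytic surface construction.
#'
#' @inheritParams pbGrid
#' @param topology a [Topology-class] (uses `pb_radius`)
#' @param grid optional grid from [pbGrid()]
#' @return list with `epsx`, `epsy`, `epsz` (3D arrays on faces), `inside`
#'   (logical array of interior nodes) and the grid geometry
#' @export
dielectricMap <- function(coords, topology, params = pbParams(), grid = NULL) {
  radii <- topology@atoms$pb_radius
  if (any(is.na(radii) | radii <= 0)) stop("pb_radius must be set for all atoms")
  if (is.null(grid)) grid <- pbGrid(coords, radii, params)
  lo <- grid$origin; hi <- grid$origin + (grid$dims - 1L) * grid$h
  if (any(apply(coords - radii, 2, min) < lo) ||
      any(apply(coords + radii, 2, max) > hi))
    stop("molecule does not fit the grid after padding")
  res <- cpp_dielectric_faces(as.matrix(coords), radii, grid$origin, grid$h,
                              grid$dims, params$probe, params$epsIn,
                              params$epsOut)
  dm <- lapply(res[c("epsx", "epsy", "epsz", "inside")], array, dim = grid$dims)
  c(dm, grid)
}

# trilinear spread of point charges onto grid nodes
.spreadCharges <- function(coords, q, grid) {
  g <- array(0, dim = grid$dims)
  t0 <- sweep(coords, 2, grid$origin) / grid$h
  i0 <- pmin(pmax(floor(t0), 0), matrix(rep(grid$dims - 2L, each = nrow(coords)),
                                        ncol = 3))
  f <- t0 - i0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
         (if (dy == 1) f[, 2] else 1 - f[, 2]) *
         (if (dz == 1) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L, i0[, 3] + dz + 1L)
    for (r in seq_len(nrow(idx)))
      g[idx[r, 1], idx[r, 2], idx[r, 3]] <- g[idx[r, 1], idx[r, 2], idx[r, 3]] +
        w[r] * q[r]
  }
  g
}

# trilinear interpolation of a grid field at points
.interpGrid <- function(field, grid, coords) {
  t0 <- sweep(coords, 2, grid$origin) / grid$h
  i0 <- pmin(pmax(floor(t0), 0), matrix(rep(grid$dims - 2L, each = nrow(coords)),
                                        ncol = 3))
  f <- t0 - i0
  out <- numeric(nrow(coords))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx == 1) f[, 1] else 1 - f[, 1]) *
         (if (dy == 1) f[, 2] else 1 - f[, 2]) *
         (if (dz == 1) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L, i0[, 3] + dz + 1L)
    out <- out + w * field[idx]
  }
  out
}

# Coulomb potential of the atoms, screened by a uniform dielectric, on a
# set of grid nodes given by index matrix (n x 3, 1-based)
.coulombAtNodes <- function(coords, q, grid, nodeIdx, eps) {
  pos <- sweep((nodeIdx - 1L), 2, grid$h, "*")
  pos <- sweep(pos, 2, grid$origin, "+")
  out <- numeric(nrow(pos))
  for (a in seq_len(nrow(coords))) {
    r <- sqrt((pos[, 1] - coords[a, 1])^2 + (pos[, 2] - coords[a, 2])^2 +
              (pos[, 3] - coords[a, 3])^2)
    r[r < grid$h / 2] <- grid$h / 2
    out <- out + .kCoulomb * q[a] / (eps * r)
  }
  out
}

#' Solve the linear Poisson-Boltzmann equation on a grid
#'
#' Discretizes `div(eps grad phi) = -4 pi k rho` (zero ionic strength) with
#' trilinear charge spreading and face dielectrics from [dielectricMap()],
#' fixes the box boundary to the atom-centred Coulomb potential screened by
#' the solvent dielectric, and relaxes with red-black SOR until the relative
#' residual drops below `params$tol`.
#'
#' @inheritParams dielectricMap
#' @param chargeSource [ChargeSet-class], [Topology-class] or numeric vector
#' @param uniform if `TRUE`, solve the reference state with dielectric
#'   `epsIn` everywhere (same grid, same charge spreading)
#' @param dielectric optional precomputed [dielectricMap()] for this
#'   grid/conformation (reused across solves that share both)
#' @return list of class `pbSolution`: `phi` (3D array, kcal/(mol e)),
#'   `grid`, `dielectric` (when not uniform), `q` (node source charges),
#'   `iterations`, `residual`, `converged`
#' @export
solvePB <- function(coords, topology, chargeSource = topology,
                    params = pbParams(), grid = NULL, uniform = FALSE,
                    dielectric = NULL) {
  coords <- as.matrix(coords)
  q <- if (is(chargeSource, "ChargeSet")) charges(chargeSource)
       else if (is(chargeSource, "Topology")) charges(chargeSource)
       else as.numeric(chargeSource)
  radii <- topology@atoms$pb_radius
  if (is.null(grid)) grid <- pbGrid(coords, radii, params)
  dm <- NULL
  if (uniform) {
    epsx <- epsy <- epsz <- array(params$epsIn, dim = grid$dims)
    epsBC <- params$epsIn
  } else {
    dm <- if (is.null(dielectric)) dielectricMap(coords, topology, params, grid)
          else dielectric
    epsx <- dm$epsx; epsy <- dm$epsy; epsz <- dm$epsz
    epsBC <- params$epsOut
  }
  qGrid <- .spreadCharges(coords, q, grid)
  src <- 4 * pi * .kCoulomb * qGrid / grid$h

  # initial guess + Dirichlet boundary: screened Coulomb
  dims <- grid$dims
  phi <- array(0, dim = dims)
  allIdx <- arrayInd(seq_along(phi), dims)
  phi[] <- .coulombAtNodes(coords, q, grid, allIdx, epsBC)

  sol <- cpp_sor_solve(phi, epsx, epsy, epsz, src, dims,
                       params$maxIter, params$tol,
                       2 / (1 + sin(pi / max(dims))))
  if (sol$residual > params$tol)
    stop(sprintf("PB solver did not converge: relative residual %.3g after %d iterations",
                 sol$residual, sol$iterations))
  structure(list(phi = phi, grid = grid, dielectric = dm, q = qGrid,
                 params = params, iterations = sol$iterations,
                 residual = sol$residual, converged = TRUE),
            class = "pbSolution")
}

#' Reaction-field potential and polar solvation energy
#'
#' Solves the solvated state (dielectric boundary) and the uniform reference
#' state (`epsIn` everywhere) on the identical grid with identical charge
#' spreading, so the grid self-energy cancels exactly in the difference.
#' `DeltaG_pol = 1/2 sum_i q_i * (phi_solv - phi_ref)(r_i)` with trilinear
#' interpolation at atom sites.
#'
#' @inheritParams solvePB
#' @return list: `energy` (kcal/mol), `phiRF` (reaction-field potential at
#'   each atom, kcal/(mol e)), `solution` (the solvated [solvePB()] result)
#' @export
reactionField <- function(coords, topology, chargeSource = topology,
                          params = pbParams(), grid = NULL,
                          dielectric = NULL) {
  coords <- as.matrix(coords)
  q <- if (is(chargeSource, "ChargeSet")) charges(chargeSource)
       else if (is(chargeSource, "Topology")) charges(chargeSource)
       else as.numeric(chargeSource)
  if (is.null(grid)) grid <- pbGrid(coords, topology@atoms$pb_radius, params)
  solv <- solvePB(coords, topology, q, params, grid, dielectric = dielectric)
  ref  <- solvePB(coords, topology, q, params, grid, uniform = TRUE)
  phiRF <- .interpGrid(solv$phi - ref$phi, grid, coords)
  list(energy = 0.5 * sum(q * phiRF), phiRF = phiRF, solution = solv)
}

#' @rdname reactionField
#' @return `polarSolvationEnergy` returns the energy alone (kcal/mol)
#' @export
polarSolvationEnergy <- function(coords, topology, chargeSource = topology,
                                 params = pbParams(), grid = NULL) {
  reactionField(coords, topology, chargeSource, params, grid)$energy
}

#' Induced surface charges at the dielectric boundary
#'
#' Recovers the bound (polarization) charge that the solvent induces at the
#' solute-solvent interface from the discrete solution: at each interior
#' node, `q_b = -(h / 4 pi k) * sum_faces (phi_nb - phi_c) - q_free`. In the
#' uniform-dielectric bulk this vanishes; at the boundary it reproduces the
#' reaction field. Gauss's law fixes the total at `-q_total (1 - 1/epsOut)`
#' for a fully enclosed solute with `epsIn = 1`.
#'
#' @param solution a converged [solvePB()] result (solvated state)
#' @param threshold drop nodes with `|q| <` threshold e (default 1e-5,
#'   which also suppresses discretization residue at the source nodes)
#' @return data.frame with `x`, `y`, `z` (Angstrom) and `charge` (e)
#' @export
inducedSurfaceCharges <- function(solution, threshold = 1e-5) {
  if (!isTRUE(solution$converged)) stop("solution not converged")
  phi <- solution$phi; g <- solution$grid
  d <- dim(phi)
  lap <- array(0, dim = d)
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
  lap[ix, iy, iz] <-
    phi[ix - 1, iy, iz] + phi[ix + 1, iy, iz] +
    phi[ix, iy - 1, iz] + phi[ix, iy + 1, iz] +
    phi[ix, iy, iz - 1] + phi[ix, iy, iz + 1] - 6 * phi[ix, iy, iz]
  qb <- -(g$h / (4 * pi * .kCoulomb)) * lap - solution$q
  qb[-ix, , ] <- 0; qb[, -iy, ] <- 0; qb[, , -iz] <- 0
  keep <- which(abs(qb) >= threshold)
  idx <- arrayInd(keep, d)
  pos <- sweep((idx - 1L), 2, g$h, "*")
  pos <- sweep(pos, 2, g$origin, "+")
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], charge = qb[keep])
}

#' Nonpolar solvation parameters
#' @param gamma surface tension, kcal/(mol Angstrom^2) (default 0.00542)
#' @param beta offset, kcal/mol (default 0.92)
#' @param spherePoints Shrake-Rupley sphere points per atom (default 960)
#' @export
nonpolarParams <- function(gamma = 0.00542, beta = 0.92, spherePoints = 960L) {
  if (gamma <= 0) stop("gamma must be > 0")
  structure(list(gamma = gamma, beta = beta,
                 spherePoints = as.integer(spherePoints)),
            class = "nonpolarParams")
}

# deterministic Fibonacci sphere points (unit radius)
.fibSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z * z))
  cbind(cos(phi) * s, sin(phi) * s, z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Counts, per atom, the fraction of `spherePoints` points on the
#' probe-expanded sphere not buried inside any neighbour's expanded sphere;
#' per-atom contributions sum to the total.
#'
#' @param coords `N x 3` coordinates
#' @param topology a [Topology-class] (`pb_radius` doubles as the vdW radius)
#' @param params a [nonpolarParams()]
#' @param probe probe radius, Angstrom (default 1.4)
#' @param subset optional atom indices to compute over (others ignored
#'   entirely, as for the separated-species terms)
#' @return list: `total` (Angstrom^2), `perAtom`
#' @export
sasa <- function(coords, topology, params = nonpolarParams(), probe = 1.4,
                 subset = NULL) {
  radii <- topology@atoms$pb_radius
  if (is.null(subset)) subset <- seq_len(nrow(coords))
  X <- as.matrix(coords)[subset, , drop = FALSE]
  R <- radii[subset] + probe
  n <- length(subset)
  pts <- .fibSphere(params$spherePoints)
  per <- numeric(n)
  for (a in seq_len(n)) {
    d2 <- rowSums(sweep(X, 2, X[a, ])^2)
    nb <- which(d2 < (R + R[a])^2 & seq_len(n) != a)
    sp <- sweep(pts * R[a], 2, X[a, ], "+")
    acc <- rep(TRUE, nrow(sp))
    for (b in nb) {
      acc <- acc & (rowSums(sweep(sp, 2, X[b, ])^2) > R[b]^2)
      if (!any(acc)) break
    }
    per[a] <- 4 * pi * R[a]^2 * mean(acc)
  }
  list(total = sum(per), perAtom = per)
}

#' Nonpolar solvation energy: gamma * SASA + beta
#'
#' For binding differences the `beta` offsets of complex, receptor and
#' ligand cancel, so `DeltaG_nonpol = gamma * DeltaSASA`.
#'
#' @param sasaTotal total SASA, Angstrom^2
#' @param params a [nonpolarParams()]
#' @return kcal/mol
#' @export
nonpolarEnergy <- function(sasaTotal, params = nonpolarParams()) {
  if (sasaTotal < 0) stop("negative SASA")
  params$gamma * sasaTotal + params$beta
}

#' Dump a grid field in OpenDX scalar format
#' @param solution a [solvePB()] result
#' @param path output path
#' @export
writeOpenDX <- function(solution, path) {
  g <- solution$grid; d <- g$dims
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %g 0 0", g$h), sprintf("delta 0 %g 0", g$h),
    sprintf("delta 0 0 %g", g$h),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.numeric(aperm(solution$phi, c(3, 2, 1)))
  writeLines(apply(matrix(c(vals, rep(NA, (3 - length(vals) %% 3) %% 3)),
                          nrow = 3), 2,
                   function(v) paste(format(v[!is.na(v)], digits = 6),
                                     collapse = " ")), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
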