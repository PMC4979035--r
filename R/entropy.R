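# Normal-mode entropy: local minimization on the toy force field, numerical
# mass-weighted Hessian, projection of rigid-body modes, and ideal-gas /
# rigid-rotor / quantum-harmonic-oscillator entropies.

#' Entropy calculation parameters
#'
#' @param temperature K (default 300, the simulation temperature)
#' @param minTol convergence tolerance on the gradient norm,
#'   kcal/mol/Angstrom (default 1e-4; RMS over coordinates)
#' @param hessianStep central-difference displacement, Angstrom (default 1e-4)
#' @param snapshots snapshots used for the entropy average in a pipeline run
#'   (default 20)
#' @export
entropyParams <- function(temperature = 300, minTol = 1e-4,
                          hessianStep = 1e-4, snapshots = 20L) {
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(temperature = temperature, minTol = minTol,
                 hessianStep = hessianStep, snapshots = as.integer(snapshots)),
            class = "entropyParams")
}

#' Minimize a structure on the toy force field
#'
#' L-BFGS-B on the toy energy (harmonic bonded terms plus all nonbonded
#' pairs excluding 1-2/1-3 neighbours) with the analytic gradient, run until
#' the RMS gradient falls below `params$minTol` or `maxRounds` restarts are
#' exhausted.
#'
#' @param coords `N x 3` start coordinates
#' @param topology a [Topology-class]
#' @param chargeSource charges for the nonbonded term
#' @param params an [entropyParams()]
#' @param subset optional atom indices: minimize that species alone
#' @param maxRounds optimizer restarts (default 5)
#' @return minimized `N x 3` (or `length(subset) x 3`) coordinates with
#'   attributes `energy` and `gradientNorm`
#' @export
minimizeStructure <- function(coords, topology, chargeSource = topology,
                              params = entropyParams(), subset = NULL,
                              maxRounds = 5L) {
  q <- if (is(chargeSource, "ChargeSet")) charges(chargeSource)
       else if (is(chargeSource, "Topology")) charges(chargeSource)
       else as.numeric(chargeSource)
  full <- as.matrix(coords)
  idx <- if (is.null(subset)) seq_len(nrow(full)) else selectionIndices(subset)
  x0 <- as.numeric(if (nrow(full) == length(idx)) full
                   else full[idx, , drop = FALSE])
  n <- length(idx)
  model <- .toyModel(topology, q, idx)
  fn <- function(x) as.numeric(.toyEval(model, matrix(x, n, 3)))
  gr <- function(x) as.numeric(attr(.toyEval(model, matrix(x, n, 3),
                                             gradient = TRUE), "gradient"))
  x <- x0
  for (round in seq_len(maxRounds)) {
    opt <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = 2000L, factr = 10))
    x <- opt$par
    gnorm <- sqrt(mean(gr(x)^2))
    if (gnorm <= params$minTol) break
  }
  if (gnorm > params$minTol)
    stop(sprintf("minimization did not converge: RMS gradient %.3g kcal/mol/A",
                 gnorm))
  out <- matrix(x, n, 3)
  attr(out, "energy") <- fn(x)
  attr(out, "gradientNorm") <- gnorm
  out
}

# numerical Hessian of the toy energy by central differences of the
# analytic gradient
.numericalHessian <- function(coords, topology, q, step, subset = NULL) {
  n <- nrow(coords)
  model <- .toyModel(topology, q, subset)
  grad <- function(m) as.numeric(attr(.toyEval(model, m, gradient = TRUE),
                                      "gradient"))
  H <- matrix(0, 3 * n, 3 * n)
  for (d in seq_len(3 * n)) {
    at <- (d - 1) %% n + 1; cc <- (d - 1) %/% n + 1
    mp <- coords; mp[at, cc] <- mp[at, cc] + step
    mm <- coords; mm[at, cc] <- mm[at, cc] - step
    H[, d] <- (grad(mp) - grad(mm)) / (2 * step)
  }
  # gradient layout is column-major over (atom, xyz); symmetrize
  (H + t(H)) / 2
}

#' Normal modes from a mass-weighted numerical Hessian
#'
#' Builds the Hessian by central differences of the analytic gradient,
#' mass-weights it, projects out the six rigid translations/rotations, and
#' converts eigenvalues to harmonic frequencies in cm^-1.
#'
#' @inheritParams minimizeStructure
#' @param coords minimized coordinates (warns if the RMS gradient exceeds
#'   10x `params$minTol`)
#' @return list of class `modeSpectrum`: `frequencies` (cm^-1, ascending,
#'   rigid modes removed), `eigenvectors` (mass-weighted), `nProjected`
#' @export
normalModes <- function(coords, topology, chargeSource = topology,
                        params = entropyParams(), subset = NULL) {
  q <- if (is(chargeSource, "ChargeSet")) charges(chargeSource)
       else if (is(chargeSource, "Topology")) charges(chargeSource)
       else as.numeric(chargeSource)
  full <- as.matrix(coords)
  idx <- if (is.null(subset)) seq_len(nrow(full)) else selectionIndices(subset)
  X <- if (nrow(full) == length(idx) && is.null(subset)) full else {
    if (nrow(full) == length(idx)) full else full[idx, , drop = FALSE]
  }
  n <- nrow(X)
  g <- attr(.toyTotalEnergy(X, topology, q, gradient = TRUE, subset = idx),
            "gradient")
  if (sqrt(mean(g^2)) > 10 * params$minTol)
    warning(sprintf("normal modes at a non-stationary point: RMS gradient %.3g",
                    sqrt(mean(g^2))))
  H <- .numericalHessian(X, topology, q, params$hessianStep, subset = idx)
  mass <- topology@atoms$mass[idx]
  invSqrtM <- rep(1 / sqrt(mass), 3)     # column-major (atom, xyz) layout
  Hm <- H * outer(invSqrtM, invSqrtM)

  # rigid-body basis in mass-weighted coordinates
  com <- colSums(X * mass) / sum(mass)
  Xc <- sweep(X, 2, com)
  B <- matrix(0, 3 * n, 6)
  sqm <- sqrt(mass)
  for (d in 1:3) B[(d - 1) * n + seq_len(n), d] <- sqm
  rot <- function(ax) {
    v <- t(vapply(seq_len(n), function(a) .cross(ax, Xc[a, ]) * sqm[a],
                  numeric(3)))
    as.numeric(v)  # column-major (atom, xyz)
  }
  B[, 4] <- rot(c(1, 0, 0)); B[, 5] <- rot(c(0, 1, 0)); B[, 6] <- rot(c(0, 0, 1))
  qr_ <- qr(B)
  B <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  P <- diag(3 * n) - B %*% t(B)
  Hp <- P %*% Hm %*% P
  ev <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE)
  lam <- rev(ev$values)
  vec <- ev$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  nRigid <- ncol(B)
  thresh <- max(abs(lam)) * 1e-8
  zero <- abs(lam) < max(thresh, 1e-6)
  nImag <- sum(lam < 0 & !zero)
  if (nImag > 0)
    stop(sprintf("saddle point: %d imaginary mode(s) after projection", nImag))
  keep <- which(!zero & lam > 0)
  if (length(keep) < 3 * n - nRigid - 1L)
    warning("more than the rigid-body modes were near zero")
  structure(list(frequencies = .freqFactor * sqrt(lam[keep]),
                 eigenvectors = vec[, keep, drop = FALSE],
                 nProjected = sum(zero)),
            class = "modeSpectrum")
}

#' Ideal-gas, rigid-rotor and harmonic-oscillator entropies
#'
#' Standard statistical-mechanics entropies at temperature T: Sackur-Tetrode
#' translation at 1 atm, classical rigid rotor (symmetry number 1), quantum
#' harmonic oscillator vibrations from a [normalModes()] spectrum.
#'
#' @param coords `N x 3` coordinates of the species (for mass and inertia)
#' @param topology a [Topology-class]
#' @param spectrum a `modeSpectrum`, or `NULL` for a monatomic species
#' @param params an [entropyParams()]
#' @param subset optional atom indices of the species
#' @return list: `S_trans`, `S_rot`, `S_vib`, `S_total` (kcal/mol/K) and
#'   `TS` (kcal/mol)
#' @export
entropyTerms <- function(coords, topology, spectrum = NULL,
                         params = entropyParams(), subset = NULL) {
  T <- params$temperature
  idx <- if (is.null(subset)) seq_len(nrow(as.matrix(coords)))
         else selectionIndices(subset)
  X <- as.matrix(coords)
  X <- if (nrow(X) == length(idx)) X else X[idx, , drop = FALSE]
  mass <- topology@atoms$mass[idx]
  R <- .gasConstKcal
  Mkg <- sum(mass) * .amuKg
  qt <- (2 * pi * Mkg * .kBoltzmannJ * T / .hPlanckJ^2)^1.5 *
    (.kBoltzmannJ * T / .pressurePa)
  S_trans <- R * (log(qt) + 2.5)

  n <- length(idx)
  S_rot <- 0
  if (n > 1L) {
    com <- colSums(X * mass) / sum(mass)
    Xc <- sweep(X, 2, com)
    I <- matrix(0, 3, 3)
    for (a in seq_len(n)) {
      r <- Xc[a, ]
      I <- I + mass[a] * (sum(r * r) * diag(3) - outer(r, r))
    }
    Iev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
    IkgM2 <- Iev * .amuKg * 1e-20
    linear <- Iev[1] < 1e-4 * Iev[3]
    if (linear) {
      qr_ <- 8 * pi^2 * IkgM2[3] * .kBoltzmannJ * T / .hPlanckJ^2
      S_rot <- R * (log(qr_) + 1)
    } else {
      qr_ <- sqrt(pi) * (8 * pi^2 * .kBoltzmannJ * T / .hPlanckJ^2)^1.5 *
        sqrt(prod(IkgM2))
      S_rot <- R * (log(qr_) + 1.5)
    }
  }

  S_vib <- 0
  if (!is.null(spectrum) && length(spectrum$frequencies)) {
    nu <- spectrum$frequencies
    if (any(nu <= 0)) stop("non-positive frequency passed to vibrational entropy")
    x <- .hPlanckJ * .cLightCm * nu / (.kBoltzmannJ * T)
    S_vib <- R * sum(x / (exp(x) - 1) - log1p(-exp(-x)))
  }
  S <- S_trans + S_rot + S_vib
  list(S_trans = S_trans, S_rot = S_rot, S_vib = S_vib, S_total = S,
       TS = T * S)
}

#' Normal-mode TdS of binding for one snapshot
#'
#' Minimizes complex, receptor and ligand from the same snapshot, computes
#' their mode spectra and entropies, and returns
#' `TdS_bind = T * (S_complex - S_receptor - S_ligand)` (kcal/mol; negative
#' for rigid association, so the `-TdS` contribution to `DeltaG` is
#' positive).
#'
#' @param coords snapshot coordinates (full complex)
#' @param topology a [Topology-class]
#' @param chargeSource charges for the nonbonded terms
#' @param receptor,ligand selections partitioning the solute
#' @param params an [entropyParams()]
#' @return list with `TdS` and the per-species entropy lists
#' @export
bindingEntropy <- function(coords, topology, chargeSource = topology,
                           receptor, ligand, params = entropyParams()) {
  rIdx <- selectionIndices(receptor); lIdx <- selectionIndices(ligand)
  sol <- sort(c(rIdx, lIdx))
  species <- list(complex = sol, receptor = rIdx, ligand = lIdx)
  ent <- lapply(species, function(idx) {
    m <- minimizeStructure(coords, topology, chargeSource, params, subset = idx)
    spec <- if (length(idx) > 1L)
      normalModes(m, topology, chargeSource, params, subset = idx) else NULL
    entropyTerms(m, topology, spec, params, subset = idx)
  })
  list(TdS = params$temperature * (ent$complex$S_total - ent$receptor$S_total -
                                     ent$ligand$S_total),
       entropies = ent)
}
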