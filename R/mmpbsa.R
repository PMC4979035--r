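# Single-trajectory MM/PBSA: snapshot extraction, per-snapshot component
# assembly (gas-phase + PB + SASA), condition averaging with dispersions,
# per-residue decomposition and condition differences.

#' Pipeline configuration
#'
#' Bundles every tunable of a binding free-energy run. Defaults mirror the
#' standard protocol: 200 snapshots for the enthalpic terms, 20 for the
#' normal-mode entropy, PB at 1/80 dielectrics and 4 grids/Angstrom,
#' gamma/beta nonpolar constants, 3.5 Angstrom / 120 degree hydrogen-bond
#' criteria, 300 K.
#'
#' @param snapshots snapshot count for MM/PB/SASA terms (default 200)
#' @param entropySnapshots snapshot count for the entropy term (default 20;
#'   must not exceed `snapshots`)
#' @param pb a [pbParams()]
#' @param nonpolar a [nonpolarParams()]
#' @param entropy an [entropyParams()]
#' @param criteria an [hbondCriteria()]
#' @param seed RNG seed recorded with the run
#' @export
pipelineConfig <- function(snapshots = 200L, entropySnapshots = 20L,
                           pb = pbParams(), nonpolar = nonpolarParams(),
                           entropy = entropyParams(), criteria = hbondCriteria(),
                           seed = 1L) {
  if (entropySnapshots > snapshots)
    stop("entropySnapshots must not exceed snapshots")
  structure(list(snapshots = as.integer(snapshots),
                 entropySnapshots = as.integer(entropySnapshots),
                 pb = pb, nonpolar = nonpolar, entropy = entropy,
                 criteria = criteria, seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Extract evenly spaced snapshots from a trajectory window
#'
#' Deterministic: `n` frames at near-even stride over the window, always
#' including the window's first and last frame (for `n = 1`, the last).
#'
#' @param traj a [Trajectory-class]
#' @param n snapshot count
#' @param window integer `c(first, last)` frame positions (default: the
#'   final half of the trajectory, the "after equilibrium" convention)
#' @return a [Trajectory-class] with `n` frames
#' @export
extractSnapshots <- function(traj, n, window = NULL) {
  nf <- nFrames(traj)
  if (is.null(window)) window <- c(max(1L, nf %/% 2L + 1L), nf)
  len <- window[2] - window[1] + 1L
  if (n > len) stop(sprintf("cannot extract %d snapshots from a %d-frame window", n, len))
  pos <- if (n == 1L) window[2] else
    unique(round(seq(window[1], window[2], length.out = n)))
  Trajectory(traj@topology, traj@coords[, , pos, drop = FALSE],
             frameIndex = traj@frameIndex[pos], time = traj@time[pos])
}

#' Binding free-energy components of one snapshot (no entropy)
#'
#' Single-trajectory protocol: complex, receptor and ligand coordinates all
#' come from the same frame, so every intramolecular gas-phase term cancels
#' and only the intergroup electrostatic and van der Waals interactions
#' remain. The polar term is the reaction-field difference
#' `pol(complex) - pol(receptor) - pol(ligand)` with all three species
#' solved on the identical grid (the complex's), cancelling grid artifacts;
#' the nonpolar term is `gamma * (SASA_complex - SASA_receptor -
#' SASA_ligand)` (the `beta` offsets cancel).
#'
#' @param coords frame coordinates, `N x 3`
#' @param topology a [Topology-class]
#' @param chargeSource [ChargeSet-class] or charge vector
#' @param receptor,ligand selections partitioning the solute
#' @param config a [pipelineConfig()]
#' @param grid optional fixed grid (defaults to the complex's)
#' @return named numeric: `ele`, `vdw`, `pol`, `nonpol`, `sub_total`
#' @export
snapshotComponents <- function(coords, topology, chargeSource = topology,
                               receptor, ligand, config = pipelineConfig(),
                               grid = NULL) {
  rIdx <- selectionIndices(receptor); lIdx <- selectionIndices(ligand)
  if (length(intersect(rIdx, lIdx))) stop("receptor and ligand overlap")
  q <- if (is(chargeSource, "ChargeSet")) charges(chargeSource)
       else if (is(chargeSource, "Topology")) charges(chargeSource)
       else as.numeric(chargeSource)
  gas <- groupInteraction(coords, topology, q, rIdx, lIdx)
  sol <- sort(c(rIdx, lIdx))
  if (is.null(grid))
    grid <- pbGrid(coords[sol, , drop = FALSE],
                   topology@atoms$pb_radius[sol], config$pb)
  polC <- .speciesRF(coords, topology, q, sol, config$pb, grid)$energy
  polR <- .speciesRF(coords, topology, q, rIdx, config$pb, grid)$energy
  polL <- .speciesRF(coords, topology, q, lIdx, config$pb, grid)$energy
  sasaC <- sasa(coords, topology, config$nonpolar, config$pb$probe, sol)$total
  sasaR <- sasa(coords, topology, config$nonpolar, config$pb$probe, rIdx)$total
  sasaL <- sasa(coords, topology, config$nonpolar, config$pb$probe, lIdx)$total
  pol <- polC - polR - polL
  nonpol <- config$nonpolar$gamma * (sasaC - sasaR - sasaL)
  c(ele = unname(gas["ele"]), vdw = unname(gas["vdw"]), pol = pol,
    nonpol = nonpol, sub_total = unname(gas["ele"] + gas["vdw"]) + pol + nonpol)
}

# reaction field of a species (atom subset) on a fixed grid
.speciesRF <- function(coords, topology, q, idx, pb, grid) {
  sub <- new("Topology", atoms = topology@atoms[idx, , drop = FALSE],
             bonds = data.frame(i = integer(), j = integer(),
                                k = numeric(), r0 = numeric()),
             angles = data.frame(i = integer(), j = integer(), k = integer(),
                                 kth = numeric(), th0 = numeric()))
  reactionField(coords[idx, , drop = FALSE], sub, q[idx], pb, grid)
}

#' Assemble the total binding free energy from its five components
#'
#' `total = ele + vdw + pol + nonpol + TdS`, where the `TdS` entry is the
#' entropy column as tabulated (positive when entropy loss opposes binding,
#' i.e. the `-T dS_bind` contribution).
#'
#' @param components named numeric or list with `ele`, `vdw`, `pol`,
#'   `nonpol`, `TdS`
#' @return kcal/mol
#' @export
assembleTotal <- function(components) {
  need <- c("ele", "vdw", "pol", "nonpol", "TdS")
  components <- unlist(components)
  if (!all(need %in% names(components)))
    stop("missing component(s): ",
         paste(setdiff(need, names(components)), collapse = ", "))
  unname(sum(components[need]))
}

#' Run one charge-set-by-trajectory condition
#'
#' The engine behind the mixed-design table: evaluates every snapshot of the
#' named trajectory under the named charge set, averages components with
#' sample standard deviations, adds the normal-mode entropy term from its
#' snapshot subset, and assembles sub-total and total.
#'
#' @param condition list with `charge` and `trajectory` labels (see
#'   [condition()])
#' @param registry list with `chargeSets` (named [ChargeSet-class]s),
#'   `trajectories` (named [Trajectory-class]s), `receptor` and `ligand`
#'   selections
#' @param config a [pipelineConfig()]
#' @param window snapshot window passed to [extractSnapshots()] (default:
#'   whole trajectory, assuming it is already post-equilibrium)
#' @param entropy compute the TdS column (default TRUE; FALSE leaves it 0,
#'   for enthalpy-only comparisons)
#' @return list of class `conditionResult`: `condition`, `mean` (named
#'   vector: ele, vdw, pol, nonpol, sub_total, TdS, total), `sd` (matching;
#'   zero for single-frame conditions), `perSnapshot` (data.frame), `nFailed`
#' @export
runCondition <- function(condition, registry, config = pipelineConfig(),
                         window = NULL, entropy = TRUE) {
  cs <- registry$chargeSets[[condition$charge]]
  traj <- registry$trajectories[[condition$trajectory]]
  if (is.null(cs)) stop("unregistered charge set: ", condition$charge)
  if (is.null(traj)) stop("unregistered trajectory: ", condition$trajectory)
  topo <- traj@topology
  if (is.null(window)) window <- c(1L, nFrames(traj))
  n <- min(config$snapshots, window[2] - window[1] + 1L)
  snaps <- extractSnapshots(traj, n, window)
  rIdx <- selectionIndices(registry$receptor)
  lIdx <- selectionIndices(registry$ligand)
  sol <- sort(c(rIdx, lIdx))
  grid <- pbGrid(frameCoords(snaps, 1L)[sol, , drop = FALSE],
                 topo@atoms$pb_radius[sol], config$pb)

  rows <- vector("list", nFrames(snaps))
  for (f in seq_len(nFrames(snaps))) {
    rows[[f]] <- tryCatch(
      snapshotComponents(frameCoords(snaps, f), topo, cs, rIdx, lIdx,
                         config, grid),
      error = function(e) e)
  }
  failed <- vapply(rows, inherits, logical(1), "error")
  if (mean(failed) > 0.05)
    stop(sprintf("condition %s/%s failed: %d of %d snapshots errored (first: %s)",
                 condition$charge, condition$trajectory, sum(failed),
                 length(rows), conditionMessage(rows[[which(failed)[1]]])))
  tab <- as.data.frame(do.call(rbind, rows[!failed]))
  tab$frame <- snaps@frameIndex[!failed]

  TdSmean <- 0; TdSsd <- 0
  if (entropy) {
    ne <- min(config$entropySnapshots, nFrames(snaps))
    esnaps <- extractSnapshots(snaps, ne, c(1L, nFrames(snaps)))
    tds <- vapply(seq_len(nFrames(esnaps)), function(f)
      -bindingEntropy(frameCoords(esnaps, f), topo, cs, rIdx, lIdx,
                      config$entropy)$TdS, numeric(1))
    TdSmean <- mean(tds); TdSsd <- if (length(tds) > 1L) stats::sd(tds) else 0
  }
  mu <- colMeans(tab[, c("ele", "vdw", "pol", "nonpol", "sub_total")])
  sdv <- if (nrow(tab) > 1L)
    vapply(tab[, c("ele", "vdw", "pol", "nonpol", "sub_total")], stats::sd,
           numeric(1)) else stats::setNames(rep(0, 5), names(mu))
  mean <- c(mu, TdS = TdSmean,
            total = assembleTotal(c(mu[c("ele", "vdw", "pol", "nonpol")],
                                    TdS = TdSmean)))
  sd <- c(sdv, TdS = TdSsd, total = NA_real_)
  structure(list(condition = condition, mean = mean, sd = sd,
                 perSnapshot = tab, nFailed = sum(failed)),
            class = "conditionResult")
}

#' @rdname runCondition
#' @param charge,trajectory labels resolving in the registry
#' @export
condition <- function(charge, trajectory) {
  list(charge = charge, trajectory = trajectory)
}

#' Run a condition matrix and shape the results as a decomposition table
#'
#' @param conditions list of [condition()]s (rows of the table)
#' @inheritParams runCondition
#' @return data.frame, one row per condition: charge, trajectory, component
#'   means, sds, sub_total, TdS, total
#' @export
runConditionMatrix <- function(conditions, registry, config = pipelineConfig(),
                               window = NULL, entropy = TRUE) {
  res <- lapply(conditions, runCondition, registry = registry, config = config,
                window = window, entropy = entropy)
  tab <- do.call(rbind, lapply(res, function(r)
    data.frame(charge = r$condition$charge, trajectory = r$condition$trajectory,
               ele = r$mean["ele"], ele_sd = r$sd["ele"],
               vdw = r$mean["vdw"], vdw_sd = r$sd["vdw"],
               pol = r$mean["pol"], pol_sd = r$sd["pol"],
               nonpol = r$mean["nonpol"], nonpol_sd = r$sd["nonpol"],
               sub_total = r$mean["sub_total"], sub_total_sd = r$sd["sub_total"],
               TdS = r$mean["TdS"], TdS_sd = r$sd["TdS"],
               total = r$mean["total"], row.names = NULL)))
  attr(tab, "results") <- res
  tab
}

#' Per-snapshot component differences between two conditions
#'
#' Element-wise `a - b` per component per snapshot; the differencing that
#' isolates which component a charge-set swap actually changes.
#'
#' @param a,b `conditionResult`s or their `perSnapshot` data.frames with
#'   matched frames
#' @return data.frame of per-snapshot differences (`ele`, `vdw`, `pol`,
#'   `nonpol`, `sub_total`, plus `frame`)
#' @export
conditionDifference <- function(a, b) {
  ta <- if (inherits(a, "conditionResult")) a$perSnapshot else a
  tb <- if (inherits(b, "conditionResult")) b$perSnapshot else b
  if (nrow(ta) != nrow(tb)) stop("snapshot counts differ")
  if (!isTRUE(all.equal(ta$frame, tb$frame))) stop("snapshot frames not matched")
  comp <- c("ele", "vdw", "pol", "nonpol", "sub_total")
  out <- ta[comp] - tb[comp]
  out$frame <- ta$frame
  out
}

#' Per-residue decomposition of the binding free energy
#'
#' Averaged over snapshots: gas-phase `ele`/`vdw` from the residue-ligand
#' interaction spectrum; polar term by linear attribution
#' `1/2 sum_{i in res} q_i * [phiRF_complex(r_i) - phiRF_separate(r_i)]`
#' (receptor atoms against the receptor-alone solve, ligand atoms against
#' the ligand-alone solve, identical grids); nonpolar term as
#' `gamma * DeltaSASA` of the residue's atoms. Includes one row for the
#' ligand so the residue sums reproduce the whole-system components.
#'
#' @param traj a [Trajectory-class] of snapshots (use [extractSnapshots()])
#' @param topology a [Topology-class]
#' @param chargeSource [ChargeSet-class] or charge vector
#' @param receptor,ligand selections partitioning the solute
#' @param config a [pipelineConfig()]
#' @return data.frame: `resid`, `resname`, `ele`, `vdw`, `pol`, `nonpol`,
#'   `total` (kcal/mol, snapshot means)
#' @export
perResidueDecomposition <- function(traj, topology, chargeSource = topology,
                                    receptor, ligand,
                                    config = pipelineConfig()) {
  q <- if (is(chargeSource, "ChargeSet")) charges(chargeSource)
       else if (is(chargeSource, "Topology")) charges(chargeSource)
       else as.numeric(chargeSource)
  rIdx <- selectionIndices(receptor); lIdx <- selectionIndices(ligand)
  sol <- sort(c(rIdx, lIdx))
  rt <- residueTable(topology)
  rt <- rt[rt$segment == "protein", , drop = FALSE]
  grid <- pbGrid(frameCoords(traj, 1L)[sol, , drop = FALSE],
                 topology@atoms$pb_radius[sol], config$pb)
  acc <- NULL
  for (f in seq_len(nFrames(traj))) {
    coords <- frameCoords(traj, f)
    spec <- perResidueSpectrum(coords, topology, q, lIdx)
    rfC <- .speciesRF(coords, topology, q, sol, config$pb, grid)
    rfR <- .speciesRF(coords, topology, q, rIdx, config$pb, grid)
    rfL <- .speciesRF(coords, topology, q, lIdx, config$pb, grid)
    # phiRF vectors are ordered by the species' own index vector
    dphi <- numeric(nrow(coords))
    dphi[sol] <- rfC$phiRF
    dphi[rIdx] <- dphi[rIdx] - rfR$phiRF
    dphi[lIdx] <- dphi[lIdx] - rfL$phiRF
    sasC <- sasa(coords, topology, config$nonpolar, config$pb$probe, sol)
    sasR <- sasa(coords, topology, config$nonpolar, config$pb$probe, rIdx)
    sasL <- sasa(coords, topology, config$nonpolar, config$pb$probe, lIdx)
    dsasa <- numeric(nrow(coords))
    dsasa[sol] <- sasC$perAtom
    dsasa[rIdx] <- dsasa[rIdx] - sasR$perAtom
    dsasa[lIdx] <- dsasa[lIdx] - sasL$perAtom
    polRes <- vapply(seq_len(nrow(rt)), function(r) {
      idx <- intersect(rt$first[r]:rt$last[r], rIdx)
      0.5 * sum(q[idx] * dphi[idx])
    }, numeric(1))
    npRes <- vapply(seq_len(nrow(rt)), function(r) {
      idx <- intersect(rt$first[r]:rt$last[r], rIdx)
      config$nonpolar$gamma * sum(dsasa[idx])
    }, numeric(1))
    row <- data.frame(resid = c(rt$resid, NA),
                      resname = c(rt$resname, "LIG"),
                      ele = c(spec$ele, 0), vdw = c(spec$vdw, 0),
                      pol = c(polRes, 0.5 * sum(q[lIdx] * dphi[lIdx])),
                      nonpol = c(npRes, config$nonpolar$gamma * sum(dsasa[lIdx])))
    acc <- if (is.null(acc)) row else {
      acc[, 3:6] <- acc[, 3:6] + row[, 3:6]; acc
    }
  }
  acc[, 3:6] <- acc[, 3:6] / nFrames(traj)
  acc$total <- rowSums(acc[, c("ele", "vdw", "pol", "nonpol")])
  acc
}

#' @export
print.conditionResult <- function(x, ...) {
  cat(sprintf("Condition charge=%s trajectory=%s (%d snapshots)\n",
              x$condition$charge, x$condition$trajectory, nrow(x$perSnapshot)))
  m <- x$mean; s <- x$sd
  for (k in names(m))
    cat(sprintf("  %-9s %8.2f %s\n", k, m[k],
                if (is.na(s[k])) "" else sprintf("+- %.2f", s[k])))
  invisible(x)
}
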