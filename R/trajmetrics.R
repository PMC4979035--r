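# Superposition-based stability metrics: least-squares rigid superposition,
# RMSD time series and distributions, per-atom/per-residue RMSF.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD of
#' `mobile` onto `reference`, via SVD of the weighted covariance matrix with
#' the usual determinant correction so the returned rotation is proper
#' (det = +1, no reflection).
#'
#' @param mobile,reference `N x 3` coordinate matrices, N >= 3 non-collinear
#' @param weights per-atom weights (default equal)
#' @return list with `rotation` (3x3), `translation` (length 3; the fitted
#'   coordinates are `mobile %*% t(rotation) + translation`), `rmsd`
#'   (Angstrom) and `fitted` (`N x 3`)
#' @export
kabschSuperpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n)
    stop("superposition needs >= 3 paired points")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  s <- svd(H)
  if (min(s$d) < 1e-12 && sum(s$d > 1e-12) < 2L)
    stop("degenerate (collinear) coordinates: superposition undefined")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - (R %*% cm)),
       rmsd = rmsd, fitted = sweep(fitted, 2, cr, "+"))
}

#' RMSD time series against a reference frame
#'
#' One value per frame: the minimized RMSD of the selected atoms after
#' optimal rigid superposition onto the reference.
#'
#' @param traj a [Trajectory-class]
#' @param reference `N x 3` reference coordinates (full atom set), e.g.
#'   `refCoords(topology)` for the crystal structure or `frameCoords(traj, 1)`
#' @param selection an [AtomSelection-class] or integer indices (non-empty)
#' @param weights optional per-selected-atom weights; `"mass"` uses topology
#'   masses
#' @return data.frame with columns `frame`, `time`, `rmsd`; selection and
#'   reference provenance in attributes
#' @export
rmsdSeries <- function(traj, reference, selection, weights = NULL) {
  idx <- selectionIndices(selection)
  if (!length(idx)) stop("empty selection")
  if (identical(weights, "mass")) weights <- atoms(traj)$mass[idx]
  ref <- as.matrix(reference)[idx, , drop = FALSE]
  vals <- vapply(seq_len(nFrames(traj)), function(f)
    kabschSuperpose(frameCoords(traj, f)[idx, , drop = FALSE], ref,
                    weights)$rmsd, numeric(1))
  out <- data.frame(frame = traj@frameIndex, time = traj@time, rmsd = vals)
  attr(out, "selection") <- if (is(selection, "AtomSelection")) selection@expr else "indices"
  attr(out, "reference") <- "user-supplied frame"
  out
}

#' Normalized histogram of an RMSD series
#'
#' @param values numeric series (Angstrom), or a data.frame from
#'   [rmsdSeries()] (its `rmsd` column is used)
#' @param binWidth bin width, Angstrom (> 0)
#' @return data.frame with `center` and `density`; the density integrates to
#'   1 over the bins (`sum(density) * binWidth == 1`)
#' @export
rmsdDistribution <- function(values, binWidth = 0.1) {
  if (is.data.frame(values)) values <- values$rmsd
  if (!length(values)) stop("empty series")
  if (!is.numeric(binWidth) || binWidth <= 0) stop("bin width must be > 0")
  lo <- floor(min(values) / binWidth) * binWidth
  breaks <- seq(lo, max(values) + binWidth, by = binWidth)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  data.frame(center = h$mids, density = h$density)
}

#' Root-mean-square fluctuation about the iterated mean structure
#'
#' Frames are superposed (on the selection) to a mean structure which is
#' itself re-estimated: superpose to the first frame, average, then superpose
#' all frames to that average and re-average (two passes). RMSF_i is the RMS
#' distance of atom i from its mean position over superposed frames.
#'
#' @param traj a [Trajectory-class] (>= 2 frames)
#' @param selection atoms to superpose on and report ([AtomSelection-class]
#'   or indices)
#' @param byResidue if `TRUE`, aggregate to one value per residue (RMS over
#'   the residue's selected atoms), the convention for C-alpha plots
#' @param weights optional superposition weights (`"mass"` for mass weighting)
#' @return data.frame with `index` (atom index) and `rmsf` (Angstrom), or
#'   `resid`/`rmsf` when `byResidue`
#' @export
rmsf <- function(traj, selection, byResidue = FALSE, weights = NULL) {
  idx <- selectionIndices(selection)
  if (!length(idx)) stop("empty selection")
  if (nFrames(traj) < 2L) stop("RMSF needs at least 2 frames")
  if (identical(weights, "mass")) weights <- atoms(traj)$mass[idx]
  nf <- nFrames(traj)
  frames <- lapply(seq_len(nf), function(f) frameCoords(traj, f)[idx, , drop = FALSE])
  mean0 <- frames[[1]]
  for (pass in 1:2) {
    fitted <- lapply(frames, function(m) kabschSuperpose(m, mean0, weights)$fitted)
    mean0 <- Reduce(`+`, fitted) / nf
  }
  dev2 <- Reduce(`+`, lapply(fitted, function(m) rowSums((m - mean0)^2))) / nf
  vals <- sqrt(dev2)
  if (byResidue) {
    resid <- atoms(traj)$resid[idx]
    agg <- tapply(dev2, resid, function(v) sqrt(mean(v)))
    data.frame(resid = as.integer(names(agg)), rmsf = as.numeric(agg))
  } else {
    data.frame(index = idx, rmsf = vals)
  }
}

#' Pearson correlation of two per-residue profiles
#'
#' Convenience wrapper used to compare fluctuation profiles (e.g. computed
#' RMSF against crystallographic B-factor-derived values).
#' @param a,b numeric vectors of equal length
#' @return correlation coefficient
#' @export
profileCorrelation <- function(a, b) stats::cor(a, b)
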