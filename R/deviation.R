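#' Smooth 4-D mapping of a scaled pair vector
#'
#' Maps a scaled pair vector to the 4-vector
#' \deqn{G(\tilde r) = \left(\sin(\gamma\tilde r)\,\tilde r_x/\tilde r,\;
#'   \sin(\gamma\tilde r)\,\tilde r_y/\tilde r,\;
#'   \sin(\gamma\tilde r)\,\tilde r_z/\tilde r,\;
#'   1+\cos(\gamma\tilde r)\right)\;
#'   \Theta(\tilde r_{cutoff}-\tilde r)/\gamma}
#' with \eqn{\gamma = \pi/\tilde r_{cutoff}}.  G vanishes continuously at
#' the cutoff, is approximately an isometry for small vectors, and its norm
#' is bounded by \eqn{2/\gamma}, which makes the derived metric local and
#' differentiable.
#'
#' @param rtilde scaled pair vector: numeric length-3 vector or n x 3 matrix.
#' @param params a \linkS4class{ScalingParams} (provides the cutoff).
#' @return Numeric length-4 vector or n x 4 matrix.
#' @examples
#' gVector(c(1.2, 0, 0))          # ~ (0.764, 0, 0, 0.764)
#' gVector(c(2.4, 0, 0))          # zero: at the cutoff
#' @export
gVector <- function(rtilde, params = scalingParams()) {
  single <- !is.matrix(rtilde)
  if (single) rtilde <- matrix(rtilde, ncol = 3)
  rc <- params@rCutoff
  gamma <- pi / rc
  rn <- sqrt(rowSums(rtilde^2))
  out <- matrix(0, nrow(rtilde), 4)
  inside <- rn < rc
  if (any(inside)) {
    rni <- rn[inside]
    s <- sin(gamma * rni)
    dir <- rtilde[inside, , drop = FALSE] / ifelse(rni > 0, rni, 1)
    dir[rni == 0, ] <- 0            # direction term vanishes at the origin
    out[inside, 1:3] <- dir * s
    out[inside, 4] <- 1 + cos(gamma * rni)
    out[inside, ] <- out[inside, , drop = FALSE] / gamma
  }
  if (single) out[1, ] else out
}

#' Scalar (contact-map-like) variant of the G mapping
#'
#' \eqn{G_s(\tilde r) = (\tilde r_{cutoff} - \tilde r)\,
#'   \Theta(\tilde r_{cutoff} - \tilde r)}: the scalar shortfall from the
#' cutoff, ignoring direction.
#'
#' @param rtilde scaled pair vector (length-3) or n x 3 matrix.
#' @param params a \linkS4class{ScalingParams}.
#' @return Numeric scalar or vector.
#' @export
gScalar <- function(rtilde, params = scalingParams()) {
  if (!is.matrix(rtilde)) rtilde <- matrix(rtilde, ncol = 3)
  rn <- sqrt(rowSums(rtilde^2))
  pmax(params@rCutoff - rn, 0)
}

.checkCorrespondence <- function(a, b) {
  if (!is(a, "RnaStructure") || !is(b, "RnaStructure"))
    stop("need two RnaStructure objects")
  if (nNucleotides(a) != nNucleotides(b))
    stop("correspondence error: structures have different nucleotide counts")
}

# scaled pair-vector matrices for all ordered pairs, fixed (j,k) ordering
.rtildeMatrix <- function(structure, params) {
  pv <- .allPairVectors(structure, params)
  pv <- pv[order(pv$j, pv$k), , drop = FALSE]
  as.matrix(pv[, c("rtx", "rty", "rtz")])
}

#' Interaction-network-aware deviation between two structures
#'
#' Root-mean-square difference of the G-mapped scaled pair vectors over all
#' ordered base pairs (both permutations), normalized by the number of
#' nucleotides N:
#' \deqn{\sqrt{\frac{1}{N}\sum_{j \ne k}
#'   |G(\tilde r_{jk}^A) - G(\tilde r_{jk}^B)|^2}}
#' Nucleotides correspond positionally (i-th with i-th).  The measure is
#' non-negative, symmetric, satisfies the triangle inequality, requires no
#' superposition, and only changes when pairs within the cutoff change.
#'
#' @param a,b \linkS4class{RnaStructure} objects with equal nucleotide
#'   counts.
#' @param params a \linkS4class{ScalingParams}.
#' @return Numeric scalar (dimensionless).
#' @examples
#' d <- makeAformDuplex("GGGG")
#' eRMSD(d, perturbStructure(d, sigma = 1, seed = 1))
#' @export
eRMSD <- function(a, b, params = scalingParams()) {
  .checkCorrespondence(a, b)
  n <- nNucleotides(a)
  if (n < 2L) return(0)
  ga <- gVector(.rtildeMatrix(a, params), params)
  gb <- gVector(.rtildeMatrix(b, params), params)
  sqrt(sum((ga - gb)^2) / n)
}

#' @rdname eRMSD
#' @details \code{eRMSDScalar} replaces the 4-D mapping by the scalar
#'   variant \code{\link{gScalar}}; it behaves like a smooth contact-map
#'   distance and is highly correlated with \code{eRMSD} for structures of
#'   more than four nucleotides.
#' @export
eRMSDScalar <- function(a, b, params = scalingParams()) {
  .checkCorrespondence(a, b)
  n <- nNucleotides(a)
  if (n < 2L) return(0)
  ga <- gScalar(.rtildeMatrix(a, params), params)
  gb <- gScalar(.rtildeMatrix(b, params), params)
  sqrt(sum((ga - gb)^2) / n)
}

#' Cutoff-free deviation of scaled pair vectors
#'
#' \deqn{d = \sqrt{\frac{1}{N}\sum_{j\ne k}
#'   |\tilde r_{jk}^A - \tilde r_{jk}^B|^2}}
#' over all ordered pairs, with no cutoff: a highly non-local quantity, since
#' distant pairs contribute fully.  Provided as the naive baseline that the
#' G mapping localizes.
#'
#' @inheritParams eRMSD
#' @return Numeric scalar (dimensionless).
#' @export
naiveDistance <- function(a, b, params = scalingParams()) {
  .checkCorrespondence(a, b)
  n <- nNucleotides(a)
  if (n < 2L) return(0)
  ra <- .rtildeMatrix(a, params)
  rb <- .rtildeMatrix(b, params)
  sqrt(sum((ra - rb)^2) / n)
}

#' Heavy-atom RMSD after optimal superposition
#'
#' Least-squares rigid superposition (proper rotation only, no reflection)
#' followed by root-mean-square deviation, computed over all heavy atoms
#' (requires identical atom composition) or over the ring-centroid beads.
#'
#' @param a,b \linkS4class{RnaStructure} objects.
#' @param selection \code{"heavy"} (all heavy atoms; atom tables must match)
#'   or \code{"ring"} (one centroid bead per nucleotide).
#' @return RMSD in Angstrom.
#' @export
atomRMSD <- function(a, b, selection = c("heavy", "ring")) {
  selection <- match.arg(selection)
  .checkCorrespondence(a, b)
  if (selection == "heavy") {
    if (nrow(a@atoms) != nrow(b@atoms))
      stop("correspondence error: structures have different atom counts")
    pa <- atomCoords(a)
    pb <- atomCoords(b)
  } else {
    pa <- ringCenters(a)
    pb <- ringCenters(b)
  }
  bio3d::rmsd(as.vector(t(pa)), as.vector(t(pb)), fit = TRUE)
}

#' Distance-matrix RMSD
#'
#' Root-mean-square difference between the internal pairwise distance
#' matrices of the two structures, computed on the ring-centroid beads by
#' default (all heavy atoms optionally).  Superposition-free and invariant
#' under rigid motion of either structure.
#'
#' @param a,b \linkS4class{RnaStructure} objects.
#' @param selection \code{"ring"} (default) or \code{"heavy"}.
#' @return dRMSD in Angstrom.
#' @export
dRMSD <- function(a, b, selection = c("ring", "heavy")) {
  selection <- match.arg(selection)
  .checkCorrespondence(a, b)
  if (selection == "heavy" && nrow(a@atoms) != nrow(b@atoms))
    stop("correspondence error: structures have different atom counts")
  pa <- if (selection == "ring") ringCenters(a) else atomCoords(a)
  pb <- if (selection == "ring") ringCenters(b) else atomCoords(b)
  da <- stats::dist(pa)
  db <- stats::dist(pb)
  sqrt(mean((da - db)^2))
}

#' Interaction network fidelity between two annotations
#'
#' Compares the annotated base-base interactions of a structure with those
#' of a reference: with TP the interactions present in both, INF is the
#' geometric mean of the positive predictive value TP/(TP+FP) and the
#' sensitivity TP/(TP+FN).  An interaction is identified by its unordered
#' pair indices and zone (PAIRING/STACKING); edge sectors are ignored.
#'
#' @param refAnn annotation of the reference structure
#'   (\code{\link{annotateStructure}} output).
#' @param cmpAnn annotation of the compared structure.
#' @return INF in [0, 1]: 1 for identical interaction networks, 0 for
#'   disjoint ones.
#' @export
infScore <- function(refAnn, cmpAnn) {
  keys <- function(ann) {
    ann <- ann[ann$zone %in% c("PAIRING", "STACKING"), , drop = FALSE]
    paste(pmin(ann$j, ann$k), pmax(ann$j, ann$k), ann$zone)
  }
  kr <- keys(refAnn)
  if (length(kr) == 0L)
    stop("undefined score: reference annotation is empty")
  kc <- keys(cmpAnn)
  tp <- length(intersect(kr, kc))
  if (tp == 0L) return(0)
  ppv <- tp / length(unique(kc))
  sty <- tp / length(unique(kr))
  sqrt(ppv * sty)
}

# Flyvbjerg-Petersen block-doubling standard error of the mean of x,
# taken at the largest block level retaining at least minBlocks blocks
.blockError <- function(x, minBlocks = 8) {
  x <- as.numeric(x)
  best <- stats::sd(x) / sqrt(length(x))
  while (length(x) >= 2 * minBlocks) {
    n2 <- floor(length(x) / 2)
    x <- (x[seq_len(n2) * 2 - 1] + x[seq_len(n2) * 2]) / 2
    best <- stats::sd(x) / sqrt(length(x))
  }
  best
}

#' Coefficient of variation of a deviation metric along a trajectory
#'
#' For each time lag tau, evaluates the chosen deviation d between all frame
#' pairs (t, t + tau) and reports the mean, standard deviation and their
#' ratio \eqn{CV_d(\tau) = \sigma_d(\tau) / \langle d(\tau)\rangle}.  A low
#' CV means frames at equal time separation are also at similar structural
#' distance, i.e. the metric tracks kinetic proximity; the CV is invariant
#' under rescaling of the metric.  Uncertainties come from a
#' block-doubling (blocking) analysis of the correlated per-pair series.
#'
#' @param traj an \linkS4class{RnaTrajectory}.
#' @param metric one of \code{"ermsd"}, \code{"ermsd_scalar"},
#'   \code{"rmsd"}, \code{"drmsd"}, \code{"naive"}, or a function of two
#'   structures.
#' @param lags integer vector of time lags (frames).
#' @param params a \linkS4class{ScalingParams} (for the bead metrics).
#' @return data.frame with columns \code{lag}, \code{meanD}, \code{sdD},
#'   \code{cv} and \code{cvError}.  When the mean distance is zero the CV is
#'   reported as 0.
#' @export
cvCurve <- function(traj, metric = "ermsd", lags = c(1, 2, 5, 10),
                    params = scalingParams()) {
  stopifnot(is(traj, "RnaTrajectory"))
  nf <- nFrames(traj)
  lags <- as.integer(lags)
  if (any(lags < 1L)) stop("lags must be positive")
  if (nf <= max(lags) + 1L)
    stop(sprintf("trajectory too short (%d frames) for max lag %d",
                 nf, max(lags)))
  f <- if (is.function(metric)) metric else switch(
    match.arg(metric, c("ermsd", "ermsd_scalar", "rmsd", "drmsd", "naive")),
    ermsd = function(a, b) eRMSD(a, b, params),
    ermsd_scalar = function(a, b) eRMSDScalar(a, b, params),
    rmsd = function(a, b) atomRMSD(a, b),
    drmsd = function(a, b) dRMSD(a, b),
    naive = function(a, b) naiveDistance(a, b, params))
  frames <- lapply(seq_len(nf), function(i) getFrame(traj, i))
  out <- lapply(lags, function(tau) {
    ts <- seq_len(nf - tau)
    d <- vapply(ts, function(t) f(frames[[t]], frames[[t + tau]]), 0)
    m <- mean(d)
    s <- stats::sd(d)
    cv <- if (m > 0) s / m else 0
    # error propagation for s/m from blocking estimates of mean(d) and
    # var(d); covariance neglected
    if (m > 0 && s > 0) {
      em <- .blockError(d)
      ev <- .blockError((d - m)^2)
      es <- ev / (2 * s)
      cvErr <- cv * sqrt((em / m)^2 + (es / s)^2)
    } else cvErr <- 0
    data.frame(lag = tau, meanD = m, sdD = s, cv = cv, cvError = cvErr)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
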