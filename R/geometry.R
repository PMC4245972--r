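#' Local coordinate frames of the nucleobases
#'
#' For each nucleotide, builds the orthonormal frame anchored at the centroid
#' of the six-membered ring atoms C2, C4 and C6: the x axis points from the
#' centroid toward C2, the z axis is normal to the ring plane (computed from
#' the ordered atom pair (C2, C4) for pyrimidines and (C2, C6) for purines,
#' which makes the Watson-Crick edge of both base classes fall at similar
#' positive angles theta), and y completes a right-handed system.
#'
#' @param structure an \linkS4class{RnaStructure}.
#' @return A list with \code{origin} (N x 3 matrix of ring centroids,
#'   Angstrom) and \code{axes} (3 x 3 x N array; rows of \code{axes[,,i]} are
#'   the unit vectors x, y, z of nucleotide i).
#' @examples
#' fr <- baseFrames(makeAformDuplex("GC"))
#' crossprod(t(fr$axes[, , 1]))   # identity
#' @export
baseFrames <- function(structure) {
  rc <- .ringAtomCoords(structure)
  n <- nrow(rc)
  cls <- structure@info$class
  origin <- (rc[, 1:3, drop = FALSE] + rc[, 4:6, drop = FALSE] +
             rc[, 7:9, drop = FALSE]) / 3
  axes <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n)) {
    c2 <- rc[i, 1:3] - origin[i, ]
    c4 <- rc[i, 4:6] - origin[i, ]
    c6 <- rc[i, 7:9] - origin[i, ]
    # degenerate (collinear) ring atoms: triangle area below 1e-3 A^2
    zraw <- if (cls[i] == "purine") .cross3(c2, c6) else .cross3(c2, c4)
    area <- sqrt(sum(.cross3(c2 - c4, c6 - c4)^2)) / 2
    if (!is.finite(area) || area <= 1e-3)
      stop(sprintf("degenerate ring geometry at nucleotide %d", i))
    x <- c2 / sqrt(sum(c2^2))
    z <- zraw / sqrt(sum(zraw^2))
    y <- .cross3(z, x)
    axes[, , i] <- rbind(x, y, z)
  }
  list(origin = origin, axes = axes)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Scale a pair vector by the ellipsoidal semi-axes
#'
#' Componentwise division by (a, a, b): in-plane components are divided by
#' the in-plane semi-axis, the normal component by the normal semi-axis.
#'
#' @param r numeric length-3 vector or n x 3 matrix (Angstrom).
#' @param params a \linkS4class{ScalingParams}.
#' @return Scaled vector or matrix (dimensionless).
#' @export
scaleVector <- function(r, params = scalingParams()) {
  if (is.matrix(r)) {
    r %*% diag(1 / c(params@a, params@a, params@b))
  } else {
    r / c(params@a, params@a, params@b)
  }
}

.pairRow <- function(r, j, k, params) {
  rho <- sqrt(r[1]^2 + r[2]^2)
  theta <- atan2(r[2], r[1]) * 180 / pi
  if (theta < 0) theta <- theta + 360
  rt <- scaleVector(r, params)
  data.frame(j = j, k = k, rx = r[1], ry = r[2], rz = r[3],
             rho = rho, theta = theta, z = r[3],
             rtx = rt[1], rty = rt[2], rtz = rt[3],
             rtnorm = sqrt(sum(rt^2)))
}

#' Relative position of one base in another base's frame
#'
#' The pair vector r_jk is the position of the ring centroid of nucleotide k
#' expressed in the local frame of nucleotide j.  It is returned together
#' with its cylindrical form (rho, theta, z) and its ellipsoidally scaled
#' form.  The vector is invariant under any common rigid motion of the two
#' bases.
#'
#' @param structure an \linkS4class{RnaStructure}.
#' @param j,k nucleotide indices (1-based): observer and observed.
#' @param params a \linkS4class{ScalingParams}.
#' @param frames optional precomputed result of \code{\link{baseFrames}}.
#' @return One-row data.frame with columns \code{j}, \code{k}, \code{rx},
#'   \code{ry}, \code{rz} (Angstrom), \code{rho} (Angstrom), \code{theta}
#'   (degrees in [0, 360)), \code{z} (Angstrom), \code{rtx}, \code{rty},
#'   \code{rtz}, \code{rtnorm} (scaled, dimensionless).
#' @export
pairVector <- function(structure, j, k, params = scalingParams(),
                       frames = NULL) {
  if (is.null(frames)) frames <- baseFrames(structure)
  r <- as.vector(frames$axes[, , j] %*%
                 (frames$origin[k, ] - frames$origin[j, ]))
  .pairRow(r, j, k, params)
}

# all ordered pair vectors as a data.frame (no shell filter)
.allPairVectors <- function(structure, params, frames = NULL) {
  if (is.null(frames)) frames <- baseFrames(structure)
  n <- nrow(frames$origin)
  if (n < 2L)
    return(data.frame(j = integer(), k = integer(), rx = numeric(),
                      ry = numeric(), rz = numeric(), rho = numeric(),
                      theta = numeric(), z = numeric(), rtx = numeric(),
                      rty = numeric(), rtz = numeric(), rtnorm = numeric()))
  out <- vector("list", n)
  ks <- seq_len(n)
  for (j in seq_len(n)) {
    d <- sweep(frames$origin, 2, frames$origin[j, ])
    r <- d %*% t(frames$axes[, , j])  # rows: r_jk components
    keep <- ks != j
    r <- r[keep, , drop = FALSE]
    rho <- sqrt(r[, 1]^2 + r[, 2]^2)
    theta <- atan2(r[, 2], r[, 1]) * 180 / pi
    theta[theta < 0] <- theta[theta < 0] + 360
    rt <- scaleVector(r, params)
    out[[j]] <- data.frame(j = j, k = ks[keep], rx = r[, 1], ry = r[, 2],
                           rz = r[, 3], rho = rho, theta = theta, z = r[, 3],
                           rtx = rt[, 1], rty = rt[, 2], rtz = rt[, 3],
                           rtnorm = sqrt(rowSums(rt^2)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enumerate ordered pair vectors inside the interaction shell
#'
#' Returns every ordered pair (j, k), j != k, whose scaled norm is below the
#' outer shell radius; both orderings of a pair appear independently when
#' each qualifies.  The inner shell bound is not applied here (it is a
#' reporting device only).
#'
#' @param structure an \linkS4class{RnaStructure}.
#' @param params a \linkS4class{ScalingParams}.
#' @return data.frame in the format of \code{\link{pairVector}}, one row per
#'   qualifying ordered pair, ordered by (j, k).
#' @export
enumerateShellPairs <- function(structure, params = scalingParams()) {
  pv <- .allPairVectors(structure, params)
  res <- pv[pv$rtnorm < params@shellMax, , drop = FALSE]
  res <- res[order(res$j, res$k), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.edgeSector <- function(theta, params) {
  if (theta >= params@wcSector[1] && theta <= params@wcSector[2]) "WC"
  else if (theta > params@hoogsteenSector[1] &&
           theta <= params@hoogsteenSector[2]) "HOOGSTEEN"
  else if (theta > params@sugarSector[1] &&
           theta < params@sugarSector[2]) "SUGAR"
  else "UNASSIGNED"
}

#' Classify one base pair into pairing/stacking zones
#'
#' Given the two ordered pair vectors of one unordered pair, decides whether
#' the contact falls in the interaction shell and, if so, whether it is an
#' in-plane (PAIRING, |z| <= zSplit) or out-of-plane (STACKING) contact.
#' When the two orderings disagree, the ordering with the smaller scaled norm
#' decides.  Pairing contacts are further assigned an edge sector from theta.
#' The \code{mutual} flag records whether both orderings are inside the
#' shell (the convention used for annotation counting).
#'
#' @param vjk,vkj one-row data.frames from \code{\link{pairVector}} for the
#'   (j,k) and (k,j) orderings of the same pair.
#' @param params a \linkS4class{ScalingParams}.
#' @return One-row data.frame with columns \code{j}, \code{k} (j < k),
#'   \code{zone} (PAIRING, STACKING or NONE), \code{edge} (WC, HOOGSTEEN,
#'   SUGAR or UNASSIGNED; NA unless PAIRING), \code{mutual}, \code{rho},
#'   \code{theta}, \code{z}, \code{rtnorm} (taken from the deciding
#'   ordering).
#' @export
classifyPair <- function(vjk, vkj, params = scalingParams()) {
  if (!(vjk$j == vkj$k && vjk$k == vkj$j))
    stop("pair vectors do not describe the two orderings of one pair")
  inj <- vjk$rtnorm < params@shellMax
  ink <- vkj$rtnorm < params@shellMax
  jj <- min(vjk$j, vjk$k)
  kk <- max(vjk$j, vjk$k)
  if (!inj && !ink) {
    return(data.frame(j = jj, k = kk, zone = "NONE", edge = NA_character_,
                      mutual = FALSE, rho = NA_real_, theta = NA_real_,
                      z = NA_real_, rtnorm = NA_real_,
                      stringsAsFactors = FALSE))
  }
  use <- if (vjk$rtnorm <= vkj$rtnorm) vjk else vkj
  zone <- if (abs(use$z) <= params@zSplit) "PAIRING" else "STACKING"
  edge <- if (zone == "PAIRING") .edgeSector(use$theta, params)
          else NA_character_
  data.frame(j = jj, k = kk, zone = zone, edge = edge,
             mutual = inj && ink, rho = use$rho, theta = use$theta,
             z = use$z, rtnorm = use$rtnorm, stringsAsFactors = FALSE)
}

#' Annotate all base-base contacts of a structure
#'
#' Runs \code{\link{classifyPair}} over every unordered pair with at least
#' one ordering inside the interaction shell.
#'
#' @param structure an \linkS4class{RnaStructure}.
#' @param params a \linkS4class{ScalingParams}.
#' @return data.frame with one row per annotated pair (zone != NONE),
#'   ordered by (j, k), with the columns of \code{\link{classifyPair}} plus
#'   \code{chain_j}, \code{resno_j}, \code{chain_k}, \code{resno_k}.
#' @examples
#' ann <- annotateStructure(makeAformDuplex("GGGG"))
#' table(ann$zone)
#' @export
annotateStructure <- function(structure, params = scalingParams()) {
  pv <- .allPairVectors(structure, params)
  empty <- data.frame(j = integer(), k = integer(), zone = character(),
                      edge = character(), mutual = logical(),
                      rho = numeric(), theta = numeric(), z = numeric(),
                      rtnorm = numeric(), chain_j = character(),
                      resno_j = integer(), chain_k = character(),
                      resno_k = integer(), stringsAsFactors = FALSE)
  if (nrow(pv) == 0L) return(empty)
  shell <- pv[pv$rtnorm < params@shellMax, , drop = FALSE]
  if (nrow(shell) == 0L) return(empty)
  cand <- unique(data.frame(j = pmin(shell$j, shell$k),
                            k = pmax(shell$j, shell$k)))
  cand <- cand[order(cand$j, cand$k), , drop = FALSE]
  key <- paste(pv$j, pv$k)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    j <- cand$j[i]; k <- cand$k[i]
    classifyPair(pv[match(paste(j, k), key), ],
                 pv[match(paste(k, j), key), ], params)
  })
  ann <- do.call(rbind, rows)
  info <- structure@info
  ann$chain_j <- info$chain[ann$j]
  ann$resno_j <- info$resno[ann$j]
  ann$chain_k <- info$chain[ann$k]
  ann$resno_k <- info$resno[ann$k]
  rownames(ann) <- NULL
  ann
}
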