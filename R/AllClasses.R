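#' Geometric parameters of the nucleobase representation
#'
#' Holds the constants that define the anisotropic (ellipsoidal) metric
#' around a nucleobase and the zones used for contact classification and
#' scoring.  The defaults are the values the representation was calibrated
#' with and should rarely be changed:
#' \describe{
#'   \item{a, b}{in-plane and normal semi-axes of the ellipsoidal scaling
#'     (Angstrom).  A pair vector r is scaled to
#'     \eqn{\tilde r = (r_x/a, r_y/a, r_z/b)}.}
#'   \item{shellMax}{outer radius of the interaction shell in scaled units
#'     (\eqn{\sqrt{2.5}}); essentially all base-base contacts fall below it.}
#'   \item{shellMin}{inner radius of the shell (scaled units), used for
#'     reporting only.}
#'   \item{zSplit}{|z| boundary (Angstrom) separating the in-plane pairing
#'     zone from the stacking zone.}
#'   \item{rCutoff}{cutoff (scaled units) of the smooth G mapping used by the
#'     deviation metrics.}
#'   \item{bandwidth}{Gaussian kernel bandwidth (Angstrom) of the scoring
#'     density.}
#'   \item{wcSector, hoogsteenSector, sugarSector}{angular sectors (degrees,
#'     theta in [0, 360)) assigning pairing-zone contacts to base edges.}
#' }
#'
#' @slot a,b,shellMax,shellMin,zSplit,rCutoff,bandwidth numeric scalars, see
#'   above.
#' @slot wcSector,hoogsteenSector,sugarSector numeric length-2 vectors of
#'   sector bounds in degrees.
#' @export
setClass("ScalingParams",
  representation(a = "numeric", b = "numeric", shellMax = "numeric",
                 shellMin = "numeric", zSplit = "numeric",
                 rCutoff = "numeric", bandwidth = "numeric",
                 wcSector = "numeric", hoogsteenSector = "numeric",
                 sugarSector = "numeric"),
  prototype(a = 5.0, b = 3.0, shellMax = sqrt(2.5), shellMin = 1.0,
            zSplit = 2.0, rCutoff = 2.4, bandwidth = 0.25,
            wcSector = c(30, 100), hoogsteenSector = c(100, 190),
            sugarSector = c(190, 290)))

setValidity("ScalingParams", function(object) {
  msg <- character()
  for (s in c("a", "b", "shellMax", "shellMin", "zSplit", "rCutoff",
              "bandwidth")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a positive scalar", s))
  }
  if (length(msg) == 0L && !(object@shellMin < object@shellMax &&
                             object@shellMax < object@rCutoff))
    msg <- c(msg, "need shellMin < shellMax < rCutoff")
  if (length(msg)) msg else TRUE
})

#' Construct scaling parameters
#'
#' @param a,b ellipsoidal semi-axes (Angstrom).
#' @param shellMax,shellMin interaction-shell radii (scaled units).
#' @param zSplit pairing/stacking |z| boundary (Angstrom).
#' @param rCutoff cutoff of the G mapping (scaled units).
#' @param bandwidth kernel bandwidth of the scoring density (Angstrom).
#' @param wcSector,hoogsteenSector,sugarSector edge sectors (degrees).
#' @return A \linkS4class{ScalingParams} object.
#' @examples
#' p <- scalingParams()
#' p@shellMax^2   # 2.5
#' @export
scalingParams <- function(a = 5.0, b = 3.0, shellMax = sqrt(2.5),
                          shellMin = 1.0, zSplit = 2.0, rCutoff = 2.4,
                          bandwidth = 0.25, wcSector = c(30, 100),
                          hoogsteenSector = c(100, 190),
                          sugarSector = c(190, 290)) {
  new("ScalingParams", a = a, b = b, shellMax = shellMax,
      shellMin = shellMin, zSplit = zSplit, rCutoff = rCutoff,
      bandwidth = bandwidth, wcSector = wcSector,
      hoogsteenSector = hoogsteenSector, sugarSector = sugarSector)
}

#' An RNA (or DNA) structure at nucleotide resolution
#'
#' Ordered collection of nucleotides with their heavy-atom coordinates.
#' Only residues possessing all three frame atoms (C2, C4, C6 of the
#' six-membered ring) are retained, because those three atoms define the
#' oriented bead that represents the base.
#'
#' @slot info data.frame with one row per nucleotide: \code{seq} (1-based
#'   index), \code{chain}, \code{resno}, \code{insert}, \code{resid}
#'   (residue name as in the file), \code{base} (one of A, C, G, U, T) and
#'   \code{class} ("purine" or "pyrimidine").
#' @slot atoms data.frame with one row per heavy atom: \code{seq}, \code{atom}
#'   (name), \code{x}, \code{y}, \code{z} (Angstrom).
#' @seealso \code{\link{readStructure}}, \code{\link{rnaStructure}},
#'   \code{\link{makeAformDuplex}}
#' @export
setClass("RnaStructure",
  representation(info = "data.frame", atoms = "data.frame"))

.PURINES <- c("A", "G")

setValidity("RnaStructure", function(object) {
  info <- object@info
  atoms <- object@atoms
  need <- c("seq", "chain", "resno", "insert", "resid", "base", "class")
  if (!all(need %in% names(info)))
    return(sprintf("info must have columns %s", paste(need, collapse = ", ")))
  if (!all(c("seq", "atom", "x", "y", "z") %in% names(atoms)))
    return("atoms must have columns seq, atom, x, y, z")
  if (nrow(info) == 0L)
    return("structure contains no nucleotides")
  if (!identical(info$seq, seq_len(nrow(info))))
    return("info$seq must be 1..N in order")
  want <- ifelse(info$base %in% .PURINES, "purine", "pyrimidine")
  if (!all(info$class == want))
    return("base class inconsistent with base identity")
  sp <- split(atoms$atom, factor(atoms$seq, levels = info$seq))
  if (any(vapply(sp, anyDuplicated, 0L) > 0L))
    return("duplicated atom names within a nucleotide")
  ok <- vapply(sp, function(a) all(c("C2", "C4", "C6") %in% a), TRUE)
  if (!all(ok))
    return("every nucleotide must have ring atoms C2, C4 and C6")
  TRUE
})

#' Construct an RnaStructure from tables
#'
#' Low-level constructor; most users will use \code{\link{readStructure}} or
#' the fixture generators instead.
#'
#' @param info per-nucleotide data.frame (see \linkS4class{RnaStructure}).
#'   Columns \code{insert}, \code{resid} and \code{class} are filled with
#'   defaults when missing; \code{seq} is renumbered 1..N in row order.
#' @param atoms per-atom data.frame with columns \code{seq}, \code{atom},
#'   \code{x}, \code{y}, \code{z}.  \code{seq} must refer to the row numbers
#'   of \code{info} prior to renumbering.
#' @return A validated \linkS4class{RnaStructure}.
#' @export
rnaStructure <- function(info, atoms) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(info$insert)) info$insert <- ""
  if (is.null(info$resid)) info$resid <- info$base
  if (is.null(info$class))
    info$class <- ifelse(info$base %in% .PURINES, "purine", "pyrimidine")
  if (is.null(info$resno)) info$resno <- seq_len(nrow(info))
  if (is.null(info$chain)) info$chain <- "A"
  old <- info$seq
  if (is.null(old)) old <- seq_len(nrow(info))
  info$seq <- seq_len(nrow(info))
  atoms$seq <- match(atoms$seq, old)
  atoms <- atoms[order(atoms$seq), , drop = FALSE]
  rownames(info) <- rownames(atoms) <- NULL
  new("RnaStructure", info = info, atoms = atoms)
}

#' @describeIn nNucleotides number of nucleotides of a structure
#' @export
setMethod("nNucleotides", "RnaStructure", function(x) nrow(x@info))

#' @describeIn baseSequence base identities of a structure
#' @export
setMethod("baseSequence", "RnaStructure", function(x) x@info$base)

#' @describeIn chainIds chain labels of a structure
#' @export
setMethod("chainIds", "RnaStructure", function(x) x@info$chain)

#' @describeIn atomCoords heavy-atom coordinate matrix
#' @export
setMethod("atomCoords", "RnaStructure", function(x)
  as.matrix(x@atoms[, c("x", "y", "z")]))

#' @describeIn ringCenters ring-centroid matrix of a structure
#' @export
setMethod("ringCenters", "RnaStructure", function(x) {
  rc <- .ringAtomCoords(x)
  (rc[, 1:3, drop = FALSE] + rc[, 4:6, drop = FALSE] +
   rc[, 7:9, drop = FALSE]) / 3
})

#' @describeIn subStructure subset of a structure
#' @export
setMethod("subStructure", "RnaStructure", function(x, indices) {
  indices <- as.integer(indices)
  if (any(is.na(indices)) || any(indices < 1L) ||
      any(indices > nNucleotides(x)))
    stop("nucleotide indices out of range")
  info <- x@info[indices, , drop = FALSE]
  atoms <- x@atoms[x@atoms$seq %in% indices, , drop = FALSE]
  atoms <- atoms[order(match(atoms$seq, indices)), , drop = FALSE]
  rnaStructure(info, atoms)
})

setMethod("show", "RnaStructure", function(object) {
  n <- nNucleotides(object)
  ch <- unique(chainIds(object))
  cat(sprintf("RnaStructure: %d nucleotide%s, %d chain%s, %d heavy atoms\n",
              n, if (n == 1) "" else "s", length(ch),
              if (length(ch) == 1) "" else "s", nrow(object@atoms)))
  s <- paste(baseSequence(object), collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  sequence: ", s, "\n", sep = "")
})

#' A multi-model trajectory sharing one topology
#'
#' @slot frames list of \linkS4class{RnaStructure} objects with identical
#'   nucleotide count, ordering and base identities.
#' @slot timeStep time per frame, arbitrary units (metadata only).
#' @export
setClass("RnaTrajectory",
  representation(frames = "list", timeStep = "numeric"),
  prototype(timeStep = 1))

setValidity("RnaTrajectory", function(object) {
  fr <- object@frames
  if (length(fr) < 1L) return("trajectory needs at least one frame")
  if (!all(vapply(fr, is, TRUE, "RnaStructure")))
    return("all frames must be RnaStructure objects")
  b0 <- baseSequence(fr[[1]])
  same <- vapply(fr, function(f) identical(baseSequence(f), b0), TRUE)
  if (!all(same))
    return("all frames must share nucleotide count and ordering")
  TRUE
})

#' Construct a trajectory from frames
#'
#' @param frames list of \linkS4class{RnaStructure} objects sharing topology.
#' @param timeStep time per frame (arbitrary units).
#' @return An \linkS4class{RnaTrajectory}.
#' @export
rnaTrajectory <- function(frames, timeStep = 1) {
  new("RnaTrajectory", frames = frames, timeStep = timeStep)
}

#' @describeIn nFrames number of frames
#' @export
setMethod("nFrames", "RnaTrajectory", function(x) length(x@frames))

#' @describeIn getFrame extract frame i
#' @export
setMethod("getFrame", "RnaTrajectory", function(x, i) x@frames[[i]])

setMethod("show", "RnaTrajectory", function(object) {
  cat(sprintf("RnaTrajectory: %d frames of %d nucleotides\n",
              nFrames(object), nNucleotides(object@frames[[1]])))
})

#' Knowledge-based scoring model
#'
#' The empirical density p(r) of relative nucleobase positions, represented
#' as a Gaussian kernel density estimate over the pair vectors observed in
#' the training structures (interaction-shell members only).
#'
#' @slot vectors numeric matrix (n x 3) of training pair vectors r, in
#'   Angstrom, expressed in the observing base's local frame.
#' @slot bandwidth isotropic Gaussian kernel bandwidth (Angstrom).
#' @slot params the \linkS4class{ScalingParams} the model was trained with.
#' @slot metadata free-text description of the training source.
#' @seealso \code{\link{fitScoreModel}}, \code{\link{eScore}}
#' @export
setClass("ScoreModel",
  representation(vectors = "matrix", bandwidth = "numeric",
                 params = "ScalingParams", metadata = "character"))

setValidity("ScoreModel", function(object) {
  if (ncol(object@vectors) != 3L) return("vectors must be an n x 3 matrix")
  if (nrow(object@vectors) < 1L) return("model has no training vectors")
  if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
    return("bandwidth must be a positive scalar")
  TRUE
})

setMethod("show", "ScoreModel", function(object) {
  cat(sprintf("ScoreModel: %d training vectors, bandwidth %.3g A\n",
              nrow(object@vectors), object@bandwidth))
  if (length(object@metadata) && nzchar(object@metadata[1]))
    cat("  source: ", object@metadata[1], "\n", sep = "")
})

#' Ideal A-form helix parameters
#'
#' Parameters of the fixture generator for ideal A-form duplexes.  Base-pair
#' geometry comes from idealized per-nucleotide heavy-atom templates shipped
#' with the package (see \code{inst/extdata/nucleotide_templates.csv});
#' consecutive base pairs are related by a right-handed screw of
#' \code{twist} degrees about and \code{rise} Angstrom along the helix axis.
#'
#' @slot twist helical twist per step (degrees).
#' @slot rise helical rise per step (Angstrom).
#' @slot xDisplacement displacement of the base-pair origin from the helix
#'   axis along the pair x-axis (Angstrom, negative in A-form).
#' @slot inclination base-pair inclination (degrees).
#' @export
setClass("HelixParams",
  representation(twist = "numeric", rise = "numeric",
                 xDisplacement = "numeric", inclination = "numeric"),
  prototype(twist = 32.7, rise = 2.81, xDisplacement = -4.4,
            inclination = 15.0))

setValidity("HelixParams", function(object) {
  if (object@rise <= 0) return("rise must be positive")
  if (abs(object@twist) <= 0) return("twist must be nonzero")
  TRUE
})

#' Construct A-form helix parameters
#'
#' Defaults are standard fiber-model values for A-RNA.
#'
#' @param twist helical twist per step (degrees).
#' @param rise helical rise per step (Angstrom).
#' @param xDisplacement base-pair x-displacement (Angstrom).
#' @param inclination base-pair inclination (degrees).
#' @return A \linkS4class{HelixParams} object.
#' @export
helixParams <- function(twist = 32.7, rise = 2.81, xDisplacement = -4.4,
                        inclination = 15.0) {
  new("HelixParams", twist = twist, rise = rise,
      xDisplacement = xDisplacement, inclination = inclination)
}
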