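# Synthetic-structure generators: ideal A-form duplexes, register-shifted
# duplexes, Gaussian-noise decoys and diffusive toy trajectories.  These
# define the reference geometries used throughout the test suite, so their
# defaults are fixed study conditions, not tuning knobs.

.templateCache <- new.env(parent = emptyenv())

# per-base heavy-atom templates in the standard WC pair frame (strand I);
# the strand-II partner of base b is the (x,-y,-z) flip of complement(b)
.baseTemplates <- function() {
  if (!is.null(.templateCache$tpl)) return(.templateCache$tpl)
  path <- system.file("extdata", "nucleotide_templates.csv",
                      package = "ebase", mustWork = TRUE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tpl <- lapply(split(df, df$base), function(d) {
    m <- as.matrix(d[, c("x", "y", "z")])
    rownames(m) <- d$atom
    m
  })
  .templateCache$tpl <- tpl
  tpl
}

# place template atoms (rows xyz) at helical step i
.helixPlace <- function(m, step, hp) {
  v <- m %*% t(.rotY(hp@inclination))
  v[, 1] <- v[, 1] + hp@xDisplacement
  v <- v %*% t(.rotZ(hp@twist * step))
  v[, 3] <- v[, 3] + hp@rise * step
  v
}

.checkSeq <- function(seq) {
  if (length(seq) == 1L && is.character(seq)) {
    seq <- strsplit(seq, "")[[1]]
  }
  seq <- toupper(seq)
  if (length(seq) < 2L)
    stop("sequence must contain at least 2 nucleotides")
  bad <- setdiff(unique(seq), c("A", "C", "G", "U"))
  if (length(bad))
    stop("invalid sequence characters: ", paste(bad, collapse = ", "))
  seq
}

.buildDuplex <- function(seq, shift, hp) {
  tpl <- .baseTemplates()
  flip <- diag(c(1, -1, -1))
  n <- length(seq)
  comp <- .complementBase(seq)
  info <- list(); atoms <- list()
  addRes <- function(i, chain, resno, base, coords) {
    info[[i]] <<- data.frame(seq = i, chain = chain, resno = resno,
                             insert = "", resid = base, base = base,
                             class = if (base %in% .PURINES) "purine"
                                     else "pyrimidine",
                             stringsAsFactors = FALSE)
    atoms[[i]] <<- data.frame(seq = i, atom = rownames(coords),
                              x = coords[, 1], y = coords[, 2],
                              z = coords[, 3], stringsAsFactors = FALSE)
  }
  i <- 0L
  for (s in seq_len(n)) {           # strand I, 5'->3', steps 0..n-1
    i <- i + 1L
    addRes(i, "A", s, seq[s], .helixPlace(tpl[[seq[s]]], s - 1L, hp))
  }
  for (s in seq(n, 1L)) {           # strand II, its own 5'->3'
    i <- i + 1L
    m <- tpl[[comp[s]]] %*% flip
    addRes(i, "B", n - s + 1L, comp[s],
           .helixPlace(m, s - 1L + shift, hp))
  }
  rnaStructure(do.call(rbind, info), do.call(rbind, atoms))
}

# construction self-check: WC partners in the pairing zone, sequential
# intra-strand neighbours in the stacking zone
.duplexSelfCheck <- function(structure, n) {
  ann <- annotateStructure(structure)
  for (s in seq_len(n)) {
    row <- ann[ann$j == s & ann$k == 2L * n + 1L - s, ]
    if (nrow(row) != 1L || row$zone != "PAIRING")
      stop("A-form generator self-check failed: WC partner of position ",
           s, " not in the pairing zone")
  }
  for (s in seq_len(n - 1L)) {
    row <- ann[ann$j == s & ann$k == s + 1L, ]
    if (nrow(row) != 1L || row$zone != "STACKING")
      stop("A-form generator self-check failed: stacked neighbour ",
           s, " not in the stacking zone")
  }
  invisible(TRUE)
}

#' Generate an ideal A-form duplex
#'
#' Builds the double helix formed by \code{seq} and its reverse complement
#' on an ideal A-form helix (idealized per-nucleotide templates placed by a
#' right-handed screw; see \code{\link{helixParams}}).  Strand I is chain A
#' (the given sequence, 5' to 3'); strand II is chain B.  Construction is
#' deterministic and self-checks that Watson-Crick partners fall in the
#' pairing zone and sequential neighbours in the stacking zone.
#'
#' @param seq character string (or vector) over A, C, G, U; length >= 2.
#' @param params a \linkS4class{HelixParams}.
#' @param selfCheck verify the pairing/stacking geometry after construction.
#' @return An \linkS4class{RnaStructure} with 2 * nchar(seq) nucleotides.
#' @examples
#' d <- makeAformDuplex("GGGG")
#' table(annotateStructure(d)$zone)
#' @export
makeAformDuplex <- function(seq, params = helixParams(), selfCheck = TRUE) {
  seq <- .checkSeq(seq)
  s <- .buildDuplex(seq, 0L, params)
  if (selfCheck) .duplexSelfCheck(s, length(seq))
  s
}

#' Generate a register-shifted duplex
#'
#' The same two strands as \code{\link{makeAformDuplex}(seq)}, but with the
#' complementary strand displaced by \code{shift} helical steps along the
#' same ideal helix, producing single-stranded overhangs at both ends while
#' keeping the atom count identical to the unshifted duplex.  The resulting
#' structure is geometrically close to the in-register duplex (small RMSD)
#' yet has a different base-pairing network.
#'
#' @param seq character string over A, C, G, U.
#' @param shift integer register offset in helical steps;
#'   \code{abs(shift) < nchar(seq)}.
#' @param params a \linkS4class{HelixParams}.
#' @return An \linkS4class{RnaStructure}.
#' @examples
#' atomRMSD(makeAformDuplex("GGGG"), makeRegisterShift("GGGG", 1))
#' @export
makeRegisterShift <- function(seq, shift = 1L, params = helixParams()) {
  seq <- .checkSeq(seq)
  shift <- as.integer(shift)
  if (abs(shift) >= length(seq))
    stop("shift must be smaller than the strand length")
  .buildDuplex(seq, shift, params)
}

#' Add Gaussian coordinate noise to a structure
#'
#' Displaces every heavy atom independently by isotropic Gaussian noise of
#' standard deviation \code{sigma} per coordinate.  Reproducible given the
#' seed; the global random number generator state is left untouched.
#'
#' @param structure an \linkS4class{RnaStructure}.
#' @param sigma noise standard deviation per coordinate (Angstrom).
#' @param seed integer seed.
#' @return A perturbed \linkS4class{RnaStructure}.
#' @export
perturbStructure <- function(structure, sigma, seed = 1L) {
  stopifnot(is(structure, "RnaStructure"), sigma >= 0)
  if (sigma == 0) return(structure)
  atoms <- structure@atoms
  noise <- .withSeed(seed,
                     matrix(stats::rnorm(3L * nrow(atoms), sd = sigma),
                            ncol = 3))
  atoms$x <- atoms$x + noise[, 1]
  atoms$y <- atoms$y + noise[, 2]
  atoms$z <- atoms$z + noise[, 3]
  new("RnaStructure", info = structure@info, atoms = atoms)
}

#' Generate a diffusive toy trajectory
#'
#' Starting from \code{base}, each frame adds independent Gaussian
#' displacements of standard deviation \code{stepSigma} per coordinate to
#' the previous frame (a random walk in conformation space), emulating
#' progressive structural drift.  Deterministic given the seed.
#'
#' @param base starting \linkS4class{RnaStructure}.
#' @param nFrames number of frames (>= 2); frame 1 is \code{base}.
#' @param stepSigma per-step displacement scale (Angstrom).
#' @param seed integer seed.
#' @return An \linkS4class{RnaTrajectory}.
#' @export
makeTrajectory <- function(base, nFrames, stepSigma, seed = 1L) {
  stopifnot(is(base, "RnaStructure"))
  nFrames <- as.integer(nFrames)
  if (nFrames < 2L) stop("need at least 2 frames")
  frames <- vector("list", nFrames)
  frames[[1]] <- base
  cur <- base
  for (t in 2:nFrames) {
    cur <- perturbStructure(cur, stepSigma, seed = seed + t - 1L)
    frames[[t]] <- cur
  }
  rnaTrajectory(frames)
}
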