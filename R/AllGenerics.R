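#' @import methods
NULL

#' Number of nucleotides in a structure
#'
#' @param x an \linkS4class{RnaStructure}.
#' @return Integer scalar.
#' @export
setGeneric("nNucleotides", function(x) standardGeneric("nNucleotides"))

#' Base identities along a structure
#'
#' @param x an \linkS4class{RnaStructure}.
#' @return Character vector of one-letter base identities (A, C, G, U or T),
#'   in sequence order.
#' @export
setGeneric("baseSequence", function(x) standardGeneric("baseSequence"))

#' Per-nucleotide chain identifiers
#'
#' @param x an \linkS4class{RnaStructure}.
#' @return Character vector of chain labels, one per nucleotide.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' Centroids of the six-membered base rings
#'
#' The centroid of the C2/C4/C6 ring atoms is the single bead that represents
#' a nucleobase in all shell, scoring and deviation computations.
#'
#' @param x an \linkS4class{RnaStructure}.
#' @return Numeric matrix with one row per nucleotide and columns x, y, z
#'   (Angstrom).
#' @export
setGeneric("ringCenters", function(x) standardGeneric("ringCenters"))

#' Heavy-atom coordinates of a structure
#'
#' @param x an \linkS4class{RnaStructure}.
#' @return Numeric matrix of atom coordinates (rows follow the atom table).
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' Extract a subset of nucleotides as a new structure
#'
#' @param x an \linkS4class{RnaStructure}.
#' @param indices integer vector of nucleotide indices (1-based, in the order
#'   they should appear in the result).
#' @return An \linkS4class{RnaStructure} containing only those nucleotides.
#' @export
setGeneric("subStructure", function(x, indices) standardGeneric("subStructure"))

#' Number of frames in a trajectory
#'
#' @param x an \linkS4class{RnaTrajectory}.
#' @return Integer scalar.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Extract one frame of a trajectory
#'
#' @param x an \linkS4class{RnaTrajectory}.
#' @param i frame index (1-based).
#' @return An \linkS4class{RnaStructure}.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
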