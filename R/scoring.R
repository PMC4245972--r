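#' Train the empirical pair-vector density
#'
#' Collects the (unscaled) pair vectors r of all ordered base pairs inside
#' the interaction shell of the training structures and represents their
#' empirical distribution p(r) as an average of isotropic Gaussian kernels.
#' Base identity is ignored: the molecule is treated as a homopolymer of
#' oriented beads.  By default a vector r_jk is included when its own scaled
#' norm is inside the shell (one-sided rule); \code{mutual = TRUE} requires
#' both orderings inside the shell.
#'
#' @param structures an \linkS4class{RnaStructure} or a list of them.
#' @param bandwidth Gaussian kernel bandwidth (Angstrom).
#' @param params a \linkS4class{ScalingParams}.
#' @param mutual require both orderings of a pair inside the shell.
#' @param metadata free-text description of the training source.
#' @return A \linkS4class{ScoreModel}.
#' @examples
#' m <- fitScoreModel(makeAformDuplex("GGCC"))
#' m
#' @export
fitScoreModel <- function(structures, bandwidth = 0.25,
                          params = scalingParams(), mutual = FALSE,
                          metadata = "") {
  if (is(structures, "RnaStructure")) structures <- list(structures)
  vecs <- lapply(structures, function(s) {
    pv <- enumerateShellPairs(s, params)
    if (mutual && nrow(pv)) {
      key <- paste(pv$j, pv$k)
      rev <- paste(pv$k, pv$j)
      pv <- pv[rev %in% key, , drop = FALSE]
    }
    as.matrix(pv[, c("rx", "ry", "rz")])
  })
  v <- do.call(rbind, vecs)
  if (is.null(v) || nrow(v) == 0L)
    stop("no interaction-shell pairs in the training structures")
  colnames(v) <- c("x", "y", "z")
  new("ScoreModel", vectors = v, bandwidth = bandwidth, params = params,
      metadata = as.character(metadata))
}

#' Evaluate the trained density at query vectors
#'
#' Standard Gaussian kernel density estimate: the average over training
#' vectors v_i of \eqn{(2\pi h^2)^{-3/2} \exp(-|r - v_i|^2 / 2h^2)}.  The
#' result is a true probability density over r (integrates to 1).
#'
#' @param model a \linkS4class{ScoreModel}.
#' @param r numeric length-3 vector or n x 3 matrix of query vectors
#'   (Angstrom, in the observing base's frame).
#' @return Non-negative density value(s), one per query row.
#' @export
evaluateDensity <- function(model, r) {
  if (!is.matrix(r)) r <- matrix(r, ncol = 3)
  v <- model@vectors
  h2 <- model@bandwidth^2
  norm <- (2 * pi * h2)^(-1.5)
  # squared distances query x training
  d2 <- outer(rowSums(r^2), rowSums(v^2), "+") - 2 * r %*% t(v)
  d2[d2 < 0] <- 0
  as.vector(norm * rowMeans(exp(-d2 / (2 * h2))))
}

#' Score a structure against a trained density
#'
#' The score is the sum over all ordered base pairs (both permutations) of
#' the trained density evaluated at the pair vector r_jk.  Relative base
#' arrangements never seen in training -- including steric clashes --
#' contribute essentially nothing, so higher scores indicate conformations
#' compatible with the training distribution.  Pairs whose scaled norm
#' exceeds \code{shellMax + 3 bandwidth / min(a, b)} are skipped as
#' numerically negligible.
#'
#' @param structure an \linkS4class{RnaStructure}.
#' @param model a \linkS4class{ScoreModel}.
#' @return Numeric scalar (0 for a single-nucleotide structure).
#' @examples
#' m <- fitScoreModel(makeAformDuplex("GGCC"))
#' eScore(makeAformDuplex("GGCC"), m)
#' @export
eScore <- function(structure, model) {
  params <- model@params
  pv <- .allPairVectors(structure, params)
  if (nrow(pv) == 0L) return(0)
  lim <- params@shellMax + 3 * model@bandwidth / min(params@a, params@b)
  pv <- pv[pv$rtnorm < lim, , drop = FALSE]
  if (nrow(pv) == 0L) return(0)
  sum(evaluateDensity(model, as.matrix(pv[, c("rx", "ry", "rz")])))
}

#' Rank a native structure within a decoy set
#'
#' The normalized rank is the fraction of decoys scoring strictly better
#' (higher) than the native structure: 0 means perfect recognition, 1 means
#' every decoy outscored the native.  Ties with the native do not count as
#' better.
#'
#' @param native the reference \linkS4class{RnaStructure}.
#' @param decoys list of decoy \linkS4class{RnaStructure} objects.
#' @param model a \linkS4class{ScoreModel}.
#' @return A list with \code{nativeScore}, \code{decoyScores} and
#'   \code{normalizedRank}.
#' @export
rankDecoys <- function(native, decoys, model) {
  if (is(decoys, "RnaStructure")) decoys <- list(decoys)
  if (length(decoys) < 1L) stop("need at least one decoy")
  ns <- eScore(native, model)
  ds <- vapply(decoys, eScore, 0, model = model)
  list(nativeScore = ns, decoyScores = ds,
       normalizedRank = sum(ds > ns) / length(ds))
}

#' Save a scoring model as portable JSON
#'
#' @param model a \linkS4class{ScoreModel}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeScoreModel <- function(model, path) {
  p <- model@params
  obj <- list(
    format = "ebase-score-model",
    version = 1L,
    bandwidth = model@bandwidth,
    metadata = model@metadata,
    params = list(a = p@a, b = p@b, shellMax = p@shellMax,
                  shellMin = p@shellMin, zSplit = p@zSplit,
                  rCutoff = p@rCutoff, bandwidth = p@bandwidth),
    vectors = unname(as.matrix(model@vectors)))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Load a scoring model from JSON
#'
#' @param path file written by \code{\link{writeScoreModel}}.
#' @return A \linkS4class{ScoreModel}.
#' @export
readScoreModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ebase-score-model"))
    stop("not an ebase score model file: ", path)
  pl <- obj$params
  params <- scalingParams(a = pl$a, b = pl$b, shellMax = pl$shellMax,
                          shellMin = pl$shellMin, zSplit = pl$zSplit,
                          rCutoff = pl$rCutoff, bandwidth = pl$bandwidth)
  v <- matrix(as.numeric(obj$vectors), ncol = 3)
  colnames(v) <- c("x", "y", "z")
  new("ScoreModel", vectors = v, bandwidth = obj$bandwidth,
      params = params,
      metadata = as.character(obj$metadata %||% ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
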