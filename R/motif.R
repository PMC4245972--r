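#' Split a motif query into contiguous segments
#'
#' A query motif may span several strands (e.g. an internal loop) or contain
#' physical chain breaks.  Segments are split at chain boundaries and at
#' backbone gaps, detected as consecutive ring centroids more than
#' \code{gap} Angstrom apart.
#'
#' @param structure an \linkS4class{RnaStructure} holding the motif.
#' @param gap centroid distance (Angstrom) beyond which consecutive
#'   nucleotides are considered disconnected.
#' @return A list with \code{structure} and \code{segments}, a list of
#'   integer index vectors partitioning the query; every segment has at
#'   least 2 nucleotides.
#' @export
segmentQuery <- function(structure, gap = 12) {
  segments <- .segmentStructure(structure, gap)
  if (any(lengths(segments) < 2L))
    stop("query error: every motif segment needs at least 2 nucleotides")
  list(structure = structure, segments = segments)
}

# segmentation without the minimum-length requirement (targets may contain
# isolated nucleotides; they simply host no windows)
.segmentStructure <- function(structure, gap = 12) {
  stopifnot(is(structure, "RnaStructure"))
  n <- nNucleotides(structure)
  rc <- ringCenters(structure)
  ch <- chainIds(structure)
  breaks <- integer()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      d <- sqrt(sum((rc[i + 1L, ] - rc[i, ])^2))
      if (ch[i + 1L] != ch[i] || d > gap) breaks <- c(breaks, i)
    }
  }
  bounds <- c(0L, breaks, n)
  lapply(seq_len(length(bounds) - 1L), function(i)
    seq.int(bounds[i] + 1L, bounds[i + 1L]))
}

# candidate windows for one segment of length L within the target segments:
# exact windows plus, when bulges are allowed, length L+1 windows with one
# internal nucleotide deleted.  Each candidate is list(idx, bulged).
.segmentWindows <- function(targetSegments, len, maxBulges) {
  out <- list()
  for (seg in targetSegments) {
    ns <- length(seg)
    if (ns >= len) {
      for (s in seq_len(ns - len + 1L)) {
        out[[length(out) + 1L]] <- list(idx = seg[s:(s + len - 1L)],
                                        bulged = integer())
      }
    }
    if (maxBulges >= 1L && ns >= len + 1L) {
      for (s in seq_len(ns - len)) {
        w <- seg[s:(s + len)]
        for (drop in 2:len) {        # internal deletions only
          out[[length(out) + 1L]] <- list(idx = w[-drop], bulged = w[drop])
        }
      }
    }
  }
  out
}

# enumerate ordered non-overlapping combinations of per-segment windows
.combineWindows <- function(perSegment, maxCombinations) {
  combos <- list(list(idx = integer(), bulged = integer(), last = 0L))
  for (cands in perSegment) {
    nxt <- list()
    for (cb in combos) {
      for (w in cands) {
        if (min(w$idx) <= cb$last) next   # preserve order, no overlap
        nxt[[length(nxt) + 1L]] <- list(idx = c(cb$idx, w$idx),
                                        bulged = c(cb$bulged, w$bulged),
                                        last = max(w$idx))
        if (length(nxt) > maxCombinations) {
          warning("combination cap reached; some window sets not explored",
                  call. = FALSE)
          return(nxt)
        }
      }
    }
    combos <- nxt
  }
  combos
}

#' Search a target structure for occurrences of a 3D motif
#'
#' Slides windows matching the query's segment lengths over the target and
#' reports window sets whose deviation (\code{\link{eRMSD}}) from the query
#' is below \code{threshold}.  With \code{maxBulges >= 1}, windows one
#' nucleotide longer are also tried with each internal nucleotide deleted,
#' recovering motif copies interrupted by a bulged base.  Overlapping
#' matches (sharing more than half their nucleotides) are deduplicated
#' keeping the lowest-deviation variant; deduplication is performed before
#' thresholding, so the match set at a smaller threshold is always a subset
#' of the match set at a larger one.
#'
#' @param query result of \code{\link{segmentQuery}} (or an
#'   \linkS4class{RnaStructure}, segmented automatically).
#' @param target an \linkS4class{RnaStructure} to search.
#' @param threshold report matches with eRMSD below this value.
#' @param maxBulges number of bulged-base insertions tolerated per segment
#'   (0 or 1).
#' @param params a \linkS4class{ScalingParams}.
#' @param maxCombinations cap on multi-segment window combinations.
#' @return data.frame with one row per match, sorted by ascending
#'   \code{ermsd}: \code{ermsd}, \code{window} (comma-separated nucleotide
#'   indices), \code{residues} (chain:author-number labels), \code{bulged}
#'   (indices of deleted bulge nucleotides, empty when none).
#' @examples
#' d <- makeAformDuplex("GGCGCC")
#' q <- subStructure(d, c(1:3, 10:12))
#' searchMotif(q, d, threshold = 0.5)
#' @export
searchMotif <- function(query, target, threshold = 0.7, maxBulges = 1,
                        params = scalingParams(), maxCombinations = 1e5) {
  if (is(query, "RnaStructure")) query <- segmentQuery(query)
  stopifnot(is(target, "RnaStructure"))
  if (threshold <= 0) stop("threshold must be positive")
  qlen <- sum(lengths(query$segments))
  if (nNucleotides(target) < qlen)
    stop("target is shorter than the query")
  qs <- subStructure(query$structure, unlist(query$segments))
  tSegs <- .segmentStructure(target)
  perSegment <- lapply(lengths(query$segments), function(L)
    .segmentWindows(tSegs, L, as.integer(maxBulges)))
  if (any(lengths(perSegment) == 0L)) return(.emptyMatches())
  combos <- .combineWindows(perSegment, maxCombinations)
  combos <- Filter(function(cb) length(cb$idx) == qlen, combos)
  if (length(combos) == 0L) return(.emptyMatches())
  ermsd <- vapply(combos, function(cb)
    eRMSD(qs, subStructure(target, cb$idx), params), 0)
  ord <- order(ermsd)
  kept <- list()
  for (i in ord) {                       # greedy dedup, best first
    idx <- combos[[i]]$idx
    dup <- any(vapply(kept, function(kb)
      length(intersect(kb$idx, idx)) > qlen / 2, TRUE))
    if (!dup)
      kept[[length(kept) + 1L]] <- list(idx = idx,
                                        bulged = combos[[i]]$bulged,
                                        ermsd = ermsd[i])
  }
  kept <- Filter(function(kb) kb$ermsd < threshold, kept)
  if (length(kept) == 0L) return(.emptyMatches())
  info <- target@info
  lab <- function(ix) paste(sprintf("%s:%d%s", info$chain[ix],
                                    info$resno[ix], info$insert[ix]),
                            collapse = ",")
  data.frame(
    ermsd = vapply(kept, function(kb) kb$ermsd, 0),
    window = vapply(kept, function(kb) paste(kb$idx, collapse = ","), ""),
    residues = vapply(kept, function(kb) lab(kb$idx), ""),
    bulged = vapply(kept, function(kb)
      if (length(kb$bulged)) lab(kb$bulged) else "", ""),
    stringsAsFactors = FALSE)
}

.emptyMatches <- function() {
  data.frame(ermsd = numeric(), window = character(),
             residues = character(), bulged = character(),
             stringsAsFactors = FALSE)
}

#' Search several target files for a motif
#'
#' Applies \code{\link{searchMotif}} to each file; unreadable targets are
#' skipped with a warning.  Matches carry per-target provenance and are
#' returned in input order (deterministic).
#'
#' @param query a segmented query (see \code{\link{searchMotif}}).
#' @param targets character vector of structure file paths.
#' @param ... passed to \code{\link{searchMotif}}.
#' @return data.frame of matches with a leading \code{target} column.
#' @export
batchSearchMotif <- function(query, targets, ...) {
  if (length(targets) < 1L) stop("need at least one target file")
  out <- lapply(seq_along(targets), function(i) {
    s <- tryCatch(readStructure(targets[i], quiet = TRUE),
                  error = function(e) {
                    warning("skipping target ", targets[i], ": ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (is.null(s)) return(NULL)
    m <- searchMotif(query, s, ...)
    if (nrow(m)) cbind(target = targets[i], m, stringsAsFactors = FALSE)
    else NULL
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0L)
    return(cbind(target = character(), .emptyMatches()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
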