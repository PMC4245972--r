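#' @importFrom utils read.csv
NULL

.RESIDUE_BASE <- c(A = "A", C = "C", G = "G", U = "U",
                   DA = "A", DC = "C", DG = "G", DT = "T",
                   RA = "A", RC = "C", RG = "G", RU = "U")

# split raw PDB text into per-model character vectors
.splitModels <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(list(lines))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  mapply(function(s, e) lines[s:e], starts, ends[seq_along(starts)],
         SIMPLIFY = FALSE)
}

.parsePdbChunk <- function(lines, source = "pdb") {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  bio3d::read.pdb(tf, verbose = FALSE)
}

# convert one bio3d pdb object into an RnaStructure
.pdbToStructure <- function(pdb, nameMap = NULL, quiet = FALSE) {
  at <- pdb$atom
  # single conformer: altloc blank or 'A'
  if (!is.null(at$alt)) {
    alt <- at$alt
    alt[is.na(alt)] <- ""
    at <- at[alt %in% c("", "A"), , drop = FALSE]
  }
  # heavy atoms only
  elt <- at$elesy
  if (is.null(elt) || all(is.na(elt)) || all(!nzchar(trimws(elt)))) {
    elt <- substr(gsub("[0-9']", "", trimws(at$elety)), 1, 1)
  }
  at <- at[toupper(trimws(elt)) != "H", , drop = FALSE]
  ins <- at$insert
  if (is.null(ins)) ins <- ""
  ins[is.na(ins)] <- ""
  resKey <- paste(at$chain, at$resno, ins, at$resid, sep = "\r")
  resKey <- factor(resKey, levels = unique(resKey))  # file order
  skipped <- character()
  info <- list()
  atoms <- list()
  for (key in levels(resKey)) {
    rows <- at[resKey == key, , drop = FALSE]
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    parts <- c(parts, rep("", 4 - length(parts)))
    resid <- trimws(parts[4])
    lab <- sprintf("%s:%s%s %s", parts[1], parts[2], parts[3], resid)
    base <- .RESIDUE_BASE[resid]
    if (!is.null(nameMap) && resid %in% names(nameMap))
      base <- .RESIDUE_BASE[nameMap[[resid]]]
    if (is.na(base)) {
      if (resid %in% c("HOH", "WAT", "MG", "NA", "K", "CL")) next
      skipped <- c(skipped, paste0(lab, " (unrecognized residue)"))
      next
    }
    nm <- trimws(rows$elety)
    nm <- gsub("\\*", "'", nm)  # old-style primes
    rows <- rows[!duplicated(nm), , drop = FALSE]
    nm <- nm[!duplicated(nm)]
    if (!all(c("C2", "C4", "C6") %in% nm)) {
      skipped <- c(skipped, paste0(lab, " (missing ring atoms C2/C4/C6)"))
      next
    }
    i <- length(info) + 1L
    info[[i]] <- data.frame(seq = i, chain = parts[1],
                            resno = as.integer(parts[2]), insert = parts[3],
                            resid = resid, base = unname(base),
                            class = if (base %in% .PURINES) "purine"
                                    else "pyrimidine",
                            stringsAsFactors = FALSE)
    atoms[[i]] <- data.frame(seq = i, atom = nm, x = rows$x, y = rows$y,
                             z = rows$z, stringsAsFactors = FALSE)
  }
  if (length(skipped) && !quiet)
    warning(sprintf("skipped %d residue(s): %s", length(skipped),
                    paste(skipped, collapse = "; ")), call. = FALSE)
  if (length(info) == 0L)
    stop("no usable nucleotides found (need C2/C4/C6 ring atoms)")
  rnaStructure(do.call(rbind, info), do.call(rbind, atoms))
}

#' Read a structure file into an RnaStructure
#'
#' Parses a PDB (or mmCIF) file, keeps recognized nucleotides (A, C, G, U and
#' the DNA names DA, DC, DG, DT) that carry all three frame atoms C2/C4/C6,
#' and returns them in file order with chains concatenated.  Residues lacking
#' ring atoms, or with unrecognized names, are skipped with a warning; a
#' mapping from modified-residue names to parent bases can be supplied.
#' Only the blank/'A' alternate location is kept.
#'
#' @param path path to a PDB or mmCIF file.
#' @param model model number to read from a multi-model file (default 1).
#' @param nameMap optional named character vector mapping nonstandard residue
#'   names to parent names, e.g. \code{c(PSU = "U", "1MA" = "A")}.
#' @param quiet suppress the skipped-residue warning.
#' @return An \linkS4class{RnaStructure}.
#' @examples
#' tf <- tempfile(fileext = ".pdb")
#' writeStructure(makeAformDuplex("GGGG"), tf)
#' s <- readStructure(tf)
#' nNucleotides(s)  # 8
#' @export
readStructure <- function(path, model = 1, nameMap = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    pdb <- tryCatch(bio3d::read.cif(path, verbose = FALSE),
                    error = function(e) stop("parse error: ",
                                             conditionMessage(e)))
    return(.pdbToStructure(pdb, nameMap, quiet))
  }
  lines <- readLines(path, warn = FALSE)
  chunks <- .splitModels(lines)
  if (model < 1 || model > length(chunks))
    stop(sprintf("model %d requested but file has %d model(s)",
                 model, length(chunks)))
  pdb <- tryCatch(.parsePdbChunk(chunks[[model]]),
                  error = function(e) stop("parse error: ",
                                           conditionMessage(e)))
  .pdbToStructure(pdb, nameMap, quiet)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL record becomes one frame; all frames must contain the same
#' nucleotides in the same order.
#'
#' @param path path to a (multi-model) PDB file.
#' @param timeStep time per frame, arbitrary units.
#' @param nameMap,quiet passed on to \code{\link{readStructure}}.
#' @return An \linkS4class{RnaTrajectory}.
#' @export
readTrajectory <- function(path, timeStep = 1, nameMap = NULL, quiet = TRUE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  chunks <- .splitModels(lines)
  frames <- lapply(chunks, function(ch) {
    pdb <- tryCatch(.parsePdbChunk(ch),
                    error = function(e) stop("parse error: ",
                                             conditionMessage(e)))
    .pdbToStructure(pdb, nameMap, quiet)
  })
  b0 <- baseSequence(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(baseSequence(frames[[i]]), b0))
      stop(sprintf("topology error: model %d does not match model 1", i))
  }
  rnaTrajectory(frames, timeStep = timeStep)
}

#' Write an RnaStructure to a PDB file
#'
#' Coordinates are written at the PDB format precision of 1e-3 Angstrom;
#' chains, author residue numbers and insertion codes are preserved, so a
#' written structure re-reads to an equivalent object.
#'
#' @param structure an \linkS4class{RnaStructure}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeStructure <- function(structure, path) {
  stopifnot(is(structure, "RnaStructure"))
  atoms <- structure@atoms
  info <- structure@info
  i <- atoms$seq
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = info$resno[i], resid = info$resid[i],
                     chain = info$chain[i], insert = {
                       ins <- info$insert[i]
                       ins[!nzchar(ins)] <- ""
                       ins
                     },
                     elety = atoms$atom)
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj an \linkS4class{RnaTrajectory}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "RnaTrajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  for (m in seq_len(nFrames(traj))) {
    writeStructure(getFrame(traj, m), tf)
    body <- readLines(tf, warn = FALSE)
    body <- body[!grepl("^END", body)]
    writeLines(sprintf("MODEL %8d", m), con)
    writeLines(body, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
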