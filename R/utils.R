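# internal helpers shared across modules

# ring-atom coordinates as an N x 9 matrix (C2 xyz, C4 xyz, C6 xyz)
.ringAtomCoords <- function(structure) {
  atoms <- structure@atoms
  n <- nNucleotides(structure)
  out <- matrix(NA_real_, n, 9)
  for (nm in c("C2", "C4", "C6")) {
    sel <- atoms[atoms$atom == nm, ]
    idx <- match(seq_len(n), sel$seq)
    cols <- switch(nm, C2 = 1:3, C4 = 4:6, C6 = 7:9)
    out[, cols] <- as.matrix(sel[idx, c("x", "y", "z")])
  }
  if (anyNA(out)) stop("structure is missing ring atoms")
  out
}

# run code with a temporary RNG seed, restoring global RNG state afterwards
.withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

.rotZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

.rotY <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

.complementBase <- function(b) {
  c(A = "U", U = "A", G = "C", C = "G", T = "A")[b]
}
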