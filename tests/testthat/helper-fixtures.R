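# Shared helpers: toy-structure builders, random rigid motions and
# independent brute-force oracles used to validate the implementation.

# structure whose only heavy atoms are the three ring atoms of each base
toyStructure <- function(rings, classes = NULL) {
  n <- length(rings)
  if (is.null(classes)) classes <- rep("pyrimidine", n)
  base <- ifelse(classes == "purine", "G", "C")
  info <- data.frame(seq = seq_len(n), chain = "A", resno = seq_len(n),
                     insert = "", resid = base, base = base,
                     class = classes, stringsAsFactors = FALSE)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    m <- rings[[i]]
    data.frame(seq = i, atom = c("C2", "C4", "C6"),
               x = m[, 1], y = m[, 2], z = m[, 3],
               stringsAsFactors = FALSE)
  }))
  rnaStructure(info, atoms)
}

# ring atoms of a planar base at a given origin, rotated by R (3x3)
ringAt <- function(origin, R = diag(3), radius = 1.4) {
  ang <- c(30, -90, 150) * pi / 180
  m <- cbind(radius * cos(ang), radius * sin(ang), 0) %*% t(R)
  sweep(m, 2, origin, "+")
}

randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2+b^2-c^2-d^2, 2*(b*c+a*d),     2*(b*d-a*c),
           2*(b*c-a*d),     a^2-b^2+c^2-d^2, 2*(c*d+a*b),
           2*(b*d+a*c),     2*(c*d-a*b),     a^2-b^2-c^2+d^2), 3, 3)
}

rigidMove <- function(structure, R = randomRotation(), t = rnorm(3, sd = 10)) {
  atoms <- structure@atoms
  m <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- m[, 1] + t[1]
  atoms$y <- m[, 2] + t[2]
  atoms$z <- m[, 3] + t[3]
  rnaStructure(structure@info, atoms)
}

# ---- independent oracles (deliberately plain, loop-based code) ----

oracleFrame <- function(ring, class) {
  o <- colMeans(ring)
  x <- ring[1, ] - o; x <- x / sqrt(sum(x^2))
  second <- if (class == "purine") ring[3, ] else ring[2, ]
  v1 <- ring[1, ] - o; v2 <- second - o
  z <- c(v1[2]*v2[3]-v1[3]*v2[2], v1[3]*v2[1]-v1[1]*v2[3],
         v1[1]*v2[2]-v1[2]*v2[1])
  z <- z / sqrt(sum(z^2))
  y <- c(z[2]*x[3]-z[3]*x[2], z[3]*x[1]-z[1]*x[3], z[1]*x[2]-z[2]*x[1])
  list(origin = o, axes = rbind(x, y, z))
}

oracleRtilde <- function(structure, a = 5, b = 3) {
  n <- nNucleotides(structure)
  at <- structure@atoms
  rings <- lapply(seq_len(n), function(i) {
    m <- at[at$seq == i & at$atom %in% c("C2", "C4", "C6"), ]
    as.matrix(m[match(c("C2", "C4", "C6"), m$atom), c("x", "y", "z")])
  })
  cls <- structure@info$class
  frames <- lapply(seq_len(n), function(i) oracleFrame(rings[[i]], cls[i]))
  out <- list()
  for (j in seq_len(n)) for (k in seq_len(n)) if (j != k) {
    r <- as.vector(frames[[j]]$axes %*%
                   (frames[[k]]$origin - frames[[j]]$origin))
    out[[paste(j, k)]] <- c(r[1] / a, r[2] / a, r[3] / b)
  }
  out
}

oracleG <- function(rt, cutoff = 2.4) {
  gamma <- pi / cutoff
  rn <- sqrt(sum(rt^2))
  if (rn >= cutoff) return(c(0, 0, 0, 0))
  dir <- if (rn > 0) rt / rn else c(0, 0, 0)
  c(sin(gamma * rn) * dir, 1 + cos(gamma * rn)) / gamma
}

oracleErmsd <- function(A, B) {
  ra <- oracleRtilde(A)
  rb <- oracleRtilde(B)
  n <- nNucleotides(A)
  s <- 0
  for (key in names(ra)) s <- s + sum((oracleG(ra[[key]]) -
                                       oracleG(rb[[key]]))^2)
  sqrt(s / n)
}

oracleNaive <- function(A, B) {
  ra <- oracleRtilde(A)
  rb <- oracleRtilde(B)
  n <- nNucleotides(A)
  s <- 0
  for (key in names(ra)) s <- s + sum((ra[[key]] - rb[[key]])^2)
  sqrt(s / n)
}

oracleDrmsd <- function(A, B) {
  ca <- ringCenters(A)
  cb <- ringCenters(B)
  n <- nrow(ca)
  ds <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ds <- c(ds, (sqrt(sum((ca[i, ] - ca[j, ])^2)) -
                 sqrt(sum((cb[i, ] - cb[j, ])^2)))^2)
  }
  sqrt(mean(ds))
}
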