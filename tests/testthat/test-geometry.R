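test_that("frames of a regular hexagonal ring follow the stated convention", {
  ring <- ringAt(c(0, 0, 0), radius = 1)
  pyr <- toyStructure(list(ring), "pyrimidine")
  fr <- baseFrames(pyr)
  expect_equal(as.vector(fr$origin[1, ]), c(0, 0, 0), tolerance = 1e-12)
  # x axis toward C2 (placed at 30 degrees on the unit circle)
  expect_equal(fr$axes[1, , 1], c(cos(pi / 6), sin(pi / 6), 0),
               tolerance = 1e-10)
  # proper rotation
  expect_lt(abs(det(fr$axes[, , 1]) - 1), 1e-10)
  expect_equal(crossprod(t(fr$axes[, , 1])), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # same atoms labelled purine flip the normal (ordered triple C2,C6)
  pur <- toyStructure(list(ring), "purine")
  fr2 <- baseFrames(pur)
  expect_equal(fr2$axes[3, , 1], -fr$axes[3, , 1], tolerance = 1e-10)
  # z orthogonal to the ring plane
  expect_lt(abs(sum(fr$axes[3, , 1] * c(1, 0, 0))), 1e-8)
  expect_lt(abs(sum(fr$axes[3, , 1] * c(0, 1, 0))), 1e-8)
})

test_that("collinear ring atoms are a geometry error", {
  ring <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  s <- toyStructure(list(ring, ringAt(c(10, 0, 0))))
  expect_error(baseFrames(s), "degenerate ring geometry")
})

test_that("pair vectors follow the ellipsoidal scaling", {
  s <- toyStructure(list(ringAt(c(0, 0, 0)), ringAt(c(0, 0, 0))))
  v <- pairVector(s, 1, 2)
  expect_equal(c(v$rx, v$ry, v$rz, v$rho, v$rtnorm), rep(0, 5),
               tolerance = 1e-12)
  # partner displaced 5 A along the observer's x axis: the observer ring has
  # C2 at 30 deg, so its x axis points at 30 deg in laboratory coordinates
  xhat <- c(cos(pi / 6), sin(pi / 6), 0)
  s2 <- toyStructure(list(ringAt(c(0, 0, 0)), ringAt(5 * xhat)))
  v2 <- pairVector(s2, 1, 2)
  expect_equal(c(v2$rx, v2$ry, v2$rz), c(5, 0, 0), tolerance = 1e-9)
  expect_equal(v2$rho, 5, tolerance = 1e-9)
  expect_equal(v2$theta, 0, tolerance = 1e-7)
  expect_equal(c(v2$rtx, v2$rty, v2$rtz), c(1, 0, 0), tolerance = 1e-9)
})

test_that("scaleVector divides componentwise by (a, a, b)", {
  expect_equal(scaleVector(c(0, 0, 3)), c(0, 0, 1))
  expect_equal(scaleVector(c(5, 0, 0)), c(1, 0, 0))
  expect_equal(scaleVector(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(scaleVector(rbind(c(5, 5, 3), c(0, 0, 0))),
               rbind(c(1, 1, 1), c(0, 0, 0)))
})

test_that("shell enumeration matches a brute-force scan over ordered pairs", {
  d <- makeAformDuplex("GGGG")
  pv <- enumerateShellPairs(d)
  rt <- oracleRtilde(d)
  inShell <- names(rt)[vapply(rt, function(v) sqrt(sum(v^2)), 0) < sqrt(2.5)]
  expect_setequal(paste(pv$j, pv$k), inShell)
  # scaled norms agree with the oracle
  for (i in seq_len(nrow(pv))) {
    expect_equal(pv$rtnorm[i],
                 sqrt(sum(rt[[paste(pv$j[i], pv$k[i])]]^2)),
                 tolerance = 1e-9)
  }
  # a lone nucleotide and far-apart bases give empty enumerations
  expect_equal(nrow(enumerateShellPairs(
    toyStructure(list(ringAt(c(0, 0, 0)), ringAt(c(50, 0, 0)))))), 0L)
})

test_that("zone classification respects the shell and |z| thresholds", {
  p <- scalingParams()
  mk <- function(j, k, rtnorm, z, theta = 60) {
    rho <- 1  # unused by the zone decision beyond bookkeeping
    data.frame(j = j, k = k, rx = NA, ry = NA, rz = z, rho = rho,
               theta = theta, z = z, rtx = NA, rty = NA, rtz = NA,
               rtnorm = rtnorm)
  }
  # inside shell, in-plane -> PAIRING
  ann <- classifyPair(mk(1, 2, 1.2, 0.5), mk(2, 1, 1.3, 0.6), p)
  expect_identical(ann$zone, "PAIRING")
  expect_identical(ann$edge, "WC")
  expect_true(ann$mutual)
  # inside shell, out of plane -> STACKING
  ann2 <- classifyPair(mk(1, 2, 1.2, 3.2), mk(2, 1, 1.3, 3.4), p)
  expect_identical(ann2$zone, "STACKING")
  expect_true(is.na(ann2$edge))
  # both orderings outside the shell -> NONE
  ann3 <- classifyPair(mk(1, 2, 1.7, 0.5), mk(2, 1, 1.7, 0.5), p)
  expect_identical(ann3$zone, "NONE")
  # one-sided shell membership is enough, but mutual is FALSE
  ann4 <- classifyPair(mk(1, 2, 1.5, 0.1), mk(2, 1, 1.7, 0.1), p)
  expect_identical(ann4$zone, "PAIRING")
  expect_false(ann4$mutual)
  # disagreeing orderings: the smaller scaled norm decides
  ann5 <- classifyPair(mk(1, 2, 1.2, 3.0), mk(2, 1, 1.1, 1.0), p)
  expect_identical(ann5$zone, "PAIRING")
  expect_error(classifyPair(mk(1, 2, 1, 0), mk(3, 1, 1, 0), p),
               "orderings of one pair")
})

test_that("the ideal duplex annotation shows the expected contact network", {
  d <- makeAformDuplex("GGGG")
  ann <- annotateStructure(d)
  wc <- ann[ann$zone == "PAIRING", ]
  expect_equal(nrow(wc), 4L)
  expect_true(all(wc$edge == "WC"))
  expect_setequal(paste(wc$j, wc$k), c("1 8", "2 7", "3 6", "4 5"))
  # sequential intra-strand neighbours stack
  stack <- ann[ann$zone == "STACKING", ]
  for (s in 1:3) expect_true(paste(s, s + 1) %in% paste(stack$j, stack$k))
  # a base displaced far away appears in no annotation
  d2 <- d
  sel <- d2@atoms$seq == 3
  d2@atoms$x[sel] <- d2@atoms$x[sel] + 20
  ann2 <- annotateStructure(d2)
  expect_false(any(ann2$j == 3 | ann2$k == 3))
})

test_that("frames and pair vectors are invariant under rigid motion", {
  set.seed(42)
  d <- makeAformDuplex("GAGC")
  pv <- enumerateShellPairs(d)
  for (rep in 1:5) {
    d2 <- rigidMove(d)
    pv2 <- enumerateShellPairs(d2)
    expect_equal(nrow(pv2), nrow(pv))
    expect_lt(max(abs(pv2$rtnorm - pv$rtnorm)), 1e-9)
    expect_lt(max(abs(pv2$rx - pv$rx)), 1e-9)
    expect_lt(max(abs(pv2$theta - pv$theta)), 1e-6)
  }
})

test_that("A-form geometry: WC sector occupied, sugar sector empty", {
  d <- makeAformDuplex("GGCAGC")
  n <- 6
  pv <- enumerateShellPairs(d)
  fr <- baseFrames(d)
  for (s in 2:(n - 1)) {                # interior bases, both strands
    partner <- 2 * n + 1 - s
    for (ord in list(c(s, partner), c(partner, s))) {
      v <- pairVector(d, ord[1], ord[2], frames = fr)
      expect_gt(v$theta, 50)
      expect_lt(v$theta, 70)
      expect_lt(abs(v$z), 2)
    }
  }
  # no shell partner observed through the sugar sector
  expect_false(any(pv$theta > 190 & pv$theta < 290 & abs(pv$z) <= 2))
  # |z| is nearly symmetric between the two orderings of an ideal WC pair
  key <- paste(pv$j, pv$k)
  for (s in seq_len(n)) {
    z1 <- pv$z[key == paste(s, 2 * n + 1 - s)]
    z2 <- pv$z[key == paste(2 * n + 1 - s, s)]
    expect_lt(abs(abs(z1) - abs(z2)), 0.5)
  }
})
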