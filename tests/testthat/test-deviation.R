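test_that("the G mapping matches its analytic values and contracts", {
  # hand-evaluated points
  expect_equal(gVector(c(2.4, 0, 0)), c(0, 0, 0, 0))
  expect_equal(gVector(c(0, 3, 0)), c(0, 0, 0, 0))
  expect_equal(gVector(c(0, 0, 0)), c(0, 0, 0, 2 * 2.4 / pi),
               tolerance = 1e-12)
  expect_equal(gVector(c(1.2, 0, 0)),
               c(2.4 / pi, 0, 0, 2.4 / pi), tolerance = 1e-12)
  gamma <- pi / 2.4
  # |G| bounded by 2 / gamma everywhere
  set.seed(1)
  pts <- matrix(rnorm(300, sd = 1.5), ncol = 3)
  gn <- sqrt(rowSums(gVector(pts)^2))
  expect_true(all(gn <= 2 / gamma + 1e-12))
  # continuity at the cutoff
  eps <- 1e-7
  expect_lt(sqrt(sum(gVector(c(2.4 - eps, 0, 0))^2)), 1e-6)
  # near-isometry for small vectors
  set.seed(2)
  for (i in 1:50) {
    a <- rnorm(3, sd = 0.2); b <- rnorm(3, sd = 0.2)
    if (sqrt(sum(a^2)) >= 0.5 || sqrt(sum(b^2)) >= 0.5) next
    dg <- sqrt(sum((gVector(a) - gVector(b))^2))
    dr <- sqrt(sum((a - b)^2))
    if (dr > 1e-6) expect_lt(abs(dg - dr) / dr, 0.1)
  }
})

test_that("the scalar mapping is the truncated shortfall from the cutoff", {
  expect_equal(gScalar(c(2.4, 0, 0)), 0)
  expect_equal(gScalar(c(0, 0, 0)), 2.4)
  expect_equal(gScalar(c(1, 0, 0)), 1.4)
  expect_equal(gScalar(c(5, 5, 5)), 0)
})

test_that("eRMSD agrees with the brute-force evaluation on 3-nt toys", {
  R1 <- randomRotation()
  A <- toyStructure(list(ringAt(c(0, 0, 0)), ringAt(c(4, 1, 1), R1),
                         ringAt(c(1, 5, 3))),
                    c("purine", "pyrimidine", "pyrimidine"))
  B <- toyStructure(list(ringAt(c(0.5, 0, 0)), ringAt(c(4, 2, 1)),
                         ringAt(c(0, 5, 4), R1)),
                    c("purine", "pyrimidine", "pyrimidine"))
  expect_equal(eRMSD(A, B), oracleErmsd(A, B), tolerance = 1e-12)
  expect_equal(eRMSD(A, A), 0)
  expect_equal(eRMSD(A, B), eRMSD(B, A), tolerance = 1e-12)
  expect_equal(naiveDistance(A, B), oracleNaive(A, B), tolerance = 1e-12)
  expect_equal(dRMSD(A, B), oracleDrmsd(A, B), tolerance = 1e-12)
  expect_error(eRMSD(A, subStructure(B, 1:2)), "correspondence error")
})

test_that("eRMSD satisfies the metric axioms on random fixture triples", {
  set.seed(9)
  base <- makeAformDuplex("GCAU")
  for (i in 1:20) {
    A <- perturbStructure(base, 1.0, seed = 100 + i)
    B <- perturbStructure(base, 1.0, seed = 200 + i)
    C <- perturbStructure(base, 1.0, seed = 300 + i)
    dab <- eRMSD(A, B); dbc <- eRMSD(B, C); dac <- eRMSD(A, C)
    expect_gte(dab, 0)
    expect_equal(dab, eRMSD(B, A), tolerance = 1e-12)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("deviation measures are invariant under rigid motion", {
  set.seed(5)
  A <- makeAformDuplex("GGCC")
  B <- perturbStructure(A, 1.5, seed = 77)
  B2 <- rigidMove(B)
  expect_equal(eRMSD(A, B2), eRMSD(A, B), tolerance = 1e-9)
  expect_equal(eRMSDScalar(A, B2), eRMSDScalar(A, B), tolerance = 1e-9)
  expect_equal(dRMSD(A, B2), dRMSD(A, B), tolerance = 1e-9)
  expect_equal(atomRMSD(A, B2), atomRMSD(A, B), tolerance = 1e-7)
  ann <- annotateStructure(A)
  expect_equal(infScore(ann, annotateStructure(B2)),
               infScore(ann, annotateStructure(B)), tolerance = 1e-12)
})

test_that("the naive distance is non-local where eRMSD is local", {
  d <- makeAformDuplex("GGGGGG")
  # displace the terminal base far beyond the cutoff in both structures
  far1 <- d; sel <- far1@atoms$seq == 12
  far1@atoms$x[sel] <- far1@atoms$x[sel] + 60
  far2 <- d
  far2@atoms$x[sel] <- far2@atoms$x[sel] + 70
  far2@atoms$y[sel] <- far2@atoms$y[sel] + 10
  expect_equal(eRMSD(far1, far2), 0, tolerance = 1e-9)
  expect_gt(naiveDistance(far1, far2), 0.1)
})

test_that("naive distance matches a hand calculation on a 2-nt toy", {
  # two parallel rings separated along z: r_12 = r_21 = (0, 0, dz)
  A <- toyStructure(list(ringAt(c(0, 0, 0)), ringAt(c(0, 0, 3))))
  B <- toyStructure(list(ringAt(c(0, 0, 0)), ringAt(c(0, 0, 4.5))))
  # rtilde_12 differs by (0, 0, 1.5/3) in both orderings; N = 2
  expect_equal(naiveDistance(A, B), sqrt(2 * 0.5^2 / 2), tolerance = 1e-12)
})

test_that("optimal-superposition RMSD behaves like a proper Kabsch fit", {
  d <- makeAformDuplex("GACU")
  moved <- rigidMove(d)
  expect_equal(atomRMSD(d, moved), 0, tolerance = 1e-7)
  # mirror images are not superposable (no improper rotations)
  mirror <- d
  mirror@atoms$x <- -mirror@atoms$x
  expect_gt(atomRMSD(d, mirror), 0.5)
  # ring-bead selection works on structures with different atom tables
  noP <- d
  noP@atoms <- noP@atoms[noP@atoms$atom != "P", ]
  expect_equal(atomRMSD(d, rigidMove(noP), selection = "ring"), 0,
               tolerance = 1e-7)
})

test_that("dRMSD ignores rigid motion without superposition", {
  d <- makeAformDuplex("GCGC")
  expect_equal(dRMSD(d, rigidMove(d)), 0, tolerance = 1e-9)
})

test_that("interaction network fidelity follows the PPV/sensitivity formula", {
  mk <- function(pairs, zones) data.frame(
    j = vapply(pairs, `[`, 0, 1), k = vapply(pairs, `[`, 0, 2),
    zone = zones, stringsAsFactors = FALSE)
  ref <- mk(list(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
            c("PAIRING", "STACKING", "PAIRING", "STACKING"))
  expect_equal(infScore(ref, ref), 1)
  disjoint <- mk(list(c(1, 3), c(2, 4)), c("PAIRING", "STACKING"))
  expect_equal(infScore(ref, disjoint), 0)
  # TP = 2, FP = 2, FN = 2 -> sqrt(0.5 * 0.5) = 0.5
  cmp <- mk(list(c(1, 2), c(2, 3), c(1, 4), c(2, 5)),
            c("PAIRING", "STACKING", "PAIRING", "STACKING"))
  expect_equal(infScore(ref, cmp), 0.5)
  # zone must match, not just the pair
  zoneflip <- mk(list(c(1, 2)), "STACKING")
  expect_equal(infScore(mk(list(c(1, 2)), "PAIRING"), zoneflip), 0)
  expect_error(infScore(mk(list(), character()), ref), "undefined score")
})

test_that("register shift is farther in eRMSD than matched random noise", {
  d <- makeAformDuplex("GGGG")
  sh <- makeRegisterShift("GGGG", 1)
  eShift <- eRMSD(d, sh)
  eNoise <- vapply(1:25, function(i)
    eRMSD(d, perturbStructure(d, 0.5, seed = 400 + i)), 0)
  expect_gt(eShift, mean(eNoise))
})

test_that("CV curves match a direct two-pass computation", {
  d <- makeAformDuplex("GC")
  traj <- makeTrajectory(d, 30, 0.4, seed = 21)
  lags <- c(1, 3, 5)
  res <- cvCurve(traj, metric = "drmsd", lags = lags)
  for (li in seq_along(lags)) {
    tau <- lags[li]
    ds <- vapply(seq_len(30 - tau), function(t)
      oracleDrmsd(getFrame(traj, t), getFrame(traj, t + tau)), 0)
    expect_equal(res$meanD[li], mean(ds), tolerance = 1e-12)
    expect_equal(res$sdD[li], sd(ds), tolerance = 1e-12)
    expect_equal(res$cv[li], sd(ds) / mean(ds), tolerance = 1e-12)
  }
})

test_that("the CV is scale-invariant and zero for constant distances", {
  d <- makeAformDuplex("GC")
  traj <- makeTrajectory(d, 25, 0.4, seed = 22)
  base <- cvCurve(traj, metric = function(a, b) dRMSD(a, b), lags = c(1, 4))
  doubled <- cvCurve(traj, metric = function(a, b) 2 * dRMSD(a, b),
                     lags = c(1, 4))
  expect_equal(doubled$cv, base$cv, tolerance = 1e-12)
  expect_equal(doubled$cvError, base$cvError, tolerance = 1e-12)
  constant <- cvCurve(traj, metric = function(a, b) 3.7, lags = c(1, 4))
  expect_equal(constant$cv, c(0, 0))
  expect_error(cvCurve(traj, lags = 30), "too short")
})
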