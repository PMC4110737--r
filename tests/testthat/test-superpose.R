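test_that("Kabsch superposition recovers rigid transforms exactly", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  fit <- kabsch(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  # rigid invariance: any rotated+translated copy is recovered to rmsd 0
  for (i in 1:5) {
    rot <- randomRotation()
    y <- x %*% rot + matrix(rnorm(3, 0, 10), 10, 3, byrow = TRUE)
    fit <- kabsch(x, y)
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
  expect_error(kabsch(x, x[1:5, ]), "equal length")
  expect_error(kabsch(x[1:2, ], x[1:2, ]), "3 points")
})

test_that("Kabsch is never beaten by random rotations", {
  set.seed(2)
  x <- matrix(rnorm(30), 10, 3)
  y <- x + matrix(rnorm(30, 0, 1), 10, 3)
  best <- kabsch(x, y)$rmsd
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  oracle <- min(vapply(1:2000, function(i) {
    r <- randomRotation()
    sqrt(mean(rowSums((xc %*% r - yc)^2)))
  }, numeric(1)))
  expect_lte(best, oracle + 1e-6)
})

test_that("TM-score identities, invariance and symmetry hold", {
  m <- coilModel(10)
  expect_equal(tmScore(NULL, m, m), 1.0, tolerance = 1e-9)
  n <- noisyCopy(m, 1.5, seed = 3, label = "n")
  tm0 <- tmScore(NULL, m, n)
  expect_gt(tm0, 0)
  expect_lte(tm0, 1)
  # invariance under joint rigid motion of either input
  set.seed(4)
  mR <- applyRigid(m, randomRotation(), rnorm(3, 0, 20))
  expect_equal(tmScore(NULL, mR, n), tm0, tolerance = 1e-6)
  # symmetry with normalize_by = shorter
  expect_equal(tmScore(NULL, m, n, normalizeBy = "shorter"),
               tmScore(NULL, n, m, normalizeBy = "shorter"),
               tolerance = 1e-9)
  expect_error(tmScore(NULL, maskModel(m, 1:2), maskModel(m, 1:2)),
               "too short")
})

test_that("iterative TM-score search matches an exhaustive seed oracle", {
  # 30-residue pair: enumerate every 7-residue seed window superposition
  m <- maskModel(coilModel(11), 1:30)
  n <- noisyCopy(m, 1.0, seed = 5, label = "n30")
  impl <- tmScore(NULL, m, n)
  a <- caCoords(m)
  b <- caCoords(n)
  ln <- 30L
  d0 <- tmD0(ln)
  oracle <- max(vapply(1:(30 - 6), function(s) {
    idx <- s:(s + 6)
    fit <- kabsch(a[idx, ], b[idx, ])
    af <- a %*% fit$rotation +
      matrix(fit$translation, 30, 3, byrow = TRUE)
    d <- sqrt(rowSums((af - b)^2))
    sum(1 / (1 + (d / d0)^2)) / ln
  }, numeric(1)))
  expect_gte(impl + 1e-9, oracle)
  expect_lte(impl, 1)
})

test_that("mean TM-score degrades monotonically with coordinate noise", {
  sig <- c(0, 0.5, 1, 2, 4)
  means <- vapply(sig, function(s) {
    mean(vapply(1:20, function(seed) {
      m <- coilModel(seed + 100)
      n <- if (s == 0) m else noisyCopy(m, s, seed = seed, label = "n")
      tmScore(NULL, m, n)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(means[1], 1, tolerance = 1e-9)
  expect_true(all(diff(means) < 0))
})

test_that("structural self-alignment is exact and never crosses", {
  m <- coilModel(12)
  aln <- tmAlign(m, m)
  expect_identical(aln@alignedLength, 60L)
  expect_true(all(aln@pairs[, 1] == aln@pairs[, 2]))
  expect_equal(aln@tmScore, 1, tolerance = 1e-9)
  expect_lt(aln@rmsd, 1e-9)
  expect_equal(aln@seqIdentity, 1)
  # a masked reference keeps unresolved residues out of the pairs
  ref <- maskModel(m, setdiff(1:60, 25:40))
  aln2 <- tmAlign(m, ref)
  expect_true(all(aln2@pairs[, 2] %in% residuePositions(ref)))
  expect_true(all(diff(aln2@pairs[, 1]) > 0))
  expect_true(all(diff(aln2@pairs[, 2]) > 0))
})

test_that("alignment recovers a known correspondence under noise and masking", {
  set.seed(6)
  recov <- vapply(1:8, function(i) {
    m <- coilModel(200 + i)
    r <- noisyCopy(m, 0.5, seed = 300 + i, label = "r")
    r <- maskModel(r, sort(sample(1:60, 50)))
    aln <- tmAlign(m, r)
    truth <- residuePositions(r)
    sum(aln@pairs[, 1] == aln@pairs[, 2] & aln@pairs[, 2] %in% truth) /
      length(truth)
  }, numeric(1))
  expect_gte(mean(recov), 0.95)
})

test_that("unrelated coil chains score near the random-alignment level", {
  # fixed identity correspondence: the setting for the 0.17 random level
  tms <- vapply(1:20, function(i) {
    a <- coilModel(400 + i, label = "a")
    b <- coilModel(700 + i, label = "b")
    tmScore(NULL, a, b)
  }, numeric(1))
  expect_lt(median(tms), 0.17)
  # optimized alignment inflates random scores but stays far below the
  # same-fold level 0.5
  tma <- vapply(1:10, function(i) {
    tmAlign(coilModel(900 + i, label = "a"),
            coilModel(1200 + i, label = "b"))@tmScore
  }, numeric(1))
  expect_true(all(tma < 0.4))
})

test_that("sequence identity counts matching residue codes over pairs", {
  m <- coilModel(13)
  aln <- tmAlign(m, m)
  expect_equal(sequenceIdentity(aln@pairs, m, m), 1.0)
  # 17 Q-Q pairs out of 25: distinct head/tail codes never match
  cdA <- toyConstruct("ACDE", "FGHI")
  cdB <- toyConstruct("WYWY", "LKLK")
  a <- buildBackbone(constructSequence(cdA), coilDihedrals(25, 1), cdA,
                     label = "a")
  b <- buildBackbone(constructSequence(cdB), coilDihedrals(25, 2), cdB,
                     label = "b")
  idpairs <- cbind(1:25, 1:25)
  expect_equal(sequenceIdentity(idpairs, a, b), 17 / 25)
  headpairs <- cbind(1:4, 1:4)
  expect_equal(sequenceIdentity(headpairs, a, b), 0)
})
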