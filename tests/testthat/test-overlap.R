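test_that("self-alignment yields full exact overlap and perfect scores", {
  m <- coilModel(20)
  aln <- tmAlign(m, m)
  ov <- exactMatches(aln, m, m)
  expect_identical(nrow(ov@exactClose), 60L)
  expect_identical(nrow(ov@exactOther), 0L)
  expect_equal(ov@so, 100)
  expect_equal(ov@eso, 100)
  expect_equal(ov@esop, 100)
  expect_identical(ov@exactQClose, 17L)
  # construct has Qs outside the tract too; code-based Q-Q count is larger
  expect_gte(ov@alignedQClose, ov@exactQClose)
  expect_error(exactMatches(aln, m, m, threshold = 0), "positive")
  expect_error(exactMatches(aln, m, m, threshold = -1), "positive")
})

test_that("a +1 register shift zeroes ESO and ESOP while SO stays high", {
  ref <- coilModel(21, label = "ref")
  shifted <- registerShift(ref)
  aln <- tmAlign(shifted, ref, normalizeBy = "shorter")
  ov <- exactMatches(aln, shifted, ref)
  expect_equal(ov@eso, 0)
  expect_equal(ov@esop, 0)
  expect_gt(ov@so, 90)
  expect_gt(aln@tmScore, 0.9)
})

test_that("an off-diagonal correspondence has no exact matches", {
  m <- coilModel(22)
  pairs <- cbind(1:59, 2:60)
  aln <- makeAlignment(pairs)
  ov <- exactMatches(aln, m, m)
  expect_identical(nrow(ov@exactClose) + nrow(ov@exactOther), 0L)
  expect_equal(ov@eso, 0)
})

test_that("a known displacement field stratifies exact matches by distance", {
  ref <- coilModel(23, label = "ref")
  pushed <- sort(c(5, 11, 19, 25, 33, 41, 47, 50, 55, 58))
  m <- ref
  m@label <- "pushed"
  idx <- match(pushed, m@positions)
  m@coords[idx, , 1] <- m@coords[idx, , 1] + 8  # 8 A along x
  aln <- makeAlignment(cbind(1:60, 1:60))
  ov <- exactMatches(aln, m, ref)
  expect_identical(nrow(ov@exactClose), 50L)
  expect_identical(nrow(ov@exactOther), 10L)
  expect_identical(sort(ov@exactOther[, 1]), as.integer(pushed))
})

test_that("overlap scores follow their closed-form definitions", {
  expect_equal(soScore(24, 60, 32), 75.0)
  expect_equal(soScore(32, 60, 32), 100)
  expect_equal(soScore(0, 60, 32), 0)
  expect_error(soScore(10, 0, 32), ">= 1")
  expect_error(soScore(40, 60, 32), "exceed")

  # achievable quantile values: 17/32 and 1/11 on the 0-100 scale
  ov <- new("OverlapResult",
            exactClose = cbind(1:17, 1:17), exactOther = cbind(18L, 18L),
            exactQClose = 1L, exactQOther = 0L,
            alignedQClose = 5L, alignedQOther = 1L,
            so = 80, eso = NA_real_, esop = NA_real_, threshold = 5,
            lm = 60L, le = 32L, lqm = 17L, lqe = 11L)
  expect_equal(esoScore(ov, 60, 32), 100 * 17 / 32)     # 53.125
  expect_lt(abs(esoScore(ov, 60, 32) - 53.13), 0.01)
  expect_equal(esoScore(ov, 60, 32, stratum = "all"), 100 * 18 / 32)
  expect_equal(esopScore(ov, 17, 11), 100 * 1 / 11)     # 9.0909...
  expect_lt(abs(esopScore(ov, 17, 11) - 9.09), 0.01)
  ov@exactQClose <- 9L
  expect_lt(abs(esopScore(ov, 17, 17) - 52.94), 0.01)
  expect_error(esopScore(ov, 17, 0), "no resolved poly-Q")
  cnt <- overlapCounts(ov)
  expect_identical(unname(cnt["exact_all"]),
                   unname(cnt["exact_close"] + cnt["exact_other"]))
})

test_that("exact-match extraction agrees with a brute-force double loop", {
  set.seed(30)
  for (i in 1:25) {
    m <- coilModel(2000 + i, label = "m")
    r <- noisyCopy(coilModel(3000 + i, label = "r"), 0.3, seed = i,
                   label = "r")
    keepM <- sort(sample(1:60, sample(40:60, 1)))
    keepR <- sort(sample(1:60, sample(40:60, 1)))
    m2 <- maskModel(m, keepM)
    r2 <- maskModel(r, keepR)
    aln <- tmAlign(m2, r2)
    th <- sample(c(2, 5, 8), 1)
    ov <- exactMatches(aln, m2, r2, threshold = th)
    # oracle: loop over aligned pairs applying the definition directly
    a <- caCoords(m2)[match(aln@pairs[, 1], residuePositions(m2)), ,
                      drop = FALSE]
    a <- a %*% aln@rotation + matrix(aln@translation, nrow(a), 3,
                                     byrow = TRUE)
    b <- caCoords(r2)[match(aln@pairs[, 2], residuePositions(r2)), ,
                      drop = FALSE]
    ec <- eo <- 0L
    for (k in seq_len(nrow(aln@pairs))) {
      if (aln@pairs[k, 1] != aln@pairs[k, 2]) next
      if (sqrt(sum((a[k, ] - b[k, ])^2)) < th) ec <- ec + 1L
      else eo <- eo + 1L
    }
    expect_identical(nrow(ov@exactClose), ec)
    expect_identical(nrow(ov@exactOther), eo)
    expect_lte(ov@eso, ov@so + 1e-9)
    expect_true(all(c(ov@so, ov@eso) >= 0 & c(ov@so, ov@eso) <= 100))
  }
})

test_that("ESOP is non-increasing as the distance threshold tightens", {
  m <- coilModel(40, label = "m")
  r <- noisyCopy(m, 2.0, seed = 41, label = "r")
  aln <- tmAlign(m, r)
  esops <- vapply(c(8, 5, 3, 1, 0.5), function(th)
    exactMatches(aln, m, r, threshold = th)@esop, numeric(1))
  expect_true(all(diff(esops) <= 0))
})
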