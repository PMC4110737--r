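smallEnsemble <- function(nRuns = 3L, m = 2L, sigma = 1, seed = 70) {
  generateEnsemble(cdHtt, nRuns = nRuns, modelsPerRun = m,
                   noiseSigma = sigma, seed = seed)
}

test_that("pairwise matrices hold choose(n, 2) values with TM identities", {
  ens <- smallEnsemble(3L, 2L)          # 6 models, 15 pairs
  pm <- pairwiseTmMatrix(ens)
  off <- pm@values[upper.tri(pm@values)]
  expect_length(off, choose(6, 2))
  expect_true(all(off > 0 & off <= 1))
  expect_equal(pm@values, t(pm@values))
  # duplicated models give TM exactly 1
  tmpl <- coilModel(71, label = "t")
  dup <- perturbedEnsemble(tmpl, nRuns = 2L, modelsPerRun = 1L,
                           noiseSigma = 0, seed = 1)
  pm2 <- pairwiseTmMatrix(dup)
  expect_equal(pm2@values[1, 2], 1, tolerance = 1e-9)
  expect_error(pairwiseTmMatrix(perturbedEnsemble(tmpl, 1L, 1L, 0, 1)),
               "at least 2")
})

test_that("count_above applies a strict cutoff and is monotone in it", {
  v <- matrix(NA_real_, 5, 5)
  vals <- c(0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 0.4, 0.3, 0.5)
  v[upper.tri(v)] <- vals
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  pm <- new("PairMatrix", labels = paste0("m", 1:5), values = v)
  expect_identical(countAbove(pm, 0.5), 7L)   # 0.5 itself not counted
  expect_identical(countAbove(pm, 1.0), 0L)
  cuts <- seq(0, 1, by = 0.1)
  counts <- vapply(cuts, function(ct) countAbove(pm, ct), integer(1))
  expect_true(all(diff(counts) <= 0))
  # all-identical ensemble: C(n,2) pairs above any cutoff < 1
  tmpl <- coilModel(72, label = "t")
  dup <- perturbedEnsemble(tmpl, nRuns = 4L, modelsPerRun = 1L,
                           noiseSigma = 0, seed = 1)
  expect_equal(countAbove(pairwiseTmMatrix(dup), 0.5), choose(4, 2))
})

test_that("run-level counts are bounded by m^2 and detect duplicated runs", {
  tmpl <- coilModel(73, label = "t")
  # two runs of identical models: every cross pair exceeds the cutoff
  dup <- perturbedEnsemble(tmpl, nRuns = 2L, modelsPerRun = 3L,
                           noiseSigma = 0, seed = 1)
  rc <- runLevelCounts(dup)
  expect_identical(rc[1, 2], 9L)              # m^2
  # mutually dissimilar coils never cross the fold threshold
  ens <- generateEnsemble(cdHtt,
                          list(head = regionSpec(coil = 1),
                               polyq = regionSpec(coil = 1),
                               cterm = regionSpec(coil = 1)),
                          nRuns = 2L, modelsPerRun = 3L, noiseSigma = 2,
                          seed = 74)
  rc2 <- runLevelCounts(ens)
  expect_identical(rc2[1, 2], 0L)
  expect_true(all(rc2[upper.tri(rc2)] <= 9L))
})

test_that("best-model analysis uses one rank-1 model per run", {
  ens <- smallEnsemble(4L, 3L, seed = 75)
  bm <- bestModelMatrix(ens)
  expect_length(bm$matrix@labels, 4L)
  expect_true(all(grepl("_model1$", bm$matrix@labels)))
  off <- bm$matrix@values[upper.tri(bm$matrix@values)]
  expect_length(off, choose(4, 2))
  # duplicated best models count all pairs
  tmpl <- coilModel(76, label = "t")
  dup <- perturbedEnsemble(tmpl, nRuns = 5L, modelsPerRun = 2L,
                           noiseSigma = 0, seed = 1)
  expect_equal(bestModelMatrix(dup)$countAbove, choose(5, 2))
  # brute-force recount matches
  v <- bm$matrix@values
  expect_identical(bm$countAbove, sum(v[upper.tri(v)] > 0.5))
})

test_that("validity panel has n_models x n_references records and exact
           identities on diagonal self-pairs", {
  refs <- generateReferenceSet(cdHtt, n = 3L, resolvedQ = c(17, 12, 10),
                               seed = 77)
  ens <- smallEnsemble(2L, 2L, seed = 78)
  vp <- validityPanel(ens, refs$models)
  expect_identical(nrow(vp$records), 4L * 3L)
  expect_true(all(vp$records$eso <= vp$records$so + 1e-9))
  expect_true(all(vp$records$tm > 0 & vp$records$tm <= 1))
  # an "ensemble" that IS the reference set
  copies <- lapply(seq_along(refs$models), function(i) {
    m <- refs$models[[i]]
    m@label <- sprintf("run%d_model1", i)
    m@source <- "predicted"
    m
  })
  idEns <- EnsembleSet(copies, run = seq_along(copies),
                       rank = rep(1L, length(copies)))
  vpId <- validityPanel(idEns, refs$models)
  diag_ <- vpId$records[as.integer(sub("run(\\d+)_model1",
                                       "\\1", vpId$records$model)) ==
                          match(vpId$records$reference,
                                names(refs$models)), ]
  expect_equal(diag_$tm, rep(1, 3), tolerance = 1e-9)
  expect_equal(diag_$eso, rep(100, 3))
  expect_equal(diag_$esop, rep(100, 3))
  expect_equal(diag_$rmsd, rep(0, 3), tolerance = 1e-9)
  expect_error(validityPanel(ens, list()), "no usable references")
})

test_that("summaries follow the normality-driven reporting policy", {
  s <- summarizeMetric(c(1, 2, 3, 4, 100))
  expect_true(s$min <= s$q25 && s$q25 <= s$q75 && s$q75 <= s$max)
  withr::with_seed(80, {
    norm <- summarizeMetric(rnorm(100))
    expect_true(norm$is_normal)
    heavy <- summarizeMetric(rlnorm(100, sdlog = 2))
    expect_false(heavy$is_normal)
  })
  expect_false(summarizeMetric(rep(5, 10))$is_normal)  # degenerate sample
})

test_that("two-sample tests pick t-test or Wilcoxon by normality", {
  withr::with_seed(83, {
    tt <- compareSamples(rnorm(100), rnorm(100, 2))
    expect_identical(tt$method, "t_test")
    expect_true(tt$significant)
    expect_lt(tt$p_value, 0.05)
    ww <- compareSamples(rlnorm(100, sdlog = 2), rlnorm(100, sdlog = 2))
    expect_identical(ww$method, "wilcoxon")
    same <- compareSamples(rnorm(60), rnorm(60))
    expect_false(same$significant)
  })
  ident <- compareSamples(rep(1, 10), rep(1, 10))
  expect_false(ident$significant)
})

test_that("panel comparison separates low-noise from high-noise ensembles", {
  tmpl <- coilModel(82, label = "t")
  refs <- list(maskModel(tmpl, c(1:30, 35:50)))
  refs[[1]]@label <- "ref1"
  lo <- perturbedEnsemble(tmpl, nRuns = 2L, modelsPerRun = 5L,
                          noiseSigma = 0.5, seed = 83)
  hi <- perturbedEnsemble(tmpl, nRuns = 2L, modelsPerRun = 5L,
                          noiseSigma = 3, seed = 84)
  vpLo <- validityPanel(lo, refs)
  vpHi <- validityPanel(hi, refs)
  cmp <- compareEnsembles(vpLo, vpHi, metrics = c("tm", "rmsd"))
  expect_true(all(cmp$significant))
  expect_gt(mean(vpLo$records$tm), mean(vpHi$records$tm))
  expect_lt(mean(vpLo$records$rmsd), mean(vpHi$records$rmsd))
})
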