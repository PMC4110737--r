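test_that("PDB round-trip preserves residues, codes and coordinates", {
  m <- coilModel(1)
  f <- withr::local_tempfile(fileext = ".pdb")
  writePdbModel(m, f)
  back <- readPdbChain(f, "A", cdHtt, 0L, label = m@label)
  expect_identical(residuePositions(back), residuePositions(m))
  expect_identical(residueCodes(back), residueCodes(m))
  expect_equal(backboneCoords(back), backboneCoords(m), tolerance = 2e-3)

  # masked model: only positions 5..20 present
  sub <- maskModel(m, 5:20)
  writePdbModel(sub, f)
  back <- readPdbChain(f, "A", cdHtt, 0L)
  expect_identical(resolvedLength(back), 16L)
  expect_identical(range(residuePositions(back)), c(5L, 20L))

  # two internal gaps of 3 and 5 leave 52 residues
  gapped <- maskModel(m, setdiff(1:60, c(20:22, 40:44)))
  writePdbModel(gapped, f)
  expect_identical(resolvedLength(readPdbChain(f, "A", cdHtt, 0L)), 52L)
})

test_that("offset mapping is validated against the construct sequence", {
  m <- coilModel(2)
  f <- withr::local_tempfile(fileext = ".pdb")
  # write with fusion-like author numbering, read back with the offset
  writePdbModel(m, f, chainId = "B", positionOffset = 600L)
  back <- readPdbChain(f, "B", cdHtt, 600L)
  expect_identical(residuePositions(back), residuePositions(m))
  # wrong offset shifts codes off the construct sequence
  expect_error(readPdbChain(f, "B", cdHtt, 599L), "sequence mismatch")
  expect_error(readPdbChain(f, "C", cdHtt, 600L), "chain not found")
})

test_that("residues mapped outside the construct are discarded", {
  # fusion-carrier residues sit below the construct range in author
  # numbering and must be dropped on import, whatever their identity
  m <- coilModel(3)
  carrier <- maskModel(coilModel(3, label = "carrier"), 1:15)
  fC <- withr::local_tempfile(fileext = ".pdb")
  fM <- withr::local_tempfile(fileext = ".pdb")
  f <- withr::local_tempfile(fileext = ".pdb")
  writePdbModel(carrier, fC, positionOffset = 585L)  # author 586..600
  writePdbModel(m, fM, positionOffset = 600L)        # author 601..660
  atoms <- c(grep("^ATOM", readLines(fC), value = TRUE),
             grep("^ATOM", readLines(fM), value = TRUE))
  # re-serialize so the concatenated file has unique atom numbers
  atoms <- vapply(seq_along(atoms), function(i)
    paste0("ATOM  ", formatC(i, width = 5), substring(atoms[i], 12)),
    character(1))
  writeLines(c(atoms, "TER", "END"), f)
  back <- readPdbChain(f, "A", cdHtt, 600L)
  expect_identical(residuePositions(back), 1:60)
  expect_identical(resolvedLength(back), 60L)
})

test_that("consecutive resolved glutamine counting follows the tract mask", {
  m <- coilModel(4)
  expect_identical(maxConsecutiveResolvedQ(m), 17L)
  expect_identical(maxConsecutiveResolvedQ(maskModel(m, c(1:17, 18))), 1L)
  # resolved 18-24 and 27-34: runs of 7 and 8
  m2 <- maskModel(m, c(1:17, 18:24, 27:34))
  expect_identical(maxConsecutiveResolvedQ(m2), 8L)
  expect_identical(maxConsecutiveResolvedQ(maskModel(m, 1:17)), 0L)
  expect_lte(maxConsecutiveResolvedQ(m), diff(polyqRegion(cdHtt)) + 1L)
})

test_that("reference filtering is monotone, idempotent and mirrors the panel", {
  refs <- generateReferenceSet(cdHtt, seed = 5)
  expect_length(refs$models, 21L)
  kept <- filterReferences(refs$models)
  expect_length(kept, 10L)
  expect_identical(filterReferences(kept), kept)        # idempotent
  # raising the threshold never adds members
  sizes <- vapply(6:18, function(th)
    length(filterReferences(refs$models, th)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  # a threshold beyond the tract length is unsatisfiable
  expect_length(filterReferences(refs$models, 18L), 0L)
  expect_length(filterReferences(list(), 9L), 0L)
})

test_that("best-k-by-score selection reproduces the per-run C-score ranking", {
  m <- coilModel(6)
  run1 <- c(-2.91, -3.69, -3.33, -3.62, -4.72)
  models <- lapply(seq_along(run1), function(i) {
    x <- m
    x@label <- paste0("cand", i)
    x
  })
  scores <- data.frame(label = paste0("cand", seq_along(run1)),
                       score = run1)
  ens <- selectEnsemble(models, scores, "best_k_by_score", k = 1L)
  expect_identical(nModels(ens), 1L)
  expect_equal(modelScore(ensembleModels(ens)[[1]]), -2.91)
  # k = 5 on 5 models keeps all, ranked best-first
  ens5 <- selectEnsemble(models, scores, "best_k_by_score", k = 5L)
  expect_identical(nModels(ens5), 5L)
  byRank <- names(sort(rankIndex(ens5)))
  expect_equal(vapply(ensembleModels(ens5)[byRank], modelScore, numeric(1)),
               sort(run1, decreasing = TRUE), ignore_attr = TRUE)
})

test_that("cluster selection uses only clusters above the size threshold", {
  m <- coilModel(7)
  sizes <- c(200, 150, 80, 40, 12, 11, 9)
  cluster <- rep(seq_along(sizes), sizes)
  n <- length(cluster)
  set.seed(7)
  scores <- data.frame(label = sprintf("d%04d", seq_len(n)),
                       score = runif(n, 16, 21), cluster = cluster)
  models <- lapply(scores$label, function(lab) {
    x <- m
    x@label <- lab
    x
  })
  ens <- selectEnsemble(models, scores, "best_per_cluster", k = 5L)
  expect_identical(nModels(ens), 5L)
  sel <- scores[match(modelLabels(ens), scores$label), ]
  expect_identical(anyDuplicated(sel$cluster), 0L)      # distinct clusters
  expect_false(any(sel$cluster == 7))                   # size-9 never used
  # each pick is its cluster's energy minimum
  for (cl in sel$cluster)
    expect_equal(sel$score[sel$cluster == cl],
                 min(scores$score[scores$cluster == cl]))
  # fewer eligible clusters than k: warn and return the eligible ones
  small <- scores[scores$cluster %in% 1:3, ]
  expect_warning(
    ens3 <- selectEnsemble(models[match(small$label, scores$label)],
                           small, "best_per_cluster", k = 5L),
    "eligible clusters")
  expect_identical(nModels(ens3), 3L)
})
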