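#' @useDynLib polyQeval, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Length-dependent TM-score distance scale
#'
#' \code{d0 = 1.24 (L - 15)^(1/3) - 1.8}, with the normalization length
#' floored at 17 and the result floored at 0.5 Angstroms so short chains do
#' not blow up the cube root.
#'
#' @param ln normalization length (number of residues).
#' @return d0 in Angstroms.
#' @export
tmD0 <- function(ln) {
  ln <- max(ln, 17)
  max(1.24 * (ln - 15)^(1 / 3) - 1.8, 0.5)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of one point set onto another, reflection
#' corrected so the rotation is always proper. The transform maps
#' \code{a} onto \code{b} as \code{a \%*\% rotation + translation} (row
#' vectors).
#'
#' @param a,b n x 3 coordinate matrices with matched rows, n >= 3.
#' @return list with \code{rotation} (3x3), \code{translation} (length 3)
#'   and \code{rmsd} (Angstroms, the minimized value).
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' kabsch(x, x)$rmsd
#' @export
kabsch <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("coordinate sets must have equal length")
  if (nrow(a) < 3L)
    stop("at least 3 points are required")
  if (ncol(a) != 3L || ncol(b) != 3L)
    stop("coordinates must be n x 3 matrices")
  res <- cpp_kabsch(a, b)
  res$translation <- as.numeric(res$translation)
  res
}

# CA coordinates of a model at given construct positions (must be resolved)
caAt <- function(model, positions) {
  idx <- match(positions, model@positions)
  if (anyNA(idx))
    stop("positions not resolved in model '", model@label, "'")
  caCoords(model)[idx, , drop = FALSE]
}

normLength <- function(model, reference,
                       normalizeBy = c("reference", "model", "shorter")) {
  normalizeBy <- match.arg(normalizeBy)
  switch(normalizeBy,
         reference = resolvedLength(reference),
         model     = resolvedLength(model),
         shorter   = min(resolvedLength(model), resolvedLength(reference)))
}

#' TM-score of an established residue correspondence
#'
#' Maximizes \code{(1/L_N) * sum_i 1 / (1 + (d_i/d0)^2)} over rigid
#' superpositions of the paired CA atoms, using the standard iterative
#' fragment-seeded search (seed windows of several lengths, refined by
#' reselecting close residues). Deterministic given its inputs.
#'
#' @param pairs two-column integer matrix of (model, reference) construct
#'   positions, or NULL to pair identical positions resolved in both.
#' @param model,reference [StructureModel-class] objects.
#' @param normalizeBy which chain's resolved length normalizes the score:
#'   \code{"reference"} (default), \code{"model"}, or \code{"shorter"}.
#' @return TM-score in (0, 1].
#' @seealso [tmAlign()] which finds the correspondence itself.
#' @export
tmScore <- function(pairs = NULL, model, reference,
                    normalizeBy = c("reference", "model", "shorter")) {
  if (is.null(pairs)) {
    common <- intersect(model@positions, reference@positions)
    pairs <- cbind(common, common)
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) stop("pairs must be non-empty")
  ln <- normLength(model, reference, normalizeBy)
  if (ln < 3L) stop("chain too short")
  a <- caAt(model, pairs[, 1])
  b <- caAt(reference, pairs[, 2])
  cpp_tmscore(a, b, tmD0(ln), ln)$tm
}

#' Fraction of aligned pairs with matching residue codes
#'
#' @inheritParams tmScore
#' @return fraction in [0, 1].
#' @export
sequenceIdentity <- function(pairs, model, reference) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) stop("pairs must be non-empty")
  cm <- model@codes[match(pairs[, 1], model@positions)]
  cr <- reference@codes[match(pairs[, 2], reference@positions)]
  mean(cm == cr)
}

#' Sequence-independent structural alignment
#'
#' TM-align-style alignment of two chains: initial correspondences from
#' gapless threading, a coarse secondary-structure string alignment, and a
#' combined distance/secondary-structure seed are each refined by
#' iterating superposition, TM-score-based residue-pair scoring and
#' dynamic programming (flat gap penalty, ties toward the diagonal) until
#' the pair set repeats or 30 iterations; the alignment with the highest
#' TM-score is reported. Unresolved reference residues never appear in the
#' correspondence because only resolved residues enter the alignment.
#'
#' @inheritParams tmScore
#' @param gap dynamic-programming gap penalty (flat, no extension cost).
#' @param maxit iteration cap per seed.
#' @return an [AlignmentResult-class].
#' @examples
#' cd <- htt17qConstruct()
#' m <- buildBackbone(constructSequence(cd), helixDihedrals(60), cd)
#' tmAlign(m, m)
#' @export
tmAlign <- function(model, reference,
                    normalizeBy = c("reference", "model", "shorter"),
                    gap = -0.6, maxit = 30L) {
  normalizeBy <- match.arg(normalizeBy)
  if (resolvedLength(model) < 5L || resolvedLength(reference) < 5L)
    stop("both chains need at least 5 resolved residues")
  ln <- normLength(model, reference, normalizeBy)
  a <- caCoords(model)
  b <- caCoords(reference)
  res <- tryCatch(
    cpp_tmalign(a, b, tmD0(ln), ln, gap, as.integer(maxit)),
    error = function(e) {
      stop("structural alignment of '", model@label, "' vs '",
           reference@label, "' failed: ", conditionMessage(e))
    })
  pairs <- cbind(model = model@positions[res$pairs[, 1]],
                 reference = reference@positions[res$pairs[, 2]])
  tr <- as.numeric(res$translation)
  # reported RMSD is the least-squares value over the aligned pairs (the
  # convention structural aligners print); the stored transform stays the
  # TM-optimal one, which the overlap scores use
  lsq <- kabsch(a[res$pairs[, 1], , drop = FALSE],
                b[res$pairs[, 2], , drop = FALSE])
  new("AlignmentResult",
      pairs = pairs,
      rotation = res$rotation,
      translation = tr,
      tmScore = res$tm,
      rmsd = lsq$rmsd,
      alignedLength = nrow(pairs),
      seqIdentity = sequenceIdentity(pairs, model, reference),
      normalizedBy = normalizeBy)
}

#' Per-pair CA distances of an alignment in its superposition frame
#'
#' @param alignment an [AlignmentResult-class].
#' @param model,reference the structures it was computed from.
#' @return numeric vector of CA-CA distances (Angstroms), one per pair.
#' @export
alignmentDistances <- function(alignment, model, reference) {
  p <- alignment@pairs
  if (nrow(p) == 0L) return(numeric(0))
  a <- caAt(model, p[, 1]) %*% alignment@rotation
  a <- sweep(a, 2L, -alignment@translation)
  b <- caAt(reference, p[, 2])
  sqrt(rowSums((a - b)^2))
}

#' Write an alignment report
#'
#' \code{writeAlignmentReport} emits one TSV row per aligned pair
#' (model_pos, ref_pos, distance); \code{writeAlignmentSummary} emits a
#' JSON summary (tm_score, rmsd, aligned_length, seq_identity).
#'
#' @inheritParams alignmentDistances
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeAlignmentReport <- function(alignment, model, reference, file) {
  df <- data.frame(model_pos = alignment@pairs[, 1],
                   ref_pos = alignment@pairs[, 2],
                   distance = round(alignmentDistances(alignment, model,
                                                       reference), 4))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeAlignmentReport
#' @export
writeAlignmentSummary <- function(alignment, file) {
  jsonlite::write_json(
    list(tm_score = alignment@tmScore, rmsd = alignment@rmsd,
         aligned_length = alignment@alignedLength,
         seq_identity = alignment@seqIdentity,
         normalized_by = alignment@normalizedBy),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
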