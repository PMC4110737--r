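#' Exact-match extraction and structure-overlap scores
#'
#' An aligned pair is an \emph{exact match} when model and reference
#' residue sit at the same construct position (which, after sequence
#' validation, forces the same residue identity). Exact matches are
#' stratified by CA-CA distance in the alignment's superposition frame:
#' \emph{close} below the threshold (5 Angstroms by default), \emph{other}
#' at or above it. Q-restricted variants are kept alongside: exact matches
#' at polyQ-tract positions (the ESOP numerator), and aligned Q-Q pairs
#' (residue code Q on both sides, position equality not required — the
#' "total Qs match" count). The returned object carries SO, ESO (close
#' stratum) and ESOP computed from the resolved lengths.
#'
#' @param alignment an [AlignmentResult-class] from these two structures.
#' @param model,reference the aligned [StructureModel-class] objects.
#' @param threshold distance threshold in Angstroms, must be positive.
#' @return an [OverlapResult-class].
#' @seealso [soScore()], [esoScore()], [esopScore()], [tmAlign()]
#' @export
exactMatches <- function(alignment, model, reference, threshold = 5.0) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a positive number")
  p <- alignment@pairs
  d <- alignmentDistances(alignment, model, reference)
  exact <- p[, 1] == p[, 2]
  close <- d < threshold

  qreg <- polyqRegion(model@construct)
  inQreg <- p[, 1] >= qreg[1] & p[, 1] <= qreg[2]
  cm <- model@codes[match(p[, 1], model@positions)]
  cr <- reference@codes[match(p[, 2], reference@positions)]
  qq <- cm == "Q" & cr == "Q"

  lm <- resolvedLength(model)
  le <- resolvedLength(reference)
  lqm <- resolvedQCount(model)
  lqe <- resolvedQCount(reference)

  ov <- new("OverlapResult",
    exactClose = p[exact & close, , drop = FALSE],
    exactOther = p[exact & !close, , drop = FALSE],
    exactQClose = sum(exact & close & inQreg),
    exactQOther = sum(exact & !close & inQreg),
    alignedQClose = sum(qq & close),
    alignedQOther = sum(qq & !close),
    so = soScore(alignment@alignedLength, lm, le),
    eso = NA_real_, esop = NA_real_,
    threshold = threshold,
    lm = lm, le = le, lqm = as.integer(lqm), lqe = as.integer(lqe))
  ov@eso <- esoScore(ov, lm, le)
  ov@esop <- if (lqe >= 1L && lqm >= 1L) esopScore(ov, lqm, lqe)
             else NA_real_
  validObject(ov)
  ov
}

#' Structure overlap (SO)
#'
#' \code{SO = 100 * L(A) / min(Lm, Le)}: the aligned length normalized by
#' the shorter of the two resolved chain lengths, on a 0-100 scale.
#'
#' @param alignedLength L(A), the number of aligned pairs.
#' @param lm,le resolved lengths of model and reference (>= 1).
#' @return SO in [0, 100].
#' @export
soScore <- function(alignedLength, lm, le) {
  if (lm < 1L || le < 1L) stop("chain lengths must be >= 1")
  if (alignedLength > min(lm, le))
    stop("aligned length cannot exceed min(Lm, Le)")
  100 * alignedLength / min(lm, le)
}

#' Exact structure overlap (ESO)
#'
#' \code{ESO = 100 * L(EA) / min(Lm, Le)} where L(EA) counts exact matches
#' — aligned pairs at the same construct position — in the chosen distance
#' stratum (\code{"close"}, the below-threshold default matching the 5-A
#' definition, or \code{"all"} = close + other).
#'
#' @param overlap an [OverlapResult-class].
#' @param lm,le resolved lengths (default: taken from \code{overlap}).
#' @param stratum \code{"close"} or \code{"all"}.
#' @return ESO in [0, 100].
#' @export
esoScore <- function(overlap, lm = overlap@lm, le = overlap@le,
                     stratum = c("close", "all")) {
  stratum <- match.arg(stratum)
  if (lm < 1L || le < 1L) stop("chain lengths must be >= 1")
  lea <- nrow(overlap@exactClose) +
    if (stratum == "all") nrow(overlap@exactOther) else 0L
  100 * lea / min(lm, le)
}

#' Exact structure overlap of the polyQ tract (ESOP)
#'
#' \code{ESOP = 100 * L(EAQ) / min(LQm, LQe)} where L(EAQ) counts exact
#' matches at polyQ-tract positions (close stratum) and LQm, LQe are the
#' resolved tract lengths of model and reference. A reference with no
#' resolved tract residue leaves ESOP undefined.
#'
#' @param overlap an [OverlapResult-class].
#' @param lqm,lqe resolved polyQ-tract lengths (default: from
#'   \code{overlap}).
#' @param stratum \code{"close"} or \code{"all"}.
#' @return ESOP in [0, 100].
#' @export
esopScore <- function(overlap, lqm = overlap@lqm, lqe = overlap@lqe,
                      stratum = c("close", "all")) {
  stratum <- match.arg(stratum)
  if (lqe < 1L) stop("no resolved poly-Q in reference")
  if (lqm < 1L) stop("no resolved poly-Q in model")
  leaq <- overlap@exactQClose +
    if (stratum == "all") overlap@exactQOther else 0L
  100 * leaq / min(lqm, lqe)
}

#' Six stratified match counts of an overlap result
#'
#' The Table-9-style panel: exact matches, exact Q matches and total Q-Q
#' matches in the close, other and all strata.
#'
#' @param overlap an [OverlapResult-class].
#' @return named integer vector of length 9.
#' @export
overlapCounts <- function(overlap) {
  ec <- nrow(overlap@exactClose)
  eo <- nrow(overlap@exactOther)
  c(exact_close = ec, exact_other = eo, exact_all = ec + eo,
    exact_q_close = overlap@exactQClose,
    exact_q_other = overlap@exactQOther,
    exact_q_all = overlap@exactQClose + overlap@exactQOther,
    total_q_close = overlap@alignedQClose,
    total_q_other = overlap@alignedQOther,
    total_q_all = overlap@alignedQClose + overlap@alignedQOther)
}

#' Write per-pair overlap report and summary
#'
#' \code{writeOverlapReport}: one TSV row per aligned pair (model_pos,
#' ref_pos, distance, is_exact, stratum). \code{writeOverlapSummary}:
#' JSON with so/eso/esop and the stratified counts.
#'
#' @param overlap an [OverlapResult-class].
#' @param alignment,model,reference the inputs it came from.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeOverlapReport <- function(overlap, alignment, model, reference, file) {
  p <- alignment@pairs
  d <- alignmentDistances(alignment, model, reference)
  df <- data.frame(model_pos = p[, 1], ref_pos = p[, 2],
                   distance = round(d, 4),
                   is_exact = p[, 1] == p[, 2],
                   stratum = ifelse(d < overlap@threshold, "close", "other"))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeOverlapReport
#' @export
writeOverlapSummary <- function(overlap, file) {
  jsonlite::write_json(
    c(list(so = overlap@so, eso = overlap@eso, esop = overlap@esop,
           threshold = overlap@threshold),
      as.list(overlapCounts(overlap))),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
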