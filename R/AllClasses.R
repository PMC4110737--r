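#' @import methods
NULL

SS_STATES <- c("H", "B", "E", "G", "I", "T", "S", "C", "M")
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct definition for a polyglutamine fragment
#'
#' Describes the evaluated construct: its one-letter sequence and the
#' partition into an N-terminal head, the polyglutamine tract, and the
#' C-terminal region. The three regions must be disjoint, contiguous,
#' ordered, and tile positions \code{1..nchar(sequence)} exactly; every
#' position inside the polyQ interval must carry residue code Q.
#'
#' @slot sequence one-letter amino-acid string.
#' @slot headRegion,polyqRegion,ctermRegion inclusive 1-based position
#'   intervals, each \code{integer(2)}.
#'
#' @seealso [ConstructDef()], [htt17qConstruct()]
#' @exportClass ConstructDef
setClass("ConstructDef",
  representation(
    sequence    = "character",
    headRegion  = "integer",
    polyqRegion = "integer",
    ctermRegion = "integer"
  )
)

setValidity("ConstructDef", function(object) {
  seq <- object@sequence
  if (length(seq) != 1L || is.na(seq) || nchar(seq) < 1L)
    return("sequence must be a single non-empty string")
  L <- nchar(seq)
  regs <- list(head = object@headRegion, polyq = object@polyqRegion,
               cterm = object@ctermRegion)
  for (nm in names(regs)) {
    r <- regs[[nm]]
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2])
      return(sprintf("%s region must be an increasing integer pair", nm))
  }
  if (regs$head[1] != 1L ||
      regs$polyq[1] != regs$head[2] + 1L ||
      regs$cterm[1] != regs$polyq[2] + 1L ||
      regs$cterm[2] != L)
    return("regions must be ordered, contiguous, and tile 1..L exactly")
  qpos <- seq.int(regs$polyq[1], regs$polyq[2])
  codes <- substring(seq, qpos, qpos)
  if (!all(codes == "Q"))
    return("every position in polyqRegion must be Q")
  TRUE
})

#' Single-chain structure model
#'
#' One chain mapped onto a [ConstructDef-class]: only resolved residues
#' (those with a CA coordinate) are stored. Backbone coordinates live in an
#' \code{n x 4 x 3} array over atoms N, CA, C, O; missing N/C/O entries are
#' NA and mark the residue as CA-only (usable for superposition and overlap
#' scoring, excluded from secondary-structure assignment).
#'
#' @slot label model identifier, e.g. \code{"run3_model2"} or \code{"3iow_b"}.
#' @slot source one of \code{"predicted"}, \code{"experimental"},
#'   \code{"synthetic"}.
#' @slot construct the [ConstructDef-class] the chain is mapped onto.
#' @slot positions strictly increasing construct positions of the resolved
#'   residues.
#' @slot codes one-letter residue codes at those positions.
#' @slot coords \code{n x 4 x 3} numeric array, atoms N/CA/C/O, Angstroms.
#' @slot score optional predictor score (C-score or energy), NA if absent.
#'
#' @seealso [readPdbChain()], [buildBackbone()], [resolvedLength()]
#' @exportClass StructureModel
setClass("StructureModel",
  representation(
    label     = "character",
    source    = "character",
    construct = "ConstructDef",
    positions = "integer",
    codes     = "character",
    coords    = "array",
    score     = "numeric"
  )
)

setValidity("StructureModel", function(object) {
  n <- length(object@positions)
  if (!object@source %in% c("predicted", "experimental", "synthetic"))
    return("source must be predicted, experimental or synthetic")
  if (length(object@codes) != n)
    return("codes and positions must have equal length")
  d <- dim(object@coords)
  if (length(d) != 3L || d[1] != n || d[2] != 4L || d[3] != 3L)
    return("coords must be an n x 4 x 3 array")
  if (n > 0L) {
    if (any(diff(object@positions) <= 0L))
      return("positions must be strictly increasing")
    L <- nchar(object@construct@sequence)
    if (object@positions[1] < 1L || object@positions[n] > L)
      return("positions must lie within 1..L_construct")
    if (anyNA(object@coords[, "CA", ]))
      return("every stored residue must have CA coordinates")
    want <- substring(object@construct@sequence, object@positions,
                      object@positions)
    if (any(want != object@codes))
      return("codes must match the construct sequence at mapped positions")
  }
  if (length(object@score) != 1L)
    return("score must be a single numeric (possibly NA)")
  TRUE
})

#' Grouped prediction ensemble
#'
#' Models grouped by prediction run and within-run rank (the paper-style
#' layout: several independent seeded runs, a handful of retained models
#' per run).
#'
#' @slot models list of [StructureModel-class], named by label.
#' @slot run integer run index per label.
#' @slot rank integer rank within run per label (contiguous from 1).
#'
#' @seealso [generateEnsemble()], [selectEnsemble()]
#' @exportClass EnsembleSet
setClass("EnsembleSet",
  representation(models = "list", run = "integer", rank = "integer")
)

setValidity("EnsembleSet", function(object) {
  labs <- unname(vapply(object@models, function(m) m@label, character(1)))
  if (is.null(names(object@models)) || !identical(names(object@models), labs))
    return("models must be named by their labels")
  if (anyDuplicated(labs))
    return("model labels must be unique")
  if (!identical(sort(names(object@run)), sort(labs)) ||
      !identical(sort(names(object@rank)), sort(labs)))
    return("run and rank must be named for every model label")
  key <- paste(object@run[labs], object@rank[labs])
  if (anyDuplicated(key))
    return("(run, rank) pairs must be unique")
  for (r in unique(object@run)) {
    rk <- sort(object@rank[names(object@run)[object@run == r]])
    if (!identical(as.integer(rk), seq_along(rk)))
      return(sprintf("ranks in run %d must be contiguous from 1", r))
  }
  TRUE
})

#' Structural alignment result
#'
#' Residue correspondence between a model and a reference plus the rigid
#' transform that realizes it. \code{pairs} holds construct positions
#' (model, reference) and is strictly increasing in both columns (no
#' crossing). The rotation is proper (det +1); applying
#' \code{x \%*\% rotation + translation} to model CA coordinates moves them
#' into the reference frame.
#'
#' @slot pairs integer matrix, columns \code{model} and \code{reference}.
#' @slot rotation 3x3 proper rotation matrix.
#' @slot translation length-3 numeric, Angstroms.
#' @slot tmScore TM-score in (0, 1].
#' @slot rmsd RMSD over aligned CA pairs, Angstroms.
#' @slot alignedLength number of aligned pairs L(A).
#' @slot seqIdentity fraction of aligned pairs with equal residue codes.
#' @slot normalizedBy which chain length normalized the TM-score.
#'
#' @seealso [tmAlign()], [tmScore()], [exactMatches()]
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(
    pairs         = "matrix",
    rotation      = "matrix",
    translation   = "numeric",
    tmScore       = "numeric",
    rmsd          = "numeric",
    alignedLength = "integer",
    seqIdentity   = "numeric",
    normalizedBy  = "character"
  )
)

setValidity("AlignmentResult", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns")
  if (nrow(p) > 1L && (any(diff(p[, 1]) <= 0) || any(diff(p[, 2]) <= 0)))
    return("pairs must be strictly increasing in both columns")
  if (object@alignedLength != nrow(p))
    return("alignedLength must equal nrow(pairs)")
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)) || abs(det(R) - 1) > 1e-6)
    return("rotation must be a 3x3 proper rotation (det +1)")
  if (nrow(p) > 0L &&
      (object@tmScore <= 0 || object@tmScore > 1 + 1e-9))
    return("tmScore must lie in (0, 1]")
  if (object@seqIdentity < 0 || object@seqIdentity > 1)
    return("seqIdentity must lie in [0, 1]")
  TRUE
})

#' Exact-structure-overlap result
#'
#' Exact matches (aligned pairs at the same construct position, stratified
#' by CA-CA distance in the superposition frame) plus the SO, ESO and ESOP
#' scores and Q-restricted counts.
#'
#' @slot exactClose,exactOther integer pair matrices (model, reference):
#'   exact matches below / at-or-above the distance threshold.
#' @slot exactQClose,exactQOther exact matches at polyQ-tract positions.
#' @slot alignedQClose,alignedQOther aligned Q-Q pairs (residue code Q on
#'   both sides, position equality not required) below / above threshold.
#' @slot so,eso,esop scores on the 0-100 scale.
#' @slot threshold distance threshold, Angstroms.
#' @slot lm,le resolved lengths of model and reference.
#' @slot lqm,lqe resolved polyQ-tract lengths of model and reference.
#'
#' @seealso [exactMatches()], [soScore()], [esoScore()], [esopScore()]
#' @exportClass OverlapResult
setClass("OverlapResult",
  representation(
    exactClose    = "matrix",
    exactOther    = "matrix",
    exactQClose   = "integer",
    exactQOther   = "integer",
    alignedQClose = "integer",
    alignedQOther = "integer",
    so            = "numeric",
    eso           = "numeric",
    esop          = "numeric",
    threshold     = "numeric",
    lm            = "integer",
    le            = "integer",
    lqm           = "integer",
    lqe           = "integer"
  )
)

setValidity("OverlapResult", function(object) {
  if (object@threshold <= 0) return("threshold must be positive")
  for (s in c(object@so, object@eso)) {
    if (!is.na(s) && (s < 0 || s > 100 + 1e-9))
      return("scores must lie in [0, 100]")
  }
  if (!is.na(object@eso) && !is.na(object@so) &&
      object@eso > object@so + 1e-9)
    return("ESO cannot exceed SO")
  TRUE
})

#' Secondary-structure frequency profile
#'
#' Position-by-state count and frequency matrices over an ensemble of
#' per-model secondary-structure strings (states H, B, E, G, I, T, S, C
#' plus M for missing data), the machine-readable form of a sequence-logo
#' panel.
#'
#' @slot counts integer matrix, positions x states; each row sums to
#'   \code{nStructures}.
#' @slot frequencies row-normalized counts.
#' @slot nStructures number of structures profiled.
#'
#' @seealso [ssProfile()], [assignDssp()]
#' @exportClass SSProfile
setClass("SSProfile",
  representation(counts = "matrix", frequencies = "matrix",
                 nStructures = "integer")
)

setValidity("SSProfile", function(object) {
  if (!identical(colnames(object@counts), SS_STATES))
    return("counts columns must be the nine SS states")
  if (any(rowSums(object@counts) != object@nStructures))
    return("each counts row must sum to nStructures")
  if (any(abs(rowSums(object@frequencies) - 1) > 1e-9))
    return("frequency rows must sum to 1")
  TRUE
})

#' Symmetric pairwise TM-score matrix
#'
#' @slot labels ordered model labels.
#' @slot values symmetric numeric matrix of TM-scores; diagonal NA.
#'
#' @seealso [pairwiseTmMatrix()], [countAbove()]
#' @exportClass PairMatrix
setClass("PairMatrix",
  representation(labels = "character", values = "matrix")
)

setValidity("PairMatrix", function(object) {
  v <- object@values
  n <- length(object@labels)
  if (!all(dim(v) == c(n, n))) return("values must be n x n")
  off <- v[upper.tri(v)]
  if (any(!is.na(off) & (off <= 0 | off > 1 + 1e-9)))
    return("TM-scores must lie in (0, 1]")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-9, check.attributes = FALSE)))
    return("values must be symmetric")
  TRUE
})
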