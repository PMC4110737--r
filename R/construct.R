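#' Create a construct definition
#'
#' @param sequence one-letter amino-acid string.
#' @param headRegion,polyqRegion,ctermRegion inclusive position intervals
#'   (length-2 integer vectors) that must tile \code{1..nchar(sequence)}.
#' @return a [ConstructDef-class] object.
#' @examples
#' cd <- ConstructDef(paste0(strrep("A", 5), strrep("Q", 4), strrep("P", 3)),
#'                    c(1, 5), c(6, 9), c(10, 12))
#' constructLength(cd)
#' @export
ConstructDef <- function(sequence, headRegion, polyqRegion, ctermRegion) {
  new("ConstructDef",
      sequence    = as.character(sequence),
      headRegion  = as.integer(headRegion),
      polyqRegion = as.integer(polyqRegion),
      ctermRegion = as.integer(ctermRegion))
}

#' The default 60-residue huntingtin exon-1 construct with 17 glutamines
#'
#' Head region residues 1-17, polyQ tract 18-34 (17 Qs), proline-rich
#' C-terminal region 35-60.
#'
#' @return a [ConstructDef-class].
#' @examples
#' htt17qConstruct()
#' @export
htt17qConstruct <- function() {
  ConstructDef(
    sequence = paste0("MATLEKLMKAFESLKSF", strrep("Q", 17),
                      "PPPPPPPPPPPQLPQPPPQAQPLLPQ"),
    headRegion  = c(1L, 17L),
    polyqRegion = c(18L, 34L),
    ctermRegion = c(35L, 60L))
}

#' Construct accessors
#'
#' @param x a [ConstructDef-class].
#' @return \code{constructLength}: integer length;
#'   \code{constructSequence}: the sequence string; \code{polyqRegion},
#'   \code{headRegion}, \code{ctermRegion}: inclusive intervals;
#'   \code{polyqPositions}: integer vector of tract positions.
#' @export
constructLength <- function(x) nchar(x@sequence)

#' @rdname constructLength
#' @export
constructSequence <- function(x) x@sequence

#' @rdname constructLength
#' @export
headRegion <- function(x) x@headRegion

#' @rdname constructLength
#' @export
polyqRegion <- function(x) x@polyqRegion

#' @rdname constructLength
#' @export
ctermRegion <- function(x) x@ctermRegion

#' @rdname constructLength
#' @export
polyqPositions <- function(x) seq.int(x@polyqRegion[1], x@polyqRegion[2])

constructCodes <- function(x, positions) {
  substring(x@sequence, positions, positions)
}

setMethod("show", "ConstructDef", function(object) {
  cat(sprintf("ConstructDef of %d residues\n", constructLength(object)))
  cat(sprintf("  head  %d-%d | polyQ %d-%d | C-term %d-%d\n",
              object@headRegion[1], object@headRegion[2],
              object@polyqRegion[1], object@polyqRegion[2],
              object@ctermRegion[1], object@ctermRegion[2]))
  cat("  ", object@sequence, "\n", sep = "")
})

#' Model accessors
#'
#' @param x a [StructureModel-class].
#' @return \code{modelLabel}: label string; \code{modelSource}: source
#'   enum; \code{modelScore}: predictor score (NA if absent);
#'   \code{residuePositions}: resolved construct positions;
#'   \code{residueCodes}: their one-letter codes; \code{caCoords}: n x 3
#'   CA coordinate matrix; \code{backboneCoords}: the full n x 4 x 3
#'   array; \code{isCaOnly}: logical, TRUE where N/C/O are incomplete.
#' @export
modelLabel <- function(x) x@label

#' @rdname modelLabel
#' @export
modelSource <- function(x) x@source

#' @rdname modelLabel
#' @export
modelScore <- function(x) x@score

#' @rdname modelLabel
#' @export
modelConstruct <- function(x) x@construct

#' @rdname modelLabel
#' @export
residuePositions <- function(x) x@positions

#' @rdname modelLabel
#' @export
residueCodes <- function(x) x@codes

#' @rdname modelLabel
#' @export
caCoords <- function(x) {
  m <- x@coords[, "CA", , drop = FALSE]
  dim(m) <- c(length(x@positions), 3L)
  rownames(m) <- x@positions
  colnames(m) <- c("x", "y", "z")
  m
}

#' @rdname modelLabel
#' @export
backboneCoords <- function(x) x@coords

#' @rdname modelLabel
#' @export
isCaOnly <- function(x) {
  n <- length(x@positions)
  if (n == 0L) return(logical(0))
  apply(x@coords[, c("N", "C", "O"), , drop = FALSE], 1L,
        function(a) anyNA(a))
}

setMethod("show", "StructureModel", function(object) {
  n <- length(object@positions)
  cat(sprintf("StructureModel '%s' (%s): %d resolved residues",
              object@label, object@source, n))
  if (n > 0L)
    cat(sprintf(" [%d..%d]", object@positions[1], object@positions[n]))
  if (!is.na(object@score)) cat(sprintf(", score %.3g", object@score))
  cat("\n")
})

newStructureModel <- function(label, source, construct, positions, codes,
                              coords, score = NA_real_) {
  new("StructureModel", label = label, source = source,
      construct = construct, positions = as.integer(positions),
      codes = codes, coords = coords, score = as.numeric(score))
}

emptyCoords <- function(n) {
  array(NA_real_, dim = c(n, 4L, 3L),
        dimnames = list(NULL, BACKBONE_ATOMS, c("x", "y", "z")))
}

#' Ensemble accessors
#'
#' @param x an [EnsembleSet-class].
#' @param label model label.
#' @return \code{nModels}: model count; \code{modelLabels}: labels in
#'   storage order; \code{ensembleModels}: list of models;
#'   \code{runIndex}/\code{rankIndex}: named integer vectors;
#'   \code{getModel}: one [StructureModel-class].
#' @export
nModels <- function(x) length(x@models)

#' @rdname nModels
#' @export
modelLabels <- function(x) names(x@models)

#' @rdname nModels
#' @export
ensembleModels <- function(x) x@models

#' @rdname nModels
#' @export
runIndex <- function(x) x@run

#' @rdname nModels
#' @export
rankIndex <- function(x) x@rank

#' @rdname nModels
#' @export
getModel <- function(x, label) {
  if (!label %in% names(x@models)) stop("no model labelled '", label, "'")
  x@models[[label]]
}

setMethod("show", "EnsembleSet", function(object) {
  cat(sprintf("EnsembleSet: %d models in %d runs (ranks 1..%d)\n",
              length(object@models), length(unique(object@run)),
              max(object@rank)))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    "AlignmentResult: %d pairs, TM %.4f (norm: %s), RMSD %.2f A, id %.2f\n",
    object@alignedLength, object@tmScore, object@normalizedBy,
    object@rmsd, object@seqIdentity))
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf(
    "OverlapResult (<%.1f A): SO %.2f, ESO %.2f, ESOP %s\n",
    object@threshold, object@so, object@eso,
    ifelse(is.na(object@esop), "NA", sprintf("%.2f", object@esop))))
  cat(sprintf("  exact close/other: %d/%d; aligned Q-Q close/other: %d/%d\n",
              nrow(object@exactClose), nrow(object@exactOther),
              object@alignedQClose, object@alignedQOther))
})

setMethod("show", "SSProfile", function(object) {
  cat(sprintf("SSProfile: %d positions x %d states over %d structures\n",
              nrow(object@counts), ncol(object@counts), object@nStructures))
})

setMethod("show", "PairMatrix", function(object) {
  n <- length(object@labels)
  cat(sprintf("PairMatrix: %d models, %d pairwise TM-scores\n",
              n, n * (n - 1L) %/% 2L))
})
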