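AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA123 <- stats::setNames(names(AA321), AA321)

#' Read one chain of a PDB file onto a construct
#'
#' Extracts backbone atoms (N, CA, C, O) of a single chain, renumbers
#' author residue numbers into construct positions
#' (\code{author - positionOffset = position}), discards residues mapped
#' outside the construct (e.g. a fusion-protein carrier), and validates
#' every mapped residue code against the construct sequence. Residues
#' absent from the ATOM records stay absent (unresolved); a residue with
#' CA but incomplete N/C/O is kept as CA-only. Alternate locations are
#' resolved to the highest occupancy, ties alphabetically. Insertion codes
#' and non-standard residues inside the mapped range are errors.
#'
#' @param path PDB file.
#' @param chainId single chain identifier character.
#' @param construct a [ConstructDef-class].
#' @param positionOffset integer offset subtracted from author numbering.
#' @param label model label; defaults to file stem + chain.
#' @param source provenance tag, default \code{"experimental"}.
#' @return a [StructureModel-class].
#' @export
readPdbChain <- function(path, chainId, construct, positionOffset = 0L,
                         label = NULL,
                         source = c("experimental", "predicted",
                                    "synthetic")) {
  source <- match.arg(source)
  if (is.null(label)) {
    label <- paste0(sub("\\.pdb$", "", basename(path), ignore.case = TRUE),
                    "_", tolower(chainId))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chainId, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("chain not found: '", chainId, "' in ", path)
  at <- at[at$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  at$position <- at$resno - as.integer(positionOffset)
  L <- constructLength(construct)
  at <- at[at$position >= 1L & at$position <= L, , drop = FALSE]
  if (nrow(at) == 0L) {
    return(newStructureModel(label, source, construct, integer(0),
                             character(0), emptyCoords(0L)))
  }
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes in mapped range of ", path, " chain ", chainId)
  bad <- !at$resid %in% names(AA321)
  if (any(bad))
    stop("non-standard residue(s) in mapped range: ",
         paste(unique(at$resid[bad]), collapse = ", "))
  # altloc: highest occupancy wins, ties alphabetically
  at$alt[is.na(at$alt)] <- ""
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(at$position, at$elety, -occ, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(at[, c("position", "elety")]), , drop = FALSE]

  positions <- sort(unique(at$position))
  coords <- emptyCoords(length(positions))
  codes <- character(length(positions))
  for (i in seq_along(positions)) {
    rows <- at[at$position == positions[i], , drop = FALSE]
    codes[i] <- AA321[[rows$resid[1]]]
    for (k in seq_len(nrow(rows)))
      coords[i, rows$elety[k], ] <- c(rows$x[k], rows$y[k], rows$z[k])
  }
  # drop residues without CA (unresolved for our purposes)
  hasCA <- !apply(coords[, "CA", , drop = FALSE], 1L, anyNA)
  positions <- positions[hasCA]
  codes <- codes[hasCA]
  coords <- coords[hasCA, , , drop = FALSE]

  want <- constructCodes(construct, positions)
  if (any(want != codes)) {
    off <- positions[want != codes]
    stop("sequence mismatch at construct position(s) ",
         paste(off, collapse = ", "), " in ", path, " chain ", chainId)
  }
  newStructureModel(label, source, construct, positions, codes, coords)
}

#' Write a model as a minimal PDB file
#'
#' Backbone-only ATOM records at construct numbering (plus an optional
#' offset), used for synthetic fixtures and report output. Coordinates are
#' written at PDB precision (3 decimals).
#'
#' @param model a [StructureModel-class].
#' @param path output file.
#' @param chainId chain identifier to write.
#' @param positionOffset added to construct positions to form author
#'   numbering.
#' @return the path, invisibly.
#' @export
writePdbModel <- function(model, path, chainId = "A", positionOffset = 0L) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (i in seq_along(model@positions)) {
    res3 <- AA123[[model@codes[i]]]
    for (atom in BACKBONE_ATOMS) {
      xyz <- model@coords[i, atom, ]
      if (anyNA(xyz)) next
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, atom, res3, chainId,
        model@positions[i] + as.integer(positionOffset),
        xyz[1], xyz[2], xyz[3], 1.0, 0.0, substr(atom, 1, 1)), con)
    }
  }
  writeLines(c("TER", "END"), con)
  invisible(path)
}

#' Number of resolved residues
#'
#' @param model a [StructureModel-class].
#' @return integer count of residues with coordinates.
#' @export
resolvedLength <- function(model) length(model@positions)

#' Longest run of consecutive resolved glutamines in the polyQ tract
#'
#' @param model a [StructureModel-class].
#' @return integer, 0 if no tract residue is resolved.
#' @export
maxConsecutiveResolvedQ <- function(model) {
  qpos <- polyqPositions(model@construct)
  mask <- qpos %in% model@positions
  if (!any(mask)) return(0L)
  r <- rle(mask)
  max(r$lengths[r$values])
}

#' Number of resolved residues inside the polyQ tract
#'
#' @param model a [StructureModel-class].
#' @return integer.
#' @export
resolvedQCount <- function(model) {
  sum(polyqPositions(model@construct) %in% model@positions)
}

#' Filter reference structures by consecutive resolved glutamines
#'
#' Keeps chains whose polyQ tract has at least \code{minConsecutiveQ}
#' consecutive resolved residues (default 9, more than half a 17-Q tract),
#' preserving input order. Idempotent and monotone in the threshold.
#'
#' @param models list of [StructureModel-class].
#' @param minConsecutiveQ threshold.
#' @return the qualifying subset (possibly empty).
#' @export
filterReferences <- function(models, minConsecutiveQ = 9L) {
  keep <- vapply(models, maxConsecutiveResolvedQ, integer(1)) >=
    as.integer(minConsecutiveQ)
  models[keep]
}

#' Read a predictor score table
#'
#' TSV with header; columns \code{label}, \code{score}, optional
#' \code{cluster} and \code{run}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readScoreTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "score") %in% names(df)))
    stop("score table needs 'label' and 'score' columns")
  df
}

#' Assemble an ensemble from models grouped by run and rank
#'
#' @param models list of [StructureModel-class].
#' @param run,rank integer vectors parallel to \code{models} (or named by
#'   label).
#' @return an [EnsembleSet-class].
#' @export
EnsembleSet <- function(models, run, rank) {
  labs <- vapply(models, modelLabel, character(1))
  names(models) <- labs
  if (is.null(names(run))) names(run) <- labs
  if (is.null(names(rank))) names(rank) <- labs
  new("EnsembleSet", models = models,
      run = stats::setNames(as.integer(run[labs]), labs),
      rank = stats::setNames(as.integer(rank[labs]), labs))
}

#' Select models into an ensemble using a predictor score table
#'
#' Two policies mirror common predictor output handling.
#' \code{"best_k_by_score"} keeps the k best-scoring models per run
#' (direction set by \code{scoreDirection}: C-score-like scores are
#' better high, energies better low). \code{"best_per_cluster"} first
#' restricts to clusters with more than \code{minClusterSize} members,
#' takes each such cluster's best-energy member, then keeps the k best of
#' those; models of one run never come from the same cluster twice. If
#' fewer than k clusters qualify, all qualifying ones are returned with a
#' warning.
#'
#' @param models list of [StructureModel-class], labels matching the table.
#' @param scores data.frame with columns \code{label}, \code{score},
#'   optional \code{cluster} and \code{run}.
#' @param policy \code{"best_k_by_score"} or \code{"best_per_cluster"}.
#' @param k models retained per run.
#' @param minClusterSize strict lower bound on usable cluster size.
#' @param scoreDirection \code{"higher"} or \code{"lower"} is better;
#'   defaults to higher for \code{best_k_by_score} (C-score) and lower for
#'   \code{best_per_cluster} (energy).
#' @return an [EnsembleSet-class] with per-run ranks 1..k by score.
#' @export
selectEnsemble <- function(models, scores,
                           policy = c("best_k_by_score", "best_per_cluster"),
                           k = 5L, minClusterSize = 10L,
                           scoreDirection = NULL) {
  policy <- match.arg(policy)
  if (is.null(scoreDirection))
    scoreDirection <- if (policy == "best_k_by_score") "higher" else "lower"
  scoreDirection <- match.arg(scoreDirection, c("higher", "lower"))
  labs <- vapply(models, modelLabel, character(1))
  names(models) <- labs
  if (!all(scores$label %in% labs))
    stop("score table labels missing from models: ",
         paste(setdiff(scores$label, labs), collapse = ", "))
  if (is.null(scores$run)) scores$run <- 1L
  better <- if (scoreDirection == "higher") scores$score else -scores$score

  chosen <- list()
  for (r in sort(unique(scores$run))) {
    sr <- scores[scores$run == r, , drop = FALSE]
    br <- better[scores$run == r]
    if (policy == "best_k_by_score") {
      ord <- order(-br, sr$label)
      sel <- sr[ord[seq_len(min(k, nrow(sr)))], , drop = FALSE]
    } else {
      if (is.null(sr$cluster))
        stop("best_per_cluster policy needs a 'cluster' column")
      sizes <- table(sr$cluster)
      eligible <- names(sizes)[sizes > minClusterSize]
      picks <- do.call(rbind, lapply(eligible, function(cl) {
        sc <- sr[sr$cluster == cl, , drop = FALSE]
        bc <- br[sr$cluster == cl]
        sc[order(-bc, sc$label)[1], , drop = FALSE]
      }))
      if (is.null(picks) || nrow(picks) == 0L)
        stop("no cluster exceeds minClusterSize")
      if (nrow(picks) < k)
        warning(sprintf("run %s: only %d eligible clusters (k = %d)",
                        r, nrow(picks), k))
      bp <- if (scoreDirection == "higher") picks$score else -picks$score
      ord <- order(-bp, picks$label)
      sel <- picks[ord[seq_len(min(k, nrow(picks)))], , drop = FALSE]
    }
    bsel <- if (scoreDirection == "higher") sel$score else -sel$score
    sel <- sel[order(-bsel, sel$label), , drop = FALSE]
    for (i in seq_len(nrow(sel))) {
      m <- models[[sel$label[i]]]
      m@score <- sel$score[i]
      chosen[[sel$label[i]]] <-
        list(model = m, run = as.integer(r), rank = i)
    }
  }
  EnsembleSet(lapply(chosen, `[[`, "model"),
              vapply(chosen, `[[`, integer(1), "run"),
              vapply(chosen, function(x) as.integer(x$rank), integer(1)))
}
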