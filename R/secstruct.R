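vnorm <- function(v) sqrt(sum(v^2))

#' Place the backbone amide hydrogen
#'
#' Standard Kabsch-Sander construction: the H sits 1.0 Angstrom from the
#' donor N along the direction of the previous residue's C=O bond
#' reversed (O to C), i.e. \code{H = N + (C_prev - O_prev)/|C_prev -
#' O_prev|}.
#'
#' @param n donor backbone N coordinate (length-3).
#' @param cPrev,oPrev previous residue's C and O coordinates.
#' @return length-3 H coordinate.
#' @export
placeAmideHydrogen <- function(n, cPrev, oPrev) {
  for (nm in c("n", "cPrev", "oPrev")) {
    v <- get(nm)
    if (length(v) != 3L || anyNA(v))
      stop("missing backbone atom coordinate: ", nm)
  }
  d <- cPrev - oPrev
  n + d / vnorm(d)
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic model
#' \code{E = 0.084 * (1/r(ON) + 1/r(CH) - 1/r(OH) - 1/r(CN)) * 332}
#' kcal/mol between a backbone N-H donor and a backbone C=O acceptor. A
#' hydrogen bond is assigned when E < -0.5 kcal/mol. Proline has no amide
#' hydrogen and cannot donate; enforce that upstream.
#'
#' @param donorN,donorH donor backbone N and placed amide H coordinates.
#' @param acceptorC,acceptorO acceptor backbone C and O coordinates.
#' @return energy in kcal/mol.
#' @export
hbondEnergy <- function(donorN, donorH, acceptorC, acceptorO) {
  args <- list(donorN = donorN, donorH = donorH, acceptorC = acceptorC,
               acceptorO = acceptorO)
  for (nm in names(args)) {
    if (length(args[[nm]]) != 3L || anyNA(args[[nm]]))
      stop("missing backbone atom coordinate: ", nm)
  }
  rON <- vnorm(acceptorO - donorN)
  rCH <- vnorm(acceptorC - donorH)
  rOH <- vnorm(acceptorO - donorH)
  rCN <- vnorm(acceptorC - donorN)
  if (min(rON, rCH, rOH, rCN) < 0.5) return(-9.9)  # clash guard
  0.084 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN) * 332
}

HBOND_CUTOFF <- -0.5
BEND_ANGLE <- 70

# n x n logical: hb[i, j] TRUE when CO of residue i accepts the amide H of
# residue j. Rows/cols indexed over the model's stored residues.
hbondMatrix <- function(model) {
  n <- length(model@positions)
  pos <- model@positions
  co <- model@coords
  # donor H for residue i needs residue at pos-1 with C and O, and non-Pro
  H <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    if (model@codes[i] == "P" || anyNA(co[i, "N", ])) next
    prev <- match(pos[i] - 1L, pos)
    if (is.na(prev)) next
    if (anyNA(co[prev, "C", ]) || anyNA(co[prev, "O", ])) next
    H[i, ] <- placeAmideHydrogen(co[i, "N", ], co[prev, "C", ],
                                 co[prev, "O", ])
  }
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {                       # acceptor
    if (anyNA(co[i, "C", ]) || anyNA(co[i, "O", ])) next
    for (j in seq_len(n)) {                     # donor
      if (abs(pos[i] - pos[j]) < 2L || anyNA(H[j, ])) next
      # cheap distance gate: CA-CA beyond 9 A cannot H-bond
      if (vnorm(co[i, "CA", ] - co[j, "CA", ]) > 9) next
      e <- hbondEnergy(co[j, "N", ], H[j, ], co[i, "C", ], co[i, "O", ])
      hb[i, j] <- e < HBOND_CUTOFF
    }
  }
  hb
}

#' Eight-state secondary-structure assignment
#'
#' Kabsch-Sander rules from backbone hydrogen bonds: n-turns (n = 3, 4, 5)
#' from i to i+n bonds; two consecutive 4-turns make an alpha-helix (H),
#' 3-turns a 3-10 helix (G), 5-turns a pi-helix (I); isolated bridges are
#' B and laddered bridges strand E; remaining turn interiors are T; a bend
#' (S) where the CA(i-2), CA(i), CA(i+2) direction change exceeds 70
#' degrees; everything else coil (C). Overlaps resolve with precedence
#' H > E > B > G > I > T > S. Positions that are unresolved or lack a full
#' backbone (CA-only) are reported as M (missing).
#'
#' @param model a [StructureModel-class].
#' @return character vector of length \code{constructLength}, one state
#'   code per construct position.
#' @examples
#' cd <- htt17qConstruct()
#' m <- buildBackbone(constructSequence(cd), helixDihedrals(60), cd)
#' table(assignDssp(m))
#' @export
assignDssp <- function(model) {
  L <- constructLength(model@construct)
  ss <- rep("M", L)
  pos <- model@positions
  n <- length(pos)
  if (n == 0L) return(ss)
  co <- model@coords
  full <- !apply(co, 1L, anyNA)
  ss[pos[full]] <- "C"
  if (!any(full)) return(ss)

  hb <- hbondMatrix(model)
  # turns: turn_k[p] TRUE when CO(p) -- HN(p+k)
  turn <- list()
  for (k in 3:5) {
    tk <- rep(FALSE, L)
    for (i in seq_len(n)) {
      j <- match(pos[i] + k, pos)
      if (!is.na(j) && hb[i, j]) tk[pos[i]] <- TRUE
    }
    turn[[as.character(k)]] <- tk
  }

  assignable <- rep(FALSE, L)
  assignable[pos[full]] <- TRUE
  put <- function(ss, idx, code) {
    idx <- idx[idx >= 1 & idx <= L]
    ss[idx[assignable[idx]]] <- code
    ss
  }

  # lowest priority first; later assignments overwrite earlier ones
  # S: bend
  for (i in seq_len(n)) {
    p <- pos[i]
    a <- match(p - 2L, pos); b <- match(p + 2L, pos)
    if (is.na(a) || is.na(b)) next
    u <- co[i, "CA", ] - co[a, "CA", ]
    v <- co[b, "CA", ] - co[i, "CA", ]
    ang <- acos(pmin(1, pmax(-1, sum(u * v) / (vnorm(u) * vnorm(v))))) *
      180 / pi
    if (ang > BEND_ANGLE) ss <- put(ss, p, "S")
  }
  # T: interiors of any n-turn
  for (k in 3:5) {
    for (p in which(turn[[as.character(k)]]))
      ss <- put(ss, (p + 1L):(p + k - 1L), "T")
  }
  # I, G: consecutive 5-turns / 3-turns at p and p+1
  consec <- function(tk) which(tk & c(tk[-1], FALSE))
  for (p in consec(turn[["5"]]))
    ss <- put(ss, (p + 1L):(p + 5L), "I")
  for (p in consec(turn[["3"]]))
    ss <- put(ss, (p + 1L):(p + 3L), "G")

  # bridges
  bridge <- matrix(FALSE, L, L)
  hbp <- function(a, b) {  # CO(a) -- HN(b), by construct position
    i <- match(a, pos); j <- match(b, pos)
    !is.na(i) && !is.na(j) && hb[i, j]
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      pi_ <- pos[i]; pj <- pos[j]
      if (pj - pi_ <= 2L) next
      par <- (hbp(pi_ - 1L, pj) && hbp(pj, pi_ + 1L)) ||
             (hbp(pj - 1L, pi_) && hbp(pi_, pj + 1L))
      anti <- (hbp(pi_, pj) && hbp(pj, pi_)) ||
              (hbp(pi_ - 1L, pj + 1L) && hbp(pj - 1L, pi_ + 1L))
      if (par || anti) bridge[pi_, pj] <- bridge[pj, pi_] <- TRUE
    }
  }
  bpos <- which(rowSums(bridge) > 0)
  ladder <- rep(FALSE, L)
  for (p in bpos) {
    js <- which(bridge[p, ])
    for (j in js) {
      nb <- FALSE
      for (dp in c(-1L, 1L)) for (dj in c(-1L, 1L)) {
        pp <- p + dp; jj <- j + dj
        if (pp >= 1 && pp <= L && jj >= 1 && jj <= L && bridge[pp, jj])
          nb <- TRUE
      }
      if (nb) ladder[p] <- TRUE
    }
  }
  ss <- put(ss, bpos[!ladder[bpos]], "B")
  ss <- put(ss, bpos[ladder[bpos]], "E")

  # H: consecutive 4-turns (highest priority)
  for (p in consec(turn[["4"]]))
    ss <- put(ss, (p + 1L):(p + 4L), "H")
  ss
}

#' Secondary-structure frequency profile over an ensemble
#'
#' Counts each state per construct position over a list of
#' secondary-structure strings (as returned by [assignDssp()]) and
#' row-normalizes to frequencies — the machine-readable form of a
#' sequence-logo panel. M (missing) is a regular state so reference
#' ensembles with unresolved residues profile correctly.
#'
#' @param ensemble list of character vectors (or single strings) of equal
#'   length.
#' @return an [SSProfile-class].
#' @export
ssProfile <- function(ensemble) {
  strings <- lapply(ensemble, function(s) {
    if (length(s) == 1L && nchar(s) > 1L) strsplit(s, "")[[1]] else s
  })
  lens <- vapply(strings, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all secondary-structure strings must have equal length")
  L <- lens[1]
  counts <- matrix(0L, L, length(SS_STATES),
                   dimnames = list(seq_len(L), SS_STATES))
  for (s in strings) {
    bad <- setdiff(unique(s), SS_STATES)
    if (length(bad) > 0)
      stop("unknown state code(s): ", paste(bad, collapse = ", "))
    for (p in seq_len(L)) counts[p, s[p]] <- counts[p, s[p]] + 1L
  }
  new("SSProfile", counts = counts,
      frequencies = counts / length(strings),
      nStructures = length(strings))
}

#' Write secondary-structure strings and profiles
#'
#' \code{writeSsFasta}: FASTA-like text, one record per model.
#' \code{writeSsProfileTsv}: TSV with rows = positions, columns = states.
#'
#' @param strings named list of SS strings/vectors.
#' @param profile an [SSProfile-class].
#' @param file output path.
#' @param what \code{"counts"} or \code{"frequencies"}.
#' @return the path, invisibly.
#' @export
writeSsFasta <- function(strings, file) {
  con <- file(file, "w")
  on.exit(close(con))
  nms <- names(strings)
  if (is.null(nms)) nms <- paste0("model", seq_along(strings))
  for (i in seq_along(strings)) {
    writeLines(paste0(">", nms[i]), con)
    writeLines(paste(strings[[i]], collapse = ""), con)
  }
  invisible(file)
}

#' @rdname writeSsFasta
#' @export
writeSsProfileTsv <- function(profile, file, what = c("counts",
                                                      "frequencies")) {
  what <- match.arg(what)
  m <- slot(profile, what)
  df <- data.frame(position = seq_len(nrow(m)), m, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
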