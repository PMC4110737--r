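# Ideal backbone geometry (Engh-Huber-style averages), Angstroms / degrees
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
ANG_N_CA_C <- 111.2
ANG_CA_C_N <- 116.2
ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.5

# run expr with a temporary RNG state seeded from `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# place atom D given A-B-C, bond |CD|, angle B-C-D, torsion A-B-C-D (deg)
nerfPlace <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / vnorm(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Canonical dihedral sets
#'
#' Per-residue phi/psi/omega tables: ideal alpha-helix (-57, -47), ideal
#' strand (-135, 135), and a 6-pair coil library sampled per residue
#' (polyproline-II, extended-beta, bridge, right- and left-handed helical
#' and a generic extended basin).
#'
#' @param n number of residues.
#' @param seed RNG seed for the coil sampler.
#' @return data.frame with columns phi, psi, omega (degrees).
#' @export
helixDihedrals <- function(n) {
  data.frame(phi = rep(-57, n), psi = rep(-47, n), omega = rep(180, n))
}

#' @rdname helixDihedrals
#' @export
strandDihedrals <- function(n) {
  data.frame(phi = rep(-135, n), psi = rep(135, n), omega = rep(180, n))
}

COIL_LIBRARY <- matrix(c(
  -75, 145,    # polyproline II
  -120, 130,   # beta basin
  -90, 0,      # bridge
  -60, -40,    # alpha-R
  57, 42,      # alpha-L
  -150, 155),  # extended
  ncol = 2, byrow = TRUE, dimnames = list(NULL, c("phi", "psi")))

#' @rdname helixDihedrals
#' @export
coilDihedrals <- function(n, seed = NULL) {
  pick <- function() COIL_LIBRARY[sample.int(nrow(COIL_LIBRARY), n,
                                             replace = TRUE), , drop = FALSE]
  ps <- if (is.null(seed)) pick() else withSeed(seed, pick())
  data.frame(phi = ps[, "phi"], psi = ps[, "psi"], omega = rep(180, n))
}

#' Build a full-backbone chain from internal coordinates
#'
#' Internal-to-Cartesian (NeRF) construction with standard bond lengths
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 A) and angles (111.2, 116.2, 121.7
#' degrees); the carbonyl O is placed in the peptide plane. Deterministic:
#' the same dihedrals always give the same coordinates. Consecutive CA-CA
#' distances come out at 3.80 +/- 0.05 A for trans peptides.
#'
#' @param sequence one-letter amino-acid string.
#' @param dihedrals data.frame with per-residue \code{phi}, \code{psi},
#'   \code{omega} (degrees); \code{phi[1]} is unused.
#' @param construct the [ConstructDef-class] the chain belongs to; its
#'   sequence must contain \code{sequence} starting at \code{startPos}.
#' @param label model label.
#' @param startPos construct position of the first residue.
#' @param source provenance tag.
#' @param score optional synthetic score.
#' @return a [StructureModel-class] with all residues resolved.
#' @examples
#' cd <- htt17qConstruct()
#' m <- buildBackbone(constructSequence(cd), helixDihedrals(60), cd)
#' resolvedLength(m)
#' @export
buildBackbone <- function(sequence, dihedrals, construct,
                          label = "synthetic", startPos = 1L,
                          source = "synthetic", score = NA_real_) {
  n <- nchar(sequence)
  stopifnot(n >= 1, nrow(dihedrals) == n)
  coords <- emptyCoords(n)
  ang <- ANG_N_CA_C * pi / 180
  coords[1, "N", ] <- c(0, 0, 0)
  coords[1, "CA", ] <- c(BOND_N_CA, 0, 0)
  coords[1, "C", ] <- coords[1, "CA", ] +
    BOND_CA_C * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      coords[i, "N", ] <- nerfPlace(coords[i - 1, "N", ],
                                    coords[i - 1, "CA", ],
                                    coords[i - 1, "C", ],
                                    BOND_C_N, ANG_CA_C_N,
                                    dihedrals$psi[i - 1])
      coords[i, "CA", ] <- nerfPlace(coords[i - 1, "CA", ],
                                     coords[i - 1, "C", ],
                                     coords[i, "N", ],
                                     BOND_N_CA, ANG_C_N_CA,
                                     dihedrals$omega[i - 1])
      coords[i, "C", ] <- nerfPlace(coords[i - 1, "C", ],
                                    coords[i, "N", ],
                                    coords[i, "CA", ],
                                    BOND_CA_C, ANG_N_CA_C,
                                    dihedrals$phi[i])
    }
    coords[i, "O", ] <- nerfPlace(coords[i, "N", ], coords[i, "CA", ],
                                  coords[i, "C", ],
                                  BOND_C_O, ANG_CA_C_O,
                                  dihedrals$psi[i] - 180)
  }
  positions <- seq.int(startPos, startPos + n - 1L)
  codes <- strsplit(sequence, "")[[1]]
  newStructureModel(label, source, construct, positions, codes, coords,
                    score)
}

#' Region conformation specification
#'
#' Probabilities of sampling each backbone state for one region of the
#' construct when generating synthetic models.
#'
#' @param helix,strand,coil state probabilities; must sum to 1.
#' @return named numeric vector of class probabilities.
#' @export
regionSpec <- function(helix = 0, strand = 0, coil = 0) {
  p <- c(helix = helix, strand = strand, coil = coil)
  if (abs(sum(p) - 1) > 1e-9) stop("state probabilities must sum to 1")
  p
}

#' Default per-region conformation distributions
#'
#' The head is mostly helical, the polyQ tract conformationally variable
#' (helix / coil with occasional strand), and the Pro-rich C-terminus coil
#' dominated — the qualitative picture crystal structures of
#' huntingtin-exon-1-like fragments show.
#'
#' @return named list of [regionSpec()] vectors (head, polyq, cterm).
#' @export
defaultRegionSpecs <- function() {
  list(head  = regionSpec(helix = 0.90, strand = 0.00, coil = 0.10),
       polyq = regionSpec(helix = 0.40, strand = 0.10, coil = 0.50),
       cterm = regionSpec(helix = 0.05, strand = 0.05, coil = 0.90))
}

#' Reference-style unresolved masking specification
#'
#' Controls how synthetic reference chains lose residues: the head stays
#' resolved, the polyQ tract keeps a consecutive run of
#' \code{minResolvedQ..maxResolvedQ} residues from its start, and the
#' C-terminus is resolved up to a position drawn uniformly from
#' \code{ctermResolvedRange} (emulating the rapid loss of resolution past
#' the head region seen in the crystals).
#'
#' @param minResolvedQ,maxResolvedQ bounds on the resolved polyQ run.
#' @param ctermResolvedRange interval the C-terminal resolution cutoff is
#'   drawn from.
#' @return a list of class settings.
#' @export
maskSpec <- function(minResolvedQ = 0L, maxResolvedQ = 17L,
                     ctermResolvedRange = c(34L, 48L)) {
  stopifnot(minResolvedQ <= maxResolvedQ)
  list(minResolvedQ = as.integer(minResolvedQ),
       maxResolvedQ = as.integer(maxResolvedQ),
       ctermResolvedRange = as.integer(ctermResolvedRange))
}

# sample per-region dihedrals for one model
sampleDihedrals <- function(construct, specs) {
  L <- constructLength(construct)
  dh <- data.frame(phi = numeric(L), psi = numeric(L), omega = rep(180, L))
  regions <- list(head = headRegion(construct),
                  polyq = polyqRegion(construct),
                  cterm = ctermRegion(construct))
  states <- character(0)
  for (nm in names(regions)) {
    r <- regions[[nm]]
    idx <- seq.int(r[1], r[2])
    state <- sample(names(specs[[nm]]), 1L, prob = specs[[nm]])
    states[nm] <- state
    k <- length(idx)
    ps <- switch(state,
      helix  = cbind(rep(-57, k), rep(-47, k)),
      strand = cbind(rep(-135, k), rep(135, k)),
      coil   = COIL_LIBRARY[sample.int(nrow(COIL_LIBRARY), k,
                                       replace = TRUE), , drop = FALSE])
    dh$phi[idx] <- ps[, 1]
    dh$psi[idx] <- ps[, 2]
  }
  attr(dh, "states") <- states
  dh
}

addNoise <- function(model, sigma) {
  if (sigma <= 0) return(model)
  co <- model@coords
  ok <- !is.na(co)
  co[ok] <- co[ok] + stats::rnorm(sum(ok), 0, sigma)
  model@coords <- co
  model
}

#' Generate a synthetic prediction ensemble
#'
#' Emulates the shape of a multi-seed prediction study: \code{nRuns}
#' independent runs of \code{modelsPerRun} retained models. Each model
#' samples one backbone state per region from \code{specs}, is built with
#' [buildBackbone()], and receives isotropic Gaussian coordinate noise of
#' \code{noiseSigma} Angstroms. Each model carries a synthetic
#' C-score-like score in (-5, 2), a monotone decreasing function of the
#' realized noise magnitude, so selection policies are exercisable; ranks
#' within a run follow that score. Deterministic given \code{seed}.
#'
#' @param construct a [ConstructDef-class].
#' @param specs per-region state distributions, see [defaultRegionSpecs()].
#' @param nRuns,modelsPerRun ensemble shape (defaults 10 x 5).
#' @param noiseSigma coordinate noise, Angstroms.
#' @param seed RNG seed.
#' @return an [EnsembleSet-class]; model states are attached as attribute
#'   \code{"states"}.
#' @examples
#' ens <- generateEnsemble(htt17qConstruct(), nRuns = 2, modelsPerRun = 2,
#'                         noiseSigma = 1, seed = 1)
#' nModels(ens)
#' @export
generateEnsemble <- function(construct, specs = defaultRegionSpecs(),
                             nRuns = 10L, modelsPerRun = 5L,
                             noiseSigma = 1.0, seed = 1L) {
  stopifnot(nRuns >= 1L, modelsPerRun >= 1L)
  withSeed(seed, {
    models <- list()
    run <- integer(0)
    rank <- integer(0)
    allStates <- list()
    for (r in seq_len(nRuns)) {
      raw <- vector("list", modelsPerRun)
      mag <- numeric(modelsPerRun)
      for (k in seq_len(modelsPerRun)) {
        dh <- sampleDihedrals(construct, specs)
        m <- buildBackbone(constructSequence(construct), dh, construct,
                           label = "tmp", source = "predicted")
        before <- m@coords
        m <- addNoise(m, noiseSigma)
        mag[k] <- sqrt(mean((m@coords - before)^2, na.rm = TRUE))
        attr(m, "states") <- attr(dh, "states")
        raw[[k]] <- m
      }
      ord <- order(mag)
      for (i in seq_along(ord)) {
        m <- raw[[ord[i]]]
        lab <- sprintf("run%d_model%d", r, i)
        m@label <- lab
        m@score <- -5 + 7 * exp(-mag[ord[i]] / 2)  # C-score-like, (-5, 2)
        models[[lab]] <- m
        run[lab] <- r
        rank[lab] <- i
        allStates[[lab]] <- attr(m, "states")
      }
    }
    ens <- EnsembleSet(models, run, rank)
    attr(ens, "states") <- allStates
    ens
  })
}

#' Ensemble of noisy copies of a template structure
#'
#' Every model is the template plus isotropic Gaussian coordinate noise —
#' the parameter-recovery setting where the noise level is the only thing
#' separating an ensemble from the structure it should recover. Ranks
#' within a run follow the realized noise magnitude (synthetic
#' C-score-like scores as in [generateEnsemble()]).
#'
#' @param template a [StructureModel-class].
#' @param nRuns,modelsPerRun ensemble shape.
#' @param noiseSigma coordinate noise, Angstroms.
#' @param seed RNG seed.
#' @return an [EnsembleSet-class].
#' @export
perturbedEnsemble <- function(template, nRuns = 1L, modelsPerRun = 5L,
                              noiseSigma = 1.0, seed = 1L) {
  stopifnot(nRuns >= 1L, modelsPerRun >= 1L)
  withSeed(seed, {
    models <- list()
    run <- integer(0)
    rank <- integer(0)
    for (r in seq_len(nRuns)) {
      raw <- vector("list", modelsPerRun)
      mag <- numeric(modelsPerRun)
      for (k in seq_len(modelsPerRun)) {
        m <- template
        m@source <- "predicted"
        before <- m@coords
        m <- addNoise(m, noiseSigma)
        mag[k] <- if (noiseSigma > 0)
          sqrt(mean((m@coords - before)^2, na.rm = TRUE)) else 0
        raw[[k]] <- m
      }
      ord <- order(mag)
      for (i in seq_along(ord)) {
        m <- raw[[ord[i]]]
        lab <- sprintf("run%d_model%d", r, i)
        m@label <- lab
        m@score <- -5 + 7 * exp(-mag[ord[i]] / 2)
        models[[lab]] <- m
        run[lab] <- r
        rank[lab] <- i
      }
    }
    EnsembleSet(models, run, rank)
  })
}

#' Generate synthetic partially resolved reference chains
#'
#' Emulates crystal reference chains: full chains built like ensemble
#' models (default specs), then masked per [maskSpec()] — the head region
#' always resolved, a consecutive run of resolved glutamines from the
#' tract start, and a C-terminal resolution cutoff. Resolved-Q counts can
#' be forced per chain via \code{resolvedQ}, whose default mirrors a
#' crystallographic panel where 10 of 21 chains keep at least 9
#' consecutive tract residues (counts 10-17) and the rest fewer.
#'
#' @param construct a [ConstructDef-class].
#' @param n number of chains.
#' @param mask a [maskSpec()].
#' @param specs per-region state distributions.
#' @param noiseSigma coordinate noise, Angstroms.
#' @param seed RNG seed.
#' @param resolvedQ optional integer vector (length \code{n}) forcing the
#'   resolved polyQ run length of each chain.
#' @param labels optional chain labels.
#' @return list with \code{models} (list of [StructureModel-class]),
#'   \code{resolvedQ} (the realized run lengths) and \code{masks} (the
#'   resolved construct positions per chain) for ground-truth tests.
#' @export
generateReferenceSet <- function(construct, n = 21L, mask = maskSpec(),
                                 specs = defaultRegionSpecs(),
                                 noiseSigma = 0.3, seed = 1L,
                                 resolvedQ = NULL, labels = NULL) {
  stopifnot(n >= 1L)
  if (is.null(resolvedQ) && n == 21L &&
      identical(mask$minResolvedQ, 0L) && identical(mask$maxResolvedQ, 17L))
    resolvedQ <- defaultReferenceQCounts()
  if (is.null(labels)) labels <- sprintf("synthref_%02d", seq_len(n))
  withSeed(seed, {
    models <- vector("list", n)
    masks <- vector("list", n)
    qs <- integer(n)
    qreg <- polyqRegion(construct)
    for (i in seq_len(n)) {
      dh <- sampleDihedrals(construct, specs)
      full <- buildBackbone(constructSequence(construct), dh, construct,
                            label = labels[i], source = "experimental")
      full <- addNoise(full, noiseSigma)
      q <- if (!is.null(resolvedQ)) as.integer(resolvedQ[i])
           else sample(mask$minResolvedQ:mask$maxResolvedQ, 1L)
      ctCut <- sample(mask$ctermResolvedRange[1]:mask$ctermResolvedRange[2],
                      1L)
      keep <- c(seq.int(headRegion(construct)[1], headRegion(construct)[2]),
                if (q > 0L) seq.int(qreg[1], qreg[1] + q - 1L),
                if (ctCut >= ctermRegion(construct)[1])
                  seq.int(ctermRegion(construct)[1], ctCut))
      keep <- sort(unique(keep))
      models[[i]] <- maskModel(full, keep)
      masks[[i]] <- keep
      qs[i] <- q
    }
    names(models) <- labels
    list(models = models, resolvedQ = qs, masks = masks)
  })
}

#' Resolved-Q counts emulating a crystallographic reference panel
#'
#' 21 values: ten chains with 10-17 consecutive resolved tract glutamines
#' (the spread a real panel showed, including one fully resolved 17 and
#' one 15) followed by eleven chains below the 9-residue filter, one with
#' a single resolved Q.
#'
#' @return integer vector of length 21.
#' @export
defaultReferenceQCounts <- function() {
  as.integer(c(10, 11, 14, 10, 13, 12, 14, 11, 15, 17,
               1, 2, 3, 4, 5, 6, 7, 8, 8, 6, 4))
}

#' Restrict a model to a subset of resolved positions
#'
#' @param model a [StructureModel-class].
#' @param keep construct positions to retain.
#' @return the masked [StructureModel-class].
#' @export
maskModel <- function(model, keep) {
  idx <- which(model@positions %in% keep)
  newStructureModel(model@label, model@source, model@construct,
                    model@positions[idx], model@codes[idx],
                    model@coords[idx, , , drop = FALSE], model@score)
}
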