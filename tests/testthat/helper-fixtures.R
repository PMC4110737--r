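# Shared fixtures: everything is generated in code, nothing read from disk.

cdHtt <- htt17qConstruct()
httSeq <- constructSequence(cdHtt)
httCodes <- strsplit(httSeq, "")[[1]]

# small construct with distinct head/tail codes around a 17-Q tract
toyConstruct <- function(head = "ACDE", tail = "FGHI") {
  ConstructDef(paste0(head, strrep("Q", 17), tail),
               c(1, nchar(head)),
               c(nchar(head) + 1, nchar(head) + 17),
               c(nchar(head) + 18, nchar(head) + 17 + nchar(tail)))
}

# deterministic coil model on the default construct
coilModel <- function(seed, label = paste0("coil", seed), cd = cdHtt) {
  buildBackbone(constructSequence(cd), coilDihedrals(constructLength(cd),
                                                     seed = seed),
                cd, label = label)
}

helixModel <- function(label = "helix", cd = cdHtt) {
  buildBackbone(constructSequence(cd), helixDihedrals(constructLength(cd)),
                cd, label = label)
}

# copy of a model with Gaussian coordinate noise
noisyCopy <- function(model, sigma, seed, label = paste0(model@label,
                                                         "_noisy")) {
  set.seed(seed)
  co <- model@coords
  ok <- !is.na(co)
  co[ok] <- co[ok] + rnorm(sum(ok), 0, sigma)
  m <- model
  m@coords <- co
  m@label <- label
  m
}

# uniformly random proper rotation
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

applyRigid <- function(model, rot, trans) {
  co <- model@coords
  for (atom in c("N", "CA", "C", "O")) {
    m <- co[, atom, , drop = FALSE]
    dim(m) <- c(dim(co)[1], 3L)
    ok <- !apply(m, 1L, anyNA)
    m[ok, ] <- m[ok, , drop = FALSE] %*% rot +
      matrix(trans, sum(ok), 3, byrow = TRUE)
    co[, atom, ] <- m
  }
  out <- model
  out@coords <- co
  out
}

# register-shifted copy: residue i carries the coordinates of residue i+1
registerShift <- function(model) {
  n <- length(model@positions)
  newStructureModel <- getFromNamespace("newStructureModel", "polyQeval")
  newStructureModel(paste0(model@label, "_shift"), "synthetic",
                    model@construct, model@positions[-n],
                    model@codes[-n],
                    model@coords[-1, , , drop = FALSE])
}

# hand-built AlignmentResult (identity frame unless given)
makeAlignment <- function(pairs, rotation = diag(3),
                          translation = c(0, 0, 0), normalizedBy = "reference") {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  new("AlignmentResult", pairs = pairs, rotation = rotation,
      translation = translation, tmScore = 0.5, rmsd = 0,
      alignedLength = nrow(pairs), seqIdentity = 0,
      normalizedBy = normalizedBy)
}

# tiny all-helix region spec (degenerate, zero conformational variability)
allHelixSpecs <- list(head = regionSpec(helix = 1),
                      polyq = regionSpec(helix = 1),
                      cterm = regionSpec(helix = 1))
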