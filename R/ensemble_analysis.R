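#' Pairwise TM-score matrix of an ensemble
#'
#' TM-score for every unordered model pair, using the identity
#' correspondence over jointly resolved construct positions (the models
#' share one sequence). Normalization defaults to the shorter chain,
#' which for equal-length predicted models is symmetric and unambiguous.
#'
#' @param ensemble an [EnsembleSet-class] with at least 2 models.
#' @param normalizeBy TM-score normalization, see [tmScore()].
#' @return a [PairMatrix-class]; \code{n*(n-1)/2} computed values.
#' @export
pairwiseTmMatrix <- function(ensemble, normalizeBy = "shorter") {
  models <- ensemble@models
  n <- length(models)
  if (n < 2L) stop("need at least 2 models")
  v <- matrix(NA_real_, n, n, dimnames = list(names(models), names(models)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      tm <- tmScore(NULL, models[[i]], models[[j]],
                    normalizeBy = normalizeBy)
      v[i, j] <- v[j, i] <- tm
    }
  }
  new("PairMatrix", labels = names(models), values = v)
}

#' Count pairs above a TM cutoff
#'
#' @param matrix a [PairMatrix-class].
#' @param cutoff strict lower bound (default 0.5, the same-fold level).
#' @return number of unordered pairs with value strictly above the cutoff.
#' @export
countAbove <- function(matrix, cutoff = 0.5) {
  v <- matrix@values[upper.tri(matrix@values)]
  sum(v > cutoff, na.rm = TRUE)
}

#' Run-level cross-run pair counts
#'
#' For every unordered pair of runs, counts cross-run model pairs with
#' TM-score strictly above the cutoff (0..m^2 for m models per run).
#'
#' @param ensemble an [EnsembleSet-class]; every run must hold the same
#'   number of models.
#' @param cutoff strict TM cutoff.
#' @param matrix optional precomputed [pairwiseTmMatrix()] to reuse.
#' @return run x run integer matrix, upper triangle filled, diagonal NA.
#' @export
runLevelCounts <- function(ensemble, cutoff = 0.5, matrix = NULL) {
  runs <- sort(unique(ensemble@run))
  m <- table(ensemble@run)
  if (length(unique(as.integer(m))) != 1L)
    stop("every run must hold the same number of models")
  if (is.null(matrix)) matrix <- pairwiseTmMatrix(ensemble)
  v <- matrix@values
  labs <- matrix@labels
  out <- base::matrix(NA_integer_, length(runs), length(runs),
                      dimnames = list(paste0("run", runs),
                                      paste0("run", runs)))
  for (a in seq_along(runs)[-length(runs)]) {
    for (b in seq.int(a + 1L, length(runs))) {
      la <- labs[ensemble@run[labs] == runs[a]]
      lb <- labs[ensemble@run[labs] == runs[b]]
      out[a, b] <- sum(v[la, lb] > cutoff)
    }
  }
  out
}

#' Best-model (rank 1) pairwise matrix and count
#'
#' Restricts the ensemble to each run's rank-1 model, computes the
#' pairwise TM matrix, and counts pairs strictly above the cutoff
#' (10 runs give 45 pairs).
#'
#' @inheritParams runLevelCounts
#' @return list with \code{matrix} (a [PairMatrix-class]) and
#'   \code{countAbove}.
#' @export
bestModelMatrix <- function(ensemble, cutoff = 0.5) {
  best <- names(ensemble@rank)[ensemble@rank == 1L]
  if (length(best) < length(unique(ensemble@run)))
    stop("every run needs a rank-1 model")
  sub <- EnsembleSet(ensemble@models[best],
                     ensemble@run[best],
                     stats::setNames(rep(1L, length(best)), best))
  pm <- pairwiseTmMatrix(sub)
  list(matrix = pm, countAbove = countAbove(pm, cutoff))
}

PANEL_METRICS <- c("tm", "rmsd", "aligned", "seq_identity",
                   "exact_close", "exact_other", "exact_all",
                   "exact_q_close", "exact_q_other", "exact_q_all",
                   "total_q_close", "total_q_other", "total_q_all",
                   "so", "eso", "esop")

#' Model-versus-reference validity panel
#'
#' Aligns every ensemble model against every reference with [tmAlign()],
#' extracts [exactMatches()], and returns one record per (model,
#' reference) pair carrying TM-score, RMSD, aligned length, sequence
#' identity, the stratified match counts, and SO/ESO/ESOP. Per-metric
#' summaries follow the normality policy of [summarizeMetric()].
#'
#' @param ensemble an [EnsembleSet-class].
#' @param references list of [StructureModel-class], already passed
#'   through [filterReferences()].
#' @param threshold exact-match distance threshold, Angstroms.
#' @param normalizeBy TM-score normalization (reference by default so
#'   values are comparable across references).
#' @return list with \code{records} (data.frame, n_models x n_references
#'   rows) and \code{summary} (one row per metric from
#'   [summarizeMetric()]).
#' @export
validityPanel <- function(ensemble, references, threshold = 5.0,
                          normalizeBy = "reference") {
  if (length(references) == 0L) stop("no usable references")
  models <- ensemble@models
  rows <- vector("list", length(models) * length(references))
  k <- 0L
  for (m in models) {
    for (ref in references) {
      aln <- tmAlign(m, ref, normalizeBy = normalizeBy)
      ov <- exactMatches(aln, m, ref, threshold = threshold)
      cnt <- overlapCounts(ov)
      k <- k + 1L
      rows[[k]] <- data.frame(
        model = m@label, reference = ref@label,
        run = unname(ensemble@run[m@label]),
        rank = unname(ensemble@rank[m@label]),
        tm = aln@tmScore, rmsd = aln@rmsd,
        aligned = aln@alignedLength, seq_identity = aln@seqIdentity,
        exact_close = unname(cnt["exact_close"]),
        exact_other = unname(cnt["exact_other"]),
        exact_all = unname(cnt["exact_all"]),
        exact_q_close = unname(cnt["exact_q_close"]),
        exact_q_other = unname(cnt["exact_q_other"]),
        exact_q_all = unname(cnt["exact_q_all"]),
        total_q_close = unname(cnt["total_q_close"]),
        total_q_other = unname(cnt["total_q_other"]),
        total_q_all = unname(cnt["total_q_all"]),
        so = ov@so, eso = ov@eso, esop = ov@esop)
    }
  }
  records <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(PANEL_METRICS, function(mt) {
    s <- summarizeMetric(records[[mt]])
    cbind(metric = mt, s)
  }))
  list(records = records, summary = summary)
}

#' Distribution summary under the normality policy
#'
#' Normality is decided by a Shapiro-Wilk test at 0.05 (degenerate
#' constant samples count as non-normal). Normal samples are meant to be
#' reported as mean +/- sd, others by their 25 and 75 percent quantiles;
#' all fields are returned so callers can format either way.
#'
#' @param values numeric vector (NAs dropped), n >= 3 for the test.
#' @return one-row data.frame: n, is_normal, mean, sd, q25, q75, min, max.
#' @export
summarizeMetric <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  isNormal <- FALSE
  if (n >= 3L && stats::sd(x) > 0) {
    # shapiro.test caps at n = 5000
    xs <- if (n > 5000L) x[seq_len(5000L)] else x
    isNormal <- stats::shapiro.test(xs)$p.value > 0.05
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  data.frame(n = n, is_normal = isNormal,
             mean = mean(x), sd = stats::sd(x),
             q25 = q[1], q75 = q[2], min = min(x), max = max(x))
}

#' Two-sample comparison under the normality policy
#'
#' Both samples normal by Shapiro-Wilk at 0.05: Welch t-test; otherwise
#' Wilcoxon rank-sum (the samples are unpaired model sets). Significance
#' at alpha = 0.05.
#'
#' @param a,b numeric samples.
#' @param alpha significance level.
#' @return list: method ("t_test" or "wilcoxon"), statistic, p_value,
#'   significant.
#' @export
compareSamples <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  normal <- function(x) {
    length(x) >= 3L && stats::sd(x) > 0 &&
      stats::shapiro.test(if (length(x) > 5000L) x[seq_len(5000L)] else
                          x)$p.value > 0.05
  }
  if (normal(a) && normal(b)) {
    ht <- stats::t.test(a, b)
    method <- "t_test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    method <- "wilcoxon"
  }
  # degenerate all-tie samples give an undefined p; that is no evidence
  # of a difference
  list(method = method, statistic = unname(ht$statistic),
       p_value = ht$p.value,
       significant = isTRUE(ht$p.value < alpha))
}

#' Metric-wise comparison of two validity panels
#'
#' @param panelA,panelB results of [validityPanel()].
#' @param metrics metric columns to compare.
#' @param alpha significance level.
#' @return data.frame: metric, method, statistic, p_value, significant.
#' @export
compareEnsembles <- function(panelA, panelB, metrics = PANEL_METRICS,
                             alpha = 0.05) {
  do.call(rbind, lapply(metrics, function(mt) {
    tr <- compareSamples(panelA$records[[mt]], panelB$records[[mt]], alpha)
    data.frame(metric = mt, method = tr$method, statistic = tr$statistic,
               p_value = tr$p_value, significant = tr$significant)
  }))
}
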