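#' @include utils.R
NULL

checkScores <- function(scores, labels) {
  if (length(scores) != length(labels))
    stopf("scores and labels differ in length (%d vs %d)",
          length(scores), length(labels))
  if (!all(labels %in% c(0, 1)))
    stopf("labels must be 0/1")
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic with mid-rank tie handling:
#' the probability that a random positive scores above a random negative,
#' counting ties as one half.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcome labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  checkScores(scores, labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stopf("AUROC needs both classes (have %d positives, %d negatives)",
          npos, nneg)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Computed as average precision without interpolation: the mean over
#' positives of the precision at each positive's rank, walking the
#' score-sorted list (stable order for ties).
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  checkScores(scores, labels)
  if (sum(labels == 1) == 0) stopf("AUPRC needs at least one positive")
  ord <- order(-scores)
  y <- labels[ord]
  cum <- cumsum(y)
  prec <- cum / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' PPV and sensitivity at a top-k% risk threshold
#'
#' Selects the `ceiling(k * n)` highest-scoring individuals (stable order
#' breaks ties; a flag reports when the threshold cuts through tied
#' scores). PPV is the fraction of selected individuals who are positive,
#' sensitivity the fraction of all positives selected. At `k = 1` PPV
#' equals prevalence and sensitivity is 1.
#'
#' @inheritParams auroc
#' @param k fraction of the cohort flagged as high risk, in `(0, 1]`.
#' @return list with `ppv`, `sensitivity`, `nSelected`, `tiesAtThreshold`.
#' @export
ppvAtTopFraction <- function(scores, labels, k) {
  checkScores(scores, labels)
  if (k <= 0 || k > 1) stopf("k must be in (0, 1]")
  n <- length(scores)
  m <- ceiling(k * n)
  ord <- order(-scores)      # stable: ties keep input order
  sel <- ord[seq_len(m)]
  ties <- m < n && scores[ord[m]] == scores[ord[m + 1L]]
  list(ppv = sum(labels[sel] == 1) / m,
       sensitivity = if (sum(labels == 1) == 0) NA_real_
                     else sum(labels[sel] == 1) / sum(labels == 1),
       nSelected = m, tiesAtThreshold = ties)
}

#' Threshold sweep of PPV and sensitivity
#'
#' @inheritParams auroc
#' @param ks fractions to sweep (default 0.1 to 0.6 in steps of 0.1).
#' @return data.frame with columns `k`, `ppv`, `sensitivity`, `nSelected`.
#' @export
thresholdSweep <- function(scores, labels, ks = seq(0.1, 0.6, by = 0.1)) {
  do.call(rbind, lapply(ks, function(k) {
    r <- ppvAtTopFraction(scores, labels, k)
    data.frame(k = k, ppv = r$ppv, sensitivity = r$sensitivity,
               nSelected = r$nSelected)
  }))
}

#' Point estimate with a bootstrap confidence interval
#'
#' Percentile bootstrap over individuals (1,000 replicates by default),
#' seeded for reproducibility.
#'
#' @inheritParams auroc
#' @param metric `"auroc"` or `"auprc"`.
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed.
#' @param level confidence level.
#' @return list with `metric`, `estimate`, `lower`, `upper`, `nPos`, `nNeg`.
#' @export
metricReport <- function(scores, labels, metric = c("auroc", "auprc"),
                         nBoot = 1000L, seed = 1L, level = 0.95) {
  metric <- match.arg(metric)
  f <- if (metric == "auroc") auroc else auprc
  est <- f(scores, labels)
  n <- length(scores)
  reps <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
    ix <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[ix])) < 2L) return(NA_real_)
    f(scores[ix], labels[ix])
  }, 0))
  qs <- quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  list(metric = metric, estimate = est,
       lower = unname(qs[1]), upper = unname(qs[2]),
       nPos = sum(labels == 1), nNeg = sum(labels == 0))
}

#' Stratify predictions into new-onset versus recurrent
#'
#' Partitions instances by whether the target code already occurs anywhere
#' in the context visits: the "R" (recurrent) stratum has prior history of
#' the code, the "0" (new onset) stratum does not. Metrics are computed per
#' stratum; a stratum that is empty or single-class is reported as
#' not-evaluable rather than raising an error.
#'
#' @param contextCodeSets list of character vectors: the set of codes in
#'   each instance's context (e.g. `contextCodeSets` from [doapDataset()]).
#' @param scores numeric scores for the target code.
#' @param labels 0/1 labels (target code present in the future visit).
#' @param targetCode the code being predicted.
#' @return data.frame with rows "R" and "0": `n`, `nPos`, `auroc`, `auprc`,
#'   `evaluable`.
#' @export
stratifyNewRecurrent <- function(contextCodeSets, scores, labels, targetCode) {
  checkScores(scores, labels)
  if (length(contextCodeSets) != length(scores))
    stopf("contextCodeSets and scores differ in length")
  recurrent <- vapply(contextCodeSets, function(s) targetCode %in% s, TRUE)
  strat <- function(ix) {
    ev <- length(ix) > 0L && length(unique(labels[ix])) == 2L
    data.frame(
      n = length(ix), nPos = sum(labels[ix] == 1),
      auroc = if (ev) auroc(scores[ix], labels[ix]) else NA_real_,
      auprc = if (ev) auprc(scores[ix], labels[ix]) else NA_real_,
      evaluable = ev)
  }
  out <- rbind(strat(which(recurrent)), strat(which(!recurrent)))
  rownames(out) <- NULL
  cbind(stratum = c("R", "0"), out)
}

#' Per-subgroup metric report
#'
#' Computes AUROC and AUPRC per demographic subgroup with seeded percentile
#' bootstrap confidence intervals, and flags each pair of groups whose
#' intervals overlap. Groups with fewer than two members of either class
#' are marked not-evaluable.
#'
#' @inheritParams auroc
#' @param groups subgroup label per individual.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list with `table` (data.frame: group, n, nPos, auroc, auprc and
#'   their CIs, evaluable) and `overlap` (data.frame of pairwise AUPRC CI
#'   overlap flags).
#' @export
subgroupReport <- function(scores, labels, groups, nBoot = 1000L, seed = 1L) {
  checkScores(scores, labels)
  if (length(groups) != length(scores))
    stopf("groups and scores differ in length")
  gs <- sort(unique(as.character(groups)))
  rows <- lapply(seq_along(gs), function(gi) {
    ix <- which(as.character(groups) == gs[gi])
    ev <- sum(labels[ix] == 1) >= 2 && sum(labels[ix] == 0) >= 2
    if (!ev)
      return(data.frame(group = gs[gi], n = length(ix),
                        nPos = sum(labels[ix] == 1), auroc = NA_real_,
                        aurocLo = NA_real_, aurocHi = NA_real_,
                        auprc = NA_real_, auprcLo = NA_real_,
                        auprcHi = NA_real_, evaluable = FALSE))
    ra <- metricReport(scores[ix], labels[ix], "auroc", nBoot,
                       deriveSeed(seed, paste0("sg.roc.", gs[gi])))
    rp <- metricReport(scores[ix], labels[ix], "auprc", nBoot,
                       deriveSeed(seed, paste0("sg.pr.", gs[gi])))
    data.frame(group = gs[gi], n = length(ix), nPos = sum(labels[ix] == 1),
               auroc = ra$estimate, aurocLo = ra$lower, aurocHi = ra$upper,
               auprc = rp$estimate, auprcLo = rp$lower, auprcHi = rp$upper,
               evaluable = TRUE)
  })
  tab <- do.call(rbind, rows)
  ov <- list()
  ev <- tab[tab$evaluable, ]
  if (nrow(ev) >= 2L)
    for (i in seq_len(nrow(ev) - 1L)) for (j in (i + 1L):nrow(ev))
      ov[[length(ov) + 1L]] <- data.frame(
        group1 = ev$group[i], group2 = ev$group[j],
        auprcOverlap = ev$auprcLo[i] <= ev$auprcHi[j] &&
          ev$auprcLo[j] <= ev$auprcHi[i])
  list(table = tab,
       overlap = if (length(ov)) do.call(rbind, ov) else
         data.frame(group1 = character(0), group2 = character(0),
                    auprcOverlap = logical(0)))
}
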