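#' @include AllClasses.R
NULL

#' Specification of a synthetic longitudinal cohort
#'
#' The generator plants recoverable statistical structure so that every
#' downstream stage can be validated without access to restricted clinical
#' data: per-patient latent comorbidity cluster memberships (drawn once per
#' patient), per-visit emission as the union of chronic-code recurrence,
#' cluster co-activation and Poisson acute noise, deterministic-lag
#' progression rules, and a rare outcome driven by a per-visit hazard that
#' trigger codes multiply.
#'
#' The code universe is `C001..C<vocabSize>`: cluster `k` owns codes
#' `C[(k-1)*clusterSize+1] .. C[k*clusterSize]`. The first member of each
#' cluster is chronic, with background onset and recency-driven recurrence
#' (see the slots below); the remaining members co-activate at every visit
#' for patients carrying the cluster; codes above `nClusters*clusterSize`
#' are acute noise codes.
#'
#' Within a visit, codes are listed in priority order: outcome code first
#' (if it fires), then progression consequences (an acute triggered event
#' presents as the leading diagnosis), then chronic recurrences, then
#' cluster co-activations, then noise; each sub-block is shuffled by the
#' cohort's generator stream.
#'
#' @slot nPatients,vocabSize,nClusters,clusterSize,seed integers.
#' @slot membershipProb probability a patient carries each cluster (at least
#'   one cluster is always assigned).
#' @slot clusterCoactivation probability each member code of a carried
#'   cluster is emitted at a given visit.
#' @slot chronicPersistence probability a chronic code present at the
#'   previous visit recurs at the next one; a chronic code that lapses is
#'   mostly resolved and revives with probability `chronicPersistence/16`,
#'   so recurrence is predictable from the recent history.
#' @slot chronicOnsetRate per-visit probability that a never-seen chronic
#'   code onsets, for every patient. Onset is deliberately a background
#'   process, independent of cluster membership: new onset of a chronic
#'   condition is largely unpredictable, while its recurrence is highly
#'   predictable — the asymmetry that new-vs-recurrent stratification
#'   measures.
#' @slot noiseRate Poisson mean of acute noise codes per visit.
#' @slot progressionRules data.frame with columns `trigger`, `consequence`,
#'   `lag` (visits), `prob`.
#' @slot outcomeCode,outcomeTriggerCodes outcome code string and the codes
#'   multiplying its hazard.
#' @slot outcomeBaseRate per-eligible-visit outcome hazard (visits 2..n).
#' @slot outcomeHazardRatio hazard multiplier once a trigger code has
#'   appeared in the history (>= 1).
#' @slot visitsMin,visitsMax,visitsMean,visitsSd discretized-normal
#'   visit-count distribution (defaults mean 10.1, sd 3.3 — the shape of a
#'   typical multi-visit clinical cohort).
#' @slot gapMeanlog,gapSdlog discretized lognormal inter-visit gap (days).
#' @slot firstDateMin,firstDateMax window for the uniform first visit date.
#' @slot demographicsDists named list of category-probability vectors for
#'   `gender`, `race`, `marital_status`.
#' @slot ageMean,ageSd,ageMin,ageMax rounded-normal age distribution.
#' @export
setClass("SyntheticSpec",
  representation(nPatients = "integer", vocabSize = "integer",
                 nClusters = "integer", clusterSize = "integer",
                 membershipProb = "numeric", clusterCoactivation = "numeric",
                 chronicPersistence = "numeric", chronicOnsetRate = "numeric",
                 noiseRate = "numeric",
                 progressionRules = "data.frame", outcomeCode = "character",
                 outcomeBaseRate = "numeric",
                 outcomeTriggerCodes = "character",
                 outcomeHazardRatio = "numeric",
                 visitsMin = "integer", visitsMax = "integer",
                 visitsMean = "numeric", visitsSd = "numeric",
                 gapMeanlog = "numeric", gapSdlog = "numeric",
                 firstDateMin = "Date", firstDateMax = "Date",
                 demographicsDists = "list", ageMean = "numeric",
                 ageSd = "numeric", ageMin = "integer", ageMax = "integer",
                 seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  pr <- c(object@membershipProb, object@clusterCoactivation,
          object@chronicPersistence, object@chronicOnsetRate,
          object@outcomeBaseRate)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "all probabilities must be in [0, 1]")
  if (object@outcomeHazardRatio < 1)
    msg <- c(msg, "outcomeHazardRatio must be >= 1")
  if (object@vocabSize < object@nClusters * object@clusterSize)
    msg <- c(msg, "vocabSize must be >= nClusters * clusterSize")
  if (object@visitsMin < 1L || object@visitsMax < object@visitsMin)
    msg <- c(msg, "visit-count range must satisfy 1 <= min <= max")
  if (nrow(object@progressionRules) &&
      !all(c("trigger", "consequence", "lag", "prob") %in%
           colnames(object@progressionRules)))
    msg <- c(msg, "progressionRules needs columns trigger, consequence, lag, prob")
  if (nrow(object@progressionRules) &&
      any(object@progressionRules$prob < 0 | object@progressionRules$prob > 1))
    msg <- c(msg, "progression rule probabilities must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticSpec constructor. Defaults emulate the statistical
#'   shape of a multi-visit clinical cohort: mean 10.1 (sd 3.3) visits per
#'   patient and a rare outcome whose patient-level prevalence works out to
#'   roughly 1.9\% (base rate 8e-4/visit, hazard ratio 5.5, with just under
#'   half of patients acquiring a trigger code through cluster membership
#'   or background chronic onset).
#' @param nPatients,vocabSize,nClusters,clusterSize,membershipProb see slots.
#' @param clusterCoactivation,chronicPersistence,chronicOnsetRate see slots.
#' @param noiseRate,progressionRules see slots.
#' @param outcomeCode,outcomeBaseRate,outcomeTriggerCodes,outcomeHazardRatio see slots.
#' @param visitsMin,visitsMax,visitsMean,visitsSd,gapMeanlog,gapSdlog see slots.
#' @param firstDateMin,firstDateMax,demographicsDists see slots.
#' @param ageMean,ageSd,ageMin,ageMax,seed see slots.
#' @export
syntheticSpec <- function(nPatients = 1000L, vocabSize = 200L,
                          nClusters = 8L, clusterSize = 5L,
                          membershipProb = 0.25, clusterCoactivation = 0.5,
                          chronicPersistence = 0.8, chronicOnsetRate = 0.03,
                          noiseRate = 2,
                          progressionRules = data.frame(
                            trigger = character(0), consequence = character(0),
                            lag = integer(0), prob = numeric(0)),
                          outcomeCode = "OUTCOME", outcomeBaseRate = 8e-4,
                          outcomeTriggerCodes = sprintf("C%03d",
                                                        seq_len(clusterSize)),
                          outcomeHazardRatio = 5.5,
                          visitsMin = 2L, visitsMax = 20L,
                          visitsMean = 10.1, visitsSd = 3.3,
                          gapMeanlog = log(30), gapSdlog = 0.6,
                          firstDateMin = as.Date("2016-01-01"),
                          firstDateMax = as.Date("2018-12-31"),
                          demographicsDists = list(
                            gender = c(male = 0.88, female = 0.12),
                            race = c(white = 0.7, black = 0.18, other = 0.12),
                            marital_status = c(married = 0.5, single = 0.3,
                                               divorced = 0.15, widowed = 0.05)),
                          ageMean = 55, ageSd = 14, ageMin = 20L, ageMax = 95L,
                          seed = 1L) {
  new("SyntheticSpec", nPatients = as.integer(nPatients),
      vocabSize = as.integer(vocabSize), nClusters = as.integer(nClusters),
      clusterSize = as.integer(clusterSize), membershipProb = membershipProb,
      clusterCoactivation = clusterCoactivation,
      chronicPersistence = chronicPersistence,
      chronicOnsetRate = chronicOnsetRate, noiseRate = noiseRate,
      progressionRules = progressionRules, outcomeCode = outcomeCode,
      outcomeBaseRate = outcomeBaseRate,
      outcomeTriggerCodes = as.character(outcomeTriggerCodes),
      outcomeHazardRatio = outcomeHazardRatio,
      visitsMin = as.integer(visitsMin), visitsMax = as.integer(visitsMax),
      visitsMean = visitsMean, visitsSd = visitsSd, gapMeanlog = gapMeanlog,
      gapSdlog = gapSdlog, firstDateMin = as.Date(firstDateMin),
      firstDateMax = as.Date(firstDateMax),
      demographicsDists = demographicsDists, ageMean = ageMean, ageSd = ageSd,
      ageMin = as.integer(ageMin), ageMax = as.integer(ageMax),
      seed = as.integer(seed))
}

specCodes <- function(spec) sprintf("C%03d", seq_len(spec@vocabSize))

#' @describeIn syntheticSpec chronic codes of a spec (first member of each
#'   cluster).
#' @param spec a [SyntheticSpec-class].
#' @export
chronicCodes <- function(spec)
  sprintf("C%03d", (seq_len(spec@nClusters) - 1L) * spec@clusterSize + 1L)

#' @describeIn syntheticSpec member codes of cluster `k`.
#' @param k cluster index.
#' @export
clusterCodes <- function(spec, k)
  sprintf("C%03d", (k - 1L) * spec@clusterSize + seq_len(spec@clusterSize))

sampleVisitCount <- function(spec)
  max(spec@visitsMin,
      min(spec@visitsMax, as.integer(round(rnorm(1, spec@visitsMean,
                                                 spec@visitsSd)))))

#' Generate a synthetic cohort
#'
#' Deterministic given `spec@seed` (one generator stream for the whole
#' cohort; no ambient randomness is consumed). The outcome hazard applies at
#' visits 2..n; when the outcome fires, its code is placed first (primary
#' diagnosis) in that visit and the record is truncated there, so the
#' outcome visit is always the final visit of a case.
#'
#' @param spec a [SyntheticSpec-class].
#' @return an [EHRCohort-class].
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  if (spec@nPatients < 1L) stopf("nPatients must be >= 1")
  chronicSet <- chronicCodes(spec)
  noiseStart <- spec@nClusters * spec@clusterSize + 1L
  if (noiseStart > spec@vocabSize && spec@noiseRate > 0)
    stopf("infeasible spec: noiseRate > 0 but no noise codes available")
  noisePool <- if (noiseStart <= spec@vocabSize)
    sprintf("C%03d", noiseStart:spec@vocabSize) else character(0)
  rules <- spec@progressionRules
  dd <- spec@demographicsDists
  windowDays <- as.integer(spec@firstDateMax - spec@firstDateMin)
  if (windowDays < 0) stopf("infeasible spec: firstDateMax < firstDateMin")

  pats <- withSeed(spec@seed, lapply(seq_len(spec@nPatients), function(i) {
    demo <- list(
      gender = sample(names(dd$gender), 1L, prob = dd$gender),
      age = as.integer(max(spec@ageMin, min(spec@ageMax,
                          round(rnorm(1, spec@ageMean, spec@ageSd))))),
      race = sample(names(dd$race), 1L, prob = dd$race),
      marital_status = sample(names(dd$marital_status), 1L,
                              prob = dd$marital_status))
    nv <- sampleVisitCount(spec)
    firstDate <- spec@firstDateMin + as.integer(floor(runif(1) *
                                                      (windowDays + 1)))
    gaps <- pmax(1L, as.integer(ceiling(rlnorm(nv - 1L, spec@gapMeanlog,
                                               spec@gapSdlog))))
    dates <- firstDate + c(0L, cumsum(gaps))

    member <- which(rbinom(spec@nClusters, 1L, spec@membershipProb) == 1L)
    if (!length(member))
      member <- sample.int(spec@nClusters, 1L)
    memberCodes <- unlist(lapply(member, clusterCodes, spec = spec))

    chronicSeen <- character(0)
    prevCodes <- character(0)
    pending <- vector("list", nv)   # consequences scheduled per visit
    historyCodes <- character(0)
    visits <- vector("list", nv)
    for (t in seq_len(nv)) {
      # chronic recurrence is recency-driven: a chronic code present at the
      # previous visit recurs with the persistence probability; one that
      # has lapsed is mostly resolved and revives only rarely
      # (persistence/16). This makes recurrence predictable from the
      # observable recent history rather than an unpredictable lapse.
      pRec <- ifelse(chronicSeen %in% prevCodes, spec@chronicPersistence,
                     spec@chronicPersistence / 16)
      recur <- chronicSeen[runif(length(chronicSeen)) < pRec]
      # chronic onset is background (membership-independent): any never-seen
      # chronic code can onset at any visit
      unseen <- setdiff(chronicSet, chronicSeen)
      onset <- unseen[runif(length(unseen)) < spec@chronicOnsetRate]
      chronicBlock <- c(recur, onset)
      if (length(chronicBlock) > 1L) chronicBlock <- sample(chronicBlock)
      # cluster co-activation drives the non-chronic member codes
      clusterCand <- memberCodes[!(memberCodes %in% chronicSet)]
      clusterBlock <- clusterCand[runif(length(clusterCand)) <
                                    spec@clusterCoactivation]
      if (length(clusterBlock) > 1L) clusterBlock <- sample(clusterBlock)
      consBlock <- character(0)
      for (cons in pending[[t]])
        if (runif(1) < cons$prob) consBlock <- c(consBlock, cons$code)
      nNoise <- if (length(noisePool)) min(rpois(1, spec@noiseRate),
                                           length(noisePool)) else 0L
      noiseBlock <- if (nNoise > 0L) sample(noisePool, nNoise) else character(0)

      # outcome hazard at visits 2..n, driven by the history before this visit
      fired <- FALSE
      if (t >= 2L && spec@outcomeBaseRate > 0) {
        hazard <- spec@outcomeBaseRate *
          if (length(intersect(historyCodes, spec@outcomeTriggerCodes)))
            spec@outcomeHazardRatio else 1
        fired <- runif(1) < hazard
      }
      codes <- c(if (fired) spec@outcomeCode, consBlock, chronicBlock,
                 clusterBlock, noiseBlock)
      codes <- codes[!duplicated(codes)]
      if (!length(codes)) codes <- if (length(noisePool))
        sample(noisePool, 1L) else memberCodes[1L]
      visits[[t]] <- list(date = dates[t], codes = codes)

      chronicSeen <- union(chronicSeen, intersect(codes, chronicSet))
      historyCodes <- union(historyCodes, codes)
      prevCodes <- codes
      if (nrow(rules) && t < nv)
        for (r in seq_len(nrow(rules)))
          if (rules$trigger[r] %in% codes) {
            tgt <- t + rules$lag[r]
            if (tgt <= nv)
              pending[[tgt]] <- c(pending[[tgt]],
                                  list(list(code = rules$consequence[r],
                                            prob = rules$prob[r])))
          }
      if (fired) { visits <- visits[seq_len(t)]; break }
    }
    list(patient_id = sprintf("P%06d", i), demographics = demo,
         visits = visits)
  }))
  cohort <- EHRCohort(pats)
  validObject(cohort)
  cohort
}

#' Expected outcome prevalence under the hazard model
#'
#' Closed-form patient-level outcome prevalence implied by a spec,
#' marginalizing over the discretized-normal visit-count distribution:
#' `E_n[1 - (1 - r)^(n-1)]` with `r` the per-eligible-visit base rate. Exact
#' when `outcomeHazardRatio` is 1 or no trigger codes are configured (the
#' trigger-carrier fraction is not available in closed form otherwise).
#'
#' @param spec a [SyntheticSpec-class].
#' @return expected fraction of patients whose record contains the outcome.
#' @export
expectedOutcomePrevalence <- function(spec) {
  if (spec@outcomeHazardRatio > 1 && length(spec@outcomeTriggerCodes))
    warning("hazard ratio > 1 with trigger codes: value is the base-rate-only lower bound")
  ks <- spec@visitsMin:spec@visitsMax
  lo <- stats::pnorm(ks - 0.5, spec@visitsMean, spec@visitsSd)
  hi <- stats::pnorm(ks + 0.5, spec@visitsMean, spec@visitsSd)
  pmf <- hi - lo
  pmf[1] <- hi[1]                       # clipping mass
  pmf[length(ks)] <- 1 - lo[length(ks)]
  pmf <- pmf / sum(pmf)
  # the record truncates at the outcome, so eligible visits form a geometric
  # scan over visits 2..n
  sum(pmf * (1 - (1 - spec@outcomeBaseRate)^(ks - 1)))
}

#' Summarize a cohort
#'
#' Reports patient and visit counts, patient-level per-code prevalence, the
#' top pairwise code co-occurrences (patient-level Jaccard), and outcome
#' prevalence.
#'
#' @param cohort an [EHRCohort-class].
#' @param outcomeCode code treated as the outcome (default `"OUTCOME"`).
#' @param topPairs number of top Jaccard pairs to report.
#' @param minPrevalence codes below this patient-level prevalence are
#'   excluded from the pairwise table (keeps it readable).
#' @return a list with elements `nPatients`, `visitMean`, `visitSd`,
#'   `meanCodesPerVisit`, `codePrevalence` (named, decreasing),
#'   `outcomePrevalence`, and `topJaccard` (data.frame `code1,code2,jaccard`).
#' @export
cohortSummary <- function(cohort, outcomeCode = "OUTCOME", topPairs = 10L,
                          minPrevalence = 0.02) {
  if (nPatients(cohort) == 0L) stopf("cohort is empty")
  vc <- visitCounts(cohort)
  sets <- lapply(cohort@patients, function(p)
    unique(unlist(lapply(p$visits, `[[`, "codes"))))
  codes <- sort(unique(unlist(sets)))
  M <- matrix(0L, length(sets), length(codes),
              dimnames = list(NULL, codes))
  for (i in seq_along(sets)) M[i, sets[[i]]] <- 1L
  prev <- colMeans(M)
  keep <- names(prev)[prev >= minPrevalence]
  topJ <- data.frame(code1 = character(0), code2 = character(0),
                     jaccard = numeric(0))
  if (length(keep) >= 2L) {
    Mk <- M[, keep, drop = FALSE]
    inter <- crossprod(Mk)
    n <- colSums(Mk)
    uni <- outer(n, n, "+") - inter
    J <- ifelse(uni > 0, inter / uni, 0)
    J[lower.tri(J, diag = TRUE)] <- NA
    ord <- order(J, decreasing = TRUE, na.last = NA)
    take <- head(ord, topPairs)
    idx <- arrayInd(take, dim(J))
    topJ <- data.frame(code1 = keep[idx[, 1]], code2 = keep[idx[, 2]],
                       jaccard = J[take], row.names = NULL)
  }
  ncodes <- unlist(lapply(cohort@patients, function(p)
    vapply(p$visits, function(v) length(v$codes), 0L)))
  list(nPatients = nPatients(cohort), visitMean = mean(vc), visitSd = sd(vc),
       meanCodesPerVisit = mean(ncodes),
       codePrevalence = sort(prev, decreasing = TRUE),
       outcomePrevalence = unname(ifelse(outcomeCode %in% names(prev),
                                         prev[outcomeCode], 0)),
       topJaccard = topJ)
}

#' Patient-level Jaccard co-occurrence of two codes
#'
#' @param cohort an [EHRCohort-class].
#' @param codeA,codeB code strings.
#' @return `|A intersect B| / |A union B|` over patients carrying each code
#'   anywhere in their record; 0 when the union is empty.
#' @export
codeJaccard <- function(cohort, codeA, codeB) {
  sets <- lapply(cohort@patients, function(p)
    unique(unlist(lapply(p$visits, `[[`, "codes"))))
  a <- vapply(sets, function(s) codeA %in% s, TRUE)
  b <- vapply(sets, function(s) codeB %in% s, TRUE)
  u <- sum(a | b)
  if (u == 0) 0 else sum(a & b) / u
}
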