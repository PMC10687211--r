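#' @include AllClasses.R
NULL

# Demographic attributes become individual tokens of the form field=value;
# ages are binned by decade so the vocabulary stays bounded.
ageBin <- function(age) sprintf("age=%d-%d", 10L * (age %/% 10L),
                                10L * (age %/% 10L) + 9L)

#' Demographic tokens for a patient
#'
#' @param demographics list with `gender`, `age`, `race`, `marital_status`.
#' @return character vector of four `field=value` tokens (age decade-binned).
#' @export
demographicTokens <- function(demographics) {
  c(paste0("gender=", demographics$gender),
    ageBin(demographics$age),
    paste0("race=", demographics$race),
    paste0("marital_status=", demographics$marital_status))
}

#' Build a token vocabulary from a cohort
#'
#' Special tokens take reserved ids 0..4, followed by every demographic
#' `field=value` token observed in the cohort (sorted), followed by codes
#' sorted by descending occurrence count with ties broken lexically. Codes
#' occurring fewer than `minCount` times are excluded and encode to `[UNK]`.
#' Deterministic given the cohort.
#'
#' @param cohort an [EHRCohort-class].
#' @param minCount non-negative integer occurrence threshold.
#' @return a [CodeVocabulary-class].
#' @export
buildVocabulary <- function(cohort, minCount = 0L) {
  if (nPatients(cohort) == 0L) stopf("cohort is empty")
  demo <- sort(unique(unlist(lapply(cohort@patients, function(p)
    demographicTokens(p$demographics)))))
  counts <- table(unlist(lapply(cohort@patients, function(p)
    unlist(lapply(p$visits, `[[`, "codes")))))
  counts <- counts[counts >= max(minCount, 1L)]
  ord <- order(-as.integer(counts), names(counts))
  new("CodeVocabulary",
      tokens = c(SPECIAL_TOKENS, demo, names(counts)[ord]),
      minCount = as.integer(minCount))
}

#' Encode tokens to integer ids
#'
#' @param vocab a [CodeVocabulary-class].
#' @param tokens character vector.
#' @return 0-based integer ids; tokens absent from the vocabulary map to
#'   `[UNK]` (id 4).
#' @export
encodeTokens <- function(vocab, tokens) {
  idx <- match(tokens, vocab@tokens)
  ids <- idx - 1L
  ids[is.na(idx)] <- UNK_ID
  ids
}

#' @describeIn encodeTokens inverse mapping (ids to tokens).
#' @param ids 0-based integer ids.
#' @export
decodeTokens <- function(vocab, ids) vocab@tokens[ids + 1L]

#' Write / read a vocabulary as a two-column text file
#'
#' @param vocab a [CodeVocabulary-class].
#' @param path file path (tab-separated `token<TAB>id`).
#' @return `path` (write) or a [CodeVocabulary-class] (read).
#' @export
writeVocabulary <- function(vocab, path) {
  writeLines(sprintf("%s\t%d", vocab@tokens, seq_along(vocab@tokens) - 1L),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    quote = "", col.names = c("token", "id"))
  tab <- tab[order(tab$id), ]
  new("CodeVocabulary", tokens = tab$token, minCount = 0L)
}

#' Per-visit time values
#'
#' @param dates `Date` vector of visit dates (ascending) or a list of visits.
#' @param mode `"date"` (integer days since 1970-01-01), `"daysdiff"` (days
#'   between the visit and the most recent visit, so the last visit gets 0
#'   and earlier visits positive values) or `"none"` (all 0).
#' @return numeric vector, one value per visit.
#' @export
computeTimeValues <- function(dates, mode = c("daysdiff", "date", "none")) {
  mode <- match.arg(mode)
  if (is.list(dates))
    dates <- as.Date(vapply(dates, function(v) as.character(as.Date(v$date)),
                            ""))
  dates <- as.Date(dates)
  switch(mode,
         date = as.numeric(dates),
         daysdiff = as.numeric(dates[length(dates)] - dates),
         none = rep(0, length(dates)))
}

# Encode the demographics block plus visits 1..k of a patient as one
# context sequence (token ids, per-token visit index and time value),
# truncating oldest clinical tokens first when over maxLen.
encodeContext <- function(patient, k, vocab, timeMode, maxLen) {
  visits <- patient$visits[seq_len(k)]
  dtoks <- demographicTokens(patient$demographics)
  tvals <- computeTimeValues(visits, timeMode)
  ncv <- vapply(visits, function(v) length(v$codes), 0L)
  toks <- c(dtoks, unlist(lapply(visits, `[[`, "codes")))
  vidx <- c(rep(0L, length(dtoks)), rep(seq_len(k), ncv))
  tv <- c(rep(0, length(dtoks)), rep(tvals, ncv))
  if (length(toks) > maxLen) {
    # drop oldest clinical tokens first; the demographics block is retained
    nKeep <- maxLen - length(dtoks)
    clin <- (length(dtoks) + 1L):length(toks)
    keep <- c(seq_along(dtoks), utils::tail(clin, nKeep))
    toks <- toks[keep]; vidx <- vidx[keep]; tv <- tv[keep]
  }
  list(tokens = toks, ids = encodeTokens(vocab, toks), vidx = vidx, tv = tv)
}

# Internal constructor of one (context, target-visit) instance.
makeInstance <- function(patient, vocab, k, timeMode, maxLen) {
  ctx <- encodeContext(patient, k, vocab, timeMode, maxLen)
  target <- patient$visits[[k + 1L]]
  list(patientId = patient$patient_id,
       contextTokens = ctx$tokens,
       contextTokenIds = ctx$ids,
       contextVisitIndex = ctx$vidx,
       contextTimeValue = ctx$tv,
       isCodeToken = ctx$vidx > 0L,
       targetCodes = target$codes,
       targetCodeIds = encodeTokens(vocab, target$codes),
       targetVisitDate = as.Date(target$date),
       lastContextDate = as.Date(patient$visits[[k]]$date),
       nContextVisits = k,
       timeMode = timeMode)
}

#' Expand a patient into recursive next-visit instances
#'
#' An n-visit patient yields exactly n-1 instances: instance k has context =
#' demographics block (visit index 0, time value 0) plus visits 1..k, and
#' target = the priority-ordered codes of visit k+1. Contexts longer than
#' `maxLen` tokens are truncated by dropping the oldest clinical-visit
#' tokens first; the demographics block is always retained and surviving
#' tokens keep their order.
#'
#' @param patient a patient record (see [EHRCohort-class]).
#' @param vocab a [CodeVocabulary-class].
#' @param timeMode time feature mode, see [computeTimeValues()].
#' @param maxLen maximum context length in tokens (default 512).
#' @return list of instances; patients with fewer than 2 visits yield an
#'   empty list with a warning (they fall outside the inclusion rule).
#' @export
expandRecursiveInstances <- function(patient, vocab,
                                     timeMode = c("daysdiff", "date", "none"),
                                     maxLen = 512L) {
  timeMode <- match.arg(timeMode)
  n <- length(patient$visits)
  if (n < 2L) {
    warning(sprintf("patient %s has %d visit(s); skipped (needs >= 2)",
                    patient$patient_id, n))
    return(list())
  }
  lapply(seq_len(n - 1L), makeInstance, patient = patient, vocab = vocab,
         timeMode = timeMode, maxLen = maxLen)
}

#' @describeIn expandRecursiveInstances expand every eligible patient of a
#'   cohort (patients with < 2 visits are skipped silently here; use
#'   [filterMinVisits()] upstream to make the inclusion rule explicit).
#' @param cohort an [EHRCohort-class].
#' @export
expandCohortInstances <- function(cohort, vocab,
                                  timeMode = c("daysdiff", "date", "none"),
                                  maxLen = 512L) {
  timeMode <- match.arg(timeMode)
  ok <- visitCounts(cohort) >= 2L
  unlist(lapply(cohort@patients[ok], expandRecursiveInstances, vocab = vocab,
                timeMode = timeMode, maxLen = maxLen),
         recursive = FALSE)
}

#' Corrupt an instance for denoising pretraining
#'
#' Under `visit_mask` the target visit is withheld from the encoder entirely
#' (it is the decoder's generation target) and each remaining context visit
#' is independently dropped with probability `visitDropRate`, always leaving
#' at least one context visit; surviving visits are re-indexed compactly
#' (1..k) and keep their original time values. Under `code_mask` the target
#' visit is appended to the encoder input (time values re-expressed so the
#' target visit is the reference when `timeMode = "daysdiff"`), each code
#' token is independently replaced by `[MASK]` with probability
#' `codeMaskRate` (demographic tokens are never masked), the masked codes
#' become the prediction targets in their original order, and selection is
#' resampled if it comes up empty so there is always at least one target.
#'
#' Randomness is drawn from the caller's RNG stream; seed upstream.
#'
#' @param instance an instance from [expandRecursiveInstances()].
#' @param cspec a [CorruptionSpec-class].
#' @return list with `encIds`, `encVisitIndex`, `encTimeValue` (the corrupted
#'   encoder input), `targetIds` (decoder / masked-LM prediction targets, in
#'   order), `maskPositions` (code_mask only), `scheme`, `nDroppedVisits`
#'   (visit_mask only).
#' @export
corruptForPretraining <- function(instance, cspec) {
  stopifnot(is(cspec, "CorruptionSpec"))
  if (cspec@scheme == "visit_mask") {
    nv <- instance$nContextVisits
    drop <- runif(nv) < cspec@visitDropRate
    if (all(drop)) drop[sample.int(nv, 1L)] <- FALSE
    keepTok <- instance$contextVisitIndex == 0L |
      !drop[pmax(instance$contextVisitIndex, 1L)]
    vidx <- instance$contextVisitIndex[keepTok]
    # re-index surviving visits compactly, demographics stay at 0
    surv <- sort(unique(vidx[vidx > 0L]))
    vmap <- integer(nv); vmap[surv] <- seq_along(surv)
    vidx[vidx > 0L] <- vmap[vidx[vidx > 0L]]
    list(encIds = instance$contextTokenIds[keepTok],
         encVisitIndex = vidx,
         encTimeValue = instance$contextTimeValue[keepTok],
         targetIds = instance$targetCodeIds,
         maskPositions = integer(0),
         scheme = "visit_mask",
         nDroppedVisits = sum(drop), nContextVisits = nv)
  } else {
    delta <- as.numeric(instance$targetVisitDate - instance$lastContextDate)
    tvTarget <- switch(instance$timeMode,
                       daysdiff = 0,
                       date = as.numeric(instance$targetVisitDate),
                       none = 0)
    tvCtx <- switch(instance$timeMode,
                    daysdiff = instance$contextTimeValue + delta,
                    instance$contextTimeValue)
    m <- length(instance$targetCodeIds)
    ids <- c(instance$contextTokenIds, instance$targetCodeIds)
    vidx <- c(instance$contextVisitIndex,
              rep(instance$nContextVisits + 1L, m))
    tv <- c(tvCtx, rep(tvTarget, m))
    isCode <- c(instance$isCodeToken, rep(TRUE, m))
    cand <- which(isCode)
    sel <- logical(length(cand))
    for (i in 1:100) {
      sel <- runif(length(cand)) < cspec@codeMaskRate
      if (any(sel)) break
    }
    if (!any(sel)) sel[sample.int(length(cand), 1L)] <- TRUE
    pos <- cand[sel]
    targets <- ids[pos]
    ids[pos] <- MASK_ID
    list(encIds = ids, encVisitIndex = vidx, encTimeValue = tv,
         targetIds = targets, maskPositions = pos, scheme = "code_mask",
         nDroppedVisits = 0L, nContextVisits = instance$nContextVisits + 1L)
  }
}

# Uncorrupted encoder view of an instance (used for classification and
# generation).
instanceEncoderInput <- function(instance)
  list(encIds = instance$contextTokenIds,
       encVisitIndex = instance$contextVisitIndex,
       encTimeValue = instance$contextTimeValue)

#' Encoder input for whole-record classification
#'
#' Demographics block plus every visit of the record (the caller truncates
#' the record to the prediction point), as one encoder input.
#'
#' @param patient a patient record.
#' @param vocab a [CodeVocabulary-class].
#' @param timeMode see [computeTimeValues()].
#' @param maxLen maximum length in tokens.
#' @return list with `encIds`, `encVisitIndex`, `encTimeValue`.
#' @export
classifierInput <- function(patient, vocab,
                            timeMode = c("daysdiff", "date", "none"),
                            maxLen = 512L) {
  timeMode <- match.arg(timeMode)
  ctx <- encodeContext(patient, length(patient$visits), vocab, timeMode,
                       maxLen)
  list(encIds = ctx$ids, encVisitIndex = ctx$vidx, encTimeValue = ctx$tv)
}
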