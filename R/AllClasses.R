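#' @include utils.R
NULL

DEMOGRAPHIC_FIELDS <- c("gender", "age", "race", "marital_status")

# ---- patient-record validation (patients are plain lists inside EHRCohort) --

validatePatient <- function(p, where = "") {
  msg <- character(0)
  push <- function(m) msg <<- c(msg, paste0(where, m))
  if (!is.character(p$patient_id) || length(p$patient_id) != 1L ||
      !nzchar(p$patient_id))
    push("patient_id must be a non-empty string")
  d <- p$demographics
  if (!is.list(d) || !all(DEMOGRAPHIC_FIELDS %in% names(d))) {
    push("demographics must contain gender, age, race, marital_status")
  } else {
    age <- d$age
    if (!is.numeric(age) || length(age) != 1L || is.na(age) ||
        age != round(age) || age < 0 || age > 130)
      push("age must be an integer in [0, 130]")
    for (f in setdiff(DEMOGRAPHIC_FIELDS, "age"))
      if (!is.character(d[[f]]) || length(d[[f]]) != 1L || !nzchar(d[[f]]))
        push(sprintf("%s must be a non-empty string", f))
  }
  if (!is.list(p$visits) || length(p$visits) == 0L) {
    push("visits must be a non-empty list")
  } else {
    dates <- vapply(p$visits, function(v) as.numeric(as.Date(v$date)), 0)
    if (anyNA(dates)) push("visit dates must be valid dates")
    else if (any(diff(dates) <= 0))
      push("visit dates must be strictly increasing")
    for (i in seq_along(p$visits)) {
      codes <- p$visits[[i]]$codes
      if (!is.character(codes) || length(codes) == 0L || any(!nzchar(codes)))
        push(sprintf("visit %d has an empty or invalid code list", i))
      else if (anyDuplicated(codes))
        push(sprintf("visit %d has duplicate codes", i))
    }
  }
  msg
}

# ---- EHRCohort ---------------------------------------------------------------

#' Cohort of longitudinal patient records
#'
#' An `EHRCohort` holds a list of patient records, each a list with elements
#' `patient_id` (string), `demographics` (list with `gender`, `age`, `race`,
#' `marital_status`) and `visits` (date-ascending list of visits, each with a
#' `date` and a character vector `codes` of diagnosis codes ordered from
#' highest to lowest priority; element 1 is the primary diagnosis).
#'
#' @slot patients list of patient records.
#' @slot indexDate `Date` used as the cohort index date for ages; by
#'   convention the latest visit date in the cohort.
#' @export
setClass("EHRCohort",
  representation(patients = "list", indexDate = "Date"),
  prototype(patients = list(), indexDate = as.Date("1970-01-01")))

setValidity("EHRCohort", function(object) {
  ids <- vapply(object@patients, function(p) p$patient_id %||% NA_character_,
                NA_character_)
  msg <- character(0)
  if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate patient_id: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (i in seq_along(object@patients))
    msg <- c(msg, validatePatient(object@patients[[i]],
                                  sprintf("patient %s: ", ids[i])))
  if (length(msg)) msg else TRUE
})

#' Construct an EHRCohort
#'
#' @param patients list of patient records (see [EHRCohort-class]).
#' @param indexDate cohort index `Date`; defaults to the latest visit date.
#' @return an [EHRCohort-class] object.
#' @export
EHRCohort <- function(patients, indexDate = NULL) {
  if (is.null(indexDate)) {
    all <- unlist(lapply(patients, function(p)
      vapply(p$visits, function(v) as.character(v$date), "")))
    indexDate <- if (length(all)) max(as.Date(all)) else as.Date("1970-01-01")
  }
  new("EHRCohort", patients = patients, indexDate = as.Date(indexDate))
}

#' @describeIn EHRCohort list of patient records.
#' @param cohort an `EHRCohort`.
#' @export
patients <- function(cohort) cohort@patients

#' @describeIn EHRCohort number of patients.
#' @export
nPatients <- function(cohort) length(cohort@patients)

#' @describeIn EHRCohort cohort index date.
#' @export
indexDate <- function(cohort) cohort@indexDate

#' @describeIn EHRCohort integer vector of per-patient visit counts.
#' @export
visitCounts <- function(cohort)
  vapply(cohort@patients, function(p) length(p$visits), 0L)

setMethod("show", "EHRCohort", function(object) {
  vc <- visitCounts(object)
  cat(sprintf("EHRCohort with %d patients\n", length(object@patients)))
  if (length(vc))
    cat(sprintf("  visits/patient: mean %.2f, sd %.2f, range [%d, %d]\n",
                mean(vc), sd(vc), min(vc), max(vc)))
  cat(sprintf("  index date: %s\n", format(object@indexDate)))
})

# ---- CodeVocabulary ----------------------------------------------------------

SPECIAL_TOKENS <- c("[PAD]", "[BOS]", "[EOS]", "[MASK]", "[UNK]")
PAD_ID <- 0L; BOS_ID <- 1L; EOS_ID <- 2L; MASK_ID <- 3L; UNK_ID <- 4L

#' Token vocabulary for coded EHR sequences
#'
#' Maps tokens (diagnosis codes and `field=value` demographic tokens) to
#' integer ids. Special tokens occupy fixed reserved ids 0..4:
#' `[PAD]`=0, `[BOS]`=1, `[EOS]`=2, `[MASK]`=3, `[UNK]`=4.
#'
#' @slot tokens character vector; id of `tokens[i]` is `i - 1`.
#' @slot minCount codes observed fewer than this many times at build time are
#'   not in the vocabulary and encode to `[UNK]`.
#' @export
setClass("CodeVocabulary",
  representation(tokens = "character", minCount = "integer"))

setValidity("CodeVocabulary", function(object) {
  msg <- character(0)
  if (length(object@tokens) < 5L ||
      !identical(object@tokens[1:5], SPECIAL_TOKENS))
    msg <- c(msg, "ids 0..4 must be the special tokens PAD,BOS,EOS,MASK,UNK")
  if (anyDuplicated(object@tokens))
    msg <- c(msg, "tokens must be unique (token -> id must be a bijection)")
  if (length(msg)) msg else TRUE
})

#' @describeIn CodeVocabulary total number of tokens (ids run `0..vocabSize-1`).
#' @param vocab a `CodeVocabulary`.
#' @export
vocabSize <- function(vocab) length(vocab@tokens)

#' @describeIn CodeVocabulary stable content hash, used to guard
#'   checkpoint/vocabulary compatibility.
#' @export
vocabHash <- function(vocab) contentHash(vocab@tokens)

setMethod("show", "CodeVocabulary", function(object) {
  cat(sprintf("CodeVocabulary with %d tokens (5 special), hash %s\n",
              length(object@tokens), vocabHash(object)))
})

# ---- CorruptionSpec ----------------------------------------------------------

#' Corruption scheme for denoising pretraining
#'
#' `visit_mask` withholds the whole future visit from the encoder (the
#' decoder must generate all of its codes) and additionally drops a fraction
#' of the remaining context visits. `code_mask` is the conventional
#' masked-code objective: individual codes are replaced by `[MASK]` in the
#' encoder input and become the prediction targets in their original order.
#'
#' @slot scheme `"visit_mask"` or `"code_mask"`.
#' @slot codeMaskRate fraction of codes masked under `code_mask` (default 0.25).
#' @slot visitDropRate fraction of context visits dropped under `visit_mask`
#'   (default 0.15).
#' @export
setClass("CorruptionSpec",
  representation(scheme = "character", codeMaskRate = "numeric",
                 visitDropRate = "numeric"))

setValidity("CorruptionSpec", function(object) {
  msg <- character(0)
  if (!object@scheme %in% c("visit_mask", "code_mask"))
    msg <- c(msg, "scheme must be 'visit_mask' or 'code_mask'")
  if (object@codeMaskRate < 0 || object@codeMaskRate > 1)
    msg <- c(msg, "codeMaskRate must be in [0, 1]")
  if (object@visitDropRate < 0 || object@visitDropRate > 1)
    msg <- c(msg, "visitDropRate must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn CorruptionSpec constructor with the conventional defaults
#'   (25\% code masking, 15\% visit dropping).
#' @param scheme,codeMaskRate,visitDropRate see slots.
#' @export
corruptionSpec <- function(scheme = c("visit_mask", "code_mask"),
                           codeMaskRate = 0.25, visitDropRate = 0.15) {
  new("CorruptionSpec", scheme = match.arg(scheme),
      codeMaskRate = codeMaskRate, visitDropRate = visitDropRate)
}

# ---- SeqModelConfig ----------------------------------------------------------

#' Sequence-model architecture configuration
#'
#' @slot architecture `"encoder_decoder"` (generative model with
#'   cross-attention) or `"encoder_only"` (masked-LM baseline).
#' @slot nEncoderLayers,nDecoderLayers transformer block counts. The
#'   reference configuration is 6+6; desk-scale work uses 2+2.
#' @slot dModel embedding width; must be divisible by `nHeads`.
#' @slot nHeads attention heads.
#' @slot ffnDim feed-forward inner width.
#' @slot dropout dropout rate applied to embeddings, attention output and
#'   feed-forward output during training (default 0.1).
#' @slot maxLen maximum encoder sequence length in tokens (default 512).
#' @slot maxVisits size of the learned visit-index embedding table (index 0
#'   is the demographics block).
#' @slot timeMode `"daysdiff"` (days before the most recent context visit;
#'   default, shares no absolute dates), `"date"` (days since 1970-01-01) or
#'   `"none"`.
#' @slot vocabSize token vocabulary size.
#' @slot seed integer seed for weight initialization.
#' @export
setClass("SeqModelConfig",
  representation(architecture = "character", nEncoderLayers = "integer",
                 nDecoderLayers = "integer", dModel = "integer",
                 nHeads = "integer", ffnDim = "integer", dropout = "numeric",
                 maxLen = "integer", maxVisits = "integer",
                 timeMode = "character", vocabSize = "integer",
                 seed = "integer"))

setValidity("SeqModelConfig", function(object) {
  msg <- character(0)
  if (!object@architecture %in% c("encoder_decoder", "encoder_only"))
    msg <- c(msg, "architecture must be 'encoder_decoder' or 'encoder_only'")
  if (object@dModel %% object@nHeads != 0L)
    msg <- c(msg, "dModel must be divisible by nHeads")
  if (object@architecture == "encoder_only" && object@nDecoderLayers != 0L)
    msg <- c(msg, "encoder_only requires nDecoderLayers = 0")
  if (object@architecture == "encoder_decoder" && object@nDecoderLayers < 1L)
    msg <- c(msg, "encoder_decoder requires nDecoderLayers >= 1")
  if (!object@timeMode %in% c("date", "daysdiff", "none"))
    msg <- c(msg, "timeMode must be 'date', 'daysdiff' or 'none'")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn SeqModelConfig constructor. Defaults give a desk-scale
#'   encoder-decoder (2+2 layers, width 64); the reference configuration in
#'   the literature is 6+6 layers.
#' @param architecture,nEncoderLayers,nDecoderLayers,dModel,nHeads,ffnDim see slots.
#' @param dropout,maxLen,maxVisits,timeMode,vocabSize,seed see slots.
#' @export
seqModelConfig <- function(architecture = c("encoder_decoder", "encoder_only"),
                           vocabSize,
                           nEncoderLayers = 2L,
                           nDecoderLayers = if (match.arg(architecture) ==
                             "encoder_only") 0L else 2L,
                           dModel = 64L, nHeads = 4L, ffnDim = 4L * dModel,
                           dropout = 0.1, maxLen = 512L, maxVisits = 64L,
                           timeMode = c("daysdiff", "date", "none"),
                           seed = 1L) {
  new("SeqModelConfig", architecture = match.arg(architecture),
      nEncoderLayers = as.integer(nEncoderLayers),
      nDecoderLayers = as.integer(nDecoderLayers),
      dModel = as.integer(dModel), nHeads = as.integer(nHeads),
      ffnDim = as.integer(ffnDim), dropout = dropout,
      maxLen = as.integer(maxLen), maxVisits = as.integer(maxVisits),
      timeMode = match.arg(timeMode), vocabSize = as.integer(vocabSize),
      seed = as.integer(seed))
}

# ---- EHRModel ----------------------------------------------------------------

#' A sequence model with its learned parameters
#'
#' Container for a configured (and possibly trained) model: architecture
#' config, the named list of parameter matrices, an optional task head, and
#' the hash of the vocabulary the model was built against (checked when a
#' checkpoint is reused, so a model can never silently be applied with a
#' mismatched vocabulary).
#'
#' @slot config a [SeqModelConfig-class].
#' @slot params named list of parameter matrices/vectors.
#' @slot head list describing the attached task head (`kind`, `nOutputs`),
#'   or an empty list.
#' @slot vocabHash hash of the [CodeVocabulary-class] used to build inputs.
#' @export
setClass("EHRModel",
  representation(config = "SeqModelConfig", params = "list", head = "list",
                 vocabHash = "character"))

setMethod("show", "EHRModel", function(object) {
  cat(sprintf("EHRModel (%s): %d+%d layers, d=%d, %d heads, vocab %d\n",
              object@config@architecture, object@config@nEncoderLayers,
              object@config@nDecoderLayers, object@config@dModel,
              object@config@nHeads, object@config@vocabSize))
  cat(sprintf("  parameters: %s; head: %s; vocab hash %s\n",
              format(parameterCount(object), big.mark = ","),
              if (length(object@head)) object@head$kind else "none",
              object@vocabHash))
})

#' @describeIn EHRModel model configuration.
#' @param model an `EHRModel`.
#' @export
modelConfig <- function(model) model@config

# ---- TrainConfig -------------------------------------------------------------

#' Optimization configuration
#'
#' Defaults follow the reference training recipe: learning rate 1e-3 with a
#' linear warmup over the first 10\% of steps then linear decay, dropout 0.1
#' and decoupled L2 weight decay 1e-3 (AdamW-style; decay is not applied to
#' biases or layer-norm parameters).
#'
#' @slot learningRate peak learning rate.
#' @slot warmupRatio fraction of total steps used for linear warmup.
#' @slot weightDecay decoupled L2 weight decay.
#' @slot batchSize instances per optimizer step.
#' @slot epochs passes over the instance set.
#' @slot maxSteps optional cap on optimizer steps (`Inf` = no cap).
#' @slot seed seed governing shuffling and corruption sampling.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", warmupRatio = "numeric",
                 weightDecay = "numeric", batchSize = "integer",
                 epochs = "integer", maxSteps = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@warmupRatio < 0 || object@warmupRatio >= 1)
    msg <- c(msg, "warmupRatio must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrainConfig constructor.
#' @param learningRate,warmupRatio,weightDecay,batchSize,epochs,maxSteps,seed see slots.
#' @export
trainConfig <- function(learningRate = 1e-3, warmupRatio = 0.1,
                        weightDecay = 1e-3, batchSize = 16L, epochs = 1L,
                        maxSteps = Inf, seed = 1L) {
  new("TrainConfig", learningRate = learningRate, warmupRatio = warmupRatio,
      weightDecay = weightDecay, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), maxSteps = as.numeric(maxSteps),
      seed = as.integer(seed))
}

# ---- SplitSpec ---------------------------------------------------------------

#' Patient-level dataset split specification
#'
#' The cohort is first split patient-wise into a pretraining set and a
#' held-out set (default 95:5), and the held-out set (or any labeled cohort)
#' is partitioned into train/validation/test by the default 7:1:2 ratio.
#'
#' @slot pretrainFraction fraction of patients used for pretraining.
#' @slot ratios length-3 numeric train:validation:test ratio.
#' @slot seed split seed.
#' @export
setClass("SplitSpec",
  representation(pretrainFraction = "numeric", ratios = "numeric",
                 seed = "integer"))

setValidity("SplitSpec", function(object) {
  msg <- character(0)
  if (object@pretrainFraction <= 0 || object@pretrainFraction >= 1)
    msg <- c(msg, "pretrainFraction must be in (0, 1)")
  if (length(object@ratios) != 3L || any(object@ratios <= 0))
    msg <- c(msg, "ratios must be 3 positive numbers")
  if (length(msg)) msg else TRUE
})

#' @describeIn SplitSpec constructor.
#' @param pretrainFraction,ratios,seed see slots.
#' @export
splitSpec <- function(pretrainFraction = 0.95, ratios = c(7, 1, 2), seed = 1L) {
  new("SplitSpec", pretrainFraction = pretrainFraction,
      ratios = as.numeric(ratios), seed = as.integer(seed))
}
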