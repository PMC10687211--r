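#' @include model.R sequence.R
NULL

#' Linear warmup / linear decay learning-rate schedule
#'
#' The rate rises linearly to the peak over the first
#' `ceiling(warmupRatio * totalSteps)` steps, then decays linearly towards
#' zero at `totalSteps`; at the last warmup step it equals the peak exactly.
#'
#' @param step 1-based optimizer step.
#' @param totalSteps total number of steps.
#' @param warmupRatio fraction of steps used for warmup (default 0.1).
#' @param peak peak learning rate.
#' @return the learning rate at `step`.
#' @export
lrSchedule <- function(step, totalSteps, warmupRatio = 0.1, peak = 1e-3) {
  warm <- ceiling(warmupRatio * totalSteps)
  if (warm > 0 && step <= warm) return(peak * step / warm)
  if (totalSteps == warm) return(peak)
  peak * max(0, totalSteps - step) / (totalSteps - warm)
}

# ---- AdamW ------------------------------------------------------------------

adamInit <- function(params)
  list(m = zeroLike(params), v = zeroLike(params), t = 0L,
       paths = paramPaths(params))

# Decoupled weight decay (applied to weight matrices only, not to biases or
# layer-norm parameters).
adamStep <- function(params, grads, state, lr, weightDecay,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (path in state$paths) {
    g <- treeGet(grads, path)
    if (is.null(g)) next
    m <- beta1 * state$m[[path]] + (1 - beta1) * g
    v <- beta2 * state$v[[path]] + (1 - beta2) * g * g
    state$m[[path]] <- m
    state$v[[path]] <- v
    w <- params[[path]]
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    if (!is.null(dim(w))) upd <- upd + weightDecay * w
    params[[path]] <- w - lr * upd
  }
  list(params = params, state = state)
}

# ---- splitting --------------------------------------------------------------

#' Split a cohort into pretraining and finetuning partitions
#'
#' Patient-level disjoint: a patient appears in exactly one of pretrain /
#' train / validation / test. Deterministic given `spec@seed`; sizes honor
#' the requested fractions to within one patient.
#'
#' @param cohort an [EHRCohort-class].
#' @param spec a [SplitSpec-class].
#' @return list with `pretrain`, `heldout` (both [EHRCohort-class]) and
#'   `finetune`, itself a list of `train`, `val`, `test` cohorts
#'   partitioning `heldout`.
#' @export
splitCohort <- function(cohort, spec = splitSpec()) {
  validObject(spec)
  n <- nPatients(cohort)
  perm <- withSeed(spec@seed, sample.int(n))
  nPre <- round(spec@pretrainFraction * n)
  m <- n - nPre
  if (m < 3L)
    stopf("cohort too small: %d held-out patients cannot fill a %s split",
          m, paste(spec@ratios, collapse = ":"))
  pre <- perm[seq_len(nPre)]
  rest <- perm[(nPre + 1L):n]
  # largest-remainder allocation, then guarantee non-empty strata
  prop <- spec@ratios / sum(spec@ratios)
  sizes <- floor(prop * m)
  rem <- m - sum(sizes)
  if (rem > 0) {
    give <- order(prop * m - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[give] <- sizes[give] + 1L
  }
  while (any(sizes == 0L)) {
    sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
    sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
  }
  cuts <- cumsum(sizes)
  tr <- rest[seq_len(cuts[1])]
  va <- rest[(cuts[1] + 1L):cuts[2]]
  te <- rest[(cuts[2] + 1L):cuts[3]]
  sub <- function(ix) EHRCohort(cohort@patients[sort(ix)],
                                indexDate = cohort@indexDate)
  list(pretrain = sub(pre), heldout = sub(rest),
       finetune = list(train = sub(tr), val = sub(va), test = sub(te)))
}

# ---- pretraining ------------------------------------------------------------

#' Pretrain a sequence model on recursive next-visit instances
#'
#' Expands every eligible patient (>= 2 visits) into its n-1 prefix
#' instances, corrupts each according to `corruption`, and optimizes the
#' denoising objective with AdamW under a linear warmup/decay schedule.
#' For the encoder-decoder architecture, `visit_mask` withholds the future
#' visit (the decoder regenerates its codes in priority order) and
#' `code_mask` replaces random codes with `[MASK]` in the encoder input
#' while the decoder emits the masked codes in their original order. The
#' encoder-only architecture is pretrained as a masked LM (`code_mask`).
#'
#' Fully seeded: identical cohort, configs and seed reproduce the loss
#' history bitwise in single-threaded deterministic mode.
#'
#' @param cohort an [EHRCohort-class] (patients with < 2 visits are outside
#'   the inclusion rule and are skipped).
#' @param config a [SeqModelConfig-class].
#' @param tc a [TrainConfig-class].
#' @param corruption a [CorruptionSpec-class].
#' @param vocab optional [CodeVocabulary-class]; built from `cohort` when
#'   missing.
#' @return list with `model` (trained [EHRModel-class]), `lossHistory`
#'   (numeric, one mean loss per optimizer step), `vocab`, and `manifest`
#'   (configs, seeds and hashes sufficient to reproduce the run).
#' @export
pretrain <- function(cohort, config, tc = trainConfig(),
                     corruption = corruptionSpec("visit_mask"),
                     vocab = NULL) {
  validObject(tc); validObject(corruption)
  if (is.null(vocab)) vocab <- buildVocabulary(cohort)
  if (config@vocabSize != vocabSize(vocab))
    stopf("config vocabSize (%d) does not match the vocabulary (%d)",
          config@vocabSize, vocabSize(vocab))
  encOnly <- config@architecture == "encoder_only"
  if (encOnly && corruption@scheme == "visit_mask")
    stopf("visit_mask pretraining requires the encoder_decoder architecture")
  instances <- suppressWarnings(
    expandCohortInstances(cohort, vocab, config@timeMode, config@maxLen))
  if (!length(instances)) stopf("no training instances (empty instance set)")
  model <- initModel(config, vocab)
  n <- length(instances)
  stepsPerEpoch <- ceiling(n / tc@batchSize)
  totalSteps <- min(tc@maxSteps, tc@epochs * stepsPerEpoch)
  state <- adamInit(model@params)
  lossHistory <- numeric(0)
  step <- 0L
  withSeed(tc@seed, {
    for (ep in seq_len(tc@epochs)) {
      ord <- sample.int(n)
      for (b in seq_len(stepsPerEpoch)) {
        if (step >= totalSteps) break
        ix <- ord[((b - 1L) * tc@batchSize + 1L):min(b * tc@batchSize, n)]
        corrs <- lapply(instances[ix], corruptForPretraining,
                        cspec = corruption)
        fw <- if (encOnly) fwdMlmBatch(model, corrs, training = TRUE,
                                       computeGrads = TRUE)
              else fwdGenBatch(model, corrs, training = TRUE,
                               computeGrads = TRUE)
        step <- step + 1L
        lr <- lrSchedule(step, totalSteps, tc@warmupRatio, tc@learningRate)
        up <- adamStep(model@params, fw$grads, state, lr, tc@weightDecay)
        model@params <- up$params
        state <- up$state
        lossHistory[step] <- fw$loss
      }
      if (step >= totalSteps) break
    }
  })
  manifest <- list(
    stage = "pretrain",
    architecture = config@architecture,
    scheme = corruption@scheme,
    codeMaskRate = corruption@codeMaskRate,
    visitDropRate = corruption@visitDropRate,
    modelSeed = config@seed, trainSeed = tc@seed,
    vocabHash = vocabHash(vocab),
    nPatients = nPatients(cohort), nInstances = n,
    totalSteps = as.integer(totalSteps),
    learningRate = tc@learningRate, warmupRatio = tc@warmupRatio,
    weightDecay = tc@weightDecay, batchSize = tc@batchSize,
    package = as.character(utils::packageVersion("nextvisit")))
  list(model = model, lossHistory = lossHistory, vocab = vocab,
       manifest = manifest)
}

# ---- finetuning -------------------------------------------------------------

labelMatrix <- function(labels) {
  if (is.matrix(labels)) labels else matrix(as.numeric(labels), ncol = 1L)
}

#' Finetune a model for disease or outcome prediction
#'
#' Attaches (or reuses) a linear classifier head and optimizes the full
#' network (backbone and head) on labeled records with binary cross-entropy.
#' When a validation set is supplied, the parameters of the epoch with the
#' best validation AUPRC (mean over outputs for multilabel) are kept.
#'
#' @param model a pretrained or freshly initialized [EHRModel-class].
#' @param records list of patient records, each truncated to its prediction
#'   point (all visits before the outcome visit for cases, before the final
#'   visit for controls).
#' @param labels 0/1 vector (binary task) or n x k 0/1 matrix (multilabel).
#' @param vocab the [CodeVocabulary-class] the model was built against.
#' @param tc a [TrainConfig-class].
#' @param valRecords,valLabels optional validation set for epoch selection.
#' @return list with `model` (finetuned), `trace` (data.frame of epoch and
#'   validation AUPRC; empty without a validation set), and `manifest`.
#' @export
finetune <- function(model, records, labels, vocab, tc = trainConfig(),
                     valRecords = NULL, valLabels = NULL) {
  validObject(tc)
  if (vocabHash(vocab) != model@vocabHash)
    stopf("vocabulary hash mismatch: model was built against %s, got %s",
          model@vocabHash, vocabHash(vocab))
  Y <- labelMatrix(labels)
  if (nrow(Y) != length(records))
    stopf("labels and records differ in length")
  if (ncol(Y) == 1L && length(unique(Y[, 1L])) < 2L)
    stopf("training labels contain a single class (%d positives of %d)",
          sum(Y[, 1L]), nrow(Y))
  if (!length(model@head))
    model <- attachHead(model, if (ncol(Y) > 1L) "multilabel_classifier"
                               else "binary_classifier", ncol(Y))
  cfg <- model@config
  encs <- lapply(records, classifierInput, vocab = vocab,
                 timeMode = cfg@timeMode, maxLen = cfg@maxLen)
  valEncs <- if (!is.null(valRecords))
    lapply(valRecords, classifierInput, vocab = vocab,
           timeMode = cfg@timeMode, maxLen = cfg@maxLen)
  valY <- if (!is.null(valLabels)) labelMatrix(valLabels)
  n <- length(encs)
  stepsPerEpoch <- ceiling(n / tc@batchSize)
  totalSteps <- min(tc@maxSteps, tc@epochs * stepsPerEpoch)
  state <- adamInit(model@params)
  trace <- data.frame(epoch = integer(0), valAUPRC = numeric(0))
  best <- list(params = model@params, metric = -Inf)
  step <- 0L
  withSeed(tc@seed, {
    for (ep in seq_len(tc@epochs)) {
      ord <- sample.int(n)
      for (b in seq_len(stepsPerEpoch)) {
        if (step >= totalSteps) break
        ix <- ord[((b - 1L) * tc@batchSize + 1L):min(b * tc@batchSize, n)]
        fw <- fwdClsBatch(model, encs[ix], Y[ix, , drop = FALSE],
                          training = TRUE, computeGrads = TRUE)
        step <- step + 1L
        lr <- lrSchedule(step, totalSteps, tc@warmupRatio, tc@learningRate)
        up <- adamStep(model@params, fw$grads, state, lr, tc@weightDecay)
        model@params <- up$params
        state <- up$state
      }
      if (!is.null(valEncs)) {
        S <- scoreEncs(model, valEncs)
        ap <- mean(vapply(seq_len(ncol(valY)), function(j) {
          if (length(unique(valY[, j])) < 2L) return(NA_real_)
          auprc(S[, j], valY[, j])
        }, 0), na.rm = TRUE)
        trace <- rbind(trace, data.frame(epoch = ep, valAUPRC = ap))
        if (!is.nan(ap) && ap > best$metric)
          best <- list(params = model@params, metric = ap)
      }
      if (step >= totalSteps) break
    }
  })
  if (!is.null(valEncs) && is.finite(best$metric))
    model@params <- best$params
  manifest <- list(stage = "finetune", head = model@head$kind,
                   nOutputs = model@head$nOutputs, trainSeed = tc@seed,
                   vocabHash = model@vocabHash, n = n,
                   totalSteps = as.integer(totalSteps))
  list(model = model, trace = trace, manifest = manifest)
}

scoreEncs <- function(model, encs, chunkSize = 8L) {
  k <- model@head$nOutputs
  out <- matrix(0, length(encs), k)
  for (start in seq(1L, length(encs), by = chunkSize)) {
    ix <- start:min(start + chunkSize - 1L, length(encs))
    out[ix, ] <- fwdClsBatch(model, encs[ix])$scores
  }
  out
}

#' Score records with a finetuned classifier
#'
#' @param model a finetuned [EHRModel-class] (head attached).
#' @param records list of patient records.
#' @param vocab the matching [CodeVocabulary-class].
#' @return n x nOutputs matrix of sigmoid scores in (0, 1).
#' @export
predictScores <- function(model, records, vocab) {
  if (vocabHash(vocab) != model@vocabHash)
    stopf("vocabulary hash mismatch: model was built against %s, got %s",
          model@vocabHash, vocabHash(vocab))
  cfg <- model@config
  encs <- lapply(records, classifierInput, vocab = vocab,
                 timeMode = cfg@timeMode, maxLen = cfg@maxLen)
  scoreEncs(model, encs)
}

# ---- labeled-dataset builders -----------------------------------------------

#' Build a single-outcome finetuning dataset
#'
#' Cases are patients whose record contains `outcomeCode`; their input is
#' every visit before the first outcome visit. Controls contribute every
#' visit before their final visit, so both classes are scored strictly
#' before the visit being predicted. Patients left without context visits
#' are dropped.
#'
#' @param cohort an [EHRCohort-class].
#' @param outcomeCode the outcome code string.
#' @return list with `records` (truncated patient records) and `labels`
#'   (0/1 vector).
#' @export
outcomeDataset <- function(cohort, outcomeCode = "OUTCOME") {
  records <- list(); labels <- numeric(0)
  for (p in cohort@patients) {
    hit <- which(vapply(p$visits, function(v) outcomeCode %in% v$codes, TRUE))
    cut <- if (length(hit)) hit[1L] - 1L else length(p$visits) - 1L
    if (cut < 1L) next
    q <- p; q$visits <- p$visits[seq_len(cut)]
    records[[length(records) + 1L]] <- q
    labels <- c(labels, as.numeric(length(hit) > 0L))
  }
  list(records = records, labels = labels)
}

#' Build a disease/outcome-agnostic prediction (DOAP) dataset
#'
#' For each patient with >= 2 visits, the input is every visit before the
#' final one and the multilabel target marks which of `codes` occur in the
#' final visit.
#'
#' @param cohort an [EHRCohort-class].
#' @param codes character vector of tracked codes.
#' @return list with `records`, `labels` (n x length(codes) 0/1 matrix with
#'   the codes as column names), and `contextCodeSets` (per-record set of
#'   codes occurring anywhere in the context, for new-vs-recurrent
#'   stratification).
#' @export
doapDataset <- function(cohort, codes) {
  keep <- visitCounts(cohort) >= 2L
  pats <- cohort@patients[keep]
  records <- lapply(pats, function(p) {
    q <- p; q$visits <- p$visits[seq_len(length(p$visits) - 1L)]; q
  })
  labels <- matrix(vapply(pats, function(p)
    as.numeric(codes %in% p$visits[[length(p$visits)]]$codes),
    numeric(length(codes))), ncol = length(codes), byrow = TRUE,
    dimnames = list(NULL, codes))
  ctx <- lapply(records, function(p)
    unique(unlist(lapply(p$visits, `[[`, "codes"))))
  list(records = records, labels = labels, contextCodeSets = ctx)
}

# ---- multi-arm comparison ---------------------------------------------------

#' One-sided two-sample Welch t-test
#'
#' Tests whether `x` (the focal arm's per-seed metrics) has a greater mean
#' than `y`. Zero-variance inputs (identical metric values within an arm)
#' are handled in closed form: equal means give p = 0.5, otherwise p is 0
#' or 1 by direction.
#'
#' @param x,y numeric vectors of per-seed metric values.
#' @return list with `t`, `df`, `p`.
#' @export
oneSidedT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- if (nx > 1) var(x) else 0
  vy <- if (ny > 1) var(y) else 0
  se2 <- vx / nx + vy / ny
  d <- mean(x) - mean(y)
  if (se2 <= 0) {
    p <- if (d > 0) 0 else if (d < 0) 1 else 0.5
    return(list(t = if (d == 0) 0 else sign(d) * Inf, df = NA_real_, p = p))
  }
  tstat <- d / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / max(nx - 1, 1) + (vy / ny)^2 / max(ny - 1, 1))
  list(t = tstat, df = df, p = pt(tstat, df, lower.tail = FALSE))
}

armConfig <- function(arm, baseConfig, seed, vocabSize = NULL) {
  cfg <- baseConfig
  if (!is.null(vocabSize)) cfg@vocabSize <- as.integer(vocabSize)
  cfg@architecture <- arm$architecture
  if (!is.null(arm$nEncoderLayers))
    cfg@nEncoderLayers <- as.integer(arm$nEncoderLayers)
  cfg@nDecoderLayers <- if (arm$architecture == "encoder_only") 0L
    else if (!is.null(arm$nDecoderLayers)) as.integer(arm$nDecoderLayers)
    else baseConfig@nDecoderLayers
  cfg@seed <- seed
  validObject(cfg)
  cfg
}

#' Run a multi-arm, multi-seed comparison experiment
#'
#' Reproduces the standard comparison design: the cohort is split
#' patient-wise (pretraining set, then train/validation/test for
#' finetuning), each arm is pretrained (optionally) and finetuned once per
#' seed, test metrics are collected per arm and seed, and each non-reference
#' arm is compared against the reference with a one-sided Welch t-test on
#' the direction "reference is better".
#'
#' @param cohort an [EHRCohort-class].
#' @param arms named list; each arm is a list with `architecture`
#'   (`"encoder_decoder"`/`"encoder_only"`), `corruption` (a
#'   [CorruptionSpec-class]), `pretrain` (logical) and optional layer-count
#'   overrides `nEncoderLayers`/`nDecoderLayers`.
#' @param task list: `type = "outcome"` with `outcomeCode`, or
#'   `type = "doap"` with `codes` (tracked code panel).
#' @param seeds integer vector of finetuning seeds (one run per seed).
#' @param baseConfig a [SeqModelConfig-class] template (architecture and
#'   seed are overridden per arm/seed).
#' @param pretrainTc,finetuneTc [TrainConfig-class] for the two stages
#'   (their seeds are re-derived per arm and run seed).
#' @param split a [SplitSpec-class].
#' @param referenceArm name of the focal arm (default: first).
#' @param keepModels keep the first-seed finetuned model of each arm (for
#'   follow-up analyses such as new-vs-recurrent stratification).
#' @return list with `metrics` (tidy data.frame arm/seed/metric/value),
#'   `tests` (per metric and comparison: t, df, p), `models` (when
#'   requested), `vocab`, `testData` (the held-out test dataset), and
#'   `provenance`.
#' @export
runComparison <- function(cohort, arms, task, seeds = 1:5, baseConfig,
                          pretrainTc = trainConfig(),
                          finetuneTc = trainConfig(),
                          split = splitSpec(),
                          referenceArm = names(arms)[1],
                          keepModels = FALSE) {
  stopifnot(length(arms) >= 2L, !is.null(names(arms)), length(seeds) >= 2L)
  sp <- splitCohort(cohort, split)
  vocab <- buildVocabulary(sp$pretrain)
  dsets <- lapply(sp$finetune, function(co) {
    if (task$type == "outcome") outcomeDataset(co, task$outcomeCode)
    else doapDataset(co, task$codes)
  })
  rows <- list()
  models <- list()
  for (armName in names(arms)) {
    arm <- arms[[armName]]
    # pretraining does not depend on the finetuning seed: do it once per arm
    ptCache <- NULL
    for (sd in seeds) {
      cfg <- armConfig(arm, baseConfig, deriveSeed(sd, paste0(armName, ".init")),
                       vocabSize(vocab))
      if (isTRUE(arm$pretrain)) {
        if (is.null(ptCache)) {
          ptcfg <- armConfig(arm, baseConfig,
                             deriveSeed(1L, paste0(armName, ".pt")),
                             vocabSize(vocab))
          ptc <- pretrainTc
          ptc@seed <- deriveSeed(1L, paste0(armName, ".ptrain"))
          ptCache <- pretrain(sp$pretrain, ptcfg, ptc, arm$corruption, vocab)
        }
        model <- ptCache$model
      } else {
        model <- initModel(cfg, vocab)
      }
      ftc <- finetuneTc
      ftc@seed <- deriveSeed(sd, paste0(armName, ".ft"))
      ft <- finetune(model, dsets$train$records, dsets$train$labels, vocab,
                     ftc, dsets$val$records, dsets$val$labels)
      if (keepModels && identical(sd, seeds[1]))
        models[[armName]] <- ft$model
      S <- predictScores(ft$model, dsets$test$records, vocab)
      Yte <- labelMatrix(dsets$test$labels)
      vals <- if (task$type == "outcome") {
        c(auroc = auroc(S[, 1L], Yte[, 1L]), auprc = auprc(S[, 1L], Yte[, 1L]))
      } else {
        percode <- vapply(seq_len(ncol(Yte)), function(j)
          if (length(unique(Yte[, j])) < 2L) NA_real_
          else auroc(S[, j], Yte[, j]), 0)
        c(auroc = mean(percode, na.rm = TRUE))
      }
      for (mname in names(vals))
        rows[[length(rows) + 1L]] <- data.frame(
          arm = armName, seed = sd, metric = mname, value = vals[[mname]])
    }
  }
  metrics <- do.call(rbind, rows)
  tests <- list()
  for (mname in unique(metrics$metric)) {
    ref <- metrics$value[metrics$arm == referenceArm & metrics$metric == mname]
    for (other in setdiff(names(arms), referenceArm)) {
      ov <- metrics$value[metrics$arm == other & metrics$metric == mname]
      tt <- oneSidedT(ref, ov)
      tests[[length(tests) + 1L]] <- data.frame(
        metric = mname, reference = referenceArm, against = other,
        meanRef = mean(ref), meanOther = mean(ov),
        t = tt$t, df = tt$df, p = tt$p)
    }
  }
  list(metrics = metrics, tests = do.call(rbind, tests),
       models = if (keepModels) models,
       vocab = vocab, testData = dsets$test,
       provenance = list(seeds = seeds, splitSeed = split@seed,
                         vocabHash = vocabHash(vocab),
                         referenceArm = referenceArm))
}
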