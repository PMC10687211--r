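#' @include training.R evaluation.R synthetic.R
NULL

# Canonical desk-scale study designs. These functions ARE the package's
# experiments: the synthetic study conditions (cohort shapes, planted
# structure, rare-outcome regime) live here, the compute budgets are
# arguments. The methods vignette documents the choices.

#' Study spec: planted progression-rule cohort
#'
#' Two small comorbidity clusters over a 100-code vocabulary, plus one
#' deterministic progression rule: the recurring cluster code C002 at
#' visit t forces the acute consequence C050 at visit t+1 (the trigger is
#' a non-chronic member code, so carriers express it at most visits and
#' the rule fires often enough to be learnable). No outcome process;
#' moderate Poisson noise.
#'
#' @param nPatients cohort size.
#' @param seed generator seed.
#' @return a [SyntheticSpec-class].
#' @export
ruleCohortSpec <- function(nPatients = 2000L, seed = 1L)
  syntheticSpec(
    nPatients = nPatients, vocabSize = 100L, nClusters = 2L,
    clusterSize = 3L, membershipProb = 0.3, clusterCoactivation = 0.6,
    chronicPersistence = 0.9, noiseRate = 2,
    progressionRules = data.frame(trigger = "C002", consequence = "C050",
                                  lag = 1L, prob = 1.0),
    outcomeBaseRate = 0, visitsMin = 3L, visitsMax = 12L, visitsMean = 7,
    visitsSd = 2, seed = seed)

#' Study spec: planted-structure cohort with a rare triggered outcome
#'
#' Four 4-code clusters (chronic persistence 0.9, co-activation 0.6) over
#' a 60-code vocabulary, with a rare outcome (base hazard 9e-4 per
#' eligible visit, hazard ratio 5.5 once any first-cluster code has
#' appeared) yielding a patient-level prevalence near 2%.
#'
#' @inheritParams ruleCohortSpec
#' @export
outcomeCohortSpec <- function(nPatients = 1000L, seed = 1L)
  syntheticSpec(
    nPatients = nPatients, vocabSize = 60L, nClusters = 4L,
    clusterSize = 4L, membershipProb = 0.3, clusterCoactivation = 0.6,
    chronicPersistence = 0.9, noiseRate = 1, outcomeBaseRate = 9e-4,
    outcomeHazardRatio = 5.5, outcomeTriggerCodes = sprintf("C%03d", 1:4),
    visitsMin = 2L, visitsMax = 16L, visitsMean = 8, visitsSd = 2.5,
    seed = seed)

#' Tracked code panel for disease/outcome-agnostic prediction
#'
#' Ten recurring (non-chronic) cluster codes of [outcomeCohortSpec()];
#' chronic codes follow separate onset/recurrence dynamics and are
#' evaluated by the new-vs-recurrent stratification instead.
#' @export
doapTrackedCodes <- function()
  sprintf("C%03d", c(2L, 3L, 4L, 6L, 7L, 8L, 10L, 11L, 12L, 14L))

#' Planted-rule recovery experiment
#'
#' Pretrains an encoder-decoder with visit masking on a [ruleCohortSpec()]
#' cohort and measures how much first-decode-step probability the model
#' assigns to the planted consequence code, comparing evaluation contexts
#' that contain the trigger against contexts that do not. A model that has
#' recovered the rule concentrates first-step mass on the consequence
#' exactly when the trigger is present.
#'
#' @param seed seed for this replicate (weights, corruption, shuffling).
#' @param cohort a [ruleCohortSpec()] cohort (pass one in to share across
#'   replicates; built at 2,000 patients when NULL).
#' @param evalCohort held-out cohort for scoring (400 patients when NULL).
#' @param dModel,nLayers architecture scale (reference: width 128, 2+2).
#' @param batchSize,maxSteps training budget.
#' @param learningRate peak learning rate for this pretraining run.
#' @return list with `gap` (mean P(consequence) with trigger minus
#'   without), `pWithTrigger`, `pWithoutTrigger`, `lossFirst`, `lossLast`,
#'   `model`, `vocab`.
#' @export
plantedRuleExperiment <- function(seed, cohort = NULL, evalCohort = NULL,
                                  dModel = 128L, nLayers = 2L,
                                  batchSize = 16L, maxSteps = 1100,
                                  learningRate = 1e-3) {
  if (is.null(cohort))
    cohort <- generateCohort(ruleCohortSpec(2000L, deriveSeed(seed, "rule")))
  if (is.null(evalCohort))
    evalCohort <- generateCohort(ruleCohortSpec(400L,
                                                deriveSeed(seed, "ruleEval")))
  vocab <- buildVocabulary(cohort)
  cfg <- seqModelConfig("encoder_decoder", vocabSize = vocabSize(vocab),
                        dModel = dModel, nHeads = 4L,
                        nEncoderLayers = nLayers, nDecoderLayers = nLayers,
                        ffnDim = 2L * dModel, dropout = 0.1,
                        seed = deriveSeed(seed, "ruleInit"))
  pt <- pretrain(cohort, cfg,
                 trainConfig(learningRate = learningRate,
                             batchSize = batchSize, epochs = 2L,
                             maxSteps = maxSteps,
                             seed = deriveSeed(seed, "ruleTrain")),
                 corruptionSpec("visit_mask"), vocab)
  dd <- doapDataset(evalCohort, "C050")
  encs <- lapply(dd$records, classifierInput, vocab = vocab,
                 timeMode = cfg@timeMode)
  hasTrig <- vapply(dd$contextCodeSets, function(s) "C002" %in% s, TRUE)
  idB <- encodeTokens(vocab, "C050") + 1L
  pb <- nextVisitProbsMany(pt$model, encs)[, idB]
  list(gap = mean(pb[hasTrig]) - mean(pb[!hasTrig]),
       pWithTrigger = mean(pb[hasTrig]),
       pWithoutTrigger = mean(pb[!hasTrig]),
       lossFirst = pt$lossHistory[1],
       lossLast = mean(utils::tail(pt$lossHistory, 5)),
       model = pt$model, vocab = vocab)
}

#' Pretrain the two masking-objective backbones
#'
#' One visit-masking and one code-masking encoder-decoder, pretrained on
#' the same [outcomeCohortSpec()] cohort with identical budgets.
#'
#' @param seed global seed.
#' @param nPretrain pretraining cohort size.
#' @param dModel width; layers are 1+1 at this scale.
#' @param epochs,batchSize pretraining budget (identical across arms).
#' @return list with `visit`, `code` (trained models), `vocab`, `cohort`.
#' @export
pretrainBackbones <- function(seed, nPretrain = 500L, dModel = 32L,
                              epochs = 4L, batchSize = 8L) {
  cohort <- generateCohort(outcomeCohortSpec(nPretrain,
                                             deriveSeed(seed, "preCo")))
  vocab <- buildVocabulary(cohort)
  run <- function(scheme) {
    cfg <- seqModelConfig("encoder_decoder", vocabSize = vocabSize(vocab),
                          dModel = dModel, nHeads = 4L,
                          nEncoderLayers = 1L, nDecoderLayers = 1L,
                          ffnDim = 2L * dModel, dropout = 0.1,
                          seed = deriveSeed(seed, paste0(scheme, ".init")))
    pretrain(cohort, cfg,
             trainConfig(batchSize = batchSize, epochs = epochs,
                         seed = deriveSeed(seed, paste0(scheme, ".train"))),
             corruptionSpec(scheme), vocab)$model
  }
  list(visit = run("visit_mask"), code = run("code_mask"), vocab = vocab,
       cohort = cohort)
}

#' Masking-objective ablation (visit vs code masking on DOAP)
#'
#' Finetunes a 10-code multilabel head from each backbone with `nSeeds`
#' finetuning seeds, evaluates mean per-code AUROC on an independent test
#' cohort, and compares the arms with a one-sided Welch t-test in the
#' direction "visit masking is better".
#'
#' @param seed global seed.
#' @param backbones output of [pretrainBackbones()]; built when NULL.
#' @param nSeeds finetuning seeds per arm.
#' @param nLabeled,nTest labeled and test cohort sizes.
#' @param ftEpochs,ftLr,ftBatch finetuning budget.
#' @return list with `metrics` (arm/seed/auroc), `meanVisit`, `meanCode`,
#'   `test` (t, df, p), and `strat` (instance-level new-vs-recurrent AUROC
#'   for the chronic code C001, scored zero-shot by the visit-masking
#'   backbone's first-step generative probability).
#' @export
maskingAblationExperiment <- function(seed, backbones = NULL, nSeeds = 5L,
                                      nLabeled = 400L, nTest = 500L,
                                      ftEpochs = 10L, ftLr = 3e-3,
                                      ftBatch = 16L) {
  if (is.null(backbones)) backbones <- pretrainBackbones(seed)
  vocab <- backbones$vocab
  tracked <- doapTrackedCodes()
  lab <- doapDataset(generateCohort(outcomeCohortSpec(
    nLabeled, deriveSeed(seed, "abLab"))), tracked)
  teCohort <- generateCohort(outcomeCohortSpec(nTest,
                                               deriveSeed(seed, "abTest")))
  te <- doapDataset(teCohort, tracked)
  rows <- list()
  stratOut <- NULL
  for (armName in c("visit", "code")) {
    for (s in seq_len(nSeeds)) {
      m0 <- attachHead(backbones[[armName]], "multilabel_classifier",
                       length(tracked))
      ft <- finetune(m0, lab$records, lab$labels, vocab,
                     trainConfig(batchSize = ftBatch, epochs = ftEpochs,
                                 learningRate = ftLr,
                                 seed = deriveSeed(seed + s,
                                                   paste0(armName, ".ft"))))
      S <- predictScores(ft$model, te$records, vocab)
      percode <- vapply(seq_along(tracked), function(j) {
        y <- te$labels[, j]
        if (length(unique(y)) < 2L) NA_real_ else auroc(S[, j], y)
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = armName, seed = s, auroc = mean(percode, na.rm = TRUE))
    }
  }
  # instance-level new-vs-recurrent stratification for the chronic code
  # C001 (persistence 0.9): every (prefix, next-visit) instance of the
  # test cohort, scored zero-shot by the visit-masking backbone's
  # first-decode-step probability of the code. Recurrence is
  # recency-predictable (and chronic recurrences lead the priority order),
  # so the generative first-step score carries the history signal
  # directly; new onset is background noise by design.
  chronic <- "C001"
  insts <- expandCohortInstances(teCohort, vocab)
  if (length(insts) > 1500L)
    insts <- insts[withSeed(deriveSeed(seed, "strat"),
                            sample.int(length(insts), 1500L))]
  sEnc <- lapply(insts, instanceEncoderInput)
  idc <- encodeTokens(vocab, chronic) + 1L
  sScores <- nextVisitProbsMany(backbones$visit, sEnc)[, idc]
  sLabels <- vapply(insts, function(i)
    as.numeric(chronic %in% i$targetCodes), 0)
  sCtx <- lapply(insts, function(i) unique(i$contextTokens[i$isCodeToken]))
  stratOut <- stratifyNewRecurrent(sCtx, sScores, sLabels, chronic)
  metrics <- do.call(rbind, rows)
  v <- metrics$auroc[metrics$arm == "visit"]
  cdm <- metrics$auroc[metrics$arm == "code"]
  list(metrics = metrics, meanVisit = mean(v), meanCode = mean(cdm),
       test = oneSidedT(v, cdm), strat = stratOut)
}

#' Pretraining-benefit experiment on a rare outcome
#'
#' Finetunes a binary outcome classifier from the visit-masking backbone
#' and from fresh random initializations (one per seed), on a small
#' labeled cohort (~2% outcome prevalence), and evaluates AUPRC on a large
#' independent test cohort.
#'
#' @param seed global seed.
#' @param backbone a pretrained visit-masking model; when NULL one is
#'   pretrained on a 1,000-patient cohort for 3 epochs (a larger budget
#'   than the ablation backbones, so the backbone has seen enough outcome
#'   events to encode the outcome association).
#' @param vocab its vocabulary.
#' @param nSeeds finetuning seeds per arm.
#' @param nLabeled,nTest labeled and test cohort sizes.
#' @param ftEpochs,ftLr,ftBatch finetuning budget.
#' @return list with `metrics` (arm/seed/auprc/auroc), `meanPretrained`,
#'   `meanFresh` (AUPRC), `prevalence` (test prevalence), `scores`
#'   (first pretrained seed's test scores), `labels`.
#' @export
pretrainBenefitExperiment <- function(seed, backbone = NULL, vocab = NULL,
                                      nSeeds = 5L, nLabeled = 700L,
                                      nTest = 2000L, ftEpochs = 5L,
                                      ftLr = 3e-3, ftBatch = 8L) {
  if (is.null(backbone)) {
    cohort <- generateCohort(outcomeCohortSpec(1000L,
                                               deriveSeed(seed, "pbPre")))
    vocab <- buildVocabulary(cohort)
    cfg <- seqModelConfig("encoder_decoder", vocabSize = vocabSize(vocab),
                          dModel = 32L, nHeads = 4L, nEncoderLayers = 1L,
                          nDecoderLayers = 1L, ffnDim = 64L, dropout = 0.1,
                          seed = deriveSeed(seed, "pbInit"))
    backbone <- pretrain(cohort, cfg,
                         trainConfig(batchSize = 8L, epochs = 3L,
                                     seed = deriveSeed(seed, "pbTrain")),
                         corruptionSpec("visit_mask"), vocab)$model
  }
  lab <- outcomeDataset(generateCohort(outcomeCohortSpec(
    nLabeled, deriveSeed(seed, "pbLab"))))
  te <- outcomeDataset(generateCohort(outcomeCohortSpec(
    nTest, deriveSeed(seed, "pbTest"))))
  nv <- max(2L, round(0.12 * length(lab$records)))
  rows <- list()
  keepScores <- NULL
  for (armName in c("pretrained", "fresh")) {
    for (s in seq_len(nSeeds)) {
      m0 <- if (armName == "pretrained") backbone else
        initModel({
          cfg <- backbone@config
          cfg@seed <- deriveSeed(seed + s, "pbFresh")
          cfg
        }, vocab)
      perm <- withSeed(deriveSeed(seed + s, "pbSplit"),
                       sample.int(length(lab$records)))
      vix <- perm[seq_len(nv)]
      tix <- perm[(nv + 1L):length(perm)]
      ft <- finetune(m0, lab$records[tix], lab$labels[tix], vocab,
                     trainConfig(batchSize = ftBatch, epochs = ftEpochs,
                                 learningRate = ftLr,
                                 seed = deriveSeed(seed + s,
                                                   paste0(armName, ".pb"))),
                     valRecords = lab$records[vix],
                     valLabels = lab$labels[vix])
      sc <- predictScores(ft$model, te$records, vocab)[, 1L]
      if (armName == "pretrained" && s == 1L) keepScores <- sc
      rows[[length(rows) + 1L]] <- data.frame(
        arm = armName, seed = s, auprc = auprc(sc, te$labels),
        auroc = auroc(sc, te$labels))
    }
  }
  metrics <- do.call(rbind, rows)
  list(metrics = metrics,
       meanPretrained = mean(metrics$auprc[metrics$arm == "pretrained"]),
       meanFresh = mean(metrics$auprc[metrics$arm == "fresh"]),
       prevalence = mean(te$labels),
       scores = keepScores, labels = te$labels)
}
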