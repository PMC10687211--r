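test_that("learning-rate schedule warms up linearly to the peak, then decays", {
  peak <- 1e-3
  T <- 100L
  warm <- ceiling(0.1 * T)
  # exact peak at the last warmup step
  expect_equal(lrSchedule(warm, T, 0.1, peak), peak)
  expect_equal(lrSchedule(warm / 2, T, 0.1, peak), peak / 2, tolerance = 1e-12)
  # linear decay afterwards, reaching 0 at T
  expect_equal(lrSchedule(T, T, 0.1, peak), 0)
  mid <- warm + (T - warm) / 2
  expect_equal(lrSchedule(mid, T, 0.1, peak), peak / 2, tolerance = 1e-12)
  expect_true(all(diff(vapply(1:warm, lrSchedule, 0, totalSteps = T,
                              warmupRatio = 0.1, peak = peak)) > 0))
})

test_that("splitCohort is patient-disjoint, ratio-faithful and seeded", {
  co <- generateCohort(smallSpec(n = 100L, seed = 50L))
  sp <- splitCohort(co, splitSpec(pretrainFraction = 0.95, seed = 3L))
  expect_equal(nPatients(sp$pretrain), 95L)
  expect_equal(nPatients(sp$heldout), 5L)
  ids <- function(x) vapply(patients(x), `[[`, "", "patient_id")
  # partition laws: union = all ids, pairwise disjoint
  expect_setequal(c(ids(sp$pretrain), ids(sp$heldout)), ids(co))
  expect_length(intersect(ids(sp$pretrain), ids(sp$heldout)), 0L)
  f <- sp$finetune
  expect_setequal(c(ids(f$train), ids(f$val), ids(f$test)), ids(sp$heldout))
  expect_length(intersect(ids(f$train), ids(f$val)), 0L)
  expect_length(intersect(ids(f$train), ids(f$test)), 0L)
  # 10 held-out patients at 7:1:2 -> exactly 7/1/2
  sp2 <- splitCohort(co, splitSpec(pretrainFraction = 0.9, seed = 3L))
  expect_equal(vapply(sp2$finetune, nPatients, 0L),
               c(train = 7L, val = 1L, test = 2L))
  # determinism
  sp3 <- splitCohort(co, splitSpec(pretrainFraction = 0.95, seed = 3L))
  expect_identical(ids(sp3$pretrain), ids(sp$pretrain))
  expect_error(splitCohort(EHRCohort(patients(co)[1:20]),
                           splitSpec(pretrainFraction = 0.95)),
               "too small")
})

test_that("pretraining is plumbed, seeded and bitwise reproducible", {
  co <- generateCohort(smallSpec(n = 12L, seed = 3L))
  v <- buildVocabulary(co)
  cfg <- seqModelConfig("encoder_decoder", vocabSize = vocabSize(v),
                        dModel = 16L, nHeads = 2L, nEncoderLayers = 1L,
                        nDecoderLayers = 1L, ffnDim = 24L, seed = 4L)
  one <- pretrain(co, cfg, trainConfig(batchSize = 8L, maxSteps = 1,
                                       seed = 9L), vocab = v)
  expect_length(one$lossHistory, 1L)
  expect_s4_class(one$model, "EHRModel")
  expect_equal(one$manifest$vocabHash, vocabHash(v))
  a <- pretrain(co, cfg, trainConfig(batchSize = 8L, epochs = 2L, seed = 9L),
                vocab = v)
  b <- pretrain(co, cfg, trainConfig(batchSize = 8L, epochs = 2L, seed = 9L),
                vocab = v)
  expect_identical(a$lossHistory, b$lossHistory)
  expect_identical(a$model@params, b$model@params)
  c2 <- pretrain(co, cfg, trainConfig(batchSize = 8L, epochs = 2L,
                                      seed = 10L), vocab = v)
  expect_false(identical(a$lossHistory, c2$lossHistory))
})

test_that("the generative loss decreases during pretraining on structured data", {
  co <- generateCohort(syntheticSpec(
    nPatients = 150L, vocabSize = 60L, nClusters = 4L, clusterSize = 4L,
    clusterCoactivation = 0.6, chronicPersistence = 0.8, noiseRate = 1,
    outcomeBaseRate = 0, visitsMin = 3L, visitsMax = 10L, visitsMean = 6,
    visitsSd = 2, seed = 44L))
  v <- buildVocabulary(co)
  cfg <- seqModelConfig("encoder_decoder", vocabSize = vocabSize(v),
                        dModel = 32L, nHeads = 4L, nEncoderLayers = 1L,
                        nDecoderLayers = 1L, ffnDim = 64L, seed = 2L)
  pt <- pretrain(co, cfg, trainConfig(batchSize = 16L, epochs = 2L,
                                      seed = 7L), vocab = v)
  h <- pt$lossHistory
  early <- mean(head(h, 5))
  late <- mean(utils::tail(h, 5))
  expect_lt(late, early - sd(utils::tail(h, 10)))
})

test_that("visit-mask pretraining refuses the encoder-only architecture", {
  co <- generateCohort(smallSpec(n = 8L, seed = 3L))
  v <- buildVocabulary(co)
  cfg <- seqModelConfig("encoder_only", vocabSize = vocabSize(v),
                        dModel = 16L, nHeads = 2L, nEncoderLayers = 1L)
  expect_error(pretrain(co, cfg, trainConfig(maxSteps = 1),
                        corruptionSpec("visit_mask"), vocab = v),
               "encoder_decoder")
})

test_that("finetuning guards labels and vocabulary compatibility", {
  sc <- smallCohort()
  ds <- outcomeDataset(sc$co)
  m <- toyModel("encoder_decoder", sc$vocab)
  expect_error(finetune(m, ds$records[1:4], c(1, 1, 1, 1), sc$vocab),
               "single class")
  other <- buildVocabulary(tinyCohort())
  expect_error(finetune(m, ds$records, ds$labels, other), "hash mismatch")
  expect_error(predictScores(m, ds$records, other), "hash mismatch")
})

test_that("a fully determined label is learned to near-perfect test AUROC", {
  co <- generateCohort(syntheticSpec(
    nPatients = 160L, vocabSize = 40L, nClusters = 2L, clusterSize = 3L,
    membershipProb = 0.5, clusterCoactivation = 0.7, noiseRate = 1.5,
    outcomeBaseRate = 0, visitsMin = 3L, visitsMax = 8L, visitsMean = 5,
    visitsSd = 1.5, seed = 21L))
  v <- buildVocabulary(co)
  recs <- patients(co)
  # C002 is a recurring (non-chronic) cluster code: a salient, fully
  # determined signal for carriers
  hasX <- vapply(recs, function(p)
    any(vapply(p$visits, function(vv) "C002" %in% vv$codes, TRUE)), TRUE)
  m <- toyModel("encoder_decoder", v, dModel = 32L, layers = 1L)
  ft <- finetune(m, recs[1:120], as.numeric(hasX[1:120]), v,
                 trainConfig(batchSize = 8L, epochs = 30L, seed = 3L))
  s <- predictScores(ft$model, recs[121:160], v)[, 1]
  expect_gt(auroc(s, as.numeric(hasX[121:160])), 0.95)
})

test_that("labels independent of the input give chance-level test AUROC", {
  co <- generateCohort(smallSpec(n = 120L, seed = 33L))
  v <- buildVocabulary(co)
  recs <- patients(co)
  y <- local({ set.seed(8); rbinom(length(recs), 1, 0.5) })
  m <- toyModel("encoder_decoder", v, dModel = 16L, layers = 1L)
  ft <- finetune(m, recs[1:80], y[1:80], v,
                 trainConfig(batchSize = 16L, epochs = 2L, seed = 3L))
  s <- predictScores(ft$model, recs[81:120], v)[, 1]
  expect_lt(abs(auroc(s, y[81:120]) - 0.5), 0.25)
})

test_that("finetuning tracks validation AUPRC and keeps the best epoch", {
  sc <- smallCohort()
  ds <- outcomeDataset(sc$co)
  hasX <- vapply(ds$records, function(p)
    any(vapply(p$visits, function(vv) "C002" %in% vv$codes, TRUE)), TRUE)
  y <- as.numeric(hasX)
  m <- toyModel("encoder_decoder", sc$vocab)
  ft <- finetune(m, ds$records[1:25], y[1:25], sc$vocab,
                 trainConfig(batchSize = 8L, epochs = 3L, seed = 2L),
                 valRecords = ds$records[26:35], valLabels = y[26:35])
  expect_equal(nrow(ft$trace), 3L)
  expect_true(all(is.finite(ft$trace$valAUPRC)))
})

test_that("outcome and DOAP dataset builders respect the prediction point", {
  p1 <- makePatient("P1", visits = list(
    list(date = as.Date("2018-01-01"), codes = "A"),
    list(date = as.Date("2018-02-01"), codes = "B"),
    list(date = as.Date("2018-03-01"), codes = c("OUTCOME", "C"))))
  p2 <- makePatient("P2", visits = makeVisits(3, function(i) sprintf("N%d", i)))
  co <- EHRCohort(list(p1, p2))
  ds <- outcomeDataset(co)
  expect_equal(ds$labels, c(1, 0))
  # case context stops before the outcome visit; control before final visit
  expect_length(ds$records[[1]]$visits, 2L)
  expect_length(ds$records[[2]]$visits, 2L)
  expect_false(any(vapply(ds$records[[1]]$visits,
                          function(v) "OUTCOME" %in% v$codes, TRUE)))
  dd <- doapDataset(co, c("C", "N3", "B"))
  expect_equal(dim(dd$labels), c(2L, 3L))
  expect_equal(dd$labels["P1" == c("P1", "P2"), ], c(C = 1, N3 = 0, B = 0))
  expect_equal(unname(dd$labels[2, ]), c(0, 1, 0))
  expect_setequal(dd$contextCodeSets[[2]], c("N1", "N2"))
})
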