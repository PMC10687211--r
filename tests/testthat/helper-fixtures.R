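# Fixtures built in code: tiny hand-written patients and small seeded
# synthetic cohorts shared across test files.

makePatient <- function(id = "P1", gender = "male", age = 51L,
                        race = "white", marital = "married",
                        visits = list(
                          list(date = as.Date("2018-01-01"),
                               codes = c("A10", "B20")),
                          list(date = as.Date("2018-02-01"),
                               codes = c("C30")))) {
  list(patient_id = id,
       demographics = list(gender = gender, age = age, race = race,
                           marital_status = marital),
       visits = visits)
}

# k visits, one day apart, each with the given codes
makeVisits <- function(k, codes = function(i) sprintf("V%02d", i),
                       start = as.Date("2018-01-01"), step = 7L) {
  lapply(seq_len(k), function(i)
    list(date = start + (i - 1L) * step, codes = codes(i)))
}

tinyCohort <- function() {
  EHRCohort(list(
    makePatient("P1"),
    makePatient("P2", gender = "female", age = 34L, race = "black",
                marital = "single",
                visits = makeVisits(5, function(i) c("A10", sprintf("X%d", i)))),
    makePatient("P3", age = 72L,
                visits = makeVisits(3, function(i) sprintf("Z%d", i)))))
}

# Small planted-structure synthetic cohort used across model tests.
smallSpec <- function(n = 40L, seed = 7L, ...)
  syntheticSpec(nPatients = n, vocabSize = 60L, nClusters = 4L,
                clusterSize = 4L, visitsMin = 2L, visitsMax = 12L,
                visitsMean = 6, visitsSd = 2, seed = seed, ...)

smallCohortCache <- new.env()
smallCohort <- function() {
  if (is.null(smallCohortCache$co)) {
    smallCohortCache$co <- generateCohort(smallSpec())
    smallCohortCache$vocab <- buildVocabulary(smallCohortCache$co)
  }
  smallCohortCache
}

toyModel <- function(architecture = "encoder_decoder", vocab,
                     dModel = 16L, layers = 1L, seed = 5L, dropout = 0) {
  cfg <- seqModelConfig(architecture, vocabSize = vocabSize(vocab),
                        dModel = dModel, nHeads = 2L,
                        nEncoderLayers = layers,
                        nDecoderLayers = if (architecture == "encoder_only")
                          0L else layers,
                        ffnDim = 2L * dModel, dropout = dropout, seed = seed)
  initModel(cfg, vocab)
}
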