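test_that("vocabulary layout: reserved specials, demographic tokens, count-ordered codes", {
  co <- EHRCohort(list(
    makePatient("P1", visits = makeVisits(3, function(i) c("A", "B")[seq_len(
      if (i == 1) 2 else 1)])),
    makePatient("P2", age = 34L, visits = makeVisits(2, function(i) "A"))))
  v <- buildVocabulary(co)
  expect_identical(v@tokens[1:5],
                   c("[PAD]", "[BOS]", "[EOS]", "[MASK]", "[UNK]"))
  expect_true(all(c("gender=male", "age=50-59", "age=30-39") %in% v@tokens))
  # A occurs 5x, B once: A precedes B
  expect_lt(match("A", v@tokens), match("B", v@tokens))
  # determinism: rebuilding yields the identical bijection
  expect_identical(v@tokens, buildVocabulary(co)@tokens)
})

test_that("minCount drops rare codes and encoding maps them to UNK", {
  co <- EHRCohort(list(makePatient("P1", visits = makeVisits(
    4, function(i) if (i < 4) "A" else "B"))))
  v <- buildVocabulary(co, minCount = 2L)
  expect_false("B" %in% v@tokens)
  expect_equal(encodeTokens(v, c("A", "B", "neverseen")),
               c(encodeTokens(v, "A"), 4L, 4L))
})

test_that("vocabulary round-trips through its two-column text serialization", {
  sc <- smallCohort()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeVocabulary(sc$vocab, f)
  v2 <- readVocabulary(f)
  expect_identical(v2@tokens, sc$vocab@tokens)
  expect_identical(vocabHash(v2), vocabHash(sc$vocab))
})

test_that("time values follow the declared conventions", {
  d <- as.Date(c("2018-01-01", "2018-01-11"))
  expect_equal(computeTimeValues(d, "daysdiff"), c(10, 0))
  expect_equal(computeTimeValues(as.Date("2018-05-05"), "daysdiff"), 0)
  expect_equal(computeTimeValues(as.Date("1970-01-02"), "date"), 1)
  expect_equal(computeTimeValues(d, "none"), c(0, 0))
  # daysdiff is invariant under a global shift; date mode is equivariant
  expect_equal(computeTimeValues(d + 30, "daysdiff"),
               computeTimeValues(d, "daysdiff"))
  expect_equal(computeTimeValues(d + 30, "date"),
               computeTimeValues(d, "date") + 30)
})

test_that("recursive expansion yields n-1 prefix instances matching brute force", {
  sc <- smallCohort()
  for (p in patients(sc$co)[1:8]) {
    n <- length(p$visits)
    inst <- expandRecursiveInstances(p, sc$vocab)
    expect_length(inst, n - 1L)
    for (k in seq_len(n - 1L)) {
      i <- inst[[k]]
      # context visit set = prefix 1..k (brute-force enumeration)
      expect_equal(sort(unique(i$contextVisitIndex[i$contextVisitIndex > 0])),
                   seq_len(k))
      expect_equal(i$targetCodes, p$visits[[k + 1L]]$codes)
      expect_false(any(duplicated(i$targetCodeIds)))
      # demographics block first, visit indices non-decreasing
      expect_equal(i$contextVisitIndex[1:4], rep(0L, 4))
      expect_true(all(diff(i$contextVisitIndex) >= 0))
      # instance 1 context holds visit-1 codes only
      if (k == 1L)
        expect_equal(i$contextTokens[-(1:4)], p$visits[[1]]$codes)
    }
  }
  # cohort-level instance-count identity
  inst <- expandCohortInstances(sc$co, sc$vocab)
  expect_length(inst, sum(pmax(visitCounts(sc$co) - 1L, 0L)))
})

test_that("patients with fewer than two visits are skipped with a warning", {
  p <- makePatient("P9", visits = makeVisits(1))
  expect_warning(out <- expandRecursiveInstances(p, smallCohort()$vocab),
                 "P9")
  expect_length(out, 0L)
})

test_that("truncation drops oldest clinical tokens, keeps demographics and order", {
  v <- buildVocabulary(EHRCohort(list(makePatient("P1", visits = makeVisits(
    3, function(i) sprintf("K%02d_%d", 1:30, i))))))
  p <- makePatient("P1", visits = makeVisits(3, function(i)
    sprintf("K%02d_%d", 1:30, i)))
  inst <- expandRecursiveInstances(p, v, maxLen = 40L)
  i2 <- inst[[2]]                      # context = 4 demo + 60 codes -> 40
  expect_length(i2$contextTokenIds, 40L)
  expect_equal(i2$contextVisitIndex[1:4], rep(0L, 4))
  # surviving clinical tokens are the most recent 36, order preserved
  full <- c(sprintf("K%02d_1", 1:30), sprintf("K%02d_2", 1:30))
  expect_equal(i2$contextTokens[-(1:4)], utils::tail(full, 36L))
})

test_that("visit masking withholds the target and drops context visits at the configured rate", {
  sc <- smallCohort()
  inst <- Filter(function(i) i$nContextVisits >= 4L,
                 expandCohortInstances(sc$co, sc$vocab))
  i1 <- inst[[1]]
  # rate 0: encoder sees exactly visits 1..k, targets = all target codes
  set.seed(1)
  c0 <- corruptForPretraining(i1, corruptionSpec("visit_mask",
                                                 visitDropRate = 0))
  expect_identical(c0$encIds, i1$contextTokenIds)
  expect_identical(c0$targetIds, i1$targetCodeIds)
  expect_equal(c0$nDroppedVisits, 0L)
  # drop fraction concentrates at the configured rate over many draws
  set.seed(42)
  fr <- replicate(400, {
    co <- corruptForPretraining(i1, corruptionSpec("visit_mask"))
    co$nDroppedVisits / i1$nContextVisits
  })
  expect_lt(abs(mean(fr) - 0.15),
            3 * sqrt(0.15 * 0.85 / (400 * i1$nContextVisits)) + 0.02)
  # at least one context visit always survives, re-indexed compactly
  set.seed(7)
  cAll <- corruptForPretraining(i1, corruptionSpec("visit_mask",
                                                   visitDropRate = 1))
  kept <- unique(cAll$encVisitIndex[cAll$encVisitIndex > 0])
  expect_identical(kept, 1L)
})

test_that("code masking replaces codes with MASK and targets them in order", {
  sc <- smallCohort()
  i1 <- expandCohortInstances(sc$co, sc$vocab)[[3]]
  # rate 1: every code token masked (demographics untouched), full targets
  set.seed(1)
  c1 <- corruptForPretraining(i1, corruptionSpec("code_mask",
                                                 codeMaskRate = 1))
  nCtxCodes <- sum(i1$isCodeToken)
  nTgt <- length(i1$targetCodeIds)
  expect_length(c1$maskPositions, nCtxCodes + nTgt)
  expect_true(all(c1$encIds[c1$maskPositions] == 3L))
  expect_identical(c1$encIds[1:4], i1$contextTokenIds[1:4])
  expect_identical(c1$targetIds,
                   c(i1$contextTokenIds[i1$isCodeToken], i1$targetCodeIds))
  # binomial rate check at 0.25
  set.seed(99)
  tot <- 0L; masked <- 0L
  for (r in 1:300) {
    cc <- corruptForPretraining(i1, corruptionSpec("code_mask"))
    tot <- tot + nCtxCodes + nTgt
    masked <- masked + length(cc$maskPositions)
  }
  expect_lt(abs(masked / tot - 0.25), 3 * sqrt(0.25 * 0.75 / tot))
  # at least one code is always masked even at tiny rates
  set.seed(5)
  cc <- corruptForPretraining(i1, corruptionSpec("code_mask",
                                                 codeMaskRate = 1e-9))
  expect_gte(length(cc$maskPositions), 1L)
})

test_that("daysdiff instances are invariant under a global date shift", {
  sc <- smallCohort()
  p <- patients(sc$co)[[2]]
  shifted <- p
  shifted$visits <- lapply(p$visits, function(v) {
    v$date <- v$date + 37L; v
  })
  a <- expandRecursiveInstances(p, sc$vocab, "daysdiff")
  b <- expandRecursiveInstances(shifted, sc$vocab, "daysdiff")
  for (k in seq_along(a)) {
    expect_identical(a[[k]]$contextTokenIds, b[[k]]$contextTokenIds)
    expect_identical(a[[k]]$contextTimeValue, b[[k]]$contextTimeValue)
  }
  # date mode is equivariant instead
  a2 <- expandRecursiveInstances(p, sc$vocab, "date")
  b2 <- expandRecursiveInstances(shifted, sc$vocab, "date")
  expect_equal(b2[[1]]$contextTimeValue[-(1:4)],
               a2[[1]]$contextTimeValue[-(1:4)] + 37)
})
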