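# The model's losses are checked against independent cross-entropy
# computations on the returned logits, gradients against central finite
# differences, and the embedding/time machinery against closed forms.

test_that("sinusoidal embedding matches the closed form and is 0/1 at t = 0", {
  d <- 8L
  E <- nextvisit:::sinusoidalEmbedding(c(0, 5), d)
  expect_equal(E[1, ], rep(c(0, 1), d / 2))
  i <- 1:(d / 2)
  freq <- 1 / 10000^((2 * (i - 1)) / d)
  expect_equal(E[2, 2 * i - 1], sin(5 * freq))
  expect_equal(E[2, 2 * i], cos(5 * freq))
})

test_that("input embeddings are additive in code, visit and time terms", {
  sc <- smallCohort()
  m <- toyModel("encoder_decoder", sc$vocab)
  enc <- list(encIds = c(7L, 9L), encVisitIndex = c(2L, 2L),
              encTimeValue = c(4, 4))
  X <- embedInputs(m, enc)
  # two tokens sharing visit index and time differ by code embeddings alone
  expect_equal(X[1, ] - X[2, ],
               m@params$emb$code[8, ] - m@params$emb$code[10, ])
  # visit index beyond the table is a configuration error
  expect_error(embedInputs(m, list(encIds = 1L, encVisitIndex = 999L,
                                   encTimeValue = 0)), "maxVisits")
})

test_that("teacher-forced generative loss equals an independent cross-entropy", {
  sc <- smallCohort()
  m <- toyModel("encoder_decoder", sc$vocab)
  i1 <- expandRecursiveInstances(patients(sc$co)[[1]], sc$vocab)[[1]]
  fw <- forwardGenerative(m, instanceEncoderInput(i1), i1$targetCodeIds)
  # oracle: row-wise -log softmax at the true targets, from the logits
  tgt <- c(i1$targetCodeIds, 2L) + 1L      # EOS id 2, 1-based
  want <- mean(vapply(seq_along(tgt), function(r) {
    z <- fw$logits[r, ]
    -(z[tgt[r]] - max(z) - log(sum(exp(z - max(z)))))
  }, 0))
  expect_equal(fw$loss, want, tolerance = 1e-10)
  expect_equal(nrow(fw$logits), length(tgt))
})

test_that("uniform logits give loss ln(V) for generative and masked-LM paths", {
  sc <- smallCohort()
  V <- vocabSize(sc$vocab)
  m <- toyModel("encoder_decoder", sc$vocab)
  m@params$out$W[] <- 0
  m@params$out$b[] <- 0
  i1 <- expandCohortInstances(sc$co, sc$vocab)[[1]]
  fw <- forwardGenerative(m, instanceEncoderInput(i1), i1$targetCodeIds)
  expect_equal(fw$loss, log(V), tolerance = 1e-12)
  m2 <- toyModel("encoder_only", sc$vocab)
  m2@params$out$W[] <- 0
  m2@params$out$b[] <- 0
  set.seed(2)
  cm <- corruptForPretraining(i1, corruptionSpec("code_mask"))
  fm <- forwardMaskedLM(m2, cm, cm$maskPositions, cm$targetIds)
  expect_equal(fm$loss, log(V), tolerance = 1e-12)
})

test_that("masked-LM loss uses masked positions only", {
  sc <- smallCohort()
  m2 <- toyModel("encoder_only", sc$vocab)
  i1 <- expandCohortInstances(sc$co, sc$vocab)[[2]]
  set.seed(4)
  cm <- corruptForPretraining(i1, corruptionSpec("code_mask"))
  f1 <- forwardMaskedLM(m2, cm, cm$maskPositions, cm$targetIds)
  # single masked position: loss is that position's -log softmax prob
  one <- forwardMaskedLM(m2, cm, cm$maskPositions[1], cm$targetIds[1])
  z <- one$logits[1, ]
  expect_equal(one$loss,
               -(z[cm$targetIds[1] + 1] - max(z) -
                   log(sum(exp(z - max(z))))), tolerance = 1e-10)
  # perturbing labels at unmasked positions cannot change the loss
  expect_error(forwardMaskedLM(m2, cm, integer(0), integer(0)),
               "at least one masked position")
  expect_equal(f1$loss,
               forwardMaskedLM(m2, cm, cm$maskPositions, cm$targetIds)$loss)
})

test_that("analytic gradients match central finite differences on all loss paths", {
  sc <- smallCohort()
  i1 <- expandCohortInstances(sc$co, sc$vocab)[[3]]
  checkGrads <- function(m, lossFn, nprobe = 60L) {
    g <- lossFn(m)$grads
    paths <- nextvisit:::paramPaths(m@params)
    set.seed(99)
    for (r in seq_len(nprobe)) {
      p <- paths[[sample.int(length(paths), 1)]]
      w <- m@params[[p]]
      k <- sample.int(length(w), 1)
      eps <- 1e-5
      m1 <- m; m1@params[[p]][k] <- w[k] + eps
      m2 <- m; m2@params[[p]][k] <- w[k] - eps
      num <- (lossFn(m1)$loss - lossFn(m2)$loss) / (2 * eps)
      ga <- nextvisit:::treeGet(g, p)
      ana <- if (is.null(ga)) 0 else ga[k]
      expect_lt(abs(num - ana), 1e-4 * max(1, abs(num) + abs(ana)))
    }
  }
  m <- toyModel("encoder_decoder", sc$vocab)
  set.seed(3)
  cv <- corruptForPretraining(i1, corruptionSpec("visit_mask"))
  checkGrads(m, function(mm)
    forwardGenerative(mm, cv, cv$targetIds, computeGrads = TRUE))
  mh <- attachHead(m, "multilabel_classifier", 3L)
  set.seed(11)
  mh@params$cls$W <- matrix(rnorm(16 * 3, 0, 0.5), 16, 3)
  enc <- instanceEncoderInput(i1)
  checkGrads(mh, function(mm)
    forwardClassifier(mm, enc, labels = c(1, 0, 1), computeGrads = TRUE))
  m2 <- toyModel("encoder_only", sc$vocab, seed = 8L)
  set.seed(5)
  cm <- corruptForPretraining(i1, corruptionSpec("code_mask"))
  checkGrads(m2, function(mm)
    forwardMaskedLM(mm, cm, cm$maskPositions, cm$targetIds,
                    computeGrads = TRUE))
})

test_that("packed mini-batches reproduce single-instance numerics", {
  sc <- smallCohort()
  inst <- expandCohortInstances(sc$co, sc$vocab)
  m <- toyModel("encoder_decoder", sc$vocab)
  set.seed(6)
  corrs <- lapply(inst[1:3], corruptForPretraining,
                  cspec = corruptionSpec("visit_mask", visitDropRate = 0))
  fb <- nextvisit:::fwdGenBatch(m, corrs)
  singles <- lapply(corrs, function(co)
    forwardGenerative(m, co, co$targetIds))
  lens <- vapply(corrs, function(co) length(co$targetIds) + 1L, 0L)
  expect_equal(fb$loss,
               sum(vapply(singles, `[[`, 0, "loss") * lens) / sum(lens),
               tolerance = 1e-10)
  expect_equal(fb$logits[seq_len(lens[1]), ], singles[[1]]$logits,
               tolerance = 1e-10)
  # classifier batch equals per-instance scores
  mh <- attachHead(m, "binary_classifier")
  set.seed(7)
  mh@params$cls$W <- matrix(rnorm(16, 0, 0.3), 16, 1)
  encs <- lapply(inst[1:3], instanceEncoderInput)
  sb <- nextvisit:::fwdClsBatch(mh, encs)$scores
  for (j in 1:3)
    expect_equal(sb[j, ], forwardClassifier(mh, encs[[j]])$scores,
                 tolerance = 1e-10)
})

test_that("a zero-weight linear head scores 0.5 and multilabel scores stay in (0,1)", {
  sc <- smallCohort()
  m <- attachHead(toyModel("encoder_decoder", sc$vocab),
                  "multilabel_classifier", 10L)
  enc <- instanceEncoderInput(expandCohortInstances(sc$co, sc$vocab)[[1]])
  s <- forwardClassifier(m, enc)$scores
  expect_equal(s, rep(0.5, 10))
  set.seed(2)
  m@params$cls$W <- matrix(rnorm(16 * 10), 16, 10)
  s2 <- forwardClassifier(m, enc)$scores
  expect_length(s2, 10L)
  expect_true(all(s2 > 0 & s2 < 1))
})

test_that("greedy generation is deterministic and never repeats a code", {
  sc <- smallCohort()
  m <- toyModel("encoder_decoder", sc$vocab)
  enc <- instanceEncoderInput(expandCohortInstances(sc$co, sc$vocab)[[4]])
  g1 <- generateNextVisit(m, enc, sc$vocab, maxCodes = 8L)
  g2 <- generateNextVisit(m, enc, sc$vocab, maxCodes = 8L)
  expect_identical(g1, g2)
  expect_false(any(duplicated(g1$code)))
  # generated tokens are codes, never demographic or special tokens
  expect_false(any(grepl("=", g1$code, fixed = TRUE)))
  expect_false(any(g1$code %in% c("[PAD]", "[BOS]", "[EOS]", "[MASK]",
                                  "[UNK]")))
})

test_that("first-step probabilities are a proper distribution", {
  sc <- smallCohort()
  m <- toyModel("encoder_decoder", sc$vocab)
  encs <- lapply(expandCohortInstances(sc$co, sc$vocab)[1:4],
                 instanceEncoderInput)
  P <- nextVisitProbsMany(m, encs)
  expect_equal(rowSums(P), rep(1, 4))
  expect_true(all(P >= 0))
  expect_equal(nextVisitProbs(m, encs[[1]]), P[1, ])
})

test_that("matched encoder-only and encoder-decoder configs differ by < 10% in parameters", {
  # the comparison pairing used throughout: 2+2 encoder-decoder vs a
  # 5-layer encoder-only model of the same width
  encdec <- seqModelConfig("encoder_decoder", vocabSize = 100L,
                           dModel = 128L, nHeads = 4L, nEncoderLayers = 2L,
                           nDecoderLayers = 2L)
  enconly <- seqModelConfig("encoder_only", vocabSize = 100L, dModel = 128L,
                            nHeads = 4L, nEncoderLayers = 5L)
  p1 <- parameterCount(encdec)
  p2 <- parameterCount(enconly)
  expect_lt(abs(p1 - p2) / max(p1, p2), 0.10)
})

test_that("daysdiff models are end-to-end invariant to global date shifts", {
  sc <- smallCohort()
  p <- patients(sc$co)[[2]]
  shifted <- p
  shifted$visits <- lapply(p$visits, function(v) {
    v$date <- v$date + 365L; v
  })
  m <- attachHead(toyModel("encoder_decoder", sc$vocab),
                  "binary_classifier")
  set.seed(3)
  m@params$cls$W <- matrix(rnorm(16, 0, 0.3), 16, 1)
  e1 <- classifierInput(p, sc$vocab, "daysdiff")
  e2 <- classifierInput(shifted, sc$vocab, "daysdiff")
  expect_equal(forwardClassifier(m, e1)$scores,
               forwardClassifier(m, e2)$scores)
  expect_equal(nextVisitProbs(m, e1), nextVisitProbs(m, e2))
})
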