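#' @include AllClasses.R model-layers.R
NULL

# ---- initialization ---------------------------------------------------------

tnMat <- function(nr, nc, sd = 0.02) matrix(rtruncnorm(nr * nc, sd), nr, nc)

initAttnParams <- function(d) {
  list(Wq = tnMat(d, d), bq = numeric(d), Wk = tnMat(d, d), bk = numeric(d),
       Wv = tnMat(d, d), bv = numeric(d), Wo = tnMat(d, d), bo = numeric(d))
}

initEncLayer <- function(d, ffn) {
  list(ln1 = list(g = rep(1, d), b = numeric(d)),
       attn = initAttnParams(d),
       ln2 = list(g = rep(1, d), b = numeric(d)),
       ffn = list(W1 = tnMat(d, ffn), b1 = numeric(ffn),
                  W2 = tnMat(ffn, d), b2 = numeric(d)))
}

initDecLayer <- function(d, ffn) {
  list(ln1 = list(g = rep(1, d), b = numeric(d)),
       self = initAttnParams(d),
       ln2 = list(g = rep(1, d), b = numeric(d)),
       cross = initAttnParams(d),
       ln3 = list(g = rep(1, d), b = numeric(d)),
       ffn = list(W1 = tnMat(d, ffn), b1 = numeric(ffn),
                  W2 = tnMat(ffn, d), b2 = numeric(d)))
}

#' Initialize a sequence model
#'
#' All weights are drawn truncated-normal (sd 0.02, clipped at 2 sd) from
#' the config seed; layer-norm gains start at 1 and all biases at 0.
#'
#' @param config a [SeqModelConfig-class].
#' @param vocab the [CodeVocabulary-class] the model will be used with (its
#'   hash is stored and later checked), or a hash string.
#' @return an [EHRModel-class] with no task head attached.
#' @export
initModel <- function(config, vocab) {
  validObject(config)
  vh <- if (is(vocab, "CodeVocabulary")) vocabHash(vocab)
        else as.character(vocab)
  d <- config@dModel; ffn <- config@ffnDim
  params <- withSeed(config@seed, {
    p <- list(emb = list(code = tnMat(config@vocabSize, d),
                         visit = tnMat(config@maxVisits + 1L, d)))
    for (i in seq_len(config@nEncoderLayers))
      p[[paste0("enc", i)]] <- initEncLayer(d, ffn)
    p$encf <- list(g = rep(1, d), b = numeric(d))
    for (i in seq_len(config@nDecoderLayers))
      p[[paste0("dec", i)]] <- initDecLayer(d, ffn)
    if (config@nDecoderLayers > 0L)
      p$decf <- list(g = rep(1, d), b = numeric(d))
    p$out <- list(W = tnMat(d, config@vocabSize),
                  b = numeric(config@vocabSize))
    p
  })
  new("EHRModel", config = config, params = params, head = list(),
      vocabHash = vh)
}

#' Attach a task-specific classifier head
#'
#' Adds a linear layer read from the first decoder step's hidden state
#' (encoder-decoder) or the pooling token's final encoder state
#' (encoder-only), mapped through a sigmoid per output. The linear layer is
#' zero-initialized, so an untrained head scores every input at 0.5.
#'
#' @param model an [EHRModel-class].
#' @param kind `"binary_classifier"` (1 output) or `"multilabel_classifier"`.
#' @param nOutputs number of outputs (1 for binary).
#' @return the model with a head attached.
#' @export
attachHead <- function(model, kind = c("binary_classifier",
                                       "multilabel_classifier"),
                       nOutputs = 1L) {
  kind <- match.arg(kind)
  if (kind == "binary_classifier") nOutputs <- 1L
  model@params$cls <- list(W = matrix(0, model@config@dModel, nOutputs),
                           b = numeric(nOutputs))
  model@head <- list(kind = kind, nOutputs = as.integer(nOutputs))
  model
}

#' Total number of learned parameters
#'
#' Used to configure encoder-only baselines that match an encoder-decoder
#' model's capacity (the comparison convention is a parameter-count gap
#' under 10\%).
#'
#' @param model an [EHRModel-class] or [SeqModelConfig-class].
#' @return integer parameter count.
#' @export
parameterCount <- function(model) {
  if (is(model, "SeqModelConfig")) model <- initModel(model, "probe")
  sum(vapply(paramPaths(model@params), function(p)
    length(model@params[[p]]), 0))
}

# ---- embedding --------------------------------------------------------------

#' Embed an encoder input sequence
#'
#' Each token vector is the sum of its learned code embedding, the learned
#' embedding of its visit index (0 = demographics block), and the sinusoidal
#' embedding of its time value; with `timeMode = "none"` the time term is a
#' zero vector.
#'
#' @param model an [EHRModel-class].
#' @param enc list with `encIds` (0-based token ids), `encVisitIndex` and
#'   `encTimeValue`, as produced by [corruptForPretraining()] or
#'   [classifierInput()].
#' @return an n x dModel matrix.
#' @export
embedInputs <- function(model, enc) {
  cfg <- model@config
  if (any(enc$encIds >= cfg@vocabSize))
    stopf("token id %d outside vocabulary of size %d",
          max(enc$encIds), cfg@vocabSize)
  if (any(enc$encVisitIndex > cfg@maxVisits))
    stopf("visit index %d exceeds the visit-embedding table (maxVisits = %d)",
          max(enc$encVisitIndex), cfg@maxVisits)
  X <- model@params$emb$code[enc$encIds + 1L, , drop = FALSE] +
    model@params$emb$visit[enc$encVisitIndex + 1L, , drop = FALSE]
  if (cfg@timeMode != "none")
    X <- X + sinusoidalEmbedding(enc$encTimeValue, cfg@dModel)
  X
}

# Pack several encoder inputs into one sequence; `inst` tags each token
# with its instance so attention masks can keep instances separate, and
# `offsets` gives the first row of each instance.
packEncs <- function(encs) {
  lens <- vapply(encs, function(e) length(e$encIds), 0L)
  list(encIds = as.integer(unlist(lapply(encs, `[[`, "encIds"))),
       encVisitIndex = as.integer(unlist(lapply(encs, `[[`,
                                                "encVisitIndex"))),
       encTimeValue = as.numeric(unlist(lapply(encs, `[[`, "encTimeValue"))),
       inst = rep(seq_along(encs), lens),
       offsets = cumsum(c(1L, lens[-length(lens)])),
       lens = lens)
}

# ---- encoder ----------------------------------------------------------------

encoderFwd <- function(params, cfg, enc, training = FALSE) {
  model <- new("EHRModel", config = cfg, params = params, head = list(),
               vocabHash = "")
  X <- embedInputs(model, enc)
  mask <- if (!is.null(enc$inst) && enc$inst[length(enc$inst)] > 1L)
    outer(enc$inst, enc$inst, "==") else NULL
  dr <- cfg@dropout
  caches <- list(emb = dropFwd(X, dr, training))
  X <- caches$emb$out
  for (i in seq_len(cfg@nEncoderLayers)) {
    p <- params[[paste0("enc", i)]]
    l1 <- lnFwd(X, p$ln1$g, p$ln1$b)
    at <- attnFwd(l1$out, l1$out, p$attn, cfg@nHeads, mask = mask)
    d1 <- dropFwd(at$out, dr, training)
    X1 <- X + d1$out
    l2 <- lnFwd(X1, p$ln2$g, p$ln2$b)
    ff <- ffnFwd(l2$out, p$ffn)
    d2 <- dropFwd(ff$out, dr, training)
    caches[[paste0("enc", i)]] <- list(l1 = l1, at = at, d1 = d1, X1 = X1,
                                       l2 = l2, ff = ff, d2 = d2)
    X <- X1 + d2$out
  }
  lf <- lnFwd(X, params$encf$g, params$encf$b)
  caches$encf <- lf
  list(H = lf$out, caches = caches, enc = enc)
}

encoderBwd <- function(dH, fwd, params, cfg) {
  grads <- list()
  lb <- lnBwd(dH, fwd$caches$encf, params$encf$g)
  grads$encf <- list(g = lb$dg, b = lb$db)
  dX <- lb$dX
  for (i in rev(seq_len(cfg@nEncoderLayers))) {
    p <- params[[paste0("enc", i)]]
    cc <- fwd$caches[[paste0("enc", i)]]
    dff <- ffnBwd(dropBwd(dX, cc$d2), cc$ff, p$ffn)
    l2b <- lnBwd(dff$dX, cc$l2, p$ln2$g)
    dX1 <- dX + l2b$dX
    ab <- attnBwd(dropBwd(dX1, cc$d1), cc$at, p$attn, cfg@nHeads)
    l1b <- lnBwd(ab$dXq + ab$dXkv, cc$l1, p$ln1$g)
    grads[[paste0("enc", i)]] <- list(
      ln1 = list(g = l1b$dg, b = l1b$db), attn = ab$grads,
      ln2 = list(g = l2b$dg, b = l2b$db), ffn = dff$grads)
    dX <- dX1 + l1b$dX
  }
  dX <- dropBwd(dX, fwd$caches$emb)
  emb <- list(code = matrix(0, cfg@vocabSize, cfg@dModel),
              visit = matrix(0, cfg@maxVisits + 1L, cfg@dModel))
  rc <- rowsum(dX, fwd$enc$encIds)
  emb$code[as.integer(rownames(rc)) + 1L, ] <- rc
  rv <- rowsum(dX, fwd$enc$encVisitIndex)
  emb$visit[as.integer(rownames(rv)) + 1L, ] <- rv
  grads$emb <- emb
  grads
}

# ---- decoder ----------------------------------------------------------------

# decPos: within-instance positions (1-based); decInst/encInst: instance
# tags for packed batches (NULL = single instance).
decoderFwd <- function(params, cfg, decIds, H, training = FALSE,
                       decInst = NULL, decPos = NULL, encInst = NULL) {
  dr <- cfg@dropout
  if (is.null(decPos)) decPos <- seq_along(decIds)
  selfMask <- outer(decPos, decPos, ">=")
  crossMask <- NULL
  if (!is.null(decInst)) {
    selfMask <- selfMask & outer(decInst, decInst, "==")
    if (!is.null(encInst) && decInst[length(decInst)] > 1L)
      crossMask <- outer(decInst, encInst, "==")
  }
  Y <- params$emb$code[decIds + 1L, , drop = FALSE] +
    sinusoidalEmbedding(decPos, cfg@dModel)
  caches <- list(emb = dropFwd(Y, dr, training))
  Y <- caches$emb$out
  for (i in seq_len(cfg@nDecoderLayers)) {
    p <- params[[paste0("dec", i)]]
    l1 <- lnFwd(Y, p$ln1$g, p$ln1$b)
    sa <- attnFwd(l1$out, l1$out, p$self, cfg@nHeads, mask = selfMask)
    d1 <- dropFwd(sa$out, dr, training)
    Y1 <- Y + d1$out
    l2 <- lnFwd(Y1, p$ln2$g, p$ln2$b)
    ca <- attnFwd(l2$out, H, p$cross, cfg@nHeads, mask = crossMask)
    d2 <- dropFwd(ca$out, dr, training)
    Y2 <- Y1 + d2$out
    l3 <- lnFwd(Y2, p$ln3$g, p$ln3$b)
    ff <- ffnFwd(l3$out, p$ffn)
    d3 <- dropFwd(ff$out, dr, training)
    caches[[paste0("dec", i)]] <- list(l1 = l1, sa = sa, d1 = d1, Y1 = Y1,
                                       l2 = l2, ca = ca, d2 = d2, Y2 = Y2,
                                       l3 = l3, ff = ff, d3 = d3)
    Y <- Y2 + d3$out
  }
  lf <- lnFwd(Y, params$decf$g, params$decf$b)
  caches$decf <- lf
  list(Hd = lf$out, caches = caches, decIds = decIds)
}

decoderBwd <- function(dHd, fwd, params, cfg) {
  grads <- list()
  lb <- lnBwd(dHd, fwd$caches$decf, params$decf$g)
  grads$decf <- list(g = lb$dg, b = lb$db)
  dY <- lb$dX
  dH <- NULL
  for (i in rev(seq_len(cfg@nDecoderLayers))) {
    p <- params[[paste0("dec", i)]]
    cc <- fwd$caches[[paste0("dec", i)]]
    dff <- ffnBwd(dropBwd(dY, cc$d3), cc$ff, p$ffn)
    l3b <- lnBwd(dff$dX, cc$l3, p$ln3$g)
    dY2 <- dY + l3b$dX
    cb <- attnBwd(dropBwd(dY2, cc$d2), cc$ca, p$cross, cfg@nHeads)
    dH <- treeAdd(dH, cb$dXkv)
    l2b <- lnBwd(cb$dXq, cc$l2, p$ln2$g)
    dY1 <- dY2 + l2b$dX
    sb <- attnBwd(dropBwd(dY1, cc$d1), cc$sa, p$self, cfg@nHeads)
    l1b <- lnBwd(sb$dXq + sb$dXkv, cc$l1, p$ln1$g)
    grads[[paste0("dec", i)]] <- list(
      ln1 = list(g = l1b$dg, b = l1b$db), self = sb$grads,
      ln2 = list(g = l2b$dg, b = l2b$db), cross = cb$grads,
      ln3 = list(g = l3b$dg, b = l3b$db), ffn = dff$grads)
    dY <- dY1 + l1b$dX
  }
  dY <- dropBwd(dY, fwd$caches$emb)
  emb <- list(code = matrix(0, cfg@vocabSize, cfg@dModel))
  rc <- rowsum(dY, fwd$decIds)
  emb$code[as.integer(rownames(rc)) + 1L, ] <- rc
  grads$emb <- emb
  list(grads = grads, dH = dH)
}

# ---- batched loss paths -----------------------------------------------------

# Batched teacher-forced generative loss over a list of corrupted instances
# (each with encIds/encVisitIndex/encTimeValue and targetIds). One packed
# forward/backward for the whole mini-batch; loss is the mean token
# cross-entropy over all target positions of the batch.
fwdGenBatch <- function(model, corrs, training = FALSE, computeGrads = FALSE) {
  cfg <- model@config
  enc <- packEncs(corrs)
  decLens <- vapply(corrs, function(co) length(co$targetIds) + 1L, 0L)
  decIds <- unlist(lapply(corrs, function(co) c(BOS_ID, co$targetIds)))
  decTgt <- unlist(lapply(corrs, function(co) c(co$targetIds, EOS_ID)))
  decPos <- unlist(lapply(decLens, seq_len))
  decInst <- rep(seq_along(corrs), decLens)
  ef <- encoderFwd(model@params, cfg, enc, training)
  df <- decoderFwd(model@params, cfg, decIds, ef$H, training,
                   decInst = decInst, decPos = decPos, encInst = enc$inst)
  lin <- linFwd(df$Hd, model@params$out$W, model@params$out$b)
  ce <- ceFwd(lin$out, decTgt + 1L, wantGrad = computeGrads)
  res <- list(loss = ce$loss, logits = lin$out, logp = ce$logp)
  if (computeGrads) {
    lb <- linBwd(ce$dlogits, lin, model@params$out$W)
    db <- decoderBwd(lb$dX, df, model@params, cfg)
    eg <- encoderBwd(db$dH, ef, model@params, cfg)
    grads <- treeAdd(db$grads, eg)
    grads$out <- list(W = lb$dW, b = lb$db)
    res$grads <- grads
  }
  res
}

# Batched masked-LM loss over a list of corrupted instances carrying
# maskPositions/targetIds (encoder-only architecture).
fwdMlmBatch <- function(model, corrs, training = FALSE, computeGrads = FALSE) {
  cfg <- model@config
  enc <- packEncs(corrs)
  pos <- unlist(lapply(seq_along(corrs), function(i)
    corrs[[i]]$maskPositions + enc$offsets[i] - 1L))
  targets <- unlist(lapply(corrs, `[[`, "targetIds"))
  if (!length(pos))
    stopf("masked-LM loss requires at least one masked position")
  ef <- encoderFwd(model@params, cfg, enc, training)
  Hm <- ef$H[pos, , drop = FALSE]
  lin <- linFwd(Hm, model@params$out$W, model@params$out$b)
  ce <- ceFwd(lin$out, targets + 1L, wantGrad = computeGrads)
  res <- list(loss = ce$loss, logits = lin$out, logp = ce$logp)
  if (computeGrads) {
    lb <- linBwd(ce$dlogits, lin, model@params$out$W)
    dH <- matrix(0, nrow(ef$H), cfg@dModel)
    dH[pos, ] <- dH[pos, , drop = FALSE] + lb$dX
    grads <- encoderBwd(dH, ef, model@params, cfg)
    grads$out <- list(W = lb$dW, b = lb$db)
    res$grads <- grads
  }
  res
}

# Batched classifier pass over a list of encoder inputs; Y is an optional
# b x k 0/1 label matrix.
fwdClsBatch <- function(model, encs, Y = NULL, training = FALSE,
                        computeGrads = FALSE) {
  cfg <- model@config
  encdec <- cfg@architecture == "encoder_decoder"
  if (!encdec) encs <- lapply(encs, poolEncInput)
  enc <- packEncs(encs)
  b <- length(encs)
  ef <- encoderFwd(model@params, cfg, enc, training)
  if (encdec) {
    df <- decoderFwd(model@params, cfg, rep(BOS_ID, b), ef$H, training,
                     decInst = seq_len(b), decPos = rep(1L, b),
                     encInst = enc$inst)
    h <- df$Hd
  } else h <- ef$H[enc$offsets, , drop = FALSE]
  logits <- addBias(h %*% model@params$cls$W, model@params$cls$b)
  scores <- 1 / (1 + exp(-logits))
  res <- list(scores = scores)
  if (!is.null(Y)) {
    eps <- 1e-12
    # mean over instances, sum over outputs: keeps per-output gradient
    # magnitudes comparable between binary and multilabel heads
    res$loss <- -sum(Y * log(scores + eps) +
                       (1 - Y) * log(1 - scores + eps)) / b
    if (computeGrads) {
      dlogits <- (scores - Y) / b
      grads <- list(cls = list(W = crossprod(h, dlogits),
                               b = colSums(dlogits)))
      dh <- tcrossprod(dlogits, model@params$cls$W)
      if (encdec) {
        db <- decoderBwd(dh, df, model@params, cfg)
        eg <- encoderBwd(db$dH, ef, model@params, cfg)
        grads <- treeAdd(grads, treeAdd(db$grads, eg))
      } else {
        dH <- matrix(0, nrow(ef$H), cfg@dModel)
        dH[enc$offsets, ] <- dh
        grads <- treeAdd(grads, encoderBwd(dH, ef, model@params, cfg))
      }
      res$grads <- grads
    }
  }
  res
}

# ---- public single-instance operations --------------------------------------

#' Teacher-forced generative forward pass
#'
#' Encodes the (corrupted) context and decodes the target codes with
#' teacher forcing: the decoder input is `BOS + targets`, the prediction
#' targets are `targets + EOS`, and position t's logits condition on the
#' encoder states (via cross-attention) and targets before t. The loss is
#' the mean token cross-entropy over target positions.
#'
#' @param model an encoder-decoder [EHRModel-class].
#' @param enc encoder input (see [embedInputs()]).
#' @param targetIds 0-based ids of the target codes in priority order
#'   (without BOS/EOS; they are added here).
#' @param training apply dropout (draws from the caller's RNG stream).
#' @param computeGrads also return parameter gradients of the loss.
#' @return list with `loss`, `logits` (one row per target position, columns
#'   = vocabulary), and optionally `grads`.
#' @export
forwardGenerative <- function(model, enc, targetIds, training = FALSE,
                              computeGrads = FALSE) {
  cfg <- model@config
  if (cfg@architecture != "encoder_decoder")
    stopf("forwardGenerative requires an encoder_decoder model")
  if (length(targetIds) + 1L > cfg@maxLen)
    stopf("target longer than maxLen (%d codes)", cfg@maxLen)
  co <- list(encIds = enc$encIds, encVisitIndex = enc$encVisitIndex,
             encTimeValue = enc$encTimeValue, targetIds = targetIds)
  fwdGenBatch(model, list(co), training, computeGrads)
}

#' Masked-language-model forward pass (encoder-only baseline)
#'
#' @param model an encoder-only [EHRModel-class].
#' @param enc corrupted encoder input containing `[MASK]` tokens.
#' @param maskPositions 1-based positions of the masked tokens.
#' @param targetIds true 0-based ids at those positions.
#' @inheritParams forwardGenerative
#' @return list with `loss` (mean cross-entropy at masked positions only),
#'   `logits` (one row per masked position), optionally `grads`.
#' @export
forwardMaskedLM <- function(model, enc, maskPositions, targetIds,
                            training = FALSE, computeGrads = FALSE) {
  co <- list(encIds = enc$encIds, encVisitIndex = enc$encVisitIndex,
             encTimeValue = enc$encTimeValue,
             maskPositions = maskPositions, targetIds = targetIds)
  fwdMlmBatch(model, list(co), training, computeGrads)
}

# Prepend the pooling token (BOS doubles as [CLS]) for encoder-only
# classification.
poolEncInput <- function(enc)
  list(encIds = c(BOS_ID, enc$encIds),
       encVisitIndex = c(0L, enc$encVisitIndex),
       encTimeValue = c(0, enc$encTimeValue))

#' Classifier forward pass
#'
#' For an encoder-decoder model, the classifier reads the decoder's hidden
#' state at the BOS position (the first decode step); for an encoder-only
#' model it reads the pooled encoder state at a designated pooling token
#' prepended to the input. Scores are sigmoid-mapped per output.
#'
#' @param model an [EHRModel-class] with a head attached ([attachHead()]).
#' @param enc encoder input.
#' @param labels optional 0/1 vector (length `nOutputs`); when supplied, the
#'   mean binary cross-entropy is returned (and its gradients if requested).
#' @inheritParams forwardGenerative
#' @return list with `scores` in (0,1), and `loss`/`grads` when labels are
#'   given.
#' @export
forwardClassifier <- function(model, enc, labels = NULL, training = FALSE,
                              computeGrads = FALSE) {
  if (!length(model@head)) stopf("no task head attached; see attachHead()")
  Y <- if (is.null(labels)) NULL else matrix(as.numeric(labels), nrow = 1L)
  res <- fwdClsBatch(model, list(enc), Y, training, computeGrads)
  res$scores <- as.numeric(res$scores)
  res
}

#' Next-visit code probabilities at the first decode step
#'
#' Softmax distribution over the vocabulary for the primary diagnosis of
#' the next visit, conditioned on the encoded context only (decoder input =
#' BOS). This is the zero-shot generative score a pretrained model assigns
#' to each code.
#'
#' @param model an encoder-decoder [EHRModel-class].
#' @param enc encoder input.
#' @param vocab optional [CodeVocabulary-class] for naming.
#' @return named numeric probability vector of length `vocabSize`.
#' @export
nextVisitProbs <- function(model, enc, vocab = NULL) {
  p <- nextVisitProbsMany(model, list(enc))[1L, ]
  if (!is.null(vocab)) names(p) <- vocab@tokens
  p
}

#' @describeIn nextVisitProbs vectorized over a list of encoder inputs;
#'   returns a length(encs) x vocabSize matrix of first-step probabilities.
#' @param encs list of encoder inputs.
#' @param chunkSize contexts per packed forward pass.
#' @export
nextVisitProbsMany <- function(model, encs, chunkSize = 8L) {
  cfg <- model@config
  out <- matrix(0, length(encs), cfg@vocabSize)
  for (start in seq(1L, length(encs), by = chunkSize)) {
    ix <- start:min(start + chunkSize - 1L, length(encs))
    enc <- packEncs(encs[ix])
    b <- length(ix)
    ef <- encoderFwd(model@params, cfg, enc, FALSE)
    df <- decoderFwd(model@params, cfg, rep(BOS_ID, b), ef$H, FALSE,
                     decInst = seq_len(b), decPos = rep(1L, b),
                     encInst = enc$inst)
    logits <- addBias(df$Hd %*% model@params$out$W, model@params$out$b)
    z <- logits - rowMaxs(logits)
    e <- exp(z)
    out[ix, ] <- e / rowSums(e)
  }
  out
}

#' Autoregressively generate the next visit's codes
#'
#' Decodes from BOS until EOS or `maxCodes`, excluding special and
#' demographic tokens and never repeating an already-emitted code (a visit
#' holds no duplicate codes). Emission order is priority order: the first
#' generated code is the predicted primary diagnosis.
#'
#' @param model an encoder-decoder [EHRModel-class].
#' @param enc encoder input.
#' @param vocab a [CodeVocabulary-class] (used to identify code tokens and
#'   name the output).
#' @param maxCodes maximum number of codes to emit.
#' @param strategy `"greedy"` (deterministic argmax) or
#'   `"top_k_probability"` (sample among the k most probable candidates).
#' @param topK k for the sampling strategy.
#' @return data.frame with columns `code` and `probability` (the per-step
#'   model probability of the emitted code).
#' @export
generateNextVisit <- function(model, enc, vocab, maxCodes = 10L,
                              strategy = c("greedy", "top_k_probability"),
                              topK = 5L) {
  strategy <- match.arg(strategy)
  cfg <- model@config
  ef <- encoderFwd(model@params, cfg, enc, FALSE)
  banned <- c(PAD_ID, BOS_ID, MASK_ID, UNK_ID,
              which(grepl("=", vocab@tokens, fixed = TRUE)) - 1L)
  emitted <- integer(0)
  probs <- numeric(0)
  repeat {
    decIn <- c(BOS_ID, emitted)
    df <- decoderFwd(model@params, cfg, decIn, ef$H, FALSE)
    logits <- as.numeric(df$Hd[length(decIn), , drop = FALSE] %*%
                           model@params$out$W + model@params$out$b)
    z <- logits - max(logits)
    p <- exp(z) / sum(exp(z))
    p[c(banned, emitted) + 1L] <- 0
    if (sum(p) == 0) break
    p <- p / sum(p)
    nxt <- if (strategy == "greedy") which.max(p) else {
      cand <- head(order(p, decreasing = TRUE), topK)
      cand[sample.int(length(cand), 1L, prob = p[cand])]
    }
    if (nxt - 1L == EOS_ID) break
    emitted <- c(emitted, nxt - 1L)
    probs <- c(probs, p[nxt])
    if (length(emitted) >= maxCodes) break
  }
  data.frame(code = decodeTokens(vocab, emitted), probability = probs,
             stringsAsFactors = FALSE)
}
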