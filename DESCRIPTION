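Package: nextvisit
Title: Generative Encoder-Decoder Pretraining for Longitudinal Diagnosis-Code Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sequence modelling of longitudinal coded electronic
    health records. Implements a generative encoder-decoder transformer that
    is pretrained by predicting the complete, priority-ordered set of
    diagnosis codes of a masked future visit (visit masking), alongside the
    conventional encoder-only masked-code baseline. Includes S4 containers
    and readers/writers for per-patient visit sequences (JSON-lines and long
    CSV), a seeded synthetic-cohort simulator with planted comorbidity
    clusters, chronic-code recurrence, progression rules and rare outcomes,
    recursive next-visit instance expansion with visit/code/time embeddings,
    pretraining and finetuning loops with multi-seed comparison designs, and
    evaluation utilities for imbalanced clinical outcomes (AUROC, AUPRC,
    PPV and sensitivity at top-k% risk, new-versus-recurrent stratification,
    demographic subgroup reports with bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'cohort-io.R'
    'evaluation.R'
    'synthetic.R'
    'sequence.R'
    'model-layers.R'
    'model.R'
    'training.R'
    'experiments.R'
    'nextvisit-package.R'
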