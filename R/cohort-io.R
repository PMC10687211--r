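#' @include AllClasses.R
NULL

# Merge same-date visits of one patient: code lists are concatenated in visit
# order (earlier-listed visit first) and de-duplicated keeping the first
# occurrence, preserving priority order.
mergeSameDateVisits <- function(visits) {
  dates <- vapply(visits, function(v) as.character(as.Date(v$date)), "")
  if (!anyDuplicated(dates)) {
    ord <- order(as.Date(dates))
    return(lapply(visits[ord], function(v)
      list(date = as.Date(v$date), codes = as.character(v$codes))))
  }
  lapply(sort(unique(as.Date(dates))), function(d) {
    codes <- unlist(lapply(visits[as.Date(dates) == d],
                           function(v) as.character(v$codes)))
    list(date = d, codes = codes[!duplicated(codes)])
  })
}

#' Read a cohort from disk
#'
#' Two interchange formats are supported. `jsonl` is canonical: one JSON
#' object per patient per line with fields `patient_id`, `demographics`
#' (`gender`, `age`, `race`, `marital_status`) and `visits` (each with
#' `date` in ISO-8601 and a priority-ordered `codes` array). `csv-long` is a
#' visits table with columns `patient_id,date,priority,code` (priority 0 =
#' primary diagnosis) plus a demographics table with columns
#' `patient_id,gender,age,race,marital_status`.
#'
#' Visits are sorted by date and same-date visits are merged (codes
#' concatenated, de-duplicated keeping first occurrence). Malformed rows are
#' not dropped silently: all problems are collected and raised together,
#' naming the offending line/patient/field.
#'
#' @param path file path. For `csv-long` this is the visits table; the
#'   demographics table defaults to `<path-sans-ext>_demographics.csv`.
#' @param format `"jsonl"` or `"csv-long"`.
#' @param demographicsPath demographics table path for `csv-long`.
#' @param indexDate optional cohort index date; defaults to the latest visit
#'   date in the file.
#' @return an [EHRCohort-class].
#' @export
readCohort <- function(path, format = c("jsonl", "csv-long"),
                       demographicsPath = NULL, indexDate = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  pats <- if (format == "jsonl") readCohortJsonl(path)
          else readCohortCsvLong(path, demographicsPath)
  ids <- vapply(pats, `[[`, "", "patient_id")
  if (anyDuplicated(ids))
    stopf("duplicate patient_id in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cohort <- EHRCohort(pats, indexDate = indexDate)
  validObject(cohort)
  cohort
}

readCohortJsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  problems <- character(0)
  pats <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      problems <- c(problems, sprintf("line %d: invalid JSON (%s)",
                                      i, conditionMessage(rec)))
      next
    }
    err <- jsonlPatientProblems(rec, i)
    if (length(err)) { problems <- c(problems, err); next }
    visits <- lapply(rec$visits, function(v)
      list(date = as.Date(v$date),
           codes = vapply(v$codes, as.character, "")))
    pats[[i]] <- list(
      patient_id = as.character(rec$patient_id),
      demographics = list(
        gender = as.character(rec$demographics$gender),
        age = as.integer(rec$demographics$age),
        race = as.character(rec$demographics$race),
        marital_status = as.character(rec$demographics$marital_status)),
      visits = mergeSameDateVisits(visits))
  }
  if (length(problems))
    stopf("parse errors in %s:\n  %s", path,
          paste(problems, collapse = "\n  "))
  pats[!vapply(pats, is.null, TRUE)]
}

jsonlPatientProblems <- function(rec, line) {
  msg <- character(0)
  id <- if (is.null(rec$patient_id)) sprintf("line %d", line)
        else sprintf("line %d (patient %s)", line, rec$patient_id)
  if (is.null(rec$patient_id))
    msg <- c(msg, sprintf("line %d: missing field patient_id", line))
  if (is.null(rec$demographics))
    msg <- c(msg, sprintf("%s: missing field demographics", id))
  else for (f in DEMOGRAPHIC_FIELDS)
    if (is.null(rec$demographics[[f]]))
      msg <- c(msg, sprintf("%s: missing demographics field %s", id, f))
  if (is.null(rec$visits) || length(rec$visits) == 0L)
    msg <- c(msg, sprintf("%s: missing or empty visits", id))
  else for (k in seq_along(rec$visits)) {
    v <- rec$visits[[k]]
    if (is.null(v$date) ||
        is.na(suppressWarnings(as.Date(as.character(v$date), optional = TRUE))))
      msg <- c(msg, sprintf("%s: visit %d has a missing/invalid date", id, k))
    if (is.null(v$codes) || length(v$codes) == 0L)
      msg <- c(msg, sprintf("%s: visit %d has an empty code list", id, k))
  }
  msg
}

defaultDemographicsPath <- function(path)
  paste0(tools::file_path_sans_ext(path), "_demographics.csv")

readCohortCsvLong <- function(path, demographicsPath = NULL) {
  demographicsPath <- demographicsPath %||% defaultDemographicsPath(path)
  if (!file.exists(demographicsPath))
    stopf("demographics table not found: %s", demographicsPath)
  vis <- data.table::fread(path, colClasses = list(
    character = c("patient_id", "date", "code"), integer = "priority"))
  dem <- data.table::fread(demographicsPath, colClasses = list(
    character = c("patient_id", "gender", "race", "marital_status"),
    integer = "age"))
  need <- c("patient_id", "date", "priority", "code")
  if (!all(need %in% names(vis)))
    stopf("visits table %s lacks columns: %s", path,
          paste(setdiff(need, names(vis)), collapse = ", "))
  needd <- c("patient_id", DEMOGRAPHIC_FIELDS)
  if (!all(needd %in% names(dem)))
    stopf("demographics table %s lacks columns: %s", demographicsPath,
          paste(setdiff(needd, names(dem)), collapse = ", "))
  problems <- character(0)
  if (anyNA(as.Date(vis$date)))
    problems <- c(problems, sprintf("invalid dates at visits rows: %s",
      paste(head(which(is.na(as.Date(vis$date))), 5L), collapse = ", ")))
  orphans <- setdiff(vis$patient_id, dem$patient_id)
  if (length(orphans))
    problems <- c(problems, sprintf("patients with visits but no demographics: %s",
                                    paste(head(orphans, 5L), collapse = ", ")))
  if (length(problems))
    stopf("parse errors in %s:\n  %s", path, paste(problems, collapse = "\n  "))
  dem <- dem[order(dem$patient_id), ]
  lapply(seq_len(nrow(dem)), function(i) {
    pid <- dem$patient_id[i]
    pv <- vis[vis$patient_id == pid, ]
    if (nrow(pv) == 0L)
      stopf("patient %s has demographics but no visits", pid)
    visits <- lapply(split(pv, as.character(pv$date)), function(g) {
      g <- g[order(g$priority), ]
      list(date = as.Date(g$date[1]), codes = g$code[!duplicated(g$code)])
    })
    visits <- visits[order(as.Date(names(visits)))]
    names(visits) <- NULL
    list(patient_id = pid,
         demographics = list(gender = dem$gender[i], age = as.integer(dem$age[i]),
                             race = dem$race[i],
                             marital_status = dem$marital_status[i]),
         visits = visits)
  })
}

#' Write a cohort to disk
#'
#' Inverse of [readCohort()]: `readCohort(writeCohort(x))` reproduces the
#' cohort field-for-field in either format.
#'
#' @param cohort an [EHRCohort-class].
#' @inheritParams readCohort
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path, format = c("jsonl", "csv-long"),
                        demographicsPath = NULL) {
  format <- match.arg(format)
  stopifnot(is(cohort, "EHRCohort"))
  if (format == "jsonl") {
    lines <- vapply(cohort@patients, function(p) {
      jsonlite::toJSON(list(
        patient_id = p$patient_id,
        demographics = list(gender = p$demographics$gender,
                            age = p$demographics$age,
                            race = p$demographics$race,
                            marital_status = p$demographics$marital_status),
        visits = lapply(p$visits, function(v)
          list(date = format(as.Date(v$date)), codes = as.list(v$codes)))),
        auto_unbox = TRUE)
    }, "")
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  } else {
    demographicsPath <- demographicsPath %||% defaultDemographicsPath(path)
    rows <- lapply(cohort@patients, function(p) {
      do.call(rbind, lapply(p$visits, function(v)
        data.frame(patient_id = p$patient_id, date = format(as.Date(v$date)),
                   priority = seq_along(v$codes) - 1L, code = v$codes,
                   stringsAsFactors = FALSE)))
    })
    vis <- if (length(rows)) do.call(rbind, rows) else
      data.frame(patient_id = character(0), date = character(0),
                 priority = integer(0), code = character(0))
    dem <- do.call(rbind, c(list(
      data.frame(patient_id = character(0), gender = character(0),
                 age = integer(0), race = character(0),
                 marital_status = character(0))),
      lapply(cohort@patients, function(p)
        data.frame(patient_id = p$patient_id, gender = p$demographics$gender,
                   age = p$demographics$age, race = p$demographics$race,
                   marital_status = p$demographics$marital_status,
                   stringsAsFactors = FALSE))))
    data.table::fwrite(vis, path)
    data.table::fwrite(dem, demographicsPath)
  }
  invisible(path)
}

#' Keep only patients with at least a minimum number of visits
#'
#' The standard inclusion rule requires at least two visits: one outcome
#' visit and at least one prior visit usable as context.
#'
#' @param cohort an [EHRCohort-class].
#' @param minVisits minimum visit count (>= 1).
#' @return a new [EHRCohort-class]; the input is unchanged.
#' @export
filterMinVisits <- function(cohort, minVisits) {
  stopifnot(minVisits >= 1)
  keep <- visitCounts(cohort) >= minVisits
  EHRCohort(cohort@patients[keep], indexDate = cohort@indexDate)
}
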