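# Cohort table I/O, covariate discretization, and natural-language prompt
# serialization with an explicit missingness contract: a missing value is
# never silently defaulted, it is carried as NA end-to-end and surfaces as a
# presence_mask = FALSE token downstream.

.sf_variables <- list(
  sex = c("male", "female"),
  kps = as.character(seq(30, 100, by = 10)),
  who_grade = c("2", "3", "4"),
  histology = c("glioblastoma IDH-wt", "astrocytoma IDH-mut",
                "oligodendroglioma IDH-mut 1p/19q-codel"),
  idh = c("wildtype", "mutated"),
  codeletion_1p19q = c("non-codeleted", "codeleted"),
  mgmtp = c("unmethylated", "methylated"),
  eor = c("gross total", "subtotal", "biopsy"),
  radiotherapy = c("received", "not received"),
  chemotherapy = c("received", "not received")
)

.sf_columns <- c("subject_id", "age", "sex", "kps", "who_grade", "histology",
                 "idh", "codeletion_1p19q", "mgmtp", "eor", "radiotherapy",
                 "chemotherapy", "os_months", "event", "volume_ref")

# tabular variables in canonical token order; first 8 are clinical/genetic,
# last 3 are the treatment stream
.sf_prompt_vars <- c("age_bin", "sex", "kps_bin", "who_grade", "histology",
                     "idh", "codeletion_1p19q", "mgmtp",
                     "eor", "radiotherapy", "chemotherapy")
.sf_treatment_vars <- c("eor", "radiotherapy", "chemotherapy")

#' Construct one patient record
#'
#' All covariates are optional (use `NA` for missing); `os_months` and
#' `event` are required. Category strings are validated case-insensitively
#' against the canonical level sets.
#'
#' @param subject_id character id.
#' @param os_months positive overall survival in months.
#' @param event 1 = death observed, 0 = censored.
#' @param age years; `sex`,`kps`,`who_grade`,`histology`,`idh`,
#'   `codeletion_1p19q`,`mgmtp`,`eor`,`radiotherapy`,`chemotherapy`
#'   categorical covariates; `volume_ref` optional path to the subject's
#'   4-channel volume.
#' @param ... unused.
#' @return a `patient_record` (named list).
#' @export
patient_record <- function(subject_id, os_months, event, age = NA, sex = NA,
                           kps = NA, who_grade = NA, histology = NA, idh = NA,
                           codeletion_1p19q = NA, mgmtp = NA, eor = NA,
                           radiotherapy = NA, chemotherapy = NA,
                           volume_ref = NA, ...) {
  os_months <- suppressWarnings(as.numeric(os_months))
  if (!is.finite(os_months) || os_months <= 0)
    stop("invalid os_months for subject ", subject_id, ": must be a positive number")
  event <- suppressWarnings(as.numeric(event))
  if (!event %in% c(0, 1))
    stop("invalid event for subject ", subject_id, ": must be 0 or 1")
  if (!is.na(age)) {
    age <- suppressWarnings(as.numeric(age))
    if (!is.finite(age) || age < 0) stop("invalid age for subject ", subject_id)
  }
  rec <- list(subject_id = as.character(subject_id), age = age)
  for (v in names(.sf_variables)) {
    val <- switch(v, sex = sex, kps = kps, who_grade = who_grade,
                  histology = histology, idh = idh,
                  codeletion_1p19q = codeletion_1p19q, mgmtp = mgmtp,
                  eor = eor, radiotherapy = radiotherapy,
                  chemotherapy = chemotherapy)
    rec[[v]] <- validate_category(val, v, subject_id)
  }
  rec$os_months <- os_months
  rec$event <- event
  rec$volume_ref <- if (is.na(volume_ref)) NA_character_ else as.character(volume_ref)
  structure(rec, class = "patient_record")
}

validate_category <- function(val, var, subject_id) {
  if (length(val) != 1L || is.na(val) || identical(val, "")) return(NA_character_)
  levels <- .sf_variables[[var]]
  hit <- match(tolower(as.character(val)), tolower(levels))
  if (is.na(hit))
    stop("illegal category for ", var, " (subject ", subject_id, "): '", val, "'")
  if (var == "kps") {
    k <- as.numeric(levels[hit])
    if (k %% 10 != 0) stop("KPS must be a multiple of 10")
  }
  levels[hit]
}

#' Read a cohort table (TSV or CSV, autodetected)
#'
#' Expects a header with the canonical column names; unknown columns are
#' ignored with a warning. `"NA"` and empty strings are missing.
#'
#' @param path file path.
#' @return list of [patient_record()]s.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = c("NA", ""), stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  unknown <- setdiff(names(df), .sf_columns)
  if (length(unknown))
    warning("read_cohort: ignoring unknown column(s): ", paste(unknown, collapse = ", "))
  need <- c("subject_id", "os_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("read_cohort: missing required column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    getv <- function(col) if (col %in% names(row)) row[[col]] else NA
    patient_record(subject_id = getv("subject_id"), os_months = getv("os_months"),
                   event = getv("event"), age = getv("age"), sex = getv("sex"),
                   kps = getv("kps"), who_grade = getv("who_grade"),
                   histology = getv("histology"), idh = getv("idh"),
                   codeletion_1p19q = getv("codeletion_1p19q"),
                   mgmtp = getv("mgmtp"), eor = getv("eor"),
                   radiotherapy = getv("radiotherapy"),
                   chemotherapy = getv("chemotherapy"),
                   volume_ref = getv("volume_ref"))
  })
}

#' Write a cohort table (TSV; `NA` for missing)
#'
#' @param records list of [patient_record()]s; @param path output path.
#' @export
write_cohort <- function(records, path) {
  df <- records_to_df(records)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Convert a record list to a data frame
#' @param records list of [patient_record()]s.
#' @export
records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(subject_id = r$subject_id, age = r$age, sex = r$sex,
               kps = r$kps, who_grade = r$who_grade, histology = r$histology,
               idh = r$idh, codeletion_1p19q = r$codeletion_1p19q,
               mgmtp = r$mgmtp, eor = r$eor, radiotherapy = r$radiotherapy,
               chemotherapy = r$chemotherapy, os_months = r$os_months,
               event = r$event, volume_ref = r$volume_ref,
               stringsAsFactors = FALSE)
  }))
}

#' Discretize age and KPS into prognostic bins
#'
#' Age maps to `{"<=47", "48-63", ">=64"}` (47 and 63 close the lower
#' bins); KPS, a decadal scale, maps to `{"<=50", "60-70", ">=80"}`.
#' Missing inputs propagate to missing bins.
#'
#' @param record a [patient_record()].
#' @return the record with `age_bin` and `kps_bin` added.
#' @export
discretize <- function(record) {
  record$age_bin <- if (is.na(record$age)) NA_character_
    else if (record$age <= 47) "<=47"
    else if (record$age <= 63) "48-63"
    else ">=64"
  record$kps_bin <- if (is.na(record$kps)) NA_character_
    else {
      k <- as.numeric(record$kps)
      if (k <= 50) "<=50" else if (k <= 70) "60-70" else ">=80"
    }
  record
}

# prompt templates: one English declarative sentence per (variable, level),
# mirroring the fixed-template style; loaded from inst/extdata so the table
# is auditable and versioned
prompt_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "prompt_templates.tsv", package = "survfuse")
      if (path == "") path <- file.path("inst", "extdata", "prompt_templates.tsv")
      cache <<- utils::read.table(path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE, quote = "",
                                  comment.char = "")
    }
    cache
  }
})

#' Serialize a discretized record as natural-language prompts
#'
#' One template sentence per non-missing variable; missing variables carry
#' a `NA` prompt and no text. Treatment variables (EOR, radiotherapy,
#' chemotherapy) are tagged `"treatment"`, all others
#' `"clinical_genetic"`.
#'
#' @param record a discretized [patient_record()] (see [discretize()]).
#' @return a `prompt_set` data frame: `variable`, `prompt`, `modality`.
#' @export
to_prompts <- function(record) {
  if (is.null(record$age_bin)) record <- discretize(record)
  tpl <- prompt_templates()
  rows <- lapply(.sf_prompt_vars, function(v) {
    val <- record[[v]]
    prompt <- NA_character_
    if (!is.na(val)) {
      hit <- tpl$prompt[tpl$variable == v & tpl$level == val]
      if (length(hit) != 1L) stop("no prompt template for ", v, " = ", val)
      prompt <- hit
    }
    data.frame(variable = v, prompt = prompt,
               modality = if (v %in% .sf_treatment_vars) "treatment" else "clinical_genetic",
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("prompt_set", "data.frame"))
}
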