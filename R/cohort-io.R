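# Patient records and cohort tables.
#
# A cohort is a data.frame with one row per patient. Stage carries the A/B
# substage explicitly ("I","IIA","IIB","IIIA","IIIB","IV"); a stage-number
# view (I-IV) is derived where needed. Optional fields (tg_tl, response) use
# NA for "unset".

#' Allowed stage tokens (with A/B substage)
#' @export
STAGE_LEVELS <- c("I", "IIA", "IIB", "IIIA", "IIIB", "IV")

#' Allowed protocol tokens
#' @export
PROTOCOL_LEVELS <- c("C1", "C2")

#' Construct a single patient record
#'
#' @param id Patient identifier (string).
#' @param stage One of `STAGE_LEVELS`.
#' @param esr_elevated Logical: erythrocyte sedimentation rate >= 30 mm/h.
#' @param bulk_present Logical: tumor bulk >= 200 ml present at staging.
#' @param extranodal Logical: extranodal disease.
#' @param b_symptoms Logical: B-symptoms.
#' @param protocol `"C1"` or `"C2"` (EuroNet-PHL protocol).
#' @param tg_tl Treatment group/level 1-3, or `NA` if not yet assigned.
#' @param response `"IR"`, `"AR"`, or `NA` if not yet evaluated.
#' @return One-row data.frame.
#' @export
patient_record <- function(id, stage, esr_elevated, bulk_present, extranodal,
                           b_symptoms = FALSE, protocol = "C2",
                           tg_tl = NA_integer_, response = NA_character_) {
  rec <- data.frame(
    id = as.character(id), stage = as.character(stage),
    esr_elevated = as.logical(esr_elevated),
    bulk_present = as.logical(bulk_present),
    extranodal = as.logical(extranodal),
    b_symptoms = as.logical(b_symptoms),
    protocol = as.character(protocol),
    tg_tl = as.integer(tg_tl), response = as.character(response),
    stringsAsFactors = FALSE
  )
  validate_cohort(rec)
  rec
}

#' Validate a cohort data.frame
#'
#' Checks vocabulary (stage, protocol, response, tg_tl) and reports the first
#' offending row and column.
#'
#' @param cohort Cohort data.frame.
#' @return The cohort, invisibly, or an error.
#' @export
validate_cohort <- function(cohort) {
  required <- c("id", "stage", "esr_elevated", "bulk_present", "extranodal",
                "protocol")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_vocab <- function(col, allowed, allow_na = FALSE) {
    vals <- cohort[[col]]
    bad <- !(vals %in% allowed) & !(allow_na & is.na(vals))
    if (any(bad)) {
      row <- which(bad)[1]
      stop(sprintf("invalid value '%s' in column '%s', row %d (allowed: %s)",
                   vals[row], col, row, paste(allowed, collapse = ", ")),
           call. = FALSE)
    }
  }
  check_vocab("stage", STAGE_LEVELS)
  check_vocab("protocol", PROTOCOL_LEVELS)
  if ("response" %in% names(cohort)) check_vocab("response", c("IR", "AR"), TRUE)
  if ("tg_tl" %in% names(cohort)) check_vocab("tg_tl", 1:3, TRUE)
  invisible(cohort)
}

#' Roman stage number (I-IV) without substage
#' @param stage Character vector of `STAGE_LEVELS` tokens.
#' @return Character vector in `c("I","II","III","IV")`.
#' @export
stage_number <- function(stage) {
  sub("[AB]$", "", stage)
}

#' Read a cohort table from CSV
#'
#' Comma-separated, UTF-8, header row mandatory. Empty strings and `NA` in
#' `tg_tl` / `response` are kept as unset.
#'
#' @param path CSV file path.
#' @return Validated cohort data.frame (possibly zero rows).
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0) return(df)
  for (col in c("esr_elevated", "bulk_present", "extranodal", "b_symptoms")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  if ("tg_tl" %in% names(df)) df$tg_tl <- as.integer(df$tg_tl)
  if ("response" %in% names(df)) {
    df$response[!is.na(df$response) & df$response == ""] <- NA_character_
  }
  validate_cohort(df)
  df
}

#' Write a cohort table to CSV
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deterministic 50-patient reference cohort (synthetic)
#'
#' A hand-constructed cohort reproducing the marginal structure of the
#' pediatric Hodgkin's lymphoma cohort that this package's defaults emulate:
#' 50 patients, stages 1/26/7/16 (I/II/III/IV), treatment groups/levels
#' 12/17/21, responses 28 IR / 22 AR with per-group IR counts 6/10/12. The
#' stored `tg_tl` is consistent with [assign_tg_tl()] on every row. This is
#' synthetic tabular data, not patient data.
#'
#' @return Cohort data.frame with 50 rows.
#' @export
synthetic_reference_cohort <- function() {
  rows <- list()
  add <- function(n, stage, esr, bulk, extra, bsym, protocol) {
    for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <<- list(stage = stage, esr = esr, bulk = bulk,
                                         extra = extra, bsym = bsym,
                                         protocol = protocol)
    }
  }
  # TG/TL 1 (12): stage I + IIA, risk-factor free
  add(1, "I", FALSE, FALSE, FALSE, FALSE, "C1")
  add(9, "IIA", FALSE, FALSE, FALSE, FALSE, "C1")
  add(2, "IIA", FALSE, FALSE, FALSE, FALSE, "C2")
  # TG/TL 2 (17): IIB / IIIA without extranodal (+ IIA with ESR on C2)
  add(11, "IIB", TRUE, FALSE, FALSE, TRUE, "C1")
  add(2, "IIB", TRUE, TRUE, FALSE, TRUE, "C2")
  add(3, "IIIA", TRUE, FALSE, FALSE, FALSE, "C1")
  add(1, "IIIA", TRUE, TRUE, FALSE, FALSE, "C1")
  # TG/TL 3 (21): IIB/IIIA with extranodal + IIIB + IV
  add(2, "IIB", TRUE, TRUE, TRUE, TRUE, "C1")
  add(2, "IIIA", TRUE, FALSE, TRUE, FALSE, "C1")
  add(1, "IIIB", TRUE, TRUE, FALSE, TRUE, "C2")
  add(12, "IV", TRUE, FALSE, FALSE, TRUE, "C1")
  add(3, "IV", TRUE, TRUE, TRUE, TRUE, "C1")
  add(1, "IV", TRUE, TRUE, FALSE, TRUE, "C2")

  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    patient_record(sprintf("P%02d", i), r$stage, r$esr, r$bulk, r$extra,
                   r$bsym, r$protocol)
  }))
  df$tg_tl <- assign_tg_tl(df)
  # per-group IR counts 6 / 10 / 12 (first k of each group -> IR)
  df$response <- NA_character_
  ir_per_group <- c(`1` = 6L, `2` = 10L, `3` = 12L)
  for (g in 1:3) {
    idx <- which(df$tg_tl == g)
    df$response[idx] <- c(rep("IR", ir_per_group[[g]]),
                          rep("AR", length(idx) - ir_per_group[[g]]))
  }
  validate_cohort(df)
  df
}
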