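#' Load the packaged CEE metadata and expert severity-score tables
#'
#' The package ships two plain-text fixtures transcribing the published
#' records of the SOCAL-BRS fin whale controlled exposure experiments:
#' `cee_metadata.csv` (21 tagged whales: subject, date, CEE id, treatment
#' type, behavioural state at onset, phase start times, exposure minutes,
#' prey-mapping flag) and `expert_severity_scores.csv` (the adjudicated
#' expert scoring of each CEE: change flag and confidence, severity score on
#' the 0-9 scale, and the cumulative sound exposure level at the change point
#' for responders or at the end of the exposure otherwise).
#'
#' Both tables are validated on load (schema, subject uniqueness,
#' cross-table consistency and the published totals); any mismatch raises a
#' fixture-corruption error.
#'
#' @return list with data frames `cee_table` and `severity_table`.
#' @export
load_cee_fixtures <- function() {
  f1 <- system.file("extdata", "cee_metadata.csv", package = "sonarCEE")
  f2 <- system.file("extdata", "expert_severity_scores.csv", package = "sonarCEE")
  if (f1 == "" || f2 == "") stop_invalid("packaged fixture files are missing")
  cee <- utils::read.csv(f1, stringsAsFactors = FALSE)
  sev <- utils::read.csv(f2, stringsAsFactors = FALSE)
  rep <- validate_tables(cee, sev)
  if (!rep$ok) {
    stop_invalid("fixture corruption: %s", paste(rep$failures, collapse = "; "))
  }
  list(cee_table = cee, severity_table = sev)
}

#' Validate CEE and severity tables
#'
#' Checks the schema of both tables, subject-identifier uniqueness,
#' cross-table identifier consistency, and the published count structure:
#' 21 subjects; 11 MFAS, 4 PRN and 6 control CEEs; 9 deep-feeding, 7
#' shallow-feeding and 5 non-feeding whales; 5 responders, all in exposure
#' (MFAS/PRN) CEEs; no responders among controls.
#'
#' @param cee_table CEE metadata data frame.
#' @param severity_table expert severity-score data frame.
#' @return list with `ok` (logical), `failures` (character), and `counts`.
#' @export
validate_tables <- function(cee_table, severity_table) {
  fail <- character(0)
  note <- function(cond, msg) if (!cond) fail <<- c(fail, msg)
  if (nrow(cee_table) == 0 || nrow(severity_table) == 0) {
    stop_invalid("empty table supplied")
  }
  need_cee <- c("subject_id", "cee_date", "cee_id", "cee_type",
                "behavioural_state", "exposure_min")
  need_sev <- c("subject_id", "cee_type", "behavioural_state", "csel_db",
                "change", "confidence", "severity_score")
  note(all(need_cee %in% names(cee_table)), "cee table schema mismatch")
  note(all(need_sev %in% names(severity_table)), "severity table schema mismatch")
  if (length(fail)) return(list(ok = FALSE, failures = fail, counts = NULL))
  note(!anyDuplicated(cee_table$subject_id), "duplicated subject id in cee table")
  note(!anyDuplicated(severity_table$subject_id),
       "duplicated subject id in severity table")
  note(setequal(cee_table$subject_id, severity_table$subject_id),
       "subject ids differ between tables")
  type_counts <- table(cee_table$cee_type)
  state_counts <- table(cee_table$behavioural_state)
  responders <- severity_table[severity_table$change == "yes", , drop = FALSE]
  counts <- list(
    n_subjects = nrow(cee_table),
    cee_types = type_counts,
    behavioural_states = state_counts,
    n_responders = nrow(responders),
    n_exposure_cees = sum(cee_table$cee_type != "CONTROL"),
    control_responses = sum(severity_table$change == "yes" &
                              severity_table$cee_type == "CONTROL"))
  note(counts$n_subjects == 21, "expected 21 subjects")
  note(identical(as.integer(type_counts[c("MFAS", "PRN", "CONTROL")]),
                 c(11L, 4L, 6L)), "expected 11 MFAS / 4 PRN / 6 CONTROL")
  note(identical(as.integer(state_counts[c("deep-feeding", "shallow-feeding",
                                           "non-feeding")]), c(9L, 7L, 5L)),
       "expected 9 deep / 7 shallow / 5 non-feeding")
  note(counts$n_responders == 5, "expected 5 responders")
  note(all(responders$cee_type %in% c("MFAS", "PRN")),
       "responders must be exposure CEEs")
  note(counts$control_responses == 0, "controls must have no responses")
  note(all(!is.na(severity_table$csel_db[severity_table$cee_type != "CONTROL"])),
       "every exposure CEE needs a cSEL")
  list(ok = length(fail) == 0, failures = fail, counts = counts)
}
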