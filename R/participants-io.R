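# Participant-table schema, validation, and CSV round-trip.
#
# Schema (CSV header exactly): id,first_contestant,speaker_rank1,evidence1,slider1
#   first_contestant  "longer" / "shorter": agenda of the contestant revealing first
#   speaker_rank1     stick (from {2,4,7,8,9}) the participant expected that
#                     contestant to show first
#   evidence1         first revealed stick: in {6,7,8,9} when the long-biased
#                     contestant goes first, {1,2,3,4} when the short-biased does
#   slider1           belief report in [0, 100] (0 = definitely shorter)

PARTICIPANT_SCHEMA <- c("id", "first_contestant", "speaker_rank1",
                        "evidence1", "slider1")

#' Validate a participant table
#'
#' Checks the schema and the per-record invariants (agenda labels, evidence
#' range per contestant order, slider range, candidate-set membership of the
#' speaker-phase choice) and derives the `group` label
#' (`"strongest-expected"` if the rank-1 stick is the contestant's most
#' persuasive one, else `"other"`).
#'
#' @param records A data frame with the participant schema columns.
#' @param reject How to treat invalid rows: `"error"` (default) or `"drop"`
#'   (drop with a warning listing the offending row numbers).
#' @return The validated table with a derived `group` column.
#' @export
validate_participants <- function(records, reject = c("error", "drop")) {
  reject <- match.arg(reject)
  missing <- setdiff(PARTICIPANT_SCHEMA, names(records))
  if (length(missing) > 0L)
    stop("participant table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  fc_ok <- records$first_contestant %in% c("longer", "shorter")
  ev <- suppressWarnings(as.integer(records$evidence1))
  sl <- suppressWarnings(as.numeric(records$slider1))
  sr <- suppressWarnings(as.integer(records$speaker_rank1))
  ev_ok <- !is.na(ev) & ifelse(records$first_contestant == "longer",
                               ev %in% 6:9, ev %in% 1:4)
  sl_ok <- !is.na(sl) & sl >= 0 & sl <= 100
  sr_ok <- !is.na(sr) & sr %in% speaker_phase_sticks()
  bad <- which(!(fc_ok & ev_ok & sl_ok & sr_ok))
  if (length(bad) > 0L) {
    msg <- paste0("invalid participant record(s) at row(s): ",
                  paste(bad, collapse = ", "))
    if (reject == "error") stop(msg, call. = FALSE)
    warning(msg, " (dropped)", call. = FALSE)
    records <- records[-bad, , drop = FALSE]
    ev <- ev[-bad]; sl <- sl[-bad]; sr <- sr[-bad]
  }
  records$evidence1 <- ev
  records$slider1 <- sl
  records$speaker_rank1 <- sr
  strongest <- ifelse(records$first_contestant == "longer",
                      max(speaker_phase_sticks()), min(speaker_phase_sticks()))
  records$group <- ifelse(records$speaker_rank1 == strongest,
                          "strongest-expected", "other")
  rownames(records) <- NULL
  records
}

#' Write a participant table as CSV
#'
#' Writes exactly the five schema columns (derived columns such as `group`
#' are recomputed on read).
#'
#' @param records Participant table.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_participants <- function(records, file) {
  records <- validate_participants(records)
  utils::write.csv(records[, PARTICIPANT_SCHEMA], file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read and validate a participant table from CSV
#'
#' @param file CSV path with the participant schema.
#' @inheritParams validate_participants
#' @return Validated table with the derived `group` column.
#' @export
read_participants <- function(file, reject = c("error", "drop")) {
  records <- utils::read.csv(file, stringsAsFactors = FALSE,
                             colClasses = "character")
  validate_participants(records, reject = match.arg(reject))
}
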