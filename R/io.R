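#' Read and write registrant records
#'
#' Registrant files are tab-delimited UTF-8 text, one row per subject, with
#' ISO-8601 dates and the nested updates encoding
#' `day:cpra:status;day:cpra:status` (empty cpra or status field = value
#' unchanged). Columns: subject_id, listing_date, age_at_listing,
#' first_time, multi_organ, age_group, gender, abo, race, esrd_diagnosis,
#' initial_cpra, initial_status, updates, terminal_day, terminal_state,
#' censor_day.
#'
#' @param path File path.
#' @return A registrant-record data frame.
#' @export
read_registrants <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(subject_id = "character",
                                          updates = "character",
                                          terminal_state = "character"),
                           na.strings = c("NA", ""))
  out$listing_date <- as.Date(out$listing_date)
  out$updates[is.na(out$updates)] <- ""
  out
}

#' @param records Registrant-record data frame.
#' @rdname read_registrants
#' @return `write_registrants` invisibly returns the path.
#' @export
write_registrants <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and write the long-format transition table
#'
#' Columns, in order: subject_id, from_index, to_index, transition_id,
#' t_start, t_stop, status.
#'
#' @param path File path.
#' @param space,struct State space and structure to re-attach on read.
#' @return A `msm_transition_table` data frame.
#' @export
read_transition_table <- function(path, space = build_state_space(),
                                  struct = build_transition_structure(space)) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(subject_id = "character"))
  attr(out, "space") <- space
  attr(out, "struct") <- struct
  class(out) <- c("msm_transition_table", "data.frame")
  out
}

#' @param table A `msm_transition_table`.
#' @rdname read_transition_table
#' @export
write_transition_table <- function(table, path) {
  cols <- c("subject_id", "from_index", "to_index", "transition_id",
            "t_start", "t_stop", "status")
  utils::write.table(table[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write hazard increments and probability estimates
#'
#' Hazards: columns transition_id, time, dA, var_dA (one row per observed
#' jump). Probabilities: columns origin_s, time, from_index, to_index,
#' estimate, se, lower, upper.
#'
#' @param hazards A `msm_cumhaz` object.
#' @param path Output path.
#' @export
write_hazards <- function(hazards, path) {
  utils::write.table(as.data.frame(hazards), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param trajectory A `msm_probtrans` object (with bands).
#' @rdname write_hazards
#' @export
write_probabilities <- function(trajectory, path) {
  utils::write.table(as.data.frame(trajectory), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
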