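# Event-log plumbing shared by all modules.
#
# Every discrete life event is one flat row; event-specific payload fields
# (service number, diagnosis index, cull reason, ...) live in typed columns
# that are NA when not applicable. Column order is fixed and documented in
# `event_columns()`.

EVENT_CODES <- c("BIRTH", "ENTRY", "MALE_SOLD", "FIRST_OVULATION", "OVULATION",
                 "HEAT_DETECTED", "INSEMINATION", "DIAGNOSIS_PREGNANT",
                 "DIAGNOSIS_OPEN", "PREGNANCY_LOSS", "CALVING", "DRY_OFF",
                 "CULLED", "EXIT")

event_row <- function(sim_day, animal_id, event,
                      age = NA_integer_, dim = NA_integer_,
                      parity = NA_integer_, service = NA_integer_,
                      diagnosis = NA_integer_, reason = NA_character_,
                      value = NA_real_) {
  stopifnot(event %in% EVENT_CODES)
  list(sim_day = as.integer(sim_day), animal_id = as.integer(animal_id),
       event = event, age = as.integer(age), dim = as.integer(dim),
       parity = as.integer(parity), service = as.integer(service),
       diagnosis = as.integer(diagnosis), reason = as.character(reason),
       value = as.numeric(value))
}

#' Event-log column order
#'
#' @return character vector naming the columns of an event log, in the
#'   order written by [write_event_log()].
#' @export
event_columns <- function() {
  c("sim_day", "animal_id", "event", "age", "dim", "parity",
    "service", "diagnosis", "reason", "value")
}

# Bind a list of event rows into a data.table with the canonical schema.
events_to_table <- function(rows) {
  if (!length(rows)) {
    return(data.table::data.table(
      sim_day = integer(), animal_id = integer(), event = character(),
      age = integer(), dim = integer(), parity = integer(),
      service = integer(), diagnosis = integer(), reason = character(),
      value = numeric()))
  }
  data.table::rbindlist(rows)
}
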