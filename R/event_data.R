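#' @section Event-history records:
#' A multistate event history is a table with one row per observed sojourn:
#' subject identifier, entry time, exit time, the state occupied during the
#' sojourn, and the destination state (or the censoring sentinel `"cens"`).
#' Left-truncation is expressed through positive entry times, independent
#' right-censoring through the sentinel destination.
#' @name event-data
NULL

#' Censoring sentinel used in the `to` column of event histories
#' @export
CENSORED <- "cens"

#' Construct a validated table of event-history records
#'
#' @param id subject identifiers (coerced to character).
#' @param entry sojourn entry times, `>= 0`.
#' @param exit sojourn exit times, strictly greater than `entry`.
#' @param from state occupied during the sojourn.
#' @param to destination state, or [CENSORED] for a right-censored sojourn.
#' @return a `data.frame` of class `"event_records"`.
#' @examples
#' event_records(c("a", "b", "c"), 0, c(1, 2, 2.5), "0", c("2", "2", "cens"))
#' @export
event_records <- function(id, entry, exit, from, to) {
  df <- data.frame(
    id = as.character(id), entry = as.numeric(entry),
    exit = as.numeric(exit), from = as.character(from),
    to = as.character(to), stringsAsFactors = FALSE
  )
  if (any(df$entry < 0)) stop("entry times must be nonnegative")
  if (any(df$entry >= df$exit)) {
    stop("every record must have entry_time < exit_time")
  }
  if (any(df$to == df$from)) {
    stop("destination state must differ from the occupied state")
  }
  class(df) <- c("event_records", "data.frame")
  df
}

#' Diagnostic report on an event-history table
#'
#' Reporting only: lists zero-length or reversed sojourns, exits into the
#' occupied state, overlapping sojourns of the same subject, and state
#' labels outside a declared state space.  Never mutates or rejects its
#' input, so it can be run on raw files before [event_records()] validation.
#'
#' @param records a `data.frame` with columns `id, entry, exit, from, to`.
#' @param state_space optional character vector of admissible state labels.
#' @return a `data.frame` with columns `id`, `issue`, `detail`; zero rows
#'   when the history is clean.
#' @export
validate_histories <- function(records, state_space = NULL) {
  issues <- list()
  flag <- function(id, issue, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      id = as.character(id), issue = issue, detail = detail,
      stringsAsFactors = FALSE
    )
  }
  bad_len <- which(records$entry >= records$exit)
  for (i in bad_len) {
    flag(records$id[i], "zero_length_sojourn",
         sprintf("entry %g >= exit %g", records$entry[i], records$exit[i]))
  }
  self <- which(records$from == records$to)
  for (i in self) {
    flag(records$id[i], "self_transition",
         sprintf("exit into occupied state '%s'", records$from[i]))
  }
  if (!is.null(state_space)) {
    known <- c(state_space, CENSORED)
    bad <- which(!(records$from %in% state_space) | !(records$to %in% known))
    for (i in bad) {
      flag(records$id[i], "unknown_state",
           sprintf("from '%s' to '%s'", records$from[i], records$to[i]))
    }
  }
  for (sid in unique(records$id)) {
    rr <- records[records$id == sid, , drop = FALSE]
    rr <- rr[order(rr$entry), , drop = FALSE]
    if (nrow(rr) > 1L && any(rr$entry[-1L] < rr$exit[-nrow(rr)])) {
      flag(sid, "overlapping_sojourns",
           "a sojourn starts before the previous one ends")
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(id = character(0), issue = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Aggregate an event history into a per-transition counting process
#'
#' For one transition `from -> to`, collapses the records into the jump
#' times of the aggregated counting process N, the jump sizes dN, and the
#' at-risk counts Y just prior to each jump.  A subject is at risk in state
#' `from` at time s iff `entry < s <= exit` (left-open, right-closed), which
#' makes Y left-continuous and, at a tie between an event and a censoring,
#' counts the censored subject as still at risk (events precede censorings).
#' Set `censoring_ties = "censor-first"` for the opposite convention.
#'
#' Tied event times are retained as a single jump of size `dN > 1`;
#' downstream resampling treats such a tie as `dN` unit jumps.
#'
#' @param records an event-history table (columns `id, entry, exit, from, to`).
#' @param from,to state labels of the transition of interest.
#' @param tau horizon time; jumps after `tau` are dropped.
#' @param n sample-size-related number used for normalisation; defaults to
#'   the number of distinct subjects in `records`.
#' @param state_space optional declared state space; labels outside it error.
#' @param censoring_ties tie convention between events and censorings at the
#'   same time, see above.
#' @return an object of class `"counting_data"` with fields `transition`,
#'   `times`, `delta_n`, `y`, `n`, `tau`.
#' @examples
#' rec <- event_records(c("a", "b", "c"), 0, c(1, 2, 2.5), "0",
#'                      c("2", "2", "cens"))
#' build_counting_data(rec, "0", "2", tau = 3)
#' @export
build_counting_data <- function(records, from, to, tau, n = NULL,
                                state_space = NULL,
                                censoring_ties = c("event-first",
                                                   "censor-first")) {
  censoring_ties <- match.arg(censoring_ties)
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0)
  if (from == to) stop("a transition requires from_state != to_state")
  if (any(records$entry >= records$exit)) {
    stop("invalid event history: a record has entry_time >= exit_time")
  }
  if (!is.null(state_space)) {
    known <- c(state_space, CENSORED)
    if (!all(records$from %in% state_space) ||
        !all(records$to %in% known)) {
      stop("event history contains state labels outside the declared ",
           "state space")
    }
  }
  if (is.null(n)) n <- length(unique(records$id))
  stopifnot(n >= 1)

  ev_times <- records$exit[records$from == from & records$to == to &
                             records$exit <= tau]
  if (length(ev_times) == 0L) {
    return(structure(
      list(transition = c(from = from, to = to), times = numeric(0),
           delta_n = integer(0), y = integer(0), n = as.integer(n),
           tau = tau),
      class = "counting_data"
    ))
  }
  r <- rle(sort(ev_times))
  jump_times <- r$values
  delta_n <- r$lengths

  at <- records[records$from == from, , drop = FALSE]
  if (censoring_ties == "event-first") {
    # Y(s) = #{entry < s} - #{exit < s}
    y <- count_lt(jump_times, sort(at$entry)) -
      count_lt(jump_times, sort(at$exit))
  } else {
    cens <- at$to == CENSORED
    y <- count_lt(jump_times, sort(at$entry)) -
      count_lt(jump_times, sort(at$exit[!cens])) -
      count_le(jump_times, sort(at$exit[cens]))
  }
  if (any(delta_n > y)) {
    stop("internal inconsistency: jump size exceeds the at-risk count")
  }
  structure(
    list(transition = c(from = from, to = to), times = jump_times,
         delta_n = as.integer(delta_n), y = as.integer(y),
         n = as.integer(n), tau = tau),
    class = "counting_data"
  )
}

#' @export
print.counting_data <- function(x, ...) {
  cat(sprintf("counting process %s -> %s: %d jump times, %d events, n = %d, tau = %g\n",
              x$transition["from"], x$transition["to"], length(x$times),
              sum(x$delta_n), x$n, x$tau))
  invisible(x)
}

#' Read / write event-history files
#'
#' Delimited text with header `id,entry,exit,from,to`; the `to` value
#' `"cens"` flags right-censoring.  Reader and writer round-trip.
#'
#' @param path file path.
#' @param sep field separator, comma by default.
#' @return `read_event_history()` returns an [event_records()] table.
#' @export
read_event_history <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "character"),
                          stringsAsFactors = FALSE)
  need <- c("id", "entry", "exit", "from", "to")
  if (!all(need %in% names(df))) {
    stop("event-history file must have columns: ", paste(need, collapse = ", "))
  }
  event_records(df$id, df$entry, df$exit, df$from, df$to)
}

#' @param records an [event_records()] table.
#' @rdname read_event_history
#' @export
write_event_history <- function(records, path, sep = ",") {
  utils::write.table(records[, c("id", "entry", "exit", "from", "to")],
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
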