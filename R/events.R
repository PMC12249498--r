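EVENT_KINDS <- c("corridor_cross", "box_entry", "box_exit", "reward_consumed")

#' Construct an event stream for one animal-trial
#'
#' An event stream is the raw substrate of all behavioral scores: the
#' time-ordered beam-break events recorded during one 300 s trial at 1 ms
#' resolution. Kinds are \code{corridor_cross} (midpoint sensor),
#' \code{box_entry}, \code{box_exit} and \code{reward_consumed}.
#'
#' @param animal Animal id (character).
#' @param trial_id Trial id, matching a schedule row (e.g. \code{"post_03"}).
#' @param phase Phase label (see \code{\link{ambitus_phases}}).
#' @param events data.frame with columns \code{timestamp} (integer ms),
#'   \code{kind} and \code{location}; must be sorted by timestamp.
#' @param group Optional treatment-group label.
#' @param task Task id; defaults to the phase's task.
#' @return Object of class \code{"event_stream"}.
#' @export
event_stream <- function(animal, trial_id, phase, events, group = NA_character_,
                         task = phase_task(phase)) {
  stopifnot(is.data.frame(events),
            all(c("timestamp", "kind", "location") %in% names(events)))
  events <- events[, c("timestamp", "kind", "location")]
  events$timestamp <- as.integer(events$timestamp)
  events$kind <- as.character(events$kind)
  events$location <- as.character(events$location)
  if (is.unsorted(events$timestamp))
    stop("non-monotone timestamps in trial ", trial_id, " of animal ", animal)
  s <- list(animal = as.character(animal), trial_id = as.character(trial_id),
            phase = as.character(phase), group = as.character(group),
            task = as.integer(task), events = events)
  class(s) <- "event_stream"
  s
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("Event stream: animal %s, trial %s (%s, task %d), %d events\n",
              x$animal, x$trial_id, x$phase, x$task, nrow(x$events)))
  invisible(x)
}

#' Validate an event stream against the apparatus and task
#'
#' Checks every stream invariant and returns all violations as data, never as
#' an error: timestamps within the 300 s window and non-decreasing; every
#' location a known box or midpoint sensor of the right kind; rewards
#' consumed only at boxes baited under the task and at most once per box;
#' and, per box, no exit before the matching entry. The input is not
#' modified.
#'
#' @param stream An \code{\link{event_stream}}.
#' @param task A \code{\link{task_config}}; defaults to the stream's task.
#' @param layout Apparatus layout.
#' @return data.frame with columns \code{code} and \code{message}, one row
#'   per violation; zero rows means the stream is valid.
#' @export
validate_event_stream <- function(stream, task = task_config(stream$task),
                                  layout = build_layout()) {
  ev <- stream$events
  bad <- function(code, message) data.frame(code = code, message = message,
                                            stringsAsFactors = FALSE)
  out <- list()
  if (nrow(ev) == 0L)
    return(data.frame(code = character(), message = character(),
                      stringsAsFactors = FALSE))

  if (any(ev$timestamp < 0L | ev$timestamp > TRIAL_DURATION_MS)) {
    t <- ev$timestamp[ev$timestamp < 0L | ev$timestamp > TRIAL_DURATION_MS]
    out[[length(out) + 1L]] <- bad("timestamp_range",
      sprintf("timestamp %d outside [0, %d] ms", t, TRIAL_DURATION_MS))
  }
  if (is.unsorted(ev$timestamp))
    out[[length(out) + 1L]] <- bad("timestamp_order",
      sprintf("timestamps not non-decreasing in trial %s", stream$trial_id))

  unknown_kind <- setdiff(unique(ev$kind), EVENT_KINDS)
  if (length(unknown_kind))
    out[[length(out) + 1L]] <- bad("unknown_kind",
      sprintf("unknown event kind '%s'", unknown_kind))

  is_cross <- ev$kind == "corridor_cross"
  bad_mid <- setdiff(unique(ev$location[is_cross]), layout$midpoints)
  if (length(bad_mid))
    out[[length(out) + 1L]] <- bad("unknown_location",
      sprintf("corridor_cross at unknown midpoint '%s'", bad_mid))
  bad_box <- setdiff(unique(ev$location[!is_cross & ev$kind %in% EVENT_KINDS]),
                     layout$boxes$box)
  if (length(bad_box))
    out[[length(out) + 1L]] <- bad("unknown_location",
      sprintf("box event at unknown box '%s'", bad_box))

  rw <- ev[ev$kind == "reward_consumed", , drop = FALSE]
  unbaited <- setdiff(unique(rw$location), task$baited)
  unbaited <- intersect(unbaited, layout$boxes$box)
  if (length(unbaited))
    out[[length(out) + 1L]] <- bad("reward_unbaited",
      sprintf("reward_consumed at box '%s' not baited under task %d",
              unbaited, task$task))
  dup <- table(rw$location)
  dup <- names(dup)[dup > 1L]
  if (length(dup))
    out[[length(out) + 1L]] <- bad("reward_duplicate",
      sprintf("more than one reward_consumed at box '%s'", dup))

  # per box: running entry/exit balance must never go negative
  for (b in unique(ev$location[ev$kind %in% c("box_entry", "box_exit")])) {
    k <- ev$kind[ev$location == b & ev$kind %in% c("box_entry", "box_exit")]
    if (any(cumsum(ifelse(k == "box_entry", 1L, -1L)) < 0L))
      out[[length(out) + 1L]] <- bad("exit_before_entry",
        sprintf("box_exit precedes box_entry at box '%s'", b))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(code = character(), message = character(),
               stringsAsFactors = FALSE)
}

LOG_HEADER <- c("animal_id", "trial_id", "phase", "task", "timestamp_ms",
                "kind", "location")

#' Read an event-log CSV into event streams
#'
#' The event-log dialect is plain UTF-8 CSV with the header
#' \code{animal_id,trial_id,phase,task,timestamp_ms,kind,location}, integer
#' millisecond timestamps, and one trial stored as a contiguous block of
#' rows. Structural problems (malformed rows, unknown kinds or locations,
#' timestamps running backwards within a trial) are errors naming the line
#' or trial; softer invariant violations are left to
#' \code{\link{validate_event_stream}}.
#'
#' @param file Path to a CSV file, or a character vector of CSV lines
#'   (anything \code{textConnection} accepts via \code{text}).
#' @param layout Apparatus layout used to check locations.
#' @return List of \code{\link{event_stream}} objects, one per
#'   (animal, trial), in file order.
#' @seealso \code{\link{write_event_log}} for the inverse; the two
#'   round-trip byte-stably on canonical logs.
#' @export
read_event_log <- function(file, layout = build_layout()) {
  lines <- if (length(file) == 1L && file.exists(file))
    readLines(file) else as.character(file)
  if (length(lines) == 0L) stop("empty input: missing header")
  hdr <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (!identical(hdr, LOG_HEADER))
    stop("bad header: expected '", paste(LOG_HEADER, collapse = ","), "'")
  if (length(lines) == 1L) return(list())

  parts <- strsplit(lines[-1L], ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 7L))
    stop("parse error at line ", which(nf != 7L)[1L] + 1L,
         ": expected 7 fields, got ", nf[nf != 7L][1L])
  m <- matrix(unlist(parts), ncol = 7L, byrow = TRUE)
  df <- data.frame(animal_id = m[, 1L], trial_id = m[, 2L], phase = m[, 3L],
                   task = m[, 4L], timestamp_ms = m[, 5L], kind = m[, 6L],
                   location = m[, 7L], stringsAsFactors = FALSE)
  ts <- suppressWarnings(as.integer(df$timestamp_ms))
  if (anyNA(ts))
    stop("parse error at line ", which(is.na(ts))[1L] + 1L,
         ": non-integer timestamp '", df$timestamp_ms[is.na(ts)][1L], "'")
  df$timestamp_ms <- ts
  bad_kind <- setdiff(unique(df$kind), EVENT_KINDS)
  if (length(bad_kind)) stop("unknown event kind: ", bad_kind[1L])
  known_loc <- c(layout$boxes$box, layout$midpoints)
  bad_loc <- setdiff(unique(df$location), known_loc)
  if (length(bad_loc)) stop("unknown location: ", bad_loc[1L])

  key <- paste(df$animal_id, df$trial_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
    function(i) {
      d <- df[i, , drop = FALSE]
      if (is.unsorted(d$timestamp_ms))
        stop("non-monotone timestamps in trial ", d$trial_id[1L],
             " of animal ", d$animal_id[1L])
      event_stream(animal = d$animal_id[1L], trial_id = d$trial_id[1L],
                   phase = d$phase[1L], task = as.integer(d$task[1L]),
                   events = data.frame(timestamp = d$timestamp_ms,
                                       kind = d$kind, location = d$location,
                                       stringsAsFactors = FALSE))
    })
  names(out) <- NULL
  out
}

#' Write event streams to the canonical event-log CSV
#'
#' @param streams A list of \code{\link{event_stream}} objects (or one).
#' @param file Path to write, or \code{NULL} to return the lines invisibly.
#' @return Character vector of CSV lines, invisibly.
#' @export
write_event_log <- function(streams, file = NULL) {
  if (inherits(streams, "event_stream")) streams <- list(streams)
  rows <- unlist(lapply(streams, function(s) {
    if (nrow(s$events) == 0L) return(character())
    sprintf("%s,%s,%s,%d,%d,%s,%s", s$animal, s$trial_id, s$phase, s$task,
            s$events$timestamp, s$events$kind, s$events$location)
  }))
  lines <- c(paste(LOG_HEADER, collapse = ","), rows)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
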