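#' Trial duration of the corridor maze test, in milliseconds
#'
#' Every trial lasts 300 s; all timestamps are expressed in integer
#' milliseconds from trial start.
#' @export
TRIAL_DURATION_MS <- 300000L

#' Build the apparatus layout
#'
#' The apparatus is a rectangular corridor of four segments. Each corridor
#' segment carries four side boxes -- two on the inner and two on the outer
#' side, sixteen boxes in total -- plus one infrared locomotion sensor at its
#' midpoint. Box identifiers encode corridor index (0--3, clockwise from the
#' start corner), side and within-corridor position, e.g. \code{"c2_in1"};
#' midpoint sensors are \code{"m0"} ... \code{"m3"}.
#'
#' @return An object of class \code{"ambitus_layout"}: a list with
#'   \item{boxes}{data.frame with columns \code{box} (id), \code{corridor}
#'     (0--3), \code{side} (\code{"inner"}/\code{"outer"}) and \code{position}
#'     (0/1).}
#'   \item{midpoints}{character vector of the four corridor sensor ids.}
#' @examples
#' layout <- build_layout()
#' nrow(layout$boxes)        # 16
#' table(layout$boxes$side)  # 8 inner, 8 outer
#' @export
build_layout <- function() {
  corridor <- rep(0:3, each = 4L)
  side <- rep(c("inner", "inner", "outer", "outer"), times = 4L)
  position <- rep(c(0L, 1L), times = 8L)
  box <- sprintf("c%d_%s%d", corridor, ifelse(side == "inner", "in", "out"),
                 position)
  layout <- list(
    boxes = data.frame(box = box, corridor = corridor, side = side,
                       position = position, stringsAsFactors = FALSE),
    midpoints = sprintf("m%d", 0:3)
  )
  class(layout) <- "ambitus_layout"
  layout
}

#' @export
print.ambitus_layout <- function(x, ...) {
  cat("Ambitus apparatus layout: 4 corridors,", nrow(x$boxes),
      "side boxes (", sum(x$boxes$side == "inner"), "inner /",
      sum(x$boxes$side == "outer"), "outer ),",
      length(x$midpoints), "midpoint sensors\n")
  invisible(x)
}

#' Task configuration
#'
#' Three baiting tasks are used. Task 1 baits all sixteen boxes (symmetric);
#' Task 2 baits only the eight inner boxes; Task 3 only the eight outer
#' boxes. Each bait is a single 20 mg puffed-rice reward and trials last
#' 300 s. The side-restricted parameters (exploration frequency and latency
#' on the non-rewarded side, working and reference memory) are only defined
#' for the asymmetric tasks 2 and 3.
#'
#' @param task Integer task id, 1, 2 or 3.
#' @param layout An \code{\link{build_layout}} apparatus layout.
#' @return Object of class \code{"task_config"}: list with \code{task},
#'   \code{baited} (character vector of baited box ids), \code{n_rewards},
#'   \code{reward_mass_mg}, \code{duration_ms} and \code{symmetric} (TRUE iff
#'   all boxes are baited).
#' @examples
#' task_config(2)$n_rewards  # 8
#' task_config(1)$symmetric  # TRUE
#' @export
task_config <- function(task, layout = build_layout()) {
  task <- as.integer(task)
  if (length(task) != 1L || is.na(task) || !task %in% 1:3)
    stop("'task' must be 1, 2 or 3")
  baited <- switch(task,
                   layout$boxes$box,
                   layout$boxes$box[layout$boxes$side == "inner"],
                   layout$boxes$box[layout$boxes$side == "outer"])
  cfg <- list(task = task, baited = baited, n_rewards = length(baited),
              reward_mass_mg = 20, duration_ms = TRIAL_DURATION_MS,
              symmetric = task == 1L)
  class(cfg) <- "task_config"
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("Task", x$task, ":", x$n_rewards, "baited boxes",
      if (x$symmetric) "(symmetric)" else "(asymmetric)",
      "- trial duration", x$duration_ms / 1000, "s\n")
  invisible(x)
}

#' Phases of the study and their tasks
#'
#' The five phases map one-to-one onto tasks: the all-baited task before
#' (PRE_ALL) and after treatment (POST_ALL), the inner-baited task before
#' (PRE_IN) and after treatment (POST_IN), and the outer-baited task after
#' treatment only (POST_EX).
#'
#' @param phase Character vector of phase labels.
#' @return Integer task ids, same length as \code{phase}.
#' @export
phase_task <- function(phase) {
  map <- c(PRE_ALL = 1L, PRE_IN = 2L, POST_ALL = 1L, POST_EX = 3L,
           POST_IN = 2L)
  bad <- setdiff(unique(phase), names(map))
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "))
  unname(map[phase])
}

#' All phase labels, in study order
#' @export
ambitus_phases <- function() c("PRE_ALL", "PRE_IN", "POST_ALL", "POST_EX",
                               "POST_IN")

#' Build the trial schedule of the study
#'
#' Pre-treatment testing is a single day of four trials: trials 1--2 with all
#' boxes baited (PRE_ALL, morning) and trials 3--4 with only the inner boxes
#' baited (PRE_IN, afternoon). After 14 days of treatment, sixteen
#' post-treatment trials run over four days (days 11--14 of the treatment
#' protocol, four trials per day): trials 1--2 POST_ALL on day 11, trials
#' 3--8 POST_EX (3--4 on day 11, 5--8 on day 12) and trials 9--16 POST_IN on
#' days 13--14. Within a two-trial session the inter-trial interval is 2 min;
#' between the morning and afternoon sessions of a day it is 3 h.
#'
#' @return Object of class \code{"ambitus_schedule"}: a data.frame with one
#'   row per trial and columns \code{trial_id} (e.g. \code{"post_07"}),
#'   \code{period} (\code{"pre"}/\code{"post"}), \code{trial} (index within
#'   period), \code{phase}, \code{task}, \code{day} (study day), \code{day_trial}
#'   (1--4 within day) and \code{iti} (\code{"start"}, \code{"2min"} or
#'   \code{"3h"}).
#' @examples
#' sched <- make_schedule()
#' sum(sched$period == "post")              # 16
#' length(unique(sched$day[sched$period == "post"]))  # 4
#' @export
make_schedule <- function() {
  pre <- data.frame(
    period = "pre", trial = 1:4,
    phase = rep(c("PRE_ALL", "PRE_IN"), each = 2L),
    day = 0L, stringsAsFactors = FALSE)
  post <- data.frame(
    period = "post", trial = 1:16,
    phase = c(rep("POST_ALL", 2L), rep("POST_EX", 6L), rep("POST_IN", 8L)),
    day = c(rep(11L, 4L), rep(12L, 4L), rep(13L, 4L), rep(14L, 4L)),
    stringsAsFactors = FALSE)
  sched <- rbind(pre, post)
  sched$task <- phase_task(sched$phase)
  sched$day_trial <- stats::ave(sched$trial, sched$period, sched$day,
                                FUN = seq_along)
  sched$iti <- ifelse(sched$day_trial == 1L, "start",
                      ifelse(sched$day_trial == 3L, "3h", "2min"))
  sched$trial_id <- sprintf("%s_%02d", sched$period, sched$trial)
  sched <- sched[, c("trial_id", "period", "trial", "phase", "task", "day",
                     "day_trial", "iti")]
  class(sched) <- c("ambitus_schedule", "data.frame")
  sched
}

#' @export
print.ambitus_schedule <- function(x, ...) {
  cat("Ambitus study schedule:", sum(x$period == "pre"), "pre +",
      sum(x$period == "post"), "post-treatment trials\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
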