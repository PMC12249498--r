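#' Names of the eleven behavioral parameters, in canonical order
#'
#' \code{loco} locomotion (corridor entries); \code{expl} exploration (box
#' visits); \code{expl_fr_rw}/\code{expl_fr_nrw} exploration frequency into
#' rewarded / non-rewarded boxes up to collection of all rewards, per 300 s;
#' \code{lat_rw}/\code{lat_nrw} latency (s) to the first rewarded /
#' non-rewarded box visit; \code{skipping} corridor entries before the first
#' box exploration; \code{a_e} adequate exploration (\%); \code{l_c} learning
#' capacity (\%); \code{w_m} working memory (\%); \code{r_m} reference memory
#' (\%). The four side-restricted parameters (\code{expl_fr_nrw},
#' \code{lat_nrw}, \code{w_m}, \code{r_m}) are only defined for the
#' asymmetric tasks.
#' @export
score_parameters <- function() {
  c("loco", "expl", "expl_fr_rw", "expl_fr_nrw", "lat_rw", "lat_nrw",
    "skipping", "a_e", "l_c", "w_m", "r_m")
}

#' Eating summary of one trial
#'
#' \code{eat_n} is the number of rewards consumed. \code{eat_t}, the eating
#' time in seconds, is the time of the last reward consumption when all of
#' the task's rewards were collected; when collection is incomplete it is the
#' full 300 s trial window, which makes learning capacity degrade gracefully
#' to the fraction of rewards collected.
#'
#' @param stream An \code{\link{event_stream}}.
#' @param task A \code{\link{task_config}}; defaults to the stream's task.
#' @return List with \code{eat_n}, \code{eat_t} (s) and \code{all_collected}.
#' @export
compute_eating_summary <- function(stream, task = task_config(stream$task)) {
  v <- validate_event_stream(stream, task)
  if (nrow(v) > 0L)
    stop("invalid event stream: ", v$message[1L])
  rw <- stream$events[stream$events$kind == "reward_consumed", , drop = FALSE]
  eat_n <- nrow(rw)
  all_collected <- eat_n == task$n_rewards
  eat_t <- if (all_collected) max(rw$timestamp) / 1000 else
    TRIAL_DURATION_MS / 1000
  list(eat_n = eat_n, eat_t = eat_t, all_collected = all_collected)
}

#' Score one trial: the eleven behavioral parameters
#'
#' Computes, from the raw event stream of one 300 s trial:
#' \describe{
#'   \item{loco}{number of entries into the corridors (midpoint sensor
#'     crossings) up to 5 min.}
#'   \item{expl}{overall number of box visits (box entries) up to 5 min.}
#'   \item{expl_fr_rw}{(number of rewarded-box visits up to collection of all
#'     rewards) x 300 / Eat_T.}
#'   \item{expl_fr_nrw}{(number of non-rewarded-box visits up to collection)
#'     x 300 / Eat_T; asymmetric tasks only.}
#'   \item{lat_rw, lat_nrw}{time (s) to the first visit of a rewarded /
#'     non-rewarded box; censored at 300 s if no such visit;
#'     \code{lat_nrw} asymmetric tasks only.}
#'   \item{skipping}{number of corridor entries before the first box
#'     exploration.}
#'   \item{a_e}{Eat_N x 100 / (number of explorations up to Eat_T).}
#'   \item{l_c}{Eat_N x 300 x 100 / (number of rewards x Eat_T).}
#'   \item{w_m}{Eat_N x 100 / (number of rewarded-box explorations up to
#'     collection); asymmetric tasks only.}
#'   \item{r_m}{(rewarded-box explorations up to collection) x 100 / (all
#'     box explorations up to collection); asymmetric tasks only.}
#' }
#' "Up to Eat_T / up to collection" windows are closed: events with timestamp
#' less than or equal to Eat_T x 1000 count, so the visit consuming the final
#' reward is included. Side-restricted parameters are \code{NA} for the
#' symmetric task, never zero-filled; undefined ratios (division by zero)
#' are \code{NA} with a reason recorded in the \code{"reasons"} attribute.
#'
#' @param stream An \code{\link{event_stream}}.
#' @param task A \code{\link{task_config}}; defaults to the stream's task.
#' @return Object of class \code{"trial_scores"}: named list of the eleven
#'   parameters plus \code{eat_n}, \code{eat_t}, \code{all_collected}, with
#'   attribute \code{"reasons"} naming any NA caused by 0/0.
#' @examples
#' s <- simulate_trial(rat_profile(), task_config(2), seed = 42)
#' score_trial(s)
#' @export
score_trial <- function(stream, task = task_config(stream$task)) {
  eat <- compute_eating_summary(stream, task)
  ev <- stream$events
  cutoff <- eat$eat_t * 1000

  crossings <- ev$timestamp[ev$kind == "corridor_cross"]
  entries <- ev[ev$kind == "box_entry", , drop = FALSE]
  is_rw <- entries$location %in% task$baited

  loco <- length(crossings)
  expl <- nrow(entries)

  first_entry <- if (expl > 0L) min(entries$timestamp) else Inf
  skipping <- sum(crossings < first_entry)

  first_rw <- entries$timestamp[is_rw]
  first_nrw <- entries$timestamp[!is_rw]
  lat_rw <- if (length(first_rw)) min(first_rw) / 1000 else
    TRIAL_DURATION_MS / 1000
  lat_nrw <- if (length(first_nrw)) min(first_nrw) / 1000 else
    TRIAL_DURATION_MS / 1000

  n_rw_upto <- sum(is_rw & entries$timestamp <= cutoff)
  n_nrw_upto <- sum(!is_rw & entries$timestamp <= cutoff)
  n_all_upto <- sum(entries$timestamp <= cutoff)

  reasons <- character()
  ratio <- function(num, den, name) {
    if (den == 0) {
      reasons[name] <<- "division by zero"
      NA_real_
    } else num / den
  }

  expl_fr_rw <- n_rw_upto * 300 / eat$eat_t
  l_c <- eat$eat_n * 300 * 100 / (task$n_rewards * eat$eat_t)
  a_e <- ratio(eat$eat_n * 100, n_all_upto, "a_e")

  if (task$symmetric) {
    expl_fr_nrw <- lat_nrw <- w_m <- r_m <- NA_real_
    reasons[c("expl_fr_nrw", "lat_nrw", "w_m", "r_m")] <- "symmetric task"
  } else {
    expl_fr_nrw <- n_nrw_upto * 300 / eat$eat_t
    w_m <- ratio(eat$eat_n * 100, n_rw_upto, "w_m")
    r_m <- ratio(n_rw_upto * 100, n_all_upto, "r_m")
  }

  out <- list(loco = loco, expl = expl, expl_fr_rw = expl_fr_rw,
              expl_fr_nrw = expl_fr_nrw, lat_rw = lat_rw, lat_nrw = lat_nrw,
              skipping = skipping, a_e = a_e, l_c = l_c, w_m = w_m, r_m = r_m,
              eat_n = eat$eat_n, eat_t = eat$eat_t,
              all_collected = eat$all_collected)
  attr(out, "reasons") <- reasons
  class(out) <- "trial_scores"
  out
}

#' @export
print.trial_scores <- function(x, digits = 4, ...) {
  cat("Trial scores:\n")
  v <- unlist(x[score_parameters()])
  print(round(v, digits))
  cat(sprintf("eating: %d rewards, Eat_T = %g s%s\n", x$eat_n, x$eat_t,
              if (x$all_collected) " (all collected)" else ""))
  r <- attr(x, "reasons")
  if (length(r)) cat("NA fields:", paste(names(r), r, sep = ": ",
                                         collapse = "; "), "\n")
  invisible(x)
}

#' Score a whole dataset of trials
#'
#' Scores every stream against the task of its scheduled trial, producing
#' the long score table that feeds phase aggregation and normalization.
#' Inapplicable or undefined parameters are encoded as \code{NA}, never as
#' sentinel numbers.
#'
#' @param streams List of \code{\link{event_stream}} objects (e.g. from
#'   \code{\link{simulate_cohort}} or \code{\link{read_event_log}}).
#' @param schedule Trial schedule; every stream's \code{trial_id} must match
#'   a schedule row.
#' @return data.frame with one row per animal-trial: \code{animal},
#'   \code{group}, \code{trial_id}, \code{phase}, \code{task}, \code{day},
#'   the eleven parameters, \code{eat_n}, \code{eat_t}, \code{all_collected}.
#' @export
score_dataset <- function(streams, schedule = make_schedule()) {
  if (inherits(streams, "event_stream")) streams <- list(streams)
  layout <- build_layout()
  tasks <- lapply(1:3, task_config, layout = layout)
  rows <- lapply(streams, function(s) {
    i <- match(s$trial_id, schedule$trial_id)
    if (is.na(i))
      stop("stream trial '", s$trial_id, "' (animal ", s$animal,
           ") has no matching schedule row")
    sc <- score_trial(s, tasks[[schedule$task[i]]])
    data.frame(animal = s$animal, group = s$group, trial_id = s$trial_id,
               phase = schedule$phase[i], task = schedule$task[i],
               day = schedule$day[i],
               as.data.frame(unclass(sc)[c(score_parameters(), "eat_n",
                                           "eat_t", "all_collected")]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
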