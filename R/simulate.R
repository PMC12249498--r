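#' Latent behavioral trait profile of a simulated rat
#'
#' The simulator represents a rat as a small set of latent traits that map
#' onto the scored behavioral parameters: \code{move_rate} drives locomotion
#' counts, \code{explore_prob} drives box visits, \code{baited_side_bias}
#' proxies reference memory (side fidelity under asymmetric baiting),
#' \code{revisit_prob} proxies working-memory failure (re-entering emptied
#' baited boxes), \code{lapse_prob} proxies attention lapses (corridor passes
#' with exploration suppressed, raising skipping), and \code{consume_prob}
#' and \code{dwell_ms} shape eating behavior.
#'
#' @param move_rate Corridor transitions per second (> 0).
#' @param explore_prob Probability of entering a side box on a corridor pass.
#' @param baited_side_bias Probability an exploration targets the baited side
#'   given asymmetric baiting; ignored (uniform side choice) under the
#'   symmetric task.
#' @param revisit_prob Probability an exploration of the baited side ignores
#'   which boxes were already emptied.
#' @param consume_prob Probability of eating on entering a baited, non-empty
#'   box.
#' @param lapse_prob Probability a corridor pass occurs with exploration
#'   suppressed.
#' @param dwell_ms Mean in-box dwell time (ms).
#' @return Object of class \code{"rat_profile"} (a named list).
#' @export
rat_profile <- function(move_rate = 0.25, explore_prob = 0.6,
                        baited_side_bias = 0.65, revisit_prob = 0.3,
                        consume_prob = 0.9, lapse_prob = 0.15,
                        dwell_ms = 2000) {
  p <- list(move_rate = move_rate, explore_prob = explore_prob,
            baited_side_bias = baited_side_bias, revisit_prob = revisit_prob,
            consume_prob = consume_prob, lapse_prob = lapse_prob,
            dwell_ms = dwell_ms)
  probs <- c("explore_prob", "baited_side_bias", "revisit_prob",
             "consume_prob", "lapse_prob")
  for (nm in probs)
    if (!is.numeric(p[[nm]]) || is.na(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      stop("'", nm, "' must be a probability in [0, 1]")
  for (nm in c("move_rate", "dwell_ms"))
    if (!is.numeric(p[[nm]]) || is.na(p[[nm]]) || p[[nm]] <= 0)
      stop("'", nm, "' must be strictly positive")
  class(p) <- "rat_profile"
  p
}

#' @export
print.rat_profile <- function(x, ...) {
  cat("Rat trait profile:\n")
  for (nm in names(x)) cat(sprintf("  %-17s %g\n", nm, x[[nm]]))
  invisible(x)
}

# Deterministic sub-seed for one (animal, trial) cell under a master seed.
# Kept well below 2^31 so set.seed() always accepts it.
derive_seed <- function(seed, animal_index, trial_index) {
  (as.integer(seed) %% 100000L) * 10007L + animal_index * 211L +
    trial_index
}

#' Simulate one trial of a rat in the corridor maze
#'
#' Discrete-event simulation on the corridor graph. The rat circles the
#' rectangle; inter-transition times are exponential with rate
#' \code{move_rate}, and each transition fires the midpoint sensor of the
#' corridor it enters. On each pass, unless an attentional lapse occurs, the
#' rat explores one side box of the current corridor with probability
#' \code{explore_prob}; under asymmetric baiting the baited side is chosen
#' with probability \code{baited_side_bias}, otherwise sides are uniform.
#' When exploring the baited side the rat avoids already-emptied boxes except
#' with probability \code{revisit_prob}. Entering a baited, non-empty box
#' consumes its single reward with probability \code{consume_prob}; eating
#' and dwelling occupy \code{dwell_ms} on average, after which a
#' \code{box_exit} is emitted. The stream ends at 300 s.
#'
#' @param profile A \code{\link{rat_profile}}.
#' @param task A \code{\link{task_config}}.
#' @param seed Integer seed; identical (profile, task, seed) give
#'   byte-identical streams.
#' @param animal,trial_id,phase,group Metadata stored on the stream.
#' @param layout Apparatus layout.
#' @return A valid \code{\link{event_stream}}.
#' @examples
#' s <- simulate_trial(rat_profile(), task_config(2), seed = 1)
#' nrow(validate_event_stream(s))  # 0
#' @export
simulate_trial <- function(profile, task, seed, animal = "a1",
                           trial_id = "t1", phase = NA_character_,
                           group = NA_character_, layout = build_layout()) {
  if (!inherits(profile, "rat_profile"))
    profile <- do.call(rat_profile, as.list(profile))
  if (!inherits(task, "task_config")) task <- task_config(task, layout)
  set.seed(as.integer(seed))

  boxes <- layout$boxes
  by_corr <- split(boxes, boxes$corridor)
  baited <- task$baited
  emptied <- character()   # baited boxes whose reward is gone
  full <- setdiff(baited, emptied)

  cap <- 4096L
  ts <- integer(cap); kind <- character(cap); loc <- character(cap)
  n <- 0L
  push <- function(t, k, l) {
    n <<- n + 1L
    ts[n] <<- as.integer(t); kind[n] <<- k; loc[n] <<- l
  }

  t <- 0
  corridor <- 0L
  repeat {
    t <- t + stats::rexp(1L, profile$move_rate) * 1000
    if (t > TRIAL_DURATION_MS) break
    push(floor(t), "corridor_cross", sprintf("m%d", corridor))
    corridor_boxes <- by_corr[[as.character(corridor)]]
    corridor <- (corridor + 1L) %% 4L

    if (stats::runif(1L) < profile$lapse_prob) next
    if (stats::runif(1L) >= profile$explore_prob) next

    # side choice
    sides <- unique(corridor_boxes$side)
    baited_sides <- unique(corridor_boxes$side[corridor_boxes$box %in% baited])
    side <- if (task$symmetric || length(baited_sides) != 1L) {
      sides[1L + (stats::runif(1L) < 0.5)]
    } else if (stats::runif(1L) < profile$baited_side_bias) {
      baited_sides
    } else {
      setdiff(sides, baited_sides)
    }
    cand <- corridor_boxes$box[corridor_boxes$side == side]
    cand_baited <- intersect(cand, baited)
    if (length(cand_baited) == length(cand)) {
      # baited side: avoid emptied boxes unless memory lapses
      not_empty <- setdiff(cand, emptied)
      ignore_memory <- stats::runif(1L) < profile$revisit_prob
      pool <- if (ignore_memory) cand else not_empty
      if (length(pool) == 0L) next
      box <- pool[sample.int(length(pool), 1L)]
    } else {
      box <- cand[sample.int(length(cand), 1L)]
    }

    t_entry <- t + stats::runif(1L, 100, 500)
    if (t_entry > TRIAL_DURATION_MS) break
    push(floor(t_entry), "box_entry", box)
    dwell <- stats::rexp(1L, 1 / profile$dwell_ms)
    if (box %in% baited && !(box %in% emptied) &&
        stats::runif(1L) < profile$consume_prob) {
      t_eat <- t_entry + dwell * 0.5
      if (t_eat <= TRIAL_DURATION_MS) {
        push(floor(t_eat), "reward_consumed", box)
        emptied <- c(emptied, box)
      }
    }
    t_exit <- t_entry + dwell
    if (t_exit <= TRIAL_DURATION_MS) push(floor(t_exit), "box_exit", box)
    t <- t_exit
  }

  event_stream(animal = animal, trial_id = trial_id, phase = phase,
               group = group, task = task$task,
               events = data.frame(timestamp = ts[seq_len(n)],
                                   kind = kind[seq_len(n)],
                                   loc = loc[seq_len(n)],
                                   stringsAsFactors = FALSE) |>
                 stats::setNames(c("timestamp", "kind", "location")))
}

#' Group-level effect on the trait profile
#'
#' A treatment group is modeled as multiplicative modifiers on each latent
#' trait plus between-animal variability. Modified probabilities are clipped
#' to [0, 1].
#'
#' @param label Group label.
#' @param multipliers Named numeric vector of multipliers on
#'   \code{\link{rat_profile}} fields (unnamed traits default to 1).
#' @param cv Between-animal coefficient of variation applied to every trait
#'   (log-normal), a single value or named per trait.
#' @return Object of class \code{"group_effect"}.
#' @export
group_effect <- function(label, multipliers = numeric(), cv = 0.15) {
  traits <- names(rat_profile())
  bad <- setdiff(names(multipliers), traits)
  if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
  if (any(cv < 0)) stop("'cv' must be >= 0")
  m <- stats::setNames(rep(1, length(traits)), traits)
  m[names(multipliers)] <- multipliers
  cvv <- stats::setNames(rep(cv[[1L]], length(traits)), traits)
  if (!is.null(names(cv))) cvv[names(cv)] <- cv
  e <- list(label = label, multipliers = m, cv = cvv)
  class(e) <- "group_effect"
  e
}

#' Simulation configuration for a cohort
#'
#' @param seed Master integer seed; fixes the entire output.
#' @param n_per_group Animals per group (recycled over groups).
#' @param groups List of \code{\link{group_effect}} objects.
#' @param baseline Baseline \code{\link{rat_profile}}.
#' @param schedule Trial schedule (default \code{\link{make_schedule}}).
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(seed, n_per_group, groups, baseline = rat_profile(),
                       schedule = make_schedule()) {
  stopifnot(length(groups) >= 1L, all(vapply(groups, inherits, TRUE,
                                             "group_effect")))
  cfg <- list(seed = as.integer(seed),
              n_per_group = rep_len(as.integer(n_per_group), length(groups)),
              groups = groups, baseline = baseline, schedule = schedule)
  class(cfg) <- "sim_config"
  cfg
}

# Draw one animal's realized traits from baseline x group effect.
draw_traits <- function(baseline, effect) {
  probs <- c("explore_prob", "baited_side_bias", "revisit_prob",
             "consume_prob", "lapse_prob")
  out <- lapply(names(baseline), function(nm) {
    cv <- effect$cv[[nm]]
    noise <- if (cv > 0)
      stats::rlnorm(1L, meanlog = -0.5 * log1p(cv^2),
                    sdlog = sqrt(log1p(cv^2))) else 1
    v <- baseline[[nm]] * effect$multipliers[[nm]] * noise
    if (nm %in% probs) v <- min(max(v, 0), 1)
    v
  })
  do.call(rat_profile, stats::setNames(out, names(baseline)))
}

#' Simulate a full cohort over the study schedule
#'
#' Draws per-animal latent traits from each group's effect (log-normal
#' between-animal variability around baseline times multiplier), then
#' simulates every scheduled trial for every animal. Per-trial seeds are
#' derived deterministically from the master seed so the whole dataset is
#' reproducible bit-for-bit.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{streams} (list of \code{\link{event_stream}}, one
#'   per animal-trial) and \code{truth} (data.frame of the latent per-animal
#'   traits, for parameter-recovery checks).
#' @examples
#' cfg <- sim_config(1, 2, list(group_effect("A"), group_effect("B")))
#' cohort <- simulate_cohort(cfg)
#' length(cohort$streams)  # 2 groups x 2 animals x 20 trials = 80
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- list(); profiles <- list(); animal_group <- character()
  a <- 0L
  for (g in seq_along(config$groups)) {
    eff <- config$groups[[g]]
    for (i in seq_len(config$n_per_group[g])) {
      a <- a + 1L
      pr <- draw_traits(config$baseline, eff)
      id <- sprintf("%s_%02d", eff$label, i)
      profiles[[id]] <- pr
      animal_group[id] <- eff$label
      truth[[id]] <- data.frame(animal = id, group = eff$label,
                                as.data.frame(unclass(pr)),
                                stringsAsFactors = FALSE)
    }
  }
  sched <- config$schedule
  layout <- build_layout()
  tasks <- lapply(1:3, task_config, layout = layout)
  streams <- vector("list", length(profiles) * nrow(sched))
  k <- 0L
  for (ai in seq_along(profiles)) {
    id <- names(profiles)[ai]
    for (ti in seq_len(nrow(sched))) {
      k <- k + 1L
      streams[[k]] <- simulate_trial(
        profiles[[ai]], tasks[[sched$task[ti]]],
        seed = derive_seed(config$seed, ai, ti),
        animal = id, trial_id = sched$trial_id[ti],
        phase = sched$phase[ti], group = animal_group[[id]], layout = layout)
    }
  }
  list(streams = streams, truth = do.call(rbind, c(truth,
                                                   make.row.names = FALSE)))
}
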