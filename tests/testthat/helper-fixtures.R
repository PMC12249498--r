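# Shared fixtures built in code.

# Hand-worked toy trial (Task 2, inner boxes baited), scored by hand before
# any implementation: 10 corridor crossings, 11 box entries (9 rewarded-side
# incl. one revisit, 2 outer), 8/8 rewards with the last at 80 500 ms.
toy_trial <- function() {
  inner <- sprintf("c%d_in%d", rep(0:3, each = 2), rep(0:1, 4))  # I1..I8
  outer <- c("c0_out0", "c0_out1")                               # O1, O2
  ev <- rbind(
    data.frame(timestamp = c(2000, 4000), kind = "corridor_cross",
               location = c("m0", "m1")),
    data.frame(timestamp = 6000, kind = "box_entry", location = inner[1]),
    data.frame(timestamp = 6500, kind = "reward_consumed",
               location = inner[1]),
    data.frame(timestamp = 10000, kind = "box_entry", location = outer[1]),
    data.frame(timestamp = c(12000, 12500), kind = c("box_entry",
               "reward_consumed"), location = inner[2]),
    data.frame(timestamp = c(20000, 20500), kind = c("box_entry",
               "reward_consumed"), location = inner[3]),
    data.frame(timestamp = c(30000, 30500), kind = c("box_entry",
               "reward_consumed"), location = inner[4]),
    data.frame(timestamp = c(40000, 40500), kind = c("box_entry",
               "reward_consumed"), location = inner[5]),
    data.frame(timestamp = c(50000, 50500), kind = c("box_entry",
               "reward_consumed"), location = inner[6]),
    data.frame(timestamp = c(60000, 60500), kind = c("box_entry",
               "reward_consumed"), location = inner[7]),
    data.frame(timestamp = 70000, kind = "box_entry", location = inner[1]),
    data.frame(timestamp = c(80000, 80500), kind = c("box_entry",
               "reward_consumed"), location = inner[8]),
    data.frame(timestamp = 90000, kind = "box_entry", location = outer[2]),
    data.frame(timestamp = seq(100000, 170000, by = 10000),
               kind = "corridor_cross",
               location = rep(c("m2", "m3"), 4))
  )
  ev <- ev[order(ev$timestamp), ]
  event_stream(animal = "toy", trial_id = "post_09", phase = "POST_IN",
               events = ev)
}

# A flawless Task-2 run: each of the 8 baited boxes entered once, reward
# taken immediately, no other events, last reward exactly at 300 s.
perfect_trial <- function() {
  inner <- sprintf("c%d_in%d", rep(0:3, each = 2), rep(0:1, 4))
  t_entry <- seq(30000, 299000, length.out = 8)
  t_entry[8] <- 299000
  ev <- data.frame(
    timestamp = as.vector(rbind(t_entry, t_entry + 1000)),
    kind = rep(c("box_entry", "reward_consumed"), 8),
    location = rep(inner, each = 2))
  ev$timestamp[16] <- 300000  # final reward at the window edge
  event_stream(animal = "perfect", trial_id = "post_09", phase = "POST_IN",
               events = ev)
}

empty_trial <- function(phase = "POST_IN") {
  event_stream(animal = "none", trial_id = "post_09", phase = phase,
               events = data.frame(timestamp = integer(), kind = character(),
                                   location = character()))
}

# A random but always-valid profile for property sweeps.
random_profile <- function() {
  rat_profile(move_rate = runif(1, 0.05, 0.6),
              explore_prob = runif(1),
              baited_side_bias = runif(1),
              revisit_prob = runif(1),
              consume_prob = runif(1),
              lapse_prob = runif(1, 0, 0.6),
              dwell_ms = runif(1, 300, 5000))
}
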