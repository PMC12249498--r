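test_that("eating summary follows the censoring decision rule", {
  eat <- compute_eating_summary(toy_trial(), task_config(2))
  expect_equal(eat$eat_n, 8)
  expect_equal(eat$eat_t, 80.5)
  expect_true(eat$all_collected)

  expect_equal(compute_eating_summary(empty_trial(), task_config(2)),
               list(eat_n = 0, eat_t = 300, all_collected = FALSE))

  partial <- toy_trial()
  keep <- !(partial$events$kind == "reward_consumed" &
              partial$events$timestamp > 21000)
  partial$events <- partial$events[keep, ]
  eat <- compute_eating_summary(partial, task_config(2))
  expect_equal(eat$eat_n, 3)
  expect_equal(eat$eat_t, 300)
})

test_that("the hand-worked toy trial reproduces all eleven parameters", {
  sc <- score_trial(toy_trial(), task_config(2))
  expect_equal(sc$loco, 10)
  expect_equal(sc$expl, 11)
  expect_equal(sc$skipping, 2)
  expect_equal(sc$lat_rw, 6.0)
  expect_equal(sc$lat_nrw, 10.0)
  expect_equal(sc$eat_t, 80.5)
  expect_equal(sc$eat_n, 8)
  expect_equal(sc$expl_fr_rw, 9 * 300 / 80.5)
  expect_equal(sc$expl_fr_nrw, 1 * 300 / 80.5)
  expect_equal(sc$a_e, 80)
  expect_equal(sc$l_c, 8 * 300 * 100 / (8 * 80.5))
  expect_equal(sc$w_m, 800 / 9)
  expect_equal(sc$r_m, 90)
})

test_that("a flawless run is the identity case of each formula", {
  sc <- score_trial(perfect_trial(), task_config(2))
  expect_equal(sc$skipping, 0)
  expect_equal(sc$w_m, 100)
  expect_equal(sc$r_m, 100)
  expect_equal(sc$l_c, 100)
  expect_equal(sc$a_e, 100)
  expect_equal(sc$eat_t, 300)   # final reward exactly at the window edge
})

test_that("an empty stream degrades gracefully", {
  sc <- score_trial(empty_trial(), task_config(2))
  expect_equal(sc$loco, 0)
  expect_equal(sc$expl, 0)
  expect_equal(sc$skipping, 0)
  expect_equal(sc$eat_n, 0)
  expect_equal(sc$l_c, 0)
  expect_equal(sc$lat_rw, 300)
  expect_true(is.na(sc$a_e))
  expect_true(is.na(sc$w_m))
  expect_true(is.na(sc$r_m))
  reasons <- attr(sc, "reasons")
  expect_equal(unname(reasons[["a_e"]]), "division by zero")
})

test_that("side-restricted parameters are NA exactly under the symmetric task", {
  s <- simulate_trial(rat_profile(), task_config(1), seed = 3,
                      phase = "POST_ALL")
  sc <- score_trial(s, task_config(1))
  expect_true(all(is.na(unlist(sc[c("expl_fr_nrw", "lat_nrw", "w_m",
                                    "r_m")]))))
  expect_false(anyNA(unlist(sc[c("loco", "expl", "expl_fr_rw", "lat_rw",
                                 "skipping", "l_c")])))
})

test_that("events after Eat_T never change the collection-window scores", {
  base <- toy_trial()
  sc0 <- score_trial(base, task_config(2))
  more <- base
  more$events <- rbind(more$events,
    data.frame(timestamp = c(250000, 260000, 270000),
               kind = c("box_entry", "box_entry", "corridor_cross"),
               location = c("c1_out0", "c0_in0", "m0")))
  sc1 <- score_trial(more, task_config(2))
  for (p in c("expl_fr_rw", "expl_fr_nrw", "a_e", "w_m", "r_m"))
    expect_equal(sc1[[p]], sc0[[p]], info = p)
  expect_equal(sc1$expl, sc0$expl + 2)  # the 5-min counts do move
})

test_that("scoring identities hold over random simulated trials", {
  set.seed(21)
  for (i in 1:40) {
    task <- task_config(sample(2:3, 1))
    s <- simulate_trial(random_profile(), task, seed = 5000 + i)
    sc <- score_trial(s, task)
    if (!is.na(sc$w_m)) expect_lte(sc$w_m, 100)
    if (!is.na(sc$r_m)) {
      cutoff <- sc$eat_t * 1000
      entries <- s$events[s$events$kind == "box_entry" &
                            s$events$timestamp <= cutoff, ]
      nrw_share <- sum(!(entries$location %in% task$baited)) * 100 /
        nrow(entries)
      expect_equal(sc$r_m + nrw_share, 100)
    }
  }
})

test_that("brute-force oracle and score_trial agree on random streams", {
  set.seed(22)
  for (i in 1:150) {
    task <- task_config(sample(1:3, 1))
    s <- simulate_trial(random_profile(), task, seed = 20000 + i)
    sc <- score_trial(s, task)
    or <- oracle_score(s, task)
    for (p in c(score_parameters(), "eat_n", "eat_t"))
      expect_identical(sc[[p]], or[[p]], label = paste(p, "seed", 20000 + i))
  }
})

test_that("score_dataset keys streams by schedule and keeps NA semantics", {
  cfg <- sim_config(5, 3, list(group_effect("A"), group_effect("B")))
  cohort <- simulate_cohort(cfg)
  tab <- score_dataset(cohort$streams)
  expect_equal(nrow(tab), 6 * 20)
  expect_true(all(is.na(tab$w_m[tab$phase %in% c("PRE_ALL", "POST_ALL")])))
  expect_true(all(!is.na(tab$loco)))
  asym <- tab[tab$task != 1, ]
  expect_true(all(is.na(asym$w_m) | asym$w_m <= 100))
  expect_true(all(tab$skipping >= 0 & tab$l_c >= 0 & tab$lat_rw <= 300))
  expect_true(all(is.na(tab$a_e) | (tab$a_e >= 0 & tab$a_e <= 100)))

  bad <- cohort$streams[[1]]
  bad$trial_id <- "nonexistent"
  expect_error(score_dataset(list(bad)), "no matching schedule row")
})
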