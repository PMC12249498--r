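# Independent oracles, deliberately naive: plain linear scans and textbook
# sums of squares, no reuse of package internals beyond data containers.

# Brute-force trial scorer: one event-by-event pass with explicit
# accumulators, then literal transcription of each defining formula.
oracle_score <- function(stream, task) {
  ev <- stream$events
  n_rewards <- task$n_rewards
  baited <- task$baited

  crossings <- numeric(0); entry_ts <- numeric(0)
  entry_rw <- logical(0); reward_ts <- numeric(0)
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]; t <- ev$timestamp[i]; loc <- ev$location[i]
    if (k == "corridor_cross") crossings <- c(crossings, t)
    if (k == "box_entry") {
      entry_ts <- c(entry_ts, t)
      entry_rw <- c(entry_rw, loc %in% baited)
    }
    if (k == "reward_consumed") reward_ts <- c(reward_ts, t)
  }

  eat_n <- length(reward_ts)
  eat_t <- if (eat_n == n_rewards) max(reward_ts) / 1000 else 300
  cutoff <- eat_t * 1000

  loco <- length(crossings)
  expl <- length(entry_ts)
  first_entry <- if (expl > 0) min(entry_ts) else Inf
  skipping <- 0L
  for (t in crossings) if (t < first_entry) skipping <- skipping + 1L

  lat_rw <- 300; lat_nrw <- 300
  if (any(entry_rw)) lat_rw <- min(entry_ts[entry_rw]) / 1000
  if (any(!entry_rw)) lat_nrw <- min(entry_ts[!entry_rw]) / 1000

  n_rw <- sum(entry_rw & entry_ts <= cutoff)
  n_nrw <- sum(!entry_rw & entry_ts <= cutoff)
  n_all <- sum(entry_ts <= cutoff)

  res <- list(loco = loco, expl = expl,
              expl_fr_rw = n_rw * 300 / eat_t,
              expl_fr_nrw = n_nrw * 300 / eat_t,
              lat_rw = lat_rw, lat_nrw = lat_nrw,
              skipping = skipping,
              a_e = if (n_all == 0) NA_real_ else eat_n * 100 / n_all,
              l_c = eat_n * 300 * 100 / (n_rewards * eat_t),
              w_m = if (n_rw == 0) NA_real_ else eat_n * 100 / n_rw,
              r_m = if (n_all == 0) NA_real_ else n_rw * 100 / n_all,
              eat_n = eat_n, eat_t = eat_t)
  if (task$symmetric)
    res[c("expl_fr_nrw", "lat_nrw", "w_m", "r_m")] <- NA_real_
  res
}

# Textbook split-plot sums of squares for balanced designs (equal animals
# per group, complete phases).
oracle_split_plot <- function(d) {
  d$animal <- as.character(d$animal)
  k <- length(unique(d$phase))
  G <- length(unique(d$group))
  N <- length(unique(d$animal))
  grand <- mean(d$value)
  subj_mean <- tapply(d$value, d$animal, mean)
  group_of <- tapply(d$group, d$animal, function(g) g[1])
  group_mean <- tapply(d$value, d$group, mean)
  phase_mean <- tapply(d$value, d$phase, mean)
  cell_mean <- tapply(d$value, list(d$group, d$phase), mean)
  n_per_group <- N / G

  ss_between_subj <- k * sum((subj_mean - grand)^2)
  ss_group <- k * n_per_group * sum((group_mean - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_phase <- N * sum((phase_mean - grand)^2)
  ss_cells <- n_per_group * sum((cell_mean - grand)^2)
  ss_inter <- ss_cells - ss_group - ss_phase
  ss_total <- sum((d$value - grand)^2)
  ss_error <- ss_total - ss_between_subj - ss_phase - ss_inter

  df_group <- G - 1; df_subj <- N - G
  df_phase <- k - 1; df_inter <- (G - 1) * (k - 1)
  df_error <- (N - G) * (k - 1)
  list(
    F_group = (ss_group / df_group) / (ss_subj_within / df_subj),
    F_phase = (ss_phase / df_phase) / (ss_error / df_error),
    F_inter = (ss_inter / df_inter) / (ss_error / df_error),
    df = list(group = c(df_group, df_subj),
              phase = c(df_phase, df_error),
              inter = c(df_inter, df_error)))
}

# Long-format balanced two-group x k-phase dataset from a matrix generator.
balanced_rm_data <- function(n_per_group, k, gen = function(n, k)
                             matrix(rnorm(n * k), n, k)) {
  rows <- list()
  for (g in c("A", "B")) {
    Y <- gen(n_per_group, k)
    for (i in seq_len(n_per_group))
      rows[[length(rows) + 1]] <- data.frame(
        animal = paste0(g, i), group = g,
        phase = paste0("p", seq_len(k)), value = Y[i, ],
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# N x k matrix with column means exactly 0 and sample covariance exactly S.
exact_cov_matrix <- function(n, S) {
  k <- ncol(S)
  X <- matrix(rnorm(n * k), n, k)
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- X %*% solve(chol(stats::cov(X)))
  X %*% chol(S)
}
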