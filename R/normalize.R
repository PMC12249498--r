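#' Parameters whose z-scores are inverted
#'
#' For latency and skipping, higher raw values indicate impairment, so their
#' z-scores are sign-flipped: after inversion, every parameter reads
#' "higher = better performance / more activity".
#' @export
inverted_parameters <- function() c("lat_rw", "lat_nrw", "skipping")

#' Aggregate trial scores to per-animal phase means
#'
#' Each animal's trials within a phase are reduced to their mean, parameter
#' by parameter, ignoring missing trials; a phase with no applicable trial
#' for a parameter yields a missing value.
#'
#' @param scores Long score table from \code{\link{score_dataset}}.
#' @param parameters Which parameter columns to aggregate.
#' @return data.frame with columns \code{animal}, \code{group}, \code{phase},
#'   \code{parameter}, \code{value}, one row per combination.
#' @export
aggregate_phase <- function(scores, parameters = score_parameters()) {
  stopifnot(all(c("animal", "phase") %in% names(scores)),
            all(parameters %in% names(scores)))
  grp <- if ("group" %in% names(scores)) scores$group else NA_character_
  key <- data.frame(animal = scores$animal, group = grp,
                    phase = scores$phase, stringsAsFactors = FALSE)
  rows <- lapply(parameters, function(p) {
    agg <- stats::aggregate(scores[[p]], by = key,
                            FUN = function(v) mean(v, na.rm = TRUE))
    agg$parameter <- p
    names(agg)[names(agg) == "x"] <- "value"
    agg
  })
  out <- do.call(rbind, rows)
  out$value[is.nan(out$value)] <- NA_real_
  out <- out[order(out$animal, out$phase,
                   match(out$parameter, parameters)), ]
  rownames(out) <- NULL
  out[, c("animal", "group", "phase", "parameter", "value")]
}

#' Phase-wise z-score normalization with impairment inversion
#'
#' Within each (phase, parameter) cell, each animal's phase mean is
#' normalized by subtracting the mean and dividing by the standard deviation
#' of all animals in the phase (all groups pooled). For parameters where a
#' higher raw value indicates impairment (the inversion registry: latencies
#' and skipping by default) the z-score sign is flipped, so positive z always
#' reads as enhanced activity or better performance. Cells with fewer than
#' two non-missing values or zero spread are flagged and their z left
#' missing, never silently zeroed.
#'
#' @param phase_means Output of \code{\link{aggregate_phase}}.
#' @param invert Character vector of parameters to sign-flip.
#' @param sd_type \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"} (n denominator).
#' @return Object of class \code{"zscore_table"}: the input data.frame plus
#'   columns \code{z} and \code{flag} (\code{NA}, \code{"degenerate_sd"} or
#'   \code{"too_few"}), with attributes \code{"stats"} (per-cell mean, SD, n)
#'   and \code{"inverted"}.
#' @examples
#' raw <- data.frame(animal = c("a", "b", "c"), group = "g",
#'                   phase = "POST_IN", parameter = "expl", value = 1:3)
#' zscore_phase(raw)$z  # -1 0 1
#' @export
zscore_phase <- function(phase_means, invert = inverted_parameters(),
                         sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(all(c("animal", "phase", "parameter", "value") %in%
                  names(phase_means)))
  out <- phase_means
  out$z <- NA_real_
  out$flag <- NA_character_
  cell <- interaction(out$phase, out$parameter, drop = TRUE)
  stats_rows <- list()
  for (cl in levels(cell)) {
    i <- which(cell == cl)
    x <- out$value[i]
    ok <- !is.na(x)
    n <- sum(ok)
    m <- if (n > 0) mean(x[ok]) else NA_real_
    s <- if (n > 1) {
      s0 <- stats::sd(x[ok])
      if (sd_type == "population") s0 * sqrt((n - 1) / n) else s0
    } else NA_real_
    stats_rows[[cl]] <- data.frame(phase = out$phase[i][1L],
                                   parameter = out$parameter[i][1L],
                                   mean = m, sd = s, n = n,
                                   stringsAsFactors = FALSE)
    if (n < 2L) {
      out$flag[i][ok] <- "too_few"
    } else if (s == 0) {
      out$flag[i][ok] <- "degenerate_sd"
    } else {
      sign <- if (out$parameter[i][1L] %in% invert) -1 else 1
      out$z[i] <- sign * (x - m) / s
    }
  }
  attr(out, "stats") <- do.call(rbind, c(stats_rows,
                                         make.row.names = FALSE))
  attr(out, "inverted") <- invert
  attr(out, "sd_type") <- sd_type
  class(out) <- c("zscore_table", "data.frame")
  out
}
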