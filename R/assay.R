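#' Normalize western-blot densitometry to beta-actin
#'
#' Per sample, the normalized expression is the local-background-subtracted
#' target band optical density divided by the background-subtracted
#' beta-actin density of the same lane. Samples whose actin net OD is not
#' positive are flagged invalid and excluded with a reason. The mean +/- 2 SD
#' outlier rule (\code{\link{exclude_outliers}}) is then applied within each
#' group.
#'
#' @param records data.frame with columns \code{sample}, \code{group},
#'   \code{target_od}, \code{target_bg}, \code{actin_od}, \code{actin_bg}
#'   (e.g. from \code{\link{generate_densitometry_dataset}}).
#' @return data.frame with the input columns plus \code{value} (normalized
#'   expression), \code{invalid} (actin net OD <= 0), \code{outlier}
#'   (excluded by the 2 SD rule within group) and \code{reason}. Rows with
#'   \code{invalid} or \code{outlier} TRUE are excluded from downstream
#'   summaries; \code{attr(, "group_summary")} holds mean, SEM and n per
#'   group after exclusions (SEM = sample SD / sqrt(n)).
#' @examples
#' r <- data.frame(sample = "s1", group = "g", target_od = 150,
#'                 target_bg = 50, actin_od = 200, actin_bg = 100)
#' normalize_densitometry(r)$value  # 1
#' @export
normalize_densitometry <- function(records) {
  need <- c("group", "target_od", "target_bg", "actin_od", "actin_bg")
  stopifnot(all(need %in% names(records)))
  if (any(records[, c("target_od", "target_bg", "actin_od",
                      "actin_bg")] < 0, na.rm = TRUE))
    stop("optical densities must be non-negative")
  out <- records
  target_net <- out$target_od - out$target_bg
  actin_net <- out$actin_od - out$actin_bg
  out$invalid <- actin_net <= 0
  out$value <- ifelse(out$invalid, NA_real_, target_net / actin_net)
  out$outlier <- FALSE
  out$reason <- ifelse(out$invalid, "actin net OD <= 0", NA_character_)
  for (g in unique(out$group)) {
    i <- which(out$group == g & !out$invalid)
    if (length(i) >= 3L) {
      ex <- exclude_outliers(out$value[i])
      drop <- out$value[i] %in% ex$excluded
      out$outlier[i][drop] <- TRUE
      out$reason[i][drop] <- "beyond mean +/- 2 SD"
    }
  }
  keep <- !out$invalid & !out$outlier
  summ <- do.call(rbind, lapply(unique(out$group), function(g) {
    v <- out$value[keep & out$group == g]
    data.frame(group = g, mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), n = length(v),
               stringsAsFactors = FALSE)
  }))
  attr(out, "group_summary") <- summ
  out
}

#' Fluid-intake and drug-dose accounting
#'
#' From daily fluid-intake and body-weight records, computes per-day fluid
#' intake normalized to body weight (mL/kg/day) and, for each drug dissolved
#' in the drinking water, the ingested dose (mg/kg/day) = fluid intake x
#' concentration (mg/mL). Days are averaged within animal first, then group
#' summaries (mean +/- SEM across animals) are formed.
#'
#' @param records data.frame with columns \code{animal}, \code{group},
#'   \code{day}, \code{fluid_ml}, \code{weight_kg}, plus one column
#'   \code{conc_<drug>} (mg/mL) per drug.
#' @return List with \code{per_day} (row-level fluid_ml_per_kg and
#'   dose_<drug>), \code{per_animal} (day-averaged) and
#'   \code{group_summary} (mean and SEM per group and quantity).
#' @examples
#' r <- data.frame(animal = "a1", group = "CAFF_FURO", day = 1,
#'                 fluid_ml = 73, weight_kg = 0.5, conc_caffeine = 0.5)
#' compute_intake_dose(r)$per_day$dose_caffeine  # 73 mg/kg/day
#' @export
compute_intake_dose <- function(records) {
  need <- c("animal", "group", "day", "fluid_ml", "weight_kg")
  stopifnot(all(need %in% names(records)))
  if (anyNA(records$weight_kg) || any(records$weight_kg <= 0))
    stop("missing or non-positive body weight in row ",
         which(is.na(records$weight_kg) | records$weight_kg <= 0)[1L])
  if (any(records$fluid_ml < 0)) stop("fluid intake must be >= 0")
  drug_cols <- grep("^conc_", names(records), value = TRUE)
  drugs <- sub("^conc_", "", drug_cols)

  per_day <- records
  per_day$fluid_ml_per_kg <- per_day$fluid_ml / per_day$weight_kg
  for (i in seq_along(drugs))
    per_day[[paste0("dose_", drugs[i])]] <-
      per_day$fluid_ml_per_kg * per_day[[drug_cols[i]]]

  qty <- c("fluid_ml_per_kg", paste0("dose_", drugs))
  per_animal <- stats::aggregate(per_day[, qty, drop = FALSE],
                                 by = list(animal = per_day$animal,
                                           group = per_day$group),
                                 FUN = mean)
  group_summary <- do.call(rbind, lapply(unique(per_animal$group),
    function(g) {
      do.call(rbind, lapply(qty, function(q) {
        v <- per_animal[[q]][per_animal$group == g]
        data.frame(group = g, quantity = q, mean = mean(v),
                   sem = if (length(v) > 1L)
                     stats::sd(v) / sqrt(length(v)) else NA_real_,
                   n = length(v), stringsAsFactors = FALSE)
      }))
    }))
  list(per_day = per_day, per_animal = per_animal,
       group_summary = group_summary)
}
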