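anova_result <- function(effect, F, df1, df2, p, ms_effect = NA_real_,
                         ms_error = NA_real_, eps = NA_real_,
                         p_gg = NA_real_, mauchly_p = NA_real_,
                         gg_applied = FALSE, degenerate = FALSE) {
  r <- list(effect = effect, F = F, df1 = df1, df2 = df2, p = p,
            ms_effect = ms_effect, ms_error = ms_error, eps = eps,
            p_gg = p_gg, mauchly_p = mauchly_p, gg_applied = gg_applied,
            degenerate = degenerate)
  class(r) <- "anova_result"
  r
}

#' @export
print.anova_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("%s: degenerate (zero error variance)\n", x$effect))
    return(invisible(x))
  }
  df1 <- if (x$gg_applied) x$df1 * x$eps else x$df1
  df2 <- if (x$gg_applied) x$df2 * x$eps else x$df2
  p <- if (x$gg_applied) x$p_gg else x$p
  cat(sprintf("%s: F(%.4g, %.4g) = %.4g; p = %.4g%s\n", x$effect, df1, df2,
              x$F, p,
              if (x$gg_applied) sprintf(" [Greenhouse-Geisser, eps = %.3f]",
                                        x$eps) else ""))
  invisible(x)
}

#' One-way between-groups ANOVA
#'
#' Classical fixed-effects one-way ANOVA with F on (k - 1, N - k) degrees of
#' freedom, used for treatment comparisons of phase-mean z-scores. The fit
#' is delegated to \code{\link[stats]{lm}}; mean squares are returned so
#' Fisher's LSD can reuse the pooled error.
#'
#' @param value Numeric response vector.
#' @param group Group labels, same length.
#' @return \code{"anova_result"} with effect \code{"group"}. A fit with zero
#'   error variance is flagged \code{degenerate} (F undefined) unless the
#'   between-group variance is also zero, in which case F = 0.
#' @export
one_way_anova <- function(value, group) {
  ok <- !is.na(value) & !is.na(group)
  value <- value[ok]; group <- factor(as.character(group[ok]))
  if (nlevels(group) < 2L) stop("need at least two groups")
  if (any(table(group) < 2L))
    stop("every group needs at least two non-missing values")
  fit <- stats::lm(value ~ group)
  tab <- suppressWarnings(stats::anova(fit))  # degeneracy handled below
  ms_b <- tab$`Mean Sq`[1L]; ms_w <- tab$`Mean Sq`[2L]
  df1 <- tab$Df[1L]; df2 <- tab$Df[2L]
  # zero within-group variance up to numerical noise of the lm fit
  if (ms_w <= 1e-12 * (ms_b + mean(value)^2)) {
    return(anova_result("group", F = if (ms_b == 0) 0 else Inf,
                        df1 = df1, df2 = df2,
                        p = if (ms_b == 0) 1 else 0,
                        ms_effect = ms_b, ms_error = 0, degenerate = TRUE))
  }
  anova_result("group", F = tab$`F value`[1L], df1 = df1, df2 = df2,
               p = tab$`Pr(>F)`[1L], ms_effect = ms_b, ms_error = ms_w)
}

#' Two-factor mixed (split-plot) repeated-measures ANOVA
#'
#' Group is a between-subjects factor, phase a within-subject factor. Fits a
#' multivariate linear model over the phase columns and decomposes it with
#' Type-III sums of squares (\code{\link[car]{Anova}}), returning the
#' between-subjects group effect and the within-subject phase and
#' group-by-phase effects. Sphericity is assessed by Mauchly's test and the
#' Greenhouse-Geisser epsilon is reported for the within effects; under
#' \code{gg = "auto"} the GG-corrected p-value is adopted whenever Mauchly's
#' p < 0.05 (with two phase levels sphericity holds trivially and epsilon is
#' 1). Animals with any missing phase are dropped listwise with a warning.
#'
#' @param data data.frame with one row per animal-phase observation.
#' @param value,animal,group,phase Column names.
#' @param gg \code{"auto"} (Mauchly-gated), \code{"always"} or
#'   \code{"never"}.
#' @return List of three \code{"anova_result"} objects named \code{group},
#'   \code{phase} and \code{group_by_phase}.
#' @export
mixed_anova_gg <- function(data, value = "value", animal = "animal",
                           group = "group", phase = "phase",
                           gg = c("auto", "always", "never")) {
  gg <- match.arg(gg)
  d <- data.frame(animal = as.character(data[[animal]]),
                  group = as.character(data[[group]]),
                  phase = as.character(data[[phase]]),
                  value = as.numeric(data[[value]]),
                  stringsAsFactors = FALSE)
  phases <- unique(d$phase)
  k <- length(phases)
  if (k < 2L) stop("need at least two phases")
  wide <- stats::reshape(d, idvar = c("animal", "group"),
                         timevar = "phase", direction = "wide")
  ycols <- paste0("value.", phases)
  complete <- stats::complete.cases(wide[, ycols])
  if (any(!complete)) {
    warning(sum(!complete), " animal(s) dropped listwise (incomplete phases)")
    wide <- wide[complete, , drop = FALSE]
  }
  if (any(table(wide$group) < 2L))
    stop("need at least two complete animals per group")
  Y <- as.matrix(wide[, ycols])
  g <- factor(wide$group)
  # sum-to-zero contrasts: required for meaningful Type-III within effects
  mod <- stats::lm(Y ~ g, contrasts = list(g = "contr.sum"))
  idata <- data.frame(phase = factor(phases, levels = phases))
  A <- car::Anova(mod, idata = idata, idesign = ~phase, type = 3)
  s <- suppressWarnings(summary(A, multivariate = FALSE))
  tab <- s$univariate.tests

  pick <- function(row_name, effect, within) {
    r <- tab[row_name, ]
    eps <- NA_real_; p_gg <- NA_real_; mau <- NA_real_
    if (within) {
      if (k == 2L) {
        eps <- 1; p_gg <- r[["Pr(>F)"]]; mau <- NA_real_
      } else {
        adj <- s$pval.adjustments
        sph <- s$sphericity.tests
        eps <- adj[row_name, "GG eps"]
        p_gg <- adj[row_name, "Pr(>F[GG])"]
        mau <- sph[row_name, "p-value"]
      }
    }
    applied <- within && switch(gg, always = TRUE, never = FALSE,
                                auto = !is.na(mau) && mau < 0.05)
    anova_result(effect, F = r[["F value"]],
                 df1 = r[["num Df"]], df2 = r[["den Df"]],
                 p = r[["Pr(>F)"]],
                 ms_effect = r[["Sum Sq"]] / r[["num Df"]],
                 ms_error = r[["Error SS"]] / r[["den Df"]],
                 eps = eps, p_gg = p_gg, mauchly_p = mau,
                 gg_applied = applied)
  }
  list(group = pick("g", "group", within = FALSE),
       phase = pick("phase", "phase", within = TRUE),
       group_by_phase = pick("g:phase", "group_by_phase", within = TRUE))
}

#' Fisher's LSD post hoc test
#'
#' Unadjusted pairwise comparisons reusing the one-way ANOVA pooled error
#' mean square: \eqn{t = (m_i - m_j) / \sqrt{MSE (1/n_i + 1/n_j)}} on the
#' ANOVA error degrees of freedom, two-sided p, no multiplicity adjustment
#' (that is what LSD is; multiplicity is uncontrolled by design).
#'
#' @param value,group As in \code{\link{one_way_anova}}.
#' @param anova Optional precomputed \code{\link{one_way_anova}} result on
#'   the same data.
#' @return data.frame with one row per unordered pair: \code{group1},
#'   \code{group2}, \code{diff} (mean1 - mean2), \code{t}, \code{df},
#'   \code{p}.
#' @export
fisher_lsd <- function(value, group, anova = one_way_anova(value, group)) {
  if (anova$degenerate && anova$ms_error == 0)
    stop("degenerate ANOVA (zero error mean square): LSD undefined")
  ok <- !is.na(value) & !is.na(group)
  value <- value[ok]; group <- as.character(group[ok])
  means <- tapply(value, group, mean)
  ns <- tapply(value, group, length)
  gs <- names(means)
  pairs <- utils::combn(gs, 2L)
  mse <- anova$ms_error; df <- anova$df2
  rows <- apply(pairs, 2L, function(pr) {
    d <- means[[pr[1L]]] - means[[pr[2L]]]
    se <- sqrt(mse * (1 / ns[[pr[1L]]] + 1 / ns[[pr[2L]]]))
    t <- d / se
    data.frame(group1 = pr[1L], group2 = pr[2L], diff = d, t = t, df = df,
               p = 2 * stats::pt(-abs(t), df), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Unpaired two-tailed t-test (pooled variance)
#'
#' Student's pooled-variance form by default (\code{welch = FALSE}); Welch's
#' unequal-variance form is available behind the flag.
#'
#' @param a,b Numeric samples, each with at least two values.
#' @param welch Use Welch's correction instead of pooling.
#' @return List with \code{t}, \code{df}, \code{p}, \code{mean_a},
#'   \code{mean_b} and \code{degenerate} (TRUE when the pooled variance is
#'   zero, in which case the statistic is undefined).
#' @export
unpaired_t <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least two values")
  if (!welch && stats::var(a) == 0 && stats::var(b) == 0) {
    return(list(t = NA_real_, df = length(a) + length(b) - 2L, p = NA_real_,
                mean_a = mean(a), mean_b = mean(b), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       degenerate = FALSE)
}

#' Mean +/- 2 SD outlier exclusion
#'
#' Single-pass rule used before group summaries of in vitro measurements:
#' values beyond two standard deviations from the sample mean (both computed
#' once from all values) are excluded. The rule is not iterated; with zero
#' spread nothing is excluded.
#'
#' @param values Numeric vector of at least three values.
#' @return List with \code{retained}, \code{excluded} and the \code{mean},
#'   \code{sd} and \code{bounds} used.
#' @examples
#' exclude_outliers(c(0, 0, 0, 0, 0, 100))$excluded  # 100
#' @export
exclude_outliers <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3L) stop("need at least three values")
  m <- mean(x); s <- stats::sd(x)
  out <- if (s == 0) rep(FALSE, length(x)) else abs(x - m) > 2 * s
  list(retained = x[!out], excluded = x[out], mean = m, sd = s,
       bounds = c(m - 2 * s, m + 2 * s))
}
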