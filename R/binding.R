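#' Specific binding from total and nonspecific measurements
#'
#' Replicates are averaged within each ligand concentration, then specific
#' binding = mean total - mean nonspecific. Negative specific values are
#' retained in \code{specific} but floored at zero in \code{specific_floored}
#' and flagged, so no information is silently discarded.
#'
#' @param dataset data.frame with columns \code{conc_nM}, \code{total},
#'   \code{nonspecific} (and optionally \code{replicate}), e.g. from
#'   \code{\link{generate_saturation_dataset}}.
#' @return data.frame with one row per concentration: \code{conc_nM},
#'   \code{total}, \code{nonspecific}, \code{specific},
#'   \code{specific_floored}, \code{negative_flag}.
#' @export
specific_binding <- function(dataset) {
  stopifnot(all(c("conc_nM", "total", "nonspecific") %in% names(dataset)))
  if (anyNA(dataset$nonspecific)) {
    L <- unique(dataset$conc_nM[is.na(dataset$nonspecific)])
    stop("missing nonspecific binding at concentration(s) ",
         paste(signif(L, 4), collapse = ", "), " nM")
  }
  tot <- tapply(dataset$total, dataset$conc_nM, mean)
  ns <- tapply(dataset$nonspecific, dataset$conc_nM, mean)
  L <- as.numeric(names(tot))
  o <- order(L)
  spec <- (tot - ns)[o]
  data.frame(conc_nM = L[o], total = as.numeric(tot[o]),
             nonspecific = as.numeric(ns[o]), specific = as.numeric(spec),
             specific_floored = pmax(as.numeric(spec), 0),
             negative_flag = as.numeric(spec) < 0)
}

#' Fit the one-site specific-binding model
#'
#' Nonlinear least-squares fit of the single-class receptor occupancy model
#' \deqn{B(L) = B_{max} \, L / (K_d + L)}
#' to specific binding versus free ligand concentration, the standard
#' saturation-analysis model for radioligand assays. Fitting is unweighted
#' Levenberg-Marquardt least squares with a deterministic start heuristic
#' (\eqn{B_{max,0}} = 1.2 x the largest specific value; \eqn{K_{d,0}} = the
#' concentration at half of \eqn{B_{max,0}}, linearly interpolated), so the
#' fit involves no randomness. Standard errors come from the estimate
#' covariance; for a noise-free curve they are zero and the generating
#' parameters are recovered exactly.
#'
#' @param conc_nM Free ligand concentrations (nM), at least three distinct,
#'   or a data.frame from \code{\link{specific_binding}} (columns
#'   \code{conc_nM} and \code{specific}).
#' @param specific Specific binding (fmol/mg protein); ignored when
#'   \code{conc_nM} is a data.frame.
#' @return Object of class \code{"one_site_fit"} with \code{coef}-,
#'   \code{predict}-, \code{plot}-, \code{summary}-, \code{fitted}- and
#'   \code{residuals}-methods. Fields: \code{bmax}, \code{kd}, \code{se}
#'   (named vector), \code{rss}, \code{converged},
#'   \code{poorly_constrained} (Kd more than 3x the largest tested
#'   concentration), \code{data}, \code{fit} (the underlying \code{nls}
#'   object, NULL on failure).
#' @examples
#' L <- exp(seq(log(0.09), log(4.95), length.out = 12))
#' fit <- fit_one_site(L, 100 * L / (1 + L))
#' coef(fit)  # bmax 100, kd 1
#' @export
fit_one_site <- function(conc_nM, specific = NULL) {
  if (is.data.frame(conc_nM)) {
    specific <- conc_nM$specific
    conc_nM <- conc_nM$conc_nM
  }
  stopifnot(length(conc_nM) == length(specific))
  ok <- !is.na(conc_nM) & !is.na(specific)
  L <- conc_nM[ok]; B <- specific[ok]
  if (length(unique(L)) < 3L)
    stop("need at least three distinct concentrations")
  if (max(B) <= 0)
    stop("no positive specific binding at the top of the curve")

  o <- order(L)
  bmax0 <- 1.2 * max(B)
  half <- bmax0 / 2
  kd0 <- tryCatch(stats::approx(B[o], L[o], xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (is.na(kd0) || kd0 <= 0) kd0 <- stats::median(L)

  d <- data.frame(L = L, B = B)
  fit <- tryCatch(
    minpack.lm::nlsLM(B ~ bmax * L / (kd + L), data = d,
                      start = list(bmax = bmax0, kd = kd0),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(bmax = NA_real_, kd = NA_real_,
                se = c(bmax = NA_real_, kd = NA_real_), rss = NA_real_,
                converged = FALSE, poorly_constrained = NA,
                diagnostics = conditionMessage(fit), data = d, fit = NULL)
    class(out) <- "one_site_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  out <- list(bmax = unname(cf[["bmax"]]), kd = unname(cf[["kd"]]),
              se = c(bmax = unname(se[["bmax"]]), kd = unname(se[["kd"]])),
              rss = sum(stats::residuals(fit)^2),
              converged = TRUE,
              poorly_constrained = unname(cf[["kd"]]) > 3 * max(L),
              diagnostics = NULL, data = d, fit = fit)
  class(out) <- "one_site_fit"
  out
}

#' @export
print.one_site_fit <- function(x, digits = 4, ...) {
  cat("One-site specific binding fit: B(L) = Bmax * L / (Kd + L)\n")
  if (!x$converged) {
    cat("  did not converge:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("  Bmax = %s +/- %s fmol/mg protein\n",
              signif(x$bmax, digits), signif(x$se[["bmax"]], digits)))
  cat(sprintf("  Kd   = %s +/- %s nM\n",
              signif(x$kd, digits), signif(x$se[["kd"]], digits)))
  cat(sprintf("  RSS = %s on %d points\n", signif(x$rss, digits),
              nrow(x$data)))
  if (isTRUE(x$poorly_constrained))
    cat("  warning: Kd far above the largest tested concentration;",
        "poorly constrained\n")
  invisible(x)
}

#' @export
summary.one_site_fit <- function(object, ...) {
  print(object, ...)
  if (object$converged) print(summary(object$fit))
  invisible(object)
}

#' @export
coef.one_site_fit <- function(object, ...) {
  c(bmax = object$bmax, kd = object$kd)
}

#' @export
fitted.one_site_fit <- function(object, ...) {
  object$bmax * object$data$L / (object$kd + object$data$L)
}

#' @export
residuals.one_site_fit <- function(object, ...) {
  object$data$B - fitted(object)
}

#' @rdname fit_one_site
#' @param object A \code{"one_site_fit"}.
#' @param newdata Optional data.frame with column \code{L} (or
#'   \code{conc_nM}) of concentrations to predict at.
#' @param ... Unused.
#' @export
predict.one_site_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$data$L else
    if (is.data.frame(newdata)) {
      if ("L" %in% names(newdata)) newdata$L else newdata$conc_nM
    } else as.numeric(newdata)
  object$bmax * L / (object$kd + L)
}

#' @export
plot.one_site_fit <- function(x, ...) {
  graphics::plot(x$data$L, x$data$B, xlab = "free ligand (nM)",
                 ylab = "specific binding (fmol/mg protein)",
                 main = "One-site saturation binding", ...)
  Lg <- seq(0, max(x$data$L) * 1.05, length.out = 200)
  graphics::lines(Lg, x$bmax * Lg / (x$kd + Lg))
  graphics::abline(h = x$bmax, lty = 3)
  invisible(x)
}

#' Convert counted radioactivity to bound ligand per mg protein
#'
#' 1 Ci = 2.22e12 dpm, so a ligand of molar specific activity SA (Ci/mmol)
#' emits 2.22 x SA dpm per fmol. Counting efficiency divides the counts
#' first: fmol/mg = dpm / efficiency / (2.22 x SA) / protein.
#'
#' @param dpm Disintegrations (counts) per minute, corrected or raw.
#' @param specific_activity Molar specific activity (Ci/mmol); the assay
#'   ligand's is 80.2.
#' @param efficiency Counting efficiency in (0, 1].
#' @param protein_mg Protein in the assay (mg), > 0.
#' @return Bound ligand (fmol per mg protein).
#' @examples
#' dpm_to_fmol(2.22 * 80.2, specific_activity = 80.2, protein_mg = 1)  # 1
#' @export
dpm_to_fmol <- function(dpm, specific_activity = 80.2, efficiency = 1,
                        protein_mg = 1) {
  if (any(c(specific_activity, protein_mg) <= 0))
    stop("'specific_activity' and 'protein_mg' must be > 0")
  if (efficiency <= 0 || efficiency > 1)
    stop("'efficiency' must be in (0, 1]")
  dpm / efficiency / (2.22 * specific_activity) / protein_mg
}

#' Compare fitted binding parameters between groups
#'
#' Independent assay repeats are the experimental units: each repeat is
#' fitted separately and the per-group sets of fitted Bmax and Kd are
#' compared pairwise with the unpaired two-tailed pooled t-test.
#'
#' @param fits Named list (one element per group) of lists of
#'   \code{\link{fit_one_site}} results, or a data.frame with columns
#'   \code{group}, \code{bmax}, \code{kd}.
#' @return data.frame with one row per (pair, parameter): \code{group1},
#'   \code{group2}, \code{parameter}, \code{mean1}, \code{mean2}, \code{t},
#'   \code{df}, \code{p}.
#' @export
compare_binding <- function(fits) {
  d <- if (is.data.frame(fits)) fits else {
    do.call(rbind, lapply(names(fits), function(g) {
      data.frame(group = g,
                 bmax = vapply(fits[[g]], function(f) f$bmax, 0),
                 kd = vapply(fits[[g]], function(f) f$kd, 0),
                 stringsAsFactors = FALSE)
    }))
  }
  if (any(table(d$group) < 2L))
    stop("need at least two replicate fits per group")
  gs <- unique(d$group)
  pairs <- utils::combn(gs, 2L)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    for (par in c("bmax", "kd")) {
      a <- d[[par]][d$group == pairs[1L, j]]
      b <- d[[par]][d$group == pairs[2L, j]]
      tt <- unpaired_t(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = pairs[1L, j], group2 = pairs[2L, j], parameter = par,
        mean1 = tt$mean_a, mean2 = tt$mean_b, t = tt$t, df = tt$df,
        p = tt$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
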